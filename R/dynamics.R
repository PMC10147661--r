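# Assembly and integration of the mechanistic ODE model for a circuit
# genotype. Species per present edge: free sgRNA, dCas:sgRNA, and the
# DNA-bound ternary complex on the target promoter; per node: mRNA,
# immature protein (PI) and mature reporter (P). Free dCas and free promoter
# DNA are eliminated algebraically from their conservation relations. The
# right-hand side is compiled C (src/grn_rhs.c) driven through deSolve.

#' Hill drive for arabinose-inducible production
#'
#' `Ara^n / (Ara^n + K_m^n) * k2 * DNA_avail * (1 - b)`: the production rate
#' of an arabinose-induced transcript from available promoter DNA, with leak
#' fraction `b` removed from the inducible part.
#'
#' @param ara Arabinose concentration (% w/v), `>= 0`.
#' @param n Hill coefficient.
#' @param K_m Half-saturation constant (% w/v).
#' @param k2 Production rate constant (min^-1).
#' @param DNA_avail Available promoter DNA (nM).
#' @param b Leak fraction in `[0, 1)`.
#' @return Production rate (nM min^-1), vectorised over `ara`.
#' @export
hill_induction <- function(ara, n, K_m, k2, DNA_avail, b = 0) {
  if (any(ara < 0)) stop("arabinose concentration must be non-negative")
  frac <- ifelse(ara == 0, 0, ara^n / (ara^n + K_m^n))
  frac * k2 * DNA_avail * (1 - b)
}

#' Assemble the ODE model for a genotype
#'
#' Wires the reaction template to the genotype: every present edge
#' contributes an sgRNA produced from its source node (arabinose Hill drive
#' for node A per the inducible law; constitutive production scaled by the
#' source promoter's efficiency for B and C) that sequesters dCas and binds
#' the target promoter; each node carries mRNA/PI/P states. The model also
#' fixes the simulation context: growth model, reversibility of the
#' DNA-bound complex, and the algebraic-form switches.
#'
#' @param g Genotype (object or encoding) or a circuit from
#'   [two_node_circuit()].
#' @param theta A [parameter_set()] covering every part in `g`.
#' @param parts The parts library.
#' @param growth A [growth_model()]; default microplate growth.
#' @param irreversible If `TRUE`, sets `kr_dsd = 0` (microfluidic /
#'   oscillation context).
#' @param literal_hill_dna If `TRUE`, the Hill drive uses total promoter DNA
#'   as printed in the source equations; default `FALSE` uses free DNA so
#'   that repression of node A is effective.
#' @param literal_pi If `TRUE`, the immature-protein balance removes
#'   maturation flux proportional to the mature species (the literal printed
#'   form); default `FALSE` uses the mass-balanced form.
#' @return An object of class `grn_model`.
#' @export
build_model <- function(g, theta = default_parameters(parts),
                        parts = parts_library(),
                        growth = growth_model(),
                        irreversible = FALSE,
                        literal_hill_dna = FALSE,
                        literal_pi = FALSE) {
  g <- as_genotype(g, parts)
  slots <- which(g$edges > 0L)
  E <- length(slots)
  edges <- tibble::tibble(
    slot = slots,
    src = EDGE_SRC[slots],
    tgt = EDGE_TGT[slots],
    sgrna = parts$sgrna_ids[g$edges[slots]]
  )
  miss <- setdiff(edges$sgrna, theta$sgrna$id)
  if (length(miss)) {
    stop("parameter set lacks sgRNA entries for: ", paste(miss, collapse = ", "))
  }
  key <- as.character(max(E, 1L))
  if (is.na(theta$d_rna[key])) stop("d_rna table lacks an entry for E = ", key)
  if (is.na(theta$dcas_total[key])) stop("dcas_total table lacks an entry for E = ", key)

  nodes <- c("A", "B", "C")
  state_names <- c(
    if (E > 0) paste0("sg.", edges$slot),
    if (E > 0) paste0("ds.", edges$slot),
    if (E > 0) paste0("tern.", edges$slot),
    paste0("mRNA.", nodes), paste0("PI.", nodes), paste0("P.", nodes)
  )
  structure(
    list(
      genotype = g, parts = parts, theta = theta, edges = edges, E = E,
      state_names = state_names, n_states = 3L * E + 9L,
      growth = growth, irreversible = irreversible,
      literal_hill_dna = literal_hill_dna, literal_pi = literal_pi
    ),
    class = "grn_model"
  )
}

#' @export
print.grn_model <- function(x, ...) {
  cat("<grn_model> ", encode_genotype(x$genotype, x$parts),
      ": ", x$E, " edges, ", x$n_states, " states, growth mode ",
      x$growth$mode, if (x$irreversible) ", irreversible DNA binding", "\n", sep = "")
  invisible(x)
}

#' Two-node calibration circuit
#'
#' The calibration experiments use two-node circuits: the arabinose-induced
#' orange node expresses one sgRNA repressing the constitutive blue node
#' (slot `A->B`). These circuits live outside the 3-6-edge genotype space
#' but use the identical reaction template (`E = 1`).
#'
#' @param sgrna sgRNA identifier or index for the `A->B` edge.
#' @param promoter_B Promoter token for the blue node.
#' @param parts The parts library.
#' @return A circuit object usable by [build_model()].
#' @export
two_node_circuit <- function(sgrna, promoter_B = "PH", parts = parts_library()) {
  idx <- if (is.numeric(sgrna)) as.integer(sgrna) else match(sgrna, parts$sgrna_ids)
  if (is.na(idx) || idx < 1 || idx > parts$s) stop("unknown sgRNA '", sgrna, "'")
  structure(
    list(edges = c(idx, integer(5)),
         prom = c(resolve_promoter(promoter_B, parts), resolve_promoter("ZERO", parts))),
    class = "grn_genotype"
  )
}

# Pack the model + context into the flat parameter vector read by the C
# right-hand side. Layout documented in src/grn_rhs.c.
pack_parms <- function(model, ara, growth = model$growth) {
  th <- model$theta
  E <- model$E
  key <- as.character(max(E, 1L))
  p <- numeric(81)
  p[1] <- E
  p[2] <- ara
  p[3] <- if (growth$mode == "constant") 1 else 0
  p[4] <- growth$m_const
  p[5] <- if (model$irreversible) 0 else th$shared$kr_dsd
  p[6] <- th$shared$kf_ds
  p[7] <- th$shared$kr_ds
  p[8] <- unname(th$d_rna[key])
  p[9] <- unname(th$dcas_total[key])
  p[10] <- th$shared$n_hill
  p[11] <- th$shared$K_m
  p[12] <- th$shared$k2
  p[13] <- as.numeric(model$literal_hill_dna)
  p[14] <- as.numeric(model$literal_pi)
  p[15] <- growth$p1
  p[16:18] <- growth$p2
  p[19:21] <- growth$p3
  p[22:24] <- growth$p4
  p[25:27] <- growth$p5
  p[28] <- th$ara_translation$base
  p[29] <- th$ara_translation$h
  p[30] <- th$ara_translation$K_t
  eff <- c(1, unname(model$parts$promoters[model$genotype$prom]))
  for (j in 1:3) {
    off <- 30 + 7 * (j - 1)
    nd <- th$nodes[j, ]
    p[off + 1] <- nd$dna_total
    p[off + 2] <- nd$b
    p[off + 3] <- if (is.na(nd$k_mrna)) 0 else nd$k_mrna
    p[off + 4] <- eff[j]
    p[off + 5] <- nd$k_pi
    p[off + 6] <- nd$m_pi
    p[off + 7] <- nd$d_pi
  }
  if (E > 0) {
    for (e in seq_len(E)) {
      off <- 51 + 5 * (e - 1)
      i <- match(model$edges$sgrna[e], th$sgrna$id)
      p[off + 1] <- model$edges$src[e]
      p[off + 2] <- model$edges$tgt[e]
      p[off + 3] <- th$sgrna$b[i]
      p[off + 4] <- th$sgrna$k_sg[i]
      p[off + 5] <- th$sgrna$kf_dsd[i]
    }
  }
  p
}

ode_run <- function(model, init, t_grid, ara, growth,
                    rtol = 1e-6, atol = 1e-9) {
  parms <- pack_parms(model, ara, growth)
  out <- deSolve::ode(
    y = init, times = t_grid, parms = parms,
    func = "grnmap_derivs", initfunc = "grnmap_initmod",
    dllname = "grnmap", nout = 6,
    outnames = c("G", "m", "dCas_free", "DNA_free.A", "DNA_free.B", "DNA_free.C"),
    rtol = rtol, atol = atol, method = "lsoda"
  )
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed for genotype ",
         encode_genotype(model$genotype, model$parts),
         " at arabinose ", ara, " (istate ", attr(out, "istate")[1], ")")
  }
  colnames(out) <- c("time", model$state_names,
                     c("G", "m", "dCas_free", "DNA_free.A", "DNA_free.B", "DNA_free.C"))
  out
}

#' Preculture initial conditions
#'
#' Integrates the model from the zero state at arabinose 0 under the
#' preculture growth model (LB, default six hours) and returns the terminal
#' state, used as the initial condition of the main run.
#'
#' @param model A [build_model()] result.
#' @param duration Preculture duration (min).
#' @param growth Growth model for the preculture.
#' @return Named numeric state vector.
#' @export
preculture_state <- function(model, duration = 360, growth = preculture_growth()) {
  init <- stats::setNames(numeric(model$n_states), model$state_names)
  out <- ode_run(model, init, c(0, duration), ara = 0, growth = growth)
  st <- out[nrow(out), model$state_names]
  pmax(st, 0)
}

#' Simulate a circuit trajectory
#'
#' Stiff integration (lsoda, rtol 1e-6 / atol 1e-9 nM) from the preculture
#' state. Reporter fluorescence is the per-reporter scaling factor times the
#' mature protein concentration.
#'
#' @param model A [build_model()] result.
#' @param ara Arabinose dose (% w/v).
#' @param t_grid Ascending time grid (min).
#' @param init Initial state; default computes [preculture_state()].
#' @param rtol,atol Solver tolerances.
#' @return A `grn_trajectory`: the deSolve matrix with attributes; use
#'   [trajectory_tbl()] for a tidy view.
#' @export
simulate_grn <- function(model, ara, t_grid = seq(0, 960, by = 10),
                         init = NULL, rtol = 1e-6, atol = 1e-9) {
  if (ara < 0) stop("arabinose concentration must be non-negative")
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be strictly increasing")
  if (is.null(init)) init <- preculture_state(model)
  out <- ode_run(model, init, t_grid, ara, model$growth, rtol = rtol, atol = atol)
  structure(out, class = c("grn_trajectory", class(out)),
            model = model, ara = ara)
}

#' Tidy view of a trajectory
#'
#' @param traj A `grn_trajectory`.
#' @return Long tibble with columns `time`, `species`, `value`, plus
#'   `ara` and `genotype`; reporter fluorescence rows are named
#'   `fluo.<reporter>`.
#' @export
trajectory_tbl <- function(traj) {
  model <- attr(traj, "model")
  m <- as.data.frame(unclass(traj))
  fl <- reporter_fluorescence(traj)
  m <- cbind(m, fl)
  tb <- tidyr::pivot_longer(tibble::as_tibble(m), -"time",
                            names_to = "species", values_to = "value")
  tb$ara <- attr(traj, "ara")
  tb$genotype <- encode_genotype(model$genotype, model$parts)
  tb
}

# scaled mature protein per reporter, matrix n_times x 3 named fluo.<reporter>
reporter_fluorescence <- function(traj) {
  model <- attr(traj, "model")
  sc <- model$theta$scaling[model$theta$nodes$reporter]
  P <- unclass(traj)[, paste0("P.", model$theta$nodes$node), drop = FALSE]
  fl <- sweep(P, 2, unname(sc), `*`)
  colnames(fl) <- paste0("fluo.", model$theta$nodes$reporter)
  fl
}

#' Dose response across an arabinose gradient
#'
#' Runs one simulation per dose from a shared preculture state and reads the
#' reporters at `t_read` (default 900 min).
#'
#' @param g Genotype (object or encoding).
#' @param theta Parameter set.
#' @param ara_levels Ascending arabinose doses; at least 5 (default
#'   [default_doses()], 9 levels).
#' @param t_read Read time (min).
#' @param parts,growth,... Passed to [build_model()].
#' @return A tibble of class `grn_dose_response` with columns `genotype`,
#'   `ara`, `node`, `reporter`, `value` (scaled fluorescence, `>= 0`).
#' @export
dose_response <- function(g, theta = default_parameters(parts),
                          ara_levels = default_doses(), t_read = 900,
                          parts = parts_library(), growth = growth_model(), ...) {
  if (length(ara_levels) < 5) stop("need at least 5 dose levels")
  if (is.unsorted(ara_levels, strictly = TRUE)) stop("ara_levels must be ascending")
  model <- build_model(g, theta, parts, growth = growth, ...)
  init <- preculture_state(model)
  tgrid <- c(0, t_read)
  rows <- lapply(ara_levels, function(a) {
    out <- ode_run(model, init, tgrid, a, growth)
    P <- out[nrow(out), paste0("P.", theta$nodes$node)]
    tibble::tibble(
      genotype = encode_genotype(model$genotype, parts),
      ara = a,
      node = theta$nodes$node,
      reporter = theta$nodes$reporter,
      value = pmax(unname(P) * unname(theta$scaling[theta$nodes$reporter]), 0)
    )
  })
  dr <- dplyr::bind_rows(rows)
  class(dr) <- c("grn_dose_response", class(dr))
  attr(dr, "t_read") <- t_read
  dr
}

#' Default arabinose dose grid
#'
#' Zero plus eight log-spaced doses from 1e-5 to 0.2 % w/v, the nine-level
#' gradient used throughout.
#'
#' @return Ascending numeric vector of length 9.
#' @export
default_doses <- function() {
  c(0, 10^seq(log10(1e-5), log10(2e-1), length.out = 8))
}

#' Conservation residuals along a trajectory
#'
#' Checks the dCas and promoter-DNA conservation relations: free dCas plus
#' all complexes must equal total dCas, and bound plus free promoter DNA must
#' equal the total, at every output time.
#'
#' @param traj A `grn_trajectory`.
#' @return Tibble with columns `quantity`, `max_rel_error`.
#' @export
conservation_residuals <- function(traj) {
  model <- attr(traj, "model")
  m <- unclass(traj)
  E <- model$E
  th <- model$theta
  key <- as.character(max(E, 1L))
  dcas_tot <- unname(th$dcas_total[key])
  ds <- if (E > 0) m[, paste0("ds.", model$edges$slot), drop = FALSE] else 0
  tern <- if (E > 0) m[, paste0("tern.", model$edges$slot), drop = FALSE] else 0
  dcas_sum <- m[, "dCas_free"] +
    (if (E > 0) rowSums(ds) + rowSums(tern) else 0)
  res <- tibble::tibble(
    quantity = "dCas_total",
    max_rel_error = max(abs(dcas_sum - dcas_tot)) / dcas_tot
  )
  for (j in 1:3) {
    node <- c("A", "B", "C")[j]
    bound <- if (E > 0 && any(model$edges$tgt == j)) {
      rowSums(m[, paste0("tern.", model$edges$slot[model$edges$tgt == j]), drop = FALSE])
    } else 0
    tot <- th$nodes$dna_total[j]
    res <- dplyr::bind_rows(res, tibble::tibble(
      quantity = paste0("DNA_total.", node),
      max_rel_error = max(abs(m[, paste0("DNA_free.", node)] + bound - tot)) / tot
    ))
  }
  res
}
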