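# Shared kinetic parameter set for the CRISPRi circuit ensemble.
#
# Parameters map 1:1 to biological components: one entry per sgRNA, per
# reporter node, and one shared value for everything the parts have in
# common (dCas binding, RNA turnover keyed by the total number of
# repressions, Hill induction by arabinose). A single set drives every model
# in the ensemble, which is what makes forward prediction over the whole
# genotype space meaningful.

#' Construct a parameter set
#'
#' Units: concentrations nM, time min, arabinose % w/v. `sgrna` holds one row
#' per sgRNA with its leak fraction `b` (dimensionless, also the additive
#' leak via `b * k2 * DNA_total`), constitutive production rate `k_sg`
#' (min^-1 per nM promoter DNA) and the dCas:sgRNA-to-DNA binding rate
#' `kf_dsd` (nM^-1 min^-1); together with the shared unbinding rate `kr_dsd`
#' this sets the repression strength (dissociation constant
#' `kr_dsd / kf_dsd`). `d_rna` and `dcas_total` are keyed by the total number
#' of repressions E of a circuit (models with more sgRNA genes differ in RNA
#' turnover and available dCas). `nodes` holds the reporter-specific
#' transcription/translation/maturation/degradation constants; node A
#' (orange, mKO2) is arabinose-induced, nodes B (blue, mKate2) and C (green,
#' sfGFP) are constitutive.
#'
#' @param sgrna Data frame with columns `id`, `b`, `k_sg`, `kf_dsd`.
#' @param shared Named list: `kr_dsd`, `kf_ds`, `kr_ds`, `n_hill`, `K_m`, `k2`.
#' @param d_rna,dcas_total Numeric vectors named `"1"`..`"6"` (keyed by E).
#' @param nodes Data frame with columns `node` (`A`,`B`,`C`), `reporter`,
#'   `dna_total`, `b`, `k_mrna`, `k_pi`, `m_pi`, `d_pi`.
#' @param ara_translation Named list `base`, `h`, `K_t`: phenomenological
#'   arabinose dependence of node A's translation constant,
#'   `k_pi_A * (base + (1-base) * Ara^h / (Ara^h + K_t^h))`.
#' @param scaling Named numeric: fluorescence per nM mature protein, one
#'   factor per reporter.
#' @param od_cells Cells per OD600 unit.
#' @return An object of class `grn_parameters`.
#' @seealso [default_parameters()], [write_parameters()], [read_parameters()]
#' @export
parameter_set <- function(sgrna, shared, d_rna, dcas_total, nodes,
                          ara_translation, scaling, od_cells = 8e8) {
  sgrna <- tibble::as_tibble(sgrna)
  nodes <- tibble::as_tibble(nodes)
  stopifnot(
    all(c("id", "b", "k_sg", "kf_dsd") %in% names(sgrna)),
    all(c("node", "reporter", "dna_total", "b", "k_mrna", "k_pi", "m_pi", "d_pi") %in% names(nodes)),
    identical(nodes$node, c("A", "B", "C")),
    all(unlist(shared[c("kr_dsd", "kf_ds", "kr_ds", "n_hill", "K_m", "k2")]) >= 0),
    all(sgrna$kf_dsd >= 0), all(sgrna$k_sg >= 0),
    all(d_rna > 0), all(dcas_total >= 0)
  )
  structure(
    list(
      sgrna = sgrna, shared = shared,
      d_rna = d_rna, dcas_total = dcas_total,
      nodes = nodes, ara_translation = ara_translation,
      scaling = scaling, od_cells = od_cells
    ),
    class = "grn_parameters"
  )
}

#' @export
print.grn_parameters <- function(x, ...) {
  cat("<grn_parameters> ", nrow(x$sgrna), " sgRNAs, E keys ",
      paste(names(x$d_rna), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Default (synthetic, literature-scale) parameter set
#'
#' A plausible mechanistic parameterisation of the six experimental sgRNAs
#' and three reporters, on the scales reported for CRISPRi kinetics in E.
#' coli: minutes-scale RNA turnover, nM-scale dCas/sgRNA/DNA affinities with
#' truncated (t4) sgRNAs several-fold weaker than their full-length parents,
#' slow fluorophore maturation for the red/orange reporters and fast for
#' sfGFP. These defaults are a synthetic stand-in for a fitted parameter
#' vector: the values are the package's own choices, fixed once, not
#' measurements.
#'
#' @param parts The parts library the set should cover.
#' @return A `grn_parameters` object covering every part in `parts`.
#' @export
default_parameters <- function(parts = parts_library()) {
  kd <- attr(parts, "kd_nM")
  kr_dsd <- 0.01
  if (is.null(kd)) {
    # experimentally characterised parts: full-length strong, t4 weaker
    kd <- c(sg1 = 0.8, sg1t4 = 5, sg2 = 1.2, sg3 = 2, sg4 = 1, sg4t4 = 6)
    kd <- kd[parts$sgrna_ids]
    if (anyNA(kd)) kd[is.na(kd)] <- 2
  }
  sgrna <- tibble::tibble(
    id = parts$sgrna_ids,
    b = 0.02,
    k_sg = 0.3,
    kf_dsd = kr_dsd / as.numeric(kd)
  )
  nodes <- tibble::tibble(
    node = c("A", "B", "C"),
    reporter = c("mKO2", "mKate2", "sfGFP"),
    dna_total = 30,
    b = c(0.02, 0, 0),
    k_mrna = c(NA_real_, 0.6, 0.6), # A transcribes via the Hill drive (k2)
    k_pi = c(2, 2, 2),
    m_pi = c(0.023, 0.035, 0.1),
    d_pi = c(0.025, 0.025, 0.025)
  )
  parameter_set(
    sgrna = sgrna,
    shared = list(kr_dsd = kr_dsd, kf_ds = 0.02, kr_ds = 0.2,
                  n_hill = 1.5, K_m = 0.01, k2 = 0.25),
    d_rna = c(`1` = 0.25, `2` = 0.23, `3` = 0.21, `4` = 0.20, `5` = 0.19, `6` = 0.18),
    dcas_total = c(`1` = 150, `2` = 180, `3` = 210, `4` = 240, `5` = 270, `6` = 300),
    nodes = nodes,
    ara_translation = list(base = 0.2, h = 2, K_t = 0.01),
    scaling = c(mKO2 = 20, mKate2 = 10, sfGFP = 50),
    od_cells = 8e8
  )
}

#' Growth model: superposition of three generalized logistic functions
#'
#' `G(t) = p1 + sum_k p2[k] / (1 + p3[k] * exp(-t * p4[k]))^(1/p5[k])`, with
#' the dilution rate `m(t) = G'(t)/G(t)` (the specific growth rate) computed
#' from the analytic derivative. In `constant` mode (continuous culture in a
#' microfluidic device) `m` is a fixed value, 1e-3 min^-1 by default.
#'
#' @param p1 Baseline OD.
#' @param p2,p3,p4,p5 Numeric length-3: amplitude, shift, rate and shape of
#'   each logistic term; `p5` must be nonzero.
#' @param mode `"microplate"` (OD curve) or `"constant"` (fixed dilution).
#' @param m_const Dilution rate used in constant mode (min^-1).
#' @return An object of class `grn_growth`.
#' @export
growth_model <- function(p1 = 0.05,
                         p2 = c(1.2, 0.3, 0),
                         p3 = c(50, 2000, 1),
                         p4 = c(0.015, 0.010, 0.010),
                         p5 = c(1, 1, 1),
                         mode = c("microplate", "constant"),
                         m_const = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(length(p2) == 3, length(p3) == 3, length(p4) == 3, length(p5) == 3,
            all(p5 != 0))
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5,
                 mode = mode, m_const = m_const),
            class = "grn_growth")
}

#' Constant-dilution growth model (microfluidic conditions)
#' @param m_const Dilution rate (min^-1).
#' @return A `grn_growth` in constant mode.
#' @export
constant_growth <- function(m_const = 1e-3) {
  growth_model(mode = "constant", m_const = m_const)
}

#' Default preculture growth model (LB, single logistic)
#' @return A `grn_growth`.
#' @export
preculture_growth <- function() {
  growth_model(p1 = 0.05, p2 = c(0.9, 0, 0), p3 = c(30, 1, 1),
               p4 = c(0.02, 0.01, 0.01), p5 = c(1, 1, 1))
}

#' Evaluate a growth model and its dilution rate
#'
#' @param gm A [growth_model()].
#' @param t Time (min), vectorised.
#' @return A tibble with columns `time`, `G`, `m` where `m = G'(t)/G(t)`
#'   (analytic derivative); in constant mode `G = 1` and `m = m_const`.
#' @export
growth_and_dilution <- function(gm, t) {
  stopifnot(inherits(gm, "grn_growth"), all(t >= 0))
  if (gm$mode == "constant") {
    return(tibble::tibble(time = t, G = 1, m = gm$m_const))
  }
  G <- rep(gm$p1, length(t))
  dG <- rep(0, length(t))
  for (k in 1:3) {
    ek <- exp(-t * gm$p4[k])
    den <- 1 + gm$p3[k] * ek
    term <- gm$p2[k] / den^(1 / gm$p5[k])
    G <- G + term
    dG <- dG + term * (gm$p4[k] * gm$p3[k] * ek) / (gm$p5[k] * den)
  }
  if (any(G <= 0)) stop("growth model yields G(t) <= 0 on the requested interval")
  tibble::tibble(time = t, G = G, m = dG / G)
}

#' Calibration bounds for the free parameters
#'
#' Literature-plausible log-uniform ranges used by [fit_parameters()] and by
#' the `plausible` style of [make_truth()]. Names use the flat addressing
#' `sgrna.<id>.<field>`, `shared.<field>`, `node.<node>.<field>`,
#' `scaling.<reporter>`.
#'
#' @return A tibble with columns `name`, `lower`, `upper`.
#' @export
default_bounds <- function(parts = parts_library()) {
  sg <- parts$sgrna_ids
  tibble::tibble(
    name = c(
      paste0("sgrna.", sg, ".kf_dsd"),
      paste0("sgrna.", sg, ".k_sg"),
      "shared.kr_dsd", "shared.kf_ds", "shared.kr_ds",
      "shared.n_hill", "shared.K_m", "shared.k2",
      "node.A.k_pi", "node.B.k_pi", "node.C.k_pi",
      "node.A.m_pi", "node.B.m_pi", "node.C.m_pi",
      "node.A.d_pi", "node.B.d_pi", "node.C.d_pi",
      "node.B.k_mrna", "node.C.k_mrna",
      "scaling.mKO2", "scaling.mKate2", "scaling.sfGFP"
    ),
    lower = c(rep(1e-4, length(sg)), rep(0.1, length(sg)),
              1e-4, 1e-3, 1e-2, 1, 1e-4, 0.1,
              rep(0.1, 3), rep(5e-3, 3), rep(5e-3, 3),
              rep(0.05, 2), rep(1, 3)),
    upper = c(rep(0.1, length(sg)), rep(20, length(sg)),
              0.1, 1, 2, 4, 0.1, 20,
              rep(20, 3), rep(0.5, 3), rep(0.2, 3),
              rep(5, 2), rep(200, 3))
  )
}

#' Get / set a parameter by flat name
#'
#' Flat addressing used by bounds, fitting and serialisation:
#' `sgrna.<id>.<field>`, `shared.<field>`, `node.<A|B|C>.<field>`,
#' `scaling.<reporter>`, `d_rna.<E>`, `dcas_total.<E>`,
#' `ara_translation.<field>`.
#'
#' @param theta A `grn_parameters`.
#' @param name Flat parameter name.
#' @param value Replacement value (`set_param`).
#' @return `get_param`: numeric scalar. `set_param`: modified `grn_parameters`.
#' @export
get_param <- function(theta, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  switch(parts[1],
    sgrna = {
      i <- match(parts[2], theta$sgrna$id)
      if (is.na(i)) stop("unknown sgRNA '", parts[2], "'")
      theta$sgrna[[parts[3]]][i]
    },
    shared = theta$shared[[parts[2]]],
    node = {
      i <- match(parts[2], theta$nodes$node)
      theta$nodes[[parts[3]]][i]
    },
    scaling = unname(theta$scaling[parts[2]]),
    d_rna = unname(theta$d_rna[parts[2]]),
    dcas_total = unname(theta$dcas_total[parts[2]]),
    ara_translation = theta$ara_translation[[parts[2]]],
    stop("unknown parameter group '", parts[1], "'")
  )
}

#' @rdname get_param
#' @export
set_param <- function(theta, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  switch(parts[1],
    sgrna = {
      i <- match(parts[2], theta$sgrna$id)
      if (is.na(i)) stop("unknown sgRNA '", parts[2], "'")
      theta$sgrna[[parts[3]]][i] <- value
    },
    shared = theta$shared[[parts[2]]] <- value,
    node = {
      i <- match(parts[2], theta$nodes$node)
      theta$nodes[[parts[3]]][i] <- value
    },
    scaling = theta$scaling[parts[2]] <- value,
    d_rna = theta$d_rna[parts[2]] <- value,
    dcas_total = theta$dcas_total[parts[2]] <- value,
    ara_translation = theta$ara_translation[[parts[2]]] <- value,
    stop("unknown parameter group '", parts[1], "'")
  )
  theta
}
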