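# Synthetic-data generation: ground-truth parameter sets, microplate
# time-series datasets with the heteroscedastic measurement noise, growth
# curves, and rule-labeled toy phenotype maps. Everything the calibration
# and map machinery consumes can be generated here, reproducibly from a
# seed, with the statistical structure the analysis assumes.

#' Generate a ground-truth configuration
#'
#' `plausible` style draws a truth near the default parameter set: each
#' bounded kinetic parameter is jittered log-normally (20% scale) and
#' clipped to the calibration bounds. `artificial_grid` style builds the
#' regular control grid: five promoter efficiencies evenly spaced on
#' `[0, 1]` and five sgRNAs with DNA dissociation constants evenly spaced
#' from 5 to 45 nM.
#'
#' @param seed RNG seed.
#' @param style `"plausible"` or `"artificial_grid"`.
#' @return An object of class `grn_truth`: list with `theta`, `parts`,
#'   `growth`, `preculture`, `measurement`, `style`, `seed`.
#' @export
make_truth <- function(seed = 1, style = c("plausible", "artificial_grid")) {
  style <- match.arg(style)
  set.seed(seed)
  if (style == "artificial_grid") {
    parts <- grid_parts_library()
    theta <- default_parameters(parts)
  } else {
    parts <- parts_library()
    theta <- default_parameters(parts)
    bnd <- default_bounds(parts)
    for (i in seq_len(nrow(bnd))) {
      cur <- get_param(theta, bnd$name[i])
      val <- exp(log(cur) + stats::rnorm(1, 0, 0.2))
      theta <- set_param(theta, bnd$name[i],
                         min(max(val, bnd$lower[i]), bnd$upper[i]))
    }
  }
  structure(
    list(theta = theta, parts = parts, growth = growth_model(),
         preculture = preculture_growth(), measurement = measurement_model(),
         style = style, seed = seed),
    class = "grn_truth"
  )
}

#' @export
print.grn_truth <- function(x, ...) {
  cat("<grn_truth> style ", x$style, ", seed ", x$seed, ", ",
      nrow(x$theta$sgrna), " sgRNAs\n", sep = "")
  invisible(x)
}

#' Default microplate calibration design
#'
#' Mirrors the calibration layout: two-node circuits covering all six
#' repression strengths (one sgRNA each, high promoter on the target node)
#' across nine arabinose doses and 100 time points, plus four three-node
#' circuits spanning 3-6 repressions (analogs of the calibration networks:
#' an IFFL, a non-functional symmetric variant, a five-repression and the
#' complete six-repression network).
#'
#' @param parts Parts library.
#' @return List with elements `two_node` (circuit ids), `three_node`
#'   (genotype encodings), `doses`, `times`.
#' @export
default_design <- function(parts = parts_library()) {
  list(
    two_node = paste0("2n:", parts$sgrna_ids, ":PH"),
    three_node = c(
      "1-2-0-4-0-0|PH-PH",   # IFFL, stronger blue promoter
      "1-1-0-4-0-5|PH-PM",   # symmetric mutual-inhibition variant (NF-like)
      "1-2-0-4-3-5|PH-PM",   # five repressions
      "1-2-3-4-5-6|PH-PM"    # complete six-repression network
    ),
    doses = default_doses(),
    times = seq(0, 990, by = 10) # 100 points
  )
}

#' Generate a synthetic microplate calibration dataset
#'
#' Simulates every circuit x dose condition of the design under the truth,
#' maps reporter outputs through the fluorescence scaling factors, and adds
#' independent Gaussian noise with the measurement model's mean-dependent
#' standard deviation, truncated at zero. The default design yields
#' 6 x 9 x 100 = 5400 records per reporter from the two-node circuits.
#'
#' @param truth A [make_truth()] result.
#' @param design A [default_design()]-shaped list.
#' @param seed RNG seed for the noise.
#' @param noise_scale Multiplier on the noise s.d. (0 gives the exact scaled
#'   simulation).
#' @return Calibration tibble with columns `circuit`, `reporter`, `ara`,
#'   `time`, `value`, `sd` (the format consumed by
#'   [calibration_objective()]).
#' @export
generate_microplate_dataset <- function(truth, design = default_design(truth$parts),
                                        seed = 1, noise_scale = 1) {
  set.seed(seed)
  th <- truth$theta
  rows <- list()
  for (id in c(design$two_node, design$three_node)) {
    circ <- parse_circuit(id, truth$parts)
    model <- build_model(circ, th, truth$parts, growth = truth$growth)
    init <- preculture_state(model, growth = truth$preculture)
    # two-node circuits carry no green node: only report expressed nodes
    active <- th$nodes$reporter[c(TRUE, TRUE, !startsWith(id, "2n:"))]
    for (a in design$doses) {
      tgrid <- if (design$times[1] > 0) c(0, design$times) else design$times
      out <- ode_run(model, init, tgrid, a, truth$growth)
      out <- out[match(design$times, out[, "time"]), , drop = FALSE]
      for (rep_name in active) {
        node <- th$nodes$node[th$nodes$reporter == rep_name]
        mu <- pmax(out[, paste0("P.", node)] * unname(th$scaling[rep_name]), 0)
        sdv <- measurement_sd(rep_name, mu)
        val <- if (noise_scale > 0) {
          pmax(mu + stats::rnorm(length(mu), 0, noise_scale * sdv), 0)
        } else {
          mu
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          circuit = id, reporter = rep_name, ara = a,
          time = design$times, value = val, sd = sdv
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a noisy OD600 growth curve
#'
#' Samples the truth's growth model on a uniform grid and adds Gaussian
#' noise.
#'
#' @param truth A [make_truth()] result.
#' @param n_points Number of samples (`>= 20`).
#' @param t_max Horizon (min).
#' @param sd Noise standard deviation (OD units).
#' @param seed RNG seed.
#' @return Tibble with columns `time`, `od`.
#' @export
generate_growth_curve <- function(truth, n_points = 100, t_max = 990,
                                  sd = 0.01, seed = 1) {
  stopifnot(n_points >= 20)
  set.seed(seed)
  t <- seq(0, t_max, length.out = n_points)
  g <- growth_and_dilution(truth$growth, t)$G
  tibble::tibble(time = t, od = pmax(g + stats::rnorm(n_points, 0, sd), 1e-6))
}

#' Rule-labeled toy phenotype map over a connected genotype sample
#'
#' Grows a connected sample of the genotype space by randomised
#' breadth-first expansion from a uniform start and attaches a
#' deterministic labeling rule. These maps are the oracle fixtures for the
#' graph statistics: every statistic can be recomputed by brute force on
#' them.
#'
#' @param n_genotypes Sample size.
#' @param rule Function `function(genotype_string) label`.
#' @param seed RNG seed.
#' @param parts Parts library.
#' @param mode Phenotype alphabet of the map.
#' @return List: `map` (a rule-backed [phenotype_map()], total over the
#'   space), `genotypes` (the connected sample).
#' @export
make_toy_phenotype_map <- function(n_genotypes, rule, seed = 1,
                                   parts = parts_library(),
                                   mode = "steady") {
  set.seed(seed)
  start <- sample_genotypes(1, parts)
  seen <- start
  frontier <- start
  while (length(seen) < n_genotypes && length(frontier)) {
    g <- frontier[sample.int(length(frontier), 1)]
    nb <- setdiff(genotype_neighbors(g, parts), seen)
    if (!length(nb)) {
      frontier <- setdiff(frontier, g)
      next
    }
    take <- utils::head(sample(nb), max(1, min(length(nb), 5)))
    need <- n_genotypes - length(seen)
    take <- utils::head(take, need)
    seen <- c(seen, take)
    frontier <- c(frontier, take)
  }
  map <- phenotype_map(parts = parts, mode = mode, rule = rule)
  list(map = map, genotypes = seen)
}

#' Simple labeling rules for toy maps
#'
#' `rule_constant(label)` labels everything identically;
#' `rule_by_promoter_B(parts)` labels by the blue node's promoter level
#' (levels 1-2 BLUE, others NF), so promoter-slot perturbations are maximally
#' disruptive; `rule_hash(parts, probs, seed)` assigns a deterministic
#' pseudo-random label per genotype with the given phenotype probabilities.
#'
#' @param label Constant label.
#' @param parts Parts library.
#' @param probs Named probabilities for `rule_hash`.
#' @param seed Salt for `rule_hash`.
#' @return A labeling function for [phenotype_map()].
#' @export
rule_constant <- function(label) {
  force(label)
  function(g) label
}

#' @rdname rule_constant
#' @export
rule_by_promoter_B <- function(parts = parts_library()) {
  function(g) {
    if (as_genotype(g, parts)$prom[1] <= 2) "BLUE" else "NF"
  }
}

#' @rdname rule_constant
#' @export
rule_hash <- function(parts = parts_library(),
                      probs = c(NF = 0.8, BLUE = 0.1, GREEN = 0.1),
                      seed = 0) {
  labs <- names(probs)
  cum <- cumsum(probs) / sum(probs)
  function(g) {
    h <- strtoi(substr(fnv1a(list(seed, g)), 1, 7), 16L) / 16^7
    labs[which(h <= cum)[1]]
  }
}
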