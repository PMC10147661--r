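# Phenotype classification. Steady mode maps a dose response to
# GREEN-stripe / BLUE-stripe / NF via the 6% flank rule; dynamic mode maps a
# time course to OSC / NF via normalized autocorrelation.

#' Stripe acceptance criterion
#'
#' A candidate stripe node must show, in its normalized dose response at the
#' read time, both an increase and a decrease of at least `delta` (default
#' 6%) relative to the averages of the `flank` lowest-dose and `flank`
#' highest-dose readouts.
#'
#' @param delta Required flank deficit, in `(0, 1)`.
#' @param flank Number of doses averaged on each flank.
#' @param t_read Read time (min).
#' @return An object of class `stripe_criterion`.
#' @export
stripe_criterion <- function(delta = 0.06, flank = 2, t_read = 900) {
  stopifnot(delta > 0, delta < 1, flank >= 1)
  structure(list(delta = delta, flank = flank, t_read = t_read),
            class = "stripe_criterion")
}

#' Normalize a dose response per reporter
#'
#' Divides each reporter's readouts by its own maximum across doses so the
#' peak is 1; an all-zero reporter stays all-zero (guarded division).
#'
#' @param dr A dose-response tibble with columns `ara`, `node`, `value`
#'   (e.g. from [dose_response()]).
#' @return The tibble with `value` normalized to `[0, 1]` within each node.
#' @export
normalize_dose_response <- function(dr) {
  dplyr::mutate(dr,
    value = ifelse(rep(max(.data$value) > 0, dplyr::n()),
                   .data$value / max(.data$value), .data$value),
    .by = "node"
  )
}

#' Classify a dose response as GREEN-stripe, BLUE-stripe or NF
#'
#' Only the constitutive nodes B (blue) and C (green) can define a
#' functional phenotype; node A is the arabinose input readout. For each
#' candidate node, the normalized response must rise at least `delta` above
#' the mean of the two lowest-dose readouts and fall at least `delta` below
#' 1 at the mean of the two highest-dose readouts (low-high-low pattern). If
#' both nodes qualify, the node with the larger total flank deficit wins;
#' an exact tie is NF.
#'
#' @param dr Dose-response tibble (`ara`, `node`, `value`), raw scale; it is
#'   normalized internally, so the label is invariant to uniform rescaling
#'   of any reporter.
#' @param criterion A [stripe_criterion()].
#' @param details If `TRUE`, return a one-row tibble with the label, peak
#'   node/dose and flank deficits instead of the bare label.
#' @return Character label `"GREEN"`, `"BLUE"` or `"NF"` (or a tibble when
#'   `details = TRUE`).
#' @export
classify_stripe <- function(dr, criterion = stripe_criterion(), details = FALSE) {
  doses <- sort(unique(dr$ara))
  if (length(doses) < 2 * criterion$flank + 1) {
    stop("need at least ", 2 * criterion$flank + 1, " doses, got ", length(doses))
  }
  ndr <- normalize_dose_response(dr)
  info <- list()
  for (node in c("B", "C")) {
    v <- ndr$value[ndr$node == node][order(ndr$ara[ndr$node == node])]
    lo <- 1 - mean(v[seq_len(criterion$flank)])
    hi <- 1 - mean(v[seq(length(v) - criterion$flank + 1, length(v))])
    info[[node]] <- list(
      low = lo, high = hi,
      pass = lo >= criterion$delta && hi >= criterion$delta,
      peak_ara = doses[which.max(v)]
    )
  }
  passing <- names(info)[vapply(info, `[[`, logical(1), "pass")]
  label <- if (length(passing) == 0) {
    "NF"
  } else if (length(passing) == 1) {
    c(B = "BLUE", C = "GREEN")[[passing]]
  } else {
    tot <- vapply(info, function(x) x$low + x$high, numeric(1))
    if (tot["B"] == tot["C"]) "NF" else c(B = "BLUE", C = "GREEN")[[names(which.max(tot))]]
  }
  if (!details) return(label)
  peak_node <- if (label == "BLUE") "B" else if (label == "GREEN") "C" else NA_character_
  tibble::tibble(
    label = label,
    peak_node = peak_node,
    peak_ara = if (is.na(peak_node)) NA_real_ else info[[peak_node]]$peak_ara,
    low_deficit_B = info$B$low, high_deficit_B = info$B$high,
    low_deficit_C = info$C$low, high_deficit_C = info$C$high,
    both_passed = length(passing) == 2
  )
}

#' Detect sustained oscillation in a reporter time course
#'
#' Removes the leading transient (default first 25% of samples), computes
#' the normalized autocorrelation of each reporter (value 1 at lag 0) and
#' reports `TRUE` if any reporter shows a strict local maximum at positive
#' lag with height at least `threshold` (default 0.01). A constant series
#' never oscillates; non-uniform sampling is an error.
#'
#' @param traj A `grn_trajectory` or a numeric matrix/data frame of reporter
#'   series (one column per reporter) sampled uniformly in time.
#' @param threshold Minimum autocorrelation side-peak height.
#' @param transient_frac Fraction of leading samples discarded.
#' @param times Sample times; taken from the trajectory when omitted.
#' @return Logical scalar; attribute `"peak_height"` carries the best
#'   side-peak height found (`NA` if none).
#' @export
detect_oscillation <- function(traj, threshold = 0.01, transient_frac = 0.25,
                               times = NULL) {
  if (inherits(traj, "grn_trajectory")) {
    model <- attr(traj, "model")
    times <- unclass(traj)[, "time"]
    x <- unclass(traj)[, paste0("P.", model$theta$nodes$node), drop = FALSE]
  } else {
    x <- as.matrix(traj)
  }
  if (!is.null(times)) {
    dt <- diff(times)
    if (max(dt) - min(dt) > 1e-8 * max(dt)) stop("series must be uniformly sampled")
  }
  if (nrow(x) < 50) stop("need at least 50 uniformly spaced samples")
  drop <- floor(nrow(x) * transient_frac)
  x <- x[(drop + 1):nrow(x), , drop = FALSE]
  best <- NA_real_
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (stats::sd(v) < 1e-12 * (abs(mean(v)) + 1e-12)) next
    a <- as.numeric(stats::acf(v, lag.max = length(v) - 2, plot = FALSE,
                               demean = TRUE)$acf)
    if (length(a) < 3) next
    # strict local maxima over lags >= 1
    interior <- 2:(length(a) - 1)
    is_peak <- a[interior] > a[interior - 1] & a[interior] > a[interior + 1]
    pk <- a[interior][is_peak]
    if (length(pk) && (is.na(best) || max(pk) > best)) best <- max(pk)
  }
  structure(!is.na(best) && best >= threshold, peak_height = best)
}

#' Classify a genotype's dynamic phenotype (OSC / NF)
#'
#' Simulates the genotype under microfluidic conditions: irreversible
#' promoter binding (`kr_dsd = 0`), constant dilution 1e-3 min^-1, effective
#' arabinose 1e-5 %, horizon 2880 min sampled every 10 min ("imaged every 10
#' min for up to two days"), then applies [detect_oscillation()].
#'
#' @param g Genotype (object or encoding).
#' @param theta Parameter set.
#' @param parts Parts library.
#' @param ara Effective arabinose concentration (% w/v).
#' @param horizon,by Simulation horizon and sampling interval (min).
#' @param threshold Oscillation detection threshold.
#' @return `"OSC"` or `"NF"`.
#' @export
classify_dynamic <- function(g, theta = default_parameters(parts),
                             parts = parts_library(), ara = 1e-5,
                             horizon = 2880, by = 10, threshold = 0.01) {
  model <- build_model(g, theta, parts, growth = constant_growth(1e-3),
                       irreversible = TRUE)
  traj <- simulate_grn(model, ara = ara, t_grid = seq(0, horizon, by = by))
  if (detect_oscillation(traj, threshold = threshold)) "OSC" else "NF"
}

#' Classify a genotype's steady (stripe) phenotype
#'
#' Convenience wrapper: [dose_response()] then [classify_stripe()].
#'
#' @inheritParams classify_dynamic
#' @param criterion A [stripe_criterion()].
#' @param ara_levels Dose grid.
#' @param growth Growth model for the microplate context.
#' @return `"GREEN"`, `"BLUE"` or `"NF"`.
#' @export
classify_steady <- function(g, theta = default_parameters(parts),
                            parts = parts_library(),
                            criterion = stripe_criterion(),
                            ara_levels = default_doses(),
                            growth = growth_model()) {
  dr <- dose_response(g, theta, ara_levels = ara_levels,
                      t_read = criterion$t_read, parts = parts, growth = growth)
  classify_stripe(dr, criterion)
}
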