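# Measurement-error models, growth-curve fitting, and global estimation of
# the shared parameter set against microplate fluorescence time series.

#' Per-reporter measurement standard deviation
#'
#' Piecewise-linear heteroscedastic error models mapping the mean
#' fluorescence signal `x` to its standard deviation, one model per
#' reporter:
#' \itemize{
#'   \item sfGFP: 10350 below 7e4; `0.13 x + 1250` on `[7e4, 2.5e5]`;
#'     3.375e4 above (the pieces meet exactly at both breakpoints).
#'   \item mKO2: 899 below 6e3; `0.08 x + 419` on `[6e3, 2e4]`; 2000 above.
#'     (The lower breakpoint is 6e3 by continuity: `0.08*6e3 + 419 = 899`.)
#'   \item mKate2: 43 below 500; `0.03 x + 23` from 500 up.
#' }
#'
#' @param reporter `"sfGFP"`, `"mKO2"` or `"mKate2"`.
#' @param x Mean signal (arbitrary fluorescence units), `>= 0`, vectorised.
#' @return Standard deviation(s), strictly positive.
#' @export
measurement_sd <- function(reporter, x) {
  if (any(x < 0)) stop("mean signal must be non-negative")
  switch(reporter,
    sfGFP = ifelse(x < 7e4, 10350, ifelse(x <= 2.5e5, 0.13 * x + 1250, 3.375e4)),
    mKO2 = ifelse(x < 6e3, 899, ifelse(x <= 2e4, 0.08 * x + 419, 2e3)),
    mKate2 = ifelse(x < 500, 43, 0.03 * x + 23),
    stop("unknown reporter '", reporter, "'")
  )
}

#' Measurement model bundle
#'
#' @param reporters Reporters covered.
#' @return A function-backed object of class `grn_measurement`: call
#'   `mm$sd(reporter, x)`.
#' @export
measurement_model <- function(reporters = c("sfGFP", "mKO2", "mKate2")) {
  structure(list(reporters = reporters, sd = measurement_sd),
            class = "grn_measurement")
}

# decode a calibration circuit id: either a canonical genotype encoding or
# the two-node form "2n:<sgRNA>:<promoter_B>"
parse_circuit <- function(id, parts) {
  if (startsWith(id, "2n:")) {
    tok <- strsplit(id, ":", fixed = TRUE)[[1]]
    if (length(tok) != 3) stop("malformed two-node circuit id '", id, "'")
    two_node_circuit(tok[2], tok[3], parts)
  } else {
    decode_genotype(id, parts)
  }
}

#' Weighted least-squares calibration objective
#'
#' `sum_i ((x_i - x_i^s(theta)) / sigma_i)^2` over all records: each
#' circuit/dose condition is simulated once under `theta`, the scaled
#' reporter outputs are interpolated at the record times, and standardized
#' residuals are accumulated. Records must carry their own `sd`. A
#' simulation failure contributes a large finite penalty (never `NaN`) so
#' population optimizers remain stable; failures are collected in the
#' `"failures"` attribute.
#'
#' @param theta Parameter set.
#' @param dataset Calibration tibble with columns `circuit`, `reporter`,
#'   `ara`, `time`, `value`, `sd`.
#' @param parts Parts library.
#' @param growth Growth model of the experiment.
#' @param penalty Value added per failed condition.
#' @return Numeric objective (weighted SSR), with attribute `"failures"`.
#' @export
calibration_objective <- function(theta, dataset, parts = parts_library(),
                                  growth = growth_model(), penalty = 1e10) {
  stopifnot(all(c("circuit", "reporter", "ara", "time", "value", "sd") %in% names(dataset)))
  obj <- 0
  failures <- character(0)
  for (id in unique(dataset$circuit)) {
    model <- try(build_model(parse_circuit(id, parts), theta, parts, growth = growth),
                 silent = TRUE)
    if (inherits(model, "try-error")) {
      failures <- c(failures, id)
      obj <- obj + penalty
      next
    }
    init <- try(preculture_state(model), silent = TRUE)
    if (inherits(init, "try-error")) {
      failures <- c(failures, id)
      obj <- obj + penalty
      next
    }
    dsub <- dataset[dataset$circuit == id, ]
    for (a in unique(dsub$ara)) {
      dd <- dsub[dsub$ara == a, ]
      tq <- sort(unique(dd$time))
      tgrid <- if (tq[1] > 0) c(0, tq) else tq
      out <- try(ode_run(model, init, tgrid, a, growth), silent = TRUE)
      if (inherits(out, "try-error")) {
        failures <- c(failures, paste0(id, "@", a))
        obj <- obj + penalty
        next
      }
      P <- out[match(dd$time, out[, "time"]), paste0("P.", theta$nodes$node), drop = FALSE]
      colnames(P) <- theta$nodes$reporter
      pred <- P[cbind(seq_len(nrow(dd)), match(dd$reporter, colnames(P)))] *
        unname(theta$scaling[dd$reporter])
      obj <- obj + sum(((dd$value - pmax(pred, 0)) / dd$sd)^2)
    }
  }
  structure(obj, failures = failures)
}

#' Fit a growth model to an OD time series
#'
#' Least-squares fit of the 16-parameter three-logistic superposition by
#' multi-start local optimization (positivity enforced by log
#' parameterisation). The individual logistic parameters are generally
#' non-identifiable; the fitted curve, not the parameters, is the result.
#'
#' @param od Tibble/data frame with columns `time`, `od` (`>= 20` points).
#' @param n_starts Number of random restarts around a heuristic start.
#' @param seed RNG seed for the restarts.
#' @return A `grn_growth` with attributes `rmse` (relative RMSE) and
#'   `objective`; warns (not errors) if no restart converged cleanly.
#' @export
fit_growth <- function(od, n_starts = 40, seed = 1) {
  stopifnot(all(c("time", "od") %in% names(od)), nrow(od) >= 20, all(od$od > 0))
  t <- od$time; y <- od$od
  obj <- function(lp) {
    p <- exp(lp)
    gm <- try(growth_model(p1 = p[1], p2 = p[2:4], p3 = p[5:7],
                           p4 = p[8:10], p5 = p[11:13]), silent = TRUE)
    if (inherits(gm, "try-error")) return(1e12)
    g <- try(growth_and_dilution(gm, t)$G, silent = TRUE)
    if (inherits(g, "try-error") || any(!is.finite(g))) return(1e12)
    sum((g - y)^2)
  }
  # heuristic start: baseline = min, one dominant logistic spanning the rise
  rise <- max(y) - min(y)
  base <- c(max(min(y), 1e-4), max(rise, 1e-4), rep(max(rise, 1e-4) / 10, 2),
            50, 50, 50, 0.015, 0.01, 0.02, 1, 1, 1)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- log(base) + if (i == 1) 0 else stats::rnorm(13, 0, 0.8)
    fit <- try(stats::nlminb(start, obj, control = list(iter.max = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("growth fit failed for every start")
  p <- exp(best$par)
  gm <- growth_model(p1 = p[1], p2 = p[2:4], p3 = p[5:7], p4 = p[8:10], p5 = p[11:13])
  attr(gm, "objective") <- best$objective
  attr(gm, "rmse") <- sqrt(best$objective / length(y)) / mean(y)
  if (best$convergence != 0) {
    warning("growth fit did not formally converge; returning best found")
  }
  gm
}

#' Global estimation of the shared parameter set
#'
#' Fits selected parameters of a single shared parameter set simultaneously
#' against all records of a calibration dataset by minimising
#' [calibration_objective()]. The global strategy is Latin-hypercube
#' multi-start in log-parameter space followed by derivative-free local
#' polish (`nlminb`) of the best candidates; any comparable global scheme
#' could be substituted behind this interface.
#'
#' @param dataset Calibration tibble (see [calibration_objective()]).
#' @param free Character vector of flat parameter names to estimate (see
#'   [get_param()]).
#' @param bounds Tibble `name`, `lower`, `upper` covering `free` (default
#'   [default_bounds()]).
#' @param theta0 Template parameter set supplying all fixed values.
#' @param parts,growth Context.
#' @param n_starts Latin-hypercube samples.
#' @param polish_top Number of best candidates refined locally.
#' @param seed RNG seed (sampling is bit-reproducible given the seed).
#' @return An object of class `grn_fit`: `theta` (fitted set), `objective`,
#'   `n_data`, `n_params`, `dof`, `chi2` (from [chi2_report()]), `trace`
#'   (tibble of all evaluated starts), `free`, `converged`.
#' @export
fit_parameters <- function(dataset, free, bounds = default_bounds(parts),
                           theta0 = default_parameters(parts),
                           parts = parts_library(), growth = growth_model(),
                           n_starts = 30, polish_top = 2, seed = 1) {
  bnd <- bounds[match(free, bounds$name), ]
  if (anyNA(bnd$lower)) {
    stop("no bounds for: ", paste(free[is.na(bnd$lower)], collapse = ", "))
  }
  if (any(bnd$lower <= 0)) stop("bounds must be positive (log-space search)")
  lo <- log(bnd$lower); hi <- log(bnd$upper)
  apply_free <- function(lp) {
    th <- theta0
    for (i in seq_along(free)) th <- set_param(th, free[i], exp(lp[i]))
    th
  }
  fobj <- function(lp) {
    as.numeric(calibration_objective(apply_free(lp), dataset, parts, growth))
  }
  set.seed(seed)
  lhs_pts <- lhs::randomLHS(n_starts, length(free))
  starts <- t(t(lhs_pts) * (hi - lo) + lo)
  # include the template's own values as a candidate
  lp0 <- pmin(pmax(log(vapply(free, get_param, numeric(1), theta = theta0)), lo), hi)
  starts <- rbind(lp0, starts)
  vals <- apply(starts, 1, fobj)
  ord <- order(vals)
  best_par <- starts[ord[1], ]
  best_val <- vals[ord[1]]
  converged <- FALSE
  for (i in seq_len(min(polish_top, nrow(starts)))) {
    fit <- try(stats::nlminb(starts[ord[i], ], fobj, lower = lo, upper = hi,
                             control = list(iter.max = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (fit$objective < best_val) {
      best_val <- fit$objective
      best_par <- fit$par
      converged <- fit$convergence == 0
    }
  }
  n_data <- nrow(dataset)
  n_params <- length(free)
  structure(
    list(
      theta = apply_free(best_par),
      estimates = stats::setNames(exp(best_par), free),
      objective = best_val,
      n_data = n_data, n_params = n_params, dof = n_data - n_params,
      chi2 = chi2_report(best_val, n_data, n_params),
      trace = tibble::tibble(start = seq_along(vals), objective = vals),
      free = free, bounds = bnd, converged = converged, seed = seed
    ),
    class = "grn_fit"
  )
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("<grn_fit> ", x$n_params, " free parameters, objective ",
      signif(x$objective, 6), " on ", x$dof, " dof (",
      x$chi2$verdict, ")\n", sep = "")
  invisible(x)
}

#' Chi-square goodness-of-fit report
#'
#' Compares the weighted SSR to the chi-square distribution with
#' `n_data - n_params` degrees of freedom.
#'
#' @param objective Weighted sum of squared standardized residuals.
#' @param n_data Number of data points.
#' @param n_params Number of estimated parameters.
#' @param level Test level.
#' @return List: `dof`, `reduced` (objective/dof), `p_value` (upper tail),
#'   `verdict` (`"non-rejection"` / `"rejection"`).
#' @export
chi2_report <- function(objective, n_data, n_params, level = 0.05) {
  if (n_data <= n_params) stop("need more data points than parameters")
  dof <- n_data - n_params
  p <- stats::pchisq(objective, df = dof, lower.tail = FALSE)
  list(dof = dof, reduced = objective / dof, p_value = p,
       verdict = if (p < level) "rejection" else "non-rejection")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted parameter set
#' @param x A `grn_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`, `lower`, `upper`.
#' @export
tidy.grn_fit <- function(x, ...) {
  tibble::tibble(term = x$free, estimate = unname(x$estimates),
                 lower = x$bounds$lower, upper = x$bounds$upper)
}

#' One-row fit summary
#' @param x A `grn_fit`.
#' @param ... Unused.
#' @return Tibble: `objective`, `n_data`, `n_params`, `dof`, `reduced_chi2`,
#'   `p_value`, `verdict`, `converged`.
#' @export
glance.grn_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, n_data = x$n_data, n_params = x$n_params,
    dof = x$dof, reduced_chi2 = x$chi2$reduced, p_value = x$chi2$p_value,
    verdict = x$chi2$verdict, converged = x$converged
  )
}
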