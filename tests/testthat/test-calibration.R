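# Measurement-error models, objective arithmetic, chi-square bookkeeping,
# growth-curve fitting and the estimation landscape.

test_that("measurement s.d. models evaluate the printed pieces and breakpoints", {
  expect_equal(measurement_sd("sfGFP", 5e4), 10350)
  expect_equal(measurement_sd("sfGFP", 2e5), 0.13 * 2e5 + 1250) # 27250
  expect_equal(measurement_sd("sfGFP", 3e5), 3.375e4)
  # the sfGFP pieces meet exactly at both breakpoints
  expect_equal(0.13 * 7e4 + 1250, 10350)
  expect_equal(0.13 * 2.5e5 + 1250, 3.375e4)
  expect_equal(measurement_sd("sfGFP", 7e4), 10350)
  expect_equal(measurement_sd("sfGFP", 2.5e5), 3.375e4)
  expect_equal(measurement_sd("mKate2", 400), 43)
  expect_equal(measurement_sd("mKate2", 1000), 0.03 * 1000 + 23)
  expect_equal(measurement_sd("mKO2", 5e3), 899)
  expect_equal(measurement_sd("mKO2", 6e3), 0.08 * 6e3 + 419) # = 899: continuous
  expect_equal(measurement_sd("mKO2", 1e4), 0.08 * 1e4 + 419)
  expect_equal(measurement_sd("mKO2", 5e4), 2e3)
  expect_true(all(measurement_sd("sfGFP", seq(0, 5e5, length.out = 200)) > 0))
  expect_error(measurement_sd("sfGFP", -1), "non-negative")
  expect_error(measurement_sd("venus", 10), "unknown reporter")
})

test_that("the weighted objective is exact, order-invariant and additive", {
  truth <- make_truth(3)
  design <- list(two_node = "2n:sg1:PH", three_node = character(0),
                 doses = c(0, 1e-4, 1e-3, 1e-2, 0.1),
                 times = seq(60, 900, by = 60))
  ds <- generate_microplate_dataset(truth, design, noise_scale = 0)
  # perfect model: zero residual
  expect_equal(as.numeric(calibration_objective(truth$theta, ds, truth$parts,
                                                truth$growth)), 0, tolerance = 1e-6)
  # known residuals: one record moved 2 s.d. -> 4; plus one at 3 s.d. -> 13
  ds2 <- ds
  ds2$value[5] <- ds2$value[5] + 2 * ds2$sd[5]
  expect_equal(as.numeric(calibration_objective(truth$theta, ds2, truth$parts,
                                                truth$growth)), 4, tolerance = 1e-4)
  ds2$value[40] <- ds2$value[40] - 3 * ds2$sd[40]
  o_both <- as.numeric(calibration_objective(truth$theta, ds2, truth$parts, truth$growth))
  expect_equal(o_both, 13, tolerance = 1e-4)
  # order invariance and additivity over datasets
  perm <- sample(nrow(ds2))
  expect_equal(as.numeric(calibration_objective(truth$theta, ds2[perm, ], truth$parts,
                                                truth$growth)), o_both, tolerance = 1e-8)
  half <- seq_len(nrow(ds2)) <= nrow(ds2) / 2
  expect_equal(
    as.numeric(calibration_objective(truth$theta, ds2[half, ], truth$parts, truth$growth)) +
      as.numeric(calibration_objective(truth$theta, ds2[!half, ], truth$parts, truth$growth)),
    o_both, tolerance = 1e-8
  )
  # an unbuildable circuit contributes the finite penalty, never NaN
  ds3 <- ds[1:3, ]
  ds3$circuit <- "2n:sgZZ:PH"
  o_pen <- calibration_objective(truth$theta, ds3, truth$parts, truth$growth)
  expect_true(is.finite(as.numeric(o_pen)))
  expect_match(attr(o_pen, "failures"), "sgZZ")
})

test_that("chi-square bookkeeping matches the printed degrees of freedom", {
  rep_ok <- chi2_report(27312, 27383, 71)
  expect_equal(rep_ok$dof, 27312)
  expect_equal(rep_ok$verdict, "non-rejection") # objective at the chi2 mean
  expect_equal(chi2_report(10 * 27312, 27383, 71)$verdict, "rejection")
  expect_error(chi2_report(10, 5, 10), "more data")
})

test_that("growth fitting recovers noiseless curves and degenerate inputs", {
  gm_true <- growth_model()
  t <- seq(0, 990, length.out = 60)
  g <- growth_and_dilution(gm_true, t)$G
  fit <- suppressWarnings(fit_growth(tibble::tibble(time = t, od = g), n_starts = 25, seed = 2))
  expect_lt(attr(fit, "rmse"), 1e-3)
  gd <- growth_and_dilution(fit, t)
  expect_true(all(gd$G > 0))
  # constant series: fitted curve reproduces the constant
  const <- tibble::tibble(time = t, od = rep(0.7, length(t)))
  fitc <- suppressWarnings(fit_growth(const, n_starts = 10, seed = 1))
  expect_lt(max(abs(growth_and_dilution(fitc, t)$G - 0.7)), 0.01)
  expect_error(fit_growth(tibble::tibble(time = 1:5, od = rep(1, 5))), "20")
})

test_that("the objective landscape is minimal at the generating truth", {
  truth <- make_truth(5)
  design <- list(two_node = paste0("2n:", c("sg1", "sg4t4"), ":PH"),
                 three_node = character(0),
                 doses = c(0, 1e-3, 5e-3, 2e-2, 0.2),
                 times = seq(60, 900, by = 120))
  ds <- generate_microplate_dataset(truth, design, noise_scale = 0)
  at_truth <- as.numeric(calibration_objective(truth$theta, ds, truth$parts, truth$growth))
  for (nm in c("sgrna.sg1.kf_dsd", "shared.k2", "node.B.k_pi")) {
    th_off <- set_param(truth$theta, nm, 10 * get_param(truth$theta, nm))
    off <- as.numeric(calibration_objective(th_off, ds, truth$parts, truth$growth))
    expect_gt(off, at_truth)
  }
})

test_that("a small noiseless fit recovers a perturbed repression strength", {
  truth <- make_truth(8)
  design <- list(two_node = "2n:sg3:PH", three_node = character(0),
                 doses = c(0, 1e-3, 5e-3, 2e-2, 0.2),
                 times = seq(60, 900, by = 120))
  ds <- generate_microplate_dataset(truth, design, noise_scale = 0)
  fit <- fit_parameters(ds, free = "sgrna.sg3.kf_dsd",
                        theta0 = truth$theta, parts = truth$parts,
                        growth = truth$growth, n_starts = 10, polish_top = 1,
                        seed = 4)
  expect_equal(unname(fit$estimates), get_param(truth$theta, "sgrna.sg3.kf_dsd"),
               tolerance = 0.02)
  expect_equal(fit$dof, nrow(ds) - 1)
  # broom-style accessors
  td <- tidy(fit)
  expect_equal(td$term, "sgrna.sg3.kf_dsd")
  gl <- glance(fit)
  expect_equal(gl$n_params, 1)
  expect_true(gl$objective >= 0)
  # reproducible under the same seed
  fit2 <- fit_parameters(ds, free = "sgrna.sg3.kf_dsd",
                         theta0 = truth$theta, parts = truth$parts,
                         growth = truth$growth, n_starts = 10, polish_top = 1,
                         seed = 4)
  expect_identical(fit$estimates, fit2$estimates)
})
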