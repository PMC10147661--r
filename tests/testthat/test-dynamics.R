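# Mechanistic ODE model: Hill drive, growth/dilution, assembly, integration,
# conservation, closed-form limits, model-reduction consistency.

test_that("Hill induction has the right limits and rejects negative doses", {
  expect_equal(hill_induction(0, 2, 0.01, 1, 30, 0.02), 0)
  expect_equal(hill_induction(0.01, 2, 0.01, 1, 30, 0.02), 0.5 * 1 * 30 * 0.98)
  expect_equal(hill_induction(1e6, 2, 0.01, 2, 30, 0), 2 * 30, tolerance = 1e-9)
  # monotone in dose
  v <- hill_induction(c(1e-4, 1e-3, 1e-2, 1e-1), 1.5, 0.01, 1, 30)
  expect_true(all(diff(v) > 0))
  expect_error(hill_induction(-1, 2, 0.01, 1, 30), "non-negative")
})

test_that("dilution rate equals the analytic G'/G (finite-difference cross-check)", {
  gm <- growth_model(p1 = 0, p2 = c(1, 0, 0), p3 = c(5, 1, 1),
                     p4 = c(0.02, 0.01, 0.01), p5 = c(1, 1, 1))
  t <- seq(10, 800, by = 10)
  gd <- growth_and_dilution(gm, t)
  # single logistic with p5 = 1, p1 = 0: m = p4 p3 e^(-p4 t) / (1 + p3 e^(-p4 t))
  m_closed <- 0.02 * 5 * exp(-0.02 * t) / (1 + 5 * exp(-0.02 * t))
  expect_equal(gd$m, m_closed, tolerance = 1e-12)
  h <- 1e-4
  m_fd <- (growth_and_dilution(gm, t + h)$G - growth_and_dilution(gm, t - h)$G) /
    (2 * h * gd$G)
  expect_equal(gd$m, m_fd, tolerance = 1e-6)
  # all shifts zero: constant G, zero dilution
  gm0 <- growth_model(p1 = 0.2, p2 = c(1, 1, 1), p3 = c(0, 0, 0),
                      p4 = c(0.01, 0.01, 0.01), p5 = c(1, 1, 1))
  gd0 <- growth_and_dilution(gm0, t)
  expect_true(all(gd0$m == 0))
  expect_equal(unique(gd0$G), 3.2)
  # microfluidic constant mode
  expect_equal(growth_and_dilution(constant_growth(), t)$m, rep(1e-3, length(t)))
})

test_that("model assembly follows the reaction template (3E + 9 states)", {
  m3 <- build_model("1-2-0-4-0-0|PH-PM")
  expect_equal(m3$n_states, 18)
  expect_equal(nrow(m3$edges), 3)
  m6 <- build_model("1-2-3-4-5-6|PH-PM")
  expect_equal(m6$n_states, 27)
  # wiring: slots map to the fixed (source, target) order
  expect_equal(m3$edges$src, c(1L, 1L, 2L))
  expect_equal(m3$edges$tgt, c(2L, 3L, 3L))
  # missing sgRNA parameters are reported by part
  th <- default_parameters()
  th$sgrna <- th$sgrna[th$sgrna$id != "sg2", ]
  expect_error(build_model("1-3-0-4-0-0|PH-PM", th), "sg2")
})

test_that("preculture from the zero state is non-negative and near-zero without any production", {
  th <- default_parameters()
  th$sgrna$b <- 0
  th$sgrna$k_sg <- 0
  th$nodes$b <- 0
  th$nodes$k_mrna <- c(NA, 0, 0)
  model <- build_model("1-2-0-4-0-0|0-0", th)
  st <- preculture_state(model)
  expect_true(all(st >= 0))
  # at arabinose 0 nothing is transcribed except node A's (zeroed) leak
  expect_lt(max(st[grep("^(mRNA|PI|P)\\.", names(st))]), 1e-8)
  st2 <- preculture_state(build_model("1-2-0-4-0-0|PH-PM"))
  expect_true(all(st2 >= 0))
})

test_that("an unrepressed constitutive node reaches the closed-form steady state", {
  th <- flat_key_parameters()
  # circuit with no edges at all: pure expression under constant dilution
  circ <- structure(list(edges = integer(6), prom = c(1L, 2L)), class = "grn_genotype")
  mconst <- 5e-4
  model <- build_model(circ, th, growth = constant_growth(mconst))
  tr <- simulate_grn(model, ara = 0, t_grid = seq(0, 30000, by = 500),
                     init = setNames(numeric(9), model$state_names))
  final <- unclass(tr)[nrow(tr), ]
  for (j in 2:3) {
    nd <- th$nodes[j, ]
    eff <- unname(parts_library()$promoters[circ$prom[j - 1]])
    mrna <- nd$k_mrna * eff * nd$dna_total / unname(th$d_rna["1"])
    pi_ss <- nd$k_pi * mrna / (nd$m_pi + mconst + nd$d_pi)
    p_ss <- nd$m_pi * pi_ss / (mconst + nd$d_pi)
    expect_equal(unname(final[paste0("mRNA.", nd$node)]), mrna, tolerance = 1e-4)
    expect_equal(unname(final[paste0("P.", nd$node)]), p_ss, tolerance = 1e-4)
  }
})

test_that("dCas and promoter DNA conservation hold along trajectories", {
  for (enc in c("1-2-0-4-0-0|PH-PM", "1-2-3-4-5-6|PL-PM", "0-2-3-0-5-0|PM-0")) {
    tr <- simulate_grn(build_model(enc), ara = 0.01, t_grid = seq(0, 960, 30))
    res <- conservation_residuals(tr)
    expect_lt(max(res$max_rel_error), 1e-6)
    expect_true(all(unclass(tr)[, -1] > -1e-9))
  }
})

test_that("with no dCas binding the reporters match the unrepressed steady state", {
  th <- flat_key_parameters()
  th$shared$kf_ds <- 0
  mconst <- 5e-4
  model <- build_model("1-2-0-4-0-0|PH-PM", th, growth = constant_growth(mconst))
  tr <- simulate_grn(model, ara = 0, t_grid = seq(0, 30000, 500),
                     init = setNames(numeric(model$n_states), model$state_names))
  final <- unclass(tr)[nrow(tr), ]
  for (j in 2:3) {
    nd <- th$nodes[j, ]
    eff <- unname(parts_library()$promoters[model$genotype$prom[j - 1]])
    mrna <- nd$k_mrna * eff * nd$dna_total / unname(th$d_rna["3"])
    p_ss <- nd$m_pi * (nd$k_pi * mrna / (nd$m_pi + mconst + nd$d_pi)) / (mconst + nd$d_pi)
    expect_equal(unname(final[paste0("P.", nd$node)]), p_ss, tolerance = 1e-4)
  }
})

test_that("doubling total dCas is inert when no sgRNA is ever produced", {
  th <- flat_key_parameters()
  th$sgrna$b <- 0
  th$sgrna$k_sg <- 0
  # every edge originates from a constitutive node, so zeroing k_sg and the
  # leak silences all guides
  run <- function(th) {
    tr <- simulate_grn(build_model("0-0-3-4-0-5|PH-PM", th), ara = 0.01,
                       t_grid = seq(0, 900, 100))
    unclass(tr)[, c("P.A", "P.B", "P.C")]
  }
  base <- run(th)
  th2 <- th
  th2$dcas_total[] <- 2 * th2$dcas_total
  expect_equal(run(th2), base, tolerance = 1e-5)
})

test_that("zeroing an edge's sgRNA production reproduces the reduced model", {
  th <- flat_key_parameters()
  # the 4th edge slot (B->C) carries sg4t4, used nowhere else; silence it
  th0 <- th
  th0$sgrna$b[th0$sgrna$id == "sg4t4"] <- 0
  th0$sgrna$k_sg[th0$sgrna$id == "sg4t4"] <- 0
  full <- simulate_grn(build_model("1-2-0-6-0-5|PH-PM", th0), ara = 0.003,
                       t_grid = seq(0, 960, 60))
  reduced <- simulate_grn(build_model("1-2-0-0-0-5|PH-PM", th), ara = 0.003,
                          t_grid = seq(0, 960, 60))
  for (col in c("P.A", "P.B", "P.C", "mRNA.A", "mRNA.B", "mRNA.C")) {
    expect_equal(unclass(full)[, col], unclass(reduced)[, col], tolerance = 1e-5)
  }
})

test_that("the microfluidic context honors the irreversibility switch", {
  th <- default_parameters()
  m_irr <- build_model("1-0-0-1-1-0|PH-PH", th, growth = constant_growth(),
                       irreversible = TRUE)
  th0 <- th
  th0$shared$kr_dsd <- 0
  m_zero <- build_model("1-0-0-1-1-0|PH-PH", th0, growth = constant_growth())
  t_grid <- seq(0, 1500, 50)
  expect_equal(unclass(simulate_grn(m_irr, 1e-5, t_grid)),
               unclass(simulate_grn(m_zero, 1e-5, t_grid)),
               ignore_attr = TRUE)
})

test_that("dose responses are deterministic, ordered, and respect promoter knockouts", {
  th <- default_parameters()
  th$nodes$b <- 0
  dr1 <- dose_response("1-2-0-4-0-0|0-0", th)
  expect_true(all(dr1$value[dr1$node %in% c("B", "C")] < 1e-6))
  dr2 <- dose_response("1-2-0-4-0-0|PH-PM")
  expect_identical(dr2, dose_response("1-2-0-4-0-0|PH-PM"))
  expect_error(dose_response("1-2-0-4-0-0|PH-PM", ara_levels = c(0, 0.1, 0.2)),
               "5 dose levels")
  # node A readout is non-decreasing in dose when nothing represses A
  a_vals <- dr2$value[dr2$node == "A"][order(dr2$ara[dr2$node == "A"])]
  expect_true(all(diff(a_vals) > -1e-9))
})
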