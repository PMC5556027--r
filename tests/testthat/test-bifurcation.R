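test_that("equilibria respect the closed-form eliminations and residuals", {
  p <- fk_params()

  eq4 <- subsystem_equilibria(p53 = 1, cIAP = 4, p)
  expect_true(all(abs(eq4$Caspase8 - 0.03 / 0.7) < 1e-12))

  # residual of the subsystem RHS vanishes at every reported equilibrium
  for (ctl in list(c(0.3, 0.01), c(1, 0.01), c(0.8, 0.5))) {
    eq <- subsystem_equilibria(ctl[1L], ctl[2L], p)
    for (i in seq_len(nrow(eq))) {
      st <- fk_state(BaxmT = eq$BaxmT[i], BaxmBcl = eq$BaxmBcl[i],
                     Bh3Bcl = eq$Bh3Bcl[i], Bh3T = eq$Bh3T[i],
                     Caspase8 = eq$Caspase8[i], cIAP = ctl[2L])
      res <- apoptosis_module_rhs(st, ctl[1L], p)
      expect_lt(max(abs(res)), 1e-9)
    }
  }
})

test_that("the equilibrium count is 1 or 3 across the control plane", {
  p <- fk_params()
  for (p53 in seq(0, 2, by = 0.25)) for (ci in c(0.01, 0.5, 2, 4)) {
    n <- nrow(subsystem_equilibria(p53, ci, p))
    expect_true(n %in% c(1L, 3L))
  }
})

test_that("high p53 leaves a single attractor that dynamics also find", {
  p <- fk_params()
  eq <- subsystem_equilibria(p53 = 10, cIAP = 0.01, p)
  expect_equal(nrow(eq), 1L)
  expect_true(eq$stable)

  # brute-force oracle: integrate the frozen subsystem from scattered
  # initial conditions; all must land on the reported equilibrium
  sub_rhs <- function(t, y, parms) {
    st <- fk_state(BaxmT = y[1L], BaxmBcl = y[2L], Bh3Bcl = y[3L],
                   Bh3T = y[4L], Caspase8 = y[5L], cIAP = 0.01)
    d <- apoptosis_module_rhs(st, p53 = 10, parms, free_tol = Inf)
    list(unname(d))
  }
  for (y0 in list(c(0, 0, 0, 0, 0.3), c(0.4, 0.3, 0.2, 1, 0.1),
                  c(0.1, 0.05, 0.3, 2, 0.5))) {
    out <- deSolve::ode(y0, c(0, 500), sub_rhs, p, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(out[2L, 2L] - out[2L, 3L]), eq$Baxm,
                 tolerance = 1e-6)
  }
})

test_that("stability labels agree with the S-curve branch structure", {
  p <- fk_params()
  sc <- one_param_scurve(p, cIAP = 0.01)
  # inside the bistable window: two stable branches bracket an unstable one
  mid <- (sc$theta_inact + sc$theta_act) / 2
  eq <- subsystem_equilibria(mid, 0.01, p)
  eq <- eq[order(eq$Baxm), ]
  expect_equal(eq$stable, c(TRUE, FALSE, TRUE))
  expect_true(all((eq$eig < 0) == eq$stable))
})

test_that("the basal S-curve is hysteretic and CIAP moves the threshold up", {
  p <- fk_params()
  sc <- one_param_scurve(p, cIAP = 0.01, branches = FALSE)
  expect_false(is.na(sc$theta_act))
  expect_false(is.na(sc$theta_inact))
  expect_lt(sc$theta_inact, sc$theta_act)
  expect_gt(sc$theta_act, 0.2)
  expect_lt(sc$theta_act, 0.8)

  hi <- one_param_scurve(p, cIAP = 1, range = c(0, 2), branches = FALSE)
  expect_gt(hi$theta_act, sc$theta_act)

  # without the BH3 -> BAX coupling there is no switch to fold
  flat <- one_param_scurve(fk_params(kf2 = 0), cIAP = 0.01,
                           branches = FALSE)
  expect_true(is.na(flat$theta_act))
  expect_true(is.na(flat$theta_inact))
})

test_that("bisected folds agree with a dense brute-force scan", {
  p0 <- fk_params()
  set.seed(21)
  for (k in 1:8) {
    p <- p0
    for (nm in c("kf2", "kb", "kasXC", "kasHC", "BclT"))
      p[[nm]] <- p[[nm]] * stats::runif(1, 0.9, 1.1)
    sc <- one_param_scurve(p, cIAP = 0.01, range = c(0, 1.5),
                           branches = FALSE)
    # oracle: exhaustive scan of the equilibrium count at step 1e-4
    grid <- seq(0, 1.5, by = 1e-4)
    bh3t <- (p$ksBh3 + p$ks2 * grid +
               p$ks3 * p$kaC8 / (p$kiC8 + p$ki2 * 0.01)) / p$kdBh3
    cnt <- vapply(bh3t, frackill:::.fk_eq_count, 0L, p = p)
    jumps <- grid[which(diff(cnt) != 0)]
    folds <- sort(c(sc$theta_inact, sc$theta_act))
    folds <- folds[!is.na(folds)]
    expect_equal(length(jumps), length(folds))
    if (length(folds))
      expect_lt(max(abs(jumps - folds)), 1e-3)
  }
})

test_that("threshold curves are monotone and label the plane correctly", {
  p <- fk_params()
  th <- two_param_thresholds(p, ciap_grid = seq(0, 1, by = 0.25))
  expect_true(all(diff(th$curves$theta_act) >= 0, na.rm = TRUE))
  expect_true(all(th$curves$theta_inact <= th$curves$theta_act,
                  na.rm = TRUE))

  # region definition
  cu <- th$curves
  expect_equal(classify_point(cu$theta_act[1L] + 0.05, 0, th), "apoptosis")
  expect_equal(classify_point(cu$theta_inact[1L] - 0.05, 0, th), "survival")
  expect_equal(classify_point(mean(c(cu$theta_act[1L], cu$theta_inact[1L])),
                              0, th), "hysteresis")

  expect_error(two_param_thresholds(p, ciap_grid = c(1, 0.5)), "ascending")
})

test_that("treatment-path curves sit left of the equilibrium curves", {
  p <- fk_params()
  grid <- seq(0, 1, by = 0.25)
  eq <- two_param_thresholds(p, ciap_grid = grid)
  tr <- two_param_thresholds(p, ciap_grid = grid, caspase8 = "treatment",
                             drug = 0.45)
  # a treated cell carries more Caspase8 (hence more BH3) than the static
  # steady state once cIAP has risen, lowering the p53 threshold
  expect_true(all(tr$curves$theta_act[-1L] <= eq$curves$theta_act[-1L]))
  expect_equal(tr$curves$theta_act[1L], eq$curves$theta_act[1L],
               tolerance = 0.05)
})

test_that("trajectory overlays report region entry and fate consistency", {
  p <- fk_params()
  th <- two_param_thresholds(p, caspase8 = "treatment", drug = 0.45)

  # a quiescent path never enters the apoptosis region
  flat <- synthetic_trajectory(time = 0:60, p53 = rep(0, 61),
                               Baxm = rep(0, 61), cIAP = 0.01 * (0:60) / 60)
  ov0 <- overlay_trajectory(flat, th)
  expect_true(is.na(ov0$entry_time))
  expect_equal(ov0$geometric_fate, "surviving")
  expect_true(ov0$consistent)

  # representative cells from the seeded population
  cells <- sample_population(p, heterogeneity_spec(30, seed = 1))
  pops <- run_population(cells, fk_protocol(drug = 0.45))
  # representative cells: the earliest death and the weakest p53 responder
  apo <- which.min(pops$fates$death_time)
  sur <- which(pops$fates$fate == "surviving")
  sur <- sur[which.min(pops$fates$p53_peak[sur])]

  tr_a <- simulate_cell(cells[[apo]], fk_protocol(drug = 0.45))
  ov_a <- overlay_trajectory(tr_a, th)
  expect_equal(ov_a$geometric_fate, "apoptotic")
  expect_lte(ov_a$entry_time, pops$fates$death_time[apo])

  tr_s <- simulate_cell(cells[[sur]], fk_protocol(drug = 0.45))
  ov_s <- overlay_trajectory(tr_s, th)
  expect_equal(ov_s$geometric_fate, "surviving")
})

test_that("calibration selects totals satisfying the documented criteria", {
  prof <- calibrate_model(bclt_grid = c(0.65, 0.725),
                          sigma_drug_grid = c(15, 25), gate_n = 300)
  cal <- attr(prof, "calibration")
  expect_equal(cal$BclT, 0.725)
  expect_equal(cal$sigma_drug, 25)
  expect_gt(cal$theta_act_basal, 0.2)
  expect_lt(cal$theta_act_basal, 0.8)
  expect_lt(cal$theta_inact_basal, cal$theta_act_basal)
  expect_gt(cal$theta_act_ciap4, 1)
  expect_equal(prof$death_threshold,
               death_threshold_default(prof$params), tolerance = 1e-10)
  # no candidate at an implausible grid
  expect_error(calibrate_model(bclt_grid = 0.2, sigma_drug_grid = 5),
               "no grid candidate")
})
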