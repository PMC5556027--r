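test_that("protocols resolve to the documented parameter changes", {
  p <- fk_params()

  # identity protocol leaves parameters untouched at all times
  id <- apply_protocol(p, fk_protocol(drug = 0.45), t = 30)
  expect_identical(id$params, p)
  expect_equal(id$drug_ciap, 0.45)
  expect_equal(id$drug_mdm2, 0.45)

  # multipliers land on the right parameters
  pr <- fk_protocol(drug = 0.45, ciap_inhibition = 0, bcl_inhibition = 0.9,
                    casp8_activation = 1.2)
  m <- apply_protocol(p, pr, 0)$params
  expect_equal(m$ksIAP2, 0)
  expect_equal(m$BclT, 0.9 * p$BclT)
  expect_equal(m$kaC8, 1.2 * p$kaC8)

  # Nutlin is a step on the Mdm2 drug argument only
  nut <- fk_protocol(drug = 0.45, nutlin_time = 5, nutlin_strength = 1)
  expect_equal(apply_protocol(p, nut, 4.9)$drug_mdm2, 0.45)
  expect_equal(apply_protocol(p, nut, 5.1)$drug_mdm2, 1.45)
  expect_equal(apply_protocol(p, nut, 5.1)$drug_ciap, 0.45)

  expect_error(fk_protocol(drug = 0.45, nutlin_time = 70, t_end = 60),
               "nutlin_time")
})

test_that("complete CIAP inhibition keeps cIAP at its basal level", {
  p <- fk_params()
  tr <- simulate_cell(p, fk_protocol(drug = 1, ciap_inhibition = 0,
                                     t_end = 60))
  expect_lte(max(tr$cIAP), 0.011)  # basal steady state + tolerance
})

test_that("single-cell simulation is deterministic and handles edge cases", {
  p <- fk_params()
  pr <- fk_protocol(drug = 0.45, t_end = 30)
  a <- simulate_cell(p, pr)
  b <- simulate_cell(p, pr)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # zero-horizon protocol: the initial state only
  tr0 <- simulate_cell(p, fk_protocol(drug = 1, t_end = 0))
  expect_equal(nrow(tr0), 1L)
  st <- initial_state(p, quiet = TRUE)
  expect_equal(tr0$BaxmT, st[["BaxmT"]])
  expect_equal(tr0$Mdm2, st[["Mdm2"]])

  # output grid strictly increasing, starts at the initial state
  expect_true(all(diff(a$time) > 0))
  expect_equal(a$p53[1L], 0)
})

test_that("a resting cell never activates p53 without drug", {
  tr <- simulate_cell(fk_params(), fk_protocol(drug = 0, t_end = 100))
  expect_lt(max(tr$p53), 0.3)
  expect_lt(max(tr$Baxm), fk_profile()$death_threshold)
})

test_that("the p53 plateau level is set by the fixed point, not the timescale", {
  lvl <- vapply(c(0.45, 0.6, 0.72), function(ts) {
    tr <- simulate_cell(fk_params(tsp53 = ts),
                        fk_protocol(drug = 1, t_end = 400))
    tr$p53[nrow(tr)]
  }, 0)
  expect_lt(max(lvl) - min(lvl), 1e-4)
})

test_that("fate classification implements the stated definitions", {
  # never-activating trajectory: survives, no timings
  t1 <- synthetic_trajectory(time = 0:10, p53 = rep(0.1, 11),
                             Baxm = rep(0, 11))
  f1 <- classify_fate(t1, death_threshold = 0.1, activation_threshold = 0.3)
  expect_equal(f1$fate, "surviving")
  expect_true(is.na(f1$death_time))
  expect_true(is.na(f1$p53_activation_time))
  # rectangle integral for constant p53
  expect_equal(f1$integrated_p53, 0.1 * 10)

  # equal plateaus, death at T/2 vs survival to T: survivor integrates ~2x
  tt <- seq(0, 10, by = 0.1)
  apo <- synthetic_trajectory(tt, p53 = rep(0.5, length(tt)),
                              Baxm = ifelse(tt >= 5, 1, 0))
  sur <- synthetic_trajectory(tt, p53 = rep(0.5, length(tt)),
                              Baxm = rep(0, length(tt)))
  fa <- classify_fate(apo, 0.5, 0.3)
  fs <- classify_fate(sur, 0.5, 0.3)
  expect_equal(fa$fate, "apoptotic")
  expect_equal(fs$integrated_p53 / fa$integrated_p53, 2, tolerance = 0.05)

  # death time interpolates linearly between grid points
  t2 <- synthetic_trajectory(time = c(0, 1, 2), p53 = c(0, 0, 0),
                             Baxm = c(0, 0.2, 0.6))
  f2 <- classify_fate(t2, death_threshold = 0.4, activation_threshold = 0.3)
  expect_equal(f2$death_time, 1.5)
})

test_that("raising the death threshold never converts survivors to deaths", {
  tr <- simulate_cell(fk_params(), fk_protocol(drug = 1, t_end = 60))
  thr <- seq(0.05, 0.4, by = 0.05)
  dead <- vapply(thr, function(d)
    classify_fate(tr, d, 0.3)$fate == "apoptotic", TRUE)
  expect_true(all(diff(dead) <= 0))  # once surviving, stays surviving
})
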