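test_that("free species follow the conservation relations", {
  p <- fk_params(BaxT = 1, BclT = 0.6)

  # empty system: everything free
  s0 <- fk_state()
  f0 <- derive_free_species(s0, p)
  expect_equal(unname(f0), c(1, 0, 0, 0.6))

  # arithmetic on a mixed state
  s <- fk_state(BaxmT = 0.3, BaxmBcl = 0.2, Bh3T = 0.6, Bh3Bcl = 0.16)
  f <- derive_free_species(s, p)
  expect_equal(f[["Bax"]], 0.7)
  expect_equal(f[["Baxm"]], 0.1)
  expect_equal(f[["Bh3"]], 0.44)
  expect_equal(f[["Bcl"]], 0.6 - 0.2 - 0.16)

  # the printed initial dimer exceeds its total: rejected beyond tolerance
  bad <- fk_state(BaxmT = 0.3, BaxmBcl = 0.33, Bh3T = 0.4, Bh3Bcl = 0.16)
  expect_error(derive_free_species(bad, p), "conservation violated")

  # and the initial-state constructor projects it to consistency
  expect_warning(st <- initial_state(p), "projected")
  expect_equal(st[["BaxmBcl"]], st[["BaxmT"]])
  expect_silent(derive_free_species(st, p))
})

test_that("regulatory input is the exact affine combination", {
  # p53 weights at rest (p53 = 0, Mdm2 = 1)
  expect_equal(regulatory_input(c(-0.4, 2, -1), c(0, 1)), -1.4)
  # Mdm2 weights at rest
  expect_equal(regulatory_input(c(-0.55, 1), 0), -0.55)
  expect_equal(regulatory_input(c(0, 0, 0), c(3, 7)), 0)
  expect_error(regulatory_input(c(1, 2), c(1, 2)), "background weight")
})

test_that("sigmoid fraction is a proper overflow-safe logistic", {
  expect_equal(sigmoid_fraction(0, 5), 0.5)
  expect_equal(sigmoid_fraction(1e6, 5), 1)
  expect_equal(sigmoid_fraction(-1e6, 5), 0)
  expect_equal(sigmoid_fraction(-1.4, 5), 1 / (1 + exp(7)))
  w <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(sigmoid_fraction(w, 5)) > 0))
  expect_error(sigmoid_fraction(0, 0), "steepness")
})

test_that("drug coupling modes have the documented sign conventions", {
  # at the printed steepness the two modes give the printed values
  lit <- fk_params(sigma_drug = 5, drug_coupling_mode = "literal")
  rep <- fk_params(sigma_drug = 5, drug_coupling_mode = "repressive")
  d_lit <- p53_module_rhs(0, 0, drug = 1, lit)
  d_rep <- p53_module_rhs(0, 0, drug = 1, rep)
  # dMdm2/dt = tsMdm2 * (sigmoid2(wMdm2) + drug_term - Mdm2); solve back
  term <- function(d, p) d[["Mdm2"]] / p$tsMdm2 -
    sigmoid_fraction(p$R0_Mdm2, p$sigma2)
  expect_equal(term(d_lit, lit), 1 / (1 + exp(-1.65)), tolerance = 1e-10)
  expect_equal(term(d_rep, rep), 1 / (1 + exp(1.65)), tolerance = 1e-10)

  # mode contract: identical right-hand sides at drug = 0
  st <- initial_state(quiet = TRUE)
  lit0 <- fk_params(drug_coupling_mode = "literal")
  rep0 <- fk_params(drug_coupling_mode = "repressive")
  expect_equal(full_rhs(st, lit0, 0, 0), full_rhs(st, rep0, 0, 0))
  expect_equal(term(p53_module_rhs(0, 0, 0, lit0), lit0), 0.5,
               tolerance = 1e-12)
})

test_that("module right-hand sides vanish at their closed-form steady states", {
  p <- fk_params()
  # Caspase8 balance without CIAP
  s <- fk_state(Caspase8 = 0.3, cIAP = 0, Bh3T = 1)
  expect_equal(apoptosis_module_rhs(s, 0, p)[["Caspase8"]], 0)
  # BH3 synthesis/degradation balance
  s2 <- fk_state(Caspase8 = 0.3, Bh3T = 0.6)
  expect_equal(apoptosis_module_rhs(s2, p53 = 1, p)[["Bh3T"]],
               0.1 + 0.2 + 0.3 - 0.6)
  # CIAP: half-saturation and basal balance
  expect_equal(ciap_rhs(0.01, 0, p), 0)
  h <- ciap_rhs(0, p$J, p) - p$ksIAP  # synthesis at drug = J
  expect_equal(h, p$ksIAP2 * 0.5)
  # drug-driven steady state ~ 4.01
  ss <- (p$ksIAP + p$ksIAP2 * (1 / (1 + (p$J / 1)^p$n))) / p$kdIAP
  expect_equal(ciap_rhs(ss, 1, p), 0, tolerance = 1e-12)
  expect_equal(ss, 4.01, tolerance = 1e-3)
})

test_that("closed-form steady states match numerical root finding", {
  p <- fk_params()
  for (drug in c(0, 0.45, 1)) {
    hill <- if (drug > 0) drug^p$n / (drug^p$n + p$J^p$n) else 0
    alg <- (p$ksIAP + p$ksIAP2 * hill) / p$kdIAP
    expect_equal(ciap_ss_numeric(drug, p), alg, tolerance = 1e-8)
  }
  for (ci in c(0.01, 1, 4))
    expect_equal(c8_ss_numeric(ci, p), p$kaC8 / (p$kiC8 + p$ki2 * ci),
                 tolerance = 1e-8)
})

test_that("steady states are monotone in their drivers", {
  p <- fk_params()
  drugs <- c(0, 0.05, 0.1, 0.2, 0.45, 1, 2)
  ciap_ss <- vapply(drugs, ciap_ss_numeric, 0, params = p)
  expect_true(all(diff(ciap_ss) >= 0))
  cis <- c(0.01, 0.1, 0.5, 1, 2, 4)
  c8 <- vapply(cis, c8_ss_numeric, 0, params = p)
  expect_true(all(diff(c8) < 0))
})

test_that("full RHS is zero at an independently assembled fixed point", {
  p <- fk_params()
  # resting p53/Mdm2 fixed point from the scalar reduction of the
  # two-variable module (Mdm2 at its p53-slaved steady state)
  mdm2_ss <- function(x) {
    fm <- sigmoid_fraction(p$R0_Mdm2 + p$Rp53_Mdm2 * x, p$sigma2) + 0.5
    min(max(fm, 0), 1)
  }
  r <- stats::uniroot(function(x)
    sigmoid_fraction(p$R0_p53 + p$Rp53_p53 * x + p$RMdm2_p53 * mdm2_ss(x),
                     p$sigma) - x, c(0, 0.2), tol = 1e-14)$root
  ci <- p$ksIAP / p$kdIAP
  eq <- subsystem_equilibria(r, ci, p)
  low <- which.min(eq$Baxm)
  st <- fk_state(BaxmT = eq$BaxmT[low], BaxmBcl = eq$BaxmBcl[low],
                 Bh3Bcl = eq$Bh3Bcl[low], Bh3T = eq$Bh3T[low],
                 Caspase8 = eq$Caspase8[low], cIAP = ci, p53 = r,
                 Mdm2 = mdm2_ss(r))
  expect_lt(max(abs(full_rhs(st, p, 0, 0))), 1e-12)
})

test_that("full RHS directional derivatives match finite differences", {
  p <- fk_params()
  st <- fk_state(BaxmT = 0.2, BaxmBcl = 0.15, Bh3Bcl = 0.2, Bh3T = 0.45,
                 Caspase8 = 0.25, cIAP = 0.3, p53 = 0.4, Mdm2 = 0.5)
  set.seed(11)
  for (k in 1:5) {
    v <- stats::rnorm(8); v <- v / sqrt(sum(v^2))
    h <- 1e-6
    fd <- (full_rhs(st + h * v, p, 1, 1) - full_rhs(st - h * v, p, 1, 1)) /
      (2 * h)
    # Jacobian-vector product by one-sided differences at a finer scale
    h2 <- 1e-8
    jv <- (full_rhs(st + h2 * v, p, 1, 1) - full_rhs(st, p, 1, 1)) / h2
    expect_equal(unname(fd), unname(jv), tolerance = 1e-4)
  }
})

test_that("RHS has the documented sign structure", {
  p <- fk_params()
  st <- fk_state(Bh3T = 0.5, Caspase8 = 0.2, Bh3Bcl = 0.1)
  d1 <- apoptosis_module_rhs(st, 0.5, p)[["Bh3T"]]
  p2 <- fk_params(kdBh3 = 2 * p$kdBh3)
  d2 <- apoptosis_module_rhs(st, 0.5, p2)[["Bh3T"]]
  expect_lt(d2, d1)
})

test_that("compiled and R right-hand sides integrate to the same solution", {
  p <- fk_params()
  pr <- fk_protocol(drug = 1, t_end = 20)
  a <- simulate_cell(p, pr, engine = "compiled")
  b <- simulate_cell(p, pr, engine = "R")
  expect_lt(max(abs(as.matrix(a[, 2:9]) - as.matrix(b[, 2:9]))), 1e-5)
})

test_that("integrated solutions stay non-negative from resting conditions", {
  p <- fk_params()
  for (drug in c(0, 0.45, 1)) {
    tr <- simulate_cell(p, fk_protocol(drug = drug, t_end = 60))
    states <- as.matrix(tr[, c("BaxmT", "BaxmBcl", "Bh3Bcl", "Bh3T",
                               "Caspase8", "cIAP", "p53", "Mdm2")])
    expect_gt(min(states), -1e-6)
  }
})

test_that("parameter validation names the offending field", {
  expect_error(fk_params(nonsense = 1), "nonsense")
  expect_error(fk_params(kf1 = -1), "kf1")
  expect_error(fk_params(J = 0), "J")
  expect_error(fk_params(drug_coupling_mode = "both"), "drug_coupling_mode")
  expect_s3_class(fk_params(BclT = 0.9), "fk_params")
})
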