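## Shared fixtures.  Heavy seeded populations used by several acceptance
## checks are computed once per test run and memoised here.

.fk_test_cache <- new.env(parent = emptyenv())

## the reference 300-cell population at both printed doses, seed 1
acceptance_populations <- function() {
  if (is.null(.fk_test_cache$pops)) {
    cells <- sample_population(fk_params(),
                               heterogeneity_spec(n_cells = 300, seed = 1))
    .fk_test_cache$pops <- list(
      cells = cells,
      low = run_population(cells, fk_protocol(drug = 0.45)),
      high = run_population(cells, fk_protocol(drug = 1)))
  }
  .fk_test_cache$pops
}

## build a synthetic trajectory data.frame for classifier tests
synthetic_trajectory <- function(time, p53, Baxm, cIAP = 0) {
  structure(data.frame(time = time, p53 = p53, Baxm = Baxm, cIAP = cIAP),
            class = c("fk_trajectory", "data.frame"))
}

## steady-state cIAP by numerical root finding (independent of the algebra)
ciap_ss_numeric <- function(drug, params) {
  stats::uniroot(function(x) ciap_rhs(x, drug, params),
                 c(0, 100), tol = 1e-14)$root
}

## steady-state Caspase8 by numerical root finding
c8_ss_numeric <- function(cIAP, params) {
  f <- function(x) params$kaC8 - (params$kiC8 + params$ki2 * cIAP) * x
  stats::uniroot(f, c(0, 10), tol = 1e-14)$root
}
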