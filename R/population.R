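## Heterogeneous virtual-cell populations --------------------------------------

#' Default randomized parameter set
#'
#' The parameters controlling p53 and Mdm2 dynamics (regulatory weights and
#' timescales), the CIAP degradation rate (`kdIAP`, responsible for
#' fate-timing exceptions), and the lumped per-cell drug-effect strength
#' (`R_drug_effect`).
#'
#' @return Character vector of parameter names.
#' @export
default_randomized_params <- function() {
  c("tsp53", "tsMdm2", "R0_p53", "Rp53_p53", "RMdm2_p53",
    "R0_Mdm2", "Rp53_Mdm2", "kdIAP", "R_drug_effect")
}

#' Heterogeneity specification for a virtual-cell population
#'
#' Cell-to-cell variability is modelled by scaling each named parameter,
#' independently per cell and per parameter, by a uniform factor covering
#' 70--120% of its basal value (the published noise level).
#'
#' @param n_cells population size.
#' @param seed RNG seed; each cell draws from its own L'Ecuyer-CMRG
#'   substream, so cell `i`'s parameters depend only on `(seed, i)`.
#' @param randomized_params names of the parameters to scale.
#' @param low,high multiplicative range (fractions of basal).
#' @return An object of class `fk_hetero_spec`.
#' @export
heterogeneity_spec <- function(n_cells = 300, seed = 1,
                               randomized_params = default_randomized_params(),
                               low = 0.7, high = 1.2) {
  stopifnot(n_cells >= 1, low > 0, low <= high)
  structure(list(n_cells = as.integer(n_cells), seed = as.integer(seed),
                 randomized_params = randomized_params,
                 low = low, high = high),
            class = "fk_hetero_spec")
}

#' Sample a heterogeneous population of virtual cells
#'
#' Draws one parameter set per cell: every parameter named in the spec is
#' scaled by an independent `Uniform(low, high)` factor.  Draws for cell
#' `i` come from the `i`-th L'Ecuyer-CMRG substream seeded by `spec$seed`,
#' so they are reproducible and independent of population size and
#' execution order.  The caller's RNG state is left untouched.
#'
#' @param basal_params the basal [fk_params] shared by all cells.
#' @param spec an [heterogeneity_spec()].
#' @return A list of `fk_params`, one per cell, with a `scale_factors`
#'   attribute (cells x parameters matrix of the drawn factors).
#' @export
#' @examples
#' cells <- sample_population(fk_params(), heterogeneity_spec(n_cells = 3))
#' length(cells)
sample_population <- function(basal_params, spec) {
  unknown <- setdiff(spec$randomized_params, names(basal_params))
  if (length(unknown))
    stop("unknown randomized parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  k <- length(spec$randomized_params)
  fac <- matrix(NA_real_, spec$n_cells, k,
                dimnames = list(NULL, spec$randomized_params))
  stream <- .fk_seed_stream(spec$seed)
  for (i in seq_len(spec$n_cells)) {
    stream <- parallel::nextRNGStream(stream)
    fac[i, ] <- .fk_runif_stream(stream, k, spec$low, spec$high)
  }
  cells <- lapply(seq_len(spec$n_cells), function(i) {
    p <- basal_params
    for (nm in spec$randomized_params)
      p[[nm]] <- p[[nm]] * unname(fac[i, nm])
    p
  })
  attr(cells, "scale_factors") <- fac
  cells
}

## root of the L'Ecuyer-CMRG stream tree for a seed, without disturbing
## the global RNG state
.fk_seed_stream <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  globalenv()$.Random.seed
}

## draw k uniforms from a given CMRG stream state, restoring the caller RNG
.fk_runif_stream <- function(stream, k, low, high) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  assign(".Random.seed", stream, envir = globalenv())
  stats::runif(k, low, high)
}

#' Run a population under a treatment protocol
#'
#' Simulates every cell under the same protocol and aggregates the fate
#' records.  Cells are independent, so results do not depend on execution
#' order; per-cell integration failures are collected and reported without
#' aborting the population.
#'
#' @param cells list of [fk_params] from [sample_population()].
#' @param protocol an [fk_protocol].
#' @param death_threshold,activation_threshold fate thresholds, see
#'   [classify_fate()].
#' @param engine integration engine, see [simulate_cell()].
#' @return An `fk_population`: list with `fates` (one row per cell),
#'   `fraction_apoptotic`, `n_cells`, `protocol` and `failures`.
#' @export
run_population <- function(cells, protocol,
                           death_threshold = fk_profile()$death_threshold,
                           activation_threshold =
                             fk_profile()$activation_threshold,
                           engine = "compiled") {
  stopifnot(length(cells) >= 1)
  failures <- list()
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rec <- tryCatch(
      classify_fate(simulate_cell(cells[[i]], protocol, engine = engine),
                    death_threshold, activation_threshold),
      error = function(e) e)
    if (inherits(rec, "error")) {
      failures[[length(failures) + 1L]] <-
        list(cell = i, message = conditionMessage(rec))
      rows[[i]] <- data.frame(fate = NA_character_, death_time = NA_real_,
                              p53_peak = NA_real_,
                              p53_activation_time = NA_real_,
                              integrated_p53 = NA_real_)
    } else rows[[i]] <- as.data.frame(rec)
  }
  fates <- do.call(rbind, rows)
  fates <- cbind(cell_id = seq_along(cells), fates)
  ok <- !is.na(fates$fate)
  structure(list(
    fates = fates,
    fraction_apoptotic = mean(fates$fate[ok] == "apoptotic"),
    n_cells = length(cells),
    protocol = protocol,
    failures = failures), class = "fk_population")
}

#' @export
print.fk_population <- function(x, ...) {
  cat("<fk_population> ", x$n_cells, " cells at drug = ",
      x$protocol$drug, "\n", sep = "")
  cat(sprintf("  fraction apoptotic: %.3f\n", x$fraction_apoptotic))
  if (length(x$failures))
    cat("  integration failures:", length(x$failures), "\n")
  invisible(x)
}

## median that treats 'never activated' as later than any observed time
.fk_median_act <- function(t) stats::median(ifelse(is.na(t), Inf, t))

#' Evaluate the five hallmark features of fractional killing
#'
#' Given the same seeded population run at a low and a high drug dose,
#' checks the five population-level features that characterize fractional
#' killing: (F1) similar p53 peaks across fates (relative difference of
#' fate-class median peaks at most `peak_tol` of the pooled median);
#' (F2) dispersed p53 activation times (positive interquartile range);
#' (F3) apoptotic cells activate p53 earlier (median, never-activated
#' cells counted as late); (F4) survivors accumulate more integrated p53
#' (median); (F5) the apoptotic fraction strictly increases with dose.
#' F1--F4 are evaluated at the low dose, the dose of primary interest.
#'
#' @param result_low_drug,result_high_drug `fk_population` results for the
#'   same seeded cells at the two doses.
#' @param peak_tol relative tolerance for F1.
#' @return An `fk_features` data.frame: one row per feature with `feature`,
#'   `pass` and a computed `statistic`; features that cannot be evaluated
#'   (an empty fate class) have `pass = NA`.
#' @export
feature_report <- function(result_low_drug, result_high_drug,
                           peak_tol = 0.2) {
  f <- result_low_drug$fates
  f <- f[!is.na(f$fate), ]
  ap <- f[f$fate == "apoptotic", ]
  sv <- f[f$fate == "surviving", ]
  both <- nrow(ap) > 0 && nrow(sv) > 0

  if (both) {
    pk <- abs(stats::median(ap$p53_peak) - stats::median(sv$p53_peak)) /
      stats::median(f$p53_peak)
    f1 <- pk <= peak_tol
    f3stat <- .fk_median_act(ap$p53_activation_time) -
      .fk_median_act(sv$p53_activation_time)
    f3 <- f3stat < 0
    f4stat <- stats::median(sv$integrated_p53) -
      stats::median(ap$integrated_p53)
    f4 <- f4stat > 0
  } else {
    pk <- f3stat <- f4stat <- NA_real_
    f1 <- f3 <- f4 <- NA
  }
  act <- f$p53_activation_time[!is.na(f$p53_activation_time)]
  f2stat <- if (length(act) >= 2) stats::IQR(act) else NA_real_
  f2 <- isTRUE(f2stat > 0)
  f5stat <- result_high_drug$fraction_apoptotic -
    result_low_drug$fraction_apoptotic
  f5 <- f5stat > 0

  structure(data.frame(
    feature = c("similar_p53_peaks", "dispersed_activation_times",
                "early_activation_dies", "survivors_higher_integrated_p53",
                "higher_dose_more_apoptosis"),
    pass = c(f1, f2, f3, f4, f5),
    statistic = c(pk, f2stat, f3stat, f4stat, f5stat),
    stringsAsFactors = FALSE), class = c("fk_features", "data.frame"))
}

#' @export
print.fk_features <- function(x, ...) {
  cat("<fk_features> hallmark features of fractional killing\n")
  df <- as.data.frame(x)
  df$statistic <- signif(df$statistic, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Audit the drug-coupling sign convention
#'
#' Runs the same seeded population in both drug-coupling modes and reports
#' whether the dose-response feature (more apoptosis at the higher dose)
#' holds in each.  In mode `"literal"` the drug term raises Mdm2 production
#' so p53 is never released and the dose response is lost; the default
#' `"repressive"` mode (drug relieves Mdm2-mediated repression) restores
#' it.  See the methods vignette for the rationale.
#'
#' @param basal_params basal [fk_params]; the mode field is overridden.
#' @param spec an [heterogeneity_spec()].
#' @param drug_low,drug_high the two doses compared.
#' @param ... passed to [run_population()].
#' @return A data.frame with one row per mode: apoptotic fractions at both
#'   doses and whether the dose response holds.
#' @export
mode_audit <- function(basal_params = fk_params(),
                       spec = heterogeneity_spec(n_cells = 100),
                       drug_low = 0.45, drug_high = 1, ...) {
  out <- lapply(c("repressive", "literal"), function(mode) {
    p <- basal_params; p$drug_coupling_mode <- mode
    cells <- sample_population(p, spec)
    lo <- run_population(cells, fk_protocol(drug = drug_low), ...)
    hi <- run_population(cells, fk_protocol(drug = drug_high), ...)
    data.frame(mode = mode,
               fraction_low = lo$fraction_apoptotic,
               fraction_high = hi$fraction_apoptotic,
               dose_response = hi$fraction_apoptotic > lo$fraction_apoptotic)
  })
  do.call(rbind, out)
}
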