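## Intervention assessment: the three dynamical categories ---------------------
##
## A strategy against fractional killing can act by reshaping the threshold
## curves in the (p53, cIAP) control plane (bifurcation geometry, BG), by
## redirecting where cells travel in that plane (cellular trajectory, CT),
## or both (AB).  Geometry is a property of the frozen apoptosis subsystem,
## so only interventions touching its structural parameters (BclT, kaC8)
## move the curves; CIAP- and Nutlin-type interventions act purely on the
## trajectories because cIAP is itself one of the control axes.

#' Assess an intervention against its baseline
#'
#' Quantifies the two dynamical signatures of an intervention:
#' `geometry_delta`, the largest displacement of the activation-threshold
#' curve over the cIAP grid between the intervention's and the baseline's
#' structural parameters; and `trajectory_delta`, the largest max-norm
#' distance between the `(p53(t), cIAP(t))` paths of matched cells under
#' the two protocols.  The category is `"BG"` if only the geometry moved
#' beyond tolerance, `"CT"` if only the trajectories, `"AB"` if both, and
#' `"none"` if neither.  Matched seeded populations give the apoptotic
#' fraction under each arm.
#'
#' @param basal_params basal [fk_params].
#' @param protocol_baseline,protocol_intervention the two arms; they should
#'   differ only in intervention fields.
#' @param spec an [heterogeneity_spec()]; the same seeded cells are used in
#'   both arms.
#' @param tol_geometry,tol_trajectory category tolerances on the p53 scale.
#' @param ciap_grid grid for the threshold curves.
#' @param n_trajectory_cells number of matched cells used for the
#'   trajectory distance (the first cells of the population).
#' @param death_threshold,activation_threshold fate thresholds.
#' @return An `fk_strategy`: list with the deltas, `category`,
#'   `kill_fraction_baseline`, `kill_fraction_intervention` and the two
#'   threshold-curve sets.
#' @export
assess_strategy <- function(basal_params, protocol_baseline,
                            protocol_intervention,
                            spec = heterogeneity_spec(n_cells = 100),
                            tol_geometry = 0.02, tol_trajectory = 0.02,
                            ciap_grid = seq(0, 1, by = 0.1),
                            n_trajectory_cells = 10,
                            death_threshold = fk_profile()$death_threshold,
                            activation_threshold =
                              fk_profile()$activation_threshold) {
  ## geometry under each arm's structural parameters
  pb <- apply_protocol(basal_params, protocol_baseline, 0)$params
  p_int <- apply_protocol(basal_params, protocol_intervention, 0)$params
  thb <- two_param_thresholds(pb, ciap_grid = ciap_grid)
  thi <- if (identical(pb, p_int)) thb else
    two_param_thresholds(p_int, ciap_grid = ciap_grid)
  geometry_delta <- max(abs(thi$curves$theta_act - thb$curves$theta_act),
                        na.rm = TRUE)

  ## matched-cell trajectories under each protocol
  cells <- sample_population(basal_params, spec)
  m <- min(n_trajectory_cells, length(cells))
  trajectory_delta <- 0
  for (i in seq_len(m)) {
    t1 <- simulate_cell(cells[[i]], protocol_baseline)
    t2 <- simulate_cell(cells[[i]], protocol_intervention)
    n <- min(nrow(t1), nrow(t2))
    d <- pmax(abs(t1$p53[seq_len(n)] - t2$p53[seq_len(n)]),
              abs(t1$cIAP[seq_len(n)] - t2$cIAP[seq_len(n)]))
    trajectory_delta <- max(trajectory_delta, d)
  }

  bg <- geometry_delta >= tol_geometry
  ct <- trajectory_delta >= tol_trajectory
  category <- if (bg && ct) "AB" else if (bg) "BG" else if (ct) "CT"
    else "none"

  base <- run_population(cells, protocol_baseline,
                         death_threshold, activation_threshold)
  intv <- run_population(cells, protocol_intervention,
                         death_threshold, activation_threshold)
  structure(list(
    geometry_delta = geometry_delta, trajectory_delta = trajectory_delta,
    category = category,
    kill_fraction_baseline = base$fraction_apoptotic,
    kill_fraction_intervention = intv$fraction_apoptotic,
    thresholds_baseline = thb, thresholds_intervention = thi),
    class = "fk_strategy")
}

#' @export
print.fk_strategy <- function(x, ...) {
  cat("<fk_strategy> category:", x$category, "\n")
  cat(sprintf("  geometry_delta = %.4f  trajectory_delta = %.4f\n",
              x$geometry_delta, x$trajectory_delta))
  cat(sprintf("  kill fraction: %.3f (baseline) -> %.3f (intervention)\n",
              x$kill_fraction_baseline, x$kill_fraction_intervention))
  invisible(x)
}

#' Screen the canonical anti-fractional-killing strategies
#'
#' Assesses the six canonical strategies against a common low-dose
#' cisplatin baseline and assigns each to one of the three dynamical
#' categories: raising the drug concentration, CIAP inhibition and Nutlin-3
#' addition act on cellular trajectories (CT); BCL inhibition and Caspase8
#' activation reshape the bifurcation geometry (BG); co-inhibition of CIAP
#' and BCL alters both (AB).
#'
#' @param basal_params basal [fk_params].
#' @param spec an [heterogeneity_spec()]; the same seeded population is
#'   reused across strategies.
#' @param drug_low,drug_high baseline and raised cisplatin levels.
#' @param ciap_inhibition,bcl_inhibition,casp8_activation intervention
#'   multipliers (see [fk_protocol()]).
#' @param nutlin_time_early time of early Nutlin-3 addition.
#' @param nutlin_strength additive Mdm2 drug-term argument for Nutlin-3.
#' @param ... passed to [assess_strategy()].
#' @return An `fk_strategy_table` data.frame: one row per strategy with the
#'   deltas, kill fractions, assigned and expected category and a match
#'   flag.
#' @export
screen_strategies <- function(basal_params = fk_params(),
                             spec = heterogeneity_spec(n_cells = 100),
                             drug_low = 0.45, drug_high = 1,
                             ciap_inhibition = 0, bcl_inhibition = 0.9,
                             casp8_activation = 1.2,
                             nutlin_time_early = 5, nutlin_strength = 1,
                             ...) {
  base <- fk_protocol(drug = drug_low)
  defs <- list(
    increase_drug = list(fk_protocol(drug = drug_high), "CT"),
    ciap_inhibition = list(fk_protocol(drug = drug_low,
                                       ciap_inhibition = ciap_inhibition),
                           "CT"),
    bcl_inhibition = list(fk_protocol(drug = drug_low,
                                      bcl_inhibition = bcl_inhibition),
                          "BG"),
    nutlin = list(fk_protocol(drug = drug_low,
                              nutlin_time = nutlin_time_early,
                              nutlin_strength = nutlin_strength), "CT"),
    ciap_bcl_coinhibition = list(
      fk_protocol(drug = drug_low, ciap_inhibition = ciap_inhibition,
                  bcl_inhibition = bcl_inhibition), "AB"),
    casp8_activation = list(fk_protocol(drug = drug_low,
                                        casp8_activation = casp8_activation),
                            "BG"))
  rows <- lapply(names(defs), function(nm) {
    a <- assess_strategy(basal_params, base, defs[[nm]][[1L]], spec = spec,
                         ...)
    data.frame(strategy = nm,
               kill_fraction_baseline = a$kill_fraction_baseline,
               kill_fraction_intervention = a$kill_fraction_intervention,
               geometry_delta = a$geometry_delta,
               trajectory_delta = a$trajectory_delta,
               category = a$category, expected = defs[[nm]][[2L]],
               match = a$category == defs[[nm]][[2L]],
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("fk_strategy_table", "data.frame"))
}

#' @export
print.fk_strategy_table <- function(x, ...) {
  cat("<fk_strategy_table> dynamical categories of intervention",
      "strategies\n")
  df <- as.data.frame(x)
  for (nm in c("kill_fraction_baseline", "kill_fraction_intervention",
               "geometry_delta", "trajectory_delta"))
    df[[nm]] <- signif(df[[nm]], 3)
  print(df, row.names = FALSE)
  invisible(x)
}
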