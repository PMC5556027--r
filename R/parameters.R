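## Model parameterization -----------------------------------------------------

## Fixed order of the numeric parameter block passed to the compiled
## right-hand side (src/frackill.c).  The last two slots are the
## protocol-resolved drug inputs, appended by simulate_cell().
.fk_par_order <- c(
  "kf1", "kf2", "kb", "kasXC", "kdsXC", "kasHC", "kdsHC",
  "ksBh3", "ks2", "ks3", "kdBh3",
  "kaC8", "kiC8", "ki2",
  "ksIAP", "ksIAP2", "kdIAP", "J", "n",
  "R0_p53", "Rp53_p53", "RMdm2_p53", "R0_Mdm2", "Rp53_Mdm2",
  "sigma", "sigma2", "sigma_drug", "tsp53", "tsMdm2", "R_drug_effect",
  "BaxT", "BclT"
)

#' Model parameters for the fractional-killing model
#'
#' Constructs the full parameter set of the hybrid model: mass-action rate
#' constants of the apoptosis initiation module (BAX/BCL/BH3 dimerization,
#' BH3 synthesis, Caspase8 turnover, drug-induced CIAP accumulation) and the
#' generic-formula coefficients of the p53/Mdm2 module (regulatory weights,
#' sigmoid steepnesses, timescales).  One virtual cell is one instance.
#'
#' Defaults are the basal published rate constants together with three
#' calibrated values that the published parameter table leaves open: the
#' conserved totals `BaxT` and `BclT` and the steepness `sigma_drug` of the
#' drug term in the Mdm2 equation.  The shipped defaults are the ones
#' selected by [calibrate_model()] (profile `"table1_basal"`); see the
#' methods vignette for the calibration procedure.
#'
#' @param ... named parameter overrides, e.g. `fk_params(BclT = 0.8)`.
#' @param drug_coupling_mode either `"repressive"` (default; the drug term
#'   in the Mdm2 target decreases with drug so that cisplatin relieves the
#'   Mdm2-mediated repression of p53) or `"literal"` (the term increases
#'   with drug, the sign convention printed in the source model table;
#'   retained for fidelity audits, see [mode_audit()]).
#' @param clamp_f logical; clamp the Mdm2 sigmoid-sum target to `[0, 1]`
#'   before use (default `TRUE`), preserving the generic-formula semantics
#'   of a steady-state activity ratio.
#'
#' @return An object of class `fk_params`: a named list of numeric rate
#'   constants plus the two mode switches.
#' @seealso [initial_state()], [simulate_cell()], [calibrate_model()]
#' @export
#' @examples
#' p <- fk_params()
#' p$kf2
#' fk_params(BclT = 0.8)$BclT
fk_params <- function(..., drug_coupling_mode = NULL, clamp_f = NULL) {
  p <- .fk_basal_params()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(over)] <- over
  }
  if (!is.null(drug_coupling_mode)) p$drug_coupling_mode <- drug_coupling_mode
  if (!is.null(clamp_f)) p$clamp_f <- clamp_f
  validate_params(p)
}

## Basal parameter values.  Rate constants and regulatory weights are the
## published Table values; BaxT, BclT and sigma_drug are calibrated (see
## calibrate_model() and the methods vignette).
.fk_basal_params <- function() {
  structure(list(
    kf1 = 1, kf2 = 300, kb = 2,
    kasXC = 9000, kdsXC = 0.05,
    kasHC = 1000, kdsHC = 0.01,
    ksBh3 = 0.1, ks2 = 0.2, ks3 = 1, kdBh3 = 1,
    kaC8 = 0.03, kiC8 = 0.1, ki2 = 0.15,
    ksIAP = 0.00004, ksIAP2 = 0.016, kdIAP = 0.004, J = 0.1, n = 10,
    R0_p53 = -0.4, Rp53_p53 = 2, RMdm2_p53 = -1,
    R0_Mdm2 = -0.55, Rp53_Mdm2 = 1,
    sigma = 5, sigma2 = 10, sigma_drug = 25,
    tsp53 = 0.6, tsMdm2 = 0.3,
    R_drug_effect = 0.33,
    BaxT = 0.5, BclT = 0.725,
    drug_coupling_mode = "repressive", clamp_f = TRUE
  ), class = "fk_params")
}

#' Validate a parameter set
#'
#' Checks the invariants of the model parameterization: non-negative rate
#' constants, positive totals, steepnesses and Hill constants, and a valid
#' drug-coupling mode.
#'
#' @param p an `fk_params` object or a named list with the same fields.
#' @return `p`, invisibly classed as `fk_params`, if valid; otherwise an
#'   error describing the offending field.
#' @export
validate_params <- function(p) {
  need <- c(.fk_par_order[.fk_par_order != "sigma_drug"], "sigma_drug",
            "drug_coupling_mode", "clamp_f")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  rates <- c("kf1", "kf2", "kb", "kasXC", "kdsXC", "kasHC", "kdsHC",
             "ksBh3", "ks2", "ks3", "kdBh3", "kaC8", "kiC8", "ki2",
             "ksIAP", "ksIAP2", "kdIAP")
  for (nm in rates)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("rate constant ", nm, " must be finite and >= 0", call. = FALSE)
  for (nm in c("J", "n", "sigma", "sigma2", "sigma_drug",
               "tsp53", "tsMdm2", "BaxT"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(nm, " must be finite and > 0", call. = FALSE)
  if (!is.finite(p$BclT) || p$BclT <= 0)
    stop("BclT must be finite and > 0", call. = FALSE)
  if (!p$drug_coupling_mode %in% c("literal", "repressive"))
    stop("drug_coupling_mode must be \"literal\" or \"repressive\"",
         call. = FALSE)
  if (!is.logical(p$clamp_f) || length(p$clamp_f) != 1L || is.na(p$clamp_f))
    stop("clamp_f must be TRUE or FALSE", call. = FALSE)
  class(p) <- "fk_params"
  invisible(p)
}

#' @export
print.fk_params <- function(x, ...) {
  cat("<fk_params> hybrid fractional-killing model parameters\n")
  num <- unlist(x[.fk_par_order])
  cat(paste0(format(names(num), width = 14), format(num)), sep = "\n")
  cat("drug_coupling_mode:", x$drug_coupling_mode,
      " clamp_f:", x$clamp_f, "\n")
  invisible(x)
}

## numeric parameter block (without drug inputs), in compiled-code order
.fk_par_vector <- function(p) {
  v <- vapply(.fk_par_order, function(nm) as.numeric(p[[nm]]), 0)
  c(v, mode_literal = as.numeric(p$drug_coupling_mode == "literal"),
    clamp_f = as.numeric(isTRUE(p$clamp_f)))
}

#' Load or store a named parameter profile
#'
#' Profiles are flat key-value YAML files.  The packaged profile
#' `"table1_basal"` holds the basal published rate constants together with
#' the calibrated totals, drug-term steepness and fate thresholds selected
#' by [calibrate_model()].
#'
#' @param name profile name (packaged) or a path to a YAML file.
#' @return A list with elements `params` (an [fk_params] object),
#'   `death_threshold` (free BAXm level called as apoptosis) and
#'   `activation_threshold` (p53 level called as activation).
#' @export
#' @examples
#' prof <- fk_profile("table1_basal")
#' prof$death_threshold
fk_profile <- function(name = "table1_basal") {
  if (!is.null(.fk_profile_cache[[name]]))
    return(.fk_profile_cache[[name]])
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".yaml"), package = "frackill")
  if (!nzchar(path) || !file.exists(path))
    stop("no such profile: ", name, call. = FALSE)
  y <- yaml::read_yaml(path)
  ## YAML 1.1 parses a bare key `n` (the Hill exponent) as a boolean
  names(y)[names(y) == "FALSE"] <- "n"
  pars <- y[setdiff(names(y), c("death_threshold", "activation_threshold",
                                "profile", "calibration"))]
  p <- do.call(fk_params, pars)
  prof <- list(params = p,
               death_threshold = as.numeric(y$death_threshold),
               activation_threshold = as.numeric(y$activation_threshold))
  if (grepl("^[A-Za-z0-9_]+$", name)) .fk_profile_cache[[name]] <- prof
  prof
}

.fk_profile_cache <- new.env(parent = emptyenv())

#' @rdname fk_profile
#' @param profile a list as returned by [fk_profile()] or built from
#'   [calibrate_model()].
#' @param path file to write.
#' @export
write_profile <- function(profile, path) {
  p <- profile$params
  y <- c(lapply(p[.fk_par_order], as.numeric),
         list(drug_coupling_mode = p$drug_coupling_mode,
              clamp_f = isTRUE(p$clamp_f),
              death_threshold = as.numeric(profile$death_threshold),
              activation_threshold = as.numeric(profile$activation_threshold)))
  yaml::write_yaml(y, path, precision = 12L)
  invisible(path)
}
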