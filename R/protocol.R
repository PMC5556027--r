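## Treatment protocols ---------------------------------------------------------

#' Treatment protocol
#'
#' Describes the treatment applied to a cell: a constant cisplatin level
#' from time 0, an optional Nutlin-3 addition (an Mdm2 inhibitor, modelled
#' as an additive argument to the Mdm2 drug term from `nutlin_time` on),
#' and intervention multipliers: `ciap_inhibition` scales the drug-induced
#' CIAP synthesis rate `ksIAP2` (0 = complete inhibition), `bcl_inhibition`
#' scales the conserved BCL total (reduced availability), and
#' `casp8_activation` scales the Caspase8 activation rate `kaC8`
#' (>= 1, e.g. TRAIL-type activators).
#'
#' @param drug constant cisplatin level from `t = 0` (e.g. 0.45 or 1).
#' @param nutlin_time time of Nutlin-3 addition, or `NULL` for none.
#' @param nutlin_strength additive argument to the Mdm2 drug term after
#'   `nutlin_time`.
#' @param ciap_inhibition multiplier on `ksIAP2`, in `[0, 1]`.
#' @param bcl_inhibition multiplier on `BclT`, in `[0, 1]`.
#' @param casp8_activation multiplier on `kaC8`, `>= 1`.
#' @param t_end simulation horizon (time units).
#' @return An object of class `fk_protocol`.
#' @export
#' @examples
#' fk_protocol(drug = 0.45)
#' fk_protocol(drug = 0.45, nutlin_time = 5, nutlin_strength = 1)
fk_protocol <- function(drug = 0, nutlin_time = NULL, nutlin_strength = 1,
                        ciap_inhibition = 1, bcl_inhibition = 1,
                        casp8_activation = 1, t_end = 60) {
  stopifnot(drug >= 0, ciap_inhibition >= 0, bcl_inhibition >= 0,
            casp8_activation >= 0, t_end >= 0)
  if (!is.null(nutlin_time)) {
    stopifnot(nutlin_time >= 0)
    if (nutlin_time >= t_end && t_end > 0)
      stop("nutlin_time must be < t_end", call. = FALSE)
  }
  structure(list(drug = drug, nutlin_time = nutlin_time,
                 nutlin_strength = nutlin_strength,
                 ciap_inhibition = ciap_inhibition,
                 bcl_inhibition = bcl_inhibition,
                 casp8_activation = casp8_activation, t_end = t_end),
            class = "fk_protocol")
}

#' @export
print.fk_protocol <- function(x, ...) {
  cat("<fk_protocol> drug =", x$drug, " t_end =", x$t_end, "\n")
  if (!is.null(x$nutlin_time))
    cat("  Nutlin-3: +", x$nutlin_strength, "on Mdm2 drug term from t =",
        x$nutlin_time, "\n")
  if (x$ciap_inhibition != 1)
    cat("  CIAP inhibition: ksIAP2 x", x$ciap_inhibition, "\n")
  if (x$bcl_inhibition != 1)
    cat("  BCL inhibition: BclT x", x$bcl_inhibition, "\n")
  if (x$casp8_activation != 1)
    cat("  Caspase8 activation: kaC8 x", x$casp8_activation, "\n")
  invisible(x)
}

#' Resolve a protocol at a time point
#'
#' Applies the structural multipliers of a protocol to the parameter set
#' (`ksIAP2 * ciap_inhibition`, `BclT * bcl_inhibition`,
#' `kaC8 * casp8_activation`) and resolves the two drug inputs at time
#' `t`: the CIAP equation sees the cisplatin level only, while the Mdm2
#' drug term sees cisplatin plus `nutlin_strength` once `t >= nutlin_time`.
#' Nutlin-3 stabilizes p53 without creating DNA adducts, so it never
#' enters the CIAP equation.
#'
#' @param params an [fk_params] object.
#' @param protocol an [fk_protocol] object.
#' @param t time at which to resolve the inputs.
#' @return A list with `params` (modified), `drug_ciap` and `drug_mdm2`.
#' @export
apply_protocol <- function(params, protocol, t = 0) {
  stopifnot(t >= 0, t <= protocol$t_end || protocol$t_end == 0)
  p <- params
  p$ksIAP2 <- p$ksIAP2 * protocol$ciap_inhibition
  p$BclT <- p$BclT * protocol$bcl_inhibition
  p$kaC8 <- p$kaC8 * protocol$casp8_activation
  nut <- if (!is.null(protocol$nutlin_time) && t >= protocol$nutlin_time)
    protocol$nutlin_strength else 0
  list(params = p, drug_ciap = protocol$drug,
       drug_mdm2 = protocol$drug + nut)
}
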