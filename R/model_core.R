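## Model core: state, conservation relations, right-hand sides ----------------

.fk_state_names <- c("BaxmT", "BaxmBcl", "Bh3Bcl", "Bh3T",
                     "Caspase8", "cIAP", "p53", "Mdm2")

#' Cell state vector
#'
#' Builds a named state vector of the eight dynamic variables: total
#' mitochondrial BAX (`BaxmT`), the BAXm:BCL and BH3:BCL dimers, total BH3,
#' active Caspase8, CIAP, and the p53 and Mdm2 activity ratios.
#'
#' @param BaxmT,BaxmBcl,Bh3Bcl,Bh3T,Caspase8,cIAP,p53,Mdm2 numeric scalars.
#' @return A named numeric vector in canonical state order.
#' @export
fk_state <- function(BaxmT = 0, BaxmBcl = 0, Bh3Bcl = 0, Bh3T = 0,
                     Caspase8 = 0, cIAP = 0, p53 = 0, Mdm2 = 0) {
  c(BaxmT = BaxmT, BaxmBcl = BaxmBcl, Bh3Bcl = Bh3Bcl, Bh3T = Bh3T,
    Caspase8 = Caspase8, cIAP = cIAP, p53 = p53, Mdm2 = Mdm2)
}

#' Initial conditions of a resting cell
#'
#' The published initial conditions set `BaxmT = 0.3`, `BaxmBcl = 0.33`,
#' `Bh3Bcl = 0.16`, `p53 = 0`, `Mdm2 = 1`, `cIAP = 0`.  As printed the
#' dimer exceeds its own total (`BaxmBcl > BaxmT`), violating the BAXm
#' conservation relation, so the dimer is projected to consistency
#' (`BaxmBcl <- min(BaxmBcl, BaxmT)`) with a warning.  `Bh3T` and
#' `Caspase8`, which the published table leaves unset, start at the values
#' consistent with a resting cell: `Bh3T` equal to the bound pool (no free
#' BH3) and Caspase8 at its drug-free steady state `kaC8/kiC8`.
#'
#' @param params an [fk_params] object.
#' @param quiet suppress the projection warning.
#' @return A named state vector, consistent with the conservation relations.
#' @export
initial_state <- function(params = fk_params(), quiet = FALSE) {
  BaxmT <- 0.3; BaxmBcl <- 0.33; Bh3Bcl <- 0.16
  if (BaxmBcl > BaxmT) {
    if (!quiet)
      warning("initial BaxmBcl (", BaxmBcl, ") exceeds BaxmT (", BaxmT,
              "); projected to BaxmBcl = BaxmT", call. = FALSE)
    BaxmBcl <- BaxmT
  }
  fk_state(BaxmT = BaxmT, BaxmBcl = BaxmBcl, Bh3Bcl = Bh3Bcl,
           Bh3T = Bh3Bcl,                       # no free BH3 at rest
           Caspase8 = params$kaC8 / params$kiC8, # drug-free steady state
           cIAP = 0, p53 = 0, Mdm2 = 1)
}

#' Free species by conservation
#'
#' Derives the free concentrations from the totals: cytoplasmic BAX
#' `Bax = BaxT - BaxmT`, free mitochondrial BAXm `Baxm = BaxmT - BaxmBcl`,
#' free BH3 `Bh3 = Bh3T - Bh3Bcl`, and free BCL
#' `Bcl = BclT - BaxmBcl - Bh3Bcl` (total BCL is conserved; both dimers
#' draw on the same pool).
#'
#' @param state named state vector (see [fk_state()]).
#' @param params an [fk_params] object.
#' @param tol negative excursions larger than this signal a conservation
#'   violation.
#' @return Named numeric vector `c(Bax, Baxm, Bh3, Bcl)`.
#' @export
#' @examples
#' s <- fk_state(BaxmT = 0.3, BaxmBcl = 0.2, Bh3T = 0.6, Bh3Bcl = 0.16)
#' derive_free_species(s, fk_params(BaxT = 1, BclT = 0.6))
derive_free_species <- function(state, params, tol = 1e-6) {
  if (!all(is.finite(state)))
    stop("state contains non-finite values", call. = FALSE)
  free <- c(Bax  = params$BaxT - state[["BaxmT"]],
            Baxm = state[["BaxmT"]] - state[["BaxmBcl"]],
            Bh3  = state[["Bh3T"]] - state[["Bh3Bcl"]],
            Bcl  = params$BclT - state[["BaxmBcl"]] - state[["Bh3Bcl"]])
  if (any(free < -tol))
    stop("conservation violated: free ",
         paste(names(free)[free < -tol], collapse = ", "),
         " negative beyond tolerance", call. = FALSE)
  free
}

#' Net regulatory effect
#'
#' The affine regulatory sum of the generic formula,
#' `W = R0 + sum_j R_j * X_j`; a coefficient is negative where component j
#' inhibits the target, positive where it activates it.
#'
#' @param weights numeric vector `c(R0, R_1, ..., R_k)`.
#' @param levels numeric vector of the k component levels.
#' @return The scalar net effect `W`.
#' @export
#' @examples
#' regulatory_input(c(-0.4, 2, -1), c(0, 1))  # p53 weights at rest: -1.4
regulatory_input <- function(weights, levels) {
  if (length(weights) != length(levels) + 1L)
    stop("need one weight per level plus the background weight",
         call. = FALSE)
  weights[1L] + sum(weights[-1L] * levels)
}

#' Sigmoidal steady-state fraction
#'
#' The generic-formula response `F = 1/(1 + exp(-steepness * W))`, a value
#' in (0, 1) interpreted as the ratio between the steady state of a
#' component and its maximum.  Overflow-safe for large `|steepness * W|`.
#'
#' @param W net regulatory effect (see [regulatory_input()]).
#' @param steepness positive sigmoid steepness.
#' @return Value(s) in (0, 1); vectorized over `W`.
#' @export
#' @examples
#' sigmoid_fraction(0, 5)      # 0.5
#' sigmoid_fraction(-1.4, 5)   # ~9.1e-4
sigmoid_fraction <- function(W, steepness) {
  if (any(steepness <= 0)) stop("steepness must be > 0", call. = FALSE)
  x <- steepness * W
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

## drug term of the Mdm2 target; sign set by the coupling mode
.fk_drug_term <- function(drug, params) {
  s <- if (identical(params$drug_coupling_mode, "literal")) 1 else -1
  sigmoid_fraction(s * params$R_drug_effect * drug, params$sigma_drug)
}

#' p53/Mdm2 module right-hand side
#'
#' Generic-formula dynamics of the p53 activity ratio and its inhibitor
#' Mdm2: `dp53/dt = tsp53 * (fp53 - p53)` with
#' `fp53 = sigmoid(sigma * (R0_p53 + Rp53_p53*p53 + RMdm2_p53*Mdm2))`, and
#' `dMdm2/dt = tsMdm2 * (fMdm2 - Mdm2)` where `fMdm2` is the sum of the
#' p53-driven sigmoid and a drug term.  In mode `"repressive"` the drug
#' term `1/(1 + exp(sigma_drug * R_drug_effect * drug))` falls from 0.5
#' towards 0 with drug, so cisplatin lowers Mdm2 production and releases
#' p53; in mode `"literal"` the exponent sign is flipped and the term rises
#' with drug.  With `clamp_f` the summed target is clamped to `[0, 1]`.
#'
#' @param p53,Mdm2 current activity ratios.
#' @param drug effective drug level entering the Mdm2 equation.
#' @param params an [fk_params] object.
#' @return Named vector `c(p53 = dp53/dt, Mdm2 = dMdm2/dt)`.
#' @export
p53_module_rhs <- function(p53, Mdm2, drug, params) {
  stopifnot(drug >= 0)
  wp53 <- regulatory_input(
    c(params$R0_p53, params$Rp53_p53, params$RMdm2_p53), c(p53, Mdm2))
  wMdm2 <- regulatory_input(c(params$R0_Mdm2, params$Rp53_Mdm2), p53)
  fp53 <- sigmoid_fraction(wp53, params$sigma)
  fMdm2 <- sigmoid_fraction(wMdm2, params$sigma2) + .fk_drug_term(drug, params)
  if (isTRUE(params$clamp_f)) fMdm2 <- min(max(fMdm2, 0), 1)
  c(p53 = params$tsp53 * (fp53 - p53),
    Mdm2 = params$tsMdm2 * (fMdm2 - Mdm2))
}

#' Apoptosis initiation module right-hand side
#'
#' Mass-action dynamics of the BAX/BCL/BH3 switch under a frozen p53 input:
#' BH3-catalysed BAX activation and translocation
#' (`dBaxmT/dt = (kf1 + kf2*Bh3)*Bax - kb*BaxmT`), reversible
#' sequestration of BAXm and BH3 by BCL (first-order dimer dissociation),
#' p53- and Caspase8-driven BH3 synthesis, and CIAP-dependent Caspase8
#' inactivation.  BAXm is inactivated from the monomer and from the
#' BAXm:BCL dimer (`-kb*BaxmBcl`), the path responsible for hysteresis.
#'
#' @param state named state vector; `cIAP` is read as a frozen input here.
#' @param p53 frozen p53 control input.
#' @param params an [fk_params] object.
#' @param free_tol conservation tolerance passed to
#'   [derive_free_species()]; the integrator wrapper disables the check
#'   (`Inf`) because the printed equations degrade total BH3 without
#'   degrading the BH3:BCL dimer, so free BH3 transiently undershoots zero
#'   by ~1e-4 around the apoptotic switch.
#' @return Named derivative vector of
#'   `c(BaxmT, BaxmBcl, Bh3Bcl, Bh3T, Caspase8)`.
#' @export
apoptosis_module_rhs <- function(state, p53, params, free_tol = 1e-6) {
  f <- derive_free_species(state, params, tol = free_tol)
  c(BaxmT = (params$kf1 + params$kf2 * f[["Bh3"]]) * f[["Bax"]] -
      params$kb * state[["BaxmT"]],
    BaxmBcl = params$kasXC * f[["Baxm"]] * f[["Bcl"]] -
      params$kdsXC * state[["BaxmBcl"]] - params$kb * state[["BaxmBcl"]],
    Bh3Bcl = params$kasHC * f[["Bh3"]] * f[["Bcl"]] -
      params$kdsHC * state[["Bh3Bcl"]],
    Bh3T = params$ksBh3 + params$ks2 * p53 +
      params$ks3 * state[["Caspase8"]] - params$kdBh3 * state[["Bh3T"]],
    Caspase8 = params$kaC8 -
      (params$kiC8 + params$ki2 * state[["cIAP"]]) * state[["Caspase8"]])
}

#' CIAP right-hand side
#'
#' Drug-induced CIAP accumulation with basal turnover:
#' `dcIAP/dt = ksIAP + ksIAP2 * drug^n/(drug^n + J^n) - kdIAP * cIAP`.
#' The Hill term lies in `[0, 1)` and is monotone increasing in drug.
#'
#' @param cIAP current CIAP level.
#' @param drug drug level entering the CIAP equation.
#' @param params an [fk_params] object.
#' @return `dcIAP/dt`, a scalar.
#' @export
ciap_rhs <- function(cIAP, drug, params) {
  stopifnot(drug >= 0)
  hill <- if (drug > 0)
    drug^params$n / (drug^params$n + params$J^params$n) else 0
  params$ksIAP + params$ksIAP2 * hill - params$kdIAP * cIAP
}

#' Full model right-hand side
#'
#' Assembles the module derivatives into the complete 8-variable system.
#' The two drug inputs are protocol-resolved: `drug_ciap` drives the CIAP
#' equation (cisplatin only) and `drug_mdm2` drives the Mdm2 drug term
#' (cisplatin plus, after the addition time, Nutlin-3; see
#' [apply_protocol()]).  Pure and deterministic.
#'
#' @param state named state vector.
#' @param params an [fk_params] object.
#' @param drug_ciap,drug_mdm2 resolved drug inputs (both `>= 0`).
#' @param free_tol conservation tolerance, see [apoptosis_module_rhs()].
#' @return Named derivative vector in canonical state order.
#' @export
#' @examples
#' full_rhs(initial_state(quiet = TRUE), fk_params(), 1, 1)
full_rhs <- function(state, params, drug_ciap, drug_mdm2, free_tol = 1e-6) {
  apo <- apoptosis_module_rhs(state, state[["p53"]], params, free_tol)
  pm  <- p53_module_rhs(state[["p53"]], state[["Mdm2"]], drug_mdm2, params)
  c(apo[c("BaxmT", "BaxmBcl", "Bh3Bcl", "Bh3T", "Caspase8")],
    cIAP = ciap_rhs(state[["cIAP"]], drug_ciap, params),
    p53 = pm[["p53"]], Mdm2 = pm[["Mdm2"]])
}
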