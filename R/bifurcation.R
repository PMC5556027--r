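## Equilibria, folds and threshold curves of the apoptosis subsystem -----------
##
## The apoptosis initiation module is fast relative to p53 accumulation and
## CIAP build-up, so thresholds are computed in the frozen-parameter
## (quasi-static) convention: p53 and cIAP are held as control parameters,
## Caspase8 and total BH3 are eliminated by their closed-form steady states,
## and the remaining three dimer equations reduce algebraically to one
## scalar conservation equation in free BCL.  All equilibria are the
## bracketed roots of that scalar equation on a deterministic grid, which
## finds every branch of the S-curve without continuation.

## steady-state Caspase8 and total BH3 for frozen (p53, cIAP)
.fk_c8_ss <- function(cIAP, p) p$kaC8 / (p$kiC8 + p$ki2 * cIAP)
.fk_bh3t_ss <- function(p53, cIAP, p)
  (p$ksBh3 + p$ks2 * p53 + p$ks3 * .fk_c8_ss(cIAP, p)) / p$kdBh3

## conservation residual g(b) for free Bcl = b at frozen Bh3T, vectorized
.fk_bcl_residual <- function(b, Bh3T, p) {
  KH <- p$kasHC / p$kdsHC
  KX <- p$kasXC / (p$kdsXC + p$kb)
  h <- Bh3T / (1 + KH * b)                    # free BH3
  a <- p$kf1 + p$kf2 * h
  BaxmT <- a * p$BaxT / (a + p$kb)            # BAXm total at steady state
  b + KX * b * BaxmT / (1 + KX * b) + KH * b * h - p$BclT
}

## all roots of the conservation equation; returns free-Bcl values
.fk_bcl_roots <- function(Bh3T, p, nb = 400L) {
  bs <- exp(seq(log(1e-10), log(p$BclT), length.out = nb))
  gv <- .fk_bcl_residual(bs, Bh3T, p)
  ix <- which(gv[-nb] * gv[-1L] <= 0 & gv[-nb] != 0)
  roots <- vapply(ix, function(i)
    stats::uniroot(.fk_bcl_residual, c(bs[i], bs[i + 1L]), Bh3T = Bh3T,
                   p = p, tol = 1e-14)$root, 0)
  ## Newton polish: the conservation residual is well-conditioned in b but
  ## the assembled dimer equations amplify b-error by kasXC ~ 9000
  for (k in seq_len(2L)) {
    g <- .fk_bcl_residual(roots, Bh3T, p)
    h <- pmax(1e-12, 1e-7 * roots)
    dg <- (.fk_bcl_residual(roots + h, Bh3T, p) - g) / h
    step <- ifelse(dg != 0, g / dg, 0)
    roots <- pmax(roots - step, 0)
  }
  roots
}

## number of equilibria (used for fold bisection); sign-change count only
.fk_eq_count <- function(Bh3T, p, nb = 400L) {
  bs <- exp(seq(log(1e-10), log(p$BclT), length.out = nb))
  gv <- .fk_bcl_residual(bs, Bh3T, p)
  sum(gv[-nb] * gv[-1L] <= 0 & gv[-nb] != 0)
}

## assemble the full 5-variable subsystem state from a free-Bcl root
.fk_eq_state <- function(b, Bh3T, cIAP, p) {
  KH <- p$kasHC / p$kdsHC
  KX <- p$kasXC / (p$kdsXC + p$kb)
  h <- Bh3T / (1 + KH * b)
  a <- p$kf1 + p$kf2 * h
  BaxmT <- a * p$BaxT / (a + p$kb)
  BaxmBcl <- KX * b * BaxmT / (1 + KX * b)
  fk_state(BaxmT = BaxmT, BaxmBcl = BaxmBcl, Bh3Bcl = KH * b * h,
           Bh3T = Bh3T, Caspase8 = .fk_c8_ss(cIAP, p), cIAP = cIAP)
}

## Jacobian of the 5-variable apoptosis subsystem at a state (p53 frozen)
.fk_sub_jacobian <- function(state, p53, p, h = 1e-7) {
  vars <- c("BaxmT", "BaxmBcl", "Bh3Bcl", "Bh3T", "Caspase8")
  f0 <- apoptosis_module_rhs(state, p53, p)[vars]
  J <- matrix(0, 5, 5, dimnames = list(vars, vars))
  for (v in vars) {
    s <- state
    dv <- h * max(1, abs(s[[v]]))
    s[[v]] <- s[[v]] + dv
    J[, v] <- (apoptosis_module_rhs(s, p53, p)[vars] - f0) / dv
  }
  J
}

#' Equilibria of the frozen apoptosis subsystem
#'
#' Computes all equilibria of the five-variable apoptosis subsystem
#' (`BaxmT`, `BaxmBcl`, `Bh3Bcl`, `Bh3T`, `Caspase8`) with p53 and cIAP
#' frozen as control parameters.  Caspase8 and total BH3 are eliminated by
#' their closed forms (`Caspase8 = kaC8/(kiC8 + ki2*cIAP)`,
#' `Bh3T = (ksBh3 + ks2*p53 + ks3*Caspase8)/kdBh3`); the dimer equations
#' then reduce to a single conservation equation in free BCL whose
#' bracketed roots on a deterministic grid give every equilibrium.
#' Stability is classified by the leading eigenvalue of the full
#' five-variable Jacobian.
#'
#' @param p53,cIAP frozen control values (`>= 0`).
#' @param params an [fk_params] object.
#' @param Bh3T optional: freeze total BH3 at this value instead of its
#'   closed form (used when BH3 is the control parameter).
#' @return A data.frame with one row per equilibrium: the subsystem state,
#'   free `Baxm`, `stable` and the leading eigenvalue real part `eig`.
#' @export
#' @examples
#' subsystem_equilibria(1, 0.01, fk_params())
subsystem_equilibria <- function(p53, cIAP, params, Bh3T = NULL) {
  stopifnot(p53 >= 0 || !is.null(Bh3T), cIAP >= 0)
  if (is.null(Bh3T)) Bh3T <- .fk_bh3t_ss(p53, cIAP, params)
  roots <- .fk_bcl_roots(Bh3T, params)
  if (!length(roots))
    stop("no equilibrium found; the dissipative subsystem must have one ",
         "(solver failure)", call. = FALSE)
  ## merge near-duplicates
  roots <- sort(roots)
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 1e-6 * max(roots))]
  rows <- lapply(roots, function(b) {
    st <- .fk_eq_state(b, Bh3T, cIAP, params)
    J <- .fk_sub_jacobian(st, p53, params)
    eig <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(BaxmT = st[["BaxmT"]], BaxmBcl = st[["BaxmBcl"]],
               Bh3Bcl = st[["Bh3Bcl"]], Bh3T = st[["Bh3T"]],
               Caspase8 = st[["Caspase8"]],
               Baxm = st[["BaxmT"]] - st[["BaxmBcl"]],
               Bcl_free = b, stable = eig < 0, eig = eig)
  })
  do.call(rbind, rows)
}

## Bh3T value implied by a control setting
.fk_control_bh3t <- function(control, value, cIAP, p) {
  if (control == "p53") .fk_bh3t_ss(value, cIAP, p) else value
}

#' One-parameter bifurcation scan (S-curve) of BAXm activation
#'
#' Scans a control parameter (p53 by default, or total BH3) at frozen cIAP,
#' collecting the equilibrium branches of free BAXm and locating the two
#' saddle-node folds of the S-shaped curve: `theta_act`, where the low
#' (inactive) branch disappears and BAXm switches on, and `theta_inact`,
#' where the high branch is lost on the way down.  Folds are bracketed by
#' the change in equilibrium count along the scan and refined by bisection.
#'
#' @param params an [fk_params] object.
#' @param cIAP frozen cIAP level (default basal steady state `ksIAP/kdIAP`).
#' @param control `"p53"` or `"Bh3T"`.
#' @param range control range scanned.
#' @param resolution scan step used to bracket folds.
#' @param fold_tol bisection tolerance on the fold location.
#' @param branches also collect the equilibrium branches (slower); fold
#'   locations alone do not need them.
#' @return An `fk_scurve`: list with `branches` (data.frame of control
#'   value, `Baxm`, `stable`), `theta_act`, `theta_inact` (NA when the fold
#'   is not in range), `control` and `cIAP`.
#' @export
#' @examples
#' sc <- one_param_scurve(fk_params(), cIAP = 0.01)
#' c(sc$theta_inact, sc$theta_act)
one_param_scurve <- function(params, cIAP = params$ksIAP / params$kdIAP,
                             control = c("p53", "Bh3T"), range = c(0, 2),
                             resolution = 0.005, fold_tol = 1e-5,
                             branches = TRUE) {
  control <- match.arg(control)
  grid <- seq(range[1L], range[2L], by = resolution)
  cnt <- vapply(grid, function(v)
    .fk_eq_count(.fk_control_bh3t(control, v, cIAP, params), params), 0L)
  folds <- list()
  for (i in seq_along(grid)[-1L]) {
    if (cnt[i] != cnt[i - 1L]) {
      a <- grid[i - 1L]; b <- grid[i]; ca <- cnt[i - 1L]
      while (b - a > fold_tol) {
        m <- (a + b) / 2
        cm <- .fk_eq_count(.fk_control_bh3t(control, m, cIAP, params), params)
        if (cm == ca) a <- m else b <- m
      }
      folds[[length(folds) + 1L]] <-
        list(at = (a + b) / 2, rising = cnt[i] > cnt[i - 1L])
    }
  }
  ## ascending scan: count 1 -> 3 marks the inactivation fold (high branch
  ## born), 3 -> 1 the activation fold (low branch lost)
  theta_inact <- NA_real_; theta_act <- NA_real_
  for (f in folds) {
    if (f$rising && is.na(theta_inact)) theta_inact <- f$at
    if (!f$rising) theta_act <- f$at
  }
  br <- if (branches) do.call(rbind, lapply(seq_along(grid), function(i) {
    eq <- subsystem_equilibria(if (control == "p53") grid[i] else 0, cIAP,
                               params,
                               Bh3T = if (control == "Bh3T") grid[i] else NULL)
    data.frame(control = grid[i], Baxm = eq$Baxm, stable = eq$stable)
  })) else NULL
  if (!is.na(theta_act) && !is.na(theta_inact) && theta_act < theta_inact)
    warning("fold ordering inverted; inspect the raw scan", call. = FALSE)
  structure(list(branches = br, theta_act = theta_act,
                 theta_inact = theta_inact, control = control, cIAP = cIAP,
                 counts = data.frame(control = grid, n_equilibria = cnt)),
            class = "fk_scurve")
}

#' @export
print.fk_scurve <- function(x, ...) {
  cat("<fk_scurve> control:", x$control, " cIAP =", signif(x$cIAP, 3), "\n")
  cat("  theta_inact =", signif(x$theta_inact, 5),
      " theta_act =", signif(x$theta_act, 5), "\n")
  invisible(x)
}

#' @export
plot.fk_scurve <- function(x, ...) {
  b <- x$branches
  plot(b$control, b$Baxm, pch = ifelse(b$stable, 16, 1),
       cex = 0.4, xlab = x$control, ylab = "free BAXm", ...)
  if (!is.na(x$theta_act)) abline(v = x$theta_act, lty = 2)
  if (!is.na(x$theta_inact)) abline(v = x$theta_inact, lty = 3)
  invisible(x)
}

#' Two-parameter threshold curves in the (p53, cIAP) plane
#'
#' Traces the BAXm activation threshold `theta_act(cIAP)` and inactivation
#' threshold `theta_inact(cIAP)` over a grid of cIAP levels, the
#' bifurcation geometry that partitions the control plane into a survival
#' region (left of `theta_inact`), an apoptosis region (right of
#' `theta_act`) and the hysteretic region between them, where BAXm activity
#' depends on the cell's history.
#'
#' @param params an [fk_params] object.
#' @param ciap_grid ascending cIAP levels.
#' @param p53_range p53 range scanned per level.
#' @param resolution scan step, see [one_param_scurve()].
#' @param caspase8 how Caspase8 is eliminated when drawing the curves.
#'   `"equilibrium"` (default) uses its closed-form steady state at each
#'   cIAP, the strict frozen-parameter construction.  `"treatment"` slaves
#'   Caspase8 to cIAP along the drug-driven time course instead: Caspase8
#'   relaxes on a timescale (`1/kiC8` = 10 time units) comparable to the
#'   p53 race, so a treated cell carries more Caspase8 (hence more BH3)
#'   than the static steady state predicts, and the threshold it actually
#'   experiences sits left of the equilibrium curve by roughly
#'   `ks3/ks2` times the Caspase8 lag.  Use `"treatment"` when overlaying
#'   treated-cell trajectories (see [overlay_trajectory()]).
#' @param drug cisplatin level defining the treatment path (only used for
#'   `caspase8 = "treatment"`).
#' @return An `fk_thresholds`: list with `curves` (data.frame of `cIAP`,
#'   `theta_act`, `theta_inact`; NA where a fold leaves the range) and the
#'   scan settings.  Use [classify_point()] to label points.
#' @export
two_param_thresholds <- function(params,
                                 ciap_grid = seq(0, 1, by = 0.1),
                                 p53_range = c(0, 2), resolution = 0.005,
                                 caspase8 = c("equilibrium", "treatment"),
                                 drug = 0.45) {
  caspase8 <- match.arg(caspase8)
  if (is.unsorted(ciap_grid, strictly = TRUE))
    stop("ciap_grid must be sorted ascending", call. = FALSE)
  if (caspase8 == "equilibrium") {
    rows <- lapply(ciap_grid, function(ci) {
      sc <- one_param_scurve(params, cIAP = ci, range = p53_range,
                             resolution = resolution, branches = FALSE)
      data.frame(cIAP = ci, theta_act = sc$theta_act,
                 theta_inact = sc$theta_inact)
    })
    curves <- do.call(rbind, rows)
  } else {
    ## The dimer switch depends on the controls only through total BH3, so
    ## the folds are two fixed BH3 totals; each theta curve is their
    ## linear conversion through Bh3T = (ksBh3 + ks2*p53 + ks3*C8)/kdBh3
    ## with C8 taken from the treatment path.
    c8fun <- treatment_c8_path(params, drug)
    bh3_hi <- (params$ksBh3 + params$ks2 * max(p53_range) +
                 params$ks3 * params$kaC8 / params$kiC8) / params$kdBh3
    scb <- one_param_scurve(params, cIAP = ciap_grid[1L], control = "Bh3T",
                            range = c(0, bh3_hi), resolution = resolution,
                            branches = FALSE)
    to_p53 <- function(bh3_fold, ci)
      (bh3_fold * params$kdBh3 - params$ksBh3 -
         params$ks3 * c8fun(ci)) / params$ks2
    curves <- data.frame(
      cIAP = ciap_grid,
      theta_act = vapply(ciap_grid, function(ci)
        to_p53(scb$theta_act, ci), 0),
      theta_inact = vapply(ciap_grid, function(ci)
        to_p53(scb$theta_inact, ci), 0))
  }
  structure(list(curves = curves, p53_range = p53_range,
                 params = params, caspase8 = caspase8,
                 drug = if (caspase8 == "treatment") drug else NA_real_),
            class = "fk_thresholds")
}

#' Caspase8 along the drug-driven treatment path
#'
#' Integrates the (cIAP, Caspase8) pair under a constant drug level from
#' resting initial conditions and returns Caspase8 as a function of cIAP,
#' the slaved value a treated cell carries when its cIAP has reached a
#' given level.
#'
#' @param params an [fk_params] object.
#' @param drug constant cisplatin level.
#' @param t_max horizon of the path (long enough for cIAP to span the
#'   threshold grids).
#' @return A function mapping cIAP to Caspase8 (constant extrapolation
#'   outside the path).
#' @export
treatment_c8_path <- function(params, drug, t_max = 400) {
  rhs <- function(t, y, p) {
    list(c(ciap_rhs(y[1L], drug, p),
           p$kaC8 - (p$kiC8 + p$ki2 * y[1L]) * y[2L]))
  }
  out <- deSolve::ode(c(cIAP = 0, C8 = params$kaC8 / params$kiC8),
                      seq(0, t_max, by = 0.5), rhs, params,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  stats::approxfun(out[, "cIAP"], out[, "C8"], rule = 2)
}

#' @export
print.fk_thresholds <- function(x, ...) {
  cat("<fk_thresholds> (p53, cIAP) bifurcation geometry\n")
  print(transform(x$curves, theta_act = signif(theta_act, 4),
                  theta_inact = signif(theta_inact, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fk_thresholds <- function(x, ...) {
  cu <- x$curves
  plot(range(c(cu$theta_act, cu$theta_inact, x$p53_range[1L]), na.rm = TRUE),
       range(cu$cIAP), type = "n", xlab = "p53", ylab = "cIAP", ...)
  lines(cu$theta_act, cu$cIAP, lwd = 2)
  lines(cu$theta_inact, cu$cIAP, lty = 2)
  invisible(x)
}

#' Classify a point of the (p53, cIAP) control plane
#'
#' @param p53,cIAP coordinates (vectorized).
#' @param thresholds an `fk_thresholds` object.
#' @return Character vector: `"apoptosis"` (right of the activation
#'   threshold), `"survival"` (left of the inactivation threshold) or
#'   `"hysteresis"` (between the curves).
#' @export
classify_point <- function(p53, cIAP, thresholds) {
  cu <- thresholds$curves
  th_a <- stats::approx(cu$cIAP, cu$theta_act, xout = cIAP, rule = 2)$y
  th_i <- stats::approx(cu$cIAP, cu$theta_inact, xout = cIAP, rule = 2)$y
  out <- rep("hysteresis", length(p53))
  out[p53 >= th_a] <- "apoptosis"
  out[p53 < th_i] <- "survival"
  out
}

#' Overlay a cell trajectory on the bifurcation geometry
#'
#' Maps the time-dependent `(p53(t), cIAP(t))` path of a simulated cell
#' onto the threshold curves and reports whether and when the path first
#' enters the apoptosis region.  The geometric fate call (apoptotic if the
#' path ever crosses the activation threshold) is compared with the
#' dynamical call from [classify_fate()]; the two can disagree for cells
#' that pass a fold too slowly for the switch to engage.
#'
#' @param traj an `fk_trajectory`.
#' @param thresholds an `fk_thresholds` computed under the trajectory's
#'   structural parameters.
#' @param death_threshold,activation_threshold passed to [classify_fate()].
#' @return An `fk_overlay`: list with `path` (data.frame of `time`, `p53`,
#'   `cIAP`, `region`), `entry_time` (first apoptosis-region entry or NA),
#'   `geometric_fate`, `dynamic_fate` and `consistent`.
#' @export
overlay_trajectory <- function(traj, thresholds,
                               death_threshold =
                                 fk_profile()$death_threshold,
                               activation_threshold =
                                 fk_profile()$activation_threshold) {
  region <- classify_point(traj$p53, traj$cIAP, thresholds)
  ix <- which(region == "apoptosis")[1L]
  entry <- if (is.na(ix)) NA_real_ else traj$time[ix]
  dyn <- classify_fate(traj, death_threshold, activation_threshold)$fate
  geo <- if (is.na(entry)) "surviving" else "apoptotic"
  structure(list(
    path = data.frame(time = traj$time, p53 = traj$p53, cIAP = traj$cIAP,
                      region = region),
    entry_time = entry, geometric_fate = geo, dynamic_fate = dyn,
    consistent = identical(geo, dyn)), class = "fk_overlay")
}

#' @export
print.fk_overlay <- function(x, ...) {
  cat("<fk_overlay> geometric:", x$geometric_fate,
      " dynamic:", x$dynamic_fate,
      if (!is.na(x$entry_time))
        paste(" entry at t =", signif(x$entry_time, 4)) else "", "\n")
  invisible(x)
}

#' Default death threshold from the calibrated S-curve
#'
#' Half the upper-branch free BAXm at `p53 = 1` and basal cIAP: the call is
#' tied to the model's own bistable geometry rather than an arbitrary
#' constant.
#'
#' @param params an [fk_params] object.
#' @return A scalar free-BAXm level.
#' @export
death_threshold_default <- function(params = fk_params()) {
  eq <- subsystem_equilibria(1, params$ksIAP / params$kdIAP, params)
  0.5 * max(eq$Baxm)
}

#' Calibrate the open parameters of the apoptosis switch
#'
#' The published parameter table leaves the conserved totals `BaxT` and
#' `BclT` unset, and the printed steepness of the Mdm2 drug term does not
#' let the drug release p53 at the low dose (see the methods vignette).
#' This procedure fixes all three on a coarse deterministic grid, accepting
#' the first candidate (ascending `BaxT`, then `BclT`, then `sigma_drug`)
#' that satisfies, in order:
#'
#' * C1 (switch geometry): the apoptosis subsystem is hysteretic at basal
#'   cIAP, with both folds in range and `theta_act` in `(0.2, 0.8)`;
#' * C2 (CIAP protection): `theta_act` exceeds 1 at the drug-driven cIAP
#'   steady state (`cIAP = 4`), so a late-activating cell cannot die;
#' * the population gate: a seeded heterogeneous population reproduces the
#'   five hallmark features of fractional killing at the two doses, with
#'   an apoptotic fraction near one half at the low dose.
#'
#' C1 and C2 are cheap equilibrium checks and act as a filter; the gate is
#' only evaluated for candidates that pass them.
#'
#' @param basal_params starting parameter set (totals/steepness overridden).
#' @param baxt_grid,bclt_grid,sigma_drug_grid candidate values.
#' @param gate_n,gate_seed population size and seed used for the gate.
#' @param drug_low,drug_high the two doses of the gate.
#' @param fraction_band acceptable apoptotic-fraction band at the low dose;
#'   the default keeps a margin inside the expected "about half".
#' @param f1_margin maximum relative peak difference accepted for the
#'   similar-peaks feature, stricter than the feature's own 0.2 so the
#'   shipped defaults hold away from the edge.
#' @param verbose print progress.
#' @return A profile list (`params`, `death_threshold`,
#'   `activation_threshold`) with a `calibration` attribute recording the
#'   chosen values and the gate statistics.
#' @export
calibrate_model <- function(basal_params = fk_params(),
                            baxt_grid = c(0.5, 1, 1.5, 2),
                            bclt_grid = seq(0.4, 1.2, by = 0.025),
                            sigma_drug_grid = c(5, 10, 15, 20, 25),
                            gate_n = 300, gate_seed = 1,
                            drug_low = 0.45, drug_high = 1,
                            fraction_band = c(0.43, 0.57),
                            f1_margin = 0.15,
                            verbose = FALSE) {
  act_thr <- 0.3
  for (BaxT in baxt_grid) for (BclT in bclt_grid) {
    p <- basal_params; p$BaxT <- BaxT; p$BclT <- BclT
    sc <- one_param_scurve(p, cIAP = p$ksIAP / p$kdIAP, branches = FALSE)
    c1 <- !is.na(sc$theta_act) && !is.na(sc$theta_inact) &&
      sc$theta_inact < sc$theta_act &&
      sc$theta_act > 0.2 && sc$theta_act < 0.8
    if (!c1) next
    sc4 <- one_param_scurve(p, cIAP = 4, range = c(0, 3), branches = FALSE)
    c2 <- is.na(sc4$theta_act) || sc4$theta_act > 1
    if (!c2) next
    dthr <- 0.5 * max(subsystem_equilibria(1, p$ksIAP / p$kdIAP, p)$Baxm)
    for (sd in sigma_drug_grid) {
      p$sigma_drug <- sd
      if (verbose)
        message(sprintf("gate: BaxT=%g BclT=%g sigma_drug=%g", BaxT, BclT, sd))
      cells <- sample_population(p, heterogeneity_spec(gate_n, gate_seed))
      lo <- run_population(cells, fk_protocol(drug = drug_low),
                           death_threshold = dthr,
                           activation_threshold = act_thr)
      hi <- run_population(cells, fk_protocol(drug = drug_high),
                           death_threshold = dthr,
                           activation_threshold = act_thr)
      feats <- feature_report(lo, hi)
      ok <- all(feats$pass %in% TRUE) &&
        feats$statistic[feats$feature == "similar_p53_peaks"] <= f1_margin &&
        lo$fraction_apoptotic >= fraction_band[1L] &&
        lo$fraction_apoptotic <= fraction_band[2L]
      if (verbose)
        message(sprintf("  fraction(low)=%.3f features=%s",
                        lo$fraction_apoptotic,
                        paste(feats$pass, collapse = ",")))
      if (ok) {
        prof <- list(params = p, death_threshold = dthr,
                     activation_threshold = act_thr)
        attr(prof, "calibration") <- list(
          BaxT = BaxT, BclT = BclT, sigma_drug = sd,
          theta_act_basal = sc$theta_act, theta_inact_basal = sc$theta_inact,
          theta_act_ciap4 = sc4$theta_act,
          fraction_low = lo$fraction_apoptotic,
          fraction_high = hi$fraction_apoptotic,
          features = feats)
        return(prof)
      }
    }
  }
  stop("no grid candidate satisfied the calibration criteria", call. = FALSE)
}
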