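## Single-cell simulation and fate classification ------------------------------

## deSolve wrapper around the R reference implementation of the RHS
.fk_rhs_desolve <- function(t, y, parms) {
  d <- full_rhs(y, parms$params, parms$drug_ciap, parms$drug_mdm2,
                free_tol = Inf)
  free <- c(Bax  = parms$params$BaxT - y[["BaxmT"]],
            Baxm = y[["BaxmT"]] - y[["BaxmBcl"]],
            Bh3  = y[["Bh3T"]] - y[["Bh3Bcl"]],
            Bcl  = parms$params$BclT - y[["BaxmBcl"]] - y[["Bh3Bcl"]])
  list(unname(d), free)
}

.fk_integrate_phase <- function(y0, times, params, drug_ciap, drug_mdm2,
                                engine, rtol, atol) {
  if (engine == "compiled") {
    parms <- c(.fk_par_vector(params),
               drug_ciap = drug_ciap, drug_mdm2 = drug_mdm2)
    out <- deSolve::ode(y = y0, times = times, func = "fk_derivs",
                        parms = parms, dllname = "frackill",
                        initfunc = "fk_initmod", nout = 4,
                        outnames = c("Bax", "Baxm", "Bh3", "Bcl"),
                        method = "lsoda", rtol = rtol, atol = atol)
  } else {
    out <- deSolve::ode(y = y0, times = times, func = .fk_rhs_desolve,
                        parms = list(params = params, drug_ciap = drug_ciap,
                                     drug_mdm2 = drug_mdm2),
                        method = "lsoda", rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1L] < 0)
    stop("integration failed", call. = FALSE)
  out
}

#' Simulate one virtual cell under a treatment protocol
#'
#' Integrates the full model from the (projected) initial conditions over
#' `[0, t_end]` with a stiff-capable adaptive integrator (lsoda; the fast
#' dimer association `kasXC = 9000` makes the system stiff), reporting the
#' state and the free species on a dense output grid.  When the protocol
#' adds Nutlin-3, the time span is split at `nutlin_time` so the step
#' discontinuity in the Mdm2 drug input is not smoothed over.
#'
#' @param params an [fk_params] object (one virtual cell).
#' @param protocol an [fk_protocol] object.
#' @param init initial state; defaults to [initial_state()] for `params`.
#' @param step dense output step (time units).
#' @param engine `"compiled"` (C right-hand side, default) or `"R"` (pure-R
#'   reference implementation); the two agree to integrator tolerance.
#' @param rtol,atol relative and absolute integration tolerances.
#' @return An `fk_trajectory`: a data.frame with `time`, the eight state
#'   variables and the four free species, carrying the protocol-modified
#'   parameters and the protocol as attributes.
#' @export
#' @examples
#' tr <- simulate_cell(fk_params(), fk_protocol(drug = 1, t_end = 20))
#' max(tr$p53)
simulate_cell <- function(params = fk_params(), protocol = fk_protocol(),
                          init = NULL, step = 0.1,
                          engine = c("compiled", "R"),
                          rtol = 1e-8, atol = 1e-10) {
  engine <- match.arg(engine)
  res0 <- apply_protocol(params, protocol, t = 0)
  p <- res0$params
  if (is.null(init)) init <- initial_state(p, quiet = TRUE)
  init <- init[.fk_state_names]
  if (protocol$t_end == 0) {
    free <- derive_free_species(init, p)
    tr <- data.frame(time = 0, as.list(init), as.list(free))
    return(.fk_trajectory(tr, p, protocol))
  }
  times <- seq(0, protocol$t_end, by = step)
  if (times[length(times)] < protocol$t_end)
    times <- c(times, protocol$t_end)
  nt <- protocol$nutlin_time
  out <- tryCatch({
    if (is.null(nt)) {
      .fk_integrate_phase(init, times, p, res0$drug_ciap, res0$drug_mdm2,
                          engine, rtol, atol)
    } else {
      times <- sort(unique(c(times, nt)))
      t1 <- times[times <= nt]
      t2 <- times[times >= nt]
      res1 <- apply_protocol(params, protocol, t = nt)
      o1 <- .fk_integrate_phase(init, t1, p, res0$drug_ciap,
                                res0$drug_mdm2, engine, rtol, atol)
      y1 <- o1[nrow(o1), .fk_state_names]
      o2 <- .fk_integrate_phase(unlist(y1), t2, p, res1$drug_ciap,
                                res1$drug_mdm2, engine, rtol, atol)
      rbind(o1, o2[-1L, , drop = FALSE])
    }
  }, error = function(e) {
    stop("integration failed for cell with parameters: ",
         paste(sprintf("%s=%g", .fk_par_order, unlist(params[.fk_par_order])),
               collapse = " "), "\n  ", conditionMessage(e), call. = FALSE)
  })
  tr <- as.data.frame(unclass(out))
  .fk_trajectory(tr, p, protocol)
}

.fk_trajectory <- function(df, params, protocol) {
  rownames(df) <- NULL
  structure(df, params = params, protocol = protocol,
            class = c("fk_trajectory", "data.frame"))
}

#' @export
print.fk_trajectory <- function(x, ...) {
  cat("<fk_trajectory> ", nrow(x), " time points over [",
      x$time[1L], ", ", x$time[nrow(x)], "]\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

## first grid crossing of `values >= threshold`, linearly interpolated
.fk_first_crossing <- function(times, values, threshold) {
  ix <- which(values >= threshold)[1L]
  if (is.na(ix)) return(NA_real_)
  if (ix == 1L) return(times[1L])
  t0 <- times[ix - 1L]; t1 <- times[ix]
  v0 <- values[ix - 1L]; v1 <- values[ix]
  t0 + (threshold - v0) * (t1 - t0) / (v1 - v0)
}

## trapezoid integral of `values` over [times[1], t_stop]
.fk_trapz_to <- function(times, values, t_stop) {
  keep <- times <= t_stop
  tt <- times[keep]; vv <- values[keep]
  if (t_stop > tt[length(tt)] && t_stop <= times[length(times)]) {
    v_stop <- stats::approx(times, values, xout = t_stop)$y
    tt <- c(tt, t_stop); vv <- c(vv, v_stop)
  }
  if (length(tt) < 2L) return(0)
  sum(diff(tt) * (vv[-length(vv)] + vv[-1L]) / 2)
}

#' Classify the fate of a simulated cell
#'
#' A cell is called apoptotic when its free mitochondrial BAXm ever reaches
#' `death_threshold` (BAXm activation as the indicator of apoptosis
#' commitment); the death time is the first crossing, linearly interpolated
#' between output grid points.  p53 summary statistics are truncated at
#' death — apoptotic cells lose their p53 trace when they die — so the
#' integrated p53 runs to the death time in apoptotic cells and to the end
#' of the run in survivors.
#'
#' @param traj an `fk_trajectory` from [simulate_cell()].
#' @param death_threshold free-BAXm level called as apoptosis; the shipped
#'   default is half the upper-branch BAXm at `p53 = 1` and basal CIAP
#'   (see [death_threshold_default()]).
#' @param activation_threshold p53 level called as activation.
#' @return An `fk_fate`: a one-row data.frame with `fate`
#'   (`"apoptotic"`/`"surviving"`), `death_time`, `p53_peak`,
#'   `p53_activation_time` and `integrated_p53`.
#' @export
classify_fate <- function(traj,
                          death_threshold = fk_profile()$death_threshold,
                          activation_threshold =
                            fk_profile()$activation_threshold) {
  stopifnot(death_threshold > 0, activation_threshold > 0)
  death_time <- .fk_first_crossing(traj$time, traj$Baxm, death_threshold)
  apoptotic <- !is.na(death_time)
  t_stop <- if (apoptotic) death_time else traj$time[nrow(traj)]
  pre <- traj$time <= t_stop
  p53_at_stop <- stats::approx(traj$time, traj$p53, xout = t_stop,
                               rule = 2)$y
  p53_pre <- c(traj$p53[pre], p53_at_stop)
  act <- .fk_first_crossing(traj$time[pre], traj$p53[pre],
                            activation_threshold)
  structure(data.frame(
    fate = if (apoptotic) "apoptotic" else "surviving",
    death_time = death_time,
    p53_peak = max(p53_pre),
    p53_activation_time = act,
    integrated_p53 = .fk_trapz_to(traj$time, traj$p53, t_stop),
    stringsAsFactors = FALSE), class = c("fk_fate", "data.frame"))
}
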