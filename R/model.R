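#' @title Model core
#' @description
#' The cardiovascular response to fluid perturbation is an 11-state ODE
#' system driven by the infusion rate `U(t)` and loss rate `V(t)`.  Four
#' coupled sub-models produce the outputs: a two-compartment blood-volume
#' model with a proportional fluid-shift controller, a heart-rate model with
#' transient and controller-mediated long-term responses, a stroke-volume
#' model combining relaxation, blood-volume coupling and an inverse
#' heart-rate coupling (Frank-Starling), and a total-peripheral-resistance
#' model regulating mean arterial pressure toward a subject-specific
#' reference.
#' @name model_core
NULL

.state_names <- c("r_U_bv", "r_V_bv", "bv", "rbc", "r_hv_l", "h_v_t",
                  "h_v_l", "e_int", "h_u_t", "sv", "tpr")

.output_names <- c("BV", "HCT", "HR", "SV", "CO", "BP")

#' Baseline-consistent initial state
#'
#' Reference volume changes and all heart-rate perturbation states start at
#' zero; blood volume, red-cell content, stroke volume and resistance start
#' at their baseline values, so that with zero inputs (and consistent
#' `r_SV`, `r_BP`) the system is at rest.
#'
#' @param params A [subject_parameters] vector.
#' @return Named numeric state vector of length 11.
#' @export
initial_state <- function(params) {
  params <- as_subject_parameters(params)
  y <- numeric(11)
  names(y) <- .state_names
  y["bv"] <- params[["BV0"]]
  y["rbc"] <- params[["HCT0"]] * params[["BV0"]]
  y["sv"] <- params[["SV0"]]
  y["tpr"] <- params[["TPR0"]]
  y
}

sv_hr_coefficient <- function(sv_hr_sign = c("physiological", "literal")) {
  # physiological reading: a rising heart rate shortens ventricular filling
  # and depresses stroke volume (net -G_HR * dH/dt); the literal composition
  # of the channel equations gives the opposite sign, kept as an option
  switch(match.arg(sv_hr_sign), physiological = -1, literal = +1)
}

#' Time derivatives of the model state
#'
#' Reference (pure R) implementation of the right-hand side, exposed for
#' inspection and used by the `"lsoda"` solver path; the default `"rk4"`
#' path uses an equivalent compiled kernel.
#'
#' @param state Named numeric state vector (see [initial_state()]).
#' @param t Time in minutes.
#' @param params A [subject_parameters] vector.
#' @param protocol A [fluid_protocol]; its rates are evaluated at `t`.
#' @param sv_hr_sign `"physiological"` (default) or `"literal"` reading of
#'   the heart-rate/stroke-volume coupling sign.
#' @return Named numeric vector of the 11 time derivatives.
#' @export
derivatives <- function(state, t, params, protocol,
                        sv_hr_sign = c("physiological", "literal")) {
  if (any(!is.finite(state))) {
    stop("numerical divergence: non-finite state", call. = FALSE)
  }
  if (state[["bv"]] <= 0) {
    stop("blood volume exhausted", call. = FALSE)
  }
  r <- protocol_rates(protocol, t)
  derivatives_uv(state, params, U = r$U[1], V = r$V[1],
                 sv_hr = sv_hr_coefficient(match.arg(sv_hr_sign)))
}

# RHS at explicit input rates; the workhorse behind derivatives() and the
# lsoda path (rates constant within a protocol segment)
derivatives_uv <- function(state, params, U, V, sv_hr) {
  p <- unclass(as_subject_parameters(params))
  y <- state
  pow0 <- function(rate, expo) if (rate <= 0) 0 else rate^expo

  hct <- y[["rbc"]] / y[["bv"]]
  q <- p[["K_P_BV"]] * (y[["bv"]] - p[["BV0"]] - (y[["r_U_bv"]] + y[["r_V_bv"]]))
  e <- y[["r_hv_l"]] - y[["h_v_t"]] - y[["h_v_l"]]

  d <- numeric(11)
  names(d) <- .state_names
  d[["r_U_bv"]] <- p[["A_U_BV"]] * y[["r_U_bv"]] + U / (1 + p[["alpha_U"]])
  d[["r_V_bv"]] <- p[["A_V_BV"]] * y[["r_V_bv"]] - V / (1 + p[["alpha_V"]])
  d[["bv"]] <- U - V - q
  d[["rbc"]] <- -V * hct
  d[["r_hv_l"]] <- p[["G_V_L"]] * pow0(V, p[["P_V_L"]])
  d[["h_v_t"]] <- p[["G_V_T"]] * V
  d[["h_v_l"]] <- p[["K_P_H"]] * e + p[["K_I_H"]] * y[["e_int"]]
  d[["e_int"]] <- e
  d[["h_u_t"]] <- p[["G_U_T"]] * pow0(U, p[["P_U_T"]])

  h_dot <- d[["h_v_l"]] + d[["h_v_t"]] - d[["h_u_t"]]
  d[["sv"]] <- p[["A_SV"]] * (y[["sv"]] - p[["SV0"]]) +
    p[["G_BV"]] * d[["bv"]] + p[["K_P_SV"]] * (p[["r_SV"]] - y[["sv"]]) +
    sv_hr * p[["G_HR"]] * h_dot

  H <- p[["H0"]] + y[["h_v_t"]] + y[["h_v_l"]] - y[["h_u_t"]]
  BP <- H * y[["sv"]] * y[["tpr"]]
  d[["tpr"]] <- p[["A_BP"]] * (y[["tpr"]] - p[["TPR0"]]) +
    p[["K_P_BP"]] * (p[["r_BP"]] - BP)
  d
}

#' Algebraic outputs of a model state
#'
#' @param state Named numeric state vector.
#' @param params A [subject_parameters] vector.
#' @return Named list with `HCT` (%), `HR` (bpm), `CO` (l/min),
#'   `BP` (mmHg), `r_BV` (l, the reference blood-volume change) and `q`
#'   (l/min, the fluid-shift rate).
#' @export
derived_outputs <- function(state, params) {
  p <- unclass(as_subject_parameters(params))
  if (state[["bv"]] <= 0) stop("blood volume exhausted", call. = FALSE)
  HR <- p[["H0"]] + state[["h_v_t"]] + state[["h_v_l"]] - state[["h_u_t"]]
  CO <- HR * state[["sv"]]
  list(
    HCT = state[["rbc"]] / state[["bv"]],
    HR = HR,
    CO = CO,
    BP = CO * state[["tpr"]],
    r_BV = state[["r_U_bv"]] + state[["r_V_bv"]],
    q = p[["K_P_BV"]] * (state[["bv"]] - p[["BV0"]] -
                           (state[["r_U_bv"]] + state[["r_V_bv"]]))
  )
}

#' Simulate a subject under a fluid-perturbation protocol
#'
#' Integrates the 11-state system from the baseline-consistent initial
#' state and returns the six observable outputs on the requested time grid.
#' The integrator restarts exactly at protocol breakpoints so that
#' piecewise-constant inputs are never smoothed across discontinuities.
#'
#' The default solver is a compiled fixed-step classical Runge-Kutta scheme
#' (`dt` = 0.01 min), sized for cohort-scale use where tens of thousands of
#' piecewise-protocol simulations are required; the system is non-stiff
#' (rate constants at most ~1/min) so this is far inside the accuracy
#' budget.  `solver = "lsoda"` integrates the pure-R [derivatives()] with
#' [deSolve::ode()] and serves as an independent cross-check.
#'
#' @param params A [subject_parameters] vector.
#' @param protocol A [fluid_protocol].
#' @param output_interval Output grid spacing in minutes (default 1).
#' @param times Explicit output times (overrides `output_interval`); must be
#'   non-negative, non-decreasing and within the protocol duration.
#' @param solver `"rk4"` (compiled, default) or `"lsoda"` (deSolve).
#' @param dt Fixed step size for `"rk4"`, minutes.
#' @param sv_hr_sign Sign convention for the HR->SV coupling, see
#'   [derivatives()].
#' @return A data frame of class `"cv_simulation"` with columns `time`,
#'   `BV`, `HCT`, `HR`, `SV`, `CO`, `BP`; attributes `success` (logical),
#'   `t_fail` (time of failure or `NA`), `states` (full state matrix) and
#'   solver metadata.  On solver failure the partial trajectory is returned
#'   with `success = FALSE` and `NA` rows beyond the failure time.
#' @examples
#' p <- reference_subjects()[["LR1"]]
#' prot <- fluid_protocol(c(0, 15), U = c(0, 0),
#'                        V = c(25 * 40 / 1000 / 15, 0), duration = 60)
#' sim <- simulate_subject(p, prot, output_interval = 5)
#' head(sim)
#' @export
simulate_subject <- function(params, protocol, output_interval = 1,
                             times = NULL, solver = c("rk4", "lsoda"),
                             dt = 0.01,
                             sv_hr_sign = c("physiological", "literal")) {
  params <- as_subject_parameters(params)
  solver <- match.arg(solver)
  sv_hr_sign <- match.arg(sv_hr_sign)
  duration <- protocol_duration(protocol)
  if (is.null(times)) {
    if (output_interval <= 0) stop("output_interval must be > 0",
                                   call. = FALSE)
    times <- seq(0, duration, by = output_interval)
    if (times[length(times)] < duration) times <- c(times, duration)
  } else {
    times <- as.numeric(times)
    if (any(times < 0) || any(diff(times) < 0) || any(times > duration)) {
      stop("times must be non-decreasing within [0, duration]",
           call. = FALSE)
    }
  }
  sv_hr <- sv_hr_coefficient(sv_hr_sign)

  if (solver == "rk4") {
    res <- .Call(C_simulate_rk4, as.numeric(unclass(params)),
                 as.numeric(sv_hr), as.numeric(protocol$time),
                 as.numeric(protocol$U), as.numeric(protocol$V),
                 as.numeric(duration), times, as.numeric(dt))
    states <- res$states
    success <- res$success
    t_fail <- res$t_fail
  } else {
    out <- simulate_lsoda(params, protocol, times, sv_hr)
    states <- out$states
    success <- out$success
    t_fail <- out$t_fail
  }
  colnames(states) <- .state_names

  p <- unclass(params)
  HR <- p[["H0"]] + states[, "h_v_t"] + states[, "h_v_l"] - states[, "h_u_t"]
  CO <- HR * states[, "sv"]
  df <- data.frame(
    time = times,
    BV = states[, "bv"],
    HCT = states[, "rbc"] / states[, "bv"],
    HR = HR,
    SV = states[, "sv"],
    CO = CO,
    BP = CO * states[, "tpr"]
  )
  structure(df,
            class = c("cv_simulation", "data.frame"),
            states = states, success = success, t_fail = t_fail,
            solver = solver, dt = if (solver == "rk4") dt else NA_real_,
            subject_id = attr(params, "subject_id"))
}

# deSolve path: lsoda over the pure-R RHS, restarted at every protocol
# breakpoint and output time
simulate_lsoda <- function(params, protocol, times, sv_hr,
                           rtol = 1e-8, atol = 1e-10, hmax = 0.5) {
  duration <- protocol_duration(protocol)
  events <- sort(unique(c(times, protocol$time, duration)))
  events <- events[events > 0 & events <= max(times)]
  y <- initial_state(params)
  states <- matrix(NA_real_, nrow = length(times), ncol = 11)
  success <- TRUE
  t_fail <- NA_real_
  record <- function(upto, y) {
    hit <- which(times <= upto + 1e-12 & is.na(states[, 3]))
    if (length(hit)) states[hit, ] <<- matrix(y, length(hit), 11,
                                              byrow = TRUE)
  }
  record(0, y)
  t <- 0
  func <- function(tt, yy, parms) {
    names(yy) <- .state_names
    list(derivatives_uv(yy, params, U = parms[1], V = parms[2],
                        sv_hr = sv_hr))
  }
  for (t1 in events) {
    if (t1 <= t) next
    r <- protocol_rates(protocol, t)
    sol <- try(deSolve::ode(y = y, times = c(t, t1), func = func,
                            parms = c(r$U[1], r$V[1]), method = "lsoda",
                            rtol = rtol, atol = atol, hmax = hmax), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < 2 ||
        any(!is.finite(sol[nrow(sol), -1]))) {
      success <- FALSE
      t_fail <- t1
      break
    }
    y <- sol[nrow(sol), -1]
    names(y) <- .state_names
    if (y[["bv"]] <= 0) {
      success <- FALSE
      t_fail <- t1
      break
    }
    t <- t1
    record(t, y)
  }
  list(states = states, success = success, t_fail = t_fail)
}

#' @export
print.cv_simulation <- function(x, ...) {
  cat("<cv_simulation> ", nrow(x), " time points over [",
      min(x$time), ", ", max(x$time), "] min; solver ", attr(x, "solver"),
      if (!isTRUE(attr(x, "success"))) " (FAILED)", "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Closed-form resistance fixed point at constant cardiac output
#'
#' With cardiac output held constant at `H_const * SV_const`, the
#' resistance dynamics are linear and relax to
#' `TPR* = (A_BP * TPR0 - K_P_BP * r_BP) / (A_BP - K_P_BP * H * SV)`.
#' Used as an independent oracle for long-horizon simulations.
#'
#' @param params A [subject_parameters] vector.
#' @param H_const Constant heart rate (bpm).
#' @param SV_const Constant stroke volume (l).
#' @return Named list with `TPR` (mmHg.min/l) and `BP` (mmHg) at the fixed
#'   point.
#' @export
equilibrium_tpr <- function(params, H_const, SV_const) {
  p <- unclass(as_subject_parameters(params))
  den <- p[["A_BP"]] - p[["K_P_BP"]] * H_const * SV_const
  if (abs(den) < .Machine$double.eps * 100) {
    stop("degenerate equilibrium: A_BP - K_P_BP * H * SV is zero",
         call. = FALSE)
  }
  tpr <- (p[["A_BP"]] * p[["TPR0"]] - p[["K_P_BP"]] * p[["r_BP"]]) / den
  list(TPR = tpr, BP = H_const * SV_const * tpr)
}

#' Write a simulated trajectory to CSV
#'
#' Columns: `time_min,BV_l,HCT_pct,HR_bpm,SV_l,CO_l_per_min,BP_mmHg`.
#'
#' @param sim A `"cv_simulation"` data frame from [simulate_subject()].
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  df <- data.frame(time_min = sim$time, BV_l = sim$BV, HCT_pct = sim$HCT,
                   HR_bpm = sim$HR, SV_l = sim$SV, CO_l_per_min = sim$CO,
                   BP_mmHg = sim$BP)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
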