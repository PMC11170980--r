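#' @title Synthetic protocols and measurement series
#' @description
#' Emulators of the two animal experiment designs the model is meant to
#' operate under: a conscious-sheep protocol (bulk hemorrhage, two follow-up
#' hemorrhages, closed-loop crystalloid resuscitation) and an
#' anesthetized-swine-like protocol (hemorrhage to a pressure target, then
#' weight-scaled boluses with washouts).  Together with the noisy
#' measurement sampler these make every downstream module testable without
#' any external data.
#' @name fixtures
NULL

#' Construct a measurement series
#'
#' Sparse observations of the five observable variables at common sample
#' times.  `NA` marks a missing value; all present values must be finite
#' and positive and each variable needs at least two observations.
#'
#' @param time Strictly increasing sample times (min).
#' @param HCT,HR,SV,CO,BP Observed values (`%`, bpm, l, l/min, mmHg).
#' @param provenance Optional list recording how a synthetic series was
#'   generated (ground-truth subject id, noise SDs, seed).
#' @return Data frame of class `"measurement_series"`.
#' @export
measurement_series <- function(time, HCT, HR, SV, CO, BP,
                               provenance = NULL) {
  n <- length(time)
  vars <- list(HCT = HCT, HR = HR, SV = SV, CO = CO, BP = BP)
  if (any(vapply(vars, length, 1L) != n)) {
    stop("all variables must have the same length as time", call. = FALSE)
  }
  if (n < 2 || any(diff(time) <= 0)) {
    stop("need at least 2 strictly increasing sample times", call. = FALSE)
  }
  for (v in names(vars)) {
    x <- vars[[v]]
    if (sum(!is.na(x)) < 2) {
      stop("variable ", v, " needs at least 2 observed values",
           call. = FALSE)
    }
    if (any(!is.finite(x[!is.na(x)])) || any(x <= 0, na.rm = TRUE)) {
      stop("variable ", v, " has non-finite or non-positive values",
           call. = FALSE)
    }
  }
  structure(
    data.frame(time = as.numeric(time), HCT = HCT, HR = HR, SV = SV,
               CO = CO, BP = BP),
    class = c("measurement_series", "data.frame"),
    provenance = provenance
  )
}

#' @export
print.measurement_series <- function(x, ...) {
  cat("<measurement_series> ", nrow(x), " samples over [", min(x$time),
      ", ", max(x$time), "] min\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Default measurement noise (fraction of baseline, per variable)
#'
#' Hematocrit assays are tight (2% of baseline); the hemodynamic variables
#' get 5%.  These make parameter recovery non-trivial but feasible.
#'
#' @return Named numeric vector of SD fractions for HCT, HR, SV, CO, BP.
#' @export
default_noise_sd <- function() {
  c(HCT = 0.02, HR = 0.05, SV = 0.05, CO = 0.05, BP = 0.05)
}

#' Sample noisy measurements from a simulated trajectory
#'
#' Picks trajectory values every `interval_min` minutes (starting at 0) and
#' adds zero-mean i.i.d. Gaussian noise with standard deviation
#' `noise_sd[v] * baseline(v)`, the baseline being the trajectory value at
#' time 0.  With `noise_sd = 0` the samples equal the trajectory exactly.
#'
#' Readings that come out non-positive (possible when a trajectory
#' collapses toward zero, or past a simulation failure) are censored as
#' missing values, mirroring monitor dropout during hemodynamic collapse;
#' a series needs at least two valid samples per variable to be usable.
#'
#' @param sim A `"cv_simulation"` whose grid contains the sample times.
#' @param interval_min Sampling interval (min), typically 5 or 10.
#' @param noise_sd Named SD fractions per variable (see
#'   [default_noise_sd()]), recycled scalar allowed.
#' @param seed Optional integer seed for reproducibility.
#' @return A [measurement_series] with provenance.
#' @export
sample_measurements <- function(sim, interval_min = 5,
                                noise_sd = default_noise_sd(),
                                seed = NULL) {
  if (!inherits(sim, "cv_simulation")) stop("sim must be a cv_simulation",
                                            call. = FALSE)
  horizon <- max(sim$time)
  if (interval_min > horizon) {
    stop("sampling interval exceeds the simulation horizon", call. = FALSE)
  }
  vars <- c("HCT", "HR", "SV", "CO", "BP")
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, 5), vars)
  }
  if (any(noise_sd < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  tk <- seq(0, horizon, by = interval_min)
  idx <- match(tk, sim$time)
  if (any(is.na(idx))) {
    stop("simulation grid does not contain all sample times; ",
         "simulate with times including multiples of interval_min",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  base <- vapply(vars, function(v) sim[[v]][sim$time == 0][1], 1.0)
  obs <- lapply(vars, function(v) {
    x <- sim[[v]][idx] + stats::rnorm(length(tk), 0, noise_sd[[v]] * base[[v]])
    x[!is.na(x) & x <= 0] <- NA_real_   # censor non-physical readings
    x
  })
  names(obs) <- vars
  measurement_series(tk, HCT = obs$HCT, HR = obs$HR, SV = obs$SV,
                     CO = obs$CO, BP = obs$BP,
                     provenance = list(subject_id = attr(sim, "subject_id"),
                                       noise_sd = noise_sd, seed = seed,
                                       interval_min = interval_min))
}

#' Controller settings for the sheep-protocol infusion phase
#'
#' The original resuscitation used a closed-loop infusion controller that
#' is not specified here; the stand-in is a discrete proportional-integral
#' law that updates the infusion rate every `update_min` minutes to drive
#' the simulated mean arterial pressure of a reference subject back toward
#' its baseline, with the rate clamped to `[0, u_max]` l/min.  This
#' produces qualitatively realistic resuscitation profiles and is a fixture
#' of this package, not a reconstruction of the original device.
#'
#' @param kp Proportional gain, l/min per mmHg.  The default 0.002 maps the
#'   worst-case pressure error after the bulk hemorrhage (~40 mmHg) to
#'   about 0.08 l/min, i.e. ~2 ml/kg/min for a 40-kg animal -- the upper
#'   end of realistic crystalloid resuscitation rates.
#' @param ki Integral gain, l/min per (mmHg.min); recovers residual offset
#'   over tens of minutes.
#' @param u_max Infusion-rate clamp, l/min.
#' @param update_min Controller update interval, min.
#' @param reference_params Parameter vector the controller is simulated
#'   against when freezing the infusion profile; default: reference subject
#'   LR1.
#' @return Named list of settings.
#' @export
sheep_controller <- function(kp = 0.002, ki = 1e-4, u_max = 0.3,
                             update_min = 5, reference_params = NULL) {
  list(kp = kp, ki = ki, u_max = u_max, update_min = update_min,
       reference_params = reference_params)
}

#' Synthetic sheep fluid-perturbation protocol
#'
#' A 180-minute experiment: 25 ml/kg hemorrhage spread uniformly over
#' minutes 0--15, two further 5 ml/kg hemorrhages over minutes 50--55 and
#' 70--75, and a resuscitation infusion over the final 150 minutes
#' (starting at minute 30) produced by the stand-in closed-loop law of
#' [sheep_controller()] and frozen into an open-loop piecewise-constant
#' profile.
#'
#' @param weight_kg Body weight in kg.
#' @param controller Settings from [sheep_controller()].
#' @param seed Unused by the deterministic controller; accepted so callers
#'   can treat protocol generation uniformly.
#' @return A [fluid_protocol] of duration 180 min.
#' @examples
#' p <- make_sheep_protocol(40)
#' protocol_volumes(p)["lost"]  # = 35 ml/kg * 40 kg = 1.4 l
#' @export
make_sheep_protocol <- function(weight_kg, controller = sheep_controller(),
                                seed = NULL) {
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be positive", call. = FALSE)
  }
  duration <- 180
  # loss schedule (l/min): 25 ml/kg over [0,15), 5 ml/kg over [50,55) and
  # [70,75)
  v_of <- function(ml_per_kg, mins) ml_per_kg * weight_kg / 1000 / mins
  btime <- c(0, 15, 30, 50, 55, 70, 75)
  bV <- c(v_of(25, 15), 0, 0, v_of(5, 5), 0, v_of(5, 5), 0)

  ref <- controller$reference_params
  if (is.null(ref)) ref <- reference_subjects()[["LR1"]]
  ref <- as_subject_parameters(ref)
  bp_ref <- ref[["H0"]] * ref[["SV0"]] * ref[["TPR0"]]

  upd <- controller$update_min
  tU <- seq(30, duration - upd, by = upd)   # infusion update times
  Uvals <- numeric(length(tU))

  v_at <- function(x) bV[findInterval(x, btime)]
  u_at <- function(x, k) {
    # U after the first k controller updates; zero elsewhere
    if (k < 1) return(numeric(length(x)))
    j <- findInterval(x, tU)
    ifelse(j >= 1 & j <= k, Uvals[pmax(pmin(j, k), 1)], 0)
  }
  protocol_upto <- function(k) {
    times <- sort(unique(c(btime, tU)))
    fluid_protocol(times, U = u_at(times, k), V = v_at(times),
                   duration = duration)
  }

  # grow the infusion profile update by update: simulate the reference
  # subject under the profile built so far, read its BP at the update time,
  # and hold the PI-controlled rate for the next update_min minutes
  e_int <- 0
  for (i in seq_along(tU)) {
    sim <- simulate_subject(ref, protocol_upto(i - 1), times = tU[i])
    err <- bp_ref - sim$BP[nrow(sim)]
    e_int <- e_int + err * upd
    u <- controller$kp * err + controller$ki * e_int
    Uvals[i] <- min(max(u, 0), controller$u_max)
  }
  protocol_upto(length(tU))
}

#' Synthetic swine-like fluid-perturbation protocol
#'
#' Hemorrhage at a fixed weight-scaled rate until the simulated mean
#' arterial pressure of `params` first crosses `bp_stop_mmHg`, followed by
#' repeated boluses of `500 * weight_kg / 70` ml (each infused over
#' `bolus_min` minutes) separated by 60-minute washouts, up to
#' `max_duration` minutes.
#'
#' @param weight_kg Body weight in kg.
#' @param params Parameter vector used to locate the pressure target by
#'   forward simulation.
#' @param hemorrhage_rate_ml_per_kg_min Hemorrhage rate; the default
#'   1 ml/kg/min is a package choice, configurable.
#' @param bp_stop_mmHg Pressure at which hemorrhage stops (mmHg).
#' @param bolus_min Duration of each bolus infusion (min).
#' @param washout_min Washout after each bolus (min).
#' @param max_duration Maximum protocol duration (min).
#' @return A [fluid_protocol].
#' @export
make_swine_protocol <- function(weight_kg, params,
                                hemorrhage_rate_ml_per_kg_min = 1,
                                bp_stop_mmHg = 40, bolus_min = 5,
                                washout_min = 60, max_duration = 240) {
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be positive", call. = FALSE)
  }
  if (hemorrhage_rate_ml_per_kg_min <= 0) {
    stop("hemorrhage rate must be positive", call. = FALSE)
  }
  if (bp_stop_mmHg <= 0 || bp_stop_mmHg >= 150) {
    stop("bp_stop_mmHg must lie in (0, 150)", call. = FALSE)
  }
  params <- as_subject_parameters(params)
  v_rate <- hemorrhage_rate_ml_per_kg_min * weight_kg / 1000

  # find the first BP crossing under pure hemorrhage on a fine grid
  probe <- fluid_protocol(0, U = 0, V = v_rate, duration = max_duration)
  sim <- simulate_subject(params, probe, output_interval = 0.1)
  cross <- which(sim$BP <= bp_stop_mmHg & is.finite(sim$BP))
  if (!length(cross)) {
    stop("target unreachable: BP never fell to ", bp_stop_mmHg,
         " mmHg within ", max_duration, " min", call. = FALSE)
  }
  t_stop <- sim$time[cross[1]]

  bolus_l <- 0.5 * weight_kg / 70
  u_bolus <- bolus_l / bolus_min
  btime <- 0
  bU <- 0
  bV <- v_rate
  t <- t_stop
  while (t + bolus_min + washout_min <= max_duration) {
    btime <- c(btime, t, t + bolus_min)
    bU <- c(bU, u_bolus, 0)
    bV <- c(bV, 0, 0)
    t <- t + bolus_min + washout_min
  }
  if (t == t_stop) {       # no full bolus cycle fits: just stop hemorrhage
    btime <- c(btime, t_stop)
    bU <- c(bU, 0)
    bV <- c(bV, 0)
    t <- t_stop + washout_min
  }
  duration <- min(max(120, t), max_duration)
  fluid_protocol(btime, bU, bV, duration = duration)
}

#' Read a measurement series from CSV
#'
#' Expected columns: `time_min,HCT_pct,HR_bpm,SV_l,CO_l_per_min,BP_mmHg`;
#' empty cells are missing values.
#'
#' @param path CSV file path.
#' @return A [measurement_series].
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_min", "HCT_pct", "HR_bpm", "SV_l", "CO_l_per_min",
            "BP_mmHg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("measurement file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  measurement_series(df$time_min, HCT = df$HCT_pct, HR = df$HR_bpm,
                     SV = df$SV_l, CO = df$CO_l_per_min, BP = df$BP_mmHg)
}

#' Write a measurement series to CSV
#'
#' @param meas A [measurement_series].
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(meas, path) {
  df <- data.frame(time_min = meas$time, HCT_pct = meas$HCT,
                   HR_bpm = meas$HR, SV_l = meas$SV,
                   CO_l_per_min = meas$CO, BP_mmHg = meas$BP)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
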