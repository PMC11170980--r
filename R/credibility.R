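#' @title Credibility metrics and predictive-capability assessment
#' @description
#' Calibration quality is summarized by normalized errors (NRMSE, NMAE) and
#' the negative log-likelihood.  Predictive capability against a test
#' subject follows a three-step pipeline: simulate a virtual cohort under
#' the test protocol, keep physiologically plausible simulations, keep the
#' *relevant* ones (NRMSE at or below 25% on every observed variable),
#' then summarize the best virtual subject, the prediction envelope
#' (pointwise min/max over relevant simulations at measurement times), the
#' data coverage of the envelope, and the normalized interval score (NIS),
#' which penalizes observations falling outside the envelope at
#' significance level 0.05.
#' @name credibility
NULL

.assessed_vars <- c("HCT", "HR", "SV", "CO", "BP")

#' Normalized root-mean-square error (percent)
#'
#' `100 * sqrt(mean((v - vhat)^2)) / mean(v)`; pairs with a missing
#' observation are skipped.
#'
#' @param observed Observed series (may contain `NA`).
#' @param simulated Simulated series, same length.
#' @return NRMSE in percent of the observed mean.
#' @export
nrmse <- function(observed, simulated) {
  keep <- !is.na(observed) & !is.na(simulated)
  v <- observed[keep]
  vh <- simulated[keep]
  if (!length(v)) stop("no overlapping observations", call. = FALSE)
  vbar <- mean(v)
  if (vbar == 0) stop("observed mean is zero", call. = FALSE)
  100 * sqrt(mean((v - vh)^2)) / vbar
}

#' Normalized mean absolute error (percent)
#'
#' `100 * mean(abs(v - vhat)) / mean(v)`.
#'
#' @inheritParams nrmse
#' @return NMAE in percent of the observed mean.
#' @export
nmae <- function(observed, simulated) {
  keep <- !is.na(observed) & !is.na(simulated)
  v <- observed[keep]
  vh <- simulated[keep]
  if (!length(v)) stop("no overlapping observations", call. = FALSE)
  vbar <- mean(v)
  if (vbar == 0) stop("observed mean is zero", call. = FALSE)
  100 * mean(abs(v - vh)) / vbar
}

#' Physiological plausibility ranges
#'
#' A simulation is physiological when, at every output time, hematocrit
#' lies in (0, 50] %, heart rate in (0, 300] bpm, stroke volume in
#' (0, 0.100] l and pressure in (0, 150] mmHg (cardiac output is
#' unconstrained).  Boundary values are kept.
#'
#' @param sim A `"cv_simulation"`.
#' @return Logical: `TRUE` if physiological over the whole trajectory (a
#'   failed simulation is not).
#' @export
is_physiological <- function(sim) {
  if (!isTRUE(attr(sim, "success"))) return(FALSE)
  all(sim$HCT > 0 & sim$HCT <= 50) &&
    all(sim$HR > 0 & sim$HR <= 300) &&
    all(sim$SV > 0 & sim$SV <= 0.100) &&
    all(sim$BP > 0 & sim$BP <= 150)
}

#' Filter simulations to the physiological subset
#'
#' @param sims List of `"cv_simulation"` objects.
#' @return List with `kept` (the surviving simulations), `indices` and
#'   `percentage` of the input that survived.
#' @export
physiological_filter <- function(sims) {
  ok <- vapply(sims, is_physiological, TRUE)
  list(kept = sims[ok], indices = which(ok),
       percentage = 100 * mean(ok))
}

# per-variable NRMSE of one simulation against the measurements; the
# simulation grid must contain the measurement times
sim_nrmse <- function(sim, measurements) {
  idx <- match(measurements$time, sim$time)
  if (any(is.na(idx))) {
    stop("simulation grid does not contain the measurement times",
         call. = FALSE)
  }
  vapply(.assessed_vars, function(v)
    nrmse(measurements[[v]], sim[[v]][idx]), 1.0)
}

#' Filter physiological simulations to the relevant subset
#'
#' A simulation is relevant when its NRMSE against the test measurements
#' is at or below `threshold` percent on every one of HCT, HR, SV, CO and
#' BP; a single failing variable disqualifies it.
#'
#' @param sims List of physiological `"cv_simulation"` objects.
#' @param measurements Test [measurement_series].
#' @param threshold Relevance threshold in percent (default 25).
#' @return List with `kept`, `indices`, `percentage` (of the input) and
#'   `nrmse` (matrix of per-variable NRMSE, one row per input simulation).
#' @export
relevance_filter <- function(sims, measurements, threshold = 25) {
  if (!length(sims)) {
    return(list(kept = list(), indices = integer(0), percentage = NaN,
                nrmse = NULL))
  }
  err <- t(vapply(sims, sim_nrmse, numeric(5), measurements = measurements))
  colnames(err) <- .assessed_vars
  ok <- apply(err <= threshold, 1, all)
  list(kept = sims[ok], indices = which(ok), percentage = 100 * mean(ok),
       nrmse = err)
}

#' Build a prediction envelope from relevant simulations
#'
#' The envelope is the pointwise minimum and maximum across the relevant
#' simulations, per variable, at each measurement time.
#'
#' @param sims Non-empty list of relevant `"cv_simulation"` objects.
#' @param times Measurement times at which to evaluate the envelope.
#' @return Long data frame of class `"prediction_envelope"` with columns
#'   `variable`, `time`, `lower`, `upper`; attribute `n_relevant`.
#' @export
build_envelope <- function(sims, times) {
  if (!length(sims)) {
    stop("no relevant simulations: envelope undefined", call. = FALSE)
  }
  rows <- lapply(.assessed_vars, function(v) {
    vals <- vapply(sims, function(s) s[[v]][match(times, s$time)],
                   numeric(length(times)))
    vals <- matrix(vals, nrow = length(times))
    data.frame(variable = v, time = times,
               lower = apply(vals, 1, min), upper = apply(vals, 1, max))
  })
  structure(do.call(rbind, rows),
            class = c("prediction_envelope", "data.frame"),
            n_relevant = length(sims))
}

envelope_bounds <- function(envelope, variable, times) {
  e <- envelope[envelope$variable == variable, , drop = FALSE]
  idx <- match(times, e$time)
  list(lower = e$lower[idx], upper = e$upper[idx])
}

#' Envelope coverage of the test data (percent)
#'
#' Per variable, the fraction of measurement points lying inside
#' `[lower, upper]`; the unweighted mean across the five variables is
#' returned, in percent.
#'
#' @param envelope A [build_envelope()] result.
#' @param measurements Test [measurement_series].
#' @return Coverage in percent.
#' @export
envelope_coverage <- function(envelope, measurements) {
  fr <- vapply(.assessed_vars, function(v) {
    b <- envelope_bounds(envelope, v, measurements$time)
    obs <- measurements[[v]]
    keep <- !is.na(obs) & !is.na(b$lower)
    mean(obs[keep] >= b$lower[keep] & obs[keep] <= b$upper[keep])
  }, 1.0)
  100 * mean(fr)
}

#' Normalized interval score of the envelope
#'
#' Per observation the score is the relative envelope width
#' `(upper - lower) / v`, plus a penalty `(2 / alpha) * distance / v` when
#' the observation falls outside the envelope.  The per-variable score is
#' the mean over measurement points; smaller is better, and values below 1
#' indicate predictions within +/-50% of the observations at the default
#' `alpha`.
#'
#' @param envelope A [build_envelope()] result.
#' @param measurements Test [measurement_series]; all observed values must
#'   be positive.
#' @param alpha Significance level (default 0.05).
#' @return Named numeric vector of per-variable NIS.
#' @export
nis <- function(envelope, measurements, alpha = 0.05) {
  vapply(.assessed_vars, function(v) {
    b <- envelope_bounds(envelope, v, measurements$time)
    obs <- measurements[[v]]
    keep <- !is.na(obs) & !is.na(b$lower)
    obs <- obs[keep]
    lo <- b$lower[keep]
    up <- b$upper[keep]
    if (any(obs <= 0)) stop("observed values must be positive for NIS",
                            call. = FALSE)
    width <- up - lo
    pen <- ifelse(obs < lo, (2 / alpha) * (lo - obs),
                  ifelse(obs > up, (2 / alpha) * (obs - up), 0))
    mean((width + pen) / obs)
  }, 1.0)
}

#' Select and score the best virtual subject
#'
#' Among the relevant simulations the best subject minimizes the average
#' NRMSE across the five variables (ties: smaller maximum NRMSE, then the
#' smaller cohort index).  Its maximum/average NRMSE and NMAE and its
#' negative log-likelihood against the test data (concentrated per-variable
#' SD over HCT, HR, SV, BP) are reported.
#'
#' @param sims Non-empty list of relevant `"cv_simulation"` objects.
#' @param measurements Test [measurement_series].
#' @param sigma_floor Floor for the concentrated error SD.
#' @return List with `index`, `subject_id`, `max_nrmse`, `avg_nrmse`,
#'   `max_nmae`, `avg_nmae`, `neg_ll`.
#' @export
best_virtual_subject <- function(sims, measurements, sigma_floor = 1e-6) {
  if (!length(sims)) stop("no relevant simulations", call. = FALSE)
  err <- t(vapply(sims, sim_nrmse, numeric(5), measurements = measurements))
  avg <- rowMeans(err)
  mx <- apply(err, 1, max)
  best <- order(avg, mx, seq_along(sims))[1]
  sim <- sims[[best]]
  idx <- match(measurements$time, sim$time)
  nm <- vapply(.assessed_vars, function(v)
    nmae(measurements[[v]], sim[[v]][idx]), 1.0)
  res <- lapply(.calibrated_vars, function(v) {
    e <- measurements[[v]] - sim[[v]][idx]
    e[!is.na(e)]
  })
  names(res) <- .calibrated_vars
  nl <- neg_ll_concentrated(res, sigma_floor = sigma_floor)
  list(index = best, subject_id = attr(sim, "subject_id"),
       max_nrmse = mx[best], avg_nrmse = avg[best],
       max_nmae = max(nm), avg_nmae = mean(nm), neg_ll = nl$neg_ll)
}

#' Assess predictive capability of a cohort against a test subject
#'
#' Simulates every cohort member under the test protocol, applies the
#' physiological and relevance filters, builds the prediction envelope and
#' computes the full credibility report.  Deterministic given the cohort.
#'
#' @param measurements Test [measurement_series].
#' @param protocol Test [fluid_protocol].
#' @param cohort List of virtual subjects (parameter vectors).
#' @param nrmse_threshold Relevance threshold, percent.
#' @param alpha NIS significance level.
#' @param output_interval Grid spacing (min) for the physiological check;
#'   measurement times are always included in the grid.
#' @param sv_hr_sign Model sign convention.
#' @return List of class `"credibility_report"` with elements `best`
#'   (best-virtual-subject metrics or `NULL`), `cohort`
#'   (`pct_physiological`, `pct_relevant`, `pct_coverage`), `nis`
#'   (per-variable or `NULL`), `envelope` (or `NULL`), `flags`, `n`.
#' @export
assess_cohort <- function(measurements, protocol, cohort,
                          nrmse_threshold = 25, alpha = 0.05,
                          output_interval = 1,
                          sv_hr_sign = "physiological") {
  stopifnot(inherits(measurements, "measurement_series"))
  duration <- protocol_duration(protocol)
  grid <- sort(unique(c(seq(0, duration, by = output_interval),
                        measurements$time)))
  n <- length(cohort)
  n_phys <- 0L
  relevant <- list()
  rel_global_idx <- integer(0)
  for (i in seq_len(n)) {
    sim <- simulate_subject(cohort[[i]], protocol, times = grid,
                            sv_hr_sign = sv_hr_sign)
    if (!is_physiological(sim)) next
    n_phys <- n_phys + 1L
    err <- sim_nrmse(sim, measurements)
    if (all(err <= nrmse_threshold)) {
      # keep only the measurement-time restriction to bound memory
      idx <- match(measurements$time, sim$time)
      small <- as.data.frame(sim)[idx, , drop = FALSE]
      class(small) <- c("cv_simulation", "data.frame")
      attr(small, "success") <- TRUE
      attr(small, "subject_id") <- attr(sim, "subject_id")
      relevant[[length(relevant) + 1L]] <- small
      rel_global_idx <- c(rel_global_idx, i)
    }
  }
  flags <- list(no_physiological = n_phys == 0L,
                no_relevant = length(relevant) == 0L)
  envelope <- NULL
  cov <- NA_real_
  nis_v <- NULL
  best <- NULL
  if (length(relevant)) {
    envelope <- build_envelope(relevant, measurements$time)
    cov <- envelope_coverage(envelope, measurements)
    nis_v <- nis(envelope, measurements, alpha = alpha)
    best <- best_virtual_subject(relevant, measurements)
    best$index <- rel_global_idx[best$index]
  }
  structure(list(
    best = best,
    cohort = list(
      pct_physiological = 100 * n_phys / n,
      pct_relevant = if (n_phys > 0)
        100 * length(relevant) / n_phys else NaN,
      pct_coverage = cov
    ),
    nis = nis_v,
    envelope = envelope,
    flags = flags,
    n = n
  ), class = "credibility_report")
}

#' @export
print.credibility_report <- function(x, ...) {
  cat("<credibility_report> cohort n = ", x$n, "\n", sep = "")
  cat(sprintf("  physiological: %.1f%%  relevant: %.1f%%  coverage: %.1f%%\n",
              x$cohort$pct_physiological, x$cohort$pct_relevant,
              x$cohort$pct_coverage))
  if (!is.null(x$nis)) {
    cat("  NIS: ", paste(sprintf("%s=%.2f", names(x$nis), x$nis),
                         collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$best)) {
    cat(sprintf("  best subject: avg NRMSE %.2f%%, max NRMSE %.2f%%, -LL %.1f\n",
                x$best$avg_nrmse, x$best$max_nrmse, x$best$neg_ll))
  }
  if (x$flags$no_relevant) cat("  [no relevant simulations]\n")
  invisible(x)
}

#' Serialize a credibility report to JSON
#'
#' @param report A `"credibility_report"`.
#' @param path Output JSON file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    best_subject = if (!is.null(report$best)) report$best[
      c("subject_id", "max_nrmse", "avg_nrmse", "max_nmae", "avg_nmae",
        "neg_ll")],
    cohort = report$cohort,
    nis = if (!is.null(report$nis)) as.list(report$nis),
    flags = report$flags,
    n = report$n
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a prediction envelope to CSV
#'
#' Columns: `variable,time_min,lower,upper,n_relevant`.
#'
#' @param envelope A [build_envelope()] result.
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  df <- data.frame(variable = envelope$variable,
                   time_min = envelope$time,
                   lower = envelope$lower, upper = envelope$upper,
                   n_relevant = attr(envelope, "n_relevant"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
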