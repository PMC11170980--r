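#' @title Maximum-likelihood calibration
#' @description
#' Calibration fits the 22 free model parameters of a subject (everything
#' except the measured baselines `BV0`, `HCT0`, `SV0`) to sparse noisy
#' measurement series by maximum likelihood under an i.i.d. Gaussian error
#' model with an independent error variance per variable.  The per-variable
#' variances are concentrated out analytically, and an L2 penalty on
#' scale-normalized parameters regularizes the fit.  Cardiac output is not
#' part of the likelihood (it is the product of two fitted variables) but
#' is reported in the fit metrics.
#' @name calibration
NULL

.calibrated_vars <- c("HCT", "HR", "SV", "BP")

#' Free (calibrated) parameter names
#'
#' All parameters except the measured baselines `BV0`, `HCT0` and `SV0`;
#' note that `H0` and `TPR0` are estimated.
#'
#' @return Character vector of 22 names.
#' @export
calibrated_parameter_names <- function() {
  setdiff(parameter_names("all"), c("BV0", "HCT0", "SV0"))
}

reference_parameter_matrix <- function() {
  do.call(rbind, lapply(reference_subjects(), unclass))
}

#' Per-parameter scale constants
#'
#' The parameters span several orders of magnitude, so the L2 penalty and
#' the optimizer operate on `theta / scale`.  The scale of each parameter
#' is the largest magnitude it attains across the packaged reference
#' subjects (floored at 1e-3 for parameters that are essentially zero
#' everywhere).
#'
#' @return Named numeric vector over the free parameters.
#' @export
parameter_scales <- function() {
  m <- reference_parameter_matrix()
  nm <- calibrated_parameter_names()
  s <- apply(abs(m[, nm, drop = FALSE]), 2, max)
  pmax(s, 1e-3)
}

#' Box bounds for the free parameters
#'
#' Sign-constrained boxes derived from the spread of the packaged reference
#' subjects, widened threefold: stability parameters stay non-positive,
#' gains non-negative, the power exponents in `[0, 1]`, the fluid
#' distribution ratios above -0.95 (so `1 + alpha > 0`), and the positive
#' reference/baseline parameters within a threefold band of the observed
#' range.
#'
#' @return List with named numeric vectors `lower` and `upper`.
#' @export
parameter_bounds <- function() {
  m <- reference_parameter_matrix()
  nm <- calibrated_parameter_names()
  lo <- apply(m[, nm, drop = FALSE], 2, min)
  hi <- apply(m[, nm, drop = FALSE], 2, max)
  lower <- numeric(length(nm))
  upper <- numeric(length(nm))
  names(lower) <- names(upper) <- nm
  for (p in nm) {
    if (p %in% c("A_U_BV", "A_V_BV", "A_SV", "A_BP")) {
      lower[p] <- 3 * lo[p]
      upper[p] <- 0
    } else if (p %in% c("alpha_U", "alpha_V")) {
      lower[p] <- max(-0.95, 3 * lo[p])
      upper[p] <- 3 * hi[p]
    } else if (p %in% c("P_U_T", "P_V_L")) {
      lower[p] <- 0
      upper[p] <- 1
    } else if (p %in% c("r_SV", "r_BP", "H0", "TPR0")) {
      lower[p] <- lo[p] / 3
      upper[p] <- 3 * hi[p]
    } else {
      lower[p] <- 0
      upper[p] <- 3 * hi[p]
    }
  }
  list(lower = lower, upper = upper)
}

#' Calibration configuration
#'
#' @param beta L2 penalty weight (>= 0); default 1e-3.
#' @param n_starts Number of optimization starts (>= 1).
#' @param seed Integer seed for the random starts.
#' @param maxit Iteration cap per start (L-BFGS-B).
#' @param sigma_floor Lower bound on each concentrated error SD, in the
#'   variable's units; prevents likelihood divergence on noiseless data.
#' @param penalty `"squared"` penalizes `2*beta*||theta/s||^2` (default);
#'   `"norm"` the unsquared norm.
#' @param bounds,scales Optional overrides of [parameter_bounds()] /
#'   [parameter_scales()].
#' @param init Optional [subject_parameters] (or named vector) used as the
#'   first start.
#' @param max_start_tries Rejection-sampling cap when drawing a feasible
#'   start (uniform draws within bounds are kept only if the initial
#'   simulation succeeds).
#' @param polish_top,polish_maxit After the first pass, the `polish_top`
#'   best starts are continued for up to `polish_maxit` further iterations.
#' @param staged_init Seed one start from a staged block-by-block fit that
#'   follows the model's cascade structure (see the methods vignette).
#' @param sv_hr_sign Model sign convention, see [derivatives()].
#' @return List of class `"calibration_config"`.
#' @export
calibration_config <- function(beta = 1e-3, n_starts = 16, seed = 1,
                               maxit = 150, sigma_floor = 1e-6,
                               penalty = c("squared", "norm"),
                               bounds = NULL, scales = NULL, init = NULL,
                               max_start_tries = 500, polish_top = 4,
                               polish_maxit = 400, staged_init = TRUE,
                               sv_hr_sign = "physiological") {
  stopifnot(beta >= 0, n_starts >= 1, sigma_floor > 0)
  structure(list(beta = beta, n_starts = n_starts, seed = seed,
                 maxit = maxit, sigma_floor = sigma_floor,
                 penalty = match.arg(penalty), bounds = bounds,
                 scales = scales, init = init,
                 max_start_tries = max_start_tries,
                 polish_top = polish_top, polish_maxit = polish_maxit,
                 staged_init = staged_init, sv_hr_sign = sv_hr_sign),
            class = "calibration_config")
}

#' Residuals of a parameter set against measurements
#'
#' Simulates the model at the exact measurement times and returns, per
#' variable, the observation-minus-model residual sequence (missing values
#' skipped).
#'
#' @param params A [subject_parameters] vector.
#' @param measurements A [measurement_series].
#' @param protocol A [fluid_protocol].
#' @param sv_hr_sign Model sign convention.
#' @return Named list of numeric residual vectors for HCT, HR, SV, CO, BP.
#' @export
model_residuals <- function(params, measurements, protocol,
                            sv_hr_sign = "physiological") {
  sim <- simulate_subject(params, protocol, times = measurements$time,
                          sv_hr_sign = sv_hr_sign)
  if (!isTRUE(attr(sim, "success"))) {
    stop("simulation failed at t = ", attr(sim, "t_fail"),
         " min during residual evaluation", call. = FALSE)
  }
  vars <- c("HCT", "HR", "SV", "CO", "BP")
  out <- lapply(vars, function(v) {
    e <- measurements[[v]] - sim[[v]]
    e[!is.na(e)]
  })
  names(out) <- vars
  out
}

#' Concentrated maximum-likelihood error SD
#'
#' For fixed model parameters the Gaussian likelihood is maximized at
#' `sigma^2 = mean(e^2)`; the result is floored to avoid degeneracy on
#' noiseless data.
#'
#' @param residuals Numeric residual vector (length >= 2).
#' @param floor Lower bound on the returned SD.
#' @return The estimated SD.
#' @export
sigma_mle <- function(residuals, floor = 1e-6) {
  if (length(residuals) < 2) {
    stop("need at least 2 residuals to estimate sigma", call. = FALSE)
  }
  max(sqrt(mean(residuals^2)), floor)
}

#' Gaussian log-likelihood of a residual sequence
#'
#' `L* = -(K/2) log(2 pi) - (K/2) log sigma^2 - sum(e^2) / (2 sigma^2)`.
#'
#' @param residuals Numeric residual vector.
#' @param sigma Error SD (> 0).
#' @return The log-likelihood value.
#' @export
log_likelihood <- function(residuals, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  K <- length(residuals)
  -K / 2 * log(2 * pi) - K / 2 * log(sigma^2) -
    sum(residuals^2) / (2 * sigma^2)
}

# -LL over the calibrated variables at the concentrated sigma
neg_ll_concentrated <- function(res, sigma_floor = 1e-6) {
  s <- vapply(.calibrated_vars,
              function(v) sigma_mle(res[[v]], floor = sigma_floor), 1.0)
  ll <- vapply(.calibrated_vars,
               function(v) log_likelihood(res[[v]], s[[v]]), 1.0)
  list(neg_ll = -sum(ll), sigma = s, ll = ll)
}

#' Calibration objective
#'
#' The regularized negative log-likelihood minimized during calibration:
#' `-sum_v L*_v` over HCT, HR, SV and BP (cardiac output excluded) at the
#' per-variable concentrated SD, plus the L2 penalty on scale-normalized
#' free parameters.  A failed simulation returns the large finite value
#' 1e12 so line searches can back off rather than abort.
#'
#' @param params A [subject_parameters] vector.
#' @param measurements A [measurement_series].
#' @param protocol A [fluid_protocol].
#' @param beta Penalty weight (>= 0).
#' @param config A [calibration_config] (supplies floor, penalty form,
#'   scales and sign convention); `beta` overrides its penalty weight.
#' @return Scalar objective value.
#' @export
calibration_objective <- function(params, measurements, protocol,
                                  beta = NULL,
                                  config = calibration_config()) {
  if (is.null(beta)) beta <- config$beta
  sim <- tryCatch(
    simulate_subject(params, protocol, times = measurements$time,
                     sv_hr_sign = config$sv_hr_sign),
    error = function(e) NULL
  )
  if (is.null(sim)) return(1e12)
  if (!isTRUE(attr(sim, "success"))) {
    # graded penalty: failing later is better, so finite differences point
    # back toward the feasible region
    t_fail <- attr(sim, "t_fail")
    horizon <- max(measurements$time)
    frac <- if (is.finite(t_fail)) min(t_fail / horizon, 1) else 0
    return(1e10 * (2 - frac))
  }
  vars <- c("HCT", "HR", "SV", "CO", "BP")
  res <- lapply(vars, function(v) {
    e <- measurements[[v]] - sim[[v]]
    e[!is.na(e)]
  })
  names(res) <- vars
  if (any(!vapply(res, function(e) all(is.finite(e)), TRUE))) {
    return(1e10)   # numerically overflowing but formally successful run
  }
  nl <- neg_ll_concentrated(res, sigma_floor = config$sigma_floor)
  scales <- if (is.null(config$scales)) parameter_scales() else config$scales
  free <- calibrated_parameter_names()
  z <- unclass(as_subject_parameters(params))[free] / scales[free]
  pen <- if (config$penalty == "squared") {
    2 * beta * sum(z^2)
  } else {
    2 * beta * sqrt(sum(z^2))
  }
  val <- nl$neg_ll + pen
  if (!is.finite(val)) return(1e10)   # overflow in the error sums
  val
}

# Fast objective over scaled free parameters: numerically equivalent to
# calibration_objective() but talks to the compiled kernel directly and
# skips per-call validation/data-frame construction (the optimizer spends
# ~10^5 evaluations here).  The returned closure takes an optional subset
# of likelihood variables, which the staged initializer uses to fit one
# sub-model at a time.
make_fast_objective <- function(measurements, protocol, baselines, config,
                                scales, free, dt = 0.02) {
  all_names <- parameter_names("all")
  idx_free <- match(free, all_names)
  pvec <- numeric(25)
  pvec[match(c("HCT0", "BV0", "SV0"), all_names)] <-
    baselines[c("HCT0", "BV0", "SV0")]
  tk <- as.numeric(measurements$time)
  horizon <- max(tk)
  obs <- lapply(c("HCT", "HR", "SV", "BP"), function(v) measurements[[v]])
  names(obs) <- c("HCT", "HR", "SV", "BP")
  keep <- lapply(obs, function(x) !is.na(x))
  Kv <- vapply(keep, sum, 1L)
  sv_hr <- sv_hr_coefficient(config$sv_hr_sign)
  bt <- as.numeric(protocol$time)
  bU <- as.numeric(protocol$U)
  bV <- as.numeric(protocol$V)
  dur <- as.numeric(protocol_duration(protocol))
  sfree <- scales[free]
  eps <- config$sigma_floor
  beta <- config$beta
  squared <- config$penalty == "squared"
  i_H0 <- match("H0", all_names)

  function(z, vars = c("HCT", "HR", "SV", "BP")) {
    pvec[idx_free] <- z * sfree
    res <- .Call(C_simulate_rk4, pvec, sv_hr, bt, bU, bV, dur, tk, dt)
    if (!res$success) {
      t_fail <- res$t_fail
      frac <- if (is.finite(t_fail)) min(t_fail / horizon, 1) else 0
      return(1e10 * (2 - frac))
    }
    st <- res$states
    HR <- pvec[i_H0] + st[, 6] + st[, 7] - st[, 9]
    sim <- list(HCT = st[, 4] / st[, 3], HR = HR, SV = st[, 10],
                BP = HR * st[, 10] * st[, 11])
    nll <- 0
    for (v in vars) {
      e <- (obs[[v]] - sim[[v]])[keep[[v]]]
      rss <- sum(e * e)
      K <- Kv[[v]]
      s2 <- max(rss / K, eps^2)
      nll <- nll + K / 2 * log(2 * pi) + K / 2 * log(s2) + rss / (2 * s2)
    }
    pen <- if (squared) 2 * beta * sum(z^2) else 2 * beta * sqrt(sum(z^2))
    val <- nll + pen
    if (!is.finite(val)) return(1e10)
    val
  }
}

# Random start in scaled coordinates.  Rate constants and gains span
# orders of magnitude (and cluster orders of magnitude below their bound,
# which is set by the extreme reference subject), so sign-constrained
# parameters draw their magnitude log-uniformly over three decades below
# the bound; exponents, distribution ratios and the positive reference
# levels are O(1) and draw uniformly.
draw_scaled_start <- function(zl, zu, free) {
  vapply(seq_along(free), function(j) {
    l <- zl[j]
    u <- zu[j]
    if (free[j] %in% c("P_U_T", "P_V_L") || (l < 0 && u > 0) || l > 0) {
      stats::runif(1, l, u)
    } else if (u == 0 && l < 0) {
      -10^stats::runif(1, log10(-l) - 3, log10(-l))
    } else if (l == 0 && u > 0) {
      10^stats::runif(1, log10(u) - 3, log10(u))
    } else {
      stats::runif(1, l, u)
    }
  }, 1.0)
}

# Staged initialization exploiting the cascade structure of the model: the
# hematocrit trajectory depends only on the blood-volume compartment, heart
# rate only on the heart-rate compartment (plus H0), stroke volume on the
# BV/HR/SV compartments, and pressure on everything.  Each block is fitted
# to its own variable with a small multi-start before the joint refinement.
staged_start <- function(fnv, free, zl, zu, n_sub = 8, maxit = 150) {
  blocks <- list(
    list(pars = c("A_U_BV", "A_V_BV", "alpha_U", "alpha_V", "K_P_BV"),
         var = "HCT"),
    list(pars = c("G_U_T", "G_V_T", "G_V_L", "P_U_T", "P_V_L", "K_P_H",
                  "K_I_H", "H0"), var = "HR"),
    list(pars = c("G_BV", "G_HR", "A_SV", "r_SV", "K_P_SV"), var = "SV"),
    list(pars = c("A_BP", "K_P_BP", "r_BP", "TPR0"), var = "BP")
  )
  # inert base point: zero gains and state parameters wherever the box
  # allows (guaranteed-stable dynamics), positive references mid-box --
  # this always simulates, so every stage starts feasible
  z <- pmin(pmax(0, zl), zu)
  for (p in c("r_SV", "r_BP", "H0", "TPR0")) {
    j <- match(p, free)
    z[j] <- (zl[j] + zu[j]) / 2
  }
  for (b in blocks) {
    idx <- match(b$pars, free)
    fsub <- function(zi) {
      zz <- z
      zz[idx] <- zi
      fnv(zz, vars = b$var)
    }
    gsub <- function(zi) {
      f0 <- fsub(zi)
      h <- 1e-6 * pmax(abs(zi), 1)
      vapply(seq_along(zi), function(j) {
        zj <- zi
        zj[j] <- min(zj[j] + h[j], zu[idx][j])
        if (zj[j] == zi[j]) zj[j] <- max(zi[j] - h[j], zl[idx][j])
        if (zj[j] == zi[j]) return(0)
        (fsub(zj) - f0) / (zj[j] - zi[j])
      }, 1.0)
    }
    inits <- c(list(z[idx]),
               lapply(seq_len(n_sub), function(i)
                 draw_scaled_start(zl[idx], zu[idx], free[idx])))
    best <- NULL
    for (zi in inits) {
      r <- tryCatch(
        stats::optim(zi, fsub, gr = gsub, method = "L-BFGS-B",
                     lower = zl[idx], upper = zu[idx],
                     control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(r) && (is.null(best) || r$value < best$value)) best <- r
    }
    if (!is.null(best)) z[idx] <- best$par
  }
  z
}

#' Calibrate a subject from measurements
#'
#' Multi-start bounded quasi-Newton (L-BFGS-B) minimization of
#' [calibration_objective()] over the 22 free parameters, holding the
#' measured baselines `BV0`, `HCT0`, `SV0` fixed.  The optimizer works on
#' scale-normalized parameters; starts are uniform draws within the bounds
#' under the configuration seed (with `config$init` as the first start if
#' supplied), and the most promising starts are polished with a longer
#' iteration budget.  Gradients are forward finite differences of a fast
#' internal objective path that talks to the compiled simulation kernel
#' directly.  The best start by final objective is returned.
#'
#' @param measurements A [measurement_series] spanning at least two samples
#'   per calibrated variable.
#' @param protocol The [fluid_protocol] the measurements were collected
#'   under.
#' @param baselines Named values for the fixed baselines: `BV0`, `HCT0`,
#'   `SV0`.
#' @param config A [calibration_config].
#' @return List of class `"calibration_result"`: `params` (fitted
#'   [subject_parameters]), `sigma` (per calibrated variable), `neg_ll`,
#'   `objective`, `nrmse` and `nmae` per variable (all five), `starts`
#'   (per-start objective and convergence), `best_start`.
#' @export
calibrate_subject <- function(measurements, protocol, baselines,
                              config = calibration_config()) {
  stopifnot(inherits(measurements, "measurement_series"))
  for (v in .calibrated_vars) {
    if (sum(!is.na(measurements[[v]])) < 2) {
      stop("need at least 2 samples of ", v, " to calibrate",
           call. = FALSE)
    }
  }
  baselines <- unlist(baselines)
  if (!all(c("BV0", "HCT0", "SV0") %in% names(baselines))) {
    stop("baselines must name BV0, HCT0 and SV0", call. = FALSE)
  }

  free <- calibrated_parameter_names()
  scales <- if (is.null(config$scales)) parameter_scales() else config$scales
  bounds <- if (is.null(config$bounds)) parameter_bounds() else config$bounds
  zl <- bounds$lower[free] / scales[free]
  zu <- bounds$upper[free] / scales[free]

  build_params <- function(z) {
    theta <- z * scales[free]
    full <- c(theta, baselines[c("HCT0", "BV0", "SV0")])
    names(full) <- c(free, "HCT0", "BV0", "SV0")
    subject_parameters(full[parameter_names("all")])
  }
  fn <- make_fast_objective(measurements, protocol, baselines, config,
                            scales, free)

  # uniform draws within the bounds, rejected until the initial simulation
  # is feasible (most of the widened box is dynamically unstable, where the
  # objective carries no local information)
  set.seed(config$seed)
  draw_start <- function() {
    for (try in seq_len(config$max_start_tries)) {
      z0 <- draw_scaled_start(zl, zu, free)
      if (fn(z0) < 1e10) return(z0)
    }
    z0
  }
  starts <- lapply(seq_len(config$n_starts), function(i) draw_start())
  if (isTRUE(config$staged_init) && config$n_starts > 1) {
    starts[[length(starts)]] <- staged_start(fn, free, zl, zu)
  }
  if (!is.null(config$init)) {
    th <- unclass(as_subject_parameters(config$init))[free]
    starts[[1]] <- pmin(pmax(th / scales[free], zl), zu)
  }

  # forward-difference gradient of the fast objective
  gr <- function(z) {
    f0 <- fn(z)
    h <- 1e-6 * pmax(abs(z), 1)
    vapply(seq_along(z), function(j) {
      zj <- z
      zj[j] <- min(zj[j] + h[j], zu[j])
      if (zj[j] == z[j]) {           # at the upper bound: step inward
        zj[j] <- max(z[j] - h[j], zl[j])
        if (zj[j] == z[j]) return(0)
        return((f0 - fn(zj)) / (z[j] - zj[j]))
      }
      (fn(zj) - f0) / (zj[j] - z[j])
    }, 1.0)
  }
  one_run <- function(z0, maxit) {
    tryCatch(
      stats::optim(z0, fn, gr = gr, method = "L-BFGS-B", lower = zl,
                   upper = zu, control = list(maxit = maxit)),
      error = function(e) list(par = z0, value = fn(z0), convergence = 99,
                               message = conditionMessage(e))
    )
  }
  runs <- lapply(starts, one_run, maxit = config$maxit)
  # polish the most promising starts with a longer iteration budget
  vals <- vapply(runs, function(r) r$value, 1.0)
  top <- order(vals)[seq_len(min(config$polish_top, length(runs)))]
  for (i in top) {
    runs[[i]] <- one_run(runs[[i]]$par, maxit = config$polish_maxit)
  }
  values <- vapply(runs, function(r) r$value, 1.0)
  if (all(values >= 1e12)) {
    stop("all optimization starts failed; per-start objectives: ",
         paste(signif(values, 4), collapse = ", "), call. = FALSE)
  }
  best <- which.min(values)
  params <- build_params(runs[[best]]$par)
  res <- model_residuals(params, measurements, protocol,
                         sv_hr_sign = config$sv_hr_sign)
  nl <- neg_ll_concentrated(res, sigma_floor = config$sigma_floor)
  vars <- c("HCT", "HR", "SV", "CO", "BP")
  sim <- simulate_subject(params, protocol, times = measurements$time,
                          sv_hr_sign = config$sv_hr_sign)
  err_nrmse <- vapply(vars, function(v)
    nrmse(measurements[[v]], sim[[v]]), 1.0)
  err_nmae <- vapply(vars, function(v)
    nmae(measurements[[v]], sim[[v]]), 1.0)

  structure(list(
    params = params,
    sigma = nl$sigma,
    neg_ll = nl$neg_ll,
    objective = values[best],
    nrmse = err_nrmse,
    nmae = err_nmae,
    starts = data.frame(
      start = seq_along(runs),
      objective = values,
      convergence = vapply(runs, function(r) as.integer(r$convergence),
                           1L)
    ),
    best_start = best,
    config = config
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> -LL = ", format(x$neg_ll, digits = 6),
      ", objective = ", format(x$objective, digits = 6),
      " (best of ", nrow(x$starts), " starts)\n", sep = "")
  cat("  NRMSE [%]: ",
      paste(sprintf("%s=%.2f", names(x$nrmse), x$nrmse), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Serialize a calibration result to JSON
#'
#' @param result A `"calibration_result"`.
#' @param path Output JSON file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(result, path) {
  out <- list(
    parameters = as.list(unclass(result$params)),
    sigma = as.list(result$sigma),
    neg_ll = result$neg_ll,
    objective = result$objective,
    nrmse = as.list(result$nrmse),
    nmae = as.list(result$nmae),
    starts = result$starts,
    best_start = result$best_start,
    config = list(beta = result$config$beta,
                  n_starts = result$config$n_starts,
                  seed = result$config$seed)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
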