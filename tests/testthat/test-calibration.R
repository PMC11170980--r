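make_synthetic <- function(id = "LR1", noise = default_noise_sd(),
                           seed = 11, interval = 5) {
  p <- ref_subjects()[[id]]
  prot <- sheep_protocol_40kg()
  sim <- simulate_subject(p, prot, output_interval = 1)
  list(params = p, protocol = prot,
       measurements = sample_measurements(sim, interval_min = interval,
                                          noise_sd = noise, seed = seed))
}

test_that("sigma_mle is the closed-form concentrated estimator", {
  expect_equal(sigma_mle(c(1, -1, 1, -1)), 1)
  expect_equal(sigma_mle(rep(0, 10)), 1e-6)       # floored when degenerate
  expect_error(sigma_mle(0.5), "at least 2")

  set.seed(3)
  e <- rnorm(10000, 0, 2)
  expect_gt(sigma_mle(e), 1.94)
  expect_lt(sigma_mle(e), 2.06)
})

test_that("the Gaussian log-likelihood matches its closed form", {
  expect_equal(log_likelihood(c(1, 1, 1, 1), 1), -2 * log(2 * pi) - 2)
  expect_equal(log_likelihood(c(0, 0), 1), -log(2 * pi))
  expect_error(log_likelihood(c(1, 2), 0), "positive")

  # concentrated-likelihood identity and optimality of sigma-hat
  set.seed(5)
  for (i in 1:10) {
    e <- rnorm(sample(5:50, 1), 0, runif(1, 0.1, 3))
    s_hat <- sigma_mle(e)
    K <- length(e)
    expect_equal(log_likelihood(e, s_hat),
                 -K / 2 * (log(2 * pi) + log(s_hat^2) + 1))
    for (f in c(0.7, 1.3)) {
      expect_gte(log_likelihood(e, s_hat), log_likelihood(e, f * s_hat))
    }
  }
})

test_that("residuals vanish on self-generated noiseless data and shift linearly", {
  syn <- make_synthetic(noise = 0)
  res <- model_residuals(syn$params, syn$measurements, syn$protocol)
  for (v in names(res)) expect_equal(res[[v]], rep(0, length(res[[v]])))

  shifted <- syn$measurements
  shifted$HR <- shifted$HR + 2
  res <- model_residuals(syn$params, shifted, syn$protocol)
  expect_equal(res$HR, rep(2, length(res$HR)))
  expect_equal(res$BP, rep(0, length(res$BP)))
})

test_that("residual spread reflects the injected measurement noise", {
  syn <- make_synthetic(seed = 21)
  res <- model_residuals(syn$params, syn$measurements, syn$protocol)
  p <- syn$params
  base <- c(HCT = p[["HCT0"]], HR = p[["H0"]], SV = p[["SV0"]],
            BP = p[["H0"]] * p[["SV0"]] * p[["TPR0"]])
  nominal <- default_noise_sd()[names(base)] * base
  for (v in names(base)) {
    expect_lt(abs(stats::sd(res[[v]]) - nominal[[v]]) / nominal[[v]], 0.30,
              label = paste("residual SD mismatch for", v))
  }
})

test_that("the objective is the concentrated -LL plus the scaled L2 penalty", {
  syn <- make_synthetic(noise = 0)
  cfg <- calibration_config()
  eps <- cfg$sigma_floor
  K <- sum(!is.na(syn$measurements$HCT))

  # noiseless self-fit at beta = 0: all residuals zero, sigma at the floor
  obj0 <- calibration_objective(syn$params, syn$measurements, syn$protocol,
                                beta = 0, config = cfg)
  expect_equal(obj0, 4 * (K / 2) * (log(2 * pi) + log(eps^2)))

  # doubling beta adds exactly the penalty difference
  obj1 <- calibration_objective(syn$params, syn$measurements, syn$protocol,
                                beta = 1e-3, config = cfg)
  obj2 <- calibration_objective(syn$params, syn$measurements, syn$protocol,
                                beta = 2e-3, config = cfg)
  s <- parameter_scales()
  free <- calibrated_parameter_names()
  pen_unit <- sum((unclass(syn$params)[free] / s[free])^2)
  expect_equal(obj1 - obj0, 2 * 1e-3 * pen_unit)
  expect_equal(obj2 - obj1, 2 * 1e-3 * pen_unit)
})

test_that("calibration preconditions and bounds are enforced", {
  syn <- make_synthetic(noise = 0)
  short <- syn$measurements[1:2, ]
  short$HR[2] <- NA
  class(short) <- c("measurement_series", "data.frame")
  expect_error(
    calibrate_subject(short, syn$protocol,
                      subject_baselines(syn$params)[c("BV0", "HCT0", "SV0")]),
    "at least 2 samples of HR")

  b <- parameter_bounds()
  expect_true(all(b$upper[c("A_U_BV", "A_V_BV", "A_SV", "A_BP")] == 0))
  expect_true(all(b$lower[c("P_U_T", "P_V_L")] == 0))
  expect_true(all(b$upper[c("P_U_T", "P_V_L")] == 1))
  expect_gte(b$lower[["alpha_U"]], -0.95)
  expect_true(all(b$lower <= b$upper))
  # every reference subject lies inside the box
  for (p in ref_subjects()) {
    th <- unclass(p)[calibrated_parameter_names()]
    expect_true(all(th >= b$lower - 1e-12 & th <= b$upper + 1e-12))
  }
})

test_that("the truth is a fixed point of calibration on noiseless data", {
  syn <- make_synthetic(noise = 0)
  cfg <- calibration_config(beta = 0, n_starts = 1, init = syn$params,
                            maxit = 40, seed = 2)
  fit <- calibrate_subject(syn$measurements, syn$protocol,
                           subject_baselines(syn$params)[c("BV0", "HCT0",
                                                           "SV0")],
                           config = cfg)
  th_true <- unclass(syn$params)[calibrated_parameter_names()]
  th_fit <- unclass(fit$params)[calibrated_parameter_names()]
  s <- parameter_scales()[calibrated_parameter_names()]
  expect_lt(max(abs(th_fit - th_true) / s), 1e-3)
  # objective sits at the sigma-floor bound attained by zero residuals
  K <- nrow(syn$measurements)
  expect_equal(fit$objective, 4 * (K / 2) * (log(2 * pi) + log(1e-12)),
               tolerance = 1e-6)
  expect_lt(max(fit$nrmse), 1e-4)
})

test_that("stronger L2 regularization never grows the fitted parameter norm", {
  syn <- make_synthetic(seed = 31)
  base <- subject_baselines(syn$params)[c("BV0", "HCT0", "SV0")]
  s <- parameter_scales()[calibrated_parameter_names()]
  norms <- vapply(c(0, 1, 30, 300), function(beta) {
    cfg <- calibration_config(beta = beta, n_starts = 1, init = syn$params,
                              maxit = 60, seed = 2)
    fit <- calibrate_subject(syn$measurements, syn$protocol, base,
                             config = cfg)
    sqrt(sum((unclass(fit$params)[calibrated_parameter_names()] / s)^2))
  }, 1.0)
  expect_true(all(diff(norms) <= 1e-6 + 0.02 * norms[-length(norms)]))
})
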