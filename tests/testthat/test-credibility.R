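const_meas <- function(time, HCT = 20, HR = 80, SV = 0.05, CO = 4, BP = 100) {
  measurement_series(time, rep(HCT, length(time)), rep(HR, length(time)),
                     rep(SV, length(time)), rep(CO, length(time)),
                     rep(BP, length(time)))
}

test_that("normalized errors match their defining formulas", {
  expect_equal(nrmse(c(10, 10), c(10, 10)), 0)
  expect_equal(nrmse(c(10, 10), c(12, 8)), 20.0)
  expect_equal(nmae(c(10, 10), c(10, 10)), 0)
  expect_equal(nmae(c(10, 10), c(12, 8)), 20.0)

  # literal re-evaluation on random series
  set.seed(14)
  for (i in 1:20) {
    K <- sample(3:40, 1)
    v <- runif(K, 10, 100)
    vh <- v + rnorm(K, 0, 5)
    expect_equal(nrmse(v, vh),
                 100 * sqrt(sum((v - vh)^2) / K) / mean(v),
                 tolerance = 1e-12)
    expect_equal(nmae(v, vh),
                 100 * (sum(abs(v - vh)) / K) / mean(v),
                 tolerance = 1e-12)
    expect_lte(nmae(v, vh), nrmse(v, vh) + 1e-12)   # Jensen
  }
  expect_error(nrmse(c(1, -1), c(0, 0)), "zero")
})

test_that("the physiological filter applies the documented ranges to whole trajectories", {
  tt <- 0:5
  ok <- fake_simulation(tt, HCT = 30, HR = 100, SV = 0.05, CO = 5, BP = 120)
  hr_spike <- fake_simulation(tt, 30, c(100, 100, 310, 100, 100, 100),
                              0.05, 5, 120)
  sv_edge <- fake_simulation(tt, 30, 100, 0.100, 5, 150)  # boundaries kept
  failed <- fake_simulation(tt, 30, 100, 0.05, 5, 120, success = FALSE)
  hct_hi <- fake_simulation(tt, 50.5, 100, 0.05, 5, 120)

  expect_true(is_physiological(ok))
  expect_false(is_physiological(hr_spike))
  expect_true(is_physiological(sv_edge))
  expect_false(is_physiological(failed))
  expect_false(is_physiological(hct_hi))

  sims <- c(rep(list(ok), 6), list(hr_spike, failed, hct_hi,
                                   fake_simulation(tt, 30, 100, 0.2, 5, 120)))
  f <- physiological_filter(sims)
  expect_equal(f$percentage, 60)
  expect_equal(f$indices, 1:6)
})

test_that("relevance requires NRMSE at or below threshold on every variable", {
  tt <- seq(0, 50, by = 10)
  m <- const_meas(tt)
  good <- fake_simulation(tt, 20 * 1.24, 80 * 1.24, 0.05 * 1.24, 4 * 1.24,
                          100 * 1.24)          # 24% NRMSE everywhere
  bad1 <- fake_simulation(tt, 20 * 1.26, 80 * 1.05, 0.05 * 1.05, 4 * 1.05,
                          100 * 1.05)          # one variable at 26%
  f <- relevance_filter(list(good, bad1), m)
  expect_equal(f$indices, 1L)
  expect_equal(f$percentage, 50)
  expect_equal(unname(f$nrmse[1, ]), rep(24, 5), tolerance = 1e-12)

  empty <- relevance_filter(list(), m)
  expect_length(empty$kept, 0)
  expect_true(is.nan(empty$percentage))
})

test_that("the envelope is the pointwise span and grows monotonically", {
  tt <- seq(0, 30, by = 10)
  lo <- fake_simulation(tt, 18, 70, 0.04, 3, 90)
  hi <- fake_simulation(tt, 22, 90, 0.06, 5, 110)
  mid <- fake_simulation(tt, 20, 80, 0.05, 4, 100)

  single <- build_envelope(list(mid), tt)
  expect_equal(single$lower, single$upper)

  env2 <- build_envelope(list(lo, hi), tt)
  b <- envelope_bounds(env2, "HR", tt)
  expect_equal(b$lower, rep(70, 4))
  expect_equal(b$upper, rep(90, 4))

  env3 <- build_envelope(list(lo, hi, mid), tt)
  expect_true(all(env3$lower <= env2$lower + 1e-12))
  expect_true(all(env3$upper >= env2$upper - 1e-12))

  expect_error(build_envelope(list(), tt), "no relevant")
})

test_that("coverage counts points inside the envelope, averaged across variables", {
  tt <- seq(0, 30, by = 10)
  m <- const_meas(tt)
  same <- fake_simulation(tt, 20, 80, 0.05, 4, 100)
  env <- build_envelope(list(same), tt)
  expect_equal(envelope_coverage(env, m), 100)

  below <- fake_simulation(tt, 10, 40, 0.02, 2, 50)
  env <- build_envelope(list(below), tt)
  expect_equal(envelope_coverage(env, m), 0)

  # nested envelopes: adding simulations never reduces coverage
  env_small <- build_envelope(list(below), tt)
  env_big <- build_envelope(list(below, same), tt)
  expect_gte(envelope_coverage(env_big, m), envelope_coverage(env_small, m))
})

test_that("the normalized interval score matches its three branches", {
  tt <- c(0, 10)
  mk_env <- function(lo, up) {
    build_envelope(list(fake_simulation(tt, lo, lo, lo, lo, lo),
                        fake_simulation(tt, up, up, up, up, up)), tt)
  }
  env <- mk_env(8, 12)
  inside <- const_meas(tt, 10, 10, 10, 10, 10)
  expect_equal(unname(nis(env, inside)), rep(0.4, 5))

  below <- const_meas(tt, 4, 4, 4, 4, 4)
  expect_equal(unname(nis(env, below)), rep((4 + 40 * 4) / 4, 5))
  expect_equal(unname(nis(env, below))[1], 41.0)

  above <- const_meas(tt, 16, 16, 16, 16, 16)
  expect_equal(unname(nis(env, above))[1], (4 + 40 * 4) / 16)
  expect_equal(unname(nis(env, above))[1], 10.25)

  # continuity at the envelope boundary: the penalty vanishes there
  eps <- 1e-9
  at_edge <- const_meas(tt, 8, 8, 8, 8, 8)
  just_out <- const_meas(tt, 8 - eps, 8 - eps, 8 - eps, 8 - eps, 8 - eps)
  expect_equal(unname(nis(env, at_edge))[1],
               unname(nis(env, just_out))[1], tolerance = 1e-6)
})

test_that("the best virtual subject minimizes average NRMSE with documented tie-breaks", {
  tt <- seq(0, 40, by = 10)
  m <- const_meas(tt)
  exact <- fake_simulation(tt, 20, 80, 0.05, 4, 100, id = "exact")
  off10 <- fake_simulation(tt, 22, 88, 0.055, 4.4, 110, id = "off10")
  off12 <- fake_simulation(tt, 22.4, 89.6, 0.056, 4.48, 112, id = "off12")

  b <- best_virtual_subject(list(off10, exact, off12), m)
  expect_equal(b$subject_id, "exact")
  expect_equal(b$avg_nrmse, 0)
  expect_equal(b$max_nrmse, 0)
  expect_equal(b$max_nmae, 0)

  b <- best_virtual_subject(list(off12, off10), m)
  expect_equal(b$subject_id, "off10")
  expect_equal(b$avg_nrmse, 10, tolerance = 1e-9)

  # tie on average: the smaller maximum NRMSE wins
  flat10 <- fake_simulation(tt, 22, 88, 0.055, 4.4, 110, id = "flat")
  spread <- fake_simulation(tt, 20 * 1.3, 80 * 1.05, 0.05 * 1.05, 4 * 1.05,
                            100 * 1.05, id = "spread")  # avg 10, max 30
  b <- best_virtual_subject(list(spread, flat10), m)
  expect_equal(b$subject_id, "flat")
})

test_that("assessment recovers a test subject present in the cohort", {
  subj <- ref_subjects()
  prot <- sheep_protocol_40kg()
  truth <- subj[["LR1"]]
  sim <- simulate_subject(truth, prot, output_interval = 1)
  m <- sample_measurements(sim, interval_min = 10, noise_sd = 0)

  cohort <- subj[c("LR1", "LR2", "LR3", "LR4", "LR5")]
  rep_ <- assess_cohort(m, prot, cohort, output_interval = 2)
  expect_s3_class(rep_, "credibility_report")
  expect_false(rep_$flags$no_relevant)
  expect_equal(rep_$cohort$pct_coverage, 100)
  expect_lt(rep_$best$avg_nrmse, 1e-6)
  expect_equal(rep_$best$subject_id, "LR1")
  expect_true(all(rep_$nis >= 0))

  # report serialization round-trips the headline numbers
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, tmp)
  back <- jsonlite::read_json(tmp)
  expect_equal(back$cohort$pct_coverage, 100)
  expect_equal(back$best_subject$subject_id, "LR1")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_envelope(rep_$envelope, tmp2)
  env_back <- utils::read.csv(tmp2)
  expect_identical(sort(unique(env_back$variable)),
                   sort(c("HCT", "HR", "SV", "CO", "BP")))
})

test_that("an all-non-physiological cohort is flagged", {
  tt <- seq(0, 30, by = 10)
  m <- const_meas(tt)
  prot <- fluid_protocol(0, 0, 0, duration = 30)
  # SV bounds force exclusion: a subject with SV0 above the 0.100 l range
  bad <- unclass(ref_subjects()[["LR1"]])
  bad["SV0"] <- 0.2
  bad["r_SV"] <- 0.2
  cohort <- list(subject_parameters(bad, subject_id = "bad"))
  rep_ <- assess_cohort(m, prot, cohort)
  expect_true(rep_$flags$no_physiological)
  expect_true(rep_$flags$no_relevant)
  expect_equal(rep_$cohort$pct_physiological, 0)
  expect_null(rep_$best)
  expect_null(rep_$envelope)
})
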