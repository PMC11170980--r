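test_that("the baseline state with consistent references is an equilibrium", {
  p <- consistent_references(ref_subjects()[["LR1"]])
  prot <- zero_protocol()
  d <- derivatives(initial_state(p), t = 1, p, prot)
  expect_equal(unname(d), rep(0, 11))
})

test_that("single-term derivative values match direct substitution", {
  subj <- ref_subjects()
  # pure mass balance: no fluid shift, loss only
  p <- unclass(subj[["LR1"]])
  p["K_P_BV"] <- 0
  p <- subject_parameters(p)
  prot <- fluid_protocol(0, U = 0, V = 0.05, duration = 30)
  d <- derivatives(initial_state(p), t = 1, p, prot)
  expect_equal(d[["bv"]], -0.05)

  # transient HR response: dH_V,T/dt = G_V,T * V
  lr1 <- subj[["LR1"]]
  prot <- fluid_protocol(0, U = 0, V = 0.0667, duration = 30)
  d <- derivatives(initial_state(lr1), t = 1, lr1, prot)
  expect_equal(d[["h_v_t"]], 63.9160 * 0.0667, tolerance = 1e-10)
  expect_equal(d[["h_v_t"]], 4.263, tolerance = 1e-3)
})

test_that("power-law perturbation terms vanish at rest regardless of exponent", {
  p <- unclass(ref_subjects()[["LR4"]])
  p["P_V_L"] <- 0   # LR4 reference value; 0^0 := 0 by convention
  p["P_U_T"] <- 0
  p <- subject_parameters(p)
  d <- derivatives(initial_state(p), t = 1, p, zero_protocol())
  expect_equal(d[["r_hv_l"]], 0)
  expect_equal(d[["h_u_t"]], 0)
})

test_that("derived outputs follow the algebraic identities", {
  p <- ref_subjects()[["LR1"]]
  y <- initial_state(p)
  o <- derived_outputs(y, p)
  expect_equal(o$HCT, p[["HCT0"]])
  expect_equal(o$HR, p[["H0"]])
  expect_equal(o$r_BV, 0)
  expect_equal(o$q, 0)

  y["h_v_t"] <- 0; y["h_v_l"] <- 0; y["h_u_t"] <- 0
  y["sv"] <- 0.05; y["tpr"] <- 25
  p2 <- unclass(p); p2["H0"] <- 80; p2 <- subject_parameters(p2)
  o <- derived_outputs(y, p2)
  expect_equal(o$CO, 4.0)
  expect_equal(o$BP, 100)

  y["bv"] <- 0
  expect_error(derived_outputs(y, p), "blood volume exhausted")
})

test_that("derivative preconditions reject degenerate states", {
  p <- ref_subjects()[["LR1"]]
  y <- initial_state(p)
  y["bv"] <- -0.1
  expect_error(derivatives(y, 0, p, zero_protocol()),
               "blood volume exhausted")
  y <- initial_state(p)
  y["sv"] <- NaN
  expect_error(derivatives(y, 0, p, zero_protocol()), "divergence")
})

test_that("zero-input simulation holds every output constant", {
  p <- consistent_references(ref_subjects()[["LR7"]])
  sim <- simulate_subject(p, zero_protocol(200), output_interval = 10)
  base <- as.numeric(sim[1, -1])
  dev <- apply(abs(sweep(as.matrix(sim[, -1]), 2, base)), 2, max) / abs(base)
  expect_lt(max(dev), 1e-9)
})

test_that("red cells are conserved exactly when there is no loss", {
  p <- ref_subjects()[["LR2"]]
  prot <- fluid_protocol(c(0, 10), U = c(0.1, 0), V = c(0, 0),
                         duration = 60)
  sim <- simulate_subject(p, prot, output_interval = 5)
  rbc <- attr(sim, "states")[, "rbc"]
  expect_equal(rbc, rep(p[["HCT0"]] * p[["BV0"]], length(rbc)),
               tolerance = 1e-12)
})

test_that("output identities CO = HR*SV and BP = CO*TPR hold at every point", {
  p <- ref_subjects()[["LR5"]]
  sim <- simulate_subject(p, sheep_protocol_40kg(), output_interval = 2)
  st <- attr(sim, "states")
  expect_equal(sim$CO, sim$HR * sim$SV, tolerance = 0)
  expect_equal(sim$BP, sim$CO * st[, "tpr"], tolerance = 0)
  expect_equal(sim$HCT, st[, "rbc"] / st[, "bv"], tolerance = 0)
})

test_that("blood volume obeys mass balance along the trajectory", {
  p <- ref_subjects()[["LR1"]]
  prot <- sheep_protocol_40kg()
  sim <- simulate_subject(p, prot, output_interval = 0.05)
  st <- attr(sim, "states")
  q <- p[["K_P_BV"]] * (st[, "bv"] - p[["BV0"]] -
                          (st[, "r_U_bv"] + st[, "r_V_bv"]))
  # U and V are piecewise constant on half-open intervals, so the left-
  # endpoint rectangle rule integrates them exactly on the aligned grid;
  # q is continuous, so the trapezoid rule applies
  h <- diff(sim$time)
  r_left <- protocol_rates(prot, sim$time[-length(sim$time)])
  integ <- c(0, cumsum((r_left$U - r_left$V) * h -
                         (q[-1] + q[-length(q)]) / 2 * h))
  expect_lt(max(abs(st[, "bv"] - p[["BV0"]] - integ)), 2e-5)
})

test_that("hematocrit never rises under loss-only protocols", {
  prot <- fluid_protocol(c(0, 15, 50, 55, 70, 75),
                         U = rep(0, 6),
                         V = c(0.0667, 0, 0.04, 0, 0.04, 0),
                         duration = 120)
  for (id in c("LR1", "LR9", "LR19", "HEX3")) {
    sim <- simulate_subject(ref_subjects()[[id]], prot, output_interval = 1)
    expect_true(all(diff(sim$HCT) <= 1e-10), info = id)
  }
})

test_that("the compiled RK4 path agrees with the deSolve/lsoda path", {
  p <- ref_subjects()[["LR11"]]
  prot <- sheep_protocol_40kg()
  times <- seq(0, 180, by = 10)
  a <- simulate_subject(p, prot, times = times, solver = "rk4")
  b <- simulate_subject(p, prot, times = times, solver = "lsoda")
  for (v in c("BV", "HCT", "HR", "SV", "CO", "BP")) {
    expect_lt(max(abs(a[[v]] - b[[v]])) / max(abs(b[[v]])), 1e-6)
  }
})

test_that("catastrophic hemorrhage fails cleanly with a partial trajectory", {
  p <- ref_subjects()[["LR1"]]   # BV0 = 2.34 l
  prot <- fluid_protocol(0, U = 0, V = 0.5, duration = 30)
  sim <- simulate_subject(p, prot, output_interval = 1)
  expect_false(attr(sim, "success"))
  expect_true(is.finite(attr(sim, "t_fail")))
  expect_true(any(is.na(sim$BV)))
  expect_false(anyNA(sim$BV[sim$time < attr(sim, "t_fail") - 1]))
})

test_that("the resistance fixed point matches its closed form", {
  p <- unclass(ref_subjects()[["LR1"]])
  # pure relaxation when the pressure feedback is off
  p0 <- p; p0["K_P_BP"] <- 0
  eq <- equilibrium_tpr(subject_parameters(p0), 80, 0.05)
  expect_equal(eq$TPR, p0[["TPR0"]])

  # hand-computed fixed point
  p1 <- p
  p1["A_BP"] <- -1; p1["K_P_BP"] <- 0.1; p1["TPR0"] <- 25; p1["r_BP"] <- 80
  eq <- equilibrium_tpr(subject_parameters(p1), 80, 0.05)  # H*SV = 4
  expect_equal(eq$TPR, (-25 - 8) / (-1 - 0.4))
  expect_equal(eq$BP, 4 * eq$TPR)

  # degenerate denominator: with valid signs this requires both the
  # relaxation and the pressure feedback to vanish
  p2 <- p
  p2["A_BP"] <- 0; p2["K_P_BP"] <- 0
  expect_error(equilibrium_tpr(subject_parameters(p2), 80, 0.05),
               "degenerate")
})

test_that("the literal HR->SV sign convention flips the coupling term", {
  p <- ref_subjects()[["LR3"]]   # largest G_HR in the reference set
  prot <- fluid_protocol(0, U = 0, V = 0.05, duration = 20)
  y <- initial_state(p)
  d_phys <- derivatives(y, 1, p, prot, sv_hr_sign = "physiological")
  d_lit <- derivatives(y, 1, p, prot, sv_hr_sign = "literal")
  h_dot <- d_phys[["h_v_l"]] + d_phys[["h_v_t"]] - d_phys[["h_u_t"]]
  expect_equal(d_lit[["sv"]] - d_phys[["sv"]], 2 * p[["G_HR"]] * h_dot)
  # hemorrhage raises HR; the physiological reading must depress SV more
  expect_lt(d_phys[["sv"]], d_lit[["sv"]])
})
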