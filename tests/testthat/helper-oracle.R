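# Independent fixed-step forward-Euler integration of the model equations,
# transcribed directly from the sub-model definitions (not from the
# package's RK4 kernel or R right-hand side).  Used as a brute-force oracle
# for trajectory checks.
euler_simulate <- function(params, protocol, times, dt = 0.001) {
  p <- as.list(unclass(params))
  duration <- protocol_duration(protocol)
  btime <- protocol$time
  bU <- protocol$U
  bV <- protocol$V

  rU <- 0; rV <- 0
  BV <- p$BV0
  RBC <- p$HCT0 * p$BV0
  rHVL <- 0; HVT <- 0; HVL <- 0; eint <- 0; HUT <- 0
  SV <- p$SV0
  TPR <- p$TPR0

  out <- matrix(NA_real_, length(times), 6,
                dimnames = list(NULL, c("BV", "HCT", "HR", "SV", "CO", "BP")))
  record <- function(i) {
    HR <- p$H0 + HVT + HVL - HUT
    CO <- HR * SV
    out[i, ] <<- c(BV, RBC / BV, HR, SV, CO, CO * TPR)
  }
  iout <- 1L
  while (iout <= length(times) && times[iout] <= 0) {
    record(iout); iout <- iout + 1L
  }

  events <- sort(unique(c(times, btime, duration)))
  events <- events[events > 0 & events <= max(times)]
  t <- 0
  for (t1 in events) {
    if (t1 <= t) next
    seg <- findInterval(t, btime)
    U <- if (t < duration) bU[seg] else 0
    V <- if (t < duration) bV[seg] else 0
    Upow <- if (U > 0) U^p$P_U_T else 0
    Vpow <- if (V > 0) V^p$P_V_L else 0
    n <- ceiling((t1 - t) / dt - 1e-9)
    h <- (t1 - t) / n
    for (s in seq_len(n)) {
      d_rU <- p$A_U_BV * rU + U / (1 + p$alpha_U)
      d_rV <- p$A_V_BV * rV - V / (1 + p$alpha_V)
      q <- p$K_P_BV * (BV - p$BV0 - (rU + rV))
      d_BV <- U - V - q
      d_RBC <- -V * (RBC / BV)
      d_rHVL <- p$G_V_L * Vpow
      d_HVT <- p$G_V_T * V
      e <- rHVL - HVT - HVL
      d_HVL <- p$K_P_H * e + p$K_I_H * eint
      d_eint <- e
      d_HUT <- p$G_U_T * Upow
      d_H <- d_HVL + d_HVT - d_HUT
      d_SV <- p$A_SV * (SV - p$SV0) + p$G_BV * d_BV +
        p$K_P_SV * (p$r_SV - SV) - p$G_HR * d_H
      H <- p$H0 + HVT + HVL - HUT
      d_TPR <- p$A_BP * (TPR - p$TPR0) + p$K_P_BP * (p$r_BP - H * SV * TPR)

      rU <- rU + h * d_rU
      rV <- rV + h * d_rV
      BV <- BV + h * d_BV
      RBC <- RBC + h * d_RBC
      rHVL <- rHVL + h * d_rHVL
      HVT <- HVT + h * d_HVT
      HVL <- HVL + h * d_HVL
      eint <- eint + h * d_eint
      HUT <- HUT + h * d_HUT
      SV <- SV + h * d_SV
      TPR <- TPR + h * d_TPR
    }
    t <- t1
    while (iout <= length(times) && times[iout] <= t + 1e-12) {
      record(iout); iout <- iout + 1L
    }
  }
  data.frame(time = times, out)
}
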