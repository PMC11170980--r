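# shared, lazily built fixtures (reference subjects and the synthetic sheep
# protocol are reused by many tests)
.fixture_cache <- new.env(parent = emptyenv())

ref_subjects <- function() {
  if (is.null(.fixture_cache$ref)) {
    .fixture_cache$ref <- reference_subjects()
  }
  .fixture_cache$ref
}

sheep_protocol_40kg <- function() {
  if (is.null(.fixture_cache$sheep)) {
    .fixture_cache$sheep <- make_sheep_protocol(40)
  }
  .fixture_cache$sheep
}

# reference levels consistent with the baseline state, so that zero input
# leaves every output constant
consistent_references <- function(params) {
  params["r_SV"] <- params[["SV0"]]
  params["r_BP"] <- params[["H0"]] * params[["SV0"]] * params[["TPR0"]]
  subject_parameters(unclass(params), subject_id = attr(params, "subject_id"))
}

zero_protocol <- function(duration = 100) {
  fluid_protocol(0, U = 0, V = 0, duration = duration)
}

# a minimal fake simulation for metric-level tests, bypassing the solver
fake_simulation <- function(time, HCT, HR, SV, CO, BP, success = TRUE,
                            id = NULL) {
  df <- data.frame(time = time, BV = 2.5, HCT = HCT, HR = HR, SV = SV,
                   CO = CO, BP = BP)
  class(df) <- c("cv_simulation", "data.frame")
  attr(df, "success") <- success
  attr(df, "subject_id") <- id
  df
}
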