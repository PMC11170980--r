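#' @title Subject parameter vectors
#' @name subject_parameters
#' @description
#' A subject is described by 25 named parameters: 20 dynamic parameters
#' grouped into four compartments (blood volume, heart rate, stroke volume,
#' blood pressure) plus 5 baseline values measured at rest.  The canonical
#' column order used throughout the package (and in parameter CSV files) is
#' the reference-table order returned by [parameter_names()].
NULL

# canonical parameter order: 20 compartment parameters then 5 baselines
.param_names <- c(
  # blood volume compartment
  "A_U_BV", "A_V_BV", "alpha_U", "alpha_V", "K_P_BV",
  # heart rate compartment
  "G_U_T", "G_V_T", "G_V_L", "P_U_T", "P_V_L", "K_P_H", "K_I_H",
  # stroke volume compartment
  "G_BV", "G_HR", "A_SV", "r_SV", "K_P_SV",
  # blood pressure compartment
  "A_BP", "K_P_BP", "r_BP",
  # baselines
  "HCT0", "BV0", "H0", "SV0", "TPR0"
)

.baseline_names <- c("HCT0", "BV0", "H0", "SV0", "TPR0")

.compartment_map <- list(
  BV = c("A_U_BV", "A_V_BV", "alpha_U", "alpha_V", "K_P_BV"),
  HR = c("G_U_T", "G_V_T", "G_V_L", "P_U_T", "P_V_L", "K_P_H", "K_I_H"),
  SV = c("G_BV", "G_HR", "A_SV", "r_SV", "K_P_SV"),
  BP = c("A_BP", "K_P_BP", "r_BP")
)

#' Canonical parameter names
#'
#' @param what `"all"` (25 names, compartments then baselines), `"free"`
#'   (the 20 non-baseline parameters) or `"baseline"` (the 5 baselines).
#' @return Character vector of parameter names in canonical order.
#' @export
parameter_names <- function(what = c("all", "free", "baseline")) {
  what <- match.arg(what)
  switch(what,
    all = .param_names,
    free = setdiff(.param_names, .baseline_names),
    baseline = .baseline_names
  )
}

#' Construct a validated subject parameter vector
#'
#' Builds a named numeric vector of the 25 model parameters.  Stability
#' parameters (`A_U_BV`, `A_V_BV`, `A_SV`, `A_BP`) must be non-positive;
#' baselines must be positive with hematocrit below 50%; the fluid
#' distribution ratios must satisfy `1 + alpha > 0` so that the infusion and
#' loss gains keep their sign.
#'
#' @param ... Either a single named numeric vector/list of length 25, or the
#'   25 parameters given as named arguments.
#' @param subject_id Optional subject label, stored as an attribute.
#' @return A named numeric vector of class `"subject_parameters"`.
#' @examples
#' p <- reference_subjects()[["LR1"]]
#' p["G_V_T"]
#' @export
subject_parameters <- function(..., subject_id = NULL) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && length(dots[[1]]) > 1L) {
    x <- unlist(dots[[1]])
  } else {
    x <- unlist(dots)
  }
  if (is.null(names(x)) || !all(.param_names %in% names(x))) {
    missing <- setdiff(.param_names, names(x))
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(x), .param_names)
  if (length(extra)) {
    stop("unknown parameters: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  x <- as.numeric(x[.param_names])
  names(x) <- .param_names
  if (any(!is.finite(x))) {
    stop("all parameters must be finite", call. = FALSE)
  }
  stab <- c("A_U_BV", "A_V_BV", "A_SV", "A_BP")
  if (any(x[stab] > 0)) {
    stop("stability parameters ", paste(stab[x[stab] > 0], collapse = ", "),
         " must be <= 0", call. = FALSE)
  }
  if (x["BV0"] <= 0 || x["H0"] <= 0 || x["SV0"] <= 0 || x["TPR0"] <= 0) {
    stop("baselines BV0, H0, SV0, TPR0 must be positive", call. = FALSE)
  }
  if (x["HCT0"] <= 0 || x["HCT0"] >= 50) {
    stop("HCT0 must lie in (0, 50) percent", call. = FALSE)
  }
  if (1 + x["alpha_U"] <= 0 || 1 + x["alpha_V"] <= 0) {
    stop("distribution ratios must satisfy 1 + alpha > 0", call. = FALSE)
  }
  structure(x, class = "subject_parameters", subject_id = subject_id)
}

#' @export
print.subject_parameters <- function(x, ...) {
  id <- attr(x, "subject_id")
  cat("<subject_parameters>", if (!is.null(id)) paste0(" id: ", id), "\n",
      sep = "")
  for (comp in names(.compartment_map)) {
    v <- unclass(x)[.compartment_map[[comp]]]
    cat(sprintf("  %-3s: %s\n", comp,
                paste(sprintf("%s=%.4g", names(v), v), collapse = ", ")))
  }
  v <- unclass(x)[.baseline_names]
  cat("  baselines: ",
      paste(sprintf("%s=%.4g", names(v), v), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Split a parameter vector into its four compartments
#'
#' The 20 non-baseline parameters are partitioned into the blood-volume (5),
#' heart-rate (7), stroke-volume (5) and blood-pressure (3) compartments used
#' by the virtual-cohort generator; baselines are excluded.
#'
#' @param params A [subject_parameters] vector.
#' @return Named list with elements `BV`, `HR`, `SV`, `BP`, each a named
#'   numeric vector.
#' @export
compartments <- function(params) {
  params <- as_subject_parameters(params)
  lapply(.compartment_map, function(nm) unclass(params)[nm])
}

#' Reassemble a parameter vector from compartments and baselines
#'
#' Inverse of [compartments()]: combines the four compartment blocks with a
#' set of baseline values into a full [subject_parameters] vector.
#'
#' @param comps Named list with elements `BV`, `HR`, `SV`, `BP` as returned
#'   by [compartments()].
#' @param baselines Named numeric vector with `HCT0`, `BV0`, `H0`, `SV0`,
#'   `TPR0`.
#' @param subject_id Optional label for the assembled subject.
#' @return A [subject_parameters] vector.
#' @export
assemble_parameters <- function(comps, baselines, subject_id = NULL) {
  stopifnot(all(c("BV", "HR", "SV", "BP") %in% names(comps)))
  x <- c(unlist(unname(lapply(comps[c("BV", "HR", "SV", "BP")], identity))),
         unlist(baselines)[.baseline_names])
  names(x) <- c(unlist(lapply(comps[c("BV", "HR", "SV", "BP")], names)),
                .baseline_names)
  subject_parameters(x, subject_id = subject_id)
}

as_subject_parameters <- function(x) {
  if (inherits(x, "subject_parameters")) x else subject_parameters(x)
}

#' Reference calibrated subjects
#'
#' Loads the packaged table of 27 calibrated sheep parameter vectors
#' (22 subjects resuscitated with Lactated Ringer's, `LR1`--`LR22`, and 5
#' with Hextend, `HEX1`--`HEX5`).  These serve as the calibration set for
#' virtual-cohort generation and as ground truth for synthetic experiments.
#'
#' @return Named list of 27 [subject_parameters] vectors.
#' @examples
#' subj <- reference_subjects()
#' length(subj)
#' subj[["LR1"]]["A_U_BV"]
#' @export
reference_subjects <- function() {
  path <- system.file("extdata", "reference_sheep_parameters.csv",
                      package = "cvfluid")
  if (path == "" || !file.exists(path)) {
    stop("packaged reference parameter table not found", call. = FALSE)
  }
  read_parameters(path)
}

#' Read a parameter table from CSV
#'
#' The file must have a `subject_id` column followed by the 25 parameter
#' columns in canonical order (see [parameter_names()]).  Extra provenance
#' columns (as written by [write_cohort()]) are ignored.
#'
#' @param path CSV file path.
#' @return Named list of [subject_parameters] vectors.
#' @export
read_parameters <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("subject_id", .param_names)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parameter file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, .param_names])
    names(v) <- .param_names
    subject_parameters(v, subject_id = as.character(df$subject_id[i]))
  })
  names(out) <- as.character(df$subject_id)
  out
}

#' Write a parameter table to CSV
#'
#' @param subjects List of [subject_parameters] (or a single one).
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(subjects, path) {
  if (inherits(subjects, "subject_parameters")) subjects <- list(subjects)
  ids <- vapply(seq_along(subjects), function(i) {
    id <- attr(subjects[[i]], "subject_id")
    if (is.null(id)) {
      nm <- names(subjects)[i]
      if (is.null(nm) || !nzchar(nm)) paste0("S", i) else nm
    } else id
  }, character(1))
  m <- do.call(rbind, lapply(subjects, function(p) unclass(p)[.param_names]))
  df <- data.frame(subject_id = ids, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
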