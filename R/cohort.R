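#' @title Compartment-method virtual cohort generation
#' @description
#' Virtual subjects are assembled from the calibration set by transplanting
#' whole parameter compartments: a *mixing* subject takes its BV, HR, SV
#' and BP compartments from four distinct calibrated subjects; an *average*
#' subject takes every compartment as the arithmetic mean over three
#' distinct calibrated subjects.  Baseline parameters are not inherited
#' from donors but resampled around the test subject's measured baselines,
#' so the cohort probes dynamic-pattern similarity rather than
#' initial-condition similarity.
#' @name cohort
NULL

#' Pool sizes of the compartment method
#'
#' With `N` calibration subjects there are `N^4` ordered donor assignments
#' for mixing subjects (one donor index per compartment), `N^3` for average
#' subjects, and their sum in total.  These counts describe the enumeration
#' underlying the quoted pool sizes; the runtime sampler additionally
#' enforces distinct donors within a tuple.
#'
#' @param N Calibration-set size (>= 1).
#' @return Integer-valued count.
#' @examples
#' count_mixing(26)   # 456976
#' count_total(27)    # 551124
#' @export
count_mixing <- function(N) {
  if (!is.finite(N) || N < 1) stop("N must be >= 1", call. = FALSE)
  N^4
}

#' @rdname count_mixing
#' @export
count_average <- function(N) {
  if (!is.finite(N) || N < 1) stop("N must be >= 1", call. = FALSE)
  N^3
}

#' @rdname count_mixing
#' @export
count_total <- function(N) {
  count_mixing(N) + count_average(N)
}

#' Resample baseline parameters around measured values
#'
#' Each of the five baselines is drawn independently from
#' `Normal(measured, sd_fraction * measured)`; non-positive draws (and
#' hematocrit draws at or above 50%) are redrawn, which at the default 10%
#' SD is vanishingly rare and leaves the normal shape essentially intact.
#'
#' @param measured Named numeric vector with `BV0`, `HCT0`, `H0`, `SV0`,
#'   `TPR0`, all positive.
#' @param sd_fraction SD as a fraction of the measured value (default 0.10).
#' @return Named numeric vector of resampled baselines.
#' @export
sample_baselines <- function(measured, sd_fraction = 0.10) {
  measured <- unlist(measured)
  need <- c("BV0", "HCT0", "H0", "SV0", "TPR0")
  if (!all(need %in% names(measured))) {
    stop("measured baselines must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  measured <- measured[need]
  if (any(measured <= 0)) {
    stop("measured baselines must be positive", call. = FALSE)
  }
  if (sd_fraction < 0) stop("sd_fraction must be >= 0", call. = FALSE)
  out <- numeric(length(need))
  names(out) <- need
  for (nm in need) {
    repeat {
      x <- stats::rnorm(1, measured[[nm]], sd_fraction * measured[[nm]])
      if (x > 0 && (nm != "HCT0" || x < 50)) break
    }
    out[[nm]] <- x
  }
  out
}

#' Baselines of a parameter vector
#'
#' Convenience extractor used to treat a reference subject as a test
#' subject: returns its five baseline parameters as the "measured" values.
#'
#' @param params A [subject_parameters] vector.
#' @return Named numeric vector `BV0`, `HCT0`, `H0`, `SV0`, `TPR0`.
#' @export
subject_baselines <- function(params) {
  p <- unclass(as_subject_parameters(params))
  p[c("BV0", "HCT0", "H0", "SV0", "TPR0")]
}

#' Measured baselines from observed values
#'
#' Builds the baseline set from directly observed quantities; `TPR0` is not
#' observed directly and is derived as `BP0 / (H0 * SV0)`.
#'
#' @param BV0,HCT0,H0,SV0 Observed baselines.
#' @param BP0 Observed baseline mean arterial pressure (mmHg).
#' @return Named numeric vector with the five baselines.
#' @export
measured_baselines <- function(BV0, HCT0, H0, SV0, BP0) {
  c(BV0 = BV0, HCT0 = HCT0, H0 = H0, SV0 = SV0,
    TPR0 = BP0 / (H0 * SV0))
}

check_donors <- function(donors, n) {
  if (length(donors) != n) {
    stop("need exactly ", n, " donors", call. = FALSE)
  }
  ids <- vapply(seq_along(donors), function(i) {
    id <- attr(donors[[i]], "subject_id")
    if (is.null(id)) {
      nm <- names(donors)[i]
      if (is.null(nm) || !nzchar(nm)) stop("donors must carry subject ids",
                                           call. = FALSE)
      nm
    } else id
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("donors must be distinct subjects", call. = FALSE)
  }
  ids
}

#' Assemble a mixing virtual subject
#'
#' Takes the BV, HR, SV and BP compartments whole from four distinct donor
#' subjects (in that order) and attaches resampled baselines.
#'
#' @param donors List of four distinct [subject_parameters]; donor `i`
#'   supplies compartment `i` of (BV, HR, SV, BP).
#' @param baselines Resampled baselines from [sample_baselines()].
#' @param subject_id Optional id for the virtual subject.
#' @return A [subject_parameters] vector with provenance attributes
#'   `kind = "mixing"` and `donors` (named per compartment).
#' @export
make_mixing_subject <- function(donors, baselines, subject_id = NULL) {
  ids <- check_donors(donors, 4)
  comp_names <- c("BV", "HR", "SV", "BP")
  comps <- lapply(seq_len(4), function(i) {
    compartments(donors[[i]])[[comp_names[i]]]
  })
  names(comps) <- comp_names
  out <- assemble_parameters(comps, baselines, subject_id = subject_id)
  attr(out, "kind") <- "mixing"
  attr(out, "donors") <- stats::setNames(ids, comp_names)
  out
}

#' Assemble an average virtual subject
#'
#' Every non-baseline parameter is the arithmetic mean of the corresponding
#' parameter across three distinct donor subjects.
#'
#' @param donors List of three distinct [subject_parameters].
#' @param baselines Resampled baselines from [sample_baselines()].
#' @param subject_id Optional id for the virtual subject.
#' @return A [subject_parameters] vector with provenance attributes
#'   `kind = "average"` and `donors`.
#' @export
make_average_subject <- function(donors, baselines, subject_id = NULL) {
  ids <- check_donors(donors, 3)
  free <- parameter_names("free")
  m <- do.call(rbind, lapply(donors, function(d) {
    unclass(as_subject_parameters(d))[free]
  }))
  comps <- lapply(.compartment_map, function(nm) colMeans(m)[nm])
  out <- assemble_parameters(comps, baselines, subject_id = subject_id)
  attr(out, "kind") <- "average"
  attr(out, "donors") <- ids
  out
}

#' Generate a virtual cohort against a test subject
#'
#' Draws `size` virtual subjects from the calibration set: each is a mixing
#' subject with probability `N / (N + 1)` (the mixing share of the
#' enumeration pool, `N^4 / (N^4 + N^3)`) and an average subject
#' otherwise.  Donor tuples are drawn uniformly without repetition within a
#' tuple, and every subject gets freshly resampled baselines around the
#' test subject's measured values.
#'
#' @param calibration_set Named list of [subject_parameters] (>= 4); for
#'   leave-one-out validation, exclude the test subject before calling.
#' @param test_baselines Measured baselines of the test subject (see
#'   [sample_baselines()], [measured_baselines()]).
#' @param size Cohort size (>= 1).
#' @param sd_fraction Baseline resampling SD fraction.
#' @param seed Integer seed; the cohort is fully reproducible given the
#'   seed.
#' @return List of `size` virtual subjects (see [make_mixing_subject()],
#'   [make_average_subject()]), ids `VS1..VSn`.
#' @export
generate_cohort <- function(calibration_set, test_baselines, size,
                            sd_fraction = 0.10, seed = 1) {
  N <- length(calibration_set)
  if (N < 4) stop("calibration set must contain at least 4 subjects",
                  call. = FALSE)
  if (size < 1) stop("size must be >= 1", call. = FALSE)
  if (is.null(names(calibration_set))) {
    names(calibration_set) <- vapply(calibration_set, function(p) {
      id <- attr(p, "subject_id")
      if (is.null(id)) stop("calibration subjects must carry ids",
                            call. = FALSE)
      id
    }, character(1))
  }
  set.seed(seed)
  p_mix <- N / (N + 1)
  lapply(seq_len(size), function(i) {
    baselines <- sample_baselines(test_baselines, sd_fraction)
    if (stats::runif(1) < p_mix) {
      idx <- sample.int(N, 4)      # random donors, random compartment order
      make_mixing_subject(calibration_set[idx], baselines,
                          subject_id = paste0("VS", i))
    } else {
      idx <- sample.int(N, 3)
      make_average_subject(calibration_set[idx], baselines,
                           subject_id = paste0("VS", i))
    }
  })
}

#' Write a cohort to CSV with provenance columns
#'
#' The parameter columns follow the canonical layout of
#' [write_parameters()]; provenance columns `kind`, `donor_bv`, `donor_hr`,
#' `donor_sv`, `donor_bp` record the construction (for average subjects the
#' three donor ids are joined with `+` in every compartment column).
#'
#' @param cohort List of virtual subjects from [generate_cohort()].
#' @param path Output CSV file path.
#' @param seed Seed to record alongside, if any.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NA) {
  m <- do.call(rbind, lapply(cohort, function(p) {
    unclass(p)[parameter_names("all")]
  }))
  prov <- do.call(rbind, lapply(cohort, function(p) {
    kind <- attr(p, "kind")
    donors <- attr(p, "donors")
    if (identical(kind, "mixing")) {
      data.frame(kind = kind, donor_bv = donors[["BV"]],
                 donor_hr = donors[["HR"]], donor_sv = donors[["SV"]],
                 donor_bp = donors[["BP"]])
    } else {
      joined <- paste(donors, collapse = "+")
      data.frame(kind = kind, donor_bv = joined, donor_hr = joined,
                 donor_sv = joined, donor_bp = joined)
    }
  }))
  ids <- vapply(cohort, function(p) {
    id <- attr(p, "subject_id")
    if (is.null(id)) "VS" else id
  }, character(1))
  df <- data.frame(subject_id = ids, m, prov, seed = seed,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV file path.
#' @return List of [subject_parameters] with provenance attributes.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  subjects <- read_parameters(path)
  for (i in seq_along(subjects)) {
    if ("kind" %in% names(df)) {
      attr(subjects[[i]], "kind") <- df$kind[i]
      if (identical(df$kind[i], "mixing")) {
        attr(subjects[[i]], "donors") <- c(
          BV = df$donor_bv[i], HR = df$donor_hr[i],
          SV = df$donor_sv[i], BP = df$donor_bp[i])
      } else {
        attr(subjects[[i]], "donors") <-
          strsplit(df$donor_bv[i], "+", fixed = TRUE)[[1]]
      }
    }
  }
  subjects
}
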