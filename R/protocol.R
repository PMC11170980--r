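#' Piecewise-constant fluid perturbation protocol
#'
#' A protocol prescribes the two model inputs over time: the fluid infusion
#' rate `U(t)` and the fluid loss rate `V(t)` (hemorrhage plus urine), both
#' in l/min.  Rates are piecewise constant: row `i` holds on the half-open
#' interval `[time[i], time[i+1])`, the last row holds until `duration`, and
#' both rates are zero afterwards.  Negative rates are rejected, never
#' clipped: loss and infusion are separate non-negative channels.
#'
#' @param time Strictly increasing breakpoint times in minutes; the first
#'   breakpoint must be 0.
#' @param U Infusion rate per interval, l/min, same length as `time`.
#' @param V Loss rate per interval, l/min, same length as `time`.
#' @param duration Total protocol duration in minutes (> last breakpoint).
#' @return A data frame of class `"fluid_protocol"` with columns `time`,
#'   `U`, `V` and a `duration` attribute.
#' @examples
#' # 1 l hemorrhage over the first 15 minutes, nothing afterwards
#' p <- fluid_protocol(time = c(0, 15), U = c(0, 0),
#'                     V = c(1 / 15, 0), duration = 60)
#' protocol_rates(p, c(10, 20))
#' @export
fluid_protocol <- function(time, U, V, duration) {
  if (length(time) < 1L || length(U) != length(time) ||
      length(V) != length(time)) {
    stop("time, U and V must have equal positive length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(U)) || any(!is.finite(V))) {
    stop("protocol entries must be finite", call. = FALSE)
  }
  if (time[1] != 0 || any(diff(time) <= 0)) {
    stop("breakpoints must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  if (any(U < 0) || any(V < 0)) {
    stop("negative rates are not allowed: U(t) >= 0 and V(t) >= 0",
         call. = FALSE)
  }
  if (!is.finite(duration) || duration <= time[length(time)]) {
    stop("duration must exceed the last breakpoint", call. = FALSE)
  }
  structure(
    data.frame(time = as.numeric(time), U = as.numeric(U),
               V = as.numeric(V)),
    class = c("fluid_protocol", "data.frame"),
    duration = as.numeric(duration)
  )
}

#' @export
print.fluid_protocol <- function(x, ...) {
  cat("<fluid_protocol> ", nrow(x), " segment(s), duration ",
      attr(x, "duration"), " min\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Protocol duration
#' @param protocol A [fluid_protocol].
#' @return Duration in minutes.
#' @export
protocol_duration <- function(protocol) {
  attr(protocol, "duration")
}

#' Evaluate protocol rates at given times
#'
#' @param protocol A [fluid_protocol].
#' @param t Numeric vector of times (min).
#' @return Data frame with columns `U` and `V` (l/min); zero outside
#'   `[0, duration)`.
#' @export
protocol_rates <- function(protocol, t) {
  idx <- findInterval(t, protocol$time)
  U <- ifelse(idx >= 1, protocol$U[pmax(idx, 1)], 0)
  V <- ifelse(idx >= 1, protocol$V[pmax(idx, 1)], 0)
  off <- t < 0 | t >= attr(protocol, "duration")
  U[off] <- 0
  V[off] <- 0
  data.frame(U = U, V = V)
}

#' Total infused and lost volume
#'
#' Integrates the piecewise-constant rates over `[0, duration]`.
#'
#' @param protocol A [fluid_protocol].
#' @return Named numeric vector with `infused` and `lost` volumes in liters.
#' @export
protocol_volumes <- function(protocol) {
  edges <- c(protocol$time, attr(protocol, "duration"))
  w <- diff(edges)
  c(infused = sum(protocol$U * w), lost = sum(protocol$V * w))
}

#' Read a protocol from CSV
#'
#' Expected columns: `time_min`, `U_l_per_min`, `V_l_per_min`.  Each row's
#' rates hold from its time until the next row; the final row holds until
#' `duration` (an optional `duration_min` attribute row is not used --
#' supply `duration` or the final breakpoint is extended by `tail_min`).
#'
#' @param path CSV file path.
#' @param duration Protocol duration in minutes.  If `NULL` and the file's
#'   final row has both rates zero (as written by [write_protocol()]) that
#'   row's time is taken as the duration; otherwise the last breakpoint plus
#'   `tail_min` is used.
#' @param tail_min Fallback tail length after the last breakpoint (min).
#' @return A [fluid_protocol].
#' @export
read_protocol <- function(path, duration = NULL, tail_min = 5) {
  df <- utils::read.csv(path)
  need <- c("time_min", "U_l_per_min", "V_l_per_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("protocol file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  if (is.null(duration)) {
    if (n > 1 && df$U_l_per_min[n] == 0 && df$V_l_per_min[n] == 0) {
      duration <- df$time_min[n]
      df <- df[-n, , drop = FALSE]
    } else {
      duration <- df$time_min[n] + tail_min
    }
  }
  fluid_protocol(df$time_min, df$U_l_per_min, df$V_l_per_min, duration)
}

#' Write a protocol to CSV
#'
#' Writes `time_min,U_l_per_min,V_l_per_min` rows plus a terminal zero-rate
#' row at `duration` so the file round-trips through [read_protocol()] with
#' the exact duration.
#'
#' @param protocol A [fluid_protocol].
#' @param path Output CSV file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  df <- data.frame(time_min = c(protocol$time, attr(protocol, "duration")),
                   U_l_per_min = c(protocol$U, 0),
                   V_l_per_min = c(protocol$V, 0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
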