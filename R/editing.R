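#' Normal-to-normal (NN) interval series
#'
#' The substrate of all HRV metrics: RR intervals between consecutive sinus
#' beats retained by the editing rules, with per-interval contiguity flags
#' marking where edited-out beats left gaps.  Removed intervals are never
#' interpolated; gaps are represented, not filled.
#'
#' @param intervals numeric vector of NN intervals (ms), all > 0.
#' @param end_times numeric vector, time (ms) of each interval's terminating
#'   beat; strictly increasing.
#' @param contiguous logical vector; `contiguous[i]` is `TRUE` iff interval
#'   `i - 1` ends exactly where interval `i` starts (no edited-out gap).  The
#'   first flag is always `FALSE`.
#' @param sinus_fraction proportion of `N`-labeled beats in the source
#'   recording.
#' @return An object of class `nn_series`.
#' @export
nn_series <- function(intervals, end_times = cumsum(intervals),
                      contiguous = c(FALSE, rep(TRUE, max(0L, length(intervals) - 1L))),
                      sinus_fraction = 1) {
  intervals <- as.numeric(intervals)
  end_times <- as.numeric(end_times)
  n <- length(intervals)
  stopifnot(length(end_times) == n, length(contiguous) == n)
  if (n && any(intervals <= 0)) stop("NN intervals must be positive")
  if (n >= 2 && any(diff(end_times) <= 0)) stop("end_times must be strictly increasing")
  if (n) contiguous[1] <- FALSE
  structure(list(intervals = intervals, end_times = end_times,
                 contiguous = as.logical(contiguous),
                 sinus_fraction = sinus_fraction),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  n <- length(x$intervals)
  cat("<nn_series> ", n, " NN intervals", sep = "")
  if (n) {
    cat(sprintf(", span %.1f s, %d gap(s), sinus fraction %.3f",
                (x$end_times[n] - (x$end_times[1] - x$intervals[1])) / 1000,
                sum(!x$contiguous) - 1L, x$sinus_fraction))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.nn_series <- function(x) length(x$intervals)

# indices of maximal runs of mutually contiguous intervals
contiguous_runs <- function(nn) {
  n <- length(nn$intervals)
  if (!n) return(list())
  starts <- which(!nn$contiguous)
  ends <- c(starts[-1] - 1L, n)
  Map(seq.int, starts, ends)
}

#' Edit a labeled beat series into an NN interval series
#'
#' An interval between consecutive beats is retained iff both endpoint beats
#' are labeled `N`; this removes intervals ending at an abnormal beat and
#' intervals succeeding an ectopic (or unknown) beat.  No interpolation is
#' performed for eliminated intervals: removals are recorded as gaps in the
#' contiguity flags.
#'
#' @param series a [beat_series()] with at least 2 beats.
#' @return An [nn_series()].  May hold zero intervals (flagged with a
#'   warning) if no pair of adjacent `N` beats exists.
#' @examples
#' b <- beat_series(c(0, 1000, 1500, 2600, 3600), c("N", "N", "V", "N", "N"))
#' edit_beats(b)  # keeps (b1,b2) and (b4,b5); the latter is non-contiguous
#' @export
edit_beats <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  n <- length(series$time_ms)
  if (n < 2) stop("need at least 2 beats to form an interval")
  is_n <- series$label == "N"
  keep <- which(is_n[-n] & is_n[-1])          # interval i spans beats i, i+1
  if (!length(keep)) {
    warning("editing removed every interval")
    return(nn_series(numeric(0), numeric(0), logical(0), mean(is_n)))
  }
  rr <- diff(series$time_ms)[keep]
  nn_series(intervals = rr,
            end_times = series$time_ms[keep + 1L],
            contiguous = c(FALSE, diff(keep) == 1L),
            sinus_fraction = mean(is_n))
}

#' Moving-window average outlier filter
#'
#' For each set of five contiguous NN intervals (all five inside one
#' contiguous run), a local average of the four neighbors is computed
#' excluding the central interval; a central interval more than
#' `threshold` (default 20%) greater or smaller than that local average is
#' considered an outlier and replaced by the local average.  A single
#' left-to-right pass is made and every comparison and replacement uses the
#' original, pre-pass values, so corrections never cascade.  Exactly
#' `threshold` deviation is not an outlier.
#'
#' @param nn an [nn_series()] (normally from [edit_beats()]).
#' @param threshold relative deviation bound (default 0.20).
#' @return An [nn_series()] of the same length; the number of replaced
#'   intervals is attached as attribute `"n_replaced"`.  Contiguous runs
#'   shorter than 5 intervals pass through unfiltered.
#' @export
filter_outliers <- function(nn, threshold = 0.20) {
  stopifnot(inherits(nn, "nn_series"), threshold > 0)
  out <- nn$intervals
  n_rep <- 0L
  for (run in contiguous_runs(nn)) {
    if (length(run) < 5L) next
    orig <- nn$intervals[run]
    for (c in 3:(length(run) - 2L)) {
      avg <- (orig[c - 2L] + orig[c - 1L] + orig[c + 1L] + orig[c + 2L]) / 4
      if (orig[c] > (1 + threshold) * avg || orig[c] < (1 - threshold) * avg) {
        out[run[c]] <- avg
        n_rep <- n_rep + 1L
      }
    }
  }
  res <- nn_series(out, nn$end_times, nn$contiguous, nn$sinus_fraction)
  attr(res, "n_replaced") <- n_rep
  res
}

#' Sinus-rhythm quality gate
#'
#' Recordings qualify for HRV analysis only when strictly more than
#' `threshold` (default 95%) of their beats are pure sinus beats; a
#' recording at exactly the threshold fails.
#'
#' @param series a [beat_series()].
#' @param threshold minimum sinus-beat proportion (default 0.95).
#' @return `TRUE` if the recording passes the gate.
#' @export
sinus_gate <- function(series, threshold = 0.95) {
  isTRUE(sinus_fraction(series) > threshold)
}
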