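# Population (ddof = 0) standard deviation; the panel's default throughout.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# successive differences rr[i] - rr[i-1] across contiguous interval pairs only
contiguous_diffs <- function(nn) {
  i <- which(nn$contiguous)
  nn$intervals[i] - nn$intervals[i - 1L]
}

#' Time-domain HRV panel
#'
#' Computes the standard short-term time-domain statistics from an edited NN
#' series.  Successive-difference statistics (RMSSD, NNx, pNNx) use only
#' contiguous interval pairs, so editing gaps never fabricate differences.
#' All standard deviations are population (ddof = 0) unless `ddof = 1`.
#'
#' @param nn an [nn_series()] with at least 2 intervals.
#' @param x_ms threshold (ms) for the NNx/pNNx count; default 50 ms (the
#'   conventional NN50).
#' @param segment_s segment length (s) for SDANN/SDNNi; default 300 s
#'   (5 min), segments aligned to the recording start, a trailing partial
#'   segment is included when it spans at least 60 s.
#' @param ddof 0 (population, default) or 1 (sample) for all SDs.
#' @return A list of class `time_domain_metrics`:
#'   \describe{
#'     \item{sdnn}{SD of all NN intervals, ms.}
#'     \item{sdann}{SD of the per-segment mean NN, ms (`NA` with fewer than
#'       2 segments).}
#'     \item{sdnni}{mean of the per-segment NN SDs, ms.}
#'     \item{rmssd}{root mean square of contiguous successive differences, ms.}
#'     \item{nnx, pnnx}{count / proportion of contiguous successive
#'       differences with `|diff| > x_ms`.}
#'     \item{mean_hr, sd_hr}{mean and SD of the instantaneous heart rate
#'       `60000 / NN`, bpm.}
#'   }
#' @examples
#' nn <- nn_series(rep(1000, 120))
#' time_domain_metrics(nn)$sdnn  # 0
#' @export
time_domain_metrics <- function(nn, x_ms = 50, segment_s = 300, ddof = 0) {
  stopifnot(inherits(nn, "nn_series"), length(nn$intervals) >= 2,
            x_ms >= 0, segment_s > 0, ddof %in% c(0, 1))
  sdfun <- if (ddof == 0) pop_sd else stats::sd
  rr <- nn$intervals
  start <- nn$end_times[1] - rr[1]
  rec_end <- nn$end_times[length(rr)]
  seg_ms <- segment_s * 1000

  # interval belongs to the segment containing its terminating beat; an
  # interval ending exactly on a boundary closes the earlier segment
  seg <- ceiling((nn$end_times - start) / seg_ms) - 1L
  seg[seg < 0L] <- 0L
  keep_seg <- function(k) {
    span <- min(rec_end, start + (k + 1) * seg_ms) - (start + k * seg_ms)
    span >= 60000
  }
  segs <- Filter(keep_seg, sort(unique(seg)))
  seg_means <- vapply(segs, function(k) mean(rr[seg == k]), 0)
  seg_sds <- vapply(segs, function(k) {
    v <- rr[seg == k]
    if (length(v) >= 2) sdfun(v) else NA_real_
  }, 0)

  d <- contiguous_diffs(nn)
  hr <- 60000 / rr
  structure(list(
    sdnn = sdfun(rr),
    sdann = if (length(segs) >= 2) sdfun(seg_means) else NA_real_,
    sdnni = if (any(!is.na(seg_sds))) mean(seg_sds, na.rm = TRUE) else NA_real_,
    rmssd = if (length(d)) sqrt(mean(d^2)) else NA_real_,
    nnx = if (length(d)) sum(abs(d) > x_ms) else NA_integer_,
    pnnx = if (length(d)) mean(abs(d) > x_ms) else NA_real_,
    mean_hr = mean(hr),
    sd_hr = sdfun(hr),
    x_ms = x_ms, n_intervals = length(rr), n_segments = length(segs)
  ), class = "time_domain_metrics")
}

#' @export
print.time_domain_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "Time-domain HRV (%d NN intervals)\n",
    "  SDNN %.1f  SDANN %s  SDNNi %s  RMSSD %.1f ms\n",
    "  NN%g %s  pNN%g %s  mean HR %.1f  SD HR %.2f bpm\n"),
    x$n_intervals, x$sdnn, fmt_na(x$sdann, "%.1f"), fmt_na(x$sdnni, "%.1f"),
    x$rmssd, x$x_ms, fmt_na(x$nnx, "%d"), x$x_ms,
    fmt_na(x$pnnx, "%.3f"), x$mean_hr, x$sd_hr))
  invisible(x)
}

fmt_na <- function(v, fmt) if (is.na(v)) "NA" else sprintf(fmt, v)

#' Geometric HRV measures: triangular index and TINN
#'
#' Bins the NN intervals into a histogram of width `bin_width` (default
#' 1/128 s = 7.8125 ms, the conventional resolution, with bin edges aligned
#' to multiples of the width).  The HRV triangular index is the total
#' interval count divided by the modal bin height.  TINN is the baseline
#' width `M - N` of the best least-squares triangular fit to the histogram:
#' the apex is fixed at the modal bin (its center and height) and the
#' baseline endpoints `N <= mode <= M` are searched over bin edges,
#' minimizing the squared error against the bin counts; the left and right
#' sides separate, so each is optimized independently.
#'
#' @param nn an [nn_series()] with at least 2 intervals.
#' @param bin_width histogram bin width, ms.
#' @return A list with `hrv_ti`, `tinn` (ms), and the histogram
#'   (`breaks`, `counts`).  A single-bin (degenerate) histogram gives
#'   `hrv_ti = 1`, `tinn = bin_width`.
#' @export
geometric_metrics <- function(nn, bin_width = 7.8125) {
  stopifnot(inherits(nn, "nn_series"), length(nn$intervals) >= 2, bin_width > 0)
  rr <- nn$intervals
  lo <- floor(min(rr) / bin_width) * bin_width
  hi <- ceiling(max(rr) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi - 1e-9) breaks <- c(breaks, hi)
  idx <- pmin(findInterval(rr, breaks, rightmost.closed = TRUE), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mode_i <- which.max(counts)
  hrv_ti <- length(rr) / counts[mode_i]

  nz <- which(counts > 0)
  if (length(nz) <= 1L) {
    tinn <- bin_width
  } else {
    X <- centers[mode_i]
    Y <- counts[mode_i]
    # candidate baseline endpoints on bin edges
    left_cand <- breaks[breaks <= X]
    right_cand <- breaks[breaks >= X]
    sse_left <- vapply(left_cand, function(N) {
      q <- ifelse(centers < N | centers >= X, 0,
                  Y * (centers - N) / (X - N))
      sum((counts - q)[centers < X]^2)
    }, 0)
    sse_right <- vapply(right_cand, function(M) {
      q <- ifelse(centers > M | centers <= X, 0,
                  Y * (M - centers) / (M - X))
      sum((counts - q)[centers > X]^2)
    }, 0)
    tinn <- right_cand[which.min(sse_right)] - left_cand[which.min(sse_left)]
  }
  list(hrv_ti = hrv_ti, tinn = tinn, breaks = breaks, counts = counts)
}
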