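#' Poincaré plot dispersion measures SD1 and SD2
#'
#' The lag-1 return map plots each NN interval against its successor; SD1 is
#' the dispersion perpendicular to the line of identity (beat-to-beat,
#' short-term variability) and SD2 the dispersion along it (long-term
#' variability).  With pairs `(x_i, x_{i+1})` taken only across contiguous
#' intervals, `sd1 = SD((x_{i+1} - x_i)/sqrt(2))` and
#' `sd2 = SD((x_{i+1} + x_i)/sqrt(2))` (population SDs).
#'
#' @param nn an [nn_series()] with at least 2 contiguous interval pairs.
#' @return A list with `sd1`, `sd2` (ms) and `n_pairs`; `NA`s when no
#'   contiguous pair exists.
#' @export
poincare <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  i <- which(nn$contiguous)
  if (length(i) < 2) {
    return(list(sd1 = NA_real_, sd2 = NA_real_, n_pairs = length(i)))
  }
  x1 <- nn$intervals[i - 1L]
  x2 <- nn$intervals[i]
  list(sd1 = pop_sd((x2 - x1) / sqrt(2)),
       sd2 = pop_sd((x2 + x1) / sqrt(2)),
       n_pairs = length(i))
}

# Chebyshev template match counts for sample entropy.  Returns the number of
# ordered template pairs (i < j) within tolerance r at lengths m (B) and
# m + 1 (A), using N - m templates for both so the counts are comparable.
sampen_counts <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  D <- abs(outer(x, x, "-"))
  cheb <- D[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m >= 2) {
    for (k in seq_len(m - 1L)) {
      cheb <- pmax(cheb, D[k + seq_len(nt), k + seq_len(nt), drop = FALSE])
    }
  }
  B <- (sum(cheb <= r) - nt) / 2
  chebA <- pmax(cheb, D[m + seq_len(nt), m + seq_len(nt), drop = FALSE])
  A <- (sum(chebA <= r) - nt) / 2
  c(A = A, B = B)
}

#' Sample entropy of an NN series
#'
#' SampEn(m, r) is the negative natural logarithm of the conditional
#' probability that two length-`m` templates matching within tolerance `r`
#' (Chebyshev distance, self-matches excluded) still match at length
#' `m + 1`.  It quantifies the irregularity of the series largely
#' independently of its length.  Gaps are ignored (the concatenated
#' interval list is used): edited gaps are rare after the sinus gate.
#'
#' @param nn an [nn_series()] (or bare numeric vector) with at least
#'   `m + 2` values.
#' @param m template (embedding) length; default 2.
#' @param r match tolerance in ms; default `r_factor` times the population
#'   SD of the series.
#' @param r_factor tolerance as a fraction of the SD (default 0.2), used
#'   when `r` is not given.
#' @return SampEn in nats, with the template match counts attached as
#'   attributes `A` and `B`.  `NA` (with a message) when either count is
#'   zero — never infinity.
#' @export
sample_entropy <- function(nn, m = 2, r = NULL, r_factor = 0.2) {
  x <- if (inherits(nn, "nn_series")) nn$intervals else as.numeric(nn)
  stopifnot(m >= 1, length(x) >= m + 2)
  if (is.null(r)) r <- r_factor * pop_sd(x)
  stopifnot(r >= 0)
  cnt <- sampen_counts(x, m, r)
  if (cnt[["A"]] == 0 || cnt[["B"]] == 0) {
    message("sample_entropy: no template matches at length ",
            if (cnt[["B"]] == 0) m else m + 1, "; returning NA")
    return(structure(NA_real_, A = cnt[["A"]], B = cnt[["B"]]))
  }
  structure(-log(cnt[["A"]] / cnt[["B"]]), A = cnt[["A"]], B = cnt[["B"]])
}

# RMS residual about a per-box least-squares line, all boxes of size n
dfa_fluctuation <- function(y, n) {
  N <- length(y)
  nb <- N %/% n
  if (nb < 1L) return(NA_real_)
  M <- matrix(y[seq_len(nb * n)], nrow = n)      # leftover tail discarded
  t <- seq_len(n)
  X <- cbind(1, t)
  H <- X %*% solve(crossprod(X), t(X))
  R <- M - H %*% M
  sqrt(sum(R^2) / (nb * n))
}

#' Detrended fluctuation analysis scaling exponents
#'
#' The mean-centered NN series is integrated into a profile; for each box
#' size `n` the profile is partitioned into non-overlapping boxes, a
#' least-squares line is removed from each box, and `F(n)` is the RMS
#' residual.  `alpha1` is the slope of `log F(n)` versus `log n` over the
#' short box range (default 4–11 beats) and `alpha2` over the long range
#' (default 12–64 beats).  0.5 indicates uncorrelated noise, 1.0 1/f-like
#' correlations, 1.5 Brownian motion; physiological alpha1 is typically in
#' \[0.3, 1.7\] (a value outside that range only raises a warning).
#'
#' @param nn an [nn_series()] or bare numeric vector; at least 100 intervals
#'   for `alpha1`, 300 for `alpha2` (an exponent with insufficient data is
#'   `NA`).
#' @param short_boxes integer box sizes for `alpha1`.
#' @param long_boxes integer box sizes for `alpha2`.
#' @return A list of class `dfa` with `alpha1`, `alpha2`, and the `n`,
#'   `fn` profile of fluctuations.
#' @export
dfa <- function(nn, short_boxes = 4:11, long_boxes = 12:64) {
  x <- if (inherits(nn, "nn_series")) nn$intervals else as.numeric(nn)
  N <- length(x)
  y <- cumsum(x - mean(x))
  sizes <- sort(unique(c(short_boxes, long_boxes)))
  fn <- vapply(sizes, function(n) dfa_fluctuation(y, n), 0)
  fit_alpha <- function(rng, n_min) {
    if (N < n_min) return(NA_real_)
    i <- sizes %in% rng & is.finite(fn) & fn > 0
    if (sum(i) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log(fn[i]) ~ log(sizes[i])))[2])
  }
  a1 <- fit_alpha(short_boxes, 100L)
  a2 <- fit_alpha(long_boxes, 300L)
  if (!is.na(a1) && (a1 < 0.3 || a1 > 1.7)) {
    warning(sprintf("alpha1 = %.2f outside the typical physiological range [0.3, 1.7]", a1))
  }
  structure(list(alpha1 = a1, alpha2 = a2, n = sizes, fn = fn), class = "dfa")
}

#' @export
print.dfa <- function(x, ...) {
  cat(sprintf("DFA scaling exponents: alpha1 = %s (short boxes), alpha2 = %s (long boxes)\n",
              fmt_na(x$alpha1, "%.3f"), fmt_na(x$alpha2, "%.3f")))
  invisible(x)
}

#' Non-linear HRV panel
#'
#' Combines [poincare()], [sample_entropy()] and [dfa()].
#'
#' @param nn an [nn_series()].
#' @param m,r_factor sample entropy settings.
#' @param short_boxes,long_boxes DFA box ranges.
#' @return A list of class `nonlinear_metrics` with `sd1`, `sd2`, `sampen`,
#'   `alpha1`, `alpha2`.
#' @export
nonlinear_metrics <- function(nn, m = 2, r_factor = 0.2,
                              short_boxes = 4:11, long_boxes = 12:64) {
  pc <- poincare(nn)
  se <- sample_entropy(nn, m = m, r_factor = r_factor)
  df <- dfa(nn, short_boxes = short_boxes, long_boxes = long_boxes)
  structure(list(sd1 = pc$sd1, sd2 = pc$sd2, sampen = as.numeric(se),
                 alpha1 = df$alpha1, alpha2 = df$alpha2),
            class = "nonlinear_metrics")
}

#' @export
print.nonlinear_metrics <- function(x, ...) {
  cat(sprintf("Non-linear HRV: SD1 %.1f  SD2 %.1f ms  SampEn %s  alpha1 %s  alpha2 %s\n",
              x$sd1, x$sd2, fmt_na(x$sampen, "%.2f"),
              fmt_na(x$alpha1, "%.2f"), fmt_na(x$alpha2, "%.2f")))
  invisible(x)
}

#' Poincaré plot
#'
#' Scatter of each NN interval against its successor (contiguous pairs
#' only) with the identity line and the SD1/SD2 ellipse axes.
#'
#' @param nn an [nn_series()].
#' @param ... passed to [graphics::plot()].
#' @return The [poincare()] result, invisibly.
#' @export
plot_poincare <- function(nn, ...) {
  i <- which(nn$contiguous)
  x1 <- nn$intervals[i - 1L]
  x2 <- nn$intervals[i]
  graphics::plot(x1, x2, xlab = expression(NN[i] ~ (ms)),
                 ylab = expression(NN[i + 1] ~ (ms)), asp = 1, ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  pc <- poincare(nn)
  m <- c(mean(x1), mean(x2))
  s2 <- pc$sd2 / sqrt(2)
  s1 <- pc$sd1 / sqrt(2)
  graphics::segments(m[1] - s2, m[2] - s2, m[1] + s2, m[2] + s2, col = 2, lwd = 2)
  graphics::segments(m[1] - s1, m[2] + s1, m[1] + s1, m[2] - s1, col = 4, lwd = 2)
  invisible(pc)
}
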