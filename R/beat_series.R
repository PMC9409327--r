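#' Beat-annotated event series
#'
#' A `beat_series` holds the times (ms, strictly increasing, 1 ms resolution)
#' and labels of detected heartbeats.  Labels follow the usual annotation
#' scheme: `N` (normal sinus), `V` (ventricular ectopic), `S`
#' (supraventricular ectopic), `U` (unknown).
#'
#' @param time_ms numeric vector of beat times in milliseconds, strictly
#'   increasing.  Values are rounded to the nearest millisecond.
#' @param label character vector of beat labels, one of `"N"`, `"V"`, `"S"`,
#'   `"U"`.  Defaults to all-`N`.
#' @return An object of class `beat_series`: a list with elements `time_ms`
#'   and `label`.
#' @examples
#' b <- beat_series(c(0, 1000, 2000, 3000))
#' b
#' @export
beat_series <- function(time_ms, label = rep("N", length(time_ms))) {
  time_ms <- round(as.numeric(time_ms))
  label <- as.character(label)
  if (length(time_ms) != length(label)) {
    stop("`time_ms` and `label` must have the same length")
  }
  bad <- setdiff(unique(label), c("N", "V", "S", "U"))
  if (length(bad)) {
    stop("unknown beat label(s): ", paste(sQuote(bad), collapse = ", "))
  }
  if (length(time_ms) >= 2 && any(diff(time_ms) <= 0)) {
    i <- which(diff(time_ms) <= 0)[1]
    stop("beat times must be strictly increasing (violated at beat ", i + 1, ")")
  }
  structure(list(time_ms = time_ms, label = label), class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  n <- length(x$time_ms)
  cat("<beat_series> ", n, " beats", sep = "")
  if (n) {
    span <- (x$time_ms[n] - x$time_ms[1]) / 1000
    tab <- table(factor(x$label, levels = c("N", "V", "S", "U")))
    cat(sprintf(", %.1f s span; labels: N=%d V=%d S=%d U=%d",
                span, tab[["N"]], tab[["V"]], tab[["S"]], tab[["U"]]))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$time_ms)

#' Proportion of sinus (normal) beats
#'
#' @param series a [beat_series()].
#' @return Proportion of beats labeled `N`.
#' @export
sinus_fraction <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  if (!length(series$time_ms)) return(NA_real_)
  mean(series$label == "N")
}

#' Read a beat-annotation CSV file
#'
#' Expects a header line `time_ms,label` followed by one beat per line.  As a
#' fallback, a bare RR text file (one integer interval in ms per line, no
#' header) is accepted: intervals are cumulated into beat times starting at 0
#' and all beats are labeled `N`.
#'
#' @param path path to the file.
#' @return A [beat_series()].
#' @export
read_beat_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*time_ms\\s*,\\s*label\\s*$", first)) {
    df <- utils::read.csv(path, colClasses = c("numeric", "character"))
    bad <- which(!df$label %in% c("N", "V", "S", "U"))
    if (length(bad)) {
      stop("unknown label ", sQuote(df$label[bad[1]]),
           " at line ", bad[1] + 1L, " of ", path)
    }
    if (anyNA(df$time_ms)) stop("non-numeric time in ", path)
    d <- diff(df$time_ms)
    if (length(d) && any(d <= 0)) {
      i <- which(d <= 0)[1]
      stop("duplicate or decreasing time at line ", i + 2L, " of ", path)
    }
    beat_series(df$time_ms, df$label)
  } else {
    rr <- suppressWarnings(as.numeric(readLines(path)))
    rr <- rr[!is.na(rr)]
    if (!length(rr)) stop("no usable data in ", path)
    if (any(rr <= 0)) stop("non-positive RR interval in ", path)
    beat_series(cumsum(c(0, rr)))
  }
}

#' Write a beat-annotation CSV file
#'
#' Writes the two-column `time_ms,label` format read by [read_beat_csv()].
#'
#' @param series a [beat_series()].
#' @param path destination path.
#' @param force overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_beat_csv <- function(series, path, force = FALSE) {
  stopifnot(inherits(series, "beat_series"))
  if (file.exists(path) && !force) {
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  }
  df <- data.frame(time_ms = series$time_ms, label = series$label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
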