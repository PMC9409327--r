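#' Pipeline configuration
#'
#' A single validated document of every tunable in the pipeline; no stage
#' has hidden defaults outside this schema.
#'
#' @param filter_threshold moving-window outlier bound (default 0.20).
#' @param sinus_threshold sinus-gate proportion (default 0.95, strict).
#' @param fs tachogram resampling rate, Hz.
#' @param welch_segment_s,welch_overlap Welch segmentation.
#' @param vlf,lf,hf spectral band edges, Hz.
#' @param sampen_m,sampen_r_factor sample entropy settings.
#' @param dfa_short,dfa_long DFA box ranges (beats).
#' @param nnx_x NNx/pNNx threshold, ms.
#' @param bin_width geometric histogram bin width, ms.
#' @param segment_s SDANN/SDNNi segment length, s.
#' @param ddof 0 (population SDs, default) or 1.
#' @return A list of class `hrv_config`.
#' @export
hrv_config <- function(filter_threshold = 0.20, sinus_threshold = 0.95,
                       fs = 4, welch_segment_s = 256, welch_overlap = 0.5,
                       vlf = c(0.0033, 0.04), lf = c(0.04, 0.15),
                       hf = c(0.15, 0.40), sampen_m = 2,
                       sampen_r_factor = 0.2, dfa_short = 4:11,
                       dfa_long = 12:64, nnx_x = 50, bin_width = 7.8125,
                       segment_s = 300, ddof = 0) {
  stopifnot(filter_threshold > 0, filter_threshold < 1,
            sinus_threshold > 0, sinus_threshold <= 1,
            fs > 2 * hf[2], welch_segment_s > 0,
            welch_overlap >= 0, welch_overlap < 1,
            vlf[1] < vlf[2], vlf[2] <= lf[1], lf[1] < lf[2],
            lf[2] <= hf[1], hf[1] < hf[2],
            sampen_m >= 1, sampen_r_factor > 0,
            all(dfa_short >= 2), all(dfa_long > max(dfa_short)),
            nnx_x >= 0, bin_width > 0, segment_s > 0, ddof %in% c(0, 1))
  structure(as.list(environment()), class = "hrv_config")
}

#' Analyze one recording end to end
#'
#' Composes the pipeline stages in order: beat editing, moving-window
#' outlier filtering, the sinus quality gate, and the three metric panels
#' (time-domain + geometric, Welch frequency-domain, non-linear).  A
#' recording failing the sinus gate yields a QC record without metrics.
#'
#' @param series a [beat_series()].
#' @param config an [hrv_config()].
#' @return An object of class `hrv_analysis`: `qc_pass`,
#'   `sinus_fraction`, the filtered [nn_series()], and (when the gate
#'   passes) `time`, `geometric`, `spectral`, `nonlinear` panels.
#' @examples
#' b <- generate_rr_series(rr_gen_params(duration = 300, seed = 1))
#' a <- hrv_analyze(b)
#' a$time$sdnn
#' @export
hrv_analyze <- function(series, config = hrv_config()) {
  stopifnot(inherits(series, "beat_series"), inherits(config, "hrv_config"))
  sf <- sinus_fraction(series)
  if (!sinus_gate(series, config$sinus_threshold)) {
    return(structure(list(qc_pass = FALSE, sinus_fraction = sf,
                          config = config),
                     class = "hrv_analysis"))
  }
  nn <- filter_outliers(edit_beats(series), config$filter_threshold)
  td <- time_domain_metrics(nn, x_ms = config$nnx_x,
                            segment_s = config$segment_s, ddof = config$ddof)
  geo <- geometric_metrics(nn, bin_width = config$bin_width)
  sp <- spectral_metrics(nn, fs = config$fs,
                         segment_s = config$welch_segment_s,
                         overlap = config$welch_overlap,
                         vlf = config$vlf, lf = config$lf, hf = config$hf)
  nl <- nonlinear_metrics(nn, m = config$sampen_m,
                          r_factor = config$sampen_r_factor,
                          short_boxes = config$dfa_short,
                          long_boxes = config$dfa_long)
  structure(list(qc_pass = TRUE, sinus_fraction = sf, nn = nn,
                 time = td, geometric = geo, spectral = sp, nonlinear = nl,
                 config = config),
            class = "hrv_analysis")
}

#' @export
print.hrv_analysis <- function(x, ...) {
  if (!x$qc_pass) {
    cat(sprintf("<hrv_analysis> QC FAILED: sinus fraction %.3f below gate\n",
                x$sinus_fraction))
    return(invisible(x))
  }
  cat(sprintf("<hrv_analysis> QC pass (sinus fraction %.3f), %d NN intervals\n",
              x$sinus_fraction, length(x$nn)))
  print(x$time)
  cat(sprintf("  HRVti %.1f  TINN %.1f ms\n", x$geometric$hrv_ti, x$geometric$tinn))
  print(x$spectral)
  print(x$nonlinear)
  invisible(x)
}

#' Flatten an analysis into one metric panel row
#'
#' Columns follow the published panel order: time-domain (SDNN, SDANN, NNx,
#' pNNx, RMSSD, SDNNi, meanHR, sdHR, HRVti, TINN), frequency-domain (TP,
#' nLF, nHF, LF/HF, peak frequencies) and non-linear (SD1, SD2, SampEn,
#' alpha1, alpha2).
#'
#' @param x an `hrv_analysis`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @return A one-row data frame (zero rows for a QC-failed recording).
#' @export
as.data.frame.hrv_analysis <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (!x$qc_pass) return(data.frame())
  data.frame(
    sdnn = x$time$sdnn, sdann = x$time$sdann, nnx = x$time$nnx,
    pnnx = x$time$pnnx, rmssd = x$time$rmssd, sdnni = x$time$sdnni,
    mean_hr = x$time$mean_hr, sd_hr = x$time$sd_hr,
    hrv_ti = x$geometric$hrv_ti, tinn = x$geometric$tinn,
    tp = x$spectral$tp, vlf = x$spectral$vlf, lf = x$spectral$lf,
    hf = x$spectral$hf, n_lf = x$spectral$n_lf, n_hf = x$spectral$n_hf,
    lf_hf = x$spectral$lf_hf, peak_vlf = x$spectral$peak_vlf,
    peak_lf = x$spectral$peak_lf, peak_hf = x$spectral$peak_hf,
    sd1 = x$nonlinear$sd1, sd2 = x$nonlinear$sd2,
    sampen = x$nonlinear$sampen, alpha1 = x$nonlinear$alpha1,
    alpha2 = x$nonlinear$alpha2
  )
}

# serializable panel list for JSON output
panel_list <- function(x) {
  if (!x$qc_pass) {
    return(list(qc_pass = FALSE, sinus_fraction = x$sinus_fraction))
  }
  c(list(qc_pass = TRUE, sinus_fraction = x$sinus_fraction),
    as.list(as.data.frame(x)))
}

#' Analyze a batch of recording files
#'
#' Reads each file with [read_beat_csv()], runs [hrv_analyze()], and
#' (optionally) writes one metrics JSON per recording plus a combined CSV
#' mirroring the panel column order.  Outputs are deterministic: the same
#' inputs and config always give byte-identical files.
#'
#' @param paths character vector of recording files.
#' @param config an [hrv_config()].
#' @param out_dir directory for outputs, or `NULL` for none.
#' @param force overwrite existing outputs?
#' @return A named list of `hrv_analysis` objects, invisibly when
#'   `out_dir` is given.
#' @export
analyze_recordings <- function(paths, config = hrv_config(), out_dir = NULL,
                               force = FALSE) {
  res <- lapply(paths, function(p) hrv_analyze(read_beat_csv(p), config))
  names(res) <- sub("\\.[^.]*$", "", basename(paths))
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res)) {
    jp <- file.path(out_dir, paste0(nm, "_metrics.json"))
    if (file.exists(jp) && !force) {
      stop("refusing to overwrite ", jp, " (use force = TRUE)")
    }
    jsonlite::write_json(panel_list(res[[nm]]), jp, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  rows <- lapply(names(res), function(nm) {
    df <- as.data.frame(res[[nm]])
    if (!nrow(df)) return(NULL)
    cbind(recording = nm, df)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows)) {
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
  }
  invisible(res)
}

#' Run the trial comparison from cohort files
#'
#' Consumes a cohort manifest (`subject_id,arm,age,pre_file,post_file`)
#' whose per-recording metric JSONs were produced by
#' [analyze_recordings()], assembles subject records, and calls
#' [run_trial()].  Subjects with a QC-failed visit are dropped (with a
#' message).
#'
#' @param manifest path to the manifest CSV.
#' @param metrics_dir directory holding `<stem>_metrics.json` files.
#' @param metrics metric keys to analyze (default: the standard panel).
#' @return An `hrv_trial` object.
#' @export
trial_from_files <- function(manifest, metrics_dir, metrics = NULL) {
  man <- utils::read.csv(manifest, colClasses = c(subject_id = "character"))
  read_panel <- function(f) {
    jp <- file.path(metrics_dir, paste0(sub("\\.[^.]*$", "", f), "_metrics.json"))
    if (!file.exists(jp)) stop("missing metrics file ", jp)
    jsonlite::read_json(jp, simplifyVector = TRUE)
  }
  records <- list()
  n_qc <- 0L
  for (i in seq_len(nrow(man))) {
    pre <- read_panel(man$pre_file[i])
    post <- read_panel(man$post_file[i])
    if (!isTRUE(pre$qc_pass) || !isTRUE(post$qc_pass)) {
      n_qc <- n_qc + 1L
      next
    }
    records[[length(records) + 1L]] <-
      list(subject_id = man$subject_id[i], arm = man$arm[i],
           age = man$age[i], pre = pre, post = post)
  }
  if (n_qc) message("trial_from_files: dropped ", n_qc, " subject(s) failing QC")
  run_trial(records, metrics = metrics)
}
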