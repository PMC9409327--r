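#' Parameters for the RR-series generator
#'
#' The generator works directly in the interval (tachogram) domain: each RR
#' interval is a mean level plus two sinusoidal autonomic modulations — one
#' inside the LF band (sympathetic/baroreflex, default 0.1 Hz) and one
#' inside the HF band (respiratory, default 0.25 Hz) — plus white Gaussian
#' noise.  This emulates a 20-min resting recording sampled at the device's
#' 1 ms timing resolution.
#'
#' @param mean_rr mean RR interval, ms (> 0).
#' @param lf_amp,hf_amp sinusoid amplitudes, ms (>= 0).
#' @param lf_freq LF modulation frequency, Hz, in \[0.04, 0.15).
#' @param hf_freq HF modulation frequency, Hz, in \[0.15, 0.40\].
#' @param noise_sd white-noise standard deviation, ms (>= 0).
#' @param duration recording duration, s (default 1200 = 20 min).
#' @param lf_phase,hf_phase sinusoid phases, radians (default 0).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A validated parameter list of class `rr_gen_params`.
#' @export
rr_gen_params <- function(mean_rr = 1000, lf_amp = 25, lf_freq = 0.1,
                          hf_amp = 15, hf_freq = 0.25, noise_sd = 15,
                          duration = 1200, lf_phase = 0, hf_phase = 0,
                          seed = NULL) {
  stopifnot(mean_rr > 0, lf_amp >= 0, hf_amp >= 0, noise_sd >= 0,
            lf_freq >= 0.04, lf_freq < 0.15,
            hf_freq >= 0.15, hf_freq <= 0.40,
            duration > 0)
  structure(list(mean_rr = mean_rr, lf_amp = lf_amp, lf_freq = lf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq, noise_sd = noise_sd,
                 duration = duration, lf_phase = lf_phase,
                 hf_phase = hf_phase, seed = seed),
            class = "rr_gen_params")
}

#' Generate a synthetic all-sinus beat series
#'
#' Starting from a beat at time 0, the i-th interval is
#' `mean_rr + lf_amp * sin(2*pi*lf_freq*t + lf_phase)
#'  + hf_amp * sin(2*pi*hf_freq*t + hf_phase) + eps`, with `t` the cumulative
#' time (s) at the interval's start and `eps ~ N(0, noise_sd^2)`.  Beats are
#' appended until the series spans at least `duration` seconds, then the
#' cumulative beat times are quantized to 1 ms (so quantization errors do
#' not accumulate).  All beats are labeled `N`.
#'
#' @param params an [rr_gen_params()] object (or a list coercible to one).
#' @return A [beat_series()].  Identical seeds give bit-identical output.
#' @examples
#' b <- generate_rr_series(rr_gen_params(mean_rr = 1000, lf_amp = 0,
#'                                       hf_amp = 0, noise_sd = 0,
#'                                       duration = 10))
#' diff(b$time_ms)  # ten 1000 ms intervals
#' @export
generate_rr_series <- function(params) {
  p <- if (inherits(params, "rr_gen_params")) params else do.call(rr_gen_params, params)
  if (p$lf_amp + p$hf_amp >= p$mean_rr) {
    stop("modulation amplitudes too large relative to mean_rr: ",
         "non-positive intervals possible")
  }
  if (!is.null(p$seed)) set.seed(p$seed)
  dur_ms <- p$duration * 1000
  n_max <- ceiling(dur_ms / p$mean_rr * 2) + 16L
  noise <- if (p$noise_sd > 0) stats::rnorm(n_max, 0, p$noise_sd) else numeric(n_max)
  times <- numeric(n_max + 1L)
  t <- 0
  i <- 0L
  while (t < dur_ms) {
    i <- i + 1L
    if (i > n_max) stop("generator overflow: interval model drifted far below mean_rr")
    ts <- t / 1000  # seconds, time of the interval's starting beat
    rr <- p$mean_rr +
      p$lf_amp * sin(2 * pi * p$lf_freq * ts + p$lf_phase) +
      p$hf_amp * sin(2 * pi * p$hf_freq * ts + p$hf_phase) +
      noise[i]
    if (rr <= 0) {
      stop("generated a non-positive interval: amplitudes/noise too large ",
           "relative to mean_rr")
    }
    t <- t + rr
    times[i + 1L] <- t
  }
  times <- round(times[seq_len(i + 1L)])
  if (any(diff(times) <= 0)) {
    stop("1 ms quantization collapsed adjacent beats; intervals too short")
  }
  beat_series(times)
}

#' Parameters for ectopy injection
#'
#' @param ectopic_fraction proportion of beats to relabel as ectopic, in
#'   \[0, 0.5).
#' @param label_mix named proportions over `c(V = , S = )`, summing to 1.
#' @param prematurity fraction of the local RR interval by which a `V` beat
#'   is moved earlier (default 0.5).
#' @param compensatory if `TRUE` (default), the beat following a `V` is held
#'   fixed, producing a full compensatory pause; if `FALSE` it is advanced by
#'   the same shift, so the post-ectopic interval keeps its original length.
#' @return A validated list of class `ectopy_params`.
#' @export
ectopy_params <- function(ectopic_fraction = 0.03, label_mix = c(V = 1, S = 0),
                          prematurity = 0.5, compensatory = TRUE) {
  stopifnot(ectopic_fraction >= 0, ectopic_fraction < 0.5,
            prematurity >= 0, prematurity < 1,
            all(c("V", "S") %in% names(label_mix)),
            abs(sum(label_mix) - 1) < 1e-9)
  structure(list(ectopic_fraction = ectopic_fraction,
                 label_mix = label_mix[c("V", "S")],
                 prematurity = prematurity, compensatory = compensatory),
            class = "ectopy_params")
}

#' Inject ectopic beats into an all-sinus series
#'
#' Relabels `round(ectopic_fraction * n)` beats as `V` or `S` (positions
#' drawn uniformly without replacement, excluding the first and last two
#' beats so downstream edit windows are well defined).  Each `V` beat is
#' moved earlier by `prematurity` times its local (preceding) RR interval;
#' with `compensatory = TRUE` the following beat is untouched (full
#' compensatory pause).  The beat count and the ordering of times are never
#' changed.
#'
#' @param series an all-`N` [beat_series()].
#' @param params an [ectopy_params()] object.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A [beat_series()] of the same length.
#' @export
inject_ectopy <- function(series, params = ectopy_params(), seed = NULL) {
  stopifnot(inherits(series, "beat_series"))
  p <- if (inherits(params, "ectopy_params")) params else do.call(ectopy_params, params)
  if (any(series$label != "N")) stop("input series must be all-N")
  if (!is.null(seed)) set.seed(seed)
  n <- length(series$time_ms)
  k <- round(p$ectopic_fraction * n)
  if (k == 0L) return(series)
  eligible <- seq.int(3L, n - 2L)
  if (k > length(eligible)) stop("too many ectopics for series length")
  pos <- sort(sample(eligible, k))
  lab <- series$label
  lab[pos] <- sample(c("V", "S"), k, replace = TRUE, prob = p$label_mix)
  times <- series$time_ms
  for (i in pos[lab[pos] == "V"]) {
    shift <- p$prematurity * (series$time_ms[i] - series$time_ms[i - 1L])
    times[i] <- series$time_ms[i] - shift
    if (!p$compensatory) times[i + 1L] <- series$time_ms[i + 1L] - shift
  }
  times <- round(times)
  if (any(diff(times) <= 0)) {
    stop("prematurity shift would violate time monotonicity")
  }
  beat_series(times, lab)
}

#' Three-arm pre/post cohort configuration
#'
#' Defaults describe a cardiac-rehabilitation trial with land-based
#' exercise, water-based exercise and control arms (30/29/30 completers) of
#' mean ages 62.4 (7.6), 56.7 (8.4) and 60.6 (8.3) years.  Each subject gets
#' log-normal random effects on the modulation amplitudes (sigma
#' `subject_sigma`) and on `mean_rr` (sigma `mean_rr_sigma`), shared between
#' the pre and post visits; visits differ in modulation phase, noise
#' realization, and the arm's post-visit effect multipliers.  The default
#' water-arm multipliers raise the LF-to-HF modulation ratio (LF amplitude
#' up, HF down) and mean heart rate (mean RR down); land and control default
#' to no change.
#'
#' @param n_per_arm named integer vector of completers per arm; arms may be
#'   a subset of `c("land", "water", "control")`.
#' @param age named list of `c(mean, sd)` per arm, years.
#' @param pre an [rr_gen_params()] used as the base pre-visit model for
#'   every arm (per-arm overrides via a named list of such objects).
#' @param post_mult named list, per arm, of multipliers applied at the post
#'   visit to `lf_amp`, `hf_amp` and `mean_rr` (all > 0).
#' @param subject_sigma log-normal sigma of the subject amplitude effects.
#' @param mean_rr_sigma log-normal sigma of the subject mean-RR effect.
#' @param seed integer seed driving every random stream of the cohort.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = c(land = 30, water = 29, control = 30),
                          age = list(land = c(62.4, 7.6),
                                     water = c(56.7, 8.4),
                                     control = c(60.6, 8.3)),
                          pre = rr_gen_params(),
                          post_mult = list(land = c(lf_amp = 1, hf_amp = 1, mean_rr = 1),
                                           water = c(lf_amp = 1.3, hf_amp = 0.8, mean_rr = 0.94),
                                           control = c(lf_amp = 1, hf_amp = 1, mean_rr = 1)),
                          subject_sigma = 0.2, mean_rr_sigma = 0.06,
                          seed = 1L) {
  arms <- names(n_per_arm)
  stopifnot(length(arms) >= 1, all(arms %in% c("land", "water", "control")),
            all(n_per_arm >= 2), all(arms %in% names(age)),
            all(arms %in% names(post_mult)))
  for (a in arms) {
    stopifnot(all(post_mult[[a]][c("lf_amp", "hf_amp", "mean_rr")] > 0))
  }
  if (inherits(pre, "rr_gen_params")) {
    pre <- stats::setNames(rep(list(pre), length(arms)), arms)
  }
  stopifnot(all(arms %in% names(pre)))
  structure(list(n_per_arm = n_per_arm, age = age, pre = pre,
                 post_mult = post_mult, subject_sigma = subject_sigma,
                 mean_rr_sigma = mean_rr_sigma, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a three-arm pre/post cohort
#'
#' @param config a [cohort_config()].
#' @return A list of subject records, each a list with `subject_id`, `arm`,
#'   `age`, and `pre`/`post` [beat_series()] recordings.  All randomness is
#'   derived deterministically from `config$seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  records <- list()
  id <- 0L
  for (arm in names(config$n_per_arm)) {
    base <- config$pre[[arm]]
    mult <- config$post_mult[[arm]]
    for (s in seq_len(config$n_per_arm[[arm]])) {
      id <- id + 1L
      age <- stats::rnorm(1, config$age[[arm]][1], config$age[[arm]][2])
      amp_eff <- stats::rlnorm(2, 0, config$subject_sigma)   # lf, hf
      rr_eff <- stats::rlnorm(1, 0, config$mean_rr_sigma)
      phases <- stats::runif(4, 0, 2 * pi)                   # pre lf/hf, post lf/hf
      seeds <- sample.int(.Machine$integer.max, 2)
      mk <- function(visit) {
        m <- if (visit == "post") mult else c(lf_amp = 1, hf_amp = 1, mean_rr = 1)
        ph <- if (visit == "post") phases[3:4] else phases[1:2]
        rr_gen_params(mean_rr = base$mean_rr * rr_eff * m[["mean_rr"]],
                      lf_amp = base$lf_amp * amp_eff[1] * m[["lf_amp"]],
                      lf_freq = base$lf_freq,
                      hf_amp = base$hf_amp * amp_eff[2] * m[["hf_amp"]],
                      hf_freq = base$hf_freq,
                      noise_sd = base$noise_sd, duration = base$duration,
                      lf_phase = ph[1], hf_phase = ph[2],
                      seed = seeds[[if (visit == "post") 2L else 1L]])
      }
      records[[id]] <- list(subject_id = sprintf("S%03d", id), arm = arm,
                            age = age,
                            pre = generate_rr_series(mk("pre")),
                            post = generate_rr_series(mk("post")))
    }
  }
  records
}

#' Write a simulated cohort to disk
#'
#' Writes one beat-annotation CSV per recording plus a manifest CSV with
#' columns `subject_id,arm,age,pre_file,post_file`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir destination directory (created if needed).
#' @param force overwrite existing files?
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(dir, "manifest.csv")
  if (file.exists(manifest) && !force) {
    stop("refusing to overwrite ", manifest, " (use force = TRUE)")
  }
  rows <- lapply(cohort, function(r) {
    pre <- file.path(dir, paste0(r$subject_id, "_pre.csv"))
    post <- file.path(dir, paste0(r$subject_id, "_post.csv"))
    write_beat_csv(r$pre, pre, force = force)
    write_beat_csv(r$post, post, force = force)
    data.frame(subject_id = r$subject_id, arm = r$arm, age = r$age,
               pre_file = basename(pre), post_file = basename(post))
  })
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
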