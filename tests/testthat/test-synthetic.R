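test_that("constant generator parameters give an exact metronome", {
  b <- generate_rr_series(rr_gen_params(mean_rr = 1000, lf_amp = 0, hf_amp = 0,
                                        noise_sd = 0, duration = 10))
  expect_identical(diff(b$time_ms), rep(1000, 10))
  expect_true(all(b$label == "N"))
})

test_that("sinusoidal modulation stays within its amplitude bounds", {
  b <- generate_rr_series(rr_gen_params(mean_rr = 1000, lf_amp = 50,
                                        hf_amp = 0, noise_sd = 0,
                                        duration = 1200))
  rr <- diff(b$time_ms)
  expect_true(all(rr >= 950 & rr <= 1050))
  expect_gte(b$time_ms[length(b$time_ms)], 1200 * 1000)
  expect_true(all(diff(b$time_ms) > 0))
})

test_that("identical seeds give bit-identical series, different seeds differ", {
  p <- rr_gen_params(noise_sd = 20, duration = 120, seed = 7)
  expect_identical(generate_rr_series(p), generate_rr_series(p))
  p2 <- rr_gen_params(noise_sd = 20, duration = 120, seed = 8)
  expect_false(identical(generate_rr_series(p), generate_rr_series(p2)))
})

test_that("tachogram variance matches (lf_amp^2 + hf_amp^2)/2 for noiseless input", {
  b <- generate_rr_series(rr_gen_params(mean_rr = 1000, lf_amp = 30,
                                        hf_amp = 20, noise_sd = 0,
                                        duration = 1200))
  rr <- diff(b$time_ms)
  expect_equal(mean((rr - mean(rr))^2), (30^2 + 20^2) / 2, tolerance = 0.05)
})

test_that("overlarge amplitudes are rejected, not silently clipped", {
  expect_error(generate_rr_series(rr_gen_params(mean_rr = 300, lf_amp = 290,
                                                hf_amp = 50, noise_sd = 0,
                                                duration = 60)),
               "non-positive")
})

test_that("generator parameter domains are validated", {
  expect_error(rr_gen_params(mean_rr = -1))
  expect_error(rr_gen_params(lf_freq = 0.2))   # outside the LF band
  expect_error(rr_gen_params(hf_freq = 0.1))   # outside the HF band
  expect_error(rr_gen_params(duration = 0))
})

test_that("ectopy injection relabels the exact rounded count and keeps times", {
  b <- generate_rr_series(rr_gen_params(mean_rr = 1000, lf_amp = 0, hf_amp = 0,
                                        noise_sd = 0, duration = 99))
  expect_length(b, 100)
  out0 <- inject_ectopy(b, ectopy_params(ectopic_fraction = 0), seed = 1)
  expect_identical(out0, b)
  out <- inject_ectopy(b, ectopy_params(ectopic_fraction = 0.03,
                                        label_mix = c(V = 1, S = 0)), seed = 1)
  expect_identical(sum(out$label != "N"), 3L)
  expect_length(out, length(b))
  expect_true(all(diff(out$time_ms) > 0))
  # only V beats move; a full compensatory pause holds the next beat fixed
  moved <- which(out$time_ms != b$time_ms)
  expect_true(all(out$label[moved] == "V"))
})

test_that("injection is reproducible given a seed", {
  b <- generate_rr_series(rr_gen_params(duration = 120, seed = 3))
  p <- ectopy_params(ectopic_fraction = 0.05, label_mix = c(V = 0.6, S = 0.4))
  expect_identical(inject_ectopy(b, p, seed = 11), inject_ectopy(b, p, seed = 11))
})

test_that("default cohort emits 89 subjects across the three arms", {
  cfg <- cohort_config(seed = 5)
  coh <- generate_cohort(cfg)
  expect_length(coh, 89)
  arms <- vapply(coh, `[[`, "", "arm")
  expect_identical(as.integer(table(arms)[c("land", "water", "control")]),
                   c(30L, 29L, 30L))
  expect_s3_class(coh[[1]]$pre, "beat_series")
  expect_s3_class(coh[[1]]$post, "beat_series")
  # same seed reproduces the cohort exactly
  expect_identical(generate_cohort(cfg), coh)
})

test_that("null multipliers give paired pre/post differences centered at zero", {
  cfg <- cohort_config(
    n_per_arm = c(control = 20),
    pre = rr_gen_params(duration = 300),
    post_mult = list(control = c(lf_amp = 1, hf_amp = 1, mean_rr = 1)),
    seed = 9)
  coh <- generate_cohort(cfg)
  d <- vapply(coh, function(r) {
    mean(diff(r$post$time_ms)) - mean(diff(r$pre$time_ms))
  }, 0)
  expect_lt(abs(mean(d)), 5)  # ms; no systematic pre/post shift
})
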