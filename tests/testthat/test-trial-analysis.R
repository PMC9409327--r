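test_that("identical pre and post give p = 1 by convention", {
  x <- rnorm(10, 100, 10)
  w <- within_group_change(x, x)
  expect_equal(w$p, 1)
  expect_equal(w$test, "none")
})

test_that("the normality gate picks the paired t or the Wilcoxon test", {
  set.seed(41)
  pre <- rnorm(30, 100, 10)
  w <- within_group_change(pre, pre + rnorm(30, 2, 3))
  expect_equal(w$test, "paired t")
  skewed <- pre + rexp(30, 0.1)^2 / 20
  w2 <- within_group_change(pre, skewed)
  expect_equal(w2$test, "wilcoxon")
  expect_true(w$p >= 0 && w$p <= 1)
  expect_error(within_group_change(1:3, 2:4), "at least 5")
})

test_that("a calibrated shift is detected with high power", {
  set.seed(42)
  hits <- replicate(100, {
    pre <- rnorm(29, 2.6, 1)
    within_group_change(pre, pre + rnorm(29, 0.6, 0.8))$p < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Sidak adjustment matches its closed form and bounds", {
  expect_equal(sidak_adjust(0.05, 3), 0.142625)
  set.seed(43)
  p <- runif(50)
  for (k in c(2, 3, 6)) {
    padj <- sidak_adjust(p, k)
    expect_true(all(padj >= p))
    expect_true(all(padj <= pmin(1, k * p) + 1e-15))
    expect_true(all(diff(padj[order(p)]) >= 0))
  }
})

test_that("ANCOVA recovers a known arm effect and flags collinearity", {
  set.seed(44)
  n <- 30
  arm <- rep(c("land", "water", "control"), each = n)
  base <- rnorm(3 * n, 100, 10)
  age <- rnorm(3 * n, 60, 8)
  post <- 0.8 * base + 0.1 * age + 10 * (arm == "water") + rnorm(3 * n, 0, 5)
  df <- data.frame(arm, age, baseline = base, post)
  res <- ancova_end_of_study(df)
  expect_lt(res$p_omnibus, 1e-6)
  i <- res$pairwise$pair == "water - land"
  expect_equal(res$pairwise$estimate[i], 10, tolerance = 0.2)
  expect_true(all(res$pairwise$p_sidak >= res$pairwise$p))
  df$age <- df$baseline  # perfectly collinear covariates
  expect_error(ancova_end_of_study(df), "collinear")
})

test_that("pairwise contrasts match emmeans with Sidak adjustment", {
  skip_if_not_installed("emmeans")
  set.seed(45)
  n <- 20
  df <- data.frame(arm = rep(c("land", "water", "control"), each = n),
                   age = rnorm(3 * n, 60, 8),
                   baseline = rnorm(3 * n, 100, 10))
  df$post <- 0.5 * df$baseline + 3 * (df$arm == "water") + rnorm(3 * n, 0, 8)
  res <- ancova_end_of_study(df)
  em <- emmeans::emmeans(res$fit, "arm")
  ep <- as.data.frame(graphics::pairs(em, adjust = "sidak"))
  for (i in seq_len(nrow(res$pairwise))) {
    parts <- strsplit(res$pairwise$pair[i], " - ")[[1]]
    j <- which(ep$contrast %in% paste(parts, collapse = " - ") |
               ep$contrast %in% paste(rev(parts), collapse = " - "))
    expect_length(j, 1)
    expect_equal(res$pairwise$p_sidak[i], ep$p.value[j], tolerance = 1e-8)
  }
})

test_that("the omnibus arm p matches an independent type-II ANCOVA", {
  skip_if_not_installed("car")
  set.seed(46)
  n <- 15
  df <- data.frame(arm = rep(c("land", "water", "control"), each = n),
                   age = rnorm(3 * n, 60, 8), baseline = rnorm(3 * n),
                   post = rnorm(3 * n, 100, 10))
  res <- ancova_end_of_study(df)
  ca <- car::Anova(res$fit, type = 2)
  expect_equal(res$p_omnibus, ca["arm", "Pr(>F)"], tolerance = 1e-12)
})

test_that("summaries follow the mean(SD) / median(Q1-Q3) convention", {
  s <- summarize_values(1:9)
  expect_equal(as.character(s), "5.0 (2.7)")
  expect_true(attr(s, "normal"))
  set.seed(47)
  sk <- summarize_values(rexp(200, 1)^2)
  expect_false(attr(sk, "normal"))
  q <- quantile(rexp(1, 1), c(0.25, 0.5, 0.75))  # formatting only below
  expect_match(as.character(sk), "^[0-9.]+ \\([0-9.]+–[0-9.]+\\)$")
  cs <- summarize_values(rep(3, 10))
  expect_equal(as.character(cs), "3.0 (0.0)")
})

test_that("run_trial assembles summaries, within-group and ANCOVA results", {
  set.seed(48)
  mk <- function(id, arm, eff) {
    lfhf_pre <- rlnorm(1, log(2), 0.4)
    list(subject_id = id, arm = arm, age = rnorm(1, 60, 8),
         pre = list(lf_hf = lfhf_pre, sdnn = rnorm(1, 37, 10)),
         post = list(lf_hf = lfhf_pre * exp(rnorm(1, eff, 0.2)),
                     sdnn = rnorm(1, 37, 10)))
  }
  recs <- c(lapply(1:12, function(i) mk(paste0("L", i), "land", 0)),
            lapply(1:12, function(i) mk(paste0("W", i), "water", 0.5)),
            lapply(1:12, function(i) mk(paste0("C", i), "control", 0)))
  tr <- run_trial(recs)
  expect_s3_class(tr, "hrv_trial")
  expect_named(tr, c("lf_hf", "sdnn"))
  expect_lt(tr$lf_hf$within$water$p, 0.05)
  expect_gt(tr$sdnn$ancova$p_omnibus, 0.001)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 2)
  expect_true(all(c("water_baseline", "water_after", "p_between") %in% names(df)))
})

test_that("missing metric values are dropped listwise with a message", {
  set.seed(49)
  df <- data.frame(arm = rep(c("land", "water", "control"), each = 10),
                   age = rnorm(30, 60, 8), baseline = rnorm(30),
                   post = rnorm(30))
  df$post[c(1, 15)] <- NA
  expect_message(res <- ancova_end_of_study(df), "dropping 2")
  expect_equal(res$n, 28)
})
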