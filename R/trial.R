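#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^k` for `k` comparisons; monotone in `p` and bounded
#' by `min(1, k * p)`.
#'
#' @param p numeric vector of raw p-values.
#' @param k number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, k = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), k >= 1)
  pmin(1, 1 - (1 - p)^k)
}

# Shapiro-Wilk normality gate at alpha; constant input counts as normal
# (its summary is exact either way and shapiro.test() would error).
is_normal <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 3) return(TRUE)
  tryCatch(stats::shapiro.test(x)$p.value >= alpha,
           error = function(e) TRUE)
}

#' Within-group pre/post change test
#'
#' A Shapiro–Wilk test on the paired differences (alpha 0.05) selects the
#' paired t-test when the differences look normal and the Wilcoxon
#' signed-rank test otherwise.  All-zero differences give `p = 1` by
#' convention.
#'
#' @param pre,post paired numeric vectors (same length, n >= 5 after
#'   removing incomplete pairs).
#' @param alpha normality-gate significance level.
#' @return A list with `p` (two-sided), `test` (`"paired t"`,
#'   `"wilcoxon"`, or `"none"`), and `n` pairs used.
#' @export
within_group_change <- function(pre, post, alpha = 0.05) {
  stopifnot(length(pre) == length(post))
  ok <- !(is.na(pre) | is.na(post))
  pre <- pre[ok]
  post <- post[ok]
  if (length(pre) < 5) stop("need at least 5 complete pairs")
  d <- post - pre
  if (all(d == 0)) return(list(p = 1, test = "none", n = length(d)))
  if (is_normal(d, alpha) && stats::sd(d) > 0) {
    ht <- stats::t.test(post, pre, paired = TRUE)
    list(p = unname(ht$p.value), test = "paired t", n = length(d))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    list(p = unname(ht$p.value), test = "wilcoxon", n = length(d))
  }
}

#' End-of-study ANCOVA with age and baseline covariates
#'
#' Fits `post ~ arm + age + baseline` by least squares.  The omnibus arm
#' p-value comes from the partial F-test of the arm term; pairwise arm
#' contrasts are computed from the fitted coefficients and their covariance
#' (t-tests on the model's residual degrees of freedom) and Sidak-adjusted
#' for the number of pairs.
#'
#' @param records list of subject records (each with `arm`, `age`, and
#'   `pre`/`post` metric panels, as produced by the cohort pipeline), or a
#'   data frame with columns `arm`, `age`, `baseline`, `post`.
#' @param metric metric key to analyze when `records` is a list of panels.
#' @return A list of class `ancova_result`: `metric`, `p_omnibus`,
#'   `pairwise` (data frame: pair, estimate, se, p, p_sidak), `n`,
#'   `n_dropped`.
#' @export
ancova_end_of_study <- function(records, metric = NULL) {
  df <- if (is.data.frame(records)) records else trial_frame(records, metric)
  stopifnot(all(c("arm", "age", "baseline", "post") %in% names(df)))
  ok <- stats::complete.cases(df[c("arm", "age", "baseline", "post")])
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message("ancova_end_of_study: dropping ", n_dropped,
            " subject(s) with missing values",
            if (!is.null(metric)) paste0(" for ", metric))
  }
  df <- df[ok, ]
  df$arm <- factor(df$arm)
  counts <- table(df$arm)
  if (length(counts) < 2 || any(counts < 3)) {
    stop("need at least 2 arms with at least 3 subjects each")
  }
  fit <- stats::lm(post ~ arm + age + baseline, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("collinear covariates: coefficient(s) not estimable for ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  fit0 <- stats::lm(post ~ age + baseline, data = df)
  p_omni <- stats::anova(fit0, fit)[2, "Pr(>F)"]

  lev <- levels(df$arm)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  dfres <- stats::df.residual(fit)
  arm_coef <- function(a) {
    v <- stats::setNames(numeric(length(beta)), names(beta))
    if (a != lev[1]) v[paste0("arm", a)] <- 1
    v
  }
  rows <- lapply(pairs, function(pr) {
    L <- arm_coef(pr[2]) - arm_coef(pr[1])
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- est / se
    data.frame(pair = paste(pr[2], "-", pr[1]), estimate = est, se = se,
               p = 2 * stats::pt(-abs(tval), dfres))
  })
  pw <- do.call(rbind, rows)
  pw$p_sidak <- sidak_adjust(pw$p, k = nrow(pw))
  structure(list(metric = metric, p_omnibus = p_omni, pairwise = pw,
                 n = nrow(df), n_dropped = n_dropped, fit = fit),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA (post ~ arm + age + baseline)%s: omnibus p = %.4g, n = %d\n",
              if (!is.null(x$metric)) paste0(" for ", x$metric) else "",
              x$p_omnibus, x$n))
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}

# flatten subject records (arm, age, pre/post panels) into an ANCOVA frame
trial_frame <- function(records, metric) {
  stopifnot(!is.null(metric))
  getm <- function(panel) {
    v <- panel[[metric]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id %||% NA_character_,
               arm = r$arm, age = r$age,
               baseline = getm(r$pre), post = getm(r$post))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary string in the trial's reporting style
#'
#' A Shapiro–Wilk test (alpha 0.05) selects `"mean (SD)"` for normally
#' distributed values and `"median (Q1–Q3)"` otherwise; quartiles use
#' linear interpolation.  SDs are sample SDs, as conventional in cohort
#' tables.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha normality-gate level.
#' @param digits decimal places (default 1).
#' @return A character string; whether the normal branch was taken is
#'   attached as attribute `"normal"`.
#' @examples
#' summarize_values(1:9)  # "5.0 (2.7)"
#' @export
summarize_values <- function(values, alpha = 0.05, digits = 1) {
  v <- values[!is.na(values)]
  stopifnot(length(v) >= 3)
  fmt <- function(x) sprintf(paste0("%.", digits, "f"), x)
  if (is_normal(v, alpha)) {
    s <- stats::sd(v)
    structure(paste0(fmt(mean(v)), " (", fmt(s), ")"), normal = TRUE)
  } else {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    structure(paste0(fmt(q[2]), " (", fmt(q[1]), "–", fmt(q[3]), ")"),
              normal = FALSE)
  }
}

#' Full pre/post trial comparison over a metric panel
#'
#' For each metric: per-arm baseline and end-of-study summaries
#' (mean (SD) or median (Q1–Q3)), the within-arm paired change test, the
#' between-arm ANCOVA omnibus p (age and baseline as covariates), and the
#' Sidak-adjusted pairwise arm contrasts.  Subjects missing a metric are
#' dropped listwise for that metric only.
#'
#' @param records list of subject records with `arm`, `age`, and named
#'   `pre`/`post` metric panels (numeric values per metric key).
#' @param metrics metric keys to analyze; default: every key of the first
#'   record's `pre` panel.
#' @return A list of class `hrv_trial`; one element per metric with
#'   `summaries`, `within` (per arm), `ancova`.
#' @export
run_trial <- function(records, metrics = NULL) {
  stopifnot(length(records) >= 6)
  if (is.null(metrics)) metrics <- names(records[[1]]$pre)
  arms <- unique(vapply(records, function(r) r$arm, ""))
  out <- lapply(metrics, function(mt) {
    df <- trial_frame(records, mt)
    within <- lapply(stats::setNames(arms, arms), function(a) {
      sub <- df[df$arm == a & stats::complete.cases(df[c("baseline", "post")]), ]
      within_group_change(sub$baseline, sub$post)
    })
    summ <- lapply(stats::setNames(arms, arms), function(a) {
      sub <- df[df$arm == a, ]
      list(pre = summarize_values(sub$baseline),
           post = summarize_values(sub$post))
    })
    list(metric = mt, summaries = summ, within = within,
         ancova = ancova_end_of_study(df, metric = mt))
  })
  structure(stats::setNames(out, metrics), class = "hrv_trial")
}

#' @export
print.hrv_trial <- function(x, ...) {
  for (e in x) {
    cat("== ", e$metric, " ==\n", sep = "")
    for (a in names(e$summaries)) {
      cat(sprintf("  %-8s %s -> %s  (within p = %.3f, %s)\n", a,
                  e$summaries[[a]]$pre, e$summaries[[a]]$post,
                  e$within[[a]]$p, e$within[[a]]$test))
    }
    cat(sprintf("  between-arm ANCOVA p = %.4g; Sidak-adjusted pairwise: %s\n",
                e$ancova$p_omnibus,
                paste(sprintf("%s p=%.3f", e$ancova$pairwise$pair,
                              e$ancova$pairwise$p_sidak), collapse = ", ")))
  }
  invisible(x)
}

#' Empirical power of the end-of-study ANCOVA by simulation
#'
#' Simulates a parallel three-arm design: standard-normal baseline, age
#' noise, end-of-study value correlated `rho` with baseline (unit marginal
#' SD) plus an `effect_sd`-standard-deviation shift in one arm, then runs
#' [ancova_end_of_study()] and counts omnibus rejections at `alpha`.  With
#' `effect_sd = 0` this measures the type-I error rate.
#'
#' @param n_per_arm subjects per arm (default 26).
#' @param effect_sd between-group difference in end-of-study SD units.
#' @param alpha two-sided significance level.
#' @param reps number of simulated trials.
#' @param rho baseline/end-of-study correlation (default 0: covariates are
#'   pure noise and the ANCOVA reduces to an ANOVA in expectation).
#' @param seed integer seed, or `NULL`.
#' @return Empirical rejection proportion, with attribute `"reps"`.
#' @export
power_simulation <- function(n_per_arm = 26, effect_sd = 1, alpha = 0.05,
                             reps = 2000, rho = 0, seed = NULL) {
  stopifnot(n_per_arm >= 3, reps >= 1, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  arm <- rep(c("land", "water", "control"), each = n_per_arm)
  n <- length(arm)
  hits <- 0L
  for (i in seq_len(reps)) {
    base <- stats::rnorm(n)
    df <- data.frame(
      arm = arm,
      age = stats::rnorm(n, 60, 8),
      baseline = base,
      post = rho * base + sqrt(1 - rho^2) * stats::rnorm(n) +
        effect_sd * (arm == "water"))
    if (ancova_end_of_study(df)$p_omnibus < alpha) hits <- hits + 1L
  }
  structure(hits / reps, reps = reps)
}

#' Tabulate a trial result
#'
#' One row per metric mirroring the published table layout: per-arm
#' baseline/after summaries and within-arm p, then the between-arm ANCOVA
#' p.
#'
#' @param x an `hrv_trial` object.
#' @param ... unused.
#' @return A data frame.
#' @export
as.data.frame.hrv_trial <- function(x, ...) {
  do.call(rbind, lapply(x, function(e) {
    row <- list(metric = e$metric)
    for (a in names(e$summaries)) {
      row[[paste0(a, "_baseline")]] <- as.character(e$summaries[[a]]$pre)
      row[[paste0(a, "_after")]] <- as.character(e$summaries[[a]]$post)
      row[[paste0(a, "_p")]] <- e$within[[a]]$p
    }
    row$p_between <- e$ancova$p_omnibus
    as.data.frame(row)
  }))
}
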