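#' Bootstrapped Spearman correlation
#'
#' Spearman's rank correlation (ties by average ranks) with a percentile
#' bootstrap confidence interval over paired resamples, as used to relate
#' quantitative lesion measures to visual rating scores.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the two paired variables.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed for the resampling; the result is deterministic
#'   given the seed.
#' @param conf Confidence level of the percentile interval.
#' @return Object of class `wm_cor`: `rho`, `ci_low`, `ci_high`, `p_value`
#'   (asymptotic, two-sided), `n`, `n_boot`, `conf`, `boot_rho` (the
#'   resampled coefficients). `tidy()` returns these as a one-row tibble.
#' @examples
#' d <- tibble::tibble(a = 1:20, b = (1:20)^3)
#' tidy(bootstrap_spearman(d, a, b, n_boot = 200, seed = 1))
#' @export
bootstrap_spearman <- function(data, x, y, n_boot = 2000L, seed = NULL,
                               conf = 0.95) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  if (length(xv) != length(yv)) abort("`x` and `y` must be paired.")
  ok <- complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 5L) abort("Need at least 5 complete pairs.")
  if (length(unique(xv)) < 2L || length(unique(yv)) < 2L)
    abort("Spearman correlation is undefined for a constant vector.")
  rho <- cor(xv, yv, method = "spearman")
  p <- suppressWarnings(
    cor.test(xv, yv, method = "spearman", exact = FALSE)$p.value)
  boot_rho <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(xv[idx])) < 2L || length(unique(yv[idx])) < 2L)
        return(NA_real_)
      cor(xv[idx], yv[idx], method = "spearman")
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot_rho, c(alpha, 1 - alpha), na.rm = TRUE))
  structure(
    list(rho = rho, ci_low = min(ci[1], rho), ci_high = max(ci[2], rho),
         p_value = p, n = n, n_boot = n_boot, conf = conf,
         boot_rho = boot_rho),
    class = "wm_cor")
}

#' @export
print.wm_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f  %d%% CI [%.3f, %.3f]  p = %.3g  (n = %d, %d resamples)\n",
              x$rho, round(100 * x$conf), x$ci_low, x$ci_high, x$p_value,
              x$n, x$n_boot))
  invisible(x)
}

#' @rdname bootstrap_spearman
#' @param ... Unused.
#' @method tidy wm_cor
#' @export
tidy.wm_cor <- function(x, ...) {
  tibble(rho = x$rho, ci_low = x$ci_low, ci_high = x$ci_high,
         p_value = x$p_value, n = x$n, n_boot = x$n_boot, conf = x$conf)
}

#' Bland-Altman agreement analysis
#'
#' Paired differences against pair means with limits of agreement at
#' mean difference +/- 1.96 SD. By default the differences are expressed as
#' percentages of the pair mean, which puts measurements of different
#' magnitude on a common ordinate when comparing repeatability across
#' metrics; `relative = FALSE` gives the classical absolute form.
#'
#' @param data A data frame.
#' @param a,b Unquoted column names of the two paired measurements.
#' @param relative Percentage differences (default) or absolute.
#' @return Object of class `wm_agreement`: `mean_diff`, `loa_low`,
#'   `loa_high`, `sd_diff`, `relative`, `n`, and `pairs` (a tibble with
#'   per-pair `a`, `b`, `mean`, `diff`). `tidy()` returns the summary row;
#'   `autoplot()` draws the Bland-Altman plot.
#' @export
bland_altman <- function(data, a, b, relative = TRUE) {
  av <- eval_tidy(enquo(a), data)
  bv <- eval_tidy(enquo(b), data)
  if (length(av) != length(bv)) abort("`a` and `b` must be paired.")
  ok <- complete.cases(av, bv)
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  if (n < 3L) abort("Need at least 3 complete pairs.")
  pair_mean <- (av + bv) / 2
  if (relative && any(pair_mean == 0))
    abort(paste0("Zero pair mean at pair(s) ",
                 paste(which(pair_mean == 0), collapse = ", "),
                 ": percentage differences undefined."))
  diffs <- if (relative) 100 * (av - bv) / pair_mean else av - bv
  m <- mean(diffs)
  s <- sd(diffs)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         relative = relative, n = n,
         pairs = tibble(a = av, b = bv, mean = pair_mean, diff = diffs)),
    class = "wm_agreement")
}

#' @export
print.wm_agreement <- function(x, ...) {
  unit <- if (x$relative) "%" else ""
  cat(sprintf("Bland-Altman (n = %d): mean difference %.3g%s, limits of agreement [%.3g, %.3g]%s\n",
              x$n, x$mean_diff, unit, x$loa_low, x$loa_high, unit))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `wm_agreement`.
#' @param ... Unused.
#' @method tidy wm_agreement
#' @export
tidy.wm_agreement <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         relative = x$relative, n = x$n)
}

#' @rdname bland_altman
#' @param object A `wm_agreement`.
#' @method autoplot wm_agreement
#' @export
autoplot.wm_agreement <- function(object, ...) {
  ylab <- if (object$relative) "Difference (% of pair mean)" else "Difference"
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Pair mean", y = ylab,
                  title = "Bland-Altman agreement",
                  subtitle = sprintf("mean %.3g, LoA [%.3g, %.3g]",
                                     object$mean_diff, object$loa_low,
                                     object$loa_high)) +
    ggplot2::theme_minimal()
}

#' ANCOVA of a follow-up measurement on baseline and a change score
#'
#' Fits `followup ~ baseline + score` by ordinary least squares: the score
#' coefficient estimates how strongly the visual change rating predicts the
#' follow-up measurement after adjusting for baseline. Rows with missing
#' values are dropped listwise (reported). The outcome may be
#' log-transformed, the usual variance-stabilising choice for lesion
#' measures.
#'
#' @param data A data frame.
#' @param followup,baseline,score Unquoted column names.
#' @param log_outcome Log-transform the outcome (requires positive values).
#' @param conf Confidence level for the score coefficient interval.
#' @param condition_warn Warn when the design matrix condition number
#'   exceeds this (near-collinearity).
#' @return Object of class `wm_ancova`: `score_coef`, `ci_low`, `ci_high`,
#'   `p_value`, `n_used`, `n_dropped`, `log_outcome`, and the underlying
#'   `fit`. `tidy()` gives the full coefficient table; `glance()` the model
#'   summary.
#' @export
ancova_followup <- function(data, followup, baseline, score,
                            log_outcome = FALSE, conf = 0.95,
                            condition_warn = 1e6) {
  df <- tibble(
    followup = eval_tidy(enquo(followup), data),
    baseline = eval_tidy(enquo(baseline), data),
    score = eval_tidy(enquo(score), data))
  ok <- complete.cases(df)
  n_dropped <- sum(!ok)
  df <- df[ok, ]
  if (nrow(df) <= 10L) abort("Need more than 10 complete cases.")
  if (n_dropped > 0)
    inform(sprintf("Dropped %d incomplete case(s) (listwise deletion).", n_dropped))
  if (log_outcome) {
    if (any(df$followup <= 0))
      abort("Log transform requires a strictly positive outcome.")
    df$followup <- log(df$followup)
  }
  fit <- lm(followup ~ baseline + score, data = df)
  kap <- kappa(model.matrix(fit), exact = TRUE)
  if (kap > condition_warn)
    warn(sprintf("Design matrix condition number %.3g: predictors are nearly collinear.", kap))
  ci <- confint(fit, "score", level = conf)
  sm <- summary(fit)
  structure(
    list(score_coef = unname(coef(fit)["score"]),
         ci_low = ci[1], ci_high = ci[2],
         p_value = sm$coefficients["score", "Pr(>|t|)"],
         n_used = nrow(df), n_dropped = n_dropped,
         log_outcome = log_outcome, conf = conf, fit = fit),
    class = "wm_ancova")
}

#' @export
print.wm_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA %s ~ baseline + score (n = %d): score coefficient %.4g, %d%% CI [%.4g, %.4g], p = %.3g\n",
              if (x$log_outcome) "log(followup)" else "followup",
              x$n_used, x$score_coef, round(100 * x$conf),
              x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @rdname ancova_followup
#' @param x A `wm_ancova`.
#' @param ... Unused.
#' @method tidy wm_ancova
#' @export
tidy.wm_ancova <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = x$conf)
  tibble(term = rownames(sm),
         estimate = unname(sm[, "Estimate"]),
         std_error = unname(sm[, "Std. Error"]),
         statistic = unname(sm[, "t value"]),
         p_value = unname(sm[, "Pr(>|t|)"]),
         ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]))
}

#' @rdname ancova_followup
#' @method glance wm_ancova
#' @export
glance.wm_ancova <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         sigma = sm$sigma, n = x$n_used,
         n_dropped = x$n_dropped, log_outcome = x$log_outcome)
}

# Pratt signed-rank test: zero differences keep their ranks (all |d| are
# ranked together) but contribute to neither sum; normal approximation with
# tie and Pratt corrections, continuity-corrected.
wilcoxon_pratt <- function(d) {
  n <- length(d)
  n0 <- sum(d == 0)
  if (n0 == n) return(list(statistic = NA_real_, p_value = 1))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  e_w <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  ties <- table(r[d != 0])
  v_w <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w_pos - e_w - sign(w_pos - e_w) * 0.5) / sqrt(v_w)
  list(statistic = w_pos, p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Paired tests for method comparison
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test on the same pairs.
#' Zero differences are handled by the Pratt method (they are ranked but
#' contribute to neither rank sum); the identical-pairs degenerate case is
#' reported as p = 1 with `degenerate = TRUE` rather than an error.
#'
#' @param data A data frame.
#' @param a,b Unquoted column names of the paired measurements.
#' @return A two-row tibble: `method`, `statistic`, `p_value`, `degenerate`.
#' @export
paired_tests <- function(data, a, b) {
  av <- eval_tidy(enquo(a), data)
  bv <- eval_tidy(enquo(b), data)
  if (length(av) != length(bv)) abort("`a` and `b` must be paired.")
  ok <- complete.cases(av, bv)
  d <- av[ok] - bv[ok]
  if (length(d) < 6L) abort("Need at least 6 complete pairs.")
  degenerate <- all(d == 0)
  if (degenerate) {
    t_stat <- NA_real_; t_p <- 1
    w <- list(statistic = NA_real_, p_value = 1)
  } else {
    tt <- t.test(d)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
    w <- wilcoxon_pratt(d)
  }
  tibble(method = c("paired_t", "wilcoxon_pratt"),
         statistic = c(t_stat, w$statistic),
         p_value = c(t_p, w$p_value),
         degenerate = degenerate)
}

#' Change scores
#'
#' Per-subject change (follow-up minus baseline) of any measure; the same
#' contract as [volume_change()] but on a tidy table.
#'
#' @param data A data frame.
#' @param baseline,followup Unquoted column names.
#' @param name Name of the new change column.
#' @return The input tibble with the change column appended.
#' @export
change_scores <- function(data, baseline, followup, name = "change") {
  bv <- eval_tidy(enquo(baseline), data)
  fv <- eval_tidy(enquo(followup), data)
  out <- as_tibble(data)
  out[[name]] <- fv - bv
  out
}
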