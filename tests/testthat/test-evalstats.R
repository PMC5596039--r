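test_that("Spearman correlation honours monotone transforms and sign", {
  d <- tibble::tibble(x = 1:20, y = (1:20)^3, z = -(1:20))
  expect_equal(bootstrap_spearman(d, x, y, n_boot = 50, seed = 1)$rho, 1)
  expect_equal(bootstrap_spearman(d, x, z, n_boot = 50, seed = 1)$rho, -1)
  expect_error(bootstrap_spearman(tibble::tibble(x = rep(1, 10), y = 1:10),
                                  x, y),
               "constant")
  expect_error(bootstrap_spearman(tibble::tibble(x = 1:4, y = 4:1), x, y),
               "at least 5")
})

test_that("bootstrap is deterministic given a seed and CI is ordered", {
  d <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  a <- bootstrap_spearman(d, x, y, n_boot = 200, seed = 11)
  b <- bootstrap_spearman(d, x, y, n_boot = 200, seed = 11)
  expect_identical(a$boot_rho, b$boot_rho)
  expect_true(a$ci_low <= a$rho && a$rho <= a$ci_high)
  expect_true(a$ci_low >= -1 && a$ci_high <= 1)
})

test_that("independent variables give near-zero rho with a covering CI", {
  withr::with_seed(12, {
    d <- tibble::tibble(x = runif(500), y = runif(500))
  })
  r <- bootstrap_spearman(d, x, y, n_boot = 500, seed = 13)
  expect_lt(abs(r$rho), 0.1)
  expect_true(r$ci_low < 0 && r$ci_high > 0)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    withr::with_seed(n, {
      x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    })
    r <- bootstrap_spearman(tibble::tibble(x = x, y = y), x, y,
                            n_boot = 400, seed = 14)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_gt(widths[1] / widths[3], 2)    # ~ sqrt(16) ideally
})

test_that("Bland-Altman of identical measurements is exactly zero", {
  d <- tibble::tibble(a = c(3, 7, 12, 20), b = c(3, 7, 12, 20))
  ba <- bland_altman(d, a, b)
  expect_identical(ba$mean_diff, 0)
  expect_identical(ba$loa_low, 0)
  expect_identical(ba$loa_high, 0)
})

test_that("a constant 10% ratio gives the closed-form percentage difference", {
  a <- c(5, 10, 20, 40)
  d <- tibble::tibble(a = a, b = 1.1 * a)
  ba <- bland_altman(d, a, b)
  # 100 * (a - 1.1a) / (1.05a) for every pair
  expect_equal(ba$mean_diff, -100 * 0.1 / 1.05, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0, tolerance = 1e-9)
})

test_that("Bland-Altman matches the direct formula on random pairs", {
  withr::with_seed(15, {
    for (i in 1:20) {
      a <- runif(10, 1, 50); b <- runif(10, 1, 50)
      ba <- bland_altman(tibble::tibble(a = a, b = b), a, b)
      diffs <- 100 * (a - b) / ((a + b) / 2)
      expect_equal(ba$mean_diff, mean(diffs), tolerance = 1e-12)
      expect_equal(ba$loa_high, mean(diffs) + 1.96 * sd(diffs),
                   tolerance = 1e-12)
      abs_ba <- bland_altman(tibble::tibble(a = a, b = b), a, b,
                             relative = FALSE)
      expect_equal(abs_ba$mean_diff, mean(a - b), tolerance = 1e-12)
    }
  })
  expect_error(bland_altman(tibble::tibble(a = c(1, -1, 3), b = c(1, 1, 3)),
                            a, b),
               "pair")
})

test_that("paired tests flag the degenerate identical case as p = 1", {
  d <- tibble::tibble(a = 1:10, b = 1:10)
  out <- paired_tests(d, a, b)
  expect_true(all(out$p_value == 1))
  expect_true(all(out$degenerate))
})

test_that("a clear paired shift is detected by both tests", {
  withr::with_seed(16, {
    a <- rnorm(100, 10); b <- a + 1 + rnorm(100, 0, 0.5)
  })
  out <- paired_tests(tibble::tibble(a = a, b = b), a, b)
  expect_true(all(out$p_value < 0.001))
  expect_false(any(out$degenerate))
})

test_that("the Pratt signed-rank test agrees with the standard test when no zeros", {
  withr::with_seed(17, {
    for (i in 1:10) {
      a <- rnorm(30); b <- rnorm(30, 0.3)
      out <- paired_tests(tibble::tibble(a = a, b = b), a, b)
      ref <- suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))$p.value
      p <- out$p_value[out$method == "wilcoxon_pratt"]
      expect_equal(p, ref, tolerance = 1e-10)
    }
  })
})

test_that("the signed-rank test holds its size under the null", {
  withr::with_seed(18, {
    rejections <- sum(vapply(1:200, function(i) {
      a <- rnorm(30); b <- a + rnorm(30)
      out <- paired_tests(tibble::tibble(a = a, b = b), a, b)
      out$p_value[out$method == "wilcoxon_pratt"] < 0.05
    }, logical(1)))
  })
  expect_gte(rejections, 1)      # binomial(200, 0.05): central range
  expect_lte(rejections, 21)
})

test_that("ANCOVA recovers a noiseless linear model exactly", {
  d <- tibble::tibble(baseline = seq(1, 20, length.out = 40),
                      score = rep(c(-2, 0, 1, 3), 10))
  d$followup <- 2 + 1 * d$baseline + 0.5 * d$score
  fit <- suppressWarnings(ancova_followup(d, followup, baseline, score))
  expect_equal(fit$score_coef, 0.5, tolerance = 1e-10)
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "baseline"], 1, tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit))$r_squared, 1, tolerance = 1e-10)
})

test_that("ANCOVA recovers a noisy score effect within its interval", {
  withr::with_seed(19, {
    n <- 400
    d <- tibble::tibble(baseline = rnorm(n, 10, 3),
                        score = sample(-3:3, n, replace = TRUE))
    d$followup <- 2 + 1 * d$baseline + 0.5 * d$score +
      rnorm(n, 0, 0.1 * sd(2 + d$baseline + 0.5 * d$score))
  })
  fit <- ancova_followup(d, followup, baseline, score)
  expect_true(fit$ci_low <= 0.5 && 0.5 <= fit$ci_high)
  expect_lt(abs(fit$score_coef - 0.5), 0.05)
})

test_that("ANCOVA coefficient recovery is nearly unbiased at n = 400", {
  withr::with_seed(20, {
    coefs <- vapply(1:50, function(i) {
      n <- 400
      baseline <- rnorm(n, 10, 3)
      score <- sample(-3:3, n, replace = TRUE)
      mu <- 2 + baseline + 0.5 * score
      followup <- mu + rnorm(n, 0, 0.1 * sd(mu))
      ancova_followup(tibble::tibble(followup, baseline, score),
                      followup, baseline, score)$score_coef
    }, numeric(1))
  })
  expect_lt(abs(mean(coefs) / 0.5 - 1), 0.02)
})

test_that("ANCOVA reports listwise deletion and log-transforms on request", {
  d <- tibble::tibble(baseline = c(NA, 2:20), score = rep_len(0:3, 20))
  d$followup <- exp(1 + 0.1 * ifelse(is.na(d$baseline), 0, d$baseline))
  suppressWarnings(
    expect_message(fit <- ancova_followup(d, followup, baseline, score,
                                          log_outcome = TRUE),
                   "1 incomplete"))
  expect_equal(fit$n_used, 19)
  expect_equal(fit$score_coef, 0, tolerance = 1e-8)
  d$followup[2] <- -1
  expect_error(ancova_followup(d, followup, baseline, score,
                               log_outcome = TRUE),
               "positive")
})

test_that("change scores mirror the volume-change contract on tables", {
  d <- tibble::tibble(id = 1:3, baseline = c(2, 2.6, 5),
                      followup = c(2.7, 8.3, 5))
  out <- change_scores(d, baseline, followup)
  expect_equal(out$change, c(0.7, 5.7, 0))
  expect_identical(out$change, volume_change(d$baseline, d$followup))
  expect_equal(sign(change_scores(d, followup, baseline)$change[1]), -1)
})
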