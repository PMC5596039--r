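test_that("colour fusion min-max normalises each channel within the mask", {
  d <- c(4, 4, 4)
  ramp <- array(seq(0, 100, length.out = prod(d)), d)
  msk <- array(TRUE, d)
  f <- fuse_rg(ramp, ramp, msk)
  expect_equal(range(f$red[msk]), c(0, 1))
  expect_identical(f$red, f$green)    # identical sources, identical channels

  withr::with_seed(3, {
    va <- array(rnorm(prod(d), 50, 10), d)
    vb <- array(rnorm(prod(d), 20, 5), d)
    msk2 <- random_mask(d, 0.6)
    f2 <- fuse_rg(va, vb, msk2)
    # per-voxel oracle
    xa <- va[msk2]
    expect_equal(f2$red[msk2], (xa - min(xa)) / (max(xa) - min(xa)),
                 tolerance = 1e-12)
    expect_true(all(is.na(f2$red[!msk2])))
  })
  expect_error(fuse_rg(array(5, d), ramp, msk), "constant")
  expect_error(fuse_rg(ramp, ramp, array(FALSE, d)), "empty")
})

test_that("quantisation is exact when the palette has exactly k colours", {
  d <- c(6, 6, 6)
  vals <- array(rep(c(10, 50, 90), length.out = prod(d)), d)
  f <- fuse_rg(vals, vals, array(TRUE, d))
  q <- minimum_variance_quantise(f, 3)
  expect_equal(q$within_variance, 0)
  expect_equal(sort(unique(as.vector(q$labels))), 1:3)
  expect_error(minimum_variance_quantise(f, 4), "distinct")

  q1 <- minimum_variance_quantise(f, 1)
  expect_equal(nrow(q1$centroids), 1)
  expect_equal(q1$centroids[1, "red"], mean(f$red[f$mask]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("quantisation beats a uniform grid partition of colour space", {
  d <- c(8, 5, 5)
  withr::with_seed(4, {
    va <- array(runif(prod(d)), d)
    vb <- array(runif(prod(d)), d)
  })
  msk <- array(TRUE, d)
  f <- fuse_rg(va, vb, msk)
  q <- minimum_variance_quantise(f, 4)
  # oracle bound: fixed 2x2 partition of the RG unit square
  cols <- cbind(f$red[msk], f$green[msk])
  cell <- 1 + (cols[, 1] >= 0.5) + 2 * (cols[, 2] >= 0.5)
  grid_ss <- sum(vapply(unique(cell), function(cl) {
    cc <- cols[cell == cl, , drop = FALSE]
    sum(sweep(cc, 2, colMeans(cc))^2)
  }, numeric(1)))
  expect_lte(q$within_variance, grid_ss)
})

test_that("within-level variance is non-increasing in k", {
  f <- fuse_rg(lownoise_phantom()$scan$t2star, lownoise_phantom()$scan$flair,
               wm_candidate_mask(lownoise_phantom()))
  wv <- vapply(1:5, function(k) minimum_variance_quantise(f, k)$within_variance,
               numeric(1))
  expect_true(all(diff(wv) <= 1e-9))
})

test_that("level selection recovers the phantom tissues", {
  ph <- lownoise_phantom()
  bm <- wm_candidate_mask(ph)
  s <- segment_mcmxxxvi(ph$scan, bm, k = 3)
  expect_gte(dice(s$wm, ph$truth$masks$nawm), 0.9)
  expect_gte(dice(s$wmh_total, ph$truth$masks$wmh_total), 0.9)
  expect_gte(dice(s$wmh_intense, ph$truth$masks$wmh_intense), 0.9)
  # intense and less-intense always partition the total, by construction
  expect_identical(s$wmh_intense | s$wmh_less_intense, s$wmh_total)
  expect_equal(sum(s$wmh_intense & s$wmh_less_intense), 0)
})

test_that("level selection on a lesion-free phantom yields empty WMH", {
  ph <- cached_phantom("nolesion", grid_shape = c(24, 24, 24), n_lesions = 0,
                       noise_sd = 1)
  s <- segment_mcmxxxvi(ph$scan, wm_candidate_mask(ph), k = 2)
  expect_equal(sum(s$wmh_total), 0)
  expect_identical(s$wm, wm_candidate_mask(ph))
})

test_that("FLAIR thresholding recovers noiseless truth at the 3-SD convention", {
  ph <- noiseless_phantom()
  bm <- wm_candidate_mask(ph)
  # reference statistics are the nominal NAWM distribution the k*SD
  # convention refers to
  nominal <- tibble::tibble(mean = 100, sd = 10, min = 100, max = 100,
                            n = sum(ph$truth$masks$nawm))
  wmh <- flair_histogram_threshold(ph$scan$flair, bm, nominal, k_sd = 3)
  expect_identical(wmh, ph$truth$masks$wmh_total)
  # k_sd = 0 puts the threshold at the NAWM mean: everything qualifies
  all_in <- flair_histogram_threshold(ph$scan$flair, bm, nominal, k_sd = 0)
  expect_identical(all_in, bm)
})

test_that("threshold masks are monotone in k_sd and empty above the ceiling", {
  ph <- noisy_phantom()
  bm <- wm_candidate_mask(ph)
  st <- nawm_stats_robust(ph$scan$flair, bm)
  sizes <- vapply(c(0, 1, 2, 3, 5, 20), function(k)
    sum(flair_histogram_threshold(ph$scan$flair, bm, st, k_sd = k)),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))    # raising k_sd never adds voxels
  expect_equal(sizes[length(sizes)], 0)
  flat <- tibble::tibble(mean = 100, sd = 0, min = 100, max = 100, n = 10)
  expect_warning(
    flair_histogram_threshold(ph$scan$flair, bm, flat, k_sd = 3),
    "SD is zero")
})

test_that("threshold route masks satisfy the tissue partition invariants", {
  ph <- noisy_phantom()
  bm <- wm_candidate_mask(ph)
  seg <- segment_flair_threshold(ph$scan, bm)
  ms <- tissue_mask_set(icv = ph$truth$masks$icv, nawm = seg$nawm,
                        wmh_total = seg$wmh_total,
                        wmh_intense = seg$wmh_intense,
                        wmh_less_intense = seg$wmh_less_intense)
  expect_s3_class(ms, "tissue_mask_set")
  expect_gte(dice(seg$wmh_total, ph$truth$masks$wmh_total), 0.9)
})
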