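test_that("intensity statistics match the definitional voxel loop", {
  v <- array(100, c(3, 3, 3))
  s <- intensity_stats(v, array(TRUE, c(3, 3, 3)))
  expect_equal(s$mean, 100); expect_equal(s$sd, 0); expect_equal(s$n, 27)

  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  v[2, 2, 2] <- 42
  expect_equal(intensity_stats(v, m1)$mean, 42)

  withr::with_seed(1, {
    for (i in 1:20) {
      vol <- array(rnorm(64, 50, 20), c(4, 4, 4))
      msk <- random_mask(c(4, 4, 4), 0.4)
      if (sum(msk) == 0) next
      # brute-force voxel loop over the definition
      acc <- 0; n <- 0; vals <- c()
      for (ix in 1:4) for (iy in 1:4) for (iz in 1:4)
        if (msk[ix, iy, iz]) {
          acc <- acc + vol[ix, iy, iz]; n <- n + 1
          vals <- c(vals, vol[ix, iy, iz])
        }
      s <- intensity_stats(vol, msk)
      expect_equal(s$mean, acc / n, tolerance = 1e-12)
      expect_equal(s$sd, sqrt(mean((vals - mean(vals))^2)), tolerance = 1e-12)
      expect_equal(s$n, n)
    }
  })
  expect_error(intensity_stats(v, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("the damage metric reproduces its analytic cases", {
  nawm <- list(mean = 100)
  # equal intensities: zero contrast, zero damage
  expect_equal(wm_damage(list(mean = 100), nawm, 10, 490)$wm_damage, 0)
  # absent WMH: defined as zero
  z <- wm_damage(NULL, nawm, 0, 500)
  expect_equal(z$wm_damage, 0)
  expect_true(z$valid)
  # hand evaluation: contrast 0.5, proportion 10/500
  r <- wm_damage(list(mean = 150), nawm, 10, 490)
  expect_equal(r$wm_damage, 0.01)
  expect_equal(r$contrast_term, 0.5)
  expect_equal(r$proportion_term, 0.02)
  expect_equal(r$wm_damage, r$contrast_term * r$proportion_term)
})

test_that("the metric is scale-invariant in intensity but not shift-invariant", {
  base <- wm_damage(list(mean = 150), list(mean = 100), 10, 490)$wm_damage
  scaled <- wm_damage(list(mean = 450), list(mean = 300), 10, 490)$wm_damage
  expect_equal(scaled, base, tolerance = 1e-15)
  shifted <- wm_damage(list(mean = 200), list(mean = 150), 10, 490)$wm_damage
  expect_false(isTRUE(all.equal(shifted, base)))
})

test_that("the metric increases with WMH intensity and with WMH volume", {
  vals_i <- vapply(c(120, 140, 160), function(iw)
    wm_damage(list(mean = iw), list(mean = 100), 10, 490)$wm_damage, numeric(1))
  expect_true(all(diff(vals_i) > 0))
  vals_v <- vapply(c(5, 15, 40), function(v)
    wm_damage(list(mean = 150), list(mean = 100), v, 490)$wm_damage, numeric(1))
  expect_true(all(diff(vals_v) > 0))
})

test_that("negative contrast is reported raw and flagged, never clamped", {
  expect_warning(
    r <- wm_damage(list(mean = 80), list(mean = 100), 10, 490),
    "negative contrast")
  expect_false(r$valid)
  expect_equal(r$wm_damage, -0.2 * 0.02)
  expect_error(wm_damage(list(mean = 80), list(mean = 0), 10, 490), "positive")
})

test_that("the metric stays in [0, 1] across its validity region", {
  sw <- wm_damage_sweep(2000, seed = 123)
  expect_gte(min(sw$wm_damage), 0)
  expect_lte(max(sw$wm_damage), 1)
  # constraints actually held in the draws
  expect_true(all(sw$i_wmh >= sw$i_nawm + 3 * sw$sd_nawm - 1e-12))
  expect_true(all(sw$i_nawm <= 2 / 3 * 100 + 1e-12))
})

test_that("head-size normalisation behaves at its boundaries", {
  expect_equal(pct_icv(10, 1000), 1)
  expect_equal(pct_icv(0, 1000), 0)
  expect_equal(pct_icv(1000, 1000), 100)
  expect_warning(pct_icv(1001, 1000), "exceeds")
  expect_error(pct_icv(10, 0), "positive")
})

test_that("numeric volume change subtracts baseline from follow-up", {
  expect_equal(volume_change(2, 2.7), 0.7)
  expect_equal(volume_change(2.6, 8.3), 5.7)
  expect_equal(volume_change(5, 5), 0)
  expect_equal(volume_change(c(1, 2), c(3, 1)), c(2, -1))
  expect_error(volume_change(-1, 2), ">= 0")
})

test_that("spatial change agrees with voxelwise set differences", {
  d <- c(5, 5, 5)
  m <- random_mask(d, 0.3)
  same <- spatial_change(m, m, c(1, 1, 1))
  expect_equal(same$new_ml, 0); expect_equal(same$vanished_ml, 0)

  a <- array(FALSE, d); a[1:2, , ] <- TRUE
  b <- array(FALSE, d); b[4:5, , ] <- TRUE
  disj <- spatial_change(a, b, c(2, 2, 2))
  expect_equal(disj$new_ml, sum(b) * 8 / 1000)
  expect_equal(disj$vanished_ml, sum(a) * 8 / 1000)

  withr::with_seed(2, {
    for (i in 1:20) {
      a <- random_mask(d); b <- random_mask(d)
      ch <- spatial_change(a, b, c(1, 2, 1.5))
      vv <- prod(c(1, 2, 1.5)) / 1000
      expect_equal(ch$new_ml, sum(b & !a) * vv, tolerance = 1e-12)
      expect_equal(ch$vanished_ml, sum(a & !b) * vv, tolerance = 1e-12)
      # net spatial change equals the numeric volume change
      expect_equal(ch$net_ml, volume_change(sum(a) * vv, sum(b) * vv),
                   tolerance = 1e-12)
    }
  })
  expect_error(spatial_change(a, array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
               "grids")
})

test_that("excluded voxels are dropped from every compartment of the metric", {
  ph <- noiseless_phantom()
  m <- ph$truth$masks
  excl <- array(FALSE, dim(m$icv))
  w <- which(m$wmh_total)
  excl[w[1:5]] <- TRUE
  masks <- tissue_mask_set(m$icv, m$nawm & !excl, m$wmh_total & !excl,
                           exclusion = excl)
  res <- wm_damage_from_scan(ph$scan, masks)
  vv <- voxel_volume_ml(ph$scan)
  expect_equal(res$wmh_volume_ml, (sum(m$wmh_total) - 5) * vv)
})
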