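#' Fuse two sequences into a red-green colour image
#'
#' The multispectral colour-fusion segmentation route maps two co-registered
#' sequences onto the red and green channels of a colour image: each volume
#' is min-max normalised to \[0, 1\] within the brain mask. The usual pairs
#' are T1W+T2W (for normal white matter) and T2*W+FLAIR (for WMH).
#'
#' @param vol_a Volume mapped to the red channel.
#' @param vol_b Volume mapped to the green channel.
#' @param brain_mask Logical 3D array; voxels outside are excluded (`NA`).
#' @param source_pair Label recording which sequences were fused.
#' @return An object of class `fused_rg`: list with `red`, `green` (arrays,
#'   `NA` outside the mask), `mask`, `source_pair`.
#' @export
fuse_rg <- function(vol_a, vol_b, brain_mask, source_pair = "T2star+FLAIR") {
  brain_mask <- as_binary_mask(brain_mask)
  if (!identical(dim(vol_a), dim(brain_mask)) ||
      !identical(dim(vol_b), dim(brain_mask)))
    abort("Volumes and brain mask are on different grids.")
  if (sum(brain_mask) == 0L) abort("Brain mask is empty.")
  norm1 <- function(v, nm) {
    x <- v[brain_mask]
    rng <- range(x)
    if (rng[1] == rng[2])
      abort(sprintf("Channel `%s` is constant within the mask: min-max normalisation undefined.", nm))
    out <- array(NA_real_, dim = dim(v))
    out[brain_mask] <- (x - rng[1]) / (rng[2] - rng[1])
    out
  }
  structure(list(red = norm1(vol_a, "red"), green = norm1(vol_b, "green"),
                 mask = brain_mask, source_pair = source_pair),
            class = "fused_rg")
}

# Greedy variance-minimising cuts over distinct colours: recursively take
# the box with the largest within-box weighted sum of squares and split it
# along the axis and threshold that minimise the resulting total SSE (the
# 1D optimal two-level quantiser, found by prefix sums).
variance_cut_init <- function(uc, w, k) {
  box_ss <- function(idx) {
    ww <- w[idx]
    cc <- uc[idx, , drop = FALSE]
    mu <- colSums(cc * ww) / sum(ww)
    sum(ww * sweep(cc, 2, mu)^2)
  }
  best_cut <- function(idx) {
    best <- list(ss = Inf)
    for (j in 1:2) {
      ord <- idx[order(uc[idx, j])]
      ww <- w[ord]
      sw <- cumsum(ww)
      tot_w <- sw[length(sw)]
      ss_cut <- rep(0, length(ord) - 1L)
      for (ch in 1:2) {
        x <- uc[ord, ch]
        swx <- cumsum(ww * x)
        swx2 <- cumsum(ww * x^2)
        t <- seq_len(length(ord) - 1L)
        left <- swx2[t] - swx[t]^2 / sw[t]
        right <- (swx2[length(ord)] - swx2[t]) -
          (swx[length(ord)] - swx[t])^2 / (tot_w - sw[t])
        ss_cut <- ss_cut + left + right
      }
      t_best <- which.min(ss_cut)
      if (ss_cut[t_best] < best$ss)
        best <- list(ss = ss_cut[t_best],
                     left = ord[seq_len(t_best)],
                     right = ord[-seq_len(t_best)])
    }
    best
  }
  boxes <- list(seq_len(nrow(uc)))
  while (length(boxes) < k) {
    ss <- vapply(boxes, box_ss, numeric(1))
    splittable <- vapply(boxes, length, integer(1)) > 1L
    if (!any(splittable)) break
    ss[!splittable] <- -Inf
    b <- which.max(ss)
    cut <- best_cut(boxes[[b]])
    boxes[[b]] <- cut$left
    boxes[[length(boxes) + 1L]] <- cut$right
  }
  t(vapply(boxes, function(idx) {
    ww <- w[idx]
    colSums(uc[idx, , drop = FALSE] * ww) / sum(ww)
  }, numeric(2)))
}

#' Minimum-variance quantisation of a fused colour image
#'
#' Partitions the red-green colours of the in-mask voxels into `k` levels so
#' as to (approximately) minimise the total within-level squared deviation:
#' greedy variance-minimising cuts of the distinct colours initialise the
#' level centroids, which Lloyd's algorithm ([stats::kmeans()]) then refines. The
#' procedure is deterministic.
#'
#' @param img A [fuse_rg()] image.
#' @param k Number of quantisation levels (>= 1, at most the number of
#'   distinct in-mask colours).
#' @return An object of class `rg_quantisation`: `labels` (3D integer array
#'   of level indices 1..k, `NA` outside the mask), `centroids` (k x 2
#'   matrix, columns red/green), `sizes`, `within_variance` (total
#'   within-level sum of squares), `k`.
#' @export
minimum_variance_quantise <- function(img, k) {
  if (!inherits(img, "fused_rg")) abort("`img` must come from fuse_rg().")
  if (k < 1) abort("`k` must be >= 1.")
  cols <- cbind(red = img$red[img$mask], green = img$green[img$mask])
  key <- paste(cols[, 1], cols[, 2], sep = "/")
  tab <- table(key)
  if (k > length(tab))
    abort(sprintf("k = %d exceeds the %d distinct colours in the mask.",
                  k, length(tab)))
  first <- !duplicated(key)
  uc <- cols[first, , drop = FALSE]
  w <- as.numeric(tab[match(key[first], names(tab))])
  centers <- variance_cut_init(uc, w, k)
  # tie-break: Lloyd refinement needs distinct starting centroids
  while (anyDuplicated(round(centers, 12))) {
    d <- duplicated(round(centers, 12))
    centers[d, ] <- centers[d, , drop = FALSE] +
      matrix(seq_len(sum(d)) * 1e-9, sum(d), 2)
  }
  fit <- tryCatch(
    kmeans(cols, centers = centers, iter.max = 100L, algorithm = "Lloyd"),
    error = function(e) NULL, warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(fit)) {
    # empty-cluster degeneracy: keep the initial cut partition itself
    d2 <- vapply(seq_len(k), function(j)
      (cols[, 1] - centers[j, 1])^2 + (cols[, 2] - centers[j, 2])^2,
      numeric(nrow(cols)))
    cl <- max.col(-d2, ties.method = "first")
    cent <- t(vapply(seq_len(k), function(j) {
      idx <- cl == j
      if (!any(idx)) centers[j, ] else colMeans(cols[idx, , drop = FALSE])
    }, numeric(2)))
    wss <- sum((cols - cent[cl, , drop = FALSE])^2)
    fit <- list(cluster = cl, centers = cent, tot.withinss = wss)
  }
  labels <- array(NA_integer_, dim = dim(img$mask))
  labels[img$mask] <- fit$cluster
  centroids <- fit$centers
  colnames(centroids) <- c("red", "green")
  structure(list(labels = labels, centroids = centroids,
                 sizes = as.integer(tabulate(fit$cluster, nbins = k)),
                 within_variance = fit$tot.withinss, k = k),
            class = "rg_quantisation")
}

#' Select tissue levels from a quantised colour image
#'
#' Encodes the level-selection step of the colour-fusion route as an
#' explicit centroid rule (the original procedure is operator-guided): the
#' level containing most voxels is taken as normal white matter; any level
#' whose green (FLAIR/T2-driven) centroid exceeds the WM level's green
#' centroid by more than `margin` is WMH; among WMH levels the one with the
#' highest green centroid is the intense compartment and the remaining WMH
#' levels form the less-intense compartment. All in-mask levels not
#' classified as WMH count as normal white matter, the mask being the
#' tissue in which WMH can appear.
#'
#' @param quant An [minimum_variance_quantise()] result.
#' @param margin Minimum green-centroid excess over WM (in normalised
#'   \[0, 1\] units) for a level to count as WMH.
#' @return A list of logical masks `wm`, `wmh_total`, `wmh_intense`,
#'   `wmh_less_intense`, plus `wm_level` and `wmh_levels` (integer level
#'   indices). The three WMH masks always satisfy
#'   `wmh_intense | wmh_less_intense == wmh_total`.
#' @export
select_tissue_levels <- function(quant, margin = 0.1) {
  if (!inherits(quant, "rg_quantisation"))
    abort("`quant` must come from minimum_variance_quantise().")
  if (all(quant$sizes == 0L)) abort("No voxels were quantised; cannot identify WM.")
  wm_level <- which.max(quant$sizes)
  g <- quant$centroids[, "green"]
  wmh_levels <- which(g > g[wm_level] + margin)
  intense_level <- if (length(wmh_levels)) wmh_levels[which.max(g[wmh_levels])]
                   else integer(0)
  lab <- quant$labels
  in_levels <- function(lv) {
    m <- array(FALSE, dim = dim(lab))
    if (length(lv)) m[!is.na(lab) & (lab %in% lv)] <- TRUE
    m
  }
  list(wm = in_levels(setdiff(seq_len(quant$k), wmh_levels)),
       wmh_total = in_levels(wmh_levels),
       wmh_intense = in_levels(intense_level),
       wmh_less_intense = in_levels(setdiff(wmh_levels, intense_level)),
       wm_level = wm_level, wmh_levels = wmh_levels)
}

#' Colour-fusion (MCMxxxVI-style) segmentation of a scan
#'
#' Runs the full colour-fusion route on a scan: fuses the T2*-weighted
#' volume (red) with FLAIR (green) within the brain mask, quantises the
#' colours into `k` minimum-variance levels and selects WM / WMH levels by
#' the centroid rule of [select_tissue_levels()]. When no T2*W volume is
#' available the FLAIR volume is fused with itself, degrading gracefully to
#' a single-sequence quantisation.
#'
#' @param scan A [multi_sequence_scan()].
#' @param brain_mask Logical array delimiting the tissue in which WM and WMH
#'   are sought (brain tissue excluding the cortex; on real data the user
#'   supplies this, the phantom provides it).
#' @param k Number of quantisation levels.
#' @param margin Passed to [select_tissue_levels()].
#' @return A list with the masks of [select_tissue_levels()] plus the
#'   `quantisation` object and the `fused` image.
#' @export
segment_mcmxxxvi <- function(scan, brain_mask, k = 3, margin = 0.1) {
  if (!inherits(scan, "multi_sequence_scan")) abort("`scan` must be a multi_sequence_scan.")
  red_src <- scan$t2star %||% scan$flair
  pair <- if (is.null(scan$t2star)) "FLAIR+FLAIR" else "T2star+FLAIR"
  fused <- fuse_rg(red_src, scan$flair, brain_mask, source_pair = pair)
  quant <- minimum_variance_quantise(fused, k)
  sel <- select_tissue_levels(quant, margin = margin)
  c(sel, list(quantisation = quant, fused = fused))
}

#' Robust NAWM intensity estimate from a brain mask
#'
#' Median/MAD estimate of the NAWM FLAIR intensity distribution, usable as
#' the reference statistics for [flair_histogram_threshold()] when no NAWM
#' mask exists yet. Valid when NAWM is the modal tissue within the mask, as
#' it is in brain tissue excluding the cortex.
#'
#' @param flair FLAIR volume.
#' @param brain_mask Logical 3D array.
#' @return An `intensity_stats` tibble (`mean` = median, `sd` = MAD).
#' @export
nawm_stats_robust <- function(flair, brain_mask) {
  brain_mask <- as_binary_mask(brain_mask)
  x <- flair[brain_mask]
  if (length(x) == 0L) abort("Brain mask is empty.")
  out <- tibble(mean = median(x), sd = mad(x),
                min = min(x), max = max(x), n = length(x))
  class(out) <- c("intensity_stats", class(out))
  out
}

#' FLAIR histogram threshold segmentation of WMH
#'
#' Implements the standard-deviation form of histogram thresholding: WMH are
#' the in-mask voxels whose FLAIR intensity is at least
#' `mean_NAWM + k_sd * SD_NAWM`, following the convention that WMH lie at
#' least 3 NAWM SDs above the NAWM mean (`k_sd = 3` default).
#'
#' @param flair FLAIR volume.
#' @param brain_mask Logical array of tissue in which WMH may appear.
#' @param nawm_stats Reference NAWM [intensity_stats()] (measured on an NAWM
#'   region, or nominal values, or [nawm_stats_robust()]).
#' @param k_sd Threshold in NAWM SD units.
#' @param exclusion Optional mask of voxels (stroke lesions, artefacts) to
#'   drop before thresholding.
#' @return Logical WMH mask.
#' @export
flair_histogram_threshold <- function(flair, brain_mask, nawm_stats,
                                      k_sd = 3, exclusion = NULL) {
  brain_mask <- as_binary_mask(brain_mask)
  if (!identical(dim(flair), dim(brain_mask)))
    abort("FLAIR and brain mask are on different grids.")
  if (nawm_stats$n < 1) abort("`nawm_stats` must come from a nonempty region.")
  if (nawm_stats$sd == 0 && k_sd > 0)
    warn("NAWM SD is zero: the threshold equals the NAWM mean (likely synthetic input).")
  thr <- nawm_stats$mean + k_sd * nawm_stats$sd
  keep <- brain_mask
  if (!is.null(exclusion)) keep <- keep & !as_binary_mask(exclusion)
  array(keep & (flair >= thr), dim = dim(flair))
}

#' Threshold-route WMH segmentation with severity split
#'
#' Applies [flair_histogram_threshold()] twice: at `k_sd` NAWM SDs for the
#' total WMH mask and at `k_intense_sd` SDs for the intense compartment;
#' less-intense WMH are the remainder. NAWM is all other in-mask tissue.
#' When `nawm_stats` is omitted a robust median/MAD estimate over the brain
#' mask is used.
#'
#' @inheritParams flair_histogram_threshold
#' @param scan A [multi_sequence_scan()].
#' @param k_intense_sd Threshold (SD units) separating intense from
#'   less-intense WMH.
#' @return List of logical masks: `nawm`, `wmh_total`, `wmh_intense`,
#'   `wmh_less_intense`, plus the `nawm_stats` used.
#' @export
segment_flair_threshold <- function(scan, brain_mask, nawm_stats = NULL,
                                    k_sd = 3, k_intense_sd = 5,
                                    exclusion = NULL) {
  if (!inherits(scan, "multi_sequence_scan")) abort("`scan` must be a multi_sequence_scan.")
  if (k_intense_sd < k_sd) abort("`k_intense_sd` must be >= `k_sd`.")
  brain_mask <- as_binary_mask(brain_mask)
  if (is.null(nawm_stats))
    nawm_stats <- nawm_stats_robust(scan$flair, brain_mask)
  wmh <- flair_histogram_threshold(scan$flair, brain_mask, nawm_stats,
                                   k_sd = k_sd, exclusion = exclusion)
  intense <- flair_histogram_threshold(scan$flair, brain_mask, nawm_stats,
                                       k_sd = k_intense_sd, exclusion = exclusion)
  keep <- brain_mask
  if (!is.null(exclusion)) keep <- keep & !as_binary_mask(exclusion)
  list(nawm = keep & !wmh,
       wmh_total = wmh,
       wmh_intense = intense,
       wmh_less_intense = wmh & !intense,
       nawm_stats = nawm_stats)
}
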