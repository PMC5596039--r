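#' Intensity statistics of a volume within a mask
#'
#' The mean is the arithmetic mean over the masked voxels (total signal
#' divided by the number of voxels the tissue occupies); the SD is the
#' population standard deviation over the same voxels.
#'
#' @param volume 3D numeric array of intensities.
#' @param mask Logical (or 0/1) 3D array, same grid; must be nonempty.
#' @return A one-row tibble of class `intensity_stats` with columns
#'   `mean`, `sd`, `min`, `max`, `n`.
#' @examples
#' v <- array(100, c(3, 3, 3))
#' intensity_stats(v, v > 0)
#' @export
intensity_stats <- function(volume, mask) {
  if (!is.numeric(volume) || length(dim(volume)) != 3L)
    abort("`volume` must be a 3D numeric array.")
  mask <- as_binary_mask(if (is.logical(mask)) mask else mask)
  if (!identical(dim(volume), dim(mask)))
    abort("`volume` and `mask` grids differ.")
  x <- volume[mask]
  if (length(x) == 0L)
    abort("Mask is empty: intensity statistics are undefined.")
  if (!all(is.finite(x))) abort("Masked intensities contain non-finite values.")
  out <- tibble(mean = mean(x), sd = pop_sd(x),
                min = min(x), max = max(x), n = length(x))
  class(out) <- c("intensity_stats", class(out))
  out
}

#' White matter damage metric
#'
#' Computes the contrast-weighted WMH proportion
#' \deqn{WMdamage = \frac{I_{WMH} - I_{NAWM}}{I_{NAWM}} \cdot
#'   \frac{V_{WMH}}{V_{WMH} + V_{NAWM}}}
#' where \eqn{I} are mean FLAIR (or T2W) intensities over the WMH and NAWM
#' masks and \eqn{V} the compartment volumes. The metric is defined as zero
#' in the absence of WMH. Under the usual FLAIR conventions (WMH mean at
#' least 3 NAWM SDs above the NAWM mean; NAWM mean between 50% and 2/3 of
#' the maximum intensity) it takes values in \[0, 1\]. A negative contrast
#' (WMH darker than NAWM) indicates a segmentation problem: the raw value is
#' reported and `valid` is set to `FALSE`, never clamped.
#'
#' @param stats_wmh [intensity_stats()] of the WMH region, or `NULL` when
#'   there is no WMH.
#' @param stats_nawm [intensity_stats()] of the NAWM region; mean must be > 0.
#' @param vol_wmh_ml,vol_nawm_ml Compartment volumes in ml.
#' @param icv_ml Optional intracranial volume in ml, for `% WMH in ICV`.
#' @param vol_intense_ml,vol_less_intense_ml Optional subcompartment volumes.
#' @param sequence Which sequence the intensities came from
#'   (`"FLAIR"` or `"T2W"`); informational.
#' @return An object of class `wm_damage_result` with fields `wm_damage`,
#'   `contrast_term`, `proportion_term`, volumes in ml, `wmh_pct_icv`,
#'   `sequence_used` and `valid`. Use [tidy()] for a one-row tibble.
#' @examples
#' s_nawm <- tibble::tibble(mean = 100, sd = 5, min = 90, max = 110, n = 1000)
#' s_wmh <- tibble::tibble(mean = 150, sd = 5, min = 140, max = 160, n = 20)
#' wm_damage(s_wmh, s_nawm, vol_wmh_ml = 10, vol_nawm_ml = 490)
#' @export
wm_damage <- function(stats_wmh, stats_nawm, vol_wmh_ml, vol_nawm_ml,
                      icv_ml = NA_real_,
                      vol_intense_ml = NA_real_, vol_less_intense_ml = NA_real_,
                      sequence = c("FLAIR", "T2W")) {
  sequence <- match.arg(sequence)
  stopifnot_scalar_number(vol_wmh_ml, "vol_wmh_ml")
  stopifnot_scalar_number(vol_nawm_ml, "vol_nawm_ml", positive = TRUE)
  if (vol_wmh_ml < 0) abort("`vol_wmh_ml` must be >= 0.")
  i_nawm <- stats_nawm$mean
  if (!is.finite(i_nawm) || i_nawm <= 0)
    abort("NAWM mean intensity must be positive: the contrast ratio is undefined.")
  no_wmh <- vol_wmh_ml == 0
  if (no_wmh) {
    contrast <- NA_real_
    proportion <- 0
    value <- 0          # defined as zero in the absence of WMH
    valid <- TRUE
  } else {
    if (is.null(stats_wmh))
      abort("`stats_wmh` required when the WMH volume is positive.")
    contrast <- (stats_wmh$mean - i_nawm) / i_nawm
    proportion <- vol_wmh_ml / (vol_wmh_ml + vol_nawm_ml)
    value <- contrast * proportion
    valid <- contrast >= 0
    if (!valid)
      warn(sprintf(
        "WMH mean intensity (%.4g) below NAWM mean (%.4g): negative contrast reported unclamped; check the segmentation.",
        stats_wmh$mean, i_nawm))
  }
  structure(
    list(wm_damage = value,
         contrast_term = contrast,
         proportion_term = proportion,
         wmh_volume_ml = vol_wmh_ml,
         nawm_volume_ml = vol_nawm_ml,
         icv_ml = icv_ml,
         wmh_pct_icv = if (is.finite(icv_ml)) pct_icv(vol_wmh_ml, icv_ml)
                       else NA_real_,
         wmh_intense_ml = vol_intense_ml,
         wmh_less_intense_ml = vol_less_intense_ml,
         i_wmh = if (no_wmh) NA_real_ else stats_wmh$mean,
         i_nawm = i_nawm,
         sequence_used = sequence,
         valid = valid),
    class = "wm_damage_result"
  )
}

#' @export
print.wm_damage_result <- function(x, ...) {
  cat(sprintf("<wm_damage_result>  WM damage = %.6g  (%s)%s\n",
              x$wm_damage, x$sequence_used,
              if (!x$valid) "  [INVALID: negative contrast]" else ""))
  cat(sprintf("  contrast (I_WMH - I_NAWM)/I_NAWM : %s\n",
              if (is.na(x$contrast_term)) "-" else sprintf("%.6g", x$contrast_term)))
  cat(sprintf("  proportion WMH/(WMH + NAWM)      : %.6g\n", x$proportion_term))
  cat(sprintf("  WMH %.4g ml, NAWM %.4g ml", x$wmh_volume_ml, x$nawm_volume_ml))
  if (is.finite(x$icv_ml))
    cat(sprintf(", ICV %.4g ml (WMH %.3g%% of ICV)", x$icv_ml, x$wmh_pct_icv))
  cat("\n")
  invisible(x)
}

#' @rdname wm_damage
#' @param x A `wm_damage_result`.
#' @param ... Unused.
#' @method tidy wm_damage_result
#' @export
tidy.wm_damage_result <- function(x, ...) {
  tibble(wm_damage = x$wm_damage,
         contrast_term = x$contrast_term,
         proportion_term = x$proportion_term,
         wmh_volume_ml = x$wmh_volume_ml,
         nawm_volume_ml = x$nawm_volume_ml,
         icv_ml = x$icv_ml,
         wmh_pct_icv = x$wmh_pct_icv,
         wmh_intense_ml = x$wmh_intense_ml,
         wmh_less_intense_ml = x$wmh_less_intense_ml,
         i_wmh = x$i_wmh,
         i_nawm = x$i_nawm,
         sequence_used = x$sequence_used,
         valid = x$valid)
}

#' Compute the WM damage metric from a scan and validated masks
#'
#' Convenience wrapper tying [intensity_stats()] and [wm_damage()] together:
#' intensities are read from the requested sequence, volumes are voxel counts
#' times the voxel volume from the scan header. When both WMH subcompartments
#' are present the WMH intensity is taken over their union, i.e. the
#' volume-weighted mean. The exclusion mask (if any) is honoured by removing
#' excluded voxels from every compartment before measuring.
#'
#' @param scan A [multi_sequence_scan()].
#' @param masks A validated [tissue_mask_set()].
#' @param sequence `"FLAIR"` (default) or `"T2W"` (requires `scan$t2w`).
#' @return A `wm_damage_result`.
#' @export
wm_damage_from_scan <- function(scan, masks, sequence = c("FLAIR", "T2W")) {
  sequence <- match.arg(sequence)
  if (!inherits(scan, "multi_sequence_scan")) abort("`scan` must be a multi_sequence_scan.")
  validate_tissue_mask_set(masks)
  vol <- if (sequence == "FLAIR") scan$flair else scan$t2w
  if (is.null(vol)) abort(sprintf("Scan has no %s volume.", sequence))
  if (!identical(dim(vol), dim(masks$icv)))
    abort("Scan and mask grids differ.")
  drop <- if (is.null(masks$exclusion)) FALSE else masks$exclusion
  nawm <- masks$nawm & !drop
  wmh <- masks$wmh_total & !drop
  vv <- voxel_volume_ml(scan)
  stats_nawm <- intensity_stats(vol, nawm)
  n_wmh <- sum(wmh)
  stats_wmh <- if (n_wmh > 0) intensity_stats(vol, wmh) else NULL
  wm_damage(
    stats_wmh, stats_nawm,
    vol_wmh_ml = n_wmh * vv,
    vol_nawm_ml = sum(nawm) * vv,
    icv_ml = sum(masks$icv) * vv,
    vol_intense_ml = if (is.null(masks$wmh_intense)) NA_real_
                     else sum(masks$wmh_intense & !drop) * vv,
    vol_less_intense_ml = if (is.null(masks$wmh_less_intense)) NA_real_
                          else sum(masks$wmh_less_intense & !drop) * vv,
    sequence = sequence)
}

#' Head-size normalised volume
#'
#' Expresses a volume as a percentage of intracranial volume (ICV), the
#' conventional head-size correction for lesion loads.
#'
#' @param vol_ml Volume(s) in ml.
#' @param icv_ml Intracranial volume(s) in ml, > 0.
#' @return `100 * vol_ml / icv_ml`, vectorised.
#' @export
pct_icv <- function(vol_ml, icv_ml) {
  if (any(!is.finite(icv_ml)) || any(icv_ml <= 0))
    abort("`icv_ml` must be positive and finite.")
  if (any(vol_ml > icv_ml))
    warn("Volume exceeds ICV; check the masks.")
  100 * vol_ml / icv_ml
}

#' Longitudinal volume change
#'
#' Numeric change definition: the follow-up volume minus the baseline volume,
#' per compartment. Vectorised over compartments.
#'
#' @param baseline_ml,followup_ml Non-negative volumes in ml.
#' @return `followup_ml - baseline_ml`.
#' @examples
#' volume_change(c(total = 4.6, intense = 2, less = 2.6),
#'               c(total = 11, intense = 2.7, less = 8.3))
#' @export
volume_change <- function(baseline_ml, followup_ml) {
  if (any(!is.finite(baseline_ml)) || any(!is.finite(followup_ml)))
    abort("Volumes must be finite.")
  if (any(baseline_ml < 0) || any(followup_ml < 0))
    abort("Volumes must be >= 0.")
  followup_ml - baseline_ml
}

#' Longitudinal spatial change from co-registered masks
#'
#' Spatial change definition: subtract the co-registered baseline mask from
#' the follow-up mask. Voxels present only at follow-up are "new", voxels
#' present only at baseline "vanished"; the net change is new minus vanished
#' and equals the numeric volume change of the same two masks exactly.
#'
#' @param mask_baseline,mask_followup Logical/0-1 3D arrays on a common grid
#'   (co-registration assumed done upstream).
#' @param voxel_dims Voxel edge lengths in mm.
#' @return A one-row tibble: `new_ml`, `vanished_ml`, `net_ml`,
#'   `baseline_ml`, `followup_ml`.
#' @export
spatial_change <- function(mask_baseline, mask_followup, voxel_dims) {
  a <- as_binary_mask(mask_baseline)
  b <- as_binary_mask(mask_followup)
  if (!identical(dim(a), dim(b)))
    abort("Baseline and follow-up masks are on different grids; co-register first.")
  vv <- voxel_volume_ml(voxel_dims)
  new_ml <- sum(b & !a) * vv
  vanished_ml <- sum(a & !b) * vv
  tibble(new_ml = new_ml, vanished_ml = vanished_ml,
         net_ml = new_ml - vanished_ml,
         baseline_ml = sum(a) * vv, followup_ml = sum(b) * vv)
}
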