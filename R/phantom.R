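#' Specification of a synthetic brain phantom
#'
#' Defines the ground-truth parameters of a synthetic multi-sequence scan:
#' a nested-ellipsoid brain (ICV containing a cortical ribbon, a white
#' matter compartment, and central ventricular CSF) in which ellipsoidal
#' WMH lesions are embedded. Lesion mean intensity on FLAIR is
#' `mu_nawm + k * sd_nawm`, following the convention that WMH are at least 3
#' NAWM standard deviations above the NAWM mean; two lesion compartments
#' (intense, `k_intense`; less intense, `k_less`) model the differing
#' severity of established and subtle lesions. `mu_nawm` must not exceed
#' 2/3 of the intensity ceiling `imax`, the usual contrast condition for
#' T2W-based sequences.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_dims Voxel edge lengths in mm.
#' @param mu_nawm,sd_nawm NAWM FLAIR mean and nominal SD (arbitrary units).
#' @param csf_mu,cortex_mu FLAIR means of ventricular CSF and cortex.
#' @param k_intense,k_less Contrast multipliers; `k_intense >= k_less >= 3`.
#' @param n_lesions Number of WMH lesions to place (0 allowed).
#' @param lesion_radius_range Min/max lesion semi-axis in mm.
#' @param noise_sd SD of the additive Gaussian noise on every channel.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param imax Intensity ceiling of the synthetic scanner.
#' @param channel_means Named list of per-tissue means for the `t1w`, `t2w`
#'   and `t2star` channels (tissue order: background, CSF, cortex, NAWM,
#'   less-intense WMH, intense WMH). The defaults give the qualitative
#'   orderings of those sequences (e.g. bright NAWM on T1, bright CSF on
#'   T2) and are configurable constants, not claimed physiological.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_dims = c(1, 1, 1),
                         mu_nawm = 100, sd_nawm = 10,
                         csf_mu = 30, cortex_mu = 70,
                         k_intense = 5, k_less = 3.5,
                         n_lesions = 8L,
                         lesion_radius_range = c(2, 4.5),
                         noise_sd = 5,
                         seed = 42L,
                         imax = 160,
                         channel_means = list(
                           t1w    = c(0, 25, 60, 100, 85, 80),
                           t2w    = c(0, 120, 70, 50, 80, 95),
                           t2star = c(0, 110, 65, 55, 75, 85))) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    abort("`grid_shape` must be three integers >= 8.")
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    abort("`voxel_dims` must be three positive lengths in mm.")
  stopifnot_scalar_number(mu_nawm, "mu_nawm", positive = TRUE)
  stopifnot_scalar_number(sd_nawm, "sd_nawm")
  stopifnot_scalar_number(imax, "imax", positive = TRUE)
  if (sd_nawm < 0) abort("`sd_nawm` must be >= 0.")
  if (k_less < 3)
    abort("`k_less` must be >= 3: WMH are defined as at least 3 NAWM SDs above the NAWM mean.")
  if (k_intense < k_less)
    abort("`k_intense` must be >= `k_less`.")
  if (mu_nawm > 2 / 3 * imax)
    abort("`mu_nawm` must be <= 2/3 * imax (contrast convention for T2W-based sequences).")
  means <- c(csf_mu, cortex_mu, mu_nawm,
             mu_nawm + k_less * sd_nawm, mu_nawm + k_intense * sd_nawm)
  if (any(means < 0) || any(means > imax))
    abort("All tissue means must lie within [0, imax].")
  if (n_lesions < 0) abort("`n_lesions` must be >= 0.")
  if (length(lesion_radius_range) != 2L ||
      lesion_radius_range[1] <= 0 ||
      lesion_radius_range[2] < lesion_radius_range[1])
    abort("`lesion_radius_range` must be an increasing pair of positive lengths.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(grid_shape = grid_shape, voxel_dims = as.numeric(voxel_dims),
         mu_nawm = mu_nawm, sd_nawm = sd_nawm,
         csf_mu = csf_mu, cortex_mu = cortex_mu,
         k_intense = k_intense, k_less = k_less,
         n_lesions = as.integer(n_lesions),
         lesion_radius_range = as.numeric(lesion_radius_range),
         noise_sd = noise_sd, seed = as.integer(seed), imax = imax,
         channel_means = channel_means),
    class = "phantom_spec")
}

# Logical ellipsoid on a voxel grid: ((x-c1)/r1)^2 + ... <= 1.
ellipsoid_mask <- function(grid_shape, center, radii) {
  d2 <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - center[a]) / radii[a])^2)
  q <- outer(outer(d2[[1]], d2[[2]], `+`), d2[[3]], `+`)
  array(q <= 1, dim = grid_shape)
}

#' Closed-form expected WM damage of a phantom
#'
#' Evaluates the metric analytically from the noiseless tissue means and the
#' compartment volumes: the WMH mean is the volume-weighted mean of the
#' intense (`mu_nawm + k_intense*sd_nawm`) and less-intense
#' (`mu_nawm + k_less*sd_nawm`) compartments; the value is the relative
#' contrast times the WMH proportion of (WMH + NAWM). Zero WMH volume gives
#' exactly zero.
#'
#' @param spec A [phantom_spec()].
#' @param wmh_intense_ml,wmh_less_intense_ml,nawm_ml Compartment volumes
#'   (any common unit; only ratios enter).
#' @return The expected metric value in \[0, 1).
#' @export
expected_wm_damage <- function(spec, wmh_intense_ml, wmh_less_intense_ml,
                               nawm_ml) {
  if (nawm_ml <= 0) abort("`nawm_ml` must be > 0.")
  if (wmh_intense_ml < 0 || wmh_less_intense_ml < 0)
    abort("WMH volumes must be >= 0.")
  v_wmh <- wmh_intense_ml + wmh_less_intense_ml
  if (v_wmh == 0) return(0)
  mu_i <- spec$mu_nawm + spec$k_intense * spec$sd_nawm
  mu_l <- spec$mu_nawm + spec$k_less * spec$sd_nawm
  i_wmh <- (wmh_intense_ml * mu_i + wmh_less_intense_ml * mu_l) / v_wmh
  unname((i_wmh - spec$mu_nawm) / spec$mu_nawm * v_wmh / (v_wmh + nawm_ml))
}

#' Generate a synthetic multi-sequence brain phantom
#'
#' Builds a nested-ellipsoid brain (ICV > cortical ribbon > white matter
#' compartment > ventricular CSF), places `n_lesions` ellipsoidal WMH
#' entirely inside the white matter compartment (odd-numbered lesions are
#' intense, even-numbered less intense), paints each channel with its tissue
#' means and adds i.i.d. Gaussian noise. The returned truth carries the
#' exact compartment masks, a tissue label array, and the closed-form
#' expected metric, so the whole analysis pipeline can be validated end to
#' end without real data.
#'
#' @param spec A [phantom_spec()].
#' @param max_tries Placement attempts per lesion before giving up.
#' @return A list of class `wm_phantom` with elements
#'   `scan` (a [multi_sequence_scan()]),
#'   `truth` (list: `masks` — a validated [tissue_mask_set()];
#'   `tissue` — integer label array (0 background, 1 CSF, 2 cortex, 3 NAWM,
#'   4 less-intense WMH, 5 intense WMH); `cortex`, `csf` masks;
#'   `expected_wm_damage`; `expected_volumes_ml` tibble), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 32),
#'                                     n_lesions = 2, noise_sd = 0))
#' ph$truth$expected_wm_damage
#' @export
generate_phantom <- function(spec, max_tries = 200L) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  gs <- spec$grid_shape
  center <- (gs + 1) / 2
  icv_r <- 0.45 * gs
  icv <- ellipsoid_mask(gs, center, icv_r)
  inner <- ellipsoid_mask(gs, center, 0.82 * icv_r)
  vent <- ellipsoid_mask(gs, center, 0.22 * icv_r)
  cortex <- icv & !inner
  wm_region <- inner & !vent

  tissue <- array(0L, dim = gs)
  tissue[vent] <- 1L
  tissue[cortex] <- 2L
  tissue[wm_region] <- 3L

  with_seed(spec$seed, {
    # lesion placement: whole ellipsoid must fit inside the (pre-lesion)
    # white matter compartment and not touch an earlier lesion
    lesion_any <- array(FALSE, dim = gs)
    candidates <- which(wm_region)
    for (i in seq_len(spec$n_lesions)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        ctr_idx <- candidates[sample.int(length(candidates), 1L)]
        ctr <- arrayInd(ctr_idx, gs)[1, ]
        r_mm <- runif(3, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
        ell <- ellipsoid_mask(gs, ctr, r_mm / spec$voxel_dims)
        if (sum(ell) >= 1 && all(wm_region[ell]) && !any(lesion_any[ell])) {
          lesion_any <- lesion_any | ell
          tissue[ell] <- if (i %% 2L == 1L) 5L else 4L
          placed <- TRUE
          break
        }
      }
      if (!placed)
        abort(sprintf(
          "Could not place lesion %d without overlap after %d tries; reduce `n_lesions` or `lesion_radius_range`.",
          i, max_tries))
    }

    flair_lut <- c(0, spec$csf_mu, spec$cortex_mu, spec$mu_nawm,
                   spec$mu_nawm + spec$k_less * spec$sd_nawm,
                   spec$mu_nawm + spec$k_intense * spec$sd_nawm)
    paint <- function(lut) {
      v <- array(lut[tissue + 1L], dim = gs)
      if (spec$noise_sd > 0)
        v <- v + array(rnorm(prod(gs), 0, spec$noise_sd), dim = gs)
      v
    }
    flair <- paint(flair_lut)
    t1w <- paint(spec$channel_means$t1w)
    t2w <- paint(spec$channel_means$t2w)
    t2star <- paint(spec$channel_means$t2star)
  })

  masks <- tissue_mask_set(
    icv = icv,
    nawm = tissue == 3L,
    wmh_total = tissue >= 4L,
    wmh_intense = tissue == 5L,
    wmh_less_intense = tissue == 4L)
  scan <- multi_sequence_scan(flair, t1w = t1w, t2w = t2w, t2star = t2star,
                              voxel_dims = spec$voxel_dims,
                              subject_id = "phantom", timepoint = "baseline")
  vols <- mask_volumes(masks, spec$voxel_dims)
  getv <- function(nm) vols$volume_ml[vols$compartment == nm]
  expected <- expected_wm_damage(spec,
                                 wmh_intense_ml = getv("wmh_intense"),
                                 wmh_less_intense_ml = getv("wmh_less_intense"),
                                 nawm_ml = getv("nawm"))
  structure(
    list(scan = scan,
         truth = list(masks = masks, tissue = tissue,
                      cortex = cortex, csf = vent,
                      expected_wm_damage = expected,
                      expected_volumes_ml = vols),
         spec = spec),
    class = "wm_phantom")
}

#' @export
print.wm_phantom <- function(x, ...) {
  cat(sprintf(
    "<wm_phantom> grid %s, %d lesion voxel(s), expected WM damage %.6g\n",
    paste(x$spec$grid_shape, collapse = "x"),
    sum(x$truth$masks$wmh_total), x$truth$expected_wm_damage))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the scan channels and truth masks as NIfTI files plus a JSON truth
#' manifest (expected metric, compartment volumes, generating parameters)
#' into `dir`.
#'
#' @param phantom A `wm_phantom`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!inherits(phantom, "wm_phantom")) abort("`phantom` must be a wm_phantom.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vd <- phantom$spec$voxel_dims
  sc <- phantom$scan
  for (ch in c("flair", "t1w", "t2w", "t2star"))
    if (!is.null(sc[[ch]]))
      write_volume(sc[[ch]], file.path(dir, paste0(ch, ".nii.gz")), vd)
  mk <- phantom$truth$masks
  for (nm in names(mk))
    if (!is.null(mk[[nm]]))
      write_volume(mk[[nm]], file.path(dir, paste0("mask_", nm, ".nii.gz")), vd)
  manifest <- list(
    expected_wm_damage = phantom$truth$expected_wm_damage,
    expected_volumes_ml = phantom$truth$expected_volumes_ml,
    spec = unclass(phantom$spec))
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
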