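#' Tissue mask set
#'
#' Binary masks defining where the damage metric is evaluated: intracranial
#' volume (ICV), normal-appearing white matter (NAWM), total WMH, optional
#' intense / less-intense WMH subcompartments, and an optional exclusion mask
#' (e.g. stroke lesions, artefacts). Validation enforces the anatomical
#' partition: NAWM and WMH are disjoint, both lie inside the ICV, the two WMH
#' subcompartments (when present) partition the total, and excluded voxels
#' belong to neither tissue class.
#'
#' @param icv,nawm,wmh_total Logical (or 0/1 numeric) 3D arrays.
#' @param wmh_intense,wmh_less_intense,exclusion Optional masks, same grid.
#' @return An object of class `tissue_mask_set`.
#' @export
tissue_mask_set <- function(icv, nawm, wmh_total,
                            wmh_intense = NULL, wmh_less_intense = NULL,
                            exclusion = NULL) {
  masks <- list(icv = icv, nawm = nawm, wmh_total = wmh_total,
                wmh_intense = wmh_intense,
                wmh_less_intense = wmh_less_intense,
                exclusion = exclusion)
  present <- !vapply(masks, is.null, logical(1))
  masks[present] <- lapply(masks[present], as_binary_mask)
  out <- structure(masks, class = "tissue_mask_set")
  validate_tissue_mask_set(out)
}

as_binary_mask <- function(m) {
  if (is.logical(m)) {
    if (length(dim(m)) != 3L) abort("Masks must be 3D arrays.")
    return(m)
  }
  if (!is.numeric(m) || length(dim(m)) != 3L)
    abort("Masks must be 3D logical or 0/1 numeric arrays.")
  u <- unique(as.vector(m))
  if (!all(u %in% c(0, 1)))
    abort("Numeric masks must contain only 0 and 1; binarise first (see `read_masks()`).")
  array(m > 0.5, dim = dim(m))
}

#' Validate a tissue mask set
#'
#' Idempotent: a valid set is returned unchanged. Violations are fatal and
#' reported with the offending voxel counts.
#'
#' @param x A `tissue_mask_set`.
#' @return `x`, invisibly classed, unchanged.
#' @export
validate_tissue_mask_set <- function(x) {
  if (!inherits(x, "tissue_mask_set")) abort("Not a `tissue_mask_set`.")
  ref <- dim(x$icv)
  for (nm in names(x)) {
    if (!is.null(x[[nm]]) && !identical(dim(x[[nm]]), ref))
      abort(sprintf("Mask `%s` grid %s does not match ICV grid %s.", nm,
                    paste(dim(x[[nm]]), collapse = "x"),
                    paste(ref, collapse = "x")))
  }
  n_overlap <- sum(x$nawm & x$wmh_total)
  if (n_overlap > 0)
    abort(sprintf("NAWM and WMH masks overlap in %d voxel(s); they must be disjoint.",
                  n_overlap))
  if (!is.null(x$wmh_intense) && !is.null(x$wmh_less_intense)) {
    n_both <- sum(x$wmh_intense & x$wmh_less_intense)
    if (n_both > 0)
      abort(sprintf("Intense and less-intense WMH overlap in %d voxel(s).", n_both))
    n_uncovered <- sum(xor(x$wmh_intense | x$wmh_less_intense, x$wmh_total))
    if (n_uncovered > 0)
      abort(sprintf(
        "Intense + less-intense WMH do not partition the total WMH mask (%d voxel(s) differ).",
        n_uncovered))
  }
  n_outside <- sum((x$nawm | x$wmh_total) & !x$icv)
  if (n_outside > 0)
    abort(sprintf("%d tissue voxel(s) fall outside the ICV mask.", n_outside))
  if (!is.null(x$exclusion)) {
    n_excl <- sum(x$exclusion & (x$nawm | x$wmh_total))
    if (n_excl > 0)
      abort(sprintf("Exclusion mask intersects NAWM/WMH in %d voxel(s).", n_excl))
  }
  invisible(x)
}

#' @export
print.tissue_mask_set <- function(x, ...) {
  counts <- vapply(x, function(m) if (is.null(m)) NA_integer_ else sum(m),
                   integer(1))
  cat("<tissue_mask_set>\n")
  for (nm in names(counts))
    cat(sprintf("  %-17s %s\n", nm,
                if (is.na(counts[[nm]])) "-" else
                  sprintf("%d voxels", counts[[nm]])))
  invisible(x)
}

#' Compartment volumes of a mask set, in ml
#'
#' @param masks A `tissue_mask_set`.
#' @param voxel_dims Voxel edge lengths in mm (e.g. from the FLAIR header).
#' @return A tibble with one row per present compartment: `compartment`,
#'   `n_voxels`, `volume_ml`.
#' @export
mask_volumes <- function(masks, voxel_dims) {
  validate_tissue_mask_set(masks)
  vv <- voxel_volume_ml(voxel_dims)
  present <- names(masks)[!vapply(masks, is.null, logical(1))]
  n <- vapply(masks[present], sum, numeric(1))
  tibble(compartment = present, n_voxels = as.integer(n), volume_ml = n * vv)
}

#' Read tissue masks from NIfTI files
#'
#' Probabilistic maps are binarised at `threshold` (voxels with value >=
#' `threshold` are in the mask); the set is then validated as in
#' [tissue_mask_set()].
#'
#' @param icv,nawm,wmh_total Paths to NIfTI masks (required).
#' @param wmh_intense,wmh_less_intense,exclusion Optional paths.
#' @param threshold Binarisation threshold for probabilistic inputs.
#' @return A validated `tissue_mask_set`.
#' @export
read_masks <- function(icv, nawm, wmh_total,
                       wmh_intense = NULL, wmh_less_intense = NULL,
                       exclusion = NULL, threshold = 0.5) {
  paths <- list(icv = icv, nawm = nawm, wmh_total = wmh_total,
                wmh_intense = wmh_intense,
                wmh_less_intense = wmh_less_intense, exclusion = exclusion)
  present <- !vapply(paths, is.null, logical(1))
  missing <- names(paths)[present][!vapply(paths[present], file.exists, logical(1))]
  if (length(missing))
    abort(paste0("Mask file(s) not found: ", paste(missing, collapse = ", ")))
  load1 <- function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v) >= threshold, dim = dim(v))
  }
  m <- lapply(paths, function(p) if (is.null(p)) NULL else load1(p))
  tissue_mask_set(icv = m$icv, nawm = m$nawm, wmh_total = m$wmh_total,
                  wmh_intense = m$wmh_intense,
                  wmh_less_intense = m$wmh_less_intense,
                  exclusion = m$exclusion)
}
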