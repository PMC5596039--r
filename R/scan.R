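#' Multi-sequence structural MRI scan
#'
#' Bundles co-registered 3D intensity volumes for one subject and timepoint.
#' FLAIR is mandatory; T1-weighted, T2-weighted and T2*-weighted volumes are
#' optional. All volumes must share the same grid and voxel dimensions:
#' inter-sequence registration is assumed to have been done upstream, this
#' container only enforces geometric congruence.
#'
#' @param flair 3D numeric array of FLAIR intensities (arbitrary units).
#' @param t1w,t2w,t2star Optional 3D numeric arrays on the same grid.
#' @param voxel_dims Numeric length-3, voxel edge lengths in mm.
#' @param subject_id,timepoint Labels carried through to results.
#'
#' @return An object of class `multi_sequence_scan`: a list with elements
#'   `flair`, `t1w`, `t2w`, `t2star` (arrays or `NULL`), `voxel_dims`,
#'   `subject_id`, `timepoint`.
#' @examples
#' scan <- multi_sequence_scan(array(100, c(4, 4, 4)), voxel_dims = c(1, 1, 1))
#' voxel_volume_ml(scan) * sum(scan$flair > 0)  # volume of the cube in ml
#' @export
multi_sequence_scan <- function(flair, t1w = NULL, t2w = NULL, t2star = NULL,
                                voxel_dims = c(1, 1, 1),
                                subject_id = "subject",
                                timepoint = "baseline") {
  if (is.null(flair)) abort("FLAIR volume is mandatory.")
  vols <- list(flair = flair, t1w = t1w, t2w = t2w, t2star = t2star)
  vols <- vols[!vapply(vols, is.null, logical(1))]
  for (nm in names(vols)) {
    v <- vols[[nm]]
    if (!is.numeric(v) || length(dim(v)) != 3L)
      abort(sprintf("`%s` must be a 3D numeric array.", nm))
    if (!all(is.finite(v)))
      abort(sprintf("`%s` contains non-finite intensities.", nm))
  }
  ref <- dim(vols$flair)
  for (nm in names(vols)) {
    if (!identical(dim(vols[[nm]]), ref))
      abort(sprintf(
        "Grid mismatch: `%s` is %s but FLAIR is %s.",
        nm, paste(dim(vols[[nm]]), collapse = "x"),
        paste(ref, collapse = "x")
      ))
  }
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    abort("`voxel_dims` must be three positive lengths in mm.")
  structure(
    list(flair = flair, t1w = t1w, t2w = t2w, t2star = t2star,
         voxel_dims = voxel_dims,
         subject_id = as.character(subject_id),
         timepoint = as.character(timepoint)),
    class = "multi_sequence_scan"
  )
}

#' @export
print.multi_sequence_scan <- function(x, ...) {
  present <- c("flair", "t1w", "t2w", "t2star")[!vapply(
    list(x$flair, x$t1w, x$t2w, x$t2star), is.null, logical(1))]
  cat(sprintf(
    "<multi_sequence_scan> %s/%s  grid %s  voxel %s mm  sequences: %s\n",
    x$subject_id, x$timepoint,
    paste(dim(x$flair), collapse = "x"),
    paste(signif(x$voxel_dims, 3), collapse = "x"),
    paste(present, collapse = ", ")))
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param x A `multi_sequence_scan`, or a numeric length-3 vector of voxel
#'   dimensions in mm.
#' @return Volume of one voxel in ml (mm^3 / 1000).
#' @export
voxel_volume_ml <- function(x) {
  dims <- if (inherits(x, "multi_sequence_scan")) x$voxel_dims else as.numeric(x)
  prod(dims) / 1000
}

#' Read a multi-sequence scan from NIfTI files
#'
#' Loads one or more co-registered NIfTI-1/2 volumes into a
#' [multi_sequence_scan()]. Voxel dimensions are taken from the FLAIR header.
#' Grids must match exactly; affines must agree element-wise within
#' `affine_tol` (the volumes are assumed co-registered, so any larger
#' disagreement indicates a wrong file).
#'
#' @param flair Path to the FLAIR NIfTI file (required).
#' @param t1w,t2w,t2star Optional paths to further sequences.
#' @param subject_id,timepoint Labels stored on the scan.
#' @param affine_tol Maximum absolute per-element affine difference tolerated.
#' @return A `multi_sequence_scan`.
#' @export
read_scan <- function(flair, t1w = NULL, t2w = NULL, t2star = NULL,
                      subject_id = "subject", timepoint = "baseline",
                      affine_tol = 1e-3) {
  if (is.null(flair)) abort("FLAIR path is mandatory.")
  paths <- list(flair = flair, t1w = t1w, t2w = t2w, t2star = t2star)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  missing <- names(paths)[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    abort(paste0("File(s) not found: ",
                 paste(sprintf("%s (%s)", missing, unlist(paths[missing])),
                       collapse = ", ")))
  imgs <- lapply(paths, RNifti::readNifti)
  ref_dim <- dim(imgs$flair)
  ref_aff <- RNifti::xform(imgs$flair)
  problems <- character(0)
  for (nm in names(imgs)) {
    if (!identical(dim(imgs[[nm]]), ref_dim))
      problems <- c(problems, sprintf(
        "%s: grid %s != FLAIR grid %s", nm,
        paste(dim(imgs[[nm]]), collapse = "x"),
        paste(ref_dim, collapse = "x")))
    else if (max(abs(RNifti::xform(imgs[[nm]]) - ref_aff)) > affine_tol)
      problems <- c(problems, sprintf(
        "%s: affine differs from FLAIR by %.2g (tol %.2g)", nm,
        max(abs(RNifti::xform(imgs[[nm]]) - ref_aff)), affine_tol))
  }
  if (length(problems))
    abort(paste0("Input volumes are not on a common grid:\n  ",
                 paste(problems, collapse = "\n  ")))
  vdim <- RNifti::pixdim(imgs$flair)[seq_len(3)]
  arrs <- lapply(imgs, function(im) array(as.numeric(im), dim = dim(im)))
  multi_sequence_scan(
    flair = arrs$flair, t1w = arrs$t1w, t2w = arrs$t2w, t2star = arrs$t2star,
    voxel_dims = vdim, subject_id = subject_id, timepoint = timepoint)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol 3D numeric or logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_dims Voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_dims = c(1, 1, 1)) {
  if (is.logical(vol)) vol <- array(as.integer(vol), dim = dim(vol))
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}
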