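#' Total Fazekas score
#'
#' WMH burden is rated 0-3 separately for periventricular and deep white
#' matter; the total is their sum, ranging 0-6. Vectorised over subjects.
#'
#' @param periventricular,deep Integer ratings in 0..3.
#' @return Integer total(s) in 0..6.
#' @examples
#' total_fazekas(3, 3)
#' @export
total_fazekas <- function(periventricular, deep) {
  check_items(periventricular, 0:3, "periventricular")
  check_items(deep, 0:3, "deep")
  if (length(periventricular) != length(deep))
    abort("`periventricular` and `deep` must have equal length.")
  as.integer(periventricular + deep)
}

#' Total Prins change score
#'
#' The Prins scale rates perceived WMH change as -1 (decrease), 0 (no
#' change) or +1 (increase) in three periventricular and four deep regions
#' per hemisphere: 14 items, summed to a total in -14..14.
#'
#' @param items A numeric vector of 14 items, or a matrix / data frame with
#'   14 columns (one row per subject).
#' @return Integer total(s) in -14..14.
#' @examples
#' total_prins(rep(1, 14))
#' @export
total_prins <- function(items) {
  m <- if (is.data.frame(items)) as.matrix(items)
       else if (is.matrix(items)) items
       else matrix(items, nrow = 1L)
  if (ncol(m) != 14L)
    abort(sprintf("Prins ratings need exactly 14 items (3 periventricular + 4 deep per hemisphere); got %d.",
                  ncol(m)))
  check_items(as.vector(m), -1:1, "Prins items")
  as.integer(rowSums(m))
}

#' Total small vessel disease (SVD) burden score
#'
#' One point for each of four imaging features present: WMH burden, lacunes,
#' microbleeds, and perivascular spaces; total 0-4 (Staals scheme).
#'
#' @param wmh,lacunes,microbleeds,pvs Binary (0/1) indicators, vectorised.
#' @return Integer total(s) in 0..4.
#' @export
total_svd <- function(wmh, lacunes, microbleeds, pvs) {
  for (nm in c("wmh", "lacunes", "microbleeds", "pvs"))
    check_items(get(nm), 0:1, nm)
  lens <- lengths(list(wmh, lacunes, microbleeds, pvs))
  if (length(unique(lens)) != 1L) abort("All SVD items must have equal length.")
  as.integer(wmh + lacunes + microbleeds + pvs)
}

#' WMH point of the SVD score from Fazekas ratings
#'
#' The WMH point of the total SVD score is awarded when the periventricular
#' Fazekas rating is 3 or the deep rating is 2 or more (Staals scheme).
#'
#' @inheritParams total_fazekas
#' @return Binary 0/1 vector.
#' @export
svd_wmh_item <- function(periventricular, deep) {
  check_items(periventricular, 0:3, "periventricular")
  check_items(deep, 0:3, "deep")
  as.integer(periventricular == 3 | deep >= 2)
}

check_items <- function(x, allowed, name) {
  if (length(x) == 0L) abort(sprintf("`%s` is empty.", name))
  if (anyNA(x) || !all(x %in% allowed))
    abort(sprintf("`%s` items must all be in {%s}.", name,
                  paste(allowed, collapse = ", ")))
  invisible(x)
}

#' Score a table of visual ratings
#'
#' Takes a tidy table (one row per subject/timepoint) and appends whichever
#' total scores its columns support: `fazekas_total` from `fazekas_pv` +
#' `fazekas_deep`; `prins_total` from the 14 `prins_*` columns;
#' `svd_total` from `svd_wmh`, `svd_lacunes`, `svd_microbleeds`, `svd_pvs`
#' (with `svd_wmh` derived from the Fazekas columns when absent).
#'
#' @param data A data frame of per-subject rating items.
#' @return A tibble: the input plus the total-score columns.
#' @examples
#' df <- tibble::tibble(fazekas_pv = c(0, 3), fazekas_deep = c(0, 3))
#' score_ratings(df)
#' @export
score_ratings <- function(data) {
  out <- as_tibble(data)
  has <- function(...) all(c(...) %in% names(out))
  if (has("fazekas_pv", "fazekas_deep"))
    out$fazekas_total <- total_fazekas(out$fazekas_pv, out$fazekas_deep)
  prins_cols <- grep("^prins_", names(out), value = TRUE)
  if (length(prins_cols) == 14L)
    out$prins_total <- total_prins(out[prins_cols])
  else if (length(prins_cols) > 0L)
    abort(sprintf("Found %d `prins_*` columns; the Prins scale has 14 items.",
                  length(prins_cols)))
  if (has("svd_lacunes", "svd_microbleeds", "svd_pvs")) {
    if (!has("svd_wmh")) {
      if (!has("fazekas_pv", "fazekas_deep"))
        abort("Need `svd_wmh` or the Fazekas columns to derive the SVD WMH point.")
      out$svd_wmh <- svd_wmh_item(out$fazekas_pv, out$fazekas_deep)
    }
    out$svd_total <- total_svd(out$svd_wmh, out$svd_lacunes,
                               out$svd_microbleeds, out$svd_pvs)
  }
  out
}
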