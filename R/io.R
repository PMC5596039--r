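#' Serialise a WM damage result
#'
#' Writes every field of a [wm_damage()] result to JSON or CSV so that a
#' round-trip read reproduces it to full double precision (numbers are
#' written with 17 significant digits). A metric of zero serialises as the
#' number 0, never as a missing value.
#'
#' @param result A `wm_damage_result`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = NULL) {
  if (!inherits(result, "wm_damage_result"))
    abort("`result` must be a wm_damage_result.")
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  row <- tidy(result)
  if (format == "json") {
    jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    chr <- vapply(row, function(v) {
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, character(1))
    df <- as.data.frame(as.list(chr), optional = TRUE)
    names(df) <- names(row)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a serialised WM damage result
#'
#' @param path File written by [write_result()].
#' @param format `"json"` or `"csv"`; default guessed from the extension.
#' @return A one-row tibble with the same columns as `tidy(<wm_damage_result>)`.
#' @export
read_result <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  num_cols <- c("wm_damage", "contrast_term", "proportion_term",
                "wmh_volume_ml", "nawm_volume_ml", "icv_ml", "wmh_pct_icv",
                "wmh_intense_ml", "wmh_less_intense_ml", "i_wmh", "i_nawm")
  if (format == "json") {
    x <- jsonlite::read_json(path)
    x[num_cols] <- lapply(x[num_cols], function(v)
      if (is.null(v)) NA_real_ else as.numeric(v))
    x$valid <- isTRUE(x$valid)
    as_tibble(x[c(num_cols, "sequence_used", "valid")])
  } else {
    df <- read.csv(path, colClasses = "character")
    out <- as_tibble(df)
    out[num_cols] <- lapply(out[num_cols], as.numeric)
    out$valid <- as.logical(out$valid)
    out
  }
}
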