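#' Plot an axial slice of a volume with an optional mask overlay
#'
#' @param volume 3D numeric array.
#' @param z Slice index (default mid-volume).
#' @param mask Optional logical array; in-mask voxels are outlined in red.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, z = NULL, mask = NULL) {
  if (length(dim(volume)) != 3L) abort("`volume` must be a 3D array.")
  z <- z %||% ceiling(dim(volume)[3] / 2)
  sl <- volume[, , z]
  df <- tidyr::expand_grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$intensity <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Axial slice z = %d", z)) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    df$m <- as.vector(mask[, , z])
    p <- p + ggplot2::geom_point(data = df[df$m, , drop = FALSE],
                                 colour = "red", size = 0.3, alpha = 0.6)
  }
  p
}

#' @rdname bootstrap_spearman
#' @param object A `wm_cor`.
#' @method autoplot wm_cor
#' @export
autoplot.wm_cor <- function(object, ...) {
  df <- tibble(rho = object$boot_rho[!is.na(object$boot_rho)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$rho, object$ci_high),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(x = "Bootstrap Spearman rho", y = "Count",
                  title = sprintf("rho = %.3f, %d%% CI [%.3f, %.3f]",
                                  object$rho, round(100 * object$conf),
                                  object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_slice
#' @param object A `wm_phantom`.
#' @param ... Unused.
#' @method autoplot wm_phantom
#' @export
autoplot.wm_phantom <- function(object, ...) {
  plot_slice(object$scan$flair, mask = object$truth$masks$wmh_total)
}
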