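## Diagnostic plots (ggplot2, Suggests-only).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}

#' Plot an error-vs-disparity curve with an optional V-fit
#'
#' @param curve tibble with `disparity`, `e_avg`.
#' @param fit optional [fit_vcurve()] result.
#' @return a ggplot object.
#' @export
plot_error_curve <- function(curve, fit = NULL) {
  need_ggplot()
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = disparity, y = e_avg)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "retinal disparity (px)",
                  y = "average reconstruction error")
  if (!is.null(fit)) {
    dd <- seq(min(curve$disparity), max(curve$disparity), length.out = 200)
    fd <- tibble::tibble(disparity = dd,
                         e_avg = fit$c - fit$a * exp(-abs(dd - fit$mu) / fit$b))
    p <- p + ggplot2::geom_line(data = fd, colour = "red")
  }
  p
}

#' Plot a saliency map
#'
#' @param smap a `saliency_map` or a numeric matrix.
#' @return a ggplot object.
#' @export
plot_saliency <- function(smap) {
  need_ggplot()
  S <- if (inherits(smap, "saliency_map")) smap$S else smap
  df <- expand.grid(y = seq_len(nrow(S)), x = seq_len(ncol(S)))
  df$s <- as.vector(S)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = s)) +
    ggplot2::geom_raster() + ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "saliency") +
    ggplot2::coord_fixed()
}

#' Mosaic of learned basis functions as an image matrix
#'
#' Lays out the left|right 10x10 halves of the first columns of each
#' subspace basis side by side — the standard visualization of learned
#' binocular receptive fields. Returns a matrix suitable for
#' [png::writePNG()].
#'
#' @param bank a `gassom_bank`.
#' @param n_show number of subspaces to show.
#' @export
basis_mosaic <- function(bank, n_show = min(bank$n, 64L)) {
  cols <- ceiling(sqrt(n_show))
  rowsn <- ceiling(n_show / cols)
  tile_h <- 10L; tile_w <- 21L  # left | 1px gap | right
  out <- matrix(0.5, rowsn * (tile_h + 1L), cols * (tile_w + 1L))
  for (i in seq_len(n_show)) {
    v <- bank$phi[[i]][, 1L]
    L <- matrix(v[1:100], 10L, 10L); R <- matrix(v[101:200], 10L, 10L)
    rng <- range(c(L, R)); if (diff(rng) > 0) {
      L <- (L - rng[1]) / diff(rng); R <- (R - rng[1]) / diff(rng)
    }
    r0 <- ((i - 1L) %/% cols) * (tile_h + 1L)
    c0 <- ((i - 1L) %% cols) * (tile_w + 1L)
    out[r0 + 1:10, c0 + 1:10] <- L
    out[r0 + 1:10, c0 + 12:21] <- R
  }
  out
}

utils::globalVariables(c("disparity", "e_avg", "x", "y", "s"))
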