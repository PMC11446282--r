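#' Contact-map plot of an interface map
#'
#' Tile plot of binder residues against receptor residues, shaded by
#' minimum atom-atom distance of each interacting pair.
#'
#' @param object an `interface_map` from [interface_residues()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.interface_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$receptor_resid),
                                  y = factor(.data$binder_resid),
                                  fill = .data$min_atom_distance)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "min dist (Å)",
                                  direction = -1) +
    ggplot2::labs(x = "receptor residue", y = "binder residue",
                  title = "interface contact map") +
    ggplot2::theme_minimal()
}

#' Heatmap of a PAE matrix
#'
#' @param object a [confidence_data()] object with a PAE matrix.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.confidence_data <- function(object, ...) {
  if (is.null(object$pae)) stop("no PAE matrix to plot", call. = FALSE)
  n <- nrow(object$pae)
  d <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  d$pae <- as.vector(object$pae)[(d$col - 1) * n + d$row]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$pae)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "PAE (Å)", direction = -1) +
    ggplot2::labs(x = "aligned residue", y = "scored residue",
                  title = "predicted aligned error") +
    ggplot2::theme_minimal()
}

#' Screen scatter of a batch results table
#'
#' ipLDDT against iPAE for every screened model with the pass thresholds
#' drawn as dashed lines; sentinel models sit at (30, 0).
#'
#' @param results [run_screen()] output (or any table with `ipae_median`,
#'   `iplddt`, `passed`).
#' @param ipae_max,iplddt_min thresholds to draw.
#' @return a ggplot object.
#' @export
plot_screen <- function(results, ipae_max = 10, iplddt_min = 70) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$ipae_median, y = .data$iplddt,
                               colour = .data$passed)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = ipae_max, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = iplddt_min, linetype = "dashed") +
    ggplot2::labs(x = "iPAE (Å, median)", y = "interface pLDDT",
                  title = "interface confidence screen") +
    ggplot2::theme_minimal()
}
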