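#' Plot a cytokine network with force-directed layout
#'
#' Nodes are coloured by eigenvector centrality and sized by betweenness
#' centrality, mirroring the standard presentation of cytokine interaction
#' networks.
#'
#' @param object A `cytokine_network`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cytokine_network <- function(object, seed = 1, ...) {
  lay <- layout_export(object, seed = seed)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = lay$edges,
      ggplot2::aes(x = .data$x_source, y = .data$y_source,
                   xend = .data$x_target, yend = .data$y_target),
      colour = "grey60", linewidth = 0.4
    ) +
    ggplot2::geom_point(
      data = lay$nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$color_value,
                   size = .data$size_value)
    ) +
    ggplot2::geom_text(
      data = lay$nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$cytokine),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_viridis_c(name = "eigenvector") +
    ggplot2::scale_size_continuous(name = "betweenness") +
    ggplot2::theme_void()
}

#' Plot per-cytokine fold-change distributions by model
#'
#' @param fc Combined fold-change tibble (rows from one or more
#'   [fold_change_analysis()] calls).
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(fc) {
  stopifnot(all(c("model", "cytokine", "fc") %in% names(fc)))
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$cytokine, y = .data$fc,
                                   colour = .data$model)) +
    ggplot2::geom_boxplot(outlier.shape = NA, position = ggplot2::position_dodge()) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(jitter.width = 0.1)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fold change over control mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the force-displacement hysteresis loop of a loading trace
#'
#' @param object A loading-trace tibble.
#' @param cycles Cycle selection (default `"last10"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loading_trace <- function(object, cycles = "last10", ...) {
  cyc <- extract_cycles(object)
  sel <- select_cycles(cyc, cycles)
  idx <- unlist(lapply(cyc$segments[sel], function(s) s[1]:s[2]))
  df <- tibble(displacement_um = object$displacement_um[idx],
               force_N = object$force_N[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement_um, y = .data$force_N)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::labs(x = "displacement (um)", y = "force (N)") +
    ggplot2::theme_minimal()
}

#' Plot a GTT series with its trapezoidal AUC
#'
#' @param series GTT tibble (`time_h`, `glucose_mg_dl`).
#' @param cutoff Cutoff shown in the subtitle (default 435 mg.h/dl).
#' @return A ggplot object.
#' @export
plot_gtt <- function(series, cutoff = 435) {
  res <- gtt_auc(series, cutoff)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time_h, y = .data$glucose_mg_dl)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (h)", y = "blood glucose (mg/dl)",
      subtitle = sprintf("AUC = %.0f mg.h/dl (%s at cutoff %.0f)",
                         res$auc, if (res$diabetic) "diabetic" else "not diabetic",
                         cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a transverse slice of a disc volume with mask outlines
#'
#' @param vol A `disc_volume`.
#' @param masks Optional `mask_set` to overlay.
#' @param slice Transverse slice index (default: middle slice).
#' @return A ggplot object.
#' @export
plot_disc_slice <- function(vol, masks = NULL, slice = NULL) {
  stopifnot(inherits(vol, "disc_volume"))
  if (is.null(slice)) slice <- round(dim(vol$data)[1] / 2)
  sl <- vol$data[slice, , ]
  df <- tibble(
    row = rep(seq_len(nrow(sl)), times = ncol(sl)),
    col = rep(seq_len(ncol(sl)), each = nrow(sl)),
    intensity = as.vector(sl)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() + ggplot2::theme_void()
  if (!is.null(masks)) {
    for (nm in c("disc", "np")) {
      m <- masks[[nm]][slice, , ]
      if (any(m)) {
        ij <- which(m, arr.ind = TRUE)
        p <- p + ggplot2::geom_point(
          data = tibble(row = ij[, 1], col = ij[, 2]),
          ggplot2::aes(x = .data$col, y = .data$row),
          colour = if (nm == "np") "red" else "yellow",
          size = 0.1, alpha = 0.15
        )
      }
    }
  }
  p
}
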