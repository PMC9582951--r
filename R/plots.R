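#' Heatmap of a cross-scale association table
#'
#' Renders the significance-filtered correlation matrix (rows/columns without
#' any significant pair dropped, surviving non-significant cells zeroed) as a
#' diverging-colour tile plot.
#'
#' @param object An `rp_associations` tibble from [cross_correlate()] or
#'   [factor_cross_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rp_associations <- function(object, ...) {
  mats <- rp_association_matrices(object)
  hm <- filter_heatmap(mats$rho, mats$significant)
  if (nrow(hm) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::annotate("text", 0, 0, label = "no significant association") +
      ggplot2::theme_void())
  }
  d <- tibble::as_tibble(hm, rownames = "radiomic") |>
    tidyr::pivot_longer(-"radiomic", names_to = "pathomic", values_to = "rho")
  d$radiomic <- factor(d$radiomic, levels = rev(rownames(hm)))
  d$pathomic <- factor(d$pathomic, levels = colnames(hm))
  ggplot2::ggplot(d, ggplot2::aes(.data$pathomic, .data$radiomic,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = "pathomic", y = "radiomic",
                  fill = "Spearman \u03c1") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Loading heatmap of a factor model
#'
#' @param object An `rp_factor_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rp_factor_model <- function(object, ...) {
  d <- tidy(object)
  d$feature <- factor(d$feature, levels = rev(object$feature_names))
  ggplot2::ggplot(d, ggplot2::aes(.data$factor, .data$feature,
                                  fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::theme_minimal(base_size = 8)
}

#' Plot a cell-density map
#'
#' Tile plot of nuclei counts per tile; invalid tiles (centre outside the
#' ROI) are blanked.
#'
#' @param map An `rp_density_map` from [build_density_map()].
#' @return A ggplot object.
#' @export
plot_density_map <- function(map) {
  d <- tibble::tibble(
    x = rep(seq_len(nrow(map$counts)), times = ncol(map$counts)),
    y = rep(seq_len(ncol(map$counts)), each = nrow(map$counts)),
    count = as.vector(map$counts),
    valid = as.vector(map$valid_mask)
  )
  d$count[!d$valid] <- NA
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("cell-density map @ ", map$resolution,
                                 " \u00b5m"),
                  x = NULL, y = NULL, fill = "nuclei") +
    ggplot2::theme_minimal(base_size = 9)
}
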