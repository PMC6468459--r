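#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a mass spectrum
#'
#' @param object a `glyco_spectrum` tibble.
#' @param peaks optional picked-peak tibble to annotate.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot glyco_spectrum
#' @export
autoplot.glyco_spectrum <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mz,
                                            y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(data = peaks, colour = "red", size = 0.8)
  }
  p
}

#' Score plot of a glycan-profile PCA
#'
#' @param object a `glyco_pca` object.
#' @param groups optional tibble `sample`, `group` to colour scores.
#' @param components which two components to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot glyco_pca
#' @export
autoplot.glyco_pca <- function(object, groups = NULL,
                               components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  df <- object$scores
  if (!is.null(groups)) df <- dplyr::left_join(df, groups, by = "sample")
  lab <- sprintf("%s (%.1f%%)", pcs,
                 100 * object$explained_variance[components])
  aes <- if (!is.null(groups)) {
    ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Boxplots of derived traits by group
#'
#' Median/interquartile boxplots of selected derived traits split by
#' group, the standard presentation for trait contrasts.
#'
#' @param traits trait table (`sample` plus trait columns).
#' @param groups tibble `sample`, `group`.
#' @param which character vector of trait names (default: all).
#' @return A ggplot object.
#' @export
plot_trait_boxplots <- function(traits, groups, which = NULL) {
  df <- dplyr::inner_join(dplyr::select(traits, -dplyr::any_of("group")),
                          groups, by = "sample")
  trait_cols <- setdiff(names(df), c("sample", "group"))
  if (!is.null(which)) trait_cols <- intersect(trait_cols, which)
  long <- tidyr::pivot_longer(df, dplyr::all_of(trait_cols),
                              names_to = "trait", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative abundance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
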