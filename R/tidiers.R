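#' Tidy a recalibration model
#'
#' @param x a `glyco_calibration` object.
#' @param ... unused.
#' @return The per-calibrant residual table (tibble).
#' @method tidy glyco_calibration
#' @export
tidy.glyco_calibration <- function(x, ...) {
  x$residuals
}

#' One-row summary of a recalibration model
#'
#' @param x a `glyco_calibration` object.
#' @param ... unused.
#' @return A one-row tibble: `degree`, `n_calibrants`, `max_abs_ppm`,
#'   `rmse_ppm`.
#' @method glance glyco_calibration
#' @export
glance.glyco_calibration <- function(x, ...) {
  tibble::tibble(degree = x$degree, n_calibrants = x$n_calibrants,
                 max_abs_ppm = max(abs(x$residuals$residual_ppm)),
                 rmse_ppm = sqrt(mean(x$residuals$residual_ppm^2)))
}

#' Tidy a glycan-profile PCA
#'
#' @param x a `glyco_pca` object.
#' @param matrix `"scores"` (samples, default) or `"loadings"`
#'   (compositions).
#' @param ... unused.
#' @return A long tibble: `sample` (or `composition`), `PC`, `value`.
#' @method tidy glyco_pca
#' @export
tidy.glyco_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  df <- x[[matrix]]
  id <- names(df)[1]
  tidyr::pivot_longer(df, -dplyr::all_of(id), names_to = "PC",
                      names_prefix = "PC", names_transform = as.integer,
                      values_to = "value")
}

#' One-row summary of a glycan-profile PCA
#'
#' @param x a `glyco_pca` object.
#' @param ... unused.
#' @return A one-row tibble: `n_components`, `explained_total`, plus the
#'   per-component explained-variance fractions.
#' @method glance glyco_pca
#' @export
glance.glyco_pca <- function(x, ...) {
  ev <- stats::setNames(as.list(x$explained_variance),
                        paste0("explained_pc", seq_along(x$explained_variance)))
  dplyr::bind_cols(tibble::tibble(n_components = x$n_components,
                                  explained_total = x$explained_total),
                   tibble::as_tibble(ev))
}
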