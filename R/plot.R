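#' Plot an RGB image
#'
#' @param object An `rgb_image` (from [pseudo_color()] or [overlay()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rgb_image
#' @export
autoplot.rgb_image <- function(object, ...) {
  d <- dim(object)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(
    as.vector(t(object[, , 1])),
    as.vector(t(object[, , 2])),
    as.vector(t(object[, , 3]))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::theme_void()
}

#' @export
plot.rgb_image <- function(x, ...) print(autoplot(x, ...))

#' Plot tissue endmember curves
#'
#' @param object An `endmember_set`.
#' @param ... Unused.
#' @return A ggplot of absorptivity per mm against wavelength.
#' @method autoplot endmember_set
#' @export
autoplot.endmember_set <- function(object, ...) {
  df <- tibble::tibble(
    wavelength = rep(object$wavelengths, 3),
    absorptivity = c(object$gist, object$normal, object$background),
    tissue = rep(c("gist", "normal", "background"), each = length(object$wavelengths))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$absorptivity,
    color = .data$tissue
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(
      gist = "#c0392b", normal = "#2c3e50", background = "#95a5a6"
    )) +
    ggplot2::labs(
      x = "wavelength (nm)", y = "absorbance / mm", color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-specimen LOOCV metrics
#'
#' @param object A `gist_loocv` result.
#' @param ... Unused.
#' @return A ggplot: per-specimen accuracy, sensitivity and specificity with
#'   the pooled accuracy as a dashed reference line.
#' @method autoplot gist_loocv
#' @export
autoplot.gist_loocv <- function(object, ...) {
  tbl <- tidy(object) %>%
    tidyr::pivot_longer(
      c("specificity", "sensitivity", "accuracy"),
      names_to = "metric", values_to = "percent"
    )
  pooled_acc <- glance(object)$accuracy
  ggplot2::ggplot(tbl, ggplot2::aes(.data$specimen, .data$percent,
    fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = pooled_acc, linetype = "dashed") +
    ggplot2::labs(x = "specimen", y = "percent", fill = NULL) +
    ggplot2::theme_minimal()
}
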