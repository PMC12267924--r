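#' Histogram of the percent of native AOO threatened
#'
#' The per-species distribution of how much of the native range is
#' threatened, at bin width 5, with the mean marked.
#'
#' @param partitions tibble from [partition_aoo()].
#' @return a ggplot object.
#' @export
plot_pct_threatened_hist <- function(partitions) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  v <- partitions$pct_native_threatened
  df <- tibble::tibble(pct = v[!is.na(v)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct)) +
    ggplot2::geom_histogram(breaks = seq(0, 100, 5), fill = "#31a354",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(df$pct), linetype = "dotted") +
    ggplot2::labs(x = "% of native AOO threatened", y = "Species") +
    ggplot2::theme_minimal()
}

#' Naturalized vs threatened AOO with the major axis
#'
#' log10-log10 scatter of threatened native AOO against naturalized AOO,
#' with the fitted major axis (solid) and the 1:1 line (dashed).
#'
#' @param partitions tibble from [partition_aoo()], paradox species with
#'   both AOOs positive.
#' @param fit optional [ma_regression()] result (refitted if omitted).
#' @return a ggplot object.
#' @export
plot_aoo_allometry <- function(partitions, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  df <- partitions[partitions$aoo_naturalized > 0 &
                     partitions$aoo_native_threatened > 0, ]
  lx <- log10(df$aoo_naturalized)
  ly <- log10(df$aoo_native_threatened)
  if (is.null(fit)) fit <- ma_regression(lx, ly)
  ggplot2::ggplot(tibble::tibble(x = lx, y = ly),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, colour = "#2b8cbe") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept) +
    ggplot2::labs(x = "log10 naturalized AOO (km2)",
                  y = "log10 threatened native AOO (km2)") +
    ggplot2::theme_minimal()
}
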