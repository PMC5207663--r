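#' Plot MDS coordinates
#'
#' @param object An `mds_result`.
#' @param sample_sheet Optional tibble with `sample` and `population` (and
#'   `class`) columns used for colour and shape.
#' @param dims Which two dimensions to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mds_result <- function(object, sample_sheet = NULL, dims = c(1L, 2L), ...) {
  pts <- object$points
  xs <- paste0("MDS", dims[1]); ys <- paste0("MDS", dims[2])
  if (!all(c(xs, ys) %in% names(pts))) abort("Requested dimensions not present.")
  if (!is.null(sample_sheet)) {
    pts <- left_join(pts, sample_sheet, by = "sample")
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data[[xs]], y = .data[[ys]]))
  if ("population" %in% names(pts) && "class" %in% names(pts)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$population,
                                              shape = .data$class))
  } else if ("population" %in% names(pts)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$population))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = xs, y = ys) + ggplot2::theme_minimal()
}

#' @rdname autoplot.mds_result
#' @export
plot_mds <- function(object, sample_sheet = NULL, dims = c(1L, 2L), ...) {
  autoplot.mds_result(object, sample_sheet = sample_sheet, dims = dims, ...)
}

#' Plot the QC cascade audit
#'
#' Bar chart of variants dropped per cascade stage, the first-class audit
#' output of the filter cascade.
#'
#' @param object A `filter_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.filter_report <- function(object, ...) {
  sc <- mutate(object$stage_counts,
               stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$stage, y = .data$n_dropped)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cascade stage", y = "variants dropped") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.filter_report
#' @export
plot_filter_cascade <- function(object, ...) autoplot.filter_report(object, ...)

#' Plot a coverage summary as a depth-threshold profile
#'
#' @param object A one-row tibble from [coverage_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_coverage_profile <- function(object, ...) {
  cols <- grep("^pct_at_", names(object), value = TRUE)
  thr <- as.numeric(sub("^pct_at_(\\d+)x$", "\\1", cols))
  df <- tibble(threshold = thr, pct = as.numeric(object[1, cols]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "depth threshold (x)", y = "% of covered bases at or above") +
    ggplot2::theme_minimal()
}
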