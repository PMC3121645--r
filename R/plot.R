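#' Plot one marker's signal-ratio distribution and calls
#'
#' Two-panel figure in the style of the standard genotype-calling output:
#' the upper panel is a histogram of the tetraploid signal ratios with the
#' fitted mixture density drawn on the ratio scale (and, when supplied, a
#' semi-transparent overlay histogram of diploid samples, which never enter
#' the fitting); the lower panel shows the assigned dosage of each sample
#' against its signal ratio, with unassigned samples marked at the bottom.
#' Rejected markers get a histogram-only figure labelled with the rejection
#' reason.
#'
#' @param object A `marker_call` from [call_marker()].
#' @param diploid Optional tibble of diploid records with a `ratio` column.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object (patchwork stack when the lower panel is drawn).
#' @method autoplot marker_call
#' @export
autoplot.marker_call <- function(object, diploid = NULL, bins = 40, ...) {
  calls <- object$calls
  if (is.null(calls) || nrow(calls) == 0) {
    stop("autoplot.marker_call(): no usable records to plot")
  }
  title <- if (object$status == "called") {
    object$marker_id
  } else {
    sprintf("%s (rejected: %s)", object$marker_id, object$reason)
  }

  top <- ggplot2::ggplot(calls, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = bins, boundary = 0, fill = "white", colour = "grey30"
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      title = title, x = "allele signal ratio a/(a+b)",
      y = "density"
    ) +
    ggplot2::theme_minimal()

  if (!is.null(diploid) && nrow(diploid) > 0) {
    top <- top + ggplot2::geom_histogram(
      data = diploid,
      ggplot2::aes(x = .data$ratio, y = ggplot2::after_stat(density)),
      bins = bins, boundary = 0, fill = "grey60", alpha = 0.5
    )
  }

  if (!is.null(object$fit)) {
    top <- top + ggplot2::geom_line(
      data = mixture_density_curve(object$fit),
      ggplot2::aes(x = .data$ratio, y = .data$density),
      colour = "forestgreen", linewidth = 0.8
    )
    low <- dplyr::mutate(
      calls,
      dosage_plot = ifelse(is.na(.data$dosage), -1L, .data$dosage),
      assigned = !is.na(.data$dosage)
    )
    bottom <- ggplot2::ggplot(
      low,
      ggplot2::aes(
        x = .data$ratio, y = .data$dosage_plot,
        colour = .data$assigned
      )
    ) +
      ggplot2::geom_jitter(width = 0, height = 0.08, size = 0.8) +
      ggplot2::scale_y_continuous(
        breaks = -1:4,
        labels = c("unassigned", 0:4)
      ) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "grey20", `FALSE` = "red"), guide = "none"
      ) +
      ggplot2::coord_cartesian(xlim = c(0, 1)) +
      ggplot2::labs(x = "allele signal ratio a/(a+b)", y = "assigned dosage") +
      ggplot2::theme_minimal()
    if (requireNamespace("patchwork", quietly = TRUE)) {
      return(top / bottom + patchwork::plot_layout(heights = c(2, 1)))
    }
    return(top)
  }
  top
}

#' Fitted mixture density on the ratio scale
#'
#' Evaluates the fitted five-component normal mixture (defined on the
#' transformed scale) as a density over the original ratio scale, applying
#' the Jacobian of the arcsine-square-root transform, so the curve can be
#' drawn over a ratio histogram and integrates to ~1 on `[0, 1]`.
#'
#' @param fit A `mixture_fit`.
#' @param n Number of grid points.
#' @return A tibble with columns `ratio` and `density`.
#' @export
mixture_density_curve <- function(fit, n = 512) {
  stopifnot(inherits(fit, "mixture_fit"))
  ratio <- seq(1e-6, 1 - 1e-6, length.out = n)
  yy <- asr(ratio)
  dens_y <- sapply(seq_len(5), function(j) {
    fit$pi[j] * dnorm(yy, fit$mu[j], fit$sigma)
  })
  # dy/df = 1 / (2 sqrt(f (1 - f)))
  jac <- 1 / (2 * sqrt(ratio * (1 - ratio)))
  tibble::tibble(ratio = ratio, density = rowSums(dens_y) * jac)
}

#' Save per-marker figures for a calling run
#'
#' @param x A `dosage_calls` object.
#' @param dir Output directory (created if needed).
#' @param diploid Optional tibble of diploid records (`marker`, `ratio`).
#' @param format `"png"` or `"pdf"`.
#' @return Invisibly, the written file paths.
#' @export
plot_markers <- function(x, dir, diploid = NULL, format = c("png", "pdf")) {
  stopifnot(inherits(x, "dosage_calls"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (mc in x$markers) {
    if (is.null(mc$calls) || nrow(mc$calls) == 0) {
      warning("plot_markers(): no data for ", mc$marker_id, "; plot skipped")
      next
    }
    dip <- if (!is.null(diploid)) {
      diploid[diploid$marker == mc$marker_id, , drop = FALSE]
    } else {
      NULL
    }
    p <- autoplot(mc, diploid = dip)
    path <- file.path(dir, paste0(mc$marker_id, ".", format))
    ggplot2::ggsave(path, p, width = 6, height = 6, dpi = 120)
    paths <- c(paths, path)
  }
  invisible(paths)
}
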