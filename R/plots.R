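#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Region-time heat map of a statistic
#'
#' Tile plot of a region-time map (z, t, accuracy, ...) with optional
#' significance outlines, faceted by model when present.
#'
#' @param map Tibble with `region`, `time_ms`, a value column and optionally
#'   `model` and `significant`.
#' @param value Name of the value column (default `"t"`).
#' @return A ggplot object.
#' @export
plot_region_time_map <- function(map, value = "t") {
  p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$time_ms, y = factor(.data$region),
                                         fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "region", fill = value)
  if ("significant" %in% names(map)) {
    p <- p + ggplot2::geom_point(
      data = map[map$significant, , drop = FALSE],
      ggplot2::aes(x = .data$time_ms, y = factor(.data$region)),
      inherit.aes = FALSE, shape = ".", colour = "black")
  }
  if ("model" %in% names(map)) p <- p + ggplot2::facet_wrap(~model)
  p
}

#' Model correlation time courses for selected regions
#'
#' Line plot of group-mean Fisher-z model correlations over time, one panel
#' per region, one colour per model, with significant bins marked — the
#' standard per-region display of time-resolved RSA results.
#'
#' @param sig Tibble from [fdr_mask()] applied to [region_time_ttest()]
#'   output (columns `model`, `region`, `time_ms`, `mean_z`, `significant`).
#' @param regions Regions to display (default: all present).
#' @return A ggplot object.
#' @export
plot_model_timecourses <- function(sig, regions = NULL) {
  d <- if (is.null(regions)) sig else sig[sig$region %in% regions, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$mean_z,
                                  colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = d[d$significant, , drop = FALSE], size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "time (ms)", y = "mean Fisher z", colour = "model")
}

#' @export
autoplot.rdm <- function(object, ...) {
  ent <- object$entries
  d <- tidyr::expand_grid(b = 1:12, a = 1:12)  # a varies fastest: column-major
  d$value <- as.vector(object$values)        # column-major: a varies fastest
  d$valid <- as.vector(object$mask)
  d$value[!d$valid] <- NA
  d$la <- factor(ent$label[d$a], levels = ent$label)
  d$lb <- factor(ent$label[d$b], levels = rev(ent$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$la, y = .data$lb, fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_viridis_c(na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "dissimilarity") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.repetition_fit <- function(object, amplitudes = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(amplitudes)) {
    p <- p + ggplot2::geom_jitter(
      data = amplitudes,
      ggplot2::aes(x = .data$segment, y = .data$amplitude),
      width = 0.1, alpha = 0.4)
  }
  p +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$k,
                         colour = "firebrick") +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "segment (presentation order)", y = "|amplitude|")
}
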