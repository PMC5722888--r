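# ggplot2 views of scan results

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-window metric along the scanned coordinate
#'
#' @param metrics metrics tibble from [scan_sequences()].
#' @param metric one of `"zscore"`, `"mfe"`, `"pvalue"`, `"ed"`, `"fmfe"`.
#' @return a ggplot.
#' @export
plot_metric_profile <- function(metrics, metric = "zscore") {
  metric <- match.arg(metric, c("zscore", "mfe", "pvalue", "ed", "fmfe"))
  df <- metrics[!is.na(metrics[[metric]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data[[metric]],
                                   colour = .data$strand)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "window start (nt)", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a domain report
#'
#' Window z-scores along the coordinate with the threshold line and the
#' merged domains shaded.
#'
#' @param object a `domain_report` from [merge_domains()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.domain_report <- function(object, ...) {
  w <- object$windows[!is.na(object$windows$zscore), ]
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$start, y = .data$zscore,
                                       colour = .data$strand)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "window start (nt)", y = "thermodynamic z-score") +
    ggplot2::theme_minimal()
  if (nrow(object$domains) > 0)
    p <- p + ggplot2::geom_rect(
      data = object$domains,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE)
  p
}
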