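#' Plot a fitted beta-uniform mixture over the p-value histogram
#'
#' Density-scaled histogram of the fitted p-values with the BUM density
#' curve and a horizontal line at the uniform weight `lambda`.
#'
#' @param object A [`bum_fit`][fit_bum].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bum_fit <- function(object, bins = 50, ...) {
  grid <- tibble(
    x = seq(0.001, 1, length.out = 400),
    density = dbum(seq(0.001, 1, length.out = 400), object$alpha_hat, object$lambda_hat)
  )
  ggplot2::ggplot(tibble(p = object$p_values), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = bins, boundary = 0, fill = "grey80", colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(x = .data$x, y = .data$density),
      colour = "#2166AC", linewidth = 1
    ) +
    ggplot2::geom_hline(yintercept = object$lambda_hat, linetype = "dashed") +
    ggplot2::labs(
      x = "p-value", y = "density",
      title = sprintf(
        "BUM fit: alpha = %.3f, lambda = %.3f, pi upper bound = %.3f",
        object$alpha_hat, object$lambda_hat, object$pi_ub
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an observed FDP curve
#'
#' False discovery proportion against the p-value cutoff, log-scaled x.
#'
#' @param object An [`fdp_curve`][fdp_curve].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff, y = .data$fdp)) +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value cutoff", y = "observed FDP") +
    ggplot2::theme_minimal()
}

#' Plot the stability of the FDR-targeting cutoff across resamples
#'
#' Histograms of the per-resample cutoff achieving the target FDR (log10
#' scale, with the median marked) and of the effective FDR at the shared
#' median cutoff.
#'
#' @param object A [`resampling_result`][run_resampling].
#' @param ... Unused.
#' @return A ggplot object (two panels via facets).
#' @export
autoplot.resampling_result <- function(object, ...) {
  per <- object$per_resample
  long <- dplyr::bind_rows(
    tibble(panel = "log10 cutoff at target FDR", value = log10(pmax(per$tau_at_target, 1e-12))),
    tibble(panel = "effective FDR at median cutoff", value = per$effective_fdr_at_median_tau)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "resamples") +
    ggplot2::theme_minimal()
}

#' Boxplot-style view of a grid statistic
#'
#' Distribution of one recorded statistic across replicates, grouped by a
#' configuration field and optionally faceted by another — the numeric
#' analogue of the boxplot summaries used to present factorial simulation
#' grids.
#'
#' @param records Tibble from [run_grid()].
#' @param stat Statistic column to plot (character).
#' @param x Configuration field for the x axis (character).
#' @param facet Optional configuration field to facet by.
#' @return A ggplot object.
#' @export
#' @examples
#' spec <- grid_spec(sample_sizes = 5, block_sizes = c(1, 10),
#'                   theta_scenarios = list(0), psi_levels = 0.2,
#'                   n_reps = 3, config = simulation_config(n_genes = 300))
#' plot_grid_stat(run_grid(spec), "alpha_hat", x = "mean_block_size")
plot_grid_stat <- function(records, stat, x, facet = NULL) {
  missing_cols <- setdiff(c(stat, x, facet), names(records))
  if (length(missing_cols) > 0L) {
    stop_invalid(paste0("unknown field(s): ", paste(missing_cols, collapse = ", ")))
  }
  p <- ggplot2::ggplot(
    records,
    ggplot2::aes(x = factor(.data[[x]]), y = .data[[stat]])
  ) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = x, y = stat) +
    ggplot2::theme_minimal()
  if (!is.null(facet)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", facet)))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
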