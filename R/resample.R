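#' Subsample-resampling stability of the FDR-targeting cutoff
#'
#' Reproduces the resampling protocol for studying how stable an
#' FDR-controlling p-value cutoff is across subsamples of a two-group
#' dataset: each resample draws `n_per_group` samples per group without
#' replacement, runs gene-by-gene t-tests ([gene_ttests()]), fits a BUM
#' model ([fit_bum()]) and records the cutoff achieving the target FDR
#' ([cutoff_for_target_fdr()]). After all resamples, the median cutoff is
#' computed and each resample's model-based FDR at that shared median
#' cutoff (its "effective FDR") is recorded; when simulation truth is
#' supplied, the true false discovery proportion at the median cutoff is
#' recorded as well.
#'
#' @param x An [`expression_experiment`][simulate_experiment] or a numeric
#'   genes-by-samples matrix.
#' @param labels Two-group vector (ignored for an `expression_experiment`).
#' @param n_per_group Samples drawn per group in each resample.
#' @param n_resamples Number of resamples; 300 gives stable quantiles of
#'   the cutoff distribution.
#' @param target_fdr Target FDR for the per-resample cutoff.
#' @param truth Optional logical vector of true DE flags per gene; taken
#'   from the experiment's truth table automatically.
#' @param seed Integer seed; per-resample sub-seeds are derived from it.
#'
#' @return An object of class `"resampling_result"`: list with
#'   `per_resample` (tibble: resample, seed, alpha_hat, lambda_hat, pi_ub,
#'   tau_at_target, effective_fdr_at_median_tau, and
#'   `true_fdp_at_median_tau` when truth is known), `median_tau`, and
#'   `settings`.
#' @export
#' @examples
#' exp <- simulate_experiment(
#'   simulation_config(n_genes = 500, n_per_group = 15, psi = 0.2,
#'                     active_fraction = 1, mean_block_size = 1, seed = 3)
#' )
#' res <- run_resampling(exp, n_per_group = 5, n_resamples = 10, seed = 1)
#' res$median_tau
run_resampling <- function(x, labels = NULL, n_per_group = 10L,
                           n_resamples = 300L, target_fdr = 0.10,
                           truth = NULL, seed = 1L) {
  if (inherits(x, "expression_experiment")) {
    labels <- x$labels$group
    if (is.null(truth)) truth <- x$truth$is_de
    x <- x$log2
  }
  if (!is.matrix(x)) stop_invalid("`x` must be a matrix or expression_experiment.")
  if (is.null(labels) || length(labels) != ncol(x)) {
    stop_invalid("`labels` must have one entry per column of `x`.")
  }
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 2L)
  n_resamples <- check_count(n_resamples, "n_resamples")
  check_scalar_number(target_fdr, "target_fdr")
  if (target_fdr <= 0 || target_fdr >= 1) stop_invalid("`target_fdr` must be in (0, 1).")
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = unique(labels))
  if (nlevels(f) != 2L) stop_invalid("`labels` must define exactly two groups.")
  idx1 <- which(f == levels(f)[1L])
  idx2 <- which(f == levels(f)[2L])
  if (length(idx1) < n_per_group || length(idx2) < n_per_group) {
    stop_invalid("`n_per_group` exceeds the size of a group.")
  }

  resamples <- purrr::map(seq_len(n_resamples), function(r) {
    seed_r <- mix_seed(seed, 100L, r)
    cols <- with_stage_seed(seed_r, c(
      idx1[sample.int(length(idx1), n_per_group)],
      idx2[sample.int(length(idx2), n_per_group)]
    ))
    pv <- gene_ttests(x[, cols, drop = FALSE], f[cols])
    fit <- fit_bum(pv$p_value)
    list(
      seed = seed_r, fit = fit, p_values = pv$p_value,
      tau = cutoff_for_target_fdr(fit, target_fdr)
    )
  })

  taus <- vapply(resamples, `[[`, numeric(1), "tau")
  median_tau <- median(taus)
  eval_tau <- max(median_tau, 1e-12)  # bum_fdr needs tau > 0

  per <- purrr::map_dfr(seq_along(resamples), function(r) {
    rs <- resamples[[r]]
    row <- tibble(
      resample = r,
      seed = rs$seed,
      alpha_hat = rs$fit$alpha_hat,
      lambda_hat = rs$fit$lambda_hat,
      pi_ub = rs$fit$pi_ub,
      tau_at_target = rs$tau,
      effective_fdr_at_median_tau = bum_fdr_at_cutoff(rs$fit, eval_tau)
    )
    if (!is.null(truth)) {
      cc <- confusion_at_cutoff(rs$p_values, truth, eval_tau)
      row$true_fdp_at_median_tau <-
        if (cc$tp + cc$fp == 0) 0 else cc$fp / (cc$fp + cc$tp)
    }
    row
  })

  structure(
    list(
      per_resample = per,
      median_tau = median_tau,
      settings = list(
        n_per_group = n_per_group, n_resamples = n_resamples,
        target_fdr = target_fdr, seed = as.integer(seed)
      )
    ),
    class = "resampling_result"
  )
}

#' @export
print.resampling_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<resampling_result> %d resamples of %d samples/group, target FDR %.0f%%\n",
    s$n_resamples, s$n_per_group, 100 * s$target_fdr
  ))
  cat(sprintf(
    "  cutoff for target: median %.3g (range %.3g - %.3g)\n",
    x$median_tau, min(x$per_resample$tau_at_target), max(x$per_resample$tau_at_target)
  ))
  cat(sprintf(
    "  effective FDR at median cutoff: mean %.3f, sd %.3f\n",
    mean(x$per_resample$effective_fdr_at_median_tau),
    sd(x$per_resample$effective_fdr_at_median_tau)
  ))
  invisible(x)
}

#' @describeIn run_resampling Per-resample records as a tibble.
#' @param x A `resampling_result`.
#' @param ... Unused.
#' @export
tidy.resampling_result <- function(x, ...) {
  x$per_resample
}

#' @describeIn run_resampling One-row summary: median and IQR of the
#'   per-resample cutoff and the spread of the effective FDR.
#' @export
glance.resampling_result <- function(x, ...) {
  taus <- x$per_resample$tau_at_target
  tibble(
    n_resamples = x$settings$n_resamples,
    n_per_group = x$settings$n_per_group,
    target_fdr = x$settings$target_fdr,
    median_tau = x$median_tau,
    iqr_tau = unname(diff(quantile(taus, c(0.25, 0.75)))),
    min_tau = min(taus),
    max_tau = max(taus),
    mean_effective_fdr = mean(x$per_resample$effective_fdr_at_median_tau),
    sd_effective_fdr = sd(x$per_resample$effective_fdr_at_median_tau)
  )
}
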