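#' Central-matching estimate of the empirical null width
#'
#' Estimates the standard deviation `sigma0` of the central peak of a
#' z-value distribution by central matching: z-values are histogrammed in
#' bins of width `bin_width` on `range`, bins with at least `min_count`
#' observations are kept, and a quadratic is fitted to the log counts by
#' least squares. For a normal centre the log density is quadratic with
#' curvature `-1 / (2 sigma0^2)`, so `sigma0 = (-2 c2)^(-1/2)` from the
#' fitted curvature `c2`.
#'
#' @param z_values Numeric z-values; fewer than 1000 triggers a warning.
#' @param bin_width Histogram bin width.
#' @param range Central fitting window (default `[-2, 2]`).
#' @param min_count Minimum bin count for a bin to enter the fit.
#'
#' @return `sigma0 > 0`.
#' @seealso [dispersion_A()]
#' @export
#' @examples
#' set.seed(1)
#' estimate_null_width(rnorm(20000))
estimate_null_width <- function(z_values, bin_width = 0.1, range = c(-2, 2),
                                min_count = 5L) {
  if (length(z_values) < 1000L) {
    warn("fewer than 1000 z-values; the null-width estimate will be noisy.")
  }
  breaks <- seq(range[1L], range[2L], by = bin_width)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  inside <- z_values >= range[1L] & z_values <= range[2L]
  counts <- tabulate(
    findInterval(z_values[inside], breaks, rightmost.closed = TRUE),
    nbins = length(centers)
  )
  keep <- counts >= min_count
  if (sum(keep) < 3L) {
    abort("too few populated central bins to fit the null width.",
          class = "bumfdr_estimation_failure")
  }
  xc <- centers[keep]
  fit <- lm(log(counts[keep]) ~ xc + I(xc^2))
  c2 <- coef(fit)[[3L]]
  if (!is.finite(c2) || c2 >= 0) {
    abort("nonnegative curvature: the central peak is not locally normal.",
          class = "bumfdr_estimation_failure")
  }
  sigma0 <- (-2 * c2)^(-1 / 2)
  if (!is.finite(sigma0)) {
    abort("degenerate curvature: the null-width estimate is unbounded.",
          class = "bumfdr_estimation_failure")
  }
  sigma0
}

#' Efron's dispersion variate A
#'
#' Summarises how much the central peak of the z-value null distribution
#' is widened (`A > 0`) or narrowed (`A < 0`) relative to the theoretical
#' N(0, 1) null: `A = (sigma0^2 - 1) / sqrt(2)`, the coefficient of the
#' second Hermite term in the empirical-null expansion.
#'
#' @param sigma0 Empirical null width from [estimate_null_width()].
#' @return The dispersion variate `A`.
#' @export
#' @examples
#' dispersion_A(1)        # exact theoretical null
#' dispersion_A(1.2)      # widened centre
dispersion_A <- function(sigma0) {
  if (any(!is.finite(sigma0)) || any(sigma0 <= 0)) {
    abort("`sigma0` must be > 0.", class = "bumfdr_domain_error")
  }
  (sigma0^2 - 1) / sqrt(2)
}

#' Spread of the empirical pairwise-correlation density
#'
#' Samples distinct gene pairs uniformly, computes the Pearson correlation
#' of each pair across samples, and returns the sample standard deviation
#' of those correlations (`corr.std`). When the total number of pairs is
#' at most `n_pairs` all pairs are used. Pairs involving a zero-variance
#' gene are resampled a bounded number of times, then dropped with a
#' warning.
#'
#' @param x Numeric genes-by-samples matrix with at least 2 rows and 4
#'   columns.
#' @param n_pairs Number of gene pairs to sample.
#' @return The standard deviation of the sampled pairwise correlations,
#'   with the number of pairs actually used as attribute `n_pairs`.
#' @export
#' @examples
#' set.seed(1)
#' correlation_sd(matrix(rnorm(100 * 20), 100, 20), n_pairs = 1000)
correlation_sd <- function(x, n_pairs = 50000L) {
  if (!is.matrix(x) || nrow(x) < 2L || ncol(x) < 4L) {
    stop_invalid("`x` must be a matrix with >= 2 genes and >= 4 samples.")
  }
  n_pairs <- check_count(n_pairs, "n_pairs")
  g <- nrow(x)
  total <- g * (g - 1) / 2

  pick_pairs <- function(k) {
    codes <- if (total <= n_pairs) seq_len(total) else sample(total, k)
    # decode pair index: row-major upper triangle, i < j
    i <- ceiling(g - 0.5 - sqrt((g - 0.5)^2 - 2 * codes))
    j <- codes - (i - 1) * g + i * (i - 1) / 2 + i
    cbind(as.integer(i), as.integer(j))
  }

  xc <- x - rowMeans(x)
  ss <- sqrt(rowSums(xc^2))
  ok_gene <- ss > 0

  pairs <- pick_pairs(min(n_pairs, total))
  bad <- !ok_gene[pairs[, 1L]] | !ok_gene[pairs[, 2L]]
  retries <- 0L
  while (any(bad) && total > n_pairs && retries < 10L) {
    pairs[bad, ] <- pick_pairs(sum(bad))
    bad <- !ok_gene[pairs[, 1L]] | !ok_gene[pairs[, 2L]]
    retries <- retries + 1L
  }
  if (any(bad)) {
    warn(sprintf("%d pairs with zero-variance genes excluded from corr.std.", sum(bad)))
    pairs <- pairs[!bad, , drop = FALSE]
  }
  if (nrow(pairs) < 2L) {
    abort("fewer than 2 usable gene pairs.", class = "bumfdr_estimation_failure")
  }
  corr <- rowSums(xc[pairs[, 1L], , drop = FALSE] * xc[pairs[, 2L], , drop = FALSE]) /
    (ss[pairs[, 1L]] * ss[pairs[, 2L]])
  out <- sd(corr)
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Dispersion summary of one dataset
#'
#' Convenience wrapper computing the one-row summary recorded per
#' simulated dataset: the empirical null width `sigma0` and dispersion
#' variate `A` from the z-values of all genes, and `corr.std` from sampled
#' pairwise gene correlations.
#'
#' @param x An [`expression_experiment`][simulate_experiment] or a
#'   genes-by-samples matrix.
#' @param z_values Optional precomputed z-values; when missing they are
#'   obtained via [gene_ttests()] + [t_to_z()] (matrix input then requires
#'   `labels`).
#' @param labels Group labels when `x` is a bare matrix and `z_values` is
#'   missing.
#' @param n_pairs Pairs sampled for `corr.std`.
#' @return A one-row tibble: `sigma0`, `A`, `corr_std`, `n_z`, `n_pairs`.
#' @export
dispersion_summary <- function(x, z_values = NULL, labels = NULL, n_pairs = 50000L) {
  mat <- if (inherits(x, "expression_experiment")) x$log2 else x
  if (is.null(z_values)) {
    pv <- t_to_z(gene_ttests(x, labels))
    z_values <- pv$z
  }
  sigma0 <- estimate_null_width(z_values)
  cs <- correlation_sd(mat, n_pairs = n_pairs)
  tibble(
    sigma0 = sigma0,
    A = dispersion_A(sigma0),
    corr_std = as.numeric(cs),
    n_z = length(z_values),
    n_pairs = attr(cs, "n_pairs")
  )
}
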