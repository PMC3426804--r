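#' Gene-by-gene two-sample t-tests
#'
#' Computes a two-sided two-sample t-test per gene (row) between the two
#' groups, vectorised over the whole matrix. The statistic is oriented as
#' second group minus first group (cancer minus normal for simulated
#' experiments), so positive `t` means higher expression in the second
#' group. Genes with zero variance in both groups and equal means are
#' reported with `t = 0`, `p_value = 1` and flagged `zero_variance`.
#'
#' @param x An [`expression_experiment`][simulate_experiment] or a numeric
#'   matrix with genes in rows and samples in columns.
#' @param labels Two-group vector of length `ncol(x)` (ignored when `x` is
#'   an `expression_experiment`). The first level (factor order, or order
#'   of first appearance) is the reference group.
#' @param var_equal If `TRUE` (default) the classical pooled-variance
#'   t-test with `n1 + n2 - 2` degrees of freedom; if `FALSE`, Welch's
#'   unequal-variance test with Satterthwaite degrees of freedom.
#'
#' @return A tibble of class `"pvalue_set"` with columns `gene_id`, `t`,
#'   `df`, `p_value` and `zero_variance`, plus attributes `n1`, `n2`,
#'   `variant`.
#' @export
#' @examples
#' exp <- simulate_experiment(simulation_config(n_genes = 200, n_per_group = 5, seed = 1))
#' pv <- gene_ttests(exp)
#' head(pv)
gene_ttests <- function(x, labels = NULL, var_equal = TRUE) {
  if (inherits(x, "expression_experiment")) {
    labels <- x$labels$group
    x <- x$log2
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid("`x` must be a numeric genes-by-samples matrix.")
  }
  if (is.null(labels) || length(labels) != ncol(x)) {
    stop_invalid("`labels` must have one entry per column of `x`.")
  }
  if (anyNA(x)) stop_invalid("`x` must not contain missing values.")
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = unique(labels))
  if (nlevels(f) != 2L) stop_invalid("`labels` must define exactly two groups.")
  g1 <- f == levels(f)[1L]
  g2 <- f == levels(f)[2L]
  n1 <- sum(g1)
  n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L) stop_invalid("each group needs at least 2 samples.")

  x1 <- x[, g1, drop = FALSE]
  x2 <- x[, g2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  diff <- m2 - m1

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[se2 == 0] <- n1 + n2 - 2
  }

  tt <- diff / se
  zero_var <- v1 == 0 & v2 == 0
  flat <- zero_var & diff == 0
  tt[flat] <- 0
  tt[zero_var & diff != 0] <- sign(diff[zero_var & diff != 0]) * Inf
  p <- 2 * pt(-abs(tt), df)

  gene_ids <- rownames(x) %||% sprintf("g%0*d", max(4L, nchar(nrow(x))), seq_len(nrow(x)))
  out <- tibble(
    gene_id = gene_ids,
    t = unname(tt),
    df = unname(df),
    p_value = unname(p),
    zero_variance = unname(zero_var)
  )
  class(out) <- c("pvalue_set", class(out))
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  attr(out, "variant") <- if (var_equal) "pooled" else "welch"
  out
}

#' Map t statistics to normal-scale z-values
#'
#' Transforms each t statistic through its own t cumulative distribution
#' function and back through the standard-normal quantile function:
#' `z = qnorm(pt(t, df))`. The mapping is monotone in `t` and yields
#' standard-normal z-values when the t statistics follow their null
#' distribution. The CDF value is clamped to `[1e-15, 1 - 1e-15]` so `z`
#' is always finite.
#'
#' @param pset A [`pvalue_set`][gene_ttests], or a numeric vector of t
#'   statistics (then `df` must be given).
#' @param df Degrees of freedom (recycled) when `pset` is a bare vector.
#'
#' @return For a `pvalue_set`, the same tibble with a `z` column appended;
#'   for a vector, the numeric vector of z-values.
#' @export
#' @examples
#' t_to_z(c(-2, 0, 2), df = 18)
t_to_z <- function(pset, df = NULL) {
  if (inherits(pset, "pvalue_set") || (is.data.frame(pset) && all(c("t", "df") %in% names(pset)))) {
    pset$z <- t_to_z(pset$t, pset$df)
    return(pset)
  }
  if (is.null(df)) stop_invalid("`df` is required when `pset` is a numeric vector.")
  u <- pt(pset, df)
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  qnorm(u)
}
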