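#' Default p-value cutoff grid
#'
#' Fifty log-spaced cutoffs from `1e-6` to 1, the grid used by
#' [fdp_curve()] unless another is supplied.
#'
#' @param n Number of cutoffs.
#' @param from Smallest cutoff.
#' @return Strictly increasing numeric vector ending at 1.
#' @export
fdp_cutoff_grid <- function(n = 50L, from = 1e-6) {
  exp(seq(log(from), 0, length.out = n))
}

#' Confusion counts at a p-value cutoff
#'
#' Cross-tabulates significance calls (`p <= tau`) against the simulation
#' ground truth at a single cutoff.
#'
#' @param p_values Per-gene p-values.
#' @param truth_is_de Logical vector: is the gene truly differentially
#'   expressed?
#' @param tau Cutoff in (0, 1].
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_at_cutoff(c(0.001, 0.2, 0.03, 0.9), c(TRUE, FALSE, TRUE, FALSE), 0.05)
confusion_at_cutoff <- function(p_values, truth_is_de, tau) {
  if (length(p_values) != length(truth_is_de)) {
    stop_invalid("`p_values` and `truth_is_de` must have the same length.")
  }
  check_scalar_number(tau, "tau")
  if (tau <= 0 || tau > 1) {
    abort("`tau` must be in (0, 1].", class = "bumfdr_domain_error")
  }
  pos <- p_values <= tau
  tibble(
    tp = sum(pos & truth_is_de),
    fp = sum(pos & !truth_is_de),
    tn = sum(!pos & !truth_is_de),
    fn = sum(!pos & truth_is_de)
  )
}

#' Observed false discovery proportion as a function of the cutoff
#'
#' For each cutoff `tau` in the grid, genes with `p <= tau` are called
#' positive and the false discovery proportion is `FDP = FP / (FP + TP)`,
#' defined as 0 when there are no positives (the convention under which
#' FDR is the expectation of FDP). The confusion counts are computed with
#' a single sort rather than one pass per cutoff.
#'
#' @param p_values Per-gene p-values.
#' @param truth_is_de Logical ground-truth DE flags (same length).
#' @param cutoffs Strictly increasing cutoff grid in (0, 1].
#' @return A tibble of class `"fdp_curve"` with columns `cutoff`, `tp`,
#'   `fp`, `tn`, `fn`, `fdp`.
#' @export
#' @examples
#' set.seed(1)
#' p <- c(runif(90), rbeta(10, 0.2, 1))
#' curve <- fdp_curve(p, rep(c(FALSE, TRUE), c(90, 10)))
#' head(curve)
fdp_curve <- function(p_values, truth_is_de, cutoffs = fdp_cutoff_grid()) {
  if (length(p_values) != length(truth_is_de)) {
    stop_invalid("`p_values` and `truth_is_de` must have the same length.")
  }
  if (length(cutoffs) == 0L) stop_invalid("`cutoffs` must be nonempty.")
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop_invalid("`cutoffs` must be strictly increasing.")
  }
  if (any(cutoffs <= 0) || any(cutoffs > 1)) {
    abort("`cutoffs` must lie in (0, 1].", class = "bumfdr_domain_error")
  }
  truth_is_de <- as.logical(truth_is_de)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  cum_tp <- cumsum(truth_is_de[ord])
  n <- length(p_values)
  n_de <- sum(truth_is_de)

  n_pos <- findInterval(cutoffs, p_sorted)
  tp <- ifelse(n_pos == 0L, 0L, cum_tp[pmax(n_pos, 1L)])
  fp <- n_pos - tp
  fn <- n_de - tp
  tn <- n - n_de - fp
  fdp <- ifelse(n_pos == 0L, 0, fp / n_pos)

  out <- tibble(
    cutoff = cutoffs, tp = as.integer(tp), fp = as.integer(fp),
    tn = as.integer(tn), fn = as.integer(fn), fdp = fdp
  )
  class(out) <- c("fdp_curve", class(out))
  out
}

#' Summarise FDP curves across replicate datasets
#'
#' Pointwise mean and sample standard deviation of the FDP over replicate
#' simulations sharing the same cutoff grid — the replicate-mean curve
#' estimates the FDR (the marginal average of the FDP), and the sd curve
#' its dataset-to-dataset variability.
#'
#' @param curves List of [`fdp_curve`][fdp_curve] tibbles on identical
#'   grids; at least two for a meaningful sd.
#' @return Tibble with `cutoff`, `mean_fdp`, `sd_fdp`, `n_reps`.
#' @export
summarize_fdp_curves <- function(curves) {
  if (!is.list(curves) || length(curves) == 0L ||
      !all(vapply(curves, function(x) is.data.frame(x) && all(c("cutoff", "fdp") %in% names(x)),
                  logical(1)))) {
    stop_invalid("`curves` must be a nonempty list of fdp_curve tables.")
  }
  grid <- curves[[1L]]$cutoff
  same <- vapply(curves, function(x) length(x$cutoff) == length(grid) && all(x$cutoff == grid),
                 logical(1))
  if (!all(same)) stop_invalid("all curves must share the same cutoff grid.")
  fdp_mat <- vapply(curves, function(x) x$fdp, numeric(length(grid)))
  fdp_mat <- matrix(fdp_mat, nrow = length(grid))
  tibble(
    cutoff = grid,
    mean_fdp = rowMeans(fdp_mat),
    sd_fdp = apply(fdp_mat, 1L, sd),
    n_reps = length(curves)
  )
}
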