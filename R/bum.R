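#' Beta-uniform mixture density for p-values
#'
#' The BUM density `f(x) = lambda + (1 - lambda) * alpha * x^(alpha - 1)`
#' on `0 < x <= 1` mixes a uniform null component of weight `lambda` with
#' a Beta(`alpha`, 1) alternative component that peaks at zero for
#' `alpha < 1`. It integrates to 1 over (0, 1].
#'
#' @param x P-values in (0, 1].
#' @param alpha Beta shape in (0, 1); smaller values give a sharper peak
#'   near zero.
#' @param lambda Uniform-component weight in (0, 1).
#'
#' @return Density values, vectorised over `x`.
#' @export
#' @examples
#' dbum(c(0.01, 0.5, 1), alpha = 0.5, lambda = 0.7)
dbum <- function(x, alpha, lambda) {
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  check_scalar_number(lambda, "lambda", lower = 0, upper = 1)
  if (any(x <= 0) || any(x > 1)) {
    abort("`x` must be in (0, 1].", class = "bumfdr_domain_error")
  }
  lambda + (1 - lambda) * alpha * x^(alpha - 1)
}

#' Draw p-values from a beta-uniform mixture
#'
#' With probability `lambda` a draw is uniform on (0, 1); otherwise it is
#' Beta(`alpha`, 1), i.e. `U^(1/alpha)`.
#'
#' @param n Number of draws.
#' @param alpha,lambda BUM parameters in (0, 1).
#' @return Numeric vector of `n` p-values in (0, 1).
#' @export
#' @examples
#' set.seed(1); summary(rbum(1000, 0.5, 0.7))
rbum <- function(n, alpha, lambda) {
  n <- check_count(n, "n")
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  check_scalar_number(lambda, "lambda", lower = 0, upper = 1)
  null_draw <- runif(n) < lambda
  x <- runif(n)
  x[!null_draw] <- x[!null_draw]^(1 / alpha)
  x
}

#' Fit the beta-uniform mixture model to p-values
#'
#' Maximum-likelihood fit of [dbum()] to a vector of p-values. Both
#' parameters are logit-transformed so the optimisation is smooth and
#' unconstrained; a fixed set of five starting points guards against local
#' maxima, and the best converged solution is kept. P-values are floored
#' at `1e-12` (two-sided t p-values can underflow to 0) and capped at 1.
#'
#' @param p_values Numeric vector of p-values. Fewer than 100 triggers a
#'   warning (the fit is then fragile) but the model is still fitted.
#' @param pvalue_floor Lower clamp applied before taking logs.
#'
#' @return An object of class `"bum_fit"`: a list with `alpha_hat`,
#'   `lambda_hat`, `pi_ub` (the logical upper bound on the true-null
#'   proportion, `lambda + (1 - lambda) * alpha`), `loglik`, `n`,
#'   `converged`, and the clamped `p_values` used for the fit.
#' @seealso [pi_upper_bound()], [bum_fdr_at_cutoff()], [cutoff_for_target_fdr()]
#' @export
#' @examples
#' set.seed(1)
#' fit <- fit_bum(rbum(5000, alpha = 0.5, lambda = 0.7))
#' fit
#' glance(fit)
fit_bum <- function(p_values, pvalue_floor = 1e-12) {
  if (length(p_values) == 0L) stop_invalid("`p_values` is empty.")
  if (anyNA(p_values)) stop_invalid("`p_values` must not contain NA.")
  if (any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("`p_values` must lie in [0, 1].")
  }
  if (length(unique(p_values)) == 1L) {
    abort("all p-values are identical; the BUM fit is degenerate.",
          class = "bumfdr_degenerate_fit")
  }
  if (length(p_values) < 100L) {
    warn("fewer than 100 p-values; BUM parameter estimates will be unstable.")
  }
  p <- pmin(pmax(p_values, pvalue_floor), 1)

  lp <- log(p)
  nll <- function(par) {
    a <- stats::plogis(par[1L])
    l <- stats::plogis(par[2L])
    -sum(log(l + (1 - l) * a * p^(a - 1)))
  }
  nll_grad <- function(par) {
    a <- stats::plogis(par[1L])
    l <- stats::plogis(par[2L])
    pa <- p^(a - 1)
    f <- l + (1 - l) * a * pa
    # chain rule through the logit links: d plogis(x)/dx = v (1 - v)
    da <- -sum((1 - l) * pa * (1 + a * lp) / f) * a * (1 - a)
    dl <- -sum((1 - a * pa) / f) * l * (1 - l)
    c(da, dl)
  }
  starts <- rbind(
    c(0.5, 0.5), c(0.2, 0.8), c(0.8, 0.2), c(0.3, 0.95), c(0.9, 0.6)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(stats::qlogis(starts[i, ]), nll, gr = nll_grad, method = "BFGS",
            control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    abort("BUM optimisation failed from every starting point.",
          class = "bumfdr_degenerate_fit")
  }
  # keep estimates strictly inside (0, 1): pure-null data drives lambda to
  # the boundary, where plogis saturates to exactly 1 in double precision
  clamp01 <- function(v) pmin(pmax(v, 1e-8), 1 - 1e-8)
  alpha_hat <- clamp01(stats::plogis(best$par[1L]))
  lambda_hat <- clamp01(stats::plogis(best$par[2L]))
  structure(
    list(
      alpha_hat = alpha_hat,
      lambda_hat = lambda_hat,
      pi_ub = pi_upper_bound(alpha_hat, lambda_hat),
      loglik = -best$value,
      n = length(p),
      converged = best$convergence == 0L,
      p_values = p
    ),
    class = "bum_fit"
  )
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf(
    "<bum_fit> n = %d p-values\n  alpha = %.4f, lambda = %.4f, pi upper bound = %.4f\n",
    x$n, x$alpha_hat, x$lambda_hat, x$pi_ub
  ))
  cat(sprintf("  log-likelihood %.2f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @describeIn fit_bum One row per estimated parameter (broom convention).
#' @param x A `bum_fit`.
#' @param ... Unused.
#' @export
tidy.bum_fit <- function(x, ...) {
  tibble(
    term = c("alpha", "lambda", "pi_upper_bound"),
    estimate = c(x$alpha_hat, x$lambda_hat, x$pi_ub)
  )
}

#' @describeIn fit_bum One-row model summary (broom convention).
#' @export
glance.bum_fit <- function(x, ...) {
  tibble(
    alpha_hat = x$alpha_hat, lambda_hat = x$lambda_hat, pi_ub = x$pi_ub,
    loglik = x$loglik, n = x$n, converged = x$converged
  )
}

#' Logical upper bound on the true-null proportion
#'
#' The BUM density at `x = 1` is `lambda + (1 - lambda) * alpha`, the
#' largest uniform component consistent with the fitted mixture; it bounds
#' the proportion `pi` of p-values arising from the null (non-DE genes)
#' from above. The complement `1 - pi_upper_bound` is a conservative
#' estimate of the proportion of differentially expressed genes.
#'
#' @param alpha,lambda BUM parameters in (0, 1).
#' @return The upper bound, in (0, 1].
#' @export
#' @examples
#' pi_upper_bound(0.5, 0.8)
pi_upper_bound <- function(alpha, lambda) {
  if (any(alpha <= 0) || any(alpha >= 1) || any(lambda <= 0) || any(lambda >= 1)) {
    abort("`alpha` and `lambda` must lie strictly in (0, 1).",
          class = "bumfdr_domain_error")
  }
  lambda + (1 - lambda) * alpha
}

#' Model-based FDR at a p-value cutoff
#'
#' Under a fitted BUM model, calling genes with `p <= tau` significant
#' gives the false discovery rate estimate
#' `pi_ub * tau / (lambda * tau + (1 - lambda) * tau^alpha)`, i.e. the
#' worst-case null mass below `tau` over the total mixture mass below
#' `tau`, capped at 1. It is nondecreasing in `tau`.
#'
#' @param fit A [`bum_fit`][fit_bum].
#' @param tau P-value cutoffs in (0, 1] (vectorised).
#' @return FDR estimates in \[0, 1\].
#' @export
#' @examples
#' set.seed(1)
#' fit <- fit_bum(rbum(5000, 0.5, 0.7))
#' bum_fdr_at_cutoff(fit, c(0.001, 0.01, 0.05))
bum_fdr_at_cutoff <- function(fit, tau) {
  if (!inherits(fit, "bum_fit")) stop_invalid("`fit` must be a bum_fit object.")
  if (any(tau <= 0) || any(tau > 1)) {
    abort("`tau` must be in (0, 1].", class = "bumfdr_domain_error")
  }
  a <- fit$alpha_hat
  l <- fit$lambda_hat
  pmin(1, fit$pi_ub * tau / (l * tau + (1 - l) * tau^a))
}

#' P-value cutoff achieving a target FDR
#'
#' Inverts the monotone map [bum_fdr_at_cutoff()] by bisection to find the
#' largest cutoff `tau` whose model-based FDR does not exceed `target` —
#' the most permissive threshold that still controls the FDR at the target
#' level. Returns 1 when `target >= pi_ub` (every gene passes) and 0 when
#' no representable cutoff achieves the target (near-pure-null fits).
#'
#' @param fit A [`bum_fit`][fit_bum].
#' @param target Target FDR in (0, 1).
#' @param tol Bisection tolerance on `tau`.
#' @return A cutoff in \[0, 1\].
#' @export
#' @examples
#' set.seed(1)
#' fit <- fit_bum(rbum(5000, 0.3, 0.6))
#' tau <- cutoff_for_target_fdr(fit, 0.10)
#' bum_fdr_at_cutoff(fit, tau) <= 0.10 + 1e-8
cutoff_for_target_fdr <- function(fit, target, tol = 1e-10) {
  if (!inherits(fit, "bum_fit")) stop_invalid("`fit` must be a bum_fit object.")
  check_scalar_number(target, "target")
  if (target <= 0 || target >= 1) {
    abort("`target` must be in (0, 1).", class = "bumfdr_domain_error")
  }
  if (target >= fit$pi_ub) return(1)
  lo <- tol
  if (bum_fdr_at_cutoff(fit, lo) > target) return(0)
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (bum_fdr_at_cutoff(fit, mid) <= target) lo <- mid else hi <- mid
  }
  lo
}
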