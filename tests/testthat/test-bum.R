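test_that("BUM density has the right limits, closed form and unit mass", {
  x <- seq(0.01, 1, length.out = 50)
  expect_equal(dbum(x, alpha = 0.3, lambda = 1), rep(1, 50))
  expect_equal(dbum(x, alpha = 1 - 1e-12, lambda = 0.4), rep(1, 50), tolerance = 1e-9)
  expect_equal(dbum(1, 0.37, 0.61), 0.61 + 0.39 * 0.37)
  expect_error(dbum(0, 0.5, 0.5), class = "bumfdr_domain_error")

  # quadrature oracle: unit mass over (0, 1] for a grid of parameters
  for (a in c(0.1, 0.5, 0.9)) {
    for (l in c(0.05, 0.5, 0.95)) {
      mass <- stats::integrate(dbum, 0, 1, alpha = a, lambda = l,
                               rel.tol = 1e-10)$value
      expect_equal(mass, 1, tolerance = 1e-8)
    }
  }
})

test_that("maximum likelihood recovers BUM parameters and handles edge inputs", {
  set.seed(81)
  fit <- fit_bum(rbum(20000, alpha = 0.5, lambda = 0.7))
  expect_lt(abs(fit$alpha_hat - 0.5), 0.05)
  expect_lt(abs(fit$lambda_hat - 0.7), 0.05)
  expect_true(fit$converged)
  expect_equal(fit$pi_ub, pi_upper_bound(fit$alpha_hat, fit$lambda_hat))

  # pure-null recovery: uniform p-values force the upper bound toward 1
  set.seed(82)
  null_fit <- fit_bum(runif(20000))
  expect_gte(null_fit$pi_ub, 0.98)

  # p = 0 is floored, not fatal
  set.seed(83)
  with_zero <- fit_bum(c(0, rbum(5000, 0.4, 0.6)))
  expect_true(is.finite(with_zero$loglik))

  expect_error(fit_bum(numeric(0)), class = "bumfdr_invalid_input")
  expect_error(fit_bum(rep(0.5, 500)), class = "bumfdr_degenerate_fit")
  expect_warning(fit_bum(runif(50)), "fewer than 100")

  td <- tidy(fit)
  expect_identical(td$term, c("alpha", "lambda", "pi_upper_bound"))
  expect_identical(glance(fit)$n, 20000L)
})

test_that("pi upper bound evaluates the density-at-one closed form", {
  expect_equal(pi_upper_bound(0.5, 0.8), 0.9)
  expect_equal(pi_upper_bound(0.5, 1 - 1e-12), 1, tolerance = 1e-9)
  expect_equal(pi_upper_bound(1 - 1e-12, 0.3), 1, tolerance = 1e-9)
  expect_error(pi_upper_bound(1.2, 0.5), class = "bumfdr_domain_error")
  expect_error(pi_upper_bound(0.5, 0), class = "bumfdr_domain_error")
})

make_fit <- function(alpha, lambda) {
  structure(
    list(alpha_hat = alpha, lambda_hat = lambda,
         pi_ub = pi_upper_bound(alpha, lambda),
         loglik = NA_real_, n = 0L, converged = TRUE, p_values = numeric(0)),
    class = "bum_fit"
  )
}

test_that("model-based FDR matches the closed form and is monotone", {
  fit <- make_fit(0.5, 0.5)
  # frozen value from an independent high-precision evaluation
  expect_equal(bum_fdr_at_cutoff(fit, 0.01), 0.13636363636363635, tolerance = 1e-12)
  expect_equal(bum_fdr_at_cutoff(fit, 1), fit$pi_ub)

  near_null <- make_fit(0.9, 1 - 1e-8)
  expect_true(all(bum_fdr_at_cutoff(near_null, c(0.001, 0.1, 1)) > 0.999))

  tau_grid <- fdp_cutoff_grid(200)
  for (f in list(make_fit(0.2, 0.3), make_fit(0.7, 0.9), fit)) {
    expect_true(all(diff(bum_fdr_at_cutoff(f, tau_grid)) >= -1e-12))
  }
  expect_error(bum_fdr_at_cutoff(fit, 0), class = "bumfdr_domain_error")
})

test_that("FDR-target inversion is consistent with a grid-scan oracle", {
  fit <- make_fit(0.2, 0.4)
  expect_equal(cutoff_for_target_fdr(fit, fit$pi_ub + 1e-6), 1)

  tau <- cutoff_for_target_fdr(fit, 0.10)
  expect_lte(bum_fdr_at_cutoff(fit, tau), 0.10 + 1e-8)
  # largest such cutoff: a nudge above must break the target
  expect_gt(bum_fdr_at_cutoff(fit, min(1, tau + 1e-6)), 0.10)

  # grid-scan oracle
  grid <- seq(1e-6, 1, length.out = 200000)
  ok <- bum_fdr_at_cutoff(fit, grid) <= 0.10
  expect_equal(tau, max(grid[ok]), tolerance = 1e-4)

  # near-pure-null fit: no cutoff achieves 10%
  expect_equal(cutoff_for_target_fdr(make_fit(0.9, 0.99), 0.10), 0)
})

test_that("alpha and lambda estimates are negatively correlated across replicate fits", {
  corr_at <- function(n, base_seed) {
    est <- vapply(1:60, function(i) {
      set.seed(base_seed + i)
      f <- fit_bum(rbum(n, 0.4, 0.6))
      c(f$alpha_hat, f$lambda_hat)
    }, numeric(2))
    cor(est[1, ], est[2, ])
  }
  expect_lt(corr_at(1000, 300), 0)
  expect_lt(corr_at(20000, 600), 0)
})

test_that("the BUM upper bound underestimates the true null proportion with 10% DE blocks", {
  pis <- vapply(1:5, function(s) {
    e <- simulate_experiment(simulation_config(
      n_genes = 2000, n_per_group = 25, mean_block_size = 10,
      psi = 0.1, active_fraction = 1, seed = 900 + s
    ))
    fit_bum(gene_ttests(e)$p_value)$pi_ub
  }, numeric(1))
  expect_lt(mean(pis), 0.9)
})
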