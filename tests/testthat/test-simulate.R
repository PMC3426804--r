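test_that("block partition conserves the gene count and hits the target mean size", {
  expect_identical(partition_blocks(10, 1), rep(1L, 10))

  set.seed(1)
  for (i in 1:20) {
    g <- sample(50:500, 1)
    xi <- sample(c(1, 5, 10, 50), 1)
    sizes <- partition_blocks(g, xi)
    expect_true(all(sizes >= 1L))
    expect_identical(sum(sizes), g)
  }

  # Monte-Carlo check of the 1 + Poisson(xi - 1) mean
  set.seed(42)
  totals <- vapply(1:50, function(i) {
    sizes <- partition_blocks(10000, 10)
    c(sum(sizes), length(sizes))
  }, numeric(2))
  grand_mean <- sum(totals[1, ]) / sum(totals[2, ])
  expect_gt(grand_mean, 9)
  expect_lt(grand_mean, 11)

  expect_error(partition_blocks(0, 5), class = "bumfdr_invalid_input")
  expect_error(partition_blocks(100, 0.5), class = "bumfdr_invalid_input")
})

test_that("theta draws respect the fixed and tent scenarios", {
  expect_identical(draw_theta(0), 0)
  expect_identical(draw_theta(0.25, 3), rep(0.25, 3))
  expect_error(draw_theta(0.7), class = "bumfdr_invalid_input")
  expect_error(draw_theta("triangle"), class = "bumfdr_invalid_input")

  set.seed(7)
  th <- draw_theta("tent", 1e5)
  expect_true(all(th >= 0 & th <= 0.5))
  expect_equal(mean(th), 0.25, tolerance = 0.02)
  # apex: x = 0.5 maps to theta = 0.5
  expect_equal(0.5 - abs(0.5 - 0.5), 0.5)
})

test_that("block correlation matrices follow the sign rule and are PSD", {
  expect_identical(build_block_correlation(3, 0, c(1, -1, 1)), diag(3))

  cm <- build_block_correlation(2, 0.8, c(1, -1))
  expect_equal(cm[1, 2], -0.8)
  expect_equal(diag(cm), c(1, 1))

  # eigen-decomposition oracle at half-negative signs and near-unit rho
  signs <- rep(c(1, -1), each = 100)
  big <- build_block_correlation(200, 0.95, signs)
  expect_gte(min(eigen(big, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  set.seed(3)
  for (i in 1:25) {
    sz <- sample(2:40, 1)
    s <- ifelse(runif(sz) < runif(1, 0, 0.5), -1, 1)
    cm <- build_block_correlation(sz, runif(1), s)
    expect_gte(min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }

  expect_error(build_block_correlation(2, 1.2, c(1, 1)), class = "bumfdr_invalid_input")
})

test_that("differential expression injection matches the gamma/fair-coin law", {
  set.seed(11)
  none <- inject_de(c(5L, 5L), c(TRUE, TRUE), psi = 0)
  expect_false(any(none$de))
  expect_true(all(unlist(none$deltas) == 0))

  all_de <- inject_de(rep(10L, 10), rep(TRUE, 10), psi = 1)
  expect_true(all(all_de$de))

  # Gamma(10, 10) magnitude and fair sign coin at 1e5 genes
  big <- inject_de(1e5L, TRUE, psi = 1, de_shape = 10, de_rate = 10)
  d <- big$deltas[[1]]
  expect_equal(mean(abs(d)), 1, tolerance = 0.01)
  frac_up <- mean(d > 0)
  expect_gte(frac_up, 0.49)
  expect_lte(frac_up, 0.51)

  expect_error(inject_de(c(3L, 3L), c(FALSE, FALSE), psi = 0.5),
               class = "bumfdr_degenerate_input")
})

test_that("noise model reduces to clipping when silent and respects the floor", {
  s <- matrix(c(0, 0.5, 4, 100), 2, 2)
  quiet <- noise_params(mult_sd = 0, add_mean = 0, add_sd = 0, floor = 1)
  expect_equal(apply_noise(s, quiet), pmax(s, 1))

  set.seed(5)
  y <- apply_noise(matrix(runif(200, 0, 10), 20, 10), noise_params(floor = 2))
  expect_true(all(y >= 2))

  # log-scale variance grows with the multiplicative noise level
  s_fix <- matrix(2^8, 1000, 1)
  v <- vapply(c(0.05, 0.2), function(m) {
    var(log2(apply_noise(s_fix, noise_params(mult_sd = m, add_sd = 0, add_mean = 0))))
  }, numeric(1))
  expect_lt(v[1], v[2])

  expect_error(apply_noise(matrix(-1, 1, 1), noise_params()),
               class = "bumfdr_invalid_input")
})

test_that("simulated experiments satisfy the dimension, truth and determinism contracts", {
  cfg <- simulation_config(n_genes = 1000, n_per_group = 25, mean_block_size = 10,
                           psi = 0.2, seed = 33)
  exp1 <- simulate_experiment(cfg)
  expect_identical(dim(exp1$log2), c(1000L, 50L))
  expect_false(anyNA(exp1$log2))
  expect_identical(sum(exp1$labels$group == "normal"), sum(exp1$labels$group == "cancer"))

  # truth bookkeeping: DE genes = total size of DE blocks; DE implies active
  de_blocks <- unique(exp1$truth$block_id[exp1$truth$is_de])
  expect_identical(sum(exp1$truth$is_de),
                   sum(exp1$truth$block_id %in% de_blocks))
  expect_true(all(exp1$truth$active[exp1$truth$is_de]))
  expect_true(all(exp1$truth$delta[!exp1$truth$is_de] == 0))
  expect_true(all(exp1$truth$delta[exp1$truth$is_de] != 0))

  exp2 <- simulate_experiment(cfg)
  expect_identical(exp1$log2, exp2$log2)
  expect_identical(exp1$truth, exp2$truth)

  no_de <- simulate_experiment(simulation_config(n_genes = 500, n_per_group = 5,
                                                 psi = 0, seed = 1))
  expect_false(any(no_de$truth$is_de))
})

test_that("changing psi leaves the block layout and baseline untouched", {
  base <- simulation_config(n_genes = 800, n_per_group = 10, mean_block_size = 20,
                            psi = 0, seed = 5)
  shifted <- base
  shifted$psi <- 0.4
  e0 <- simulate_experiment(base)
  e1 <- simulate_experiment(shifted)
  expect_identical(e0$truth$block_id, e1$truth$block_id)
  expect_identical(e0$truth$active, e1$truth$active)
  # normal samples are identical; only cancer means move
  normal_cols <- e0$labels$group == "normal"
  expect_identical(e0$log2[, normal_cols], e1$log2[, normal_cols])
})

test_that("singleton blocks yield independent genes and uniform null p-values", {
  cfg <- simulation_config(n_genes = 5000, n_per_group = 25, mean_block_size = 1,
                           psi = 0, seed = 42)
  exp <- simulate_experiment(cfg)
  pv <- gene_ttests(exp)
  ks <- suppressWarnings(stats::ks.test(pv$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)

  # pairwise correlations centred at 0 with sd ~ 1/sqrt(2N - 1)
  active <- exp$log2[exp$truth$active, ][1:500, ]
  cors <- cor(t(active))
  offdiag <- cors[upper.tri(cors)]
  expect_lt(abs(mean(offdiag)), 0.01)
  expect_equal(sd(offdiag), 1 / sqrt(49), tolerance = 0.1)
})

test_that("opposite-sign genes in a strongly correlated block anticorrelate", {
  set.seed(9)
  mean_cors <- vapply(1:100, function(i) {
    n <- 50
    signs <- c(1, -1)
    cm <- build_block_correlation(2, 0.9, signs)
    x <- matrix(rnorm(2 * n), 2, n)
    ch <- chol(cm)
    y <- t(ch) %*% x
    cor(y[1, ], y[2, ])
  }, numeric(1))
  expect_lt(mean(mean_cors), 0)

  # and through the full generator: a theta = 0.5 block of strongly
  # correlated genes shows negatively correlated pairs
  cfg <- simulation_config(n_genes = 200, n_per_group = 50, mean_block_size = 200,
                           theta_scenario = 0.5, rho_a = 50, rho_b = 1,
                           active_fraction = 1, seed = 17)
  exp <- simulate_experiment(cfg)
  cors <- cor(t(exp$log2[1:100, ]))
  expect_lt(min(cors[upper.tri(cors)]), -0.3)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(simulation_config(psi = 1.5), class = "bumfdr_invalid_input")
  expect_error(simulation_config(mean_block_size = 0), class = "bumfdr_invalid_input")
  expect_error(simulation_config(de_shape = -1), class = "bumfdr_invalid_input")
  expect_error(simulation_config(active_fraction = -0.1), class = "bumfdr_invalid_input")
  expect_error(noise_params(mult_sd = -1), class = "bumfdr_invalid_input")
  expect_error(noise_params(floor = 0), class = "bumfdr_invalid_input")
})
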