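tiny_spec <- function(n_reps = 2L, base_seed = 1L) {
  grid_spec(
    sample_sizes = 5, block_sizes = c(1, 10), theta_scenarios = list(0, "tent"),
    psi_levels = 0.2, n_reps = n_reps, base_seed = base_seed,
    config = simulation_config(n_genes = 300)
  )
}

test_that("the factorial enumeration multiplies out and runs deterministically", {
  expect_identical(nrow(grid_configurations(grid_spec())), 128L)
  expect_identical(nrow(grid_configurations(tiny_spec())), 4L)

  rec <- run_grid(tiny_spec(n_reps = 3), n_pairs = 2000)
  expect_identical(nrow(rec), 12L)
  expect_false(any(rec$failed))

  rec2 <- run_grid(tiny_spec(n_reps = 3), n_pairs = 2000)
  expect_identical(rec, rec2)

  # a different base seed moves every replicate stream
  rec3 <- run_grid(tiny_spec(n_reps = 3, base_seed = 2), n_pairs = 2000)
  expect_false(any(rec3$seed %in% rec$seed))
})

test_that("grid records carry every per-dataset summary the study tracks", {
  rec <- run_grid(tiny_spec(), n_pairs = 2000)
  expect_true(all(c(
    "n_per_group", "mean_block_size", "theta", "psi", "rep", "seed",
    "alpha_hat", "lambda_hat", "pi_ub", "loglik", "converged",
    "fdp_0.001", "fdp_0.01", "fdp_0.05", "sigma0", "A", "corr_std",
    "failed", "message"
  ) %in% names(rec)))
  ok <- !rec$failed
  expect_true(all(rec$alpha_hat[ok] > 0 & rec$alpha_hat[ok] < 1))
  expect_true(all(rec$pi_ub[ok] <= 1))
})

test_that("group-wise summaries match an independent recomputation", {
  expect_equal(
    summarize_grid(tibble::tibble(g = c(1, 1), x = c(0.2, 0.4)), "g", "x")$x_mean,
    0.3
  )
  same <- tibble::tibble(g = rep("a", 4), x = rep(2.5, 4))
  expect_equal(summarize_grid(same, "g", "x")$x_sd, 0)

  single <- tibble::tibble(g = c("a", "b"), x = c(1, 2))
  expect_true(all(is.na(summarize_grid(single, "g", "x")$x_sd)))

  set.seed(51)
  fixture <- tibble::tibble(
    f1 = sample(letters[1:4], 100, replace = TRUE),
    f2 = sample(1:2, 100, replace = TRUE),
    stat = rnorm(100)
  )
  got <- summarize_grid(fixture, c("f1", "f2"), "stat")
  ref <- stats::aggregate(stat ~ f1 + f2, fixture, mean)
  merged <- merge(got, ref, by = c("f1", "f2"))
  expect_equal(merged$stat_mean, merged$stat)

  expect_error(summarize_grid(fixture, "nope", "stat"), class = "bumfdr_invalid_input")
})

test_that("TSV round trips preserve values and malformed files fail loudly", {
  dir <- withr::local_tempdir()

  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%04d", 1:10), paste0("s", 1:4)))
  path <- file.path(dir, "m.tsv")
  write_matrix_tsv(m, path)
  back <- read_matrix_tsv(path)
  expect_identical(dimnames(back), dimnames(m))
  expect_equal(back, m, tolerance = 0)

  # ragged row reported with its line number
  lines <- readLines(path)
  lines[4] <- paste(strsplit(lines[4], "\t")[[1]][1:3], collapse = "\t")
  ragged <- file.path(dir, "ragged.tsv")
  writeLines(lines, ragged)
  expect_error(read_matrix_tsv(ragged), "4")

  # duplicate gene ids named in the error
  lines2 <- readLines(path)
  lines2[3] <- sub("^g0002", "g0001", lines2[3])
  dups <- file.path(dir, "dup.tsv")
  writeLines(lines2, dups)
  expect_error(read_matrix_tsv(dups), "g0001")

  expect_error(read_matrix_tsv(file.path(dir, "missing.tsv")),
               class = "bumfdr_invalid_input")
})

test_that("experiments survive a disk round trip", {
  dir <- withr::local_tempdir()
  exp <- simulate_experiment(simulation_config(n_genes = 50, n_per_group = 4,
                                               psi = 0.3, seed = 8))
  write_experiment_tsv(exp, dir)
  back <- read_experiment_tsv(dir)
  expect_equal(back$log2, exp$log2, tolerance = 0)
  expect_identical(back$labels$sample_id, exp$labels$sample_id)
  expect_identical(as.character(back$labels$group), as.character(exp$labels$group))
  expect_identical(back$truth$is_de, exp$truth$is_de)
  expect_equal(back$truth$delta, exp$truth$delta, tolerance = 0)

  pv <- t_to_z(gene_ttests(exp))
  ppath <- file.path(dir, "pvalues.tsv")
  write_pvalues_tsv(pv, ppath)
  pback <- readr::read_tsv(ppath, col_types = readr::cols(.default = "c"),
                           show_col_types = FALSE)
  expect_equal(as.numeric(pback$p_value), pv$p_value, tolerance = 0)
  expect_equal(as.numeric(pback$t), pv$t, tolerance = 0)
})

test_that("plot builders return ggplot objects", {
  set.seed(52)
  fit <- fit_bum(rbum(2000, 0.4, 0.6))
  expect_s3_class(autoplot(fit), "ggplot")

  curve <- fdp_curve(runif(100), rep(c(TRUE, FALSE), 50))
  expect_s3_class(autoplot(curve), "ggplot")

  rec <- run_grid(tiny_spec(), n_pairs = 2000)
  expect_s3_class(plot_grid_stat(rec, "alpha_hat", x = "mean_block_size"), "ggplot")
  expect_error(plot_grid_stat(rec, "nope", x = "psi"), class = "bumfdr_invalid_input")
})
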