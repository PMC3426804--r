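#' Factorial simulation grid specification
#'
#' Describes a full factorial grid of simulation configurations: sample
#' sizes x mean block sizes x theta scenarios x DE levels, each replicated
#' `n_reps` times. The defaults enumerate the package's canonical 128-cell
#' factorial: `N` in {10, 25, 50, 100}, `xi` in {1, 5, 10, 50, 100,
#' 250, 500, 1000}, four theta scenarios (fixed 0, 0.1, 0.25, and the
#' random tent draw), at a single DE level.
#'
#' @param sample_sizes Per-group sample sizes `N`.
#' @param block_sizes Mean block sizes `xi`.
#' @param theta_scenarios List of theta scenarios (numbers in `[0, 0.5]`
#'   or `"tent"`).
#' @param psi_levels DE-block fractions `psi`.
#' @param n_reps Replicate datasets per configuration.
#' @param base_seed Integer seed; each (configuration, replicate) gets a
#'   deterministically derived sub-seed, so grids are reproducible and
#'   extensible.
#' @param config Template [simulation_config()] supplying every field the
#'   grid does not vary (gene count, noise, ...).
#'
#' @return A list of class `"grid_spec"`.
#' @seealso [run_grid()], [grid_configurations()]
#' @export
#' @examples
#' spec <- grid_spec()
#' nrow(grid_configurations(spec))
grid_spec <- function(sample_sizes = c(10, 25, 50, 100),
                      block_sizes = c(1, 5, 10, 50, 100, 250, 500, 1000),
                      theta_scenarios = list(0, 0.1, 0.25, "tent"),
                      psi_levels = 0.1,
                      n_reps = 20L,
                      base_seed = 1L,
                      config = simulation_config()) {
  if (length(sample_sizes) == 0L || length(block_sizes) == 0L ||
      length(theta_scenarios) == 0L || length(psi_levels) == 0L) {
    stop_invalid("all grid factor lists must be nonempty.")
  }
  if (!is.list(theta_scenarios)) theta_scenarios <- as.list(theta_scenarios)
  purrr::walk(theta_scenarios, check_theta_scenario)
  n_reps <- check_count(n_reps, "n_reps")
  check_count(base_seed, "base_seed", lower = 0L)
  if (!inherits(config, "simulation_config")) {
    stop_invalid("`config` must be a simulation_config() object.")
  }
  structure(
    list(
      sample_sizes = as.integer(sample_sizes), block_sizes = block_sizes,
      theta_scenarios = theta_scenarios, psi_levels = psi_levels,
      n_reps = n_reps, base_seed = as.integer(base_seed), config = config
    ),
    class = "grid_spec"
  )
}

#' @describeIn grid_spec Enumerate the configurations of a grid (one row
#'   each, in the deterministic execution order).
#' @param spec A `grid_spec`.
#' @export
grid_configurations <- function(spec) {
  if (!inherits(spec, "grid_spec")) stop_invalid("`spec` must be a grid_spec object.")
  theta_tags <- vapply(
    spec$theta_scenarios,
    function(s) if (is.character(s)) s else format(s),
    character(1)
  )
  out <- tidyr::expand_grid(
    n_per_group = spec$sample_sizes,
    mean_block_size = spec$block_sizes,
    theta = theta_tags,
    psi = spec$psi_levels
  )
  dplyr::mutate(out, config_index = dplyr::row_number())
}

#' Run a factorial simulation grid
#'
#' For every configuration and replicate: simulate the dataset
#' ([simulate_experiment()]), test each gene ([gene_ttests()]), fit the
#' BUM model ([fit_bum()]), record the observed FDP at the summary
#' cutoffs ([fdp_curve()]) against the known truth, and compute the
#' dispersion summaries ([dispersion_summary()]). Rows are appended in
#' deterministic configuration-major order; a failing stage flags the row
#' (`failed`, `message`) rather than dropping it.
#'
#' @param spec A [grid_spec()].
#' @param fdp_cutoffs Cutoffs at which per-dataset FDP columns are
#'   recorded.
#' @param n_pairs Gene pairs sampled for `corr.std`.
#' @param verbose Print one progress line per configuration to stderr.
#'
#' @return A tibble with one row per (configuration, replicate): the
#'   configuration fields (`n_per_group`, `mean_block_size`, `theta`,
#'   `psi`, `rep`, `seed`), BUM estimates (`alpha_hat`, `lambda_hat`,
#'   `pi_ub`, `loglik`, `converged`), `fdp_<cutoff>` columns, dispersion
#'   summaries (`sigma0`, `A`, `corr_std`), and `failed`/`message` flags.
#' @export
#' @examples
#' spec <- grid_spec(sample_sizes = 5, block_sizes = c(1, 10),
#'                   theta_scenarios = list("tent"), psi_levels = 0.2,
#'                   n_reps = 2, config = simulation_config(n_genes = 300))
#' run_grid(spec)
run_grid <- function(spec, fdp_cutoffs = c(0.001, 0.01, 0.05),
                     n_pairs = 50000L, verbose = FALSE) {
  if (!inherits(spec, "grid_spec")) stop_invalid("`spec` must be a grid_spec object.")
  configs <- grid_configurations(spec)
  theta_lookup <- setNames(
    spec$theta_scenarios,
    vapply(spec$theta_scenarios, function(s) if (is.character(s)) s else format(s), character(1))
  )
  fdp_cutoffs <- sort(fdp_cutoffs)
  fdp_names <- paste0(
    "fdp_", vapply(fdp_cutoffs, format, character(1), scientific = FALSE)
  )

  rows <- purrr::map(seq_len(nrow(configs)), function(ci) {
    cfg_row <- configs[ci, ]
    if (verbose) {
      message(sprintf(
        "config %d/%d: N=%d xi=%s theta=%s psi=%s",
        ci, nrow(configs), cfg_row$n_per_group, format(cfg_row$mean_block_size),
        cfg_row$theta, format(cfg_row$psi)
      ))
    }
    purrr::map(seq_len(spec$n_reps), function(rep) {
      seed <- mix_seed(spec$base_seed, ci, rep)
      base <- tibble(
        n_per_group = cfg_row$n_per_group,
        mean_block_size = cfg_row$mean_block_size,
        theta = cfg_row$theta,
        psi = cfg_row$psi,
        rep = rep,
        seed = seed
      )
      # each stage fails independently: a degenerate empirical-null fit on a
      # heavily correlated dataset must not discard the BUM and FDP records
      msgs <- character(0)
      stage <- function(expr) {
        tryCatch(expr, error = function(e) {
          msgs <<- c(msgs, conditionMessage(e))
          NULL
        })
      }
      exper <- stage({
        cfg <- spec$config
        cfg$n_per_group <- as.integer(cfg_row$n_per_group)
        cfg$mean_block_size <- cfg_row$mean_block_size
        cfg$theta_scenario <- theta_lookup[[cfg_row$theta]]
        cfg$psi <- cfg_row$psi
        cfg$seed <- seed
        simulate_experiment(cfg)
      })
      pv <- if (is.null(exper)) NULL else stage(t_to_z(gene_ttests(exper)))
      fit <- if (is.null(pv)) NULL else stage(fit_bum(pv$p_value))
      fdps <- if (is.null(pv)) NULL else {
        stage(fdp_curve(pv$p_value, exper$truth$is_de, fdp_cutoffs)$fdp)
      }
      sigma0 <- if (is.null(pv)) NULL else stage(estimate_null_width(pv$z))
      a_var <- if (is.null(sigma0)) NULL else stage(dispersion_A(sigma0))
      # pair sampling on its own derived stream so reruns are bit-identical
      cs <- if (is.null(exper)) NULL else {
        stage(with_stage_seed(
          mix_seed(seed, 6L),
          as.numeric(correlation_sd(exper$log2, n_pairs = n_pairs))
        ))
      }
      stats_row <- tibble(
        alpha_hat = fit$alpha_hat %||% NA_real_,
        lambda_hat = fit$lambda_hat %||% NA_real_,
        pi_ub = fit$pi_ub %||% NA_real_,
        loglik = fit$loglik %||% NA_real_,
        converged = fit$converged %||% NA
      )
      stats_row[fdp_names] <- as.list(fdps %||% rep(NA_real_, length(fdp_names)))
      dplyr::bind_cols(
        base, stats_row,
        tibble(
          sigma0 = sigma0 %||% NA_real_,
          A = a_var %||% NA_real_,
          corr_std = cs %||% NA_real_,
          failed = length(msgs) > 0L,
          message = if (length(msgs)) paste(msgs, collapse = "; ") else NA_character_
        )
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Group-wise summary of grid records
#'
#' Mean, sample standard deviation and count of chosen statistics, grouped
#' by configuration fields — the numeric backbone of boxplot-style
#' summaries of a simulation grid. Groups with a single row report `NA`
#' for the sd (undefined).
#'
#' @param records Tibble from [run_grid()].
#' @param group_by Character vector of grouping fields.
#' @param stats Character vector of statistic columns to summarise.
#'
#' @return A tibble with one row per group and columns
#'   `<stat>_mean`, `<stat>_sd` for each statistic, plus `n`.
#' @export
#' @examples
#' spec <- grid_spec(sample_sizes = 5, block_sizes = 1,
#'                   theta_scenarios = list(0), psi_levels = 0.2,
#'                   n_reps = 3, config = simulation_config(n_genes = 300))
#' summarize_grid(run_grid(spec), group_by = "psi", stats = "alpha_hat")
summarize_grid <- function(records, group_by, stats) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_invalid("`records` must be a nonempty data frame.")
  }
  missing_cols <- setdiff(c(group_by, stats), names(records))
  if (length(missing_cols) > 0L) {
    stop_invalid(paste0("unknown field(s): ", paste(missing_cols, collapse = ", ")))
  }
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(stats),
        list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE)),
        .names = "{.col}_{.fn}"
      ),
      n = dplyr::n(),
      .groups = "drop"
    )
}
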