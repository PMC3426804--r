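#' Measurement-noise parameters for the expression simulator
#'
#' Raw-scale intensities are observed as `Y = S * exp(H) + E`, where the
#' multiplicative log-noise `H` is Normal(0, `mult_sd`^2) and the additive
#' background `E` is Normal(`add_mean`, `add_sd`^2), after which `Y` is
#' clipped below at `floor` so the log2 transform is always defined.
#'
#' @param mult_sd Standard deviation of the multiplicative log-noise
#'   (dimensionless, natural-log scale). Must be `>= 0`.
#' @param add_mean Mean of the additive raw-scale background noise.
#' @param add_sd Standard deviation of the additive background. Must be `>= 0`.
#' @param floor Positive raw-scale clipping constant applied before log2.
#'
#' @return A list of class `"noise_params"`.
#' @export
#' @examples
#' noise_params(mult_sd = 0.2)
noise_params <- function(mult_sd = 0.1, add_mean = 2, add_sd = 1, floor = 1) {
  check_scalar_number(mult_sd, "mult_sd", lower = 0)
  check_scalar_number(add_mean, "add_mean")
  check_scalar_number(add_sd, "add_sd", lower = 0)
  check_scalar_number(floor, "floor")
  if (floor <= 0) stop_invalid("`floor` must be > 0.")
  structure(
    list(mult_sd = mult_sd, add_mean = add_mean, add_sd = add_sd, floor = floor),
    class = "noise_params"
  )
}

#' Configuration for a simulated two-group expression experiment
#'
#' Collects every knob of the clumpy-correlation microarray emulator: the
#' gene and sample counts, the block-structure parameters, the
#' differential-expression injection, and the noise model. An identical
#' configuration (including `seed`) always regenerates a bit-identical
#' dataset.
#'
#' @param n_genes Number of genes `G`.
#' @param n_per_group Number of samples `N` in each of the two groups
#'   (normal and cancer), so the matrix has `2 * N` columns.
#' @param mean_block_size Mean correlated-block size `xi` (`>= 1`). Block
#'   sizes are drawn as `1 + Poisson(xi - 1)`, so `xi = 1` gives independent
#'   genes.
#' @param theta_scenario Fraction `theta` of genes per block assigned a
#'   negative correlation sign: either a fixed value in `[0, 0.5]` or the
#'   string `"tent"` for the random draw `0.5 - |x - 0.5|` with `x`
#'   uniform on (0, 1).
#' @param psi Fraction of transcriptionally active blocks made
#'   differentially expressed, in `[0, 1]`.
#' @param active_fraction Fraction of blocks that are transcriptionally
#'   active, in `[0, 1]`. Inactive blocks have zero raw signal in both
#'   groups; only noise is observed for them.
#' @param de_shape,de_rate Gamma shape and rate for the absolute log2
#'   fold change `|delta|` of genes in differentially expressed blocks.
#'   The defaults (10, 10) give mean `|delta| = 1`, i.e. an average
#'   two-fold change, with a long right tail.
#' @param noise A [noise_params()] object.
#' @param baseline_mean,baseline_sd Normal parameters for per-gene baseline
#'   log2 means of active genes.
#' @param gene_sd_mean Mean of the per-gene biological log2 standard
#'   deviation (drawn from a Gamma distribution with this mean).
#' @param rho_a,rho_b Beta parameters for the per-block within-block
#'   correlation magnitude `rho`.
#' @param seed Integer RNG seed. Per-stage sub-streams are derived from it
#'   deterministically, so e.g. changing `psi` does not perturb the block
#'   layout or the sample-level noise.
#'
#' @return A list of class `"simulation_config"`.
#' @seealso [simulate_experiment()]
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 500, n_per_group = 10, psi = 0.1, seed = 7)
#' exp <- simulate_experiment(cfg)
#' dim(exp$log2)
simulation_config <- function(n_genes = 2000,
                              n_per_group = 25,
                              mean_block_size = 10,
                              theta_scenario = "tent",
                              psi = 0,
                              active_fraction = 0.7,
                              de_shape = 10,
                              de_rate = 10,
                              noise = noise_params(),
                              baseline_mean = 6,
                              baseline_sd = 1.5,
                              gene_sd_mean = 0.5,
                              rho_a = 4,
                              rho_b = 4,
                              seed = 101) {
  check_count(n_genes, "n_genes")
  check_count(n_per_group, "n_per_group")
  check_scalar_number(mean_block_size, "mean_block_size", lower = 1)
  check_theta_scenario(theta_scenario)
  check_scalar_number(psi, "psi", lower = 0, upper = 1)
  check_scalar_number(active_fraction, "active_fraction", lower = 0, upper = 1)
  check_scalar_number(de_shape, "de_shape")
  check_scalar_number(de_rate, "de_rate")
  if (de_shape <= 0 || de_rate <= 0) stop_invalid("`de_shape` and `de_rate` must be > 0.")
  if (!inherits(noise, "noise_params")) stop_invalid("`noise` must be a noise_params() object.")
  check_scalar_number(baseline_mean, "baseline_mean")
  check_scalar_number(baseline_sd, "baseline_sd", lower = 0)
  check_scalar_number(gene_sd_mean, "gene_sd_mean")
  if (gene_sd_mean <= 0) stop_invalid("`gene_sd_mean` must be > 0.")
  check_scalar_number(rho_a, "rho_a")
  check_scalar_number(rho_b, "rho_b")
  if (rho_a <= 0 || rho_b <= 0) stop_invalid("`rho_a` and `rho_b` must be > 0.")
  check_count(seed, "seed", lower = 0L)
  structure(
    list(
      n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
      mean_block_size = mean_block_size, theta_scenario = theta_scenario,
      psi = psi, active_fraction = active_fraction,
      de_shape = de_shape, de_rate = de_rate, noise = noise,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      gene_sd_mean = gene_sd_mean, rho_a = rho_a, rho_b = rho_b,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

check_theta_scenario <- function(scenario) {
  if (is.character(scenario)) {
    if (length(scenario) != 1L || scenario != "tent") {
      stop_invalid('`theta_scenario` must be "tent" or a number in [0, 0.5].')
    }
  } else {
    check_scalar_number(scenario, "theta_scenario", lower = 0, upper = 0.5)
  }
  invisible(scenario)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> G = %d genes x 2N = %d samples\n", x$n_genes, 2L * x$n_per_group
  ))
  cat(sprintf(
    "  mean block size %s, theta = %s, psi = %s, active fraction %s, seed %d\n",
    format(x$mean_block_size),
    if (is.character(x$theta_scenario)) x$theta_scenario else format(x$theta_scenario),
    format(x$psi), format(x$active_fraction), x$seed
  ))
  invisible(x)
}

#' Partition genes into correlated blocks
#'
#' Block sizes are drawn as `1 + Poisson(mean_block_size - 1)` so the mean
#' size is exactly `mean_block_size` and `mean_block_size = 1` forces
#' singleton blocks. The final block is truncated so the sizes sum exactly
#' to `n_genes`.
#'
#' @param n_genes Total number of genes to partition.
#' @param mean_block_size Mean block size `xi`, `>= 1`.
#'
#' @return An integer vector of block sizes summing to `n_genes`.
#' @export
#' @examples
#' set.seed(1)
#' sizes <- partition_blocks(100, 10)
#' sum(sizes)
partition_blocks <- function(n_genes, mean_block_size) {
  n_genes <- check_count(n_genes, "n_genes")
  check_scalar_number(mean_block_size, "mean_block_size", lower = 1)
  if (mean_block_size == 1) {
    return(rep(1L, n_genes))
  }
  sizes <- integer(0)
  total <- 0L
  # expected block count plus slack; loop in chunks until we cover n_genes
  chunk <- max(16L, ceiling(1.5 * n_genes / mean_block_size))
  while (total < n_genes) {
    new <- 1L + rpois(chunk, mean_block_size - 1)
    sizes <- c(sizes, as.integer(new))
    total <- total + sum(new)
  }
  cs <- cumsum(sizes)
  k <- which(cs >= n_genes)[1L]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- n_genes - (cs[k] - sizes[k])
  sizes[sizes > 0L]
}

#' Draw the within-block negative-correlation fraction
#'
#' @param scenario A fixed value in `[0, 0.5]`, or `"tent"` for the random
#'   draw `theta = 0.5 - |x - 0.5|` with `x` uniform on (0, 1), which makes
#'   `theta` uniform on (0, 0.5).
#' @param n Number of draws.
#'
#' @return Numeric vector of length `n` with values in `[0, 0.5]`.
#' @export
#' @examples
#' draw_theta(0.25)
#' set.seed(1); draw_theta("tent", 5)
draw_theta <- function(scenario, n = 1L) {
  check_theta_scenario(scenario)
  n <- check_count(n, "n")
  if (is.character(scenario)) {
    x <- runif(n)
    0.5 - abs(x - 0.5)
  } else {
    rep(as.numeric(scenario), n)
  }
}

#' Within-block correlation matrix with signed one-factor structure
#'
#' Builds the correlation matrix `(1 - rho) I + rho s s'` for a block whose
#' genes carry signs `s` in `{-1, +1}`: off-diagonal entry (i, j) is
#' `rho * s_i * s_j` and the diagonal is 1. The one-factor form is positive
#' semi-definite by construction for any sign pattern.
#'
#' @param size Block size.
#' @param rho Correlation magnitude in `[0, 1]`.
#' @param signs Vector of `+1`/`-1` of length `size`.
#'
#' @return A `size x size` correlation matrix.
#' @export
#' @examples
#' build_block_correlation(3, 0.8, c(1, 1, -1))
build_block_correlation <- function(size, rho, signs) {
  size <- check_count(size, "size")
  check_scalar_number(rho, "rho", lower = 0, upper = 1)
  if (length(signs) != size || !all(signs %in% c(-1, 1))) {
    stop_invalid("`signs` must be a +1/-1 vector of length `size`.")
  }
  cmat <- rho * tcrossprod(signs)
  diag(cmat) <- 1
  cmat
}

# Assemble the per-block layout: sizes, activity, correlation magnitude,
# theta and signs. Consumes RNG; caller controls the stream.
make_blocks <- function(config) {
  sizes <- partition_blocks(config$n_genes, config$mean_block_size)
  n_blocks <- length(sizes)
  n_active <- round_half_up(config$active_fraction * n_blocks)
  active <- rep(FALSE, n_blocks)
  if (n_active > 0) {
    active[sample.int(n_blocks, n_active)] <- TRUE
  }
  rho <- rbeta(n_blocks, config$rho_a, config$rho_b)
  theta <- draw_theta(config$theta_scenario, n_blocks)
  signs <- lapply(seq_len(n_blocks), function(b) {
    s <- rep(1, sizes[b])
    n_neg <- round_half_up(theta[b] * sizes[b])
    if (n_neg > 0) s[sample.int(sizes[b], n_neg)] <- -1
    s
  })
  list(
    sizes = sizes, active = active, rho = rho, theta = theta, signs = signs,
    n_blocks = n_blocks
  )
}

#' Flag differentially expressed blocks and draw per-gene shifts
#'
#' Selects `round(psi * #active)` blocks uniformly at random from the
#' transcriptionally active blocks (rounding half up), and gives every gene
#' in a selected block an absolute log2 shift `|delta| ~ Gamma(de_shape,
#' de_rate)` with an independent fair-coin up/down direction. Inactive
#' blocks are never selected.
#'
#' @param sizes Integer vector of block sizes.
#' @param active Logical vector flagging transcriptionally active blocks.
#' @param psi Fraction of active blocks to make differentially expressed.
#' @param de_shape,de_rate Gamma parameters of `|delta|`.
#'
#' @return A list with `de` (logical per block) and `deltas` (list of
#'   per-gene signed shifts, zeros for non-DE blocks).
#' @export
#' @examples
#' set.seed(1)
#' inject_de(c(3L, 2L, 4L), c(TRUE, TRUE, FALSE), psi = 0.5)
inject_de <- function(sizes, active, psi, de_shape = 10, de_rate = 10) {
  check_scalar_number(psi, "psi", lower = 0, upper = 1)
  if (length(sizes) != length(active)) {
    stop_invalid("`sizes` and `active` must have the same length.")
  }
  n_blocks <- length(sizes)
  de <- rep(FALSE, n_blocks)
  deltas <- lapply(sizes, function(s) numeric(s))
  if (psi > 0) {
    act_idx <- which(active)
    if (length(act_idx) == 0L) {
      abort("psi > 0 but no block is transcriptionally active.",
            class = "bumfdr_degenerate_input")
    }
    n_de <- round_half_up(psi * length(act_idx))
    if (n_de > 0) {
      chosen <- act_idx[sample.int(length(act_idx), n_de)]
      de[chosen] <- TRUE
      for (b in chosen) {
        mag <- rgamma(sizes[b], shape = de_shape, rate = de_rate)
        dir <- ifelse(runif(sizes[b]) < 0.5, -1, 1)
        deltas[[b]] <- mag * dir
      }
    }
  }
  list(de = de, deltas = deltas)
}

#' Apply multiplicative and additive measurement noise
#'
#' Observes `Y = S * exp(H) + E` with `H ~ Normal(0, mult_sd^2)` and
#' `E ~ Normal(add_mean, add_sd^2)` elementwise, then clips below at
#' `noise$floor` so the subsequent log2 transform is defined.
#'
#' @param raw_signal Nonnegative raw-scale matrix `S`.
#' @param noise A [noise_params()] object.
#'
#' @return Matrix of observed raw intensities, all `>= noise$floor`.
#' @export
#' @examples
#' set.seed(1)
#' apply_noise(matrix(2^6, 2, 2), noise_params())
apply_noise <- function(raw_signal, noise) {
  if (!inherits(noise, "noise_params")) stop_invalid("`noise` must be a noise_params() object.")
  if (any(raw_signal < 0)) stop_invalid("`raw_signal` entries must be >= 0.")
  n <- length(raw_signal)
  h <- if (noise$mult_sd > 0) rnorm(n, 0, noise$mult_sd) else numeric(n)
  e <- if (noise$add_sd > 0) rnorm(n, noise$add_mean, noise$add_sd) else rep(noise$add_mean, n)
  y <- raw_signal * exp(h) + e
  y[y < noise$floor] <- noise$floor
  dim(y) <- dim(raw_signal)
  y
}

#' Simulate a two-group block-correlated expression experiment
#'
#' Generates a log2 expression matrix for `G` genes and `2N` samples
#' (normal and cancer) with known differential-expression ground truth.
#' The pipeline: genes are partitioned into blocks ([partition_blocks()]);
#' a fraction of blocks is transcriptionally active; each block receives a
#' correlation magnitude `rho ~ Beta(rho_a, rho_b)`, a negative-sign
#' fraction `theta` ([draw_theta()]) and per-gene signs; active genes get
#' baseline log2 means and per-gene biological standard deviations;
#' `psi` of the active blocks is made differentially expressed
#' ([inject_de()]), shifting cancer-group means by the signed `delta`;
#' per-sample expression is drawn blockwise from a multivariate normal
#' with the signed one-factor covariance ([build_block_correlation()]);
#' raw signal is `2^X` for active genes and 0 for inactive ones (inactive
#' blocks stay inactive in both groups); measurement noise is applied
#' ([apply_noise()]) and the result is returned on the log2 scale.
#'
#' Each pipeline stage runs on its own RNG sub-stream derived from
#' `config$seed`, so changing `psi` leaves the block layout, baselines and
#' sample-level noise untouched.
#'
#' @param config A [simulation_config()].
#'
#' @return An object of class `"expression_experiment"`: a list with
#'   `log2` (G x 2N matrix, genes in rows), `labels` (tibble: sample_id,
#'   group), `truth` (tibble: gene_id, block_id, active, is_de, delta) and
#'   `config`.
#' @export
#' @examples
#' exp <- simulate_experiment(simulation_config(n_genes = 300, n_per_group = 5, seed = 1))
#' exp
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_invalid("`config` must be a simulation_config() object.")
  }
  g <- config$n_genes
  n <- config$n_per_group
  n_cols <- 2L * n

  blocks <- with_stage_seed(mix_seed(config$seed, 1L), make_blocks(config))
  base <- with_stage_seed(mix_seed(config$seed, 2L), list(
    mu = rnorm(g, config$baseline_mean, config$baseline_sd),
    sigma = rgamma(g, shape = 4, rate = 4 / config$gene_sd_mean)
  ))
  de <- with_stage_seed(
    mix_seed(config$seed, 3L),
    inject_de(blocks$sizes, blocks$active, config$psi, config$de_shape, config$de_rate)
  )
  draws <- with_stage_seed(mix_seed(config$seed, 4L), list(
    eps = matrix(rnorm(g * n_cols), g, n_cols),
    fac = matrix(rnorm(blocks$n_blocks * n_cols), blocks$n_blocks, n_cols)
  ))

  block_id <- rep.int(seq_len(blocks$n_blocks), blocks$sizes)
  gene_active <- blocks$active[block_id]
  delta <- unlist(de$deltas, use.names = FALSE)
  gene_signs <- unlist(blocks$signs, use.names = FALSE)
  gene_rho <- blocks$rho[block_id]

  # signed one-factor draw: X_g = mean_g + sigma_g * (sqrt(1-rho) eps_g
  #   + sqrt(rho) s_g f_block), exactly the covariance sigma_g sigma_h rho s_g s_h
  is_cancer <- rep(c(FALSE, TRUE), each = n)
  mean_mat <- matrix(base$mu, g, n_cols)
  mean_mat[, is_cancer] <- mean_mat[, is_cancer] + delta
  x <- mean_mat + base$sigma *
    (sqrt(1 - gene_rho) * draws$eps +
       sqrt(gene_rho) * gene_signs * draws$fac[block_id, , drop = FALSE])

  raw <- 2^x
  raw[!gene_active, ] <- 0
  observed <- with_stage_seed(
    mix_seed(config$seed, 5L),
    apply_noise(raw, config$noise)
  )
  log2_mat <- log2(observed)

  gene_ids <- sprintf("g%0*d", max(4L, nchar(g)), seq_len(g))
  sample_ids <- c(
    sprintf("n%03d", seq_len(n)),
    sprintf("c%03d", seq_len(n))
  )
  dimnames(log2_mat) <- list(gene_ids, sample_ids)

  truth <- tibble(
    gene_id = gene_ids,
    block_id = block_id,
    active = gene_active,
    is_de = de$de[block_id],
    delta = delta
  )
  labels <- tibble(
    sample_id = sample_ids,
    group = factor(rep(c("normal", "cancer"), each = n), levels = c("normal", "cancer"))
  )
  structure(
    list(log2 = log2_mat, labels = labels, truth = truth, config = config),
    class = "expression_experiment"
  )
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf(
    "<expression_experiment> %d genes x %d samples (%d per group)\n",
    nrow(x$log2), ncol(x$log2), x$config$n_per_group
  ))
  cat(sprintf(
    "  %d active genes, %d differentially expressed (psi = %s)\n",
    sum(x$truth$active), sum(x$truth$is_de), format(x$config$psi)
  ))
  invisible(x)
}

#' @describeIn simulate_experiment Ground-truth table of a simulated
#'   experiment as a tibble (one row per gene).
#' @param x An `expression_experiment`.
#' @param ... Unused.
#' @export
tidy.expression_experiment <- function(x, ...) {
  x$truth
}
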