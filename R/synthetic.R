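# Synthetic count-matrix generator with the two-regime noise structure.
#
# The default mechanism is a Poisson-gamma hierarchy: each replicate's
# count is Poisson(Lambda) with Lambda ~ Gamma(shape = k, scale = mu/k),
# giving Var = mu + mu^2/k. At small mu the Poisson term dominates
# (variance ~ mean); at large mu the gamma term dominates (variance ~
# mean^2 / k), so one mechanism produces both noise regimes observed in
# replicate sequencing data.

#' Configuration for the synthetic count generator
#'
#' @param n_genes number of genes.
#' @param n_reps_per_group replicates per group (default 6, the typical
#'   technical-replicate design).
#' @param n_groups 1 or 2.
#' @param mean_grid per-gene baseline means: a numeric vector of length
#'   `n_genes` used as-is, or a length-2 numeric `c(min, max)` from which
#'   means are drawn log-uniformly. Default `c(0.5, 1e4)` spans both
#'   regimes.
#' @param gamma_shape dispersion shape `k` (default 10); the high-read
#'   squared coefficient of variation is `1/k`.
#' @param noise_model `"poisson_gamma"` (default, hierarchical),
#'   `"pure_gamma_rounded"` (gamma draws rounded half-to-even, for testing
#'   the gamma branch without Poisson contamination), or `"pure_poisson"`.
#' @param de_fraction fraction of genes differentially expressed between
#'   the two groups (requires `n_groups = 2` when positive).
#' @param fold_changes fold change(s) applied to the second group's mean of
#'   DE genes: a scalar, or a vector sampled uniformly per DE gene.
#' @param seed optional integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes, n_reps_per_group = 6L, n_groups = 2L,
                             mean_grid = c(0.5, 1e4), gamma_shape = 10,
                             noise_model = c("poisson_gamma",
                                             "pure_gamma_rounded",
                                             "pure_poisson"),
                             de_fraction = 0, fold_changes = 1,
                             seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_genes >= 1, n_reps_per_group >= 1, n_groups %in% c(1L, 2L),
            gamma_shape > 0, de_fraction >= 0, de_fraction <= 1,
            all(fold_changes > 0), is.numeric(mean_grid), all(mean_grid > 0))
  if (de_fraction > 0 && n_groups != 2L)
    stop("de_fraction > 0 requires n_groups = 2")
  if (!(length(mean_grid) %in% c(2L, n_genes)))
    stop("'mean_grid' must have length n_genes (explicit means) or 2 (range)")
  structure(list(n_genes = as.integer(n_genes),
                 n_reps_per_group = as.integer(n_reps_per_group),
                 n_groups = as.integer(n_groups), mean_grid = mean_grid,
                 gamma_shape = gamma_shape, noise_model = noise_model,
                 de_fraction = de_fraction, fold_changes = fold_changes,
                 seed = seed),
            class = "synthetic_config")
}

draw_noise <- function(mu, n_reps, cfg) {
  # mu: per-gene means; returns genes x n_reps matrix
  N <- length(mu) * n_reps
  mu_rep <- rep(mu, times = n_reps)
  y <- switch(cfg$noise_model,
              poisson_gamma = rpois(N, rgamma(N, shape = cfg$gamma_shape,
                                              scale = mu_rep / cfg$gamma_shape)),
              pure_gamma_rounded = round(rgamma(N, shape = cfg$gamma_shape,
                                                scale = mu_rep / cfg$gamma_shape)),
              pure_poisson = rpois(N, mu_rep))
  matrix(as.numeric(y), nrow = length(mu), ncol = n_reps)
}

#' Generate a synthetic count matrix with ground truth
#'
#' Draws a genes-by-samples matrix under [synthetic_config()]'s noise model
#' and, for two-group designs, applies the configured fold changes to a
#' random subset of genes (`de_fraction`). The accompanying truth table
#' records the exact group means and DE status of every gene, so test
#' procedures can be scored against ground truth.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `synthetic_data`: `counts` (a [count_matrix()],
#'   groups `"A"`/`"B"`) and `truth` (data.frame with `gene_id`, `mean_A`,
#'   `mean_B`, `is_de`, `true_fold_change`).
#' @examples
#' sim <- generate_matrix(synthetic_config(n_genes = 50, de_fraction = 0.2,
#'                                         fold_changes = 4, seed = 7))
#' table(sim$truth$is_de)
#' @export
generate_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_genes
  # length-n_genes grid = explicit means (takes precedence at n_genes == 2);
  # length-2 grid = log-uniform range
  mu <- if (length(cfg$mean_grid) == n) cfg$mean_grid else
    exp(runif(n, log(cfg$mean_grid[1L]), log(cfg$mean_grid[2L])))
  gene_ids <- sprintf("gene_%05d", seq_len(n))
  n_de <- round(cfg$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer()
  fc <- rep(1, n)
  if (n_de > 0)
    fc[de_idx] <- if (length(cfg$fold_changes) == 1L) cfg$fold_changes else
      sample(cfg$fold_changes, n_de, replace = TRUE)
  mu_a <- mu
  mu_b <- mu * fc
  R <- cfg$n_reps_per_group
  ya <- draw_noise(mu_a, R, cfg)
  if (cfg$n_groups == 2L) {
    yb <- draw_noise(mu_b, R, cfg)
    v <- cbind(ya, yb)
    colnames(v) <- c(paste0("A_rep", seq_len(R)), paste0("B_rep", seq_len(R)))
    groups <- rep(c("A", "B"), each = R)
  } else {
    v <- ya
    colnames(v) <- paste0("A_rep", seq_len(R))
    groups <- rep("A", R)
  }
  rownames(v) <- gene_ids
  truth <- data.frame(gene_id = gene_ids, mean_A = mu_a, mean_B = mu_b,
                      is_de = seq_len(n) %in% de_idx, true_fold_change = fc,
                      stringsAsFactors = FALSE)
  structure(list(counts = count_matrix(v, groups = groups), truth = truth),
            class = "synthetic_data")
}

#' @export
print.synthetic_data <- function(x, ...) {
  cat("synthetic_data: ")
  print(x$counts)
  cat("DE genes:", sum(x$truth$is_de), "of", nrow(x$truth), "\n")
  invisible(x)
}

#' Generate replicate libraries through the PCR mechanism
#'
#' A mechanism-level alternative to [generate_matrix()]: each replicate
#' column is an independent [simulate_sequencing_library()] run — the same
#' starting molecule abundances amplified through the branching process
#' and (optionally) read-sampled to a fixed depth. Noise across replicates
#' is therefore pure amplification + counting noise.
#'
#' @param abundances per-gene starting molecule counts (integers >= 1).
#' @param cycles,efficiency branching-process parameters.
#' @param depth reads per library, or `NULL` for raw amplified counts.
#' @param n_reps number of replicate libraries (default 6).
#' @param seed optional integer seed.
#' @return A [count_matrix()] with a single group `"all"`.
#' @export
generate_from_pcr <- function(abundances, cycles, efficiency, depth = NULL,
                              n_reps = 6L, seed = NULL) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  nm <- names(abundances)
  if (is.null(nm)) nm <- paste0("gene_", seq_along(abundances))
  v <- vapply(seq_len(n_reps), function(r)
    simulate_sequencing_library(abundances, cycles, efficiency, depth = depth),
    numeric(length(abundances)))
  dimnames(v) <- list(nm, paste0("rep", seq_len(n_reps)))
  count_matrix(v)
}
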