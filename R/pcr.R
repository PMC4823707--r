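# Galton-Watson model of PCR amplification.
#
# Each template molecule independently doubles with probability p
# (the amplification efficiency) at every cycle. Starting from m molecules
# the count after n cycles is a branching process; per molecule its
# normalized limit is approximately exponential, and summing m independent
# lineages gives an approximately gamma-distributed final count with shape
# growing in m. This is the mechanistic origin of the gamma noise regime
# of sequencing counts.
#
# Simulation uses binomial thinning per cycle (count <- count +
# Binomial(count, p)), which is equivalent in distribution to tracking
# individual lineages but costs O(cycles) per replicate.

#' PCR amplification configuration
#'
#' @param initial_molecules integer >= 1, starting template copies `m`.
#' @param cycles integer >= 0, number of PCR cycles `n`.
#' @param efficiency per-cycle doubling probability `p` in \[0, 1\],
#'   constant across cycles and molecules (no plateau-phase decay).
#' @param n_replicates number of independent amplification replicates.
#' @param seed optional integer seed; all replicate draws derive from it.
#' @return An object of class `pcr_config`.
#' @export
pcr_config <- function(initial_molecules, cycles, efficiency,
                       n_replicates = 1L, seed = NULL) {
  stopifnot(length(initial_molecules) == 1L,
            initial_molecules >= 1, initial_molecules == round(initial_molecules),
            length(cycles) == 1L, cycles >= 0, cycles == round(cycles),
            length(efficiency) == 1L, efficiency >= 0, efficiency <= 1,
            length(n_replicates) == 1L, n_replicates >= 1,
            n_replicates == round(n_replicates))
  structure(list(initial_molecules = as.integer(initial_molecules),
                 cycles = as.integer(cycles), efficiency = efficiency,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "pcr_config")
}

#' @export
print.pcr_config <- function(x, ...) {
  cat("pcr_config: m =", x$initial_molecules, ", cycles =", x$cycles,
      ", efficiency =", x$efficiency, ", replicates =", x$n_replicates, "\n")
  invisible(x)
}

amplify_counts <- function(counts, cycles, efficiency) {
  for (i in seq_len(cycles))
    counts <- counts + rbinom(length(counts), counts, efficiency)
  counts
}

#' Simulate PCR amplification replicates
#'
#' Runs the branching process for each replicate: the molecule count starts
#' at `m` and each cycle adds `Binomial(count, p)` new copies. Every final
#' count lies in `[m, m * 2^cycles]`.
#'
#' @param cfg a [pcr_config()].
#' @return An object of class `pcr_sim`: list with `final_counts` (length
#'   `n_replicates`) and `config`.
#' @examples
#' sim <- simulate_amplification(pcr_config(5, 10, 1))
#' sim$final_counts  # deterministic doubling: 5 * 2^10
#' @export
simulate_amplification <- function(cfg) {
  stopifnot(inherits(cfg, "pcr_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  counts <- amplify_counts(rep(as.numeric(cfg$initial_molecules),
                               cfg$n_replicates),
                           cfg$cycles, cfg$efficiency)
  structure(list(final_counts = counts, config = cfg), class = "pcr_sim")
}

#' @export
print.pcr_sim <- function(x, ...) {
  print(x$config)
  cat("final counts: n =", length(x$final_counts),
      ", mean =", format(mean(x$final_counts), digits = 6),
      ", var =", format(var(x$final_counts), digits = 6), "\n")
  invisible(x)
}

#' @export
summary.pcr_sim <- function(object, ...) {
  ey <- expected_yield(object$config$initial_molecules, object$config$cycles,
                       object$config$efficiency)
  list(empirical_mean = mean(object$final_counts),
       empirical_variance = var(object$final_counts),
       analytic_mean = ey[["mean"]], analytic_variance = ey[["variance"]])
}

#' Analytic mean and variance of the amplified count
#'
#' For the branching process with offspring mean `1 + p` per cycle:
#' `mean = m (1+p)^n` and
#' `variance = m p(1-p) (1+p)^(n-1) ((1+p)^n - 1) / p`
#' (zero for `p` 0 or 1, where amplification is deterministic).
#'
#' @param m initial molecules (>= 1).
#' @param n cycles (>= 0).
#' @param p efficiency in \[0, 1\].
#' @return Named numeric vector `c(mean = ..., variance = ...)`.
#' @examples
#' expected_yield(1, 2, 0.5)  # mean 2.25, variance 0.9375
#' @export
expected_yield <- function(m, n, p) {
  stopifnot(m >= 1, n >= 0, p >= 0, p <= 1)
  mu <- 1 + p
  mean <- m * mu^n
  variance <- if (p == 0 || p == 1 || n == 0) 0 else
    m * p * (1 - p) * mu^(n - 1) * (mu^n - 1) / (mu - 1)
  c(mean = mean, variance = variance)
}

#' Simulate a sequencing library from per-gene molecule counts
#'
#' Amplifies each gene's starting molecules independently through the
#' branching process, then (optionally) samples `depth` total reads
#' multinomially with probabilities proportional to the amplified counts —
#' the counting stage of sequencing. Without `depth` the amplified counts
#' themselves are returned.
#'
#' @param abundances vector of starting molecule counts per gene (>= 1,
#'   integers).
#' @param cycles,efficiency branching-process parameters as in
#'   [pcr_config()].
#' @param depth total reads to draw, or `NULL` to return amplified counts.
#' @param seed optional integer seed.
#' @return Named numeric vector of per-gene counts (names from
#'   `abundances` if present, else `gene_1 ...`).
#' @export
simulate_sequencing_library <- function(abundances, cycles, efficiency,
                                        depth = NULL, seed = NULL) {
  abundances <- as.numeric(abundances)
  stopifnot(all(abundances >= 1), all(abundances == round(abundances)))
  if (!is.null(seed)) set.seed(seed)
  nm <- names(abundances)
  if (is.null(nm)) nm <- paste0("gene_", seq_along(abundances))
  amplified <- amplify_counts(abundances, cycles, efficiency)
  out <- if (is.null(depth)) amplified else {
    stopifnot(depth >= 0, depth == round(depth))
    rmultinom(1L, depth, amplified)[, 1L]
  }
  setNames(as.numeric(out), nm)
}

#' Gamma-convergence report for amplified counts
#'
#' Quantifies how well the branching-process final counts are approximated
#' by a gamma distribution: fits a gamma by the method of moments, runs the
#' plug-in KS test ([ks_gof_gamma()]) against it, and compares empirical
#' with analytic moments. The gamma approximation is asymptotic in cycle
#' number; this report measures its adequacy at the requested parameters
#' instead of assuming it.
#'
#' @param cfg a [pcr_config()] with `n_replicates >= 1000`.
#' @return A list of class `pcr_gamma_report`: `degenerate` flag,
#'   `gamma_fit` (shape/scale or NULL), `ks` (htest or NULL),
#'   `empirical_mean`, `empirical_variance`, `analytic_mean`,
#'   `analytic_variance`, `config`.
#' @export
gamma_convergence_report <- function(cfg) {
  stopifnot(inherits(cfg, "pcr_config"))
  if (cfg$n_replicates < 1000L)
    stop("need n_replicates >= 1000 for a convergence report")
  sim <- simulate_amplification(cfg)
  ey <- expected_yield(cfg$initial_molecules, cfg$cycles, cfg$efficiency)
  x <- sim$final_counts
  degenerate <- cfg$efficiency %in% c(0, 1) || cfg$cycles == 0L || var(x) == 0
  rep <- list(degenerate = degenerate, gamma_fit = NULL, ks = NULL,
              empirical_mean = mean(x), empirical_variance = var(x),
              analytic_mean = ey[["mean"]], analytic_variance = ey[["variance"]],
              config = cfg)
  if (!degenerate) {
    rep$gamma_fit <- fit_gamma_moments(x)
    rep$ks <- ks_gof_gamma(x)
  }
  structure(rep, class = "pcr_gamma_report")
}

#' @export
print.pcr_gamma_report <- function(x, ...) {
  print(x$config)
  if (x$degenerate) {
    cat("degenerate amplification (zero variance): no gamma fit\n")
  } else {
    cat(sprintf("gamma fit: shape = %.4g, scale = %.4g\n",
                x$gamma_fit$shape, x$gamma_fit$scale))
    cat(sprintf("KS vs fitted gamma: D = %.4g, p = %.4g\n",
                unname(x$ks$statistic), x$ks$p.value))
  }
  cat(sprintf("mean: empirical %.6g vs analytic %.6g\n",
              x$empirical_mean, x$analytic_mean))
  cat(sprintf("variance: empirical %.6g vs analytic %.6g\n",
              x$empirical_variance, x$analytic_variance))
  invisible(x)
}
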