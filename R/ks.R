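# One-sample Kolmogorov-Smirnov machinery with plug-in parameters.
#
# D is computed from the order statistics as
#   D = max_i max( i/n - F(x_(i)),  F(x_(i)) - (i-1)/n ),
# i.e. both one-sided gaps are evaluated at every support point. For a
# discrete model CDF this is the standard (continuous-sample) convention;
# ties make the statistic larger and the test conservative. The p-value is
# the asymptotic Kolmogorov tail evaluated at sqrt(n) * D; combined with
# plug-in parameter estimation it is conservative, which is documented
# behaviour, not corrected for.

ks_statistic <- function(x, cdf) {
  n <- length(x)
  Fx <- cdf(sort(x))
  i <- seq_len(n)
  max(i / n - Fx, Fx - (i - 1) / n)
}

ks_asymptotic_p <- function(stat, n) {
  t <- sqrt(n) * stat
  if (t <= 0) return(1)
  k <- seq_len(101L)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

ks_htest <- function(D, p, method, data.name, ...) {
  structure(c(list(statistic = c(D = D), p.value = p, method = method,
                   data.name = data.name, alternative = "two-sided"),
              list(...)),
            class = "htest")
}

#' KS goodness-of-fit test against a plug-in Poisson
#'
#' Tests whether replicate counts for one gene are consistent with a
#' Poisson distribution whose rate is the sample mean (plug-in estimate).
#' Low-read genes, where sequencing noise is dominated by counting
#' statistics, should pass; high-read genes with gamma-inflated variance
#' should fail.
#'
#' @param replicates vector of >= 3 non-negative integer counts.
#' @return An object of class `htest` with the sup-distance `D`, the
#'   asymptotic p-value, and `lambda_hat`, the plug-in rate.
#' @examples
#' ks_gof_poisson(c(4, 6, 5, 3, 7, 5))
#' @export
ks_gof_poisson <- function(replicates) {
  x <- as.numeric(replicates)
  if (length(x) < 3L) stop("need >= 3 replicate values")
  if (any(x < 0) || any(x != round(x)))
    stop("Poisson goodness-of-fit requires non-negative integer counts")
  lambda <- mean(x)
  D <- ks_statistic(x, function(q) ppois(q, lambda))
  ks_htest(D, ks_asymptotic_p(D, length(x)),
           "One-sample KS test, plug-in Poisson",
           deparse(substitute(replicates)), lambda_hat = lambda)
}

#' KS goodness-of-fit test against a plug-in gamma
#'
#' Tests whether replicate values for one gene are consistent with a gamma
#' distribution whose shape and scale come from the method-of-moments fit
#' ([fit_gamma_moments()]). High-read genes, whose noise is dominated by
#' stochastic PCR amplification, should pass. Values equal to zero
#' contribute model CDF 0.
#'
#' @param replicates vector of >= 3 non-negative values with positive
#'   sample variance. Zero sample variance yields `NA` with a warning (the
#'   gamma fit is degenerate) so that whole-matrix scans never abort.
#' @return An object of class `htest` with `D`, the asymptotic p-value and
#'   the fitted `gamma_params`; `D` and the p-value are `NA` for degenerate
#'   input.
#' @export
ks_gof_gamma <- function(replicates) {
  x <- as.numeric(replicates)
  if (length(x) < 3L) stop("need >= 3 replicate values")
  if (any(x < 0)) stop("negative replicate value")
  dn <- deparse(substitute(replicates))
  if (var(x) <= 0 || mean(x) <= 0) {
    warning("zero sample variance or mean: gamma fit degenerate, returning NA")
    return(ks_htest(NA_real_, NA_real_,
                    "One-sample KS test, plug-in gamma (degenerate)", dn,
                    gamma_params = NULL))
  }
  gp <- fit_gamma_moments(x)
  D <- ks_statistic(x, function(q) pgamma(q, shape = gp$shape, scale = gp$scale))
  ks_htest(D, ks_asymptotic_p(D, length(x)),
           "One-sample KS test, plug-in gamma", dn, gamma_params = gp)
}

#' Goodness-of-fit scan over a count matrix
#'
#' Runs [ks_gof_poisson()] and [ks_gof_gamma()] for every gene in every
#' group and collects the plug-in parameters and both p-values. The result
#' is the per-gene regime picture: plotted against the log mean, Poisson
#' p-values are uniform for low-read genes and collapse toward zero for
#' high-read genes, while gamma p-values stay uniform for high-read genes.
#'
#' Non-integer inputs (e.g. reads-per-million) set the Poisson p-value to
#' `NA` with a single warning; constant genes set the gamma p-value to
#' `NA`. The scan itself never aborts.
#'
#' @param m a [count_matrix()]; every group needs >= 3 replicates.
#' @return A data.frame of class `gof_scan` with columns `gene_id`,
#'   `group`, `mean`, `lambda_hat`, `shape`, `scale`, `D_poisson`,
#'   `p_poisson`, `D_gamma`, `p_gamma`.
#' @export
gof_scan <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  rows <- list()
  warned_nonint <- FALSE
  for (g in levels(m$groups)) {
    cols <- group_cols(m, g)
    if (length(cols) < 3L)
      stop("group '", g, "' has < 3 replicates; KS tests need >= 3")
    v <- m$values[, cols, drop = FALSE]
    n_g <- nrow(v)
    if (n_g == 0L) next
    res <- data.frame(gene_id = rownames(v), group = g, mean = rowMeans(v),
                      lambda_hat = NA_real_, shape = NA_real_,
                      scale = NA_real_, D_poisson = NA_real_,
                      p_poisson = NA_real_, D_gamma = NA_real_,
                      p_gamma = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(n_g)) {
      x <- v[i, ]
      if (all(x == round(x))) {
        kp <- ks_gof_poisson(x)
        res$lambda_hat[i] <- kp$lambda_hat
        res$D_poisson[i] <- unname(kp$statistic)
        res$p_poisson[i] <- kp$p.value
      } else if (!warned_nonint) {
        warning("non-integer values: Poisson p-values set to NA")
        warned_nonint <- TRUE
      }
      if (var(x) > 0 && mean(x) > 0) {
        kg <- ks_gof_gamma(x)
        res$shape[i] <- kg$gamma_params$shape
        res$scale[i] <- kg$gamma_params$scale
        res$D_gamma[i] <- unname(kg$statistic)
        res$p_gamma[i] <- kg$p.value
      }
    }
    rows[[g]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), group = character(), mean = numeric(),
               lambda_hat = numeric(), shape = numeric(), scale = numeric(),
               D_poisson = numeric(), p_poisson = numeric(),
               D_gamma = numeric(), p_gamma = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gof_scan", "data.frame")
  out
}

#' Plot a goodness-of-fit scan
#'
#' Per-gene KS p-values against the log10 mean: Poisson in blue, gamma in
#' red.
#'
#' @param x a [gof_scan()] result.
#' @param ... passed to [plot()].
#' @export
plot.gof_scan <- function(x, ...) {
  plot(log10(x$mean + 1), x$p_poisson, col = "blue", pch = 20,
       xlab = "log10(mean + 1)", ylab = "KS p-value", ylim = c(0, 1), ...)
  points(log10(x$mean + 1), x$p_gamma, col = "red", pch = 20)
  legend("topright", legend = c("Poisson", "gamma"), col = c("blue", "red"),
         pch = 20, bty = "n")
  invisible(x)
}
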