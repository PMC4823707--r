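#' Per-gene moments across replicates
#'
#' For each gene, the sample mean and unbiased sample variance (denominator
#' n-1) of its counts across the replicate libraries of a group. The
#' mean-variance relationship of these moments is the basic noise
#' diagnostic: variance ~ mean indicates Poisson noise, variance ~ mean^2
#' indicates gamma noise.
#'
#' @param m a [count_matrix()].
#' @param group a group name present in `sample_groups(m)`, or `NULL` for
#'   all groups (results stacked).
#' @return A data.frame with columns `gene_id`, `group`, `n_reps`, `mean`,
#'   `variance`.
#' @examples
#' sim <- generate_matrix(synthetic_config(n_genes = 10, seed = 1))
#' head(gene_moments(sim$counts, "A"))
#' @export
gene_moments <- function(m, group = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  grps <- if (is.null(group)) levels(m$groups) else group
  out <- lapply(grps, function(g) {
    cols <- group_cols(m, g)
    if (length(cols) == 0L) stop("unknown group: ", g)
    if (length(cols) < 2L)
      stop("group '", g, "' has ", length(cols),
           " sample(s); >= 2 replicates required for variance")
    v <- m$values[, cols, drop = FALSE]
    mu <- rowMeans(v)
    s2 <- rowSums((v - mu)^2) / (ncol(v) - 1L)
    data.frame(gene_id = rownames(v), group = g, n_reps = ncol(v),
               mean = unname(mu), variance = unname(s2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit the log-log mean-variance line
#'
#' Ordinary least squares fit of `log10(variance + 1)` on `log10(mean + 1)`
#' over the genes whose mean exceeds `mean_threshold`. A slope near 1 is
#' the Poisson signature (variance equals mean); a slope near 2 is the
#' gamma signature (variance proportional to squared mean). The +1 offsets
#' keep zero-mean and zero-variance genes on the plot.
#'
#' @param moments a data.frame from [gene_moments()].
#' @param mean_threshold fit only genes with `mean > mean_threshold`
#'   (default 10, the high-read regime).
#' @return An object of class `mv_fit` with elements `slope`, `intercept`,
#'   `n_genes_used`, `mean_threshold_used`, and the underlying `lm` fit.
#' @export
fit_mean_variance_line <- function(moments, mean_threshold = 10) {
  stopifnot(is.data.frame(moments),
            all(c("mean", "variance") %in% names(moments)))
  sub <- moments[moments$mean > mean_threshold, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need >= 3 genes with mean > ", mean_threshold,
         " to fit the mean-variance line (got ", nrow(sub), ")")
  fit <- lm(log10(variance + 1) ~ log10(mean + 1), data = sub)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 n_genes_used = nrow(sub),
                 mean_threshold_used = mean_threshold,
                 fit = fit),
            class = "mv_fit")
}

#' @export
print.mv_fit <- function(x, ...) {
  cat("log-log mean-variance fit (", x$n_genes_used, " genes with mean > ",
      x$mean_threshold_used, ")\n", sep = "")
  cat(sprintf("  log10(var + 1) = %.4f + %.4f * log10(mean + 1)\n",
              x$intercept, x$slope))
  invisible(x)
}

#' @export
coef.mv_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Classify genes into read regimes
#'
#' A gene is `high_read` iff its mean strictly exceeds `mean_threshold`,
#' otherwise `low_read`. Low-read genes show Poisson-like noise; high-read
#' genes show gamma-like noise.
#'
#' @param mean numeric vector of per-gene means (e.g. column `mean` of
#'   [gene_moments()]).
#' @param mean_threshold regime boundary (default 10).
#' @return A factor with levels `low_read`, `high_read`.
#' @export
classify_regime <- function(mean, mean_threshold = 10) {
  factor(ifelse(mean > mean_threshold, "high_read", "low_read"),
         levels = c("low_read", "high_read"))
}

#' Method-of-moments gamma fit
#'
#' Closed-form estimates `shape = mean^2 / variance` and
#' `scale = variance / mean` from a vector of replicate values; stable even
#' at the small replicate numbers (n = 6) typical of technical-replicate
#' designs. By construction `shape * scale` equals the sample mean and
#' `shape * scale^2` the sample variance. Maximum likelihood is available
#' as an opt-in alternative.
#'
#' @param replicates numeric vector (length >= 2, non-negative, positive
#'   mean, positive sample variance).
#' @param method `"moments"` (default) or `"mle"` (Newton iterations on the
#'   gamma log-likelihood, started from the moment estimate).
#' @return A list with elements `shape` and `scale`.
#' @export
fit_gamma_moments <- function(replicates, method = c("moments", "mle")) {
  method <- match.arg(method)
  x <- as.numeric(replicates)
  if (length(x) < 2L) stop("need >= 2 replicate values")
  if (any(x < 0)) stop("negative replicate value")
  mu <- mean(x)
  if (mu <= 0) stop("zero mean: gamma fit undefined")
  s2 <- var(x)
  if (s2 <= 0) stop("degenerate fit: zero sample variance")
  shape <- mu^2 / s2
  scale <- s2 / mu
  if (method == "mle") {
    if (any(x <= 0)) stop("maximum likelihood requires strictly positive values")
    # Newton on the profile likelihood in log(shape); scale = mu / shape
    s <- log(mu) - mean(log(x))
    k <- shape
    for (i in 1:50) {
      f <- log(k) - digamma(k) - s
      fp <- 1 / k - trigamma(k)
      step <- f / fp
      k_new <- k - step
      if (k_new <= 0) k_new <- k / 2
      if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
      k <- k_new
    }
    shape <- k
    scale <- mu / k
  }
  list(shape = shape, scale = scale)
}
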