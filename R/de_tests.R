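# Two-group differential expression tests matched to the noise regimes.
#
# Both GLM tests use the identity link, so the group effect is the raw
# difference of mean counts. For the saturated two-group model the MLE
# fitted means equal the sample means under either family, which gives the
# Wald statistics in closed form:
#   Poisson:  z = (mu1 - mu0) / sqrt(mu0/n0 + mu1/n1),          N(0,1) ref
#   gamma:    t = (mu1 - mu0) / sqrt(phi (mu0^2/n0 + mu1^2/n1)), t_{N-2} ref
# with phi the Pearson dispersion (gamma variance function V(mu) = mu^2).
# These agree with an iteratively reweighted glm() fit to rounding error;
# the closed forms are exact, not approximations.

de_result <- function(mean_g0, mean_g1, method, statistic, df, dispersion,
                      p_value) {
  lr <- if (mean_g0 > 0 && mean_g1 > 0) log2(mean_g1 / mean_g0) else NA_real_
  structure(list(estimate = c(mean_g0 = mean_g0, mean_g1 = mean_g1),
                 log2_ratio = lr, method = method,
                 statistic = c(statistic = statistic),
                 parameter = c(df = df), dispersion = dispersion,
                 p.value = p_value,
                 data.name = "two-group counts",
                 alternative = "two-sided"),
            class = c("de_test", "htest"))
}

#' @export
print.de_test <- function(x, ...) {
  cat("Two-group test (", x$method, ")\n", sep = "")
  cat(sprintf("  mean_g0 = %.4g, mean_g1 = %.4g, log2 ratio = %.4g\n",
              x$estimate[1L], x$estimate[2L], x$log2_ratio))
  cat(sprintf("  statistic = %.4g, df = %s, dispersion = %s, p = %.4g\n",
              unname(x$statistic),
              if (is.na(x$parameter)) "NA" else format(unname(x$parameter)),
              if (is.na(x$dispersion)) "NA" else format(x$dispersion, digits = 4),
              x$p.value))
  invisible(x)
}

#' Identity-link Poisson GLM Wald test
#'
#' Compares two groups of replicate counts under a Poisson noise model with
#' identity link: the effect is the difference of group means and its Wald
#' standard error assumes variance = mean with dispersion fixed at 1. This
#' is the appropriate test only in the low-read regime; under gamma
#' (high-read) noise it severely underestimates the variance and is
#' strongly anticonservative.
#'
#' @param y0,y1 non-negative integer counts for group 0 and group 1, each
#'   of length >= 2.
#' @return A `de_test` object (z statistic, normal reference, `df = NA`,
#'   `dispersion = 1`). If both group means are zero the statistic and
#'   p-value are `NA`, with a warning.
#' @examples
#' glm_identity_poisson_test(c(98, 102, 100, 99), c(205, 195, 200, 202))
#' @export
glm_identity_poisson_test <- function(y0, y1) {
  y0 <- as.numeric(y0); y1 <- as.numeric(y1)
  if (length(y0) < 2L || length(y1) < 2L) stop("each group needs >= 2 values")
  if (any(c(y0, y1) < 0) || any(c(y0, y1) != round(c(y0, y1))))
    stop("Poisson GLM requires non-negative integer counts")
  m0 <- mean(y0); m1 <- mean(y1)
  if (m0 == 0 && m1 == 0) {
    warning("both group means are zero: Poisson test undefined")
    return(de_result(m0, m1, "poisson_glm", NA_real_, NA_real_, 1, NA_real_))
  }
  se <- sqrt(m0 / length(y0) + m1 / length(y1))
  z <- (m1 - m0) / se
  de_result(m0, m1, "poisson_glm", z, NA_real_, 1, 2 * pnorm(-abs(z)))
}

#' Identity-link gamma GLM Wald test
#'
#' Compares two groups of replicate counts under a gamma noise model with
#' identity link. The gamma variance function V(mu) = mu^2 matches the
#' quadratic mean-variance law of the high-read regime; the dispersion is
#' estimated by the Pearson statistic over N - 2 residual degrees of
#' freedom and the Wald statistic is referred to a t distribution with the
#' same df. The statistic is invariant to rescaling both groups by a
#' common factor (only the coefficient of variation matters).
#'
#' @param y0,y1 strictly positive values for each group, length >= 2. Zeros
#'   are a hard error; add a pseudocount first if needed (see
#'   [run_de_table()]'s `pseudocount` argument).
#' @return A `de_test` object (t statistic, `df = n0 + n1 - 2`, Pearson
#'   `dispersion`). If both groups are constant (zero dispersion) the
#'   statistic and p-value are `NA`, with a warning.
#' @export
glm_identity_gamma_test <- function(y0, y1) {
  y0 <- as.numeric(y0); y1 <- as.numeric(y1)
  if (length(y0) < 2L || length(y1) < 2L) stop("each group needs >= 2 values")
  if (any(c(y0, y1) <= 0))
    stop("gamma GLM requires strictly positive values; ",
         "use a pseudocount (e.g. run_de_table(..., pseudocount = 0.5)) ",
         "for zero counts")
  n0 <- length(y0); n1 <- length(y1)
  m0 <- mean(y0); m1 <- mean(y1)
  df <- n0 + n1 - 2
  phi <- (sum((y0 - m0)^2) / m0^2 + sum((y1 - m1)^2) / m1^2) / df
  if (phi == 0) {
    warning("zero Pearson dispersion (both groups constant): test undefined")
    return(de_result(m0, m1, "gamma_glm", NA_real_, df, 0, NA_real_))
  }
  se <- sqrt(phi * (m0^2 / n0 + m1^2 / n1))
  t <- (m1 - m0) / se
  de_result(m0, m1, "gamma_glm", t, df, phi, 2 * pt(-abs(t), df))
}

#' Cube-root transformation + two-sample t-test
#'
#' Transforms counts by the cube root, which approximately normalizes
#' gamma-distributed data (the Wilson-Hilferty approximation), then applies
#' an ordinary two-sample t-test to the transformed values. This simple
#' procedure tracks the identity-link gamma GLM closely on high-read genes
#' while needing no GLM machinery.
#'
#' @param y0,y1 non-negative values for each group, length >= 2.
#' @param variant `"welch"` (default, unequal variances) or `"pooled"`.
#' @return A `de_test` object; the statistic is the t statistic on the
#'   transformed scale (its sign follows `mean(y1^(1/3)) - mean(y0^(1/3))`),
#'   while the reported group means and log2 ratio are on the original
#'   scale. If both transformed groups have zero variance the result is
#'   `NA` with a warning.
#' @export
crt_ttest <- function(y0, y1, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  y0 <- as.numeric(y0); y1 <- as.numeric(y1)
  if (length(y0) < 2L || length(y1) < 2L) stop("each group needs >= 2 values")
  if (any(c(y0, y1) < 0)) stop("counts must be non-negative")
  x0 <- y0^(1 / 3); x1 <- y1^(1 / 3)
  m0 <- mean(y0); m1 <- mean(y1)
  if (var(x0) == 0 && var(x1) == 0) {
    warning("zero variance in both transformed groups: t-test undefined")
    return(de_result(m0, m1, "crt_ttest", NA_real_, NA_real_, NA_real_,
                     NA_real_))
  }
  tt <- t.test(x1, x0, var.equal = (variant == "pooled"))
  de_result(m0, m1, "crt_ttest", unname(tt$statistic),
            unname(tt$parameter), NA_real_, tt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`); monotone, capped at 1, order
#' preserved, `NA`s passed through.
#'
#' @param p vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Run differential-expression tests over a count matrix
#'
#' Applies the requested two-group tests to every gene of a two-group
#' count matrix and returns one row per gene per method. A pseudocount, if
#' requested, is added to the *gamma GLM inputs only* (the gamma family
#' cannot accept zeros; the other tests can). Genes that an individual test
#' cannot handle (non-integer counts for the Poisson branch, degenerate
#' variance) get `NA` p-values with a single warning rather than aborting
#' the scan.
#'
#' @param m a [count_matrix()] with exactly 2 groups (>= 2 replicates each).
#' @param methods subset of `c("poisson_glm", "gamma_glm", "crt_ttest")`.
#' @param pseudocount value added to counts before the gamma GLM (default
#'   0, i.e. zeros in a gamma-tested gene give an `NA` row with a warning;
#'   0.5 is the conventional choice when enabled).
#' @param adjust `"none"` (default, raw p-values) or `"bh"`
#'   (Benjamini-Hochberg per method across genes).
#' @param crt_variant t-test variant for [crt_ttest()].
#' @return A data.frame of class `de_table` with columns `gene_id`,
#'   `method`, `mean_g0`, `mean_g1`, `log2_ratio`, `statistic`, `df`,
#'   `dispersion`, `p_value`, `p_adjusted`. Group 0 is the first group
#'   level, group 1 the second.
#' @export
run_de_table <- function(m,
                         methods = c("poisson_glm", "gamma_glm", "crt_ttest"),
                         pseudocount = 0, adjust = c("none", "bh"),
                         crt_variant = c("welch", "pooled")) {
  stopifnot(inherits(m, "count_matrix"))
  adjust <- match.arg(adjust)
  crt_variant <- match.arg(crt_variant)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount >= 0)
  if (nlevels(m$groups) != 2L)
    stop("differential expression needs exactly 2 groups, got ",
         nlevels(m$groups))
  g0 <- levels(m$groups)[1L]; g1 <- levels(m$groups)[2L]
  v0 <- m$values[, group_cols(m, g0), drop = FALSE]
  v1 <- m$values[, group_cols(m, g1), drop = FALSE]
  if (ncol(v0) < 2L || ncol(v1) < 2L)
    stop("each group needs >= 2 replicates")
  warned <- character()
  run_one <- function(method, y0, y1) {
    res <- withCallingHandlers(
      tryCatch(switch(method,
                      poisson_glm = glm_identity_poisson_test(y0, y1),
                      gamma_glm = glm_identity_gamma_test(y0, y1),
                      crt_ttest = crt_ttest(y0, y1, variant = crt_variant)),
               error = function(e) {
                 if (!(method %in% warned)) {
                   warning(method, ": ", conditionMessage(e),
                           " (p-value set to NA)", call. = FALSE)
                   warned <<- c(warned, method)
                 }
                 de_result(mean(y0), mean(y1), method, NA_real_, NA_real_,
                           NA_real_, NA_real_)
               }),
      warning = function(w) invokeRestart("muffleWarning"))
    res
  }
  rows <- vector("list", length(methods))
  names(rows) <- methods
  n_genes <- nrow(m$values)
  for (method in methods) {
    ps <- if (method == "gamma_glm") pseudocount else 0
    cols <- matrix(NA_real_, n_genes, 7L)
    for (i in seq_len(n_genes)) {
      r <- run_one(method, v0[i, ] + ps, v1[i, ] + ps)
      cols[i, ] <- c(r$estimate[1L], r$estimate[2L], r$log2_ratio,
                     r$statistic, r$parameter, r$dispersion, r$p.value)
    }
    tab <- data.frame(gene_id = rownames(m$values), method = method,
                      mean_g0 = cols[, 1L], mean_g1 = cols[, 2L],
                      log2_ratio = cols[, 3L], statistic = cols[, 4L],
                      df = cols[, 5L], dispersion = cols[, 6L],
                      p_value = cols[, 7L], stringsAsFactors = FALSE)
    tab$p_adjusted <- if (adjust == "bh") bh_adjust(tab$p_value) else NA_real_
    rows[[method]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- c(g0 = g0, g1 = g1)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Volcano plot of a DE table
#'
#' @param x a [run_de_table()] result.
#' @param method which method's rows to plot (default: first present).
#' @param ... passed to [plot()].
#' @export
plot.de_table <- function(x, method = NULL, ...) {
  if (is.null(method)) method <- x$method[1L]
  sub <- x[x$method == method, , drop = FALSE]
  plot(sub$log2_ratio, -log10(sub$p_value), pch = 20,
       xlab = "log2 ratio", ylab = "-log10 p", main = method, ...)
  abline(h = -log10(0.05), lty = 2, col = "grey50")
  invisible(x)
}
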