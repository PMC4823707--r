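# Independent oracles used across the suite. These deliberately take the
# slow/naive route (grid evaluation, exhaustive enumeration, generic IRLS)
# so they share no code with the package's closed forms.

# sup-distance between empirical and model CDF, evaluating both one-sided
# empirical limits at every support point
ks_oracle_D <- function(x, cdf) {
  pts <- sort(unique(x))
  f_right <- vapply(pts, function(t) mean(x <= t), 0)
  f_left <- vapply(pts, function(t) mean(x < t), 0)
  fm <- cdf(pts)
  max(abs(f_right - fm), abs(f_left - fm))
}

# exhaustive pmf of the Galton-Watson count: start at m molecules, each
# cycle every molecule doubles independently with probability p
gw_oracle_pmf <- function(m, n, p) {
  pmf <- stats::setNames(1, as.character(m))
  for (cyc in seq_len(n)) {
    new <- numeric()
    for (key in names(pmf)) {
      cnt <- as.integer(key)
      probs <- stats::dbinom(0:cnt, cnt, p)
      for (k in 0:cnt) {
        nk <- as.character(cnt + k)
        new[nk] <- sum(new[nk], pmf[[key]] * probs[k + 1L], na.rm = TRUE)
      }
    }
    pmf <- new
  }
  pmf
}

gw_oracle_moments <- function(m, n, p) {
  pmf <- gw_oracle_pmf(m, n, p)
  v <- as.numeric(names(pmf))
  mu <- sum(v * pmf)
  c(mean = mu, variance = sum((v - mu)^2 * pmf))
}

# generic iteratively-reweighted GLM fit of the two-group identity-link
# model; returns the Wald statistic and p-value for the group effect as
# summary.glm reports them
glm_irls_oracle <- function(y0, y1, family) {
  y <- c(y0, y1)
  g <- factor(rep(c("a", "b"), c(length(y0), length(y1))))
  fit <- stats::glm(y ~ g, family = family,
                    start = c(mean(y0), mean(y1) - mean(y0)))
  co <- stats::summary.glm(fit)$coefficients
  list(statistic = co[2L, 3L], p_value = co[2L, 4L])
}

# textbook Welch t-test on already-transformed values
welch_oracle <- function(x0, x1) {
  n0 <- length(x0); n1 <- length(x1)
  v0 <- var(x0) / n0; v1 <- var(x1) / n1
  t <- (mean(x1) - mean(x0)) / sqrt(v0 + v1)
  df <- (v0 + v1)^2 / (v0^2 / (n0 - 1) + v1^2 / (n1 - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# small two-group count matrix used by several IO / DE tests
tiny_matrix <- function() {
  v <- matrix(c(0, 5, 2, 7, 1, 6, 3, 8, 4, 9, 2, 7), nrow = 2,
              dimnames = list(c("miR-1", "miR-21"),
                              paste0("s", 1:6)))
  count_matrix(v, groups = rep(c("A", "B"), each = 3))
}
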