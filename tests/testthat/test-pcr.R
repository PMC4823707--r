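test_that("amplification is exact in the deterministic limits and bounded", {
  s <- simulate_amplification(pcr_config(5, 10, 1, n_replicates = 20, seed = 1))
  expect_true(all(s$final_counts == 5 * 2^10))
  s0 <- simulate_amplification(pcr_config(7, 12, 0, n_replicates = 20, seed = 1))
  expect_true(all(s0$final_counts == 7))
  sr <- simulate_amplification(pcr_config(3, 8, 0.6, n_replicates = 500, seed = 2))
  expect_true(all(sr$final_counts >= 3 & sr$final_counts <= 3 * 2^8))
  # reproducible from the seed
  sr2 <- simulate_amplification(pcr_config(3, 8, 0.6, n_replicates = 500, seed = 2))
  expect_identical(sr$final_counts, sr2$final_counts)
})

test_that("expected yield matches exhaustive enumeration of the branching process", {
  # m = 1, p = 0.5, n = 2: P(1) = .25, P(2) = .375, P(3) = .25, P(4) = .125
  pmf <- gw_oracle_pmf(1, 2, 0.5)
  expect_equal(unname(pmf[c("1", "2", "3", "4")]),
               c(0.25, 0.375, 0.25, 0.125))
  expect_equal(expected_yield(1, 2, 0.5), gw_oracle_moments(1, 2, 0.5),
               tolerance = 1e-12)
  for (p in c(0.3, 0.8)) for (m in c(1, 2)) for (n in c(1, 3))
    expect_equal(expected_yield(m, n, p), gw_oracle_moments(m, n, p),
                 tolerance = 1e-10)
  expect_equal(expected_yield(4, 6, 1), c(mean = 4 * 2^6, variance = 0))
  # mean is linear in the number of starting molecules
  expect_equal(expected_yield(10, 5, 0.7)[["mean"]],
               10 * expected_yield(1, 5, 0.7)[["mean"]])
})

test_that("simulated moments match the analytic yield within Monte-Carlo error", {
  set.seed(15)
  cfg <- pcr_config(5, 12, 0.8, n_replicates = 20000)
  s <- simulate_amplification(cfg)
  ey <- expected_yield(5, 12, 0.8)
  se_mean <- sqrt(ey[["variance"]] / cfg$n_replicates)
  expect_lt(abs(mean(s$final_counts) - ey[["mean"]]), 3 * se_mean)
  expect_lt(abs(var(s$final_counts) - ey[["variance"]]) / ey[["variance"]], 0.1)
})

test_that("independent lineages: m-fold start equals the m-fold sum in moments", {
  set.seed(16)
  m5 <- simulate_amplification(pcr_config(5, 10, 0.7, n_replicates = 20000))
  one <- matrix(simulate_amplification(
    pcr_config(1, 10, 0.7, n_replicates = 100000))$final_counts, ncol = 5)
  summed <- rowSums(one)
  expect_equal(mean(m5$final_counts), mean(summed), tolerance = 0.02)
  expect_equal(var(m5$final_counts), var(summed), tolerance = 0.1)
})

test_that("squared CV of the final count decays like 1/m", {
  set.seed(17)
  cv2 <- vapply(c(1, 5, 25), function(m) {
    s <- simulate_amplification(pcr_config(m, 10, 0.7, n_replicates = 20000))
    var(s$final_counts) / mean(s$final_counts)^2
  }, 0)
  expect_equal(cv2[1] / cv2[2], 5, tolerance = 0.2)
  expect_equal(cv2[2] / cv2[3], 5, tolerance = 0.25)
})

test_that("sequencing libraries route reads through the amplified pool", {
  lib0 <- simulate_sequencing_library(c(a = 10, b = 10), 15, 0.8, depth = 0,
                                      seed = 1)
  expect_equal(unname(lib0), c(0, 0))
  lib1 <- simulate_sequencing_library(c(solo = 4), 10, 0.9, depth = 1234,
                                      seed = 1)
  expect_equal(unname(lib1), 1234)
  # without depth the raw amplified counts are returned, within bounds
  raw <- simulate_sequencing_library(c(5, 7), 6, 0.5, seed = 3)
  expect_true(all(raw >= c(5, 7) & raw <= c(5, 7) * 2^6))
})

test_that("amplification noise makes read counts overdispersed vs Poisson", {
  set.seed(18)
  libs <- vapply(1:300, function(i)
    simulate_sequencing_library(c(10, 10), 15, 0.8, depth = 1e6),
    numeric(2))
  v <- apply(libs, 1, var); m <- rowMeans(libs)
  expect_true(all(v > 1.5 * m))
})

test_that("gamma convergence report quantifies the gamma approximation", {
  rep <- gamma_convergence_report(pcr_config(20, 15, 0.8,
                                             n_replicates = 2000, seed = 19))
  expect_false(rep$degenerate)
  expect_gt(rep$ks$p.value, 0.05)
  expect_lt(abs(rep$empirical_mean - rep$analytic_mean) / rep$analytic_mean,
            0.02)
  degen <- gamma_convergence_report(pcr_config(2, 4, 1, n_replicates = 1000))
  expect_true(degen$degenerate)
  expect_null(degen$gamma_fit)
  expect_error(gamma_convergence_report(pcr_config(2, 4, 0.5,
                                                   n_replicates = 10)),
               ">= 1000")
})
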