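test_that("Poisson identity-link Wald test matches its closed form and symmetries", {
  # mean 100 vs 200 at n = 6: z = 100 / sqrt(50)
  y0 <- c(98, 102, 100, 99, 101, 100)
  y1 <- c(198, 202, 200, 199, 201, 200)
  r <- glm_identity_poisson_test(y0, y1)
  expect_equal(unname(r$statistic), 100 / sqrt(50), tolerance = 1e-12)
  # equal means -> z = 0, p = 1
  r0 <- glm_identity_poisson_test(c(5, 7, 6), c(6, 6, 6))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p.value, 1)
  # antisymmetry
  rs <- glm_identity_poisson_test(y1, y0)
  expect_equal(unname(rs$statistic), -unname(r$statistic))
  expect_equal(rs$p.value, r$p.value)
  # contracts
  expect_error(glm_identity_poisson_test(c(1.5, 2), c(1, 2)), "integer")
  expect_warning(rz <- glm_identity_poisson_test(c(0, 0), c(0, 0)), "zero")
  expect_true(is.na(rz$p.value))
})

test_that("gamma identity-link Wald test matches its closed form and is scale-free", {
  y0 <- c(90, 100, 110, 95, 105, 100)
  y1 <- c(180, 200, 220, 190, 210, 200)
  r <- glm_identity_gamma_test(y0, y1)
  expect_equal(r$dispersion, 0.005, tolerance = 1e-12)
  expect_equal(unname(r$statistic), 100 / sqrt(0.005 * 50000 / 6),
               tolerance = 1e-12)
  expect_equal(unname(r$parameter), 10)
  # scale invariance: only the CV matters under the gamma family
  rc <- glm_identity_gamma_test(y0 * 37.5, y1 * 37.5)
  expect_equal(unname(rc$statistic), unname(r$statistic), tolerance = 1e-12)
  expect_equal(rc$p.value, r$p.value, tolerance = 1e-12)
  # identical groups -> t = 0, p = 1
  r0 <- glm_identity_gamma_test(c(9, 10, 11), c(9, 10, 11))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p.value, 1)
  expect_error(glm_identity_gamma_test(c(0, 1), c(2, 3)), "pseudocount")
  expect_warning(rd <- glm_identity_gamma_test(c(4, 4), c(9, 9)), "dispersion")
  expect_true(is.na(rd$p.value))
})

test_that("closed-form Wald statistics match an IRLS GLM oracle", {
  set.seed(9)
  for (i in 1:25) {
    n0 <- sample(3:8, 1); n1 <- sample(3:8, 1)
    y0 <- rpois(n0, runif(1, 5, 200)); y1 <- rpois(n1, runif(1, 5, 200))
    if (mean(y0) == 0 || mean(y1) == 0) next
    r <- glm_identity_poisson_test(y0, y1)
    o <- glm_irls_oracle(y0, y1, poisson(link = "identity"))
    expect_equal(unname(r$statistic), o$statistic, tolerance = 1e-8)
    expect_equal(r$p.value, o$p_value, tolerance = 1e-8)

    g0 <- rgamma(n0, 8, scale = runif(1, 5, 50))
    g1 <- rgamma(n1, 8, scale = runif(1, 5, 50))
    rg <- glm_identity_gamma_test(g0, g1)
    og <- glm_irls_oracle(g0, g1, Gamma(link = "identity"))
    expect_equal(unname(rg$statistic), og$statistic, tolerance = 1e-6)
    expect_equal(rg$p.value, og$p_value, tolerance = 1e-6)
  }
})

test_that("cube-root t-test matches a textbook Welch computation", {
  expect_equal(c(8, 27, 0)^(1 / 3), c(2, 3, 0))
  set.seed(10)
  y0 <- rgamma(6, shape = 5, scale = 20)
  y1 <- rgamma(6, shape = 5, scale = 80)
  r <- crt_ttest(y0, y1)
  o <- welch_oracle(y0^(1 / 3), y1^(1 / 3))
  expect_equal(unname(r$statistic), o$statistic, tolerance = 1e-10)
  expect_equal(unname(r$parameter), o$df, tolerance = 1e-10)
  expect_equal(r$p.value, o$p_value, tolerance = 1e-10)
  expect_lt(r$p.value, 0.05)
  # identical groups with spread -> t = 0, p = 1
  r0 <- crt_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p.value, 1)
  # pooled variant equals var.equal t-test
  rp <- crt_ttest(y0, y1, variant = "pooled")
  tt <- t.test(y1^(1 / 3), y0^(1 / 3), var.equal = TRUE)
  expect_equal(unname(rp$statistic), unname(tt$statistic), tolerance = 1e-12)
  expect_warning(rc <- crt_ttest(c(4, 4), c(4, 4)), "zero variance")
  expect_true(is.na(rc$p.value))
})

test_that("all three tests are invariant to sample order within groups", {
  set.seed(12)
  y0 <- rpois(6, 80); y1 <- rpois(6, 120)
  for (fn in list(glm_identity_poisson_test, glm_identity_gamma_test,
                  crt_ttest)) {
    a <- fn(y0, y1); b <- fn(sample(y0), sample(y1))
    expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(13)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_de_table orchestrates methods, pseudocounts and adjustment", {
  set.seed(14)
  v <- matrix(rpois(36, 50), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:12)))
  v[1, 1] <- 0  # a zero to exercise the pseudocount path
  m <- count_matrix(v, groups = rep(c("A", "B"), each = 6))
  tab <- suppressWarnings(run_de_table(m, methods = c("poisson_glm", "gamma_glm")))
  expect_equal(nrow(tab), 6L)
  # without a pseudocount the zero-containing gene is NA under the gamma GLM
  expect_true(is.na(tab$p_value[tab$method == "gamma_glm" &
                                tab$gene_id == "g1"]))
  tab2 <- run_de_table(m, methods = c("poisson_glm", "gamma_glm"),
                       pseudocount = 0.5, adjust = "bh")
  g1 <- tab2[tab2$gene_id == "g1", ]
  # pseudocount shifts only the gamma means, not the Poisson ones
  expect_equal(g1$mean_g0[g1$method == "gamma_glm"],
               g1$mean_g0[g1$method == "poisson_glm"] + 0.5)
  expect_true(all(tab2$p_adjusted >= tab2$p_value, na.rm = TRUE))
  expect_error(run_de_table(count_matrix(v)), "exactly 2 groups")
})
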