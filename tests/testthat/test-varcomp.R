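test_that("inverse normal transform matches the Blom closed form", {
  # n = 3 distinct: p = (0.1923, 0.5, 0.8077) -> (-0.8694, 0, 0.8694)
  z <- inverse_normal_transform(c(10, 50, 20))
  expect_equal(z, stats::qnorm((c(1, 3, 2) - 3/8) / 3.25), tolerance = 1e-12)
  expect_equal(z[3], 0)
  expect_equal(z[1], -z[2])

  # monotone relabeling leaves the output unchanged; NAs propagate
  y <- c(3.2, NA, -1, 7, 0.4)
  expect_equal(inverse_normal_transform(y), inverse_normal_transform(exp(y)))
  expect_true(is.na(inverse_normal_transform(y)[2]))

  # the transform normalizes even strongly skewed input
  set.seed(4)
  x <- stats::rexp(300)^2
  expect_gt(stats::shapiro.test(inverse_normal_transform(x))$p.value, 0.05)

  expect_error(inverse_normal_transform(rep(1, 10)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), ">= 3")
})

test_that("optimizer attains the brute-force grid maximum on small pedigrees", {
  worst <- 0
  for (seed in 1:20) {
    ped <- random_small_ped(seed)
    n <- nrow(ped)
    K <- 2 * kinship_matrix(ped)
    H <- household_matrix(ped)
    set.seed(1000 + seed)
    y <- as.numeric(crossprod(chol(0.5 * K + 0.5 * diag(n)), stats::rnorm(n)))
    X <- cbind(1, stats::rnorm(n))
    fit <- fit_polygenic_ml(y, K, X = X[, 2, drop = FALSE], H = H,
                            se = FALSE, pvalues = FALSE)
    oracle <- grid_loglik_oracle(y, X, K, H, steps = 50)
    expect_gte(fit$loglik, oracle - 1e-4)
    worst <- max(worst, oracle - fit$loglik)
  }
  expect_lt(worst, 1e-4)
})

test_that("variance estimates are scale-equivariant and invariant in h2", {
  ped <- generate_pedigree(sim_config(n_families = 6L, seed = 14L))
  cfg <- sim_config(h2_true = 0.4, c2_true = 0.1, seed = 14L)
  sim <- simulate_trait(ped, cfg, seed = 200)
  ph <- sim$phenotypes
  K <- 2 * kinship_matrix(ped)
  H <- household_matrix(ped)
  X <- cbind(age = ph$age, sex = as.integer(ph$sex == "male"))
  f1 <- fit_polygenic_ml(ph$trait, K, X = X, H = H, pvalues = TRUE)
  k <- 3.7
  f2 <- fit_polygenic_ml(k * ph$trait, K, X = X, H = H, pvalues = TRUE)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-8)
  expect_equal(f2$c2, f1$c2, tolerance = 1e-8)
  expect_equal(f2$sigma2, f1$sigma2 * k^2, tolerance = 1e-6)
  expect_equal(f2$p_h2, f1$p_h2, tolerance = 1e-8)
  expect_equal(f2$p_c2, f1$p_c2, tolerance = 1e-8)
})

test_that("null simulations pile at the zero boundary", {
  cfg <- sim_config(h2_true = 0, c2_true = 0, seed = 15L)
  ped <- generate_pedigree(cfg)
  out <- replicate_h2(ped, cfg, n_reps = 100, seed0 = 3000)
  expect_lt(mean(out$h2), 0.05)
})

test_that("heritability and household proportions are jointly recovered", {
  cfg <- sim_config(h2_true = 0.5, c2_true = 0.1, seed = 16L)
  ped <- generate_pedigree(cfg)
  out <- replicate_h2(ped, cfg, n_reps = 40, seed0 = 4000, use_H = TRUE)
  expect_equal(mean(out$h2), 0.5, tolerance = 0.07)
  expect_equal(mean(out$c2), 0.1, tolerance = 0.05)
})

test_that("REML is offered and shifts estimates only slightly at this n", {
  cfg <- sim_config(h2_true = 0.5, seed = 17L)
  ped <- generate_pedigree(cfg)
  sim <- simulate_trait(ped, cfg, seed = 21)
  K <- 2 * kinship_matrix(ped)
  f_ml <- fit_polygenic_ml(sim$phenotypes$trait, K, se = FALSE, pvalues = FALSE)
  f_reml <- fit_polygenic_ml(sim$phenotypes$trait, K, reml = TRUE,
                             se = FALSE, pvalues = FALSE)
  expect_true(f_reml$reml)
  expect_equal(f_ml$h2, f_reml$h2, tolerance = 0.1)
})

test_that("boundary LRT mixture has the stated closed-form values", {
  expect_equal(lrt_component(-50, -50)$p, 0.5)                  # Lambda = 0
  expect_equal(lrt_component(-50, -50 - 2.706 / 2)$p, 0.05,
               tolerance = 1e-3)          # Lambda = 2.706 (table-rounded)
  expect_equal(lrt_component(-50, -51, boundary = FALSE)$p,
               stats::pchisq(2, 1, lower.tail = FALSE))
  expect_error(lrt_component(-51, -50), "optimization failure")
})

test_that("bivariate fit recovers limits: identical, independent, constant", {
  cfg <- sim_config(h2_true = 0.5, seed = 18L)
  ped <- generate_pedigree(cfg)
  K <- 2 * kinship_matrix(ped)
  sim <- simulate_trait(ped, cfg, seed = 31)
  y <- sim$phenotypes$trait

  f_same <- fit_bivariate(y, y, K, pvalue = FALSE)
  expect_gt(f_same$rhoG, 0.98)

  expect_error(fit_bivariate(y, rep(1, length(y)), K), "constant")

  cfg0 <- sim_config(h2_true = 0.5, rhoG_true = 0, rhoE_true = 0, seed = 18L)
  rg <- vapply(1:30, function(r) {
    ph <- simulate_bivariate(ped, cfg0, dichotomize = FALSE,
                             seed = 5000 + r)$phenotypes
    fit_bivariate(ph$trait1, ph$trait2, K, pvalue = FALSE)$rhoG
  }, numeric(1))
  expect_lt(abs(mean(rg)), 0.05)
})

test_that("bivariate fit handles a 0/1 coded second trait", {
  cfg <- sim_config(h2_true = 0.5, rhoG_true = 0.55, seed = 19L)
  ped <- generate_pedigree(cfg)
  K <- 2 * kinship_matrix(ped)
  ph <- simulate_bivariate(ped, cfg, seed = 61)$phenotypes
  f <- fit_bivariate(inverse_normal_transform(ph$trait1), ph$diagnosis, K,
                     pvalue = TRUE)
  expect_true(abs(f$rhoG) <= 1)
  expect_true(f$p_rhoG >= 0 && f$p_rhoG <= 1)
  expect_true(is.finite(f$loglik))
})

test_that("heritability difference test reproduces the two-sample arithmetic", {
  f1 <- structure(list(h2 = 0.46, se_h2 = 0.15), class = "varcomp_fit")
  f2 <- structure(list(h2 = 0.59, se_h2 = 0.18), class = "varcomp_fit")
  out <- h2_difference_test(f1, f2)
  expect_equal(out$z, -0.13 / sqrt(0.15^2 + 0.18^2), tolerance = 1e-12)
  expect_equal(abs(out$z), 0.555, tolerance = 1e-3)
  expect_equal(out$p, 0.579, tolerance = 1e-3)     # not significant

  same <- h2_difference_test(f1, f1)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  far <- h2_difference_test(
    structure(list(h2 = 0.8, se_h2 = 0.05), class = "varcomp_fit"),
    structure(list(h2 = 0.3, se_h2 = 0.08), class = "varcomp_fit"))
  expect_lt(far$p, 1e-5)

  f3 <- structure(list(h2 = 0.4, se_h2 = NA_real_), class = "varcomp_fit")
  expect_error(h2_difference_test(f1, f3), "standard error")
})

test_that("liability conversion applies the threshold-model factor", {
  p <- 0.065
  z <- stats::dnorm(stats::qnorm(1 - p))
  expect_equal(liability_h2(0.71, p), 0.71 * p * (1 - p) / z^2)
  expect_error(liability_h2(0.5, 1.2), "prevalence")
})
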