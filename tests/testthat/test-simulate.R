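test_that("one founder couple with sibship 3 yields exactly 5 individuals", {
  cfg <- sim_config(n_families = 1L, generations = 1L,
                    sibship_probs = c(0, 1, 0, 0, 0, 0, 0, 0),  # size 3
                    seed = 1L)
  ped <- generate_pedigree(cfg)
  expect_equal(nrow(ped), 5L)
  expect_equal(sum(is.na(ped$father)), 2L)
  expect_equal(attr(ped, "n_nuclear_families"), 1L)
})

test_that("pedigree generation is deterministic and at the cohort scale", {
  cfg <- sim_config(seed = 8L)
  p1 <- generate_pedigree(cfg)
  p2 <- generate_pedigree(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  # the phenotyped participant cohort is at the study scale, embedded in
  # a larger genealogy it connects through
  for (s in 1:4) {
    cfg <- sim_config(seed = s)
    ped <- generate_pedigree(cfg)
    ids <- sample_participants(ped, cfg$n_participants,
                               cfg$participation_probs, seed = s)
    expect_true(length(ids) >= 250 && length(ids) <= 400)
    expect_gt(nrow(ped), length(ids))
    expect_gte(attr(ids, "n_families"), 100)
  }
})

test_that("participant sampling is deterministic and id-consistent", {
  ped <- generate_pedigree(sim_config(seed = 31L))
  a <- sample_participants(ped, 310L, seed = 5L)
  b <- sample_participants(ped, 310L, seed = 5L)
  expect_identical(a, b)
  expect_true(all(a %in% ped$id))
  expect_false(any(duplicated(a)))
})

test_that("the incrementally built kinship equals the recursive computation", {
  ped <- generate_pedigree(sim_config(n_families = 5L, seed = 4L))
  expect_equal(attr(ped, "phi"), kinship_matrix(ped), tolerance = 1e-12)
})

test_that("mates never exceed the kinship ceiling", {
  cfg <- sim_config(seed = 12L)
  ped <- generate_pedigree(cfg)
  phi <- kinship_matrix(ped)
  nf <- !is.na(ped$father)
  pairs <- unique(cbind(ped$father[nf], ped$mother[nf]))
  for (k in seq_len(nrow(pairs)))
    expect_lte(phi[pairs[k, 1L], pairs[k, 2L]], cfg$kinship_ceiling + 1e-12)
})

test_that("trait moments match the generative model", {
  cfg <- sim_config(h2_true = 0.5, c2_true = 0.1, beta_age = 0, beta_sex = 0,
                    seed = 2L)
  ped <- generate_pedigree(cfg)
  hh <- attr(household_matrix(ped), "household")
  sib_rows <- which(duplicated(hh) | duplicated(hh, fromLast = TRUE))
  # pair products are correlated within a replicate, so compare the
  # replicate-level means against their between-replicate Monte-Carlo SE
  nf <- !is.na(ped$father)
  po_i <- match(ped$id[nf], ped$id); po_f <- match(ped$father[nf], ped$id)
  sp <- t(utils::combn(sib_rows, 2))
  sp <- sp[hh[sp[, 1]] == hh[sp[, 2]], , drop = FALSE]
  n_rep <- 60
  vtot <- spc <- poc <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    # no covariates here, so E[y] = 0 exactly; centering on the sample
    # mean would bias pair products (the mean is kin-correlated with
    # every member), so raw products estimate the covariances directly
    y <- simulate_trait(ped, cfg, seed = 100 + r)$phenotypes$trait
    vtot[r] <- mean(y^2)
    spc[r] <- mean(y[sp[, 1]] * y[sp[, 2]])
    poc[r] <- mean(y[po_i] * y[po_f])
  }
  expect_equal(mean(vtot), 1, tolerance = 0.1)
  # exact generative expectations: cov(i,j) = h2 * 2phi_ij + c2 * H_ij;
  # loops push sib 2phi slightly above 0.5, so use the realized kinship
  K <- 2 * kinship_matrix(ped)
  exp_sib <- cfg$h2_true * mean(K[sp]) + cfg$c2_true
  exp_po <- cfg$h2_true * mean(K[cbind(po_i, po_f)])
  expect_equal(mean(spc), exp_sib,
               tolerance = (3 * stats::sd(spc) / sqrt(n_rep) + 0.01) / exp_sib)
  expect_equal(mean(poc), exp_po,
               tolerance = (3 * stats::sd(poc) / sqrt(n_rep) + 0.01) / exp_po)
})

test_that("independence and degenerate limits of the trait simulator", {
  cfg0 <- sim_config(h2_true = 0, c2_true = 0, beta_age = 0, beta_sex = 0,
                     seed = 3L)
  ped <- generate_pedigree(cfg0)
  hh <- attr(household_matrix(ped), "household")
  sib_rows <- which(duplicated(hh) | duplicated(hh, fromLast = TRUE))
  sp <- t(utils::combn(sib_rows, 2))
  sp <- sp[hh[sp[, 1]] == hh[sp[, 2]], , drop = FALSE]
  prods <- c()
  for (r in 1:10) {
    y <- simulate_trait(ped, cfg0, seed = 500 + r)$phenotypes$trait
    y <- (y - mean(y)) / stats::sd(y)
    prods <- c(prods, y[sp[, 1]] * y[sp[, 2]])
  }
  expect_lt(abs(mean(prods)), 0.1)  # sib correlation ~ 0 without g or c

  # h2 = 1: the trait is exactly the additive value
  cfg1 <- sim_config(h2_true = 1 - 1e-9, c2_true = 0, beta_age = 0,
                     beta_sex = 0, seed = 3L)
  sim <- simulate_trait(ped, cfg1, seed = 11)
  expect_equal(sim$phenotypes$trait, sim$phenotypes$g, tolerance = 1e-3)
})

test_that("MVN and gene-dropping trait generators agree on sib correlations", {
  cfg <- sim_config(h2_true = 0.5, beta_age = 0, beta_sex = 0, seed = 6L)
  ped <- generate_pedigree(cfg)
  hh <- attr(household_matrix(ped), "household")
  sib_rows <- which(duplicated(hh) | duplicated(hh, fromLast = TRUE))
  sp <- t(utils::combn(sib_rows, 2))
  sp <- sp[hh[sp[, 1]] == hh[sp[, 2]], , drop = FALSE]
  sibcor <- function(method, seed) {
    y <- simulate_trait(ped, cfg, method = method, seed = seed)$phenotypes$trait
    stats::cor(y[sp[, 1]], y[sp[, 2]])
  }
  r_mvn <- vapply(1:20, function(s) sibcor("mvn", 700 + s), numeric(1))
  r_gd  <- vapply(1:20, function(s) sibcor("genedrop", 900 + s), numeric(1))
  expect_gt(stats::t.test(r_mvn, r_gd)$p.value, 0.01)
})

test_that("bivariate simulation respects the generating correlations", {
  ped <- generate_pedigree(sim_config(seed = 9L))
  cfg0 <- sim_config(h2_true = 0.5, rhoG_true = 0, rhoE_true = 0,
                     beta_age = 0, beta_sex = 0, seed = 9L)
  r0 <- vapply(1:10, function(s) {
    ph <- simulate_bivariate(ped, cfg0, dichotomize = FALSE,
                             seed = 40 + s)$phenotypes
    stats::cor(ph$trait1, ph$trait2)
  }, numeric(1))
  expect_lt(abs(mean(r0)), 0.05)

  cfg1 <- sim_config(h2_true = 0.5, rhoG_true = 1, rhoE_true = 0, seed = 9L)
  ph <- simulate_bivariate(ped, cfg1, dichotomize = FALSE, seed = 77)$phenotypes
  expect_equal(stats::cor(ph$g1, ph$g2), 1, tolerance = 1e-9)

  expect_error(sim_config(rhoG_true = 1.2), "rhoG")
  # dichotomization hits the configured prevalence on average
  cfgd <- sim_config(h2_true = 0.5, rhoG_true = 0.55, seed = 10L)
  prev <- vapply(1:10, function(s)
    mean(simulate_bivariate(ped, cfgd, seed = 60 + s)$phenotypes$diagnosis),
    numeric(1))
  expect_lt(abs(mean(prev) - unname(cfgd$diagnosis_prevalence["bipolar"])),
            0.02)
})

test_that("item simulation is monotone, bounded and tracks the latent trait", {
  lo <- simulate_items(rep(-8, 5), seed = 1)
  hi <- simulate_items(rep(8, 5), seed = 1)
  expect_true(all(lo == 0))
  expect_true(all(hi == 3))
  set.seed(2)
  z <- stats::rnorm(1000)
  tot <- rowSums(simulate_items(z, seed = 3))
  expect_gt(stats::cor(z, tot), 0.9)
  expect_true(all(tot >= 0 & tot <= 75))
})

test_that("the cohort simulator produces the five-group structure", {
  co <- simulate_cohort(sim_config(seed = 5L))
  ph <- co$phenotypes
  expect_setequal(unique(ph$diagnosis),
                  c("bipolar", "control", "mdd", "other", "psychotic"))
  expect_true(all(ph$id %in% co$pedigree$id))
  expect_identical(co$truth$seed, 5L)
  # deterministic under the seed
  co2 <- simulate_cohort(sim_config(seed = 5L))
  expect_identical(co$phenotypes, co2$phenotypes)
})
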