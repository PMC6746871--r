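test_that("trapezoid AUC equals the tie-corrected Mann-Whitney statistic", {
  # hand count: positives {2, 1}, negatives {1, 0} -> (1 + 1 + 1 + .5)/4
  r <- roc_analysis(c(2, 1, 1, 0), c(1, 1, 0, 0), positive = "1")
  expect_equal(r$auc, 0.875)

  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    # integer scores force ties
    x <- sample(0:10, n1, replace = TRUE) + sample(0:3, n1, replace = TRUE)
    y <- sample(0:8, n0, replace = TRUE)
    scores <- c(x, y); labels <- rep(c("pos", "neg"), c(n1, n0))
    r <- roc_analysis(scores, labels, positive = "pos")
    u <- stats::wilcox.test(x, y, exact = FALSE)$statistic  # U with 1/2 ties
    expect_equal(r$auc, unname(u) / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC and CI agree with an independent ROC implementation", {
  set.seed(12)
  x <- stats::rnorm(40, 1); y <- stats::rnorm(60)
  r <- roc_analysis(c(x, y), rep(c("case", "ctrl"), c(40, 60)),
                    positive = "case")
  pr <- pROC::roc(response = rep(c(1, 0), c(40, 60)), predictor = c(x, y),
                  quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
})

test_that("the Youden cutoff maximizes sens + spec - 1 exhaustively", {
  set.seed(13)
  scores <- sample(0:20, 60, replace = TRUE)
  labels <- ifelse(scores + stats::rnorm(60, sd = 4) > 10, "pos", "neg")
  if (length(unique(labels)) == 2L) {
    r <- roc_analysis(scores, labels, positive = "pos")
    j_all <- vapply(sort(unique(scores)), function(t) {
      mean(scores[labels == "pos"] >= t) + mean(scores[labels == "neg"] < t) - 1
    }, numeric(1))
    expect_equal(r$youden_j, max(j_all))
    # smallest threshold on ties
    expect_equal(r$youden_cutoff,
                 sort(unique(scores))[which(j_all == max(j_all))[1L]])
  }
})

test_that("ROC behaves at the separation and null extremes", {
  r <- roc_analysis(c(10, 9, 2, 1), c("p", "p", "n", "n"), positive = "p")
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
  expect_true(r$youden_cutoff > 2 && r$youden_cutoff <= 9)

  set.seed(14)
  scores <- stats::rnorm(80)
  aucs <- vapply(1:200, function(i)
    roc_analysis(scores, sample(rep(c("a", "b"), 40)), positive = "b")$auc,
    numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)

  expect_error(roc_analysis(1:5, rep("a", 5)), "two classes")
})

test_that("group comparison with K = I reduces to the OLS ANOVA F", {
  set.seed(15)
  n <- 60
  g <- rep(c("a", "b", "c"), each = n / 3)
  age <- stats::runif(n, 20, 70)
  y <- stats::rnorm(n) + (g == "b") * 0.8 + 0.01 * age
  gc <- group_comparison(y, g, diag(n), covariates = data.frame(age = age),
                         reference = "a")
  ols <- stats::lm(y ~ factor(g) + age)
  # the omnibus test is covariate-adjusted (marginal), i.e. drop1's F
  an <- stats::drop1(ols, test = "F")
  expect_equal(gc$omnibus$F, an["factor(g)", "F value"], tolerance = 1e-6)
  # and without covariates it equals the one-way ANOVA F
  gc0 <- group_comparison(y, g, diag(n), reference = "a")
  expect_equal(gc0$omnibus$F,
               stats::anova(stats::lm(y ~ factor(g)))["factor(g)", "F value"],
               tolerance = 1e-6)
  # pairwise contrast matches the OLS coefficient
  bvsa <- gc$posthoc[gc$posthoc$group1 == "a" & gc$posthoc$group2 == "b", ]
  expect_equal(bvsa$estimate, unname(stats::coef(ols)["factor(g)b"]),
               tolerance = 1e-8)
})

test_that("identical groups give a null contrast and singletons are dropped", {
  y <- c(rep(c(1, 2, 3, 4), 2), 9)
  g <- c(rep("a", 4), rep("b", 4), "solo")
  expect_warning(gc <- group_comparison(y, g, diag(9)), "n < 2")
  ct <- gc$posthoc[1, ]
  expect_equal(ct$estimate, 0, tolerance = 1e-10)
  expect_gt(ct$p, 0.99)
})

test_that("omnibus p-values are calibrated under the null on a pedigree", {
  cfg <- sim_config(h2_true = 0.3, seed = 20L)
  ped <- generate_pedigree(cfg)
  K <- 2 * kinship_matrix(ped)
  n <- nrow(ped)
  ps <- vapply(1:200, function(r) {
    sim <- simulate_trait(ped, cfg, seed = 6000 + r)
    g <- sample(c("a", "b", "c"), n, replace = TRUE)  # labels independent of y
    group_comparison(sim$phenotypes$trait, g, K)$omnibus$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("groups separated like the observed cohort are detected", {
  co <- simulate_cohort(sim_config(h2_true = 0.46, c2_true = 0.12, seed = 5L))
  ph <- score_table(co$phenotypes)
  K <- 2 * kinship_matrix(co$pedigree, subset = ph$id)
  gc <- group_comparison(ph$qbs_total, ph$diagnosis, K,
                         covariates = ph[, c("age", "sex")])
  expect_lt(gc$omnibus$p, 0.001)
  get_p <- function(g1, g2) {
    row <- gc$posthoc[(gc$posthoc$group1 == g1 & gc$posthoc$group2 == g2) |
                      (gc$posthoc$group1 == g2 & gc$posthoc$group2 == g1), ]
    row$p
  }
  expect_lt(get_p("bipolar", "mdd"), 0.05)
  expect_lt(get_p("mdd", "control"), 0.05)
})

test_that("familial aggregation follows heritability and fails cleanly", {
  cfg <- sim_config(h2_true = 0.6, c2_true = 0, seed = 22L)
  ped <- generate_pedigree(cfg)
  wins <- ok <- 0
  for (r in 1:60) {
    sim <- simulate_trait(ped, cfg, seed = 7000 + r)
    sc <- stats::setNames(sim$phenotypes$trait, sim$phenotypes$id)
    fa <- tryCatch(familial_aggregation_contrast(sc, ped),
                   error = function(e) NULL)
    if (!is.null(fa)) {
      ok <- ok + 1
      wins <- wins + (fa$exposed$mean > fa$unexposed$mean)
    }
  }
  expect_gte(wins / ok, 0.9)

  # no index set when no score exceeds mean + 1 SD (binary scores)
  ped2 <- four_gen_ped(scramble = FALSE)
  sc2 <- stats::setNames(rep(c(0, 1), 10), ped2$id)
  expect_error(familial_aggregation_contrast(sc2, ped2), "index set")
})

test_that("familial aggregation ignores ordering and unphenotyped members", {
  cfg <- sim_config(h2_true = 0.6, seed = 23L)
  ped <- generate_pedigree(cfg)
  sim <- simulate_trait(ped, cfg, seed = 71)
  sc <- stats::setNames(sim$phenotypes$trait, sim$phenotypes$id)
  fa1 <- familial_aggregation_contrast(sc, ped)
  perm <- sample(length(sc))
  fa2 <- familial_aggregation_contrast(sc[perm], ped)
  expect_equal(fa1$t, fa2$t, tolerance = 1e-12)
  # scoring only a subset: extra pedigree members do not change the result
  sub <- sc[1:250]
  fa3 <- familial_aggregation_contrast(sub, ped)
  df <- as.data.frame(ped)
  keep <- ped$id %in% c(names(sub), ped$father, ped$mother)
  fa4 <- familial_aggregation_contrast(
    sub, pedigree(df$id[keep], df$father[keep], df$mother[keep], df$sex[keep]))
  expect_equal(fa3$t, fa4$t, tolerance = 1e-12)
})

test_that("state contrast and age correlation behave and calibrate", {
  y <- c(rnorm(10), rnorm(10))
  expect_equal(trait_state_contrast(c(y[1:10], y[1:10]),
                                    rep(c("current", "remitted"), each = 10))$t,
               0, tolerance = 1e-12)
  expect_error(trait_state_contrast(1:4, c("a", "a", "b", "b"))$t, "too small")

  age <- stats::runif(50, 18, 80)
  expect_equal(age_correlation(age, age)$r, 1)

  set.seed(24)
  rs <- ps <- numeric(200)
  for (r in 1:200) {
    a <- stats::rnorm(310); b <- stats::rnorm(310)
    out <- age_correlation(a, b)
    rs[r] <- out$r; ps[r] <- out$p
  }
  expect_lt(abs(mean(rs)), 0.02)
  rej <- mean(ps < 0.05)
  expect_true(rej >= 0.02 && rej <= 0.09)
})
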