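# Fixtures and independent oracles shared across the test files.

# trio: two founders and one child
trio_ped <- function() {
  pedigree(id = c("f", "m", "c"),
           father = c(NA, NA, "f"),
           mother = c(NA, NA, "m"),
           sex = c("male", "female", "female"))
}

# two founder couples, full sibs, and a first-cousin mating whose child
# "z" is inbred: phi(z, z) = 0.5 * (1 + 0.0625) = 0.53125
looped_ped <- function() {
  pedigree(
    id     = c("g1", "g2", "s1", "s2", "p1", "p2", "c1", "c2", "z"),
    father = c(NA, NA, NA, NA, "g1", "g1", "p1", "p2", "c1"),
    mother = c(NA, NA, NA, NA, "g2", "g2", "s1", "s2", "c2"),
    sex    = c("male", "female", "female", "female", "male", "male",
               "male", "female", "male"))
}

# 4-generation, 20-member pedigree with two cousin-mating loops; the
# generation-4 children are inbred with f = 0.125. Supplied in scrambled
# input order by default.
four_gen_ped <- function(scramble = TRUE, seed = 42) {
  df <- data.frame(
    id     = c("a1", "a2", "a3", "a4",                 # founders
               "b1", "b2", "b3", "b4",                 # gen 2 (two sibships)
               "c1", "c2", "c3", "c4", "c5", "c6",     # gen 3
               "d1", "d2", "d3", "d4", "d5", "d6"),    # gen 4
    father = c(NA, NA, NA, NA,
               "a1", "a1", "a3", "a3",
               "b1", "b1", "b1", "b3", "b3", "b3",
               "c1", "c1", "c1", "c3", "c3", "c3"),
    mother = c(NA, NA, NA, NA,
               "a2", "a2", "a4", "a4",
               "b4", "b4", "b4", "b2", "b2", "b2",
               "c4", "c4", "c4", "c6", "c6", "c6"),
    sex    = c("male", "female", "male", "female",
               "male", "female", "male", "female",
               "male", "female", "male", "female", "male", "female",
               "male", "female", "male", "female", "male", "female"))
  if (scramble) {
    set.seed(seed)
    df <- df[sample(nrow(df)), ]
  }
  pedigree(df$id, df$father, df$mother, df$sex)
}

# small random pedigree for oracle tests: founder couples plus children,
# possibly with a second generation, n <= 15
random_small_ped <- function(seed) {
  set.seed(seed)
  n_cpl <- sample(2:3, 1)
  id <- character(0); father <- character(0); mother <- character(0)
  sex <- character(0)
  for (k in seq_len(n_cpl)) {
    id <- c(id, paste0("f", k), paste0("m", k))
    father <- c(father, NA, NA); mother <- c(mother, NA, NA)
    sex <- c(sex, "male", "female")
  }
  kid <- 0L
  kids <- list()
  for (k in seq_len(n_cpl)) {
    for (j in seq_len(sample(2:3, 1))) {
      kid <- kid + 1L
      id <- c(id, paste0("k", kid))
      father <- c(father, paste0("f", k)); mother <- c(mother, paste0("m", k))
      sx <- sample(c("male", "female"), 1)
      sex <- c(sex, sx)
      kids[[kid]] <- c(paste0("k", kid), sx, k)
    }
  }
  # one cross-family mating when possible
  km <- Filter(function(x) x[2] == "male", kids)
  kf <- Filter(function(x) x[2] == "female", kids)
  if (length(km) && length(kf)) {
    for (a in km) {
      bs <- Filter(function(x) x[3] != a[3], kf)
      if (length(bs)) {
        b <- bs[[1]]
        for (j in 1:2) {
          kid <- kid + 1L
          id <- c(id, paste0("k", kid))
          father <- c(father, a[1]); mother <- c(mother, b[1])
          sex <- c(sex, sample(c("male", "female"), 1))
        }
        break
      }
    }
  }
  pedigree(id[1:min(15, length(id))],
           father[1:min(15, length(id))],
           mother[1:min(15, length(id))],
           sex[1:min(15, length(id))])
}

# Independent brute-force oracle: maximized MVN log-likelihood over a
# dense (h2, c2) grid with GLS beta and closed-form total variance,
# written directly from the density (no package internals).
grid_loglik_oracle <- function(y, X, K, H = NULL, steps = 50) {
  n <- length(y)
  grid <- seq(0, 0.98, length.out = steps)
  best <- -Inf
  c2_grid <- if (is.null(H)) 0 else grid
  for (h2 in grid) for (c2 in c2_grid) {
    if (h2 + c2 >= 0.999) next
    V <- h2 * K + (1 - h2 - c2) * diag(n)
    if (!is.null(H)) V <- V + c2 * H
    Vi <- solve(V)
    XtVi <- t(X) %*% Vi
    beta <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) +
                  as.numeric(determinant(V, logarithm = TRUE)$modulus) + n)
    if (ll > best) best <- ll
  }
  best
}

# replicate heritability fits on a fixed pedigree (optionally on a
# phenotyped participant subset); returns estimates
replicate_h2 <- function(ped, cfg, n_reps, seed0, ids = NULL,
                         use_H = FALSE, transform = TRUE, se = FALSE) {
  if (is.null(ids)) ids <- ped$id
  K <- 2 * kinship_matrix(ped, subset = ids)
  H <- if (use_H) household_matrix(ped, ids = ids) else NULL
  h2 <- c2 <- seh <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_trait(ped, cfg, ids = ids, seed = seed0 + r)
    ph <- sim$phenotypes
    X <- cbind(age = ph$age, sex = as.integer(ph$sex == "male"))
    f <- fit_polygenic_ml(ph$trait, K, X = X, H = H,
                          transform = transform, se = se, pvalues = FALSE)
    h2[r] <- f$h2; c2[r] <- f$c2; seh[r] <- f$se_h2
  }
  list(h2 = h2, c2 = c2, se_h2 = seh)
}

# the study-scale cohort: full genealogy plus ~310 sampled participants
paper_cohort <- function(cfg) {
  ped <- generate_pedigree(cfg)
  ids <- sample_participants(ped, cfg$n_participants,
                             cfg$participation_probs, seed = cfg$seed)
  list(ped = ped, ids = ids)
}
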