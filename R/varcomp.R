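#' Rank-based inverse normal (inverse Gaussian) transform
#'
#' Maps a trait to normal quantiles via average ranks,
#' `z_i = qnorm((r_i - c) / (n - 2c + 1))` with the Blom offset
#' `c = 3/8` by default, as is conventional before variance-components
#' fitting. Missing values are propagated; ranks are computed over the
#' non-missing values only.
#'
#' @param y numeric vector (>= 3 non-missing values).
#' @param offset rank offset constant; 3/8 (Blom) by default.
#' @return numeric vector of the same length as `y`.
#' @examples
#' inverse_normal_transform(c(10, 50, 20))
#' @export
inverse_normal_transform <- function(y, offset = 3/8) {
  ok <- !is.na(y)
  v <- y[ok]
  if (length(v) < 3L) stop("need >= 3 non-missing values to transform")
  if (max(v) == min(v)) stop("constant vector: ranks degenerate, cannot transform")
  r <- rank(v, ties.method = "average")
  z <- stats::qnorm((r - offset) / (length(v) - 2 * offset + 1))
  out <- rep(NA_real_, length(y))
  out[ok] <- z
  out
}

# ---------------------------------------------------------------------------
# Internal likelihood machinery.
#
# The polygenic model is y ~ N(X beta, s2p * V(p)) with
# V(p) = sum_k p_k M_k + (1 - sum_k p_k) I over unit-scale structure
# matrices M_k (the additive relationship 2*Phi, the household incidence
# H, ...). beta is profiled out by GLS and the total variance s2p by its
# closed-form ML (or REML) maximizer at every evaluation, leaving an
# optimization over the variance proportions only.
# ---------------------------------------------------------------------------

# profile loglik pieces from a weighted (rotated, diagonal-V) problem
.gls_diag <- function(yt, Xt, w, reml = FALSE) {
  sw <- 1 / w
  A <- crossprod(Xt, Xt * sw)
  b <- crossprod(Xt, yt * sw)
  beta <- solve(A, b)
  r <- yt - Xt %*% beta
  rss <- sum(r * r * sw)
  n <- length(yt); p <- ncol(Xt)
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi) + 1) + (n - p) * log(s2) +
                  sum(log(w)) + determinant(A, logarithm = TRUE)$modulus)
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi) + 1) + n * log(s2) + sum(log(w)))
  }
  list(loglik = as.numeric(ll), beta = beta, s2p = s2,
       vcov_beta = s2 * solve(A))
}

# same via Cholesky of a dense V (two or more structure matrices)
.gls_chol <- function(y, X, V, reml = FALSE) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    V <- V + diag(1e-8, nrow(V))
    warning("covariance numerically non-PSD; jittered by 1e-8")
    R <- chol(V)
  }
  logdet <- 2 * sum(log(diag(R)))
  # whiten
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  A <- crossprod(Xt)
  b <- crossprod(Xt, yt)
  beta <- solve(A, b)
  r <- yt - Xt %*% beta
  rss <- sum(r * r)
  n <- length(y); p <- ncol(X)
  if (reml) {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi) + 1) + (n - p) * log(s2) +
                  logdet + determinant(A, logarithm = TRUE)$modulus)
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi) + 1) + n * log(s2) + logdet)
  }
  list(loglik = as.numeric(ll), beta = beta, s2p = s2,
       vcov_beta = s2 * solve(A))
}

# Fit proportions for an arbitrary set of structure matrices.
# mats: named list of n x n matrices (residual implied).
# The trait is standardized internally, which makes the proportion
# estimates exactly scale-equivariant and keeps the optimizer on a
# well-conditioned scale; variances and likelihood are mapped back.
.fit_vc <- function(y, X, mats, reml = FALSE) {
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) stop("constant trait")
  fit <- .fit_vc_std(y / sdy, X, mats, reml)
  fit$s2p <- fit$s2p * sdy^2
  fit$beta <- fit$beta * sdy
  fit$vcov_beta <- fit$vcov_beta * sdy^2
  fit$loglik <- fit$loglik -
    (if (reml) length(y) - ncol(X) else length(y)) * log(sdy)
  fit
}

.fit_vc_std <- function(y, X, mats, reml = FALSE) {
  n <- length(y)
  m <- length(mats)
  if (m == 0L) {
    g <- .gls_diag(y, X, rep(1, n), reml)
    return(c(g, list(props = stats::setNames(numeric(0), character(0)),
                     convergence = 0L)))
  }
  if (m == 1L) {
    eg <- eigen(mats[[1L]], symmetric = TRUE)
    if (min(eg$values) < -1e-6)
      stop("structure matrix '", names(mats)[1L], "' is not positive semidefinite")
    lam <- pmax(eg$values, 0)
    yt <- crossprod(eg$vectors, y)
    Xt <- crossprod(eg$vectors, X)
    obj <- function(p1) .gls_diag(yt, Xt, p1 * lam + (1 - p1), reml)$loglik
    # coarse multi-start grid, then local polish in the best bracket
    grid <- seq(0, 0.99, by = 0.01)
    gl <- vapply(grid, obj, numeric(1))
    i <- which.max(gl)
    lo <- grid[max(1L, i - 1L)]; hi <- min(grid[min(length(grid), i + 1L)], 0.9999)
    op <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                          tol = 1e-9)
    p1 <- if (op$objective >= gl[i]) op$maximum else grid[i]
    if (obj(0) >= obj(p1)) p1 <- 0           # boundary check
    g <- .gls_diag(yt, Xt, p1 * lam + (1 - p1), reml)
    return(c(g, list(props = stats::setNames(p1, names(mats)),
                     convergence = 0L)))
  }
  # m >= 2: softmax parameterization, Nelder-Mead multi-start + polish
  I <- diag(n)
  Vof <- function(p) {
    V <- (1 - sum(p)) * I
    for (k in seq_len(m)) V <- V + p[k] * mats[[k]]
    V
  }
  nll_theta <- function(theta) {
    theta <- pmin(pmax(theta, -15), 15)
    e <- exp(theta)
    p <- e / (1 + sum(e))
    -.gls_chol(y, X, Vof(p), reml)$loglik
  }
  to_theta <- function(p) {
    pe <- max(1 - sum(p), 1e-6)
    log(pmax(p, 1e-6) / pe)
  }
  starts <- list(rep(0.02, m),                       # near-null
                 rep(1 / (m + 1), m),                # balanced
                 c(0.9, rep(0.05 / max(m - 1, 1), m - 1)),  # near-saturated
                 c(0.45, rep(0.1, m - 1)))           # anchor-like
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(to_theta(s), nll_theta, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pol <- suppressWarnings(
    stats::optim(best$par, nll_theta, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)))
  if (pol$value < best$value) best <- pol
  theta <- pmin(pmax(best$par, -15), 15)
  e <- exp(theta)
  p <- e / (1 + sum(e))
  p[p < 1e-5] <- 0                                   # snap to the boundary
  g <- .gls_chol(y, X, Vof(p), reml)
  c(g, list(props = stats::setNames(as.numeric(p), names(mats)),
            convergence = best$convergence))
}

.check_K <- function(K, n) {
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-8) stop("relationship matrix must be symmetric")
  invisible(TRUE)
}

.build_X <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (!any(apply(X, 2, function(c) all(c == c[1L]))))
    X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Maximum-likelihood polygenic variance-components fit
#'
#' Fits the mixed model `y ~ N(X beta, sigma2_g K + sigma2_c H +
#' sigma2_e I)` by maximum likelihood, where `K = 2 Phi` is the additive
#' relationship matrix from [kinship_matrix()] and `H` an optional
#' household incidence matrix. Fixed effects are profiled out by GLS and
#' the total variance by its closed-form maximizer, so the optimization
#' runs over the variance proportions only (multi-start Nelder-Mead with
#' BFGS polish; a spectral rotation gives an O(n)-per-evaluation
#' likelihood when `H` is absent). Heritability is
#' `h2 = sigma2_g / (sigma2_g + sigma2_c + sigma2_e)` and the household
#' proportion `c2 = sigma2_c / sigma2_p`.
#'
#' Standard errors come from the numerically differentiated observed
#' information of the profile log-likelihood on the proportion scale; at
#' a boundary estimate they are flagged unreliable (`NA`). Component
#' p-values are likelihood-ratio tests against the model with that
#' component removed, using the boundary 1/2:1/2 chi-square mixture (see
#' [lrt_component()]).
#'
#' @param y numeric trait vector (missing values dropped, with the
#'   matching rows of `X`, `K`, `H`).
#' @param K additive relationship matrix (`2 * kinship_matrix(ped)`).
#' @param X covariate matrix or data frame (age, sex, ...); an intercept
#'   is added when absent. `NULL` for intercept only.
#' @param H optional household matrix from [household_matrix()].
#' @param transform apply [inverse_normal_transform()] to `y` first.
#' @param reml use REML instead of ML (sensitivity option; ML is the
#'   default and what the reported estimates use).
#' @param se compute standard errors (default `TRUE`).
#' @param pvalues compute component LRT p-values by refitting the nested
#'   models (default `TRUE`).
#' @return Object of class `varcomp_fit`: a list with `h2`, `c2`,
#'   `se_h2`, `se_c2`, `p_h2`, `p_c2`, `sigma2` (named vector g/c/e),
#'   `beta`, `vcov_beta`, `loglik`, `covariate_R2`, `n`, `boundary`,
#'   `reml`.
#' @export
fit_polygenic_ml <- function(y, K, X = NULL, H = NULL, transform = FALSE,
                             reml = FALSE, se = TRUE, pvalues = TRUE) {
  y <- as.numeric(y)
  keep <- !is.na(y)
  if (!all(keep)) {
    y <- y[keep]
    K <- K[keep, keep, drop = FALSE]
    if (!is.null(H)) H <- H[keep, keep, drop = FALSE]
    if (!is.null(X)) X <- as.matrix(X)[keep, , drop = FALSE]
  }
  n <- length(y)
  if (transform) y <- inverse_normal_transform(y)
  .check_K(K, n)
  X <- .build_X(X, n)
  if (n < ncol(X) + 3L) stop("too few observations (n = ", n, ")")
  mats <- list(additive = K)
  if (!is.null(H)) {
    .check_K(H, n)
    mats$household <- H
  }
  fit <- .fit_vc(y, X, mats, reml)
  h2 <- unname(fit$props["additive"])
  c2 <- if (!is.null(H)) unname(fit$props["household"]) else NA_real_
  s2p <- fit$s2p
  sigma2 <- c(g = h2 * s2p,
              c = if (!is.null(H)) c2 * s2p else 0,
              e = (1 - h2 - ifelse(is.null(H), 0, c2)) * s2p)

  boundary <- c(h2 = h2 < 5e-3 || h2 > 0.995,
                c2 = !is.null(H) && (c2 < 5e-3 || c2 > 0.995))
  se_h2 <- se_c2 <- NA_real_
  if (se) {
    nll_nat <- function(p) -.profile_ll_at(y, X, mats, p, reml)
    p_hat <- fit$props
    if (!any(boundary[seq_along(p_hat)])) {
      Hs <- tryCatch(stats::optimHess(p_hat, nll_nat), error = function(e) NULL)
      if (!is.null(Hs)) {
        Vp <- tryCatch(solve(Hs), error = function(e) NULL)
        if (!is.null(Vp) && all(diag(Vp) > 0)) {
          se_h2 <- sqrt(Vp[1L, 1L])
          if (!is.null(H)) se_c2 <- sqrt(Vp[2L, 2L])
        }
      }
    }
  }

  p_h2 <- p_c2 <- NA_real_
  lrt_h2 <- lrt_c2 <- NULL
  if (pvalues) {
    red_g <- .fit_vc(y, X, mats[setdiff(names(mats), "additive")], reml)
    lrt_h2 <- lrt_component(fit$loglik, red_g$loglik, boundary = TRUE)
    p_h2 <- lrt_h2$p
    if (!is.null(H)) {
      red_c <- .fit_vc(y, X, mats[setdiff(names(mats), "household")], reml)
      lrt_c2 <- lrt_component(fit$loglik, red_c$loglik, boundary = TRUE)
      p_c2 <- lrt_c2$p
    }
  }

  # variance explained by the non-intercept covariates
  covariate_R2 <- if (ncol(X) > 1L) {
    fx <- X[, -1L, drop = FALSE] %*% fit$beta[-1L, , drop = FALSE]
    stats::var(as.numeric(fx)) / stats::var(y)
  } else 0

  structure(list(h2 = h2, c2 = c2, se_h2 = se_h2, se_c2 = se_c2,
                 p_h2 = p_h2, p_c2 = p_c2,
                 lrt_h2 = lrt_h2, lrt_c2 = lrt_c2,
                 sigma2 = sigma2, s2p = s2p,
                 beta = stats::setNames(as.numeric(fit$beta), colnames(X)),
                 vcov_beta = fit$vcov_beta,
                 loglik = fit$loglik, covariate_R2 = covariate_R2,
                 n = n, boundary = boundary, reml = reml,
                 components = names(mats)),
            class = "varcomp_fit")
}

# profile loglik at fixed proportion vector p (order = names(mats))
.profile_ll_at <- function(y, X, mats, p, reml = FALSE) {
  p <- pmin(pmax(p, 0), 0.9999)
  if (sum(p) > 0.9999) p <- p * 0.9999 / sum(p)
  V <- diag(1 - sum(p), length(y))
  for (k in seq_along(mats)) V <- V + p[k] * mats[[k]]
  .gls_chol(y, X, V, reml)$loglik
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("Polygenic %s fit (n = %d)\n", if (x$reml) "REML" else "ML", x$n))
  cat(sprintf("  h2 = %.3f (SE %s), p = %s\n", x$h2,
              .fmt(x$se_h2), .fmt(x$p_h2)))
  if (!is.na(x$c2))
    cat(sprintf("  household c2 = %.3f (SE %s), p = %s\n", x$c2,
                .fmt(x$se_c2), .fmt(x$p_c2)))
  cat(sprintf("  covariate R2 = %.3f, loglik = %.3f\n", x$covariate_R2,
              x$loglik))
  invisible(x)
}

.fmt <- function(x) if (is.na(x)) "NA" else format(signif(x, 3))

#' Likelihood-ratio test for a variance component
#'
#' `Lambda = 2 (loglik_full - loglik_reduced)`, clipped at zero. For a
#' variance component tested at the boundary of its parameter space the
#' null distribution is the 1/2:1/2 mixture of a point mass at zero and
#' chi-square(1), so `p = 0.5 * P(chisq_1 > Lambda)` (and `p = 0.5` at
#' `Lambda = 0`); otherwise the usual chi-square(1) tail is used.
#'
#' @param full,reduced `varcomp_fit` objects or bare log-likelihoods;
#'   the reduced model must be nested (one component constrained to 0).
#' @param boundary is the constrained parameter on the boundary?
#' @return list with `statistic` and `p`.
#' @examples
#' lrt_component(-100, -101.353, boundary = TRUE)  # p = 0.05
#' @export
lrt_component <- function(full, reduced, boundary = TRUE) {
  llf <- if (inherits(full, "varcomp_fit")) full$loglik else as.numeric(full)
  llr <- if (inherits(reduced, "varcomp_fit")) reduced$loglik else as.numeric(reduced)
  if (llf < llr - 1e-6)
    stop("full-model log-likelihood below reduced model (",
         format(llf), " < ", format(llr), "): optimization failure")
  lambda <- max(2 * (llf - llr), 0)
  p <- if (boundary) 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
       else stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  list(statistic = lambda, p = p)
}

#' Compare heritability estimates from two fits
#'
#' Approximate two-sample z-test on heritabilities from (sub)samples,
#' `z = (h2_1 - h2_2) / sqrt(se_1^2 + se_2^2)`, two-sided normal p. With
#' overlapping subsamples the test ignores the covariance of the
#' estimates and is flagged as such.
#'
#' @param fit1,fit2 `varcomp_fit` objects with standard errors.
#' @param overlap do the two samples share individuals?
#' @return list with `z`, `p`, `overlap`.
#' @export
h2_difference_test <- function(fit1, fit2, overlap = FALSE) {
  if (is.na(fit1$se_h2) || is.na(fit2$se_h2))
    stop("both fits need a heritability standard error")
  z <- (fit1$h2 - fit2$h2) / sqrt(fit1$se_h2^2 + fit2$se_h2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), overlap = overlap)
}

# ---------------------------------------------------------------------------
# Bivariate polygenic model
# ---------------------------------------------------------------------------

#' Bivariate polygenic fit with genetic correlation
#'
#' Joint maximum-likelihood fit of two traits on the same pedigree
#' members. The 2n x 2n covariance is `G (x) K + E (x) I` (Kronecker-
#' structured), with trait-level genetic covariance
#' `G = [[s2g1, rhoG sg1 sg2], [., s2g2]]` and environmental covariance
#' `E` analogous with `rhoE`. A joint spectral rotation of `K` reduces
#' every likelihood evaluation to n independent 2x2 problems, with the
#' fixed effects of both traits profiled out by GLS. A binary 0/1 trait
#' (e.g. a diagnosis indicator) is accepted and treated as quantitative.
#' `p_rhoG` is a 1-df (non-boundary) likelihood-ratio test against the
#' `rhoG = 0` constraint.
#'
#' @param y1,y2 numeric trait vectors on the same individuals (`y2` may
#'   be 0/1 coded); rows with a missing value in either trait are
#'   dropped.
#' @param K additive relationship matrix (`2 * Phi`).
#' @param X shared covariate matrix (intercept added when absent).
#' @param transform1 apply the inverse normal transform to `y1` first
#'   (the convention for the quantitative trait; default `FALSE`).
#' @param pvalue compute `p_rhoG` by refitting under `rhoG = 0`.
#' @return Object of class `bivariate_fit`: `rhoG`, `rhoE`, per-trait
#'   `h2` and variance components, `beta`, `loglik`, `p_rhoG`, `n`.
#' @export
fit_bivariate <- function(y1, y2, K, X = NULL, transform1 = FALSE,
                          pvalue = TRUE) {
  y1 <- as.numeric(y1); y2 <- as.numeric(y2)
  stopifnot(length(y1) == length(y2))
  keep <- !is.na(y1) & !is.na(y2)
  y1 <- y1[keep]; y2 <- y2[keep]
  K <- K[keep, keep, drop = FALSE]
  if (!is.null(X)) X <- as.matrix(X)[keep, , drop = FALSE]
  n <- length(y1)
  if (n < 10L) stop("too few observations (n = ", n, ")")
  if (transform1) y1 <- inverse_normal_transform(y1)
  .check_K(K, n)
  X <- .build_X(X, n)
  s1 <- stats::sd(y1); s2 <- stats::sd(y2)
  if (s1 == 0 || s2 == 0)
    stop("constant trait: bivariate model is not identifiable")
  z1 <- y1 / s1; z2 <- y2 / s2

  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  yt1 <- crossprod(U, z1); yt2 <- crossprod(U, z2)
  Xt <- crossprod(U, X)
  p <- ncol(Xt)

  biv_ll <- function(g1, e1, g2, e2, rG, rE) {
    a <- g1 * lam + e1
    cc <- g2 * lam + e2
    b <- rG * sqrt(g1 * g2) * lam + rE * sqrt(e1 * e2)
    det <- a * cc - b * b
    if (any(det <= 0) || any(a <= 0)) return(-Inf)
    w11 <- cc / det; w22 <- a / det; w12 <- -b / det
    N11 <- crossprod(Xt, Xt * w11)
    N22 <- crossprod(Xt, Xt * w22)
    N12 <- crossprod(Xt, Xt * w12)
    Nm <- rbind(cbind(N11, N12), cbind(N12, N22))
    rhs <- c(crossprod(Xt, w11 * yt1 + w12 * yt2),
             crossprod(Xt, w12 * yt1 + w22 * yt2))
    beta <- tryCatch(solve(Nm, rhs), error = function(e) NULL)
    if (is.null(beta)) return(-Inf)
    r1 <- yt1 - Xt %*% beta[seq_len(p)]
    r2 <- yt2 - Xt %*% beta[p + seq_len(p)]
    quad <- sum(w11 * r1 * r1 + 2 * w12 * r1 * r2 + w22 * r2 * r2)
    ll <- -0.5 * (2 * n * log(2 * pi) + sum(log(det)) + quad)
    attr(ll, "beta") <- beta
    ll
  }
  unpack <- function(th, fix_rG = NULL) {
    g1 <- exp(th[1L]); e1 <- exp(th[2L])
    g2 <- exp(th[3L]); e2 <- exp(th[4L])
    if (is.null(fix_rG)) {
      rG <- tanh(th[5L]); rE <- tanh(th[6L])
    } else {
      rG <- fix_rG; rE <- tanh(th[5L])
    }
    list(g1 = g1, e1 = e1, g2 = g2, e2 = e2, rG = rG, rE = rE)
  }
  nll <- function(th, fix_rG = NULL) {
    th <- pmin(pmax(th, -12), 12)
    q <- unpack(th, fix_rG)
    -as.numeric(biv_ll(q$g1, q$e1, q$g2, q$e2, q$rG, q$rE))
  }

  # univariate fits seed the variance starts; phenotypic correlation the rho sign
  u1 <- .fit_vc(yt1, Xt, list(additive = diag(lam)))
  u2 <- .fit_vc(yt2, Xt, list(additive = diag(lam)))
  h1 <- max(min(unname(u1$props[1L]), 0.95), 0.05)
  h2. <- max(min(unname(u2$props[1L]), 0.95), 0.05)
  v1 <- u1$s2p; v2 <- u2$s2p
  rphen <- stats::cor(z1, z2)
  base <- log(c(h1 * v1, (1 - h1) * v1, h2. * v2, (1 - h2.) * v2))
  optimize_from <- function(starts, fix_rG = NULL) {
    best <- NULL
    for (s in starts) {
      f <- stats::optim(s, nll, fix_rG = fix_rG, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-10))
      if (is.null(best) || f$value < best$value) best <- f
    }
    pol <- suppressWarnings(
      stats::optim(best$par, nll, fix_rG = fix_rG, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12)))
    if (pol$value < best$value) best <- pol
    best
  }
  sgn <- if (is.na(rphen) || rphen == 0) 1 else sign(rphen)
  starts <- list(c(base, 0, 0),
                 c(base, atanh(0.5 * sgn), 0),
                 c(base, atanh(0.9 * sgn), atanh(0.3 * sgn)))
  best <- optimize_from(starts)
  th <- pmin(pmax(best$par, -12), 12)
  q <- unpack(th)
  ll <- biv_ll(q$g1, q$e1, q$g2, q$e2, q$rG, q$rE)
  beta <- attr(ll, "beta")

  p_rhoG <- NA_real_; lrt <- NULL
  if (pvalue) {
    b0 <- optimize_from(list(c(base, 0), c(th[1:4], th[6L])), fix_rG = 0)
    lrt <- list(statistic = max(2 * (as.numeric(ll) + b0$value), 0))
    lrt$p <- stats::pchisq(lrt$statistic, df = 1, lower.tail = FALSE)
    p_rhoG <- lrt$p
  }

  trait <- function(g, e, s) c(sigma2_g = g * s^2, sigma2_e = e * s^2,
                               h2 = g / (g + e))
  structure(list(rhoG = q$rG, rhoE = q$rE,
                 trait1 = trait(q$g1, q$e1, s1),
                 trait2 = trait(q$g2, q$e2, s2),
                 beta = beta, loglik = as.numeric(ll),
                 p_rhoG = p_rhoG, lrt_rhoG = lrt, n = n,
                 convergence = best$convergence),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate polygenic ML fit (n = %d)\n", x$n))
  cat(sprintf("  rhoG = %.3f (p = %s), rhoE = %.3f\n", x$rhoG,
              .fmt(x$p_rhoG), x$rhoE))
  cat(sprintf("  h2 trait1 = %.3f, h2 trait2 = %.3f, loglik = %.3f\n",
              x$trait1["h2"], x$trait2["h2"], x$loglik))
  invisible(x)
}

#' Liability-scale conversion for a binary trait heritability
#'
#' Extension beyond the core models: converts an observed-scale
#' heritability of a 0/1 trait (fitted as if quantitative) to the
#' liability scale via the classical threshold-model factor
#' `h2_liab = h2_obs * p(1 - p) / z^2`, where p is the prevalence and z
#' the standard normal density at the p-quantile threshold. The primary
#' analyses deliberately report the observed 0/1 scale; this post-hoc
#' transform is offered for comparability with liability-scale
#' estimates.
#'
#' @param h2_obs observed-scale heritability.
#' @param prevalence trait prevalence in (0, 1).
#' @return liability-scale heritability.
#' @export
liability_h2 <- function(h2_obs, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  z <- stats::dnorm(stats::qnorm(1 - prevalence))
  h2_obs * prevalence * (1 - prevalence) / z^2
}
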