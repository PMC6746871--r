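#' Diagnosis-group comparison with a family random effect
#'
#' Compares a quantitative score across diagnostic groups in related
#' individuals: `y = group + age + sex + g + e` with
#' `cov(g) = sigma2_g K`, fitted by the polygenic ML machinery
#' ([fit_polygenic_ml()]). The omnibus test is a Wald chi-square on the
#' group coefficients (df = groups - 1; an F version is also reported).
#' Post-hoc pairwise Wald contrasts are returned both unadjusted and
#' Holm-adjusted. Raw group means with standard errors are computed
#' model-free. Groups with fewer than 2 members are dropped with a
#' warning. With `K = I` the fit reduces to ordinary least-squares
#' ANOVA.
#'
#' @param scores numeric score vector.
#' @param diagnosis group labels, same length.
#' @param K additive relationship matrix over the same individuals.
#' @param covariates optional data frame (e.g. age, sex) entered as
#'   fixed effects.
#' @param reference reference group for the dummy coding (default:
#'   `"control"` when present, else the first level).
#' @return List of class `group_comparison`: `group_means`,
#'   `omnibus` (`statistic`, `df`, `F`, `p`), `posthoc` (pairwise
#'   contrasts with unadjusted and Holm p), `fit` (the `varcomp_fit`),
#'   `n`.
#' @export
group_comparison <- function(scores, diagnosis, K, covariates = NULL,
                             reference = NULL) {
  y <- as.numeric(scores)
  diagnosis <- as.character(diagnosis)
  stopifnot(length(diagnosis) == length(y), nrow(K) == length(y))
  tab <- table(diagnosis)
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    warning("dropping group(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(diagnosis %in% small)
    y <- y[keep]; diagnosis <- diagnosis[keep]
    K <- K[keep, keep, drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  }
  groups <- sort(unique(diagnosis))
  if (length(groups) < 2L) stop("need >= 2 groups with n >= 2")
  if (is.null(reference))
    reference <- if ("control" %in% groups) "control" else groups[1L]
  lev <- c(reference, setdiff(groups, reference))
  f <- factor(diagnosis, levels = lev)
  Xg <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  colnames(Xg) <- paste0("group:", lev[-1L])
  X <- Xg
  if (!is.null(covariates)) {
    Xc <- stats::model.matrix(~., data = as.data.frame(covariates))[, -1L, drop = FALSE]
    X <- cbind(Xg, Xc)
  }
  fit <- fit_polygenic_ml(y, K, X = X, se = FALSE, pvalues = FALSE)
  b <- fit$beta
  V <- fit$vcov_beta
  gi <- grep("^group:", names(b))
  bg <- b[gi]
  Vg <- V[gi, gi, drop = FALSE]
  W <- as.numeric(t(bg) %*% solve(Vg, bg))
  df1 <- length(gi)
  # F uses the residual-df variance rescaling, so with K = I it equals
  # the ordinary least-squares ANOVA F exactly
  df2 <- fit$n - length(b)
  Fstat <- (W / df1) * df2 / fit$n
  omnibus <- list(statistic = W, df = df1, F = Fstat, df2 = df2,
                  p = stats::pchisq(W, df1, lower.tail = FALSE))

  # pairwise contrasts among all groups (reference coef implicitly 0)
  coef_of <- function(g) if (g == reference) 0 else bg[paste0("group:", g)]
  var_of <- function(g1, g2) {
    v <- 0
    if (g1 != reference) v <- v + Vg[paste0("group:", g1), paste0("group:", g1)]
    if (g2 != reference) v <- v + Vg[paste0("group:", g2), paste0("group:", g2)]
    if (g1 != reference && g2 != reference)
      v <- v - 2 * Vg[paste0("group:", g1), paste0("group:", g2)]
    v
  }
  prs <- utils::combn(lev, 2L)
  est <- se <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs))) {
    est[k] <- coef_of(prs[2L, k]) - coef_of(prs[1L, k])
    se[k] <- sqrt(var_of(prs[1L, k], prs[2L, k]))
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(group1 = prs[1L, ], group2 = prs[2L, ],
                        estimate = est, se = se, z = z,
                        p = p, p_holm = stats::p.adjust(p, "holm"),
                        row.names = NULL)
  structure(list(group_means = group_mean_se(y, diagnosis),
                 omnibus = omnibus, posthoc = posthoc, fit = fit,
                 n = length(y), reference = reference),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (n = %d): Wald chi2(%d) = %.2f (F = %.2f), p = %s\n",
              x$n, x$omnibus$df, x$omnibus$statistic, x$omnibus$F,
              format.pval(x$omnibus$p)))
  print(x$group_means, ...)
  invisible(x)
}

#' ROC analysis of a screening score
#'
#' Threshold sweep over the observed scores with the `score >= cutoff`
#' positivity convention. The area under the curve is computed by the
#' trapezoid rule, which equals the tie-corrected Mann-Whitney statistic
#' `U / (n1 n0)` (ties counted 1/2). The AUC standard error uses the
#' Hanley-McNeil formula, the 95% CI is Wald, and the p-value tests
#' AUC = 0.5 by normal approximation. The Youden cutoff maximizes
#' sensitivity + specificity - 1 (smallest cutoff on ties).
#'
#' @param scores numeric vector.
#' @param labels binary labels (anything coercible to two classes).
#' @param positive the label treated as positive (e.g. `"bipolar"`);
#'   default: the larger of the two sorted labels.
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_se`, `ci95`, `p_auc`, `youden_cutoff`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @examples
#' roc_analysis(c(3, 2, 1, 0), c(1, 1, 0, 0), positive = 1)
#' @export
roc_analysis <- function(scores, labels, positive = NULL) {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  cls <- sort(unique(labels))
  if (length(cls) != 2L)
    stop("labels must contain exactly two classes (got ",
         length(cls), ")")
  if (is.null(positive)) positive <- cls[2L]
  if (!positive %in% cls) stop("positive class '", positive, "' not in labels")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  # trapezoid over the full curve, endpoints (0,0) and (1,1)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1L]) *
             (tpr[-length(tpr)] + tpr[-1L]) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                  (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci95 <- pmin(pmax(auc + c(-1, 1) * 1.96 * auc_se, 0), 1)
  z <- (auc - 0.5) / auc_se
  p_auc <- 2 * stats::pnorm(-abs(z))
  j <- sens + spec - 1
  youden_i <- which(j == max(j))[1L]            # thr sorted: smallest on ties
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_se = auc_se, ci95 = ci95, p_auc = p_auc,
                 youden_cutoff = thr[youden_i], youden_j = j[youden_i],
                 sens_at_cutoff = sens[youden_i],
                 spec_at_cutoff = spec[youden_i],
                 n_pos = n1, n_neg = n0, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%d pos / %d neg): AUC = %.3f (SE %.3f, 95%% CI %.2f-%.2f), p = %s\n",
              x$n_pos, x$n_neg, x$auc, x$auc_se, x$ci95[1L], x$ci95[2L],
              format.pval(x$p_auc)))
  cat(sprintf("  Youden cutoff = %g (sens %.2f, spec %.2f)\n",
              x$youden_cutoff, x$sens_at_cutoff, x$spec_at_cutoff))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x a `roc_result`.
#' @param ... passed to [plot()].
#' @export
plot.roc_result <- function(x, ...) {
  fpr <- c(1, 1 - x$specificity, 0)
  tpr <- c(1, x$sensitivity, 0)
  plot(fpr, tpr, type = "l", xlab = "1 - specificity",
       ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Familial-aggregation contrast
#'
#' Tests whether relatives of high scorers themselves score high: the
#' index set is everyone above `mean + sd_multiplier * SD` of the score;
#' the exposure set is every non-index individual with at least one
#' first- or second-degree relative (kinship `phi >= kin_threshold`,
#' default 0.125, which is robust to pedigree loops) in the index set;
#' the contrast is a Welch t-test of the score between the exposure set
#' and the remaining non-index individuals. Index individuals are
#' excluded from both sides.
#'
#' @param scores named numeric vector (names = ids) or a data frame with
#'   `id` and `score` columns.
#' @param ped a [pedigree()] containing all scored ids.
#' @param sd_multiplier cutoff multiplier (default 1.0: mean + 1 SD).
#' @param kin_threshold minimum kinship defining a close relative.
#' @return List: `cutoff`, `n_index`, `exposed` and `unexposed` group
#'   summaries (n, mean, se), `t`, `df`, `p`.
#' @export
familial_aggregation_contrast <- function(scores, ped, sd_multiplier = 1.0,
                                          kin_threshold = 0.125) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("id", "score") %in% names(scores)))
    scores <- stats::setNames(scores$score, scores$id)
  }
  ids <- names(scores)
  if (is.null(ids)) stop("scores must carry individual ids (names)")
  phi <- kinship_matrix(ped, subset = ids)
  cutoff <- mean(scores) + sd_multiplier * stats::sd(scores)
  index <- ids[scores > cutoff]
  if (!length(index)) stop("empty index set: no score exceeds the cutoff ",
                           format(cutoff))
  nonindex <- setdiff(ids, index)
  rel <- phi[nonindex, index, drop = FALSE]
  diag_self <- outer(nonindex, index, "==")    # guard, sets are disjoint
  exposed <- nonindex[apply(rel >= kin_threshold & !diag_self, 1L, any)]
  unexposed <- setdiff(nonindex, exposed)
  if (length(exposed) < 2L || length(unexposed) < 2L)
    stop("need >= 2 individuals on each side of the contrast (exposed n = ",
         length(exposed), ")")
  tt <- stats::t.test(scores[exposed], scores[unexposed])
  summ <- function(v) list(n = length(v), mean = mean(v),
                           se = stats::sd(v) / sqrt(length(v)))
  list(cutoff = cutoff, n_index = length(index),
       exposed = summ(scores[exposed]), unexposed = summ(scores[unexposed]),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Trait-vs-state contrast and age correlation
#'
#' `trait_state_contrast` compares scores between currently symptomatic
#' and remitted individuals with a Welch t-test (a trait-like score
#' should not differ by current state). `age_correlation` is the Pearson
#' correlation of score with age, with the usual t-based p-value.
#'
#' @param scores numeric vector.
#' @param status labels with two levels (e.g. `"current"`,
#'   `"remitted"`).
#' @return `trait_state_contrast`: list(`t`, `df`, `p`, group means);
#'   `age_correlation`: list(`r`, `p`, `n`).
#' @export
trait_state_contrast <- function(scores, status) {
  status <- as.character(status)
  lv <- unique(status)
  if (length(lv) != 2L) stop("status must have exactly two levels")
  a <- scores[status == lv[1L]]; b <- scores[status == lv[2L]]
  if (length(a) < 3L || length(b) < 2L) stop("groups too small (n < 3)")
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       means = stats::setNames(c(mean(a), mean(b)), lv))
}

#' @rdname trait_state_contrast
#' @param age numeric age vector.
#' @export
age_correlation <- function(scores, age) {
  ok <- !is.na(scores) & !is.na(age)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs")
  ct <- stats::cor.test(scores[ok], age[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
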