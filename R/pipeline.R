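#' Write named scenario fixtures to disk
#'
#' Generates a synthetic cohort for a named scenario and writes a
#' LINKAGE pedigree file, a phenotype CSV (items + covariates +
#' diagnosis + household) and a `truth.json` with the generating
#' parameters. Scenarios: `"null"` (h2 = 0, c2 = 0), `"study_like"`
#' (h2 = 0.46, c2 = 0.12, rhoG = 0.55, five diagnosis groups) and
#' `"high_h2"` (h2 = 0.8). Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param scenario one of `"null"`, `"study_like"`, `"high_h2"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
make_fixtures <- function(seed = 1L, scenario = c("study_like", "null", "high_h2"),
                          dir = ".") {
  scenario <- match.arg(scenario)
  cfg <- switch(scenario,
    null       = sim_config(h2_true = 0, c2_true = 0, rhoG_true = 0, seed = seed),
    study_like = sim_config(h2_true = 0.46, c2_true = 0.12, rhoG_true = 0.55,
                            seed = seed),
    high_h2    = sim_config(h2_true = 0.8, c2_true = 0, seed = seed))
  cohort <- simulate_cohort(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(pedigree = file.path(dir, "pedigree.ped"),
                phenotypes = file.path(dir, "phenotypes.csv"),
                truth = file.path(dir, "truth.json"))
  write_pedigree(cohort$pedigree, paths$pedigree)
  utils::write.csv(cohort$phenotypes, paths$phenotypes, row.names = FALSE)
  jsonlite::write_json(c(unclass(cfg), list(scenario = scenario)),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

.default_run_config <- function() {
  list(pedigree = NULL, phenotypes = NULL, out_dir = ".",
       pedigree_dialect = "linkage",
       analyses = list(heritability = TRUE, household = TRUE,
                       bivariate = TRUE, group_comparison = TRUE,
                       roc = TRUE, familiality = TRUE),
       subsamples = c("whole", "no_bipolar", "controls"),
       transform = TRUE, missing_policy = "fail", seed = 1L,
       verbose = TRUE)
}

#' Run the full pedigree analysis pipeline
#'
#' Configuration-driven end-to-end analysis: score the QBS items,
#' inverse-normal transform, compute kinship and household matrices from
#' the pedigree, fit the polygenic models (unadjusted and
#' household-adjusted) on each configured subsample (`whole`,
#' `no_bipolar`, `controls`), fit the bivariate trait-diagnosis model,
#' and run the clinical-validity analyses (group comparison, ROC against
#' each non-bipolar group, familial aggregation). Subsample kinship is
#' always extracted from the full pedigree so ancestral links are
#' retained. Writes `report.json`, `heritability.tsv`, `roc.tsv` and a
#' plain-text log to `out_dir`.
#'
#' @param config a named list, or the path of a YAML file, with entries
#'   `pedigree`, `phenotypes` (file paths), `out_dir`, `analyses`
#'   (logical toggles), `subsamples`, `transform`, `seed` (see
#'   `pedherit:::.default_run_config()` for the defaults).
#' @return Invisibly, the report list (also serialized to JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_run_config(), config)
  t0 <- Sys.time()
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    if (isTRUE(cfg$verbose)) message(line)
  }
  stage <- "config"
  result <- tryCatch({
    if (is.null(cfg$pedigree) || !file.exists(cfg$pedigree))
      stop("pedigree file not found: ", cfg$pedigree %||% "<missing>")
    if (is.null(cfg$phenotypes) || !file.exists(cfg$phenotypes))
      stop("phenotype file not found: ", cfg$phenotypes %||% "<missing>")
    set.seed(cfg$seed)

    stage <- "read"
    ped <- read_pedigree(cfg$pedigree, cfg$pedigree_dialect)
    phen <- utils::read.csv(cfg$phenotypes)
    logmsg("read %d pedigree members, %d phenotyped", nrow(ped), nrow(phen))

    stage <- "score"
    if (any(grepl("^item", names(phen)))) {
      phen <- score_table(phen, missing_policy = cfg$missing_policy)
      logmsg("scored %d QBS responses", nrow(phen))
    } else if (!"qbs_total" %in% names(phen)) {
      stop("phenotypes need item_* columns or a precomputed qbs_total")
    }

    stage <- "kinship"
    ids <- as.character(phen$id)
    K <- 2 * kinship_matrix(ped, subset = ids)
    H <- household_matrix(ped, ids = ids)
    report <- list(package = "pedherit",
                   version = as.character(utils::packageVersion("pedherit")),
                   seed = cfg$seed,
                   # hash of the analytic configuration (output location
                   # and verbosity do not change the analysis)
                   config_hash = .config_hash(
                     cfg[setdiff(names(cfg), c("out_dir", "verbose"))]),
                   n_pedigree = nrow(ped), n_phenotyped = nrow(phen))

    subsample_rows <- function(which) switch(which,
      whole = rep(TRUE, nrow(phen)),
      no_bipolar = phen$diagnosis != "bipolar",
      controls = phen$diagnosis == "control",
      stop("unknown subsample: ", which))

    y_raw <- phen$qbs_total
    covars <- phen[, intersect(c("age", "sex"), names(phen)), drop = FALSE]

    if (isTRUE(cfg$analyses$heritability)) {
      stage <- "heritability"
      herit <- list()
      for (ss in cfg$subsamples) {
        rows <- subsample_rows(ss)
        yk <- y_raw[rows]
        if (cfg$transform) yk <- inverse_normal_transform(yk)
        Xk <- stats::model.matrix(~., data = covars[rows, , drop = FALSE])[, -1L, drop = FALSE]
        un <- fit_polygenic_ml(yk, K[rows, rows], X = Xk)
        ad <- if (isTRUE(cfg$analyses$household))
          fit_polygenic_ml(yk, K[rows, rows], X = Xk, H = H[rows, rows])
        else NULL
        herit[[ss]] <- list(
          n = sum(rows),
          unadjusted = list(h2 = un$h2, se = un$se_h2, p = un$p_h2,
                            covariate_R2 = un$covariate_R2),
          adjusted = if (!is.null(ad))
            list(h2 = ad$h2, se = ad$se_h2, p = ad$p_h2,
                 household = ad$c2, se_household = ad$se_c2,
                 p_household = ad$p_c2, covariate_R2 = ad$covariate_R2))
        logmsg("heritability [%s]: h2 = %.3f (p = %.2g)", ss, un$h2, un$p_h2)
      }
      report$heritability <- herit
    }

    if (isTRUE(cfg$analyses$bivariate) && "diagnosis" %in% names(phen)) {
      stage <- "bivariate"
      rows <- phen$diagnosis %in% c("bipolar", "control")
      y1 <- y_raw[rows]
      y2 <- as.integer(phen$diagnosis[rows] == "bipolar")
      if (length(unique(y2)) == 2L) {
        Xk <- stats::model.matrix(~., data = covars[rows, , drop = FALSE])[, -1L, drop = FALSE]
        bv <- fit_bivariate(y1, y2, K[rows, rows], X = Xk,
                            transform1 = cfg$transform)
        report$bivariate <- list(rhoG = bv$rhoG, rhoE = bv$rhoE,
                                 p_rhoG = bv$p_rhoG,
                                 h2_trait = unname(bv$trait1["h2"]),
                                 h2_diagnosis = unname(bv$trait2["h2"]))
        logmsg("bivariate: rhoG = %.3f (p = %.2g)", bv$rhoG, bv$p_rhoG)
      }
    }

    if (isTRUE(cfg$analyses$group_comparison) && "diagnosis" %in% names(phen)) {
      stage <- "group_comparison"
      gc <- group_comparison(y_raw, phen$diagnosis, K, covariates = covars)
      report$group_comparison <- list(
        omnibus = gc$omnibus,
        group_means = gc$group_means,
        posthoc = gc$posthoc)
      logmsg("group comparison: chi2(%d) = %.2f, p = %.2g",
             gc$omnibus$df, gc$omnibus$statistic, gc$omnibus$p)
    }

    if (isTRUE(cfg$analyses$roc) && "diagnosis" %in% names(phen)) {
      stage <- "roc"
      rocs <- list()
      for (neg in c("control", "mdd", "other")) {
        rows <- phen$diagnosis %in% c("bipolar", neg)
        if (length(unique(phen$diagnosis[rows])) == 2L) {
          r <- roc_analysis(y_raw[rows], phen$diagnosis[rows],
                            positive = "bipolar")
          rocs[[paste0("bipolar_vs_", neg)]] <-
            list(auc = r$auc, se = r$auc_se, ci95 = r$ci95, p = r$p_auc,
                 youden_cutoff = r$youden_cutoff,
                 sensitivity = r$sens_at_cutoff,
                 specificity = r$spec_at_cutoff)
        }
      }
      report$roc <- rocs
      logmsg("roc: %d comparisons", length(rocs))
    }

    if (isTRUE(cfg$analyses$familiality)) {
      stage <- "familiality"
      fa <- familial_aggregation_contrast(
        stats::setNames(y_raw, ids), ped)
      report$familiality <- fa
      logmsg("familiality: t = %.2f, p = %.2g", fa$t, fa$p)
    }

    stage <- "write"
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (!is.null(report$heritability))
      utils::write.table(.herit_tsv(report$heritability),
                         file.path(cfg$out_dir, "heritability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$roc))
      utils::write.table(.roc_tsv(report$roc),
                         file.path(cfg$out_dir, "roc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    logmsg("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    report
  }, error = function(e) {
    logmsg("ERROR in stage '%s': %s", stage, conditionMessage(e))
    if (dir.exists(cfg$out_dir %||% "."))
      writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
  invisible(result)
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, force = TRUE)
  # tiny stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Table-3-style layout: one row per subsample, unadjusted vs adjusted
.herit_tsv <- function(herit) {
  do.call(rbind, lapply(names(herit), function(ss) {
    x <- herit[[ss]]
    data.frame(subsample = ss, n = x$n,
               h2_unadj = x$unadjusted$h2, se_unadj = .naify(x$unadjusted$se),
               p_unadj = x$unadjusted$p,
               h2_adj = .naify(x$adjusted$h2), se_adj = .naify(x$adjusted$se),
               p_adj = .naify(x$adjusted$p),
               household = .naify(x$adjusted$household),
               p_household = .naify(x$adjusted$p_household),
               covariate_R2 = x$unadjusted$covariate_R2)
  }))
}

.roc_tsv <- function(rocs) {
  do.call(rbind, lapply(names(rocs), function(nm) {
    r <- rocs[[nm]]
    data.frame(comparison = nm, sensitivity = r$sensitivity,
               specificity = r$specificity, auc = r$auc, se = r$se,
               ci_lo = r$ci95[1L], ci_hi = r$ci95[2L], p = r$p,
               youden_cutoff = r$youden_cutoff)
  }))
}

.naify <- function(x) if (is.null(x)) NA_real_ else x
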