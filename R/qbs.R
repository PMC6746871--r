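#' @name qbs_items
#' @title QBS item structure
#' @description
#' The Quantitative Bipolarity Scale (QBS) consists of 24 symptom items
#' plus a global summary item asking how well the scale as a whole
#' describes the respondent, each self-rated 0-3. Predefined subscales:
#' items 3-8 are depressive symptoms, items 11-24 manic symptoms, and
#' items 1, 2, 9, 10 mood-fluctuation symptoms. The global item belongs
#' to no subscale. The total is the sum of all 25 ratings (range 0-75);
#' subscale ranges are 0-18 (depression), 0-42 (mania) and 0-12 (mood
#' fluctuation).
#' @keywords internal
NULL

.qbs_sets <- list(
  depression = 3:8,
  mania      = 11:24,
  moodfluct  = c(1L, 2L, 9L, 10L),
  total      = 1:25
)
.qbs_n_items <- 25L
.qbs_global_item <- 25L

# round-half-up to integer (prorated sums keep the integer score contract)
.round_half_up <- function(x) floor(x + 0.5)

.qbs_sum <- function(items, set, policy) {
  v <- items[set]
  n_miss <- sum(is.na(v))
  if (n_miss == 0L) return(sum(v))
  if (policy == "fail")
    stop("missing item response(s); use missing_policy = 'prorate' to prorate")
  n_ans <- length(v) - n_miss
  if (n_ans == 0L)
    stop("all items missing in a score set; cannot prorate")
  .round_half_up(sum(v, na.rm = TRUE) * length(v) / n_ans)
}

#' Score one QBS response
#'
#' Computes the QBS total and the depression, mania and mood-fluctuation
#' subscores from a vector of 25 item ratings (items 1-24 plus the
#' global summary item), each in 0-3.
#'
#' @param items numeric vector of length 25, values in `{0,1,2,3}` or
#'   `NA` for a skipped item.
#' @param missing_policy `"fail"` (default: any missing item is an
#'   error) or `"prorate"` (each affected sum is scaled by set size /
#'   answered-in-set and rounded half-up).
#' @param include_global logical; include the global summary item in the
#'   total (the default, matching the scale's scoring rule). Set `FALSE`
#'   for a 24-item sensitivity total.
#' @return List with `total`, `depression`, `mania`, `moodfluct` and
#'   `n_missing`.
#' @examples
#' score_qbs(rep(3, 25))  # total 75, subscores 18 / 42 / 12
#' @export
score_qbs <- function(items, missing_policy = c("fail", "prorate"),
                      include_global = TRUE) {
  missing_policy <- match.arg(missing_policy)
  items <- as.numeric(items)
  if (length(items) != .qbs_n_items)
    stop("expected exactly ", .qbs_n_items, " item responses, got ",
         length(items))
  ok <- is.na(items) | (items %in% 0:3)
  if (!all(ok))
    stop("item rating(s) outside 0..3 at position(s): ",
         paste(which(!ok), collapse = ", "))
  total_set <- if (include_global) .qbs_sets$total else 1:24
  list(total      = .qbs_sum(items, total_set, missing_policy),
       depression = .qbs_sum(items, .qbs_sets$depression, missing_policy),
       mania      = .qbs_sum(items, .qbs_sets$mania, missing_policy),
       moodfluct  = .qbs_sum(items, .qbs_sets$moodfluct, missing_policy),
       n_missing  = sum(is.na(items)))
}

#' Score a table of QBS responses
#'
#' Vectorized scoring over individuals. Input columns `item_01` ..
#' `item_24` and `item_global` (or any 25 columns matching
#' `^item`, in item order); an `id` column is required and must be
#' unique. Any further columns (age, sex, diagnosis, household) are
#' carried through. When a `diagnosis` column is present, per-group
#' mean and standard error of the total are attached as attribute
#' `group_summary`.
#'
#' @param responses data frame of item responses.
#' @param missing_policy passed to [score_qbs()].
#' @param include_global passed to [score_qbs()].
#' @return The input data frame with columns `qbs_total`,
#'   `qbs_depression`, `qbs_mania`, `qbs_moodfluct`, `qbs_n_missing`
#'   appended (item columns retained).
#' @export
score_table <- function(responses, missing_policy = c("fail", "prorate"),
                        include_global = TRUE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is.data.frame(responses))
  if (!"id" %in% names(responses)) stop("responses must have an 'id' column")
  if (anyDuplicated(responses$id))
    stop("duplicate id(s) in responses: ",
         paste(unique(responses$id[duplicated(responses$id)]), collapse = ", "))
  item_cols <- grep("^item", names(responses), value = TRUE)
  if (length(item_cols) != .qbs_n_items)
    stop("expected ", .qbs_n_items, " item columns (prefix 'item'), found ",
         length(item_cols))
  out <- responses
  if (nrow(responses) == 0L) {
    out$qbs_total <- out$qbs_depression <- out$qbs_mania <-
      out$qbs_moodfluct <- out$qbs_n_missing <- numeric(0)
    return(out)
  }
  sc <- lapply(seq_len(nrow(responses)), function(i)
    score_qbs(as.numeric(responses[i, item_cols]), missing_policy,
              include_global))
  out$qbs_total      <- vapply(sc, `[[`, numeric(1), "total")
  out$qbs_depression <- vapply(sc, `[[`, numeric(1), "depression")
  out$qbs_mania      <- vapply(sc, `[[`, numeric(1), "mania")
  out$qbs_moodfluct  <- vapply(sc, `[[`, numeric(1), "moodfluct")
  out$qbs_n_missing  <- vapply(sc, `[[`, numeric(1), "n_missing")
  if ("diagnosis" %in% names(out)) {
    attr(out, "group_summary") <- group_mean_se(out$qbs_total, out$diagnosis)
  }
  out
}

#' Model-free group means with standard errors
#'
#' @param y numeric vector.
#' @param group grouping labels.
#' @return data frame with `group`, `n`, `mean`, `se`.
#' @export
group_mean_se <- function(y, group) {
  group <- as.character(group)
  g <- sort(unique(group))
  data.frame(
    group = g,
    n = vapply(g, function(k) sum(group == k), integer(1)),
    mean = vapply(g, function(k) mean(y[group == k]), numeric(1)),
    se = vapply(g, function(k) {
      v <- y[group == k]
      if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL)
}
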