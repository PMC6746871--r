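#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with columns `id`, `father`, `mother`
#' (`NA` for founders) and `sex` (`"male"`, `"female"`, `"unknown"`),
#' stored in topological order so that parents always precede their
#' children. Construction validates the genealogy: ids must be unique,
#' referenced parents must exist, fathers must not be recorded female nor
#' mothers male, the graph must be acyclic, and `"unknown"` sex is only
#' accepted for founders. Individuals with exactly one recorded parent are
#' completed with a synthesized anonymous founder so that the known half
#' of the relationship is preserved.
#'
#' @param id character or integer vector of individual identifiers.
#' @param father,mother parent identifiers; `NA`, `""` or `"0"` denote a
#'   missing parent (founder).
#' @param sex `"male"`/`"female"`/`"unknown"`, or LINKAGE codes 1/2/0.
#' @return An object of class `pedigree`: a data frame in topological
#'   order with attribute `n_synthesized` (count of anonymous founders
#'   added for half-specified parentage).
#' @examples
#' ped <- pedigree(id = c("f", "m", "c"),
#'                 father = c(NA, NA, "f"),
#'                 mother = c(NA, NA, "m"),
#'                 sex = c("male", "female", "female"))
#' @export
pedigree <- function(id, father, mother, sex) {
  id <- as.character(id)
  father <- .clean_parent(father)
  mother <- .clean_parent(mother)
  sex <- .decode_sex(sex)
  if (anyDuplicated(id))
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!is.na(father) & father == id) || any(!is.na(mother) & mother == id))
    stop("cycle detected: individual listed as its own parent: ",
         paste(id[(!is.na(father) & father == id) |
                  (!is.na(mother) & mother == id)], collapse = ", "))

  # complete half-specified parentage with anonymous founders
  n_syn <- 0L
  half_f <- which(is.na(father) & !is.na(mother))
  half_m <- which(!is.na(father) & is.na(mother))
  syn <- function(k) sprintf(".anon%d", k)
  add_id <- character(0); add_sex <- character(0)
  for (i in half_f) {
    n_syn <- n_syn + 1L
    father[i] <- syn(n_syn); add_id <- c(add_id, syn(n_syn))
    add_sex <- c(add_sex, "male")
  }
  for (i in half_m) {
    n_syn <- n_syn + 1L
    mother[i] <- syn(n_syn); add_id <- c(add_id, syn(n_syn))
    add_sex <- c(add_sex, "female")
  }
  if (n_syn > 0L) {
    id <- c(id, add_id)
    father <- c(father, rep(NA_character_, n_syn))
    mother <- c(mother, rep(NA_character_, n_syn))
    sex <- c(sex, add_sex)
  }

  missing_par <- setdiff(c(father, mother), c(id, NA))
  if (length(missing_par))
    stop("referenced parent(s) not in pedigree: ",
         paste(missing_par, collapse = ", "))

  fsex <- sex[match(father, id)]
  if (any(!is.na(fsex) & fsex == "female"))
    stop("parent sex conflict: father recorded as female: ",
         paste(unique(father[!is.na(fsex) & fsex == "female"]), collapse = ", "))
  msex <- sex[match(mother, id)]
  if (any(!is.na(msex) & msex == "male"))
    stop("parent sex conflict: mother recorded as male: ",
         paste(unique(mother[!is.na(msex) & msex == "male"]), collapse = ", "))

  ord <- .topo_order(id, father, mother)
  df <- data.frame(id = id, father = father, mother = mother, sex = sex,
                   stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(df) <- NULL

  is_founder <- is.na(df$father)
  if (any(df$sex == "unknown" & !is_founder))
    stop("sex 'unknown' is only permitted for founders: ",
         paste(df$id[df$sex == "unknown" & !is_founder], collapse = ", "))

  structure(df, class = c("pedigree", "data.frame"), n_synthesized = n_syn)
}

.clean_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "")] <- NA_character_
  x
}

.decode_sex <- function(sex) {
  if (is.numeric(sex)) sex <- as.character(sex)
  sex <- as.character(sex)
  map <- c("1" = "male", "2" = "female", "0" = "unknown",
           male = "male", female = "female", unknown = "unknown",
           M = "male", F = "female", m = "male", f = "female")
  out <- unname(map[sex])
  out[is.na(sex)] <- "unknown"
  if (any(is.na(out)))
    stop("unrecognized sex code(s): ",
         paste(unique(sex[is.na(out)]), collapse = ", "))
  out
}

# Kahn-style topological sort; reports members of a cycle when stuck.
.topo_order <- function(id, father, mother) {
  n <- length(id)
  fi <- match(father, id)
  mi <- match(mother, id)
  placed <- logical(n)
  ord <- integer(0)
  f_ok <- function() is.na(fi) | c(placed, FALSE)[ifelse(is.na(fi), n + 1L, fi)]
  m_ok <- function() is.na(mi) | c(placed, FALSE)[ifelse(is.na(mi), n + 1L, mi)]
  repeat {
    ready <- which(!placed & f_ok() & m_ok())
    if (!length(ready)) {
      if (all(placed)) break
      stop("cycle detected in pedigree involving: ",
           paste(id[!placed], collapse = ", "))
    }
    placed[ready] <- TRUE
    ord <- c(ord, ready)
    if (all(placed)) break
  }
  ord
}

#' Read a pedigree file
#'
#' Reads LINKAGE-style whitespace/tab-delimited files (columns `id`,
#' `father`, `mother`, `sex`; no header; sex coded 1 = male, 2 = female,
#' 0 = unknown; parent `0` = missing) or a CSV dialect with a header
#' containing at least those four columns.
#'
#' @param path file path.
#' @param dialect `"linkage"` or `"csv"`.
#' @return A validated [pedigree()] in topological order.
#' @export
read_pedigree <- function(path, dialect = c("linkage", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (dialect == "linkage") {
    df <- utils::read.table(path, header = FALSE, colClasses = "character")
    if (ncol(df) < 4L)
      stop("LINKAGE pedigree needs >= 4 columns (id, father, mother, sex)")
    names(df)[1:4] <- c("id", "father", "mother", "sex")
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    need <- c("id", "father", "mother", "sex")
    if (!all(need %in% names(df)))
      stop("CSV pedigree must have columns: ", paste(need, collapse = ", "))
  }
  pedigree(df$id, df$father, df$mother, df$sex)
}

#' Write a pedigree file
#'
#' Emits the same dialects accepted by [read_pedigree()], rows in
#' topological order, so that a read/write round trip is stable.
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @param dialect `"linkage"` or `"csv"`.
#' @export
write_pedigree <- function(ped, path, dialect = c("linkage", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ped, "pedigree"))
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  out <- data.frame(id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = unname(sex_code))
  if (dialect == "linkage") {
    utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = "\t")
  } else {
    utils::write.csv(out, path, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Kinship coefficient matrix
#'
#' Computes the matrix of kinship coefficients phi by the standard
#' recursion over the pedigree in generation order:
#' `phi(i,i) = (1 + phi(father_i, mother_i)) / 2` and
#' `phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2` for j already
#' processed; founders are mutually unrelated and non-inbred. Inbreeding
#' loops require no special casing. `2 * phi` is the additive
#' (numerator) relationship matrix used by the variance-components
#' models.
#'
#' @param ped a [pedigree()].
#' @param subset optional character vector of ids; rows/columns are
#'   extracted after the full computation so relatedness through
#'   non-subset ancestors is preserved.
#' @return Symmetric numeric matrix with dimnames = ids.
#' @examples
#' ped <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
#'                 c("male", "female", "female"))
#' kinship_matrix(ped)["f", "c"]  # 0.25
#' @export
kinship_matrix <- function(ped, subset = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fi[i]; m <- mi[i]
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        v <- 0.5 * (phi[f, prev] + phi[m, prev])
        phi[i, prev] <- v
        phi[prev, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[f, m])
    }
  }
  if (!is.null(subset)) {
    subset <- as.character(subset)
    bad <- setdiff(subset, ped$id)
    if (length(bad))
      stop("subset id(s) not in pedigree: ", paste(bad, collapse = ", "))
    phi <- phi[subset, subset, drop = FALSE]
  }
  phi
}

#' Monte-Carlo gene-dropping estimate of kinship
#'
#' Drops two distinct alleles per founder down the pedigree with fair
#' Mendelian sampling and estimates `phi(i,j)` as the probability that a
#' random allele from i is identical by descent to a random allele from
#' j. Serves as a simulation oracle for [kinship_matrix()], including on
#' pedigrees with inbreeding loops.
#'
#' @param ped a [pedigree()].
#' @param n_reps number of independent drops (>= 1000).
#' @param seed integer seed.
#' @return List with `phi` (estimate matrix) and `se` (Monte-Carlo
#'   standard error matrix), both with id dimnames.
#' @export
gene_drop_kinship <- function(ped, n_reps = 10000L, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  if (n_reps < 1000L) stop("n_reps must be >= 1000")
  set.seed(seed)
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  a1 <- matrix(0L, n_reps, n)
  a2 <- matrix(0L, n_reps, n)
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      a1[, i] <- 2L * i - 1L
      a2[, i] <- 2L * i
    } else {
      u <- stats::runif(n_reps) < 0.5
      a1[, i] <- ifelse(u, a1[, fi[i]], a2[, fi[i]])
      u <- stats::runif(n_reps) < 0.5
      a2[, i] <- ifelse(u, a1[, mi[i]], a2[, mi[i]])
    }
  }
  phi <- se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- 0.25 * ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
                     (a2[, i] == a1[, j]) + (a2[, i] == a2[, j]))
      phi[i, j] <- phi[j, i] <- mean(ibd)
      se[i, j] <- se[j, i] <- stats::sd(ibd) / sqrt(n_reps)
    }
  }
  list(phi = phi, se = se, n_reps = n_reps)
}

#' Household (shared-environment) incidence matrix
#'
#' Builds the symmetric 0/1 matrix H with `H[i,j] = 1` when i and j share
#' a household. The default grouping places full siblings (same father
#' and same mother) in one household; founders and singletons form
#' singleton households. An explicit mapping can be supplied instead,
#' since real households also contain parents.
#'
#' @param ped a [pedigree()].
#' @param grouping `"sibship"` or `"explicit"`.
#' @param explicit_ids named character vector mapping every id in `ids`
#'   to a household label (required for `grouping = "explicit"`).
#' @param ids ids to include (default: all pedigree members).
#' @return Symmetric 0/1 matrix with attribute `household` (the label
#'   vector).
#' @export
household_matrix <- function(ped, grouping = c("sibship", "explicit"),
                             explicit_ids = NULL, ids = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ids)) ids <- ped$id
  ids <- as.character(ids)
  bad <- setdiff(ids, ped$id)
  if (length(bad)) stop("id(s) not in pedigree: ", paste(bad, collapse = ", "))
  if (grouping == "sibship") {
    i <- match(ids, ped$id)
    hh <- ifelse(is.na(ped$father[i]),
                 paste0("solo:", ids),
                 paste0("sib:", ped$father[i], "+", ped$mother[i]))
  } else {
    if (is.null(explicit_ids) || !all(ids %in% names(explicit_ids)))
      stop("explicit household map must cover every id")
    hh <- as.character(explicit_ids[ids])
  }
  H <- outer(hh, hh, "==") * 1
  dimnames(H) <- list(ids, ids)
  attr(H, "household") <- stats::setNames(hh, ids)
  H
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$father))
  cat(sprintf("pedigree: %d individuals (%d founders, %d synthesized)\n",
              nrow(x), founders, attr(x, "n_synthesized") %||% 0L))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
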