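#' Build a cluster-by-tissue EST count matrix
#' @param membership `data.frame` from [cluster_membership].
#' @param alignments an [est_alignments] table carrying tissue labels.
#' @param tissues optional tissue levels (column order).
#' @return integer matrix, rows = cluster ids, columns = tissues.
#' @export
build_expression_matrix <- function(membership, alignments, tissues = NULL) {
  tissue <- alignments$tissue[match(membership$est_id, alignments$est_id)]
  if (is.null(tissues)) tissues <- sort(unique(tissue))
  tab <- table(factor(membership$cluster_id),
               factor(tissue, levels = tissues))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Two-sided Fisher's exact test and sample odds ratio for a 2x2 table
#'
#' The two-sided p-value follows the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. The odds
#' ratio is the unconditional cross-product ratio `(a*d)/(b*c)`, reported
#' as `Inf` when `b*c == 0` with `a*d > 0`, `0` in the converse case and
#' `NaN` when both products vanish.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("negative entry in 2x2 table")
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  N <- a + b + c_ + d
  if (N < 1) stop("empty table")
  m <- a + b       # row-1 total
  k <- a + c_      # column-1 total
  support <- max(0L, m + k - N):min(m, k)
  probs <- stats::dhyper(support, k, N - k, m)
  p_obs <- probs[support == a]
  # numeric slack keeps equal-probability tables on the "included" side
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  ad <- a * d; bc <- b * c_
  or_ <- if (ad == 0 && bc == 0) NaN
         else if (bc == 0) Inf
         else if (ad == 0) 0
         else ad / bc
  list(p_value = min(p, 1), odds_ratio = or_)
}

#' Call tissue-specific clusters from EST counts
#'
#' Rows with fewer than `min_total` ESTs are skipped. For each remaining
#' cluster and tissue, a 2x2 table of (this cluster vs all others) x (this
#' tissue vs all others) is tested with [fisher_exact_2x2]. A cluster is
#' called specific to at most one tissue: among tissues passing both the
#' p-value and odds-ratio thresholds, the one with the highest odds ratio
#' wins.
#'
#' @param mat cluster-by-tissue count matrix.
#' @param min_total minimum ESTs per cluster to test (default 10).
#' @param p_threshold call threshold on the two-sided p (default 1e-3,
#'   strict `<`).
#' @param or_threshold call threshold on the odds ratio (default 10,
#'   strict `>`).
#' @return `data.frame` with one row per tested cluster-tissue pair:
#'   `cluster_id`, `tissue`, `p_value`, `odds_ratio`, `significant`.
#' @export
call_tissue_specific <- function(mat, min_total = 10L, p_threshold = 1e-3,
                                 or_threshold = 10) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least two tissues")
  if (any(mat < 0)) stop("negative count")
  row_tot <- rowSums(mat); col_tot <- colSums(mat); N <- sum(mat)
  rows <- which(row_tot >= min_total)
  out <- vector("list", length(rows) * ncol(mat))
  z <- 0L
  for (r in rows) {
    for (t in seq_len(ncol(mat))) {
      n_rt <- mat[r, t]
      tab <- matrix(c(n_rt, row_tot[r] - n_rt,
                      col_tot[t] - n_rt, N - row_tot[r] - col_tot[t] + n_rt),
                    2L, 2L, byrow = TRUE)
      ft <- fisher_exact_2x2(tab)
      z <- z + 1L
      out[[z]] <- data.frame(cluster_id = rownames(mat)[r],
                             tissue = colnames(mat)[t],
                             p_value = ft$p_value,
                             odds_ratio = ft$odds_ratio,
                             stringsAsFactors = FALSE)
    }
  }
  if (!z)
    return(data.frame(cluster_id = character(0), tissue = character(0),
                      p_value = numeric(0), odds_ratio = numeric(0),
                      significant = logical(0)))
  res <- do.call(rbind, out[seq_len(z)])
  pass <- res$p_value < p_threshold & !is.nan(res$odds_ratio) &
    res$odds_ratio > or_threshold
  res$significant <- FALSE
  for (cid in unique(res$cluster_id[pass])) {
    sel <- which(res$cluster_id == cid & pass)
    best <- sel[order(-res$odds_ratio[sel], res$tissue[sel])][1L]
    res$significant[best] <- TRUE
  }
  rownames(res) <- NULL
  res
}

#' Pearson correlation of expression profiles across species
#'
#' Counts are converted to within-species tissue proportions (each tissue
#' column divided by its library total) before correlating, so library
#' depth differences do not dominate; set `normalize = FALSE` for raw
#' counts. `per_tissue` mode correlates across genes for each tissue and
#' species pair; `per_gene` mode correlates across tissues for each gene.
#' Two-sided p-values come from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param matrices named list of per-species count matrices over shared
#'   row (gene) and column (tissue) labels.
#' @param mode `"per_tissue"` or `"per_gene"`.
#' @param normalize convert to within-species proportions first.
#' @return `data.frame` with `unit`, `species1`, `species2`, `r`,
#'   `p_value`, `n`. `p_value` is `NA` when `n < 3`.
#' @export
cross_species_correlation <- function(matrices,
                                      mode = c("per_tissue", "per_gene"),
                                      normalize = TRUE) {
  mode <- match.arg(mode)
  if (length(matrices) < 2L) stop("need at least two species")
  ref <- matrices[[1L]]
  for (m in matrices[-1L])
    if (!identical(dimnames(m), dimnames(ref)))
      stop("species matrices must share row and column labels")
  if (normalize)
    matrices <- lapply(matrices, function(m) {
      tot <- colSums(m); tot[tot == 0] <- 1
      sweep(m, 2L, tot, "/")
    })
  species <- names(matrices) %||% paste0("species", seq_along(matrices))
  units <- if (mode == "per_tissue") colnames(ref) else rownames(ref)
  out <- list()
  for (i in seq_len(length(matrices) - 1L)) {
    for (j in seq(i + 1L, length(matrices))) {
      for (u in units) {
        x <- if (mode == "per_tissue") matrices[[i]][, u] else matrices[[i]][u, ]
        y <- if (mode == "per_tissue") matrices[[j]][, u] else matrices[[j]][u, ]
        n <- length(x)
        r <- suppressWarnings(stats::cor(x, y))
        p <- if (n >= 3 && is.finite(r) && abs(r) < 1) {
          tval <- r * sqrt((n - 2) / (1 - r^2))
          2 * stats::pt(-abs(tval), df = n - 2)
        } else if (n >= 3 && is.finite(r)) 0 else NA_real_
        out[[length(out) + 1L]] <-
          data.frame(unit = u, species1 = species[i], species2 = species[j],
                     r = r, p_value = p, n = n, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pick one expression row per gene
#'
#' When several candidate rows (e.g. several UniGene clusters) map to one
#' gene, the row with the largest total EST count is kept; ties go to the
#' lexicographically smallest id.
#'
#' @param candidates matrix (or data.frame) of counts with candidate ids
#'   as row names.
#' @return the selected row name.
#' @export
select_unigene_row <- function(candidates) {
  m <- as.matrix(candidates)
  if (!nrow(m)) stop("no candidate rows")
  tot <- rowSums(m)
  ids <- rownames(m)
  ids[order(-tot, ids)][1L]
}
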