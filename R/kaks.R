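# Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor multiple-hit correction. Synonymous site fractions are
# obtained by enumerating the three single-base changes at each codon
# position under the standard genetic code (changes to stop codons count
# as non-synonymous); differences between codons are counted over all
# minimal substitution paths averaged equally, excluding paths through
# stop codons.

codon_env <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc_tab <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    codons <- names(gc_tab)
    syn_sites <- stats::setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      if (gc_tab[[cd]] == "*") { syn_sites[cd] <- NA_real_; next }
      s <- 0
      for (p in 1:3) {
        orig <- substr(cd, p, p)
        for (b in setdiff(bases, orig)) {
          mut <- cd
          substr(mut, p, p) <- b
          if (gc_tab[[mut]] == gc_tab[[cd]]) s <- s + 1 / 3
        }
      }
      syn_sites[cd] <- s
    }
    cache <<- list(code = gc_tab, syn_sites = syn_sites)
    cache
  }
})

is_stop_codon <- function(cd) codon_env()$code[[cd]] == "*"

# average (syn, nonsyn) difference counts between two codons over all
# minimal substitution paths that avoid stop codons
codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  ce <- codon_env()
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  perms <- if (length(pos) == 1L) list(pos)
           else if (length(pos) == 2L) list(pos, rev(pos))
           else {
             p <- pos
             list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                  p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
           }
  walk <- function(order_) {
    cur <- c1
    sd_ <- nd_ <- 0
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (ce$code[[nxt]] == "*") return(NULL)
      if (ce$code[[nxt]] == ce$code[[cur]]) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd_, nd_)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res))  # all paths blocked by stops: fall back to ignoring them
    res <- lapply(perms, function(order_) {
      cur <- c1; sd_ <- nd_ <- 0
      for (p in order_) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        aa1 <- ce$code[[cur]]; aa2 <- ce$code[[nxt]]
        if (aa1 == aa2 && aa1 != "*") sd_ <- sd_ + 1 else nd_ <- nd_ + 1
        cur <- nxt
      }
      c(sd_, nd_)
    })
  Reduce(`+`, res) / length(res)
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

jc_correct <- function(p) {
  if (p >= 0.75) stop("substitution proportion ", signif(p, 4),
                      " at or beyond Jukes-Cantor saturation")
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks by the Nei-Gojobori counting method
#'
#' Codons containing `N` or an alignment gap in either sequence are
#' excluded from all counts; internal stop codons are an error. `Na + Ns`
#' equals the number of analyzed nucleotides exactly. Proportions are
#' corrected with the Jukes-Cantor transform `d = -(3/4) ln(1 - 4p/3)`;
#' saturation (`p >= 3/4`) is an error. The `ratio` is `Inf` when
#' `Ks == 0` with `Ka > 0` and `NaN` when both are zero.
#'
#' @param seq1,seq2 aligned coding sequences of equal length (characters).
#' @param gene_id optional identifier carried through to the result.
#' @return list with `gene_id`, `ka`, `ks`, `ratio`, `na_sites`,
#'   `ns_sites`, `nd`, `sd`, `n_codons`.
#' @export
kaks_counting <- function(seq1, seq2, gene_id = NA_character_) {
  c1 <- split_codons(seq1); c2 <- split_codons(seq2)
  if (length(c1) != length(c2)) stop("sequences differ in length")
  ce <- codon_env()
  valid <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  c1 <- c1[valid]; c2 <- c2[valid]
  if (!length(c1)) stop("no analyzable codons")
  if (any(vapply(c1, is_stop_codon, logical(1))) ||
      any(vapply(c2, is_stop_codon, logical(1))))
    stop("internal stop codon in alignment")
  s1 <- sum(ce$syn_sites[c1]); s2 <- sum(ce$syn_sites[c2])
  S <- (s1 + s2) / 2
  L <- 3 * length(c1)
  N <- L - S
  diffs <- mapply(function(a, b) codon_path_diffs(a, b), c1, c2)
  Sd <- sum(diffs[1L, ]); Nd <- sum(diffs[2L, ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- jc_correct(ps); ka <- jc_correct(pn)
  ratio <- if (ks == 0 && ka == 0) NaN else if (ks == 0) Inf else ka / ks
  list(gene_id = gene_id, ka = ka, ks = ks, ratio = ratio,
       na_sites = N, ns_sites = S, nd = Nd, sd = Sd, n_codons = length(c1))
}

#' Ka/Ks for a collection of codon-aligned pairs
#' @param pairs `data.frame` with columns `gene_id`, `seq1`, `seq2` (as
#'   from [simulate_codon_pairs] or [read_codon_pairs_fasta]).
#' @return `data.frame` with one row per pair.
#' @export
kaks_table <- function(pairs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    as.data.frame(kaks_counting(pairs$seq1[i], pairs$seq2[i],
                                pairs$gene_id[i]), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discard ortholog groups with unusually high substitution rates
#'
#' A group is discarded when more than one of its pairwise results shows
#' `Ka >= ka_max` and/or `Ks >= ks_max` (inclusive bounds).
#'
#' @param results `data.frame` of [kaks_table] rows for one ortholog group.
#' @param ka_max,ks_max inclusive bounds (defaults 0.25 and 5).
#' @return list with `kept` and `discarded` (one of them empty) and
#'   `n_violations`.
#' @export
filter_rates <- function(results, ka_max = 0.25, ks_max = 5) {
  viol <- results$ka >= ka_max | results$ks >= ks_max
  n <- sum(viol)
  if (n > 1L) list(kept = results[0, , drop = FALSE], discarded = results,
                   n_violations = n)
  else list(kept = results, discarded = results[0, , drop = FALSE],
            n_violations = n)
}

#' Read codon-aligned sequence pairs from FASTA
#'
#' Pairs are identified by headers `<gene_id>|<species>`; each gene must
#' appear exactly twice.
#'
#' @param path FASTA file.
#' @return `data.frame` with `gene_id`, `species1`, `species2`, `seq1`,
#'   `seq2`.
#' @export
read_codon_pairs_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  sp <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
  genes <- unique(gene)
  rows <- lapply(genes, function(g) {
    ix <- which(gene == g)
    if (length(ix) != 2L) stop("gene ", g, " does not appear exactly twice")
    data.frame(gene_id = g, species1 = sp[ix[1L]], species2 = sp[ix[2L]],
               seq1 = as.character(ss[[ix[1L]]]),
               seq2 = as.character(ss[[ix[2L]]]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write codon-aligned pairs as FASTA
#' @param pairs `data.frame` as in [read_codon_pairs_fasta].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_codon_pairs_fasta <- function(pairs, path) {
  sp1 <- pairs$species1 %||% rep("sp1", nrow(pairs))
  sp2 <- pairs$species2 %||% rep("sp2", nrow(pairs))
  seqs <- Biostrings::DNAStringSet(c(pairs$seq1, pairs$seq2))
  names(seqs) <- c(paste0(pairs$gene_id, "|", sp1),
                   paste0(pairs$gene_id, "|", sp2))
  ord <- order(rep(seq_len(nrow(pairs)), 2L))
  Biostrings::writeXStringSet(seqs[ord], path, width = 60L)
  invisible(path)
}

#' Compare Ka/Ks distributions between a gene set and the background
#'
#' Per tissue, the Ka/Ks ratios of the focal gene set (e.g.
#' hibernation-related genes) are compared with those of all other genes
#' by a Wilcoxon rank-sum test, one-sided (`less`) by default since the
#' scientific claim is directional (stronger purifying selection on the
#' focal set). Non-finite ratios are excluded by default; with
#' `include_infinite = TRUE`, infinite ratios are ranked above every
#' finite value.
#'
#' @param results [kaks_table] output with one row per gene.
#' @param set_ids gene ids of the focal set.
#' @param tissue_of named character vector mapping `gene_id` to tissue.
#' @param alternative test direction (default `"less"`).
#' @param include_infinite rank `Inf` ratios largest instead of dropping.
#' @return `data.frame` with `tissue`, `n_set`, `n_rest`, `statistic`,
#'   `p_value`.
#' @export
compare_gene_sets <- function(results, set_ids, tissue_of,
                              alternative = c("less", "two_sided", "greater"),
                              include_infinite = FALSE) {
  alternative <- match.arg(alternative)
  if (!length(set_ids)) stop("empty focal gene set")
  tissue <- tissue_of[results$gene_id]
  ratio <- results$ratio
  if (include_infinite) {
    mx <- max(ratio[is.finite(ratio)], 0)
    ratio[is.infinite(ratio) & ratio > 0] <- mx + 1
  }
  usable <- is.finite(ratio) & !is.na(tissue)
  rows <- lapply(sort(unique(tissue[usable])), function(tt) {
    sel <- usable & tissue == tt
    x <- ratio[sel & results$gene_id %in% set_ids]
    y <- ratio[sel & !(results$gene_id %in% set_ids)]
    if (!length(x) || !length(y)) return(NULL)
    w <- wilcoxon_rank_sum(x, y, alternative = alternative)
    data.frame(tissue = tt, n_set = length(x), n_rest = length(y),
               statistic = w$statistic, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) stop("no tissue with both focal and background genes")
  rownames(out) <- NULL
  out
}
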