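#' Configuration for the synthetic locus/EST simulator
#'
#' The generator emulates the data regime of a medium-scale EST project
#' read against a related reference genome: a few hundred multi-exon genes
#' on both strands, single-pass reads of roughly 350-900 aligned bases,
#' five tissue libraries, a subset of genes carrying one extra splicing
#' isoform of a known type, and a subset of genes with strongly
#' tissue-tilted expression.
#'
#' @param seed integer seed; all stages derive their streams from it.
#' @param n_genes number of genes.
#' @param n_tissues number of tissue libraries.
#' @param tissues tissue labels (length `n_tissues`).
#' @param exons_per_gene inclusive integer range of exon counts (min 3, so
#'   every alternative-splicing type is constructible).
#' @param exon_length,intron_length inclusive ranges in bases.
#' @param as_variant_fraction fraction of genes given one extra isoform.
#' @param as_type_weights named 4-vector of type probabilities
#'   (`exon_skipping`, `intron_retention`, `alt5`, `alt3`), summing to 1.
#' @param alt_offset inclusive range of donor/acceptor shifts (bases) for
#'   alt-site variants.
#' @param n_ests number of ESTs to draw.
#' @param est_length inclusive range of aligned EST lengths (bases).
#' @param tissue_specific_fraction fraction of genes planted
#'   tissue-specific.
#' @param specificity_odds target 2x2 odds ratio (> 1) for planted genes;
#'   `Inf` puts all of a planted gene's ESTs in its tissue.
#' @param identity_noise list with `mean` and `sd` of the per-EST identity
#'   distribution (normal, clamped to `[0.5, 1]`).
#' @param unspliced_fraction fraction of ESTs emitted as single blocks.
#' @param ambiguous_fraction fraction of spliced ESTs given one ambiguous
#'   intron orientation call.
#' @param cds_incomplete_fraction fraction of transcripts without
#'   annotated start/stop codons.
#' @param n_chroms chromosomes over which genes are tiled.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42L,
                              n_genes = 200L,
                              n_tissues = 5L,
                              tissues = c("liver", "brain", "heart",
                                          "skm", "testis"),
                              exons_per_gene = c(4L, 8L),
                              exon_length = c(90L, 300L),
                              intron_length = c(200L, 1500L),
                              as_variant_fraction = 0.3,
                              as_type_weights = c(exon_skipping = 0.25,
                                                  intron_retention = 0.25,
                                                  alt5 = 0.25, alt3 = 0.25),
                              alt_offset = c(12L, 48L),
                              n_ests = 5000L,
                              est_length = c(350L, 900L),
                              tissue_specific_fraction = 0.1,
                              specificity_odds = 20,
                              identity_noise = list(mean = 0.93, sd = 0.03),
                              unspliced_fraction = 0.2,
                              ambiguous_fraction = 0.05,
                              cds_incomplete_fraction = 0.05,
                              n_chroms = 2L) {
  fr <- c(as_variant_fraction, tissue_specific_fraction, unspliced_fraction,
          ambiguous_fraction, cds_incomplete_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(sum(as_type_weights) - 1) > 1e-9)
    stop("as_type_weights must sum to 1")
  if (length(as_type_weights) != 4L)
    stop("as_type_weights must have 4 entries")
  if (exons_per_gene[1L] < 3L)
    stop("need at least 3 exons per gene for all alternative-splicing types")
  if (length(tissues) != n_tissues) stop("tissues must have length n_tissues")
  if (specificity_odds <= 1) stop("specificity_odds must exceed 1")
  structure(as.list(environment()), class = "simulation_config")
}

# plus-axis transcript coordinate -> genomic position, given sorted exons
t2g_point <- function(tpos, exons) {
  cum <- c(0L, cumsum(block_lengths(exons)))
  k <- findInterval(tpos, cum, rightmost.closed = FALSE)
  k <- min(k, nrow(exons))
  exons[k, 1L] + (tpos - cum[k])
}

# project a plus-axis transcript interval [ts, te) onto genomic blocks
t_window_blocks <- function(ts, te, exons) {
  cum <- c(0L, cumsum(block_lengths(exons)))
  out <- NULL
  for (k in seq_len(nrow(exons))) {
    lo <- max(ts, cum[k]); hi <- min(te, cum[k + 1L])
    if (hi > lo)
      out <- rbind(out, c(exons[k, 1L] + (lo - cum[k]),
                          exons[k, 1L] + (hi - cum[k])))
  }
  blocks_matrix(out[, 1L], out[, 2L])
}

# canonical event signatures, shared by the simulator's truth record and
# the classifier so planted and detected events compare exactly
signature_skip <- function(ex_s, ex_e, i_s, i_e)
  sprintf("exon_skipping:%s@%d-%d",
          paste(sprintf("%d-%d", ex_s, ex_e), collapse = ","), i_s, i_e)
signature_ret <- function(s, e) sprintf("intron_retention:%d-%d", s, e)
signature_alt <- function(type, b1, b2, shared)
  sprintf("%s:%d|%d@%d", type, min(b1, b2), max(b1, b2), shared)

#' Simulate a synthetic locus set with planted splicing variants
#'
#' Genes are tiled along `n_chroms` chromosomes on alternating strands.
#' Each gene receives a canonical multi-exon isoform; a configured
#' fraction additionally receives exactly one alternative isoform of an
#' assigned type (exon skipping removes an internal exon; intron retention
#' merges two adjacent exons; alt5/alt3 shift a donor/acceptor by a
#' bounded offset, orientation-aware). Only canonical isoforms enter the
#' emitted annotation - planted variants are observable through ESTs
#' alone, as in a real EST collection read against a reference
#' annotation. The truth record carries every planted event with the same
#' canonical signature strings produced by [classify_pair].
#'
#' @param config a [simulation_config].
#' @return list with `transcripts` (a [transcript_models] table of
#'   canonical isoforms) and `truth` (list with `isoforms`,
#'   `planted_as_events`, `tissue_specific_genes`, `tissue_props`).
#' @export
simulate_locus_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_locus_set_impl(config))
}

simulate_locus_set_impl <- function(config) {
  n <- config$n_genes
  cursor <- stats::setNames(rep(10000L, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  types <- c("exon_skipping", "intron_retention", "alt5", "alt3")
  n_as <- round(config$as_variant_fraction * n)
  as_genes <- if (n_as) sort(sample.int(n, n_as)) else integer(0)
  as_types <- if (n_as) sample(types, n_as, replace = TRUE,
                               prob = config$as_type_weights) else character(0)
  n_ts <- round(config$tissue_specific_fraction * n)
  ts_genes <- if (n_ts) sort(sample.int(n, n_ts)) else integer(0)
  ts_tissue <- if (n_ts) sample(config$tissues, n_ts, replace = TRUE)
               else character(0)

  tx_rows <- vector("list", n)
  isoforms <- vector("list", n)
  events <- list()
  tissue_props <- matrix(1 / config$n_tissues, n, config$n_tissues,
                         dimnames = list(sprintf("G%04d", seq_len(n)),
                                         config$tissues))
  for (g in seq_len(n)) {
    gid <- sprintf("G%04d", g)
    chrom <- paste0("chr", ((g - 1L) %% config$n_chroms) + 1L)
    strand <- if (g %% 2L == 1L) "+" else "-"
    k <- sample(seq(config$exons_per_gene[1L], config$exons_per_gene[2L]), 1L)
    ex_len <- sample(seq(config$exon_length[1L], config$exon_length[2L]), k,
                     replace = TRUE)
    in_len <- sample(seq(config$intron_length[1L], config$intron_length[2L]),
                     k - 1L, replace = TRUE)
    if (g %in% as_genes &&
        as_types[match(g, as_genes)] == "intron_retention") {
      # retained introns are strongly length-biased short in mammals; a
      # short intron also keeps the retention event within reach of
      # single-pass reads, so the planted truth stays observable
      in_len[sample.int(k - 1L, 1L)] <- sample(80:250, 1L)
    }
    start <- cursor[[chrom]]
    starts <- integer(k); ends <- integer(k)
    pos <- start
    for (e in seq_len(k)) {
      starts[e] <- pos; ends[e] <- pos + ex_len[e]
      pos <- ends[e] + if (e < k) in_len[e] else 0L
    }
    cursor[[chrom]] <- pos + 20000L
    exons <- blocks_matrix(starts, ends)
    iso <- list(list(id = paste0(gid, ".1"), exons = exons))

    if (g %in% as_genes) {
      type <- as_types[match(g, as_genes)]
      v <- make_variant(exons, strand, type, config$alt_offset)
      iso[[2L]] <- list(id = paste0(gid, ".2"), exons = v$exons)
      events[[length(events) + 1L]] <-
        data.frame(gene_id = gid, type = type, chrom = chrom,
                   start = v$start, end = v$end, signature = v$signature,
                   stringsAsFactors = FALSE)
    }
    isoforms[[g]] <- iso
    if (g %in% ts_genes) {
      tt <- ts_tissue[match(g, ts_genes)]
      p <- if (is.infinite(config$specificity_odds)) 1 else
        config$specificity_odds /
          (config$specificity_odds + config$n_tissues - 1)
      w <- rep((1 - p) / (config$n_tissues - 1), config$n_tissues)
      w[match(tt, config$tissues)] <- p
      tissue_props[g, ] <- w
    }
    # CDS with symmetric margins; length trimmed to a codon multiple
    L <- sum(ex_len)
    t_cs <- floor(0.15 * L)
    t_ce <- t_cs + ((floor(0.85 * L) - t_cs) %/% 3L) * 3L
    tx_rows[[g]] <- list(
      transcript_id = paste0(gid, ".1"), gene_id = gid, chrom = chrom,
      strand = strand, exons = exons,
      cds_start = as.integer(t2g_point(t_cs, exons)),
      cds_end = as.integer(t2g_point(t_ce - 1L, exons) + 1L),
      cds_complete = stats::runif(1) >= config$cds_incomplete_fraction)
  }
  transcripts <- transcript_models(
    transcript_id = vapply(tx_rows, `[[`, "", "transcript_id"),
    gene_id = vapply(tx_rows, `[[`, "", "gene_id"),
    chrom = vapply(tx_rows, `[[`, "", "chrom"),
    strand = vapply(tx_rows, `[[`, "", "strand"),
    exons = lapply(tx_rows, `[[`, "exons"),
    cds_start = vapply(tx_rows, function(r) r$cds_start, integer(1)),
    cds_end = vapply(tx_rows, function(r) r$cds_end, integer(1)),
    cds_complete = vapply(tx_rows, function(r) r$cds_complete, logical(1)))
  names(isoforms) <- transcripts$gene_id
  planted <- if (length(events)) do.call(rbind, events) else
    data.frame(gene_id = character(0), type = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               signature = character(0), stringsAsFactors = FALSE)
  truth <- list(isoforms = isoforms,
                planted_as_events = planted,
                tissue_specific_genes =
                  data.frame(gene_id = sprintf("G%04d", ts_genes),
                             tissue = ts_tissue, stringsAsFactors = FALSE),
                tissue_props = tissue_props)
  list(transcripts = transcripts, truth = truth)
}

# build one alternative isoform of the requested type; returns the variant
# exon matrix plus the truth coordinates and canonical signature
make_variant <- function(exons, strand, type, alt_offset) {
  k <- nrow(exons)
  ori_forward <- strand == "+"
  if (type == "exon_skipping") {
    j <- if (k == 3L) 2L else sample(2:(k - 1L), 1L)
    v <- exons[-j, , drop = FALSE]
    i_s <- exons[j - 1L, 2L]; i_e <- exons[j + 1L, 1L]
    list(exons = v, start = exons[j, 1L], end = exons[j, 2L],
         signature = signature_skip(exons[j, 1L], exons[j, 2L], i_s, i_e))
  } else if (type == "intron_retention") {
    # retained introns are characteristically short; retaining the gene's
    # shortest intron keeps the event within reach of single-pass reads
    in_lens <- exons[-1L, 1L] - exons[-k, 2L]
    j <- which.min(in_lens)
    v <- exons
    v[j, 2L] <- v[j + 1L, 2L]
    v <- v[-(j + 1L), , drop = FALSE]
    s <- exons[j, 2L]; e <- exons[j + 1L, 1L]
    list(exons = v, start = s, end = e, signature = signature_ret(s, e))
  } else {
    # alt5 shifts the donor, alt3 the acceptor, in transcription direction
    j <- sample(seq_len(k - 1L), 1L)
    delta <- sample(seq(alt_offset[1L], alt_offset[2L]), 1L)
    v <- exons
    shift_left <- (type == "alt5") == ori_forward
    if (shift_left) {
      # move the genomic-left intron boundary (end of exon j) inward
      delta <- min(delta, exons[j, 2L] - exons[j, 1L] - 10L)
      v[j, 2L] <- exons[j, 2L] - delta
      b1 <- exons[j, 2L]; b2 <- v[j, 2L]; shared <- exons[j + 1L, 1L]
    } else {
      delta <- min(delta, exons[j + 1L, 2L] - exons[j + 1L, 1L] - 10L)
      v[j + 1L, 1L] <- exons[j + 1L, 1L] + delta
      b1 <- exons[j + 1L, 1L]; b2 <- v[j + 1L, 1L]; shared <- exons[j, 2L]
    }
    list(exons = v, start = min(b1, b2), end = max(b1, b2),
         signature = signature_alt(type, b1, b2, shared))
  }
}

#' Simulate tissue-labelled spliced ESTs from a locus set
#'
#' ESTs are contiguous sub-windows of a gene isoform (chosen uniformly
#' between the canonical and, where planted, the variant isoform),
#' projected onto genomic exon blocks. Genes are sampled uniformly;
#' tissues follow each gene's multinomial weights from the truth record,
#' so planted tissue-specific genes achieve the configured expected odds
#' ratio. Configured fractions of ESTs are emitted unspliced
#' (single-block, strand unknown) or with one ambiguous intron
#' orientation; identity is drawn per EST. The RNG stream is derived from
#' `config$seed + 1` so locus and EST simulation can be rerun
#' independently.
#'
#' @param models transcripts from [simulate_locus_set] (used for labels).
#' @param truth truth record from [simulate_locus_set].
#' @param config the same [simulation_config].
#' @return list with `alignments` (an [est_alignments] table) and `truth`
#'   (input truth extended with an `est_gene` table).
#' @export
simulate_ests <- function(models, truth, config) {
  if (!nrow(models)) stop("empty locus set")
  if (config$n_ests <= 0L) stop("n_ests must be positive")
  with_seed(config$seed + 1L, simulate_ests_impl(models, truth, config))
}

simulate_ests_impl <- function(models, truth, config) {
  genes <- models$gene_id
  n <- config$n_ests
  gene_of <- sample(genes, n, replace = TRUE)
  strand_of <- models$strand[match(gene_of, models$gene_id)]
  recs <- vector("list", n)
  tg <- vector("list", n)
  for (i in seq_len(n)) {
    gid <- gene_of[i]
    iso_set <- truth$isoforms[[gid]]
    iso <- iso_set[[sample.int(length(iso_set), 1L)]]
    exons <- iso$exons
    L <- sum(block_lengths(exons))
    tissue <- sample(config$tissues, 1L,
                     prob = truth$tissue_props[gid, ])
    unspliced <- stats::runif(1) < config$unspliced_fraction
    if (unspliced) {
      e <- sample.int(nrow(exons), 1L, prob = block_lengths(exons))
      elen <- exons[e, 2L] - exons[e, 1L]
      len <- min(elen, sample(seq(config$est_length[1L],
                                  config$est_length[2L]), 1L))
      s <- exons[e, 1L] + sample.int(elen - len + 1L, 1L) - 1L
      blocks <- blocks_matrix(s, s + len)
      oris <- character(0)
    } else {
      len <- min(L, sample(seq(config$est_length[1L],
                               config$est_length[2L]), 1L))
      ts <- sample.int(L - len + 1L, 1L) - 1L
      blocks <- t_window_blocks(ts, ts + len, exons)
      ori <- if (strand_of[i] == "+") "forward" else "reverse"
      oris <- rep(ori, nrow(blocks) - 1L)
      if (length(oris) && stats::runif(1) < config$ambiguous_fraction)
        oris[sample.int(length(oris), 1L)] <- "ambiguous"
    }
    spliced <- nrow(blocks) >= 2L
    identity <- min(1, max(0.5, stats::rnorm(1, config$identity_noise$mean,
                                             config$identity_noise$sd)))
    aligned <- sum(block_lengths(blocks))
    est_length <- round(aligned / stats::runif(1, 0.45, 1))
    recs[[i]] <- list(est_id = sprintf("EST%05d", i), tissue = tissue,
                      chrom = models$chrom[match(gid, models$gene_id)],
                      strand = if (spliced) strand_of[i] else "unknown",
                      blocks = blocks, oris = oris, identity = identity,
                      est_length = est_length)
    tg[[i]] <- data.frame(est_id = recs[[i]]$est_id, gene_id = gid,
                          isoform_id = iso$id, unspliced = !spliced,
                          ambiguous = any(oris == "ambiguous"),
                          stringsAsFactors = FALSE)
  }
  aln <- est_alignments(
    est_id = vapply(recs, `[[`, "", "est_id"),
    tissue = vapply(recs, `[[`, "", "tissue"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    blocks = lapply(recs, `[[`, "blocks"),
    intron_orientations = lapply(recs, `[[`, "oris"),
    identity = vapply(recs, function(r) r$identity, numeric(1)),
    est_length = vapply(recs, function(r) r$est_length, numeric(1)))
  truth$est_gene <- do.call(rbind, tg)
  list(alignments = aln, truth = truth)
}

#' Simulate codon-aligned sequence pairs with controlled Ka and Ks
#'
#' The first sequence of each pair is drawn uniformly over sense codons;
#' the second receives synonymous and non-synonymous single-base changes
#' at per-codon probabilities calibrated (through the inverse Jukes-Cantor
#' transform) so that the expected Nei-Gojobori estimates match the
#' targets. No stop codons are ever introduced. Targets are intended for
#' the weak-saturation regime (roughly `<= 0.3`); larger targets are
#' increasingly approximate and values beyond the per-codon saturation
#' bound are an error.
#'
#' @param n_pairs number of pairs.
#' @param n_codons codons per sequence.
#' @param target_ka,target_ks target Ka and Ks (may be vectors of length
#'   `n_pairs`).
#' @param seed RNG seed.
#' @param gene_ids optional ids (default `K0001`, ...).
#' @return list with `pairs` (`data.frame`: `gene_id`, `species1`,
#'   `species2`, `seq1`, `seq2`) and `truth` (`data.frame` with the
#'   targets and realized substitution counts).
#' @export
simulate_codon_pairs <- function(n_pairs, n_codons, target_ka, target_ks,
                                 seed = 1L, gene_ids = NULL) {
  target_ka <- rep_len(target_ka, n_pairs)
  target_ks <- rep_len(target_ks, n_pairs)
  if (any(target_ka < 0) || any(target_ks < 0)) stop("negative target")
  # inverse Jukes-Cantor: expected raw substitution proportion per site
  inv_jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  pa <- inv_jc(target_ka); ps <- inv_jc(target_ks)
  # per-codon change probabilities must stay below 1 (placement scheme
  # applies at most one change of each kind per codon)
  if (any(ps * 2 >= 1) || any(pa * 3 >= 1))
    stop("target beyond the per-codon saturation bound")
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  if (is.null(gene_ids)) gene_ids <- sprintf("K%04d", seq_len(n_pairs))
  with_seed(seed, {
    rows <- vector("list", n_pairs)
    truth <- vector("list", n_pairs)
    for (i in seq_len(n_pairs)) {
      cod1 <- sample(sense, n_codons, replace = TRUE)
      cod2 <- cod1
      n_syn <- 0L; n_non <- 0L
      for (j in seq_len(n_codons)) {
        cd <- cod2[j]
        variants <- codon_single_changes(cd, gc_tab)
        s_sites <- length(variants$syn) / 3
        n_sites <- 3 - s_sites
        if (length(variants$syn) && stats::runif(1) < ps[i] * s_sites) {
          cd <- sample(variants$syn, 1L)
          n_syn <- n_syn + 1L
          variants <- codon_single_changes(cd, gc_tab)
        }
        if (length(variants$non) && stats::runif(1) < pa[i] * n_sites) {
          cd <- sample(variants$non, 1L)
          n_non <- n_non + 1L
        }
        cod2[j] <- cd
      }
      rows[[i]] <- data.frame(gene_id = gene_ids[i], species1 = "spA",
                              species2 = "spB",
                              seq1 = paste(cod1, collapse = ""),
                              seq2 = paste(cod2, collapse = ""),
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(gene_id = gene_ids[i],
                               target_ka = target_ka[i],
                               target_ks = target_ks[i],
                               n_syn_sub = n_syn, n_nonsyn_sub = n_non,
                               stringsAsFactors = FALSE)
    }
    list(pairs = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

# the single-base neighbours of a codon, split into synonymous and
# non-synonymous sense changes (stop-creating changes are never offered)
codon_single_changes <- function(cd, gc_tab) {
  bases <- c("A", "C", "G", "T")
  syn <- character(0); non <- character(0)
  aa <- gc_tab[[cd]]
  for (p in 1:3) {
    orig <- substr(cd, p, p)
    for (b in setdiff(bases, orig)) {
      mut <- cd
      substr(mut, p, p) <- b
      aa2 <- gc_tab[[mut]]
      if (aa2 == "*") next
      if (aa2 == aa) syn <- c(syn, mut) else non <- c(non, mut)
    }
  }
  list(syn = syn, non = non)
}
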