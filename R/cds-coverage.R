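# CDS-coverage profiling: where do ESTs fall on reference protein-coding
# transcripts, and how much of the CDS do they cover?

# map a genomic point (0-based, exonic) to plus-axis transcript coords
g2t_point <- function(pos, exons) {
  cum <- c(0L, cumsum(block_lengths(exons)))
  for (k in seq_len(nrow(exons))) {
    if (pos >= exons[k, 1L] && pos < exons[k, 2L])
      return(cum[k] + (pos - exons[k, 1L]))
  }
  stop("position ", pos, " outside transcript exons")
}

# project genomic blocks into plus-axis transcript intervals (merged)
project_blocks <- function(blocks, exons) {
  iv <- matrix(integer(0), 0L, 2L)
  for (i in seq_len(nrow(blocks))) {
    s <- blocks[i, 1L]; e <- blocks[i, 2L]
    hit <- which(exons[, 1L] <= s & e <= exons[, 2L])
    if (!length(hit)) stop("EST block outside transcript exons")
    ts <- g2t_point(s, exons)
    iv <- rbind(iv, c(ts, ts + (e - s)))
  }
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  # merge touching intervals (adjacent blocks across an intron are
  # contiguous in transcript coordinates)
  merged <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= merged[nrow(merged), 2L])
      merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], iv[i, 2L])
    else merged <- rbind(merged, iv[i, , drop = FALSE])
  }
  merged
}

#' Match ESTs to reference transcripts for CDS profiling
#'
#' A spliced EST matches when its splice-site set is contained in the site
#' set of transcripts of exactly one gene (with `strict_equality = TRUE`,
#' the sets must be equal); an unspliced EST matches an unspliced
#' (single-exon) transcript by genomic overlap. ESTs hitting transcripts
#' of more than one gene are discarded (`NA`), as are ESTs with ambiguous
#' intron orientations. Only transcripts with a complete annotated CDS
#' participate.
#'
#' @param prepared a [prepare_alignments] table.
#' @param transcripts a [transcript_models] table.
#' @param strict_equality require site-set equality instead of containment.
#' @return character vector of matched `transcript_id` (or `NA`) parallel
#'   to the rows of `prepared`.
#' @export
match_est_to_transcript <- function(prepared, transcripts,
                                    strict_equality = FALSE) {
  ok_tx <- which(transcripts$cds_complete & !is.na(transcripts$cds_start))
  tx_keys <- lapply(ok_tx, function(r) {
    ex <- transcripts$exons[[r]]
    ori <- if (transcripts$strand[r] == "+") "forward" else "reverse"
    site_keys(splice_sites_of(ex, rep(ori, nrow(ex) - 1L),
                              transcripts$chrom[r]))
  })
  tx_spliced <- vapply(transcripts$exons[ok_tx], nrow, integer(1)) >= 2L
  tx_cds_len <- rep(NA_integer_, length(ok_tx))
  for (z in seq_along(ok_tx)) {
    r <- ok_tx[z]
    tx_cds_len[z] <- sum(pmin(transcripts$exons[[r]][, 2L],
                              transcripts$cds_end[r]) -
                           pmax(transcripts$exons[[r]][, 1L],
                                transcripts$cds_start[r]) > 0)
  }
  out <- rep(NA_character_, nrow(prepared))
  for (i in seq_len(nrow(prepared))) {
    if (!prepared$orientation_ok[i]) next
    if (prepared$spliced[i]) {
      keys <- site_keys(prepared$sites[[i]])
      bl <- prepared$blocks[[i]]
      cand <- which(tx_spliced & vapply(seq_along(ok_tx), function(z) {
        k <- tx_keys[[z]]
        sites_ok <- if (strict_equality) setequal(keys, k) else
          all(keys %in% k)
        if (!sites_ok) return(FALSE)
        # every EST block must lie within one exon of the transcript
        ex <- transcripts$exons[[ok_tx[z]]]
        all(vapply(seq_len(nrow(bl)), function(q)
          any(ex[, 1L] <= bl[q, 1L] & bl[q, 2L] <= ex[, 2L]), logical(1)))
      }, logical(1)))
    } else {
      sp <- blocks_span(prepared$blocks[[i]])
      cand <- which(!tx_spliced & vapply(seq_along(ok_tx), function(z) {
        r <- ok_tx[z]
        transcripts$chrom[r] == prepared$chrom[i] &&
          blocks_overlap_length(prepared$blocks[[i]],
                                transcripts$exons[[r]]) > 0
      }, logical(1)))
    }
    if (!length(cand)) next
    genes <- unique(transcripts$gene_id[ok_tx[cand]])
    if (length(genes) > 1L) next
    # prefer the transcript with the longest CDS, ties to smallest id
    cds_span <- transcripts$cds_end[ok_tx[cand]] -
      transcripts$cds_start[ok_tx[cand]]
    pick <- cand[order(-cds_span, transcripts$transcript_id[ok_tx[cand]])][1L]
    out[i] <- transcripts$transcript_id[ok_tx[pick]]
  }
  out
}

#' Compute CDS coverage of one EST on its matched transcript
#'
#' EST blocks are projected into transcript coordinates; coverage is the
#' covered fraction of the CDS. ESTs falling entirely into non-coding
#' regions return `NULL` (discarded). Relative end positions are given on
#' the strand-corrected transcript axis, normalized so the CDS spans
#' `[0, 1]` (UTR positions fall outside that range).
#'
#' @param est_blocks block matrix of the EST.
#' @param tx one-row subset of a [transcript_models] table.
#' @return list with `coverage`, `full_cds`, `start_rel`, `end_rel`,
#'   `cds_len`; or `NULL` for a pure-UTR EST.
#' @export
compute_coverage <- function(est_blocks, tx) {
  exons <- tx$exons[[1L]]
  L <- sum(block_lengths(exons))
  proj <- project_blocks(est_blocks, exons)
  cds_t <- c(g2t_point(tx$cds_start, exons),
             g2t_point(tx$cds_end - 1L, exons) + 1L)
  if (tx$strand == "-") {
    proj <- cbind(L - proj[, 2L], L - proj[, 1L])[nrow(proj):1L, , drop = FALSE]
    cds_t <- c(L - cds_t[2L], L - cds_t[1L])
  }
  cds_len <- cds_t[2L] - cds_t[1L]
  ov <- sum(pmax(0L, pmin(proj[, 2L], cds_t[2L]) -
                   pmax(proj[, 1L], cds_t[1L])))
  if (ov == 0L) return(NULL)
  full <- ov == cds_len  # projection intervals are disjoint after merging
  list(coverage = unname(ov / cds_len),
       full_cds = unname(full),
       start_rel = unname((proj[1L, 1L] - cds_t[1L]) / cds_len),
       end_rel = unname((proj[nrow(proj), 2L] - cds_t[1L]) / cds_len),
       cds_len = unname(cds_len))
}

#' CDS-coverage records for all matched ESTs
#' @param prepared a [prepare_alignments] table.
#' @param transcripts a [transcript_models] table.
#' @param matches optional result of [match_est_to_transcript].
#' @return `data.frame` with `est_id`, `transcript_id`, `coverage`,
#'   `full_cds`, `start_rel`, `end_rel` (pure-UTR ESTs are dropped).
#' @export
cds_coverage_records <- function(prepared, transcripts, matches = NULL) {
  if (is.null(matches))
    matches <- match_est_to_transcript(prepared, transcripts)
  rows <- list()
  for (i in which(!is.na(matches))) {
    r <- match(matches[i], transcripts$transcript_id)
    cov <- compute_coverage(prepared$blocks[[i]], transcripts[r, ])
    if (is.null(cov)) next
    rows[[length(rows) + 1L]] <-
      data.frame(est_id = prepared$est_id[i], transcript_id = matches[i],
                 coverage = cov$coverage, full_cds = cov$full_cds,
                 start_rel = cov$start_rel, end_rel = cov$end_rel,
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(est_id = character(0), transcript_id = character(0),
               coverage = numeric(0), full_cds = logical(0),
               start_rel = numeric(0), end_rel = numeric(0))
  rownames(out) <- NULL
  out
}

#' Histogram of CDS coverage and EST positions relative to the CDS center
#'
#' The center-relative axis maps the CDS midpoint to 0 and the CDS ends to
#' -0.5 and +0.5; EST ends in UTRs fall outside that interval.
#'
#' @param records output of [cds_coverage_records].
#' @param n_bins number of equal-width coverage bins on `[0, 1]`.
#' @return list with `breaks`, `counts`, `mean_coverage`, `n_full_cds` and
#'   `center_positions` (`data.frame` of start/end center-relative
#'   positions per record).
#' @export
coverage_profile <- function(records, n_bins = 20L) {
  if (!nrow(records)) stop("no coverage records")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(records$coverage, breaks,
                                 include.lowest = TRUE)))
  list(breaks = breaks, counts = counts,
       mean_coverage = mean(records$coverage),
       n_full_cds = sum(records$full_cds),
       center_positions = data.frame(start = records$start_rel - 0.5,
                                     end = records$end_rel - 0.5))
}
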