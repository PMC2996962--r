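#' Significance thresholds for spliced alignments
#'
#' Defaults follow the usual EST-to-genome screening practice for
#' cross-species mapping: alignment identity strictly above 85% and aligned
#' length strictly above 50% of the EST length.
#'
#' @param min_identity minimum alignment identity, fraction in (0, 1].
#' @param min_coverage minimum aligned fraction of the EST length, (0, 1].
#' @param strict apply thresholds as strict inequalities (default). With
#'   `strict = FALSE` boundary values are kept.
#' @return a list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_identity = 0.85, min_coverage = 0.5,
                              strict = TRUE) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 strict = strict),
            class = "filter_thresholds")
}

#' Filter alignments by identity and EST coverage
#'
#' Coverage is computed against the EST length (the read), not the genomic
#' span. The kept and rejected sets partition the input; each rejection
#' carries a reason code (`"identity"` or `"coverage"`; identity wins when
#' both fail).
#'
#' @param aln an [est_alignments] table.
#' @param thresholds a [filter_thresholds] object.
#' @return list with elements `kept` (an `est_alignments` table) and
#'   `rejected` (`data.frame` of `est_id`, `reason`).
#' @export
filter_alignments <- function(aln, thresholds = filter_thresholds()) {
  if (any(aln$est_length == 0)) stop("est_length of zero")
  cov <- aligned_length(aln) / aln$est_length
  ok_id <- if (thresholds$strict) aln$identity > thresholds$min_identity
           else aln$identity >= thresholds$min_identity
  ok_cov <- if (thresholds$strict) cov > thresholds$min_coverage
            else cov >= thresholds$min_coverage
  keep <- ok_id & ok_cov
  reason <- ifelse(!ok_id, "identity", "coverage")
  kept <- aln[keep, , drop = FALSE]
  class(kept) <- class(aln)
  list(kept = kept,
       rejected = data.frame(est_id = aln$est_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

# donor/acceptor positions for one inter-block gap given its orientation.
# On forward orientation the genomic-left boundary (upstream block end) is
# the donor; on reverse orientation the roles swap.
gap_sites <- function(left_end, right_start, orientation) {
  if (orientation == "forward") {
    data.frame(pos = c(left_end, right_start),
               side = c("donor", "acceptor"),
               orientation = orientation, stringsAsFactors = FALSE)
  } else {
    data.frame(pos = c(right_start, left_end),
               side = c("donor", "acceptor"),
               orientation = orientation, stringsAsFactors = FALSE)
  }
}

#' Extract splice sites from one exon-block structure
#'
#' Each inter-block gap with a non-ambiguous orientation call yields a donor
#' and an acceptor site; ambiguous gaps yield nothing. Positions are the
#' 0-based exon/intron boundary coordinates.
#'
#' @param blocks two-column block matrix.
#' @param orientations character vector over gaps (`"forward"`, `"reverse"`,
#'   `"ambiguous"`).
#' @param chrom chromosome name.
#' @return `data.frame` with columns `chrom`, `pos`, `side`, `orientation`.
#' @export
splice_sites_of <- function(blocks, orientations, chrom) {
  k <- nrow(blocks)
  out <- list()
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      if (orientations[i] == "ambiguous") next
      out[[length(out) + 1L]] <-
        gap_sites(blocks[i, 2L], blocks[i + 1L, 1L], orientations[i])
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos = integer(0),
                      side = character(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- data.frame(chrom = chrom, df, stringsAsFactors = FALSE)
  df[order(df$pos, df$side), , drop = FALSE]
}

site_keys <- function(sites) {
  if (!nrow(sites)) return(character(0))
  paste(sites$chrom, sites$pos, sites$side, sites$orientation, sep = ":")
}

#' Extract splice sites from every alignment in a prepared table
#' @param aln an [est_alignments] table (typically the kept set).
#' @return list of site `data.frame`s parallel to the rows of `aln`.
#' @export
extract_splice_sites <- function(aln) {
  lapply(seq_len(nrow(aln)), function(i)
    splice_sites_of(aln$blocks[[i]], aln$intron_orientations[[i]],
                    aln$chrom[i]))
}

#' Flag splicing status and orientation consistency
#'
#' Adds per-EST columns: `spliced` (at least two blocks), `orientation_ok`
#' (all introns share one non-ambiguous orientation; trivially `TRUE` for
#' unspliced ESTs) and a `sites` list-column of extracted splice sites.
#' Downstream alternative-splicing analysis uses only members that are both
#' spliced and `orientation_ok` ("unambiguously spliced").
#'
#' @param aln an [est_alignments] table that passed [filter_alignments].
#' @return the input with columns `spliced`, `orientation_ok`, `sites`
#'   added; class `prepared_alignments`.
#' @export
prepare_alignments <- function(aln) {
  n <- nrow(aln)
  spliced <- vapply(aln$blocks, nrow, integer(1)) >= 2L
  orientation_ok <- vapply(seq_len(n), function(i) {
    ori <- aln$intron_orientations[[i]]
    if (!length(ori)) return(TRUE)
    !any(ori == "ambiguous") && length(unique(ori)) == 1L
  }, logical(1))
  aln$spliced <- spliced
  aln$orientation_ok <- orientation_ok
  aln$sites <- extract_splice_sites(aln)
  class(aln) <- unique(c("prepared_alignments", class(aln)))
  aln
}
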