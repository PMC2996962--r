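#' Construct a transcript-model table
#'
#' Reference gene structures with exon blocks and optional CDS bounds. All
#' coordinates are 0-based half-open; `cds_start`/`cds_end` are `NA` when no
#' CDS is annotated. `cds_complete` records whether both the start and stop
#' codon are annotated (transcripts with ambiguous CDS ends are excluded
#' from CDS-coverage profiling).
#'
#' @param transcript_id,gene_id,chrom character vectors.
#' @param strand character vector in `"+"`, `"-"`.
#' @param exons list of two-column integer matrices, sorted, disjoint.
#' @param cds_start,cds_end integer genomic bounds of the CDS or `NA`.
#' @param cds_complete logical.
#' @return A `data.frame` of class `transcript_models`.
#' @export
transcript_models <- function(transcript_id, gene_id, chrom, strand, exons,
                              cds_start = NA_integer_, cds_end = NA_integer_,
                              cds_complete = FALSE) {
  n <- length(transcript_id)
  if (!all(strand %in% c("+", "-"))) stop("transcript strand must be + or -")
  cds_start <- rep_len(as.integer(cds_start), n)
  cds_end <- rep_len(as.integer(cds_end), n)
  cds_complete <- rep_len(as.logical(cds_complete), n)
  for (i in seq_len(n)) {
    validate_blocks(exons[[i]], paste0("exons of ", transcript_id[i]))
    if (!is.na(cds_start[i])) {
      sp <- blocks_span(exons[[i]])
      if (cds_start[i] < sp[1L] || cds_end[i] > sp[2L] ||
          cds_start[i] >= cds_end[i])
        stop(transcript_id[i], ": CDS outside exon span")
    }
  }
  out <- data.frame(transcript_id = as.character(transcript_id),
                    gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    cds_start = cds_start, cds_end = cds_end,
                    cds_complete = cds_complete,
                    stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("transcript_models", "data.frame")
  out
}

#' Read transcript models from GTF or GFF3
#'
#' GTF/GFF 1-based closed intervals are converted to 0-based half-open.
#' `cds_complete` is `TRUE` for GTF transcripts carrying both a
#' `start_codon` and a `stop_codon` feature; for GFF3, transcripts must
#' carry an explicit `cds_complete=true` attribute.
#'
#' @param path GTF or GFF3 file; format detected from the extension
#'   (`.gtf` vs `.gff`/`.gff3`).
#' @return a [transcript_models] table.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  if (fmt == "gtf") {
    tx_of <- as.character(meta$transcript_id)
    gene_of <- as.character(meta$gene_id)
  } else {
    # exons/CDS point at their transcript via Parent; transcripts via ID
    parent <- vapply(as.list(meta$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, "")
    tx_of <- ifelse(type %in% c("exon", "CDS", "start_codon", "stop_codon"),
                    parent, as.character(meta$ID))
    gene_of <- parent
  }
  is_exon <- type == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)
  tx_ids <- unique(tx_of[is_exon])

  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand_all <- as.character(GenomicRanges::strand(gr))
  chrom_all <- as.character(GenomicRanges::seqnames(gr))

  exons <- vector("list", length(tx_ids))
  gene_id <- chrom <- strand <- character(length(tx_ids))
  cds_start <- cds_end <- rep(NA_integer_, length(tx_ids))
  cds_complete <- logical(length(tx_ids))
  for (j in seq_along(tx_ids)) {
    tid <- tx_ids[j]
    sel <- which(is_exon & tx_of == tid)
    if (length(sel) == 0L) stop("transcript with zero exons: ", tid)
    if (length(unique(strand_all[sel])) != 1L)
      stop("mixed-strand exons in transcript ", tid)
    ord <- order(start0[sel])
    exons[[j]] <- blocks_matrix(start0[sel][ord], end0[sel][ord])
    chrom[j] <- chrom_all[sel][1L]
    strand[j] <- strand_all[sel][1L]
    gid <- if (fmt == "gtf") gene_of[sel][1L] else {
      # gene of a GFF3 transcript = Parent of the mRNA record
      tx_rec <- which(!(type %in% c("exon", "CDS")) & tx_of == tid)
      if (length(tx_rec)) gene_of[tx_rec][1L] else NA_character_
    }
    gene_id[j] <- if (is.na(gid)) tid else gid
    cds_sel <- which(type == "CDS" & tx_of == tid)
    if (length(cds_sel)) {
      cds_start[j] <- min(start0[cds_sel])
      cds_end[j] <- max(end0[cds_sel])
    }
    if (fmt == "gtf") {
      cds_complete[j] <- any(type == "start_codon" & tx_of == tid) &&
        any(type == "stop_codon" & tx_of == tid)
    } else {
      tx_rec <- which(type %in% c("mRNA", "transcript") & tx_of == tid)
      flag <- if (length(tx_rec) && "cds_complete" %in% names(meta))
        as.character(meta$cds_complete[tx_rec[1L]]) else NA_character_
      cds_complete[j] <- isTRUE(tolower(flag) == "true")
    }
  }
  transcript_models(tx_ids, gene_id, chrom, strand, exons,
                    cds_start, cds_end, cds_complete)
}

#' Write transcript models as GTF
#'
#' Emits exon and CDS features (1-based closed coordinates) plus
#' `start_codon`/`stop_codon` features for transcripts flagged
#' `cds_complete`, so that [read_transcripts] round-trips the flag.
#'
#' @param tx a [transcript_models] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcripts_gtf <- function(tx, path) {
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id[i], tx$transcript_id[i])
    ex <- tx$exons[[i]]
    feat <- function(type, s0, e0)
      sprintf("%s\testpipe\t%s\t%d\t%d\t.\t%s\t.\t%s",
              tx$chrom[i], type, s0 + 1L, e0, tx$strand[i], attrs)
    lines <- c(lines, feat("exon", ex[, 1L], ex[, 2L]))
    if (!is.na(tx$cds_start[i])) {
      cs <- pmax(ex[, 1L], tx$cds_start[i]); ce <- pmin(ex[, 2L], tx$cds_end[i])
      keep <- cs < ce
      lines <- c(lines, feat("CDS", cs[keep], ce[keep]))
      if (isTRUE(tx$cds_complete[i])) {
        if (tx$strand[i] == "+") {
          lines <- c(lines, feat("start_codon", tx$cds_start[i],
                                 tx$cds_start[i] + 3L),
                     feat("stop_codon", tx$cds_end[i] - 3L, tx$cds_end[i]))
        } else {
          lines <- c(lines, feat("start_codon", tx$cds_end[i] - 3L,
                                 tx$cds_end[i]),
                     feat("stop_codon", tx$cds_start[i], tx$cds_start[i] + 3L))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
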