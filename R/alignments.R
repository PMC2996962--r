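#' Construct a spliced-alignment table
#'
#' A spliced alignment records one EST's exon-block placement on the genome
#' together with the aligner's per-intron orientation calls. The table is a
#' plain `data.frame` with one row per EST and two list-columns: `blocks`
#' (integer matrix of 0-based half-open genomic intervals, strictly
#' increasing) and `intron_orientations` (character vector over the gaps
#' between consecutive blocks, each `"forward"`, `"reverse"` or
#' `"ambiguous"`).
#'
#' @param est_id character vector of EST identifiers.
#' @param tissue character vector of tissue-of-origin labels.
#' @param chrom character vector of chromosome names.
#' @param strand character vector in `"+"`, `"-"`, `"unknown"`.
#' @param blocks list of two-column integer matrices (start, end).
#' @param intron_orientations list of character vectors, one entry per
#'   inter-block gap.
#' @param identity numeric alignment identities in `[0, 1]`.
#' @param est_length positive integer EST lengths in bases.
#' @return A `data.frame` of class `est_alignments`.
#' @export
est_alignments <- function(est_id, tissue, chrom, strand, blocks,
                           intron_orientations, identity, est_length) {
  n <- length(est_id)
  stopifnot(length(blocks) == n, length(intron_orientations) == n)
  if (!all(strand %in% c("+", "-", "unknown")))
    stop("strand must be one of '+', '-', 'unknown'")
  if (any(identity < 0 | identity > 1)) stop("identity must lie in [0, 1]")
  if (any(est_length <= 0)) stop("est_length must be positive")
  for (i in seq_len(n)) {
    validate_blocks(blocks[[i]], paste0("blocks of ", est_id[i]))
    k <- nrow(blocks[[i]])
    ori <- intron_orientations[[i]]
    if (length(ori) != k - 1L)
      stop(est_id[i], ": need ", k - 1L, " intron orientations, got ",
           length(ori))
    if (k > 1L && !all(ori %in% c("forward", "reverse", "ambiguous")))
      stop(est_id[i], ": bad intron orientation value")
    if (sum(block_lengths(blocks[[i]])) > est_length[i])
      stop(est_id[i], ": aligned length exceeds est_length")
  }
  out <- data.frame(est_id = as.character(est_id),
                    tissue = as.character(tissue),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    identity = as.numeric(identity),
                    est_length = as.integer(est_length),
                    stringsAsFactors = FALSE)
  out$blocks <- blocks
  out$intron_orientations <- intron_orientations
  class(out) <- c("est_alignments", "data.frame")
  out
}

#' Total aligned length of each EST (sum of block lengths)
#' @param aln an `est_alignments` table.
#' @return integer vector.
#' @export
aligned_length <- function(aln) {
  vapply(aln$blocks, function(b) sum(block_lengths(b)), integer(1))
}

#' Read spliced EST-to-genome alignments
#'
#' Reads exon-block alignment records either from the package's native TSV
#' dialect or from PSL. The TSV dialect has columns `est_id`, `tissue`,
#' `chrom`, `strand`, `identity`, `est_length`, `blocks` (comma-separated
#' `start-end`, 0-based half-open) and `intron_orientations`
#' (comma-separated `forward`/`reverse`/`ambiguous`, empty for single-block
#' alignments). PSL block starts are already 0-based half-open and are kept
#' as-is; PSL has no per-intron orientation calls, so orientations are
#' derived from the PSL strand (`+` forward, `-` reverse).
#'
#' @param path file to read.
#' @param dialect `"tsv"` (native dialect) or `"psl"`.
#' @return an [est_alignments] table.
#' @export
read_alignments <- function(path, dialect = c("tsv", "psl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") read_alignments_tsv(path) else read_alignments_psl(path)
}

read_alignments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("est_id", "tissue", "chrom", "strand", "identity", "est_length",
            "blocks", "intron_orientations")
  if (!all(need %in% names(df)))
    stop("alignment TSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  n <- nrow(df)
  blocks <- vector("list", n)
  oris <- vector("list", n)
  for (i in seq_len(n)) {
    line <- i + 1L  # header occupies line 1
    b <- tryCatch(parse_blocks(df$blocks[i]),
                  error = function(e) stop("line ", line, ": ",
                                           conditionMessage(e), call. = FALSE))
    if (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L]))
      stop("line ", line, ": blocks not increasing", call. = FALSE)
    blocks[[i]] <- b
    o <- df$intron_orientations[i]
    oris[[i]] <- if (is.na(o) || !nzchar(o)) character(0)
                 else strsplit(o, ",", fixed = TRUE)[[1L]]
  }
  est_alignments(df$est_id, df$tissue, df$chrom, df$strand, blocks, oris,
                 as.numeric(df$identity), as.integer(df$est_length))
}

read_alignments_psl <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && grepl("^psLayout", first)) 5L else 0L
  df <- utils::read.delim(path, header = FALSE, skip = skip,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 21L) stop("PSL requires 21 columns, got ", ncol(df))
  n <- nrow(df)
  blocks <- vector("list", n)
  oris <- vector("list", n)
  strand <- character(n)
  for (i in seq_len(n)) {
    line <- i + skip
    sizes <- suppressWarnings(as.integer(strsplit(as.character(df[i, 19L]),
                                                  ",")[[1L]]))
    tstarts <- suppressWarnings(as.integer(strsplit(as.character(df[i, 21L]),
                                                    ",")[[1L]]))
    if (anyNA(sizes) || anyNA(tstarts) || length(sizes) != length(tstarts))
      stop("line ", line, ": unparseable PSL block fields", call. = FALSE)
    b <- blocks_matrix(tstarts, tstarts + sizes)
    if (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L]))
      stop("line ", line, ": blocks not increasing", call. = FALSE)
    blocks[[i]] <- b
    s <- as.character(df[i, 9L])
    strand[i] <- if (grepl("-", s, fixed = TRUE)) "-" else "+"
    ori <- if (strand[i] == "+") "forward" else "reverse"
    oris[[i]] <- rep(ori, nrow(b) - 1L)
  }
  matches <- as.numeric(df[[1L]]); mism <- as.numeric(df[[2L]])
  repm <- as.numeric(df[[3L]])
  identity <- (matches + repm) / pmax(matches + repm + mism, 1)
  est_alignments(est_id = as.character(df[[10L]]),
                 tissue = rep("unknown", n),
                 chrom = as.character(df[[14L]]),
                 strand = strand, blocks = blocks, intron_orientations = oris,
                 identity = identity, est_length = as.integer(df[[11L]]))
}

#' Write alignments in the native TSV dialect
#' @param aln an [est_alignments] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(aln, path) {
  df <- data.frame(
    est_id = aln$est_id, tissue = aln$tissue, chrom = aln$chrom,
    strand = aln$strand, identity = aln$identity,
    est_length = aln$est_length,
    blocks = vapply(aln$blocks, format_blocks, ""),
    intron_orientations = vapply(aln$intron_orientations,
                                 paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
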