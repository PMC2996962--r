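# Small constructors used across test files. Coordinates 0-based half-open.

bl <- function(...) {
  v <- c(...)
  matrix(as.integer(v), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

# single-EST alignment table
aln1 <- function(blocks, oris = NULL, est_id = "e1", tissue = "liver",
                 chrom = "chr1", strand = "+", identity = 0.95,
                 est_length = NULL) {
  if (is.null(oris))
    oris <- rep(if (strand == "-") "reverse" else "forward",
                nrow(blocks) - 1L)
  if (is.null(est_length))
    est_length <- sum(blocks[, 2] - blocks[, 1])
  est_alignments(est_id, tissue, chrom, strand, list(blocks), list(oris),
                 identity, est_length)
}

# alignment table from a list of specs: list(blocks=, oris=, ...)
aln_many <- function(specs) {
  tabs <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    do.call(aln1, c(s, list(est_id = s$est_id %||% paste0("e", i))[
      !("est_id" %in% names(s))]))
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("est_alignments", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-transcript model table
tx1 <- function(exons, transcript_id = "T1", gene_id = "G1", chrom = "chr1",
                strand = "+", cds_start = NA, cds_end = NA,
                cds_complete = FALSE) {
  transcript_models(transcript_id, gene_id, chrom, strand, list(exons),
                    cds_start, cds_end, cds_complete)
}

# member list for linked()
member <- function(blocks, chrom = "chr1", oris = NULL, strand = "+") {
  if (is.null(oris))
    oris <- rep(if (strand == "-") "reverse" else "forward",
                nrow(blocks) - 1L)
  list(chrom = chrom, blocks = blocks,
       sites = splice_sites_of(blocks, oris, chrom))
}

# brute-force O(n^2) connected components under linked(); the independent
# clustering oracle
brute_components <- function(members) {
  n <- length(members)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && linked(members[[i]], members[[j]])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}
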