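# Shared low-level helpers. All genomic intervals in this package are
# 0-based half-open [start, end); blocks are integer matrices with columns
# "start" and "end", rows strictly increasing and non-overlapping.

blocks_matrix <- function(starts, ends) {
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  m
}

block_lengths <- function(blocks) blocks[, 2L] - blocks[, 1L]

blocks_span <- function(blocks) {
  c(blocks[1L, 1L], blocks[nrow(blocks), 2L])
}

#' @keywords internal
validate_blocks <- function(blocks, what = "blocks") {
  if (!is.matrix(blocks) || ncol(blocks) != 2L || nrow(blocks) < 1L)
    stop(what, " must be a two-column matrix with at least one row")
  if (any(blocks[, 2L] <= blocks[, 1L]))
    stop(what, ": every block end must exceed its start")
  if (nrow(blocks) > 1L) {
    if (any(blocks[-1L, 1L] < blocks[-nrow(blocks), 2L]))
      stop(what, " not increasing")
  }
  invisible(blocks)
}

# introns between consecutive blocks, as a (k-1) x 2 matrix (may have 0 rows)
introns_of <- function(blocks) {
  k <- nrow(blocks)
  if (k < 2L) return(blocks_matrix(integer(0), integer(0)))
  blocks_matrix(blocks[-k, 2L], blocks[-1L, 1L])
}

# total length of the pairwise intersection of two block sets
blocks_overlap_length <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    w <- hi - lo
    tot <- tot + sum(w[w > 0L])
  }
  tot
}

format_blocks <- function(blocks) {
  paste(sprintf("%d-%d", blocks[, 1L], blocks[, 2L]), collapse = ",")
}

parse_blocks <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1L]]
  if (length(parts) == 0L) stop("empty blocks field")
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) stop("unparseable blocks field: ", s)
  starts <- as.integer(vapply(m, `[`, "", 2L))
  ends <- as.integer(vapply(m, `[`, "", 3L))
  blocks_matrix(starts, ends)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library functions stay referentially transparent.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
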