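# Pairwise classification of local alternative-splicing patterns.
#
# Two exon-block structures are compared inside their mutual genomic
# overlap. Introns present in one structure but not the other define
# divergent regions, resolved into the four canonical patterns:
#   exon skipping    - an intron of one spans >=1 complete exon of the
#                      other, with both flanking introns shared-boundary
#   intron retention - an intron of one lies strictly inside one exon of
#                      the other
#   alt 5' site      - two introns share their acceptor, donors differ
#   alt 3' site      - two introns share their donor, acceptors differ
# Donor/acceptor are orientation-aware: the genomic-left intron boundary
# is the donor only on forward orientation. Divergences not matching any
# pattern are tagged "complex" and excluded from four-type counts.

intron_key <- function(m) if (nrow(m)) sprintf("%d-%d", m[, 1L], m[, 2L]) else character(0)

introns_within <- function(introns, lo, hi) {
  if (!nrow(introns)) return(introns)
  introns[introns[, 1L] >= lo & introns[, 2L] <= hi, , drop = FALSE]
}

#' Classify the alternative-splicing relationship of two structures
#'
#' @param t1,t2 two-column exon-block matrices (0-based half-open), same
#'   chromosome, same transcription orientation.
#' @param orientation `"forward"` or `"reverse"` (transcription direction
#'   on the genome); flips the alt-5'/alt-3' labelling.
#' @return `data.frame` with columns `type` (one of `exon_skipping`,
#'   `intron_retention`, `alt5`, `alt3`, `complex`), `start`, `end` (the
#'   divergent region) and `signature` (canonical coordinate string).
#'   Zero rows when the structures agree within their overlap.
#' @export
classify_pair <- function(t1, t2, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  validate_blocks(t1, "t1"); validate_blocks(t2, "t2")
  sp1 <- blocks_span(t1); sp2 <- blocks_span(t2)
  lo <- max(sp1[1L], sp2[1L]); hi <- min(sp1[2L], sp2[2L])
  empty <- data.frame(type = character(0), start = integer(0),
                      end = integer(0), signature = character(0),
                      stringsAsFactors = FALSE)
  shared_any <- length(intersect(intron_key(introns_of(t1)),
                                 intron_key(introns_of(t2)))) > 0L ||
    shares_boundary(t1, t2)
  if (hi <= lo) {
    if (!shared_any) stop("structures share no splice site")
    return(empty)
  }
  i1 <- introns_within(introns_of(t1), lo, hi)
  i2 <- introns_within(introns_of(t2), lo, hi)
  k1 <- intron_key(i1); k2 <- intron_key(i2)
  d1 <- i1[!(k1 %in% k2), , drop = FALSE]
  d2 <- i2[!(k2 %in% k1), , drop = FALSE]
  ev <- list()
  used1 <- rep(FALSE, nrow(d1)); used2 <- rep(FALSE, nrow(d2))

  add <- function(type, start, end, signature)
    ev[[length(ev) + 1L]] <<- data.frame(type = type, start = start,
                                         end = end, signature = signature,
                                         stringsAsFactors = FALSE)

  # exon skipping: scan each side for introns spanning the other's exons
  scan_skip <- function(da, db, used_a, used_b) {
    for (i in seq_len(nrow(da))) {
      if (used_a[i]) next
      a <- da[i, ]
      inside <- which(!used_b & db[, 1L] >= a[1L] & db[, 2L] <= a[2L])
      if (length(inside) >= 2L &&
          min(db[inside, 1L]) == a[1L] && max(db[inside, 2L]) == a[2L]) {
        sub <- db[inside, , drop = FALSE]
        sub <- sub[order(sub[, 1L]), , drop = FALSE]
        ex_s <- sub[-nrow(sub), 2L]; ex_e <- sub[-1L, 1L]
        used_a[i] <- TRUE; used_b[inside] <- TRUE
        add("exon_skipping", min(ex_s), max(ex_e),
            sprintf("exon_skipping:%s@%d-%d",
                    paste(sprintf("%d-%d", ex_s, ex_e), collapse = ","),
                    a[1L], a[2L]))
      }
    }
    list(used_a, used_b)
  }
  u <- scan_skip(d1, d2, used1, used2); used1 <- u[[1L]]; used2 <- u[[2L]]
  u <- scan_skip(d2, d1, used2, used1); used2 <- u[[1L]]; used1 <- u[[2L]]

  # intron retention: a divergent intron strictly inside one exon of the other
  scan_ret <- function(da, used_a, other_blocks) {
    for (i in seq_len(nrow(da))) {
      if (used_a[i]) next
      a <- da[i, ]
      if (any(other_blocks[, 1L] < a[1L] & other_blocks[, 2L] > a[2L])) {
        used_a[i] <- TRUE
        add("intron_retention", a[1L], a[2L],
            sprintf("intron_retention:%d-%d", a[1L], a[2L]))
      }
    }
    used_a
  }
  used1 <- scan_ret(d1, used1, t2)
  used2 <- scan_ret(d2, used2, t1)

  # alternative donor/acceptor: pairs of divergent introns sharing exactly
  # one boundary
  alt_type <- function(share_right) {
    if (orientation == "forward") {
      if (share_right) "alt5" else "alt3"   # shared acceptor -> donors differ
    } else {
      if (share_right) "alt3" else "alt5"
    }
  }
  # a clean alt call requires the differing-boundary region to be free of
  # any other divergent intron; coupled divergences stay complex
  region_clean <- function(lo, hi, skip1, skip2) {
    others <- rbind(d1[!used1 & seq_len(nrow(d1)) != skip1, , drop = FALSE],
                    d2[!used2 & seq_len(nrow(d2)) != skip2, , drop = FALSE])
    !any(others[, 1L] < hi & others[, 2L] > lo)
  }
  for (i in seq_len(nrow(d1))) {
    if (used1[i]) next
    a <- d1[i, ]
    j <- which(!used2 & d2[, 2L] == a[2L] & d2[, 1L] != a[1L])
    if (length(j)) {
      j <- j[1L]
      b <- min(a[1L], d2[j, 1L]); e <- max(a[1L], d2[j, 1L])
      if (region_clean(b, e, i, j)) {
        used1[i] <- TRUE; used2[j] <- TRUE
        add(alt_type(TRUE), b, e,
            sprintf("%s:%d|%d@%d", alt_type(TRUE), b, e, a[2L]))
        next
      }
    }
    j <- which(!used2 & d2[, 1L] == a[1L] & d2[, 2L] != a[2L])
    if (length(j)) {
      j <- j[1L]
      b <- min(a[2L], d2[j, 2L]); e <- max(a[2L], d2[j, 2L])
      if (region_clean(b, e, i, j)) {
        used1[i] <- TRUE; used2[j] <- TRUE
        add(alt_type(FALSE), b, e,
            sprintf("%s:%d|%d@%d", alt_type(FALSE), b, e, a[1L]))
      }
    }
  }

  # anything left over is a complex divergence
  for (i in which(!used1))
    add("complex", d1[i, 1L], d1[i, 2L],
        sprintf("complex:%d-%d", d1[i, 1L], d1[i, 2L]))
  for (i in which(!used2))
    add("complex", d2[i, 1L], d2[i, 2L],
        sprintf("complex:%d-%d", d2[i, 1L], d2[i, 2L]))

  out <- if (length(ev)) do.call(rbind, ev) else empty
  if (!shared_any && !nrow(out)) stop("structures share no splice site")
  out[order(out$signature), , drop = FALSE]
}

# do two structures share an intron boundary (same position, same role)?
shares_boundary <- function(t1, t2) {
  a <- introns_of(t1); b <- introns_of(t2)
  if (!nrow(a) || !nrow(b)) return(FALSE)
  any(a[, 1L] %in% b[, 1L]) || any(a[, 2L] %in% b[, 2L])
}
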