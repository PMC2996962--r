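#' Are two members linked for clustering?
#'
#' Two members (EST alignments or reference transcripts) are linked when
#' they share at least one identical splice site (same chromosome,
#' position, donor/acceptor side and orientation) or when their genomic
#' projections overlap by strictly more than half of the shorter
#' projection (projection length = sum of block lengths). Members on
#' different chromosomes are never linked.
#'
#' @param a,b member lists with elements `chrom`, `blocks` (block matrix)
#'   and `sites` (splice-site `data.frame` as from [splice_sites_of]).
#' @param min_overlap_frac overlap fraction of the shorter projection that
#'   must be exceeded (default 0.5).
#' @return logical.
#' @export
linked <- function(a, b, min_overlap_frac = 0.5) {
  if (a$chrom != b$chrom) return(FALSE)
  ka <- site_keys(a$sites); kb <- site_keys(b$sites)
  if (length(ka) && length(kb) && any(ka %in% kb)) return(TRUE)
  ovl <- blocks_overlap_length(a$blocks, b$blocks)
  shorter <- min(sum(block_lengths(a$blocks)), sum(block_lengths(b$blocks)))
  ovl > min_overlap_frac * shorter
}

# Uniform member table over prepared ESTs and reference transcripts.
# Transcript intron orientations follow the annotated strand.
members_table <- function(prepared, transcripts = NULL) {
  mk <- function(id, kind, chrom, blocks, sites) {
    df <- data.frame(member_id = id, kind = kind, chrom = chrom,
                     stringsAsFactors = FALSE)
    df$blocks <- blocks
    df$sites <- sites
    df
  }
  parts <- list()
  if (!is.null(prepared) && nrow(prepared)) {
    if (is.null(prepared$sites)) prepared <- prepare_alignments(prepared)
    parts$est <- mk(prepared$est_id, "est", prepared$chrom,
                    prepared$blocks, prepared$sites)
  }
  if (!is.null(transcripts) && nrow(transcripts)) {
    ori <- ifelse(transcripts$strand == "+", "forward", "reverse")
    sites <- lapply(seq_len(nrow(transcripts)), function(i)
      splice_sites_of(transcripts$exons[[i]],
                      rep(ori[i], nrow(transcripts$exons[[i]]) - 1L),
                      transcripts$chrom[i]))
    parts$tx <- mk(transcripts$transcript_id, "transcript",
                   transcripts$chrom, transcripts$exons, sites)
  }
  if (!length(parts))
    return(mk(character(0), character(0), character(0), list(), list()))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$proj_len <- vapply(out$blocks, function(b) sum(block_lengths(b)),
                         integer(1))
  out
}

# candidate overlap edges (i < j member indices) passing the strict
# more-than-half-of-the-shorter rule, computed chromosome-wise with IRanges
overlap_edges <- function(members, min_overlap_frac) {
  edges <- NULL
  for (ch in unique(members$chrom)) {
    idx <- which(members$chrom == ch)
    if (length(idx) < 2L) next
    nb <- vapply(members$blocks[idx], nrow, integer(1))
    owner <- rep(idx, nb)
    bl <- do.call(rbind, members$blocks[idx])
    ir <- IRanges::IRanges(start = bl[, 1L] + 1L, end = bl[, 2L])
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- owner[qi] < owner[si]
    if (!any(keep)) next
    qi <- qi[keep]; si <- si[keep]
    w <- pmin(IRanges::end(ir)[qi], IRanges::end(ir)[si]) -
      pmax(IRanges::start(ir)[qi], IRanges::start(ir)[si]) + 1L
    key <- paste(owner[qi], owner[si])
    tot <- rowsum(w, key)
    pair <- do.call(rbind, strsplit(rownames(tot), " ", fixed = TRUE))
    i1 <- as.integer(pair[, 1L]); i2 <- as.integer(pair[, 2L])
    shorter <- pmin(members$proj_len[i1], members$proj_len[i2])
    ok <- tot[, 1L] > min_overlap_frac * shorter
    if (any(ok)) edges <- rbind(edges, cbind(i1[ok], i2[ok]))
  }
  edges
}

# edges connecting all members that share an identical splice-site key
site_edges <- function(members) {
  keys <- lapply(members$sites, site_keys)
  n <- lengths(keys)
  if (!sum(n)) return(NULL)
  df <- data.frame(key = unlist(keys), member = rep(seq_len(nrow(members)), n))
  df <- unique(df)
  grp <- split(df$member, df$key)
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(NULL)
  do.call(rbind, lapply(grp, function(v) cbind(v[1L], v[-1L])))
}

#' Build primary EST clusters
#'
#' Primary clusters are the connected components of the graph over all
#' members (kept EST alignments plus reference transcripts) under
#' [linked()]: shared splice site at the same orientation, or genomic
#' overlap exceeding half of the shorter projection. Reference transcripts
#' participate in linkage but do not count toward `n_ests`. Output is
#' deterministic: clusters sorted by (chrom, span start, span end), ids
#' assigned in that order.
#'
#' @param prepared a [prepare_alignments] table (the kept set).
#' @param transcripts optional [transcript_models] table.
#' @param min_overlap_frac strict overlap threshold (default 0.5).
#' @return `data.frame` with columns `cluster_id`, `chrom`, `start`, `end`,
#'   `n_ests`, `n_transcripts` and list-columns `member_ids`, `member_kinds`.
#' @export
build_primary_clusters <- function(prepared, transcripts = NULL,
                                   min_overlap_frac = 0.5) {
  members <- members_table(prepared, transcripts)
  n <- nrow(members)
  if (!n)
    return(data.frame(cluster_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_ests = integer(0), n_transcripts = integer(0)))
  edges <- rbind(site_edges(members), overlap_edges(members, min_overlap_frac))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  spans <- t(vapply(members$blocks, blocks_span, integer(2)))
  agg <- lapply(split(seq_len(n), comp), function(ix) {
    list(chrom = members$chrom[ix[1L]],
         start = min(spans[ix, 1L]), end = max(spans[ix, 2L]),
         member_ids = members$member_id[ix],
         member_kinds = members$kind[ix])
  })
  ord <- order(vapply(agg, `[[`, "", "chrom"),
               vapply(agg, function(a) a$start, integer(1)),
               vapply(agg, function(a) a$end, integer(1)))
  agg <- unname(agg[ord])
  out <- data.frame(
    cluster_id = sprintf("PC%05d", seq_along(agg)),
    chrom = vapply(agg, `[[`, "", "chrom"),
    start = vapply(agg, function(a) a$start, integer(1)),
    end = vapply(agg, function(a) a$end, integer(1)),
    n_ests = vapply(agg, function(a) sum(a$member_kinds == "est"), integer(1)),
    n_transcripts = vapply(agg, function(a) sum(a$member_kinds == "transcript"),
                           integer(1)),
    stringsAsFactors = FALSE)
  out$member_ids <- lapply(agg, `[[`, "member_ids")
  out$member_kinds <- lapply(agg, `[[`, "member_kinds")
  out
}

#' Merge subset-redundant primary clusters into unique clusters
#'
#' An EST aligned at multiple genomic loci (e.g. across duplicated genes)
#' appears in several primary clusters; a primary whose EST-id set is a
#' subset of another's is absorbed into it, iterated to a fixpoint. The
#' representative of a unique cluster is the primary with the most ESTs
#' (ties broken by lexicographically smallest `cluster_id`). `n_ests`
#' counts distinct EST ids over the merged primaries.
#'
#' @param primaries output of [build_primary_clusters].
#' @return `data.frame` with columns `cluster_id`, `representative_primary`,
#'   `n_ests`, `is_singleton` and list-column `primary_ids`.
#' @export
merge_to_unique <- function(primaries) {
  n <- nrow(primaries)
  est_sets <- lapply(seq_len(n), function(i)
    unique(primaries$member_ids[[i]][primaries$member_kinds[[i]] == "est"]))
  # invert: EST id -> primaries containing it
  idx <- data.frame(est = unlist(est_sets),
                    prim = rep(seq_len(n), lengths(est_sets)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- max(ri, rj)
  }
  if (nrow(idx)) {
    shared <- split(idx$prim, idx$est)
    shared <- shared[lengths(shared) >= 2L]
    seen <- character(0)
    for (grp in shared) {
      for (a in seq_along(grp)) for (b in seq_along(grp)) {
        if (a >= b) next
        i <- grp[a]; j <- grp[b]
        key <- paste(i, j)
        if (key %in% seen) next
        seen <- c(seen, key)
        if (all(est_sets[[i]] %in% est_sets[[j]]) ||
            all(est_sets[[j]] %in% est_sets[[i]])) union_(i, j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  groups <- unname(groups[order(vapply(groups, min, integer(1)))])
  recs <- lapply(groups, function(ix) {
    ids <- primaries$cluster_id[ix]
    nper <- primaries$n_ests[ix]
    rep_id <- ids[order(-nper, ids)][1L]
    list(primary_ids = ids, representative_primary = rep_id,
         n_ests = length(unique(unlist(est_sets[ix]))))
  })
  out <- data.frame(
    cluster_id = sprintf("UC%05d", seq_along(recs)),
    representative_primary = vapply(recs, `[[`, "", "representative_primary"),
    n_ests = vapply(recs, function(r) r$n_ests, integer(1)),
    stringsAsFactors = FALSE)
  out$is_singleton <- out$n_ests == 1L
  out$primary_ids <- lapply(recs, `[[`, "primary_ids")
  out
}

#' Summary statistics over unique clusters
#' @param uniques output of [merge_to_unique].
#' @return list with `n_clusters`, `n_singletons`, `mean_ests` and
#'   `histogram` (named counts of clusters by EST number).
#' @export
cluster_stats <- function(uniques) {
  n <- nrow(uniques)
  if (!n)
    return(list(n_clusters = 0L, n_singletons = 0L, mean_ests = 0,
                histogram = integer(0)))
  list(n_clusters = n,
       n_singletons = sum(uniques$n_ests == 1L),
       mean_ests = sum(uniques$n_ests) / n,
       histogram = table(uniques$n_ests))
}

#' Map ESTs to their unique cluster via the representative primary
#' @param uniques output of [merge_to_unique].
#' @param primaries output of [build_primary_clusters].
#' @return `data.frame` with `est_id`, `cluster_id` (distinct EST ids over
#'   all primaries of each unique cluster).
#' @export
cluster_membership <- function(uniques, primaries) {
  rows <- lapply(seq_len(nrow(uniques)), function(i) {
    prim <- match(uniques$primary_ids[[i]], primaries$cluster_id)
    ests <- unique(unlist(lapply(prim, function(p)
      primaries$member_ids[[p]][primaries$member_kinds[[p]] == "est"])))
    if (!length(ests)) return(NULL)
    data.frame(est_id = ests, cluster_id = uniques$cluster_id[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(est_id = character(0), cluster_id = character(0))
  rownames(out) <- NULL
  out
}
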