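#' Build per-cluster views eligible for alternative-splicing analysis
#'
#' Unspliced and orientation-ambiguous members are dropped first, then
#' clusters are kept according to the membership rule. The default
#' (`rule = "ests"`) requires at least `min_spliced_ests` unambiguously
#' spliced ESTs; `rule = "members"` requires more than two usable members
#' (ESTs plus spliced reference transcripts) of which at least one is an
#' EST. Members are taken from the representative primary cluster, so all
#' coordinates within one view share a locus.
#'
#' @param uniques output of [merge_to_unique].
#' @param primaries output of [build_primary_clusters].
#' @param prepared a [prepare_alignments] table.
#' @param transcripts optional [transcript_models] table (spliced models
#'   participate as witnesses).
#' @param rule eligibility rule, `"ests"` or `"members"`.
#' @param min_spliced_ests minimum unambiguously spliced ESTs (rule
#'   `"ests"`).
#' @return list of cluster views, each a list with `cluster_id` and a
#'   `members` data.frame (`member_id`, `kind`, `orientation`, list-columns
#'   `blocks`, `sites`).
#' @export
eligible_clusters <- function(uniques, primaries, prepared,
                              transcripts = NULL,
                              rule = c("ests", "members"),
                              min_spliced_ests = 2L) {
  rule <- match.arg(rule)
  est_index <- stats::setNames(seq_len(nrow(prepared)), prepared$est_id)
  tx_index <- if (!is.null(transcripts))
    stats::setNames(seq_len(nrow(transcripts)), transcripts$transcript_id)
  views <- list()
  for (i in seq_len(nrow(uniques))) {
    p <- match(uniques$representative_primary[i], primaries$cluster_id)
    ids <- primaries$member_ids[[p]]
    kinds <- primaries$member_kinds[[p]]
    mem <- list()
    for (j in seq_along(ids)) {
      if (kinds[j] == "est") {
        r <- est_index[[ids[j]]]
        if (is.null(r) || is.na(r)) next
        if (!prepared$spliced[r] || !prepared$orientation_ok[r]) next
        mem[[length(mem) + 1L]] <- list(
          member_id = ids[j], kind = "est",
          orientation = prepared$intron_orientations[[r]][1L],
          blocks = prepared$blocks[[r]], sites = prepared$sites[[r]])
      } else if (!is.null(tx_index)) {
        r <- tx_index[[ids[j]]]
        if (is.null(r) || is.na(r)) next
        ex <- transcripts$exons[[r]]
        if (nrow(ex) < 2L) next
        ori <- if (transcripts$strand[r] == "+") "forward" else "reverse"
        mem[[length(mem) + 1L]] <- list(
          member_id = ids[j], kind = "transcript", orientation = ori,
          blocks = ex,
          sites = splice_sites_of(ex, rep(ori, nrow(ex) - 1L),
                                  transcripts$chrom[r]))
      }
    }
    if (!length(mem)) next
    kinds_u <- vapply(mem, `[[`, "", "kind")
    n_est <- sum(kinds_u == "est")
    ok <- if (rule == "ests") n_est >= min_spliced_ests
          else length(mem) > 2L && n_est >= 1L
    if (!ok) next
    members <- data.frame(member_id = vapply(mem, `[[`, "", "member_id"),
                          kind = kinds_u,
                          orientation = vapply(mem, `[[`, "", "orientation"),
                          stringsAsFactors = FALSE)
    members$blocks <- lapply(mem, `[[`, "blocks")
    members$sites <- lapply(mem, `[[`, "sites")
    views[[length(views) + 1L]] <-
      list(cluster_id = uniques$cluster_id[i], chrom = primaries$chrom[p],
           members = members)
  }
  views
}

# does a member pair share >=1 splice site and differ within its overlap?
pair_state <- function(b1, b2, k1, k2) {
  if (!length(intersect(k1, k2))) return("unpaired")
  sp1 <- blocks_span(b1); sp2 <- blocks_span(b2)
  lo <- max(sp1[1L], sp2[1L]); hi <- min(sp1[2L], sp2[2L])
  if (hi <= lo) return("unpaired")
  i1 <- introns_within(introns_of(b1), lo, hi)
  i2 <- introns_within(introns_of(b2), lo, hi)
  if (identical(intron_key(i1), intron_key(i2))) "same" else "diff"
}

#' Detect alternative-splicing events within one cluster view
#'
#' All unordered member pairs sharing at least one splice site and
#' differing in at least one are classified with [classify_pair]; events
#' are deduplicated by signature (one event per unique signature per
#' cluster) and ordered deterministically by signature.
#'
#' @param view one element of [eligible_clusters] output.
#' @param include_transcripts allow reference transcripts as witnesses
#'   (default `TRUE`).
#' @return `data.frame` with columns `cluster_id`, `event_type`,
#'   `signature`, `chrom`, `start`, `end`, `id1`, `id2`.
#' @export
detect_events <- function(view, include_transcripts = TRUE) {
  members <- view$members
  if (!include_transcripts)
    members <- members[members$kind == "est", , drop = FALSE]
  n <- nrow(members)
  empty <- data.frame(cluster_id = character(0), event_type = character(0),
                      signature = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      id1 = character(0), id2 = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  keys <- lapply(members$sites, site_keys)
  found <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (members$orientation[i] != members$orientation[j]) next
      st <- pair_state(members$blocks[[i]], members$blocks[[j]],
                       keys[[i]], keys[[j]])
      if (st != "diff") next
      cl <- classify_pair(members$blocks[[i]], members$blocks[[j]],
                          members$orientation[i])
      for (r in seq_len(nrow(cl))) {
        sig <- cl$signature[r]
        if (is.null(found[[sig]]))
          found[[sig]] <- data.frame(
            cluster_id = view$cluster_id, event_type = cl$type[r],
            signature = sig, chrom = view$chrom,
            start = cl$start[r], end = cl$end[r],
            id1 = members$member_id[i], id2 = members$member_id[j],
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found)) return(empty)
  out <- do.call(rbind, found[order(names(found))])
  rownames(out) <- NULL
  out
}

#' Summarize events over clusters
#' @param views list of cluster views.
#' @param events_by_cluster list of event tables parallel to `views`
#'   (computed if missing).
#' @param include_transcripts passed to [detect_events].
#' @return list with `n_clusters_eligible`, `n_clusters_as`, per-type
#'   counts, per-type percentages (over four-type events) and
#'   `n_complex`.
#' @export
summarize_as <- function(views, events_by_cluster = NULL,
                         include_transcripts = TRUE) {
  if (is.null(events_by_cluster))
    events_by_cluster <- lapply(views, detect_events,
                                include_transcripts = include_transcripts)
  types <- c("exon_skipping", "intron_retention", "alt5", "alt3")
  counts <- stats::setNames(integer(4), types)
  n_complex <- 0L
  n_as <- 0L
  for (ev in events_by_cluster) {
    four <- ev[ev$event_type %in% types, , drop = FALSE]
    if (nrow(four)) n_as <- n_as + 1L
    counts <- counts + vapply(types, function(t) sum(four$event_type == t),
                              integer(1))
    n_complex <- n_complex + sum(ev$event_type == "complex")
  }
  tot <- sum(counts)
  list(n_clusters_eligible = length(views), n_clusters_as = n_as,
       counts = counts,
       percentages = if (tot) 100 * counts / tot else counts * 0,
       n_complex = n_complex)
}

#' Splice-site conservation against reference transcripts
#'
#' Over clusters containing at least one unambiguously spliced EST and at
#' least one spliced reference transcript: the fraction of EST splice-site
#' instances also present in the cluster's reference transcripts, and the
#' fraction of clusters whose EST site set is entirely contained in the
#' reference site set.
#'
#' @inheritParams eligible_clusters
#' @return list with `per_site_fraction`, `per_cluster_identical_fraction`,
#'   `n_sites`, `n_clusters`.
#' @export
conserved_splice_fraction <- function(uniques, primaries, prepared,
                                      transcripts) {
  views <- eligible_clusters(uniques, primaries, prepared, transcripts,
                             rule = "ests", min_spliced_ests = 1L)
  n_sites <- 0L; n_shared <- 0L; n_clusters <- 0L; n_identical <- 0L
  for (v in views) {
    est_sel <- v$members$kind == "est"
    tx_sel <- v$members$kind == "transcript"
    if (!any(est_sel) || !any(tx_sel)) next
    tx_keys <- unique(unlist(lapply(v$members$sites[tx_sel], site_keys)))
    est_keys <- unlist(lapply(v$members$sites[est_sel], site_keys))
    n_clusters <- n_clusters + 1L
    n_sites <- n_sites + length(est_keys)
    n_shared <- n_shared + sum(est_keys %in% tx_keys)
    if (all(est_keys %in% tx_keys)) n_identical <- n_identical + 1L
  }
  list(per_site_fraction = if (n_sites) n_shared / n_sites else NA_real_,
       per_cluster_identical_fraction =
         if (n_clusters) n_identical / n_clusters else NA_real_,
       n_sites = n_sites, n_clusters = n_clusters)
}

#' EST-depth-normalized alternative-splicing rates
#'
#' Clusters with at least `n_sample` unambiguously spliced ESTs are
#' selected; in each replicate `n_sample` ESTs are drawn without
#' replacement per cluster, events re-detected, and the summary recorded.
#' Means and Monte-Carlo standard errors over replicates are returned.
#' Deterministic under a fixed seed.
#'
#' @param views list of cluster views from [eligible_clusters].
#' @param n_sample ESTs drawn per cluster (default 10).
#' @param reps number of replicates (default 100).
#' @param seed RNG seed.
#' @param include_transcripts passed to [detect_events].
#' @return list with `mean` (named vector: `as_fraction`, four type
#'   counts), `se` (matching Monte-Carlo standard errors), `n_eligible`
#'   and the per-replicate matrix `replicates`.
#' @export
normalized_as_rates <- function(views, n_sample = 10L, reps = 100L,
                                seed = 1L, include_transcripts = TRUE) {
  n_est <- vapply(views, function(v) sum(v$members$kind == "est"), integer(1))
  eligible <- views[n_est >= n_sample]
  if (!length(eligible)) stop("no cluster with at least ", n_sample,
                              " unambiguously spliced ESTs")
  types <- c("exon_skipping", "intron_retention", "alt5", "alt3")
  res <- with_seed(seed, {
    t(vapply(seq_len(reps), function(rep_i) {
      as_flag <- 0
      counts <- stats::setNames(numeric(4), types)
      for (v in eligible) {
        est_ix <- which(v$members$kind == "est")
        keep <- sort(sample(est_ix, n_sample))
        sub <- v
        sel <- sort(c(keep, which(v$members$kind == "transcript")))
        sub$members <- v$members[sel, , drop = FALSE]
        ev <- detect_events(sub, include_transcripts = include_transcripts)
        four <- ev[ev$event_type %in% types, , drop = FALSE]
        if (nrow(four)) as_flag <- as_flag + 1
        counts <- counts + vapply(types, function(t)
          sum(four$event_type == t), integer(1))
      }
      c(as_fraction = as_flag / length(eligible), counts)
    }, numeric(5)))
  })
  list(mean = colMeans(res),
       se = apply(res, 2, stats::sd) / sqrt(reps),
       n_eligible = length(eligible),
       replicates = res)
}

#' Compare alternative-splicing pattern distributions across species
#'
#' Standard contingency chi-square on an r x 4 table of per-species event
#' counts (no continuity correction), with (r-1)(4-1) degrees of freedom.
#'
#' @param count_table matrix, rows = species, columns = the four patterns.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
compare_pattern_distributions <- function(count_table) {
  count_table <- as.matrix(count_table)
  if (nrow(count_table) < 2L) stop("need at least two species rows")
  if (any(count_table < 0)) stop("negative count")
  if (any(rowSums(count_table) == 0)) stop("zero row in count table")
  ct <- suppressWarnings(stats::chisq.test(count_table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
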