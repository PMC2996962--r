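# Fixture suite for the four local alternative-splicing patterns, forward
# and reverse orientation, plus complex divergences and mirroring
# invariance.

# canonical three-exon backbone and its variants
skel <- bl(0, 100, 200, 300, 400, 500)

as_fixtures <- list(
  exon_skipping = list(t1 = skel, t2 = bl(0, 100, 400, 500),
                       region = c(200L, 300L)),
  intron_retention = list(t1 = skel, t2 = bl(0, 100, 200, 500),
                          region = c(300L, 400L)),
  alt5_fwd = list(t1 = skel, t2 = bl(0, 100, 200, 280, 400, 500),
                  type_fwd = "alt5", type_rev = "alt3",
                  region = c(280L, 300L)),
  alt3_fwd = list(t1 = skel, t2 = bl(0, 100, 230, 300, 400, 500),
                  type_fwd = "alt3", type_rev = "alt5",
                  region = c(200L, 230L)))

test_that("the four patterns classify exactly on forward and reverse fixtures", {
  for (nm in c("exon_skipping", "intron_retention")) {
    f <- as_fixtures[[nm]]
    for (ori in c("forward", "reverse")) {
      ev <- classify_pair(f$t1, f$t2, ori)
      expect_equal(nrow(ev), 1L, info = paste(nm, ori))
      expect_equal(ev$type, nm, info = paste(nm, ori))
      expect_equal(c(ev$start, ev$end), f$region, info = paste(nm, ori))
      # symmetric in argument order
      ev2 <- classify_pair(f$t2, f$t1, ori)
      expect_equal(ev2$signature, ev$signature)
    }
  }
  for (nm in c("alt5_fwd", "alt3_fwd")) {
    f <- as_fixtures[[nm]]
    ev_f <- classify_pair(f$t1, f$t2, "forward")
    expect_equal(ev_f$type, f$type_fwd, info = nm)
    expect_equal(c(ev_f$start, ev_f$end), f$region, info = nm)
    # orientation flip swaps alt5 <-> alt3 on the same coordinates
    ev_r <- classify_pair(f$t1, f$t2, "reverse")
    expect_equal(ev_r$type, f$type_rev, info = nm)
    expect_equal(c(ev_r$start, ev_r$end), f$region, info = nm)
    expect_equal(classify_pair(f$t2, f$t1, "forward")$type, f$type_fwd)
  }
})

test_that("spec textbook cases classify as stated", {
  # skipping of exon (200,300)
  ev <- classify_pair(bl(0, 100, 200, 300, 400, 500), bl(0, 100, 400, 500),
                      "forward")
  expect_equal(ev$type, "exon_skipping")
  expect_equal(c(ev$start, ev$end), c(200L, 300L))
  # retention: intron (100,200) of t1 inside the single exon of t2
  ev <- classify_pair(bl(0, 100, 200, 300), bl(0, 300), "forward")
  expect_equal(ev$type, "intron_retention")
  expect_equal(c(ev$start, ev$end), c(100L, 200L))
  # forward introns (100,200) vs (120,200): shared acceptor, donors differ
  ev <- classify_pair(bl(0, 100, 200, 300), bl(0, 120, 200, 300), "forward")
  expect_equal(ev$type, "alt5")
})

test_that("complex divergences are tagged complex, not forced into a type", {
  # overlapping divergent introns with no shared boundary: not one of the
  # four patterns (outer intron shared so the pair is comparable)
  t1 <- bl(0, 100, 200, 300, 400, 500)
  t2 <- bl(0, 130, 230, 300, 400, 500)
  ev <- classify_pair(t1, t2, "forward")
  expect_true(all(ev$type == "complex"))
  expect_equal(nrow(ev), 2L)  # one leftover divergent intron per side
  # a shifted exon with both boundaries moved splits into the two alt
  # patterns, one per flanking intron
  t3 <- bl(0, 100, 200, 300, 400, 500, 600, 700)
  t4 <- bl(0, 100, 230, 320, 400, 500, 600, 700)
  ev2 <- classify_pair(t3, t4, "forward")
  expect_setequal(ev2$type, c("alt3", "alt5"))
})

test_that("classify_pair demands some shared splice structure", {
  expect_error(classify_pair(bl(0, 100, 200, 300), bl(1000, 1100, 1200, 1300),
                             "forward"),
               "share no splice site")
})

test_that("event detection deduplicates by signature and orders deterministically", {
  # three ESTs: two witness the skipped exon against one inclusion EST
  members <- data.frame(member_id = c("a", "b", "c"),
                        kind = "est", orientation = "forward",
                        stringsAsFactors = FALSE)
  members$blocks <- list(bl(0, 100, 400, 500), bl(0, 100, 400, 500), skel)
  members$sites <- lapply(members$blocks, function(b)
    splice_sites_of(b, rep("forward", nrow(b) - 1L), "chr1"))
  view <- list(cluster_id = "UC1", chrom = "chr1", members = members)
  ev <- detect_events(view)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "exon_skipping")
  # identical structures yield nothing
  members2 <- members
  members2$blocks <- list(skel, skel, skel)
  members2$sites <- lapply(members2$blocks, function(b)
    splice_sites_of(b, rep("forward", nrow(b) - 1L), "chr1"))
  expect_equal(nrow(detect_events(list(cluster_id = "UC2", chrom = "chr1",
                                       members = members2))), 0L)
})

test_that("fragment-length differences are not events", {
  # one EST covers more junctions than the other but they agree within
  # their overlap
  members <- data.frame(member_id = c("short", "long"), kind = "est",
                        orientation = "forward", stringsAsFactors = FALSE)
  members$blocks <- list(bl(0, 100, 200, 260), skel)
  members$sites <- lapply(members$blocks, function(b)
    splice_sites_of(b, rep("forward", nrow(b) - 1L), "chr1"))
  ev <- detect_events(list(cluster_id = "UC1", chrom = "chr1",
                           members = members))
  expect_equal(nrow(ev), 0L)
})

test_that("eligibility drops ambiguous members before counting", {
  cfg <- simulation_config(seed = 5, n_genes = 12, n_ests = 240,
                           unspliced_fraction = 0, ambiguous_fraction = 0)
  locus <- simulate_locus_set(cfg)
  est <- simulate_ests(locus$transcripts, locus$truth, cfg)
  prep <- prepare_alignments(filter_alignments(est$alignments)$kept)
  primaries <- build_primary_clusters(prep, locus$transcripts)
  uniques <- merge_to_unique(primaries)
  v2 <- eligible_clusters(uniques, primaries, prep, locus$transcripts,
                          min_spliced_ests = 2L)
  # every eligible view carries >=2 spliced ESTs
  for (v in v2)
    expect_gte(sum(v$members$kind == "est"), 2L)
  # a cluster with one spliced EST is excluded
  one <- prep[1, ]
  class(one) <- class(prep)
  p1 <- build_primary_clusters(one)
  u1 <- merge_to_unique(p1)
  expect_length(eligible_clusters(u1, p1, one), 0L)
})

test_that("detected events always satisfy the shared/different-site predicate", {
  cfg <- simulation_config(seed = 9, n_genes = 30, n_ests = 900,
                           as_variant_fraction = 0.5)
  locus <- simulate_locus_set(cfg)
  est <- simulate_ests(locus$transcripts, locus$truth, cfg)
  prep <- prepare_alignments(filter_alignments(est$alignments)$kept)
  primaries <- build_primary_clusters(prep, locus$transcripts)
  uniques <- merge_to_unique(primaries)
  views <- eligible_clusters(uniques, primaries, prep, locus$transcripts)
  idx <- stats::setNames(seq_len(nrow(prep)), prep$est_id)
  for (v in views) {
    ev <- detect_events(v)
    for (r in seq_len(nrow(ev))) {
      m <- v$members
      b1 <- m$blocks[[match(ev$id1[r], m$member_id)]]
      b2 <- m$blocks[[match(ev$id2[r], m$member_id)]]
      k1 <- site_keys(m$sites[[match(ev$id1[r], m$member_id)]])
      k2 <- site_keys(m$sites[[match(ev$id2[r], m$member_id)]])
      expect_gt(length(intersect(k1, k2)), 0L)
      expect_false(identical(sort(k1), sort(k2)) &&
                     identical(b1, b2))
    }
  }
})

test_that("splice-site conservation is exact without novel isoforms", {
  cfg <- simulation_config(seed = 3, n_genes = 15, n_ests = 300,
                           as_variant_fraction = 0)
  locus <- simulate_locus_set(cfg)
  est <- simulate_ests(locus$transcripts, locus$truth, cfg)
  prep <- prepare_alignments(filter_alignments(est$alignments)$kept)
  primaries <- build_primary_clusters(prep, locus$transcripts)
  uniques <- merge_to_unique(primaries)
  cons <- conserved_splice_fraction(uniques, primaries, prep,
                                    locus$transcripts)
  expect_equal(cons$per_site_fraction, 1.0)
  expect_equal(cons$per_cluster_identical_fraction, 1.0)
  expect_gt(cons$n_sites, 0L)
})

test_that("chi-square comparison matches hand arithmetic", {
  # identical rows: statistic 0, p 1
  same <- rbind(c(10, 10, 10, 10), c(10, 10, 10, 10))
  res <- compare_pattern_distributions(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand-computed expected counts for a 2x4 table
  tab <- rbind(c(10, 10, 10, 10), c(40, 0, 0, 0))
  res2 <- compare_pattern_distributions(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res2$df, 3)
  expect_error(compare_pattern_distributions(rbind(c(0, 0, 0, 0),
                                                   c(1, 2, 3, 4))),
               "zero row")
})
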