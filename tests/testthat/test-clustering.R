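test_that("linkage by shared splice site and by mutual overlap", {
  a <- member(bl(0, 100, 200, 300))
  b <- member(bl(50, 100, 200, 250))
  expect_true(linked(a, b))  # shared donor 100 and acceptor 200
  # single blocks: overlap 40 vs 0.5 * 100 = 50 -> not linked
  expect_false(linked(member(bl(0, 100)), member(bl(60, 160))))
  # overlap 60 > 50 -> linked
  expect_true(linked(member(bl(0, 100)), member(bl(40, 140))))
  # exactly half is not enough (strict rule)
  expect_false(linked(member(bl(0, 100)), member(bl(50, 150))))
  # different chromosome is never linked, even with equal coordinates
  expect_false(linked(a, member(bl(0, 100, 200, 300), chrom = "chr2")))
  # splice-site linkage requires the same orientation
  expect_false(linked(member(bl(0, 100, 200, 220)),
                      member(bl(80, 100, 200, 280), strand = "-")))
})

test_that("transitive closure groups indirectly linked members", {
  # A overlaps B (60 > 50), B overlaps C, A does not overlap C (20)
  specs <- list(list(blocks = bl(0, 100)),
                list(blocks = bl(40, 140)),
                list(blocks = bl(80, 180)),
                list(blocks = bl(5000, 5100)))
  prep <- prepare_alignments(aln_many(specs))
  pc <- build_primary_clusters(prep)
  expect_equal(nrow(pc), 2L)
  expect_setequal(pc$member_ids[[1]], c("e1", "e2", "e3"))
  expect_equal(pc$member_ids[[2]], "e4")
})

test_that("primary clustering matches the brute-force oracle on random instances", {
  set.seed(101)
  for (rep_i in 1:25) {
    n <- sample(5:30, 1)
    specs <- lapply(seq_len(n), function(i) {
      k <- sample(1:3, 1)
      start <- sample(0:3000, 1)
      lens <- sample(40:200, k, replace = TRUE)
      gaps <- sample(c(100, 200, 300), k, replace = TRUE)
      starts <- start + cumsum(c(0, (lens + gaps)[-k]))
      list(blocks = matrix(as.integer(c(starts, starts + lens)), ncol = 2),
           chrom = sample(c("chr1", "chr2"), 1))
    })
    prep <- prepare_alignments(aln_many(specs))
    pc <- build_primary_clusters(prep)
    got <- integer(n)
    for (ci in seq_len(nrow(pc)))
      got[match(pc$member_ids[[ci]], prep$est_id)] <- ci
    mem <- lapply(seq_len(n), function(i)
      member(prep$blocks[[i]], chrom = prep$chrom[i]))
    want <- brute_components(mem)
    # same partition up to labelling
    expect_equal(match(got, unique(got)), match(want, unique(want)))
  }
})

test_that("input order does not change the partition or representatives", {
  set.seed(55)
  specs <- lapply(1:20, function(i) {
    start <- sample(0:2000, 1)
    list(blocks = bl(start, start + 150))
  })
  prep <- prepare_alignments(aln_many(specs))
  pc1 <- build_primary_clusters(prep)
  perm <- sample(nrow(prep))
  prep2 <- prep[perm, ]
  class(prep2) <- class(prep)
  pc2 <- build_primary_clusters(prep2)
  expect_equal(pc1$chrom, pc2$chrom)
  expect_equal(pc1$start, pc2$start)
  expect_equal(lapply(pc1$member_ids, sort), lapply(pc2$member_ids, sort),
               ignore_attr = TRUE)
  u1 <- merge_to_unique(pc1); u2 <- merge_to_unique(pc2)
  expect_equal(u1$representative_primary, u2$representative_primary)
})

test_that("subset primaries merge into one unique cluster with the larger representative", {
  # e1 aligned at two loci; locus B also holds e2 -> A = {e1} subset of
  # B = {e1, e2}
  specs <- list(
    list(blocks = bl(0, 100), est_id = "e1"),
    list(blocks = bl(10000, 10100), est_id = "e1"),
    list(blocks = bl(10010, 10110), est_id = "e2"))
  prep <- prepare_alignments(aln_many(specs))
  pc <- build_primary_clusters(prep)
  expect_equal(nrow(pc), 2L)
  u <- merge_to_unique(pc)
  expect_equal(nrow(u), 1L)
  bigger <- pc$cluster_id[vapply(pc$member_ids, length, integer(1)) == 2L]
  expect_equal(u$representative_primary, bigger)
  expect_equal(u$n_ests, 2L)  # distinct EST ids
  # disjoint primaries stay apart
  specs2 <- list(list(blocks = bl(0, 100), est_id = "a"),
                 list(blocks = bl(9000, 9100), est_id = "b"))
  u2 <- merge_to_unique(build_primary_clusters(
    prepare_alignments(aln_many(specs2))))
  expect_equal(nrow(u2), 2L)
})

test_that("representative ties break to the lexicographically smallest id", {
  # two loci, each with the same EST pair (both multi-locus): mutual
  # subset, equal EST counts
  specs <- list(
    list(blocks = bl(0, 100), est_id = "x"),
    list(blocks = bl(20, 120), est_id = "y"),
    list(blocks = bl(50000, 50100), est_id = "x"),
    list(blocks = bl(50020, 50120), est_id = "y"))
  prep <- prepare_alignments(aln_many(specs))
  pc <- build_primary_clusters(prep)
  u <- merge_to_unique(pc)
  expect_equal(nrow(u), 1L)
  expect_equal(u$representative_primary, min(pc$cluster_id))
})

test_that("reference transcripts link clusters but are not counted as ESTs", {
  tx <- tx1(bl(0, 100, 200, 300, 400, 500))
  # two ESTs that only connect through the transcript's splice sites
  specs <- list(list(blocks = bl(0, 100, 200, 240)),
                list(blocks = bl(260, 300, 400, 500)))
  prep <- prepare_alignments(aln_many(specs))
  alone <- build_primary_clusters(prep)
  expect_equal(nrow(alone), 2L)
  with_tx <- build_primary_clusters(prep, tx)
  expect_equal(nrow(with_tx), 1L)
  expect_equal(with_tx$n_ests, 2L)
  expect_equal(with_tx$n_transcripts, 1L)
})

test_that("cluster statistics and conservation of the histogram", {
  specs <- list(
    list(blocks = bl(0, 100), est_id = "a"),
    list(blocks = bl(5000, 5100), est_id = "b"),
    list(blocks = bl(9000, 9100), est_id = "c"),
    list(blocks = bl(9010, 9110), est_id = "d"),
    list(blocks = bl(9020, 9120), est_id = "e"),
    list(blocks = bl(9030, 9130), est_id = "f"))
  u <- merge_to_unique(build_primary_clusters(
    prepare_alignments(aln_many(specs))))
  st <- cluster_stats(u)
  expect_equal(st$n_clusters, 3L)
  expect_equal(st$n_singletons, 2L)
  expect_equal(st$mean_ests, 2.0)
  expect_equal(sum(st$histogram), st$n_clusters)
  # empty input: zeros, no division error
  empty <- prepare_alignments(aln1(bl(0, 100)))[0, ]
  st0 <- cluster_stats(merge_to_unique(build_primary_clusters(empty)))
  expect_equal(st0$n_clusters, 0L)
  expect_equal(st0$mean_ests, 0)
})
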