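# transcript fixture: 3 exons of 100, CDS from genomic 150 to 450
# (transcript coords 50..250 of 300)
cds_tx <- function(strand = "+") {
  tx1(bl(100, 200, 300, 400, 500, 600), strand = strand,
      cds_start = 150, cds_end = 550, cds_complete = TRUE)
}

prep1 <- function(blocks, oris = NULL, strand = "+", ...) {
  prepare_alignments(aln1(blocks, oris = oris, strand = strand, ...))
}

test_that("full-span EST: coverage 1, full_cds, CDS maps to [0,1]", {
  tx <- cds_tx()
  p <- prep1(bl(100, 200, 300, 400, 500, 600))
  cov <- compute_coverage(p$blocks[[1]], tx)
  expect_equal(cov$coverage, 1.0)
  expect_true(cov$full_cds)
  # CDS spans transcript coords 50..250 -> rel -0.25 .. 1.25 for the
  # full transcript
  expect_equal(cov$start_rel, -0.25)
  expect_equal(cov$end_rel, 1.25)
})

test_that("pure-UTR ESTs are discarded, partial coverage is exact", {
  tx <- cds_tx()
  # entirely in the 5' UTR (transcript coords 0..50)
  expect_null(compute_coverage(bl(100, 145), tx))
  # covers transcript coords 50..170 = CDS overlap 120 of 200
  cov <- compute_coverage(bl(150, 200, 300, 370), tx)
  expect_equal(cov$coverage, 0.6)
  expect_false(cov$full_cds)
  expect_equal(cov$start_rel, 0)
})

test_that("minus-strand transcripts mirror relative positions but not coverage", {
  txp <- cds_tx("+"); txm <- cds_tx("-")
  est <- bl(150, 200, 300, 370)
  cp <- compute_coverage(est, txp)
  cm <- compute_coverage(est, txm)
  expect_equal(cm$coverage, cp$coverage)
  # on the minus strand the same genomic window sits at the mirrored
  # position of the CDS axis
  expect_equal(cm$start_rel, 1 - cp$end_rel)
  expect_equal(cm$end_rel, 1 - cp$start_rel)
})

test_that("EST blocks outside the exon union fail projection", {
  tx <- cds_tx()
  expect_error(compute_coverage(bl(150, 250), tx), "outside transcript exons")
})

test_that("matching: site containment, like-with-like, multi-gene discard", {
  tx <- rbind(cds_tx(), tx1(bl(5000, 5600), transcript_id = "T2",
                            gene_id = "G2", cds_start = 5100, cds_end = 5500,
                            cds_complete = TRUE))
  class(tx) <- c("transcript_models", "data.frame")
  specs <- list(
    list(blocks = bl(150, 200, 300, 360)),        # subset of T1 sites
    list(blocks = bl(5100, 5400)),                # unspliced vs unspliced T2
    list(blocks = bl(150, 200, 320, 400)),        # novel acceptor: no match
    list(blocks = bl(5100, 5300), est_id = "amb", # spliced EST, unspliced gene
         oris = character(0)))
  prep <- prepare_alignments(aln_many(specs))
  m <- match_est_to_transcript(prep, tx)
  expect_equal(m[1], "T1")
  expect_equal(m[2], "T2")
  expect_true(is.na(m[3]))
  # spliced EST never matches an unspliced transcript
  sp <- prep1(bl(5000, 5100, 5300, 5400))
  expect_true(is.na(match_est_to_transcript(sp, tx)[1]))
  # transcripts without a complete CDS are excluded
  tx_inc <- cds_tx(); tx_inc$cds_complete <- FALSE
  expect_true(is.na(match_est_to_transcript(prep[1, ], tx_inc)[1]))
  # EST overlapping two genes is discarded
  tx2 <- rbind(tx1(bl(0, 1000), transcript_id = "A1", gene_id = "GA",
                   cds_start = 100, cds_end = 700, cds_complete = TRUE),
               tx1(bl(600, 1600), transcript_id = "B1", gene_id = "GB",
                   cds_start = 700, cds_end = 1300, cds_complete = TRUE))
  class(tx2) <- c("transcript_models", "data.frame")
  both <- prepare_alignments(aln1(bl(650, 950)))
  expect_true(is.na(match_est_to_transcript(both, tx2)[1]))
})

test_that("profile: conservation, top-bin mass, center symmetry of a mirror pair", {
  rec <- data.frame(est_id = c("a", "b", "c"), transcript_id = "T1",
                    coverage = c(1, 1, 0.4), full_cds = c(TRUE, TRUE, FALSE),
                    start_rel = c(0, 0, 0.2), end_rel = c(1, 1, 0.6))
  prof <- coverage_profile(rec, n_bins = 10)
  expect_equal(sum(prof$counts), nrow(rec))
  expect_equal(prof$counts[10], 2L)
  expect_equal(prof$n_full_cds, 2L)
  expect_equal(prof$mean_coverage, mean(rec$coverage))
  # center-relative axis: CDS midpoint at 0, ends at +/- 0.5
  expect_equal(prof$center_positions$start[1], -0.5)
  expect_equal(prof$center_positions$end[1], 0.5)
})

test_that("strand mirror of a synthetic locus set leaves coverage invariant", {
  cfg <- simulation_config(seed = 17, n_genes = 12, n_ests = 300,
                           ambiguous_fraction = 0, cds_incomplete_fraction = 0)
  locus <- simulate_locus_set(cfg)
  est <- simulate_ests(locus$transcripts, locus$truth, cfg)
  prep <- prepare_alignments(filter_alignments(est$alignments)$kept)
  rec <- cds_coverage_records(prep, locus$transcripts)
  expect_gt(nrow(rec), 50)
  # mirror every coordinate: x -> M - x flips all strands
  M <- 10000000L
  flip_blocks <- function(b) {
    out <- cbind(M - b[, 2L], M - b[, 1L])
    out[nrow(out):1L, , drop = FALSE]
  }
  tx_m <- locus$transcripts
  tx_m$exons <- lapply(tx_m$exons, flip_blocks)
  cs <- tx_m$cds_start
  tx_m$cds_start <- M - tx_m$cds_end
  tx_m$cds_end <- M - cs
  tx_m$strand <- ifelse(tx_m$strand == "+", "-", "+")
  prep_m <- prep
  prep_m$blocks <- lapply(prep_m$blocks, flip_blocks)
  prep_m$strand <- ifelse(prep_m$strand == "+", "-",
                          ifelse(prep_m$strand == "-", "+", "unknown"))
  prep_m$intron_orientations <- lapply(prep_m$intron_orientations, function(o)
    rev(ifelse(o == "forward", "reverse",
               ifelse(o == "reverse", "forward", "ambiguous"))))
  prep_m <- prepare_alignments(prep_m)
  rec_m <- cds_coverage_records(prep_m, tx_m)
  a <- rec[order(rec$est_id), ]
  b <- rec_m[order(rec_m$est_id), ]
  expect_equal(a$est_id, b$est_id)
  expect_equal(a$coverage, b$coverage, tolerance = 1e-12)
  expect_equal(a$full_cds, b$full_cds)
  # the strand-corrected axis undoes the mirror: relative positions are
  # invariant, not flipped
  expect_equal(a$start_rel, b$start_rel, tolerance = 1e-12)
  expect_equal(a$end_rel, b$end_rel, tolerance = 1e-12)
})

test_that("full_cds flags agree with the planted window truth", {
  cfg <- simulation_config(seed = 23, n_genes = 10, n_ests = 250,
                           as_variant_fraction = 0, ambiguous_fraction = 0,
                           cds_incomplete_fraction = 0)
  locus <- simulate_locus_set(cfg)
  est <- simulate_ests(locus$transcripts, locus$truth, cfg)
  prep <- prepare_alignments(filter_alignments(est$alignments)$kept)
  rec <- cds_coverage_records(prep, locus$transcripts)
  # truth: an EST covers the full CDS iff its genomic span contains the
  # transcript's CDS interval and no exon is skipped (no variants here)
  tx <- locus$transcripts
  for (r in seq_len(nrow(rec))) {
    i <- match(rec$transcript_id[r], tx$transcript_id)
    blocks <- prep$blocks[[match(rec$est_id[r], prep$est_id)]]
    covered <- blocks_overlap_length(
      blocks, cbind(tx$cds_start[i], tx$cds_end[i]))
    cds_exonic <- blocks_overlap_length(
      tx$exons[[i]], cbind(tx$cds_start[i], tx$cds_end[i]))
    expect_equal(rec$full_cds[r], covered == cds_exonic)
  }
})
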