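# Hand-worked NG86 oracle.
#
# 100 codons of GGG (glycine). Per codon, the third position is 4-fold
# degenerate (3/3 synonymous changes) and positions 1-2 are fully
# non-degenerate, so s(GGG) = 1. Plant 2 synonymous changes (GGG->GGA,
# still Gly, s(GGA) = 1) and 2 non-synonymous ones (GGG->AGG, Arg).
# AGG's synonymous neighbours are CGG (pos 1) and AGA (pos 3):
# s(AGG) = 2/3. Hence S1 = 100, S2 = 96 + 2 + 2*(2/3), S = (S1+S2)/2,
# N = 300 - S, Sd = 2, Nd = 2 (single-path differences).

test_that("NG86 matches the hand-worked oracle", {
  s1 <- paste(rep("GGG", 100), collapse = "")
  codons <- rep("GGG", 100)
  codons[c(3, 50)] <- "GGA"
  codons[c(10, 60)] <- "AGG"
  s2 <- paste(codons, collapse = "")
  res <- kaks_counting(s1, s2)
  S <- (100 + 96 + 2 + 2 * (2 / 3)) / 2
  expect_equal(res$ns_sites, S, tolerance = 1e-9)
  expect_equal(res$na_sites, 300 - S, tolerance = 1e-9)
  expect_equal(res$sd, 2, tolerance = 1e-12)
  expect_equal(res$nd, 2, tolerance = 1e-12)
  expect_equal(res$ks, -0.75 * log(1 - 4 * (2 / S) / 3), tolerance = 1e-9)
  expect_equal(res$ka, -0.75 * log(1 - 4 * (2 / (300 - S)) / 3),
               tolerance = 1e-9)
})

test_that("analytic special cases: identical and synonymous-only pairs", {
  s <- paste(rep(c("ATG", "GCT", "AAA"), 30), collapse = "")
  res <- kaks_counting(s, s)
  expect_equal(res$ka, 0)
  expect_equal(res$ks, 0)
  expect_true(is.nan(res$ratio))
  # single 4-fold site change among 20 codons: synonymous only, ratio 0
  g1 <- paste(rep("GGG", 20), collapse = "")
  g2 <- paste(c("GGA", rep("GGG", 19)), collapse = "")
  res2 <- kaks_counting(g1, g2)
  expect_equal(res2$ka, 0)
  expect_gt(res2$ks, 0)
  expect_equal(res2$ratio, 0)
  # non-synonymous only: Ks = 0, Ka > 0 -> ratio Inf
  res3 <- kaks_counting("ATGGAT", "ATGCAT")
  expect_equal(res3$ks, 0)
  expect_gt(res3$ka, 0)
  expect_equal(res3$ratio, Inf)
})

test_that("NG86 is symmetric and conserves sites", {
  set.seed(31)
  sim <- simulate_codon_pairs(5, 200, target_ka = 0.08, target_ks = 0.25,
                              seed = 77)
  for (i in seq_len(nrow(sim$pairs))) {
    a <- kaks_counting(sim$pairs$seq1[i], sim$pairs$seq2[i])
    b <- kaks_counting(sim$pairs$seq2[i], sim$pairs$seq1[i])
    expect_equal(a$ka, b$ka, tolerance = 1e-12)
    expect_equal(a$ks, b$ks, tolerance = 1e-12)
    expect_equal(a$na_sites + a$ns_sites,
                 3 * a$n_codons, tolerance = 1e-9)
  }
})

test_that("ambiguous codons are excluded, errors on stops and bad length", {
  a <- kaks_counting("ATGNNNGCT", "ATGAAAGCT")
  expect_equal(a$n_codons, 2L)
  expect_error(kaks_counting("ATGTAAGCT", "ATGTAAGCT"), "stop codon")
  expect_error(kaks_counting("ATGA", "ATGA"), "divisible by 3")
  expect_error(kaks_counting("ATG", "ATGGCT"), "differ in length")
})

test_that("estimator recovers planted rates on long simulated alignments", {
  sim <- simulate_codon_pairs(3, 10000, target_ka = 0.1, target_ks = 0.3,
                              seed = 19)
  res <- kaks_table(sim$pairs)
  expect_true(all(abs(res$ka - 0.1) / 0.1 < 0.1))
  expect_true(all(abs(res$ks - 0.3) / 0.3 < 0.1))
  # zero-rate targets give identical sequences
  sim0 <- simulate_codon_pairs(2, 100, 0, 0, seed = 4)
  expect_identical(sim0$pairs$seq1, sim0$pairs$seq2)
  # no stop codons anywhere
  gc_tab <- Biostrings::GENETIC_CODE
  for (s in c(sim$pairs$seq1, sim$pairs$seq2)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(gc_tab[cods] == "*"))
  }
  # determinism under the seed
  sim_b <- simulate_codon_pairs(3, 100, 0.1, 0.3, seed = 19)
  sim_c <- simulate_codon_pairs(3, 100, 0.1, 0.3, seed = 19)
  expect_identical(sim_b, sim_c)
  expect_error(simulate_codon_pairs(1, 100, 0.1, 5), "saturation")
})

test_that("high-rate group filter follows the more-than-one-pair rule", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    ka = c(0.1, 0.3, 0.05), ks = c(0.5, 0.4, 0.6))
  one <- filter_rates(res)
  expect_equal(nrow(one$kept), 3L)   # one violating pair: group kept
  res$ks[3] <- 5.0                   # boundary Ks >= 5 counts
  two <- filter_rates(res)
  expect_equal(nrow(two$kept), 0L)
  expect_equal(two$n_violations, 2L)
  clean <- filter_rates(data.frame(gene_id = "a", ka = 0.01, ks = 0.1))
  expect_equal(nrow(clean$discarded), 0L)
})

test_that("codon-pair FASTA round-trips", {
  sim <- simulate_codon_pairs(4, 50, 0.05, 0.2, seed = 3)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_codon_pairs_fasta(sim$pairs, path)
  back <- read_codon_pairs_fasta(path)
  expect_equal(back, sim$pairs)
})

test_that("exact Wilcoxon agrees with full enumeration and wilcox.test", {
  # x={1,2,3}, y={4,5,6}: one-sided exact p = 1/C(6,3) = 1/20
  w <- wilcoxon_rank_sum(1:3, 4:6, "less")
  expect_equal(w$p_value, 0.05, tolerance = 1e-12)
  expect_true(w$exact)
  # identical multisets: two-sided p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  # tie-free random layouts match wilcox.test exact p
  set.seed(12)
  for (i in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(100, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    for (alt in c("two_sided", "less", "greater")) {
      ours <- wilcoxon_rank_sum(x, y, alt)
      ref <- stats::wilcox.test(x, y, alternative = sub("_sided", ".sided",
                                                        alt), exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("exact Wilcoxon handles ties via enumeration of midranks", {
  # brute-force oracle: enumerate subsets of the midrank vector directly
  x <- c(1, 2, 2, 5); y <- c(2, 3, 3, 7)
  r <- rank(c(x, y))
  sets <- utils::combn(8, 4)
  Us <- colSums(matrix(r[sets], nrow = 4)) - 4 * 5 / 2
  U <- sum(r[1:4]) - 10
  p_less <- mean(Us <= U + 1e-9)
  got <- wilcoxon_rank_sum(x, y, "less")
  expect_equal(got$p_value, p_less, tolerance = 1e-12)
})

test_that("normal approximation tracks the exact p on moderate samples", {
  set.seed(77)
  for (i in 1:10) {
    x <- round(rnorm(6, 0, 2), 1); y <- round(rnorm(6, 0.5, 2), 1)
    pe <- wilcoxon_rank_sum(x, y, "two_sided")$p_value
    pa <- wilcoxon_rank_sum(x, y, "two_sided", exact_max = 0L)$p_value
    expect_lt(abs(pe - pa), 0.03)
  }
})

test_that("gene-set comparison is directional and validates input", {
  res <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    ratio = c(rep(0.05, 10), rep(0.2, 30)))
  tissue_of <- stats::setNames(rep("heart", 40), res$gene_id)
  cmp <- compare_gene_sets(res, sprintf("g%02d", 1:10), tissue_of)
  expect_lt(cmp$p_value, 0.01)
  expect_error(compare_gene_sets(res, character(0), tissue_of), "empty")
  # infinite ratios are dropped by default, included as largest on demand
  res$ratio[1] <- Inf
  cmp2 <- compare_gene_sets(res, sprintf("g%02d", 1:10), tissue_of)
  expect_equal(cmp2$n_set, 9L)
  cmp3 <- compare_gene_sets(res, sprintf("g%02d", 1:10), tissue_of,
                            include_infinite = TRUE)
  expect_equal(cmp3$n_set, 10L)
})
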