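#' Assemble a validated pipeline configuration
#'
#' Mirrors each stage's thresholds and defaults in one nested list; every
#' run logs the thresholds it actually applied. Unknown keys (top level or
#' within a block) are rejected before any stage runs. Per-stage RNG
#' streams are derived from the global seed by fixed offsets (simulation:
#' `seed`; EST draw: `seed + 1`; subsampling: `seed + 2`; codon pairs:
#' `seed + 3`) so stages can be rerun independently.
#'
#' @param config named list (e.g. parsed from YAML) overriding defaults.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    seed = 42L,
    outdir = "estpipe_out",
    simulate = list(n_genes = 200L, n_ests = 5000L,
                    as_variant_fraction = 0.3,
                    tissue_specific_fraction = 0.1,
                    specificity_odds = 20,
                    unspliced_fraction = 0.2, ambiguous_fraction = 0.05),
    prep = list(min_identity = 0.85, min_coverage = 0.5),
    cluster = list(min_overlap_frac = 0.5),
    splice = list(min_spliced_ests = 2L, normalize_n = 10L,
                  normalize_reps = 100L),
    express = list(min_total = 10L, p_threshold = 1e-3, or_threshold = 10),
    cdscov = list(n_bins = 20L),
    kaks = list(n_codons = 300L, target_ka = 0.1, target_ks = 0.4,
                focal_ka = 0.04, focal_fraction = 0.2,
                ka_max = 0.25, ks_max = 5))
  merged <- defaults
  for (key in names(config)) {
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    if (is.list(defaults[[key]])) {
      for (sub in names(config[[key]])) {
        if (!sub %in% names(defaults[[key]]))
          stop("unknown config key: ", key, ".", sub)
        merged[[key]][[sub]] <- config[[key]][[sub]]
      }
    } else merged[[key]] <- config[[key]]
  }
  structure(merged, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config] structure.
#' @return validated config.
#' @export
read_pipeline_config <- function(path) pipeline_config(yaml::read_yaml(path))

#' Run the full synthetic-data pipeline
#'
#' Stages run in dependency order: simulate, prep, cluster, splice,
#' express, cdscov, kaks. Every stage writes its outputs under
#' `config$outdir`; a manifest lists each file with an md5 checksum, so
#' reruns with an identical config reproduce identical manifests.
#'
#' @param config a [pipeline_config] (or a plain list passed through it).
#' @param quiet suppress progress messages.
#' @return list with `manifest` (`data.frame` of `file`, `md5`), `summary`
#'   (headline numbers per stage) and the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- file.path

  say("simulate: n_genes=", config$simulate$n_genes,
      " n_ests=", config$simulate$n_ests, " seed=", config$seed)
  sim_cfg <- simulation_config(
    seed = config$seed,
    n_genes = config$simulate$n_genes,
    n_ests = config$simulate$n_ests,
    as_variant_fraction = config$simulate$as_variant_fraction,
    tissue_specific_fraction = config$simulate$tissue_specific_fraction,
    specificity_odds = config$simulate$specificity_odds,
    unspliced_fraction = config$simulate$unspliced_fraction,
    ambiguous_fraction = config$simulate$ambiguous_fraction)
  locus <- simulate_locus_set(sim_cfg)
  est <- simulate_ests(locus$transcripts, locus$truth, sim_cfg)
  write_transcripts_gtf(locus$transcripts, out(config$outdir, "models.gtf"))
  write_alignments_tsv(est$alignments, out(config$outdir, "alignments.tsv"))

  say("prep: identity>", config$prep$min_identity,
      " coverage>", config$prep$min_coverage)
  thr <- filter_thresholds(config$prep$min_identity, config$prep$min_coverage)
  flt <- filter_alignments(est$alignments, thr)
  prepared <- prepare_alignments(flt$kept)
  utils::write.table(flt$rejected, out(config$outdir, "rejected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("cluster: overlap>", config$cluster$min_overlap_frac,
      " of the shorter projection")
  primaries <- build_primary_clusters(prepared, locus$transcripts,
                                      config$cluster$min_overlap_frac)
  uniques <- merge_to_unique(primaries)
  stats_cl <- cluster_stats(uniques)
  write_clusters_bed(primaries, out(config$outdir, "primary_clusters.bed"))

  say("splice: >=", config$splice$min_spliced_ests,
      " unambiguously spliced ESTs per cluster")
  views <- eligible_clusters(uniques, primaries, prepared, locus$transcripts,
                             min_spliced_ests = config$splice$min_spliced_ests)
  events_by_cluster <- lapply(views, detect_events)
  empty_events <- data.frame(cluster_id = character(0),
                             event_type = character(0),
                             signature = character(0), chrom = character(0),
                             start = integer(0), end = integer(0),
                             id1 = character(0), id2 = character(0),
                             stringsAsFactors = FALSE)
  events <- do.call(rbind, c(list(empty_events), events_by_cluster))
  as_summary <- summarize_as(views, events_by_cluster)
  write_events_tsv(events, out(config$outdir, "events.tsv"))
  norm <- tryCatch(
    normalized_as_rates(views, n_sample = config$splice$normalize_n,
                        reps = config$splice$normalize_reps,
                        seed = config$seed + 2L),
    error = function(e) NULL)

  say("express: Fisher 2x2, P<", config$express$p_threshold,
      " OR>", config$express$or_threshold)
  membership <- cluster_membership(uniques, primaries)
  emat <- build_expression_matrix(membership, est$alignments,
                                  tissues = sim_cfg$tissues)
  calls <- call_tissue_specific(emat, config$express$min_total,
                                config$express$p_threshold,
                                config$express$or_threshold)
  utils::write.table(calls, out(config$outdir, "tissue_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("cdscov")
  records <- cds_coverage_records(prepared, locus$transcripts)
  profile <- coverage_profile(records, config$cdscov$n_bins)
  utils::write.table(records, out(config$outdir, "cds_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("kaks: NG86 on ", config$simulate$n_genes, " simulated codon pairs")
  n_genes <- nrow(locus$transcripts)
  n_focal <- round(config$kaks$focal_fraction * n_genes)
  focal <- locus$transcripts$gene_id[seq_len(n_focal)]
  ka_targets <- ifelse(locus$transcripts$gene_id %in% focal,
                       config$kaks$focal_ka, config$kaks$target_ka)
  cp <- simulate_codon_pairs(n_genes, config$kaks$n_codons,
                             target_ka = ka_targets,
                             target_ks = config$kaks$target_ks,
                             seed = config$seed + 3L,
                             gene_ids = locus$transcripts$gene_id)
  write_codon_pairs_fasta(cp$pairs, out(config$outdir, "codon_pairs.fasta"))
  kres <- kaks_table(cp$pairs)
  # tissue of a gene = its dominant expression tissue
  gene_tissue <- apply(truth_props_of(est$truth), 1L, function(w)
    sim_cfg$tissues[which.max(w)])
  comparison <- compare_gene_sets(kres, focal, gene_tissue)
  utils::write.table(kres, out(config$outdir, "kaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gene_map <- cluster_gene_map(membership, est$truth$est_gene)
  as_score <- score_as_recovery(events, est$truth, gene_map)
  ts_score <- score_specificity(calls, est$truth, gene_map)

  summary <- list(
    thresholds = config[c("prep", "cluster", "splice", "express", "kaks")],
    n_alignments = nrow(est$alignments),
    n_kept = nrow(prepared),
    n_primary_clusters = nrow(primaries),
    n_unique_clusters = stats_cl$n_clusters,
    n_singletons = stats_cl$n_singletons,
    mean_ests_per_cluster = stats_cl$mean_ests,
    n_eligible_clusters = as_summary$n_clusters_eligible,
    n_as_clusters = as_summary$n_clusters_as,
    as_counts = as.list(as_summary$counts),
    as_percentages = as.list(round(as_summary$percentages, 2)),
    normalized_as_fraction =
      if (!is.null(norm)) unname(norm$mean["as_fraction"]) else NA,
    n_tissue_specific = sum(calls$significant),
    mean_cds_coverage = profile$mean_coverage,
    n_full_cds = profile$n_full_cds,
    as_recall = as_score$recall,
    as_type_accuracy = as_score$type_accuracy,
    tissue_recall = ts_score$recall,
    tissue_false_call_rate = ts_score$false_call_rate,
    kaks_comparison = comparison)
  write_results_json(summary, out(config$outdir, "summary.json"))

  files <- sort(list.files(config$outdir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_results_json(manifest, out(config$outdir, "manifest.json"))
  invisible(list(manifest = manifest, summary = summary,
                 locus = locus, est = est, prepared = prepared,
                 primaries = primaries, uniques = uniques, views = views,
                 events = events, expression = emat, calls = calls,
                 cds_records = records, cds_profile = profile,
                 kaks = kres, kaks_truth = cp$truth,
                 kaks_comparison = comparison,
                 normalized = norm, gene_map = gene_map,
                 as_score = as_score, ts_score = ts_score))
}

truth_props_of <- function(truth) truth$tissue_props
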