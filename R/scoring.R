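# Scoring of pipeline output against the simulator's planted truth.

#' Map each unique cluster to its dominant source gene
#' @param membership output of [cluster_membership].
#' @param est_gene `truth$est_gene` table from [simulate_ests].
#' @return named character vector, cluster_id -> gene_id.
#' @export
cluster_gene_map <- function(membership, est_gene) {
  gene <- est_gene$gene_id[match(membership$est_id, est_gene$est_id)]
  vapply(split(gene, membership$cluster_id), function(g) {
    tt <- sort(table(g), decreasing = TRUE)
    names(tt)[1L]
  }, "")
}

#' Score detected splicing events against the planted truth
#'
#' A planted event is recalled when a detected event in a cluster mapping
#' to the planted gene matches its divergent region (`start`, `end`).
#' Type accuracy is the fraction of recalled events whose type label also
#' matches; with exact signature strings this separates "the region was
#' seen" from "the region was classified correctly".
#'
#' @param events combined event table over all clusters.
#' @param truth truth record carrying `planted_as_events`.
#' @param gene_map output of [cluster_gene_map].
#' @return list with `n_planted`, `n_recalled`, `recall`,
#'   `type_accuracy` and the per-event table `detail`.
#' @export
score_as_recovery <- function(events, truth, gene_map) {
  planted <- truth$planted_as_events
  ev_gene <- gene_map[events$cluster_id]
  recalled <- logical(nrow(planted))
  type_ok <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    sel <- which(ev_gene == planted$gene_id[i] &
                   events$start == planted$start[i] &
                   events$end == planted$end[i])
    if (length(sel)) {
      recalled[i] <- TRUE
      type_ok[i] <- any(events$event_type[sel] == planted$type[i])
    }
  }
  list(n_planted = nrow(planted), n_recalled = sum(recalled),
       recall = if (nrow(planted)) mean(recalled) else NA_real_,
       type_accuracy = if (sum(recalled)) mean(type_ok[recalled]) else NA_real_,
       detail = data.frame(planted, recalled = recalled, type_ok = type_ok))
}

#' Score tissue-specificity calls against the planted truth
#'
#' Recall is over planted tissue-specific genes whose cluster was tested
#' (at least `min_total` ESTs); the false-call rate is the fraction of
#' tested null-gene clusters that received a significant call.
#'
#' @param calls output of [call_tissue_specific].
#' @param truth truth record carrying `tissue_specific_genes`.
#' @param gene_map output of [cluster_gene_map].
#' @return list with `recall`, `false_call_rate`, `n_planted_tested`,
#'   `n_null_tested`.
#' @export
score_specificity <- function(calls, truth, gene_map) {
  tested_clusters <- unique(calls$cluster_id)
  sig <- calls[calls$significant, , drop = FALSE]
  planted <- truth$tissue_specific_genes
  cluster_of_gene <- stats::setNames(names(gene_map), gene_map)
  hit <- 0L; tested <- 0L
  for (i in seq_len(nrow(planted))) {
    cl <- cluster_of_gene[planted$gene_id[i]]
    if (is.na(cl) || !(cl %in% tested_clusters)) next
    tested <- tested + 1L
    if (any(sig$cluster_id == cl & sig$tissue == planted$tissue[i]))
      hit <- hit + 1L
  }
  null_clusters <- tested_clusters[
    !(gene_map[tested_clusters] %in% planted$gene_id)]
  false_calls <- sum(unique(sig$cluster_id) %in% null_clusters)
  list(recall = if (tested) hit / tested else NA_real_,
       false_call_rate = if (length(null_clusters))
         false_calls / length(null_clusters) else NA_real_,
       n_planted_tested = tested,
       n_null_tested = length(null_clusters))
}
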