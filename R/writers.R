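# Plain-text emitters for downstream inspection; BED spans are 0-based
# half-open like everything internal.

#' Write cluster spans as BED
#' @param clusters a primary-cluster table (see [build_primary_clusters]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(clusters)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.",
                       clusters$chrom, clusters$start, clusters$end,
                       clusters$cluster_id, clusters$n_ests), con)
  }
  invisible(path)
}

#' Write / read alternative-splicing events as TSV
#'
#' The TSV round-trips losslessly: `read_events_tsv(write_events_tsv(x))`
#' reproduces `x`. An empty event set yields a header-only file.
#'
#' @param events event table from [detect_events].
#' @param path file path.
#' @return `path` (writer, invisibly) or the event table (reader).
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("cluster_id", "event_type", "signature", "chrom",
            "start", "end", "id1", "id2")
  df <- if (nrow(events)) events[, cols] else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(cluster_id = "character",
                                         event_type = "character",
                                         signature = "character",
                                         chrom = "character",
                                         start = "integer", end = "integer",
                                         id1 = "character",
                                         id2 = "character"))
  df
}

#' Write any stage result as JSON
#' @param x result object (list / data.frame of atomic columns).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
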