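#' Count gene models overlapping each CNV event
#'
#' A gene is counted for an event when the two intervals overlap by at
#' least one base on the same chromosome (1-based inclusive; strand is
#' ignored — dosage is strand-agnostic). A partially overlapping gene is
#' dosage-affected, so any overlap counts by default; `mode = "within"`
#' restricts to genes fully contained in the event for sensitivity
#' analysis. Overlap is computed with GenomicRanges.
#'
#' @param events An event tibble (see [call_events()]).
#' @param genes A gene-model tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param mode `"any"` (any overlap, default) or `"within"` (gene fully
#'   inside the event).
#' @return `events` with `n_genes` (count) and `gene_ids` (comma-separated
#'   ids) columns added.
#' @export
annotate_events <- function(events, genes, mode = c("any", "within")) {
  mode <- rlang::arg_match(mode)
  if (nrow(events) == 0) {
    events$n_genes <- integer()
    events$gene_ids <- character()
    return(events)
  }
  ev_gr <- GenomicRanges::GRanges(
    events$chrom, IRanges::IRanges(events$start, events$end))
  gn_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gn_gr, ev_gr, type = mode,
                                      ignore.strand = TRUE)
  ids_by_event <- split(genes$gene_id[S4Vectors_from(hits)],
                        factor(S4Vectors_to(hits), levels = seq_len(nrow(events))))
  out <- events
  out$n_genes <- unname(lengths(ids_by_event))
  out$gene_ids <- unname(purrr::map_chr(ids_by_event, paste, collapse = ","))
  attr(out, "bin_size") <- attr(events, "bin_size")
  out
}

# thin indirection so the S4Vectors accessors are easy to stub in tests
S4Vectors_from <- function(hits) S4Vectors::queryHits(hits)
S4Vectors_to <- function(hits) S4Vectors::subjectHits(hits)

#' Total genes affected across a set of events
#'
#' Reports both the column sum of per-event gene counts (a gene
#' overlapping two events counts twice, matching how per-row counts in a
#' CNV report add up) and the number of distinct genes in the union.
#'
#' @inheritParams annotate_events
#' @return A one-row tibble: `n_events`, `total_gene_hits`,
#'   `distinct_genes`.
#' @export
gene_totals <- function(events, genes, mode = c("any", "within")) {
  ann <- annotate_events(events, genes, mode = mode)
  ids <- unlist(strsplit(ann$gene_ids[ann$gene_ids != ""], ","))
  tibble::tibble(
    n_events = nrow(ann),
    total_gene_hits = sum(ann$n_genes),
    distinct_genes = length(unique(ids))
  )
}
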