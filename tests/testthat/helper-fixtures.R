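# Shared fixtures: small layouts and simulation shortcuts so module tests
# run in seconds; full Musa-scale layouts are reserved for the end-to-end
# recovery tests.

tiny_layout <- function(n_chr = 2, len = 3e6, bin_size = 100000L) {
  genome_layout(paste0("chr", seq_len(n_chr)), rep(len, n_chr),
                bin_size = bin_size)
}

sim_counts <- function(cfg, events = NULL, replicate_id = 1L,
                       stream = replicate_id, id = "s") {
  bin_counts(simulate_sample(cfg, events, replicate_id, stream = stream),
             cfg$layout, sample_id = id)
}

# bin-count tibble built directly from a vector of counts on a layout grid
counts_from_vector <- function(counts, layout, id = "s") {
  grid <- make_bins(layout)
  stopifnot(length(counts) == nrow(grid))
  out <- dplyr::mutate(grid, sample_id = id, count = counts)
  out <- dplyr::select(out, sample_id, chrom, bin, start, end, count)
  attr(out, "bin_size") <- bin_size(layout)
  out
}

# dosage tibble with prescribed rsrc values on a single-chromosome grid,
# for driving the caller directly
dosage_from_rsrc <- function(values, valid = rep(TRUE, length(values)),
                             bin_size = 100000, chrom = "chr1", ploidy = 3L) {
  idx <- seq_along(values) - 1
  out <- tibble::tibble(
    sample_id = "s", control_id = "c", chrom = chrom, bin = idx,
    start = idx * bin_size + 1, end = (idx + 1) * bin_size,
    rsrc = ifelse(valid, values, NA_real_), valid = valid
  )
  attr(out, "ploidy") <- ploidy
  attr(out, "bin_size") <- bin_size
  class(out) <- c("dosage_tbl", class(out))
  out
}

# Independent oracle for run calling: naive O(n^2) scan that tries every
# [i, j] window and keeps maximal same-sign runs of length >= min_run.
naive_call_runs <- function(deviation, min_run = 3) {
  n <- length(deviation)
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      win <- deviation[i:j]
      if (anyNA(win)) next
      s <- sign(win)
      if (any(s == 0) || length(unique(s)) != 1) next
      left_ok <- i == 1 || is.na(deviation[i - 1]) ||
        sign(deviation[i - 1]) != s[1] || deviation[i - 1] == 0
      right_ok <- j == n || is.na(deviation[j + 1]) ||
        sign(deviation[j + 1]) != s[1] || deviation[j + 1] == 0
      if (left_ok && right_ok && (j - i + 1) >= min_run) {
        runs[[length(runs) + 1]] <- c(i, j)
      }
    }
  }
  runs
}

# Independent oracle for gene-event overlap: all-pairs interval scan.
naive_gene_counts <- function(events, genes) {
  vapply(seq_len(nrow(events)), function(i) {
    sum(genes$chrom == events$chrom[i] &
          genes$start <= events$end[i] &
          genes$end >= events$start[i])
  }, integer(1))
}

# minimal hand-written SAM text for reader tests
sam_file <- function(records, layout, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom,
                      as.integer(layout$length)))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(chrom, pos, mapq = 60, flag = 0, qname = "r1") {
  sprintf("%s\t%d\t%s\t%d\t%d\t50M\t*\t0\t0\t*\t*",
          qname, flag, chrom, pos, mapq)
}
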