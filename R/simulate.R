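#' Configure a read-placement simulation
#'
#' Bundles the parameters of the synthetic-data generator. The generator
#' emulates low-coverage whole-genome sequencing of a polyploid: per-bin
#' expected read counts follow
#'
#'   N_b = (depth * len_b / read_length) * bias_b * (c_b / ploidy)
#'
#' where `bias_b` is a log-normal per-bin coverage bias (mappability/GC-like,
#' a property of the genome) drawn once from `seed` and therefore *shared*
#' across all samples and replicates — exactly the structure that makes
#' ratio-to-control dosage analysis work — and `c_b` is the local copy
#' number after applying any injected CNV events. Counts are Poisson
#' (negative binomial when `overdispersion > 1`) and read positions are
#' uniform within the bin.
#'
#' @param layout A [genome_layout()].
#' @param ploidy Baseline copy number (default 3, triploid).
#' @param depth Mean fold-coverage (default 3.0, the low-coverage regime).
#' @param read_length Read length in bp used to convert depth to read
#'   counts (default 300).
#' @param bin_bias_sd Standard deviation of the per-bin log-normal bias on
#'   the log scale (default 0.2). The bias is mean-one
#'   (`meanlog = -bin_bias_sd^2/2`) so `depth` is the realized mean depth.
#' @param overdispersion Variance inflation factor for per-bin counts;
#'   1 = Poisson, >1 = negative binomial with variance
#'   `overdispersion * mean`.
#' @param seed Integer seed controlling the shared bias and, combined with
#'   each sample's stream id, the per-sample counts and positions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(layout, ploidy = 3L, depth = 3.0, read_length = 300L,
                       bin_bias_sd = 0.2, overdispersion = 1.0, seed = 1L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (depth < 0) rlang::abort("`depth` must be >= 0")
  if (ploidy < 1) rlang::abort("`ploidy` must be >= 1")
  if (bin_bias_sd < 0) rlang::abort("`bin_bias_sd` must be >= 0")
  if (overdispersion < 1) rlang::abort("`overdispersion` must be >= 1")
  structure(
    list(layout = layout, ploidy = as.integer(ploidy), depth = depth,
         read_length = as.numeric(read_length), bin_bias_sd = bin_bias_sd,
         overdispersion = overdispersion, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Build a ground-truth CNV event table
#'
#' @param chrom,start,end Event spans (1-based inclusive; bin-aligned spans
#'   make downstream calls exact, off-grid edges are allowed and dilute the
#'   boundary bins proportionally).
#' @param copy_change Integer copy-number change per event, in
#'   -2, -1, +1, +2. `ploidy + copy_change` must stay >= 1.
#' @param replicates Character vector: comma-separated replicate ids
#'   carrying each event (e.g. `"1,2"`), or `NA` for all replicates. An
#'   event present in a proper subset of replicates emulates an
#'   endoreplication artifact; one present in all replicates is a true,
#'   mitotically inherited mutation.
#' @return A tibble of class `truth_events`.
#' @export
truth_events <- function(chrom, start, end, copy_change, replicates = NA) {
  ev <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    copy_change = as.integer(copy_change),
    replicates = as.character(replicates)
  )
  if (any(ev$start > ev$end)) rlang::abort("event `start` must be <= `end`")
  if (!all(ev$copy_change %in% c(-2L, -1L, 1L, 2L))) {
    rlang::abort("`copy_change` must be one of -2, -1, +1, +2")
  }
  class(ev) <- c("truth_events", class(ev))
  ev
}

event_in_replicate <- function(replicates, replicate_id) {
  is.na(replicates) |
    purrr::map_lgl(strsplit(replicates, ","),
                   ~ as.character(replicate_id) %in% trimws(.x))
}

# per-bin copy number for one replicate: ploidy + sum of overlap-weighted
# copy changes (bin-aligned events contribute their full copy_change)
bin_copy_number <- function(grid, events, ploidy, replicate_id) {
  cn <- rep(as.numeric(ploidy), nrow(grid))
  if (is.null(events) || nrow(events) == 0) return(cn)
  keep <- event_in_replicate(events$replicates, replicate_id)
  ev <- events[keep, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    on_chrom <- grid$chrom == ev$chrom[i]
    ov <- pmin(grid$end, ev$end[i]) - pmax(grid$start, ev$start[i]) + 1
    frac <- pmax(ov, 0) / (grid$end - grid$start + 1)
    cn <- cn + ifelse(on_chrom, ev$copy_change[i] * frac, 0)
  }
  if (any(cn < 0)) {
    rlang::abort("injected events drive copy number below zero in some bins")
  }
  cn
}

#' Simulate aligned read placements for one sample
#'
#' Draws per-bin read counts under the coverage model of [sim_config()] and
#' scatters read start positions uniformly within each bin. The per-bin
#' bias is derived from `config$seed` alone, so every sample simulated from
#' the same config shares it; sampling noise is driven by `stream`, which
#' must differ between samples.
#'
#' @param config A [sim_config()].
#' @param events A [truth_events()] table, or `NULL` for an event-free
#'   (control-like) sample.
#' @param replicate_id Integer replicate label; events apply only when
#'   their `replicates` mask includes it.
#' @param stream Integer noise stream distinguishing samples that share a
#'   config (defaults to `replicate_id`). Samples with equal `stream` get
#'   identical noise.
#' @return A tibble of read placements: `chrom`, `pos` (1-based leftmost
#'   aligned position), ordered by genome position.
#' @examples
#' cfg <- sim_config(genome_layout("chr1", 1e6), depth = 3, seed = 42)
#' nrow(simulate_sample(cfg)) # ~ depth * genome / read_length = ~10000
#' @export
simulate_sample <- function(config, events = NULL, replicate_id = 1L,
                            stream = replicate_id) {
  stopifnot(inherits(config, "sim_config"))
  grid <- make_bins(config$layout)
  len_b <- grid$end - grid$start + 1
  bias <- bin_bias(config, nrow(grid))
  cn <- bin_copy_number(grid, events, config$ploidy, replicate_id)
  mu <- (config$depth * len_b / config$read_length) * bias *
    (cn / config$ploidy)

  withr::with_seed(stream_seed(config$seed, stream), {
    counts <- draw_counts(mu, config$overdispersion)
    total <- sum(counts)
    pos <- rep(grid$start, counts) +
      floor(stats::runif(total) * rep(len_b, counts))
  })
  tibble::tibble(chrom = rep(grid$chrom, counts), pos = pos)
}

bin_bias <- function(config, n_bins) {
  if (config$bin_bias_sd == 0) return(rep(1, n_bins))
  withr::with_seed(config$seed, {
    stats::rlnorm(n_bins, meanlog = -config$bin_bias_sd^2 / 2,
                  sdlog = config$bin_bias_sd)
  })
}

draw_counts <- function(mu, overdispersion) {
  if (overdispersion > 1) {
    # var = od * mu  =>  NB size = mu / (od - 1)
    size <- mu / (overdispersion - 1)
    n <- stats::rnbinom(length(mu), size = pmax(size, 1e-8), mu = mu)
    n[mu == 0] <- 0L
    n
  } else {
    stats::rpois(length(mu), mu)
  }
}

stream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 7919 * (as.numeric(stream) %% 10000) + 1) %%
               2147483647)
}

#' Simulate qPCR concentration measurements
#'
#' Emulates absolute quantification of genomic regions by qPCR: each
#' region's expected product concentration is proportional to its copy
#' number, with multiplicative log-normal measurement noise. Flanking
#' (unaffected) regions are represented by entries at `ploidy` copies in
#' `copies_by_region`.
#'
#' @param copies_by_region Named numeric vector: region label -> copy
#'   number (e.g. `c(CL = 3, CNV1 = 2, CNV2 = 2, CR = 3)`).
#' @param ploidy Baseline ploidy (default 3).
#' @param noise_cv Log-scale standard deviation of the multiplicative
#'   measurement noise (default 0.05).
#' @param n_replicates Technical replicates per region (default 3).
#' @param base Concentration, in arbitrary copies-per-mL units, of a
#'   region at full ploidy.
#' @param sample Sample label carried into the output.
#' @param seed Integer seed.
#' @return A tibble: `sample`, `region_label`, `replicate`,
#'   `concentration`.
#' @export
simulate_qpcr <- function(copies_by_region, ploidy = 3, noise_cv = 0.05,
                          n_replicates = 3, base = 300, sample = "sample1",
                          seed = 1L) {
  if (is.null(names(copies_by_region)) || any(names(copies_by_region) == "")) {
    rlang::abort("`copies_by_region` must be a named vector")
  }
  if (any(copies_by_region < 0)) rlang::abort("copy numbers must be >= 0")
  if (noise_cv < 0) rlang::abort("`noise_cv` must be >= 0")
  if (n_replicates < 1) rlang::abort("`n_replicates` must be >= 1")
  regions <- names(copies_by_region)
  out <- tidyr::expand_grid(region_label = regions,
                            replicate = seq_len(n_replicates))
  mu <- base * copies_by_region[out$region_label] / ploidy
  withr::with_seed(seed, {
    conc <- mu * stats::rlnorm(nrow(out), meanlog = 0, sdlog = noise_cv)
  })
  tibble::tibble(sample = sample, region_label = out$region_label,
                 replicate = out$replicate, concentration = unname(conc))
}

#' Write read placements to SAM or BED
#'
#' SAM output carries an `@SQ` header derived from `layout` and minimal
#' single-end alignment records (MAPQ 60, CIGAR `<read_length>M`, sequence
#' and quality omitted). BED output is 0-based half-open single-bp
#' intervals, one per placement.
#'
#' @param placements Tibble with `chrom` and `pos` (1-based).
#' @param path Output path.
#' @param layout A [genome_layout()]; required for SAM.
#' @param format `"sam"` or `"bed"`.
#' @param read_length Read length recorded in SAM CIGAR strings.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path, layout = NULL,
                             format = c("sam", "bed"), read_length = 300L) {
  format <- rlang::arg_match(format)
  if (format == "sam") {
    if (is.null(layout)) rlang::abort("SAM output requires `layout`")
    header <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", layout$chrom, as.integer(layout$length))
    )
    n <- nrow(placements)
    records <- sprintf(
      "read%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
      seq_len(n), placements$chrom, as.integer(placements$pos),
      as.integer(read_length)
    )
    writeLines(c(header, records), path)
  } else {
    readr::write_tsv(
      tibble::tibble(chrom = placements$chrom,
                     start = as.integer(placements$pos) - 1L,
                     end = as.integer(placements$pos)),
      path, col_names = FALSE
    )
  }
  invisible(path)
}

#' Write and read ground-truth event tables
#'
#' The truth TSV mirrors the CNV event schema (`chrom`, `start`, `end`,
#' `copy_change`, `replicates`, `n_bins`, `size_mbp`) so simulated truth
#' and called events are directly comparable.
#'
#' @param events A [truth_events()] table.
#' @param path File path.
#' @param bin_size Bin width used to derive `n_bins` and `size_mbp`.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a
#'   [truth_events()] tibble with `n_bins` and `size_mbp` columns.
#' @export
write_truth <- function(events, path, bin_size = 100000) {
  out <- dplyr::mutate(
    events,
    n_bins = bins_spanned(.data$start, .data$end, bin_size),
    size_mbp = .data$n_bins * bin_size / 1e6
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "d", end = "d", copy_change = "i",
    replicates = "c", n_bins = "i", size_mbp = "d"
  ))
  ev <- truth_events(tab$chrom, tab$start, tab$end, tab$copy_change,
                     tab$replicates)
  ev$n_bins <- tab$n_bins
  ev$size_mbp <- tab$size_mbp
  ev
}

#' Simulate random gene models over a layout
#'
#' Convenience generator for annotation benchmarks: genes of uniform random
#' length placed uniformly along each chromosome.
#'
#' @param layout A [genome_layout()].
#' @param n_genes Total number of genes.
#' @param len_range Gene length range in bp.
#' @param seed Integer seed.
#' @return A gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
simulate_genes <- function(layout, n_genes = 1000, len_range = c(2000, 20000),
                           seed = 1L) {
  withr::with_seed(seed, {
    chrom <- sample(layout$chrom, n_genes, replace = TRUE,
                    prob = layout$length / sum(layout$length))
    len <- floor(stats::runif(n_genes, len_range[1], len_range[2] + 1))
    maxlen <- layout$length[match(chrom, layout$chrom)]
    start <- floor(stats::runif(n_genes) * pmax(maxlen - len, 1)) + 1
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  })
  out <- tibble::tibble(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    chrom = chrom, start = start, end = pmin(start + len - 1, maxlen),
    strand = strand
  )
  dplyr::arrange(out, match(.data$chrom, layout$chrom), .data$start)
}
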