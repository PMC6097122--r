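#' Reference deletion call sets for two gamma-irradiated banana lines
#'
#' Two bundled CNV call sets from triploid Cavendish banana
#' (*Musa acuminata*, AAA), used throughout the package's examples and
#' benchmarks as realistic ground-truth event complements:
#'
#' * `novaria_deletions()` — the ten single-copy deletions (0.3-3.8 Mbp)
#'   carried by the commercially released gamma-induced mutant cultivar
#'   'Novaria', with the number of annotated genes overlapping each event.
#' * `w9_deletions()` — the eighteen single-copy deletions (0.3-6.8 Mbp)
#'   accumulated in a 40-Gy-irradiated 'Williams' mutant line ("w-9"),
#'   confirmed in two clonal biological replicates.
#'
#' Coordinates are 1-based inclusive on the *Musa acuminata* v1 reference
#' assembly and aligned to the 100-kb bin grid, so each event spans a whole
#' number of bins: `n_bins = bins_spanned(start, end)` and
#' `size_mbp = n_bins / 10`.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `type`, `n_bins`,
#'   `size_mbp`, `n_genes`.
#' @examples
#' novaria_deletions()
#' sum(novaria_deletions()$n_genes) # 189 genes in deleted regions
#' @export
novaria_deletions <- function() {
  tibble::tribble(
    ~chrom, ~start,    ~end,      ~type,      ~n_bins, ~size_mbp, ~n_genes,
    "1",    26100001,  26400000,  "deletion",  3L,      0.3,       18L,
    "2",    900001,    1200000,   "deletion",  3L,      0.3,       2L,
    "5",    24400001,  28200000,  "deletion",  38L,     3.8,       129L,
    "8",    12100001,  12600000,  "deletion",  5L,      0.5,       8L,
    "8",    24100001,  24400000,  "deletion",  3L,      0.3,       3L,
    "9",    14200001,  14600000,  "deletion",  4L,      0.4,       0L,
    "10",   6000001,   6300000,   "deletion",  3L,      0.3,       3L,
    "10",   12600001,  12900000,  "deletion",  3L,      0.3,       5L,
    "10",   13000001,  13400000,  "deletion",  4L,      0.4,       9L,
    "11",   12400001,  12700000,  "deletion",  3L,      0.3,       12L
  )
}

#' @rdname novaria_deletions
#' @export
w9_deletions <- function() {
  tibble::tribble(
    ~chrom, ~start,    ~end,      ~type,      ~n_bins, ~size_mbp, ~n_genes,
    "2",    3800001,   4400000,   "deletion",  6L,      0.6,       3L,
    "2",    6600001,   7000000,   "deletion",  4L,      0.4,       9L,
    "6",    3200001,   3700000,   "deletion",  5L,      0.5,       70L,
    "6",    5600001,   6300000,   "deletion",  7L,      0.7,       142L,
    "6",    6600001,   7700000,   "deletion",  11L,     1.1,       202L,
    "6",    9300001,   11700000,  "deletion",  24L,     2.4,       479L,
    "6",    12200001,  12500000,  "deletion",  3L,      0.3,       45L,
    "6",    12800001,  13400000,  "deletion",  6L,      0.6,       103L,
    "7",    100001,    6900000,   "deletion",  68L,     6.8,       1214L,
    "7",    7100001,   9300000,   "deletion",  22L,     2.2,       128L,
    "7",    26200001,  28400000,  "deletion",  22L,     2.2,       239L,
    "11",   500001,    800000,    "deletion",  3L,      0.3,       54L,
    "11",   7800001,   8400000,   "deletion",  6L,      0.6,       1L,
    "11",   11300001,  11600000,  "deletion",  3L,      0.3,       8L,
    "11",   13200001,  13700000,  "deletion",  5L,      0.5,       8L,
    "11",   14300001,  14600000,  "deletion",  3L,      0.3,       5L,
    "11",   16200001,  16600000,  "deletion",  4L,      0.4,       46L,
    "11",   18000001,  18300000,  "deletion",  3L,      0.3,       6L
  )
}

#' Default simulation layout: a Musa-scale triploid genome
#'
#' Eleven chromosomes of 30 Mbp each on a 100-kb bin grid — large enough to
#' contain every coordinate in [novaria_deletions()] and [w9_deletions()]
#' while keeping full-genome simulations fast. A `scale` below 1 shrinks
#' every chromosome proportionally for quick tests.
#'
#' @param scale Multiplier applied to the 30-Mbp chromosome length.
#' @param bin_size Bin width in bp.
#' @return A [genome_layout()] with chromosomes named "1".."11".
#' @export
musa_layout <- function(scale = 1, bin_size = 100000L) {
  genome_layout(as.character(1:11), rep(3e7 * scale, 11),
                bin_size = bin_size)
}
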