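#' Discretize RSRC values into integer dosage states
#'
#' Each valid bin is assigned the nearest integer copy-number state
#' (rounding half away from zero, so 2.5 -> 3 and 3.5 -> 4), clamped to
#' `[0, ploidy + 2]`; the deviation is `state - ploidy`. A bin at the
#' ploidy has deviation 0; -1/-2 mark single-/double-copy losses and
#' +1/+2 gains. With `deadband` set, a bin whose RSRC is further than
#' `deadband` from its nearest state is treated as uncallable
#' (deviation `NA`), which breaks runs in [call_events()]; off by default.
#'
#' @param dosage A dosage tibble from [rsrc()].
#' @param ploidy Baseline ploidy; defaults to the table's `ploidy`
#'   attribute.
#' @param deadband Optional half-width of the acceptance window around
#'   each integer state (e.g. 0.25), or `NULL` to accept all bins.
#' @return The dosage tibble with `state` and `deviation` integer columns
#'   (`NA` on invalid bins).
#' @export
discretize <- function(dosage, ploidy = NULL, deadband = NULL) {
  if (is.null(ploidy)) ploidy <- attr(dosage, "ploidy")
  if (is.null(ploidy)) rlang::abort("`ploidy` is unknown; pass it explicitly")
  state <- round_half_away(dosage$rsrc)
  state <- pmin(pmax(state, 0), ploidy + 2)
  state[!dosage$valid] <- NA_real_
  if (!is.null(deadband)) {
    off_grid <- abs(dosage$rsrc - state) >= deadband
    state[which(off_grid)] <- NA_real_
  }
  out <- dosage
  out$state <- as.integer(state)
  out$deviation <- as.integer(state - ploidy)
  attr(out, "ploidy") <- as.integer(ploidy)
  attr(out, "bin_size") <- attr(dosage, "bin_size")
  out
}

# round .5 away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Call CNV events from per-bin dosage states
#'
#' Scans each chromosome for maximal runs of consecutive bins whose
#' dosage deviation has the same sign; runs of at least `min_run` bins
#' become one event. Runs are broken by bins at the ploidy (deviation 0),
#' by invalid/uncallable bins (a masked bin cannot support an event), and
#' by chromosome boundaries. A run may mix magnitudes (-1 next to -2);
#' its `copy_change` is the modal deviation, ties resolved toward the
#' smaller magnitude (conservative). The default `min_run = 3` at 100-kb
#' bins makes 0.3 Mbp the smallest callable event.
#'
#' @param states A discretized dosage tibble from [discretize()].
#' @param min_run Minimum run length in bins (default 3).
#' @return An event tibble: `chrom`, `start` (first bin's start), `end`
#'   (last bin's end), `type` (`"deletion"`/`"insertion"`), `copy_change`,
#'   `n_bins`, `size_mbp` (`n_bins * bin_size / 1e6`), `mean_rsrc`.
#' @examples
#' # deviations 0,0,-1,-1,-1,0 on one chromosome -> one 3-bin deletion
#' @export
call_events <- function(states, min_run = 3L) {
  if (min_run < 1) rlang::abort("`min_run` must be >= 1")
  if (!"deviation" %in% names(states)) {
    rlang::abort("`states` must come from discretize()")
  }
  bs <- attr(states, "bin_size")
  if (is.null(bs)) bs <- max(states$end - states$start + 1)

  per_chrom <- split(states, factor(states$chrom,
                                    levels = unique(states$chrom)))
  events <- purrr::map_dfr(per_chrom, function(d) {
    dev <- d$deviation
    sgn <- sign(dev)
    sgn[is.na(sgn)] <- 0L # masked bins break runs, like deviation 0
    r <- rle(sgn)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    keep <- r$values != 0 & r$lengths >= min_run
    purrr::map_dfr(which(keep), function(k) {
      i <- starts[k]:stops[k]
      cc <- modal_deviation(dev[i])
      tibble::tibble(
        chrom = d$chrom[1],
        start = d$start[i[1]],
        end = d$end[i[length(i)]],
        type = if (cc < 0) "deletion" else "insertion",
        copy_change = cc,
        n_bins = length(i),
        size_mbp = length(i) * bs / 1e6,
        mean_rsrc = mean(d$rsrc[i])
      )
    })
  })
  if (nrow(events) == 0) empty_events(bs) else {
    attr(events, "bin_size") <- bs
    events
  }
}

empty_events <- function(bs = 100000) {
  out <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    type = character(), copy_change = integer(), n_bins = integer(),
    size_mbp = numeric(), mean_rsrc = numeric()
  )
  attr(out, "bin_size") <- bs
  out
}

# modal value; ties broken toward smaller |magnitude|
modal_deviation <- function(dev) {
  tab <- table(dev)
  vals <- as.integer(names(tab))
  best <- vals[tab == max(tab)]
  as.integer(best[order(abs(best), best)][1])
}

#' Filter events by concordance across clonal replicates
#'
#' An induced mutation is mitotically inherited and therefore present in
#' every clonal replicate of a line, whereas endoreplication artifacts are
#' cell-lineage specific. `concordant_events()` keeps an event only if
#' every replicate contains a matching event — same chromosome, same
#' deviation sign, spans overlapping by at least one bin — and reports the
#' intersection of the matched spans. With a single replicate the list
#' passes through unchanged.
#'
#' @param per_replicate A list of event tibbles from [call_events()], one
#'   per replicate (>= 1).
#' @return An event tibble in the same schema; `n_bins` and `size_mbp`
#'   are recomputed for the intersected spans and `mean_rsrc` is averaged
#'   over the matched replicates.
#' @export
concordant_events <- function(per_replicate) {
  if (length(per_replicate) == 0) {
    rlang::abort("`per_replicate` must contain at least one event table")
  }
  if (length(per_replicate) == 1) return(per_replicate[[1]])
  bs <- attr(per_replicate[[1]], "bin_size")
  if (is.null(bs)) bs <- 100000
  anchor <- per_replicate[[1]]
  others <- per_replicate[-1]
  kept <- purrr::map_dfr(seq_len(nrow(anchor)), function(i) {
    ev <- anchor[i, ]
    span <- c(ev$start, ev$end)
    rsrcs <- ev$mean_rsrc
    for (rep_events in others) {
      m <- rep_events$chrom == ev$chrom &
        sign(rep_events$copy_change) == sign(ev$copy_change) &
        rep_events$start <= span[2] & rep_events$end >= span[1]
      if (!any(m)) return(empty_events(bs))
      hits <- rep_events[m, ]
      # best match = largest overlap with the current span
      ov <- pmin(hits$end, span[2]) - pmax(hits$start, span[1]) + 1
      best <- hits[which.max(ov), ]
      span <- c(max(span[1], best$start), min(span[2], best$end))
      rsrcs <- c(rsrcs, best$mean_rsrc)
    }
    n_bins <- bins_spanned(span[1], span[2], bs)
    tibble::tibble(
      chrom = ev$chrom, start = span[1], end = span[2],
      type = ev$type, copy_change = ev$copy_change,
      n_bins = n_bins, size_mbp = n_bins * bs / 1e6,
      mean_rsrc = mean(rsrcs)
    )
  })
  if (nrow(kept) == 0) return(empty_events(bs))
  attr(kept, "bin_size") <- bs
  kept
}

#' Arrange events into a report table
#'
#' Standard CNV report layout: one row per event, sorted by chromosome
#' (layout order if available, else natural order) then start, with a
#' per-event overlapping-gene count when gene models are supplied.
#'
#' @param events An event tibble.
#' @param genes Optional gene-model tibble (see [read_genes()]).
#' @param layout Optional [genome_layout()] fixing the chromosome sort
#'   order.
#' @param ... Passed to [annotate_events()] (e.g. `mode`).
#' @return A tibble `chrom`, `start`, `end`, `type`, `n_bins`, `size_mbp`
#'   (+ `n_genes` when `genes` is given).
#' @export
event_table <- function(events, genes = NULL, layout = NULL, ...) {
  if (!is.null(genes)) {
    events <- annotate_events(events, genes, ...)
  }
  chrom_levels <- if (!is.null(layout)) layout$chrom else
    unique(stringr_sortable(events$chrom))
  cols <- intersect(c("chrom", "start", "end", "type", "n_bins",
                      "size_mbp", "n_genes"), names(events))
  events |>
    dplyr::arrange(match(.data$chrom, chrom_levels), .data$start) |>
    dplyr::select(dplyr::all_of(cols))
}

# natural sort for chromosome names ("2" before "10")
stringr_sortable <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(x)
}

#' Write called events as TSV or BED
#'
#' TSV follows the report schema of [event_table()]; BED is 0-based
#' half-open with the event type and copy change in the name field, for
#' genome-browser use.
#'
#' @param events An event tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("tsv", "bed")) {
  format <- rlang::arg_match(format)
  if (format == "tsv") {
    readr::write_tsv(events, path)
  } else {
    name <- if ("copy_change" %in% names(events)) {
      sprintf("%s:%+d", events$type, events$copy_change)
    } else {
      events$type
    }
    bed <- tibble::tibble(
      chrom = events$chrom,
      start = as.integer(events$start) - 1L,
      end = as.integer(events$end),
      name = name
    )
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}
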