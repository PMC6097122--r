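test_that("discretize rounds half away from zero and clamps states", {
  dt <- dosage_from_rsrc(c(3.0, 2.079, 2.5, 3.5, 0.2, 9.9))
  d <- discretize(dt)
  expect_equal(d$state, c(3L, 2L, 3L, 4L, 0L, 5L)) # clamp at ploidy + 2
  expect_equal(d$deviation, c(0L, -1L, 0L, 1L, -3L, 2L))
  # invalid bins carry no state
  dt2 <- dosage_from_rsrc(c(3, 3), valid = c(TRUE, FALSE))
  expect_true(is.na(discretize(dt2)$state[2]))
})

test_that("the deadband option masks bins far from any integer state", {
  dt <- dosage_from_rsrc(c(3.0, 2.6, 2.1))
  d <- discretize(dt, deadband = 0.25)
  expect_equal(d$deviation, c(0L, NA, -1L)) # 2.6 is 0.4 from state 3
})

test_that("call_events applies the three-consecutive-bin rule", {
  # the minimum callable event: exactly 3 deviating bins = 0.3 Mbp
  d <- discretize(dosage_from_rsrc(c(3, 3, 2, 2, 2, 3)))
  ev <- call_events(d)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_bins, 3L)
  expect_equal(ev$size_mbp, 0.3)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$copy_change, -1L)
  expect_equal(ev$start, 200001)
  expect_equal(ev$end, 500000)

  # a 2-bin run is never called; the adjacent 3-bin run is
  d2 <- discretize(dosage_from_rsrc(c(3, 2, 2, 3, 2, 2, 2, 3)))
  ev2 <- call_events(d2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$start, 400001)

  # two runs separated by exactly one normal bin stay two events
  d3 <- discretize(dosage_from_rsrc(c(2, 2, 2, 3, 2, 2, 2, 2)))
  ev3 <- call_events(d3)
  expect_equal(nrow(ev3), 2)

  # insertions are called on the high side
  d4 <- discretize(dosage_from_rsrc(c(3, 4, 4, 4, 3)))
  expect_equal(call_events(d4)$type, "insertion")

  expect_error(call_events(d, min_run = 0), "min_run")
})

test_that("a long run is reported with bin-grid coordinates", {
  # 38-bin single-copy loss starting at bin index 244 on a 30-Mbp
  # chromosome: event spans 24400001-28200000 = 3.8 Mbp
  values <- rep(3, 300)
  values[245:282] <- 2
  d <- discretize(dosage_from_rsrc(values, chrom = "5"))
  ev <- call_events(d)
  expect_equal(ev$start, 24400001)
  expect_equal(ev$end, 28200000)
  expect_equal(ev$n_bins, 38L)
  expect_equal(ev$size_mbp, 3.8)
})

test_that("invalid bins break runs", {
  vals <- c(2, 2, 2, 2, 2)
  d <- discretize(dosage_from_rsrc(vals, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  expect_equal(nrow(call_events(d)), 0) # two 2-runs, neither callable
})

test_that("mixed-magnitude runs merge with a modal, small-magnitude-tie copy change", {
  d <- discretize(dosage_from_rsrc(c(2, 2, 1, 2, 2)))
  ev <- call_events(d)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$copy_change, -1L)
  # tie between -1 and -2 -> smaller magnitude wins
  d2 <- discretize(dosage_from_rsrc(c(2, 1, 2, 1)))
  ev2 <- call_events(d2)
  expect_equal(ev2$copy_change, -1L)
})

test_that("called runs are minimal-length-bounded and maximal (vs naive scanner)", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(20:120, 1)
      dev <- sample(c(-2, -1, 0, 0, 0, 1, 2), n, replace = TRUE)
      valid <- stats::runif(n) > 0.05
      d <- discretize(dosage_from_rsrc(3 + dev, valid = valid))
      min_run <- sample(2:4, 1)
      ev <- call_events(d, min_run = min_run)
      expect_true(all(ev$n_bins >= min_run))
      oracle <- naive_call_runs(d$deviation, min_run = min_run)
      expect_equal(nrow(ev), length(oracle))
      if (length(oracle) > 0) {
        starts <- vapply(oracle, function(r) (r[1] - 1) * 100000 + 1,
                         numeric(1))
        expect_equal(sort(ev$start), sort(starts))
      }
    }
  })
})

test_that("concordance keeps only events present in every replicate", {
  bs <- 100000
  ev_run <- function(first_bin, last_bin, cc = -1L) {
    n <- last_bin - first_bin + 1L
    out <- tibble::tibble(
      chrom = "chr1", start = (first_bin - 1) * bs + 1, end = last_bin * bs,
      type = if (cc < 0) "deletion" else "insertion", copy_change = cc,
      n_bins = n, size_mbp = n * bs / 1e6, mean_rsrc = 3 + cc
    )
    attr(out, "bin_size") <- bs
    out
  }
  # identical events in both replicates -> kept unchanged
  both <- concordant_events(list(ev_run(5, 9), ev_run(5, 9)))
  expect_equal(nrow(both), 1)
  expect_equal(both$start, ev_run(5, 9)$start)

  # replicate-1-only event (endoreplication-like) -> dropped
  none <- concordant_events(list(ev_run(5, 9), ev_run(30, 35)[0, ]))
  expect_equal(nrow(none), 0)

  # overlapping spans (bins 10-20 and 11-21) -> intersection bins 11-20
  inter <- concordant_events(list(ev_run(10, 20), ev_run(11, 21)))
  expect_equal(inter$start, (11 - 1) * bs + 1)
  expect_equal(inter$end, 20 * bs)
  expect_equal(inter$n_bins, 10L)

  # same span, opposite sign -> no match
  opp <- concordant_events(list(ev_run(5, 9, -1L), ev_run(5, 9, 1L)))
  expect_equal(nrow(opp), 0)

  # single replicate passes through
  one <- concordant_events(list(ev_run(2, 4)))
  expect_equal(one, ev_run(2, 4))

  expect_error(concordant_events(list()), "at least one")
})

test_that("injected events are recovered and sub-minimum events never called", {
  # 20 simulation seeds at depth 3 with shared bias sd 0.2: a >=3-bin
  # single-copy deletion must be recovered (right sign) in >=95% of seeds,
  # and 1-2-bin events must never be reported
  lay <- tiny_layout(2)
  hits <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(lay, depth = 3, bin_bias_sd = 0.2, seed = 1000 + seed)
    events <- truth_events(c("chr1", "chr2"),
                           c(500001, 1200001),
                           c(900000, 1400000), # 4 bins and 2 bins
                           c(-1L, -1L))
    ctrl <- sim_counts(cfg, stream = 0, id = "ctrl")
    mut <- sim_counts(cfg, events, stream = 1, id = "mut")
    calls <- call_events(discretize(rsrc(mut, ctrl)))
    # the 2-bin event must never appear
    expect_false(any(calls$chrom == "chr2"))
    ok <- any(calls$chrom == "chr1" & calls$start == 500001 &
                calls$end == 900000 & calls$copy_change < 0)
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("event-free sample pairs yield almost no calls", {
  lay <- tiny_layout(2)
  total <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(lay, depth = 3, bin_bias_sd = 0.2, seed = 2000 + seed)
    ctrl <- sim_counts(cfg, stream = 0, id = "ctrl")
    smp <- sim_counts(cfg, stream = 1, id = "s")
    total <- total + nrow(call_events(discretize(rsrc(smp, ctrl))))
  }
  expect_lte(total / n_seeds, 0.5)
})

test_that("event tables sort by chromosome then start and write out cleanly", {
  ev <- w9_deletions()[rev(seq_len(18)), ]
  tab <- event_table(ev, layout = musa_layout())
  expect_equal(tab$chrom, w9_deletions()$chrom)
  expect_equal(tab$start, w9_deletions()$start)

  # empty input -> header-only table
  empty <- event_table(call_events(discretize(dosage_from_rsrc(c(3, 3, 3)))))
  expect_equal(nrow(empty), 0)

  tsv <- tempfile(fileext = ".tsv")
  write_events(tab, tsv)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 18)
  bed <- tempfile(fileext = ".bed")
  write_events(ev, bed, format = "bed")
  raw <- readr::read_tsv(bed, col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic")
  expect_equal(raw$start, as.integer(ev$start) - 1L)
})
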