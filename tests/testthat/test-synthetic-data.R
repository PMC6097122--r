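test_that("simulated per-bin counts follow the closed-form expectation", {
  # depth * len / read_length = 3 * 100000 / 300 = 1000 reads per bin;
  # with no bias the empirical mean over 1000 bins must sit within 3%
  lay <- genome_layout("chr1", 1e8, bin_size = 100000)
  cfg <- sim_config(lay, depth = 3, read_length = 300, bin_bias_sd = 0,
                    seed = 101)
  bc <- sim_counts(cfg)
  expect_equal(nrow(bc), 1000)
  expect_lt(abs(mean(bc$count) - 1000) / 1000, 0.03)

  # zero depth -> zero reads everywhere
  cfg0 <- sim_config(lay, depth = 0, seed = 1)
  expect_equal(nrow(simulate_sample(cfg0)), 0)
})

test_that("a single-copy deletion reduces affected-bin coverage to 2/3", {
  lay <- genome_layout("chr1", 6e6)
  cfg <- sim_config(lay, depth = 3, bin_bias_sd = 0, seed = 21)
  ev <- truth_events("chr1", 2000001, 4000000, -1)
  ctrl <- sim_counts(cfg, stream = 0)
  mut <- sim_counts(cfg, ev, stream = 1)
  in_ev <- mut$start >= 2000001 & mut$end <= 4000000
  ratio <- mean(mut$count[in_ev]) / mean(ctrl$count[in_ev])
  expect_lt(abs(ratio - 2 / 3) / (2 / 3), 0.05)
  # unaffected bins stay at parity
  ratio_out <- mean(mut$count[!in_ev]) / mean(ctrl$count[!in_ev])
  expect_lt(abs(ratio_out - 1), 0.05)
})

test_that("events respect the replicate mask", {
  lay <- tiny_layout(1)
  cfg <- sim_config(lay, bin_bias_sd = 0, seed = 5)
  ev <- truth_events("chr1", 1000001, 2000000, -1, replicates = "2")
  s1 <- sim_counts(cfg, ev, replicate_id = 1, stream = 1)
  s2 <- sim_counts(cfg, ev, replicate_id = 2, stream = 2)
  in_ev <- s1$start >= 1000001 & s1$end <= 2000000
  expect_gt(mean(s1$count[in_ev]) / mean(s2$count[in_ev]), 1.2)
})

test_that("the per-bin bias is shared across samples and cancels in RSRC", {
  lay <- tiny_layout(2)
  cfg <- sim_config(lay, bin_bias_sd = 0.3, seed = 33)
  a <- sim_counts(cfg, stream = 1, id = "a")
  b <- sim_counts(cfg, stream = 2, id = "b")
  # strong bias -> raw counts vary a lot bin to bin...
  expect_gt(stats::sd(a$count) / mean(a$count), 0.2)
  # ...but the ratio profile is flat at the ploidy
  dt <- rsrc(a, b, ploidy = 3)
  expect_lt(abs(mean(dt$rsrc) - 3), 0.05)
  expect_lt(stats::sd(dt$rsrc), 0.3)
})

test_that("simulation is deterministic in config + seed", {
  lay <- tiny_layout(1)
  cfg <- sim_config(lay, seed = 77)
  ev <- truth_events("chr1", 500001, 900000, 1)
  p1 <- simulate_sample(cfg, ev, 1, stream = 4)
  p2 <- simulate_sample(cfg, ev, 1, stream = 4)
  expect_identical(p1, p2)
  # different streams differ
  p3 <- simulate_sample(cfg, ev, 1, stream = 5)
  expect_false(identical(p1, p3))
})

test_that("events that would drive copy number negative are rejected", {
  expect_error(truth_events("chr1", 1, 100000, -3), "copy_change")
  lay <- tiny_layout(1)
  cfg <- sim_config(lay, ploidy = 1, seed = 2)
  ev <- truth_events("chr1", 1, 200000, -2)
  expect_error(simulate_sample(cfg, ev), "below zero")
})

test_that("placement files round trip through SAM and BED", {
  lay <- tiny_layout(2, len = 500000)
  cfg <- sim_config(lay, depth = 0.3, seed = 9)
  pl <- simulate_sample(cfg)
  for (fmt in c("sam", "bed")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_placements(pl, path, layout = lay, format = fmt)
    back <- load_placements(path, format = fmt, layout = lay)
    expect_equal(dplyr::arrange(tibble::as_tibble(back), chrom, pos),
                 dplyr::arrange(pl, chrom, pos),
                 ignore_attr = TRUE)
  }
  # convention check: BED starts are SAM positions - 1
  bed <- tempfile(fileext = ".bed")
  write_placements(tibble::tibble(chrom = "chr1", pos = 101L), bed,
                   format = "bed")
  raw <- readr::read_tsv(bed, col_names = c("chrom", "start", "end"),
                         col_types = "cii")
  expect_equal(raw$start, 100L)
  expect_equal(raw$end, 101L)
})

test_that("truth tables round trip with derived bin counts and sizes", {
  ev <- truth_events("chr2", 200001, 500000, -1, replicates = "1,2")
  path <- tempfile(fileext = ".tsv")
  write_truth(ev, path)
  back <- read_truth(path)
  expect_equal(back$n_bins, 3L)
  expect_equal(back$size_mbp, 0.3)
  expect_equal(back$chrom, "chr2")
  expect_equal(back$replicates, "1,2")
})

test_that("simulated qPCR concentrations follow the copy-ratio model", {
  # noise-free: all regions at ploidy -> equal concentrations
  m0 <- simulate_qpcr(c(CL = 3, A = 3, CR = 3), noise_cv = 0, seed = 1)
  expect_true(all(m0$concentration == m0$concentration[1]))
  # noise-free 2-copy region -> exactly 2/3 of flanks
  m1 <- simulate_qpcr(c(CL = 3, CNV1 = 2, CR = 3), noise_cv = 0, seed = 1)
  cnv <- mean(m1$concentration[m1$region_label == "CNV1"])
  fl <- mean(m1$concentration[m1$region_label %in% c("CL", "CR")])
  expect_equal(cnv / fl, 2 / 3)
  expect_error(simulate_qpcr(c(A = 3), n_replicates = 0), "n_replicates")
})
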