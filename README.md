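# bindosage

Bin-based chromosomal dosage analysis for detecting large copy-number
variations (CNVs) from low-coverage whole-genome sequencing of polyploids.

## The problem

Triploid dessert bananas (*Musa acuminata*, AAA Cavendish) are sterile and
clonally propagated, so new alleles must be induced rather than bred in.
Gamma irradiation of shoot-tip cultures produces large genomic deletions and
insertions — 0.3 to several Mbp — whose dosage effects (including
haploinsufficiency) can generate usable phenotypes in a polyploid.
Screening a mutant population for such events does not need deep sequencing:
at ~3× coverage, read depth aggregated over 100-kb windows cleanly resolves
a chromosome segment present in 2 copies instead of 3.

`bindosage` implements that screen as a tested, reusable R pipeline, for
anyone running mutation-breeding or aneuploidy screens in organisms with a
chromosome-level assembly.

## The method

For each sample, aligned read placements are counted in fixed 100-kb bins.
Per-bin **relative sequence read coverage** (RSRC) is the sample's count
fraction over a control's count fraction, scaled to the ploidy *p*:

```
RSRC_b = p * (m_b / M) / (c_b / C)
```

where `m_b`, `c_b` are bin counts and `M`, `C` library totals. Library size
cancels in the fractions; shared per-bin biases (GC, mappability) cancel in
the ratio. The control sits at exactly *p* (3.0 for a triploid); a
single-copy deletion drops affected bins to ~2, an insertion lifts them to
~4. Each bin is rounded to its nearest integer dosage state, and a run of
**at least 3 consecutive bins** deviating in the same direction is called as
one CNV event (so 0.3 Mbp is the smallest callable event at 100-kb bins).
Because induced mutations are mitotically inherited while endoreplication
artifacts are cell-lineage specific, events can additionally be required to
appear in every clonal replicate of a line (`concordant_events()`). Called
events are annotated with overlapping gene models, and qPCR concentration
ratios against unaffected flanking regions (`qpcr_dosage()`) validate the
inferred copy number (a single-copy deletion in a triploid gives a ratio of
2/3, a ~33% reduction).

A synthetic-data module (`sim_config()`, `simulate_sample()`,
`simulate_qpcr()`) generates read placements with injected ground-truth
events, shared per-bin biases and Poisson (optionally overdispersed) counts,
so the whole pipeline is exercised end-to-end without any sequencing data.

## Worked example

Simulate a triploid control and a mutant line (two clonal replicates)
carrying one 0.5-Mbp single-copy deletion, then run the pipeline:

```r
library(bindosage)

layout <- musa_layout(scale = 0.1)          # 11 chromosomes, 3 Mbp each
cfg <- sim_config(layout, ploidy = 3, depth = 3, seed = 42)

control <- bin_counts(simulate_sample(cfg, stream = 0), layout, "control")
del <- truth_events("2", 1200001, 1700000, copy_change = -1)
reps <- lapply(1:2, function(r)
  bin_counts(simulate_sample(cfg, del, r, stream = r), layout, "mutant"))

calls <- lapply(reps, function(b) call_events(discretize(rsrc(b, control))))
concordant_events(calls)
#> # A tibble: 1 × 8
#>   chrom   start     end type     copy_change n_bins size_mbp mean_rsrc
#>   <chr>   <dbl>   <dbl> <chr>          <int>  <int>    <dbl>     <dbl>
#> 1 2     1200001 1700000 deletion          -1      5      0.5      1.96
```

The injected event comes back with bin-exact coordinates: a 5-bin
(0.5 Mbp) deletion whose mean RSRC of 1.96 ≈ 2 marks the loss of one of
three copies. qPCR validation arithmetic on simulated concentrations shows
the same dosage:

```r
m <- simulate_qpcr(c(CL = 3, CNV1 = 2, CNV2 = 2, CR = 3),
                   noise_cv = 0.05, seed = 42)
qpcr_dosage(m, flank_labels = c("CL", "CR"))
#> # A tibble: 4 × 6
#>   sample  region_label ratio est_copies pct_reduction     sd
#>   <chr>   <chr>        <dbl>      <dbl>         <dbl>  <dbl>
#> 1 sample1 CL           0.980       2.94          1.98 0.0475
#> 2 sample1 CNV1         0.650       1.95         35.0  0.0123
#> 3 sample1 CNV2         0.679       2.04         32.1  0.0370
#> 4 sample1 CR           1.02        3.06         -1.98 0.0599
```

The regions inside the deletion sit near a 2/3 ratio (~33% reduction,
~2 estimated copies); the flanks sit at ~1. Multi-line screens are
orchestrated by `run_cnv_screen()`, which returns an object with
broom-style `tidy()` (event table) and `glance()` (lines screened, lines
with ≥1 concordant event) methods, and `plot_rsrc()` /
`autoplot()` draw the per-chromosome RSRC tracks with called events shaded.

Two published banana deletion complements are bundled as reference tables:
`novaria_deletions()` (10 deletions, 0.3–3.8 Mbp, 189 genes) and
`w9_deletions()` (18 deletions, 0.3–6.8 Mbp, 20.5 Mbp total, 2762 genes).

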