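---
title: "Bin-based dosage analysis: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based dosage analysis: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindosage)
```

# The model

`bindosage` detects megabase-scale copy-number changes from low-coverage
(~2–4×) whole-genome sequencing by comparing binned read depth between a
sample and a control of known ploidy. The quantity of interest is the
per-bin relative sequence read coverage,

$$\mathrm{RSRC}_b \;=\; p \cdot \frac{m_b / M}{c_b / C},$$

with $m_b, c_b$ the read counts of sample and control in bin $b$, $M, C$
their genome-wide totals, and $p$ the ploidy. Three properties make this
ratio the right statistic for the job:

* **Library size cancels** in the within-sample fractions, so samples of
  different sequencing depth are directly comparable.
* **Per-bin coverage biases cancel** in the ratio: GC content and
  mappability are properties of the genome, not of the sample, so the same
  multiplicative bias appears in numerator and denominator. No explicit
  GC or mappability correction is needed — the control *is* the
  correction.
* The control sits identically at $p$, so integer dosage states have a
  fixed meaning: in a triploid, 2 means one copy lost, 4 one copy gained.

Bins where the control has zero reads leave the ratio undefined; they are
masked invalid and, conservatively, *break* candidate runs downstream (a
bin with no information cannot support an event).

Calling is deliberately simple — this is thresholded run detection, not
segmentation. Each valid bin's RSRC is rounded to the nearest integer
state (half away from zero) and clamped to $[0, p + 2]$; a maximal run of
at least `min_run = 3` consecutive bins whose deviation from $p$ has the
same sign becomes one event. Runs are broken by deviation-zero bins,
masked bins, and chromosome ends. No HMM or circular binary segmentation
is used: at 100-kb bins and ~1000 reads per bin, the per-bin standard
deviation of RSRC is ≈ 0.13, so a true single-copy change (a full unit
away from the baseline) is essentially never mis-rounded, while the
three-bin rule suppresses isolated fluctuations.

## Why replicate concordance works

Induced lesions in mitotically propagated material are present in every
cell, hence in every clonal replicate of a line. Endoreplication —
genome duplication without cell division — produces copy-number changes
restricted to a cell lineage, which surface in one replicate but not
another. `concordant_events()` therefore keeps an event only when every
replicate has a matching call (same chromosome, same deviation sign,
spans overlapping by ≥ 1 bin) and reports the intersection of the matched
spans. The matching criterion is a package design choice; requiring
bin-exact agreement would be fragile at event boundaries, where a single
noisy boundary bin can extend or shorten a run by one bin.

## qPCR validation arithmetic

For wet-lab validation, `qpcr_dosage()` reproduces the standard relative
quantification: each sample's measurements at unaffected flanking regions
are averaged into a per-sample baseline, and each region's ratio to that
baseline estimates `copies / ploidy`. A single-copy deletion in a
triploid gives a ratio of exactly $2/3$ — a 33.3% reduction — in the
noise-free limit. The baseline is per-sample (each sample normalized to
its own flanks), so plate-to-plate or sample-to-sample scale differences
cancel; the two flanks are pooled into one average rather than used
separately.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `bin_size` | 100000 | bp | Smallest window at which ~3× coverage gives ~1000 reads/bin, i.e. per-bin noise ≈ 0.13 dosage units; finer bins trade resolution for false structure. |
| `ploidy` | 3 | copies | Triploid Cavendish banana; any ploidy ≥ 1 works. |
| `min_run` | 3 | bins | Smallest callable event = `min_run * bin_size` = 0.3 Mbp; single- and two-bin deviations are treated as noise or sub-resolution events. |
| `mapq_min` | 20 | phred | Standard "reliably placed" alignment threshold for depth analyses. |
| `depth` (simulator) | 3.0 | fold | The low-coverage regime the method is designed for (2.2–3.5× in practice). |
| `read_length` (simulator) | 300 | bp | Converts depth to expected read counts; matches 2×300 paired-end chemistry entering the analysis as positioned single-end placements. |
| `bin_bias_sd` (simulator) | 0.2 | log units | Moderate, realistic bin-to-bin coverage unevenness; shared across samples so it cancels in RSRC. |
| `overdispersion` (simulator) | 1.0 | – | Poisson counts; no empirical variance model is available for this protocol, so variance inflation is exposed but off. |
| `deadband` (caller) | off | dosage units | Optional stricter mode: only bins within `deadband` of an integer state are callable; off by default because rounding alone is threshold-free and symmetric. |

# What the generator emulates — and what it does not

`simulate_sample()` draws per-bin counts with mean
$(\text{depth} \cdot \text{len}_b / \text{read\_length}) \cdot
\text{bias}_b \cdot (c_b / p)$
and scatters read positions uniformly within bins. It emulates the
features that drive the analysis: shared multiplicative per-bin bias
(drawn once per genome from the config seed, mean-one log-normal),
count noise, copy-number change over injected spans (with proportional
dilution when an event edge falls inside a bin), and replicate-specific
events via a replicate mask. The simulated qPCR model applies
multiplicative log-normal noise to concentrations proportional to
`copies / ploidy`.

It does **not** emulate: sequence-level errors or an aligner (no FASTQ,
no mapping ambiguity), duplicate reads, paired-end fragment structure,
reference-vs-cultivar divergence (regions absent from the reference in
*both* sample and control), or spatially correlated bias beyond the
per-bin log-normal. Passing the recovery benchmarks therefore shows the
statistic and the calling rule behave as designed under the stated noise
model — not that real libraries are free of artifacts the control fails
to share. The cancellation design is exactly why the method is robust to
the largest real-data artifact class (shared biases), but
replicate-specific wet-lab artifacts other than endoreplication are out
of the model.

# Numerical and convention choices

* **Coordinates** are 1-based inclusive everywhere; BED I/O converts at
  the boundary. Bin $i$ (0-based) on a chromosome covers
  $[i \cdot \text{bin\_size} + 1,\; \min((i+1)\text{bin\_size}, L)]$.
* **Partial terminal bins** are retained. Bin length cancels in the RSRC
  ratio, so no length correction is applied; at 100-kb granularity the
  final bin contributes at most one bin to any event span.
* **Normalization order**: fractions are computed per bin, then the
  ratio, then the ploidy scaling. For counts on a fixed grid these
  operations commute with averaging, so the order is a presentation
  choice, not a modelling one.
* **Totals are genome-wide**, not per chromosome: all chromosomes share
  one baseline, so whole-chromosome aneuploidy remains visible as a
  shifted chromosome rather than being renormalized away.
* **Rounding is half away from zero** (2.5 → 3, 3.5 → 4), applied
  symmetrically around the baseline; base R's round-half-to-even would
  make state boundaries asymmetric between gains and losses.
* **Mixed-magnitude runs** (−1 bins adjacent to −2 bins) merge into one
  event; the copy change reported is the modal deviation, ties broken
  toward the smaller magnitude (conservative).
* **Total-count side effect**: because fractions must sum to one, a
  large deletion slightly raises the RSRC of every unaffected bin
  (e.g. 20.5 Mbp deleted from a 990-Mbp triploid genome lifts the
  baseline by ~2%). At realistic event burdens this stays far from the
  0.5-unit rounding boundary; at extreme burdens (a substantial fraction
  of the genome deleted) states would shift — a known limit of
  fraction-based normalization.
* **Mean-of-samples control**: the pseudo-control is the mean of each
  sample's own fraction profile (equal weight per individual, not per
  read). Mutant individuals contribute their events to the baseline, so
  with few individuals a shared event is pulled toward the ploidy; with
  the single-control mode this cannot happen, which is why a designated
  untreated control is the default mode.
* **Gene counting** uses any-overlap semantics — a partially deleted
  gene is dosage-affected — with a full-containment mode available for
  sensitivity analysis. Per-event counts add up across events (a gene
  spanning two events counts in each row); `gene_totals()` also reports
  the distinct-gene union.
* **Read counts, not per-base depth**: each accepted placement
  increments the bin containing its leftmost aligned base. At 100-kb
  bins the binwise ratio is insensitive to the distinction; mates of a
  pair count as two placements for the same reason.

# Problem sizes used in the test suite

Module and property tests run on scaled-down layouts (one to three
chromosomes of 0.5–3 Mbp at 100-kb bins, depth 3), where each simulated
sample is tens of thousands of reads and a property can be repeated over
20+ seeds in seconds. The end-to-end recovery benchmarks use the full
default layout — 11 chromosomes × 30 Mbp (3300 bins, ~3.3 M reads per
sample at 3×) — chosen so every bundled reference coordinate
(`novaria_deletions()`, `w9_deletions()`) fits inside the simulated
genome: 20 seeds of the 10-deletion reconstruction and one fixed-seed run
of the 18-deletion two-replicate reconstruction with decoy filtering.

# Known limitations

* Resolution is the bin: breakpoints are reported at bin boundaries, and
  events shorter than `min_run` bins are invisible by design.
* Copy-change assignment assumes deviations near integer states;
  mosaicism within a sampled tissue would produce fractional dosages
  that round toward the nearest state or, with `deadband` on, become
  uncallable.
* SNPs and small indels are out of scope — they require substantially
  deeper coverage than the regime this method targets.
* The caller never merges runs across a single baseline bin; two events
  separated by one normal bin stay two events.
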