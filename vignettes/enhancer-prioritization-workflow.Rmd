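---
title: "Prioritizing and deleting a lymphoid enhancer: the methods behind enhancerscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing and deleting a lymphoid enhancer: the methods behind enhancerscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscope)
```

## The problem

Candidate enhancers identified from open chromatin or histone marks mostly
fail to show activity in functional assays, so a locus with a dozen DNase I
hypersensitive sites (DHSs) needs an integration strategy before anyone
commits to a CRISPR deletion. `enhancerscope` implements one such strategy
as a reusable pipeline: score each DHS in a massively parallel reporter
assay (CapStarr-seq style), ask which candidates are bound by the lymphoid
transcription-factor repertoire and sit inside an architectural CTCF loop,
read promoter contact from Hi-C (virtual 4C) and 4C-seq, and finally
quantify what an enhancer deletion does to expression, inducibility and
local histone acetylation. Every stage is exercised against a synthetic
locus with planted ground truth, so the pipeline is testable end to end
without any external data.

## Reporter-assay activity

Enhancer activity of a cloned fragment is the ratio of screen to input
coverage, both expressed as FPKM (fragments per kilobase per million mapped
reads):

$$\mathrm{FC} = \frac{\mathrm{FPKM}_{\mathrm{screen}}}{\mathrm{FPKM}_{\mathrm{input}}},
\qquad
\mathrm{FPKM} = \frac{c}{(L/10^3)\,(N/10^6)}$$

with $c$ the fragment's read count, $L$ its length and $N$ the library
size. A DHS with $\mathrm{FC} < 1.5$ is inactive, $1.5 \le \mathrm{FC} < 3$
a weak enhancer, and $\mathrm{FC} \ge 3$ a strong enhancer; the inclusive
boundary at 3 follows the operative "equal or higher than" rule, and the
boundary values 1.5 and 3.0 are covered by tests. Replicates are merged by
averaging their fold-changes (pooling counts first is available as an
option); fragments with zero input FPKM are flagged and excluded from
ranking rather than mapped to infinity. Ranking is by descending merged
fold-change with ties broken by genomic position, and the top 5 % of ranked
fragments are flagged, mirroring the genome-wide "most active" cut.

## Chromatin topology

Raw binned contacts (10 kb bins by default) are balanced with the
Knight–Ruiz method: a positive diagonal matrix $D$ is found so that every
row of $DMD$ sums to one, using the inner–outer Newton iteration with
conjugate-gradient inner solves. Zero-marginal bins are masked beforehand
and stay missing downstream. We require the row-sum dispersion to fall
below $10^{-8}$ and verify in tests that the result agrees elementwise
(within $10^{-6}$) with an independent Sinkhorn fixed-point iteration,
which converges to the same balanced matrix for strictly positive
symmetric inputs.

The insulation score of bin $i$ is the mean balanced contact over the
square window of pairs crossing $i$ — the `window_bins` (default 10, i.e.
100 kb) bins upstream against the 10 bins downstream, diagonal excluded —
normalized as $\log_2(\text{raw}_i / \overline{\text{raw}})$ against the
chromosome-wide average. The published description normalizes "to
chromosome-wide averages" without fixing the arithmetic; the log2-ratio
form is adopted here because it makes the flat-profile null exactly zero.
Bins within one window of the chromosome edge are undefined.

TAD boundaries are strict local minima of the insulation profile filtered
by boundary strength. The delta vector is instantiated concretely as

$$\delta_i = \operatorname{mean}(s_{i+1..i+f}) - \operatorname{mean}(s_{i-f..i-1}),
\qquad f = 3\ \text{bins},$$

and a candidate minimum is kept when $\max \delta - \min \delta \ge 0.7$
over the $\pm f$ bins around it. The flank range over which the delta
min/max are taken is not fixed by the method's published description; the
$\pm f$ window is this package's documented choice, and the 0.69/0.71
flip around the 0.7 threshold is pinned by a constructed-profile test.
Because the insulation windows of the last bin of one block and the first
bin of the next see the same cross-block contacts, the minimum at a planted
junction is a coin-flip tie under noise; recovery is therefore assessed
within one bin of the planted boundary.

Virtual 4C is exactly one row of the balanced matrix — the contacts of
every bin with a chosen anchor bin — with the anchor's own bin masked. An
anchor interval spanning two bins is refused rather than averaged.

## 4C-seq profiles and interaction calling

Per-fragment counts over an in-silico restriction map (DpnII-style GATC
cuts placed at the first base of each site occurrence) are smoothed with a
centered 21-fragment running mean; the viewpoint fragment and one
neighbour per side are masked first, as self-ligation and undigested
artifacts dominate there (the exact masking extent of the original
visualization tooling is unstated; one fragment per side is this package's
default, configurable). Profiles from multiple conditions are quantile
normalized jointly: every sample's $r$-th order statistic is replaced by
the mean of all samples' $r$-th order statistics, ties receiving the mean
of the target quantiles they span. The in-package implementation exists
because of the masked-position semantics; it is cross-checked against
`limma::normalizeQuantiles(ties = TRUE)` on complete data in the tests.

Interaction calling is a deliberately simple stand-in for rank-based
viewpoint callers, with only the 21-fragment window taken from the
original description: per side of the viewpoint, the background is a
monotone non-increasing isotonic fit against distance; residual enrichment
is signal over background; and fragments exceeding both the 0.97 residual
quantile and a floor ratio of 1.8, in runs of at least
$\lceil 21/3 \rceil = 7$ consecutive fragments, are merged into
interaction intervals. The floor matters because smoothing correlates
neighbouring residuals, so a pure quantile cut produces long
above-threshold runs even on background-only profiles; 1.8 was calibrated
on the generator's null (background-only) condition, where above-1.8
excursions never persist beyond a couple of fragments while planted
five-fold peaks sustain runs of ~17. Divergence from the published
caller's statistical model is a known limitation: these calls are
interval recoveries, not significance statements. Interactions
"conserved" across conditions are the intersections of calls overlapping
in every set.

## Expression consequences of deletion

Relative expression uses the delta-delta-Ct method with amplification
efficiency fixed at 2 (no efficiency correction is applied, matching the
stated method; the efficiency is a configuration hook):
$\Delta Ct = Ct_{\text{target}} - Ct_{\text{housekeeping}}$ paired within
replicate, and per-replicate relative expression
$2^{-(\Delta Ct_{\text{test}} - \overline{\Delta Ct}_{\text{ref}})}$. A
two-cycle shift is exactly a four-fold change. Group differences are
tested with an unpaired two-tailed Welch t-test on the $\Delta Ct$ values
(approximately normal), not on the exponentiated folds; the reported
spread is the standard deviation of the per-replicate relative
expressions, without propagating through the exponentiation. Fold
induction after stimulation is the same computation within a genotype.
Differential coverage tracks subtract mutant from wild-type per base after
lifting mutant coordinates back through the deletion (positions at or
beyond the deletion start shift right by its width); the deleted interval
has no mutant counterpart and is reported as missing.

## Evidence integration

No numeric integration score is invented. Candidates are ordered
lexicographically — activity class, then number of bound transcription
factors, then promoter-contact value, then fold-change, then position —
which reproduces the argument structure "strongest activity, only
candidate bound by all factors, directly contacting the promoter" while
keeping every evidence column auditable in the report. CTCF flanking
(nearest upstream site forward, nearest downstream site reverse) is
reported but not used in the ordering, as is overlap with called 4C
interactions.

## The synthetic locus

The default model is a 2 Mb chromosome with 200 bins of 10 kb. The gene
sits at 1.2–1.32 Mb with two alternative first exons (E1L, E1S) and a
common 3' exon; 13 candidate DHSs carry true fold-changes giving 2 strong
+ 4 weak = 6 active of 13, so the census logic is exercisable in-package.
The strong enhancer 120 kb upstream of the promoter is the designated
analogue of the functionally validated element: the only DHS overlapped by
all six lymphoid factor peak sets (Ikaros, Runx1, Tcf1, Gata3, Ets1, E2A),
bracketed by a convergent CTCF pair, connected to the promoter by a 2×
contact loop, and covered by the default 305 bp deletion.

Generator choices, once for all:

* **Counts are Poisson** (Hi-C, 4C, coverage) or multinomial (CapStarr
  libraries); no published noise model exists for these assays at this
  granularity and Poisson is the standard minimal model for sequencing
  counts, sufficient for recovery testing. Overdispersion, GC bias and
  mappability are deliberately not modelled — passing tests show the
  estimators recover planted truth under sampling noise, not that they are
  robust to real-data artifacts.
* **CapStarr libraries** clone the 13 locus DHSs plus 487 neutral
  background fragments (fold-change 1), a 500-fragment scaled-down stand-in
  for a genome-wide screen: the neutral mass keeps FPKM-ratio estimates
  centred on truth, and per-fragment depth at the default $10^6$-read
  library matches the regime where a planted four-fold activity is
  recovered within ±0.5.
* **Hi-C**: expected contacts $300\,(1+|i-j|)^{-0.8}$, multiplied by 3
  within a TAD block; planted boundaries at bins 61 and 141.
* **4C**: background $100\,(1+d/10^4)^{-1}$ around the viewpoint (a bait
  1.2 kb upstream of E1L), five-fold enrichment over ±1.5 kb around each
  true enhancer in thymic-like conditions; the ES-like condition receives
  background only.
* **qPCR**: Ct anchors 20 (housekeeping) and 25 (targets) — arbitrary,
  only differences matter — with noise sd 0.1 cycles and 3 replicates.
  Planted effects: common 3' exon and E4–E5 down four-fold, E3–E4 and
  E6–E7 down two-fold, E1L three-fold, E1S two-fold, enhancer RNA
  eight-fold; wild-type stimulation induces three-fold, mutant stimulation
  not at all.

All simulators restore the caller's RNG state, so a fixed `(config, seed)`
pair reproduces byte-identical pipeline outputs; the pipeline fans one
global seed out to per-stage seeds by hashing the stage name.

## Worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(run_config(out_dir = "run1", seed = 1))
res$census          # n_active 6, n_total 13
head(res$report[, c("fragment_id", "activity_class", "tf_overlap_count",
                    "ctcf_flanked", "priority_rank")])
res$boundaries      # bins 61 and 141 (within one bin)
res$expression      # delta-delta-Ct fold changes vs wild type
```

## Problem sizes and limitations

The test and acceptance runs use the 2 Mb / 200-bin locus, 100-seed
recovery sweeps for TAD boundaries and 4C calls, 200-seed CapStarr
calibration and 500-seed qPCR recovery — sizes chosen so the whole suite
runs in about a minute while keeping binomial noise on the 95 %-recovery
checks small. Known limitations: the interaction caller is not a port of
the published rank-based method; insulation normalization and the
delta-vector range are concrete instantiations of an underspecified
published recipe; genome-wide rank context (thousands of DHSs) is emulated
by neutral background fragments rather than real heterogeneous activity;
and no raw-read processing (mapping, duplicate filtering, peak calling) is
included — inputs begin at count tables, matrices and interval files.
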