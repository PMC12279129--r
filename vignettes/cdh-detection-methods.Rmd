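---
title: "Detecting maize drive haplotypes from GBS tag counts: methods and design"
author: "CDHscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting maize drive haplotypes from GBS tag counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CDHscan)
```

# The problem

Maize carries at least three chromosomal drive haplotypes (CDHs) that cheat
meiosis: Ab10 and K10L2, large structural variants of chromosome 10 built
around TR-1/knob180 tandem-repeat arrays and the kinesins *Kindr* and
*Trkin*, and the supernumerary B chromosome, present in 0 to 14 or more
copies. These regions are invisible to SNP genotyping — they are largely
repetitive, poorly conserved, and absent from standard references — but when
reads are aligned to a CDH-bearing assembly, their presence shows up as a
block of covered tag sites that negatives simply do not have.
Genotyping-by-sequencing (GBS) data are shallow and extremely missing at any
single site, so CDHscan aggregates the signal over megabase windows and
anchors every call in control samples of known CDH status.

# The tag index

All analysis starts from a tag-by-taxa table: integer read counts at tag
sites (64 bp read classes mapped to unique loci) by samples, with per-tag
coordinates and BWA mapping quality. After summing technical replicates,
removing samples whose missingness exceeds the blank-derived cutoff, and
dropping tags with MAPQ < 20, depth is normalized to reads per million
(RPM). For sample $s$ and a 1 Mb bin $b$:

$$\mathrm{TI}(b, s) = \sqrt{c_{bs}} + d_{bs}$$

where $c_{bs}$ is the number of the bin's tag sites with nonzero depth in
$s$ and $d_{bs}$ the sum of their RPM depths. The square root keeps breadth
of coverage informative without letting the site count swamp the depth sum.
Two details are deliberately pinned down because the statistic's verbal
definition leaves them open:

* **$c$ counts sites observed in the sample**, not reference sites in the
  bin. A reference-fixed $c$ would be constant across samples and carry no
  presence/absence information; only the per-sample count lets
  $\sqrt{c}$ discriminate. This is configurable at the assay level (both
  `"c"` and `"d"` are stored).
* **$d$ consumes RPM**, computed per sample over the filtered tag set, so
  the index is comparable across libraries of very different size.

Missingness of a sample is the fraction of tag sites with a raw count of
zero — the only observable notion of "missing" at this level. The sample
filter is strict (missingness *greater than* the cutoff removes; equality
retains), and the pipeline order is fixed: replicate merging, blank cutoff
and sample filter on raw counts, then the MAPQ tag filter, then RPM. The
blank cutoff is `min(blank missingness) - 0.001`; datasets without blanks
must supply an explicit cutoff.

# Min/max scaling

Clustering consumes the tag index min/max-scaled **per bin** (feature
scaling) so every feature lies in $[0, 1]$; constant bins scale to 0 rather
than NaN so uninformative features are inert under Euclidean distance. The
scaling axis is a genuine design choice (per-bin, per-sample and global are
all defensible); per-bin is adopted because the clustering operates on
samples as points in bin space and needs features on a common scale.
Crucially, scaling is **recomputed inside every clustering batch over
exactly the batch's samples** — batches differ in membership, and a batch
must see its own extremes, not the cohort's.

# The control-anchored consensus caller

Presence/absence of a CDH is decided by iterative k-means clustering,
anchored at every step in controls of known status:

1. **Diagnostic bins.** Only bins where positive and negative controls
   differ starkly are used: scaled-index class-mean separation above 0.5
   (configurable; a user-supplied BED of known diagnostic intervals
   overrides selection). This excludes shared homologous regions that light
   up in both classes.
2. **Batches.** Controls of a single copy stratum are class-balanced (the
   larger class is randomly downsampled to within 20% of the smaller — the
   protocol asks for "roughly equal" classes, and 20% is the adopted
   reading), and experimental samples are spiked in at no more than 25% of
   the control count (10% for B, whose copy-number variance destabilizes
   clusters more easily). Each round randomly partitions all experimentals
   into such batches, so every sample is clustered exactly once per round.
3. **k-means and naming.** k-means with $k = 2$, k-means++-style restarts
   (`nstart = 10`, Euclidean distance on the scaled diagnostic bins). A
   cluster is named positive or negative only when at least 80% of its
   *control* members carry that truth — spiked experimentals never count
   toward purity, and exactly 80% counts as named ("at least").
4. **Control verification.** If any control sits in an unnamed or
   wrongly-named cluster, the batch is redrawn (fresh random control
   balance) and reclustered. The published protocol repeats "until all
   controls are correctly identified"; CDHscan adds a retry ceiling
   (default 50) so a degenerate batch cannot loop forever — an exhausted
   batch is abandoned and its experimentals are simply uncalled that round.
5. **Consensus.** Over 125 rounds, a sample is called the majority class
   only if that class was assigned in at least 95% of its completed rounds;
   otherwise it is ambiguous. Abandoned rounds are excluded from the
   denominator, and a sample clustered in fewer than half the rounds is
   ambiguous by fiat. Aggregation depends only on the multiset of round
   calls, so round order is irrelevant.

Copy strata are analyzed separately — clustering must reflect presence
versus absence, not one versus two copies — and a sample's final presence
call is positive if *either* stratum's consensus is positive (union; the
alternative, sequential forwarding, is equally consistent with the protocol
and union is the adopted choice).

**Stepwise pipelines.** The Ab10 detector cannot see K10L2, but a K10L2
detector cannot distinguish Ab10 from K10L2 (TR-1 homology). Running Ab10
first and forwarding only its negatives to K10L2 makes the calls mutually
exclusive by construction; Ab10-ambiguous samples are not forwarded. For
the B chromosome, high-copy samples can form their own cluster and derail a
single pass, so stage 1 extracts positives with high-copy controls and
stage 2 re-runs the remainder against low-copy controls; a sample is
positive if either stage says so and otherwise takes the stage-2 call.

**Control validation.** The caller is validated on controls alone: split
into 3 random groups (redrawn until every group contains both classes),
cluster each group, name by purity, compare to truth, repeat 100 times.
Panels too small to guarantee at least three controls of each class per
group — in practice the low-copy B stratum — are clustered as a single
group instead, which is exactly how the small low-copy B panel is handled
in the published protocol.

**Randomness and reproducibility.** One master seed; per-round (and
per-stratum, per-stage) child seeds are drawn deterministically from it, so
identical inputs and seed reproduce identical calls bit for bit, while
rounds remain mutually independent.

# Copy number

The copy-number statistic is the ratio of the sample's mean tag index over
the CDH diagnostic bins to its mean tag index over single-copy core genes,
binned in 1 Mb of *concatenated gene sequence* (gene-space, not genomic,
coordinates — core genes are sparse, and genomic megabases would mix gene
and intergenic tag densities). Library size cancels in the ratio. The
values are not integers: much of a CDH is repetitive and poorly conserved,
so fewer tags align per Mb than in gene space.

Integerization is a two-point calibration from controls:
$\Delta = \mathrm{median}(\text{two-copy}) - \mathrm{median}(\text{one-copy})$,
offset $= \mathrm{median}(\text{one-copy}) - \Delta$, copies
$= \mathrm{round}((v - \text{offset})/\Delta)$, clipped below at 0. Medians
are used because control strata are small (single digits for K10L2) and one
outlier must not tilt the increment; rounding is R's ties-to-even; the
calibration function itself (two-point versus regression) is not dictated
by the protocol and two-point is the adopted, simplest choice. Ab10/K10L2
estimates are clipped at 2 (two copies = homozygous); B estimates are
reported unclipped. $\Delta \le 0$ is a hard calibration failure, and a
zero baseline flags the sample rather than producing an infinite ratio.

# Ab10 typing

A random forest over the scaled Ab10-region bins separates the cytological
types Ab10-I/II/III: stratified 70/30 train/test split (stratification
guarantees every type in training), 500 trees, $\sqrt{p}$ features per
split — standard forest defaults, configurable, all seedable. A sample is
assigned the majority type only when at least 65% of trees agree
(`>= 0.65`; "less than 65%" is ambiguous), which leaves intermediate
profiles — including recombinants between types — unclassified, by design.
Mean-decrease-Gini ranks the bins carrying type signal, and a PCA over the
top bins (default 20, configurable; the exact count used for the published
embedding is not stated) visualizes the continuum of natural variation.

# What the simulator emulates — and what it does not

`simulateCohort()` draws counts as
$\mathrm{count}[t, s] \sim \mathrm{Poisson}(\mathrm{lib}_s \cdot r \cdot
w_t \cdot \mathrm{dose}(t, s)/2)$: a log-normal library-size factor
(sdlog 0.4, unit mean), a gamma per-tag efficiency $w_t$ (shape 3, unit
mean — tag sites differ widely in restriction-site recovery), and a local
dosage — 2 for normal-genome and core-gene tags, one per CDH copy for CDH
tags (scaled by the `effect` dial and shifted by a cross-mapping
`background`), `b_copies` for B tags, background-only for blanks. Poisson
is the minimal shot-noise model for GBS coverage; a negative-binomial
option (`dispersion`) exists for overdispersion studies. Ab10 types
modulate the 20 Ab10 bins through per-type profiles (a shared block plus
type-specific blocks); Ab10 copies also cross-map fully onto the K10L2
region, which is what forces the stepwise pipeline order. The layout keeps
the normal chromosome (100 Mb) much larger than the CDH regions so that a
present CDH perturbs library composition only mildly, as in real maize
(a B chromosome is ~150 Mb against a ~2.1 Gb genome); compositional
RPM artifacts otherwise dominate and are not representative of real GBS.

The default (`"strong"`) preset — depth 4 reads per diploid tag site,
background 0.03, effect 1 — is the study condition: control classes
separate starkly on the scaled index, which is the regime the published
control panels show. The `"hard"` preset (and the `effect` dial) shrinks
the class gap toward overlap for sensitivity studies. The default control
panel mirrors a realistic design: 49 Ab10 (three types, heterozygous and
homozygous), 13 K10L2, 18 B (low = 1–2 copies, high = 4–8), 18 negatives,
4 blanks.

Not emulated: read-level sequence (no FASTQ, no restriction-site or GC
bias), population structure among samples, segregating knob variation in
the normal genome, and batch effects between sequencing providers. Passing
tests therefore demonstrate the *procedure* is correct and well-calibrated
under its stated noise model — not that any particular real dataset will
separate as cleanly.

# Numerical choices and degenerate inputs

* Constant features scale to 0; empty bins have index 0; a k-means run on
  degenerate (non-distinct) batches counts as a failed attempt and triggers
  the batch redraw.
* Tags are assigned to bins by start coordinate (half-open bins make ties
  impossible); BED input is 0-based half-open, `GRanges` internally 1-based.
* Cluster purity at exactly the 0.80 threshold names the cluster; consensus
  at exactly 0.95 calls; vote fraction at exactly 0.65 types.
* Zero-read samples stay all-zero through RPM (flagged); zero baselines
  flag the sample's relative index as undefined rather than dividing.
* Copy estimates use round-half-to-even and are reported alongside the raw
  ratio so the integerization can be ignored.

# Problem sizes in the test and validation suites

The packaged validation workflows run at desk scale, chosen to exercise the
full protocol while keeping the suite fast: control panels of 98 samples
plus blanks at 5720 tag sites; the confident-call benchmark at 500
experimental samples and the full 125 consensus rounds; module tests reuse
one cached 126-sample cohort and shrink consensus rounds (12–50) where only
logic, not the 125-round operating point, is under test.

# Known limitations

* Diagnostic-bin selection needs at least two controls per class and a real
  class gap; on data where controls barely separate it fails loudly rather
  than calling from noise (the separation it did observe is reported).
* The consensus caller gives presence/absence only; dosage beyond the
  low/high stratum split comes from the copy-number module, whose linear
  two-point calibration accumulates mild bias at high B copy numbers (the
  $\sqrt{c}$ term saturates while depth keeps growing).
* The K10L2 stage inherits any Ab10 false negatives; ambiguous Ab10 samples
  are never typed or forwarded.
* Tag discovery, alignment, and reference construction are out of scope:
  analysis starts at the tag-by-taxa table.
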