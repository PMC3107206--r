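---
title: "Peak calling and colocalization with adipoChIP: models, parameters, design"
author: "adipoChIP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak calling and colocalization with adipoChIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(adipoChIP))
suppressPackageStartupMessages(library(GenomicRanges))
```

adipoChIP implements a classical ChIP-seq analysis chain for histone-mark
and transcription-factor profiles: a Poisson-background peak caller with an
empirical mock-IP (IgG) fold filter, TSS-window gene annotation, proximity
and colocalization statistics between peak sets, exact hypergeometric
category enrichment, and an expression-association test. A synthetic read
generator with planted enriched sites makes every stage testable end to end
without external sequencing data. This vignette explains the model behind
each stage, the parameters that matter, and the design choices made where
the method leaves room.

## The peak-calling model

Aligned reads mark only the 5' end of the immunoprecipitated fragment, so
each read is first **extended** to 200 bp in its strand direction: a `+`
read starting at $s$ (0-based) becomes the fragment $[s, s+200)$, a `-`
read ending at $e$ becomes $[e-200, e)$. Extended fragments are allocated
to **25-bp bins**; a bin's count is the number of fragments overlapping it,
so a fragment increments 8 bins when it is bin-aligned and 9 otherwise.

Under a homogeneous background, the count $X$ of a bin is approximately
Poisson with mean $\lambda$, estimated genome-wide as total bin increments
divided by total bins — a single rate per sample, matching the use of one
minimum count per sample rather than local backgrounds. A bin is
**significant** when its count reaches the smallest $k$ with

$$P(X \ge k \mid \lambda) < 10^{-9},$$

computed by `poissonMinCount()`. Significant bins whose edge-to-edge gap is
at most **200 bp** are merged into one enriched region (a gap of exactly
200 bp merges); the region's **summit** is the midpoint of its
maximum-count bin, leftmost on ties, which keeps calls deterministic.

The Poisson model understates real background, which is non-random:
accessible chromatin and other artifacts produce locally elevated read
density in any IP, specific or not. The **IgG filter** addresses this
empirically: for each region the IP and control fragment counts are scaled
by their library totals and the region is kept only if the density ratio
*strictly* exceeds 3. Region counts are fragments overlapping the region
(not bin sums, which would double-count fragments spanning several bins),
so the filter works in fragment-density units. A region with zero control
reads would give an infinite ratio; a pseudocount of 1 control read is
substituted there — only there — so strong calls survive with a finite,
reportable fold. The worked consequence: an IP count of 50 against a
control count of 10 at equal depth reports fold 5, not $50/11$.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `extension` | 200 | bp | fragment length assumed for 5'-anchored reads |
| `binSize` | 25 | bp | resolution of the significance test |
| `pThreshold` | 1e-9 | — | Poisson upper-tail cutoff per bin |
| `mergeGap` | 200 | bp | maximal gap joined between significant bins |
| `minFold` | 3 | ratio | strict IP/IgG density threshold |
| `pseudocount` | 1 | reads | control stand-in for zero-control regions |

The derived minimum count is reported per sample (`callPeaks()` logs it and
stores it in the result's metadata); it is the number to quote when
describing a run, since it couples the threshold to library depth.

## What the simulator emulates — and what it does not

`simulateReads()` draws background read 5' positions as a homogeneous
Poisson process on both strands (strand fair at 1/2), then superposes two
kinds of elevated patches:

* **Hotspots** — 500-bp patches at 5× the background rate, at a default
  density of 5 per Mb, modeling the non-random background that makes an
  IgG control necessary. By default all hotspots are shared between IP and
  control (`controlCorrelation = 1`): the premise of a mock-IP control is
  precisely that it captures the same non-random background as the
  specific IP. The fraction shared can be lowered to probe filter failure,
  and `backgroundHotspots()` lets several IP samples and one control share
  a single drawn background, as one mock IP underlies all samples of an
  experiment.
* **Planted sites** — ground-truth enriched intervals whose fold
  multiplies the IP rate only; the control never carries them.

Reads are intervals, not sequences; mappability, GC bias, and duplicate
structure are not modeled. Passing tests therefore demonstrate the
statistical machinery — thresholds, merging, filtering, interval
statistics — on data that match the model's own assumptions, not
robustness to alignment artifacts of real libraries.

Sequencing depths are a simulation choice made for statistical power: the
null-calibration runs use 5×10^5 reads per sample on a 10-Mb genome and
the planted-recovery runs 10^6. Depth matters for the IgG filter: with
ample counts the density ratio of a shared hotspot concentrates near 1 and
the filter removes it reliably; at shallow depth the ratio is noisy and
occasional hotspot fluctuations can slip past a strict 3-fold cut. The
chosen depths put the simulations in the regime where the Poisson tail,
not filter noise, governs false positives — about $4\times10^5$ bins
$\times\,10^{-9}$ expected false bins per run, i.e. essentially zero.

At the boundary `fold = 3`, planted sites are frequently rejected: their
measured density ratio scatters around 3 and the filter is strict, and
read extension smears fragments across site edges, diluting the measured
ratio further. Recovery climbs steeply with fold (and with depth); the
recall-vs-fold curve is monotone, which is the property worth testing.

## Gene annotation and proximity statistics

A region is assigned to a gene when its **summit** lies within 10 kb of
the TSS (inclusive); distances are signed in the gene's transcription
direction, negative upstream. The summit is used as the region's reference
point for all gene-level statistics because it is a single well-defined
position; an alternative would be the nearest region edge, which is what
region-to-region proximity uses (below). Genes carry one TSS each;
collapsing multi-isoform annotation to a canonical TSS is the caller's
responsibility.

`fractionWithin()` measures the fraction of query peaks whose summit lies
within $d$ bp (default 300) of a target region, with distance 0 when the
summit is inside a target. Whether such statistics should be
summit-to-summit, summit-to-edge or edge-to-edge is genuinely open;
summit-to-edge is the default and the other two are selectable
(edge-to-edge counts intervening bp, so adjacent regions are at distance
0). `peaksetOverlapFraction()` is the region-level counterpart: the
fraction of one set's regions with at least 1 bp of intersection in the
other, asymmetric by design.

Genes are ranked by site count with lexicographic tie-break (determinism),
and genes with ≥ 5 sites are flagged as the heavily modified tier;
`exportRnk()` writes the ranking in the RNK text convention for external
ranked-list tools.

`expressionByBinding()` compares log2 expression between bound and unbound
genes, and between TSS-distance categories (default breaks 2 kb and 10 kb)
and the unbound group, with a two-sided Mann–Whitney rank-sum test — a
deliberate choice of a distribution-free test, since group shapes are not
Gaussian in practice.

## Colocalization windows

`extractWindowSignal()` builds, per anchor, 15 bins of 100 bp spanning
1.5 kb centered on the anchor, counting extended fragments per bin and
scaling to reads per million so samples of different depth are comparable.
Anchors are chosen by `colocalizationAnchors()`: the strongest peak per
locus (greedy by region read count, enforcing the window span between
chosen summits) among loci where every compared peak set has a summit
within the span. Per anchor, the Pearson correlation between two samples'
bin vectors summarizes whether the two signals sit at the same relative
position; a vector with zero variance has no defined correlation and is
flagged invalid and excluded from histograms. Pearson is used because the
location profile comparison is linear in normalized counts; correlating
z-scored rows gives identical values (affine invariance), which the test
suite checks.

For heatmap display, rows are z-scored with the **population** standard
deviation (denominator $n$): then a one-hot row of $b$ bins attains the
closed-form maximum $\sqrt{b-1}$ regardless of scale, a convenient
invariant (for 15 bins, $\sqrt{14}$). Constant rows become zero and are
flagged. Row order is by descending anchor strength by default, with
complete-linkage hierarchical clustering on Euclidean distances available
— the clustering method behind such heatmaps is unspecified in general,
so both orderings are exposed.

In simulation, two samples with coincident planted sites give a
correlation histogram massed above 0.5, while offsetting one sample's
sites by 300–700 bp flips the histogram predominantly negative — the
qualitative signature that distinguishes factors binding identical loci
from factors binding adjacent loci.

## Category enrichment

`hypergeometricEnrichment()` computes the exact upper-tail probability of
drawing at least $k$ category members in a set of $n$ genes from a
universe of $N$ containing $K$, $p = \sum_{i \ge k} \binom{K}{i}
\binom{N-K}{n-i} / \binom{N}{n}$. The choice of universe dominates such
p-values and is left to the caller. Because "corrected for multiple
testing" can mean different things, both Bonferroni and
Benjamini–Hochberg adjustments are reported side by side. Under a null of
random sets the p-values are conservative relative to uniform (the
discrete tail includes the observed point), which the suite verifies.

## Numerical and degenerate-input choices

* `poissonMinCount()` starts from the Poisson quantile and steps to the
  smallest $k$ with tail strictly below the threshold, avoiding the
  boundary ambiguity of quantile definitions; it agrees with brute-force
  series summation over a λ grid in the tests.
* Coordinates are 0-based half-open in every file (BED convention) and
  1-based closed inside R (GRanges convention); conversion happens only at
  I/O boundaries. Parsers validate `start < end`, strand, and chromosome
  bounds, and report the offending line number.
* Empty inputs: an empty read file warns and yields an empty set; an empty
  region list round-trips through an empty file; a gene table is required
  wherever TSS distances are computed.
* Duplicate reads are retained by default; a `dedup` flag collapses
  identical (chrom, 5'-position, strand) triples, since whether "unique
  reads" means uniquely mapped or deduplicated is ambiguous in common
  usage.
* All randomness flows from a single integer seed per simulation call;
  rerunning `runAll()` with one seed is bit-identical file for file.

## A complete run

```{r run, eval = FALSE}
cfg <- demoConfig("adipochip_demo_run", seed = 1)
summary <- runAll(cfg)
```

The run directory contains the simulated BED/TSV inputs, per-sample peak
calls and coverage, assignments, proximity and colocalization tables, the
enrichment table, and `summary.json` with per-stage counts, the derived
minimum Poisson count per sample, and recall/precision against the planted
truth. The same pipeline runs stage by stage from the shell via
`inst/cli/adipochip.R` (subcommands `simulate`, `callpeaks`, `annotate`,
`proximity`, `colocalize`, `enrich`, `run-all`).

## Known limitations

* The background rate is global; regions of genuinely elevated but
  unenriched signal are handled only through the IgG filter, not by local
  λ estimation.
* The caller has no notion of broad versus narrow peaks and no FDR beyond
  the fixed Poisson threshold.
* The simulator does not emulate fragment-length variability, duplicate
  towers, or mappability holes; conclusions about those failure modes
  cannot be drawn from these tests.
* Planted sites near the strict `minFold` boundary are systematically
  under-recovered; this is a property of a strict ratio filter, not a bug.
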