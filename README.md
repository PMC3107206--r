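# adipoChIP

Analysis of ChIP-seq profiles of histone modifications and transcription
factors — the setting in which it was developed is mapping H3K56
acetylation and the binding of regulators such as E2F4, HSF-1 and C/EBPα
in human adipocytes, but every component is generic to 5'-anchored
aligned-read data.

The package implements, as tested and reusable R functions:

* **Peak calling with a Poisson background and an empirical IgG filter.**
  Reads are extended 200 bp strand-specifically and allocated to 25-bp
  bins. With a single genome-wide background rate λ (total bin increments
  / total bins), a bin is significant when its count reaches the smallest
  k with P(X ≥ k | λ) < 10⁻⁹ for X ~ Poisson(λ). Significant bins within
  200 bp merge into enriched regions, and a region is kept only if its
  read density (fragments in region / library total) is *strictly* more
  than 3-fold the density of a mock-IP (IgG) control — the empirical
  answer to non-random background.
* **Gene-level annotation**: a gene carries a mark when a region summit
  lies within 10 kb of its TSS; signed TSS distances, distance
  histograms, gene ranking by site count (≥ 5 sites flagged), RNK export.
* **Peak-set statistics**: fraction of query peaks within d bp (default
  300) of a target set, asymmetric ≥ 1 bp overlap fractions.
* **Colocalization**: per-anchor 15 × 100-bp per-million signal vectors in
  1.5-kb windows, pairwise Pearson correlation of binding locations,
  correlation histograms, row-Z-scored heatmap matrices.
* **Exact hypergeometric category enrichment** with Bonferroni and
  Benjamini–Hochberg adjustments.
* **A synthetic-data generator** — Poisson background reads with shared
  "hotspot" patches (the non-random component an IgG control exists for)
  and planted enriched sites of chosen fold — so the whole pipeline runs
  and is validated end to end without external data.

## Worked example

```r
library(adipoChIP)

genome <- simGenome(c(chr1 = 2e6))
sites  <- plantedSites("chr1", c(5e5, 1.2e6), c(5.01e5, 1.201e6),
                       fold = c(10, 10), genome = genome)
reads  <- simulateReads(genome, sites, nReadsTarget = 2e5, seed = 42)
peaks  <- callPeaks(reads$ip, reads$control, genome)
#> IP: 204451 fragments; control: 202179 fragments
#> background lambda = 22.9 per 25-bp bin; minimum significant count = 58
#> 12 candidate region(s) before control filter
#> 2 region(s) pass the >3-fold control filter
peaks
#> GRanges object with 2 ranges and 5 metadata columns:
#>       seqnames          ranges strand |    summit  maxCount   ipReads
#>   [1]     chr1   499851-501150      * |    500563       247      1051
#>   [2]     chr1 1199851-1201150      * |   1200713       259      1127
#>       controlReads      fold
#>   [1]          169   6.14983
#>   [2]          148   7.53024
```

Reading the output: at this depth the background is λ ≈ 22.9 fragments per
25-bp bin, so a bin needs 58 fragments to clear the 10⁻⁹ Poisson tail; ten
of the twelve candidate regions are background hotspots shared with the
IgG control and fall to the 3-fold density filter, leaving exactly the two
planted sites. Each call spans ~1.3 kb around its planted 1-kb interval
(200-bp read extension widens calls), with summits 500563 and 1200713
inside the planted intervals and region-level fold enrichments 6.1 and 7.5
(region-wide density ratios, diluted below the planted 10× by flanks).

Annotation then ties the calls to genes:

```r
genes  <- syntheticGeneTable(genome, 50)
assign <- assignPeaksToGenes(peaks, genes, window = 10000)
assign[assign$n_sites > 0, ]
#>    gene_id n_sites min_tss_distance
#> 13  G00013       1              562
```

The whole chain — simulation, both peak calls, annotation, proximity,
colocalization, expression association, enrichment, report — runs from one
configuration:

```r
summary <- runAll(demoConfig("adipochip_demo_run", seed = 1))
```

or from the shell via `inst/cli/adipochip.R` (subcommands `simulate`,
`callpeaks`, `annotate`, `proximity`, `colocalize`, `enrich`, `run-all`;
a template configuration ships in `inst/extdata/demo-config.yaml`).

## Documentation

`vignettes/adipoChIP-methods.Rmd` describes the statistical model of each
stage, the tunable parameters with units and defaults, what the simulator
does and does not emulate, and the design decisions taken where the
method leaves room.
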