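---
title: "Detecting selective sweeps and functional enrichment between two populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps and functional enrichment between two populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

Two populations of one species that have been separated and selected
differently — the motivating case is humpless taurine versus humped indicine
cattle — accumulate allele-frequency differences genome wide by drift, and
much sharper local signatures where positive selection has driven a
haplotype to (near) fixation in one of them. A hard selective sweep leaves
two coupled signals in a genomic window: elevated allele-frequency
differentiation (F~ST~) between the populations, and a loss of nucleotide
diversity (π) in the swept population relative to the other. `sweepscan`
implements a windowed scan that combines the two, plus the companion
analyses such a scan feeds: classification of strongly divergent SNPs by
functional category, region-set overlap enrichment, coding-consequence
calls for fixed differences, and read-depth genotyping of a copy-number
variant that co-locates with a sweep.

## The scan model

Genotypes are hard diploid calls (0/1/2 copies of the alternate allele)
at biallelic SNPs. After cohort-level filtering (biallelic sites, at
least 4 copies of the minor allele, pooled MAF ≥ 0.05 — the thresholds
standard for sequence-derived cattle cohorts), three per-site statistics
are computed from called alleles only:

* **F~ST~** — the Weir & Cockerham (1984) two-population estimator
  \(\hat\theta = a/(a+b+c)\), from the among-population (a),
  among-individual (b) and within-individual (c) variance components.
  Negative estimates are retained, not clipped: they are ordinary
  estimator noise and clipping would bias window means upward.
* **π** — the per-site proportion of distinct allele pairs that differ,
  \(2 c_{\mathrm{ref}} c_{\mathrm{alt}} / (n(n-1))\).
* **ΔAF** — the absolute allele-frequency difference between the
  populations; identical whether computed on reference or alternate
  frequencies.

Sites are summarized in overlapping windows of `window_bp` = 20 kb with a
`step_bp` = 10 kb step, so each interior position is covered by exactly
two windows. A window is retained when it holds **more than 10** SNPs with
a defined \(\hat\theta\) (i.e. ≥ 11; the inequality is read strictly).
Window F~ST~ is the arithmetic mean of the per-site estimates (the
ratio-of-summed-components alternative is reported alongside as
`fst_ratio`); window π per population is the sum of per-site π divided by
the full window length, so invariant positions contribute zero through
the denominator, matching the windowed-π convention of VCFtools.

The composite selection score is the product of window F~ST~ and the
**log2** π ratio, Z-transformed across all windows genome wide:

\[ z_w = \frac{ \bar F_{ST,w}\,\log_2(\pi_{A,w}/\pi_{B,w}) - \mu }{ \sigma }. \]

The log form (rather than the raw ratio) was a genuinely open choice; it
makes the two tails symmetric and comparable, so one two-sided threshold
serves both directions, and the sign carries the direction: diversity
retained in A and lost in B gives a positive score — a candidate sweep in
**B** — and vice versa. The raw-ratio product remains available
(`ratio = "raw"`) for sensitivity checks. Windows where exactly one
population has zero diversity have an infinite ratio; they are excluded
from the transform but reported, rather than silently dropped.

Significance uses a Bonferroni-adjusted normal quantile,
\(z^* = \Phi^{-1}(1 - \alpha/n_{\mathrm{windows}})\), applied
symmetrically to both tails. At α = 0.05 and a genome-wide window count
of about 264,000 this gives `r round(bonferroni_threshold(264000), 2)`,
the familiar threshold for a cattle-genome scan at this resolution; the
package always recomputes it from the window count at hand rather than
hard-coding it. Significant windows of the same direction on the same
chromosome are merged when separated by **less than** 50 kb (a 50,000-bp
gap stays unmerged), giving directional sweep regions annotated with
their peak |z| and closest genes.

All coordinates are 1-based inclusive internally (VCF convention); BED
export converts to 0-based half-open at the boundary.

## Functional annotation and enrichment

Annotation tracks are derived from a GFF3 gene model: gene spans, CDS,
UTR, 1-kb strand-aware upstream (TSS) and downstream (TES) flanks,
intergenic (complement of genes), and intron defined as **gene minus CDS**
(minus UTR where UTR records exist). This subtraction-based intron
definition is deliberate — it matches how the cattle annotation tracks
behind the motivating study were built — and differs from exon-based
intron definitions when non-CDS exonic sequence is absent from the model.
Site classification applies a fixed precedence
(CDS > UTR > up1kb > down1kb > intron > gene > intergenic), which makes
the categories a partition: every placed position gets exactly one label.

For the nucleotide-level analysis, SNPs are binned by ΔAF into ten 0.1
bins, half-open with the last bin closed so ΔAF = 1 falls in the 0.9–1.0
bin. Per (category, bin), the **M-value** is the log2 ratio of the
category's relative frequency in the bin to its relative frequency over
all bins; per bin, a goodness-of-fit chi-squared (df = K−1) compares the
observed category counts with expectations from the overall proportions.
The choice of stratification for the chi-squared was open (per bin, per
category, or global); the per-bin goodness of fit is the headline and a
per-(category, bin) 2×2 statistic is emitted as a secondary column.
Fixation (ΔAF = 1) is tested with exact integer arithmetic on allele
counts, not floating-point equality, so a single heterozygote in an
otherwise fixed population correctly excludes a site.

Region-set enrichment follows the locus-overlap (LOLA-style) design: a
query region set, reference tracks, and a universe of 20-kb bins from the
scan. Universe elements are cross-classified by ≥ 1-bp overlap with query
and reference, tested with a one-sided Fisher's exact test, and BH-FDR
adjusted across the reference collection (the FDR family is all
references for one query).

Coding consequences of fixed differences are called by strand-aware CDS
concatenation (honouring GFF phase for the 5'-most segment), substitution
of the alternate base (reverse-complemented on minus strands), and
translation with the standard nuclear genetic code; each overlapping
transcript is reported. Transcripts whose CDS is not a codon multiple
are flagged and excluded from consequence calling only.

## CNV genotyping

A tandem duplication is genotyped per sample as the length-weighted mean
depth of the target region divided by the mean depth of the rest of its
chromosome (excluding the region avoids self-inflation for large CNVRs).
A diploid with 0/1/2 extra copies of a duplicated segment has expected
ratios 1.0/1.5/2.0; the default band cut-points 1.25 and 1.75 are the
midpoints between those expectations and are configurable. Ratios above
2.5 are called 2 extra copies and flagged as beyond the diploid
duplication model. No GC or mappability correction is applied. A 3×3
co-segregation table against a marker SNP reports a descriptive
concordance over the compatible pairings (hom-ref ↔ 0, het ↔ {0, 1},
hom-alt ↔ {1, 2} extra copies).

## What the synthetic cohorts emulate

The generator produces the statistical structure the scan assumes, with
planted truth for recovery tests:

* **Drift**: per site, an ancestral frequency p ~ Uniform(0.05, 0.95)
  and population frequencies Beta(p(1−F)/F, (1−p)(1−F)/F) — the
  Balding–Nichols model — with Hardy–Weinberg genotypes. F directly
  parameterizes the expected Weir–Cockerham differentiation, which makes
  parameter recovery a clean check. The default F = 0.1 reflects the
  strong subspecies-level divergence the scan is designed for.
* **Sweeps**: within a planted region, each site's swept allele is drawn
  with probability equal to its current frequency in the target
  population (one hitch-hiking haplotype); a `site_thinning` fraction of
  sites (default 0.9) is made fully monomorphic in that population and
  the remainder redrawn at 1 − `residual_af` (default residual 0.02,
  standing for residual migration/mutation after a hard sweep). The
  default fixture plants ten sweeps of 200–500 kb, five per population,
  on one 50-Mb chromosome with 100,000 SNPs and 50 diploids per
  population — sized so the full pipeline runs in well under a minute on
  one CPU while windows still hold ~40 SNPs.
* **Annotation**: a synthetic GFF3 (genes with UTR/CDS/intron structure
  on both strands, placed independently of the variant data). Planted
  category enrichment operates at the assignment level: with odds
  multiplier o > 1, sites with ΔAF > 0.8 are re-assigned to the planted
  category so their odds of carrying it are multiplied by o — emulating
  the classification output of a functional class preferentially hit by
  divergent sites — and the planted category's site-derived interval
  track is returned for region-set tests. With o = 1 the assignment is
  the purely positional classification, which is independent of ΔAF and
  therefore serves as the calibration null.
* **Depth**: per-base Poisson depth at mean 12 (the coverage regime of a
  modern sequenced cohort), scaled by (1 + extra copies/2) inside a
  6.2-kb duplication; the background is emitted in 1-kb bins carrying the
  mean of their per-base draws, which is distribution-identical for any
  length-weighted mean over whole bins. The duplication allele segregates
  at frequency 0.5 and (by default) in perfect linkage with a marker SNP,
  reproducing the co-segregation analysis.

What the generator does **not** emulate: linkage disequilibrium and
recombination (the scan does not model LD; planted sweeps create the
diversity/differentiation signature directly), realistic demography or
admixture, sequencing error, and GC/mappability structure in depth.
Passing recovery tests therefore shows that the estimators and the scan
logic are correct under the model's assumptions — not that the pipeline
is robust to artifacts of real short-read data.

## Numerical choices and degenerate inputs

* Half-calls and `./.` genotypes are missing; per-site allele counts use
  called alleles only. Fractional (imputed) dosages are rejected — the
  pipeline works on hard calls.
* \(\hat\theta\) is undefined (NA) when a + b + c = 0 (monomorphic in
  both populations) or when either population has fewer than two called
  genotypes; such sites do not enter window SNP counts. Whether
  monomorphic-in-one-population sites should count was open; sites with a
  defined estimate are counted.
* A window count below 2, or a zero-variance composite, is an error
  ("degenerate score distribution") rather than a silent NA.
* The per-sample expected homozygosity uses the small-sample correction
  n/(n−1) on 2p(1−p), the convention of the `--het` family of tools.
* Merging uses strict inequality (gap < 50 kb) and is idempotent and
  order-independent; ties in closest-gene distance report all tied genes.
* Empty enrichment bins yield NA M-values (reported, not errors);
  categories absent overall are dropped.

## Calibration-test design

Two design points in the test suite deserve a note. The null calibration
of region-set enrichment uses a **random** query sampled from a
**disjoint** 20-kb universe (every other window). Fisher's exact test
assumes exchangeable universe elements; overlapping windows share half
their span and a clustered query (e.g. top-scoring windows) violates that
exchangeability and inflates the tail beyond the nominal level even when
the annotation is truly independent. The random-query/disjoint-universe
null isolates the property being checked — correctness of the test under
its own assumptions. Second, under a global null, BH-FDR still rejects in
up to ~5% of replicate families by construction; the calibration
therefore checks that at least 95% of twenty seeded replicates are clean,
not that every replicate is. Third, the planted-enrichment **power**
check runs in the drift regime rather than on the sweep fixture: a
no-sweep Balding–Nichols cohort at F = 0.3, where roughly 1% of sites
exceed ΔAF 0.9 — the proportion seen between deeply diverged cattle
lineages — and those sites are spread across the genome. On the sweep
fixture the strongly divergent sites collapse into ten clusters, so any
category's local density fluctuates by factors comparable to the planted
odds and the per-category M-values measure cluster geography, not the
planted signal. A denser gene model (1,000 genes on 50 Mb) is used there
so the planted category has enough baseline mass for the region-set
comparison to be informative.

## Problem sizes used by the checks

Estimator oracles run on 1,000 random genotype configurations (exact
agreement with an independent transcription of the 1984 variance
components), brute-force pair counting on ≤ 50-site windows, explicit
hypergeometric summation on ≤ 60-element universes, and whole-transcript
translation on 500 random transcripts. Recovery checks use the default
fixture above (sweeps), 20,000 sites × 50/50 diploids (drift parameter),
20 seeded replicates of a 30,000-site cohort (enrichment calibration),
and 100 samples over the 6.2-kb duplication at mean depth 12 (CNV).

## Known limitations

* Exactly two populations per scan; multi-way comparisons are separate
  runs.
* No haplotype statistics (iHS/XP-EHH-class), no composite-likelihood
  sweep model, and no LD-aware significance — the Bonferroni count treats
  overlapping windows as independent tests, which is conservative in
  count but ignores their 50% overlap.
* Consequence calling covers SNPs in CDS only (no splice or regulatory
  effects), with the standard nuclear code.
* Depth-based CNV genotyping assumes a single tandem duplication on a
  diploid background and uniform coverage apart from Poisson noise.
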