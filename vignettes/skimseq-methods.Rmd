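---
title: "Skim-sequencing dosage, introgression and genotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skim-sequencing dosage, introgression and genotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimseqr)
library(data.table)
```

# Overview

`skimseqr` analyses very low-coverage (0.01–1×) whole-genome sequencing of
large multiplexed plant populations. Three analyses share one primitive —
read counts in fixed genomic bins:

1. **Aneuploidy / dosage**: bin counts on a single reference reveal whole-
   chromosome and arm-level copy number.
2. **Introgression mapping**: bin counts on a concatenated two-species
   ("hybrid") reference partition reads between genomes; copy-ratio
   segmentation delimits translocation breakpoints.
3. **Sparse genotyping**: at sites where two parents differ, any read
   covering the site identifies the local haplotype of a progeny line.

This vignette describes the models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was open.

# Coverage and normalization

Pooled coverage of a multiplexed run is

$$\text{coverage} \;=\; \frac{\text{read count} \times \text{read length} \times 2}
{\text{genome size} \times n_{\text{samples}}},$$

where *read count* is the number of read pairs; `estimate_coverage()`
implements it, and `effective_depth_from_bin_mean()` inverts the same
arithmetic from an observed mean of pairs per bin
(e.g. 30.6 pairs per 1 Mb bin at 150 bp reads is 0.0092×).

Bin counts (`count_in_bins()`) default to **pairs counted once at the
leftmost mapped mate position** in 0-based half-open 1 Mb bins; per-record
("reads") counting is available and the unit is recorded in the output
metadata, since conventions differ between tools. Normalization
(`normalize_bin_counts()`) is

$$\text{norm} = \frac{\text{reads in bin}}{\text{total reads in sample}} \times F,$$

with $F = 10^7$ (reads per 10 million) by default, or alternatively
division by the sample's mean bin count (`mode = "mean_bin"`). The
per-sample total is the number of counted units *after* filtering, so
normalization reflects usable signal; callers may pass raw totals instead.

# Alignment filtering

Only uniquely mapped, concordant pairs carry dosage information at these
depths. A record is kept iff it is mapped, primary, non-supplementary, has
the proper-pair FLAG bit, and carries `NH:i:1` and `YT:Z:CP`
(`filter_unique_concordant()`). The tag criterion is definitional for the
spliced-alignment-disabled paired-end aligner this stack assumes; records
missing both tags are dropped with a warning rather than rescued from MAPQ,
because MAPQ semantics are aligner-specific. Down-sampling
(`downsample_fastq()`, `downsample_alignments()`) draws an **exact**
`round(fraction × N)` of templates without replacement under a required
seed, so coverage titrations (0.1× / 0.05× / 0.01×) are exactly sized and
reproducible; mates always travel together.

# Copy ratios and baselines

`compute_copy_ratio()` divides each bin's normalized count by an expected
disomic level. Two baselines are supported, differing in what they assume:

* **population_median**: per-bin median across samples, then a per-sample
  rescale so the genome-wide median ratio is 1. Absorbs bin-specific bias
  (mappability, truncated end bins) but is only valid when fewer than half
  of the samples share a dosage event on the chromosome.
* **self_genome_median**: the sample's own genome-wide median bin count
  (per unit bin width). Valid when most of that sample's genome is disomic;
  insensitive to what the rest of the population is doing.

The default `auto` uses the population baseline but switches to the self
baseline for any chromosome whose population-median density deviates more
than 20% (`deviation_threshold`) from the genome-wide level. The motivating
case is a monosomic-derived panel in which ~78% of progeny are monosomic
for the same chromosome: there the population median *is* the one-copy
level, and a euploid sample would otherwise be called trisomic. Blanks and
failed samples are excluded from population baselines.

# Dosage classification

Arm copy numbers are `round(2 × arm mean ratio)` clamped to 0–4, split at
the centromere (short arm = coordinates below the centromere). Classes
derive from the arm copies: (2,2) disomic, (1,1) monosomic, (0,0)
nullisomic, (3,3) trisomic, (0,≥1)/(≥1,0) telosomic of the covered arm,
(1,2)/(2,1) a monosome plus a telosome; anything else is `partial`.
Without a centromere only the whole-chromosome class is reported. Calls
whose doubled ratio falls within `band = 0.15` of a rounding boundary
(half-integers) are flagged low-confidence; the threshold is a design
choice — the karyotypes this mimics were originally read off plots by eye,
so the band simply encodes "too close to call".

Sample QC (`detect_failed_and_blank()`): blanks pass below 0.01%
(`blank_threshold = 1e-4`) of the mean non-blank total; non-blank samples
below 5% (`failure_fraction = 0.05`) of that mean are `failed`. The 5%
figure is our cutoff: a sample at a twentieth of the nominal 0.01×
coverage has roughly 1–2 pairs per monosomic arm-length region and arm
calls become guesswork.

Alien additions (`detect_alien_additions()`) are called per donor contig
from the fraction of bins whose ratio (against the background genome's
disomic level) exceeds `presence_threshold = 0.25`, i.e. half the
single-copy expectation: ≥80% of bins → `present`, 20–80% → `partial`
(a translocated or broken chromosome), otherwise `absent`.

# Segmentation and translocation calling

Copy-ratio tracks are piecewise-constant plus noise. `segment_bins()` uses
mean-shift binary segmentation: recursively split at the bin minimizing the
within-segment sum of squares, accepting a split iff its z-score reaches
`z_threshold = 4` and both sides have at least `min_seg_bins = 3` bins.
Three numerical details matter:

* **Noise scale.** The z-score uses a per-segment estimate: the MAD of
  lag-1 bin differences divided by √2. The few differences straddling true
  changepoints do not move the median, so the estimate is not inflated by
  the signal. When over half the differences are ties (runs of exactly-zero
  bins on absent chromatin) the MAD degenerates to zero and the plain sd of
  the differences is used instead; the whole-track estimate additionally
  floors the per-segment one, guarding small-sample underestimation.
* **Refinement.** On a track with two or more steps, the first binary cut
  is a least-squares compromise between the true boundaries, and the
  minimum-segment constraint can then block a one- or two-bin correction.
  After recursion, each cut is repositioned to the unconstrained
  least-squares optimum between its neighbours and cuts whose local z-score
  no longer clears the threshold are pruned, iterating to stability. With
  breakpoints on bin boundaries this recovers them exactly at 0.025×.
* **Masking.** A BED of known artifact bins (e.g. a mispositioned
  reference scaffold inside a translocated region) can be supplied; masked
  bins are excluded from segmentation and boundaries follow retained bins.

Segment states come from the rounded copy of the segment mean: absent (0),
hemizygous (1), normal (2), gain (>2). `pair_translocations()` pairs
recipient-genome loss segments with donor-genome gain segments of matching
dosage: absent + two-copy donor gain = homozygous, hemizygous + one-copy
donor gain = heterozygous; closest-length pairing breaks ties, and
unpaired losses/gains are reported as deletions/additions. Pairing by
dosage class is our stated rule for distinguishing a heterozygous
translocation from an independent hemizygous deletion plus addition.
`min_mb = 3` (three bins) is the reporting floor — far below the ~30 Mb
floor of cytological methods, preserving the resolution advantage.
Segregation of carriers in a backcross is tested with the 1-df Pearson
goodness-of-fit against 1:1 (`segregation_test()`).

# Parental SNPs and sparse genotyping

`discover_parental_snps()` is a counting/purity caller: a site is a
parental SNP when each parent's depth lies in `[min_dp, max_dp] = [6, 100]`,
each parent's major-allele fraction is at least `min_purity = 0.9`
(homozygosity proxy), the major alleles differ, and each parent's own
allele has at least `min_allele_depth = 3` reads. The depth bounds are
applied per parent. A genotype-likelihood caller is deliberately not used:
at ~8× parental coverage the purity rule is a transparent, adequate stand-in
and keeps the dependency surface small. With the default settings the
purity rule is the binding homozygosity filter (purity 0.9 at depth ≥6
already implies ≥5 supporting reads); `min_allele_depth` becomes active
when raised, or with permissive purity.

Progeny calls (`genotype_at_sites()`): reads supporting each parental
allele are counted; A-only → `A`, B-only → `B`, both → `het`, neither →
`missing`; third alleles are ignored but tallied. In a doubled-haploid
population `het` is retained purely as a contamination/error signal.

Haplotype blocks (`call_haplotype_blocks()`) use non-overlapping windows
(`window_bp` = 5 Mb) assigned to a parent given at least `min_markers = 3`
informative calls and a `majority = 0.8` vote; an unresolved run flanked by
the same resolved parent (or at a chromosome end next to a single resolved
neighbour) is absorbed into that block, and boundaries between discordant
blocks sit midway between the flanking informative markers. The windowing
is deliberately transparent — an HMM would squeeze out somewhat sharper
boundaries but hides its failure modes; the window is configurable.

# The synthetic-data generator

All fixtures are generated in code under a mandatory seed
(`simulate_bin_counts()`, `simulate_sam()`, `simulate_monosomic_panel()`,
`simulate_bc1_population()`, `simulate_dh_population()`,
`simulate_index_reads()`); every generator emits machine-readable truth.

The signal model is per-bin independent Poisson,

$$\lambda \;=\; \text{coverage} \cdot \frac{\text{bin width}}{2\,\ell} \cdot \frac{\text{copy}}{2},$$

with read length $\ell$, so simulated totals return the configured
coverage through the pooled-coverage equation. A negative-binomial
overdispersion hook exists but is off by default. The generator emulates:
copy-number karyotypes at arbitrary intervals, multimapper fractions in
tagged SAM (`NH:i:2` records the filter must remove), dual-index reads
with substitution errors and either i5 orientation (blanks get zero
reads), DH crossovers (Poisson count per chromosome, uniform breakpoints,
alternating phase) and marker observation at probability
$1 - e^{-\text{coverage}}$.

It does **not** emulate: GC or mappability bias, fragment-size
distributions, index hopping, duplicate reads, base-call errors in genomic
reads, or linkage between neighbouring bins' noise. Passing tests on
simulated data therefore demonstrate the correctness of the arithmetic and
the recovery behaviour of the estimators under the stated noise model —
not robustness to reference artifacts (which the masking mechanism
addresses operationally) or to library-preparation pathologies.

## Study-condition defaults

The generator defaults encode the conditions of the motivating wheat
panels: 1 Mb bins, 150 bp reads; an 864-sample monosomic panel at 0.01×
composed of 674 monosomic, 130 disomic, 35 long-arm telosomic, 1 short-arm
telosomic and 10 nullisomic lines plus 5 failed samples and 9 blanks (the
few published nullisomics carrying additional rearrangements are folded
into the nullisomic class, since compound classes are not part of the call
vocabulary); a 335-line BC1 at carrier probability 0.5; translocation
scenarios at 0.025× with breakpoints at wheat 7A 362–473 Mb / barley 7H
337–456 Mb and wheat 7D 340–559 Mb / barley 7H 337–610 Mb. The toy wheat
catalog uses approximate real pseudomolecule lengths (Mb-resolution) with
roughly realistic centromere positions; failed samples are simulated at 2%
of nominal coverage (comfortably under the 5% QC cutoff, as befits a
"failed library" rather than a marginal one).

# Problem sizes used in the test suite

The suite exercises full-scale panels where the claims are population-level
(the 864-sample × 21-chromosome aneuploidy panel; the 335-line BC1 on a
group-7 hybrid catalog) and Mb-scale toys elsewhere; DH genotyping runs on
three 300 Mb chromosomes with 10 kb marker spacing at 0.05× and 0.01×.
The whole suite completes in about a minute on one CPU; the acceptance
script (two translocation lines on a 2,781-bin hybrid catalog) in under
half a minute.

# Known limitations

* Breakpoint resolution is one bin (1 Mb by default); no split-read or
  junction-assembly refinement.
* The population baseline assumes shared events affect <50% of samples;
  `auto` handles the monosomic-panel violation but a population where
  *every* chromosome is aberrant in most samples would need explicit
  `self_genome_median`.
* The segmentation assumes piecewise-constant copy ratio; focal events
  shorter than `min_seg_bins` are invisible by construction.
* The purity-based SNP caller requires adequate parental depth; it is not
  suitable for discovering variants from skim-depth parents.
* No imputation: genotype output is sparse by design, and downstream users
  are expected to work with haplotype blocks rather than per-site calls.
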