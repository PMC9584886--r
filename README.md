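# skimseqr

Skim sequencing — very low-coverage whole-genome sequencing, typically
0.01–1× per sample — turns a single cheap multiplexed library into a
general-purpose genotyping and karyotyping assay for large plant
populations. At these depths individual variant calls are hopeless, but
read *counts* remain highly informative: binned read depth along a
reference genome reveals chromosome dosage (aneuploidy), and alignment to a
concatenated "in silico hybrid" of two species' assemblies partitions reads
between genomes and exposes alien introgressions and their breakpoints. At
sites where two parents of a biparental population differ, even a single
overlapping read identifies the parental haplotype.

`skimseqr` implements this analysis stack for R, aimed at breeders and
geneticists working with large cereal populations (the design points are
hexaploid wheat panels of hundreds to ~1000 multiplexed samples):

* **Demultiplexing** of combinatorial dual-index libraries (one i5 per
  plate, one i7 per sample), with automatic i5 orientation detection,
  ambiguity rejection, and blank-well QC.
* **Alignment filtering** to uniquely mapped concordant read pairs via the
  SAM tags `NH:i:1` and `YT:Z:CP`, plus exact-count seeded down-sampling
  for coverage titrations.
* **Binned read counts**: raw and normalized counts per 1 Mb bin,
  per-chromosome densities, and pooled-coverage arithmetic.
* **Karyotyping**: copy ratios against a population or self baseline, and
  whole-chromosome / arm-level dosage classes (disomic, monosomic,
  nullisomic, trisomic, telosomic, monosome-plus-telosome), alien
  chromosome addition detection, karyogram plots.
* **Introgression mapping**: mean-shift binary segmentation of copy-ratio
  tracks, pairing of recipient losses with donor gains into translocation
  calls with zygosity, and 1:1 segregation chi-square tests.
* **Sparse genotyping**: parental SNP discovery under depth/purity filters,
  single-read progeny genotyping, and windowed haplotype-block assignment.
* **A synthetic-data generator** for all of the above, with machine-readable
  ground truth (Poisson read counts under arbitrary copy-number karyotypes,
  tagged SAM output, index-read FASTQs, DH/BC1 populations).

## The model in brief

Pooled genome coverage of a multiplexed run is estimated as

    coverage = (read count × read length × 2) / (genome size × n samples)

with read count in pairs (the ×2 counts both mates). Read counts per 1 Mb
bin are normalized per sample as

    norm = reads in bin / total reads in sample × F,        F = 10⁷ by default

(or divided by the sample's mean bin count). Copy ratio is a bin's
normalized count over the expected disomic baseline — ~1 for two copies,
~0.5 for one, ~0 for none. Segmentation models the ratio track as
piecewise-constant: recursive binary splits at the least-squares optimum,
accepted when the mean-shift z-score (noise scale = MAD of lag-1
differences / √2) exceeds a threshold, followed by boundary refinement.
The simulator draws bin counts as Poisson with mean
`coverage × bin / (2 × read length) × copy/2`, so simulated totals return
the configured coverage through the equation above.

## Worked example: mapping a wheat–barley translocation

A homozygous 7AS.7HL-7AL line carries a barley 7H segment in place of part
of wheat chromosome 7A. Simulating such a line at 0.025× on a hybrid
wheat+barley catalog and running the pipeline:

```r
library(skimseqr)

hybrid <- genome_catalog(
  contig_id     = c("wheat_chr7A", "wheat_chr7B", "wheat_chr7D", "barley_chr7H"),
  length_bp     = c(736e6, 750e6, 638e6, 657e6),
  source_genome = c("wheat", "wheat", "wheat", "barley"))

kary <- sim_karyotype(                      # ground truth for the simulation
  contig_id   = c("wheat_chr7A", "barley_chr7H", "barley_chr7H", "barley_chr7H"),
  copy_number = c(0, 0, 2, 0),
  start_bp    = c(362e6, 0,      337e6, 456e6),
  end_bp      = c(473e6, 337e6,  456e6, 657e6))

x <- simulate_bin_counts(kary, hybrid, coverage = 0.025, seed = 11)
x <- normalize_bin_counts(x)
profile  <- compute_copy_ratio(x, baseline = "self_genome_median")
segments <- segment_profile(profile)
calls    <- pair_translocations(segments, hybrid, "wheat", "barley")
calls[type == "translocation",
      .(designation, zygosity, recipient_loss_mb, donor_gain_mb)]
#>                                      designation   zygosity recipient_loss_mb
#> 1: wheat_chr7A:362-473Mb<-barley_chr7H:337-456Mb homozygous               111
#>    donor_gain_mb
#> 1:           119
```

The 111 Mb wheat loss and 119 Mb barley gain are recovered to the exact
bin. Carrier counts in a backcross population are tested against 1:1
segregation:

```r
st <- segregation_test(169, 166)
sprintf("chi-square = %.4f (df = %d), P = %.2f", st$chi_square, st$df, st$p_value)
#> "chi-square = 0.0269 (df = 1), P = 0.87"

estimate_coverage(485575828, 150, 15e9, 384)   # pooled coverage of a 384-plex run
#> 0.02529041
```

## Scope notes

The package consumes aligner output (SAM/BAM); it does not align reads or
trim adapters. Parental SNP discovery uses a counting/purity caller rather
than a genotype-likelihood model, which is adequate at the ~8× parental
coverages the filters assume. See the methods vignette
(`vignettes/skimseq-methods.Rmd`) for the full model description, parameter
defaults, and limitations.
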