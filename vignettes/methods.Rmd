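---
title: "Methods: models, parameters and design choices in flockdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in flockdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flockdiv` reconstructs, as a single tested pipeline, the analysis design
used in SNP-array surveys of livestock breeds: quality control and
relatedness pruning, within-breed diversity, runs of homozygosity (ROH)
and genomic inbreeding, linkage-disequilibrium-based effective population
size, and between-breed structure.  This vignette documents the statistics
it computes, the defaults it ships with and why, the design choices made
where the methods literature leaves room, and what the built-in simulator
does and does not establish.

## Genotype model and quality control

All statistics operate on a `genotypes` container: an n × S integer dosage
matrix (copies of `allele_b`; `NA` = missing), a SNP map sorted by
position within each chromosome, and one population label per sample.
Coordinates are 1-based inclusive (PLINK convention).  When two array
panels are merged, only SNPs present in both are kept; allele pairs are
matched explicitly, a swapped pair flips dosage 0↔2, and anything else —
including strand-ambiguous A/T and C/G conflicts — is dropped and logged
rather than guessed, because array manifests within one platform share a
strand convention and silent strand flips corrupt every downstream
frequency.

QC applies four filters in a fixed, reported order: (1) samples with
missing rate > 0.10; (2) non-autosomal SNPs (autosomes 1–26 for sheep,
configurable); (3) SNPs with call rate < 0.90; (4) SNPs with MAF < 0.05,
computed on the samples retained at step 1 from non-missing calls only.
The order is a design choice — the criteria themselves do not imply one —
fixed so that removal counts are reproducible; sample filters run first so
that a bad sample cannot drag SNPs below the call-rate or MAF thresholds.
Intensity-level QC (GenCall/GenTrain scores) requires raw intensities and
is out of scope for genotype-only inputs.

Relatedness pruning uses the unified additive relationship (UAR/GRM)
estimator: off-diagonals average (x<sub>ij</sub>−2p<sub>i</sub>)(x<sub>ik</sub>−2p<sub>i</sub>)/(2p<sub>i</sub>q<sub>i</sub>)
over SNPs non-missing in both individuals; diagonals use the
same-individual form 1 + mean[(x²−(1+2p)x+2p²)/(2pq)].  Two estimator
facts worth knowing (both asserted in the tests): the diagonal and the
off-diagonal of a duplicated individual are *different* estimators of
1 + F that agree only in expectation, and with allele frequencies
estimated from the sample itself, off-diagonals of an unrelated panel
center on −1/(n−1), not 0.  Pruning at relationship > 0.35 is greedy by
degree: the sample in the most above-threshold pairs goes first (ties:
larger mean relatedness among its offending pairs, then input order).
The survey literature states the threshold but not which member of a pair
was dropped; max-degree removal minimizes the number of animals removed
in family clusters and is deterministic.

## Diversity

Per population: observed heterozygosity is the per-locus fraction of
non-missing genotypes that are heterozygous, averaged over loci; unbiased
expected heterozygosity is Nei's small-sample estimator
(2n/(2n−1))(1−Σp²) with n the locus-wise non-missing count (loci with
n < 2 are skipped and counted); rarefied allelic richness is the
hypergeometric expectation Σₐ[1−C(2N−Nₐ,g)/C(2N,g)] of distinct alleles
in a standardized draw of g gene copies, computed with `lchoose` for
stability, with `g = "auto"` meaning the smallest per-population,
per-locus non-missing gene count so that every locus is usable in every
population (the surveyed studies do not print their rarefaction count;
`auto` documents ours in the output).

F<sub>IS</sub> is defined as 1 − H̄ₒ/H̄ₑ₍ᵤ₎ on locus-*mean*
heterozygosities (ratio of means, not mean of per-locus ratios): the
literal reading of "inbreeding coefficient based on unbiased expected
heterozygosity", and numerically stable when individual loci have
near-zero Hₑ.  Confidence intervals are a percentile bootstrap over loci
(default 1000 replicates, seed exposed and recorded); resampling loci
treats individuals as the fixed design and loci as the sampling units,
which matches how these CIs behave in the field's packages (width shrinks
with locus count — a property the tests check at 100 vs 10,000 loci).

## Runs of homozygosity and F<sub>ROH</sub>

Detection is window-free ("consecutive runs"): per individual and
chromosome, a run is a maximal stretch of consecutive SNPs containing at
most `max_het` heterozygous (default 1) and `max_missing` missing
(default 1) calls, with at least `min_snps` SNPs, spanning at least
1000 kb.  Three conventions the literature leaves open are fixed here and
tested:

* runs must start and end on homozygous SNPs — otherwise a trailing het
  or missing call could inflate run length arbitrarily;
* run length is `end_bp − start_bp` of the terminal SNPs (no +1, no
  flanking extension) — the simplest defensible reading, stated so counts
  are reproducible;
* overlapping candidate runs sharing a het/missing allowance are resolved
  by a greedy left-to-right scan, ties toward the longer run, so reported
  runs are maximal and non-overlapping.

The detector is implemented as a linear-time sliding-window scan; its
contract is *exact equality with brute-force enumeration of all maximal
qualifying intervals*, which the acceptance suite verifies on 200 random
panels.

The minimum SNP count l = ⌈ln(α/(nₛnᵢ))/ln(1−het)⌉ (α = 0.05) bounds the
expected number of chance runs across the whole dataset; one genome-wide l
is used for a merged panel.  F<sub>ROH</sub> is the summed length of runs
at or above a floor (1, 5, 10 Mb) divided by the autosomal SNP coverage;
the default denominator 2.44 Gb is the sheep autosomal coverage constant
used verbatim in the survey literature (whether it excludes inter-SNP
gaps is unstated there; we do not re-derive it).  Length classes use
half-open bins [1,2), [2,4), [4,8), [8,16), [16,∞) Mb — lower edge
inclusive, so a 2.0 Mb run is "2–4 Mb".

## LD-based effective population size

For each population, r² is the squared Pearson correlation of dosage
vectors (Rogers–Huff style — appropriate for unphased array data) over
individuals non-missing at both loci, for same-chromosome pairs binned by
physical distance.  Bin edges are constructed in t-space so that the
conventional reporting points t = 5 and t = 50 generations ago are exact
bin representatives (t = 1/(2c)).  Each correction is an explicit,
configurable step rather than a monolithic reimplementation of any one
tool, because the published tool chains do not print their internal
correction order:

* sample size: r²adj = r² − 1/(βn), β = 1 for unphased dosages
  (default), 2 for phased haplotypes; floored at a small ε with a
  warning;
* map function: linear at 0.01 M/Mb (1 cM/Mb), or Sved–Feldman
  c = d/(1+2d) applied to the linear map distance; both capped below 0.5;
  the mapping used is echoed in the output metadata;
* mutation: Nₑ(t) = (1/(4c))(1/r²adj − α) with α = 2.2.

Bins need ≥ 50 pairs by default; non-positive Nₑ points are dropped with
a warning.  `ne_at_generation` returns the nearest trajectory point
(ties to the smaller t) and reports the achieved t, warning beyond a 2×
mismatch.  Whether within-breed MAF filtering preceded pair enumeration
in the surveys is unstated; we filter at MAF ≥ 0.05 within the population
by default and expose the knob.

## Structure

Pairwise FST is Weir & Cockerham's θ from the two-level variance
components a (among populations), b (among individuals within) and c
(within individuals), combined across loci as Σa/Σ(a+b+c)
(ratio of sums — the estimator's standard multilocus combination), with
negative per-locus components retained to preserve near-zero
unbiasedness.  Loci monomorphic across both populations or with fewer
than two genotypes in either are excluded.  IBS distance is
1 − shared alleles/(2 × loci compared) on pairwise-complete loci.
Classical MDS is Torgerson double-centering of −d²/2 with coordinates
scaled by √eigenvalue and explained fractions over the positive spectrum;
PCA centers by 2p, mean-imputes missing dosages, optionally applies
Patterson scaling 1/√(p(1−p)) (monomorphic loci excluded there), and uses
the SVD.  Mean imputation (PCA) versus pairwise-complete loci (IBS/MDS)
is deliberate: imputation keeps the PCA design matrix complete without
biasing locus means, while IBS is defined naturally on observed pairs;
both conventions are recorded in output metadata.  Neighbor-Net,
ADMIXTURE and TreeMix are deliberately *not* reimplemented — the package
exports their input formats (PHYLIP/NEXUS distances, PLINK, per-population
allele counts) because re-deriving those algorithms is out of proportion
to their role in a survey pipeline.

## The simulator: what it emulates and what a green test establishes

The generator is a discrete-generation Wright–Fisher gene-dropper with an
explicit pedigree shared across chromosomes: founder haplotypes carry
unique ids, each meiosis recombines parental haplotypes under a Poisson
crossover process on a uniform 1 cM/Mb map (matching the Nₑ module's
default, so Nₑ recovery is internally consistent), populations branch
from a common ancestral population and drift at stated per-generation
sizes, and pedigree loops (half-sib F = 1/8, full-sib F = 1/4, selfing
proxy F = 1/2) are grafted onto the final generation.  Because haplotypes
are founder-id mosaics, the true autozygous tracts (both copies descending
from the same founder haplotype) are read off exactly, and genotypes
follow by assigning founder alleles from a truncated-uniform MAF spectrum
— array SNPs are ascertained toward common variants, so a uniform
spectrum above a floor is closer to array reality than a neutral site
frequency spectrum.  Missingness is uniform at random.

Defaults mirror the survey regime: 26 autosomes of 94 Mb (≈ 2.44 Gb),
~1480 SNPs per chromosome (~38k total), five populations of
31/31/30/13/24 samples in the study-shaped fixture, branch Ne 120–600
with a star split 16 generations back from an ancestral population of
800 (50 burn-in generations), giving pairwise FST ≈ 0.01–0.07, and
half-sib loops in one population.  The ancestral MAF floor of 0.09 keeps
the merged panel largely intact through the 0.05 MAF filter despite
drift; this calibration (like the FST band) is part of the fixture's
stated contract and was set by measuring the fixture itself, not any
downstream test.

What the simulator does **not** emulate: genotyping error beyond uniform
missingness, array-specific cluster artifacts, non-uniform recombination
maps, selection, gene conversion, overlapping generations, or mutation.
A green recovery test therefore establishes that an estimator inverts the
idealized Wright–Fisher process it assumes — not that it is robust to
array artifacts or demographic features outside that model.  In
particular the α = 2.2 mutation adjustment in the Nₑ formula is a
literature calibration; the constant-Nₑ acceptance test shows the whole
chain recovers a known Nₑ = 200 within its stated band, which validates
the pipeline's internal consistency, not the adjustment's universality.

## Numerical and scale choices

* Rarefaction uses log-binomials (`lchoose`), so C(n,k) with k > n
  cleanly contributes probability 0.
* The bootstrap and the simulator save and restore the caller's RNG
  state; all seeds are explicit arguments recorded in outputs.
* The pipeline writes a JSON manifest (parameters, seeds, stepwise
  counts) with no timestamps, so identical configurations produce
  byte-identical outputs — the reproducibility gap this package is built
  to close.
* Acceptance-test scales: the constant-Nₑ run uses a 250-generation
  burn-in, chosen a priori as ≈ 3× the slowest LD equilibration time
  constant (2c + 1/(2N) at c = 0.005, N = 200); the bottleneck replicates
  use a 6-chromosome genome because only the Nₑ₅ < Nₑ₅₀ ordering is
  asserted there; the half-sib F<sub>ROH</sub> recovery uses ~31k SNPs so
  the minimum-SNP threshold l corresponds to ≈ 3 Mb and truncates little
  of the exponential (mean ≈ 25 Mb) autozygous tract mass.
* The empty-result degenerate cases (all SNPs QC-removed, no usable FST
  loci, all Nₑ points non-positive, a sample pair with no comparable
  loci) are explicit errors naming the offending object, never silent
  NAs.

## Known limitations

* PED files carry no allele declaration, so at a locus where only one
  allele is observed the counted allele is unrecoverable; the reader
  assigns alleles lexicographically and round-trips are exact only for
  loci with both alleles observed (BED round-trips are always exact).
* The Weir–Cockerham implementation is biallelic (array SNPs); the
  rarefaction formula is written generically but the container is
  biallelic throughout.
* LD-based Nₑ at very recent times depends on long-range bins where pair
  counts are thin on short chromosomes; the minimum-pair filter flags
  rather than repairs this.
* Greedy relative pruning and greedy run selection are deterministic but
  not globally optimal; both choices are documented above and enforced by
  tests, so alternative conventions would be a deliberate, visible
  change.
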