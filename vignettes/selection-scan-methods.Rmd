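---
title: "Methods: diversity estimators, the theta-pi-ratio x Fst scan, and the breeding simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity estimators, the theta-pi-ratio x Fst scan, and the breeding simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatchscan)
```

## The problem

Closed hatchery lines of high-fecundity marine invertebrates adapt to
laboratory culture within a handful of generations. Two forces reshape
their genomes: genetic drift, amplified by the modest number of breeders
and by the "sweepstakes" variance in family size typical of broadcast
spawners, and selection imposed by the culture environment (density,
diet, temperature, handling). `hatchscan` implements the standard
population-genomic workflow for separating the two from SNP genotypes of
successive generations: genome-wide diversity and differentiation
estimators to quantify drift, and a windowed diversity-ratio-by-Fst scan
to localize selection.

## Estimators

All estimators work on a `genotype_matrix`: diploid alt-allele dosages
(0/1/2, `NA` missing) with locus coordinates and per-sample generation
labels, read from VCF (GT field) or a dosage TSV. Before analysis,
`filter_dataset()` applies the usual marker QC in a fixed order — sample
call rate, then locus call rate among retained samples, then minor
allele frequency recomputed on the survivors — with strict inequalities
(defaults: keep call rates > 0.9 and MAF > 0.05). The order matters only
at stage boundaries, so permuting samples never changes the surviving
set; MAF is pooled across generations by default because filtering
precedes the per-generation analyses (a per-generation mode exists via
`maf_per_generation = TRUE`, keeping loci common in at least one
generation).

Per locus and population, `locus_statistics()` reports p, MAF, observed
heterozygosity and He = 2p(1-p) from called genotypes only; a population
with nothing called at a locus is flagged `NA`, never zeroed.
`individual_inbreeding()` is the method-of-moments excess-homozygosity
statistic F = (O - E)/(L - E) with the unbiased expected homozygosity
1 - 2pq n/(n-1); the population Fis we headline is the mean individual
F (a per-locus aggregate 1 - Ho/He is also available in the locus
table, since either convention appears in published tables).

Windowed statistics use a sliding grid of 40 kb windows with 20 kb
steps (the convention for this kind of scan); `make_windows()` keeps
full windows while they fit and appends one truncated window when the
last full window stops short of the contig end, so the grid tiles every
base. Nucleotide diversity per site is the unbiased pairwise estimator
2 c_ref c_alt / (n (n-1)) over called allele copies; `window_pi()`
divides the window sum by window *length* in bp, not by callable sites
— that is what makes magnitudes comparable with RAD-density published
values (~2e-5 per bp at ~1 SNP / 40 kb). Tajima's D uses the 1989
constants; because missingness makes n vary between sites, each window
uses the modal called-copy count among its segregating sites (sites
with other n still contribute to S and the diversity sum). Windows with
S = 0 or n < 3 are undefined and excluded from averages.

Differentiation is the Weir & Cockerham (1984) two-population moment
estimator computed from observed genotype and heterozygote frequencies;
per-locus variance components a, b, c are retained, and window or
genome estimates are ratios of sums (sum a / sum(a+b+c)), never means of
per-locus ratios. Negative estimates are kept as computed: truncating
them would bias ranking in the scan's empirical-quantile step.

Structure and linkage: the genomic relationship matrix is the
allele-frequency-standardized cross-product with pairwise-complete
missing handling; PCA takes its top eigenpairs, with variance fractions
eigenvalue/trace and a fixed sign convention (largest-magnitude loading
positive) for reproducibility. The tree is Saitou-Nei neighbor joining
on identity-by-state distances with bootstrap-over-loci support; we use
NJ rather than a likelihood tree because the tree's only role here is
to display clustering of generations, and NJ over IBS is deterministic
and directly testable against closed forms. IBS counts shared alleles
as 2 - |x_i - x_j| per co-called locus, so identical genotypes —
including two heterozygotes — are at distance zero; this preserves the
metric identity property that the duplicate-sample checks rely on.
LD decay is the squared Pearson correlation of dosages (composite LD;
genotypes are unphased) for same-chromosome pairs within 50 kb, binned
by distance.

## The selection scan

The scan contrasts an ancestral population (G0) with a derived one
(G6 by default) on the shared window grid:

* theta-pi ratio: log2(pi_ancestral / pi_derived), oriented so that
  diversity *loss* in the derived line is positive. The orientation is
  recorded in the run manifest and configurable.
* windowed Fst as above.

Windows with zero diversity in either population or undefined Fst are
marked unusable with a reason code and excluded from threshold
estimation. Thresholds are empirical quantiles over usable windows at
tail probability q = 0.05, computed with the linear-interpolation
convention (`stats::quantile` type 7) so published cutoffs can be
reproduced exactly from the window table. Classification is strict:
positive means ratio above the upper ratio quantile *and* Fst above the
upper Fst quantile; negative means ratio below the lower quantile with
the same Fst condition. Runs of overlapping or bookended same-class
windows merge into candidate regions; both granularities (significant
window counts and merged region counts) are reported because published
region counts are ambiguous between the two. Significance is a
permutation test that relabels samples between the two populations,
preserving group sizes, and recomputes the window's weighted Fst;
p = (1 + #exceedances)/(B + 1) can never be zero. By default only the
Fst is permuted — the ratio already enters through the empirical
thresholds — but a joint-exceedance mode (both the Fst and the
magnitude of the log2 ratio must reach their observed values) is
available via `statistic = "joint"`.
Genes annotate to regions by >= 1 bp overlap against GFF3/BED gene
intervals, deduplicated per class.

## The breeding simulator

`sim_config()` describes the experiment the package is designed for: a
closed line bred from a founder pool with discrete, non-overlapping
generations, mass spawning with a fixed number of dams and sires, and
viability selection on the offspring. Defaults are chosen once to match
that study design at desk scale:

* 200 founders; census 180 per offspring generation; 87 dams and 93
  sires per generation, i.e. every individual of an offspring
  generation breeds. With equal expected contributions this is exactly
  the two-sex Wright-Fisher model with Ne = 4 Nf Nm / (Nf + Nm) = 179.8,
  which makes the drift calibration checks sharp.
* 7 generations, labelled G0..G6; 50 individuals genotyped per
  generation (published panels of this kind genotype 44-69).
* A scaled-down genome of 19 chromosomes x 4 Mb x 1 Morgan carrying
  2,000 SNPs: this preserves the RAD marker density of roughly 1 SNP
  per 40 kb (one marker per scan window) of a ~22k-SNP panel on a
  ~900 Mb genome, which is the quantity the window scan is sensitive
  to. Haldane recombination (Poisson crossovers, uniform positions, no
  interference).
* Founder alternate-allele frequencies uniform on (0.05, 0.5) —
  post-QC RAD panels exclude rarer alleles; ref/alt pairs are drawn
  from the empirical transition/transversion spectrum of bivalve RAD
  panels (Ts/Tv about 1.25), so the spectrum summaries are realistic.
* Selected loci default to founder frequency 0.5 ("selection on common
  standing variation"): over only six transitions, viability selection
  of realistic strength cannot lift a rare allele far enough to leave a
  diversity signature, so the interesting regime is a common variant
  swept toward fixation.
* Genotype fitness (1, 1+hs, 1+s) applied by rejection sampling on
  offspring — viability rather than fertility selection, the simplest
  mechanism that produces sweep-like Fst and diversity signatures.
* Optional reproductive skew: per-parent contribution weights drawn
  from a symmetric Dirichlet with concentration `skew_alpha`
  (infinite = equal), emulating sweepstakes reproduction; 2%
  genotype missingness.

The generator records full truth: per-generation allele-frequency
trajectories at every locus, the selected loci with (s, h), and
parental contribution variances (a realized-Ne proxy).

What it does *not* emulate: mutation during the experiment (standing
variation only, appropriate to a 7-generation span), overlapping
generations, linked-read or haplotype-level data, genotyping error
beyond missingness, and background selection. Passing the simulation
checks therefore demonstrates correctness of the estimators and the
scan under drift and single-locus viability selection, not robustness
to every property of real RAD data.

## Numerical choices and degenerate inputs

Empirical quantiles are type 7; all threshold comparisons strict, so a
degenerate scan in which every window is identical classifies nothing.
Monomorphic windows have pi = 0 exactly and undefined D and Fst.
Filtering that empties the dataset is a hard error naming the stage.
The permutation test refuses B < 19 (cannot resolve p < 0.05).
Eigen-sign and quantile conventions, the window grid, and every seeded
resampling step make a full pipeline run byte-identical under a fixed
seed; `run_full_scan()` writes the seed, the configuration, and the
ratio orientation into its manifest.

## Validation scale and known limitations

The test-suite simulations use the default desk-scale conditions: 100
neutral replicates for the drift calibration (mean expected
heterozygosity tracks He0 (1 - 1/(2 Ne))^t within three standard
errors, and Fst(G0, Gt) rises with t), 10 replicates with five selected
loci (s = 0.8, h = 0.5) for sweep recovery, and 500 windows at B = 199
for permutation uniformity.

The main known limitation is statistical, not numerical: with s = 0.8,
h = 0.5 and six transitions, the deterministic selection recursion
takes a common allele from 0.5 only to about 0.87, and drift around
that endpoint is wide at Ne about 180. The per-locus diversity ratio at
such an endpoint is modest, and any neutral marker sharing the window
dilutes it further, so the positive class recovers only roughly half of
the truth loci under these conditions rather than the large majority
one might hope for; recovery approaches completeness only when the
swept allele nears fixation (stronger or longer selection, or dominant
fitness effects). The scan's false-positive behaviour is also slightly
above the independence baseline q^2, because the ratio and Fst of a
window respond to the same allele-frequency displacement and are
therefore positively correlated under pure drift, particularly in
one-marker windows. Both behaviours are measured by the test suite and
should be kept in mind when interpreting region counts on real data.
The Tajima's D of simulated panels is positive by construction (the
founder frequency law excludes rare alleles), which mirrors the
ascertainment of post-QC RAD panels rather than neutral-equilibrium
sequence data.
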