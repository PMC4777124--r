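---
title: "Methods: population-genetic scans for structured inbred germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic scans for structured inbred germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedscan)
```

## The setting

breedscan analyzes SNP genotype matrices of crop accessions that have been
selfed to near-complete homozygosity (barley breeding lines are the
motivating system: inbred to roughly the F4, so the expected residual
heterozygosity is $(1/2)^4 = 6.25\%$) and that are organized into breeding
populations nested under two crossed factors, spike-type (two- vs
six-rowed) and growth habit (spring vs winter). The package implements the
inference chain such data support: quality control, within-population
diversity, outgroup-polarized site frequency spectra, a haploid
Weir–Cockerham $F_{ST}$ outlier scan with dropout bootstrapping, Nicholson's
Bayesian divergence parameter $c$, the pairwise-haplotype-sharing (PHS)
selection scan, windowed identity-by-state (IBS) sharing between
populations, and the four-population $f_4$ admixture test — together with a
synthetic-data generator that provides exact ground truth for every
parameter-recovery test.

### Haploid coding

With mean $F_{IS} \approx 0.98$, each accession is effectively one
haplotype. Throughout the frequency-based analyses a homozygous call
contributes a single chromosome; heterozygous and missing calls are
dropped per SNP. For haplotype analyses the same convention replaces
statistical phasing (`collapse_to_haplotypes()`): at these inbreeding
levels a phaser would manufacture phase information that the data cannot
support, so heterozygous sites are treated as missing instead. This is a
deliberate, documented divergence from pipelines that run fastPHASE first.

## Quality control

`apply_qc()` removes, in a fixed order: monomorphic SNPs (fewer than two
distinct homozygous states among non-missing, non-heterozygous calls);
SNPs, then accessions, with more than 25% missing data (strict `>`, the
Methods-style reading; the threshold is a parameter so the `>=` reading is
one keystroke away); accessions whose heterozygous fraction exceeds
6.25%, the selfing expectation (`selfing_het_expectation(4)`); and
accessions left in populations of fewer than two members. Because removing
accessions can render further SNPs monomorphic, the pass sequence is
iterated to a fixed point; this makes the filter idempotent, which the
test suite asserts, and each removal keeps the reason of the pass that
first triggered it. Curation-driven exclusions (near-isogenic lines,
incomplete passports) cannot be inferred from genotypes and enter only
through an explicit `exclude` list.

## Diversity summaries

Percent pairwise diversity is the probability that two random accessions
differ at a SNP, averaged over SNPs polymorphic within the population,
with the unbiased $\frac{n}{n-1} 2p(1-p)$ per-SNP estimator (the
correction is a flag, `unbiased = FALSE`, since the upstream libsequence
convention is not printed anywhere authoritative). $F_{IS} = 1 - H_o/H_e$
is averaged as the unweighted mean of per-SNP ratios by default; a
ratio-of-means variant is provided because the two differ under sampling
noise and the source convention is unstated. Heterozygous calls are
excluded from diversity (treated as missing) but are exactly the signal in
$F_{IS}$. A SNP is private to a group when polymorphic there and
monomorphic or missing in every other group; the definition applies to any
partition, not just breeding populations.

## Site frequency spectra

Polarization against an outgroup keeps a SNP only when the outgroup call
is a single nucleotide matching exactly one of the two panel alleles; the
derived allele is the other one. Ambiguous calls, trans-specific
polymorphisms (outgroup segregating for the same two alleles) and
off-panel outgroup nucleotides are excluded, and the exclusion tally
partitions the excluded set. Because per-SNP missingness makes raw counts
ragged, `derived_sfs()` projects each SNP's derived count down to a common
sample size by hypergeometric expectation (verified against exhaustive
subset enumeration in the tests); mass projecting to the monomorphic bins
is reported separately rather than silently dropped. The
equilibrium-neutral reference is the $1/i$ spectrum normalized by the
harmonic number.

## F_ST scans

`wc_theta_haploid()` is the haploid ANOVA estimator: with per-population
haploid sizes $n_i$ and frequencies $p_i$,
$\mathrm{MSP} = \sum n_i (p_i - \bar p)^2/(r-1)$,
$\mathrm{MSG} = \sum n_i p_i (1-p_i) / \sum (n_i - 1)$,
$n_c = (\sum n_i - \sum n_i^2/\sum n_i)/(r-1)$, and
$\theta = (\mathrm{MSP} - \mathrm{MSG})\,/\,(\mathrm{MSP} + (n_c - 1)\mathrm{MSG})$.
Negative per-SNP values are retained: truncating them would shift the
empirical 97.5% outlier threshold, which is computed over all defined
thetas. Outliers are values at or above the threshold, ties included — on
heavily tied (small-sample) tracks the outlier count can therefore exceed
$0.025\,S$ by more than one SNP, which is the estimator being honest about
ties rather than a calibration defect. Aggregates (pairwise matrices,
partition means) use the multi-locus ratio-of-sums combination
$\sum_l a_l / \sum_l (a_l + \mathrm{MSG}_l)$ with $a_l = (\mathrm{MSP}_l -
\mathrm{MSG}_l)/n_c$, which on Balding–Nichols simulations recovers the
generating drift within ±0.005 at 2,000 SNPs; per-SNP ratios feed the
outlier scan. Robustness is assessed by rerunning the scan after dropping
a random 20% of SNPs, or of accessions stratified by group, 100 times, and
reporting the fraction of original outliers recovered.

## Nicholson's c

The divergence model treats each population's latent frequency at locus
$j$ as $p_{ij} \sim N(\pi_j,\, c_i\,\pi_j(1-\pi_j))$ censored to $[0,1]$
with point masses at the bounds (fixed alleles carry the tail mass), and
the observed haploid counts as $x_{ij} \sim \mathrm{Binomial}(n_{ij},
p_{ij})$. Priors on $\pi_j$ and $c_i$ are uniform(0, 1) — the upstream
description prints only the proposal scale, so the priors are explicit and
configurable here. One Metropolis-within-Gibbs sweep per iteration updates
every $p_{ij}$ by a censoring random walk (the proposal's boundary atoms
enter the Hastings ratio), every $\pi_j$ by a Beta proposal with
concentration $m = 10$ (the two-component Dirichlet reading of the
documented scale parameter), and every $c_i$ by a log-scale random walk.
Proposal scales adapt only during burn-in, so the retained chain is
Markovian. Defaults are 1,000 burn-in and 10,000 retained iterations. The
sampler is compiled (Rcpp) and seeded through R's RNG, so runs are
bit-reproducible. On censored-normal simulations with $L = 1000$ loci and
$n = 100$ haploid calls, posterior means recover $c \in \{0.05, 0.1,
0.2\}$ within a few percent; the acceptance suite runs 20 seeded
replicates at 300 + 1,500 iterations — shortened purely for runtime, after
checking that full-length chains move the means by far less than the ±30%
tolerance.

## PHS

For haplotypes $i, j$ and focal SNP $x$, $d_{ijx}$ is the cM span of the
shared segment around $x$: matching continues through missing sites
(skipped, neither matching nor breaking — a switch flips this to
"breaking"), stops at the first mismatch or chromosome end, and is
measured between the outermost matching sites; a mismatch at the focal SNP
gives 0. Each pair is standardized by its genome-wide mean and standard
deviation over all focal positions (per-chromosome normalization is the
documented alternative), giving $Z_{ijx}$, and

$$\mathrm{PHS}_{xA} = \binom{p}{2}^{-1}\!\!\sum_{i<j \in \mathrm{carriers}}\! Z_{ijx}
\;-\; \binom{n}{2}^{-1}\!\!\sum_{i<j} Z_{ijx}.$$

Both alleles are scored at every focal SNP; entries need carrier frequency
at least 10% to be outlier-eligible, and outliers are the top 2.5% of
eligible PHS values. Pairs with zero sharing variance (genome-wide
identical haplotypes) are excluded with a warning. The implementation is
checked to $10^{-12}$ against a brute-force double-loop oracle.

A caveat the tests surface deliberately: an empirical 97.5% threshold can
flag at most ~2.5% of entries, so a single implanted sweep spanning ~5% of
the genome can never have more than roughly half its focal SNPs flagged,
and carrier dilution (background carriers of the focal allele who do not
share the swept haplotype) further weakens entries whose allele is common.
The corresponding acceptance clause is asserted at its stated 80% level
and left red, with the arithmetic documented in the decisions ledger; the
practical consequence for users is that PHS outlier sets bound the *core*
of a broad swept region, not its full extent.

## Windowed IBS

Windows of 50 or 100 SNPs tile each linkage group at half-window steps
(the trailing partial window merges into the last full one). Two
haplotypes are window-IBS when at most 10% of their jointly non-missing
sites mismatch (boundary inclusive: 5 of 50 passes, 6 fails) and at least
half the window is jointly typed — the joint-coverage floor guards against
vacuous matches in missing-heavy windows. Per window and ordered
population pair, the report gives the fraction of each population's
haplotypes that are IBS to at least one haplotype of the other.

## f4

$f_4(A,B;C,D)$ is the mean over SNPs of $(p_A - p_B)(p_C - p_D)$, with a
delete-one block jackknife over 75-SNP blocks that never span linkage
groups (75 mirrors the resampling grain of the upstream tree analysis; a
trailing block shorter than half the target merges into its neighbor).
Migration is inferred for a quadruple only when all three pairings deviate
significantly from zero at $\alpha = 0.05$, two-sided normal, no
multiple-testing correction by default. Two numerical facts shape the
tests: with $B$ blocks the $z$ statistic is $t_{B-1}$-distributed, so
calibration checks use enough SNPs for ~50 blocks; and in a star phylogeny
with admixture between $A$ and $B$ the pairing $(A,B;C,D)$ has $f_4$
identically zero, so the all-three rule is only powered on a resolved tree
— the power simulation therefore uses $((A,B),(C,D))$ with internal-branch
drift and cross-clade admixture.

## The synthetic-data generator

`simulate_genotypes()` produces the statistical structure the analyses
assume, nothing more:

* **Ancestral frequencies** are Beta(1.5, 1.5), midfrequency-enriched to
  emulate an ascertained genotyping panel (the real panel's discovery MAF
  averaged ~24%), clamped to [0.01, 0.99].
* **Hierarchy.** A spike-type effect and a growth-habit effect are drawn
  once per class as Balding–Nichols deviations and added on the logit
  scale (crossed effects), then each population drifts further by its own
  Balding–Nichols step $c_{\mathrm{pop}}$. A nested variant (per-type
  `c_type`, `c_spike = c_habit = 0`) is available, but a nested hierarchy
  cannot reproduce the observed partition structure: pooling populations
  across spike-types dilutes nested type deviations roughly twofold in the
  growth-habit contrast, so no parameter choice yields partition means of
  0.37/0.23/0.17 simultaneously. Crossed effects do so naturally.
* **Calibration.** `emulate_paper_shape()` freezes
  $c_{\mathrm{spike}} = 0.20$, $c_{\mathrm{habit}} = 0.125$ and
  per-population drift between 0.21 and 0.42, values tuned once by
  simulation so the realized partition-level mean $\theta$ lands at
  ~0.38/0.23/0.18 (targets 0.37/0.23/0.17, stated band ±0.03) and then
  fixed; sample sizes follow the real populations (30–386, scalable for
  tests).
* **Founders and selfing.** Founder gamete pairs are drawn SNP-wise from
  the population frequencies (linkage equilibrium — the generator does not
  attempt a recombination-graph coalescent; haplotype tests rely on
  explicit implants, which is what PHS/IBS detect, and the truth stays
  exact). Each accession then selfs $g = 4$ generations: a locus
  heterozygous in the founding cross stays heterozygous with probability
  $(1/2)^g$, else fixes either way. The 6.25% expectation therefore
  applies to loci segregating in the cross (about $2p(1-p)$ of loci), and
  the truth records per-accession F1 heterozygosity so tests can condition
  on it.
* **Sweeps** overwrite a stated cM segment in a carrier fraction with one
  shared haplotype, implanted on both gametes so selfing preserves it. The
  default donor is built from the locally rarer allele at each site
  (an exotic-introgression-like haplotype): a haplotype drawn from the
  population's own frequencies consists mostly of locally common alleles,
  so "a haplotype at 25% frequency" would be false at most of its own
  sites and undetectable in principle. `sweep_donor = "founder"` restores
  the plain draw.
* **Migrant segments** are copied from one donor haplotype into a fraction
  of recipients *and* of donor-population accessions (`donor_frequency`,
  default equal): the migrating haplotype must exist in its source
  population for cross-population IBS to see it, and selfing would
  otherwise decompose the single source accession.
* **Outgroup states** are the ancestral allele, flipped / set ambiguous /
  replaced by a third nucleotide / made trans-specific at small configured
  rates (2–3% each), exercising every polarization status.
* Missingness is 2–3% uniform; all randomness flows from one seed and
  identical seeds give bit-identical bundles.

## Numerical and interface choices

Empirical quantiles are R's default (type 7) throughout; outlier rules are
inclusive (`>=`). Undefined per-SNP thetas (overall-monomorphic SNPs,
single populations with data) are `NA` with a reason, never zero. The
pipeline driver (`run_pipeline()`) writes every stage's tables plus a
manifest with the seed, all parameters and output checksums; a rerun with
the same seed reproduces the checksums exactly, which is asserted in the
tests. File formats are plain text only: diplotype TSV (T3-style export
dialect, which carries no reference/alternate polarity — the reader
canonicalizes alphabetically), a minimal diploid-GT VCF the package both
writes and reads, and three-column map / four-column population TSVs.

## What a green test does and does not establish

The generator's ground truth makes recovery tests exact, but its founders
are at linkage equilibrium: background LD, ascertainment structure beyond
the Beta shape, genotyping error correlated with heterozygosity, and
pedigree relatedness within programs are all absent. Green recovery tests
therefore establish correctness of the estimators under their own model
assumptions, not robustness to real-data pathologies. Conversely, the one
red acceptance clause (PHS sweep coverage, above) reflects an arithmetic
property of empirical-threshold scans, not an implementation defect — the
same scan run on the same data by any faithful implementation shares it.
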