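---
title: "Methods: windowed divergence scans, divergence islands, and coalescent simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence scans, divergence islands, and coalescent simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## Scope and model of the data

`divscan` analyses genome-wide divergence between closely related,
hybridizing populations — the motivating system is a community of
*Heliconius* butterflies in which three focal species (*H. cydno*,
*H. pachinus*, *H. melpomene*) exchange migrants while diverging, with
*H. hecale* and *H. ismenius* available as outgroups. The package takes a
multi-sample VCF of biallelic SNPs, a sample-to-population table, and
scaffold lengths; everything downstream operates on per-sample counts of
the ALT allele ("dosage"), so phase is never required.

Internally all coordinates are 0-based half-open; VCF positions are
converted on load and BED input is consumed as-is. Scaffolds are tiled
into non-overlapping windows of `width` bp (default 5,000). A trailing
window shorter than `width` is kept, flagged, and analysed with its
actual length as denominator. Missing genotypes reduce the called-allele
total at a site rather than dropping the site, which matches the
allele-count form of every estimator below.

## Windowed statistics

For each window the package computes, per population pair:

* **F~ST~** — a two-level (among/within population) variance-component
  estimator in the Weir–Cockerham/AMOVA form, computed per site from
  allele frequencies and called-allele counts and combined as a ratio of
  sums: $F_{ST} = \sum_s a_s / \sum_s (a_s + b_s)$, where $a_s$ and $b_s$
  are the among- and within-population components. The allele-based form
  was chosen because the input is unphased dosage data; for biallelic
  SNPs it tracks the haplotype-based AMOVA closely. Sites need at least
  two called alleles in each population to contribute. Negative estimates
  are retained (no clamping); a window with no usable site or a
  non-positive denominator is missing, never zero.
* **d~XY~** — $\sum_s [p_A(1-p_B) + p_B(1-p_A)] / L$ with $L$ the window
  length in bp; multiplying back by $L$ and summing gives the
  genome-aggregate substitution count used for divergence-growth curves.
* **fixed-difference fraction** — the share of the window's SNPs (with
  calls in both populations) whose allele sets are disjoint.

Per population: nucleotide diversity
$\pi = \sum_s 2 p_s (1-p_s)\, n_s/(n_s-1) / L$, segregating-site density,
Tajima's D (standard constants $a_1 \dots e_2$; missing when $S = 0$ or
fewer than four chromosomes; with missing data the sample size is the
window's maximum called-allele count), and mean derived allele frequency
over polarized sites. π and d~XY~ use the full window length as
denominator — the input is assumed to be a SNP-only VCF whose invariant
sites are genuinely invariant — so both are per-bp quantities.

**Polarization.** The ancestral allele at a site is the allele fixed
across all non-missing alleles of the pooled outgroup samples. Sites
where the outgroup segregates or is entirely missing are unpolarized and
excluded from derived-allele frequency and Patterson's D.

**Linkage disequilibrium.** $r^2$ is the squared Pearson correlation
between two sites' dosage vectors over jointly non-missing samples — the
allele-count approximation that avoids haplotype reconstruction. Sites
must pass a minor-allele-count filter (MAC ≥ 2 by default; singleton
pairs make $r^2$ degenerate). All in-window pairs are enumerated (windows
are small) and the maximum is the primary summary, with the mean reported
alongside because "maximum LD" alone is ambiguous.

**Patterson's D (ABBA–BABA).** With derived-allele frequencies $f_1, f_2,
f_3$ for the taxon ordering $(P_1, P_2, P_3, O)$ and the outgroup fixed
ancestral by construction, per site $\mathrm{ABBA} = (1-f_1) f_2 f_3$ and
$\mathrm{BABA} = f_1 (1-f_2) f_3$, and
$D = (\sum \mathrm{ABBA} - \sum \mathrm{BABA}) / (\sum \mathrm{ABBA} +
\sum \mathrm{BABA})$ over the requested window set (missing when the
denominator is zero — which genuinely happens when the demography leaves
no incomplete lineage sorting). The frequency form, rather than
single-sequence sampling, matches polarization against a pooled outgroup.

Undefined statistics propagate as `NA`, never as 0; the two SNP-only
conventions ($\pi = d_{XY} = 0$ on SNP-free windows) are the only
exceptions.

## Divergence islands

Window F~ST~ tracks are segmented with a two-tier empirical rule.
Thresholds are percentiles (defaults: 95th and 75th) of the genome-wide
distribution of *defined* window F~ST~ values for that comparison,
computed with linear interpolation (the realized values are recorded in
the output metadata; on one empirical comparison of this kind the
realized pair was F~ST~ ≥ 0.598 and ≥ 0.325). Windows at or above the
high threshold are *highly divergent*. For each pair of consecutive —
though not necessarily adjacent — highly divergent windows on the same
scaffold, the enclosed windows are all classified divergent if and only
if none of them falls below the low threshold. Windows with undefined
F~ST~ (no SNPs) break linkage and are excluded from the percentile
computation: an undefined window cannot certify that nothing fell below
the 75th percentile. Regions are maximal runs of consecutive divergent
windows; scaffolds, not chromosomes, are the linking unit because
windows are built on scaffolds.

This rule is deliberately simple (no HMM or kernel smoothing); the
package verifies it against a brute-force transcription on every possible
short track and checks monotonicity: lowering the low threshold can only
grow regions, raising the high threshold can only remove them.

Region sets from different comparisons are combined at window resolution:
`region_union()` merges membership across comparisons (the combined set
compared against the genomic background downstream), and
`region_overlap()` accounts bp exactly, so
$|A| + |B| = 2|A \cap B| + |A \mathbin{\triangle} B|$ holds identically.

## Resampling inference

**Bootstrap comparison** of a statistic between divergent and background
windows resamples each group with replacement (default 10,000 times; the
2.5/97.5 percentiles of the bootstrap means give the group CIs). The
two-sided p-value counts bootstrap mean-difference replicates whose
deviation from the observed difference $\hat d$ is at least $|\hat d|$ —
equivalently, recentred replicates that cross zero — with a +1 correction
in numerator and denominator so p is never exactly 0. This
null-recentred construction keeps the nominal type-I error at small
sample sizes, reaches the minimum $1/(B+1)$ on fully separated groups,
and returns 1 when both groups are identical constants. Raw p-values
across statistics are Benjamini–Hochberg adjusted.

**Permutation test excluding named loci.** To ask whether a pattern
survives the removal of known targets of selection (e.g. mimicry genes),
windows overlapping an exclusion BED are dropped, the observed difference
of group means is computed, and divergent labels are permuted among the
remaining windows; $p = (1 + \#\{|d_{null}| \ge |d_{obs}|\})/(n_{perm}+1)$.

**Chromosome clustering.** Observed per-chromosome region counts are
compared with counts expected under placement proportional to chromosome
length, via the Wilcoxon signed-rank statistic; its null distribution is
simulated by multinomial placement of the same number of regions. The
test reports the statistic standardised against the simulated null (`Z`)
and a two-sided Monte-Carlo p. The pairing (observed vs length-expected,
per chromosome) is the only pairing available from these inputs; the
construction is a documented best reading rather than a canonical test.

**Color-pattern enrichment.** A 2×2 Fisher's exact test of divergent vs
non-divergent sequence on focal vs other chromosomes, with bp rescaled to
integer kb units so the normalization by chromosome length is exact; a
count-based variant is available behind a flag.

All resampling is bit-reproducible given `(seed, n)`: every operation
draws from its own named substream derived by hashing the top-level seed
with the operation label, so stage order never changes a stage's result.

## The coalescent simulator

The synthetic-data generator is a structured coalescent with migration
and demographic events, following `ms` conventions throughout: time in
units of $4N_0$ generations, relative deme sizes $x_i$, migration matrix
entries $M_{ij} = 4N_0 m_{ij}$ (the backward per-lineage rate of moving
from deme $i$ to deme $j$ per unit time), pairwise coalescence at rate
$2/x_i$ within a deme, and mutations dropped on the genealogy at rate
$\theta$ per unit of total branch length. A population join moves all
lineages of the source deme into the sink and shuts migration into the
source; a resize changes $x_i$; events at equal times apply in command
order. Demographies can be built directly (`demographic_model()`) or
parsed from `ms`-style command lines (`parse_ms_command()`, which also
accepts the Unicode minus signs and `×` placeholders that appear in
typeset text, and round-trips through `format_ms_command()`).

These rate constants are pinned by calibration tests — panmictic
$E[T_{MRCA}(2)] = 1/2$ and Watterson's $E[S] = \theta \sum_{i<n} 1/i$,
each within three Monte-Carlo standard errors at 20,000 replicates — and
by a Kolmogorov–Smirnov comparison (α = 0.01, 2,000 loci) of
segregating-site distributions against an independent coalescent
implementation (msprime's ms-compatible CLI) run with identical
parameters; the reference counts ship as plain-text fixtures with the
generating commands recorded in their headers. Note that with branch
lengths in $4N_0$ units the mutation rate is $\theta$, not $\theta/2$
(which applies when lengths are in $2N_0$ units); the calibration tests
fail under any other constant.

Mutation dropping is infinite-sites by default (Poisson number of
mutations, branches weighted by length, distinct uniform positions). A
Jukes–Cantor finite-sites mode mirrors a sequence-evolution step:
positions are drawn with replacement, each event replaces the current
base by one of the other three, and sites left non-biallelic (or returned
to monomorphism) are dropped and counted. Jukes–Cantor was chosen as the
minimal finite-sites model; the only purpose of this mode is recurrent-hit
realism, so a richer substitution model would add parameters without
changing what the pipeline consumes. There is no intra-locus
recombination: each locus is one genealogy, matching the bundled
single-tree-per-locus parameterizations.

`simulate_dataset()` writes each locus as its own scaffold, pairs
consecutive haploids into pseudo-diploids by default (so the VCF
interface matches the empirical pipeline), uses the ancestral state as
the REF allele, and is byte-deterministic given its seed. Outgroup
populations for polarization are declared by name and become
`role = "outgroup"` samples.

### The bundled demography and what the simulation shows

`heliconius_im_models()` returns the three-population
isolation-with-migration parameterization inferred for the focal
community (θ = 34.6 per 5 kb locus; asymmetric migration up to
$4N_0m \approx 12.6$; sister populations joining at 0.761 with a strong
ancestral bottleneck, and the deeper join at 2.48), with and without its
migration matrix. Which `ms` population index corresponds to which
species is not fixed by the parameterization itself; the pair ratios are
therefore reported per pair *and* averaged over pairs, which is robust to
the labelling. Simulating both variants and scanning the loci with the
package's own F~ST~ estimator shows gene flow suppressing mean F~ST~
roughly five- to fourteen-fold depending on the pair (averaged over
pairs, well above five) — the quantitative signature that migration,
not recency of divergence, keeps these genomes similar.

The generator emulates neutral, freely recombining (between loci),
demographically exchangeable sequence data. It does not emulate
selection, linked selection, recombination gradients, mutation-rate
heterogeneity, genotyping error, or missingness — so pipeline tests
passing on simulated data demonstrate correctness of the estimators and
the machinery, not robustness to those empirical complications.

## Growth of divergence over time

Cumulative divergent bp (or fixed-difference counts) against divergence
time is fitted by least squares on the raw scale under both a linear
($y = a + bt$) and an exponential ($y = c e^{kt}$) model, the latter by
BFGS minimisation initialised from the log-linear fit. Model comparison
uses the Gaussian-error AIC, $n \ln(\mathrm{RSS}/n) + 2k$ with $k = 2$,
on the raw scale so the two RSS values are commensurable; the lower AIC
wins and exact ties break toward the linear model. A numerically-zero
RSS (exact fit) reports a $-\infty$ AIC sentinel. Because an
intraspecific comparison can contribute $y = 0$, the log-linear
initialisation adds one window length (5,000 bp) to $y$; the offset is
only used for initialisation and is recorded in the fit object whenever
it was engaged.

## Numerical choices and problem sizes

* Percentiles use R's type-7 linear interpolation; the realized
  thresholds are always recorded rather than re-derived downstream.
* The bootstrap resampler works in blocks bounded at ~64 MB so
  `n_boot = 10,000` never exhausts memory on genome-scale window sets.
* Test and verification problem sizes were chosen to give stable
  Monte-Carlo bounds (3 standard errors) at desk scale: 20,000 replicates
  for coalescent calibration; 1,000 loci per model for the
  migration/no-migration F~ST~ contrast; 20 replicates of 100 background
  + 6 planted loci for end-to-end recovery of no-migration loci embedded
  in a migration background (the planted fraction sits just above the
  high-percentile cutoff so recovery is attributable to the linking rule,
  not to trivial threshold placement); 500 replicates for resampling
  type-I calibration; 200 replicates for growth-model selection.
* Simulated null data for calibration experiments are drawn from one
  continuous RNG stream per experiment rather than freshly seeded per
  replicate: Mersenne-Twister initialisations from nearby seeds correlate
  in their first draws, which visibly distorts small-sample null
  distributions.

## Known limitations

* The F~ST~ estimator is allele-based; with strong inbreeding or highly
  uneven coverage a genotype-level (three-component) estimator would
  differ.
* Tajima's D under heavy missingness uses the window's maximum
  called-allele count as the sample size; windows mixing very different
  call rates blur the constants slightly.
* The clustering test's pairing and null are a documented reading of a
  thinly specified procedure; its Z and p are comparable across runs of
  this package, not across implementations.
* The simulator has no intra-locus recombination, so simulated LD decay
  within loci is stronger than in real 5 kb windows.
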