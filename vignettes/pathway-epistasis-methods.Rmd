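---
title: "Pathway-level epistasis discovery: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level epistasis discovery: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PathwayEpistasis)
```

## The problem

Individual SNP-SNP interaction tests in case-control GWAS are
hopelessly underpowered: ~10^11 pairs, each with a tiny effect. This
package implements the alternative of testing interactions *in
aggregate* at the level of biological pathways. The organizing idea
comes from model-organism genetic networks: deleterious genetic
interactions concentrate *between* two compensatory pathways
(between-pathway models, BPMs), *within* a single pathway (WPMs), or
around hub pathways whose variants interact promiscuously with the rest
of the genome (PATH structures). Even when no single SNP pair reaches
significance, an excess of weak interaction signal connecting two gene
sets can be collectively significant.

The pipeline has five stages: (1) genotype QC and cohort
harmonization, (2) SNP-SNP interaction scoring under an explicit
disease model, (3) lenient binarization of the score matrix into a
low-confidence, high-coverage network, (4) chi-square and permutation
scoring of every BPM/WPM/PATH candidate, and (5) a hybrid
permutation false discovery rate.

## The SNP-SNP interaction statistic (hygeSSI)

Genotypes are coded per disease model: dominant (carrier of at least
one minor allele = 1) or recessive (minor homozygote = 1). For a coded
pair (s_x, s_y) and a class C (cases for the risk channel, controls
for the protective channel), every genotype pattern T defines an exact
hypergeometric upper-tail p-value

P_T = P(#\{pattern T in C\} >= observed),

computed by `hygePvalue()`. With the nominal threshold alpha = 0.05,
the interaction score is

hygeSSI = -log10( P_11 / min(P_10, P_01, P_00, P_1., P_.1) )

when P_11 <= alpha and P_10, P_01, P_00 > alpha, and 0 otherwise. The
gates demand that the double-carrier pattern, and only that pattern, is
associated with the class; the denominator discounts whatever signal
the marginal effects (P_1., P_.1) already explain. Two details the
piecewise definition leaves implicit are resolved as follows: a
negative log-ratio (P_11 above the smallest denominator term despite
passing the gates) is floored at 0, and samples missing either
genotype are excluded pairwise, which keeps the hypergeometric
counting frame exact. Four codings (RR, DD, RD, DR) are scored; the
combined model takes the elementwise maximum, deciding score and
channel jointly per pair. The additive (AA) model instead scores pairs
with a 1-df logistic-regression likelihood-ratio test on 0/1/2 codes
(`additiveLrt()`); it has no hygeSSI-style gates and no pre-filter.

Each pair is scored against cases and against controls; the larger
score wins and labels the edge's channel (risk or protective), with
ties going to risk. Risk and protective analyses then proceed
end-to-end independently.

## Network binarization

Pathway statistics are computed on a binarized network. Among pairs
with score >= 0.2 (the lenient pre-filter; not applied to AA), the top
floor(d x #pairs) pairs by score are kept, d being the target density
(5% for discovery-style runs, 1% in the power analysis). Ties at the
cutoff are broken by a seeded, recorded shuffle so reruns are
identical. Kept edges are split into the risk and protective
adjacencies against the same global ranking.

## Structure statistics

For a pathway pair, SNPs shared by both pathways are removed first; a
pathway paired with itself is never scored. With e observed edges among
`possible` cross-pairs:

* chi2_global: one-sided 1-df Pearson chi-square of the 2x2 table
  contrasting the block against the rest of the network; 0 unless the
  block is denser than the global density.
* chi2_local: one-sided 1-df goodness-of-fit chi-square against
  expected density max(m_a, m_b), where a pathway's marginal density
  m is its edge density against all other SNPs. The max of the two
  marginals (rather than a joint conditioning, which the verbal
  definition does not determine) is the conservative choice: a block
  must beat its denser flank. This is configurable in spirit - the
  statistic functions accept arbitrary expected densities.

WPMs use the same machinery with possible = |a|(|a|-1)/2 and a single
marginal. PATH candidates use a one-tailed Wilcoxon rank-sum statistic
(`rankSumTest()`) comparing pathway SNP degrees against all other
degrees; it is exact (pwilcox) when there are no ties, and
tie-corrected normal otherwise. In permutation comparisons the rank
sum itself is compared, which is equivalent and exact for fixed set
sizes.

Chi-square independence of edges does not hold in a pruned genotype
network, so significance never rests on the chi-square alone: the
permutation p-value

p_perm = (#\{permutations reaching both observed statistics\} + 1) / NP

shuffles SNP-pathway membership by applying one global random
relabeling of SNP identities per iteration, keeping the network fixed.
One global permutation (rather than per-pathway resampling) keeps
overlapping pathways consistently permuted and preserves pathway sizes
and overlaps exactly. The +1 pseudocount sets the resolution floor at
1/NP (6.7e-6 at 150,000 permutations) and the value is capped at 1.
The implementation (`snpPermutationNull()`) evaluates permutations in
blocks as sparse matrix products; 33,000 permutations of a 300x300
block on a 2,000-SNP network take seconds.

## Hybrid permutation FDR

p_perm alone cannot separate the top structures (they saturate the
resolution floor), so multiple-testing correction uses sample
permutations: case/control labels are shuffled NP_s = 10 times -
swapping labels within matched pairs with probability 1/2, which
preserves the matched population structure - and the *entire* pipeline
(network, binarization at the same density, scoring, SNP permutations)
is rerun per shuffle. For structure i,

FDR(i) = [#null structures strictly better on (chi2_global,
chi2_local, p_perm) / NP_s] / [#real structures at least as good],

clipped to [0,1] and monotonized non-decreasing along the significance
ranking (the raw ratio is not guaranteed monotone; monotonizing avoids
non-monotone q-values). BPM, WPM and PATH families and the two
channels are corrected separately. A pilot run (`pilotSelect()`) with
10,000 SNP permutations and an SNP-permutation FDR surrogate picks the
disease model and density before committing to the expensive full run.

Redundancy among overlapping gene sets is collapsed after discovery:
structures whose supporting-edge overlap coefficient (shared pairs /
possible pairs of the smaller structure) exceeds 0.25 are joined, and
unique discoveries are counted as connected components.

## Replication

A structure discovered in one cohort replicates in an independent
cohort (same SNP universe, model and density) when the validation
chi-square p-values and p_perm are all at most 0.05. Set-level
significance is a fold enrichment against NP_s = 10 label-permuted
validation cohorts, with a 10,000-set bootstrap null, and
supporting-edge overlap is tested per structure by an upper-tail
hypergeometric within the block's possible pairs. When a replication
design is planned, SNP selection should be run on the combined cohorts
before splitting, mirroring standard practice for harmonized SNP
universes.

## Genotype QC

Defaults follow standard GWAS practice: per-sample and per-SNP missing
rate <= 0.02, MAF >= 0.05, Hardy-Weinberg chi-square p >= 1e-6. HWE is
tested in controls only (cases may legitimately deviate under disease
association; the choice is configurable by passing a subsetted
dataset). The chi-square rather than the exact HWE test is used: at
these sample sizes and a 1e-6 cutoff the difference is immaterial and
the chi-square is cheap. Relatedness is filtered at proportion-IBD
0.2 with a method-of-moments IBS-based estimator; one random member of
each flagged pair is dropped (seeded). Population structure is
balanced by PCA on the standardized genotype matrix followed by greedy
1:1 nearest-neighbor case-control matching - an internal replacement
for reference-panel MDS that requires no external data; the contract
is only that matched pairs are drawn from the same sub-population.
LD pruning slides a 50-SNP window by 5 SNPs and removes one SNP of any
pair with r^2 >= 0.1; since the published greedy procedure's exact
internals are not specified, ties are broken deterministically (drop
the lower-MAF, then the lower-position SNP) for reproducibility.
Missing genotypes are excluded pairwise everywhere; nothing is imputed.

SNPs map to a pathway through any gene whose body overlaps a +-50 kb
window around the SNP (closed intervals, gene body rather than TSS -
the window is symmetric and generous precisely because regulatory
variants act at a distance). Pathways keep between 10 and 300 genes
*represented in the data* and between 10 and 300 SNPs; smaller sets
are underpowered, larger ones uninformative.

## The synthetic cohort generator

`simulateCohort()` emulates the statistical structure of a QC'd GWAS
cohort: biallelic SNPs in Hardy-Weinberg equilibrium, a configurable
number of embedded epistatic SNP pairs, and unassociated background
SNPs whose MAFs are drawn uniformly from [0.05, 0.5] (a flat spectrum
approximating a post-QC tag-SNP panel). The two-locus penetrance is
f0 d(g1,g2): relative risk d for double carriers (all four
double-carrier cells share one d), PR1 = 1 for single carriers (all
excess risk is epistatic), and f0 calibrated analytically so the
population prevalence is exactly the specified value (default 0.05).
A literal joint rejection-sampling scheme is only defined for a single
causal pair - with 100 embedded pairs a multiplicative penetrance
cannot stay below 1 - so the generator draws each pair's two-locus
genotype from the class-conditional distribution obtained by Bayes
inversion of the single-pair model, with labels fixed at the requested
case/control counts. This is exactly the distribution a
rejection-sampled cohort would have if that pair alone drove the
disease, and it keeps the pairs exchangeable.

What the generator does *not* emulate: linkage disequilibrium between
background SNPs (backgrounds are independent draws), realistic MAF
spectra, population admixture, or genotyping error. Passing tests on
these cohorts therefore demonstrates the statistical machinery, not
robustness to LD-induced confounding - which is why the QC module
prunes LD on real data before any scoring. One consequence worth
knowing: cross-pairs of causal SNPs drawn from *different* embedded
pairs carry two weak marginal effects whose product enriches the joint
carrier pattern; such pairs can earn sizable hygeSSI scores while
being exactly additive on the log-odds scale, so in synthetic cohorts
the agreement between top hygeSSI edges and logistic-regression
interaction tests is only expected where true interactions saturate
the lenient cutoff.

`simulateNetwork()` builds the stage-2 substrate for the power
analysis: an Erdos-Renyi background at the target density (or a
configuration-model realization of a supplied degree sequence), with
between-pathway blocks raised to a target density by degree-preserving
double-edge swaps - an edge leaving the block's A side and one leaving
its B side are rewired into an A-B edge plus an outside edge, so the
degree multiset and global density are exactly invariant.

## The two-stage power analysis

`powerCurve()` estimates the minimum cohort size needed to detect a
BPM of a given size, MAF and interaction effect:

1. *Pair-level sensitivity.* For each grid size n in
   {200, 500, 1000, 2000, 5000, 10000}, simulate a cohort with 100
   embedded pairs plus 2,000 background SNPs, build the dominant-model
   hygeSSI network, binarize at 1% density, and record the fraction of
   embedded pairs recovered as edges.
2. *Required block density.* On a 2,000-SNP 1%-density network, find
   (by expanding search and bisection over the embedded edge count) the
   smallest block density whose SNP-permutation p-value reaches
   3.0e-5, using 33,334 permutations - the smallest count that can
   resolve that threshold with the +1 pseudocount.

The two stages connect through the scaling parameter s, the assumed
fraction of SNP pairs crossing two genuinely interacting pathways that
are functionally deleterious (default 0.05, with 0.025 and 0.1 as
sensitivity scenarios): a cohort size suffices when
sensitivity x s >= required block density. Sensitivities are computed
lazily in ascending n and cached across block sizes.

Problem sizes here (2,000 background SNPs, one cohort per grid point,
33,334 permutations) are the package's chosen working scale for the
simulation study; the sensitivity estimate from 100 embedded pairs
carries a binomial standard error of about 0.04, so minimum-n
decisions near a threshold can move by one grid step between seeds.

## Numerical and degenerate-input conventions

* Hypergeometric p-values are exact and floored at the smallest
  positive double; -log10 ratios are floored at 0.
* Degenerate coded vectors (all 0/all 1) score 0 with a warning;
  logistic non-convergence or separation scores 0 with a warning; a
  constant interaction column scores 0 silently (no interaction df).
* chi2_local with zero expected density is 0 for an empty block and
  +Inf otherwise; blocks at or below expectation always score 0
  (one-sided statistics throughout).
* Binarization with fewer eligible pairs than requested keeps all of
  them and records the achieved density.
* Every stochastic step (binarization tie-breaks, permutations, label
  shuffles, simulators) consumes an explicit integer seed derived from
  a single master seed, and restores the caller's RNG state.

## Known limitations

* Autosomal biallelic SNPs only; no imputation, no covariates in the
  additive model, no interactions beyond two loci.
* The PCA-based case-control matching balances broad structure but is
  no substitute for reference-panel ancestry analysis on admixed
  cohorts.
* The AA (additive) network is quadratic in SNPs with a glm per pair;
  it is practical for pilot-scale SNP sets, not for hundreds of
  thousands of pairs.
* FDR estimates from NP_s = 10 sample permutations are themselves
  noisy; they correlate well with larger NP_s but individual FDR
  values should be read as estimates, not guarantees.
* The FDR numerator requires a null structure to be strictly better on
  all three criteria simultaneously. Joint strict domination in three
  dimensions is rare, so the FDR of an isolated top-ranked structure
  is anti-conservative under a global null (and, with NP_s = 10 and a
  denominator of 1, the attainable values below 0.3 are only 0, 0.1
  and 0.2). A single structure at FDR <= 0.25 with no support from
  replication or from additional structures in its component should
  therefore be read skeptically; replication in an independent cohort
  is the intended arbiter.
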