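---
title: "Odds-ratio interaction testing in discordant sib pairs: model, null distribution, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odds-ratio interaction testing in discordant sib pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcoresib)
```

## The statistic

A discordant sib pair (DSP) is one affected and one unaffected full
sibling from the same nuclear family. For a pair of SNPs $M_1, M_2$, let
$n_{ij}$ count the affected sibs with genotype $i$ at $M_1$ and $j$ at
$M_2$ ($i, j \in \{1,2,3\}$ for the minor homozygote, heterozygote and
major homozygote), and let $R_{ij}$ count both sibs, so that the
unaffected table is $R_{ij} - n_{ij}$. Each $3\times 3$ genotype table is
collapsed to a $2\times 2$ weighted allele table: a homozygote pair
contributes 4 identical allele pairs, a homozygote-heterozygote cell 2,
and the double heterozygote 1 to every cell (phase-unknown collapsing):

$$a = 4n_{11} + 2n_{12} + 2n_{21} + n_{22}, \qquad \text{etc.}$$

The allelic odds ratio $OR = ad/bc$ within a sib class measures the
association between the alleles carried at the two SNPs in that class.
Under Hardy-Weinberg and linkage equilibrium, alleles at unlinked SNPs
are uncorrelated within a class unless the joint genotype influences
affection status, so a *difference* in the log odds ratio between
affected and unaffected sibs is evidence of gene-gene interaction:

$$G = \frac{\log OR_{case} - \log OR_{control}}
           {\sqrt{4\,\widehat{Var}(\log OR_{case})}} \sim N(0, 1)
  \ \text{under } H_0 .$$

## The within-family null and the factor 4

Sibs are genetically correlated, so the two tables are not independent.
The null model conditions on the genotypes observed in each sibship and
exchanges the affection labels: within family $s$, with two-locus
genotype cells $u_s$ (currently affected) and $v_s$ (currently
unaffected), the affected label lands on either sib with probability
one half — a draw of 1 of 2 without replacement, i.e. the two-sib
multivariate hypergeometric law. A family contributes
$(e_{u_s} - e_{v_s})(e_{u_s} - e_{v_s})^{\!\top}/4$ to the covariance of
the affected-table cell counts (zero when $u_s = v_s$), and the totals
are fixed, so the unaffected counts are complementary. Consequently

$$Var(\log OR_{case}) = Var(\log OR_{control}), \qquad
  Cov(\log OR_{case}, \log OR_{control}) = -Var(\log OR_{case}),$$

and the variance of the difference is $4\,Var(\log OR_{case})$ — the
factor 4 in the denominator of $G$.

`Var(log OR_case)` is obtained by the delta method: the collapsed cells
$(a,b,c,d)$ are linear in the nine cell counts through the weight matrix
$W$, the gradient of $\log a - \log b - \log c + \log d$ is
$W^{\!\top}(1/a, -1/b, -1/c, 1/d)$, and the quadratic form with the
covariance above reduces to $\tfrac14 \sum_s (w_{u_s} - w_{v_s})^2$.

**Where the gradient is evaluated.** We evaluate the gradient at the
*null expectation* of the case cells — the midpoint of the affected and
unaffected collapsed tables — rather than at the observed affected
table. Three reasons, in order of weight. First, exactness of the
symmetries: with a midpoint gradient the variance is symmetric in the
two sib classes, so swapping every family's labels negates $G$ exactly
and the two single-class variances are identical by construction; an
observed-case gradient breaks both, since the denominator would change
under the swap. Second, agreement with the exhaustive permutation
distribution: the enumeration is centred at the midpoint, and in our
validation runs the midpoint gradient roughly quarters the fraction of
cohorts whose delta variance misses the enumerated variance by more
than 15%. Third, the identity between the closed form and the
enumeration of the linearized statistic is preserved at machine
precision (next section). The trade-off is discussed under
"Limitations".

## The permutation oracle

`permutationOracle()` enumerates all $2^k$ label assignments (or samples
them) and recomputes both log odds ratios for each. It reports two sets
of moments:

* **raw** moments of the actual log odds ratios, over the assignments in
  which all eight collapsed cells are positive (the log OR is undefined
  otherwise);
* **linearized** moments of the first-order expansions around the
  midpoint, over *all* assignments. Because the control counts are the
  fixed totals minus the case counts, the linearized statistics satisfy
  $Var_{case} = Var_{control}$, $Cov = -Var$ and
  $Var(\text{diff}) = 4\,Var_{case}$ *exactly*, and the enumerated
  linearized variance equals the closed-form delta variance to machine
  precision. This is the sense in which the covariance identity above
  "holds to enumeration precision"; for the raw log odds ratios it holds
  only to the accuracy of the delta expansion.

**Accuracy of the delta variance.** At realistic cohort sizes (hundreds
of DSPs) the collapsed cells are large and the delta variance is an
excellent approximation. At the tiny sizes where exhaustive enumeration
is feasible ($k \le 12$, i.e. at most 48 allele pairs per table) the
log's curvature is material: in our validation ensemble (k = 12, MAF
0.5, all observed cells $\ge 5$) the median relative gap between the
delta variance and the raw enumerated variance is about 7%, but the
tail is heavy — roughly one cohort in fifteen exceeds 15%, with
occasional gaps above 50% driven by assignments that push a collapsed
cell down to 1 or 2, where $\log$ swings dominate the second moment. No
first-order variance can close that tail at $k = 12$; it is a property
of the enumeration scale, not an implementation error (the oracle's raw
moments were cross-checked against an independent brute-force loop).
We therefore regard median-level agreement plus the exact linearized
identities as the meaningful small-$k$ validation, and report the full
margin distribution in the validation suite.

## Non-testable pairs

Any zero among the eight collapsed cells makes a log odds ratio
undefined; such pairs are reported as `ZERO_CELL` and no value is
invented (no continuity correction by default; `haldane = TRUE` adds 0.5
to every collapsed cell for exploratory use). If every retained family
is genotype-concordant at both SNPs the permutation distribution is
degenerate and the pair is `DEGENERATE`. Genotype-concordant families
are *retained* in the counts — they inform the odds ratios — but
contribute zero to the variance. Families missing any of the four
genotypes at a pair are excluded pair-wise, maximizing the data used for
each test.

## The simulator

`simulateDspCohort()` is a parametric nuclear-family generator used for
calibration studies. Haplotype frequencies for the two SNPs come from
the minor allele frequencies and the squared allelic correlation $r^2$
(positive-D convention, Lewontin-bounded). Parents carry two haplotypes
each; each of two offspring receives one gamete per parent. When
$r^2 = 0$ the SNPs represent unlinked genes and transmission at the two
loci is independent; when $r^2 > 0$ both SNPs ride on one haplotype and
are transmitted intact. Affection is assigned independently per
offspring by the logistic penetrance

$$P(\text{affected} \mid X) =
  \operatorname{logit}^{-1}(\rho + \lambda_1 X_1 + \lambda_2 X_2 +
                            \lambda_3 X_1 X_2),$$

with $X$ the additive (0/1/2), dominant or recessive genotype coding and
$\rho$ calibrated by monotone root-finding so the population prevalence
hits its target to within $10^{-10}$. A family is ascertained iff
exactly one of the two sibs is affected (rejection sampling; the run
aborts with a diagnostic if the acceptance rate falls below $10^{-5}$).

Defaults mirror the calibration studies: MAF 0.2/0.2 (alternatively
0.3/0.15), 250-1000 DSPs, prevalence 0.05, effect sizes 0 under the
null, $\log 2$ or $\log 2.25$ for power. Prevalence under a pure null is
immaterial — with all $\lambda = 0$ affection is independent of genotype
— so 0.05 is used for convenience; main-effect robustness runs use
prevalence 0.01 where the phenomenon is strongest. Sibship size is fixed
at two offspring, the minimal configuration that defines a DSP.

What the generator does *not* emulate: real LD structure beyond a single
two-SNP haplotype block (no flanking markers, no reference-panel
resampling), parental phenotypes, sibships larger than two, genotyping
error or missingness. Calibration results on this generator therefore
validate the statistic's null behaviour under its own assumptions; they
do not certify behaviour under, say, extended LD between a tested SNP
and an untyped causal variant.

## Experiments and their scale

`type1Experiment()` / `powerExperiment()` simulate replicate cohorts,
test the disease-SNP pair in each, and report rejection rates with exact
binomial 95% confidence intervals; non-testable replicates are counted
separately. Per-replicate seeds are drawn once from the experiment seed,
so results are bit-reproducible. Power checks are ordinal only
(monotone in the number of families and in the interaction effect),
with violations flagged only when backed by disjoint confidence
intervals.

The validation suite runs 5,000 replicates for the headline cells (the
MAF 0.2/0.2, 500-DSP null, which also supplies the 5,000 null $Z$ values
for the Kolmogorov-Smirnov normality check, and the LD $r^2 = 0.3$
scenario) and 2,000 replicates elsewhere; empirical rates are compared
at three binomial standard errors computed at the replicate count
actually used. These sizes were chosen to keep each scenario's Monte
Carlo error well below the effects being checked.

## Scan engine

`runScan()` enumerates pairs (all pairs, between-gene pairs with
disjoint gene sets, a chromosome pair, or an explicit list), skips SNPs
below the sib-MAF threshold (default 0.01, computed from the sibs — the
analysis units — not parents), partitions the stream into contiguous
chunks scored by forked workers, and merges in enumeration order, so
output is byte-identical for any worker count. No multiple-testing
correction is applied; p-values are reported raw and a report threshold
merely limits output size. The chromosome-pair mode is the unit of
manual distribution across machines.

## Limitations

* The midpoint-gradient variance slightly *raises* the denominator when
  the two sib classes' tables differ strongly, e.g. when both SNPs carry
  large main effects. This makes the test a little more conservative in
  exactly the regime where odds-ratio interaction statistics are known
  to inflate (strong dual main effects under a dominant model); users
  should in any case interpret interaction hits alongside main-effect
  tests at the same SNPs, since no variance choice removes that
  confounding.
* The normal reference for $G$ is asymptotic in the number of
  informative (genotype-discordant) families; with very few informative
  families prefer `permutationOracle()`'s empirical p-value.
* X-chromosome SNPs, phase inference, covariate adjustment and
  higher-order interactions are out of scope; covariates are the domain
  of regression-based tests, for which this statistic is a fast
  screening companion.
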