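---
title: "Candidate-gene association in half-sib designs with polygenic mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene association in half-sib designs with polygenic mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplomm)
```

## The setting

Dairy-cattle candidate-gene studies often genotype a handful of SNPs in the
daughters of a small number of sires and ask whether the variants are
associated with milk production traits. The phenotype is not a raw record
but an estimated breeding value (EBV) from the national genetic evaluation,
accompanied by a reliability (squared accuracy) in (0, 1]. Two features of
such data drive everything in this package:

* **Relatedness.** Daughters of one sire are paternal half sibs, so
  phenotypes are correlated through the pedigree. Ignoring this inflates
  association test statistics. The polygenic background is modelled as a
  random effect with covariance proportional to the additive relationship
  matrix **A** built from the pedigree.
* **Heterogeneous phenotype precision.** An EBV with reliability 0.9 is a
  far more precise observation than one with reliability 0.4. The residual
  variance of observation *i* is therefore taken proportional to
  1/reliability: the weight matrix **W** is diagonal with entries 1/REL.

## The models

For a single SNP the model is

y = 1&mu; + b x + Z a + e,&nbsp;&nbsp; a ~ N(0, **A**&sigma;&sup2;<sub>a</sub>),&nbsp;&nbsp; e ~ N(0, **W**&sigma;&sup2;<sub>e</sub>)

where x codes each daughter's genotype as 0/1/2 copies of the minor allele.
The regression coefficient and its sampling variance come from solving
Henderson's mixed model equations, and b&#770;&sup2;/Var(b&#770;) is referred
to &chi;&sup2;(1) (a Wald test).

For a haplotype block the single dosage column is replaced by the n &times; k
matrix of expected haplotype-class counts (haplotype trend regression): the
joint Wald statistic h&#770;&prime;[Var(h&#770;)]&sup1;&#8315;&sup1;h&#770; on
the identifiable contrasts is referred to &chi;&sup2;(k&minus;1). Because each
dosage row sums to 2, the full design is confounded with the intercept; the
pooled class (or the last class when nothing was pooled) is dropped, making
the reported effects contrasts against that reference. The Wald statistic is
invariant to which class is dropped, and the degrees of freedom k&minus;1
match the number of distinct haplotype classes minus the reference.

Raw p-values across the declared test family are adjusted by the
Benjamini–Hochberg step-up procedure; adjusted p &le; 0.05 is called
significant. The family defaults to *all SNPs, all blocks and all traits in
one run* and is recorded in the pipeline log; a per-trait family is
available because neither convention is canonical for small candidate-gene
panels.

## Numerical strategy

Two solution routes are implemented and cross-checked:

* `solve_mme()` assembles Henderson's coefficient matrix with
  **A**&sup1;&#8315;&sup1;&lambda; (&lambda; = &sigma;&sup2;<sub>e</sub>/&sigma;&sup2;<sub>a</sub>)
  and solves the full fixed + random system. The fixed-effect sampling
  covariance is the fixed block of the inverted coefficient matrix times
  &sigma;&sup2;<sub>e</sub>.
* The default engine rotates the model by the eigendecomposition of
  **W**^{&minus;1/2}**A**<sub>obs</sub>**W**^{&minus;1/2}, after which the
  covariance is diagonal and any phenotype vector on the same individuals
  can be solved in O(n) once the O(n&sup3;) decomposition is done. This is
  exact generalized least squares and identical to the MME solution; the
  test suite verifies both against a naive dense-GLS oracle to 1e-8.

Variance components are estimated by REML on the intercept-only model and
then held fixed for every SNP and block test of that trait (the two-stage
practice common in genomic association software; per-test re-estimation
would cost hundreds of extra REML solves for a negligible change on a
single-gene panel). The REML criterion is profiled down to a single ratio
&gamma; = &sigma;&sup2;<sub>a</sub>/&sigma;&sup2;<sub>e</sub> and maximised
by golden-section search over log &gamma; on [&minus;20, 15], which is
deterministic and start-value free; a solution at the lower boundary is
reported as &sigma;&sup2;<sub>a</sub> = 0 with a warning and the fit
degenerates to weighted least squares.

Missing genotype calls are handled per test (complete case on the tested
SNP or block); the polygenic structure always uses the full pedigree.
Individuals present in genotype or phenotype files but absent from the
pedigree are added as unrelated founders with a warning — the standard
tabular-method convention for unknown parents.

## Pedigree machinery

`build_A()` implements the tabular recurrence (a<sub>ii</sub> = 1 +
a<sub>sd</sub>/2, a<sub>ij</sub> = (a<sub>js</sub> + a<sub>jd</sub>)/2); the
matrix is kept dense because candidate-gene studies of this scale involve at
most a few thousand animals. `build_A_inverse()` uses Henderson's direct
rules with Mendelian-sampling variances from the Meuwissen–Luo inbreeding
algorithm, so inbred pedigrees are handled exactly; a dense inversion of
`build_A()` is provided as an independent route and the two must agree.

## Linkage disequilibrium and haplotypes

Haplotype frequencies over a block are estimated by an EM algorithm over all
phase configurations consistent with each multilocus genotype, initialised
at linkage equilibrium (making the run deterministic), with tolerance 1e-6
on the maximum frequency change and a 1000-iteration cap; hitting the cap
flags the result rather than failing. Candidate haplotypes whose final
frequency is numerically zero (&lt; 1e-8) are removed, so phase
configurations the EM has ruled out never surface as spurious classes.

D&prime; between two SNPs is computed from the EM two-locus frequencies:
D = p(AB) &minus; p(A)p(B) normalised by its bound given the allele
frequencies. A monomorphic locus makes D&prime; undefined and is treated as
an error, never silently reported as zero. Blocks are maximal contiguous
runs of SNPs in which at least a fraction 0.9 of the *informative* pairwise
comparisons (both MAFs &ge; 0.05 and EM converged — mirroring the exclusion
of uninformative pairs in standard LD-plotting software) have D&prime; &gt;
0.75; the search is greedy, longest first, left to right among equal
lengths. The confidence-interval machinery of Haploview-style block callers
is deliberately not reproduced: only the two threshold parameters are
specified, and the greedy rule over those two is transparent and testable by
exhaustive enumeration.

Haplotypes with frequency &gt; 5% are distinguishable classes; the rest are
merged into one pooled class. The trend-regression design uses expected
dosages under the EM phase posteriors rather than a hard best-phase
assignment — the classical haplotype-trend-regression choice, which avoids
arbitrary tie-breaking; hard assignment is available behind a flag.

## What the simulator emulates — and what it does not

`simulate_population()` generates the design the analysis assumes: 13
unrelated sires with 638 daughters by default, family sizes drawn from a
truncated negative binomial on [5, 136] with mean 638/13 &asymp; 49 and then
adjusted to hit the total exactly; each daughter receives one intact sire
haplotype and one dam haplotype (no recombination — appropriate for a
candidate-gene region tens of kilobases long); dams are unrelated,
ungenotyped founders. True breeding values are drawn jointly with covariance
**A**&sigma;&sup2;<sub>a</sub>. The EBV phenotype is TBV + marker effects +
noise with Var(noise) = ((1&minus;r)/r)&sigma;&sup2;<sub>a</sub>, so that r
equals the classical reliability &sigma;&sup2;<sub>a</sub>/(&sigma;&sup2;<sub>a</sub>
+ Var(noise)); reliabilities are uniform on (0.4, 0.9) by default, a
realistic span for daughter EBVs from a national evaluation. An optional
extra variance term is available for pure-noise null scenarios.

This generative model treats each EBV's error as independent given the true
breeding value. Real EBVs from a joint evaluation have correlated errors
(daughters contribute to their sire's proof and vice versa), and real
reliabilities are not uniform. Passing calibration on these simulations
therefore shows that the estimator and its test are correct *under the
stated model*, not that the model captures every property of deployed
genetic evaluations. Note also that the analysis model's constant
&sigma;&sup2;<sub>e</sub>/REL residual family does not contain the
generator's ((1&minus;r)/r)&sigma;&sup2;<sub>a</sub> variance exactly when
reliabilities vary — a deliberate, mild misspecification matching how such
weighted analyses are used in practice; the type-I error of both Wald tests
nevertheless stays within 5% &plusmn; 1% at n = 638 (verified at 2000
replicates in the acceptance checks).

One subtlety the simulations exposed: with whole-haplotype transmission,
daughters of one sire share haplotypes, so realized haplotype frequencies
fluctuate around their targets far more than binomial sampling suggests
(26 founder sire haplotypes dominate the variance). Frequency-recovery
properties are therefore tested against iid-gamete simulations, and EM
output on half-sib data is compared with the *realized* gamete counts from
the simulator's truth record.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `dprime_threshold` | 0.75 | D&prime; above which a pair counts as strong LD |
| `strong_fraction` | 0.9 | fraction of informative pairs that must be strong |
| `maf_min` | 0.05 | informativeness floor for LD pairs |
| `pool_threshold` | 0.05 | frequency above which a haplotype stays distinguishable |
| `fdr_alpha` | 0.05 | significance level on BH-adjusted p-values |
| EM `tol`, `max_iter` | 1e-6, 1000 | frequency-change convergence, iteration cap |
| REML interval | log &gamma; &isin; [&minus;20, 15] | variance-ratio search range |

## Degenerate inputs and tie-breaks

* monomorphic SNP: MAF 0, HWE test and D&prime; undefined (errors), single-SNP
  association skipped with the reason recorded;
* all haplotypes rare: pooling fails loudly (no distinguishable class);
* k = 1 block after pooling: no contrast, error;
* aliased haplotype-class columns: dropped with a message, df reduced;
* allele-frequency tie (0.5): minor-allele orientation leaves codes as-is;
* REML at the &sigma;&sup2;<sub>a</sub> = 0 boundary: fit proceeds with zero
  polygenic solutions and a warning;
* frequencies supplied at printed precision: pooling tolerates a sum within
  0.02 of 1 without renormalising, so published tables can be used as-is.

## Problem sizes used in the checks

The packaged test-suite and acceptance script work at the study's own scale
where that scale is the point (n = 638 phenotypes, 2000-replicate null
calibrations, 500-seed recovery runs, 200-seed EM frequency sweeps), and at
reduced scale (tens of pipeline runs, n &le; 200 oracle instances) where the
check is structural rather than statistical. The eigen-rotation fit makes
the large calibrations cheap: one decomposition per population structure,
O(n) per replicate afterwards.

## Known limitations

* No genomic (marker-based) relationship matrix, dominance or epistasis.
* No r&sup2; LD statistic, pedigree-based phasing, or imputation.
* Wald p-values are asymptotic &chi;&sup2;; no small-sample correction is
  applied, by design.
* Multi-allelic variants are rejected at input.
* The FDR family definition is a user choice, logged but not adjudicated.
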