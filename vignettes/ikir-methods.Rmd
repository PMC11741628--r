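---
title: "Methods: iKIR modification of HLA class II associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iKIR modification of HLA class II associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ikirmod)
```

## The scientific question

Inhibitory killer-cell immunoglobulin-like receptors (iKIRs) bind HLA
class I molecules in broad allele groups and are thought to prolong the
lifespan of activated T cells. Because KIR genes (chromosome 19) and HLA
genes (chromosome 6) segregate independently, a person may carry an iKIR
gene with or without the gene encoding its ligand; only the co-carried
("functional") pairs can signal. In type 1 diabetes (T1D), where class II
restricted CD4+ T cells dominate the genetic signal, the hypothesis is
that a high functional-iKIR dose *weakens* the protection conferred by
protective HLA class II genotypes: longer-lived autoreactive T cells are
bad news precisely for the people whose class II genotype would otherwise
protect them.

This package implements the full analysis pipeline for that hypothesis —
scoring, stratified and interaction association analysis, bespoke
permutation tests, a driver-genotype screen, a family transmission test,
impact estimates, and a mechanistic ODE model — together with a synthetic
cohort generator so every stage is testable without access to the original
genotype data (which are not publicly deposited).

## The iKIR score

Each functional pair contributes a weight to the iKIR score:

| iKIR gene | ligand group | default weight |
|-----------|--------------|----------------|
| KIR2DL1   | C2 (HLA-C, position-80 Lys) | 1.00 |
| KIR2DL2   | C1 (HLA-C, position-80 Asn) | 0.50 |
| KIR2DL3   | C1                           | 0.75 |
| KIR3DL1   | Bw4-80I (HLA-B/A)            | 1.00 |
| KIR3DL1   | Bw4-80T                      | 0.75 |
| KIR3DL2   | A3/A11 (off by default)      | 0.25 |

With all weights set to 1 the score reduces to the functional-iKIR count.
The published per-pair weights are not reproduced in any open source we
can cite, so the package ships this *named, versioned* default table
(`ikirmod-default-1`), chosen so that the standard stratification
thresholds (1.5, 1.75, 2.0, 2.5) fall inside the attainable range
[0, 3.25]; every scored object records the table id, and any TSV with the
same columns can be substituted. A consequence worth stating plainly:
quantities that depend on the absolute weight scale (for example a
normalized-score odds ratio) are not comparable with published values —
only signs, orderings and calibration properties are.

Allele-to-ligand assignment (Bw4 motifs, the HLA-C position-80
dimorphism, A3/A11) is by an editable lookup table of allele names, not
sequence parsing, because cohort files carry allele labels. Ties at a
stratification threshold go to "low" (the convention is score <=
threshold is low). When both Bw4 motifs are present the stronger (80I)
is used for KIR3DL1.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` define the generative model every
downstream test leans on:

* two class II haplotypes per individual drawn from a ~20-haplotype
  European-style pool (phase kept explicit, so cis/trans genotype
  predicates are exercised);
* class I alleles per locus from European-typical frequency tables, with
  optional `ld_links` odds multipliers to inject class I / class II
  linkage; KIR genes as independent Bernoulli draws — independent of HLA,
  as chromosomes dictate;
* disease status from
  `logit P(case) = b0 + sum(effect_lnors * carriage) +
  interaction_beta * score * carriage(protective) + sex_lnor * male`,
  with `b0` solved numerically so the marginal case probability equals
  the requested case fraction, and case/control quotas filled by
  rejection sampling (a case-control design, not a prospective one).

Default effects use mid-range published whole-cohort magnitudes for the
moderately protective genotypes (−1.25, −1.15), detrimental effects of
+1.0/+1.2, and −4.5 for the strongly protective DQ6-like genotype
`DQA1*01:02-DQB1*06:02` — the value at score zero which, combined with
the default `interaction_beta = 0.9` (the magnitude reported for the
DQ6-by-score interaction), leaves both score strata protective at
realistic scores. The interaction applies to DQ6 only by default,
mirroring the headline fitted model (outcome ~ DQ6 × score + sex).

What the generator does *not* emulate: recombination, allele-level KIR
typing, KIR copy number, population stratification and relatedness.
Passing tests therefore show the pipeline's statistics are correct and
calibrated under this generative model — not that real cohorts are free
of the confounders the generator omits.

Trios (`generate_trios()`) draw parents from the same pools; a child
inherits one gamete per parent (no recombination within the HLA region)
and is resampled until affected. The baseline disease probability is 1%
(rare-disease regime). This matters: transmission distortion is driven by
ratios of `P(affected)` between gamete choices, and with a common-disease
baseline those ratios compress towards 1 even for large log-odds effects.
Child KIR genes are drawn from population frequencies (KIR is unlinked to
HLA, and KIR-locus haplotype structure is out of scope).

## Association analysis

Estimates are maximum-likelihood logistic fits (`stats::glm`) with Wald
95% CIs and p-values. With one binary predictor and no covariates the
coefficient equals the crude 2×2 `ln[(a d)/(b c)]` exactly; this oracle
equivalence is asserted to six significant figures in the tests. Zero
cells are an error unless the Haldane–Anscombe +0.5 correction is
explicitly requested — a silent correction changes estimates. Genotype
coding is dominant (carriage), multi-allele genotypes are satisfied in
cis or in trans unless a phased predicate is requested, and stratified
fits adjust for sex (optionally for Bw4/C1/C2 carriage). Genotypes with
fewer than 10 case carriers are skipped rather than fitted, because their
stratum-level cells are too sparse. (Near-)perfect separation raises a
diagnostic error instead of returning a silently diverged estimate.

The interaction ("dose") model `status ~ genotype * score + sex` reports
the interaction coefficient and AIC, with the score either continuous or
as the binary stratum indicator, so the two codings (and score versus
count) can be compared.

## Permutation framework

The multi-genotype test statistic is the carriage-frequency-weighted mean
of the per-genotype iKIR effect, `ln[OR]_high − ln[OR]_low`. Carriage
frequency is used for the weights because it is the only frequency
computable from an unphased cohort table without extra assumptions. The
null distribution is built by permuting the score vector across
individuals — genotypes, status and sex stay fixed — and the p-value uses
the add-one rule `(n_as_extreme + 1)/(n_perm + 1)`, which can never
return zero. Tests are one-sided by default with the direction fixed a
priori (protective set: statistic > 0); the two-sided option exists for
the detrimental-genotype question, where no direction is predicted.

Each permutation refits two sex-adjusted logistic models per genotype.
Individual data collapse onto 2(genotype) × 2(sex) binomial cells within
each stratum, so the package refits thousands of permutations at once
with a vectorised Newton solver on the aggregated cells; agreement with
`stats::glm` at machine precision is part of the test suite. Permutations
in which a stratum estimate does not exist (e.g. no genotype-positive
cases) drop that genotype for that permutation; the run aborts if more
than 20% of permutations are lost.

## Driver screen and multiplicity

All carried single class I alleles, single class II alleles and two- and
three-allele class II combinations are enumerated (canonical sorted
labels). A genotype is a *driver* if it is marginally significant
(sex-adjusted) and never loses significance at `alpha_retain = 0.05`
(a default; the criterion's level is not stated anywhere citable) nor
flips sign when co-fitted pairwise with any other genotype. Pairs with
|r| >= 0.99 are not co-fitted — the member with the smaller marginal p
survives the pair, ties surviving both — because a joint fit of
near-collinear indicators estimates nothing interpretable.

The effective number of tests uses the Li & Ji eigenvalue estimator on
the Pearson correlation matrix of carriage indicators (Nyholt's estimator
is available as an option), with eigenvalues snapped to integers within
1e-9 — the estimator's fractional-part arithmetic is otherwise unstable
exactly at its designed limits (duplicate columns, identity). The
Bonferroni cutoff is `alpha / Meff`.

## Family transmission analysis

Trios are stratified by the *affected child's* score (ties to low, for
consistency with the case-control convention). For each heterozygous
(informative) parent we count transmissions versus non-transmissions of
the genotype-bearing haplotype; the statistic is the difference of log
transmission odds between strata, `D = log(T/NT)_high − log(T/NT)_low`
(the raw-ratio difference is available; log is the default as it is
symmetric and additive). Zero cells get +0.5 on all four cells, always
flagged in the output. Aggregation over a genotype set is the
carriage-frequency-weighted mean of per-genotype D, mirroring the
case-control statistic; the null is built by permuting children's scores
across trios, which leaves parental data untouched.

## Impact estimates

The prevented fraction uses the counterfactual formula `PF = f (1 − RR)`
with the odds ratio converted to a relative risk via
`RR = OR / ((1 − p0) + p0 OR)` at the disease prevalence. The *relative
increase* between the all-low-score and all-high-score scenarios,
`100 (PF_low − PF_high) / PF_high`, is scale-invariant, so it can be
evaluated directly on published prevented-case percentages regardless of
the exact PF derivation. The normalized-score OR rescales the score by
its attainable range under the weight table before fitting within
genotype carriers; by the reparameterisation identity this equals the
raw-score OR raised to the power of the range.

## The β-cell destruction model

The ODE system fixes one concrete realization of the described mechanism
(β-cell killing, Treg suppression, antigen-driven proliferation, shared
carrying capacity):

$$\frac{dB}{dt} = -\kappa E \frac{B}{1 + qR}, \qquad
\frac{dE}{dt} = \sigma_E + \rho_E E \frac{B}{s+B} g - \delta_E E, \qquad
\frac{dR}{dt} = \sigma_R + \rho_R R \frac{B}{s+B} g - \delta_R R$$

with `g = 1` (model 1) or `g = max(0, 1 − (E+R)/K)` (model 2); model 1 is
the `K → ∞` limit of model 2, verified numerically. The iKIR-high arm
multiplies both T cell death rates by `(1 − eps)`; outcome is T1D when
`B(t_end)/B(0) < theta` (default `theta = 0.1`; the onset threshold is a
versioned setting because the outcome classification depends on it).
Integration is `deSolve::lsoda` with rtol 1e-8 / atol 1e-10; failures
exclude the individual and more than 5% failures abort the run.

Cohorts sample parameters log-uniformly from ranges fixed once and
verified by simulation to place the cohort in the regime where the
mechanism under study operates: suppression-dominated killing
(`qR >> 1`) wherever Tregs can still scale with survival, so that a
survival change is compensated; Treg production dominated by
capacity-limited proliferation (small σ_R, larger ρ_R), so that high-σ_R
individuals — the stand-ins for protective class II carriers — pin their
Treg levels at the carrying capacity and *cannot* compensate. Under
these defaults (`eps = 0.4`, `t_end = 30`, time in arbitrary units with
β-cell mass normalised to 1) model 2 shows a rising difference in
ln[OR] between arms across Treg bins while model 1 does not, and all
three outcome classes (always-healthy, always-T1D, arm-dependent) are
populated. Quantitative curves are not a target — the equations and
parameter values stand in for unpublished ones — only this qualitative
signature is.

Binning uses quantiles of the mean Treg count over the simulation
(averaged over the two arms); a bin where either arm has zero or only
T1D outcomes has no finite odds and is reported as `NA`, not dropped.
The trend test is a one-sided Spearman correlation of the binned
difference against bin index.

## Numerical and design notes

* Permutation engine and `glm` must agree: the batch Newton solver is
  damped (step clipping at ±5), iterates to 1e-10, and flags |coef| > 15
  or unmixed genotype margins as inestimable.
* Parameter-recovery experiments generate from the model being fitted
  (one genotype, its score interaction, sex). With the full
  multi-genotype generator the two-term fitted model targets a different
  (marginal) estimand because omitted genotype effects correlate with
  carriage through the haplotype pool, and CI coverage of the generative
  coefficient is then not the property to demand. The full generator is
  still what the analysis drivers and direction/calibration checks use.
* Independence of KIR and HLA carriage is checked on a config with all
  disease effects zero: with quota sampling and non-zero effects,
  conditioning on status induces a collider dependence that is a feature
  of case-control sampling, not of the genotype model.
* Problem sizes in the test suite (200 null cohorts of n = 2,000 with
  2,000 permutations; 200 recovery replicates at n = 4,000; 50 screen
  replicates with ~100 genotypes; ODE cohorts of n = 2,000) were chosen
  as the smallest sizes at which the calibration bands are meaningfully
  narrow.
* The command-line surface of this toolkit is the set of numbered
  scripts under `analysis/` plus `scripts/acceptance.R`; the exported
  functions are the API, so no separate shell wrapper is shipped.

## Known limitations

The ligand groupings are deliberately coarse (no allele-level or
peptide-dependent binding); the weight table is a package default, not a
measured quantity; the generator omits relatedness and fine-scale LD, so
the permutation calibration says nothing about confounding by ancestry;
the ODE model is a minimal realization whose parameter ranges were tuned
for mechanism, not fitted to patient data; and the driver screen's
collinearity rule (like any such rule) can keep either member of an
effectively identical genotype pair.
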