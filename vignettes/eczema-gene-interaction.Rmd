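---
title: "Methods: case-control association and gene-gene interaction for epidermal barrier gene variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control association and gene-gene interaction for epidermal barrier gene variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcassoc)
```

## The study design the package models

`edcassoc` analyses case–control candidate-gene studies of atopic eczema in
children under two years of age, followed to age six.  Cases are children
with physician-diagnosed eczema (graded mild/moderate/severe by SCORAD:
below 25, 25–50, above 50); controls are healthy children with no eczema, no
asthma, and — by the recruitment criterion — a negative family history of
allergic disease.  Asthma is recorded only within the eczema group
("eczema-associated asthma"), so asthma ⇒ eczema is a data invariant, not an
empirical finding.  Sensitization means specific IgE ≥ 0.7 kU/L to at least
one tested allergen; polysensitization to more than one.

Exposures are genotypes at two epidermal differentiation complex SNPs — HRNR
rs877776 (reference G, risk C) and FLG2 rs12568784 (reference G, risk T) —
and the combined FLG genotype: carrier of at least one of the four common
loss-of-function mutations R501X, 2282del4, R2447X, S3247X ("FLG null").
Risk alleles are declared in the site table, never inferred from sample
frequencies.  Missing genotype calls keep the subject in the cohort but
exclude it, complete-case, from any statistic that needs the site; this is
why denominators legitimately differ across report tables.

## Association statistics

**Hardy–Weinberg.**  The allele frequency q is estimated from the tested
subgroup (controls by default), expected counts are n·((1−q)², 2q(1−q), q²),
and the statistic is the plain Pearson χ² on 1 df (one parameter estimated).
No continuity correction by default, since the plain goodness-of-fit test is
the convention in this literature; a corrected variant sits behind
`correct = TRUE`.  A monomorphic sample is flagged degenerate (χ² = 0,
p = 1) rather than erroring, so that pipeline runs on small subgroups
degrade gracefully.

**Genetic models.**  The dominant model compares carriers of ≥ 1 risk allele
with wild-type homozygotes; the recessive model isolates risk homozygotes;
`genotype3` is the 0/1/2 trend coding; the allele (multiplicative) model
expands each subject into two allele-level observations.  Crude ORs are
ad/bc with the Woolf log-scale interval — chosen because it reproduces the
published crude intervals on this design (e.g. 2.91 with CI 1.19–7.13 from
the 17/26/11/49 asthma-by-HRNR table).  When exactly one cell is zero, the
Haldane–Anscombe 0.5 correction is applied to all cells for the estimate and
interval and recorded in the method string; a double zero on a diagonal
leaves the OR undefined and is an error.  P-values follow the "χ² or Fisher
exact, as appropriate" rule: Fisher (two-sided, fixed margins, summing
hypergeometric probabilities no larger than the observed table's) whenever
any expected cell is below 5, Pearson χ² without Yates correction otherwise;
both are always computable on demand.  All p-values are two-sided and no
multiple-testing adjustment is applied (`p.adjust` can of course be applied
to any emitted column).

**Adjusted ORs.**  Covariate adjustment (age in months, sex, family history
of atopy) uses maximum-likelihood logistic regression (IRLS, log-likelihood
tolerance 1e-10, cap 100 iterations).  Because controls are
family-history-negative *by design*, the family-history covariate
quasi-separates any eczema-versus-control model; the fitter flags separation
(a fitted probability within 1e-6 of 0 or 1 with a diverging coefficient)
and, by default, refits with Firth's penalized likelihood (Newton iteration
on the hat-diagonal-corrected score), which keeps estimates finite.
Adjusted estimates are reported alongside crude ones but the package's
frozen expectations pin only crude statistics: published adjusted values
depend on unstated covariate handling and are not reproducible from counts.

**Severity and stratification.**  Severity association compares moderate
against mild cases (mild as reference; no severe cases occur in this
design — a non-empty severe class is reported and excluded with a warning).
Stratified association reruns the chosen model independently inside the
FLG-normal and FLG-null strata, reporting per-stratum n and flagging empty
strata as not estimable.

## Gene–gene interaction

The joint-exposure analysis cross-classifies two binary factors into four
strata.  The "RR" of these tables is the ratio of within-stratum case
proportions cases/(cases+controls) against the doubly-unexposed stratum.
**This is a case–control design artifact, not a population risk ratio**: it
depends on the case and control quota sizes.  It is nonetheless the scale on
which this study family reports its joint-genotype tables, and every
published stratum value is reproduced by exactly this definition, so the
package computes it, from unrounded proportions, and documents it as such.
An OR-based variant of the same measures is available by passing stratum
odds ratios to `additive_interaction()` / `multiplicative_interaction()`.

From the unrounded RRs:

* RERI = RR₁₁ − RR₁₀ − RR₀₁ + 1, AP = RERI/RR₁₁,
  S = (RR₁₁−1)/((RR₁₀−1)+(RR₀₁−1)) (undefined when the denominator is 0,
  reported as such);
* ratio of RRs = RR₁₁/(RR₁₀·RR₀₁);
* the product-term Wald test from the logistic fit of outcome ~ A + B + A·B.

Zero-control strata (which occur in the published tables) get their
uncorrected point RR — reproducing the printed values — with a
Haldane-corrected, explicitly flagged interval.  Intervals for RERI/AP/S are
delta-method on the joint log-RR covariance (the three log-RRs share the
reference-stratum variance term; S through ln S), falling back with a
warning to a stratified bootstrap (cases and controls resampled as
multinomials over the four strata, totals fixed, percentile intervals,
seeded) whenever a zero cell invalidates the log-RR variances.

## Biomarker prediction

The default evaluation contrasts outcome-positives (eczema-associated asthma
cases) with healthy controls; eczema cases who did not develop asthma belong
to neither group and are excluded from the default matrix.  This is the only
reading under which all four published HRNR/FLG2 metric quadruples are
simultaneously consistent with the joint-genotype counts; a within-eczema
evaluation is available through the `positives`/`negatives` filters.
Sensitivity and specificity intervals are Clopper–Pearson exact (these
reproduce the published intervals); the interval method for PPV/NPV is
configurable (Clopper–Pearson default, logit Wald variant) because no single
standard method reproduces the published PPV/NPV intervals.  Zero
denominators leave a metric undefined with a reason, never a silent zero.

## The synthetic-cohort generator

The generator exists so that every downstream stage is testable without
subject-level data; its defaults are fixed to the study conditions and are
not tuning knobs:

* quotas 103 cases / 85 controls; risk-allele frequencies from the control
  allele counts (HRNR C 23/170 = 0.135, FLG2 T 18/170 = 0.106);
* FLG-null carrier probability 0.03 — chosen, within the low end of European
  combined-carrier frequencies, so that the selected case/control carrier
  fractions land near the observed ones (about 2% of controls, about 14% of
  cases) under the disease model below;
* eczema model: logistic, intercept −2.0, dominant log-odds equal to the
  log crude ORs (HRNR ln 2.49, FLG2 ln 2.17, FLG null ln 6.53), no
  interaction by default;
* asthma generated only among eczema cases (intercept −2.2, dominant
  log-odds ln 2.91 / ln 5.03 / ln 3.0);
* sensitization for everyone, with an eczema term (ln 6) carrying the strong
  case–control contrast and modest direct genotype effects;
* ages truncated-normal on 0–24 months (mean 14.5, SD 6), 56.9% male,
  family history in 55.3% of cases (controls negative by design), moderate
  SCORAD for 41.7% of cases (the severity-table split, which the package's
  severity analyses use; the characteristics table's alternative 77/23 split
  conflicts with it and was not adopted), polysensitization for 28.8% of the
  sensitized, lognormal total IgE with group geometric means 24.6 / 17.7
  IU/mL.

Genotypes are drawn under Hardy–Weinberg equilibrium by construction;
case–control accrual is rejection sampling (chunked, capped at 1e7 draws
with an informative failure) which reproduces the sampling design exactly
and keeps cohorts byte-identical under a fixed seed.  Because a logistic
model cannot hit an arbitrary additive-scale interaction target exactly, a
"risk-table" mode assigns stratum-specific disease probabilities directly
for two dominant-coded factors.  The generator matches cases and controls
only marginally (same age/sex distributions), not pairwise — how the
original matching was done is not recoverable — and it simulates no linkage
disequilibrium between sites and no environmental covariates; tests passing
on simulated cohorts therefore validate the statistical machinery, not
claims about real EDC haplotype structure.

## Numerical and testing choices

Display rounding is round-half-away-from-zero at 1 decimal for percentages,
2 for ORs/RRs, 3 for p-values; all computation uses unrounded values, and
the "paper"-style renderer (with its "÷" interval separator) is formatting
only.  Monte-Carlo test scales were chosen to keep the default suite fast on
one CPU while leaving negligible simulation error relative to the asserted
bounds: the Fisher-vs-enumeration identity is exhaustive for all 2×2 tables
with total ≤ 30 (46,376 tables) plus 1,500 seeded random tables with totals
up to 60; the logistic-equals-crude-OR identity uses 1,000 random tables at
tolerance 1e-6; simulator parameter recovery uses 500 replicates at
2,000/2,000 for the central scenario (dominant OR 2.5; bias bound 0.05 on
the log-OR, Woolf coverage within the binomial 99% band of 0.95) and 120
replicates for the flanking ORs 1.5 and 5.0; the product-term test's type-I
error uses 500 replicates at 500/500 and its power check 120 replicates at
2,000/2,000 with a product log-odds of ln 3; delta-method RERI coverage uses
400 replicates of independent binomial strata on an exactly additive risk
vector.

## Known limitations

* The within-stratum "RR" caveat above: none of the interaction measures
  here estimate population risk-ratio interaction without external
  prevalence information.
* Adjusted ORs and published product-term p-values are reported but not
  pinned (covariate handling in the source analyses is unstated).
* No haplotype or linkage-disequilibrium analysis, no conditional logistic
  regression for matched pairs, no gene–environment terms, no
  prevalence-adjusted projection of PPV/NPV to other populations.
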