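---
title: "Methods: gated drug-target Mendelian randomization in lipidmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gated drug-target Mendelian randomization in lipidmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmr)
```

## The model

`lipidmr` estimates the causal effect of pharmacologically modulating a
lipid drug target on a binary outcome, using cis-acting genetic variants as
instruments. For SNP $j$ with per-allele effect $\beta_{Xj}$ (standard
error $s_{Xj}$) on the lipid exposure and $\beta_{Yj}$ ($s_{Yj}$) on the
outcome log-odds, the Wald ratio is
$\hat\theta_j = \beta_{Yj}/\beta_{Xj}$ with first-order standard error
$s_{Yj}/|\beta_{Xj}|$ (the exposure-side sampling variance is ignored,
adequate for strong instruments; see *Limitations*). The
inverse-variance-weighted (IVW) estimate is

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
\qquad w_j = \frac{\beta_{Xj}^2}{s_{Yj}^2},$$

valid when all instruments satisfy relevance, independence from
confounders, and the exclusion restriction. Restricting instruments to the
cis region of the gene encoding the drug target makes the exposure a proxy
for target modulation rather than for lipids in general.

The two-sample design assumes non-overlapping exposure and outcome GWAS
samples; a positive-control stage guards against invalid instruments:
every target is first tested against an outcome whose causal relation to
lipid lowering is established (coronary heart disease), and only targets
whose control IVW p-value falls below `gate_alpha` proceed to the disease
outcome.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_bp` | 100000 | bp | cis window flanking the gene body on each side; anchored to the gene body, not the TSS |
| `p_threshold` | 5e-8 | — | genome-wide significance, applied strictly (`<`) |
| `r2_threshold` | 0.001 | r² | SNP pairs at or above it are considered linked during clumping |
| `palindrome_eaf_window` | 0.08 | frequency | palindromic SNPs with eaf in [0.42, 0.58] are strand-ambiguous and dropped; conservative standard practice |
| `f_threshold` | 10 | — | mean F at or below 10 flags weak instruments; weak sets are flagged, never auto-excluded, since the published tables report F without stating an exclusion |
| `gate_alpha` | 0.05 | — | gate level; reproduces the published kept/excluded split (the ANGPTL3 control p of 0.064 is excluded, all retained targets have control p < 0.002) |
| `presso_n_sim` | 1000 | draws | MR-PRESSO simulation depth; p-value resolution is 1/(n_sim+1) |

## Design choices where the design was open

**Greedy clumping with deterministic tie-breaks.** Candidates are ranked by
p-value, ties broken by position and then SNP id; the best remaining SNP is
retained and all linked (r² ≥ threshold) candidates discarded. No clumping
algorithm is canonical in summary-statistic MR; greedy best-first is the
behaviour of the standard tooling, and the deterministic tie-break makes
runs byte-reproducible. An exhaustive-check oracle in the test suite
verifies the greedy invariants on random instances.

**F-statistic.** The default per-SNP F is the squared Wald z,
$(\beta/s)^2$, the definition consistent with reporting mean F per
instrument set without genotype-level data. The variance-explained form
$F = r^2(n-2)/(1-r^2)$ with $r^2 = 2\,\mathrm{eaf}(1-\mathrm{eaf})\beta^2$
is available as `f_statistics(..., method = "r2")`.

**IVW mode.** The default is multiplicative random effects: the standard
error is inflated by $\sqrt{\max(1, Q/(J-1))}$, never deflated. The point
estimate is identical to fixed effects, so the choice affects only
uncertainty; with a single instrument the estimator falls back to the Wald
ratio with a warning.

**MR-Egger conventions.** Pairs are oriented so exposure betas are
non-negative (both betas flipped jointly, to which the slope is
invariant); the regression is weighted by $1/s_{Yj}^2$; standard errors use
the WLS covariance with residual variance floored at 1; inference uses
$t_{J-2}$. The intercept estimates average directional pleiotropy, defined
on the exposure-increasing allele orientation.

**MR-PRESSO internals.** The global test simulates the leave-one-out
residual sum of squares parametrically:
$\beta^*_{Xj} \sim N(\beta_{Xj}, s_{Xj})$,
$\beta^*_{Yj} \sim N(\hat\theta_{(-j)}\beta_{Xj}, s_{Yj})$, with fresh
leave-one-out estimates recomputed on each replicate; empirical p-values
use the $(1 + \#)/(n_{sim}+1)$ convention, the per-SNP outlier test is
Bonferroni-adjusted over the $J$ instruments, and the distortion test
compares the observed estimate shift after outlier removal with the shift
distribution over random same-sized subsets. At least 4 instruments are
required. All stochastic routines take an explicit seed.

**Interval arithmetic.** All 95% intervals use $z = 1.959964$ (not 1.96) so
that interval arithmetic reproduces tabulated values at the printed
precision. IVW p-values use the normal reference. Rendered tables print
betas, standard errors and ORs to 3 decimals, I² to 3 decimals, and
p-values to 3 decimals, switching to scientific notation (e.g. `1.18E-07`)
below 0.001.

**Harmonization policy.** The source studies do not state one, so the
package declares its own: allele-label match (directly or after strand
complement) keeps a pair, a swapped match flips the outcome beta,
palindromic SNPs are resolved by frequency only outside the ambiguity
window, and anything irreconcilable is dropped with a per-SNP action label.
No LD-proxy substitution is attempted for SNPs missing from the outcome:
they are dropped and counted, which is also why instrument counts may
differ between the control and disease stages (each stage re-harmonizes
against its own outcome table).

**Degenerate inputs.** A zero exposure beta is a degenerate instrument
(error); an empty instrument set is a valid selection outcome that renders
as a blank table row and fails the gate; rows violating record invariants
(non-positive se, p outside (0,1], non-SNV or identical alleles, duplicate
ids) are dropped at read time with per-reason counts.

## What the synthetic generator emulates — and what it does not

`simulate_target()`/`simulate_study()` generate exposure, control-outcome
and disease-outcome summary tables with known truth. Emulated:

- GWAS-scale precision: $s = 1/\sqrt{2\,\mathrm{eaf}(1-\mathrm{eaf})\,n}$
  for a variance-standardized trait, with sample-size defaults matching the
  source datasets (exposure 188,577; control 184,305; disease 212,231);
- planted significant cis SNPs (true |β| uniform on [0.06, 0.14] with
  random sign — comfortably genome-wide significant at these sample sizes,
  giving mean F in the hundreds as in the published tables), decoy SNPs
  outside the window or with null effects, and planted LD pairs to
  exercise clumping;
- pleiotropy regimes (none / balanced / directional) and planted outliers,
  both defined on the exposure-increasing allele orientation so that
  directional pleiotropy is a meaningful, recoverable quantity;
- allele-orientation and strand scrambling of the outcome tables, and a
  configurable palindromic fraction (with frequencies steered away from
  0.5 so planted instruments survive harmonization);
- independent exposure/outcome noise, matching the two-sample assumption.

Not emulated: real LD architecture (LD exists only in the r² matrix fed to
clumping; estimator noise stays independent across SNPs — a documented
simplification), real lipid genetic architecture, sample overlap, and the
case/control imbalance of the disease GWAS. The last point matters for
interpretation: the disease sample-size default gives per-SNP outcome
standard errors far smaller than a GWAS with ~1,000 cases would have, so
synthetic disease-stage p-values are much smaller than the published ones,
and tiny absolute deviations can reach nominal significance in null
targets. Passing tests therefore demonstrate the correctness and
calibration of the machinery, not the reproduction of the published effect
sizes' uncertainty; the published per-target numbers enter the test suite
only through the reporting-transform and gate checks.

## Problem sizes used by the validation suite

The calibration and recovery checks use: IVW recovery at $J=30$, true
effect 0.3, 500 replicates (mean within 3 Monte-Carlo standard errors, CI
coverage in [0.92, 0.97]); Cochran's Q null calibration at $J=10$, 500
replicates under a true zero effect (where the weighted ratio residuals
are exactly chi-square); Egger-intercept recovery at $J=50$, 200
replicates, directional pleiotropy mean 0.05 and spread 0.01, simulated
under a zero causal effect so that intercept recovery is isolated from
regression-dilution attenuation of the slope; MR-PRESSO at $J=20$ with 500
simulation draws, 200 replicates for both the null rejection rate and the
detection of a planted outlier offset of 10 outcome standard errors; and
1,000 random clumping instances at $J\le12$ against the exhaustive oracle.
These sizes give stable rates while keeping the full suite's runtime modest.

## Known limitations

- First-order Wald weights ignore exposure-side variance; with very weak
  instruments CI coverage degrades (the weak-instrument flag marks such
  sets).
- MR-Egger suffers regression dilution when instrument strength varies
  little; its slope is reported as a sensitivity estimate, not the primary
  one.
- The distortion test's subset-resampling p-value is a diagnostic, not a
  calibrated test, when only one outlier exists.
- No Steiger directionality filtering and no reverse-direction analysis
  are implemented; the workflow is one-directional by design.
- LD matrices are external inputs; the package does not compute LD from
  genotypes.
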