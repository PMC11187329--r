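# lipidmr

Two-sample **drug-target Mendelian randomization** (MR) for lipid-lowering
therapies, with a positive-control gate and a full sensitivity battery.

## The scientific problem

Whether a lipid-lowering drug class could help (or harm) a second condition
can be probed without a trial by using genetics: common variants near the
gene encoding the drug's protein target (e.g. *HMGCR* for statins, *PCSK9*
for alirocumab, *NPC1L1* for ezetimibe, *APOB*, *ANGPTL3*, *PPARA*, *APOC3*,
*LDLR*, *LPL*) that also shift LDL cholesterol or triglycerides act as
lifelong, randomized proxies for pharmacological modulation of that target.
`lipidmr` implements this cis-instrument, two-sample MR design end to end:

1. **Instrument selection** — SNPs within a 100 kb window of the target
   gene, genome-wide significant for the lipid trait (p < 5×10⁻⁸), pruned
   to independence by greedy LD clumping at r² < 0.001, and screened by the
   F-statistic F = (β/se)² (mean F ≤ 10 flags weak instruments).
2. **Harmonization** — exposure and outcome summary statistics aligned to
   one effect allele, with strand-ambiguous palindromic SNPs dropped when
   their frequency is uninformative (eaf ∈ [0.42, 0.58]).
3. **Estimation** — per-SNP Wald ratios θⱼ = β_Yⱼ/β_Xⱼ with first-order
   weights wⱼ = 1/se²(θⱼ), combined by inverse-variance weighting
   (multiplicative random effects by default):
   β̂ = Σwⱼθⱼ / Σwⱼ, reported as OR = exp(β̂) with 95% CI
   exp(β̂ ± 1.959964·se).
4. **Positive-control gate** — each target is first tested against an
   outcome with an established causal link (coronary heart disease for
   lipid lowering); only targets with control IVW p < 0.05 proceed to the
   disease outcome (acne vulgaris in the motivating study).
5. **Sensitivity battery** — Cochran's Q and I², MR-Egger slope/intercept
   (directional pleiotropy), MR-PRESSO global/outlier/distortion tests,
   leave-one-out, and funnel-plot data.

Because the real consortium GWAS inputs are large external downloads, the
package ships a **synthetic summary-statistic generator** with known ground
truth (true causal effects, pleiotropy regime, planted outliers, LD
structure, allele-orientation scrambling) so that every stage is testable
and calibratable offline. It is intended for biostatisticians and
epidemiologists who want a transparent, fully tested reference
implementation of the gated drug-target MR workflow.

## Worked example

```r
library(lipidmr)

# a synthetic multi-target study with planted truth
sim <- simulate_study(seed = 1)
reports <- run_study(sim$config)
gate_summary(reports)[1:5, ]
#>    target lipid_trait n_snps     control_p gate_passed
#> 1   HMGCR         LDL      7 1.591032e-184        TRUE
#> 2   PCSK9         LDL     12 1.629494e-298        TRUE
#> 3  NPC1L1         LDL      3  1.835311e-59        TRUE
#> 4    APOB         LDL     20 1.441502e-110        TRUE
#> 5 ANGPTL3         LDL      3  4.995139e-01       FALSE
```

Every target with a planted positive-control effect passes the gate; the
ANGPTL3-like target (no planted control effect) is excluded, and targets
with zero significant cis SNPs render as blank rows. At the disease stage
the planted effects are recovered — e.g. the PCSK9-like target, simulated
with a true log-odds effect of 0.578, returns

```r
reports[["PCSK9.LDL"]]$disease_mr[, c("beta", "or_value")]
#>        beta or_value
#> 1 0.5623332 1.754762
```

The reporting transform reproduces published-style numbers directly:

```r
to_or(beta = 0.578, se = 0.233)
#>   or_value or_ci_low or_ci_high       pval
#> 1  1.78247  1.128996   2.814182 0.01311296
```

i.e. OR 1.782 (95% CI 1.129–2.814), p = 0.013.

The `analysis/` directory holds the numbered workflow drivers:

```sh
Rscript analysis/01_simulate_study.R 1       # synthetic data -> results/synthetic
Rscript analysis/02_run_gated_study.R 1      # gated MR -> results/study
Rscript analysis/03_sensitivity_diagnostics.R 1  # -> results/sensitivity
Rscript analysis/04_reported_transforms.R    # published-table checks -> results/reported
```

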