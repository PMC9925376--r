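# pgxepi

Pharmacogenetic pharmacoepidemiology with prescription-registry data:
does CYP2C19 metabolic capacity predict antidepressant treatment outcomes
— and in particular the risk of treatment-emergent mania — in bipolar
disorder?

Antidepressants metabolized by CYP2C19 (citalopram, escitalopram,
sertraline, amitriptyline, clomipramine) reach higher plasma
concentrations in slow metabolizers. `pgxepi` implements the complete
computational chain from raw registry-style tables to effect estimates:

1. **Phenotyping** — phased rs4244285/rs12248560 genotypes → star alleles
   (`*1`, `*2`, `*17`) → six metabolic phenotypes (PM, IM, IM+, EM, EM+,
   UM) → an inverted activity score (UM = 1 … PM = 6, higher = slower
   metabolism), plus the expanded ten-level CYP2C diplotype scheme built
   on rs2860840/rs11188059.
2. **Treatment episodes** — continuous exposure windows reconstructed
   from pharmacy dispensation dates: a refill gap exceeding 122 days (4
   months) splits episodes; each episode ends at its last dispense date
   plus the dispensed days of supply, capped at 90 days; episodes that
   may pre-date registry coverage are left-truncation-filtered.
3. **Outcomes** — early non-persistence (no second dispense within 122
   days), discontinuation within 365 days, switching to a different
   antidepressant under a 365-day-washout new-user design, and inpatient
   mania (ICD-10 F300–302, F308–309, F310–312, F316) within 91 days of
   treatment start, each with covariate flags (monotherapy, mood
   stabilizers, CYP2C19 inducers/inhibitors) and sensitivity variants.
4. **Inference** — GEE logistic regression with exchangeable working
   correlation for the binary outcome; Cox regression with cluster-robust
   (sandwich) standard errors for the survival outcomes, since persons
   contribute multiple episodes; the activity-score trend model whose
   hazard ratio is per one-step slowing of metabolism; nested Wald
   interaction tests; Kaplan-Meier medians; and the Schoenfeld-type
   sample-size requirement

   E = (z₁₋ₐ⁄₂ + z_power)² / { p(1−p) (log HR)² },  n = ⌈E / event rate⌉.

5. **Synthetic registry** — real registry extracts are access-restricted,
   so `simulate_registry()` generates cohorts with the same joint table
   structure (genotypes at haplotype frequencies 0.147 for `*2` and 0.19
   for `*17`, refill-interval dispense streams with dropout, rare mania
   admissions whose hazard scales with the activity score, deaths,
   co-medications), making every stage testable end to end.

## Worked example

```r
library(pgxepi)

cfg <- sim_config(n_subjects = 2500, target_mania_rate = 0.03, seed = 23)
run <- run_study(cfg)
run$manifest$n_events
#>  nonpersistence discontinuation          switch           mania
#>            1228            2725             581             115

ma <- run$records$mania
trend_cox(ma[ma$drug_group == "sertraline", ])
#> cox-clustered model (HR scale): 1201 records, 669 persons, 29 events
#>          term estimate ci_low ci_high       p
#>      exposure    1.384  1.085   1.764 0.00874
#>       sexmale    1.003  0.475   2.119 0.99300
#>         wave2    1.168  0.429   3.177 0.76100
#>         wave3    1.345  0.514   3.524 0.54600
#>  age_at_start    1.016  0.994   1.038 0.15200
```

The `exposure` row is the per-step trend: each one-step slowing of
CYP2C19 metabolism multiplies the 91-day mania hazard by 1.38 (95% CI
1.09–1.76) in this simulated cohort, whose generating per-step HR was
1.3. The remaining rows are the adjustment covariates (sex, genotyping
wave, age at treatment start); 29 events among 1,201 sertraline episodes
is the rare-event regime these analyses live in.

How large must a cohort be to detect modest effects on such rare
phenotypes? With the smaller group at 3.6% of the sample and a 50% event
rate, 80% power for HR 1.2 requires:

```r
cox_sample_size(1.2, exposed_proportion = 0.036, event_rate = 0.5)$n_total
#> [1] 13608
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
chain; each is a thin script over the package functions and writes its
tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | synthetic cohort + genotype/phenotype summary |
| `02_episodes.R` | episode reconstruction, attrition, gap sensitivity |
| `03_outcomes.R` | four outcome tables, event rates, KM medians, flags |
| `04_models.R`   | GEE/Cox grid, trend HRs, interaction Wald test |
| `05_power.R`    | sample-size grid for the rare-phenotype comparison |

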