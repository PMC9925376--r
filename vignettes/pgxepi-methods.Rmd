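---
title: "Methods: CYP2C19 pharmacogenetics and antidepressant outcomes from registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CYP2C19 pharmacogenetics and antidepressant outcomes from registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxepi)
```

## The scientific problem

Antidepressants are widely used in bipolar depression despite limited
efficacy evidence and a known risk of treatment-emergent mania. Several of
them — citalopram, escitalopram, sertraline, amitriptyline, clomipramine —
are metabolized by the CYP2C19 enzyme, and common *CYP2C19* variants shift
plasma concentrations from poor to ultra-rapid metabolism. `pgxepi`
implements the full computational chain needed to ask, with national
prescription-registry and inpatient-care data, whether CYP2C19 metabolic
capacity predicts four treatment outcomes: early non-persistence,
discontinuation within a year, switching to another antidepressant, and
inpatient mania within three months of treatment start.

Real registry extracts of this kind are access-restricted. The package
therefore ships a synthetic registry generator that reproduces the joint
*structure* of the four input tables (dispensations, admissions, phased
genotypes, demographics), so every downstream stage is exercised end to
end without any restricted data.

## Phenotype classification

Two phased SNPs define the star alleles: rs4244285-A marks the
non-functional `*2` allele, rs12248560-T the increased-function `*17`
allele, and the wild type is `*1`. A haplotype carrying both variant
alleles is not a defined star allele; because the input is phased, such a
haplotype indicates data corruption and `star_allele()` raises an error
naming the person rather than silently dropping the row.

The unordered diplotype maps to six phenotype levels — PM (`*2/*2`), IM
(`*2/*1`), IM+ (`*2/*17`), EM (`*1/*1`), EM+ (`*1/*17`), UM (`*17/*17`) —
and to an *inverted activity score* used as an ordinal trend exposure:

```{r}
phens <- c("UM", "EM+", "EM", "IM+", "IM", "PM")
setNames(activity_score(phens), phens)
```

Only the endpoints of this score (UM = 1, PM = 6) are pinned by the
published scheme; the interior follows the natural rank order of the six
levels and can be overridden through `score_map` should a different
spacing be preferred.

The no-recombinant constraint has a useful consequence: the six phenotype
counts are fully determined by the two per-SNP genotype margins plus the
number of double heterozygotes. `cohort_from_genotype_margins()` exploits
this to expand a published marginal genotype table into an explicit phased
cohort whose classification can be recomputed and checked — PM equals the
A/A count, UM the T/T count, IM + IM+ the G/A count, EM+ + IM+ the C/T
count.

An expanded ten-level CYP2C diplotype scheme adds rs2860840 and
rs11188059, which define the ultra-rapid CYP2C:TG haplotype on a `*1`
background. The scheme pins rank 1 (CYP2C:TG/CYP2C19\*17), rank 10
(CYP2C19null/CYP2C19null) and the reference diplotype (CYP2C:CG or
TA/CYP2C:CG or TA); the interior ordering comes from an external
supplement that is not reproduced here, so it ships as an editable CSV
(`inst/extdata/cyp2c_rank_table.csv`) with only the endpoints and the
reference validated on load. The packaged interior ordering is a
plausible by-metabolic-capacity default, not an assertion about the
published one.

## Treatment episodes from dispense streams

Registry data contain purchase dates and dispensed quantities (in DDD
units — one DDD approximates one day of supply), not actual intake.
Episodes are reconstructed per person and drug group by a refill-gap
rule:

* a new episode starts whenever the gap between consecutive dispense
  dates exceeds `gap_days = 122` (4 months at the 30.5 d/month
  convention); a gap of exactly 122 days continues the episode, because
  the rule is "exceeded";
* the episode ends at the last dispense date plus the last dispensed
  quantity in days, capped at `tail_cap_days = 90`;
* episodes starting on or before registry start + 122 days are dropped
  (`filter_left_truncated()`), since they may be continuations of
  pre-coverage treatment.

Month-based durations are fixed as 4 months = 122 d, 6 months = 183 d and
3 months = 91 d throughout; all are arguments, so the 183-day sensitivity
variant is one parameter away. The DDD tail is applied at the end of
*every* episode, including the final, end-of-data-truncated one: the
published rule is stated for gap-terminated episodes only, and uniform
application is the simplest consistent reading (it is configurable via
`tail_cap_days`). Quantities are rounded to whole days before the tail
computation, matching day-resolution registry arithmetic. Dispensed
amounts are expected in DDD units; `mg_to_ddd()` converts mg totals using
the WHO defined daily doses (citalopram 20 mg, escitalopram 10 mg,
sertraline 50 mg, clomipramine 100 mg, amitriptyline 75 mg).

The builder is deliberately a single greedy left-to-right scan; tests
hold it equal to an independent brute-force scanner on a thousand random
streams and assert monotonicity (a wider gap can only merge episodes).

## Outcome derivations

All four derivations run from the same episode table and person table;
sex, genotyping wave and age at treatment start are attached to every
record, and person id is the cluster variable throughout.

**Early non-persistence** (binary): failure to collect a second dispense
within 122 days of the episode's first dispense. Persons who died within
the window are excluded — they had no chance to refill. The refill window
is inclusive of day 122, chosen as the complement of the strict-exceed
gap rule; the published definition does not state inclusivity, so it is
an argument.

**Discontinuation** (survival, capped at 365 days): the event is reaching
the episode's reconstructed end before censoring at study end
(2016-12-31), death, or 365 days. An episode end coinciding with a
censoring date counts as censored, since continuation past that date is
unobservable. Variants: a 60-day follow-up cap, first-episode-only, and
exclusion of episodes with CYP2C19 inducer/inhibitor exposure.

**Switching** (survival, new-user design): index events are study-drug
dispenses with no antidepressant (ATC N06A) dispense in the preceding
365 days; the event is the first dispense of a *different* N06A substance
(different 7-character ATC code) within 365 days. Index dates are used
directly as treatment starts rather than being coarsened to calendar
months — monthly segmentation is treated as a scanning device, and
binning survival times to months would only discard resolution. A
same-day dispense of a different N06A substance makes the start ambiguous
and excludes the index rather than counting as an instantaneous switch.

**Treatment-emergent mania** (survival, capped at 91 days): the event is
the first inpatient admission carrying a mania or mixed-episode diagnosis
(ICD-10 F300–F302, F308–F309, F310–F312, F316; prefix match on the first
four characters) within 91 days of episode start, censored at the window
end or death. The event is anchored at the *admission* date by default —
the diagnosis is recorded at discharge, but admission marks onset — with
`anchor = "discharge"` available.

Covariate flags use look-back windows relative to episode start, all
inclusive of the start date: monotherapy means no other-N06A dispense in
the last 122 days; mood-stabilizer use (lithium, valproate, lamotrigine)
requires two dispenses in the last 365 days with one in the last 122; the
inducer/inhibitor flag is any dispense of carbamazepine, phenobarbital,
phenytoin, omeprazole, esomeprazole, lansoprazole, pantoprazole,
fluoxetine or fluvoxamine in the last 183 days. The published definition
of the inducer/inhibitor window ("within 6 months of treatment start")
does not state its direction; the look-back reading keeps the flag a
baseline covariate.

## Inference

Persons contribute multiple episodes, so all models treat person as the
cluster.

* **GEE logistic** (`fit_gee_logistic()`) for the binary non-persistence
  outcome: population-averaged odds ratios under an exchangeable working
  correlation with a robust sandwich covariance. No GEE fitter ships with
  the environment's R packages, so the IRLS + moment-estimator algorithm
  is implemented here; tests pin it to an independent reference fit and
  to plain logistic regression with a clustered sandwich in the
  singleton-cluster limit.
* **Cluster-robust Cox** (`fit_cox_clustered()`, via the `survival`
  package) for the three survival outcomes, with Efron tie handling —
  day-resolution registry times are heavily tied, and a declared tie
  method keeps results bit-for-bit reproducible.
* **Exposure codings** (`code_exposure()`): six-level phenotype with EM
  as reference; the sparse-event three-level collapse PM/IM/IM+ vs EM vs
  EM+/UM; the activity score as a continuous trend (`trend_cox()`; the
  HR is per one-step slowing of metabolism); and the CYP2C rank as a
  continuous or three-level exposure.
* **Interactions**: monotherapy enters as a main effect plus
  exposure-by-monotherapy term, tested jointly with a robust Wald
  chi-square on the interaction block (`wald_interaction_test()`); with
  zero extra terms the test degenerates to p = 1 rather than erroring.
* **Wave dropping**: when a genotyping wave contains no events its
  coefficient is unidentified, so the wave covariate is dropped with a
  warning and a note on the result object.
* **No multiplicity correction** is applied; p-values are reported raw,
  and the many-outcomes caveat belongs to interpretation.

`km_median()` reports Kaplan-Meier median treatment durations, absent
(NA) when the curve never crosses 0.5. `cox_sample_size()` implements the
Schoenfeld-type requirement
$E = (z_{1-\alpha/2} + z_{\beta})^2 / \{p(1-p)(\log HR)^2\}$, $n = \lceil
E/\text{event rate}\rceil$, with standard normal quantiles; it is
strictly decreasing in $|\log HR|$ and the event rate and symmetric in
$p \leftrightarrow 1-p$.

```{r}
cox_sample_size(hazard_ratio = 1.2, exposed_proportion = 0.036,
                event_rate = 0.5)$n_total
```

## The synthetic registry generator

`sim_config()` + `simulate_registry()` emulate the statistical structure
the analysis assumes, table by table, each with an independent RNG stream
derived from the master seed (adding a table never perturbs another; the
same seed reproduces byte-identical output).

* **Genotypes**: two independent haplotype draws per person at the
  configured `*1`/`*2`/`*17` frequencies (defaults 0.663/0.147/0.19, the
  frequencies of the two core variants in a European-ancestry cohort);
  SNP alleles follow deterministically, so recombinant haplotypes cannot
  occur. The CG/TA/TG background frequencies on `*1` haplotypes
  (0.6/0.2/0.2) are free parameters of the generator.
* **Dispenses**: per person and drug group, a Poisson number of streams
  with uniform start dates; refill intervals normal around 100 d (sd 25,
  floor 7), per-refill dropout probability 0.2, quantities around 100
  DDD. The published analysis reports no refill-interval or dropout
  distributions, so these defaults are chosen once as plausible for
  ~3-month dispense cycles and are not estimates of any real registry.
  Co-medication users (other antidepressants 25%, mood stabilizers 50% —
  a bipolar cohort — and inducers/inhibitors 15%) dispense those drugs at
  roughly quarterly intervals.
* **Mania admissions**: during the first 91 days of each episode an
  exponential event time with hazard
  $h_0 \exp\{\beta (s - 3)\}$, where $s$ is the activity score and
  $\beta$ the per-step log HR under test. $h_0$ is tuned by
  `tune_baseline_hazard()` so the expected 91-day event proportion is
  1.5%, matching the rare-event regime of the target analysis (about 50
  events per 3,500 episodes). Background admissions at a low per-day rate
  (default on) make the 91-day window's specificity testable.
* **Demographics**: ages 18–75 at study start, 62% female, three equal
  genotyping waves, deaths exponential at 0.6%/year (about 7% over the
  follow-up).

What the generator does *not* emulate: realistic national demography,
outpatient care, genotyping error, imputation uncertainty, dose changes,
stockpiling, or correlation between phenotype and prescribing behaviour.
A passing recovery test therefore shows that the pipeline's rules and
models are implemented correctly and estimate without material bias under
the assumed event model — not that the assumed event model describes any
real cohort.

## Parameter recovery and problem sizes

`recover_trend_hr()` is the package's end-to-end calibration experiment:
simulate a cohort, rebuild episodes from its dispenses, derive the 91-day
mania records, fit the cluster-robust trend Cox model, and repeat across
replicates. The shipped acceptance analysis uses 200 replicates of
roughly 4,000 exposed episodes (about 2,960 subjects initiating one drug
group) per effect size — per-step HR 1.3 (the sertraline-arm effect) and
1.46 (the tricyclic-arm effect) — and compares the mean estimated HR to
the simulated truth. With ~60 events per replicate the per-replicate log
HR standard error is about 0.11, so the 200-replicate mean is accurate to
about 1%; small upward (Jensen, from averaging on the HR scale) and
downward (background admissions diluting the trend) biases remain and are
well inside the ±0.1 acceptance band. Test-suite simulations (type-I
error, coverage, power) use 300–1,000 replicates of 300–600 records,
sized so each suite completes in minutes on one CPU while leaving Monte
Carlo error well below the asserted tolerances.

## Numerical choices and degenerate inputs

* Dates are handled as R `Date` (integer days) and serialized ISO-8601;
  all durations are integer days.
* GEE: IRLS stops at a 1e-8 coefficient change or 50 iterations;
  the exchangeable correlation is clamped to its positive-definite range;
  coefficients exceeding 15 in absolute value, or non-finite Pearson
  residuals, raise a separation error instead of returning garbage.
  Non-convergence is flagged on the result, not silently ignored.
* Cox: no events is an error; inestimable (NA) coefficients are dropped
  with a warning; zero score variation makes the trend model an error.
* Episode building: negative dispensed quantities are an input error;
  empty inputs return empty, correctly typed tables.
* `cox_sample_size()` refuses HR = 1 (infinite n).

## Known limitations

Adherence is unobservable in dispensation data; episode ends are
estimates under the gap/tail convention. The tricyclic group pools
amitriptyline and clomipramine, and low-dose amitriptyline for neuropathic
pain is indistinguishable from antidepressant use. The expanded CYP2C
interior ranking is configurable, not authoritative. The GEE
implementation covers the binomial/logit case with exchangeable or
independence working correlation — exactly what the analyses need, and
nothing more.
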