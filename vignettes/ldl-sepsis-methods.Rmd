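---
title: "Methods: confounder-adjusted analysis of LDL cholesterol and sepsis risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confounder-adjusted analysis of LDL cholesterol and sepsis risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisldl)
library(dplyr)
```

## The scientific problem

Patients with low LDL cholesterol (LDL-C) who are admitted to hospital with
infection have repeatedly been observed to develop sepsis, reach the ICU, and
die in hospital more often than patients with higher LDL-C. Two causal
structures can produce that observation:

* **direct**: low LDL-C itself impairs the response to infection (LDL binds
  bacterial endotoxin, so this is biologically plausible), or
* **confounded**: chronic illness lowers LDL-C *and* independently worsens
  infection outcomes, so LDL-C is a marker of frailty rather than a cause.

The distinction matters because modern lipid-lowering therapy can push LDL-C
to very low levels. `sepsisldl` implements the two complementary designs used
to separate the structures:

1. an **epidemiologic arm**: measure LDL-C well before the illness (so the
   infection cannot have depressed it), and adjust for comorbidity burden
   explicitly; and
2. a **genetic arm**: replace measured LDL-C with a genetic risk score (GRS),
   a weighted count of LDL-raising alleles fixed at conception, which no
   acquired illness can confound.

If the crude protective association disappears under comorbidity adjustment,
and the GRS — a lifelong instrument for LDL-C — shows no association at all,
the confounded structure is the parsimonious explanation.

## Cohort and exposure definitions

**Infection episode.** An admission (day 0 = admission date; all time
arithmetic is in whole days) with at least one qualifying infection billing
code dated inside the admission and at least one antibiotic record on day
−1, 0 or +1. Patients younger than 18 at admission are excluded. The index
episode is the patient's first episode; in the measured-LDL arm, the first
episode occurring more than one year after an otherwise-qualifying LDL
measurement, so that at least one measurement qualifies relative to it.
Same-day ties break lexicographically by infection code — any deterministic
rule would do; this one is reproducible across platforms.

**Baseline LDL-C.** The median of a patient's *qualifying* measurements.
A measurement qualifies when it is (i) strictly more than 365 days before the
index admission; (ii) outpatient; (iii) taken at age ≥ 18; (iv) not within
±30 days (inclusive, both directions — the rule is symmetric because acute
hypoalbuminemia flags illness both prospectively and retrospectively) of a
serum albumin below 3.0 g/dL; and (v) strictly before the first statin
mention, with a same-day LDL conservatively excluded. Medians use the
standard even-count convention (mean of the two middle values). Patients
with any configured chronic-illness code (HIV, chronic kidney disease, liver
disease, chemotherapy) in days −365..−1 are excluded from this arm.

**Units.** Lipids, creatinine and total bilirubin in mg/dL; albumin in g/dL;
platelets in 10^3/µL; BMI in kg/m². Ingest converts bilirubin µmol/L
(÷ 17.104) and albumin g/L (÷ 10); conversion is idempotent and any other
unit is a load error rather than a silent pass-through.

## The sepsis phenotype

Sepsis is called on evidence in the day −1..+1 window of the index admission
(restricting to admission-time sepsis avoids counting post-operative and
nosocomial events as outcomes of baseline LDL-C):

* an explicit severe-sepsis/septic-shock code (defaults 995.92, 785.52,
  R65.20, R65.21; config-overridable), **or** any of
* **cardiovascular** — norepinephrine, or dopamine/dobutamine together with
  a vasopressor-administration billing code;
* **respiratory** — a ventilation code *and* ICU admission;
* **renal** — window creatinine ≥ 2 × baseline;
* **hepatic** — a window bilirubin ≥ 2.0 mg/dL that is also ≥ 2 × baseline;
* **hematologic** — a window platelet count < 100 that is ≤ 0.5 × a baseline
  that was itself ≥ 100.

Baselines are per-analyte extrema (lowest creatinine, lowest bilirubin,
highest platelets) over \[admission − 365 d, discharge\]. Two consequences of
that span are deliberate and documented: window values are part of the
baseline, so a patient's *only* creatinine measurement can never satisfy the
doubling rule by itself; and an absent analyte yields an absent baseline
against which the criterion is false. All doubling/decline thresholds are
inclusive ("doubling **or greater**", "**at least** a 50% decline"). ICU
admission and in-hospital death are admission-level flags — billing data
rarely record ADT transitions, so the admission record is taken as the
source of truth for both secondary outcomes.

## Comorbidity covariates

Diagnosis codes in days −365..−1 (day 0 is outcome-era, not history) map by
longest code prefix to PheCodes and then to modified Charlson/Deyo
categories. Seventeen source categories are configured; diabetes and
diabetes-with-complications merge into one indicator, giving 16 columns.
Each category enters the models as a binary indicator — the summed Charlson
score would impose a linear severity ordering the data do not support, and
category-level indicators let each condition carry its own coefficient.
Categories that are structurally absent from the measured-LDL arm (the
chronic-illness exclusions remove mild/severe liver disease, metastatic
tumor, and HIV carriers) are dropped at fit time by an automatic
constant-column rule with a logged notice, rather than by a hard-coded list,
so the design matrix always matches the cohort actually analysed.

## The genetic risk score

For patient *i*, `GRS_i = Σ_j β_j d_ij` over the SNP panel, with `d` the
effect-allele dosage (0/1/2) and `β` the per-allele LDL-C effect in mg/dL.
Missing dosages impute at the Hardy–Weinberg mean `2·MAF` — per-patient
renormalization is the alternative, but mean imputation is simpler, standard
for score construction, and logged per SNP. Dosages are counted on the
weight table's effect allele; the VCF reader flips (`2 − d`) when the effect
allele is the REF allele. Published panels are licensed objects, so the
shipped 81-SNP table is synthetic (drawn once, labelled as such) with betas
scaled so the theoretical score variance equals 5.8% of a 32.6² LDL
variance; any user table with the documented columns can replace it. The
score is standardized at the association stage, not at construction, so
"OR per SD" is always relative to the analysis cohort. GRS models adjust for
age and sex only: genotype precedes every comorbidity, so illness-era
covariates are not confounders of the score (conditioning on them could only
introduce collider paths).

## Association models

Logistic maximum likelihood via `stats::glm`. The exposure is standardized
by the mean and SD of the final analysis cohort (after all exclusions),
making the reported OR "per 1 SD" cohort-relative; fitting raw and rescaling
by `exp(β·SD)` is algebraically identical and is asserted to 1e-8 in the
tests. Confidence intervals and p-values are Wald-based — the package does
not presume which CI method an archival analysis used, and Wald is the
common default; profile-likelihood intervals would differ only in
small-event strata. Significance uses a two-sided threshold of 0.0167
(0.05/3 for three outcomes), stored in the config rather than hard-coded.
Quartile models cut at the empirical 25/50/75 percentiles (linear
interpolation, type-7; boundary ties to the lower quartile) and code
indicators against the highest quartile. Fits with fewer than 10 events are
flagged; separation and non-convergence are classed errors naming the
predictor rather than silent estimates.

## The synthetic generator

`generate_ehr_bundle()` emulates exactly the features the pipeline's
correctness depends on:

* **Comorbidity burden** — independent Bernoulli category flags with
  configurable prevalences (defaults chosen to resemble a tertiary-care
  infection cohort); burden = the number of active categories, planting one
  coded diagnosis per category in the lookback year.
* **LDL-C** — `LDL = μ + s·(GRS − E[GRS]) + δ·(burden − E[burden]) + ε`,
  with `s` chosen so the genetic component explains `grs_target_r2`
  (default 0.058) of a `ldl_sd²` variance (default 32.6²), `δ` the
  burden shift (default −8 mg/dL per category), and `ε` sized so the
  marginal SD equals `ldl_sd`; marginal mean 103.4 mg/dL. Recorded
  measurements add small assay noise (SD 2 mg/dL).
* **Outcomes** — `logit P(sepsis) = α + 0.5·burden + β_L·z(LDL)` with the
  direct effect `β_L = 0` by default; ICU and death have their own
  burden-dependent logits. The default burden coefficient (0.5) and shift
  (−8) were fixed by a power calculation so that, after the ~25% attrition
  of the chronic-illness exclusions, the *crude* association is a per-SD OR
  near 0.86 and detectable at n = 4000 — the regime in which attenuation
  under adjustment is an informative test.
* **Evidence** — each sepsis case receives the minimal event set for one
  pathway chosen uniformly among the six (explicit code or five organ
  criteria); non-cases receive sub-threshold background labs only. Under
  default noise settings the rule-based classifier therefore reproduces the
  simulated outcome exactly, which is what makes end-to-end
  parameter-recovery tests sharp. A separate `evidence_noise_rate` plants
  random qualifying and non-qualifying events in and around the window; it
  deliberately breaks truth alignment and exists only to stress-test the
  phenotyper against its brute-force reference.
* **Filter fodder** — statin starts, post-statin and recent and inpatient
  LDL values, low-albumin windows, out-of-lookback diagnosis codes, and
  (behind a flag) additional infection episodes, so that every exclusion
  rule has work to do.

What the generator does **not** emulate: code co-occurrence and billing
realism, linkage disequilibrium between SNPs, multi-morbidity correlation
structure, time-varying LDL trajectories, and informative missingness.
Passing tests therefore demonstrate that the pipeline recovers known
parameters under the stated confounding structure — not that any particular
real-world dataset satisfies that structure.

## Numerical and reproducibility choices

* Dates are day-resolution `Date`s; all windows are inclusive integer-day
  comparisons, so there are no timezone or fractional-day edge cases.
* Age is completed years by calendar (birthday) arithmetic.
* "More than 1 year" is strictly greater than 365 days everywhere.
* A single integer seed drives the generator; identical seeds give
  byte-identical bundles, analysis tables and results.
* EHR length is (last event − first event)/365.25 years, used only as an
  extended-model covariate.
* Property tests use fixed seeds and run at reduced but informative sizes:
  10,000 episodes for the phenotyper-equivalence check, 200 replicates at
  n = 4000 for confounding attenuation, and 200 replicates at n = 8000 for
  recovery of an injected direct effect of −0.15 log-odds per SD.

## Known limitations

Exclusion-code lists and the PheCode/Charlson maps are illustrative
miniatures of their real counterparts; analyses of real data must supply
site-specific configurations. The infection-episode rule does not
distinguish community- from hospital-acquired infection beyond the antibiotic
day-window. The GRS arm takes the SNP panel as given (no LD pruning or QC),
and the package stops at the GRS–outcome association: it does not implement
formal instrumental-variable (Mendelian-randomization) estimation.
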