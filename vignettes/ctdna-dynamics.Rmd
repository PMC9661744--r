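---
title: "Paired CSF/plasma ctDNA dynamics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired CSF/plasma ctDNA dynamics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdyn)
```

## The problem

In cancers that spread to the central nervous system, the blood–brain
barrier limits how much tumor DNA from intracranial lesions reaches
peripheral blood. Cerebrospinal fluid (CSF) is therefore sampled
alongside plasma: each compartment sees a partly different slice of the
disease. `ctdyn` implements the complete analysis layer for such paired
liquid-biopsy studies, starting from per-sample somatic variant calls
(VCF) and ending at survival contrasts between molecular response
groups. It deliberately starts *after* variant calling: read alignment,
deduplication and calling are upstream concerns.

## Models and procedures

### Variant filtering and ctDNA quantification

A call is retained when its variant allele frequency (VAF) is at least
0.2%, it is supported by at least 3 unique mutant reads, and its
population allele frequency is absent or at most 1%; a user-supplied
blacklist of recurrent-artifact identity keys is honored. All
thresholds are inclusive on the passing side so that a call printed at
a cutoff passes. Copy-number calls carry no per-read allele fraction in
this data model, so they bypass the VAF/read rules and are subject only
to the blacklist.

Per sample, three quantities summarize ctDNA level:

* **maxVAF** — the largest VAF among SNV/indel/fusion calls, a proxy
  for the dominant clone's cell fraction;
* **mean VAF** — the mean over the same calls (CNVs excluded, since
  they have no allele fraction; this is a documented choice — the
  alternative of imputing CNV "VAFs" has no defensible scale);
* **ctDNA concentration** in haploid genome equivalents (hGE) per mL:

$$\mathrm{ctDNA\ (hGE/mL)} = \overline{\mathrm{VAF}} \times
  \frac{\mathrm{cfDNA\ (pg/mL)}}{3.3\ \mathrm{pg/hGE}}$$

A sample with no passing VAF-bearing call has concentration 0 but is
kept in the cohort (`is_positive = FALSE`): detection-rate statistics
need the negatives.

### Cross-compartment agreement

Two granularities are supported and must be chosen explicitly, because
they answer different questions:

* **variant-level** identity keys `(chrom, pos, ref, alt, class)` feed
  the asymmetric *consistency* statistic
  $100 \cdot |A \cap B| / |A|$ (defined only for mutation-positive
  source samples, optionally after removing CNV keys) and three-way
  Venn partitions;
* **gene-level** presence/absence feeds 2×2 contingency tables with
  Cohen's kappa, $\kappa = (p_o - p_e)/(1 - p_e)$, the form in which
  per-gene CSF-vs-plasma agreement is usually published.

Cohort consistency averages are unweighted means over qualifying
(source-positive) patients. `contingency_from_marginals()` rebuilds a
2×2 table from the positive marginals plus the agreement count — the
form in which published analyses usually report such tables — and the
reconstruction is exact or fails loudly.

### Clonality and clonal evolution

Clonality here is a relative-VAF bookkeeping definition, not a
phylogenetic one: at baseline a mutation is **clonal** when its VAF is
at least 25% of the sample's maxVAF, else **subclonal**. Equality at
the threshold is labeled clonal by default (a strict mode is exposed);
the inclusive choice makes the rule a total function and the boundary
is tested explicitly. Each compartment is assessed against its own
maxVAF. Across timepoints, variants are matched by exact identity key
(the panel and pipeline are assumed constant), every baseline mutation
is *retained* or *cleared*, and every new mutation is *acquired* and
forced subclonal whatever its VAF. The post-treatment clonal fraction
is the share of retained clonal mutations among all follow-up
mutations; **high retention** means strictly more than 80%. Complete
clearance is reported as fraction 0 with an explicit flag rather than
an error, so cohort summaries stay computable. Cohort-level
composition is reported both pooled across patients and as the mean of
per-patient fractions, since the two differ when mutation counts vary
and the field does not standardize on one.

### Molecular response and survival

A **ctDNA response** is a reduction of at least 50% in ctDNA
concentration from baseline to follow-up; the threshold is inclusive
(a patient at exactly −50% responds). Baseline-negative patients are
non-evaluable and are excluded from response-group survival contrasts;
patients with a positive baseline but no follow-up sample are skipped
and counted. Radiographic labels are binarized CR/PR → responder,
SD/PD → non-responder by default; the mapping is configurable because
published analyses rarely print their binarization.

Survival contrasts use the standard machinery: product-limit
(Kaplan-Meier) estimates with the median read as the earliest event
time where survival reaches 0.5 or below; the unweighted two-group
log-rank test (chi-square, 1 df, no continuity correction); and a
univariate proportional-hazards hazard ratio with a Wald 95% CI,
implemented on top of the `survival` package (Efron tie handling).
The package's test suite checks all three against independent
brute-force risk-set implementations to 1e-10 on random small
instances, so the wrapper cannot drift from the definitions.

## The synthetic cohort generator

No patient-level data ship with studies of this kind, so validation
runs on simulated cohorts whose *structure* matches the analysis
assumptions:

* each patient has 3–10 true somatic mutations in two VAF tiers
  (clonal 8–40%, subclonal 0.4–2%), the founder always clonal-tier, so
  the baseline maxVAF comes from the dominant clone by construction;
* a patient-level shedding gate times per-variant binomial detection
  produces compartment asymmetry; the shedding probabilities are
  derived analytically from the configured baseline positivity targets
  (63.7% CSF, 91.1% plasma) by inverting the detection model, so the
  targets are met in expectation rather than forced per sample;
* one latent CNV per patient surfaces with compartment-specific
  emission probabilities (39.3% CSF vs 21.4% plasma);
* at week 8, true VAFs scale by 0.2 for responders (≈48% of patients)
  and 1.1 for non-responders, with acquired subclonal mutations
  arriving at Poisson rate 0.7 per sample and log-normal measurement
  noise (sdlog 0.15) on observed VAFs;
* progression and survival times are exponential with group-specific
  rates (default intracranial-PFS medians 13.27 vs 6.13 months),
  censored by an independent exponential (rate 0.03/month) and a
  36-month administrative horizon — exponential by design, so hazard
  ratio recovery has a closed-form truth;
* radiographic labels flip against the true group with probability
  0.12, which sets the achievable molecular-vs-radiographic kappa.

Where no study value exists (VAF tier ranges, cfDNA log-normal
parameters, acquired-mutation rate, noise level, censoring), defaults
were chosen once at what a panel-sequencing liquid-biopsy practitioner
would call realistic, and are documented in `?cohort_config`; they are
free parameters of the simulator, not estimates of any study's data.

A single master seed drives per-patient substreams, so enlarging a
cohort leaves existing patients bit-identical, and identical
config + seed reproduce every emitted file byte for byte.

`noiseless_config()` is the degenerate limit used for exact recovery
checks: full shedding and detection, no measurement noise,
deterministic read counts, no acquired mutations, truthful radiology.
Its VAF tiers are raised (clonal 20–50%, subclonal 1.2–5%) so that
responder week-8 VAFs scaled by 0.2 stay at or above the default
detection thresholds; without this the assay floor, not the pipeline,
would bound recovery, and the 100%-agreement check would be testing
the wrong thing.

What passing these checks does *not* show: real cfDNA has fragment-level
sampling noise correlated with input mass, position-dependent error
profiles, germline contamination and clonal hematopoiesis; none of
these are modeled. The generator validates the *bookkeeping and
statistics*, not assay performance.

## Numerical and design choices

* Ties at the 25% clonality threshold and at the −50% response
  threshold are inclusive (clonal / responder), matching the way the
  defining inequalities are printed where they are printed, and tested
  at the boundary.
* Cohen's kappa returns 1 for perfect agreement with degenerate
  marginals ($p_o = p_e = 1$) and NaN when chance agreement is 1 but
  observed agreement is not.
* The log-rank statistic for two groups with zero events is 0 with
  p = 1 rather than an error.
* Variant identity is `(chrom, pos, ref, alt, class)`; the gene symbol
  is annotation. Cross-timepoint matching is exact, never fuzzy.
* Median survival is the smallest time with $\hat S(t) \le 0.5$,
  `NA` when never reached.
* Reports carry no timestamps, so reproducibility can be asserted as
  byte equality rather than "modulo volatile fields".

## Problem sizes used in validation

The shipped test suite exercises: oracle equivalence on 100 random
small instances (n ≤ 30); log-rank type-I error on 1,000 replicates of
200-per-arm cohorts (nominal 5%, accepted 3–7%); hazard-ratio coverage
on 100 cohorts of 500 patients at true HR 0.3 (≥ 90/100 Wald CIs must
cover); generator calibration as the mean baseline positivity over 5
replicate 500-patient cohorts within ±5 points of the configured
targets (a single 500-patient draw carries ≈2.2-point binomial noise,
so replication separates calibration error from sampling noise); and
exact truth recovery on noiseless cohorts. These sizes were chosen to
make the Monte-Carlo assertions statistically meaningful at desk
scale.

## Known limitations

* Multivariate survival adjustment (clinical covariates) is out of
  scope; hazard ratios are univariate.
* The consistency statistic's cohort mean is sensitive to
  low-mutation-count patients (a 1-of-1 shared variant is 100%); the
  per-patient table is always emitted so users can weight differently.
* CNV "presence" is binary; no copy-number dosage is modeled.
* Fusion calls are treated as VAF-bearing point events; breakpoint
  pairs are not modeled.
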