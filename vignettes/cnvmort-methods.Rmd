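---
title: "Methods: CNV calling, burden, and mortality association in cnvmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV calling, burden, and mortality association in cnvmort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvmort)
```

# Scope and model overview

`cnvmort` implements a complete analysis chain for studying the relation
between copy-number variation and prospective mortality in SNP-array
cohorts of long-lived individuals:

1. **Calling.** Per-sample copy-number states are decoded from the log R
   ratio (LRR, total intensity) and B allele frequency (BAF, allelic
   intensity ratio) tracks with a five-state hidden Markov model, and
   contiguous non-diploid runs become CNV calls.
2. **Sample QC.** Samples are excluded on LRR noise, call count, and
   genomic-wave contamination.
3. **Regions and burden.** Per-sample calls are merged across samples into
   CNV regions by reciprocal overlap; per-individual burden summaries
   (count, average length, total length) are computed from the calls.
4. **Association.** Burden covariates and region carrier status are tested
   against mortality with a left-truncated Cox proportional-hazards model
   on the age timescale.
5. **Joint analysis.** Per-study hazard ratios are pooled by
   inverse-variance fixed-effect meta-analysis, including a
   "published-table mode" that consumes printed HR/CI tables directly.

A synthetic-cohort generator provides marker maps, signals with implanted
CNVs, and survival outcomes with known effects, because the cohorts this
design targets are register-linked human studies whose raw data are not
publicly deposited.

# The HMM caller

## States and emissions

States are the copy numbers 0–4; the diploid state is 2.  A six-state
model with a copy-neutral LOH-like state is common in this family of
callers, but only states 0/1 (deletions) and 3/4 (duplications) feed any
downstream analysis here, so the LOH state is omitted.

At each marker the emission density is the product of

* a Gaussian LRR term with per-state means (defaults −3.5, −0.66, 0,
  +0.40, +0.68) and per-state standard deviations (CN0 is wide, 1.0,
  because with no DNA the log-ratio is essentially noise), and
* a BAF mixture whose components sit at the allelic ratios attainable at
  the state's copy number (CN2: 0, 1/2, 1; CN3: 0, 1/3, 2/3, 1; …), each
  a normal truncated to [0, 1] with sd `baf_noise_sd` (default 0.05),
  weighted by Hardy–Weinberg genotype probabilities at the marker's
  population B-allele frequency (PFB).  CN0 emits uniform BAF.

The BAF term is what distinguishes a hemizygous deletion (clusters only at
0 and 1) from diploid (a heterozygous cluster at 1/2), and it is why the
PFB table is an input of the caller.  A population-specific PFB can be
compiled as the per-marker median BAF across samples (`compile_pfb()`).

## Distance-dependent transitions

With inter-marker distance $d$ and scale $D$ (default 100 kb), the
transition matrix is

$$A(d) = e^{-d/D} A_0 + (1 - e^{-d/D})\,\Pi,$$

where $A_0$ is a near-identity base matrix (off-diagonal $10^{-4}$) and
$\Pi$ repeats the stationary distribution (heavily favouring CN2) in every
row.  Rows sum to one at every distance; adjacent markers are sticky,
distant markers decouple.  Decoding is per chromosome by the Viterbi
algorithm; ties are broken toward the lower copy number, then the earlier
state index, so the decode is deterministic.  The correctness oracle is
exhaustive path enumeration on instances of up to 8 markers.

## Call filters

Maximal constant-state non-diploid runs become candidate calls with
boundaries at the outermost marker positions (1-based inclusive).
Candidates with fewer than 3 markers or spanning less than 1 kb are
dropped.  Both cutoffs are exposed as parameters.

# Sample QC

Three per-sample metrics are computed: the standard deviation of autosomal
LRR, the number of filtered calls, and a *GC wave factor*.  The wave
factor is operationalised here as the least-squares slope of LRR on the
standardised local GC track ((gc − mean)/sd); the statistic is named but
not defined by a formula in the methods literature this mirrors, so the
definition is documented and substitutable.  A sample fails QC iff

* LRR sd > 0.30, or
* more than 100 CNVs called, or
* |GC wave factor| > 0.05.

All three are strict inequalities — boundary values pass — and every
triggered reason is reported.  Missing metrics (e.g. a constant GC track
making the slope undefined) fail closed.  The call count uses
post-filter calls; whether the original analysis counted pre- or
post-filter calls is not determinable from its description, and the
choice is documented here rather than hidden.

# Region construction

Within each (chromosome, type) stratum — deletions and duplications are
never mixed, even at identical coordinates — two calls are joined when
their overlap is at least 50% of the *shorter* call (closed inequality).
Regions are the connected components of this graph.  The pairwise rule
alone is order-dependent; taking the transitive closure makes the result
independent of input order and idempotent, at the cost of occasionally
chaining calls that do not pairwise overlap by 50%.  This is the one place
where a reimplementation of this design can systematically differ from
script-based originals, and it is deliberately the order-free variant.
Region span is the outermost boundary of the component; carriers are
distinct samples (a sample with state-0 and state-1 calls in one deletion
region counts once); frequency is carriers over QC-passing samples in the
same study.

Regions overlapping a centromere/telomere exclusion track by ≥ 1 bp are
removed (BED input, converted from 0-based half-open to the package's
1-based inclusive coordinates on read), then regions below 1% frequency
are removed.  The two filters are independent, so their order does not
affect the survivors.

# Burden

Per individual and per class (all, deletions, duplications): number of
calls, average call length (kb), total call length (kb).  Burden is
computed from per-sample calls, not merged regions, matching a workflow
where burden retrieval precedes region construction.  Zero-call
individuals get zeros and stay in the models (`drop_zero_burden = TRUE`
switches the average to `NA` instead).  Covariates are emitted pre-scaled
— per 10 CNVs, per 10 kb of average length, per 100 kb of total length —
so fitted hazard ratios are directly on the conventional reporting scales.

# Survival analysis

The Cox model runs on the **age timescale with delayed entry**: a subject
enters the risk set at the entry (baseline) age and leaves at death or
censoring, which avoids immortal follow-up time in cohorts recruited at
ages 90+.  Ties are handled with the Efron correction (age at death is
recorded at day resolution in register data, so exact ties are possible
but rare).  Adjustments are sex and, where appropriate, birth cohort
(decade bins) as categorical covariates; familial clustering is handled
with a cluster-robust (sandwich) variance rather than a frailty term —
the robust estimator is the less parametric of the two standard options
and is the default.  Constant adjustment covariates are dropped with a
message; a constant exposure, zero events, and monotone-likelihood
non-convergence are errors (per-region testing skips such regions and
logs them).  Confidence intervals use $z = 1.959964$ so that CI → SE → CI
round-trips are exact to the printed digits.

The estimation oracle is a hand-coded delayed-entry partial likelihood
maximised by grid search; `coxph` optima agree with it to $10^{-4}$ on
fixture data, and the null rejection rate is within 0.05 ± 0.02 over
1000 simulations.

# Joint analysis and multiple testing

Per-study log hazard ratios are pooled with inverse-variance weights
($w_i = \mathrm{se}_i^{-2}$); the pooled SE is $(\sum w_i)^{-1/2}$ and the
p-value a two-sided normal test.  No heterogeneity statistics are
computed by default (`heterogeneity()` exists behind an explicit call).
In published-table mode, per-study SEs are reconstructed from printed
95% CIs via the Wald identity; because printed CIs carry only 2–3
decimals, agreement with printed pooled values is asserted *after
rounding to the printed precision*.  Pooled HRs are robust to this
rounding; pooled p-values on very tight intervals are not (e.g. a printed
0.005 can reproduce as 0.009), which is why the acceptance checks assert
HRs, not p-values.

Significance policy: the burden family uses a Bonferroni correction for 8
tests (the count of primary burden hypotheses under the convention that
derived quantities — total length, the combined class, the joint analysis
— are not counted separately), i.e. 0.006 at one significant digit.  The
region family uses 0.05/m with m equal to the number of regions actually
tested in the data at hand, not a hard-coded count.  Findings with
p ≤ 0.05 (closed) are suggestive and eligible for replication; a
replication region is matched by same type and ≥ 1 bp overlap
(configurable), regions under 1% replication frequency are "not
testable", and a joint p ≤ 0.05 with concordant per-study directions is
flagged as consistently replicated.  Display rounding never feeds back
into decisions.

# The synthetic cohort: what it emulates, and what it does not

The generator's defaults state one fixed world:

* **Marker map:** log-normal inter-marker gaps with median 2.1 kb and
  mean 4.0 kb (the documented spacing of a ~730k-marker genotyping
  array); PFB a mixture of near-monomorphic and uniform components; GC a
  smooth Mb-scale process in [0.3, 0.7].
* **Signals:** state-mean LRR plus Gaussian noise, an optional planted
  genomic wave proportional to standardised GC, and BAF from
  Hardy–Weinberg genotypes at the local copy number with truncated noise
  (clipping to [0, 1] piles homozygous clusters onto the rails, as real
  arrays do).
* **Cohort:** 603 samples, 75.1% women, entry age normal (96.9, 2.0)
  truncated to [90, 103].
* **Mortality:** Gompertz baseline hazard $h_0(t) = a e^{bt}$ with
  $a = 1.7\times 10^{-5}$, $b = 0.10$ per year, proportional hazards in
  the planted covariates, death ages drawn by inversion of the cumulative
  hazard *conditional on survival to entry* (left truncation), and
  administrative censoring at entry + 6.0 years.  These values were
  calibrated once so that roughly 90% of subjects die during follow-up
  with a mean follow-up near three years — the high-event regime of
  nonagenarian cohorts — and are not revisited.
* **Seeding:** one master seed is split into per-sample seeds, so outputs
  are byte-reproducible and samples are independent.

Deliberately *not* modelled: probe-specific biases, mosaicism, batch
structure, sex chromosomes (autosomes only), informative censoring, and
real linkage-disequilibrium structure in the PFB.  A green test on this
world therefore establishes that the pipeline's logic and estimators are
correct under stated assumptions — it does not establish that any
particular cohort-level number (region counts, per-study hazard ratios)
would be reproduced, which would require the original register-linked
data.  The only quantities asserted against published values are the ones
computable from published per-study summaries: the pooled hazard ratios
and the multiple-testing cutoffs.

# Numerical choices and degenerate inputs

* Viterbi ties: lower copy number, then earlier state index.
* Cox: Newton–Raphson via `survival::coxph`, eps $10^{-9}$, 100
  iterations max; monotone-likelihood warnings are promoted to errors.
* `se_from_ci` refuses zero-width or non-positive intervals; pooling
  refuses non-positive SEs; empty estimate sets are errors.
* Zero-carrier or all-carrier regions are skipped with a log message, not
  silently dropped.
* Malformed BED lines abort with the line number.
* A follow-up floor of one day keeps `entry < exit` strict in the
  generator.

# Known limitations

* The caller does not correct signals for GC waves before decoding; the
  wave statistic is measured and used for exclusion only.  Heavily waved
  samples that pass the 0.05 cutoff may still yield excess calls.
* The transitive-closure merge can produce regions wider than any single
  call chain member; with long chains the 50% pairwise criterion is not
  guaranteed between the extremes.
* Burden covariates are tested one at a time, mirroring the reporting
  convention; no multivariable burden model is provided.
* The robust-variance option treats families as exchangeable clusters; no
  kinship matrix is used.
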