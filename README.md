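# cnvmort

Copy-number variants (CNVs) — deletions and duplications of kilobase-scale
DNA segments — are a major source of genetic variation, and their overall
burden may contribute to differences in mortality even at the extreme end
of the human lifespan. `cnvmort` is an R package for the full analysis
chain used in prospective-mortality CNV studies of SNP-array cohorts of
long-lived individuals (nonagenarians and centenarians), where subjects
enter observation at ages 90+ and follow-up runs through population
registers until death or an administrative cutoff.

The package is aimed at statistical geneticists and epidemiologists who
need each stage of such an analysis as tested, composable functions:

1. **CNV calling** from per-marker log R ratio (LRR) and B allele
   frequency (BAF) signals with a five-state hidden Markov model
   (copy numbers 0–4). Emissions combine a Gaussian LRR term with a
   Hardy–Weinberg-weighted BAF cluster mixture at the marker's population
   B-allele frequency (PFB); transitions relax toward a stationary
   distribution with inter-marker distance $d$ as
   $A(d) = e^{-d/D}A_0 + (1-e^{-d/D})\Pi$. Calls need ≥ 3 markers and
   ≥ 1 kb.
2. **Sample QC**: exclude samples with LRR sd > 0.30, > 100 calls, or
   |GC wave factor| > 0.05 (all strict inequalities).
3. **Region construction**: merge same-type calls across samples when
   they overlap ≥ 50% of the shorter call (transitive closure), span the
   outermost boundaries, drop centromere/telomere overlaps and regions
   below 1% frequency, and build a sample × region carrier matrix.
4. **Burden**: per individual and per class (all/deletions/duplications),
   the number of CNVs, average length, and total length, pre-scaled to
   the conventional per-10-CNV / per-10-kb / per-100-kb reporting units.
5. **Association**: left-truncated Cox proportional hazards on the age
   timescale, $h(t\mid x) = h_0(t)\exp(\beta^\top x)$ with delayed entry
   at baseline age, Efron ties, optional cluster-robust (family)
   variance.
6. **Joint analysis**: inverse-variance fixed-effect meta-analysis of
   per-study log hazard ratios, $\hat\beta = \sum w_i\beta_i/\sum w_i$,
   $w_i = \mathrm{se}_i^{-2}$, including a published-table mode that
   reconstructs SEs from printed 95% CIs via
   $\mathrm{se} = (\ln \mathrm{CI}_u - \ln \mathrm{CI}_l)/(2\times1.959964)$.
7. **Multiple testing**: Bonferroni thresholds (e.g. 0.05/8 → 0.006 for a
   burden family; 0.05/403 → 1.2×10⁻⁴ for a region family), suggestive
   findings at p ≤ 0.05, and replication-consistency flags.

Because register-linked cohort data of this kind are not publicly
deposited, the package ships a synthetic-cohort generator (marker maps
with 2.1 kb median / 4.0 kb mean spacing, signals with implanted CNVs,
Gompertz survival with known planted effects) so that every stage is
testable end to end, with brute-force oracles for the caller, the region
merge, and the Cox fit.

## Worked example

Pooling published per-study hazard ratios (published-table mode):

```r
library(cnvmort)
burden <- published_estimates("burden")
pooled <- pool_published_estimates(
  burden[burden$study_id %in% c("discovery", "replication"), ])
pooled[pooled$term %in% c("avg_len_all", "total_len_del"), ]
#>           term k    hr ci_low ci_high         p
#>    avg_len_all 2 1.024  1.009   1.039 1.944e-03
#>  total_len_del 2 1.009  1.005   1.014 6.279e-05
```

Read: each additional 10 kb of average CNV length multiplies the
mortality hazard by 1.024 (95% CI 1.009–1.039) in the pooled analysis,
and each additional 100 kb of total deletion length by 1.009 — small but
precisely estimated effects, both beyond the burden-family Bonferroni
threshold of 0.006.

A fully synthetic end-to-end run:

```r
cfg <- run_config(n_samples = 40L, n_markers = 2000L,
                  chrom_lengths = c(chr1 = 2.8e6, chr2 = 1.6e6),
                  mean_cnvs = 3, adjustments = "sex", seed = 11L)
b <- run_discovery(cfg)
sum(b$qc$pass)        #> 37      (3 of 40 samples fail QC)
nrow(b$calls)         #> 108     (filtered calls among passing samples)
table(b$regions$cnv_type)
#> deletion duplication
#>       33          25
b$manifest
#>             stage input kept dropped
#>         sample_qc    40   37       3
#>  calls_qc_samples   118  108      10
#>    region_filters    58   58       0
```

The manifest records row counts at every filter so that "records
surviving stated filters" is auditable; `write_bundle(b, dir)` writes all
stage tables as TSV (byte-identical across reruns with the same config
and seed). A command-line wrapper with `simulate`, `run-all`, and
`joint-published` subcommands is in `inst/cli/cnvmort.R`.

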