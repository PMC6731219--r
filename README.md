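# somaticMEI

Somatic mobile-element insertion calling and clinical association
analysis for tumor cohorts.

## What this package is for

Retrotransposons — above all LINE-1 — reactivate in gastrointestinal
tumors and litter tumor genomes with somatic insertions. Characterizing
that landscape from whole-genome sequencing takes a chain of specialized
steps: calling insertions from discordant read-pair clusters, tracing 3'
transductions back to the reference full-length source element that fired
them, annotating each insertion's breakpoint, poly-A/T tail, orientation
and chromatin/replication context, and finally asking what the insertion
burden is associated with clinically. somaticMEI implements that chain
for analysts working with colorectal (or other) tumor cohorts, together
with a fully synthetic cohort generator with known ground truth, so every
stage can be developed and tested without access-controlled patient data.

## The core methods

**Insertion calling.** A somatic insertion is supported by a plus-strand
and a minus-strand cluster of discordant read pairs flanking the
integration site (each mate mapping into a retrotransposon family).
Anchors are clustered by single linkage, clusters below three reads are
dropped (`s = 3` in the tumor, `gm = 3` in the matched normal), and
reciprocal clusters are paired by their inner coordinates
(`P_R_POS`/`N_L_POS`), which bracket the breakpoint. Candidates within
200 bp of any call in a 234-sample panel of normals or the matched normal
are removed, as are calls on decoy contigs (`hs37d5`).

**Transduction attribution.** Structural-variant calls with ≥ 3
supporting reads and mapping quality > 37 are merged (same type, both
ends within 200 bp), germline-subtracted (length > 1000 bp, matched
against normal SVs), and retained when one end falls within 1000 bp of
the 3' end of a cataloged full-length L1HS element — the other end is the
insertion site. Per-source counts and fractions quantify source activity.

**Clinical models.** Insertion counts are modeled by OLS on
`log(count + 1)` with CIMP status, allelic imbalance (per 10% of the
genome), TP53, MSI, coverage, age, sex, stage and location;
disease-specific survival by a Cox model stratified on tumor location,
with the hazard ratio per 10 insertions as the quantity of interest:
`HR = exp(beta)`, 95% CI `exp(beta ± 1.96 se)`. CIMP is scored from
MS-MLPA probes (gene methylated at ≥ 25% of probes above a
normal-derived threshold; CIMP-high at 5–8 of 8 genes). Validation
false-positive rates get exact Clopper–Pearson intervals.

See `vignettes/somatic-insertion-analysis.Rmd` for the full model
descriptions, parameter defaults and design decisions.

## Worked example

```r
library(somaticMEI)

# a 40-tumor synthetic cohort with planted ground truth
cfg    <- synthetic_config(n_tumors = 40, seed = 7)
cohort <- simulate_cohort(cfg)

calls <- call_insertions(cohort$tumor_pairs, cohort$normal_pairs,
                         cohort$panel_calls)
head(calls, 3)
#>   sample_id chrom   start     end family pos_support neg_support somatic
#> 1      T001  chr1 7171037 7171046 LINE-1           5           5    TRUE
#> 2      T001  chr1 8345035 8345040 LINE-1           4           4    TRUE
#> 3      T001  chr2 2337168 2337173 LINE-1           5           5    TRUE
```

Every one of the 1011 planted above-threshold somatic insertions is
recovered (`nrow(calls)` is 1011), and none of the germline truths leaks
through the panel filter. Transductions are attributed to their source
elements and summarized:

```r
sex <- setNames(cohort$clinical$sex, cohort$clinical$sample_id)
td  <- call_transductions(cohort$tumor_svs, cohort$normal_svs,
                          cohort$annotation$sources, sex)
head(summarize_source_activity(td), 3)
#>   source_id count  fraction recurrent
#> 1  L1HS_002    21 0.3134328      TRUE
#> 2  L1HS_034     8 0.1194030      TRUE
#> 3  L1HS_018     7 0.1044776      TRUE
```

The dominant planted source tops the table. Density over replication
timing shows the planted late-replication enrichment (bin 0 = earliest):

```r
ins  <- annotate_insertions(merge_dedupe_calls(td, calls),
                            cohort$annotation, cohort$split_reads)
compute_insertion_density(ins, cohort$annotation$replication, "bin")
#>   label      bp count density_per_mbp
#> 1     0 3992000    91        22.79559
#> 2     1 3992000   119        29.80962
#> 3     2 3992000   187        46.84369
#> 4     3 3992000   245        61.37275
#> 5     4 3992000   373        93.43687
```

Clinical associations on a larger clinical-only cohort (insertion counts
generated with CIMP effect 0.607, AI effect 0.0826 per 10%, log-hazard
0.108 per 10 insertions):

```r
cfg2 <- synthetic_config(n_tumors = 500, seed = 7,
                         genome = c(chr1 = 2e6), n_genes = 0)
ann2 <- build_annotation(cfg2)
cl   <- emit_clinical_tables(simulate_cohort_truth(cfg2, ann2), cfg2)$clinical

fit_log_count_regression(cl)$table[2:3, ]
#>     term   coef     se    z        p
#> 2 cimp_h 0.5952 0.0915 6.51 7.69e-11
#> 3   ai10 0.0715 0.0263 2.72 6.51e-03

fit_disease_specific_cox(cl)$table[1, ]
#>      term  coef     se    z        p   hr hr_lo hr_hi
#> 1 count10 0.112 0.0226 4.95 7.49e-07 1.12  1.07  1.17
```

Both generating effects are recovered within their confidence intervals;
an insertion burden 10 higher multiplies the disease-specific hazard by
about 1.12 here. The printed-arithmetic helper reproduces a published
survival-table row directly from its coefficient and standard error:

```r
h <- hazard_ratio_from_coefficient(0.108, 0.0362)
sprintf("HR %.2f [%.2f, %.2f]", h$hr, h$lower, h$upper)
#> "HR 1.11 [1.04, 1.20]"
```

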