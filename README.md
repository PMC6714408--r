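# cnvresp

Copy-number variation (CNV) association with response to TNF-α blocker
therapy in rheumatoid arthritis (RA).

About a third of RA patients do not respond to TNF-α blockers, and common
structural variants are a plausible, largely unexplored source of that
variability. `cnvresp` provides the full analysis chain needed to test
CNVs against treatment response in a SNP-array cohort, for statistical
geneticists and pharmacogenomics analysts:

1. **CNV calling** — a hidden Markov model over copy-number states 0–4
   decodes each sample's probe-level log R ratio (LRR) and B-allele
   frequency (BAF) by exact Viterbi. Emissions are
   `Normal(LRR; μ_c, σ_c) · Σ_k Binom(k; c, pfb) · TN[0,1](BAF; k/c, τ)`,
   transitions decay with inter-probe distance as
   `t₀(1 − e^(−d/D))`. Calls need more than three supporting probes;
   samples with more than 100 calls are excluded.
2. **Multi-sample segmentation** — overlapping calls are split at every
   boundary observed in the cohort, producing a samples × segments
   copy-number matrix in which every sample has a defined copy number
   (2 where no call overlaps) over every segment.
3. **Segment filtering** — classes (deletion-only / duplication-only /
   multi-class), abnormal-carrier frequency ≥ 5%, and an exact
   conditional Hardy–Weinberg test (deletion/duplication-only segments
   with P ≤ 0.05 excluded).
4. **Disease activity** — DAS28-ESR
   (`0.56√TJC28 + 0.28√SJC28 + 0.70 ln ESR + 0.014 GH`), CDAI
   (`TJC28 + SJC28 + PtGA + PhGA`), and the EULAR good/moderate/none
   classification from ΔDAS28 and attained DAS28.
5. **Association** — per segment, logistic regression of non-response on
   the deletion-carrier indicator adjusted for principal components, BMI,
   sex, baseline DAS28, drug and methotrexate (Wald inference, Firth
   refit under separation), plus a linear model for ΔCDAI; both under
   Benjamini–Hochberg FDR at 5%. Crude odds ratios and SNP↔CNV tagging
   r² are available as diagnostics.
6. **Synthetic cohorts** — a seeded generator plants a low-frequency
   deletion with a known non-response odds ratio inside a realistic
   cohort (covariates, clinical components consistent with the drawn
   EULAR labels, background CNVs with boundary jitter), so the whole
   pipeline is testable end to end without patient data.

## Worked example

```r
library(cnvresp)
res <- run_synthetic_pipeline(sim_config(seed = 42))
res
#> CNV / drug-response pipeline
#>   samples: 357 (0 excluded by call-count QC, 357 analyzed)
#>   calls: 767 -> segments: 797 -> common segments: 1
#>   FDR-significant (linear_cdai): 1
#>   FDR-significant (logistic_eular): 1

res$associations[res$associations$fdr_significant,
                 c("segment_id", "or_", "ci_low", "ci_high", "p_value")]
#>                  segment_id   or_ ci_low ci_high  p_value
#> 1 seg_2_129458211_129461327  9.76   3.25   29.33 4.98e-05
#> 2 seg_2_129458211_129461327 -6.82 -11.10   -2.54 1.96e-03
```

The 357-patient synthetic cohort carries a 5.6%-carrier deletion at
chr2:129,457,798–129,461,606 whose carriers have odds ratio 8.44 of EULAR
non-response. The pipeline calls and segments 767 CNVs into 797 segments,
keeps the common (≥ 5% carrier, HWE-consistent) segments, and flags the
planted locus in both models: deletion carriers have ~9.8-fold odds of
non-response (95% CI 3.3–29.3) and about 6.8 CDAI units less improvement
at six months. Estimates fluctuate across seeds exactly as a rare-carrier
effect in 357 patients should — the confidence intervals are wide.

Individual stages are plain functions: `call_cnvs()`, `segment_cnvs()`,
`filter_segments()`, `build_response_labels()`,
`assoc_segment_logistic()`, `bh_fdr()`, `crude_or()`, `snp_cnv_r2()`,
with PennCNV-dialect and TSV/BED readers and writers (`read_penncnv()`,
`write_segments_bed()`, …). See the methods vignette
(`vignettes/cnv-response-methods.Rmd`) for the model details, generator
assumptions and calibration notes.

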