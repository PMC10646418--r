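# cislnc

Post-alignment analysis of long non-coding RNA (lncRNA) expression in
human islet grafts, for transcriptomics researchers studying beta-cell
survival. The package covers the analysis layer between a quantified
expression matrix and the biological calls: differential-expression
(DE) threshold filtering, genomic-distance *CIS* lncRNA–mRNA pairing,
islet-specificity and graft expression-pattern calling, ΔΔCt qPCR
statistics, Fisher gene-set enrichment, and apoptosis quantification
from TUNEL counts and Annexin-V/PI flow cytometry. A synthetic-data
generator with planted ground truth makes every stage testable without
access to raw sequencing data.

## The core methods

* **DE filtering.** Per-transcript fold change
  `log2fc = log2((mean_B + c)/(mean_A + c))` and a replicate t-test on
  `log2(FPKM + c)` with Benjamini–Hochberg FDR control, filtered by
  named threshold presets (`rnaseq_de`: FC ≥ 2, q ≤ 0.05, status OK;
  `cis_screen`: |log2 FC| > 1.5, p < 0.05; `ipa_upload`; `plot_inclusion`).
* **CIS pairing.** All (DE lncRNA, DE mRNA) combinations whose distance
  from the lncRNA (nearest edge, or its 5′ end) to the mRNA
  transcription start site is ≤ 50 kb, signed positive downstream in
  mRNA orientation; pairs classified `co_down` / `co_up` / `opposite`
  and summarized with a Pearson correlation of the paired log2 fold
  changes.
* **Islet specificity.** The more-than-double rule: islet expression
  strictly greater than 2× the highest other tissue.
* **ΔΔCt.** Reference normalization against the mean Ct of GAPDH/ACTB
  (geometric mean on the quantity scale), per-replicate `2^−ΔΔCt`,
  Student's t-test, and fold regulation (negative inverse below 1).
* **Apoptosis.** TUNEL⁺ beta-cell percentages and flow quadrant
  summaries with apoptotic rate = early + late apoptotic.

See `vignettes/islet-lncrna-methods.Rmd` for the full model
descriptions, conventions and limitations.

## Worked example

Specificity calls on the packaged reference table of ten
islet-enriched lncRNA isoforms (islet FPKM against the
highest-expressing other human tissue):

```r
library(cislnc)
calls <- islet_specificity_call(islet_table1_panel())
calls[1:4, c("transcript_id", "focal_expr", "max_other_expr", "ratio", "is_specific")]
#>    transcript_id focal_expr max_other_expr      ratio is_specific
#> 1 lnc-SCYL1-1:22   321.5260        100.170   3.209803        TRUE
#> 2  lnc-POLG2-1:1   152.5890         74.410   2.050652        TRUE
#> 3  lnc-CTRB1-1:1    60.2895          0.069 873.760870        TRUE
#> 4  lnc-SRPK1-1:1   751.4020          4.366 172.103069        TRUE
sum(calls$is_specific)
#> [1] 10
```

All ten isoforms pass the strict rule; the `ratio` column says how many
times higher islet expression is than the best other tissue (e.g.
lnc-CTRB1-1:1 is ~874× its kidney level, while lnc-POLG2-1:1 clears the
2× bar at 2.05).

A zero-noise synthetic run recovers its planted truth end to end:

```r
cfg   <- truth_config(seed = 1, noise_sd_log2 = 0)
truth <- generate_annotation(cfg)
expr  <- generate_expression(truth, cfg)
res   <- test_de(expr$matrix, "Islet", "ALT")
biot  <- truth$annotation$biotype[match(res$transcript_id,
                                        truth$annotation$transcript_id)]
pairs <- screen_cis_pairs(
  filter_de(res[biot == "lncRNA", ], "cis_screen")$results,
  filter_de(res[biot == "mRNA", ],  "cis_screen")$results,
  truth$annotation)
summarize_pairs(pairs, "ALT vs Islet")
#> CIS pair summary (ALT vs Islet)
#>   pairs: 5 = co-down 2 + co-up 3 + opposite 0
#>   Pearson r = 0.9986, two-tailed p = 6.32e-05
```

The five planted pairs (and none of the three beyond-50-kb decoys) come
back, partitioned by co-regulation pattern. qPCR validation data work
the same way:

```r
relative_expression(c(5.1, 4.9, 5.0), c(4.0, 4.1, 3.9),
                    target = "lnc-CTRB1-1:1",
                    comparison = "cytokine vs control")
#> relative expression of lnc-CTRB1-1:1 (cytokine vs control):
#>   fold change 0.5008 (fold regulation -1.997), p = 0.000364 [unpaired t-test, n = 3]
```

A ΔCt one cycle above the calibrator mean is a halving of expression —
reported as fold regulation −2 (two-fold down).

`run_pipeline(pipeline_config(seed = 1), "run1")` executes every stage
on synthetic data and writes the tables, a `summary.json` and a
JSON-lines provenance log to the run directory. A thin command-line
dispatcher over the same functions ships at `inst/cli/cislnc.R`.

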