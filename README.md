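# yaptazsig

Hyperactive YAP/TAZ signalling drives growth and metastasis in many cancers,
and TEAD inhibitors that block YAP/TAZ-TEAD transcription are in clinical
trials. The practical question this package addresses is: **given a tumor's or
cell line's transcriptome, can we tell whether it depends on YAP/TAZ-TEAD for
viability?** It implements, as a tested and reusable R pipeline, the analysis
chain that answers this in melanoma:

1. **Consensus signature derivation.** From oriented differential-expression
   contrasts (constitutively active YAP vs control, or control vs YAP/TAZ
   knockdown), a gene enters the Up set iff it clears strict cutoffs
   (fold change > 2, FDR < 0.05) in the anchor cell line *and* in at least
   `min_support = 2` supporting lines, consistently after orientation
   (knockdown contrasts are sign-flipped so positive log2FC always means
   YAP/TAZ-induced). The Down set is symmetric; direction conflicts drop the
   gene.
2. **Enrichment statistics, from scratch.** Two-class GSEA with the weighted
   Kolmogorov–Smirnov running sum
   ES = max deviation of (hits add |s_i|^w / Σ|s|^w, misses subtract 1/(N−N_h)),
   signal-to-noise ranking (μ_a−μ_b)/(σ_a+σ_b) with the conventional variance
   floor, permutation-based NES/FDR q (phenotype permutation when both classes
   have ≥ 8 samples, gene-set permutation otherwise), percent-rank
   summarization, and single-sample GSVA scores built from Gaussian
   kernel-CDF estimates (bandwidth s_i/4) and a symmetric rank statistic
   |N/2 − r_ij|.
3. **Dependency prediction.** CRISPR Chronos scores are binarized at
   ≤ −0.65 (YAP/TAZ-dependent = YAP1 or WWTR1; TEAD-dependent = any TEAD1–4);
   per-line GSVA scores of the signature are evaluated as predictors by ROC:
   Mann–Whitney AUC (ties ½), DeLong p-value against AUC = 0.5, and the
   Youden-optimal cutoff J = max(sens + spec − 1).
4. **Tumor-cohort validation.** Tumors split on canonical targets CTGF/CYR61
   at mean ± 1 SD; per-gene Mann–Whitney group comparisons with BH
   correction; Spearman correlation of each signature gene with the marker
   (1000-permutation p-values), correlation bins (strong ≥ 0.4, moderate
   [0.3, 0.4), weak < 0.3), sorted pairwise similarity matrices, and the
   r ≥ 0.4 two-marker Venn.
5. **ChIP peak annotation.** Strand-aware peak-to-gene assignment with the
   fixed priority cascade Promoter (±1 kb TSS window) → Exon → Intron →
   Downstream → Intergenic, and the binary gene × dataset peak matrix.

A first-class synthetic-data module generates every input with the
statistical structure the analysis assumes (latent per-sample activity,
partially overlapping contrasts, expression-linked Chronos scores, Gaussian
copula marker correlations, promoter-planted peaks), so the whole pipeline
runs and is validated with no downloads. Readers for the real-data dialects
(DepMap `"SYMBOL (ENTREZID)"` expression/dependency CSVs, GMT gene sets,
BED peaks, plain expression TSVs) are included.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic data:

```sh
Rscript analysis/01_simulate_inputs.R      # writes results/data/
Rscript analysis/02_derive_signature.R
Rscript analysis/03_dependency_prediction.R
Rscript analysis/04_tumor_correlation.R
Rscript analysis/05_peak_annotation.R
```

Output from a run (`results/analysis/` holds the full TSV/JSON reports):

```
consensus signature: 80 up / 52 down (planted 80 / 52)
planted-up recovery: 100.0%, planted-down recovery: 100.0%

17 / 62 lines dependent on YAP/TAZ, 10 on TEADs
GSEA (phenotype permutation): YAP_TAZ_UP NES 1.38 (FDR q 0.050)
       geneset             label n_dep   auc youden_j sensitivity specificity
1   YAP_TAZ_UP dependent_yap_taz    17 0.886   0.6614       0.706      0.9556
2   YAP_TAZ_UP    dependent_tead    10 0.837   0.6077       0.800      0.8077
3 YAP_TAZ_DOWN dependent_yap_taz    17 0.124   0.0000       1.000      0.0000

CTGF grouping: 53 high / 48 low / 199 neither
100% of signature-up genes higher in CTGF-high tumors at FDR<0.05
r>=0.4 venn: CTGF-only 12, CYR61-only 0, both 68

category totals across datasets: Promoter=624
majority-rule target recovery: sensitivity 1.00, FDR 0.00 (80 called)
```

Reading: the consensus rule recovers the planted 80-up/52-down composition
exactly; the Up gene set predicts YAP/TAZ dependence with AUC ≈ 0.9 in a
single 62-line cohort (the Down set is anti-predictive, as expected for
repressed genes); signature-up genes track CTGF/CYR61 in tumors and the
promoter-planted ChIP targets are recovered cleanly. `run_pipeline()` wraps
the same stages behind one YAML-configurable call with a run manifest.

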