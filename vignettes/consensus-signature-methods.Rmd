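---
title: "Methods: consensus YAP/TAZ-TEAD signature derivation and dependency prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus YAP/TAZ-TEAD signature derivation and dependency prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yaptazsig)
```

This vignette is the package's own account of the statistical machinery: the
models and procedures, the tunable parameters and why their defaults are what
they are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open. Every empirical
claim here is one the test suite or `scripts/acceptance.R` computes.

## The problem and the data model

YAP and TAZ (gene *WWTR1*) are transcriptional co-activators restrained by
Hippo kinase signalling; they act through the TEAD1–4 DNA-binding factors,
and cancers with hyperactive YAP/TAZ-TEAD are candidate responders to the
TEAD inhibitors now in trials. The pipeline asks whether a transcriptional
signature of YAP/TAZ activity, derived by consensus across melanoma cell
lines, can report that activity in independent cohorts and predict
CRISPR-measured dependence on YAP/TAZ or TEADs.

Expression travels as a genes × samples matrix with an explicit value space
(`tpm`, `log2p1`, `zscore`). Transforms are one-way: `log2p1()` maps TPM to
log2(1 + x); `zscore_rows()` standardizes each gene across samples using the
sample (n − 1) standard deviation. Rows with zero variance map to all-zero
z-scores rather than NaN — downstream correlation and heatmap machinery then
stays finite; the choice is arbitrary but harmless because constant genes
carry no ranking information. DepMap-dialect files are stored already on the
log2(1 + TPM) scale, so the reader records that value space and never
re-transforms; symbols are normalized (upper case, whitespace stripped,
`" (ENTREZID)"` suffixes removed) because the pipeline merges symbol-keyed
data from several sources.

## Consensus signature

Each differential-expression contrast carries an orientation: *activation*
(e.g. constitutively active YAP^2SA^ vs control) or *depletion* (control vs
YAP/TAZ siRNA). `orient()` negates depletion log2FCs once, so that positive
always means YAP/TAZ-induced; orienting twice is an error rather than an
involution, because orientation is a normalization of bookkeeping, not a
data transform. Regulated calls use strict cutoffs — fold change > 2 and
FDR < 0.05, boundary values excluded — matching the printed analysis
settings. The consensus rule is:

> a gene is in the Up set iff it is called up in the anchor contrast and in
> at least `min_support = 2` supporting contrasts, and is never called down
> in any support; Down is symmetric.

The direction-consistency clause is our resolution of a case the source
analysis never had to address; a consensus signature that contains a gene
moving both ways would be uninterpretable. Genes absent from a support's
platform count as non-supporting, not contradicting. With four contrasts at
these settings the melanoma-style composition is 80 Up / 52 Down genes, and
the synthetic generator plants exactly that composition by default.

For synthetic end-to-end runs a stand-in DE test is provided (`standin_de`):
log2FC from pseudocounted TPM group means, Welch's t on log2(1 + TPM),
Benjamini–Hochberg FDR. It replaces the external alignment/assembly DE
pipelines, which are out of scope; real-data runs consume externally
produced DE tables via `read_de_table()`.

## Enrichment statistics

**Ranking.** `rank_genes()` scores each gene by signal-to-noise,
(μ~a~ − μ~b~)/(σ~a~ + σ~b~), with each class SD floored at
max(σ, 0.2·|μ|, 10^−8^) — the conventional floor used by the desktop GSEA
implementation, adopted because the source analysis ran "default settings"
without naming the metric. Ties are broken lexicographically by symbol so
every ranking is deterministic.

**GSEA.** The enrichment score is the signed maximum deviation of the
weighted Kolmogorov–Smirnov running sum (hits add |metric|^w^ normalized over
hits, misses subtract 1/(N − N~h~); w = 1 by default). The leading edge is
the hit genes at or before the extremum (at or after, for negative ES).
Significance follows the published permutation-mode rule: *phenotype*
permutation (relabel samples, re-rank) when both classes have ≥ 8 samples,
*gene-set* permutation (random same-size sets of ranked genes) otherwise.
NES divides the observed ES by the mean |permutation ES| of matching sign;
the nominal p is the add-one-smoothed same-sign tail, and FDR q follows the
pooled positive/negative NES scheme of the original GSEA method. With a
fixed seed the whole computation is bit-reproducible. Acceptance checks
verify the ES against an exhaustive brute-force walk on all 92 gene sets of
size ≤ 3 over an 8-gene list, and nominal-p calibration against a
label-independent null (the fraction below 0.05 must sit inside the binomial
99% CI around 0.05).

**GSVA.** Single-sample scores follow the published GSVA construction with
its package defaults, authored here from the algorithm description: Gaussian
kernel CDF estimates ẑ~ij~ = (1/n) Σ~k~ Φ((x~ij~ − x~ik~)/h~i~) with
bandwidth h~i~ = s~i~/4 (ε fallback for constant genes); per-sample ranks of
ẑ (ties lexicographic); the symmetric rank statistic |N/2 − r~ij~|^τ^ with
τ = 1 in a KS-like walk; and, with `mx_diff = TRUE`, score = max positive
deviation + min negative deviation. A consequence worth stating: with a
kernel CDF the scores are *exactly* invariant only under increasing affine
transforms of a gene's row (the bandwidth scales with the SD); a general
strictly increasing transform preserves the gene's own ordering but can
shift its kernel-CDF values relative to other genes and perturb scores
slightly. The tests therefore assert exact affine invariance plus agreement
with an independently coded two-pass oracle to 10^−9^.

## Dependency prediction

Chronos scores (CRISPR fitness effects; more negative = more dependent) are
binarized at ≤ −0.65, boundary dependent — the figure captions describe both
sides as inclusive at −0.65, and we resolve that contradiction in favour of
the Methods sentence. Group labels are ORs: YAP/TAZ-dependent means YAP1 or
WWTR1; TEAD-dependent means any of TEAD1–4. ROC analysis is implemented
directly so its conventions are pinned: AUC as Mann–Whitney concordance with
tied pairs counting ½; the p-value against AUC = 0.5 from the DeLong
placement variance (the documented default of the cited commercial tool,
which also offers Hanley–McNeil; we fix DeLong); the Youden-optimal cutoff
scanned over midpoints between adjacent distinct scores, ties resolved to
the lower cutoff, with a sample called positive at score ≥ cutoff. pROC
serves as an independent cross-check in the tests, never as the
implementation.

## Synthetic data: what it emulates, and what it does not

All generators are seeded, bit-reproducible, and serialize their ground
truth. The expression model is log2-scale: baseline~g~ ~ N(4, 2), plus
β·a~s~ for planted up-responsive genes (−β·a~s~ for down), plus N(0,
noise_sd) noise; TPM = 2^x^ − 1 clipped at 0. Defaults β = 2, noise_sd =
0.5 put planted effects well above the 2-fold cutoff (β − 3·noise_sd > 1
log2 unit at the contrast level), which is what "responsive gene" means in
this design. Default compositions deliberately mirror the study's
dimensions so synthetic runs read side-by-side with the original figures:
80/52 planted genes, 4 contrasts (one knockdown-oriented, sign-flipped raw),
62 cell lines with 17 dependent (all via WWTR1, with 9/1/2 sub-assignments
to TEAD1/TEAD4/YAP1), 300 tumors, 8 ChIP datasets. Per-support inclusion
probability defaults to 0.8 — partial overlap is the realistic regime the
consensus rule exists for — while recovery checks use inclusion 1 with
negligible noise, where exact recovery is the designed-in correct answer.

In the dependency cohort, dependent lines draw activity a~s~ ~ N(2, 1)
against N(0, 1); with the default gene panel the GSVA score is a nearly
noiseless monotone readout of a~s~, so the score separation is ~2 score-SDs
and the expected AUC is the binormal Φ(2/√2) ≈ 0.92. The acceptance run
averages 200 replicate cohorts against that closed form and checks the
label-shuffled null sits at 0.5. Chronos scores draw from N(−1.0, 0.15) vs
N(−0.1, 0.15), leaving negligible mass on the wrong side of −0.65.

Tumor cohorts plant per-gene Spearman targets against the marker through a
Gaussian copula, converting the target through the bivariate-normal relation
ρ~S~ = (6/π)·asin(r/2) — planting the Pearson value naively would bias the
Spearman target downward. At n = 300 the sampling SD of an estimated
Spearman correlation is ≈ 0.06, which has two consequences stated here
because they shape the checks: "within ±0.1 of the target" holds for roughly
92–99% of draws depending on the target, and a gene planted exactly at a bin
boundary (ρ = 0.3, the weak/moderate edge) lands in its nominal bin only
about half the time *by construction* — so bin-recovery is asserted for the
interior targets (0 → weak, 0.6 → strong) and ±0.1 recovery for all.

Peak datasets place 200–600 bp peaks centered within ±400 bp of target-gene
TSSs at rate 0.9 (background genes 0.05). Target recovery uses a
majority-of-datasets rule (≥ half the datasets show a peak for the gene):
with 8 datasets this separates Binomial(8, 0.9) from Binomial(8, 0.05)
essentially perfectly, which is the point of requiring recurrence across
datasets rather than a single peak.

What the generators do **not** emulate: count-level noise (no negative
binomial read model), gene–gene correlation beyond the single latent factor,
batch effects, tumor purity, isoform structure, and realistic genomic
feature density (genes are spaced so promoter windows never collide).
Passing tests therefore demonstrate that the statistics and rules are
implemented correctly and behave as designed under their assumed structure —
not that the signature generalizes to any particular real cohort.

## Peak annotation details

Coordinates are BED-style 0-based half-open throughout. The promoter is the
strand-adjusted window [TSS − w, TSS + w], inclusive at both ends, with
w = 1000 bp by default; the priority cascade is Promoter → 5′UTR → 3′UTR →
Exon → Intron → Downstream → Intergenic, with the UTR categories skipped
because the simplified gene model carries no UTR intervals (full
multi-isoform resolution is out of scope). A peak overlapping several
promoters is assigned to the gene with the smallest |midpoint − TSS|
distance, ties broken lexicographically — a deterministic rule fixed here
because the original annotation package's internal resolution is not
documented in the source analysis; real-data counts may differ slightly at
such collisions. Intergenic peaks record their nearest gene for context but
never set a 1 in the gene × dataset matrix, whose semantics are "at least
one peak assigned to the gene".

## Tumor-cohort statistics

Marker grouping uses inclusive mean ± k·SD thresholds (k = 1) on
log2(1 + TPM); for a roughly Gaussian marker about 16% of samples land in
each tail. Group comparisons use the two-sided Mann–Whitney test with BH
correction — the source analysis does not name its test, and a rank test is
robust on TPM-scale data. Marker correlation p-values come from permutation
of the marker profile with add-one smoothing, (b + 1)/(nperm + 1), so no p
is ever exactly zero; this is our concrete construction of the
"nearest-neighbor function with 1000 permutations" of the original heatmap
tool, whose algorithm is not published. Correlation bins resolve the
unassigned interval (0.39, 0.40) in the original caption as
moderate = [0.3, 0.4), strong = [0.4, 1].

## Problem sizes and runtime

The test suite and acceptance script size their simulations to run on one
CPU in a few minutes total: 500–2000 gene panels, 62-line cohorts, 200
replicate cohorts for the AUC average, 40 seeds × 150 genes for Spearman
recovery, 1000 permutations where permutation counts matter. These sizes
were chosen so that every Monte-Carlo assertion has comfortable margin
(binomial/normal sampling error well inside the asserted tolerance), and
they are stated here as the package's validation conditions.

## Known limitations

- The GSEA "gene-set" permutation mode samples uniform random same-size
  gene sets; the desktop tool's exact sampling scheme is unverifiable from
  the source analysis, so calibration (not bit-compatibility with the
  desktop tool) is the tested contract.
- GSVA general monotone-transform invariance is approximate (see above).
- ROC p-values assume the DeLong normal approximation; exact small-sample
  p-values are out of scope.
- Real-data headline counts depend on external accessions and are not
  recomputed offline; the external-format readers and every downstream rule
  are exercised on synthetic dialect-faithful fixtures instead.
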