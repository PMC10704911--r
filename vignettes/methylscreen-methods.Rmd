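---
title: "methylscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
what each stage assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The measurement model

An 850K-style array reports, per CpG probe and sample, a methylated
fraction β ∈ [0, 1]. Genome-wide, β is strongly bimodal: most CpGs are
either nearly fully methylated (β > 0.8) or nearly unmethylated
(β < 0.2). Array noise is heteroscedastic on the β scale — variance is
largest at β ≈ 0.5 and compressed at the extremes — which is why the
logit transform M = log2(β/(1−β)) approximately stabilises variance.
Group effect sizes, however, are conventionally stated as
Δβ = mean β(case) − mean β(control), because Δβ has a direct biological
reading (fraction of molecules changing state). The package keeps both
conventions where each is strongest: **inference on M, effect sizes and
gates on β** (see "Open design choices").

## Probe QC cascade

Stages, in the order applied: detection P ≥ 0.01 in one or more samples
(inclusive boundary); fewer than 3 beads in at least ⌈0.05·n⌉ samples
(at least one sample — the ceiling-with-floor reading of "5% of
samples", matching the convention of the standard preprocessing
toolchains); non-CpG probes; SNP-associated or cross-reactive probes
(taken as manifest flags — the package does not try to reconstruct any
specific published exclusion list); X/Y probes. A probe failing several
criteria is attributed to the **first** stage that removes it, so stage
counts are disjoint and sum to the total removed; the retained set
itself is order-invariant (tested by comparing against the union of raw
stage sets). Missing detection-P or bead-count matrices downgrade their
stages to warnings rather than errors, because public β matrices
frequently ship without them.

## DMP calling

Per probe, a two-sample test compares case and control groups:

* `welch_t` — unequal-variance t-test, the transparent baseline;
* `moderated_t` (default) — empirical-Bayes variance moderation: per-probe
  pooled variances s² (df = n₁+n₂−2) are modelled as draws from a scaled
  F distribution; the prior (d₀, s₀²) is estimated by moment-matching on
  log s² (with a Newton solve of the trigamma inverse), and each probe's
  variance is shrunk to (d₀s₀² + df·s²)/(d₀ + df) with the statistic
  referred to t on df + d₀ degrees of freedom. With 10 samples per group
  this is the difference between usable and hopeless per-probe inference.
  The unit tests check the implementation against limma on a shared
  fixture and against Welch ordering on nulls.

P-values are Benjamini–Hochberg adjusted (the `p_adj ≥ p_raw` and
brute-force-equality properties are tested exhaustively on random
vectors). A probe is a DMP when **adjusted P < 0.05 and |Δβ| > 0.1,
both strict** — a probe at Δβ = 0.1 exactly is not called. The raw-P
variant (`use_adjusted = FALSE`) exists because methods-section and
results-section conventions for this criterion differ in the wild; the
adjusted-P reading is the default.

Degenerate inputs: a probe with zero variance in both groups gets p = 1
when the means are equal and p = 0 when they differ; Δβ = 0 can never be
called regardless of p.

## Genomic context

Distribution tables attribute each probe **once**, to its first-listed
gene-region mapping (IGR when unmapped), so category counts sum to probe
counts and percentages are interpretable; the biomarker screen, by
contrast, sees **all** mappings of a probe, because a promoter mapping
must not be hidden by a Body mapping listed first. Island relations
follow the 0–2 kb shore / 2–4 kb shelf rule with N_/S_ assigned by
genomic coordinate (north = lower); when a manifest already carries the
label it is taken as-is, and `classify_island_region()` is the fallback
for interval inputs.

Enrichment between two probe sets is the Pearson chi-square on the 2×2
in/out-of-category table, without continuity correction (the classical
test the field quotes); any expected count < 5 triggers a warning and a
companion Fisher exact p rather than a silent switch.

## Biomarker screen

Three criteria, in order: (1) promoter residence (TSS1500, TSS200,
5'UTR, 1stExon); (2) extreme group-mean methylation, β < 0.3 or β > 0.7
strict — extreme levels are the ones most plausibly tied to loss or gain
of expression; (3) at least 3 distinct surviving DMPs per gene
(inclusive). A probe may support several genes; a gene's DMP count uses
probes surviving stages 1–2 for that gene, not raw genome-wide DMPs, so
the cascade narrows monotonically (tested as a subset chain, plus
monotonicity of the candidate count in the β bounds).

**Open choice:** whether the extreme-β criterion inspects the case
group, the control group, or both is not a settled convention. The
default inspects the **case-group mean** (a disease biomarker should be
extreme in patients); `extreme_group` exposes `control`, `either` and
`both`.

## Clinical statistics

* **2^−ΔΔCt**: ΔCt = Ct(target) − Ct(reference); ΔΔCt subtracts a
  calibrator ΔCt, by default the control-group mean, which pins the
  control geometric mean expression to 1. The algebra (shift target and
  reference together → unchanged; shift target alone by c → ×2^−c) is
  asserted exactly.
* **Normality gate**: Kolmogorov–Smirnov with estimated parameters is a
  Lilliefors-type test; the package uses Stephens' modified statistic
  D·(√n − 0.01 + 0.85/√n) against the published critical points (0.895
  at the 5% level), with an interpolated, explicitly approximate p.
  Both groups normal → Student t with mean ± SD summaries; otherwise
  Mann–Whitney U with median (Q1, Q3). Constant data fails the gate by
  definition and fully tied data yields p = 1. Type-I error of the
  gated pipeline is checked by simulation (0.05 ± 0.02 at 2000 reps).
* **Correlation**: `auto` picks Pearson only when both variables pass
  the gate, else Spearman.
* **ROC**: empirical curve over unique score thresholds (ties collapse
  to one threshold), trapezoid AUC (equal to Mann–Whitney pair counting
  on tie-free data — a tested identity), `positive_is_low = TRUE` by
  default because the motivating biomarker is hypomethylated in cases.
  The reported cutoff maximises Youden's J; no criterion beyond J is
  implied.
* **Composite score**: mean β across a gene's DMPs by default — simple,
  monotone, and robust at k = 5 probes; `pc1` is available when probes
  disagree in scale.

## The synthetic world

The generator states one fixed world; its parameters are not tuned to
test outcomes.

| parameter | default | rationale |
|---|---|---|
| samples per group | 10 | discovery-cohort scale for array studies |
| probes | 5000 | desk-scale stand-in for ~850k |
| β mixture | 0.45·Beta(2,8) + 0.55·Beta(8,2) | bimodal landscape, modes < 0.2 and > 0.8 |
| noise | logit-normal, SD 0.5 | keeps β in (0,1), heteroscedastic like arrays |
| planted DMPs | 200 at \|Δβ\| = 0.2 | moderate, recoverable effects |
| QC failures | 7/5/3/4/6, disjoint | one planted set per cascade stage |
| biomarker | 1 gene, 5 promoter CpGs, control β ≈ 0.80, case β ≈ 0.15 | extreme hypomethylation in cases |
| expression coupling | Pearson r = −0.8 with log2 expression | strong but noisy anti-correlation |
| TSH coupling | log-scale slope 3 on the composite deficit | cases hypothyroid-like (TSH ≫ controls) |

Implementation notes. Planted effects shift the **case-group latent
logit mean** so the expected β difference equals the target (sign
random, flipped when the baseline makes it infeasible); the
generator-self-check test verifies realized |Δβ| within ±0.05 of target
on average. Planted DMPs are **capped at two per gene** so that planted
background effects cannot fabricate a ≥3-DMP candidate gene — the screen
should find the biomarker because of its construction, not by
collision. Expression is linear in the biomarker composite on the log2
scale with noise solved from the realized signal variance to hit the
target correlation; Ct pairs are emitted so the 2^−ΔΔCt route reproduces
it. TSH, FT3 and FT4 are coupled to the composite with
reference-range-plausible baselines (TSH ≈ 1.8 mIU/L geometric mean in
controls; FT4 ≈ 16 pmol/L, FT3 ≈ 4.9 pmol/L). All matrices are written
at fixed decimal precision (values normalised through their decimal
text), so a generated file round-trips bit-identically and reruns are
file-identical under a seed.

What the generator does **not** emulate — so a green test does not
establish robustness to: probe-type I/II chemistry bias, batch and
position effects, cell-type composition differences (the dominant
confounder in whole-blood EWAS), genuine island-interval geometry
(island labels are sampled, not derived from intervals), SNP-driven
trimodal β patterns, or missing values.

## Other design decisions

* **Inference scale.** Testing directly on β is the literal reading of
  the conventional call criterion (a P gate plus a Δβ gate, both stated
  in β units), and some published pipelines do exactly that. Measured
  on the package's own stated world, β-scale moderated testing delivers
  ~0.85–0.90 sensitivity on the planted-DMP recovery task while M-value
  testing delivers ~0.90–0.96 at equal or lower false-discovery
  rates — the textbook argument for M-values. The package therefore
  defaults to `transform = "mvalue"` and keeps `transform = "none"` for
  the literal β-scale convention. Δβ and its gate are always computed
  on β.
* **BH rather than another FDR method**: the adjusted-P criterion names
  no method; BH is the default of the standard array toolchains.
* **JSON run configs** (not YAML): no YAML parser is assumed at run
  time; one config file drives `run_all()` and flags override it.
* **Probes in the β matrix but absent from the manifest are dropped
  with a logged count**, not an error: manifest-version mismatches are
  routine.
* **Coordinates**: manifest positions are 1-based single-base; BED
  export converts to 0-based half-open with score = round(1000·|Δβ|)
  capped at 1000.

## Known limitations

No DMR (region-level) calling, no cell-type deconvolution, no SVD/batch
confounder analysis, no normalisation (the pipeline consumes normalized
β), no GO/KEGG enrichment, and no IDAT-level input. The Lilliefors p is
interpolated between published critical points and is reliable as a
**gate** at conventional levels rather than as a precise p-value.
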