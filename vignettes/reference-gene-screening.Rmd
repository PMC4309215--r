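---
title: "Screening reference genes across gravity conditions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening reference genes across gravity conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
library(dplyr)
```

## The problem

Differential expression measurements — qPCR or microarray — are normalized
against reference ("housekeeping") genes assumed constant across the
experimental conditions. That assumption was established under normal
gravity. Experiments on parabolic flights (about 20 s of microgravity,
bracketed by 1.8 g pull-ups) and sounding rockets (about 6 min of
microgravity after a hyper-g launch) change exactly the variable the
assumption quietly holds fixed, so candidate reference genes must be
re-screened before they can anchor any altered-gravity expression study.

`refstab` implements that screen end to end for probe-level microarray data:

1. **Scale handling and normalization** — log2 intensities are
   back-transformed to linear fluorescence (FI); arrays can be
   quantile-normalized so every array shares the mean sorted-value
   distribution.
2. **Probe-to-gene aggregation** — each probe's replicate arrays are averaged
   within a gravity condition; a gene's per-condition mean, SD and n are
   then computed **across its probes**, and only genes with at least three
   retained probes are analyzable. Genes whose probes disagree wildly are
   excluded.
3. **CV screen** — the coefficient of variation (100 x sample SD / mean) of
   a gene's per-condition means, with acceptability below 25% for
   homogeneous and below 50% for heterogeneous sample groups.
4. **Contrast testing** — unpaired Welch t-tests over the campaign's ordered
   condition contrasts (four for parabolic flight, three for the rocket),
   plus a one-way ANOVA with Benjamini-Hochberg FDR across genes reported
   alongside.
5. **Verdict matrix** — `-` where p < 0.05, `+` otherwise; a gene is
   g-stable only if every contrast is `+`, and genes failing the probe or
   variance rules are unassigned.
6. **Stability ranking** — geNorm, NormFinder, BestKeeper and the
   comparative delta-Ct method, combined by the geometric mean of
   per-method ranks.

## The data model and its single most consequential convention

Summary statistics are computed on the **linear** FI scale, because the
published per-campaign summary tables that this pipeline reproduces report
linear means and SDs, and the CV screen is defined on them. The replicates
entering a gene's per-condition mean/SD/n are the **per-probe condition
means**, not the individual arrays: a gene measured by k probes contributes
k values per condition, each the average of that probe's replicate arrays.
The observed inter-probe SDs are small relative to array-to-array spread,
which is what makes this convention (rather than pooling all probe x array
values) consistent with the published tables; the probe counts implied by
the published accession lists (3-7 per gene) also match the Welch degrees
of freedom implied by the printed p-values, which we verified reproduce to
four decimals from the printed means and SDs.

Two consequences are worth keeping in mind:

* probe effects are *paired* across conditions (the same probes are
  averaged on both sides of a contrast) while the Welch test treats the two
  sides as independent — the test is therefore conservative when
  inter-probe spread dominates;
* n is small (typically 3), so single-contrast power at a 20-40% fold
  change is modest. The screen compensates by testing every contrast on two
  platforms and by requiring a clean sweep of `+` calls for a g-stable
  verdict.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_probes` | 3 | minimum retained probes for a gene to be analyzable |
| `outlier_rule` | `"none"` | probe outlier trimming; `"mad"` removes probes outside median ± 3 MAD per condition (union over conditions). Off by default because no standard rule exists for this step; reproduction of published tables should not silently drop probes. |
| `variance_threshold` | 100 (%) | inter-probe CV (any condition) above which a gene is excluded as internally inconsistent; an explicit exclusion list is also accepted for reproducing a published exclusion exactly |
| `group_type` | `"heterogeneous"` | CV acceptability threshold: 25% (homogeneous) or 50% (heterogeneous). Rapid gravity transitions make flight samples heterogeneous. |
| `alpha` | 0.05 | two-sided level for the `-`/`+` verdicts |

Threshold comparisons are strict: a CV of exactly 25% fails the 25%
criterion ("below" is read literally). The ANOVA+FDR pass does not gate the
verdict matrix — the published matrix is built from unadjusted pairwise
p-values — but is reported for stricter use.

## Numerical choices

* **Percentiles** (QC boxplots with 9th/91st whiskers) use linear
  interpolation between closest ranks (`stats::quantile` type 7, the
  spreadsheet convention).
* **Quantile normalization** maps each array's ranks onto the across-array
  mean of sorted vectors; ties receive the mean of the reference values at
  their occupied ranks, making the value map well defined. The operation is
  idempotent to floating tolerance and rank-preserving on tie-free input
  (verified against limma on tie-free matrices).
* **SDs** use the sample (n-1) divisor throughout.
* **Welch** degrees of freedom are left unrounded. If both group SDs are
  zero the test degenerates to p = 1 (equal means) or p = 0 (unequal).
* **geNorm** removes exactly one gene per iteration; when the two worst
  genes tie in M, the lexicographically larger symbol is removed. The final
  two genes, which geNorm cannot distinguish stepwise, are ordered by their
  full-panel M. Per-method rank ties and composite ties break
  lexicographically by gene symbol, making rankings deterministic.
* **NormFinder** is computed on the gene-centered, sample-centered log2
  matrix; with groups, each gene's per-group bias d and within-group SD are
  combined as `mean over groups of (|d| + sigma / sqrt(n_group))`. This
  grouped combination penalizes systematic shifts and scatter on the same
  scale; it is validated against a definitional brute-force oracle rather
  than any reference implementation.
* **BestKeeper** is applied to log2 fluorescence rather than qPCR
  crossing points — a documented adaptation; its CV is the one score in the
  package that is sensitive to per-gene rescaling, and its ranking is taken
  from the SD of log2 values.
* **Composite ranking** is the geometric mean of per-method ranks.

## What the synthetic generator emulates — and what it does not

`simulate_study()` draws probe-level linear FI as

```
FI(probe p, gene g, array a in condition c)
  = baseline_g * 2^( probe_effect_p + log2(fc_gc) + eps_pa ),
    probe_effect_p ~ N(0, probe_affinity_sd),  eps_pa ~ N(0, noise_sd_log2)
```

i.e. lognormal noise, additive on the log2 scale on which all ranking
statistics operate. Defaults mirror the flight studies: 28 parabolic-flight
arrays (6 H/W, 8 1 g, 6 1.8 g, 8 ug) and 18 rocket arrays (6 H/W, 5 BL,
7 ug); baselines log-uniform over ~2-25,000 FI (the published tables span
~18 to ~25,000); 2-6 probes per gene; g-sensitive genes with 20-40%
condition fold changes (the published TBP drop from 1 g to 1.8 g is ~30%);
probe affinity SD 0.25 log2 units, putting simulated inter-probe SDs in the
~10-50%-of-mean range seen in the published tables; wild (high-variance)
genes at 2 log2 units. The `paper_mimic_specs()` preset plants a 99-gene
panel (20 reference-like, 47 ABC-transporter-like, 32 tRNA-synthetase-like)
partitioned into 8 stable, 9 sensitive and 82 unassignable genes, mirroring
the structure of the published screen.

The generator does **not** emulate scanner images, spatial artifacts,
probe-sequence effects, RMA background correction, correlated noise between
genes, or hardware/vibration covariates. Passing tests on synthetic data
therefore validate the statistical pipeline — aggregation rules, test
calibration, ranking behaviour — not the upstream array processing, which
is assumed done (inputs are summarized probe intensities).

Seed determinism relies on R's default Mersenne-Twister generator; the same
seed reproduces a study bit-identically.

## Worked example

```{r example}
design <- flight_design("PFC")
specs <- paper_mimic_specs("PFC")
sim <- simulate_study(design, specs, seed = 1)
res <- screen_reference_genes(sim$expr, design)
glance(res)
recovery_report(sim, res$verdicts)$confusion
```

The published summary tables ship as fixtures, so the published verdict
matrix can be recomputed directly from printed means, SDs and probe counts:

```{r fixtures}
sums <- flight_gene_summaries()
tests <- test_contrasts(sums)
verdicts <- classify_genes(tests)
verdict_matrix(verdicts)$counts
```

Ranking the analyzable candidates of a simulated study:

```{r ranking}
analyzed <- unique(res$aggregation$summaries$gene_symbol)
mat <- candidate_matrix(sim$expr, genes = analyzed)
rs <- rank_stability(mat, groups = design$condition)
head(tidy(rs), 5)
glance(rs)
```

## Validation strategy and problem sizes

The test suite validates every stage against independent oracles:
brute-force all-pairs SD loops for geNorm/delta-Ct, a definitional
variance-decomposition loop for NormFinder, hand Pearson formulas for
BestKeeper, numerical t-density integration for Welch p-values, a longhand
step-up rule for BH, and sort-and-interpolate for percentiles. Calibration
and power checks use a 1000-gene null simulation (per-contrast type-I rate
within binomial 99% bounds of 0.05), 200-seed recovery of a planted 40%
fold change with six probes and low noise (the within-probe calibration
case: probe affinity spread set to zero so the unpaired test's independence
assumption holds exactly), and 100-seed ranking separation of planted
stable vs sensitive genes. These sizes keep the full suite under a minute
while leaving Monte-Carlo error well inside the asserted margins.

## Known limitations

* The screen's verdicts depend on unadjusted pairwise p-values at 0.05, as
  in the published analysis; with seven contrasts per gene the family-wise
  false-positive rate per gene is correspondingly higher, which is
  conservative for *selecting* reference genes (stability requires a clean
  sweep) but inflates the g-sensitive class.
* Printed summary tables are rounded, so recomputed p-values near 0.05 can
  flip; reproduction checks treat printed p in [0.03, 0.07] as borderline.
* The high-variance exclusion threshold (inter-probe CV > 100%) has no
  published value — only the published outcome (two genes excluded) — and
  is configurable; an explicit exclusion list reproduces a published
  analysis exactly.
* BestKeeper's Pearson correlation with the all-candidate index rewards
  genes that co-vary with the panel; with few candidates the index is not
  robust to one wild gene.
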