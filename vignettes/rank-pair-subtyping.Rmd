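---
title: "Rank-pair subtyping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-pair subtyping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gersub)
```

## The problem

Bulk transcriptomic cohorts produced on different platforms, in different
labs, at different times carry systematic non-biological differences —
batch effects — large enough to swamp the biological signal that molecular
subtype classifiers depend on. The usual remedy (explicit batch correction
such as empirical-Bayes location/scale adjustment) requires refitting
whenever a new cohort arrives and can distort the signal itself.

`gersub` takes the alternative route: discard absolute expression entirely
and work with **within-sample gene ranks**. Any batch distortion that acts as
a strictly increasing transformation of one sample's values — global scale
changes, log/linear disparities, intensity compression — leaves every
within-sample rank unchanged, so a classifier built purely on rank
comparisons is invariant to that entire distortion class *by construction*,
not approximately. The motivating application is medulloblastoma, whose four
consensus subgroups (WNT, SHH, Group 3, Group 4) drive risk stratification
and must be called reliably across heterogeneous cohorts.

## The model

Write $G_{1..n}$ for one sample's expression values and $T_{1..n}$ for their
ascending ranks (lowest expressed gene has rank 1; ties get the mean of the
positions they span, so each column of the rank matrix sums to
$n(n+1)/2$ exactly).

**Stage 1 — differentially ranked genes.** For each ordered subtype pair
$(A, B)$ and each gene, the statistic is the difference in mean rank,
$\bar T_A - \bar T_B$, tested with a two-sided Welch $t$-test on the
per-sample ranks. A gene is *up in A vs B* when the difference exceeds
$\mathrm{round}(q \cdot n)$ rank positions with $p < \alpha$ (defaults
$q = 0.11$, $\alpha = 0.05$); *down* symmetrically. Subtype $S$'s signature
genes are those consistently up in $S$ against all three other subtypes, or
consistently down — the up-sets of the three comparisons intersected, the
down-sets intersected, the two unioned. Expressing the rank cut as a
fraction of the gene count keeps the operating point meaningful on any
platform. No multiplicity adjustment is applied at this stage; the screen is
deliberately permissive and the later stages are the real filters.

**Stage 2 — gene-pair reversal screen.** For every unordered pair of
signature genes and every sample, the pair indicator is
$R_{ij} = 1$ if $T_i > T_j$, else $0$ (ties fall in the 0 branch, so a tied
pair votes for neither orientation). For a comparison of $S$ against another
subtype $O$, the samples form a 2×2 table — rows $S$/$O$, columns indicator
1/0 with counts $f_{11}, f_{12}, f_{21}, f_{22}$ — and the **reversal
ratio** is

$$\mathrm{RR} = \frac{f_{11} + f_{22}}{f_{11}+f_{12}+f_{21}+f_{22}},$$

the fraction of samples whose indicator agrees with the
subtype-characteristic orientation. A pair passes the comparison when
$\mathrm{RR}$ meets the comparison-specific threshold *and* a two-sided
Fisher exact test on the table gives $p < 0.05$. The default thresholds for
the four subgroups are 0.95 whenever the selected subtype is SHH or WNT,
0.90 for Group 3/Group 4 against SHH, 0.85 for Group 3/Group 4 against WNT
and Group 4 against Group 3, and 0.80 for Group 3 against Group 4 — the
hardest discrimination in this disease, hence the loosest cut. A pair is
retained for $S$ only if **one consistent orientation** passes all three of
$S$'s comparisons; both orientations are evaluated and the passing one is
stored (`gene_hi` outranking `gene_lo` characterises $S$). Pairs whose
passing orientation flips between comparisons are discarded. The threshold
comparison is inclusive (`>=`) so the documented values are attainable
exactly; a strict flag exists.

The Fisher $p$ is computed by a vectorised hypergeometric sum (conditional
on both margins, two-sided by the point-probability rule, with the usual
$1 + 10^{-7}$ relative guard against ties broken by rounding); tests verify
it against `stats::fisher.test` and against brute-force enumeration of all
tables with the observed margins, to $10^{-12}$.

**Stage 3 — elastic-net refinement.** The screened pairs are still highly
redundant. For each subtype $S$ and each other subtype $O$, the samples of
$S \cup O$ with the binary indicator matrix of $S$'s screened pairs are fit
by penalized logistic regression (glmnet, $\alpha = 0.1$, binomial family,
100 log-spaced penalties spanning four decades, standardization off because
\{0,1\} features share a scale). The penalty is chosen by the 1-SE rule from
10-fold class-stratified, seeded cross-validation; features with nonzero
coefficients are *selected*. $S$'s final features are the pairs selected in
all three of its runs; the stored coefficient is the mean of a pair's
nonzero coefficients across the runs in which it was selected (reported
only — the classifier below never uses it). The two-subtype restriction
mirrors the screening comparisons; the alternative (all samples with a
one-vs-one label restriction) was considered and rejected as inconsistent
with the screen's conditioning.

**Classification.** A new sample is scored per subtype by the **mean pair
indicator** over that subtype's features, a number in $[0,1]$, and assigned
the argmax. Exact ties are broken by the model's fixed subtype order and
flagged. Ranks at prediction time are computed *within the model's gene
universe* (the union of genes in retained pairs), so prediction does not
depend on the platform's full gene complement; ranking over all supplied
genes is available as a flag and provably yields the same scores, since
indicators only ever compare genes inside the universe.

## Tunable parameters

| Parameter | Default | Units / range | Why this value |
|---|---|---|---|
| `rank_frac` | 0.11 | fraction of gene count | rank-difference cut of the stage-1 screen; scales with platform size |
| `sig_alpha` | 0.05 | p-value | Welch test cut, raw (no FDR — later stages filter) |
| reversal thresholds | 0.95/0.90/0.85/0.80 | reversal-ratio | per-comparison operating points above; single value for non-MB subtype sets |
| `fisher_alpha` | 0.05 | p-value | association cut for the pair tables |
| `enet$alpha` | 0.1 | mixing in [0,1] | ridge-leaning: screened pairs are strongly correlated, groups survive while noise is zeroed |
| `enet$n_folds` | 10 | folds | CV for the 1-SE rule; degrades with a warning when a class is smaller |
| `enet$lambda_rule` | `lambda_1se` | — | sparser models at statistically indistinguishable CV loss |
| `enet$loss` | `deviance` | — | binomial CV loss; `class` available (see below) |
| `max_missing` (predict) | 0.05 | fraction of a subtype's features | missing-gene tolerance before prediction aborts |

All randomness (CV folds, the generator) flows from a single integer seed;
fits and predictions are bit-reproducible.

## Numerical choices and degenerate inputs

- **Ties.** Mean (fractional) ranks keep column sums exact and make the pair
  indicator orientation-safe: a tied pair scores 0 in both directions.
- **Zero-variance vectors** in z-scoring become all-zeros with a warning
  rather than an error, so constant probes cannot abort a run. Per-sample
  z-scoring is a strictly increasing affine map and therefore cannot change
  any downstream result; it exists for interoperability, not for the method.
- **Deviance vs misclassification CV loss.** With features that separate the
  two classes *completely* (common in this pipeline's screened sets, and the
  construction used in the selection sanity checks), CV deviance keeps
  falling along the entire penalty path while its fold SE collapses, so the
  1-SE rule sits next to the deviance minimum and is not sparse. The
  misclassification loss plateaus at zero error as soon as a separator
  enters the model, and its 1-SE rule then picks the sparsest such model.
  The pipeline default remains deviance (the convention of the reference
  implementation); the recovery sanity checks use `loss = "class"` for this
  reason.
- **Missing genes at prediction** are skipped per feature, never imputed; a
  subtype losing more than `max_missing` of its features is a hard error
  naming the genes.
- **Empty stages** (no signature genes, empty screen, empty elastic-net
  intersection) produce models with empty feature lists and prominent
  warnings; such a subtype is never predicted.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` exists so that every stage is testable without any
external download. Its defaults are fixed study conditions, not knobs:

- 763 samples in proportions 223:70:144:326 (SHH:WNT:Group 3:Group 4), the
  composition of the large public training cohort this class of classifier
  is built on; 2000 genes with a Gaussian log-expression baseline
  (mean 6, sd 2).
- 40 marker genes per subtype (20 up, 20 down), disjoint across subtypes,
  drawn from the baseline quantile bands (0.35, 0.45) and (0.55, 0.65) and
  shifted by `marker_shift = 0.2` **on the rank scale** (a marker's subtype
  mean moves to the baseline value 0.2 quantiles away). Band placement plus
  a shift larger than the band gap guarantees that in the marked subtype
  every (up, down) marker pair reverses its baseline order — these are the
  planted reversal pairs in the truth record. The 0.2 shift sits comfortably
  above the 0.11 screening cut, so recovery failures indicate defects, not
  borderline power.
- Three batches, stratified by subtype: a clean reference, an affine
  gain/offset batch, and a log-compressed batch (the classic linear-vs-log
  disparity between cohorts), the latter two with additive gene-level batch
  shifts of sd 0.8 — twice the entry noise (sd 0.4). The warps are strictly
  increasing per sample and therefore invisible to every rank-based stage;
  the gene-level shifts *do* perturb ranks and are what makes held-out-batch
  generalization a real test. They are also what breaks a naive
  nearest-centroid classifier on absolute expression: trained on the clean
  batch it loses over 50 accuracy points on the log-warped batch, while the
  rank-pair pipeline loses none.

The generator does **not** attempt platform-specific probe behaviour,
count-distribution realism for RNA-seq, correlated gene modules, or the
Group 3/Group 4 transcriptional continuum that makes the real discrimination
hard. Passing its tests therefore demonstrates the machinery — rank
invariance, screening correctness, recovery of planted structure under
rank-perturbing batch noise — not clinical-grade accuracy on real tumours;
the near-perfect held-out accuracies on synthetic cohorts are a property of
the planted-marker design, and should be read as an upper bound.

## Problem sizes used in the checks

The test suite runs cohorts of 80–200 samples and 400–800 genes for unit
checks, and the packaged acceptance analysis uses the full default spec
(763 × 2000, three batches, held-out log-warped batch, five seeds) for the
end-to-end recovery run — about a minute of compute overall on one CPU.

## Known limitations

- Screening enumerates all signature-gene pairs; cohorts whose signatures
  run to thousands of genes produce millions of tables. Iteration is chunked
  (constant memory, identical output) but time grows quadratically.
- Scores are mean indicators, not calibrated probabilities; they order
  subtypes within a sample but are not comparable across models.
- Tie-flags matter on tiny gene universes, where integer score ties occur.
- The orientation bookkeeping assumes the subtype-characteristic direction
  is stable across a subtype's three comparisons; pairs violating this are
  silently (and intentionally) dropped rather than split.
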