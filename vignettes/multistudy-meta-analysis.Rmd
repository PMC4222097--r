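---
title: "Methods: extracting and combining gene expression evidence across studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting and combining gene expression evidence across studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maex)
```

## The problem and the pipeline

Public repositories hold thousands of normalized expression studies, and a
common need is to ask a focused question of many of them at once: for a
list of candidate genes, is there consistent evidence of up- or
down-regulation in a disease relative to controls?  `maex` implements a
deliberately transparent pipeline over plain-text inputs:

1. **Extraction** — map each gene to its probes via a per-study annotation
   and pull the matching rows from the expression matrix.  Each study
   reports three disjoint gene sets: found, absent from the annotation, and
   annotated but absent from the data; these always partition the input
   list, so nothing disappears silently.
2. **Refinement** — resolve the scale to log2, cluster samples into their
   declared groups (matrices are often not ordered by group), pick one
   probe per gene, and compute per-group centers and group-minus-control
   log2 ratios.
3. **Merging** — one table: genes × (study, group) ratio columns, with
   group label, study number and sample sizes carried as column metadata,
   plus an optional curation filter.
4. **Statistics** — a one-tailed two-sample *t*-test per gene and group
   versus control within each study, combined across studies per gene.

## Model and assumptions

The statistical model is intentionally minimal.  Within a study, log2
expression of a gene in a group is treated as i.i.d. normal with a
group-specific mean; the two-sample pooled-variance Student *t*-test
(df = n₁ + n₂ − 2) compares each non-control group to the control.  We
report the one-tailed p in the *observed* direction, `p_one = P(T ≥ |t|)`,
together with the direction sign.  The direction is data-driven per
(study, group) rather than fixed a priori per gene — the pipeline has no
prior hypothesis about which way a candidate gene moves.  Welch's test is
available behind a flag for unequal variances.

Across studies, two combination routes:

* **Signed Stouffer.** `Z_i = qnorm(1 - p_one) * sign_i`, summed and
  divided by √N.  Because `p_one` is the observed-direction tail, `Z_i` is
  exactly the signed standard-normal score of the t-statistic's tail mass,
  so `Z_s` is standard normal under the null with no further assumptions.
  The combined two-sided p is `2 * (1 - pnorm(|Z_s|))`.
* **Fisher.** `chi2 = -2 * sum(log(p))` referred to `chisq(2k)`.  Fisher's
  reference distribution requires p-values that are uniform on (0, 1)
  under the null.  A direction-informed one-tailed p is uniform on
  (0, 0.5] instead, and feeding it to Fisher double-counts the observed
  direction: the false-positive rate inflates from 5% to roughly 38% in
  simulation.  The pipeline therefore hands Fisher the two-sided p-values
  `min(1, 2 * p_one)` (`combine_tests()`), which restores exact
  calibration; the low-level `fisher_combine()` computes the statistic on
  whatever p-values it is given.  Fisher output is sign-blind, so its
  consensus direction is the majority of per-study signs (an exact tie
  reports 0).

Two deliberate normalizations of commonly garbled formula conventions:
the Z transform uses `qnorm(1 - p)` so that small p maps to a large
positive score before the sign is applied, and the two-sided conversion is
`2 * (1 - pnorm(|Z_s|))`, which cannot exceed 1.  The canonical √N Stouffer
denominator is the default because it is the variance-stabilizing choice
(the statistic stays standard normal for any N); `denominator = "n"`
reproduces the plain-average variant for comparison, at the cost of
conservatism growing with N.

No multiple-testing correction is applied by default — the combined
p-values are reported raw, which is the convention this kind of candidate
screen uses; `bh = TRUE` appends a Benjamini–Hochberg column.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `center` | `mean` | central tendency for probe selection and ratios; median is robust to single-sample outliers |
| `auto_log_threshold` | 50 | log2 intensities rarely exceed ~16 while linear intensities reach thousands; the maximum finite value of a matrix is compared against this (≤ means "already log2") |
| `log_mode` | `auto` | `manual` trusts the `NOLOG` folder token instead |
| `stouffer_denominator` | `sqrt_n` | see above |
| `min_group_n`, `min_studies_per_gene`, `min_direction_agreement` | 5, 5, 0.75 | curation filters; off unless a `filter_config` is supplied |

The scale decision is logged per study ("please check if correct!")
because a 50-fold threshold cannot distinguish, say, ratio-type data
centered near 1 from log2 data; the user is the final authority.

## Probe selection

Affymetrix-style probe IDs encode specificity in their suffix (`_at`,
`_s_at`, `_x_at`).  The annotation's fourth column lists suffixes in
priority order; a probe's rank is the position of its suffix, probes
matching no listed suffix are excluded, and an empty list ranks everything
equally.  Because listed suffixes can end one another (`_s_at` ends in
`_at`), candidate suffixes are matched longest-first — otherwise `_at`
would swallow every probe.  Among minimum-rank probes the one with the
highest control-group center wins (a bright control signal indicates a
well-measured probe); an exact tie goes to annotation order and is logged.
A gene whose probes are all excluded is dropped with a warning rather than
silently.

## The merged table and hand editing

`Merged.txt` carries the column labels in its first row, `#`-prefixed
metadata rows (study number, group, N per group and control), the gene
body, and a footer row repeating the labels.  The footer plus the gene-ID
first column are what make the file safely *hand-editable*: rows may be
deleted or re-sorted and whole columns removed in a spreadsheet, and
`load_merged()` revalidates the anchors before the statistics stage
combines exactly what remains.  Statistics outputs are derived products
and are always rewritten; every other output honours the
preserve-overwrite policy so incremental reruns are cheap and safe.

The direction-agreement filter is computed per *study* (majority sign over
that study's columns, per-study ties counting to neither side) rather than
per column, so a study contributing three concordant disease groups counts
once, not three times.  One consequence worth knowing: the filters are not
jointly monotone — raising `min_group_n` can remove a small dissenting
column and thereby *rescue* a gene that previously failed the agreement
threshold.  The per-gene thresholds are individually monotone.

## What the synthetic generator emulates — and what it does not

`generate_tree()` writes a complete study tree: per-gene log2 baselines
drawn on U(6, 12), i.i.d. Gaussian noise (σ = 1 by default), a designated
brightest probe per multi-probe gene separated by 2 log2 units, optional
linear-scale (`NOLOG`) studies, scrambled sample columns, and genes
deliberately missing from annotation or data.  Defaults — 6 studies, 2
groups, 8 samples per group, σ = 1 — describe a modest but realistic
multi-study comparison and are the conditions under which the package's
operating characteristics are quoted: type-I error within binomial error
of nominal, and >90% sensitivity at p < 0.001 for a 1-unit log2 effect.

The generator's noise model is exactly the t-test's assumption, so passing
tests demonstrate *correctness of the machinery*, not robustness: real
microarray data have correlated probes, heavier tails, batch effects and
platform-dependent mean–variance relationships, none of which are
simulated.  Cross-study heterogeneity of the true effect (a random-effects
structure) is also absent — the injected effect is identical in every
study, which flatters any combination method.  Conclusions about real-data
power should not be read off these simulations.

## Numerical choices and degenerate inputs

* p-values of exactly 0 or 1 are clamped to [1e-300, 1 − 1e-16] with a
  warning before either transform; a zero pooled variance with unequal
  means yields t = ±Inf and a clamped p rather than an error.
* Comparisons with fewer than two non-missing values on either side are
  flagged untestable and excluded from combination (logged), never
  silently imputed.
* Missing cells propagate: excluded from centers sample-wise, a group with
  no finite value yields a missing ratio, and a gene with no testable
  column gets a missing combined p.
* Nonpositive values in linear-scale data are a hard error naming the
  cell; a silent +1 offset would distort every downstream ratio.
* Decimal commas anywhere in a matrix abort parsing with the offending
  coordinates — the classic locale failure is worth a hard stop.
* Test-suite and simulation sizes (2000 null genes, 500 effect genes, 6
  studies, trees of 8–50 genes) were chosen as the smallest sizes at which
  the binomial confidence bands are meaningfully tight; all are fixed-seed.

## Known limitations

* Gene identifiers match the annotation exactly and case-sensitively; no
  aliasing or cross-platform ID reconciliation.
* Inputs must be already normalized; no background correction, RMA or
  quantile step is provided or checked.
* One test per (study, group); studies with several disease groups
  contribute several comparisons to a gene's combination, which treats
  within-study groups as independent evidence.
* Fixed-effects combination only: no weighting, no between-study
  heterogeneity estimate.
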