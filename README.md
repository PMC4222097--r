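# maex — multi-study microarray expression extraction and meta-analysis

`maex` answers a recurring question for bench scientists: *given a list of
genes I care about, what do the dozens of already-normalized public
expression studies say about them, jointly?*  It extracts expression values
for a user-defined gene list from any number of normalized microarray
studies laid out as plain-text folders, collapses multi-probe genes to a
single probe, computes disease-versus-control log2 fold changes per study,
merges everything into one spreadsheet, and combines the per-study evidence
into a single p-value per gene.

It is aimed at researchers who want a transparent, file-based, offline
meta-analysis of candidate genes — not a full preprocessing framework.
Inputs are assumed already normalized (e.g. GEO series matrices pasted into
tab-separated text files).

## The statistics at the core

Within each study, every non-control group is compared to the control group
per gene with a pooled-variance two-sample Student *t*-test.  The reported
value is the one-tailed probability in the observed direction,
*p₁* = *P*(T<sub>df</sub> ≥ |t|), with df = n₁ + n₂ − 2, together with the
direction sign(x̄<sub>group</sub> − x̄<sub>control</sub>).

Across studies the evidence is combined per gene by either of:

* **Signed Stouffer Z-transform** (default):
  Z<sub>i</sub> = Φ⁻¹(1 − p₁ᵢ) · sᵢ, where sᵢ is the direction sign, and
  Z<sub>s</sub> = Σ Z<sub>i</sub> / √N (unweighted; a `/N` variant is
  available).  The combined two-sided p-value is
  p<sub>s</sub> = 2 (1 − Φ(|Z<sub>s</sub>|)).  Consistent regulation
  accumulates; opposing regulation cancels.
* **Fisher's method**: χ² = −2 Σ ln pᵢ ~ χ²<sub>2k</sub> under the null.
  Fisher's statistic is sign-blind, so the pipeline feeds it the two-sided
  p-values (2·p₁); the reported direction is the majority sign.

Fold changes are computed on the log2 scale (group center minus control
center, mean or median), with per-study automatic detection of whether a
matrix is already log2-transformed (or a manual `NOLOG` folder tag).  Genes
measured by several probes are collapsed by a suffix-priority scheme (e.g.
prefer `_at` over `_s_at` on Affymetrix arrays), breaking ties by the
highest control-group signal.

Optional merged-table filters reproduce a typical curation step: drop group
columns with fewer than 5 samples, genes covered by fewer than 5 studies,
and genes on whose direction fewer than 75% of contributing studies agree.

## Worked example

A synthetic six-study tree with two regulated genes (GENE002 at −1.5 log2
units, GENE005 at +1), one study stored on linear scale:

```r
library(maex)
root <- file.path(tempdir(), "demo")
generate_tree(synth_config(n_studies = 6, n_genes = 8,
                           effect_genes = c(GENE002 = -1.5, GENE005 = 1),
                           linear_scale_studies = 4L, seed = 20),
              root)
res <- run_pipeline(run_config(root))
```

The run logs each stage, including the per-study gene dispositions and the
scale decision that should be eyeballed:

```
[extract] study 1 (Study01): 8 found, 0 not in annotation, 0 annotated but absent from data
[refine] study 4 (Study04): treated as linear (will be log2-transformed) [auto-detected] -- please check if correct!
[merge] merging done: 8 gene(s) x 6 column(s)
[stats] statistics done (stouffer): 8 gene(s) combined
```

and the per-gene summary recovers both injected effects with the right
signs while the null genes stay flat:

```r
head(res$stats$summary[order(res$stats$summary$p_combined), ], 4)
#>   gene_id   method  statistic dof_or_n k_used n_studies_used   p_combined sign
#> 2 GENE002 stouffer -5.8396962        6      6              6 5.229610e-09   -1
#> 5 GENE005 stouffer  3.6253057        6      6              6 2.886198e-04    1
#> 6 GENE006 stouffer -1.0125079        6      6              6 3.112953e-01   -1
#> 1 GENE001 stouffer -0.7110657        6      6              6 4.770435e-01   -1
```

`statistic` is the combined Z-score (χ² for Fisher), `k_used` the number of
(study, group) comparisons combined, and `sign` the consensus direction.
On disk the run leaves `Extracted Data/`, `Refined Data/`, `Merged.txt`,
`Merged statistics.txt` and `stats_summary.txt` under `root`; existing
outputs are never overwritten unless forced, so you can hand-prune or
re-sort `Merged.txt` and re-run only the statistics.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/maex.R generate --root demo --seed 20 --n-studies 6 --n-genes 8
Rscript inst/cli/maex.R run --root demo --method stouffer --center mean
Rscript inst/cli/maex.R stats --root demo --method fisher
```

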