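# forumvigil

Infodemiology and pharmacovigilance pipelines for patient-forum text.

Online communities such as disease-specific subreddits carry candid,
unsolicited accounts of how patients actually experience a new drug —
what worked, what side effects appeared, and what it took to get the
treatment covered. `forumvigil` turns an archived forum extract (posts and
comments) into quantitative findings about those discussions. Its defaults
emulate a three-year analysis of vitiligo-forum conversations about topical
ruxolitinib, a JAK-inhibitor cream whose staggered regulatory approvals
(US 2022-07, EU 2023-04, UK 2023-07, Canada 2024-10) visibly shaped
discussion volume. The package is aimed at researchers in digital
epidemiology and drug safety who need a reproducible, testable pipeline
rather than a one-off notebook.

## What the pipeline computes

* **Corpus ingestion with an auditable ledger** — NDJSON in, drug-keyword
  filter, deleted/empty-content removal, and a retention ledger with the
  invariant `final = matched − removed` per entry kind.
* **Semisupervised topic classification** — each entry is embedded and
  compared with prototype-phrase centroids by cosine similarity
  `cos(u,v) = u·v / (‖u‖‖v‖)`; the label is the argmax if it reaches the
  abstention threshold τ (default 0.25), otherwise *off-topic*; a keyword
  override can reassign entries on unambiguous lexical evidence. Clusters:
  therapy success, side effects, insurance and cost, off-topic.
* **Sentiment** — a lexicon-and-rules engine scores each entry on the
  compound scale `s / sqrt(s² + 15)` (negation-aware valence sum `s`),
  summarized per cluster with 95% CIs.
* **Temporal analysis** — monthly volumes, 12-month trailing moving
  average, exact penalized change-point detection (piecewise-constant mean,
  variance-stabilized for counts), seasonal profile, and a paired
  post-vs-comment comparison (exact Wilcoxon signed-rank `W = min(W⁺,W⁻)`,
  paired t, Cohen's `d_z = mean(d)/sd(d)`).
* **Validation** — proportional 500-entry sample by largest remainder,
  confusion matrix, accuracy, weighted F1, and Cohen's
  `κ = (p_o − p_e)/(1 − p_e)` with seeded bootstrap CIs and the
  conventional interpretation bands.
* **Synthetic data** — a seeded generator with ground-truth labels,
  sentiment targets, volume steps and seasonality, so the entire pipeline
  is exercised offline; `generate_annotations()` simulates a human rater
  with a chosen error rate.

## Worked example

```r
library(forumvigil)

corpus <- generate_corpus(generator_config(seed = 42))   # 3000 entries, 2022-2024
annotations <- generate_annotations(corpus$gold_labels, epsilon = 0.116, seed = 43)
report <- run_pipeline(corpus$entries, annotations = annotations,
                       window = utc_seconds(c("2022-01-01", "2025-01-01")),
                       seed = 42, output_dir = "reports")

print(report$ledger)
#> Filter ledger (posts / comments / total)
#>   collected           625 /   2375 /   3000
#>   keyword_matched     607 /   2334 /   2941
#>   empty_removed         0 /      0 /      0
#>   final               607 /   2334 /   2941
```

59 entries were generated without a drug mention and fall out at the keyword
stage — the ledger records every stage by kind. The cluster table combines
classification counts, Wald intervals and mean sentiment:

```r
report$cluster_table[, c("cluster","n","pct","pct_lower","pct_upper","mean_sentiment")]
#>           cluster    n   pct pct_lower pct_upper mean_sentiment
#> 1 therapy_success 1767 60.08     58.31     61.85          0.461
#> 2    side_effects  545 18.53     17.13     19.94         -0.121
#> 3  insurance_cost  505 17.17     15.81     18.53          0.345
#> 4       off_topic  124  4.22      3.49      4.94          0.235
```

Therapy success dominates with clearly positive sentiment; side effects is
the one negative cluster — the structure the generator encodes and the
classifier recovers. The temporal module aligns detected volume shifts with
the configured approval months and finds the July peak:

```r
breakpoint_months(report$change_points$total, report$series)
#> [1] "2022-07" "2022-12" "2023-04" "2023-07" "2024-10"
which.max(report$seasonal$comments_mean)
#> [1] 7
```

All four approval months are recovered (2022-12 is a spurious extra split).
Comments exceed posts in every calendar month (median difference 44.3
messages, W = 0, p = 0.0005, t(11) = 11.56, d_z = 3.34), and validation
against the simulated annotator lands where a ~12% rater error rate should:

```r
report$validation
#> <validation_report> n = 500
#>   accuracy    0.880 (95% CI 0.852 to 0.908)
#>   weighted F1 0.875 (95% CI 0.843 to 0.905)
#>   Cohen kappa 0.802 (95% CI 0.754 to 0.848) [substantial]
```

`run_pipeline(..., output_dir =)` writes the full report bundle (ledger,
assignments, sentiment, cluster table, monthly series, breakpoints, seasonal
profile, comparison, validation, provenance header) as CSV/JSON; identical
inputs and seeds give byte-identical files. A thin command-line wrapper
lives in `inst/scripts/forumvigil-cli.R` (`simulate` and `run-all`
subcommands).

## Package layout

* `R/` — corpus I/O and ledger, embedding backends and classifier,
  sentiment engine and lexicon, statistics, temporal analysis, validation,
  synthetic generator, pipeline orchestration.
* `tests/testthat/` — unit, property and end-to-end recovery tests
  (enumeration oracles for the exact Wilcoxon test, brute-force
  classification checks, seeded parameter-recovery runs).
* `vignettes/forum-infodemiology-methods.Rmd` — the model, its assumptions,
  numerical choices, and what the synthetic benchmarks do and do not show.
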