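# combopredict

Rational selection of two-drug combinations for drug repurposing, plus
the behavioural endpoint arithmetic used to validate a nominated
combination in a preclinical model.

Pairing up the ~4000 approved drugs yields `4000 × 3999 / 2 = 7,998,000`
unordered pairs — roughly 8 million candidate experiments, far beyond any
laboratory screen. `combopredict` triages that space in silico with two
complementary engines and merges their verdicts:

* **CGEM (Combination Gene Expression Matching)** — models a pair's
  transcriptional effect as the elementwise sum of the two drugs'
  z-score signatures, re-ranks the genes, and scores the combined
  signature for *reversal* of a disease signature with the classic
  unweighted Kolmogorov–Smirnov running-sum enrichment statistic. For a
  gene set at sorted rank positions `p_1 < … < p_t` of `n` genes:

  ```
  a = max_j (j/t − p_j/n)      b = max_j (p_j/n − (j−1)/t)
  ES = a if a > b else −b
  connectivity = (ES_up − ES_down)/2   if sign(ES_up) ≠ sign(ES_down), else 0
  reversal = −connectivity
  ```

  A positive reversal means the combination pushes disease up-genes down
  and down-genes up. All `m(m−1)/2` pairs are scored exhaustively.

* **TargOpt (Target Optimisation)** — scores a pair on curated
  drug–target knowledge: `score = α·on_count − β·off_count`, where
  `on_count` counts disease targets engaged in the therapeutically
  desired direction by at least one drug of the pair, and `off_count`
  counts distinct liability engagements (targets outside the disease
  set, or disease targets pushed the wrong way). Defaults `α = 1`,
  `β = 0.5`; the `(on, off)` Pareto front is reported alongside the
  scalar ranking.

* **Prioritization** — mean-rank aggregation across the two engines
  (single-method pairs are penalized and flagged), plus advisory
  annotation flags (`ddi_alert`, `same_mechanism`) that inform a human
  expert without filtering anything.

* **Behavioural endpoints** — discrimination index
  `D2 = (t_novel − t_familiar)/(t_novel + t_familiar)` for recognition
  assays, the 3-second minimum-exploration inclusion rule, maximal-score
  latency censoring at test end (300 s), and per-group mean/SD/SEM
  tables ready for any stats package.

* **Synthetic data with planted truth** — seeded generators produce
  signature libraries, disease gene sets, target catalogues and
  behavioural cohorts in which the best answer is planted by
  construction, so the full pipeline is testable offline.

File formats: GCT 1.2 (or headered TSV) signature matrices, GMT gene
sets, plain TSV for target catalogues, trial tables and all reports.

## Worked example

```r
library(combopredict)

# a 20-compound x 200-gene library with a planted reversing pair
lib <- generate_library(m = 20, n = 200, seed = 7)
planted <- plant_reversal(lib, c("cmpd003", "cmpd011"),
                          n_up = 20, n_down = 20, sigma = 0.1, seed = 8)
head(cgem_rank_pairs(planted$library, planted$disease, top_k = 3,
                     quiet = TRUE))
#>   rank compound_a compound_b reversal_score
#> 1    1    cmpd003    cmpd011           0.87
#> 2    2    cmpd011    cmpd016           0.54
#> 3    3    cmpd003    cmpd015           0.52
```

The planted pair tops the 190-pair ranking with reversal 0.87: its
combined signature drives the 20 disease up-genes to the bottom and the
20 down-genes to the top of the list, and 0.1-SD measurement noise
barely dents the margin over the best decoy pair (0.54).

```r
gen <- generate_target_catalog(n_drugs = 12, n_disease_targets = 6,
                               n_decoy_targets = 8, seed = 3)
head(targopt_rank_pairs(gen$catalog), 3)
#>   rank  drug_a  drug_b on_count off_count score pareto
#> 1    1 drug001 drug002        6         0   6.0   TRUE
#> 2    2 drug001 drug005        6         1   5.5  FALSE
#> 3    3 drug001 drug010        5         2   4.0  FALSE
```

The planted pair covers all 6 disease targets in the desired direction
with zero off-targets (score 6.0) and is the only Pareto-optimal pair;
the runner-up matches its coverage but pays for one liability.

```r
trials <- generate_behaviour_cohort(default_cohort_spec(10), seed = 11)
summarize_groups(behaviour_endpoints(trials))
#>     group_id         assay n_included n_excluded        mean        sd   sem
#> 1 WT_vehicle           NOR         10          0  0.57       0.107     0.034
#> 2 KO_vehicle           NOR         10          0 -0.011      0.131     0.041
#> 3 KO_treated           NOR         10          0  0.43       0.124     0.039
#> 4 WT_vehicle hyponeophagia         10          0 55.7        6.34      2.01
#> 5 KO_vehicle hyponeophagia         10          0 260.1      23.3       7.37
#> 6 KO_treated hyponeophagia         10          0 74.5       22.1       6.98
```

The untreated disease-model group shows no object discrimination (D2
near 0) and a long, near-ceiling latency to eat novel food; the treated
group is restored toward control on both endpoints. These tables feed
`aov()`, `kruskal.test()` or any external statistics package directly.

## Command line

A thin Rscript wrapper over the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/combopredict.R", package="combopredict"))')" \
  simulate --mode cgem --seed 7 --out-dir sim/
# then: cgem, targopt, rank, behaviour subcommands
```

All outputs are byte-deterministic for a given seed.

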