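---
title: "Predicting drug combinations by signature reversal and target optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug combinations by signature reversal and target optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combopredict)
```

## The problem

For a disease with a broad and heterogeneous symptom spectrum — fragile X
syndrome is the motivating case — no single drug is likely to address every
phenotype, and a rational two-drug combination is an attractive repurposing
strategy. The obstacle is combinatorial: pairing up the roughly 4000
approved drugs yields

```{r}
pair_count(4000)
```

unordered pairs, on the order of 8 million candidate experiments — far
beyond any laboratory screen. `combopredict` implements an in silico
triage of that space with two complementary engines, a merge step, and the
behavioural endpoint arithmetic used to validate nominated combinations in
a mouse model.

## CGEM: Combination Gene Expression Matching

CGEM ranks pairs by how strongly their *combined* transcriptional
signature reverses a disease expression signature.

**Inputs.** A compound library: a gene-by-compound matrix of perturbation
z-scores (read from GCT 1.2 or headered TSV with `read_gct()`; public
perturbation resources such as the LINCS compendium distribute data of
this shape). A disease signature: named sets of up- and down-regulated
genes (read from GMT with `read_gmt()`, e.g. derived upstream from a
disease-versus-control differential expression study). Genes are opaque
strings; disease genes absent from the compound universe are dropped with
a logged count, the standard harmonization in connectivity mapping.

**Enrichment score.** For a gene set occupying sorted positions
$p_1 < \dots < p_t$ of a ranking of $n$ genes, the classic unweighted
Kolmogorov–Smirnov running-sum statistic is

$$a = \max_j\left(\frac{j}{t} - \frac{p_j}{n}\right),\qquad
  b = \max_j\left(\frac{p_j}{n} - \frac{j-1}{t}\right),\qquad
  ES = \begin{cases} a & a > b\\ -b & \text{otherwise,}\end{cases}$$

positive when the set crowds the top (up-regulated end) of the list.
`ks_enrichment()` implements exactly this form; the test suite checks it
against a brute-force position-scan oracle over every instance with
$n \le 8$ and $|set| \le 3$.

**Connectivity and reversal.** With $ES_{up}$ and $ES_{down}$ the scores
of the disease up- and down-sets, the two-set, sign-gated combination is

$$\mathrm{connectivity} = \begin{cases}
  (ES_{up} - ES_{down})/2 & \operatorname{sign}(ES_{up}) \ne \operatorname{sign}(ES_{down})\\
  0 & \text{otherwise,}\end{cases}$$

and the reversal score is its negation: positive when the perturbation
pushes disease up-genes down and down-genes up. The source literature for
this scoring system names the method but prints no formula; the
unweighted KS form and the sign-gated combination are the canonical
published choices and are isolated behind `connectivity_score()` so a
weighted or null-normalized variant could be swapped in. When the two
enrichment scores fall on the same side the score is gated to zero rather
than averaged — a perturbation that drags both sets the same way carries
no reversal information.

**Combination model.** The main open design point: nothing in the method's
public description states how a two-drug transcriptional effect is
modelled. `combine_signatures()` uses elementwise *additivity of
z-scores followed by re-ranking* — the minimal published assumption for
combination effects, analogous to dose additivity. It deliberately ignores
pharmacological interaction (synergy, antagonism, saturation); the
function is the single place to substitute a different merge rule.

**Ranking.** `cgem_rank_pairs()` enumerates all pairs exhaustively (no
heuristic pruning), streams over them with bounded memory, and breaks
score ties by lexicographic pair id. Rank ties by gene identifier are
likewise lexicographic throughout (`rank_transform()`), so every ranking
is deterministic across platforms.

## TargOpt: target optimisation

TargOpt ranks pairs on curated drug–target knowledge instead of
expression. Each drug engages a set of targets with a direction
($+1$ activation, $-1$ inhibition); the disease contributes a wish list of
targets with desired directions. For a pair:

* `on_count` — disease targets engaged in the desired direction by at
  least one drug of the pair (counted once);
* `off_count` — distinct targets with a liability engagement: any target
  outside the disease set, or a disease target pushed in the wrong
  direction. Counting a wrongly-pushed disease target as a liability
  (not merely a miss) is a deliberate choice: a drug driving a disease
  target the wrong way is actively harmful, not neutral.

The scalarized score is $\alpha \cdot on - \beta \cdot off$ with defaults
$\alpha = 1$, $\beta = 0.5$: covering one additional disease target
outweighs one additional liability, but two liabilities cancel a gain.
Because any fixed $(\alpha, \beta)$ is one reading of "maximize on-target
effects while minimizing off-target effects", `targopt_rank_pairs()` also
marks the $(on, off)$ Pareto front, so the bi-objective view is available
in the same report. Engagement is binary — no affinity or potency tiers —
because the data model this operates on carries none.

## Prioritization and annotation

`aggregate_ranks()` merges the two engines by mean rank. A pair surfaced
by only one engine receives a worst-rank-plus-one stand-in for the other
(one past the end of that list) and a `single_method_only` flag:
convergent predictions float to the top without single-method candidates
being discarded. `annotate()` then adds `ddi_alert` (known adverse
drug–drug interaction) and `same_mechanism` (both drugs in one mechanism
class, hence limited complementarity) flags. Flags never filter or
reorder — the workflow this mirrors ends with a human expert choosing
what to take into the animal model, and annotations inform that choice
rather than pre-empting it.

## Behavioural endpoints

Validation of a nominated combination happens in preclinical behavioural
assays; the package implements their endpoint arithmetic so trial tables
can be reduced to tidy per-group summaries:

* **Discrimination index** `d2_score(t_novel, t_familiar)` $=
  (t_n - t_f)/(t_n + t_f) \in [-1, 1]$, used identically for novel
  object recognition (NOR), object location (OL) and social recognition
  (SR). Positive values indicate recognition memory.
* **Inclusion rule** `apply_inclusion()`: an animal must accumulate a
  minimum total exploration time (default 3 s, inclusive boundary) for
  its recognition trial to enter the analysis. The threshold is read as
  applying to the novel + familiar total; it is configurable. The rule
  also guards the D2 denominator.
* **Latency censoring** `cap_latency()`: latency-to-event endpoints
  (hyponeophagia: latency to consume novel food) are censored at the test
  duration (default 300 s); a no-event animal receives the maximal score.
  Whether a latency recorded exactly at the boundary counts as censored
  is not standardized, so it is an explicit argument
  (`censor_at_limit`, default `FALSE`: an event at 300 s counts as
  observed).
* **Summaries** `summarize_groups()`: per-group n, mean, SD (n−1
  denominator) and SEM $= SD/\sqrt{n}$, matching the conventions of the
  usual graphing software. Inferential statistics (ANOVA variants, post
  hoc comparisons) are deliberately *not* reimplemented: those are
  off-the-shelf procedures, and the endpoint tables emitted here feed
  `aov()`, `kruskal.test()` or any external package directly.

## Synthetic data with planted ground truth

Every pipeline stage is testable offline through seeded generators whose
defaults are the package's fixed study conditions:

* `generate_library(m, n, seed)` — i.i.d. standard-normal z-scores. The
  tested configuration uses 50 compounds over 978 genes, mirroring the
  landmark-gene scale of public perturbation resources while keeping an
  exhaustive 1225-pair scan fast on one CPU. Gaussian independence is a
  simplification: real moderated z-scores are gene–gene correlated and
  batch-structured, so recovery results here bound what the method does
  on clean input, not on a real compendium.
* `plant_reversal()` — reverse-engineers the disease signature from a
  chosen pair: the 50 most-negative and 50 most-positive genes of the
  pair's combined profile become the disease up- and down-sets, making
  that pair the extremal reverser *by construction* (provable recovery at
  `sigma = 0`, rather than merely probable). Additive N(0, σ) measurement
  noise is then applied to the whole library with the sets held fixed, so
  σ sweeps recovery from guaranteed (σ = 0) through near-certain
  (σ = 0.1, small against the unit z-score scale) to chance
  (σ ≫ 1).
* `generate_target_catalog()` — the planted pair jointly covers all
  disease targets in the desired directions with zero off-targets (score
  $\alpha \cdot n_{targets}$); every decoy drug covers at most half the
  disease targets and carries at least one off-target, so for any
  $\beta > 0$ the planted pair strictly dominates.
* `generate_behaviour_cohort()` — per-group normal draws clamped at zero
  (times cannot be negative; with the default means, zero-clamping is a
  negligible-mass correction). The default specification emulates a
  10-animals-per-group design with an impaired untreated group and a
  treated group restored toward control.

## Numerical and degenerate-input conventions

* Rank ties (including all-zero signatures) break by ascending gene id in
  the C locale; pair-score ties break by lexicographic pair id.
* All file output is byte-deterministic: fixed `%.6g` numeric formatting,
  LF endings. A library written and re-read round-trips its z-scores
  exactly from the second write onward.
* Empty gene sets, sets disjoint from the universe, non-finite z-scores,
  directions outside ±1, single-compound libraries and zero-exploration
  trials are all rejected with named errors rather than propagated.
* KS discretization: reversing a ranked list shifts the enrichment
  magnitude by at most $1/n$ and flips its sign class exactly when the
  top and bottom deviations are separated by more than $2/n$; inside that
  tie band the sign is settled by the $a > b$ rule.

## Worked example

```{r}
lib <- generate_library(m = 20, n = 200, seed = 7)
planted <- plant_reversal(lib, c("cmpd003", "cmpd011"),
                          n_up = 20, n_down = 20, sigma = 0.1, seed = 8)
head(cgem_rank_pairs(planted$library, planted$disease, top_k = 3,
                     quiet = TRUE))

gen <- generate_target_catalog(n_drugs = 12, n_disease_targets = 6,
                               n_decoy_targets = 8, seed = 3)
head(targopt_rank_pairs(gen$catalog), 3)
```

## Scope and limitations

* Two-drug combinations only; no dose modelling (a pair is one combined
  profile at one implicit dose), no three-way combinations.
* Additive signature combination and binary target engagement are stated
  modelling floors, not claims about pharmacology.
* No permutation-null normalization of enrichment scores; scores are
  comparable within one library/disease analysis, not across analyses.
* Passing planted-truth recovery demonstrates correctness of the ranking
  machinery, not predictive validity on real perturbation data.
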