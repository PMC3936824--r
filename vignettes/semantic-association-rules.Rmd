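---
title: "Semantic association rules for phenotype-based diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic association rules for phenotype-based diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorules)
library(dplyr)
```

## The problem

Rare-disorder diagnosis from clinical findings can be framed as class
association rule mining over annotated patient cases: each case is a
transaction whose items are phenotype concepts from a deep ontology
(HPO-style) plus a single disorder concept from a shallow, group-structured
disease ontology. Rules take the form {phenotype set} → {disorder}, and a
voting classifier turns a scored rule set into a ranked differential
diagnosis.

Classical interestingness measures — support, confidence, lift, conviction,
leverage, jaccard, cosine, correlation — rely on exact concept matching. Two
clinically adjacent findings such as *Neonatal short-limb short stature* and
*Rhizomelic short stature* (siblings under *Disproportionate short-limb short
stature*) are treated as unrelated symbols, so co-occurrence structure that
is obvious to a clinician is invisible to the miner. `phenorules`
replaces the exact-match support underlying all of these measures with a
*semantic support* computed from ontology structure, leaving every measure
formula unchanged.

## The model

### Semantic support

For a transaction database $T = \{t_1,\dots,t_n\}$ and an itemset
$\{i_1,\dots,i_p\}$,

$$\mathrm{SemSupport}(i_1,\dots,i_p)
  = \frac{1}{n}\sum_{q=1}^{n}\ \prod_{j=1}^{p}\
    \max_{v \in t_q}\ \big\| \mathrm{SemSim}(i_j, i_v) \big\|$$

where $\|\cdot\|$ clamps similarities into $[0,1]$ and the maximum over an
empty transaction is 0. Each itemset item is credited with its *best* match
in the transaction; with the exact-match indicator similarity the product
collapses to set containment and semantic support equals traditional
support exactly — this reduction is tested to $10^{-12}$. Because every
best-match factor dominates the exact-match indicator, semantic support
always dominates traditional support.

Every interestingness measure is computed from three support evaluations
(antecedent, consequent, union) through a pluggable support function, so
each measure has a traditional and a semantic variant by substitution.
The union support is evaluated on the union itemset in one pass, not
factored into parts, which is the literal reading of the semantic
confidence numerator. Conviction at confidence 1 returns a `+Inf` sentinel
that outranks every finite score; a correlation with a vanishing variance
factor is defined as 0.

### Similarity metrics

The package ships six metrics behind one registry
(`similarity_metrics()`):

* **custom** — the exponential path metric. For concepts $c_1 \ne c_2$ with
  lowest common ancestor $a$,
  $\mathrm{SemSim} = \frac{d(a)}{\mathrm{Dist}(c_1,c_2) + d(a)}$, where
  $d(a)$ is the plain edge-count depth of $a$ and the concept-to-concept
  distance is exponential in the taxonomy path length $l$: $2^{l}$ on the
  phenotype graph and $10^{\,l-2}$ on the disease graph. Identical non-root
  concepts score 1; the root against itself scores 0 (avoiding 0/0). The
  numerator deliberately uses the plain depth while only the denominator's
  distance is exponentiated: deeper (more specific) ancestors reward the
  pair, and similarity decays faster than distance. The base-10 disease
  transform reflects the disease ontology's fixed maximum depth of 2 —
  intra-group disorders (distance 2 through their group) score 0.5, the
  highest value short of an exact match, and anything further scores near 0.
* **resnik**, **lin**, **jiang_conrath** — information-content metrics with
  $IC(c) = -\ln(\mathrm{freq}(c)/N)$ over *non-propagated* per-case
  frequencies (a case counts once per directly annotated concept; ancestors
  are never credited). Non-propagation is a deliberate modelling choice: it
  reproduces the documented failure mode in which the most informative
  common ancestor of two concrete clinical findings never occurs in the
  corpus, making the pair completely dissimilar (similarity 0), and the
  converse anomaly in which a rare ancestor makes Lin exceed 1 for distinct
  concepts (e.g. 2.19 for the pair with frequencies 41 and 70 under an
  ancestor of frequency 5 in 394 cases). Lin values pass through the clamp
  before entering semantic support. The printed Jiang–Conrath formula in the
  source literature is ambiguous; we use the bounded inverse
  $1/(1+\max(0, d_{JC}))$ of the standard Jiang–Conrath distance, which is
  1 on identity, monotone in the distance, and clamps the negative
  distances non-propagated IC can produce.
* **wu_palmer** — $2N_3/(N_1+N_2+2N_3)$ from the LCA depth and the edge
  counts down to it.
* **exact** — the indicator, which recovers every traditional measure.

An identical pair with corpus frequency $>0$ is treated as an exact match
(its own MICA) before the ancestor scan; otherwise, under non-propagated
frequencies, a rarer ancestor could outrank the concept itself and Lin or
Jiang–Conrath would not equal 1 on identity. Cross-ontology pairs
(phenotype vs disorder) score 0 under every metric. LCA ties on multiple
inheritance break by maximal depth then lexicographic identifier; MICA ties
by maximal IC, then depth, then identifier — determinism everywhere.

### Graph conventions

Path length counts edges, `depth(root) = 0`, and paths between distinct
concepts must ascend from each concept to a common ancestor — no
up-down-up walks. These conventions make the worked macrocephaly distances
come out exactly (1 between *Progressive macrocephaly* and *Macrocephaly*,
2 between the sibling subtypes). On trees this distance is a metric and
equals $\mathrm{depth}(c_1)+\mathrm{depth}(c_2)-2\,\mathrm{depth}(LCA)$;
on multi-parent DAGs neither the triangle inequality nor that identity is
guaranteed (minimum-depth ascents can bypass the LCA), so the test suite
asserts the tree identities on trees and only the through-LCA bound on
DAGs.

## Mining and classification

`mine_itemsets()` is a level-wise Apriori with two domain constraints:
candidate and frequent itemsets carry at most one disorder item, and
itemsets are capped at `max_size` (default 10). The minimum support is an
absolute case count (default 5) divided by the cohort size at run time —
the 5/N convention — chosen low to keep occasional associations.
Frequency counting always uses traditional support; semantic measures are
attached after discovery by `score_rules()`, and no interestingness
threshold prunes rules (every rule may vote, since any cut-off would bias
the voting). Output ordering is deterministic (size, then lexicographic),
and `brute_force_itemsets()` provides an exhaustive oracle against which
the miner is equivalence-tested on hundreds of random databases.

Each frequent itemset with exactly one disorder and at least one phenotype
is partitioned into a rule; disorder-only itemsets yield none.

`rank_diagnoses()` implements voting: fired rules are grouped by
antecedent; each group votes for its best rule's consequent, contributing 1
(simple) or its best measure value (weighted), scaled by the group's match
score in semantic mode. Rule firing generalises subset matching: the match
score is the product over antecedent items of the best similarity to any
case phenotype, with a configurable threshold (default 0, strict
exceedance). Exact similarity recovers classical subset firing; semantic
firing is what lets a rule mentioning a sibling of an observed finding
still contribute — prediction-time flexibility that pure exact matching
cannot offer and that motivates the whole construction.

`cross_validate()` runs stratified-by-diagnosis k-fold cross-validation
(default 5 folds, the 80–20 split) and reports top-K accuracy — the
percentage of held-out cases whose true disorder (the exact concept, not a
sub- or superclass) appears in the first K ranking entries. Stratification
is not optional decoration: with 15 classes, unstratified folds can lose
entire disorders from a training split. `compare_classifiers()` shares the
fold assignment and the mined rule sets between the traditional and
semantic arms (mining is mode-independent), cross-tabulates per-case
held-out correctness into a 2×2 discordance table, and applies McNemar's
test with continuity correction,
$\chi^2 = (\max(0, |b-c|-1))^2/(b+c)$ on one degree of freedom, with the
correction clamped so perfect agreement never yields a positive statistic.
Note the IC-based similarity functions are built by the caller, typically
from the full cohort's statistics; rebuilding them per training fold is
possible but not automatic, a known limitation that does not affect the
structure-only metrics (custom, wu_palmer, exact) used throughout the
benchmarks.

## The synthetic cohort generator

No public cohort of ontology-annotated rare-disorder cases exists at the
scale needed for testing, so `generate_cohort()` simulates one. Defaults
were fixed once to emulate a published referral cohort's shape: 15
disorders × 26 cases (390 cases), a depth-4 branching-5 phenotype tree
(781 concepts, 625 leaves), disorder profiles of 25 leaf phenotypes biased
toward distinct depth-1 subtrees, and a truncated-Poisson (minimum 1)
number of phenotypes per case with mean 4.49. Under these defaults the
cohort carries roughly 450–520 distinct phenotypes, matching the
several-hundred regime of real annotation datasets, and the per-case mean
is verified within ±0.5 across seeds. The disease ontology is depth-2:
root → groups → disorders, distributed round-robin.

The noise model is *sibling substitution*: with probability `eps`, a
sampled profile phenotype is replaced by a random same-parent sibling
outside the profile. This is exactly the situation the motivating clinical
examples describe — adjacent findings one edge apart in the hierarchy —
and it creates a measurable gap between the semantic and traditional
measures: the substituted finding contributes similarity
$d(a)/(4 + d(a))$ to semantic support but nothing to exact-match support.
At `eps = 0` every case phenotype lies in its disorder's profile
(parameter-recovery tests exploit this); at `eps = 1` traditional supports
collapse while semantic supports survive.

What the generator does *not* emulate: inter-disorder phenotype sharing
(real disorders overlap heavily; profiles here are near-disjoint by
construction), annotation noise other than sibling substitution (real text
annotation produces wrong-branch and coarser-than-truth concepts),
non-uniform class sizes, and the true-path expansion of annotations. A
passing benchmark therefore shows that the machinery exploits one-edge
semantic structure when it is present; it does not certify accuracy levels
on real cohorts.

Every generator output is a pure function of (configuration, seed).

## Numerical and design choices

* The "arg max" in the semantic-support definition is read as the maximum
  similarity *value*; the clamp makes the product well-typed in $[0,1]$.
* Undefined IC (frequency 0) is an `NA` marker, mapped to similarity 0
  ("completely dissimilar") in the metrics, never an error.
* Cosine and correlation take square roots in their denominators, matching
  the standard definitions and their documented ranges.
* Degenerate inputs: empty databases error; empty itemsets have support 1
  (vacuous containment); cases with zero phenotypes are retained with a
  warning and can fire no rule; b + c = 0 makes McNemar's test undefined
  (an error, reported as "no discordance" by the comparison command).
* All tie-breaks (LCA, MICA, vote ranking, group representative) are
  lexicographic after their primary keys, so every pipeline stage is
  byte-reproducible from (configuration, seed).

## Problem sizes in the test suite

The unit suite exercises random ontologies up to 30 concepts and random
databases up to 12 transactions (where brute-force oracles are exhaustive),
and the benchmark runs the full default cohort (390 cases) across 5 seeds
with `eps = 0.4` — sizes chosen so the whole suite completes in a couple of
minutes while every claim is still tested at the scale it is made.

## Worked example

```{r example}
fx <- example_fixture()
fx$db

itemset_support(c(fx$cf[["cf1"]], fx$cf[["cf3"]], fx$bd1), fx$db)

sf <- similarity_function("custom", fx$phenotype, fx$disease)
semantic_support(c(fx$cf[["cf1"]], fx$cf[["cf3"]], fx$bd1), fx$db, sf)

rules <- mine_itemsets(fx$db, min_count = 1, max_size = 3) |>
  itemsets_to_rules() |>
  score_rules(fx$db, c("confidence", "lift"),
              support_function("semantic", sf))
rules |> mutate(antecedent = sapply(antecedent, paste, collapse = ";"))

mcnemar_test(fx$discordance)
```

## Limitations

* Semantic scoring of a large rule set costs one best-match matrix per
  (database, similarity) pair; memory is O(items × transactions).
* The IC metrics depend on annotation frequencies and inherit all the
  pathologies of non-propagated counts; they are provided as baselines,
  not recommendations.
* Multi-label consequents, rule pruning (CBA-style), probability
  calibration and ontology editing are out of scope.
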