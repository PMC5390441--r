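---
title: "Allocating source variables to harmonized targets with logic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allocating source variables to harmonized targets with logic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the model

Retrospective harmonization of cohort datasets for an IPD meta-analysis
requires, for every predefined target variable of the pooled analysis
dataset, finding the one column of each incoming dataset that measures it.
`harmonizr` treats this as a per-target binary classification over
(dataset, column) pairs. The classifier is a *logic tree*: a Boolean
combination, with AND/OR internal nodes and optionally negated leaves, of
simple binary rules evaluated on a column's metadata profile.

The metadata profile deliberately uses only features that are computable
from any tabular export: the column name and optional label, the storage
type (number, date, string), the scale level (ratio, ordinal, nominal,
dichotomous), the number of distinct values and the proportion of the most
frequent value, and for numeric columns the median and interquartile
range. Content-free features make the approach portable across statistical
packages and languages of origin; they also bound what it can ever see —
two columns with identical names and similar distributions are
indistinguishable by construction.

### Rules

Five rule kinds are supported: substring containment on the name or label
(case- and accent-insensitive after Unicode transliteration), equality on
type or scale, and strict threshold comparisons on a numeric feature. Rule
evaluation is *total*: a threshold on a median that does not exist (string
column), or a label rule on an unlabelled column, evaluates to false, never
to missing — logic trees need complete binary inputs. Threshold cutoffs can
be calibrated on labeled data by ROC analysis, maximizing sensitivity +
specificity; candidate cutoffs are the midpoints between consecutive sorted
distinct feature values plus infinite sentinels, with ties broken toward
the smallest cutoff. Midpoints (rather than observed values) make the
chosen cutoff unambiguous under strict comparison, and the exhaustive scan
is exact rather than approximate.

### Scoring

Fitting minimizes the weighted least-squares score
$S = \sum_i w_i (y_i - \hat y_i)^2$, which for 0/1 predictions is a
weighted misclassification count. The class weights are the central tuning
lever: with $w_{pos} = 0.9995$ and $w_{neg} = 0.0005$ a false negative
costs exactly $1999\times$ a false positive. This is deliberate. A data
manager reviewing a candidate list can discard false alarms cheaply, but a
missed true variable defeats the purpose of the screen, and with at most
one match per target per dataset the negatives outnumber the positives by
two to three orders of magnitude. An alternative scoring method fits a
one-covariate weighted logistic regression of the labels on the tree
output and scores by weighted deviance; for a binary covariate the
weighted MLE reduces to group-wise weighted outcome means, and fitted
linear predictors are capped at ±30 so that perfect separation yields a
near-zero deviance instead of a numerical failure. A constant tree output
falls back to the intercept-only deviance.

### Simulated annealing

The tree space is searched by simulated annealing over six elementary
moves: alternate a leaf (change its rule or complement), alternate an
operator, grow a branch, prune a branch, split a leaf, delete a leaf. The
applicable subset is drawn uniformly (a single-leaf tree cannot be pruned);
growing and splitting are both leaf expansions, distinguished by whether
the original leaf stays the left or the right child of the new node.

Score-improving or score-preserving proposals are always accepted.
Worsening proposals are accepted with a *transition probability* that
decays geometrically from 0.1 at the first iteration to 0.0001 at the
last; only the endpoints of this schedule are prescribed, and the
geometric (log-linear) shape is this package's choice, as is the default
budget of 50,000 iterations. Two hard constraints filter proposals: a
maximum leaf count (`treesize`) and a minimum number of training instances
on which the candidate tree must evaluate true (`minmass`), enforced by
rejection rather than penalty. The best constraint-satisfying tree seen
anywhere in the run is returned, ties resolved toward the first
encountered; the run stops early once a zero-score tree is found, since
the score cannot improve further. The initial state is a uniformly random
single positive leaf. All randomness flows through one seeded generator,
so fits are bit-reproducible; note that runs with different iteration
budgets follow different acceptance schedules, so the returned best score
is non-increasing in the budget only in expectation, not pointwise — the
regression tests pin this property at fixed seeds.

### Tuning, cross-validation, selection

The tuning study is a full factorial over scoring method
(classification, logistic), negative-class weight
($5\cdot10^{-4}$ to $5\cdot10^{-1}$ in decades), tree size (5, 10) and
minmass (4, 8): 32 runs. Each design point is assessed by grouped k-fold
cross-validation: folds are formed over *datasets*, never over individual
variables, because variables of one dataset share naming conventions that
would otherwise leak from training into test folds (an ungrouped mode
exists behind a flag). Per-point sensitivity and specificity are pooled
over held-out predictions (micro-averaged) rather than averaged per fold:
with only a handful of positives per fold, per-fold averages would be
dominated by small-denominator noise. A fold whose test half has no
positives reports missing sensitivity; a fold whose training half has no
positives predicts all-negative with a warning.

The operating configuration is then chosen by constrained maximization:
among points with sensitivity ≥ 0.99 and specificity ≥ 0.75, the most
sensitive wins (ties: specificity, then lexicographic factor order). If no
point qualifies, the sensitivity floor is dropped first, then both floors,
and the applied relaxation is reported rather than silent.

### Allocation and reporting

A fitted tree classifies each column of a new dataset; predicted matches
are returned together with the next best-ranked negatives up to a minimum
list length, so the user always sees an escape list even when the tree
fires on nothing. Ranking is by the fraction of tree leaves a column
satisfies — an extension beyond the binary tree output (which cannot rank),
flagged as such and switchable off. Performance is reported per target as
sensitivity, specificity, PPV and NPV with missing values exactly when a
denominator is zero, plus an unweighted Average row over targets and the
share of targets with PPV ≤ 0.5. The packaged reference performance table
and 34-dataset manifest ship as fixtures for these aggregation paths; the
underlying cohort data are not distributable, so those numbers are fixture
content, not recomputed results.

## The synthetic-cohort generator

Because no cohort data can ship with the package, a generator produces
datasets whose ground truth is known by construction. Each planted target
column draws from a per-target distribution template authored from the
target's unit and typical clinical ranges (systolic blood pressure
~ Normal(130, 17) mmHg, total cholesterol ~ Normal(210, 40) mg/dl vs
Normal(5.4, 1.0) mmol/l for the SI variant, sex as a Bernoulli(0.5) flag,
and so on); names follow a dialect (verbose, abbreviated with mechanical
perturbations, or opaque codes), labels come from a sidecar with
configurable coverage, and missingness is uniform at a configurable rate.
Noise columns come from a benign pool (lexically and numerically far from
every target) or an adversarial one that adds near-miss names and one
distribution-identical "repeat measurement" shadow per planted target.

Two presets bracket the difficulty range. The *easy* preset (verbose
names, full labels, benign noise, no missingness) is constructed to be
perfectly separable — every target admits a zero-score tree that
generalizes across datasets — and serves as the end-to-end correctness
gate: the pipeline must reach pooled sensitivity 1.0 and near-perfect
specificity on held-out datasets, or something is wrong with the code, not
the data. The *hard* preset (mixed abbreviated/coded names, half-covered
labels, shadow columns, 5% missingness) is constructed so that no
metadata-based rule can separate a target from its shadow; with the
sensitivity-heavy weights the fitted trees keep sensitivity and NPV high
while PPV collapses, reproducing qualitatively the operating regime that
motivates ranked candidate lists. The generator does *not* model
between-column correlation, informative missingness, longitudinal
structure, or unit mislabeling; passing tests therefore demonstrate
correctness of the machinery and the qualitative precision/recall
trade-off, not expected performance on any real cohort.

## Numerical and design choices

- Quantiles use linear interpolation between order statistics (type 7), so
  medians and IQRs agree with mainstream numeric stacks and with the
  independent oracles in the test suite.
- Missing-value markers default to `""`, `NA`, `NaN`, `.`, `NULL`;
  missing cells are excluded from all statistics. A column is numeric
  (resp. date) when ≥ 95% of non-missing cells parse; number takes
  precedence over date, and a numeric column is never reclassified as a
  date. Numeric columns with 3–10 distinct values are treated as ordinal
  (`K_scale = 10`); these thresholds are configuration, not constants,
  since source formats carry no scale metadata.
- For numeric columns, value statistics are computed over the cells that
  parse as numerals, and `n_nonmissing` counts exactly those cells, so
  `prop_most_frequent * n_nonmissing` is always an integer count.
- Registry files are YAML (JSON accepted) with a schema version; the
  packaged 41-target registry is an authored reconstruction — name-synonym,
  label, type, scale and median-band rules per target — and makes no claim
  of fidelity to any particular production rule set.
- Target names are unique in a registry; the two conventional/SI variants
  of LDL cholesterol are therefore distinguished with an "SI" suffix, as
  the other unit pairs are.
- Desk-scale benchmark defaults: 10 representative targets, 8 datasets of
  ~300 participants and ~40 noise columns, 2,500 annealing iterations and
  `minmass` 2 (one positive per construction dataset, 4 construction
  datasets). These sizes keep the full pipeline comfortably interactive
  while leaving every constraint active; production fits on real
  registries should use the 50,000-iteration default and the tuning grid.

## Known limitations

Identification only: the package maps source columns to targets but does
not recode values or convert units. Rules are exact substring/type/
threshold predicates — no fuzzy matching, embeddings or dictionaries — so
performance is bounded by how much signal the metadata carries. Logic
trees are single-tree models fitted by annealing; multi-tree models and
MCMC model selection are out of scope. The fitted trees for the same data
can differ between seeds even when their measured operating
characteristics agree; only the latter are stable quantities.
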