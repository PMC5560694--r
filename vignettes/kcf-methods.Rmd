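---
title: "k-dependence causal forests: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{k-dependence causal forests: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcforest)
```

## The model family

All classifiers in this package are restricted Bayesian networks over a
categorical class $C$ with $t$ labels and attributes
$\mathbf{X} = (X_1, \dots, X_n)$ with finite domains. Every attribute has
the class as a parent; the families differ only in the attribute-to-
attribute arcs:

* **NB** — no attribute arcs; posterior
  $P(c \mid \mathbf{x}) \propto P(c)\prod_j P(x_j \mid c)$.
* **TAN** — the Chow–Liu construction: edge weights
  $I(X_i; X_j \mid C)$, maximum spanning tree, one attribute parent per
  non-root node.
* **KDB** — attributes ordered by $I(X_i; C)$ descending; the attribute at
  position $j$ adopts the $\min(j-1, k)$ highest-CMI attributes among its
  predecessors.
* **KCF** — the ensemble this package exists for. One shared CMI maximum
  spanning tree is rooted at each attribute in turn. In the rooting with
  root $r$, a node $X_j$ with $d$ ancestors on its root path keeps its
  tree parent and adds the $m - 1$ remaining root-path ancestors with the
  highest $I(X_P; X_j \mid C)$, where $m = \min(d, k)$. Prediction
  averages the $n$ normalized submodel posteriors with equal weight $1/n$
  (averaging normalized distributions preserves normalization, so no
  re-scaling is needed).
* **AODE** — one superparent model per attribute (that attribute parents
  all others), posteriors averaged; the one-dependence counterpart of the
  forest's bagging idea.

Two reduction identities pin the constructions together and are tested
structurally and predictively: the KCF submodel with $k = 1$ rooted at
TAN's root *is* TAN, and KDB with $k = 0$ *is* NB.

A deliberate reading of the ancestor-extension rule: $d$ counts the
ancestors of $X_j$ *excluding* $X_j$ itself, and the tree parent always
counts toward $m$, so exactly $m - 1$ extra arcs come from the remaining
ancestors. Under the alternative reading (counting $X_j$ itself), a direct
child of the root would owe an arc to a second ancestor that does not
exist. The implemented rule gives every node exactly $\min(d, k)$
attribute parents, which the test suite asserts for all $n$ rootings.

## Information estimators

Mutual information and conditional mutual information are empirical
plug-in estimates in **bits** (base-2 logs) with the $0 \log 0 = 0$
convention, computed from unsmoothed count tables. Base 2 is a fixed
convention here; reported dependency masses scale by $\ln 2$ if natural
logs are preferred. No bias-corrected estimators (Miller–Madow,
shrinkage) are offered: structure decisions only compare estimates against
each other on the same sample, where the plug-in bias largely cancels.
Pairwise (value, value, class) count tables are materialized lazily and
cached; the cached path is value-identical to a full precomputation.

## Structure determinism

Every tie in structure learning is broken deterministically so identical
inputs give bit-identical models:

* MST: Prim's algorithm started from the first attribute; among
  equal-weight crossing edges, the lexicographically smallest
  (min index, max index) pair wins.
* Ancestor extension: equal-CMI candidates are ordered by proximity to the
  child on the root path, then by smaller index.
* KDB parent choice: equal-CMI candidates are ordered by earlier position
  in the MI order, then by smaller index.
* Posterior argmax: smallest class index.

## Probability estimation and inference

CPTs use Laplace smoothing with pseudo-count $\alpha$ (default 1):
$P(x_j \mid c, \mathrm{pa}) = (n(x_j, c, \mathrm{pa}) + \alpha) /
(n(c, \mathrm{pa}) + \alpha \lvert \mathrm{dom}(X_j)\rvert)$. With
$\alpha = 0$ the tables are raw maximum-likelihood ratios and an
unobserved parent configuration falls back to a uniform conditional so
every stored distribution stays proper. Inference runs in log space with
max-shift normalization. A factor whose child or parent value is missing
or was never seen during fitting is **skipped** as uninformative — the
alternative (treating unseen values as zero-probability evidence) zeroes
the posterior and is never what a screening application wants. Whether a
published experiment smoothed its CPTs, and by how much, is generally
unstated; accuracy on real datasets can move by roughly a percent across
reasonable choices of $\alpha$, which is why $\alpha$ is exposed
everywhere.

## Discretization and missing values

Numeric attributes are binned by equal-frequency discretization (default
10 bins): cut points at the $i/\text{bins}$ type-7 (inclusive linear
interpolation) quantiles, duplicates merged and boundary cuts dropped so
that every bin is occupied on the fitting data. The map is monotone, and
out-of-range values at apply time fall into the first or last bin. During
cross-validation the map — and every attribute/class domain — is refit on
each training split only, so held-out values never influence the bins.

Missing cells (`"?"` in ARFF and the screening layout) default to an
explicit extra category per attribute, which keeps all instances and keeps
every count table well-defined; a `drop-row` policy is available. A
categorical level first seen at prediction time maps to the dedicated
unseen code and its factors are skipped, never an error.

The bundled loader for the 29-attribute thyroid screening layout exposes
the raw diagnosis labels and accepts an optional user-supplied
label-to-group mapping file; no label grouping is invented, because the
canonical 20-label-to-7-group assignment is not fully specified in public
summaries of that table.

## Evaluation machinery

Cross-validation deals shuffled instances into folds whose sizes differ by
at most one (unstratified by default, matching the plain "randomly
divided" protocol; a stratified option exists). Accuracy is the complement
of zero-one loss; the reported figure is the mean of fold accuracies.

The Friedman test ranks algorithms within each dataset with *higher metric
→ higher rank* and average ranks on ties, computes
$F_r = \frac{12}{Nt(t+1)}\sum_j R_j^2 - 3N(t+1)$, and compares it to the
upper-tail $\chi^2$ quantile with $t - 1$ degrees of freedom (computed
from `qchisq`, not a lookup table; at $\alpha = 0.02$, $t = 5$ the
threshold is 11.668). On the bundled 12-dataset accuracy table this gives
$F_r = 9.45$ and average ranks {NB 1.92, TAN 3.25, KCF 3.25, KDB 2.79,
AODE 3.79}; published rank vectors for the same table differ and are not
derivable from it under any tie-handling we could construct, so the
package reports what its input table implies rather than targeting a
printed summary.

Win/draw/loss records call a dataset a draw when the two metrics are equal
after rounding to 3 decimals (the precision such tables are printed at)
and annotate the aggregate with a two-tailed binomial sign test on the
win/loss counts. The per-dataset draw rule behind published W/D/L tables
is typically unstated; an equality-after-rounding rule is the most
reproducible choice, and it can disagree with published records on
near-ties (a 0.729 vs 0.727 pair counts as a win here, not a draw).
Similarly, two of the bundled published BAC cells (NB and KDB on the Heart
data) are inconsistent with their own printed sensitivity/specificity
pairs; the package recomputes BAC from the pair and flags, rather than
reproduces, such cells.

## The synthetic-data generator

Every module is testable offline because fixtures come from a seeded
ancestral sampler over known ground-truth models. `random_kcf_model()`
draws a uniform random labeled tree (Prüfer decode), roots it at random,
adds up to $k - 1$ random extra root-path-ancestor parents per node, and
fills the prior and CPTs from a symmetric Dirichlet (concentration 1 by
default — uniform over the simplex — and configurable to sharpen or
flatten dependencies).

Two opt-in guarantees are enforced by **exact enumeration** of the model's
joint distribution (feasible for the $\le 8$-attribute models used in
testing) with rejection sampling:

* *Recoverability* (`ensure_recoverable`): the generating tree is the
  unique exact-CMI maximum spanning tree with a margin of at least
  0.02 bits over every non-tree edge, and each node's extra parents are
  the exact-CMI argmax among its root-path ancestors with the same margin.
  Structure recovery is only asserted for such models, because MST
  recovery is unidentifiable under ties. In this mode conditionals are
  sharpened with deterministic parent channels (copy weight 0.5–0.75 from
  the tree parent, 0.15 from the extra parent) over a uniform-floored
  Dirichlet draw, making well-separated weights typical so rejection
  terminates quickly.
* *Estimability* (`ensure_config_prob`): every (class, parent
  configuration) cell has probability at least 0.02 by default. The
  parameter-recovery study uses binary domains, concentration 20 and a
  floor of 0.10: a floor of $q$ gives each conditional cell roughly
  $50{,}000\,q$ effective observations, i.e. standard error
  $\le 0.5/\sqrt{50{,}000\,q} \approx 0.007$ at $q = 0.10$, so the
  maximum over the ~40 free parameters of a binary 6-attribute $k = 2$
  model stays within the 0.02 recovery band with high probability. These
  constants were fixed from this calculation at design time.

What the generator emulates: discrete screening tables with tree-like
dependence, class-conditional attribute coupling, and (in the
thyroid-shaped schema) the 29-attribute mix of 21 binary flags, 7 ten-bin
assays and one 6-level referral category with a 7-group class. What it
does **not** emulate: real empirical marginals, label noise, measurement
artefacts, systematically missing panels ("not measured" flags that gate
assay values), or attribute blocks larger than the dependence bound.
Passing recovery and accuracy tests on these fixtures therefore
demonstrates correctness of the estimators and constructions, not
clinical-grade performance on real screening data.

## Problem sizes used in testing

The shipped studies use 6-attribute models, 50,000-sample recovery runs
(50 seeded trials), 2,000-row 10-fold cross-validation comparisons, and a
1,500-row thyroid-shaped Markov-blanket summary; spanning-tree optimality
is checked against exhaustive enumeration on 4–6 nodes. These sizes give
stable statistics (binomial standard errors well inside the asserted
bands) while keeping the full suite fast on a single CPU.

## Known limitations

* Posterior averaging is the plain equal-weight mean; no weighted or
  pruned ensemble variants.
* No general DAG search — only the constructive structures above.
* Plug-in information estimates are biased upward on tiny samples; do not
  compare dependency masses across datasets of very different size.
* The Markov-blanket mass `mb_info()` follows its defining triple sum
  literally: a node occurring in more than one index set contributes once
  per occurrence, and identical-index (co-parent, child) pairs are
  skipped since self-information is not a pairwise dependence.
* `Avg_MB_Info` is defined as 0 for an empty blanket rather than left
  undefined, so attributes depending only on the class plot at zero.
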