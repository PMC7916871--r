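---
title: "Association-chain network inference: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association-chain network inference: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snha)
```

## The method

St. Nicolas House Analysis (SNHA) infers an undirected network among
variables $X_1, \dots, X_I$ from nothing more than their correlation
matrix and the sample size $n$. Its unit of structure is the
*association chain*: starting from a variable, the greedy walk moves at
each step to the unvisited variable with the largest absolute correlation
$\rho = |r|$ to the current one, and stops when the best remaining
candidate falls below an absolute-correlation floor (default 0.1) or is
not significant at level $\alpha$ (default 0.05). A walk of at least three
variables is accepted as a chain only if it is *reversible*: the same
greedy walk started from the final element must reproduce exactly the
reversed sequence. The graph is the union of consecutive pairs over all
accepted chains; variables in no chain remain isolated nodes.

The intuition is hierarchic: along a causal or serial pathway
$A \to B \to C \to D$ with decaying dependence, correlations rank
$|r_{AB}| > |r_{AC}| > |r_{AD}|$ from one end and
$|r_{DC}| > |r_{DB}| > |r_{DA}|$ from the other, so the descending-$\rho$
walk traces the same sequence from both ends. Spurious single pairs, by
contrast, rarely embed in a sequence that survives the reversal check —
which is why the method produces far fewer edges on null data than a
plain $|r|$ threshold.

### Interpretation of the walk

The growth rule takes the arg max over *not-yet-visited* variables. The
alternative reading — arg max over all variables, stopping on a revisit —
would terminate almost every walk after its second element (the strongest
neighbor of $B$ is usually the $A$ one just came from) and cannot produce
the canonical four-variable example that motivates the method; we
therefore use the unvisited-only rule, and cyclic chains cannot arise.
Arg-max ties are broken toward the variable earliest in column order.
Ties are measure-zero for continuous data, but the deterministic rule
makes outputs reproducible and permutation-equivariant up to naming.

A walk that fails the reversal check is discarded whole; we do not trim
it back to a reversible prefix, because a chain is defined by the
agreement of its *entire* ordering from both ends, and its sub-sequences
were never themselves produced by the growth rule. The minimum length of
3 means an isolated strongly correlated pair yields *no* edge: a
two-element sequence is trivially reversible and carries no ordering
information, so it is no evidence of a serial structure. This is intended
behavior, not an oversight.

### The ordering-consistency filter is off by default

One might require that when two accepted chains share three or more
members, the shared members appear in a consistent relative order (up to
orienting either chain). `find_chains(..., consistent = TRUE)` enforces
this, dropping the shorter of two conflicting chains (on equal length,
the lexicographically larger canonical form). It is **off** by default:
reversibility is the acceptance criterion, and empirically meaningful
chain sets can order shared members differently when distinct pathways
run through the same hub variables — filtering such sets would silently
delete detected structure. The filter exists for exploratory use where a
single global ordering is desired.

## The chain likelihood-ratio test

A chain $c_1 - c_2 - \dots - c_k$ asserts a *restricted* dependence: each
member is conditionally normal given its predecessor only, a first-order
Gaussian Markov chain, equivalently a decomposable graphical model whose
cliques are the adjacent pairs. The *unrestricted* model is the saturated
$k$-variate normal. Both likelihoods are maximized on the standardized
scale (means and variances cancel in the ratio), with the sample
correlation submatrix $R$ as the unrestricted MLE and the adjacent sample
correlations as the restricted one. Decomposability gives the restricted
maximized determinant in closed form,
$\det \hat\Sigma_{\text{chain}} = \prod_{\text{adjacent}} (1 - r_{ab}^2)$,
hence the deviance

$$\chi^2 \;=\; n \left( \sum_{(a,b)\ \text{adjacent}} \log(1 - r_{ab}^2)
  \;-\; \log \det R \right) .$$

The multiplier is $n$, the standard MLE deviance convention; natural
logarithms throughout. The degrees of freedom are the number of
restrictions: $\binom{k}{2}$ member pairs minus the $k-1$ adjacent pairs
the chain keeps free, i.e. $(k-1)(k-2)/2$. This count identifies the
restricted model as *first-order* (adjacent-only) conditioning:
conditioning each member on **all** predecessors would leave a saturated
model with zero restrictions and no test. The p-value is the right-tail
$\chi^2$ probability; small values mean the chain is too sparse a summary
of its members' dependencies.

Numerical choices: the deviance is clamped at 0 (it is non-negative in
exact arithmetic since the models nest; rounding can produce tiny
negatives); a singular $R$ or an adjacent $|r| = 1$ raises an error
rather than returning an infinite deviance; `n <= k` is refused. The test
is asymptotic — no small-sample (Bartlett-type) correction is applied.
Tests verify the closed form against an independent numeric optimizer of
the restricted likelihood (quasi-Newton over tanh-transformed adjacent
correlations) to 1e-4 relative, and its type-I error at nominal 0.05 on
true first-order data (Pearson correlations, $n = 200$, 2000 simulations)
falls in [0.03, 0.08]. Calibration is claimed for Pearson correlations of
Gaussian data; with Spearman input the statistic is computed the same way
but rank correlations of a Gaussian Markov chain are not exactly
Markov-consistent, so the test is mildly conservative or liberal
depending on the structure — treat Spearman-based p-values as heuristic.

## Correlations and their p-values

Default correlation is Spearman (robust to monotone transformations,
natural for performance and rating data); Pearson is selectable.
Spearman is computed as Pearson on within-column mid-ranks. Two-sided
p-values for both methods come from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom — for Spearman a
large-sample approximation, chosen over exact permutation to keep the
operation deterministic and cheap at the sample sizes this method targets
(tens to a few hundred observations). Sidedness does not matter to the
chain search, which ranks $|r|$.

## Explained variance

`model_variance()` regresses each node on its graph neighbors by OLS and
reports unadjusted $R^2$ per node and the arithmetic mean over **all**
nodes. Unadjusted, because nesting monotonicity (adding a neighbor never
lowers a node's $R^2$) is a property the tests rely on and adjusted $R^2$
would break. Isolated nodes count as 0 rather than being excluded: the
graph is being scored on how much of the *whole* variable set it
explains, and excluding isolated nodes would make sweeps across $\alpha$
incomparable. Collinear neighbor sets fall back to the pivoted
(minimum-norm) fit with a warning.

## Baselines and the null experiment

The two comparison network builders are deliberately conventional:

* `threshold_network()` — an edge wherever $|r|$ *strictly* exceeds
  `r_min`, optionally also requiring $p \le \alpha$.
* `forward_lm_network()` — per target variable, classic forward
  selection: the candidate with the largest $R^2$ increase enters if the
  increase is at least `r2_min` **and** its partial F-test has
  $p \le \alpha$ (both conditions simultaneously; the literature using
  these builders does not fix their order, and requiring both is the
  strictest reading). Selected target–predictor pairs are symmetrized
  into undirected edges.

The falseness experiment applies every builder to replicates of null data
— column-scrambled copies of a template (marginals preserved exactly) and
independent normal draws matched to the template's column means and
variances — and counts edges, which are all spurious by construction.
Builders are compared by two-sided Wilcoxon rank-sum tests with Holm
correction over all builder pairs. The default design is 20 replicates of
each null type on a 33-observation, 10-variable template, matching the
scale of the motivating decathlon data; the acceptance test reproduces
the headline result (SNHA with either correlation method yields
significantly fewer spurious edges than the $|r| > 0.1$ threshold network
and both forward-selection variants, with no Pearson-vs-Spearman
difference) at exactly that size.

## The synthetic-data generators

`planted_structure()` defines a linear-Gaussian acyclic system: roots are
standard normal, children are coefficient-weighted parent sums plus
normal noise (default SD 0.5). This emulates the serial chains, hubs and
latent-confounder patterns the method is meant to detect, with a
closed-form implied covariance
$\Sigma = (I-B)^{-1} D (I-B)^{-\top}$ for verification. The recovery
study plants a 5-node path with unit coefficients and noise SD 0.5 at
$n = 500$ — adjacent implied correlations around 0.89–0.94, a strong
monotone structure — and requires exact edge recovery in at least 90% of
100 seeded replicates. What the generators do **not** emulate: non-Gaussian
margins, nonlinear or threshold effects, heteroscedasticity, time-series
dependence, and missingness patterns of real field data. Passing the
recovery and calibration tests therefore demonstrates correctness of the
algorithmics under the model's own assumptions, not robustness on messy
real data; the Spearman default and the null experiments are the
package's concessions to the latter.

Seeding: one integer seed drives each generator call; replicate $r$ of an
experiment uses `seed + r`. Given a seed, outputs are byte-identical
across runs.

## Degenerate inputs and other edge cases

* Missing data: complete-case (`drop_rows`) by default — the LR test and
  the regressions need one consistent $n$; pairwise-complete correlations
  are deliberately not offered on the core path.
* Zero-variance columns are refused by `correlation_matrix()` with the
  column named; the reader accepts them (a constant column may still be
  wanted in a table) and the error surfaces where it matters.
* Stored correlation matrices are validated on read: symmetry to 1e-8,
  unit diagonal, entries in $[-1, 1]$, names in header and first column
  required to match exactly.
* Graph files are written with nodes and edges lexicographically sorted,
  so identical analyses produce byte-identical artifacts.

## Known limitations

* **Threshold non-monotonicity.** Raising the $|r|$ floor (or tightening
  $\alpha$) can *add* edges: truncating a walk earlier can turn a
  non-reversible sequence into a reversible shorter one. A four-variable
  correlation pattern ($r_{AB}=.9$, $r_{BC}=.8$, $r_{CD}=.7$,
  $r_{BD}=.75$, $r_{AC}=.2$, $r_{AD}=.1$) yields no chain at floor 0.1
  but the chain C–B–A at floor 0.5. Edge sets across parameter settings
  are therefore not nested, and sweeps should be read as alternative
  snapshots, not refinements.
* Edges are undirected; the method observes ordering, not causal
  direction.
* No chain-level multiplicity control or bootstrap significance is
  provided; the per-chain LR p-values are descriptive.
* The brute-force equivalence guarantee is exercised for up to 6
  variables (200 random matrices); beyond that the greedy search is
  trusted by construction.

## Problem sizes used by the test suite

Chosen to make the statistical checks informative at desk scale: 200
random matrices for the enumeration oracle, 50 chains for the numeric MLE
oracle, 100 replicates for path recovery, 20 + 20 nulls of size 33 × 10
for the falseness experiment, and 2000 simulations at $n = 200$ for size
calibration. The full suite runs in well under a minute.
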