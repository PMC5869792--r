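---
title: "Hidden Markov tree models for gene-set testing on an ontology DAG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden Markov tree models for gene-set testing on an ontology DAG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmtree)
```

## The testing problem

Every node of a Gene Ontology style DAG carries a null hypothesis: the
multivariate expression distribution of the node's gene set is identical
across treatment conditions. Edges run from general to specific terms and
imply gene-set inclusion, so the hypotheses are logically constrained — a
true null at a term forces true nulls at all its descendants, and
equivalently any defensible rejection set must be ancestor-closed.
`hmtree` treats the unknown truth values as hidden binary states on a
tree derived from the DAG, models the observed per-node p-values with
state-dependent emission densities, and returns the posterior probability
that each original DAG term is differentially expressed (its PDE), given
*all* p-values. Computing the p-values themselves is out of scope: any
multivariate gene-set test may supply them.

## From DAG to tree

Exact inference on a loopy DAG is intractable, so the graph is first
transformed into a tree:

1. Annotations are propagated upward (a gene annotated to a term belongs
   to all its ancestors) and unannotated terms are dropped.
2. The DAG is transitively reduced; a redundant shortcut edge carries no
   extra gene-set information.
3. Every multi-parent node keeps only the incoming edge from the parent
   with the largest gene set, ties broken by lexicographically smallest
   identifier. The retained-overlap rule is a deterministic choice;
   nothing downstream depends on which admissible parent is kept, only on
   the choice being reproducible.
4. Each tree node's gene set is the union of the *direct* (unpropagated)
   annotations over its tree subtree. Equivalently, severing an edge
   removes the child's genes from the abandoned parent. This definition
   makes the sets nested along tree edges and guarantees exact
   reconstruction: every gene of a DAG term is directly annotated to some
   DAG descendant, whose tree node is a subset of the term's gene set.
   An earlier draft carved sets top-down by subtracting severed
   children's gene sets from an intersection with the parent's carving;
   that rule loses genes on denser multi-parent topologies, which is why
   the subtree-union construction is used. The reconstruction identity is
   still asserted for every DAG node at build time.
5. Tree nodes whose carved set is empty are deleted (they have no
   testable hypothesis of their own) and the deletion is recorded so the
   DAG-to-tree map stays well defined.

Each DAG term $j$ is mapped to $GT_j$, the set of tree nodes whose gene
sets are subsets of $G_j$; the term's state is the maximum of its
comprising tree states, which preserves logical consistency on the DAG.

## The hidden Markov tree model

With tree nodes indexed $1..N_T$ (root 1, parent map $\rho$), hidden
states follow

$$P(S_1 = 1) = \pi, \qquad
  P(S_i = 0 \mid S_{\rho(i)} = 0) = 1, \qquad
  P(S_i = 1 \mid S_{\rho(i)} = 1) = \omega,$$

and, given the states, p-values are independent with

$$p_i \mid S_i = 0 \sim \lambda + (1-\lambda)\,\mathrm{Beta}(\alpha_0, \beta_0),
  \qquad
  p_i \mid S_i = 1 \sim \mathrm{Beta}(\alpha, \beta).$$

The null is a uniform/beta mixture — an empirical null in Efron's sense —
because overlapping gene sets make null p-values dependent and
non-uniform in practice; $\alpha_0, \beta_0 > 1$ keep it unimodal, and a
pure uniform null is the boundary case $\lambda = 1$. The alternative
density is strictly decreasing because $\alpha \le 1 < \beta$, as
expected of p-values from false nulls. Conditional independence given
the states is an approximation (gene sets share genes); the mixture null
is the model's pressure valve for it.

### Parameters at a glance

| parameter | meaning | range | typical fitted value |
|---|---|---|---|
| $\pi$ | root is DE | $(0,1)$ | near 1 when anything is DE |
| $\omega$ | DE persists along an edge | $(0,1)$ | 0.4–0.8 |
| $\alpha, \beta$ | alternative beta shapes | $(0,1]$, $(1,\infty)$ | 0.2–0.5, 5–20 |
| $\lambda$ | uniform weight of the null | $[0,1]$ | near 1 |
| $\alpha_0, \beta_0$ | null beta shapes | $(1,\infty)$ | only active when $\lambda < 1$ |

## Exact inference

The upward-downward algorithm is the tree analogue of forward-backward,
in the numerically scaled formulation: marginal priors
$P(S_i = 1) = \pi\,\omega^{\mathrm{depth}(i)}$ are computed downward,
normalized upward beliefs $\tau_i(k)$ with per-node normalizers $N_i$ are
computed leaves-first, and downward factors $\kappa_i(k)$ complete the
smoothed posteriors $P(S_i = k \mid \mathbf{p}) = \tau_i(k)\kappa_i(k)$.
The log-likelihood is $\sum_i \log N_i$, which doubles as the EM
convergence monitor. Because all recursions manipulate normalized
quantities, no intermediate value under- or overflows even on trees of
thousands of nodes and depth beyond thirty (verified at the ~8700-node
ontology scale). Two guarded divisions exist: a vanishing edge quantity
with a vanishing numerator is the impossible-state branch implied by
$P(S_i = 1 \mid S_{\rho(i)} = 0) = 0$ and evaluates to 0; a vanishing
denominator under a positive numerator is a genuine numerical fault and
raises an error naming the node.

Both passes are vectorized over depth levels, so a pass costs a handful
of vector operations per level rather than an R-level loop per node.

## Estimation

EM updates follow the score equations: $\pi^{(t+1)}$ is the root's
smoothed posterior, $\omega^{(t+1)} = P_{11}/(P_{11}+P_{10})$ from the
expected parent-child transition counts, and the two emission blocks are
separable weighted maximum-likelihood problems solved by bounded
L-BFGS-B (analytic gradients for the alternative beta via its sufficient
statistics; numerical gradients for the three-parameter null mixture).
Box edges are inset by $10^{-6}$; if an optimizer fails or cannot improve
its block, the previous values are kept and the block is flagged, which
also protects the EM ascent property. Convergence is declared when the
relative log-likelihood change drops below `tol` ($10^{-8}$ by default)
or the largest parameter change drops below $10^{-6}$.

The likelihood is multimodal, so `fit_em()` runs plain EM from
`n_restarts` random starting points (default 20) drawn uniformly inside
the parameter boxes, plus one deterministic-annealing run in which
E-step responsibilities are computed from emission densities raised to an
inverse temperature climbing the ladder $\{0.1, 0.3, 0.5, 0.8, 1.0\}$
before a final untempered run; the result with the largest final
log-likelihood wins. The annealing schedule is a design choice of this
package (the principle — flatten the objective early, then cool — admits
many schedules) and is fully config-exposed. All randomness derives from
the control seed, so fits are bit-reproducible.

Two identifiability limits are inherent to fitting a single tree and
worth knowing. First, $\pi$ is informed by one observation (the root),
so its MLE sits essentially at the root's posterior, near 0 or 1.
Second, $\omega$ is informed only by edges whose parent is in state 1;
when a simulated or real dataset happens to carry little DE signal,
$\hat\omega$ is correspondingly noisy, and with no DE signal at all the
emission densities coincide and the likelihood is flat in $(\pi,
\omega)$ — `fit_em()` detects numerically identical emissions at the
optimum and reports the fit as uninformative rather than converged.

## Back to the DAG

For each non-root tree node the conditional transition probability

$$c_i = \frac{\omega\,\tau_i(1)}{\tau_{\rho(i),i}(1)\,P(S_i=1)},
  \qquad c_1 = \tau_1(1),$$

is the probability the node is DE given all p-values and a DE parent.
Subtree states are independent given their common ancestors, so the
probability that *every* target in a set is null factorizes along the
minimal subtree spanning the targets; a bottom-up dynamic program on
that subtree yields $\mathrm{PDE}_j = P(\max_{k \in GT_j} S_k = 1 \mid
\mathbf{p})$ at cost proportional to the number of ancestors of the
target set rather than the tree size. Because the target sets are nested
along DAG edges, PDEs are monotone (child never exceeds parent) and any
thresholded rejection set is ancestor-closed. For a rejection set $R$,
$1 - |R|^{-1}\sum_{i \in R}\widehat{\mathrm{PDE}}_i$ estimates the FDR,
but FDR control is not guaranteed under the dependence among overlapping
gene sets; the recommended practice is a PDE threshold of 0.95 or 0.99,
optionally preceded by any FWER-controlling method as a conservative
gate (not implemented here; the rejection report carries a reminder).

## The synthetic-data generator

`random_dag()` grows a random tree scaffold (children capped at
`max_children`, default 4, giving depth profiles comparable to the
biological-process ontology at equal size) and gives a configurable
fraction of nodes (default 0.15) one extra parent drawn from their
non-descendants; genes are scattered over leaf terms and propagated
upward. `simulate_states()` and `simulate_pvalues()` draw exactly from
the model above. The generator therefore emulates the model's own
assumptions — hierarchical annotation, logically consistent states,
mixture emissions — and deliberately does *not* emulate two features of
real data: correlation among p-values beyond what states induce (real
overlapping gene sets share genes) and whatever misspecification a real
gene-set test introduces. Passing tests on synthetic data consequently
validate the algorithms and the model's internal consistency, not the
model's adequacy for any particular experiment.

Brute-force oracles (`brute_force_likelihood()`,
`brute_force_posteriors()`) evaluate likelihoods and posteriors by
summing over every logically consistent state configuration — the
up-closed 1-sets, enumerated directly rather than as $2^{N_T}$ raw
configurations — and cap at 20 nodes. They share no code with the
recursions and anchor the test suite: on hundreds of random small trees
the recursive quantities match enumeration to $10^{-9}$ (observed
agreement is at machine precision).

## Numerical and design choices

- p-values are clipped to $[10^{-15}, 1-10^{-15}]$ before any density
  evaluation; beta densities diverge at the boundary for shapes below 1
  and external tests can emit exact 0 or 1.
- $c_i$ values may exceed $[0,1]$ by rounding; excursions up to $10^{-8}$
  are clipped, anything larger raises (it distinguishes rounding from
  bugs).
- Node ordering is lexicographic by identifier everywhere, making
  topological order, tree indexing and all outputs byte-deterministic.
- The prior $P(S_i=1)$ underflowing $10^{-300}$ raises an explicit error
  (it would require a pathological depth-to-$\omega$ combination).
- Empty tree carvings are deleted rather than imputed: a node with no
  genes of its own has no testable p-value.

## Validation scale

The test suite and `scripts/acceptance.R` exercise the package at sizes
chosen to make the statistical properties visible while keeping a full
run comfortable on a single CPU: 200 enumeration-oracle instances of up
to 12 nodes; EM ascent on 20 simulated 200-node trees; parameter
recovery on ten 2000-node trees simulated from $\theta^* = (\pi=0.95,
\omega=0.6, \alpha=0.3, \beta=10, \lambda=1)$ and fitted with two
restarts plus annealing; twenty end-to-end transform–fit–PDE pipelines
on 2000-node DAGs (15% multi-parent nodes) for monotonicity, the FDR
identity, calibration of the PDE ≥ 0.9 bin, and the PDE-versus-p-value
ranking comparison; and one full pipeline at the ~8700-term scale of the
biological-process ontology. On the recovery experiment, note the
identifiability limits above: realizations whose root is null (or whose
DE signal dies immediately) carry no information about $\pi$ or
$\omega$, and with ten replicates under $\theta^*$ such realizations
appear regularly; recovery of $\omega$ on the identifiable replicates is
within a few hundredths. Ranking comparisons exclude datasets with no DE
node, where AUROC is undefined for any method.

## Known limitations

- The method estimates $\theta$ by maximum likelihood and plugs it in;
  there is no posterior over $\theta$ and no standard errors.
- FDR estimates are descriptive under dependence, not controlled.
- Only `is_a`-style edges are modelled; `part_of`/`regulates` relations,
  evidence codes and multi-ontology merging are out of scope.
- The conditional-independence-given-states assumption is knowingly
  false for overlapping gene sets; the empirical null absorbs some, not
  all, of the resulting dependence.
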