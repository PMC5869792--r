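# hmtree

Structured multiple testing of gene sets on a Gene Ontology style DAG with
a hidden Markov tree model.

## The problem

High-throughput transcriptome experiments are routinely summarized by
testing predefined gene sets — typically the gene sets attached to Gene
Ontology (GO) terms — for a multivariate difference in expression across
treatment conditions. The terms form a directed acyclic graph whose edges
run from general to specific terms, so the gene sets are nested and the
null hypotheses are logically entangled: if a gene set shows no
distributional difference, neither can any of its subsets. Sequential
procedures that honor this constraint (top-down, global-up) decide each
node in isolation and lose power; `hmtree` instead models the whole graph
at once and returns, for every term, a posterior probability of
differential expression (PDE).

## The model

The DAG is first transformed into a tree: every multi-parent term keeps
only the incoming edge from its largest parent (removing a child's genes
from the abandoned parents), each tree node's gene set becomes the union
of the direct annotations in its tree subtree, and every original DAG
term *j* maps to the set **GT**<sub>j</sub> of tree nodes whose gene sets
it contains, whose union reconstructs the term's gene set exactly.

One p-value per tree node, from any multivariate gene-set test (Global
Test, MRPP, ...), is then modelled with a two-state hidden Markov tree.
Hidden states S<sub>i</sub> ∈ {0, 1} (1 = differentially expressed)
follow the root-to-leaf Markov process

- P(S<sub>root</sub> = 1) = π,
- P(S<sub>i</sub> = 0 | S<sub>ρ(i)</sub> = 0) = 1,
- P(S<sub>i</sub> = 1 | S<sub>ρ(i)</sub> = 1) = ω,

so null parents force null children, and p-values are conditionally
independent with emissions

- f<sub>0</sub>(p) = λ + (1 − λ) Beta(p; α<sub>0</sub>, β<sub>0</sub>) under the null
  (an empirical-null mixture absorbing dependence among overlapping sets),
- f<sub>1</sub>(p) = Beta(p; α, β) with α ≤ 1 < β under the alternative.

Exact inference uses the scaled upward-downward algorithm (the tree
analogue of forward-backward); all seven parameters are estimated by
maximum likelihood via EM with random restarts and a deterministic
annealing run. Tree-level beliefs convert to DAG-level probabilities
through the conditional transition probabilities
c<sub>i</sub> = P(S<sub>i</sub> = 1 | all p-values, S<sub>ρ(i)</sub> = 1):
the PDE of DAG term *j* is the probability that at least one tree node in
**GT**<sub>j</sub> is in state 1, computed by a dynamic program on the
subtree spanning the targets. For a rejection set R the estimated FDR is
1 − mean(PDE over R); the recommended practice is thresholding PDEs at
0.95 or 0.99.

## Worked example

```r
library(hmtree)

# a small annotated DAG: t1 -> {t2, t3}, {t2, t3} -> t4 (diamond)
edges <- data.frame(parent = c("t1", "t1", "t1", "t2", "t3"),
                    child  = c("t2", "t3", "t4", "t4", "t4"))
ann <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f", "g"),
                  term_id = c("t4", "t4", "t2", "t3", "t3", "t1", "t1"))
tm <- transform_to_tree(load_dag(edges, ann))
tm$tree
#> Term tree: 4 nodes, depth 2, root 't1'

# p-values per tree node (here: t1, t2, t4 strongly significant)
p <- c(t1 = 1e-5, t2 = 0.001, t3 = 0.4, t4 = 2e-4)
theta <- hmtm_params(pi = 0.9, omega = 0.7, alpha = 0.3, beta = 10,
                     lambda = 1, alpha0 = 2, beta0 = 2)
up <- upward_pass(tm$tree, p[tm$tree$ids], theta)
cv <- conditional_c(tm$tree, up, theta)
tab <- pde_all_dag_nodes(tm$map, tm$tree, cv)
tab
#>   term_id       pde n_genes n_tree_nodes
#> 1      t1 0.9999995       7            4
#> 2      t2 0.9991687       3            2
#> 3      t3 0.8409514       4            2
#> 4      t4 0.8395452       2            1
reject_by_threshold(tab, 0.95)[c("rejected", "fdr_estimate")]
#> $rejected
#> [1] "t1" "t2"
#>
#> $fdr_estimate
#> [1] 0.0004159083
```

Term `t2`'s PDE aggregates evidence over its two comprising tree nodes
(`t2` itself and `t4`, whose genes were carved out of it), and the PDEs
are monotone along DAG edges, so any thresholded rejection set is
automatically ancestor-closed. On full-size problems the parameters are
estimated first with `fit_em()`; the file-based pipeline is available as
`run_transform()` / `run_fit()` / `run_pde()` or through the installed
`exec/hmtree` command-line script, and `run_simulate()` generates
complete synthetic datasets.

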