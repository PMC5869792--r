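# DAG-level posterior probabilities of differential expression ----------------
#
# A DAG node is DE exactly when at least one of its comprising tree nodes
# is in state 1. Given all p-values, the tree states of distinct subtrees
# are independent conditional on their common ancestors, so the
# probability that a set of target tree nodes are all null factorizes
# along the minimal subtree spanning the targets. The building block is
# the conditional transition probability
#   c_i = P(S_i = 1 | all p-values, S_parent(i) = 1),
# computed from the upward quantities alone.

#' Conditional transition probabilities on the tree
#'
#' For every non-root node, `c_i = omega * tau_i(1) / (tau_edge_i(1) *
#' P(S_i = 1))`, the probability node i is DE given all p-values and a DE
#' parent; for the root, `c_1 = tau_1(1)`, its smoothed posterior. Values
#' outside `[0, 1]` by more than 1e-8 indicate a numerical fault and
#' raise; smaller excursions are clipped.
#'
#' @param tree a `go_tree`.
#' @param beliefs beliefs from [upward_pass()] (the downward pass is not
#'   required).
#' @param theta the `hmtm_params` the beliefs were computed under.
#' @return numeric vector of length `tree$n`.
#' @export
conditional_c <- function(tree, beliefs, theta) {
  theta <- validate_params(theta)
  n <- tree$n
  cv <- numeric(n)
  cv[1L] <- beliefs$tau[1L, 2L]
  if (n > 1L) {
    i <- 2:n
    den <- beliefs$tau_edge[i, 2L] * beliefs$prior[i, 2L]
    cv[i] <- safe_ratio(theta$omega * beliefs$tau[i, 2L], den, "conditional_c")
  }
  bad <- cv < -1e-8 | cv > 1 + 1e-8
  if (any(bad)) {
    hmt_numerical_error(sprintf(
      "conditional transition probability outside [0,1] beyond tolerance at tree node %d (value %.3e)",
      which(bad)[1L], cv[which(bad)[1L]]))
  }
  pmin(pmax(cv, 0), 1)
}

#' Probability that any tree node in a target set is DE
#'
#' Computes `P(max over targets of S_k = 1 | all p-values)` by a dynamic
#' program restricted to the minimal subtree spanning the root and the
#' targets: bottom-up, `h(v) = (1 - c_v) + c_v * prod h(children with
#' targets below)` is the probability that all targets under v are null
#' given a DE parent (0 replaces the product when v is itself a target),
#' and the answer unrolls the same recursion at the root. Cost is
#' proportional to the number of ancestors of the target set, not the
#' tree size.
#'
#' @param tree a `go_tree`.
#' @param cvec conditional probabilities from [conditional_c()].
#' @param targets integer vector of tree node indices.
#' @return a probability.
#' @export
pde_for_target_set <- function(tree, cvec, targets) {
  n <- tree$n
  targets <- as.integer(targets)
  if (!length(targets)) hmt_input_error("target set must be nonempty")
  if (any(is.na(targets)) || any(targets < 1L | targets > n)) {
    hmt_input_error("unknown tree node index in target set")
  }
  parent <- tree$parent
  mark <- rep(FALSE, n)
  for (v in targets) {
    while (!is.na(v) && !mark[v]) {
      mark[v] <- TRUE
      v <- parent[v]
    }
  }
  relevant <- which(mark)
  relevant <- relevant[order(tree$depth[relevant], decreasing = TRUE)]
  is_target <- rep(FALSE, n)
  is_target[targets] <- TRUE
  acc <- rep(1, n)  # product of h over marked children
  for (v in relevant) {
    if (v == 1L) break
    h <- (1 - cvec[v]) + cvec[v] * (if (is_target[v]) 0 else acc[v])
    acc[parent[v]] <- acc[parent[v]] * h
  }
  inner <- if (is_target[1L]) 0 else acc[1L]
  1 - ((1 - cvec[1L]) + cvec[1L] * inner)
}

#' Posterior probability of differential expression for every DAG node
#'
#' Plug-in PDE for each node of the original DAG: the probability that at
#' least one of its comprising tree nodes (the map's `GT_j`) is in
#' state 1, given all p-values and the fitted parameters. Because the
#' target sets are nested along DAG edges, PDEs are monotone: a child's
#' PDE never exceeds its parent's.
#'
#' @param map a `dag_tree_map` from [transform_to_tree()].
#' @param tree the corresponding `go_tree`.
#' @param cvec conditional probabilities from [conditional_c()].
#' @return a `hmtree_pde` data frame with columns `term_id`, `pde`,
#'   `n_genes`, `n_tree_nodes`.
#' @export
pde_all_dag_nodes <- function(map, tree, cvec) {
  stopifnot(inherits(map, "dag_tree_map"))
  pde <- vapply(map$gt, function(gt) pde_for_target_set(tree, cvec, gt),
                numeric(1))
  out <- data.frame(term_id = names(map$gt), pde = unname(pde),
                    n_genes = unname(map$n_genes[names(map$gt)]),
                    n_tree_nodes = unname(lengths(map$gt)),
                    stringsAsFactors = FALSE)
  class(out) <- c("hmtree_pde", "data.frame")
  out
}

#' Assign each DAG node the p-value of its carved tree node
#'
#' Convenience for structure-blind comparisons: each DAG term receives the
#' p-value of the tree node that was carved from it, or, for terms whose
#' carving was dropped as empty, the smallest p-value among its comprising
#' tree nodes.
#'
#' @param map a `dag_tree_map`.
#' @param tree the corresponding `go_tree`.
#' @param pvals p-values indexed like the tree.
#' @return named numeric vector, one entry per DAG term.
#' @export
dag_node_pvalues <- function(map, tree, pvals) {
  inv <- match(names(map$gt), map$origin)  # DAG term -> its own tree node
  out <- pvals[inv]
  miss <- which(is.na(out))
  for (j in miss) out[j] <- min(pvals[map$gt[[j]]])
  stats::setNames(out, names(map$gt))
}

#' FDR estimate for a rejection set
#'
#' One minus the average PDE of the rejected nodes: each `1 - PDE` is the
#' posterior probability of a false rejection, so the average estimates
#' the expected false discovery proportion.
#'
#' @param pde_values PDEs of the rejected nodes; must be nonempty.
#' @return the FDR estimate.
#' @export
estimate_fdr <- function(pde_values) {
  if (!length(pde_values)) hmt_input_error("rejection set is empty; FDR undefined")
  1 - mean(pde_values)
}

#' Threshold the PDE table into a rejection set
#'
#' Rejects every DAG node whose PDE meets the threshold and attaches the
#' FDR estimate. PDE monotonicity along DAG edges makes the rejection set
#' ancestor-closed automatically. Note that FDR control is not guaranteed
#' under the complex dependence among overlapping gene sets; a
#' family-wise-error pre-check with any FWER-controlling method is a
#' prudent first step before interpreting the rejections.
#'
#' @param table a `hmtree_pde` data frame from [pde_all_dag_nodes()].
#' @param threshold PDE significance threshold in (0, 1); 0.95 and 0.99
#'   are the conventional choices (default 0.99).
#' @return list with `rejected` (term identifiers), `threshold`,
#'   `n_rejected`, and `fdr_estimate` (`NA` when nothing is rejected).
#' @export
reject_by_threshold <- function(table, threshold = 0.99) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    hmt_input_error("threshold must be a single number in (0, 1)")
  }
  sel <- table$pde >= threshold
  list(rejected = table$term_id[sel],
       threshold = threshold,
       n_rejected = sum(sel),
       fdr_estimate = if (any(sel)) estimate_fdr(table$pde[sel]) else NA_real_)
}
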