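# Shared fixtures built in code.

# Four-term diamond mirroring the classic tree-transformation illustration:
# edges 1->2, 1->3, 1->4, 2->4, 3->4 with |G_3| > |G_2| so node 4 retains
# parent 3; the reduced DAG drops 1->4 and the tree has edges 1->2, 1->3, 3->4.
diamond_edges <- function() {
  data.frame(parent = c("t1", "t1", "t1", "t2", "t3"),
             child  = c("t2", "t3", "t4", "t4", "t4"),
             stringsAsFactors = FALSE)
}

diamond_annotations <- function() {
  data.frame(gene_id = c("a", "b", "c", "d", "e", "f", "g"),
             term_id = c("t4", "t4", "t2", "t3", "t3", "t1", "t1"),
             stringsAsFactors = FALSE)
}

diamond_dag <- function() load_dag(diamond_edges(), diamond_annotations())

# random tree as a plain parent vector (uniform attachment), root = 1
random_parent_vec <- function(n) {
  as.integer(c(NA, if (n > 1) vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)))
}

# valid random parameters drawn inside the boxes (caller sets the seed)
random_theta <- function() {
  hmtm_params(pi = runif(1, 0.1, 0.9), omega = runif(1, 0.1, 0.9),
              alpha = runif(1, 0.1, 1), beta = runif(1, 1.5, 15),
              lambda = runif(1, 0, 1), alpha0 = runif(1, 1.1, 5),
              beta0 = runif(1, 1.1, 5))
}

# small random instance (tree + theta + p-values) for oracle comparisons
random_instance <- function(max_nodes = 12L) {
  n <- sample.int(max_nodes, 1L)
  tree <- go_tree(random_parent_vec(n))
  theta <- random_theta()
  # half the instances use model-simulated p-values, half plain uniform
  p <- if (runif(1) < 0.5) {
    st <- simulate_states(tree, theta$pi, theta$omega,
                          seed = sample.int(1e6, 1L))
    simulate_pvalues(st, theta, seed = sample.int(1e6, 1L))
  } else {
    clip_pvalues(runif(n))
  }
  list(tree = tree, theta = theta, p = p, n = n)
}

default_theta <- function() hmtm_params(0.9, 0.7, 0.3, 10, 1, 2, 2)
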