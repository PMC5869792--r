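# Model-faithful synthetic data and brute-force oracles -----------------------
#
# The generator emulates the model's own assumptions: hidden states follow
# the root-to-leaf Markov process (a null parent forces null children),
# and p-values are drawn from the state-conditional emission densities,
# independently given the states. The enumeration oracles compute exact
# likelihoods and posteriors by summing over every logically consistent
# state configuration (the up-closed 1-sets), which is exact and fast for
# small trees and entirely independent of the recursive algorithms it
# validates.

#' Synthetic-data configuration
#'
#' @param n_dag_nodes number of DAG terms to generate.
#' @param n_genes number of genes to scatter over the leaf terms (raised
#'   to the leaf count if smaller, so every term is annotated).
#' @param max_children cap on the number of children per node of the
#'   underlying tree scaffold.
#' @param multi_parent_fraction fraction of non-root nodes given a second
#'   parent (0 generates a tree).
#' @param theta an `hmtm_params` object used when simulating states and
#'   p-values.
#' @param seed mandatory integer seed; every generator draw derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_dag_nodes, n_genes = 2L * n_dag_nodes,
                       max_children = 4L, multi_parent_fraction = 0.15,
                       theta = hmtm_params(0.9, 0.7, 0.3, 10, 1, 2, 2),
                       seed) {
  if (missing(seed)) hmt_input_error("sim_config requires an explicit seed")
  if (n_dag_nodes < 1L || n_genes < 1L || max_children < 1L) {
    hmt_input_error("counts in sim_config must be positive")
  }
  if (multi_parent_fraction < 0 || multi_parent_fraction > 1) {
    hmt_input_error("multi_parent_fraction must be in [0, 1]")
  }
  structure(list(n_dag_nodes = as.integer(n_dag_nodes),
                 n_genes = as.integer(n_genes),
                 max_children = as.integer(max_children),
                 multi_parent_fraction = multi_parent_fraction,
                 theta = validate_params(theta),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random annotated term DAG
#'
#' Grows a random rooted tree, then gives a `multi_parent_fraction` of
#' non-root nodes one extra parent drawn from their non-descendants
#' (preserving acyclicity). Genes are assigned to leaf terms (each leaf
#' gets at least one) and propagated upward through [load_dag()], so the
#' result satisfies every `go_dag` invariant. Deterministic given the
#' seed.
#'
#' @param config a [sim_config()].
#' @return list with `dag` (a `go_dag`), `edges` and `annotations` (the
#'   data frames the DAG was loaded from, for serialization).
#' @export
random_dag <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_dag_nodes
  ids <- sprintf("N%06d", seq_len(n))
  parent <- rep(NA_integer_, n)
  nkids <- integer(n)
  for (v in seq_len(n)[-1L]) {
    open <- which(nkids[seq_len(v - 1L)] < config$max_children)
    u <- if (length(open) == 1L) open else sample(open, 1L)
    parent[v] <- u
    nkids[u] <- nkids[u] + 1L
  }
  edges <- data.frame(parent = ids[parent[-1L]], child = ids[-1L],
                      stringsAsFactors = FALSE)

  if (config$multi_parent_fraction > 0 && n > 2L) {
    adj <- rep(list(integer(0)), n)  # children, tree plus added extra edges
    for (v in seq_len(n)[-1L]) adj[[parent[v]]] <- c(adj[[parent[v]]], v)
    reachable_from <- function(v) {
      seen <- logical(n)
      stack <- v
      while (length(stack)) {
        x <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (seen[x]) next
        seen[x] <- TRUE
        stack <- c(stack, adj[[x]])
      }
      which(seen)
    }
    extra <- which(stats::runif(n - 1L) < config$multi_parent_fraction) + 1L
    for (v in extra) {
      # a new parent must not be reachable from v, or a cycle would form
      cand <- setdiff(seq_len(n), c(reachable_from(v), parent[v]))
      if (!length(cand)) next
      u <- if (length(cand) == 1L) cand else sample(cand, 1L)
      adj[[u]] <- c(adj[[u]], v)
      edges <- rbind(edges, data.frame(parent = ids[u], child = ids[v],
                                       stringsAsFactors = FALSE))
    }
  }

  is_leaf <- !(seq_len(n) %in% match(edges$parent, ids))
  leaves <- which(is_leaf)
  ng <- max(config$n_genes, length(leaves))
  genes <- sprintf("g%06d", seq_len(ng))
  host <- c(leaves,
            if (ng > length(leaves))
              sample(leaves, ng - length(leaves), replace = TRUE))
  annotations <- data.frame(gene_id = genes, term_id = ids[host],
                            stringsAsFactors = FALSE)
  list(dag = load_dag(edges, annotations),
       edges = edges, annotations = annotations)
}

#' Simulate hidden states on a tree
#'
#' Root state is Bernoulli(`pi`); a child of a state-1 parent is state 1
#' with probability `omega`; a child of a state-0 parent is state 0. The
#' result is logically consistent by construction.
#'
#' @param tree a `go_tree`.
#' @param pi,omega transition parameters, see [hmtm_params()].
#' @param seed integer seed.
#' @return integer vector of 0/1 states, one per node.
#' @export
simulate_states <- function(tree, pi, omega, seed) {
  set.seed(seed)
  n <- tree$n
  s <- integer(n)
  u <- stats::runif(n)
  s[1L] <- as.integer(u[1L] < pi)
  for (lev in tree_levels(tree)[-1L]) {
    s[lev] <- as.integer(s[tree$parent[lev]] == 1L & u[lev] < omega)
  }
  s
}

#' Simulate p-values given hidden states
#'
#' State-0 nodes draw from the null mixture (uniform with probability
#' `lambda`, otherwise `Beta(alpha0, beta0)`); state-1 nodes draw from
#' `Beta(alpha, beta)`. Draws are independent across nodes given the
#' states, and the output is clipped into the open unit interval.
#'
#' @param states integer vector of 0/1 states.
#' @param theta an `hmtm_params` object.
#' @param seed integer seed.
#' @return numeric vector of p-values in (0, 1).
#' @export
simulate_pvalues <- function(states, theta, seed) {
  theta <- validate_params(theta)
  set.seed(seed)
  n <- length(states)
  p <- numeric(n)
  s1 <- states == 1L
  p[s1] <- stats::rbeta(sum(s1), theta$alpha, theta$beta)
  s0 <- which(!s1)
  from_unif <- stats::runif(length(s0)) < theta$lambda
  p[s0[from_unif]] <- stats::runif(sum(from_unif))
  p[s0[!from_unif]] <- stats::rbeta(sum(!from_unif), theta$alpha0, theta$beta0)
  clip_pvalues(p)
}

# all logically consistent configurations (rows) for a tree: the 1-set is
# empty or an up-closed set containing the root
consistent_configs <- function(tree) {
  n <- tree$n
  if (n > 20L) hmt_input_error("enumeration limited to trees of at most 20 nodes")
  expand <- function(v) {
    # configurations of subtree(v) given the parent is in state 1
    zero <- list(integer(0))
    one <- list(v)
    for (ch in tree$children[[v]]) {
      sub <- expand(ch)
      one <- unlist(lapply(one, function(a) lapply(sub, function(b) c(a, b))),
                    recursive = FALSE)
    }
    c(zero, one)
  }
  sets <- expand(1L)
  m <- matrix(0L, length(sets), n)
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  m
}

# joint probability P(S = config, p) for each enumerated configuration
config_joint <- function(tree, configs, pvals, theta) {
  p <- clip_pvalues(pvals)
  emis <- emission_matrix(p, theta)
  n <- tree$n
  apply(configs, 1L, function(s) {
    pr <- if (s[1L] == 1L) theta$pi else 1 - theta$pi
    if (n > 1L) {
      for (i in 2:n) {
        sp <- s[tree$parent[i]]
        pr <- pr * if (sp == 0L) {
          if (s[i] == 0L) 1 else 0
        } else {
          if (s[i] == 1L) theta$omega else 1 - theta$omega
        }
      }
    }
    pr * prod(emis[cbind(seq_len(n), s + 1L)])
  })
}

#' Brute-force log-likelihood by enumeration
#'
#' Sums the joint density over every logically consistent state
#' configuration of a small tree. This is the independent oracle for the
#' upward pass; it shares no code path with the recursions.
#'
#' @param tree a `go_tree` with at most 20 nodes.
#' @param pvals p-values, one per node.
#' @param theta an `hmtm_params` object.
#' @return the log-likelihood.
#' @export
brute_force_likelihood <- function(tree, pvals, theta) {
  theta <- validate_params(theta)
  configs <- consistent_configs(tree)
  log(sum(config_joint(tree, configs, pvals, theta)))
}

#' Brute-force posteriors by enumeration
#'
#' Exact smoothed marginals, pairwise parent-child expectations,
#' conditional transition probabilities, and the probability that any
#' node of a target set is in state 1, all by direct summation over
#' consistent configurations. Oracle for the downward pass, the E-step,
#' [conditional_c()] and [pde_for_target_set()].
#'
#' @param tree a `go_tree` with at most 20 nodes.
#' @param pvals p-values, one per node.
#' @param theta an `hmtm_params` object.
#' @param targets optional integer vector of tree nodes for the
#'   any-target probability.
#' @return list with `marginal` (P(S_i = 1 | p) per node), `E11`, `E10`
#'   (pairwise expectations, `NA` at the root), `cond_c`
#'   (P(S_i = 1 | p, parent DE), root entry = root marginal),
#'   `p_any_target` (`NA` when `targets` is missing), and `loglik`.
#' @export
brute_force_posteriors <- function(tree, pvals, theta, targets = NULL) {
  theta <- validate_params(theta)
  configs <- consistent_configs(tree)
  joint <- config_joint(tree, configs, pvals, theta)
  total <- sum(joint)
  wts <- joint / total
  n <- tree$n

  marginal <- as.numeric(crossprod(configs, wts))
  E11 <- rep(NA_real_, n)
  E10 <- rep(NA_real_, n)
  cond_c <- rep(NA_real_, n)
  cond_c[1L] <- marginal[1L]
  if (n > 1L) {
    for (i in 2:n) {
      sp <- configs[, tree$parent[i]]
      E11[i] <- sum(wts[sp == 1L & configs[, i] == 1L])
      E10[i] <- sum(wts[sp == 1L & configs[, i] == 0L])
      cond_c[i] <- if (E11[i] + E10[i] > 0) E11[i] / (E11[i] + E10[i]) else 0
    }
  }
  p_any <- NA_real_
  if (!is.null(targets)) {
    hit <- apply(configs[, targets, drop = FALSE] == 1L, 1L, any)
    p_any <- sum(wts[hit])
  }
  list(marginal = marginal, E11 = E11, E10 = E10, cond_c = cond_c,
       p_any_target = p_any, loglik = log(total))
}
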