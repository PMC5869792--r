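test_that("conditional probabilities match enumeration and chain identities", {
  set.seed(201)
  for (r in 1:40) {
    inst <- random_instance(12L)
    up <- upward_pass(inst$tree, inst$p, inst$theta)
    cv <- conditional_c(inst$tree, up, inst$theta)
    bf <- brute_force_posteriors(inst$tree, inst$p, inst$theta)
    expect_lt(max(abs(cv - bf$cond_c)), 1e-9)
    expect_lt(abs(cv[1] - up$tau[1, 2]), 1e-12)
  }
  # chain rule: along a path tree the product of c equals the smoothed posterior
  set.seed(202)
  tree <- go_tree(as.integer(c(NA, 1:6)))  # a 7-node path
  th <- random_theta()
  p <- clip_pvalues(runif(7))
  up <- upward_pass(tree, p, th)
  bel <- downward_pass(tree, up, th)
  cv <- conditional_c(tree, up, th)
  for (k in c(3, 5, 7)) {
    expect_equal(prod(cv[1:k]), unname(bel$posterior[k, 2]), tolerance = 1e-10)
  }
})

test_that("the target-set DP reproduces the diamond closed form", {
  # tree edges 1->2, 1->3, 3->4; targets {2, 4}
  tree <- go_tree(c(NA, 1L, 1L, 3L))
  set.seed(210)
  for (r in 1:50) {
    cv <- runif(4)
    expect_equal(pde_for_target_set(tree, cv, c(2L, 4L)),
                 cv[1] * (1 - (1 - cv[2]) * (1 - cv[3] * cv[4])),
                 tolerance = 1e-12)
  }
  expect_equal(pde_for_target_set(tree, cv, 1L), cv[1])
  expect_error(pde_for_target_set(tree, cv, integer(0)),
               class = "hmtree_input_error")
  expect_error(pde_for_target_set(tree, cv, 9L),
               class = "hmtree_input_error")
})

test_that("the target-set DP equals enumeration on random instances", {
  set.seed(211)
  for (r in 1:40) {
    inst <- random_instance(12L)
    up <- upward_pass(inst$tree, inst$p, inst$theta)
    cv <- conditional_c(inst$tree, up, inst$theta)
    targets <- sample.int(inst$n, sample.int(min(4L, inst$n), 1L))
    bf <- brute_force_posteriors(inst$tree, inst$p, inst$theta, targets = targets)
    expect_lt(abs(pde_for_target_set(inst$tree, cv, targets) - bf$p_any_target),
              1e-9)
  }
})

test_that("DAG-level PDEs are consistent, monotone and singleton-exact", {
  set.seed(220)
  cfg <- sim_config(60, theta = default_theta(), seed = 220,
                    multi_parent_fraction = 0.3)
  dag <- random_dag(cfg)$dag
  tm <- transform_to_tree(dag)
  th <- default_theta()
  s <- simulate_states(tm$tree, th$pi, th$omega, seed = 221)
  p <- simulate_pvalues(s, th, seed = 222)
  up <- upward_pass(tm$tree, p, th)
  bel <- downward_pass(tm$tree, up, th)
  cv <- conditional_c(tm$tree, up, th)
  tab <- pde_all_dag_nodes(tm$map, tm$tree, cv)

  # a DAG node mapped to a single tree node has PDE = that node's posterior
  singles <- which(lengths(tm$map$gt) == 1L)
  for (j in singles) {
    expect_lt(abs(tab$pde[j] - bel$posterior[tm$map$gt[[j]], 2]), 1e-10)
  }
  # monotone along every DAG edge
  expect_true(all(tab$pde[dag$edges[, 2]] <= tab$pde[dag$edges[, 1]] + 1e-10))
})

test_that("FDR estimate is one minus the mean PDE of the rejection set", {
  expect_equal(estimate_fdr(c(1, 1)), 0)
  expect_equal(estimate_fdr(c(0.99, 0.97)), 0.02)
  expect_equal(estimate_fdr(0.95), 0.05)
  expect_error(estimate_fdr(numeric(0)), class = "hmtree_input_error")
})

test_that("thresholding returns an ancestor-closed rejection set", {
  tab <- data.frame(term_id = c("A", "B"), pde = c(0.999, 0.5),
                    n_genes = c(2L, 1L), n_tree_nodes = c(2L, 1L))
  class(tab) <- c("hmtree_pde", "data.frame")
  r <- reject_by_threshold(tab, 0.99)
  expect_identical(r$rejected, "A")
  expect_equal(r$fdr_estimate, 1 - 0.999)
  # nothing above threshold: graceful empty set
  r <- reject_by_threshold(tab, 1 - 1e-12)
  expect_identical(r$n_rejected, 0L)
  expect_true(is.na(r$fdr_estimate))
  expect_error(reject_by_threshold(tab, 1.5), class = "hmtree_input_error")

  # on a synthetic run, every rejected node's ancestors are rejected too
  set.seed(230)
  cfg <- sim_config(80, theta = default_theta(), seed = 230,
                    multi_parent_fraction = 0.25)
  dag <- random_dag(cfg)$dag
  tm <- transform_to_tree(dag)
  th <- default_theta()
  s <- simulate_states(tm$tree, th$pi, th$omega, seed = 231)
  p <- simulate_pvalues(s, th, seed = 232)
  up <- upward_pass(tm$tree, p, th)
  tab <- pde_all_dag_nodes(tm$map, tm$tree, conditional_c(tm$tree, up, th))
  for (thr in c(0.5, 0.9, 0.95, 0.99)) {
    rej <- reject_by_threshold(tab, thr)
    sel <- tab$term_id %in% rej$rejected
    for (e in seq_len(nrow(dag$edges))) {
      if (sel[match(dag$ids[dag$edges[e, 2]], tab$term_id)]) {
        expect_true(sel[match(dag$ids[dag$edges[e, 1]], tab$term_id)])
      }
    }
  }
})
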