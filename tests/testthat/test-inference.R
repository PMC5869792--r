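test_that("prior state probabilities follow pi * omega^depth", {
  tree <- go_tree(c(NA, 1L, 2L, 2L))
  pr <- marginal_state_probs(tree, 0.9, 0.5)
  expect_equal(pr[, "p1"], c(0.9, 0.45, 0.225, 0.225))
  expect_equal(unname(pr[1, "p1"]), 0.9)
  expect_equal(rowSums(pr), rep(1, 4))
  # persistence limit: omega near 1 keeps the root probability everywhere
  pr <- marginal_state_probs(tree, 0.9, 1 - 1e-9)
  expect_equal(pr[, "p1"], rep(0.9, 4), tolerance = 1e-8)
})

test_that("single-node likelihood has its closed form", {
  tree <- go_tree(NA_integer_)
  th <- hmtm_params(0.8, 0.5, 0.4, 6, 0.7, 2, 3)
  p <- 0.03
  up <- upward_pass(tree, p, th)
  expect_equal(up$loglik,
               log(th$pi * alt_density(p, th$alpha, th$beta) +
                   (1 - th$pi) * null_density(p, th$lambda, th$alpha0, th$beta0)),
               tolerance = 1e-12)
})

test_that("two-node chain likelihood matches the explicit four-term sum", {
  tree <- go_tree(c(NA, 1L))
  th <- hmtm_params(0.7, 0.6, 0.3, 9, 0.8, 2.5, 2)
  p <- c(0.04, 0.5)
  f <- cbind(null_density(p, th$lambda, th$alpha0, th$beta0),
             alt_density(p, th$alpha, th$beta))
  q <- matrix(c(1, 0, 1 - th$omega, th$omega), 2, byrow = TRUE)
  tot <- 0
  for (s1 in 0:1) for (s2 in 0:1) {
    tot <- tot + (if (s1 == 1) th$pi else 1 - th$pi) * q[s1 + 1, s2 + 1] *
      f[1, s1 + 1] * f[2, s2 + 1]
  }
  expect_equal(upward_pass(tree, p, th)$loglik, log(tot), tolerance = 1e-12)
})

test_that("beliefs agree with enumeration on random small trees", {
  set.seed(101)
  for (r in 1:50) {
    inst <- random_instance(12L)
    up <- upward_pass(inst$tree, inst$p, inst$theta)
    bel <- downward_pass(inst$tree, up, inst$theta)
    st <- e_step(inst$tree, bel, inst$theta)
    bf <- brute_force_posteriors(inst$tree, inst$p, inst$theta)
    expect_lt(abs(up$loglik - bf$loglik), 1e-9)
    expect_lt(max(abs(bel$posterior[, 2] - bf$marginal)), 1e-9)
    if (inst$n > 1) {
      expect_lt(max(abs(st$E11[-1] - bf$E11[-1])), 1e-9)
      expect_lt(max(abs(st$E10[-1] - bf$E10[-1])), 1e-9)
    }
    # internal normalization identities
    expect_equal(rowSums(up$tau), rep(1, inst$n), tolerance = 1e-12)
    expect_equal(rowSums(bel$posterior), rep(1, inst$n), tolerance = 1e-10)
    expect_equal(bel$posterior[1, 2], up$tau[1, 2])
  }
})

test_that("E-step joints sum to the parent's posterior", {
  set.seed(7)
  tree <- go_tree(random_parent_vec(30))
  th <- default_theta()
  s <- simulate_states(tree, th$pi, th$omega, seed = 8)
  p <- simulate_pvalues(s, th, seed = 9)
  bel <- downward_pass(tree, upward_pass(tree, p, th), th)
  st <- e_step(tree, bel, th)
  i <- 2:30
  expect_equal(st$E11[i] + st$E10[i], st$w[tree$parent[i]], tolerance = 1e-10)
})

test_that("uninformative emissions leave the posterior at the prior", {
  # lambda = 1 makes f0 uniform; alpha = 1, beta -> 1 makes f1 uniform too
  th <- hmtm_params(0.8, 0.6, 1, 1 + 1e-9, 1, 2, 2)
  set.seed(5)
  tree <- go_tree(random_parent_vec(25))
  p <- clip_pvalues(runif(25))
  bel <- downward_pass(tree, upward_pass(tree, p, th), th)
  pr <- marginal_state_probs(tree, th$pi, th$omega)
  expect_equal(unname(bel$posterior[, 2]), unname(pr[, "p1"]), tolerance = 1e-6)
})

test_that("M-step solves the score equations", {
  set.seed(21)
  tree <- go_tree(random_parent_vec(40))
  th <- default_theta()
  s <- simulate_states(tree, th$pi, th$omega, seed = 22)
  p <- simulate_pvalues(s, th, seed = 23)
  bel <- downward_pass(tree, upward_pass(tree, p, th), th)
  st <- e_step(tree, bel, th)
  new <- m_step(st, p, th)
  # pi update equals the root's smoothed posterior exactly
  expect_equal(new$theta$pi, unname(bel$posterior[1, 2]), tolerance = 1e-12)
  # omega update is the ratio of expected transition counts
  expect_equal(new$theta$omega, st$P11 / (st$P11 + st$P10), tolerance = 1e-12)
  # degenerate responsibilities: all w = 1 pushes omega to the box edge
  st1 <- st
  st1$w[] <- 1
  st1$P11 <- length(p) - 1
  st1$P10 <- 0
  expect_equal(m_step(st1, p, th)$theta$omega, 1 - 1e-6)
})

test_that("weighted beta fit recovers known shapes (hard-label oracle)", {
  set.seed(31)
  n <- 5000
  alpha_t <- 0.3; beta_t <- 10
  x1 <- rbeta(n, alpha_t, beta_t)
  x0 <- runif(n)
  p <- clip_pvalues(c(x1, x0))
  w <- c(rep(1, n), rep(0, n))
  st <- list(w = w, P11 = 1, P10 = 1)
  th0 <- hmtm_params(0.5, 0.5, 0.8, 3, 0.9, 2, 2)
  fit <- m_step(st, p, th0)$theta
  expect_lt(abs(fit$alpha - alpha_t), 0.05)
  # independent oracle: unweighted beta MLE on the labelled subset
  ora <- suppressWarnings(MASS::fitdistr(clip_pvalues(x1), "beta",
           start = list(shape1 = 0.5, shape2 = 5))$estimate)
  expect_lt(abs(fit$alpha - ora[["shape1"]]), 1e-3)
  expect_lt(abs(fit$beta - ora[["shape2"]]) / ora[["shape2"]], 1e-3)
})

test_that("EM is deterministic, monotone and seed-reproducible", {
  set.seed(61)
  tree <- go_tree(random_parent_vec(300))
  th <- default_theta()
  s <- simulate_states(tree, th$pi, th$omega, seed = 62)
  p <- simulate_pvalues(s, th, seed = 63)
  ctrl <- em_control(n_restarts = 2, max_iter = 80, seed = 5)
  f1 <- fit_em(tree, p, ctrl)
  f2 <- fit_em(tree, p, ctrl)
  expect_identical(f1, f2)
  expect_true(all(diff(f1$trace) >= -1e-8))
  expect_s3_class(f1$theta, "hmtm_params")
  expect_true(is.data.frame(f1$restarts))
  expect_identical(nrow(f1$restarts), 3L)  # 2 restarts + 1 annealed run
})

test_that("identical emissions make the likelihood flat in pi and omega", {
  set.seed(71)
  tree <- go_tree(random_parent_vec(40))
  p <- clip_pvalues(runif(40))
  lls <- sapply(list(c(0.2, 0.3), c(0.5, 0.9), c(0.9, 0.1)), function(po) {
    th <- hmtm_params(po[1], po[2], 1, 1 + 1e-12, 1, 2, 2)
    upward_pass(tree, p, th)$loglik
  })
  expect_lt(max(lls) - min(lls), 1e-9)
})
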