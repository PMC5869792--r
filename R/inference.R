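# Upward-downward belief propagation and EM -----------------------------------
#
# The recursions are the scaled (numerically stable) formulation: all
# upward quantities tau_i(k) are normalized posteriors given subtree
# evidence, per-node normalizers N_i carry the likelihood, and
# log-likelihood = sum_i log N_i. Passes are vectorized over depth levels,
# so a tree of N nodes costs O(N) vector work regardless of shape.

#' Marginal prior state probabilities
#'
#' Downward recursion for the prior probability that each tree node is in
#' state 1 before seeing any p-value: the root is `pi`, and each edge
#' multiplies by the persistence `omega`, so a node at depth d has prior
#' `pi * omega^d`.
#'
#' @param tree a `go_tree`.
#' @param pi root state-1 probability in (0, 1).
#' @param omega state-1 persistence in (0, 1).
#' @return matrix with columns `p0`, `p1`, one row per node.
#' @export
marginal_state_probs <- function(tree, pi, omega) {
  p1 <- pi * omega^tree$depth
  if (any(p1 < 1e-300)) {
    hmt_numerical_error(
      "prior state-1 probability underflows below 1e-300; the tree is too deep for the given omega")
  }
  cbind(p0 = 1 - p1, p1 = p1)
}

# depth levels, shallow to deep
tree_levels <- function(tree) {
  split(seq_len(tree$n), tree$depth)
}

#' Upward pass of belief propagation
#'
#' Processes nodes leaves-first. Each node's upward belief `tau_i(k)` is
#' the posterior of its state given the p-values in its subtree; the
#' per-node normalizer `N_i` makes `tau` sum to one, and the total
#' log-likelihood of all p-values is `sum(log(N_i))`. The edge quantity
#' `tau_edge` transports a node's belief to its parent through the
#' transition matrix.
#'
#' @param tree a `go_tree`.
#' @param pvals numeric vector of p-values, one per tree node (clipped
#'   internally).
#' @param theta an `hmtm_params` object.
#' @param temper inverse temperature applied to the emission densities
#'   (1 = untempered; used by annealed EM).
#' @return a `hmtree_beliefs` list with `tau`, `tau_edge`, `N`, `prior`,
#'   `loglik`; complete it with [downward_pass()].
#' @export
upward_pass <- function(tree, pvals, theta, temper = 1) {
  theta <- validate_params(theta)
  n <- tree$n
  if (length(pvals) != n) hmt_input_error("need exactly one p-value per tree node")
  p <- clip_pvalues(pvals)
  emis <- emission_matrix(p, theta)
  if (temper != 1) emis <- emis^temper
  prior <- marginal_state_probs(tree, theta$pi, theta$omega)
  omega <- theta$omega

  tau <- matrix(NA_real_, n, 2L)
  tau_edge <- matrix(NA_real_, n, 2L)
  N <- numeric(n)
  acc0 <- rep(1, n)  # running product of children's tau_edge
  acc1 <- rep(1, n)
  parent <- tree$parent

  for (lev in rev(tree_levels(tree))) {
    b0 <- emis[lev, 1L] * prior[lev, 1L] * acc0[lev]
    b1 <- emis[lev, 2L] * prior[lev, 2L] * acc1[lev]
    Nl <- b0 + b1
    if (any(!is.finite(Nl) | Nl <= 0)) {
      bad <- lev[which(!is.finite(Nl) | Nl <= 0)[1L]]
      hmt_numerical_error(sprintf("non-finite or zero normalizer at tree node %d", bad))
    }
    N[lev] <- Nl
    tau[lev, 1L] <- b0 / Nl
    tau[lev, 2L] <- b1 / Nl
    nr <- lev[!is.na(parent[lev])]
    if (length(nr)) {
      # tau_edge(k) = sum_j tau_i(j) q_kj / P(S_i = j); q01 = 0
      te0 <- tau[nr, 1L] / prior[nr, 1L]
      te1 <- tau[nr, 1L] * (1 - omega) / prior[nr, 1L] +
             tau[nr, 2L] * omega / prior[nr, 2L]
      tau_edge[nr, 1L] <- te0
      tau_edge[nr, 2L] <- te1
      l0 <- rowsum(log(te0), parent[nr])
      l1 <- rowsum(log(te1), parent[nr])
      rows <- as.integer(rownames(l0))
      acc0[rows] <- acc0[rows] * exp(l0[, 1L])
      acc1[rows] <- acc1[rows] * exp(l1[, 1L])
    }
  }
  structure(list(tau = tau, tau_edge = tau_edge, N = N, prior = prior,
                 loglik = sum(log(N)), temper = temper, p = p),
            class = "hmtree_beliefs")
}

# 0/0 -> 0 (impossible-state branch under q01 = 0); x/0 with x > 0 is a bug
safe_ratio <- function(num, den, what) {
  out <- num / den
  zz <- den == 0
  if (any(zz)) {
    if (any(num[zz] != 0)) {
      hmt_numerical_error(sprintf("division by zero with nonzero numerator in %s", what))
    }
    out[zz] <- 0
  }
  out
}

#' Downward pass of belief propagation
#'
#' Completes the beliefs started by [upward_pass()]: the downward factor
#' `kappa_i(k)` carries the evidence outside node i's subtree, and the
#' smoothed posterior `P(S_i = k | all p-values)` is `tau_i(k) *
#' kappa_i(k)`.
#'
#' @param tree a `go_tree`.
#' @param beliefs result of [upward_pass()].
#' @param theta the same `hmtm_params` used in the upward pass.
#' @return the beliefs list extended with `kappa` and `posterior`
#'   (n x 2 matrices).
#' @export
downward_pass <- function(tree, beliefs, theta) {
  theta <- validate_params(theta)
  n <- tree$n
  tau <- beliefs$tau
  te <- beliefs$tau_edge
  prior <- beliefs$prior
  omega <- theta$omega
  parent <- tree$parent

  kappa <- matrix(NA_real_, n, 2L)
  kappa[1L, ] <- 1
  levels <- tree_levels(tree)
  for (lev in levels[-1L]) {
    par <- parent[lev]
    A0 <- safe_ratio(tau[par, 1L] * kappa[par, 1L], te[lev, 1L], "downward pass (state 0)")
    A1 <- safe_ratio(tau[par, 2L] * kappa[par, 2L], te[lev, 2L], "downward pass (state 1)")
    kappa[lev, 1L] <- (A0 + (1 - omega) * A1) / prior[lev, 1L]
    kappa[lev, 2L] <- omega * A1 / prior[lev, 2L]
  }
  beliefs$kappa <- kappa
  beliefs$posterior <- tau * kappa
  beliefs
}

#' E-step expectations for the EM algorithm
#'
#' Computes, under the current parameters, the posterior expectation
#' `w_i = P(S_i = 1 | p)` for every node and, for every non-root node,
#' the expected joint indicators of (parent state, own state) being (1,1)
#' and (1,0), together with their totals `P11` and `P10`.
#'
#' @param tree a `go_tree`.
#' @param beliefs full beliefs from [downward_pass()].
#' @param theta the `hmtm_params` the beliefs were computed under.
#' @return list with `w` (length n), `E11`, `E10` (length n, `NA` at the
#'   root), and scalars `P11`, `P10`.
#' @export
e_step <- function(tree, beliefs, theta) {
  theta <- validate_params(theta)
  n <- tree$n
  w <- beliefs$posterior[, 2L]
  E11 <- rep(NA_real_, n)
  E10 <- rep(NA_real_, n)
  if (n > 1L) {
    i <- 2:n
    par <- tree$parent[i]
    den <- beliefs$prior[i, 2L] * beliefs$tau_edge[i, 2L]
    E11[i] <- safe_ratio(beliefs$tau[i, 2L] * theta$omega * w[par], den, "E-step (1,1)")
    den0 <- beliefs$prior[i, 1L] * beliefs$tau_edge[i, 2L]
    E10[i] <- safe_ratio(beliefs$tau[i, 1L] * (1 - theta$omega) * w[par], den0, "E-step (1,0)")
    vals <- c(E11[i], E10[i])
    if (any(vals < -1e-10 | vals > 1 + 1e-10)) {
      hmt_numerical_error("E-step expectation outside [0,1] beyond tolerance")
    }
    E11[i] <- pmin(pmax(E11[i], 0), 1)
    E10[i] <- pmin(pmax(E10[i], 0), 1)
  }
  list(w = w, E11 = E11, E10 = E10,
       P11 = sum(E11[-1L]), P10 = sum(E10[-1L]))
}

# box used by the M-step optimizers; edges inset so beta densities stay finite
.param_box <- list(
  alt  = list(lower = c(alpha = 1e-6, beta = 1 + 1e-6),
              upper = c(alpha = 1, beta = 1e4)),
  null = list(lower = c(lambda = 1e-6, alpha0 = 1 + 1e-6, beta0 = 1 + 1e-6),
              upper = c(lambda = 1 - 1e-6, alpha0 = 1e3, beta0 = 1e3))
)

# weighted alternative-beta negative log-likelihood via sufficient stats
fit_alt_block <- function(w, logp, log1mp, start) {
  W <- sum(w)
  s1 <- sum(w * logp)
  s2 <- sum(w * log1mp)
  nll <- function(x) -((x[1] - 1) * s1 + (x[2] - 1) * s2 - W * lbeta(x[1], x[2]))
  grad <- function(x) {
    dab <- digamma(x[1] + x[2])
    -c(s1 - W * (digamma(x[1]) - dab), s2 - W * (digamma(x[2]) - dab))
  }
  box <- .param_box$alt
  start <- pmin(pmax(start, box$lower), box$upper)
  fit <- stats::optim(start, nll, grad, method = "L-BFGS-B",
                      lower = box$lower, upper = box$upper)
  if (fit$value > nll(start) + 1e-12) return(list(par = start, improved = FALSE))
  list(par = fit$par, improved = TRUE)
}

# weighted null-mixture negative log-likelihood (numeric gradient)
fit_null_block <- function(w0, p, start) {
  nll <- function(x) {
    -sum(w0 * log(x[1] + (1 - x[1]) * stats::dbeta(p, x[2], x[3])))
  }
  box <- .param_box$null
  start <- pmin(pmax(start, box$lower), box$upper)
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = box$lower, upper = box$upper)
  if (fit$value > nll(start) + 1e-12) return(list(par = start, improved = FALSE))
  list(par = fit$par, improved = TRUE)
}

#' M-step parameter updates
#'
#' Given E-step expectations, updates `pi` to the root's smoothed
#' posterior, `omega` to `P11 / (P11 + P10)`, and re-fits the two emission
#' blocks by bounded weighted maximum likelihood (the blocks are separable
#' in the EM objective). If an optimizer fails or cannot improve its
#' block, the previous values are kept and the block is flagged.
#'
#' @param stats E-step result from [e_step()].
#' @param pvals clipped p-values.
#' @param theta_t current parameters.
#' @return list with `theta` (valid `hmtm_params`) and `flags` (character
#'   vector of blocks that fell back to previous values).
#' @export
m_step <- function(stats, pvals, theta_t) {
  p <- clip_pvalues(pvals)
  flags <- character(0)
  eps <- 1e-6
  pi_new <- min(max(stats$w[1L], eps), 1 - eps)
  denom <- stats$P11 + stats$P10
  if (length(p) > 1L && denom > 0) {
    omega_new <- min(max(stats$P11 / denom, eps), 1 - eps)
  } else {
    omega_new <- theta_t$omega
    flags <- c(flags, "omega")
  }

  w <- stats$w
  alpha_new <- theta_t$alpha; beta_new <- theta_t$beta
  if (sum(w) > 1e-8) {
    res <- tryCatch(
      fit_alt_block(w, log(p), log1p(-p), c(theta_t$alpha, theta_t$beta)),
      error = function(e) NULL)
    if (is.null(res)) flags <- c(flags, "alt") else {
      alpha_new <- unname(res$par[1]); beta_new <- unname(res$par[2])
      if (!res$improved) flags <- c(flags, "alt")
    }
  } else flags <- c(flags, "alt")

  lambda_new <- theta_t$lambda; alpha0_new <- theta_t$alpha0; beta0_new <- theta_t$beta0
  if (sum(1 - w) > 1e-8) {
    res <- tryCatch(
      fit_null_block(1 - w, p, c(theta_t$lambda, theta_t$alpha0, theta_t$beta0)),
      error = function(e) NULL)
    if (is.null(res)) flags <- c(flags, "null") else {
      lambda_new <- unname(res$par[1])
      alpha0_new <- unname(res$par[2]); beta0_new <- unname(res$par[3])
      if (!res$improved) flags <- c(flags, "null")
    }
  } else flags <- c(flags, "null")

  list(theta = hmtm_params(pi_new, omega_new, alpha_new, beta_new,
                           lambda_new, alpha0_new, beta0_new),
       flags = flags)
}

#' EM fitting control settings
#'
#' @param n_restarts number of plain-EM runs from random starting values.
#' @param max_iter maximum EM iterations per run.
#' @param tol relative log-likelihood change declaring convergence.
#' @param param_tol alternative convergence trigger: maximum absolute
#'   parameter change below this value.
#' @param seed integer seed governing every random draw of the fit.
#' @param ladder inverse-temperature schedule for the deterministic
#'   annealing run (ends at 1).
#' @param da whether to run deterministic annealing in addition to the
#'   random restarts.
#' @param da_iter EM iterations spent at each rung below temperature 1.
#' @return list of class `em_control`.
#' @export
em_control <- function(n_restarts = 20L, max_iter = 500L, tol = 1e-8,
                       param_tol = 1e-6, seed = 1L,
                       ladder = c(0.1, 0.3, 0.5, 0.8, 1.0),
                       da = TRUE, da_iter = 50L) {
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 param_tol = param_tol, seed = as.integer(seed),
                 ladder = ladder, da = da, da_iter = as.integer(da_iter)),
            class = "em_control")
}

# random starting values covering the plausible region of each parameter
random_init <- function() {
  hmtm_params(pi = stats::runif(1, 0.05, 0.95),
              omega = stats::runif(1, 0.05, 0.95),
              alpha = stats::runif(1, 0.1, 1),
              beta = stats::runif(1, 1.5, 20),
              lambda = stats::runif(1, 0.5, 1),
              alpha0 = stats::runif(1, 1.1, 5),
              beta0 = stats::runif(1, 1.1, 5))
}

param_vec <- function(theta) {
  unlist(theta[c("pi", "omega", "alpha", "beta", "lambda", "alpha0", "beta0")])
}

# one EM run at fixed inverse temperature; returns theta matching the last
# trace entry, so the reported log-likelihood belongs to the reported theta
em_run <- function(tree, p, theta, temper, max_iter, tol, param_tol) {
  trace <- numeric(0)
  flags <- character(0)
  converged <- FALSE
  for (t in seq_len(max_iter)) {
    up <- upward_pass(tree, p, theta, temper = temper)
    bel <- downward_pass(tree, up, theta)
    trace <- c(trace, up$loglik)
    st <- e_step(tree, bel, theta)
    ms <- m_step(st, p, theta)
    flags <- union(flags, ms$flags)
    dpar <- max(abs(param_vec(ms$theta) - param_vec(theta)))
    if (t > 1L) {
      dll <- abs(trace[t] - trace[t - 1L]) / (abs(trace[t - 1L]) + 1)
      if (dll < tol || dpar < param_tol) {
        converged <- TRUE
        break
      }
    }
    if (t == max_iter) break  # keep the theta matching the last trace entry
    theta <- ms$theta
  }
  list(theta = theta, trace = trace, loglik = trace[length(trace)],
       converged = converged, iterations = length(trace), flags = flags)
}

#' Fit the hidden Markov tree model by EM
#'
#' Maximum-likelihood estimation of all seven model parameters from one
#' p-value per tree node. Runs plain EM from `n_restarts` random starting
#' values plus (by default) one deterministic-annealing run in which
#' E-step responsibilities come from emission densities raised to an
#' inverse temperature climbing the `ladder` before a final untempered
#' run; the result with the largest final log-likelihood wins. All
#' randomness derives from `control$seed`, so repeated calls are
#' bit-identical.
#'
#' @param tree a `go_tree`.
#' @param pvals numeric vector of p-values, one per tree node.
#' @param control an [em_control()] list.
#' @return a `hmtree_fit` list: `theta` (the estimate), `loglik`, `trace`
#'   (log-likelihood per iteration of the winning run), `converged`,
#'   `restarts` (per-run summary data frame), `traces` (log-likelihood
#'   trace of every run), `best` (winning run index), `uninformative`
#'   (TRUE when the emission densities carry no information and the
#'   likelihood is flat in `pi` and `omega`).
#' @export
fit_em <- function(tree, pvals, control = em_control()) {
  stopifnot(inherits(tree, "go_tree"))
  p <- clip_pvalues(pvals)
  if (length(p) != tree$n) hmt_input_error("need exactly one p-value per tree node")
  set.seed(control$seed)

  runs <- list()
  for (r in seq_len(control$n_restarts)) {
    init <- random_init()
    runs[[length(runs) + 1L]] <- c(
      em_run(tree, p, init, 1, control$max_iter, control$tol, control$param_tol),
      list(type = "em", init = init))
  }
  if (isTRUE(control$da)) {
    init <- random_init()
    theta <- init
    for (g in control$ladder[control$ladder < 1]) {
      theta <- em_run(tree, p, theta, g, control$da_iter,
                      max(control$tol, 1e-6), control$param_tol)$theta
    }
    fin <- em_run(tree, p, theta, 1, control$max_iter, control$tol, control$param_tol)
    runs[[length(runs) + 1L]] <- c(fin, list(type = "da", init = init))
  }
  if (!length(runs)) hmt_input_error("no EM run requested (n_restarts = 0 and da = FALSE)")

  lls <- vapply(runs, `[[`, numeric(1), "loglik")
  best <- which.max(lls)
  bestrun <- runs[[best]]
  if (!bestrun$converged) {
    warning("no EM run converged; returning the best non-converged fit")
  }

  # flat-likelihood detection: if the two emission densities are numerically
  # identical for all observations, (pi, omega) are unidentifiable
  em <- emission_matrix(p, bestrun$theta)
  uninformative <- max(abs(log(em[, 2L]) - log(em[, 1L]))) < 1e-8
  if (uninformative) {
    warning("emission densities are identical for all p-values; the likelihood is flat in (pi, omega) and the fit is not informative")
  }

  restarts <- data.frame(
    run = seq_along(runs),
    type = vapply(runs, `[[`, character(1), "type"),
    loglik = lls,
    converged = vapply(runs, `[[`, logical(1), "converged"),
    iterations = vapply(runs, `[[`, integer(1), "iterations"),
    stringsAsFactors = FALSE)

  structure(list(theta = bestrun$theta, loglik = bestrun$loglik,
                 trace = bestrun$trace, converged = bestrun$converged,
                 flags = bestrun$flags, restarts = restarts,
                 traces = lapply(runs, `[[`, "trace"), best = best,
                 uninformative = uninformative, seed = control$seed),
            class = "hmtree_fit")
}

#' @export
print.hmtree_fit <- function(x, ...) {
  cat(sprintf("HMTM fit: log-likelihood %.4f after %d iterations (%s run %d of %d)%s\n",
              x$loglik, length(x$trace), x$restarts$type[x$best], x$best,
              nrow(x$restarts), if (x$converged) "" else " [not converged]"))
  print(x$theta)
  invisible(x)
}
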