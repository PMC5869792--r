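#' Hidden Markov tree model parameters
#'
#' Container for the seven parameters of the two-state hidden Markov tree
#' model for gene-set p-values. Hidden states are binary: state 1 means the
#' node's gene set is differentially expressed (DE), state 0 means the null
#' holds. The state process runs root-to-leaf with transition probabilities
#' `P(child = 0 | parent = 0) = 1` and `P(child = 1 | parent = 1) = omega`,
#' so a null parent forces all descendants null (logical consistency).
#' Given the states, p-values are independent with emission densities
#' `f1 = Beta(alpha, beta)` under the alternative and the empirical-null
#' mixture `f0 = lambda * Uniform + (1 - lambda) * Beta(alpha0, beta0)`
#' under the null.
#'
#' @param pi probability the root node is in state 1; in (0, 1).
#' @param omega persistence probability of state 1 along an edge; in (0, 1).
#' @param alpha,beta shapes of the alternative beta density; `alpha` in
#'   (0, 1] and `beta` in (1, Inf) guarantee a strictly decreasing p-value
#'   density for DE gene sets.
#' @param lambda uniform mixing weight of the null density; in \[0, 1\].
#' @param alpha0,beta0 shapes of the null beta component; each in (1, Inf)
#'   so the null density is unimodal with an interior mode.
#' @return An object of class `hmtm_params` (a named list), validated.
#' @seealso [validate_params()], [null_density()], [alt_density()]
#' @export
#' @examples
#' hmtm_params(pi = 0.9, omega = 0.7, alpha = 0.3, beta = 8,
#'             lambda = 1, alpha0 = 2, beta0 = 2)
hmtm_params <- function(pi, omega, alpha, beta, lambda, alpha0, beta0) {
  theta <- structure(
    list(pi = pi, omega = omega, alpha = alpha, beta = beta,
         lambda = lambda, alpha0 = alpha0, beta0 = beta0),
    class = "hmtm_params"
  )
  validate_params(theta)
}

#' Validate hidden Markov tree model parameters
#'
#' Checks every box constraint of the model and returns the parameters
#' unchanged if all hold; otherwise raises a parameter error naming the
#' offending field.
#'
#' @param theta an `hmtm_params` object or a named list with the seven
#'   fields of [hmtm_params()].
#' @return `theta`, invisibly unchanged, with class `hmtm_params`.
#' @export
validate_params <- function(theta) {
  need <- c("pi", "omega", "alpha", "beta", "lambda", "alpha0", "beta0")
  miss <- setdiff(need, names(theta))
  if (length(miss)) {
    hmt_parameter_error(paste0("missing parameter field(s): ",
                               paste(miss, collapse = ", ")))
  }
  chk <- function(ok, field, rule) {
    if (!isTRUE(ok)) {
      hmt_parameter_error(sprintf("parameter '%s' violates %s (value: %s)",
                                  field, rule, format(theta[[field]])))
    }
  }
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in need) chk(num(theta[[f]]), f, "finite scalar")
  chk(theta$pi     > 0 && theta$pi    < 1, "pi",     "(0,1)")
  chk(theta$omega  > 0 && theta$omega < 1, "omega",  "(0,1)")
  chk(theta$alpha  > 0 && theta$alpha <= 1, "alpha",  "(0,1]")
  chk(theta$beta   > 1,                     "beta",   "(1,Inf)")
  chk(theta$lambda >= 0 && theta$lambda <= 1, "lambda", "[0,1]")
  chk(theta$alpha0 > 1,                     "alpha0", "(1,Inf)")
  chk(theta$beta0  > 1,                     "beta0",  "(1,Inf)")
  if (!inherits(theta, "hmtm_params")) class(theta) <- "hmtm_params"
  theta
}

#' @export
print.hmtm_params <- function(x, ...) {
  cat("HMTM parameters:\n")
  cat(sprintf("  pi = %.6g, omega = %.6g\n", x$pi, x$omega))
  cat(sprintf("  alternative: Beta(alpha = %.6g, beta = %.6g)\n", x$alpha, x$beta))
  cat(sprintf("  null: %.6g * U(0,1) + %.6g * Beta(%.6g, %.6g)\n",
              x$lambda, 1 - x$lambda, x$alpha0, x$beta0))
  invisible(x)
}

#' Clip p-values away from 0 and 1
#'
#' Beta densities diverge at the boundary for shape parameters below 1 and
#' external tests can emit exact 0 or 1, so all incoming p-values are
#' clipped into `[eps, 1 - eps]` before any density evaluation.
#'
#' @param p numeric vector of p-values.
#' @param eps clipping margin (default `1e-15`).
#' @return clipped vector.
#' @export
clip_pvalues <- function(p, eps = 1e-15) {
  if (!is.numeric(p) || anyNA(p)) hmt_input_error("p-values must be numeric and non-missing")
  pmin(pmax(p, eps), 1 - eps)
}

#' Null p-value density
#'
#' The empirical-null mixture `lambda + (1 - lambda) * dbeta(p, alpha0,
#' beta0)`. With `lambda = 1` this is the uniform null; the beta component
#' absorbs departures from uniformity induced by correlation among
#' overlapping null gene sets.
#'
#' @param p p-values in (0, 1) (clip first with [clip_pvalues()]).
#' @param lambda,alpha0,beta0 null parameters, see [hmtm_params()].
#' @return density values, strictly positive.
#' @export
null_density <- function(p, lambda, alpha0, beta0) {
  if (lambda >= 1) rep(1, length(p)) else
    lambda + (1 - lambda) * stats::dbeta(p, alpha0, beta0)
}

#' Alternative p-value density
#'
#' `dbeta(p, alpha, beta)`; strictly decreasing on (0, 1) when
#' `alpha <= 1 < beta`, as expected of p-values from DE gene sets.
#'
#' @param p p-values in (0, 1) (clip first with [clip_pvalues()]).
#' @param alpha,beta alternative beta shapes, see [hmtm_params()].
#' @return density values.
#' @export
alt_density <- function(p, alpha, beta) {
  stats::dbeta(p, alpha, beta)
}

#' Log emission density
#'
#' Log of the state-conditional p-value density: the null mixture for
#' state 0, the alternative beta for state 1. Exists for diagnostics and
#' the brute-force enumeration oracle; the belief-propagation recursions
#' use normalized quantities and never need log-scale emissions.
#'
#' @param p p-values in (0, 1).
#' @param state 0 or 1.
#' @param theta an `hmtm_params` object.
#' @return log densities, finite for clipped p.
#' @export
log_emission <- function(p, state, theta) {
  theta <- validate_params(theta)
  if (!all(state %in% c(0, 1))) hmt_input_error("state must be 0 or 1")
  if (length(state) == 1L) state <- rep(state, length(p))
  out <- numeric(length(p))
  s0 <- state == 0
  out[s0] <- log(null_density(p[s0], theta$lambda, theta$alpha0, theta$beta0))
  out[!s0] <- log(alt_density(p[!s0], theta$alpha, theta$beta))
  out
}

# Emission matrix (n x 2) for a clipped p-value vector.
emission_matrix <- function(p, theta) {
  cbind(f0 = null_density(p, theta$lambda, theta$alpha0, theta$beta0),
        f1 = alt_density(p, theta$alpha, theta$beta))
}
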