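# Classed conditions so callers (and the command-line wrapper) can map
# failure modes to exit codes: input/structural/parameter -> 2, numerical -> 3.

hmt_stop <- function(message, class) {
  stop(structure(
    class = c(class, "hmtree_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

hmt_input_error      <- function(msg) hmt_stop(msg, "hmtree_input_error")
hmt_structural_error <- function(msg) hmt_stop(msg, c("hmtree_structural_error", "hmtree_input_error"))
hmt_parameter_error  <- function(msg) hmt_stop(msg, c("hmtree_parameter_error", "hmtree_input_error"))
hmt_numerical_error  <- function(msg) hmt_stop(msg, "hmtree_numerical_error")

#' Rank-based AUROC
#'
#' Area under the ROC curve for a score vector against binary labels,
#' computed with the Mann-Whitney identity. Larger scores are treated as
#' more likely to be positive.
#'
#' @param score numeric scores.
#' @param label binary labels (0/1 or logical).
#' @return AUROC in `[0, 1]`; `NA` if either class is empty.
#' @export
auroc <- function(score, label) {
  label <- as.integer(as.logical(label))
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
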