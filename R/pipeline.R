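# High-level pipeline commands ------------------------------------------------
#
# These functions are the package's command surface; the installed
# `exec/hmtree` script is a thin argument-parsing wrapper around them.
# Each is deterministic given its arguments (seeds live in the config,
# never the wall clock) and logs node counts and likelihoods via message().

#' Transform an edge/annotation pair into tree and map files
#'
#' Loads the DAG, transitively reduces it, transforms it to a tree and
#' writes `<out_prefix>.tree.tsv` plus `<out_prefix>.map.json`.
#'
#' @param edge_file TSV edge list (or an OBO file when `obo = TRUE`).
#' @param annotation_file TSV gene/term annotation table.
#' @param out_prefix path prefix for the two output files.
#' @param obo parse `edge_file` as a minimal is_a-only OBO subset.
#' @return invisibly, list with `tree`, `map`, `dag`.
#' @export
run_transform <- function(edge_file, annotation_file, out_prefix, obo = FALSE) {
  edges <- if (obo) read_obo_edges(edge_file) else read_edge_tsv(edge_file)
  ann <- read_annotations(annotation_file)
  dag <- load_dag(edges, ann)
  message(sprintf("[transform] DAG: %d nodes, %d edges, %d genes",
                  dag$n, nrow(dag$edges), length(dag$gene_universe)))
  tm <- transform_to_tree(dag)
  message(sprintf("[transform] tree: %d nodes (%d empty carvings dropped)",
                  tm$tree$n, length(tm$map$dropped)))
  write_tree_tsv(tm$tree, paste0(out_prefix, ".tree.tsv"))
  write_map_json(tm$map, tm$tree, paste0(out_prefix, ".map.json"))
  invisible(c(tm, list(dag = dag)))
}

#' Simulate a full synthetic dataset to files
#'
#' Generates a DAG, transforms it, simulates states and p-values on the
#' tree, and writes the DAG edge TSV, annotation TSV, tree TSV, map JSON,
#' true-state TSV, p-value TSV and a JSON record of the configuration,
#' all under `<out_prefix>.*`.
#'
#' @param config a [sim_config()].
#' @param out_prefix path prefix for output files.
#' @return invisibly, list with `dag`, `tree`, `map`, `states`, `pvalues`.
#' @export
run_simulate <- function(config, out_prefix) {
  rd <- random_dag(config)
  tm <- transform_to_tree(rd$dag)
  states <- simulate_states(tm$tree, config$theta$pi, config$theta$omega,
                            seed = config$seed + 1L)
  pv <- simulate_pvalues(states, config$theta, seed = config$seed + 2L)
  message(sprintf("[simulate] DAG %d nodes -> tree %d nodes; %d DE tree nodes",
                  rd$dag$n, tm$tree$n, sum(states)))
  utils::write.table(rd$edges, paste0(out_prefix, ".dag.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rd$annotations, paste0(out_prefix, ".annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tree_tsv(tm$tree, paste0(out_prefix, ".tree.tsv"))
  write_map_json(tm$map, tm$tree, paste0(out_prefix, ".map.json"))
  utils::write.table(
    data.frame(node_id = tm$tree$ids, state = states),
    paste0(out_prefix, ".states.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node_id = tm$tree$ids, p_value = pv),
    paste0(out_prefix, ".pvalues.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$theta <- unclass(cfg$theta)
  jsonlite::write_json(cfg, paste0(out_prefix, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dag = rd$dag, tree = tm$tree, map = tm$map,
                 states = states, pvalues = pv))
}

#' Fit the model from tree and p-value files
#'
#' Reads a tree TSV and a p-value TSV (matched by node identifier), runs
#' [fit_em()], and writes `<out_prefix>.fit.json` (estimate, trace,
#' restart table) and `<out_prefix>.beliefs.tsv` (per-node `tau1`,
#' `kappa1`, `posterior1` at the estimate).
#'
#' @param tree_file tree TSV from [run_transform()] or [run_simulate()].
#' @param pvalue_file TSV with columns `node_id`, `p_value`.
#' @param out_prefix path prefix for output files.
#' @param control an [em_control()].
#' @return invisibly, the `hmtree_fit`.
#' @export
run_fit <- function(tree_file, pvalue_file, out_prefix, control = em_control()) {
  tree <- read_tree_tsv(tree_file)
  pv <- read_pvalues(pvalue_file)
  idx <- match(tree$ids, pv$node_id)
  if (anyNA(idx)) {
    hmt_input_error(sprintf("no p-value for tree node '%s'",
                            tree$ids[which(is.na(idx))[1L]]))
  }
  p <- pv$p_value[idx]
  fit <- fit_em(tree, p, control)
  message(sprintf("[fit] %d nodes; best log-likelihood %.4f from %s run %d; converged: %s",
                  tree$n, fit$loglik, fit$restarts$type[fit$best], fit$best,
                  fit$converged))
  out <- list(theta = unclass(fit$theta), loglik = fit$loglik,
              converged = fit$converged, best = fit$best,
              seed = fit$seed, trace = fit$trace, restarts = fit$restarts)
  jsonlite::write_json(out, paste0(out_prefix, ".fit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  bel <- downward_pass(tree, upward_pass(tree, p, fit$theta), fit$theta)
  utils::write.table(
    data.frame(node_id = tree$ids,
               tau1 = bel$tau[, 2L],
               kappa1 = bel$kappa[, 2L],
               posterior1 = bel$posterior[, 2L]),
    paste0(out_prefix, ".beliefs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fit)
}

#' Compute DAG-node PDEs and a rejection report from files
#'
#' Reads a fit JSON, the tree TSV, the p-value TSV and the map JSON,
#' recomputes beliefs at the fitted parameters, converts them into one
#' PDE per original DAG term, and writes `<out_prefix>.pde.tsv`
#' (`term_id`, `pde`, `n_genes`, `n_tree_nodes`) plus
#' `<out_prefix>.rejection.json` ({threshold, n_rejected, fdr_estimate}).
#'
#' @param fit_file fit JSON from [run_fit()].
#' @param tree_file tree TSV.
#' @param pvalue_file p-value TSV.
#' @param map_file map JSON from [run_transform()].
#' @param out_prefix path prefix for output files.
#' @param threshold PDE significance threshold (default 0.99).
#' @return invisibly, list with `pde` (the table) and `rejection`.
#' @export
run_pde <- function(fit_file, tree_file, pvalue_file, map_file, out_prefix,
                    threshold = 0.99) {
  if (!file.exists(fit_file)) hmt_input_error(sprintf("fit file not found: %s", fit_file))
  fit <- jsonlite::read_json(fit_file)
  theta <- validate_params(do.call(hmtm_params,
    fit$theta[c("pi", "omega", "alpha", "beta", "lambda", "alpha0", "beta0")]))
  tree <- read_tree_tsv(tree_file)
  pv <- read_pvalues(pvalue_file)
  idx <- match(tree$ids, pv$node_id)
  if (anyNA(idx)) hmt_input_error("p-value file does not cover all tree nodes")
  p <- pv$p_value[idx]
  map <- read_map_json(map_file, tree)

  up <- upward_pass(tree, p, theta)
  cv <- conditional_c(tree, up, theta)
  tab <- pde_all_dag_nodes(map, tree, cv)
  rej <- reject_by_threshold(tab, threshold)
  message(sprintf("[pde] %d DAG terms; %d rejected at PDE >= %g; FDR estimate %s",
                  nrow(tab), rej$n_rejected, threshold,
                  if (is.na(rej$fdr_estimate)) "NA" else
                    sprintf("%.4f", rej$fdr_estimate)))
  utils::write.table(tab, paste0(out_prefix, ".pde.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rej$note <- paste(
    "FDR control is not guaranteed under dependence among overlapping gene sets;",
    "consider an FWER-controlling pre-check before interpreting rejections.")
  jsonlite::write_json(rej, paste0(out_prefix, ".rejection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pde = tab, rejection = rej))
}
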