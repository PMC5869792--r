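# Readers and writers for the tool's plain-text interchange formats -----------
#
# All tables are tab-separated with a header row, UTF-8, '.' decimal.

#' Read a parent/child edge table
#'
#' @param path TSV file with header columns `parent` and `child`.
#' @return data frame with character columns `parent`, `child`.
#' @export
read_edge_tsv <- function(path) {
  if (!file.exists(path)) hmt_input_error(sprintf("edge file not found: %s", path))
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("parent", "child") %in% names(d))) {
    hmt_input_error("edge file must have columns 'parent' and 'child'")
  }
  d[, c("parent", "child")]
}

#' Read a minimal OBO subset restricted to is_a relationships
#'
#' Parses only `[Term]` stanzas with their `id:` and `is_a:` lines; an
#' `is_a` line makes the referenced (more general) term the parent of the
#' stanza's term. Obsolete terms are skipped. All other OBO content is
#' ignored.
#'
#' @param path an OBO file.
#' @return data frame with columns `parent`, `child`.
#' @export
read_obo_edges <- function(path) {
  if (!file.exists(path)) hmt_input_error(sprintf("OBO file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  parent <- character(0)
  child <- character(0)
  cur <- NA_character_
  in_term <- FALSE
  obsolete <- FALSE
  cur_parents <- character(0)
  flush <- function() {
    if (in_term && !obsolete && !is.na(cur) && length(cur_parents)) {
      parent <<- c(parent, cur_parents)
      child <<- c(child, rep(cur, length(cur_parents)))
    }
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE; obsolete <- FALSE
      cur <- NA_character_; cur_parents <- character(0)
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE
    } else if (in_term) {
      if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "is_a:")) {
        cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
      } else if (ln == "is_obsolete: true") obsolete <- TRUE
    }
  }
  flush()
  if (!length(child)) hmt_input_error("no is_a relationships found in OBO file")
  data.frame(parent = parent, child = child, stringsAsFactors = FALSE)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV file with header columns `gene_id` and `term_id`.
#' @return data frame with character columns `gene_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) hmt_input_error(sprintf("annotation file not found: %s", path))
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("gene_id", "term_id") %in% names(d))) {
    hmt_input_error("annotation file must have columns 'gene_id' and 'term_id'")
  }
  d[, c("gene_id", "term_id")]
}

#' Read per-node p-values
#'
#' @param path TSV file with header columns `node_id` and `p_value`.
#' @return data frame with columns `node_id` (character), `p_value`
#'   (numeric); malformed numeric entries raise an input error naming the
#'   offending line.
#' @export
read_pvalues <- function(path) {
  if (!file.exists(path)) hmt_input_error(sprintf("p-value file not found: %s", path))
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("node_id", "p_value") %in% names(d))) {
    hmt_input_error("p-value file must have columns 'node_id' and 'p_value'")
  }
  pv <- suppressWarnings(as.numeric(d$p_value))
  bad <- which(is.na(pv) | pv < 0 | pv > 1)
  if (length(bad)) {
    hmt_input_error(sprintf("malformed p-value on line %d of %s: '%s'",
                            bad[1L] + 1L, path, d$p_value[bad[1L]]))
  }
  data.frame(node_id = d$node_id, p_value = pv, stringsAsFactors = FALSE)
}

#' Serialize a tree to TSV
#'
#' Writes `node_id`, `parent_id` (empty for the root), `n_genes` and the
#' comma-separated gene list per node, in node-index order.
#'
#' @param tree a `go_tree`.
#' @param path output file.
#' @export
write_tree_tsv <- function(tree, path) {
  gl <- if (is.null(tree$gene_sets)) rep("", tree$n) else
    vapply(tree$gene_sets, function(g) paste(tree$gene_universe[g], collapse = ","),
           character(1))
  d <- data.frame(node_id = tree$ids,
                  parent_id = ifelse(is.na(tree$parent), "", tree$ids[tree$parent]),
                  n_genes = if (is.null(tree$gene_sets)) 0L else lengths(tree$gene_sets),
                  gene_list = gl,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tree serialized by [write_tree_tsv()]
#'
#' @param path TSV file.
#' @return a `go_tree`.
#' @export
read_tree_tsv <- function(path) {
  if (!file.exists(path)) hmt_input_error(sprintf("tree file not found: %s", path))
  d <- utils::read.delim(path, colClasses = "character")
  need <- c("node_id", "parent_id", "n_genes", "gene_list")
  if (!all(need %in% names(d))) {
    hmt_input_error("tree file must have columns node_id, parent_id, n_genes, gene_list")
  }
  parent <- match(d$parent_id, d$node_id)
  genes <- strsplit(d$gene_list, ",", fixed = TRUE)
  genes[d$gene_list == ""] <- list(character(0))
  universe <- sort(unique(unlist(genes)))
  gs <- lapply(genes, function(g) sort(match(g, universe)))
  if (all(lengths(gs) == 0L)) { gs <- NULL; universe <- NULL }
  go_tree(parent, ids = d$node_id, gene_sets = gs, gene_universe = universe)
}

#' Write the DAG-to-tree map as JSON
#'
#' @param map a `dag_tree_map`.
#' @param tree the corresponding `go_tree`.
#' @param path output JSON file.
#' @export
write_map_json <- function(map, tree, path) {
  obj <- list(
    gt = lapply(map$gt, function(k) tree$ids[k]),
    origin = as.list(map$origin),
    dropped = map$dropped,
    n_genes = as.list(map$n_genes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
}

#' Read a DAG-to-tree map written by [write_map_json()]
#'
#' @param path JSON file.
#' @param tree the corresponding `go_tree` (to resolve node identifiers).
#' @return a `dag_tree_map`.
#' @export
read_map_json <- function(path, tree) {
  if (!file.exists(path)) hmt_input_error(sprintf("map file not found: %s", path))
  obj <- jsonlite::read_json(path)
  gt <- lapply(obj$gt, function(idv) {
    k <- match(unlist(idv), tree$ids)
    if (anyNA(k)) hmt_input_error("map references a tree node absent from the tree file")
    sort(k)
  })
  structure(list(gt = gt,
                 origin = unlist(obj$origin),
                 dropped = as.character(unlist(obj$dropped)),
                 n_genes = unlist(obj$n_genes)),
            class = "dag_tree_map")
}

#' Serialize fitted parameters to a flat JSON object
#'
#' @param theta an `hmtm_params` object.
#' @param path output JSON file.
#' @export
write_params_json <- function(theta, path) {
  theta <- validate_params(theta)
  jsonlite::write_json(unclass(theta), path, auto_unbox = TRUE, digits = NA)
}

#' Read parameters from a flat JSON object
#'
#' @param path JSON file with the seven parameter fields.
#' @return a validated `hmtm_params`.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) hmt_input_error(sprintf("parameter file not found: %s", path))
  obj <- jsonlite::read_json(path)
  validate_params(do.call(hmtm_params, obj[c("pi", "omega", "alpha", "beta",
                                             "lambda", "alpha0", "beta0")]))
}
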