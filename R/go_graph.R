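# DAG and tree containers -----------------------------------------------------
#
# A `go_dag` is the original hypothesis graph: one node per ontology term,
# directed edges from general to specific terms, and (after upward
# propagation) a gene set per node such that every edge u -> v satisfies
# G_v subset of G_u. A `go_tree` is the computation substrate: a spanning
# tree whose carved gene sets are nested along edges, with nodes re-indexed
# 1..N_T, root = 1, parents before children. Gene sets are stored as sorted
# integer indices into `gene_universe`.

new_go_dag <- function(ids, edges, gene_sets, gene_universe, direct_sets = NULL) {
  n <- length(ids)
  parents  <- vector("list", n)
  children <- vector("list", n)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) {
      hmt_structural_error("cycle detected: self-loop in edge table")
    }
    edges <- unique(edges)
    parents  <- split_indices(edges[, 1], edges[, 2], n)
    children <- split_indices(edges[, 2], edges[, 1], n)
  }
  topo <- kahn_topo_order(n, parents, children)
  roots <- which(lengths(parents) == 0L)
  if (length(roots) != 1L) {
    hmt_structural_error(sprintf(
      "expected exactly one root, found %d (%s)", length(roots),
      paste(utils::head(ids[roots], 5L), collapse = ", ")))
  }
  structure(list(ids = ids, edges = edges, parents = parents,
                 children = children, gene_sets = gene_sets,
                 direct_sets = direct_sets, gene_universe = gene_universe,
                 root = roots, topo = topo, n = n),
            class = "go_dag")
}

# values grouped by key: list of length n, element k = sorted values with key k
split_indices <- function(values, keys, n) {
  out <- rep(list(integer(0)), n)
  grp <- split(values, keys)
  out[as.integer(names(grp))] <- lapply(grp, function(x) sort(unique(x)))
  out
}

# Deterministic topological order: Kahn's algorithm taking the smallest
# available index first (ids are stored sorted, so index order is
# lexicographic id order). Raises on cycles.
kahn_topo_order <- function(n, parents, children) {
  indeg <- lengths(parents)
  avail <- which(indeg == 0L)
  topo <- integer(n)
  k <- 0L
  while (length(avail)) {
    v <- avail[1L]
    avail <- avail[-1L]
    k <- k + 1L
    topo[k] <- v
    ch <- children[[v]]
    if (length(ch)) {
      indeg[ch] <- indeg[ch] - 1L
      newly <- ch[indeg[ch] == 0L]
      if (length(newly)) avail <- sort(c(avail, newly))
    }
  }
  if (k < n) hmt_structural_error("cycle detected in term graph")
  topo
}

#' Load a term DAG with gene annotations
#'
#' Builds a `go_dag` from a parent->child edge table and a gene-to-term
#' annotation table. Annotations are propagated upward (a gene annotated to
#' a term is annotated to all its ancestors), terms left with no genes are
#' dropped, and the graph is checked to be acyclic with a single root.
#' Node ordering is lexicographic by term identifier throughout, so the
#' result is deterministic.
#'
#' @param edge_table data frame whose first two columns are parent and
#'   child term identifiers (edges run general -> specific).
#' @param annotation_table data frame whose first two columns are gene
#'   identifier and term identifier. Annotations referencing unknown terms
#'   are skipped with a warning.
#' @return A `go_dag` object.
#' @seealso [transitive_reduce()], [transform_to_tree()], [read_edge_tsv()]
#' @export
#' @examples
#' edges <- data.frame(parent = c("A", "A"), child = c("B", "C"))
#' ann <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   term_id = c("B", "C", "A"))
#' dag <- load_dag(edges, ann)
#' dag_gene_sets(dag)$A
load_dag <- function(edge_table, annotation_table) {
  if (!is.data.frame(edge_table) || nrow(edge_table) == 0L) {
    hmt_input_error("edge table must be a nonempty data frame")
  }
  if (!is.data.frame(annotation_table) || nrow(annotation_table) == 0L) {
    hmt_input_error("annotation table must be a nonempty data frame")
  }
  par <- as.character(edge_table[[1L]])
  chi <- as.character(edge_table[[2L]])
  if (anyNA(par) || anyNA(chi)) hmt_input_error("edge table contains missing identifiers")
  ids <- sort(unique(c(par, chi)))
  edges <- cbind(match(par, ids), match(chi, ids))

  gene <- as.character(annotation_table[[1L]])
  term <- as.character(annotation_table[[2L]])
  known <- term %in% ids
  if (!all(known)) {
    warning(sprintf("skipping %d annotation(s) referencing unknown term(s): %s",
                    sum(!known),
                    paste(utils::head(unique(term[!known]), 5L), collapse = ", ")))
    gene <- gene[known]
    term <- term[known]
  }
  if (!length(gene)) hmt_input_error("no annotation maps to a known term")
  gene_universe <- sort(unique(gene))
  direct <- split_indices(match(gene, gene_universe), match(term, ids), length(ids))

  dag <- new_go_dag(ids, edges, direct, gene_universe, direct_sets = direct)

  # upward propagation: children before parents
  gs <- dag$direct_sets
  for (v in rev(dag$topo)) {
    ch <- dag$children[[v]]
    if (length(ch)) gs[[v]] <- sort(unique(c(gs[[v]], unlist(gs[ch]))))
  }

  keep <- lengths(gs) > 0L
  if (!all(keep)) {
    # empty nodes form a down-closed set (gene sets only grow upward), so
    # dropping them keeps the remainder connected with the same root
    kidx <- which(keep)
    e <- dag$edges
    e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
    e <- cbind(match(e[, 1], kidx), match(e[, 2], kidx))
    dag <- new_go_dag(dag$ids[kidx], e, gs[kidx], gene_universe,
                      direct_sets = dag$direct_sets[kidx])
  } else {
    dag$gene_sets <- gs
  }
  dag
}

#' Gene sets of a DAG or tree as character vectors
#'
#' @param x a `go_dag` or `go_tree`.
#' @return named list of gene identifier vectors, one per node.
#' @export
dag_gene_sets <- function(x) {
  stats::setNames(lapply(x$gene_sets, function(g) x$gene_universe[g]), x$ids)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("Term DAG: %d nodes, %d edges, %d genes, root '%s'\n",
              x$n, nrow(x$edges), length(x$gene_universe), x$ids[x$root]))
  invisible(x)
}

# descendant index sets (excluding self), children before parents
descendant_sets <- function(n, children, topo) {
  desc <- rep(list(integer(0)), n)
  for (v in rev(topo)) {
    ch <- children[[v]]
    if (length(ch)) desc[[v]] <- sort(unique(c(ch, unlist(desc[ch]))))
  }
  desc
}

#' Transitive reduction of a term DAG
#'
#' Removes every edge u -> v for which another directed path from u to v
#' exists. Gene sets are unchanged. The reduction of a DAG is unique, and
#' a tree is returned unchanged.
#'
#' @param dag a `go_dag`.
#' @return the reduced `go_dag`.
#' @export
transitive_reduce <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  desc <- descendant_sets(dag$n, dag$children, dag$topo)
  keep <- rep(TRUE, nrow(dag$edges))
  for (u in seq_len(dag$n)) {
    ch <- dag$children[[u]]
    if (length(ch) < 2L) next
    # v is redundant under u iff v is a descendant of a sibling child
    red <- ch[ch %in% unlist(desc[ch])]
    if (length(red)) {
      keep[dag$edges[, 1] == u & dag$edges[, 2] %in% red] <- FALSE
    }
  }
  new_go_dag(dag$ids, dag$edges[keep, , drop = FALSE],
             dag$gene_sets, dag$gene_universe, direct_sets = dag$direct_sets)
}

#' Tree node container
#'
#' Constructs a `go_tree` from a parent-index vector. Node 1 must be the
#' root (parent `NA`); every other node has exactly one parent, and the
#' tree must be connected.
#'
#' @param parent integer vector; `parent[i]` is the index of node i's
#'   parent, `NA` for the root at index 1.
#' @param ids optional node identifiers (default `"T1"..."Tn"`).
#' @param gene_sets optional list of sorted integer gene indices per node.
#' @param gene_universe optional character vector the indices refer to.
#' @return a `go_tree` with children lists and depths precomputed.
#' @export
go_tree <- function(parent, ids = NULL, gene_sets = NULL, gene_universe = NULL) {
  n <- length(parent)
  if (n < 1L) hmt_input_error("tree must have at least one node")
  if (!is.na(parent[1L]) || sum(is.na(parent)) != 1L) {
    hmt_structural_error("tree root must be node 1 and the only parentless node")
  }
  parent <- as.integer(parent)
  if (n > 1L && any(parent[-1L] < 1L | parent[-1L] > n, na.rm = TRUE)) {
    hmt_input_error("parent indices out of range")
  }
  children <- rep(list(integer(0)), n)
  if (n > 1L) {
    grp <- split(2:n, parent[-1L])
    children[as.integer(names(grp))] <- lapply(grp, as.integer)
  }
  depth <- rep(NA_integer_, n)
  depth[1L] <- 0L
  frontier <- 1L
  while (length(frontier)) {
    nxt <- unlist(children[frontier])
    if (!length(nxt)) break
    depth[nxt] <- depth[parent[nxt]] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) hmt_structural_error("tree is not connected to the root")
  if (is.null(ids)) ids <- paste0("T", seq_len(n))
  structure(list(ids = ids, parent = parent, children = children,
                 depth = depth, gene_sets = gene_sets,
                 gene_universe = gene_universe, n = n),
            class = "go_tree")
}

#' @export
print.go_tree <- function(x, ...) {
  cat(sprintf("Term tree: %d nodes, depth %d, root '%s'\n",
              x$n, max(x$depth), x$ids[1L]))
  invisible(x)
}

#' Transform a term DAG into a tree of carved gene sets
#'
#' Deterministically converts a `go_dag` into a spanning `go_tree` plus
#' the DAG-to-tree node map needed to recover DAG-level probabilities
#' later. The DAG is transitively reduced first (a no-op when already
#' reduced). For each multi-parent node the incoming edge from the parent
#' with the largest gene set is retained (ties broken by lexicographically
#' smallest identifier); severing an edge corresponds to removing the
#' child's genes from the abandoned parent. Each tree node's carved gene
#' set is the union of the direct (unpropagated) annotations over its tree
#' subtree, which makes the sets nested along tree edges and guarantees
#' that every DAG gene set is reconstructed exactly as the union of the
#' carved sets over `GT_j`, the tree nodes whose gene sets are subsets of
#' `G_j`: any gene of `G_j` is directly annotated to some DAG descendant
#' d of j, and d's tree node both contains the gene and is a subset of
#' `G_j`. Nodes whose carved set is empty are deleted with their children
#' re-parented. The reconstruction identity is still asserted for every
#' DAG node, and a failure is a hard error.
#'
#' @param dag a `go_dag`.
#' @return list with components `tree` (a `go_tree`) and `map` (a
#'   `dag_tree_map` with fields `gt`, the per-DAG-term integer vector of
#'   tree node indices; `origin`, the DAG term each tree node was carved
#'   from; `dropped`, DAG terms whose carved set vanished; `n_genes`,
#'   DAG-term gene counts).
#' @export
transform_to_tree <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  dag <- transitive_reduce(dag)
  n <- dag$n
  G <- dag$gene_sets

  # parent retention: largest gene set, ties to smallest identifier (= index)
  tree_parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    ps <- dag$parents[[v]]
    if (length(ps) == 0L) next
    tree_parent[v] <- ps[order(-lengths(G[ps]), ps)][1L]
  }

  # genes first contributed at each node: direct annotations where known,
  # otherwise genes absent from every child's (propagated) set
  own <- dag$direct_sets
  if (is.null(own)) {
    own <- lapply(seq_len(n), function(v) {
      ch <- dag$children[[v]]
      if (length(ch)) setdiff(G[[v]], unlist(G[ch])) else G[[v]]
    })
  }

  # carved gene set = union of direct annotations over the tree subtree,
  # accumulated children-before-parents
  tree_children <- rep(list(integer(0)), n)
  for (v in seq_len(n)) {
    if (!is.na(tree_parent[v])) {
      tree_children[[tree_parent[v]]] <- c(tree_children[[tree_parent[v]]], v)
    }
  }
  Tset <- vector("list", n)
  for (v in rev(dag$topo)) {
    Tset[[v]] <- sort(unique(c(own[[v]], unlist(Tset[tree_children[[v]]]))))
  }

  # delete empty carvings; children re-parent to the nearest kept ancestor
  kept <- lengths(Tset) > 0L
  eff_parent <- function(v) {
    p <- tree_parent[v]
    while (!is.na(p) && !kept[p]) p <- tree_parent[p]
    p
  }
  kidx <- dag$topo[kept[dag$topo]]  # kept nodes in topological order, root first
  new_index <- rep(NA_integer_, n)
  new_index[kidx] <- seq_along(kidx)
  parent_new <- vapply(kidx, function(v) {
    p <- eff_parent(v)
    if (is.na(p)) NA_integer_ else new_index[p]
  }, integer(1))

  tree <- go_tree(parent_new, ids = dag$ids[kidx],
                  gene_sets = Tset[kidx], gene_universe = dag$gene_universe)

  # GT_j = {k : T_k subset of G_j}. T_k is a subset of G_j exactly when the
  # count of G_j's genes falling in T_k equals |T_k|, so one pass of
  # tabulate() over the gene -> tree-node containment index settles every
  # tree node for a given j.
  nt <- tree$n
  g2t <- split_indices(rep(seq_len(nt), lengths(tree$gene_sets)),
                       unlist(tree$gene_sets), length(dag$gene_universe))
  tlen <- lengths(tree$gene_sets)
  gt <- vector("list", n)
  for (j in seq_len(n)) {
    cnt <- tabulate(unlist(g2t[G[[j]]], use.names = FALSE), nt)
    k <- which(cnt == tlen)
    gt[[j]] <- k
    # union reconstruction: GT_j is down-closed in the tree, so its union
    # equals the union over its maximal subtree roots, each of which
    # already aggregates its descendants' genes
    km <- k[!(tree$parent[k] %in% k)]
    ncov <- length(unique(unlist(tree$gene_sets[km], use.names = FALSE)))
    if (ncov != length(G[[j]])) {
      hmt_structural_error(sprintf(
        "union reconstruction failed for DAG node '%s': %d gene(s) uncovered",
        dag$ids[j], length(G[[j]]) - ncov))
    }
  }

  map <- structure(
    list(gt = stats::setNames(gt, dag$ids),
         origin = stats::setNames(dag$ids[kidx], tree$ids),
         dropped = dag$ids[!kept],
         n_genes = stats::setNames(lengths(G), dag$ids)),
    class = "dag_tree_map")
  list(tree = tree, map = map)
}

#' @export
print.dag_tree_map <- function(x, ...) {
  cat(sprintf("DAG-tree map: %d DAG terms -> %d tree nodes (%d empty carvings dropped)\n",
              length(x$gt), length(x$origin), length(x$dropped)))
  invisible(x)
}
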