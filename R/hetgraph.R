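# Heterogeneous patient-drug-procedure graph data model.
#
# A het_graph holds three typed node sets (P = patients, D = drugs,
# O = procedures) and four directed relations (P-D, D-P, P-O, O-P) as binary
# sparse adjacency matrices. The P-D/D-P (and P-O/O-P) pairs are stored
# independently: real EHR extracts report unequal counts in the two
# directions, and both are kept verbatim.

RELATIONS <- c("P-D", "D-P", "P-O", "O-P")

as_edge_df <- function(x, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(data.frame(src = character(0), dst = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop(sprintf("%s must have two columns", what))
    out <- data.frame(src = as.character(x[[1]]), dst = as.character(x[[2]]),
                      stringsAsFactors = FALSE)
  } else if (is.list(x)) {
    out <- data.frame(src = vapply(x, function(e) as.character(e[[1]]), ""),
                      dst = vapply(x, function(e) as.character(e[[2]]), ""),
                      stringsAsFactors = FALSE)
  } else {
    stop(sprintf("cannot interpret %s as an edge list", what))
  }
  if (any(!nzchar(out$src)) || any(!nzchar(out$dst))) {
    stop(sprintf("%s contains empty identifiers", what))
  }
  out
}

binary_sparse <- function(src_idx, dst_idx, dims) {
  if (length(src_idx) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = dims))
  }
  A <- Matrix::sparseMatrix(i = src_idx, j = dst_idx, x = 1, dims = dims)
  A@x[] <- 1  # collapse duplicate edges to a single binary entry
  A
}

#' Build a heterogeneous patient-drug-procedure graph
#'
#' Assembles the typed node sets and the four directed relation adjacency
#' matrices (`P-D`, `D-P`, `P-O`, `O-P`) from edge lists. Node index spaces
#' are the sorted unique identifiers per type; duplicate edge rows collapse to
#' a single binary adjacency entry. When `dp_edges`/`op_edges` are omitted
#' they default to the transposes of `pd_edges`/`po_edges`; asymmetric
#' directed counts are supported by passing them explicitly.
#'
#' @param pd_edges patient-drug edges: a two-column data frame/matrix
#'   (`patient_id`, `drug_id`) or a list of length-2 vectors.
#' @param po_edges patient-procedure edges, same formats.
#' @param dp_edges,op_edges optional reverse-direction edges
#'   (`drug_id`, `patient_id`) and (`procedure_id`, `patient_id`).
#' @param patients,drugs,procedures optional explicit identifier vectors;
#'   identifiers appearing in edges are added automatically. Use these to
#'   include isolated nodes.
#' @return An object of class `het_graph` with elements `nodes` (named list of
#'   identifier vectors for P, D, O) and `adj` (named list of binary sparse
#'   relation matrices).
#' @examples
#' g <- het_graph(pd_edges = data.frame(p = c("p1", "p2", "p3"),
#'                                      d = c("d1", "d1", "d2")),
#'                po_edges = data.frame(p = "p1", o = "o1"))
#' graph_stats(g)
#' @export
het_graph <- function(pd_edges = NULL, po_edges = NULL,
                      dp_edges = NULL, op_edges = NULL,
                      patients = NULL, drugs = NULL, procedures = NULL) {
  pd <- as_edge_df(pd_edges, "pd_edges")
  po <- as_edge_df(po_edges, "po_edges")
  dp <- if (is.null(dp_edges)) data.frame(src = pd$dst, dst = pd$src,
                                          stringsAsFactors = FALSE)
        else as_edge_df(dp_edges, "dp_edges")
  op <- if (is.null(op_edges)) data.frame(src = po$dst, dst = po$src,
                                          stringsAsFactors = FALSE)
        else as_edge_df(op_edges, "op_edges")

  P <- sort(unique(c(pd$src, po$src, dp$dst, op$dst, as.character(patients))))
  D <- sort(unique(c(pd$dst, dp$src, as.character(drugs))))
  O <- sort(unique(c(po$dst, op$src, as.character(procedures))))
  if (length(P) == 0L) stop("no patients")

  adj <- list(
    `P-D` = binary_sparse(match(pd$src, P), match(pd$dst, D),
                          c(length(P), length(D))),
    `D-P` = binary_sparse(match(dp$src, D), match(dp$dst, P),
                          c(length(D), length(P))),
    `P-O` = binary_sparse(match(po$src, P), match(po$dst, O),
                          c(length(P), length(O))),
    `O-P` = binary_sparse(match(op$src, O), match(op$dst, P),
                          c(length(O), length(P)))
  )
  structure(list(nodes = list(P = P, D = D, O = O), adj = adj),
            class = "het_graph")
}

#' @export
print.het_graph <- function(x, ...) {
  cat("Heterogeneous patient-drug-procedure graph\n")
  cat(sprintf("  nodes: %d patients, %d drugs, %d procedures\n",
              length(x$nodes$P), length(x$nodes$D), length(x$nodes$O)))
  for (r in RELATIONS) {
    cat(sprintf("  %s edges: %d\n", r, length(x$adj[[r]]@x)))
  }
  invisible(x)
}

#' Define a meta-path
#'
#' A meta-path is an alternating sequence of node types used as a semantic
#' template, e.g. `P-D-P` ("patients sharing a drug"). Only paths that start
#' and end at patients and whose consecutive types are connected by a schema
#' relation are accepted.
#'
#' @param types character vector of node types, e.g. `c("P","D","P")`, or a
#'   single dash-separated string `"P-D-P"`.
#' @return An object of class `metapath` with `types` and the implied
#'   `relations` sequence.
#' @export
metapath <- function(types) {
  if (length(types) == 1L && grepl("-", types)) {
    types <- strsplit(types, "-", fixed = TRUE)[[1]]
  }
  types <- toupper(as.character(types))
  if (length(types) < 3L || types[1] != "P" || types[length(types)] != "P") {
    stop("unsupported meta-path")
  }
  rels <- paste(types[-length(types)], types[-1], sep = "-")
  if (!all(rels %in% RELATIONS)) stop("unsupported meta-path")
  structure(list(types = types, relations = rels), class = "metapath")
}

#' @export
print.metapath <- function(x, ...) {
  cat("Meta-path:", paste(x$types, collapse = "-"), "\n")
  invisible(x)
}

as_metapath <- function(path) {
  if (inherits(path, "metapath")) path else metapath(path)
}

# Integer-weighted product of the relation matrices along a meta-path;
# entry (i, j) counts the walks from patient i to patient j.
metapath_product <- function(graph, path) {
  path <- as_metapath(path)
  M <- graph$adj[[path$relations[1]]]
  for (r in path$relations[-1]) M <- M %*% graph$adj[[r]]
  M
}

#' Compose a meta-path adjacency matrix
#'
#' Multiplies the relation adjacency matrices along the meta-path and applies
#' binary normalization: entry (i, j) is 1 iff at least one meta-path instance
#' connects patient i to patient j with i != j. The diagonal is zeroed - the
#' auxiliary patient graphs link two *distinct* patients sharing a drug or
#' procedure.
#'
#' @param graph a [het_graph()].
#' @param path a [metapath()] (or character spec accepted by it).
#' @return A binary sparse patient-by-patient matrix.
#' @export
compose_metapath <- function(graph, path) {
  M <- metapath_product(graph, path)
  Matrix::diag(M) <- 0
  M <- Matrix::drop0(M)
  if (length(M@x)) M@x[] <- 1
  M
}

#' Count meta-path instances
#'
#' Counts ordered walks following the meta-path with distinct patient
#' endpoints. Each choice of intermediate nodes is a distinct instance
#' (multiplicity counted); self-walks (equal endpoints) are excluded. Equals
#' the sum of off-diagonal entries of the unbinarized relation-matrix product.
#'
#' @inheritParams compose_metapath
#' @return A non-negative count.
#' @export
count_metapath_instances <- function(graph, path) {
  M <- metapath_product(graph, path)
  sum(M) - sum(Matrix::diag(M))
}

# Undirected union of all relations as an adjacency list over the unified
# node index space: patients 1..nP, drugs nP+1..nP+nD, procedures after that.
union_adjlist <- function(graph) {
  nP <- length(graph$nodes$P); nD <- length(graph$nodes$D)
  nO <- length(graph$nodes$O)
  pd <- (graph$adj[["P-D"]] + Matrix::t(graph$adj[["D-P"]])) != 0
  po <- (graph$adj[["P-O"]] + Matrix::t(graph$adj[["O-P"]])) != 0
  pd <- methods::as(pd, "TsparseMatrix")
  po <- methods::as(po, "TsparseMatrix")
  src <- c(pd@i + 1L, nP + pd@j + 1L, po@i + 1L, nP + nD + po@j + 1L)
  dst <- c(nP + pd@j + 1L, pd@i + 1L, nP + nD + po@j + 1L, po@i + 1L)
  n <- nP + nD + nO
  adjlist <- split(dst, factor(src, levels = seq_len(n)))
  names(adjlist) <- NULL
  adjlist
}

# Breadth-first level sets from unified index `v0`: a list whose k-th element
# holds the unified indices at shortest-path distance exactly k (up to k_max).
bfs_levels <- function(adjlist, v0, k_max) {
  n <- length(adjlist)
  dist <- rep.int(-1L, n)
  dist[v0] <- 0L
  frontier <- v0
  levels <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    if (length(frontier) == 0L) { levels[[k]] <- integer(0); next }
    nxt <- unique(unlist(adjlist[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] < 0L]
    dist[nxt] <- k
    levels[[k]] <- sort(nxt)
    frontier <- nxt
  }
  levels
}

node_unified_index <- function(graph, type, id) {
  type <- toupper(type)
  if (!type %in% c("P", "D", "O")) stop("node not found")
  pos <- match(id, graph$nodes[[type]])
  if (is.na(pos)) stop("node not found")
  off <- switch(type, P = 0L, D = length(graph$nodes$P),
                O = length(graph$nodes$P) + length(graph$nodes$D))
  off + pos
}

unified_to_ref <- function(graph, idx) {
  nP <- length(graph$nodes$P); nD <- length(graph$nodes$D)
  type <- ifelse(idx <= nP, "P", ifelse(idx <= nP + nD, "D", "O"))
  id <- character(length(idx))
  id[type == "P"] <- graph$nodes$P[idx[type == "P"]]
  id[type == "D"] <- graph$nodes$D[idx[type == "D"] - nP]
  id[type == "O"] <- graph$nodes$O[idx[type == "O"] - nP - nD]
  data.frame(type = type, id = id, stringsAsFactors = FALSE)
}

#' Exact k-hop neighbourhood
#'
#' Returns the set of nodes at shortest-path distance exactly `k` from node
#' `v`, with distances computed by breadth-first search on the undirected
#' union of all relations.
#'
#' @param graph a [het_graph()].
#' @param type node type of `v`: `"P"`, `"D"` or `"O"`.
#' @param id node identifier of `v`.
#' @param k hop distance (>= 1).
#' @return A data frame with columns `type` and `id` (possibly zero rows).
#' @export
khop_neighborhood <- function(graph, type, id, k) {
  stopifnot(k >= 1)
  v0 <- node_unified_index(graph, type, id)
  lv <- bfs_levels(union_adjlist(graph), v0, as.integer(k))
  unified_to_ref(graph, lv[[k]])
}

#' Structural statistics of a heterogeneous graph
#'
#' Node counts per type, directed edge counts per relation, meta-path instance
#' counts for P-D-P, P-O-P and P-D-P-O-P, and the bipartite sparsity
#' `1 - (E_PD + E_DP + E_PO + E_OP) / (2 |P| (|D| + |O|))`.
#'
#' @param graph a [het_graph()].
#' @param metapaths if `TRUE` (default) also count P-D-P, P-O-P and
#'   P-D-P-O-P meta-path instances; disable on very large graphs where the
#'   composed products are expensive.
#' @return An object of class `het_graph_stats` (a list of the fields above).
#' @export
graph_stats <- function(graph, metapaths = TRUE) {
  nc <- vapply(graph$nodes, length, 0L)
  ec <- vapply(RELATIONS, function(r) length(graph$adj[[r]]@x), 0L)
  sparsity <- sparsity_from_counts(nc[["P"]], nc[["D"]], nc[["O"]],
                                   ec[["P-D"]], ec[["D-P"]],
                                   ec[["P-O"]], ec[["O-P"]])
  mp <- if (metapaths) {
    c(`P-D-P` = count_metapath_instances(graph, "P-D-P"),
      `P-O-P` = count_metapath_instances(graph, "P-O-P"),
      `P-D-P-O-P` = count_metapath_instances(graph, "P-D-P-O-P"))
  } else {
    numeric(0)
  }
  structure(list(node_counts = nc, edge_counts = ec,
                 metapath_instances = mp, sparsity = sparsity),
            class = "het_graph_stats")
}

#' Bipartite sparsity from printed structural counts
#'
#' `1 - (E_PD + E_DP + E_PO + E_OP) / (2 |P| (|D| + |O|))`: the fraction of
#' absent entries over the four directed patient-drug/procedure relation
#' matrices. (The directed edge space has `|P| (|D| + |O|)` cells per
#' direction, hence the factor 2.)
#'
#' @param n_p,n_d,n_o node counts.
#' @param e_pd,e_dp,e_po,e_op directed edge counts.
#' @return Sparsity in `[0, 1]` (1, with a warning, when there are no drug or
#'   procedure nodes).
#' @export
sparsity_from_counts <- function(n_p, n_d, n_o, e_pd, e_dp, e_po, e_op) {
  denom <- 2 * n_p * (n_d + n_o)
  if (denom == 0) {
    warning("graph has no drug or procedure nodes; sparsity reported as 1")
    return(1)
  }
  1 - (e_pd + e_dp + e_po + e_op) / denom
}

#' @export
print.het_graph_stats <- function(x, ...) {
  cat("Heterogeneous graph statistics\n")
  cat(sprintf("  nodes     P: %d  D: %d  O: %d\n",
              x$node_counts[["P"]], x$node_counts[["D"]], x$node_counts[["O"]]))
  cat("  edges    ", paste(sprintf("%s: %d", names(x$edge_counts),
                                   x$edge_counts), collapse = "  "), "\n")
  if (length(x$metapath_instances)) {
    cat("  meta-path instances ",
        paste(sprintf("%s: %.0f", names(x$metapath_instances),
                      x$metapath_instances), collapse = "  "), "\n")
  }
  cat(sprintf("  sparsity  %.4f\n", x$sparsity))
  invisible(x)
}
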