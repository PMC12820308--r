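# Shared fixtures and independent oracles. Everything here is deliberately
# naive (explicit enumeration, dense arithmetic) so it cannot share a bug with
# the implementation it checks.

# Small chain graph p1-d1-p2-d2-p3 used in several k-hop examples.
chain_graph <- function() {
  het_graph(pd_edges = data.frame(src = c("p1", "p2", "p2", "p3"),
                                  dst = c("d1", "d1", "d2", "d2")),
            po_edges = NULL)
}

# Toy: p1 and p2 share d1; p3 has its own d2; p1 has procedure o1.
shared_drug_graph <- function() {
  het_graph(pd_edges = data.frame(src = c("p1", "p2", "p3"),
                                  dst = c("d1", "d1", "d2")),
            po_edges = data.frame(src = "p1", dst = "o1"))
}

# Random heterogeneous graph with <= 12 nodes. transpose_consistent = TRUE
# derives D-P/O-P as transposes; otherwise they are drawn independently.
random_het_graph <- function(seed, transpose_consistent = TRUE) {
  set.seed(seed)
  nP <- sample(2:5, 1); nD <- sample(1:4, 1); nO <- sample(1:3, 1)
  pid <- paste0("p", seq_len(nP)); did <- paste0("d", seq_len(nD))
  oid <- paste0("o", seq_len(nO))
  rnd_edges <- function(src, dst, p = 0.4) {
    grid <- expand.grid(src = src, dst = dst, stringsAsFactors = FALSE)
    grid[runif(nrow(grid)) < p, , drop = FALSE]
  }
  pd <- rnd_edges(pid, did)
  po <- rnd_edges(pid, oid)
  dp <- if (transpose_consistent) NULL else rnd_edges(did, pid)
  op <- if (transpose_consistent) NULL else rnd_edges(oid, pid)
  het_graph(pd_edges = pd, po_edges = po, dp_edges = dp, op_edges = op,
            patients = pid, drugs = did, procedures = oid)
}

# Exhaustive walk enumeration along a meta-path: returns the patient-pair
# reachability matrix (with multiplicities) by literally following edges.
walk_enumeration <- function(graph, types) {
  rels <- paste(types[-length(types)], types[-1], sep = "-")
  A <- lapply(graph$adj, function(m) as.matrix(m))
  nP <- length(graph$nodes$P)
  counts <- matrix(0, nP, nP)
  walk <- function(cur, depth) {
    if (depth > length(rels)) return(cur)
    nxt <- which(A[[rels[depth]]][cur, ] == 1)
    unlist(lapply(nxt, walk, depth = depth + 1L))
  }
  for (i in seq_len(nP)) {
    ends <- walk(i, 1L)
    for (j in ends) counts[i, j] <- counts[i, j] + 1
  }
  counts
}

# Breadth-first distance oracle on the undirected union of relations, via
# igraph when available (independent of the package's own BFS).
union_distances_oracle <- function(graph) {
  nP <- length(graph$nodes$P); nD <- length(graph$nodes$D)
  nO <- length(graph$nodes$O)
  pd <- as.matrix((graph$adj[["P-D"]] + Matrix::t(graph$adj[["D-P"]])) != 0)
  po <- as.matrix((graph$adj[["P-O"]] + Matrix::t(graph$adj[["O-P"]])) != 0)
  n <- nP + nD + nO
  adj <- matrix(0, n, n)
  if (nD) {
    adj[seq_len(nP), nP + seq_len(nD)] <- pd
    adj[nP + seq_len(nD), seq_len(nP)] <- t(pd)
  }
  if (nO) {
    adj[seq_len(nP), nP + nD + seq_len(nO)] <- po
    adj[nP + nD + seq_len(nO), seq_len(nP)] <- t(po)
  }
  if (requireNamespace("igraph", quietly = TRUE)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::distances(g)
  } else {
    # Floyd-Warshall fallback
    D <- ifelse(adj > 0, 1, Inf); diag(D) <- 0
    for (k in seq_len(n)) for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
    D
  }
}

# Dense scalar-loop softmax used as the attention arithmetic oracle.
softmax_oracle <- function(x) {
  out <- x
  for (i in seq_len(nrow(x))) {
    e <- exp(x[i, ] - max(x[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

# Central-difference gradient of f at params[[nm]][i].
numeric_grad <- function(f, params, nm, i, h = 1e-5) {
  p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + h
  p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - h
  (f(p1) - f(p2)) / (2 * h)
}

# Tiny single-patient sampled batch built by hand (B = 1).
manual_batch <- function(idx, mask, patient = 1L) {
  K <- nrow(idx); L <- ncol(idx)
  structure(list(patients = patient,
                 idx = array(idx, c(1L, K, L)),
                 mask = array(mask, c(1L, K, L)),
                 type = array(1L, c(1L, K, L)),
                 k_max = K, per_hop = L),
            class = "sampled_batch")
}
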