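# Meta-path-guided fixed-width k-hop neighbour sampling.
#
# For every patient in a mini-batch we draw `per_hop` neighbours uniformly
# WITH replacement from the exact-k-hop frontier, for each hop 1..k_max.
# Expansion follows the meta-path templates (patients expand to drugs or
# procedures, drugs/procedures expand back to patients), which on this
# tripartite schema coincides with breadth-first shortest-path level sets on
# the undirected union of relations; hop parity (odd hops D/O, even hops P)
# follows automatically. Empty frontiers leave all slots at that hop masked.

# Deterministic 32-bit sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, salt) {
  x <- (as.numeric(seed) %% 2147483647) * 69069 + as.numeric(salt) * 7919
  as.integer(x %% 2147483629) + 1L
}

#' Sampler configuration
#'
#' @param k_max maximum hop distance (default 4).
#' @param per_hop fixed number of neighbours drawn (with replacement) per hop
#'   (default 32).
#' @param batch_size mini-batch size in patient nodes (default 256).
#' @param seed integer seed controlling shuffling and neighbour draws.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(k_max = 4L, per_hop = 32L, batch_size = 256L,
                           seed = 1L) {
  stopifnot(k_max >= 1, per_hop >= 1, batch_size >= 1)
  structure(list(k_max = as.integer(k_max), per_hop = as.integer(per_hop),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "sampler_config")
}

# Precompute BFS level sets (unified indices) for the given patients.
patient_frontiers <- function(graph, patients, k_max,
                              adjlist = union_adjlist(graph)) {
  lapply(patients, function(p) bfs_levels(adjlist, p, k_max))
}

unified_type_code <- function(graph, idx) {
  nP <- length(graph$nodes$P); nD <- length(graph$nodes$D)
  ifelse(idx <= nP, 1L, ifelse(idx <= nP + nD, 2L, 3L))
}

# Draw one patient's fixed-width neighbour arrays from its frontier list.
draw_khop_row <- function(frontiers, k_max, per_hop) {
  idx <- matrix(1L, k_max, per_hop)
  mask <- matrix(FALSE, k_max, per_hop)
  for (k in seq_len(k_max)) {
    fr <- frontiers[[k]]
    if (length(fr) == 0L) next
    idx[k, ] <- fr[sample.int(length(fr), per_hop, replace = TRUE)]
    mask[k, ] <- TRUE
  }
  list(idx = idx, mask = mask)
}

#' Sample one patient's k-hop neighbourhood
#'
#' Draws `per_hop` members uniformly with replacement from the exact-k-hop
#' frontier for each hop `1..k_max`; hops with an empty frontier are fully
#' masked. Deterministic given (graph, patient, config seed).
#'
#' @param graph a [het_graph()].
#' @param v patient: an index into `graph$nodes$P` or a patient identifier.
#' @param config a [sampler_config()].
#' @return A list with `idx` (k_max x per_hop matrix of unified node indices),
#'   `mask` (parallel logical matrix, TRUE where a slot holds a real
#'   neighbour) and `type` (1 = P, 2 = D, 3 = O; meaningful where masked TRUE).
#' @export
sample_khop <- function(graph, v, config = sampler_config()) {
  if (is.character(v)) v <- match(v, graph$nodes$P)
  if (is.na(v) || v < 1L || v > length(graph$nodes$P)) stop("node not found")
  fr <- bfs_levels(union_adjlist(graph), as.integer(v), config$k_max)
  set.seed(derive_seed(config$seed, v))
  row <- draw_khop_row(fr, config$k_max, config$per_hop)
  row$type <- matrix(unified_type_code(graph, row$idx),
                     config$k_max, config$per_hop)
  row
}

# Assemble a sampled_batch for a chunk of patient indices from precomputed
# frontiers. Arrays are (B x k_max x per_hop).
build_batch <- function(graph, chunk, frontiers, config, seed) {
  B <- length(chunk); K <- config$k_max; L <- config$per_hop
  idx <- array(1L, c(B, K, L))
  mask <- array(FALSE, c(B, K, L))
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, chunk[b]))
    row <- draw_khop_row(frontiers[[b]], K, L)
    idx[b, , ] <- row$idx
    mask[b, , ] <- row$mask
  }
  structure(list(patients = chunk, idx = idx, mask = mask,
                 type = array(unified_type_code(graph, idx), c(B, K, L)),
                 k_max = K, per_hop = L),
            class = "sampled_batch")
}

#' Assemble shuffled mini-batches of sampled k-hop neighbourhoods
#'
#' Shuffles the patients by seed, partitions them into chunks of
#' `batch_size` (the last chunk may be smaller), and materializes each chunk's
#' fixed-width neighbour arrays. Neighbour draws are refreshed per `epoch`
#' (seed offset) so subgraphs are rebuilt dynamically while staying
#' reproducible.
#'
#' @param graph a [het_graph()].
#' @param patients integer indices into `graph$nodes$P`.
#' @param config a [sampler_config()].
#' @param epoch non-negative integer used as a seed offset for per-epoch
#'   resampling.
#' @param frontiers optional precomputed [patient_frontiers()] for ALL
#'   patients of the graph (indexed by patient), to avoid repeated BFS.
#' @return A list of `sampled_batch` objects.
#' @export
make_batches <- function(graph, patients, config = sampler_config(),
                         epoch = 0L, frontiers = NULL) {
  stopifnot(length(patients) > 0L)
  patients <- as.integer(patients)
  if (is.null(frontiers)) {
    adjlist <- union_adjlist(graph)
    fr_all <- patient_frontiers(graph, patients, config$k_max, adjlist)
    names(fr_all) <- as.character(patients)
  } else {
    fr_all <- frontiers[as.character(patients)]
  }
  epoch_seed <- derive_seed(config$seed, 1000003 + epoch)
  set.seed(epoch_seed)
  ord <- sample.int(length(patients))
  shuffled <- patients[ord]
  chunks <- split(shuffled, ceiling(seq_along(shuffled) / config$batch_size))
  lapply(chunks, function(ch) {
    build_batch(graph, ch, fr_all[as.character(ch)], config, epoch_seed)
  })
}
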