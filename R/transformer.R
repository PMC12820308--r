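# K-hop hierarchical transformer encoder.
#
# Per hop, the fixed-width neighbour sequence passes through that hop's own
# one-layer Transformer encoder (masked multi-head self-attention +
# position-wise feed-forward, residual + per-row normalization). A hop-level
# attention between the target patient embedding and the encoded neighbours
# aggregates each hop into z_v^(k); the length-K hop sequence is then
# contextualized by a hierarchical Transformer layer and fused by multi-head
# hop attention with a residual on the target embedding, followed by an output
# projection.
#
# All forward code below is written on the autodiff ops, so the same functions
# serve plain-matrix inference and tape-recorded training.

mat_init <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

tx_layer_params <- function(d, H, ff, pfx, sd) {
  dh <- d %/% H
  p <- list()
  for (m in seq_len(H)) {
    p[[paste0(pfx, "_h", m, "_Wq")]] <- mat_init(d, dh, sd)
    p[[paste0(pfx, "_h", m, "_Wk")]] <- mat_init(d, dh, sd)
    p[[paste0(pfx, "_h", m, "_Wv")]] <- mat_init(d, dh, sd)
  }
  p[[paste0(pfx, "_Wo")]] <- mat_init(d, d, sd)
  p[[paste0(pfx, "_ln1g")]] <- matrix(1, 1, d)
  p[[paste0(pfx, "_ln1b")]] <- matrix(0, 1, d)
  p[[paste0(pfx, "_W1")]] <- mat_init(d, ff, sd)
  p[[paste0(pfx, "_b1")]] <- matrix(0, 1, ff)
  p[[paste0(pfx, "_W2")]] <- mat_init(ff, d, 1 / sqrt(ff))
  p[[paste0(pfx, "_b2")]] <- matrix(0, 1, d)
  p[[paste0(pfx, "_ln2g")]] <- matrix(1, 1, d)
  p[[paste0(pfx, "_ln2b")]] <- matrix(0, 1, d)
  p
}

#' Initialize k-hop transformer encoder parameters
#'
#' Creates the learnable weights of the encoder branch: a shared node
#' embedding table (the datasets carry no intrinsic node attributes, so
#' initial features are a seeded-normal learnable embedding per node), one
#' intra-hop Transformer encoder layer per hop, the hop-level attention
#' projections, the hierarchical Transformer layer over the hop sequence, the
#' multi-head hop-fusion projections, and the output projection.
#'
#' @param n_nodes total number of nodes (patients + drugs + procedures).
#' @param d embedding dimension (default 128); must be divisible by `H`.
#' @param H number of attention heads (default 4).
#' @param k_max number of hops (default 4).
#' @param seed integer seed for the normal initialization.
#' @return A flat named list of parameter matrices (class `encoder_params`),
#'   with attributes `d`, `H`, `dh`, `k_max`.
#' @export
encoder_params <- function(n_nodes, d = 128L, H = 4L, k_max = 4L, seed = 1L) {
  stopifnot(d %% H == 0, H >= 1, d %/% H >= 1)
  set.seed(derive_seed(seed, 77))
  dh <- d %/% H
  sd <- 1 / sqrt(d)
  p <- list(E = mat_init(n_nodes, d, sd))
  for (k in seq_len(k_max)) {
    p <- c(p, tx_layer_params(d, H, 2L * d, paste0("ih", k), sd))
  }
  p$hop_Wq <- mat_init(d, dh, sd)
  p$hop_Wk <- mat_init(d, dh, sd)
  p$hop_Wv <- mat_init(d, d, sd)
  p <- c(p, tx_layer_params(d, H, 2L * d, "he", sd))
  for (m in seq_len(H)) {
    p[[paste0("ha_h", m, "_Wq")]] <- mat_init(d, dh, sd)
    p[[paste0("ha_h", m, "_Wk")]] <- mat_init(d, dh, sd)
    p[[paste0("ha_h", m, "_Wv")]] <- mat_init(d, d, sd)
  }
  p$Wout <- mat_init(H * d, d, 1 / sqrt(H * d))
  structure(p, d = as.integer(d), H = as.integer(H), dh = as.integer(dh),
            k_max = as.integer(k_max), class = "encoder_params")
}

enc_meta <- function(params) {
  list(d = attr(params, "d"), H = attr(params, "H"), dh = attr(params, "dh"),
       k_max = attr(params, "k_max"))
}

# One post-norm Transformer encoder layer over B blocks of length L.
# `X` is (B*L) x d (node or matrix); `keymask` is a plain B x L logical of
# valid positions. Invalid positions neither attend, are attended to, nor
# survive in the output (their rows are zeroed).
tx_layer <- function(X, B, L, keymask, p, pfx, H, dh) {
  gi <- rep(seq_len(B), each = L)
  kme <- keymask[gi, , drop = FALSE]          # (B*L) x L key validity
  qvalid <- as.numeric(t(keymask))            # length B*L query validity
  heads <- vector("list", H)
  for (m in seq_len(H)) {
    Q <- ad_mm(X, p[[paste0(pfx, "_h", m, "_Wq")]])
    K <- ad_mm(X, p[[paste0(pfx, "_h", m, "_Wk")]])
    V <- ad_mm(X, p[[paste0(pfx, "_h", m, "_Wv")]])
    S <- ad_mul(ad_bscores(Q, K, B, L), 1 / sqrt(dh))
    P <- ad_rowsoftmax(S, kme)
    heads[[m]] <- ad_bweight(P, V, B, L)
  }
  A <- ad_mm(ad_cbind(heads), p[[paste0(pfx, "_Wo")]])
  X1 <- ad_layernorm(ad_add(X, A),
                     p[[paste0(pfx, "_ln1g")]], p[[paste0(pfx, "_ln1b")]])
  F1 <- ad_relu(ad_addbias(ad_mm(X1, p[[paste0(pfx, "_W1")]]),
                           p[[paste0(pfx, "_b1")]]))
  F2 <- ad_addbias(ad_mm(F1, p[[paste0(pfx, "_W2")]]),
                   p[[paste0(pfx, "_b2")]])
  X2 <- ad_layernorm(ad_add(X1, F2),
                     p[[paste0(pfx, "_ln2g")]], p[[paste0(pfx, "_ln2b")]])
  ad_rowscale(X2, qvalid)
}

# Flatten one hop's (B x L) index slab to the stacked (B*L) row layout.
hop_flat_idx <- function(batch, k) as.integer(t(batch$idx[, k, , drop = TRUE]))

#' Encode per-hop neighbour sequences with intra-hop Transformers
#'
#' For each hop, gathers the sampled neighbours' embeddings and passes them
#' through that hop's own Transformer encoder layer. Masked slots neither
#' attend nor are attended to, and their output rows are zero; a fully masked
#' hop yields a zero block. Masked slot indices are ignored (replaced
#' internally), so slot contents cannot leak.
#'
#' @param batch a `sampled_batch` from [make_batches()] or a single-patient
#'   equivalent (arrays reshaped to B = 1).
#' @param params an [encoder_params()] (plain matrices or tape nodes).
#' @return A list of length `k_max`; element k is the (B*per_hop) x d encoded
#'   neighbour matrix for hop k (an `ad_node` when params are nodes).
#' @export
intra_hop_encode <- function(batch, params) {
  meta <- enc_meta(params)
  B <- length(batch$patients); K <- batch$k_max; L <- batch$per_hop
  out <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- hop_flat_idx(batch, k)
    mk <- matrix(batch$mask[, k, ], B, L)
    idx[!as.logical(t(mk))] <- 1L  # dummy; masked slots cannot influence
    Xk <- ad_rows(params$E, idx)
    out[[k]] <- tx_layer(Xk, B, L, mk, params, paste0("ih", k),
                         meta$H, meta$dh)
  }
  out
}

#' Hop-level attention aggregation
#'
#' Computes attention weights between the target patient embedding and each
#' encoded neighbour of one hop, softmax-normalized over the unmasked slots,
#' and returns the attention-weighted sum of the value-projected neighbours.
#' A fully masked hop yields a zero vector (and zero weights).
#'
#' @param h_v target embeddings, B x d.
#' @param encoded_hop (B*per_hop) x d encoded neighbours from
#'   [intra_hop_encode()].
#' @param mask B x per_hop logical slot validity for this hop.
#' @param params an [encoder_params()].
#' @return A list with `z` (B x d aggregated hop representation) and `alpha`
#'   (B x per_hop attention weights; rows sum to 1 over unmasked slots).
#' @export
hop_attention <- function(h_v, encoded_hop, mask, params) {
  meta <- enc_meta(params)
  B <- nrow(mask); L <- ncol(mask)
  Qh <- ad_mm(h_v, params$hop_Wq)
  Kh <- ad_mm(encoded_hop, params$hop_Wk)
  S <- ad_mul(ad_tscores(Qh, Kh, B, L), 1 / sqrt(meta$dh))
  alpha <- ad_rowsoftmax(S, mask)
  Vh <- ad_mm(encoded_hop, params$hop_Wv)
  list(z = ad_tweight(alpha, Vh, B, L), alpha = alpha)
}

#' Hierarchical fusion across hops
#'
#' The length-K hop sequence `{z_v^(k)}` first passes through a hierarchical
#' Transformer encoder layer (hops with empty frontiers are masked out), then
#' per attention head m the hop weights
#' `beta_k = softmax_k((h_v Wq')(z~_k Wk')^T / sqrt(d_h))` fuse the
#' contextualized hops with a residual, `h'^(m) = h_v + sum_k beta_k z~_k Wv'`,
#' and the concatenated heads are linearly projected. When every hop is masked
#' the result is a projection of the residual-only heads, i.e. a function of
#' `h_v` alone.
#'
#' @param h_v target embeddings, B x d.
#' @param z_list list of length k_max of B x d hop representations.
#' @param params an [encoder_params()].
#' @param hop_mask B x k_max logical; FALSE marks hops with no real
#'   neighbours. Defaults to all TRUE.
#' @return A list with `h` (B x d fused embedding) and `beta` (list per head
#'   of B x k_max hop weights summing to 1 over valid hops).
#' @export
hierarchical_fuse <- function(h_v, z_list, params, hop_mask = NULL) {
  meta <- enc_meta(params)
  B <- nrow(ad_val(h_v)); K <- length(z_list)
  if (is.null(hop_mask)) hop_mask <- matrix(TRUE, B, K)
  Z <- ad_stack_seq(z_list, B, K)
  Zc <- tx_layer(Z, B, K, hop_mask, params, "he", meta$H, meta$dh)
  heads <- vector("list", meta$H)
  betas <- vector("list", meta$H)
  for (m in seq_len(meta$H)) {
    Q2 <- ad_mm(h_v, params[[paste0("ha_h", m, "_Wq")]])
    K2 <- ad_mm(Zc, params[[paste0("ha_h", m, "_Wk")]])
    S2 <- ad_mul(ad_tscores(Q2, K2, B, K), 1 / sqrt(meta$dh))
    beta <- ad_rowsoftmax(S2, hop_mask)
    V2 <- ad_mm(Zc, params[[paste0("ha_h", m, "_Wv")]])
    heads[[m]] <- ad_add(h_v, ad_tweight(beta, V2, B, K))
    betas[[m]] <- beta
  }
  list(h = ad_mm(ad_cbind(heads), params$Wout), beta = betas)
}

#' Full k-hop transformer branch for one batch
#'
#' Runs [intra_hop_encode()], [hop_attention()] per hop and
#' [hierarchical_fuse()] to produce the structural patient embeddings
#' `h_v^HHGAT` for a sampled batch.
#'
#' @inheritParams intra_hop_encode
#' @return B x d embedding matrix (an `ad_node` when params are nodes).
#' @export
khop_encode <- function(batch, params) {
  B <- length(batch$patients); K <- batch$k_max; L <- batch$per_hop
  h_v <- ad_rows(params$E, batch$patients)
  enc <- intra_hop_encode(batch, params)
  z_list <- vector("list", K)
  hop_mask <- matrix(FALSE, B, K)
  for (k in seq_len(K)) {
    mk <- matrix(batch$mask[, k, ], B, L)
    z_list[[k]] <- hop_attention(h_v, enc[[k]], mk, params)$z
    hop_mask[, k] <- rowSums(mk) > 0
  }
  hierarchical_fuse(h_v, z_list, params, hop_mask)$h
}
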