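# Reverse-mode automatic differentiation on matrices.
#
# The model in this package (k-hop transformer + diffusion denoiser) is trained
# by gradient descent, and no deep-learning framework is available, so the
# package carries its own small tape-based autodiff engine.  Every op is
# dual-mode: called on plain matrices it just computes the forward value;
# called with at least one `ad_node` argument it records itself on that node's
# tape so `ad_backward()` can accumulate gradients.  Ops are matrix-level
# (matmul, layer norm, masked softmax, batched block attention, ...) so tapes
# stay short (a few hundred nodes per training step).

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_is <- function(x) inherits(x, "ad_node")

ad_val <- function(x) if (ad_is(x)) x$val else x

ad_register <- function(tape, val, parents, backfn) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  class(nd) <- "ad_node"
  nd
}

# A leaf node carrying a learnable parameter.
ad_param <- function(tape, val) {
  ad_register(tape, as.matrix(val), list(), NULL)
}

ad_tape_of <- function(parents) {
  for (p in parents) if (ad_is(p)) return(p$tape)
  NULL
}

# Generic op constructor. `val_fn(vals...)` computes the forward value;
# `back_fn(g, vals, val, need)` returns a list of parent gradients (NULL for
# parents flagged FALSE in `need`).
ad_make <- function(parents, val_fn, back_fn) {
  vals <- lapply(parents, ad_val)
  val <- do.call(val_fn, vals)
  tape <- ad_tape_of(parents)
  if (is.null(tape)) return(val)
  need <- vapply(parents, ad_is, logical(1))
  ad_register(tape, val, parents,
              function(g) back_fn(g, vals, val, need))
}

# Backpropagate from a scalar loss node through its tape.
ad_backward <- function(loss) {
  stopifnot(ad_is(loss), length(loss$val) == 1L)
  tape <- loss$tape
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!ad_is(p) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

## ---- elementary ops ----

ad_mm <- function(a, b) {
  ad_make(list(a, b),
          function(va, vb) va %*% vb,
          function(g, v, val, need) list(
            if (need[1]) g %*% t(v[[2]]) else NULL,
            if (need[2]) t(v[[1]]) %*% g else NULL))
}

# Constant sparse matrix (Matrix::dgCMatrix) times dense node.
ad_spmm <- function(A, x) {
  ad_make(list(x),
          function(vx) as.matrix(A %*% vx),
          function(g, v, val, need) list(as.matrix(Matrix::t(A) %*% g)))
}

ad_add <- function(a, b) {
  ad_make(list(a, b),
          function(va, vb) va + vb,
          function(g, v, val, need) list(g, g))
}

ad_sub <- function(a, b) {
  ad_make(list(a, b),
          function(va, vb) va - vb,
          function(g, v, val, need) list(g, -g))
}

# Add a 1 x d bias row to every row of `a`.
ad_addbias <- function(a, b) {
  ad_make(list(a, b),
          function(va, vb) va + matrix(as.numeric(vb), nrow(va), ncol(va), byrow = TRUE),
          function(g, v, val, need) list(
            g,
            if (need[2]) matrix(colSums(g), 1L) else NULL))
}

# Elementwise product; `b` may be a scalar or a same-shape matrix (either arg
# may be a constant mask).
ad_mul <- function(a, b) {
  ad_make(list(a, b),
          function(va, vb) va * vb,
          function(g, v, val, need) list(
            if (need[1]) g * v[[2]] else NULL,
            if (need[2]) {
              gb <- g * v[[1]]
              if (length(v[[2]]) == 1L) matrix(sum(gb), 1L, 1L) else gb
            } else NULL))
}

# Scale each row i of `a` by plain vector w[i] (used to zero masked rows).
ad_rowscale <- function(a, w) {
  ad_make(list(a),
          function(va) va * w,
          function(g, v, val, need) list(g * w))
}

ad_relu <- function(a) {
  ad_make(list(a),
          function(va) pmax(va, 0),
          function(g, v, val, need) list(g * (v[[1]] > 0)))
}

ad_tanh <- function(a) {
  ad_make(list(a),
          function(va) tanh(va),
          function(g, v, val, need) list(g * (1 - val^2)))
}

# Row-wise softmax with an optional validity mask (TRUE = usable entry).
# Rows with no valid entry yield all-zero rows. Row max is subtracted before
# exponentiation for numerical stability.
softmax_rows <- function(x, mask = NULL) {
  x <- as.matrix(x)
  if (!is.null(mask)) x[!mask] <- -Inf
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e[!is.finite(e)] <- 0
  s <- rowSums(e)
  s[s == 0] <- 1
  e / s
}

ad_rowsoftmax <- function(a, mask = NULL) {
  ad_make(list(a),
          function(va) softmax_rows(va, mask),
          function(g, v, val, need) {
            list(val * (g - rowSums(g * val)))
          })
}

# L2-normalize rows (norms floored at `eps`).
ad_rownorm <- function(a, eps = 1e-12) {
  ad_make(list(a),
          function(va) {
            n <- pmax(sqrt(rowSums(va^2)), eps)
            va / n
          },
          function(g, v, val, need) {
            n <- pmax(sqrt(rowSums(v[[1]]^2)), eps)
            list((g - val * rowSums(g * val)) / n)
          })
}

# Per-row normalization (zero mean, unit variance over the d columns, variance
# floored at `eps`) followed by a learnable affine (gamma, beta are 1 x d).
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  ad_make(list(a, gamma, beta),
          function(va, vg, vb) {
            mu <- rowMeans(va)
            xc <- va - mu
            v <- rowMeans(xc^2)
            xh <- xc / sqrt(v + eps)
            xh * matrix(as.numeric(vg), nrow(va), ncol(va), byrow = TRUE) +
              matrix(as.numeric(vb), nrow(va), ncol(va), byrow = TRUE)
          },
          function(g, v, val, need) {
            va <- v[[1]]
            mu <- rowMeans(va)
            xc <- va - mu
            vr <- rowMeans(xc^2)
            inv <- 1 / sqrt(vr + eps)
            xh <- xc * inv
            gmat <- matrix(as.numeric(v[[2]]), nrow(va), ncol(va), byrow = TRUE)
            gh <- g * gmat
            dx <- inv * (gh - rowMeans(gh) - xh * rowMeans(gh * xh))
            list(dx,
                 if (need[2]) matrix(colSums(g * xh), 1L) else NULL,
                 if (need[3]) matrix(colSums(g), 1L) else NULL)
          })
}

# Gather rows (embedding lookup). Backward scatter-adds.
ad_rows <- function(a, idx) {
  idx <- as.integer(idx)
  ad_make(list(a),
          function(va) va[idx, , drop = FALSE],
          function(g, v, val, need) {
            da <- matrix(0, nrow(v[[1]]), ncol(v[[1]]))
            rs <- rowsum(g, idx)
            da[as.integer(rownames(rs)), ] <- rs
            list(da)
          })
}

ad_cbind <- function(parts) {
  ad_make(parts,
          function(...) do.call(cbind, list(...)),
          function(g, v, val, need) {
            out <- vector("list", length(v))
            at <- 0L
            for (j in seq_along(v)) {
              w <- ncol(v[[j]])
              if (need[j]) out[[j]] <- g[, at + seq_len(w), drop = FALSE]
              at <- at + w
            }
            out
          })
}

ad_sum <- function(a) {
  ad_make(list(a),
          function(va) matrix(sum(va), 1L, 1L),
          function(g, v, val, need) list(matrix(g[1], nrow(v[[1]]), ncol(v[[1]]))))
}

ad_mean <- function(a) {
  ad_make(list(a),
          function(va) matrix(mean(va), 1L, 1L),
          function(g, v, val, need)
            list(matrix(g[1] / length(v[[1]]), nrow(v[[1]]), ncol(v[[1]]))))
}

# Mean squared error against a plain target, averaged over all entries.
ad_mse <- function(a, target) {
  target <- ad_val(target)
  ad_make(list(a),
          function(va) matrix(mean((va - target)^2), 1L, 1L),
          function(g, v, val, need)
            list(2 * g[1] * (v[[1]] - target) / length(v[[1]])))
}

# KL(q || softmax(logits)) averaged over rows; q is a plain row-stochastic
# matrix of smoothed targets. Predicted probabilities are clamped at 1e-12.
ad_kl_logits <- function(logits, q) {
  q <- ad_val(q)
  ad_make(list(logits),
          function(vl) {
            p <- pmax(softmax_rows(vl), 1e-12)
            lq <- ifelse(q > 0, log(q), 0)
            matrix(sum(q * (lq - log(p))) / nrow(vl), 1L, 1L)
          },
          function(g, v, val, need) {
            p <- softmax_rows(v[[1]])
            list(g[1] * (p - q) / nrow(p))
          })
}

## ---- batched block attention ops ----
#
# Sequences of fixed length L for B independent blocks (patients) are stored
# stacked as (B*L) x d matrices, row (b-1)*L + i holding item i of block b.
# Attention only mixes rows within a block; the ops below exploit that without
# materializing a (B*L) x (B*L) score matrix.

# S[(b-1)L+i, j] = <q[(b-1)L+i, ], k[(b-1)L+j, ]>
ad_bscores <- function(q, k, B, L) {
  gi <- rep(seq_len(B), each = L)
  ad_make(list(q, k),
          function(vq, vk) {
            S <- matrix(0, B * L, L)
            for (j in seq_len(L)) {
              kj <- vk[(seq_len(B) - 1L) * L + j, , drop = FALSE]
              S[, j] <- rowSums(vq * kj[gi, , drop = FALSE])
            }
            S
          },
          function(g, v, val, need) {
            vq <- v[[1]]; vk <- v[[2]]
            gq <- if (need[1]) matrix(0, nrow(vq), ncol(vq)) else NULL
            gk <- if (need[2]) matrix(0, nrow(vk), ncol(vk)) else NULL
            for (j in seq_len(L)) {
              idx <- (seq_len(B) - 1L) * L + j
              kje <- vk[idx, , drop = FALSE][gi, , drop = FALSE]
              if (need[1]) gq <- gq + g[, j] * kje
              if (need[2]) gk[idx, ] <- gk[idx, , drop = FALSE] +
                  rowsum(vq * g[, j], gi, reorder = FALSE)
            }
            list(gq, gk)
          })
}

# out[(b-1)L+i, ] = sum_j P[(b-1)L+i, j] * v[(b-1)L+j, ]
ad_bweight <- function(p, v, B, L) {
  gi <- rep(seq_len(B), each = L)
  ad_make(list(p, v),
          function(vp, vv) {
            out <- matrix(0, B * L, ncol(vv))
            for (j in seq_len(L)) {
              vj <- vv[(seq_len(B) - 1L) * L + j, , drop = FALSE]
              out <- out + vp[, j] * vj[gi, , drop = FALSE]
            }
            out
          },
          function(g, v, val, need) {
            vp <- v[[1]]; vv <- v[[2]]
            gp <- if (need[1]) matrix(0, nrow(vp), ncol(vp)) else NULL
            gv <- if (need[2]) matrix(0, nrow(vv), ncol(vv)) else NULL
            for (j in seq_len(L)) {
              idx <- (seq_len(B) - 1L) * L + j
              vje <- vv[idx, , drop = FALSE][gi, , drop = FALSE]
              if (need[1]) gp[, j] <- rowSums(g * vje)
              if (need[2]) gv[idx, ] <- gv[idx, , drop = FALSE] +
                  rowsum(vp[, j] * g, gi, reorder = FALSE)
            }
            list(gp, gv)
          })
}

# One query per block: S[b, j] = <q[b, ], k[(b-1)L+j, ]>; q is B x dh.
ad_tscores <- function(q, k, B, L) {
  ad_make(list(q, k),
          function(vq, vk) {
            S <- matrix(0, B, L)
            for (j in seq_len(L)) {
              kj <- vk[(seq_len(B) - 1L) * L + j, , drop = FALSE]
              S[, j] <- rowSums(vq * kj)
            }
            S
          },
          function(g, v, val, need) {
            vq <- v[[1]]; vk <- v[[2]]
            gq <- if (need[1]) matrix(0, nrow(vq), ncol(vq)) else NULL
            gk <- if (need[2]) matrix(0, nrow(vk), ncol(vk)) else NULL
            for (j in seq_len(L)) {
              idx <- (seq_len(B) - 1L) * L + j
              kj <- vk[idx, , drop = FALSE]
              if (need[1]) gq <- gq + g[, j] * kj
              if (need[2]) gk[idx, ] <- gk[idx, , drop = FALSE] + g[, j] * vq
            }
            list(gq, gk)
          })
}

# out[b, ] = sum_j P[b, j] * v[(b-1)L+j, ]; P is B x L.
ad_tweight <- function(p, v, B, L) {
  ad_make(list(p, v),
          function(vp, vv) {
            out <- matrix(0, B, ncol(vv))
            for (j in seq_len(L)) {
              vj <- vv[(seq_len(B) - 1L) * L + j, , drop = FALSE]
              out <- out + vp[, j] * vj
            }
            out
          },
          function(g, v, val, need) {
            vp <- v[[1]]; vv <- v[[2]]
            gp <- if (need[1]) matrix(0, nrow(vp), ncol(vp)) else NULL
            gv <- if (need[2]) matrix(0, nrow(vv), ncol(vv)) else NULL
            for (j in seq_len(L)) {
              idx <- (seq_len(B) - 1L) * L + j
              vj <- vv[idx, , drop = FALSE]
              if (need[1]) gp[, j] <- rowSums(g * vj)
              if (need[2]) gv[idx, ] <- gv[idx, , drop = FALSE] + vp[, j] * g
            }
            list(gp, gv)
          })
}

# Interleave K per-block matrices (each B x d) into a (B*K) x d sequence
# matrix, row (b-1)*K + k = zlist[[k]][b, ].
ad_stack_seq <- function(zlist, B, K) {
  ad_make(zlist,
          function(...) {
            zs <- list(...)
            out <- matrix(0, B * K, ncol(zs[[1]]))
            for (k in seq_len(K)) out[(seq_len(B) - 1L) * K + k, ] <- zs[[k]]
            out
          },
          function(g, v, val, need) {
            lapply(seq_len(K), function(k) {
              if (need[k]) g[(seq_len(B) - 1L) * K + k, , drop = FALSE] else NULL
            })
          })
}

## ---- optimiser ----

# Adam over a flat named list of parameter matrices.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 3e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Attach a flat named list of plain parameter matrices to a fresh tape,
# returning same-named leaf nodes.
ad_attach <- function(tape, params) {
  out <- lapply(params, function(p) ad_param(tape, p))
  names(out) <- names(params)
  out
}

# Collect gradients (by name) after ad_backward; missing gradients are NULL.
ad_grads <- function(nodes) {
  lapply(nodes, function(nd) nd$grad)
}
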