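# End-to-end trainer: k-hop transformer branch + diffusion branch, fused and
# classified under the label-smoothed KL loss, optimized jointly with the
# diffusion loss by Adam. Early stopping tracks validation macro-F1.

VARIANTS <- c("full", "my_gcn", "my_onlytrans", "my_onesub", "my_onlydiff")

#' Training configuration
#'
#' Defaults follow the reference setting: Adam at learning rate 0.003, up to
#' 300 epochs, embedding dimension 128, 4 attention heads, k = 4 hops with 32
#' neighbours sampled per hop, mini-batches of 256 patients, label smoothing
#' 0.3, diffusion noise strength 1e-5 over 50 steps with 10-step DDIM
#' inference, fusion coefficient 0.5, and a stratified 50/30/20 split.
#'
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param d node embedding dimension (divisible by `heads`).
#' @param heads attention heads in both transformer stages.
#' @param k_max number of hops.
#' @param per_hop neighbours sampled per hop.
#' @param batch_size mini-batch size (patient nodes).
#' @param label_smoothing smoothing factor mu in `[0, 1]`.
#' @param lambda fusion coefficient in `[0, 1]` (weight of the transformer
#'   branch; `1 - lambda` weights the diffusion branch).
#' @param noise_strength terminal diffusion beta.
#' @param T_steps diffusion step count.
#' @param ddim_steps DDIM inference subsequence length.
#' @param gcn_hidden denoiser hidden width.
#' @param d_t sinusoidal time-embedding width.
#' @param split train/validation/test fractions (sum to 1).
#' @param patience early-stopping patience on validation macro-F1.
#' @param seed integer seed governing splits, initialization, sampling and
#'   noise.
#' @return A list of class `khopdiff_config`.
#' @export
khopdiff_config <- function(learning_rate = 0.003, max_epochs = 300L,
                            d = 128L, heads = 4L, k_max = 4L, per_hop = 32L,
                            batch_size = 256L, label_smoothing = 0.3,
                            lambda = 0.5, noise_strength = 1e-5,
                            T_steps = 50L, ddim_steps = 10L,
                            gcn_hidden = 128L, d_t = 16L,
                            split = c(0.5, 0.3, 0.2), patience = 30L,
                            seed = 1L) {
  stopifnot(label_smoothing >= 0, label_smoothing <= 1,
            lambda >= 0, lambda <= 1, abs(sum(split) - 1) < 1e-8,
            d %% heads == 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), d = as.integer(d),
                 heads = as.integer(heads), k_max = as.integer(k_max),
                 per_hop = as.integer(per_hop),
                 batch_size = as.integer(batch_size),
                 label_smoothing = label_smoothing, lambda = lambda,
                 noise_strength = noise_strength,
                 T_steps = as.integer(T_steps),
                 ddim_steps = as.integer(ddim_steps),
                 gcn_hidden = as.integer(gcn_hidden), d_t = as.integer(d_t),
                 split = split, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "khopdiff_config")
}

with_meta <- function(x, meta) {
  attr(x, "d") <- meta$d; attr(x, "H") <- meta$H; attr(x, "dh") <- meta$dh
  attr(x, "k_max") <- meta$k_max; attr(x, "d_t") <- meta$d_t
  x
}

# Symmetric-normalized undirected union adjacency over the unified node space
# (used by the my_gcn ablation's plain GCN encoder).
union_adjacency <- function(graph) {
  nP <- length(graph$nodes$P); nD <- length(graph$nodes$D)
  nO <- length(graph$nodes$O); n <- nP + nD + nO
  pd <- methods::as((graph$adj[["P-D"]] + Matrix::t(graph$adj[["D-P"]])) != 0,
                    "TsparseMatrix")
  po <- methods::as((graph$adj[["P-O"]] + Matrix::t(graph$adj[["O-P"]])) != 0,
                    "TsparseMatrix")
  i <- c(pd@i + 1L, nP + pd@j + 1L, po@i + 1L, nP + nD + po@j + 1L)
  j <- c(nP + pd@j + 1L, pd@i + 1L, nP + nD + po@j + 1L, po@i + 1L)
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  if (length(A@x)) A@x[] <- 1
  sym_norm_adj(A)
}

# Structural branch for one batch: k-hop transformer, or a plain 2-layer GCN
# over the whole heterogeneous graph for the my_gcn ablation.
struct_embed <- function(batch, p, meta) {
  if (meta$variant == "my_gcn") {
    H1 <- ad_relu(ad_addbias(ad_spmm(meta$Au, ad_mm(p$E, p$g_W1)), p$g_b1))
    H2 <- ad_addbias(ad_spmm(meta$Au, ad_mm(H1, p$g_W2)), p$g_b2)
    ad_rows(H2, batch$patients)
  } else {
    khop_encode(batch, p)
  }
}

# Fused embedding and logits for one batch given (plain or node) params.
batch_logits <- function(batch, p, meta, h_diff) {
  B <- length(batch$patients)
  hs <- if (meta$has_struct) struct_embed(batch, p, meta)
        else matrix(0, B, meta$d)
  hb <- if (meta$use_diff) h_diff[batch$patients, , drop = FALSE]
        else matrix(0, B, meta$d)
  hf <- fuse_final(hs, hb, meta$lambda_eff, p$fu_g, p$fu_b)
  ad_addbias(ad_mm(hf, p$cls_W), p$cls_b)
}

# Class-probability forward pass for arbitrary patients with plain params.
forward_probs <- function(graph, patients, plist, meta, h_diff, frontiers,
                          eval_seed) {
  scfg <- sampler_config(meta$k_max, meta$per_hop, meta$batch_size, eval_seed)
  batches <- make_batches(graph, patients, scfg, epoch = 0L,
                          frontiers = frontiers)
  probs <- matrix(NA_real_, length(graph$nodes$P), meta$C)
  for (b in batches) {
    lg <- ad_val(batch_logits(b, plist, meta, h_diff))
    probs[b$patients, ] <- softmax_rows(lg)
  }
  probs[patients, , drop = FALSE]
}

# Refresh the denoised diffusion embeddings by a full DDIM pass.
refresh_hdiff <- function(plist, meta, views, schedule, seed) {
  pm <- with_meta(plist, meta)
  h01 <- ad_val(encode_view(views[[1]], pm))
  h02 <- ad_val(encode_view(views[[2]], pm))
  set.seed(seed)
  pair <- ddim_reverse_pair(h01, h02, views[[1]], views[[2]], schedule, pm)
  if (meta$variant == "my_onesub") pair[[1]] else
    ad_val(fuse_views(pair[[1]], pair[[2]]))
}

#' Fit the k-hop transformer + diffusion diagnosis model
#'
#' Trains the full model (or an ablated variant) on a heterogeneous
#' patient-drug-procedure graph with one disease label per patient. Per epoch,
#' mini-batches of patients are resampled, the structural branch encodes the
#' sampled k-hop neighbourhoods, the diffusion branch's DDIM reconstructions
#' are refreshed, and the label-smoothed classification loss plus the
#' diffusion loss is optimized by Adam. The checkpoint with the best
#' validation macro-F1 is kept (early stopping after `patience` stale epochs)
#' and scored on the held-out test split.
#'
#' Variants: `"full"` (both branches); `"my_gcn"` (transformer replaced by a
#' plain 2-layer GCN); `"my_onlytrans"` (diffusion removed, lambda = 1);
#' `"my_onesub"` (single P-D-P auxiliary view); `"my_onlydiff"` (transformer
#' removed, lambda = 0).
#'
#' @param graph a [het_graph()].
#' @param labels per-patient disease labels aligned with `graph$nodes$P`
#'   (factor, character or integer; >= 2 classes).
#' @param config a [khopdiff_config()].
#' @param variant one of the five model variants above.
#' @return An object of class `khopdiff`: fitted parameters, the training log
#'   (`$log`: epoch, classification loss, diffusion loss, validation
#'   macro-F1), the split, the test-set [evaluate_predictions()] report
#'   (`$test_report`), and everything [predict.khopdiff()] needs.
#' @seealso [simulate_ehr_graph()] for synthetic data to train on.
#' @export
khopdiff <- function(graph, labels, config = khopdiff_config(),
                     variant = "full") {
  variant <- match.arg(variant, VARIANTS)
  f <- factor(labels)
  y <- as.integer(f)
  C <- nlevels(f)
  stopifnot(C >= 2, length(y) == length(graph$nodes$P))
  nP <- length(graph$nodes$P)
  n_nodes <- nP + length(graph$nodes$D) + length(graph$nodes$O)

  meta <- list(d = config$d, H = config$heads, dh = config$d %/% config$heads,
               k_max = config$k_max, per_hop = config$per_hop,
               batch_size = config$batch_size, d_t = config$d_t, C = C,
               variant = variant,
               has_struct = variant != "my_onlydiff",
               use_diff = variant != "my_onlytrans",
               lambda_eff = switch(variant, my_onlytrans = 1,
                                   my_onlydiff = 0, config$lambda))

  spl <- split_patients(y, config$split, config$seed)

  adjlist <- union_adjlist(graph)
  frontiers <- patient_frontiers(graph, seq_len(nP), config$k_max, adjlist)
  names(frontiers) <- as.character(seq_len(nP))

  views <- schedule <- NULL
  plist <- list()
  set.seed(derive_seed(config$seed, 11))
  if (meta$has_struct) {
    if (variant == "my_gcn") {
      meta$Au <- union_adjacency(graph)
      plist$E <- mat_init(n_nodes, config$d, 1 / sqrt(config$d))
      plist$g_W1 <- mat_init(config$d, config$d, 1 / sqrt(config$d))
      plist$g_b1 <- matrix(0, 1, config$d)
      plist$g_W2 <- mat_init(config$d, config$d, 1 / sqrt(config$d))
      plist$g_b2 <- matrix(0, 1, config$d)
    } else {
      plist <- c(plist, unclass(encoder_params(n_nodes, config$d, config$heads,
                                               config$k_max, config$seed)))
    }
  }
  if (meta$use_diff) {
    views <- build_views(graph, seed = config$seed)
    if (variant == "my_onesub") views[[2]] <- views[[1]]
    schedule <- make_schedule(config$T_steps, config$noise_strength,
                              config$ddim_steps)
    plist <- c(plist, unclass(diffusion_params(ncol(views[[1]]$X), config$d,
                                               config$gcn_hidden, config$d_t,
                                               config$seed)))
  }
  plist$fu_g <- matrix(1, 1, config$d)
  plist$fu_b <- matrix(0, 1, config$d)
  plist$cls_W <- mat_init(config$d, C, 1 / sqrt(config$d))
  plist$cls_b <- matrix(0, 1, C)

  scfg <- sampler_config(config$k_max, config$per_hop, config$batch_size,
                         config$seed)
  eval_seed <- derive_seed(config$seed, 7777)
  state <- adam_init(plist)
  log <- data.frame(epoch = integer(0), loss_cls = numeric(0),
                    loss_diff = numeric(0), val_macro_f1 = numeric(0))
  best <- list(macro = -Inf, plist = plist, h_diff = NULL, epoch = 0L)
  stale <- 0L
  h_diff <- NULL

  for (epoch in seq_len(config$max_epochs)) {
    if (meta$use_diff) {
      h_diff <- refresh_hdiff(plist, meta, views, schedule,
                              derive_seed(config$seed, 8000 + epoch))
    }
    batches <- make_batches(graph, spl$train, scfg, epoch = epoch,
                            frontiers = frontiers)
    set.seed(derive_seed(config$seed, 6000 + epoch))
    ecls <- ediff <- 0
    for (b in batches) {
      tape <- ad_tape()
      nodes <- with_meta(ad_attach(tape, plist), meta)
      lg <- batch_logits(b, nodes, meta, h_diff)
      targets <- smooth_labels(y[b$patients], config$label_smoothing, C)
      L_cls <- ad_kl_logits(lg, targets)
      if (meta$use_diff) {
        h01 <- encode_view(views[[1]], nodes)
        h02 <- encode_view(views[[2]], nodes)
        L_diff <- diffusion_loss(h01, h02, views[[1]], views[[2]], schedule,
                                 nodes)
        L <- ad_add(L_cls, L_diff)
        ediff <- ediff + ad_val(L_diff)[1]
      } else {
        L <- L_cls
      }
      lv <- ad_val(L)[1]
      if (!is.finite(lv)) stop("training diverged (non-finite loss)")
      ecls <- ecls + ad_val(L_cls)[1]
      ad_backward(L)
      upd <- adam_step(plist, ad_grads(nodes), state,
                       lr = config$learning_rate)
      plist <- upd$params
      state <- upd$state
    }
    probs <- forward_probs(graph, spl$val, with_meta(plist, meta), meta,
                           h_diff, frontiers, eval_seed)
    rep_val <- evaluate_predictions(y[spl$val], predict_class(probs), C)
    log <- rbind(log, data.frame(epoch = epoch,
                                 loss_cls = ecls / length(batches),
                                 loss_diff = ediff / length(batches),
                                 val_macro_f1 = rep_val$macro_f1))
    if (rep_val$macro_f1 > best$macro) {
      best <- list(macro = rep_val$macro_f1, plist = plist, h_diff = h_diff,
                   epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }

  plist <- with_meta(best$plist, meta)
  h_diff <- best$h_diff
  test_probs <- forward_probs(graph, spl$test, plist, meta, h_diff, frontiers,
                              eval_seed)
  test_pred <- predict_class(test_probs)
  test_report <- evaluate_predictions(y[spl$test], test_pred, C)

  structure(list(params = plist, meta = meta, config = config,
                 variant = variant, classes = levels(f), y = y,
                 split = spl, log = log, best_epoch = best$epoch,
                 best_val_macro_f1 = best$macro, test_report = test_report,
                 h_diff = h_diff, graph = graph, frontiers = frontiers,
                 eval_seed = eval_seed),
            class = "khopdiff")
}

#' Predict disease classes or probabilities for patients
#'
#' @param object a fitted [khopdiff()] model.
#' @param patients patient indices (into `graph$nodes$P`) or identifiers;
#'   defaults to all patients.
#' @param type `"class"` for factor labels, `"prob"` for the N x C probability
#'   matrix.
#' @param ... unused.
#' @return Factor of predicted labels, or a probability matrix with one row
#'   per requested patient and one column per class.
#' @export
predict.khopdiff <- function(object, patients = NULL, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  if (is.null(patients)) patients <- seq_along(object$graph$nodes$P)
  if (is.character(patients)) {
    patients <- match(patients, object$graph$nodes$P)
    if (anyNA(patients)) stop("node not found")
  }
  probs <- forward_probs(object$graph, patients, object$params, object$meta,
                         object$h_diff, object$frontiers, object$eval_seed)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[predict_class(probs)], levels = object$classes)
}

#' @export
print.khopdiff <- function(x, ...) {
  cat(sprintf("khopdiff model (variant: %s)\n", x$variant))
  cat(sprintf("  %d patients, %d classes (%s)\n", length(x$y),
              length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  trained %d epochs; best validation macro-F1 %.4f (epoch %d)\n",
              nrow(x$log), x$best_val_macro_f1, x$best_epoch))
  cat(sprintf("  test micro-F1 %.4f, macro-F1 %.4f\n",
              x$test_report$micro_f1, x$test_report$macro_f1))
  invisible(x)
}

#' @export
summary.khopdiff <- function(object, ...) {
  print(object)
  cat("\nTest-set report:\n")
  print(object$test_report)
  cat("\nConfig: d =", object$config$d, " heads =", object$config$heads,
      " k_max =", object$config$k_max, " per_hop =", object$config$per_hop,
      " lambda =", object$config$lambda,
      " mu =", object$config$label_smoothing, "\n")
  invisible(object)
}

#' Classifier coefficients of a fitted model
#'
#' @param object a fitted [khopdiff()] model.
#' @param ... unused.
#' @return The C x d classifier weight matrix (rows named by class) with the
#'   bias in attribute `"bias"`.
#' @export
coef.khopdiff <- function(object, ...) {
  W <- t(object$params$cls_W)
  rownames(W) <- object$classes
  attr(W, "bias") <- stats::setNames(as.numeric(object$params$cls_b),
                                     object$classes)
  W
}

#' Plot training curves
#'
#' Left axis: classification and diffusion losses per epoch; right curve:
#' validation macro-F1.
#'
#' @param x a fitted [khopdiff()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.khopdiff <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(lg$epoch, lg$loss_cls, type = "l", xlab = "epoch",
                 ylab = "loss", main = "khopdiff training", ...)
  if (any(lg$loss_diff > 0)) graphics::lines(lg$epoch, lg$loss_diff, lty = 2)
  graphics::par(new = TRUE)
  graphics::plot(lg$epoch, lg$val_macro_f1, type = "l", col = "grey40",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("validation macro-F1", side = 4, line = 2.5)
  invisible(x)
}
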