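# Classification head, losses, splits and F1 evaluation.

#' Fuse structural and denoised embeddings
#'
#' Per-row normalization (zero mean, unit variance over the d features,
#' variance floored at 1e-5, then a learnable affine) of
#' `lambda * h_hhgat + (1 - lambda) * h_diff`.
#'
#' @param h_hhgat,h_diff equal-shape embedding matrices (plain or `ad_node`).
#' @param lambda fusion coefficient in `[0, 1]` balancing structural semantics
#'   (transformer branch) against noise robustness (diffusion branch).
#' @param gamma,beta 1 x d affine parameters of the normalization.
#' @return N x d fused, normalized embedding.
#' @export
fuse_final <- function(h_hhgat, h_diff, lambda, gamma, beta) {
  stopifnot(lambda >= 0, lambda <= 1)
  v1 <- ad_val(h_hhgat); v2 <- ad_val(h_diff)
  if (!all(dim(v1) == dim(v2))) stop("shape mismatch")
  mix <- ad_add(ad_mul(h_hhgat, lambda), ad_mul(h_diff, 1 - lambda))
  ad_layernorm(mix, gamma, beta, eps = 1e-5)
}

#' Linear classifier with softmax
#'
#' `softmax(h W + b)`; rows sum to 1. (The weight is stored d x C; its
#' transpose is the usual C x d classifier matrix.)
#'
#' @param h_final N x d fused embeddings.
#' @param W d x C weight matrix.
#' @param b length-C (or 1 x C) bias.
#' @return N x C probability matrix.
#' @export
classify <- function(h_final, W, b) {
  logits <- ad_addbias(ad_mm(h_final, W), b)
  ad_rowsoftmax(logits)
}

#' Argmax class prediction
#'
#' Ties break toward the lowest class index.
#'
#' @param probs N x C probability (or score) matrix.
#' @return Integer class indices in 1..C.
#' @export
predict_class <- function(probs) {
  max.col(ad_val(probs), ties.method = "first")
}

#' Smooth one-hot labels
#'
#' `(1 - mu) * onehot(y) + mu / C`; rows sum to 1.
#'
#' @param y integer class indices in 1..C.
#' @param mu smoothing factor in `[0, 1]`.
#' @param C number of classes.
#' @return length(y) x C row-stochastic target matrix.
#' @export
smooth_labels <- function(y, mu, C) {
  stopifnot(mu >= 0, mu <= 1, all(y >= 1), all(y <= C))
  out <- matrix(mu / C, length(y), C)
  out[cbind(seq_along(y), y)] <- out[cbind(seq_along(y), y)] + (1 - mu)
  out
}

#' Label-smoothed classification loss
#'
#' Mean over patients of `KL(smoothed || predicted)
#' = sum_c q_c (log q_c - log p_c)`, with predicted probabilities clamped at
#' 1e-12. Zero iff the rows match exactly; with `mu = 0` it equals standard
#' cross-entropy (the one-hot target entropy is zero).
#'
#' @param predicted N x C row-stochastic prediction matrix.
#' @param smoothed N x C row-stochastic target matrix.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(predicted, smoothed) {
  p <- pmax(as.matrix(ad_val(predicted)), 1e-12)
  q <- as.matrix(smoothed)
  lq <- ifelse(q > 0, log(q), 0)
  sum(q * (lq - log(p))) / nrow(p)
}

#' Total training loss
#'
#' Unweighted sum of the classification and diffusion objectives.
#'
#' @param cls,diff scalar losses.
#' @return `cls + diff`.
#' @export
total_loss <- function(cls, diff) cls + diff

#' Stratified train/validation/test split
#'
#' Splits patients class-by-class in the given proportions (largest-remainder
#' apportionment, so per-class counts are within one member of the exact
#' proportions), deterministically per seed. A class with fewer than 3 members
#' still places at least one member in train, with a warning.
#'
#' @param labels integer class indices in 1..C (one per patient).
#' @param fractions length-3 vector of train/validation/test fractions
#'   summing to 1.
#' @param seed integer seed.
#' @return A list with integer index vectors `train`, `val`, `test`
#'   (disjoint, union = all patients).
#' @export
split_patients <- function(labels, fractions = c(0.5, 0.3, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  set.seed(derive_seed(seed, 31))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < 3L) {
      warning(sprintf("class %s has fewer than 3 members; placing one in train",
                      cl))
    }
    idx <- idx[sample.int(length(idx))]
    ideal <- fractions * length(idx)
    n <- floor(ideal)
    rem <- length(idx) - sum(n)
    if (rem > 0) {
      extra <- order(ideal - n, decreasing = TRUE)[seq_len(rem)]
      n[extra] <- n[extra] + 1L
    }
    if (n[1] == 0L && length(idx) > 0L) {  # guarantee train membership
      don <- which.max(n[-1]) + 1L
      n[don] <- n[don] - 1L
      n[1] <- 1L
    }
    out$train <- c(out$train, idx[seq_len(n[1])])
    out$val <- c(out$val, idx[n[1] + seq_len(n[2])])
    out$test <- c(out$test, idx[n[1] + n[2] + seq_len(n[3])])
  }
  lapply(out, sort)
}

#' Micro/Macro F1 evaluation
#'
#' Builds the C x C confusion matrix and reports pooled-count micro-F1
#' (`2 TP / (2 TP + FP + FN)`, which equals accuracy in this single-label
#' setting), per-class F1 (0 when a class's denominator is 0), and macro-F1
#' (their unweighted mean).
#'
#' @param y_true,y_pred integer class indices in 1..C, equal length.
#' @param C number of classes.
#' @return An object of class `eval_report`: `confusion` (rows = true,
#'   columns = predicted), `tp`, `fp`, `fn`, `per_class_f1`, `micro_f1`,
#'   `macro_f1`, `n` (class count).
#' @export
evaluate_predictions <- function(y_true, y_pred, C) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(all(y_true >= 1), all(y_true <= C), all(y_pred >= 1),
            all(y_pred <= C))
  conf <- matrix(0L, C, C)
  for (i in seq_along(y_true)) {
    conf[y_true[i], y_pred[i]] <- conf[y_true[i], y_pred[i]] + 1L
  }
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  denom <- 2 * tp + fp + fn
  per_class <- ifelse(denom > 0, 2 * tp / denom, 0)
  micro <- if (sum(2 * tp + fp + fn) > 0) {
    2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn))
  } else 0
  structure(list(confusion = conf, tp = tp, fp = fp, fn = fn,
                 per_class_f1 = per_class, micro_f1 = micro,
                 macro_f1 = mean(per_class), n = C),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d classes (%d patients)\n",
              x$n, sum(x$confusion)))
  cat(sprintf("  micro-F1: %.4f   macro-F1: %.4f\n", x$micro_f1, x$macro_f1))
  cat("  per-class F1:", paste(sprintf("%.3f", x$per_class_f1),
                               collapse = " "), "\n")
  invisible(x)
}
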