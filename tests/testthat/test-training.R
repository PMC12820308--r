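test_that("fuse_final normalizes rows and respects the fusion coefficient", {
  set.seed(1)
  d <- 4
  g <- matrix(1, 1, d); be <- matrix(0, 1, d)
  h1 <- matrix(rnorm(8), 2, d); h2 <- matrix(rnorm(8), 2, d)

  # lambda = 1: independent of the diffusion branch
  expect_equal(fuse_final(h1, h2, 1, g, be),
               fuse_final(h1, h2 * 0 + 99, 1, g, be))

  # identity affine: rows have mean ~0 and unit variance
  out <- fuse_final(h1, h2, 0.5, g, be)
  expect_equal(rowMeans(out), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(out, 1, function(r) mean(r^2)), c(1, 1), tolerance = 1e-4)

  # lambda = 0.5 against a by-hand mean/variance computation (2 x 4)
  mix <- 0.5 * h1 + 0.5 * h2
  ref <- t(apply(mix, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  expect_equal(out, ref, tolerance = 1e-6)

  # zero-variance row survives via the variance floor
  expect_true(all(is.finite(fuse_final(matrix(1, 1, d), matrix(1, 1, d),
                                       0.5, g, be))))
  expect_error(fuse_final(h1, h2, 1.5, g, be))
  expect_error(fuse_final(h1, matrix(0, 3, d), 0.5, g, be), "shape mismatch")
})

test_that("classify produces calibrated softmax rows", {
  h <- matrix(rnorm(6), 2, 3)
  W0 <- matrix(0, 3, 4); b0 <- matrix(0, 1, 4)
  expect_equal(classify(h, W0, b0), matrix(0.25, 2, 4), ignore_attr = TRUE)

  set.seed(2)
  W <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(4), 1, 4)
  p1 <- classify(h, W, b)
  expect_equal(rowSums(p1), c(1, 1))
  # shift invariance: adding a constant to every logit leaves probs unchanged
  p2 <- classify(h, W, b + 3.7)
  expect_equal(p1, p2, tolerance = 1e-12)

  # 2-class scalar toy with logits (1, 0)
  p <- classify(matrix(1, 1, 1), matrix(c(1, 0), 1, 2), matrix(0, 1, 2))
  expect_equal(as.numeric(p), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-9)

  # argmax tie-break toward the lowest class index
  expect_equal(predict_class(matrix(c(0.4, 0.4, 0.2), 1, 3)), 1L)
})

test_that("smooth_labels produces the stated mixtures", {
  expect_equal(smooth_labels(2L, 0, 3), matrix(c(0, 1, 0), 1, 3))
  expect_equal(smooth_labels(1L, 0.3, 5),
               matrix(c(0.76, 0.06, 0.06, 0.06, 0.06), 1, 3 + 2))
  expect_equal(smooth_labels(3L, 1, 4), matrix(0.25, 1, 4))
  expect_equal(rowSums(smooth_labels(c(1L, 2L, 2L), 0.3, 4)), rep(1, 3))
})

test_that("classification loss is the stated KL divergence", {
  q <- smooth_labels(c(1L, 2L), 0.3, 3)
  expect_equal(classification_loss(q, q), 0)

  # mu = 0, uniform prediction: cross-entropy log C
  onehot <- smooth_labels(c(1L, 3L), 0, 3)
  unif <- matrix(1 / 3, 2, 3)
  expect_equal(classification_loss(unif, onehot), log(3))

  # hand-set 3-class pair against scalar arithmetic
  p <- matrix(c(0.6, 0.3, 0.1), 1, 3)
  qq <- matrix(c(0.76, 0.12, 0.12), 1, 3)
  ref <- sum(qq * (log(qq) - log(p)))
  expect_equal(classification_loss(p, qq), ref, tolerance = 1e-9)
  expect_gte(classification_loss(p, qq), 0)

  # mu = 0 equals standard cross-entropy for random predictions
  set.seed(3)
  for (i in 1:20) {
    pr <- matrix(runif(12), 4, 3); pr <- pr / rowSums(pr)
    y <- sample(3, 4, replace = TRUE)
    expect_equal(classification_loss(pr, smooth_labels(y, 0, 3)),
                 -mean(log(pr[cbind(1:4, y)])))
  }
  expect_equal(total_loss(1.5, 0.25), 1.75)
  expect_equal(total_loss(0, 0), 0)
})

test_that("split_patients is stratified, exact, and deterministic", {
  y <- rep(1:2, each = 50)  # per-class shares are integral -> exact sizes
  s <- split_patients(y, c(0.5, 0.3, 0.2), seed = 7)
  expect_equal(lengths(s), c(train = 50L, val = 30L, test = 20L))
  expect_equal(sort(c(s$train, s$val, s$test)), 1:100)
  expect_identical(s, split_patients(y, c(0.5, 0.3, 0.2), seed = 7))

  # per-class proportions within one member of the global proportions
  set.seed(8)
  y2 <- sample(1:3, 83, replace = TRUE)
  s2 <- split_patients(y2, c(0.5, 0.3, 0.2), seed = 9)
  for (cl in 1:3) {
    nc <- sum(y2 == cl)
    expect_lte(abs(sum(y2[s2$train] == cl) - 0.5 * nc), 1)
    expect_lte(abs(sum(y2[s2$val] == cl) - 0.3 * nc), 1)
    expect_lte(abs(sum(y2[s2$test] == cl) - 0.2 * nc), 1)
  }

  expect_warning(s3 <- split_patients(c(1, 1, 1, 1, 2), seed = 1),
                 "fewer than 3")
  expect_true(any(c(1, 1, 1, 1, 2)[s3$train] == 2))
})

test_that("evaluate_predictions matches confusion-matrix enumeration", {
  perfect <- evaluate_predictions(c(1, 2, 3, 2), c(1, 2, 3, 2), 3)
  expect_equal(perfect$micro_f1, 1)
  expect_equal(perfect$macro_f1, 1)

  r <- evaluate_predictions(c(1, 1, 2, 3), c(1, 2, 2, 3), 3)
  expect_equal(r$micro_f1, 0.75)
  expect_equal(r$macro_f1, 7 / 9)
  expect_equal(r$per_class_f1, c(2 / 3, 2 / 3, 1))
  expect_equal(sum(r$confusion), 4)

  collapsed <- evaluate_predictions(rep(1:3, each = 3), rep(1L, 9), 3)
  expect_equal(collapsed$micro_f1, 1 / 3)
  expect_equal(collapsed$macro_f1, 1 / 6)

  expect_error(evaluate_predictions(1:3, 1:2, 3), "length mismatch")

  # micro-F1 is accuracy for single-label predictions (property)
  set.seed(4)
  for (i in 1:200) {
    C <- sample(2:6, 1); n <- sample(3:40, 1)
    yt <- sample(C, n, replace = TRUE); yp <- sample(C, n, replace = TRUE)
    rr <- evaluate_predictions(yt, yp, C)
    expect_equal(rr$micro_f1, mean(yt == yp))
    # independent enumeration of macro-F1
    f1s <- sapply(seq_len(C), function(cl) {
      tp <- sum(yt == cl & yp == cl)
      den <- 2 * tp + sum(yt != cl & yp == cl) + sum(yt == cl & yp != cl)
      if (den == 0) 0 else 2 * tp / den
    })
    expect_equal(rr$macro_f1, mean(f1s))
  }
})

smoke_config <- function(seed = 1, ...) {
  khopdiff_config(d = 16, heads = 2, per_hop = 4, k_max = 3, batch_size = 16,
                  T_steps = 10, ddim_steps = 4, gcn_hidden = 12, d_t = 6,
                  seed = seed, ...)
}

test_that("a one-epoch fit on a 30-patient toy completes with finite losses", {
  sim <- simulate_ehr_graph(synth_spec(n_patients = 30, n_drugs = 15,
                                       n_procedures = 8, n_classes = 3,
                                       drugs_per_patient_mean = 4,
                                       procedures_per_patient_mean = 2,
                                       seed = 21))
  fit <- khopdiff(sim$graph, sim$labels, smoke_config(max_epochs = 1))
  expect_s3_class(fit, "khopdiff")
  expect_true(all(is.finite(fit$log$loss_cls)))
  expect_true(all(is.finite(fit$log$loss_diff)))
  expect_s3_class(fit$test_report, "eval_report")
  expect_true(fit$test_report$macro_f1 >= 0 && fit$test_report$macro_f1 <= 1)

  # prediction interface
  pr <- predict(fit, type = "prob")
  expect_equal(dim(pr), c(30L, 3L))
  expect_equal(rowSums(pr), rep(1, 30), tolerance = 1e-8)
  cl <- predict(fit, patients = sim$graph$nodes$P[1:5])
  expect_s3_class(cl, "factor")
  expect_length(cl, 5)
  expect_equal(unname(coef(fit)[, 1]), as.numeric(fit$params$cls_W[1, ]))
})

test_that("ablation variants toggle the stated branches", {
  sim <- simulate_ehr_graph(synth_spec(n_patients = 30, n_drugs = 15,
                                       n_procedures = 8, n_classes = 2,
                                       drugs_per_patient_mean = 4,
                                       procedures_per_patient_mean = 2,
                                       seed = 22))
  cfg <- smoke_config(max_epochs = 1)
  f_trans <- khopdiff(sim$graph, sim$labels, cfg, variant = "my_onlytrans")
  expect_equal(f_trans$meta$lambda_eff, 1)
  expect_true(all(f_trans$log$loss_diff == 0))   # diffusion loss dropped
  expect_null(f_trans$params$dn_W1)

  f_diff <- khopdiff(sim$graph, sim$labels, cfg, variant = "my_onlydiff")
  expect_equal(f_diff$meta$lambda_eff, 0)
  expect_null(f_diff$params$E)                   # no transformer branch

  f_gcn <- khopdiff(sim$graph, sim$labels, cfg, variant = "my_gcn")
  expect_false(is.null(f_gcn$params$g_W1))
  expect_null(f_gcn$params$Wout)

  f_one <- khopdiff(sim$graph, sim$labels, cfg, variant = "my_onesub")
  expect_false(is.null(f_one$params$dn_W1))
})

test_that("training loss decreases over the first 10 epochs on the easy task", {
  drops <- sapply(1:3, function(s) {
    sim <- simulate_ehr_graph(synth_spec(n_patients = 150, n_drugs = 45,
                                         n_procedures = 20, n_classes = 3,
                                         seed = s))
    fit <- khopdiff(sim$graph, sim$labels,
                    smoke_config(seed = s, max_epochs = 10, patience = 10))
    total <- fit$log$loss_cls + fit$log$loss_diff
    total[1] - total[10]
  })
  expect_gt(median(drops), 0)
})
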