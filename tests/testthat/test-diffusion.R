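small_views <- function(seed = 12) {
  sim <- simulate_ehr_graph(synth_spec(n_patients = 40, n_drugs = 16,
                                       n_procedures = 8, n_classes = 2,
                                       drugs_per_patient_mean = 4,
                                       procedures_per_patient_mean = 2,
                                       seed = seed))
  build_views(sim$graph, seed = seed)
}

test_that("build_views derives meta-path adjacencies and normalized features", {
  g <- het_graph(pd_edges = data.frame(src = c("p1", "p2"), dst = c("d1", "d1")))
  vs <- build_views(g)
  expect_equal(as.matrix(vs[[1]]$A), matrix(c(0, 1, 1, 0), 2, 2),
               ignore_attr = TRUE)

  # nothing shared anywhere: both adjacencies zero
  g0 <- het_graph(pd_edges = data.frame(src = c("p1", "p2"), dst = c("d1", "d2")),
                  po_edges = data.frame(src = c("p1", "p2"), dst = c("o1", "o2")))
  vs0 <- build_views(g0)
  expect_equal(sum(vs0[[1]]$A), 0)
  expect_equal(sum(vs0[[2]]$A), 0)

  # view 2 equals the exhaustively enumerated P-D-P-O-P reachability
  g6 <- het_graph(
    pd_edges = data.frame(src = c("p1", "p2", "p3"), dst = c("d1", "d1", "d2")),
    po_edges = data.frame(src = c("p2", "p3"), dst = c("o1", "o1")))
  W <- walk_enumeration(g6, c("P", "D", "P", "O", "P")); diag(W) <- 0
  expect_equal(as.matrix(build_views(g6)[[2]]$A), 1 * (W > 0),
               ignore_attr = TRUE)

  # features are row-L2-normalized patient incidence vectors
  vs6 <- build_views(g6)
  expect_equal(rowSums(vs6[[1]]$X^2), rep(1, 3))
  expect_equal(vs6[[1]]$X, vs6[[2]]$X)
})

test_that("encode_view is the normalized-adjacency convolution, row-normalized", {
  # zero adjacency: each row is a transform of its own features (self-loop)
  g0 <- het_graph(pd_edges = data.frame(src = c("p1", "p2"), dst = c("d1", "d2")))
  v0 <- build_views(g0)[[1]]
  expect_equal(sum(v0$A), 0)
  dp <- diffusion_params(ncol(v0$X), d = 4, hidden = 8, d_t = 4, seed = 3)
  h0 <- encode_view(v0, dp)
  byhand <- v0$X %*% dp$enc_W  # Ahat = I when A = 0
  byhand <- byhand / sqrt(rowSums(byhand^2))
  expect_equal(h0, byhand, tolerance = 1e-12)

  # identical features + identical neighbourhoods: identical rows
  g2 <- het_graph(pd_edges = data.frame(src = c("p1", "p2", "p3"),
                                        dst = c("d1", "d1", "d1")))
  v2 <- build_views(g2)[[1]]
  h2 <- encode_view(v2, diffusion_params(ncol(v2$X), 4, 8, 4, seed = 1))
  expect_equal(h2[1, ], h2[2, ])

  # 3-node toy against a dense by-hand normalized-adjacency multiply
  g3 <- het_graph(pd_edges = data.frame(src = c("p1", "p2", "p3"),
                                        dst = c("d1", "d1", "d2")))
  v3 <- build_views(g3)[[1]]
  dp3 <- diffusion_params(ncol(v3$X), 4, 8, 4, seed = 7)
  A <- as.matrix(v3$A) + diag(3)
  Ahat <- diag(1 / sqrt(rowSums(A))) %*% A %*% diag(1 / sqrt(rowSums(A)))
  ref <- Ahat %*% (v3$X %*% dp3$enc_W)
  ref <- ref / sqrt(rowSums(ref^2))
  expect_equal(encode_view(v3, dp3), ref, tolerance = 1e-6)
})

test_that("make_schedule obeys its closed forms and rejects bad input", {
  s1 <- make_schedule(1, 0.2, 1)
  expect_equal(s1$alpha_bar, 1 - s1$beta)

  sc <- make_schedule(20, 0.1, 5, beta_min_frac = 1)  # constant beta
  expect_equal(sc$beta, rep(0.1, 20))
  expect_equal(sc$alpha_bar, 0.9^(1:20))

  s <- make_schedule(50, 1e-5, 10)
  expect_true(all(diff(s$alpha_bar) < 0))  # strictly decreasing
  expect_true(s$alpha_bar[50] > 0)
  expect_equal(s$alpha_bar[50], exp(-sum(s$beta)), tolerance = 1e-8)
  expect_equal(s$sigma, rep(0, 50))  # deterministic DDIM variances

  expect_error(make_schedule(50, 1), "invalid schedule")
  expect_error(make_schedule(0, 0.1), "invalid schedule")
})

test_that("forward diffusion follows the closed form and its limits", {
  set.seed(5)
  h0 <- matrix(rnorm(12), 4, 3)
  sch <- make_schedule(10, 0.3, 5)
  expect_equal(forward_diffuse(h0, 7, sch, eps = h0 * 0),
               sqrt(sch$alpha_bar[7]) * h0)
  # near-zero noise: h_t ~ h0
  tiny <- make_schedule(10, 1e-9, 5)
  expect_equal(forward_diffuse(h0, 10, tiny, eps = matrix(1, 4, 3)), h0,
               tolerance = 1e-4)
  expect_error(forward_diffuse(h0, 11, sch), "out of range")
  expect_error(forward_diffuse(h0, 0, sch), "out of range")
})

test_that("closed-form marginal matches the sequential one-step composition", {
  # iterate h_t = sqrt(1-beta_t) h_{t-1} + sqrt(beta_t) eps_t and compare
  # mean/variance with the closed form at t = T over many draws
  sch <- make_schedule(10, 0.4, 5)
  h0 <- matrix(c(2, -1), 1, 2)
  n <- 4000
  seq_draws <- matrix(0, n, 2)
  set.seed(8)
  for (r in seq_len(n)) {
    h <- h0
    for (t in seq_len(sch$T)) {
      h <- sqrt(1 - sch$beta[t]) * h + sqrt(sch$beta[t]) * rnorm(2)
    }
    seq_draws[r, ] <- h
  }
  abT <- sch$alpha_bar[sch$T]
  se_mean <- sqrt((1 - abT) / n)
  expect_true(all(abs(colMeans(seq_draws) - sqrt(abT) * as.numeric(h0)) <
                    3 * se_mean))
  se_var <- (1 - abT) * sqrt(2 / (n - 1))
  expect_true(all(abs(apply(seq_draws, 2, var) - (1 - abT)) < 3 * se_var))
})

test_that("predict_noise: zero weights, permutation equivariance, shapes", {
  vs <- small_views()
  d <- 6
  dp <- diffusion_params(ncol(vs[[1]]$X), d, hidden = 10, d_t = 4, seed = 4)
  N <- nrow(vs[[1]]$X)
  set.seed(6)
  h1 <- matrix(rnorm(N * d), N, d); h2 <- matrix(rnorm(N * d), N, d)

  dp0 <- dp
  for (nm in names(dp0)) if (startsWith(nm, "dn_")) dp0[[nm]][] <- 0
  expect_equal(predict_noise(h1, 3, h2, vs[[1]], dp0), matrix(0, N, d))

  e <- predict_noise(h1, 3, h2, vs[[1]], dp)
  expect_equal(dim(e), c(N, d))

  # consistent patient permutation permutes the prediction identically
  perm <- sample(N)
  vperm <- vs[[1]]
  vperm$A <- vs[[1]]$A[perm, perm]
  vperm$Ahat <- getFromNamespace("sym_norm_adj", "khopdiff")(vperm$A)
  vperm$X <- vs[[1]]$X[perm, ]
  eperm <- predict_noise(h1[perm, ], 3, h2[perm, ], vperm, dp)
  expect_equal(eperm, e[perm, ], tolerance = 1e-10)

  for (N2 in c(1, 5, 17)) {
    g <- het_graph(pd_edges = data.frame(src = paste0("p", seq_len(N2)),
                                         dst = "d1"))
    v <- build_views(g)[[1]]
    dpN <- diffusion_params(ncol(v$X), d, hidden = 10, d_t = 4, seed = 4)
    hN <- matrix(rnorm(N2 * d), N2, d)
    expect_equal(dim(predict_noise(hN, 2, hN, v, dpN)), c(N2, d))
  }
})

test_that("DDIM reverse inverts the forward process under an oracle denoiser", {
  vs <- small_views()
  d <- 6
  dp <- diffusion_params(ncol(vs[[1]]$X), d, hidden = 10, d_t = 4, seed = 4)
  h01 <- khopdiff:::ad_val(encode_view(vs[[1]], dp))
  h02 <- khopdiff:::ad_val(encode_view(vs[[2]], dp))
  sch <- make_schedule(50, 0.05, 10)
  N <- nrow(h01)
  set.seed(9)
  epsT <- list(matrix(rnorm(N * d), N, d), matrix(rnorm(N * d), N, d))

  # oracle: return each view's true injected terminal noise
  oracle <- function(h_own, t, h_other, view) epsT[[view$view_id]]
  rec <- ddim_reverse(h01, h02, vs[[1]], vs[[2]], sch, dp,
                      noise_fn = oracle, eps_T = epsT)
  expect_lt(max(abs(rec - h01)) / max(abs(h01)), 1e-5)

  # eps_hat = 0 collapses to h_T / sqrt(alpha_bar_T) regardless of step count
  zerofn <- function(h_own, t, h_other, view) h_own * 0
  rec0 <- ddim_reverse(h01, h02, vs[[1]], vs[[2]], sch, dp,
                       noise_fn = zerofn, eps_T = epsT)
  hT <- forward_diffuse(h01, sch$T, sch, epsT[[1]])
  expect_equal(rec0, hT / sqrt(sch$alpha_bar[sch$T]), tolerance = 1e-10)

  # one-step DDIM equals the direct x0 formula at t = T
  sch1 <- make_schedule(50, 0.05, 1)
  ehat <- predict_noise(forward_diffuse(h01, 50, sch1, epsT[[1]]), 50,
                        forward_diffuse(h02, 50, sch1, epsT[[2]]), vs[[1]], dp)
  rec1 <- ddim_reverse(h01, h02, vs[[1]], vs[[2]], sch1, dp, eps_T = epsT)
  hT1 <- forward_diffuse(h01, 50, sch1, epsT[[1]])
  expect_equal(rec1, (hT1 - sqrt(1 - sch1$alpha_bar[50]) * ehat) /
                 sqrt(sch1$alpha_bar[50]), tolerance = 1e-10)
})

test_that("diffusion loss: perfect denoiser, zero denoiser, permutation invariance", {
  vs <- small_views()
  d <- 6
  dp <- diffusion_params(ncol(vs[[1]]$X), d, hidden = 10, d_t = 4, seed = 4)
  h01 <- khopdiff:::ad_val(encode_view(vs[[1]], dp))
  h02 <- khopdiff:::ad_val(encode_view(vs[[2]], dp))
  sch <- make_schedule(20, 0.1, 5)
  N <- nrow(h01)
  set.seed(10)
  eps <- list(matrix(rnorm(N * d), N, d), matrix(rnorm(N * d), N, d))

  perfect <- function(h_own, t, h_other, view) eps[[view$view_id]]
  expect_equal(as.numeric(diffusion_loss(h01, h02, vs[[1]], vs[[2]], sch, dp,
                                         t = 5, eps = eps,
                                         noise_fn = perfect)), 0)

  # eps_hat = 0: Monte-Carlo mean of the per-patient squared noise norm ~ d
  zerofn <- function(h_own, t, h_other, view) h_own * 0
  set.seed(11)
  draws <- replicate(400, {
    e <- list(matrix(rnorm(N * d), N, d), matrix(rnorm(N * d), N, d))
    as.numeric(diffusion_loss(h01, h02, vs[[1]], vs[[2]], sch, dp, t = 5,
                              eps = e, noise_fn = zerofn))
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - d), 3 * se)

  # loss is invariant under a consistent patient permutation
  set.seed(12)
  eps1 <- list(matrix(rnorm(N * d), N, d), matrix(rnorm(N * d), N, d))
  l0 <- as.numeric(diffusion_loss(h01, h02, vs[[1]], vs[[2]], sch, dp,
                                  t = 7, eps = eps1))
  perm <- sample(N)
  pv <- lapply(vs, function(v) {
    v$A <- v$A[perm, perm]
    v$Ahat <- getFromNamespace("sym_norm_adj", "khopdiff")(v$A)
    v$X <- v$X[perm, ]
    v
  })
  l1 <- as.numeric(diffusion_loss(h01[perm, ], h02[perm, ], pv[[1]], pv[[2]],
                                  sch, dp, t = 7,
                                  eps = lapply(eps1, function(e) e[perm, ])))
  expect_equal(l1, l0, tolerance = 1e-10)
})

test_that("fuse_views averages elementwise and checks shapes", {
  a <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(12), 3, 4)
  expect_equal(fuse_views(a, a), a)
  expect_equal(fuse_views(a, a * 0), a / 2)
  expect_equal(fuse_views(a, b), (a + b) / 2)
  expect_error(fuse_views(a, matrix(0, 2, 4)), "shape mismatch")
})

test_that("low-noise schedule keeps h_T close to h0; denoiser weights are shared", {
  vs <- small_views()
  dp <- diffusion_params(ncol(vs[[1]]$X), 8, hidden = 12, d_t = 4, seed = 4)
  h01 <- khopdiff:::ad_val(encode_view(vs[[1]], dp))
  sch <- make_schedule(50, 1e-5, 10)
  set.seed(13)
  hT <- forward_diffuse(h01, 50, sch)
  expect_lt(norm(hT - h01, "F") / norm(h01, "F"), 0.1)

  # mutating the single shared parameter set changes BOTH views' predictions
  h02 <- khopdiff:::ad_val(encode_view(vs[[2]], dp))
  e2a <- predict_noise(h02, 3, h01, vs[[2]], dp)
  dp$dn_b3[1, 1] <- dp$dn_b3[1, 1] + 0.5
  e2b <- predict_noise(h02, 3, h01, vs[[2]], dp)
  expect_false(isTRUE(all.equal(e2a, e2b)))
})

test_that("a trained denoiser reconstructs better than no denoising", {
  # run at a resolvable noise strength (0.05): at the 1e-5 training default the
  # forward process is a <2% perturbation and the two MSEs coincide, so the
  # comparison is only meaningful where alpha_bar decays visibly
  vs <- small_views()
  d <- 8
  sch <- make_schedule(50, 0.05, 10)
  dp <- diffusion_params(ncol(vs[[1]]$X), d, hidden = 24, d_t = 8, seed = 2)
  dp <- fit_denoiser(vs[[1]], vs[[2]], sch, dp, steps = 250, seed = 5)
  h01 <- khopdiff:::ad_val(encode_view(vs[[1]], dp))
  h02 <- khopdiff:::ad_val(encode_view(vs[[2]], dp))
  set.seed(14)  # fresh noise draws, unseen in training
  N <- nrow(h01)
  epsT <- list(matrix(rnorm(N * d), N, d), matrix(rnorm(N * d), N, d))
  hT <- forward_diffuse(h01, sch$T, sch, epsT[[1]])
  rec <- getFromNamespace("ddim_reverse_pair", "khopdiff")(
    h01, h02, vs[[1]], vs[[2]], sch, dp, eps_T = epsT)
  expect_lt(mean((rec[[1]] - h01)^2), mean((hT - h01)^2))
  # and training reduced the noise-prediction loss
  tr <- attr(dp, "loss_trace")
  expect_lt(mean(tail(tr, 20)), 0.5 * mean(head(tr, 20)))
})
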