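# Dual-view latent diffusion denoiser.
#
# Two auxiliary patient-patient subgraphs are built from the P-D-P and
# P-D-P-O-P meta-paths. A shallow GCN encodes each view's patient incidence
# features into clean embeddings h0; the forward process injects Gaussian
# noise under a linear low-noise schedule; a single 3-layer GCN denoiser,
# shared across views and conditioned on the *other* view's noisy state plus a
# sinusoidal time embedding, predicts the injected noise; deterministic DDIM
# sampling over a short timestep subsequence reconstructs denoised embeddings,
# which the two views average into h^diff.

# Symmetric degree-normalized adjacency with self-loops:
# D^{-1/2} (A + I) D^{-1/2}.
sym_norm_adj <- function(A) {
  A <- A + Matrix::Diagonal(nrow(A))
  dg <- 1 / sqrt(Matrix::rowSums(A))
  Matrix::Diagonal(x = dg) %*% A %*% Matrix::Diagonal(x = dg)
}

#' Build the two auxiliary diffusion views
#'
#' View 1 links patients sharing at least one drug (P-D-P); view 2 links
#' patients connected under the longer P-D-P-O-P template. Patient features
#' are the row-L2-normalized binary incidence vectors over drugs and
#' procedures (union of both edge directions); if that exceeds `d_x_max`
#' columns, a seeded Gaussian random projection reduces them to `d_x_max`.
#'
#' @param graph a [het_graph()].
#' @param d_x_max maximum feature dimension before random projection
#'   (default 256).
#' @param seed seed for the random projection (only used when projecting).
#' @return A list of two `aux_view` objects, each with `view_id`, `A` (binary
#'   symmetric zero-diagonal sparse adjacency), `Ahat` (normalized adjacency
#'   with self-loops) and `X` (patient feature matrix).
#' @export
build_views <- function(graph, d_x_max = 256L, seed = 1L) {
  stopifnot(length(graph$nodes$P) >= 1L)
  inc_d <- 1 * ((graph$adj[["P-D"]] + Matrix::t(graph$adj[["D-P"]])) != 0)
  inc_o <- 1 * ((graph$adj[["P-O"]] + Matrix::t(graph$adj[["O-P"]])) != 0)
  X <- as.matrix(cbind(inc_d, inc_o))
  if (ncol(X) > d_x_max) {
    set.seed(derive_seed(seed, 555))
    R <- mat_init(ncol(X), d_x_max, 1 / sqrt(d_x_max))
    X <- X %*% R
  }
  n <- pmax(sqrt(rowSums(X^2)), 1e-12)
  X <- X / n
  mk <- function(id, path) {
    A <- compose_metapath(graph, path)
    list(view_id = id, A = A, Ahat = sym_norm_adj(A), X = X)
  }
  list(mk(1L, "P-D-P"), mk(2L, "P-D-P-O-P"))
}

#' Initialize diffusion-module parameters
#'
#' One shallow GCN encoder weight per view feature space (shared by both views
#' since they share features) plus the shared 3-layer GCN denoiser.
#'
#' @param d_x feature dimension of the views.
#' @param d embedding dimension.
#' @param hidden denoiser hidden width (default 128).
#' @param d_t sinusoidal time-embedding width (default 16).
#' @param seed seed for initialization.
#' @return Flat named list of matrices (class `diffusion_params`), attributes
#'   `d`, `hidden`, `d_t`.
#' @export
diffusion_params <- function(d_x, d, hidden = 128L, d_t = 16L, seed = 1L) {
  set.seed(derive_seed(seed, 999))
  p <- list(
    enc_W = mat_init(d_x, d, 1 / sqrt(d_x)),
    dn_W1 = mat_init(2L * d + d_t, hidden, 1 / sqrt(2 * d + d_t)),
    dn_R1 = mat_init(2L * d + d_t, hidden, 1 / sqrt(2 * d + d_t)),
    dn_b1 = matrix(0, 1, hidden),
    dn_W2 = mat_init(hidden, hidden, 1 / sqrt(hidden)),
    dn_R2 = mat_init(hidden, hidden, 1 / sqrt(hidden)),
    dn_b2 = matrix(0, 1, hidden),
    dn_W3 = mat_init(hidden, d, 1 / sqrt(hidden)),
    dn_R3 = mat_init(hidden, d, 1 / sqrt(hidden)),
    dn_b3 = matrix(0, 1, d))
  structure(p, d = as.integer(d), hidden = as.integer(hidden),
            d_t = as.integer(d_t), class = "diffusion_params")
}

#' Encode a view with the shallow GCN
#'
#' `h0 = rownorm(Ahat X W)`: one symmetric-normalized graph convolution of the
#' view features, rows L2-normalized afterwards (embeddings are normalized
#' before entering the diffusion process).
#'
#' @param view an `aux_view` from [build_views()].
#' @param params a [diffusion_params()] (plain or tape nodes).
#' @return N x d clean embedding matrix (an `ad_node` when params are nodes).
#' @export
encode_view <- function(view, params) {
  ad_rownorm(ad_spmm(view$Ahat, ad_mm(view$X, params$enc_W)))
}

#' Create a diffusion noise schedule
#'
#' Per-step variances beta are linearly spaced from
#' `beta_min_frac * noise_strength` to `noise_strength`;
#' `alpha_bar_t = prod_{i<=t}(1 - beta_i)`. The stored per-step standard
#' deviations are zero: inference uses the deterministic DDIM sampler.
#'
#' @param T_steps number of diffusion steps (default 50).
#' @param noise_strength terminal beta, in (0, 1) (default 1e-5, the low-noise
#'   regime the model is trained in).
#' @param ddim_steps length of the DDIM inference subsequence (default 10).
#' @param beta_min_frac ratio of the initial to the terminal beta
#'   (default 0.1; 1 gives a constant schedule).
#' @return An object of class `noise_schedule` with `T`, `beta`, `alpha_bar`,
#'   `sigma`, `ddim_steps`.
#' @export
make_schedule <- function(T_steps = 50L, noise_strength = 1e-5,
                          ddim_steps = 10L, beta_min_frac = 0.1) {
  if (!(noise_strength > 0 && noise_strength < 1) || T_steps < 1) {
    stop("invalid schedule")
  }
  T_steps <- as.integer(T_steps)
  beta <- seq(beta_min_frac * noise_strength, noise_strength,
              length.out = T_steps)
  structure(list(T = T_steps, beta = beta, alpha_bar = cumprod(1 - beta),
                 sigma = rep(0, T_steps),
                 ddim_steps = as.integer(min(ddim_steps, T_steps))),
            class = "noise_schedule")
}

#' Forward diffusion (closed form)
#'
#' `h_t = sqrt(alpha_bar_t) h0 + sqrt(1 - alpha_bar_t) eps` with standard
#' normal noise.
#'
#' @param h0 clean embedding matrix.
#' @param t diffusion step, in 1..T.
#' @param schedule a [make_schedule()].
#' @param eps optional noise matrix (for reproducible or stubbed noise);
#'   defaults to a fresh standard-normal draw.
#' @return Noisy matrix `h_t` of the same shape.
#' @export
forward_diffuse <- function(h0, t, schedule, eps = NULL) {
  if (t < 1 || t > schedule$T) stop("diffusion step out of range")
  if (is.null(eps)) eps <- matrix(stats::rnorm(length(h0)), nrow(h0), ncol(h0))
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * h0 + sqrt(1 - ab) * eps
}

# Sinusoidal embedding of step t as an N x d_t constant block.
time_embedding <- function(t, d_t, N) {
  half <- d_t %/% 2L
  freqs <- 1 / (1000^((seq_len(half) - 1) / max(half - 1, 1)))
  emb <- c(sin(t * freqs), cos(t * freqs))
  if (length(emb) < d_t) emb <- c(emb, rep(0, d_t - length(emb)))
  matrix(emb, N, d_t, byrow = TRUE)
}

#' Predict injected noise with the shared cross-view GCN denoiser
#'
#' `eps_hat = eps_theta(concat(h_t_own, h_t_other, time embedding))`
#' propagated through three graph-convolution layers over the view's own
#' normalized adjacency. Each layer carries a root (self) weight,
#' `Z' = act(Ahat Z W + Z R + b)`: pure adjacency propagation dilutes a node's
#' own noisy state to ~1/deg per layer, leaving the injected noise - which is
#' node-local by construction - unrecoverable. The parameter set is shared
#' across both views.
#'
#' @param h_t_own the view's own noisy embedding (N x d).
#' @param t diffusion step.
#' @param h_t_other the other view's noisy embedding (cross-view condition).
#' @param view the `aux_view` whose adjacency propagates the convolution.
#' @param params a [diffusion_params()] (plain or tape nodes).
#' @return N x d predicted noise (an `ad_node` when params are nodes).
#' @export
predict_noise <- function(h_t_own, t, h_t_other, view, params) {
  d_t <- attr(params, "d_t")
  if (is.null(d_t)) {  # tolerate bare lists: d_t = in_dim - 2 d
    d_t <- nrow(ad_val(params$dn_W1)) - 2L * ncol(ad_val(params$dn_W3))
  }
  N <- nrow(ad_val(h_t_own))
  U <- ad_cbind(list(h_t_own, h_t_other, time_embedding(t, d_t, N)))
  gc_layer <- function(Z, W, R, b) {
    ad_addbias(ad_add(ad_spmm(view$Ahat, ad_mm(Z, W)), ad_mm(Z, R)), b)
  }
  Z1 <- ad_relu(gc_layer(U, params$dn_W1, params$dn_R1, params$dn_b1))
  Z2 <- ad_relu(gc_layer(Z1, params$dn_W2, params$dn_R2, params$dn_b2))
  gc_layer(Z2, params$dn_W3, params$dn_R3, params$dn_b3)
}

ddim_taus <- function(schedule) {
  rev(sort(unique(round(seq(schedule$T, 1, length.out = schedule$ddim_steps)))))
}

# Lockstep deterministic DDIM reverse pass over both views.
ddim_reverse_pair <- function(h0_1, h0_2, view1, view2, schedule, params,
                              noise_fn = NULL, eps_T = NULL) {
  if (is.null(noise_fn)) {
    noise_fn <- function(h_own, t, h_other, view) {
      ad_val(predict_noise(h_own, t, h_other, view, params))
    }
  }
  if (is.null(eps_T)) {
    eps_T <- list(matrix(stats::rnorm(length(h0_1)), nrow(h0_1), ncol(h0_1)),
                  matrix(stats::rnorm(length(h0_2)), nrow(h0_2), ncol(h0_2)))
  }
  h1 <- forward_diffuse(h0_1, schedule$T, schedule, eps_T[[1]])
  h2 <- forward_diffuse(h0_2, schedule$T, schedule, eps_T[[2]])
  taus <- ddim_taus(schedule)
  ab <- schedule$alpha_bar
  x01 <- h1; x02 <- h2
  for (i in seq_along(taus)) {
    t <- taus[i]
    e1 <- noise_fn(h1, t, h2, view1)
    e2 <- noise_fn(h2, t, h1, view2)
    x01 <- (h1 - sqrt(1 - ab[t]) * e1) / sqrt(ab[t])
    x02 <- (h2 - sqrt(1 - ab[t]) * e2) / sqrt(ab[t])
    if (i < length(taus)) {
      tn <- taus[i + 1]
      h1 <- sqrt(ab[tn]) * x01 + sqrt(1 - ab[tn]) * e1
      h2 <- sqrt(ab[tn]) * x02 + sqrt(1 - ab[tn]) * e2
    }
  }
  list(x01, x02)
}

#' Deterministic DDIM reverse sampling
#'
#' Starting from `h_T` (a terminal forward diffusion of the clean embedding),
#' iterates the deterministic DDIM update (`sigma_t = 0`) over the
#' `ddim_steps` timestep subsequence:
#' `x0_hat = (h_t - sqrt(1 - alpha_bar_t) eps_hat) / sqrt(alpha_bar_t)`,
#' then `h_t' = sqrt(alpha_bar_t') x0_hat + sqrt(1 - alpha_bar_t') eps_hat`.
#' Both views are advanced in lockstep so the denoiser can cross-condition on
#' the other view's current noisy state.
#'
#' @param h0_own,h0_other clean embeddings of the view being reconstructed and
#'   of the other view.
#' @param view,other_view the corresponding `aux_view` objects.
#' @param schedule a [make_schedule()].
#' @param params a [diffusion_params()].
#' @param noise_fn optional noise-prediction override,
#'   `function(h_own, t, h_other, view)`; defaults to [predict_noise()].
#'   (Passing the true injected noise makes the pass invert the forward
#'   process exactly.)
#' @param eps_T optional list of the two terminal noise draws.
#' @return The reconstructed clean embedding `h0_hat` for `view` (N x d).
#' @export
ddim_reverse <- function(h0_own, h0_other, view, other_view, schedule, params,
                         noise_fn = NULL, eps_T = NULL) {
  pair <- ddim_reverse_pair(h0_own, h0_other, view, other_view, schedule,
                            params, noise_fn = noise_fn, eps_T = eps_T)
  pair[[1]]
}

#' Diffusion training loss
#'
#' Samples a step t uniformly in 1..T and standard-normal noise, forms the
#' closed-form noisy embeddings for both views, and returns the mean (over
#' patients, then over the two views) squared row-norm of the noise-prediction
#' error `||eps_hat - eps||^2`. Both views share one denoiser parameter set.
#'
#' @param h0_1,h0_2 clean embeddings of the two views (plain or `ad_node`).
#' @param view1,view2 the `aux_view` objects.
#' @param schedule a [make_schedule()].
#' @param params a [diffusion_params()] (plain or tape nodes).
#' @param t optional fixed step (sampled uniformly when NULL).
#' @param eps optional list of two noise matrices (sampled when NULL).
#' @param noise_fn optional noise-prediction override (see [ddim_reverse()]).
#' @return Non-negative scalar loss (1 x 1 `ad_node` when params are nodes).
#' @export
diffusion_loss <- function(h0_1, h0_2, view1, view2, schedule, params,
                           t = NULL, eps = NULL, noise_fn = NULL) {
  if (is.null(t)) t <- sample.int(schedule$T, 1L)
  d <- ncol(ad_val(h0_1))
  N <- nrow(ad_val(h0_1))
  if (is.null(eps)) {
    eps <- list(matrix(stats::rnorm(N * d), N, d),
                matrix(stats::rnorm(N * d), N, d))
  }
  ab <- schedule$alpha_bar[t]
  noisy <- function(h0, e) {
    ad_add(ad_mul(h0, sqrt(ab)), sqrt(1 - ab) * e)
  }
  h1t <- noisy(h0_1, eps[[1]])
  h2t <- noisy(h0_2, eps[[2]])
  if (is.null(noise_fn)) {
    e1h <- predict_noise(h1t, t, h2t, view1, params)
    e2h <- predict_noise(h2t, t, h1t, view2, params)
  } else {
    e1h <- noise_fn(ad_val(h1t), t, ad_val(h2t), view1)
    e2h <- noise_fn(ad_val(h2t), t, ad_val(h1t), view2)
  }
  # per-patient squared error summed over coordinates = d * entrywise MSE
  l1 <- ad_mul(ad_mse(e1h, eps[[1]]), d)
  l2 <- ad_mul(ad_mse(e2h, eps[[2]]), d)
  ad_mul(ad_add(l1, l2), 0.5)
}

#' Fuse the two views' reconstructions
#'
#' Elementwise mean of the two denoised embeddings.
#'
#' @param h0_hat_1,h0_hat_2 equal-shape reconstruction matrices.
#' @return Their elementwise mean.
#' @export
fuse_views <- function(h0_hat_1, h0_hat_2) {
  v1 <- ad_val(h0_hat_1); v2 <- ad_val(h0_hat_2)
  if (!all(dim(v1) == dim(v2))) stop("shape mismatch")
  ad_mul(ad_add(h0_hat_1, h0_hat_2), 0.5)
}

#' Fit the denoiser on clean embeddings
#'
#' Standalone Adam optimization of the shared denoiser (and view encoder) on
#' [diffusion_loss()], used both inside the end-to-end trainer and on its own
#' to study denoising utility.
#'
#' @param view1,view2 `aux_view` objects.
#' @param schedule a [make_schedule()].
#' @param params a [diffusion_params()].
#' @param steps number of Adam steps.
#' @param lr learning rate.
#' @param seed RNG seed for (t, eps) draws.
#' @param train_encoder whether gradients also flow into the encoder weight.
#' @return Updated `diffusion_params` with a `loss_trace` attribute.
#' @export
fit_denoiser <- function(view1, view2, schedule, params, steps = 200L,
                         lr = 3e-3, seed = 1L, train_encoder = TRUE) {
  plist <- unclass(params)
  state <- adam_init(plist)
  trace <- numeric(steps)
  set.seed(derive_seed(seed, 4242))
  for (s in seq_len(steps)) {
    tape <- ad_tape()
    nodes <- ad_attach(tape, plist)
    attributes(nodes) <- attributes(params)
    h0_1 <- encode_view(view1, nodes)
    h0_2 <- encode_view(view2, nodes)
    if (!train_encoder) {
      h0_1 <- ad_val(h0_1); h0_2 <- ad_val(h0_2)
    }
    loss <- diffusion_loss(h0_1, h0_2, view1, view2, schedule, nodes)
    trace[s] <- ad_val(loss)[1]
    ad_backward(loss)
    upd <- adam_step(plist, ad_grads(nodes), state, lr = lr)
    plist <- upd$params; state <- upd$state
  }
  out <- structure(plist, class = "diffusion_params")
  attributes(out) <- attributes(params)
  attr(out, "loss_trace") <- trace
  out
}
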