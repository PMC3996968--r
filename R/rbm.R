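#' Restricted Boltzmann machine parameters
#'
#' A bipartite energy-based model over visible units v and hidden units h
#' with no within-layer connections.  The energy convention used throughout
#' this package is
#' \deqn{E(v, h) = h^T W v + d^T h + b^T v, \qquad P(v, h) = \frac{1}{Z}
#'   e^{E(v,h)},}
#' i.e. higher energy means higher probability — the negative of the usual
#' physics convention.  `w` is hidden x visible.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param init_scale sd of the Normal(0, init_scale^2) weight
#'   initialization; biases start at zero.
#' @return Object of class `rbm_params` with elements `w`
#'   (`n_hidden x n_visible`), `b` (visible bias), `d` (hidden bias).
#' @export
rbm_params <- function(n_visible, n_hidden, init_scale = 0.01) {
  structure(list(
    w = matrix(stats::rnorm(n_hidden * n_visible, sd = init_scale),
               n_hidden, n_visible),
    b = numeric(n_visible),
    d = numeric(n_hidden)), class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("rbm_params: %d visible, %d hidden\n", ncol(x$w), nrow(x$w)))
  invisible(x)
}

#' RBM training configuration
#'
#' None of these values is dictated by the model itself; the defaults are
#' conventional small-data choices (see the vignette).
#'
#' @param cd_k Gibbs steps per contrastive-divergence update (>= 1).
#' @param learning_rate step size (> 0; 0 is allowed and leaves parameters
#'   unchanged, which is useful for testing).
#' @param epochs passes over the data.
#' @param batch_size minibatch size.
#' @param seed RNG seed applied once at the start of training.
#' @param init_scale weight initialization sd.
#' @return Object of class `train_config`.
#' @export
train_config <- function(cd_k = 1L, learning_rate = 0.5, epochs = 100L,
                         batch_size = 16L, seed = 1L, init_scale = 0.01) {
  cd_k <- as.integer(cd_k)
  if (cd_k < 1L) stop("'cd_k' must be >= 1")
  if (learning_rate < 0) stop("'learning_rate' must be >= 0")
  structure(list(cd_k = cd_k, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), init_scale = init_scale),
            class = "train_config")
}

#' RBM energy
#'
#' \eqn{E(v,h) = h^T W v + d^T h + b^T v} under the sign convention
#' \eqn{P \propto e^E}.
#'
#' @param params an [rbm_params()].
#' @param v visible vector (binary or in \eqn{[0,1]}).
#' @param h hidden vector.
#' @return Scalar energy.
#' @export
rbm_energy <- function(params, v, h) {
  as.numeric(h %*% params$w %*% v) + sum(params$d * h) + sum(params$b * v)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Hidden-given-visible activation probabilities
#'
#' \eqn{P(h_j = 1 \mid v) = \mathrm{sigmoid}(d_j + \sum_i W_{ji} v_i)};
#' the hidden units are conditionally independent given v.
#'
#' @param params an [rbm_params()].
#' @param v a visible vector, or a matrix with one case per row.
#' @return Probabilities with the same case layout as `v`.
#' @export
prob_h_given_v <- function(params, v) {
  if (is.matrix(v))
    sigmoid(sweep(v %*% t(params$w), 2L, params$d, `+`))
  else
    sigmoid(as.numeric(params$w %*% v) + params$d)
}

#' Visible-given-hidden activation probabilities
#'
#' \eqn{P(v_i = 1 \mid h) = \mathrm{sigmoid}(b_i + \sum_j W_{ji} h_j)}.
#'
#' @param params an [rbm_params()].
#' @param h a hidden vector, or a matrix with one case per row.
#' @return Probabilities with the same case layout as `h`.
#' @export
prob_v_given_h <- function(params, h) {
  if (is.matrix(h))
    sigmoid(sweep(h %*% params$w, 2L, params$b, `+`))
  else
    sigmoid(as.numeric(h %*% params$w) + params$b)
}

# Bernoulli sampling of a probability matrix; consumes runif(length(p)) in
# column-major order.  The order is part of the package contract so that
# seeded runs can be replayed exactly.
sample_bernoulli <- function(p) {
  (matrix(stats::runif(length(p)), nrow(p), ncol(p)) < p) * 1
}

#' One contrastive-divergence update
#'
#' CD-k gradient ascent on the log-likelihood: data-phase statistics use
#' the hidden activation probabilities at the data; the model phase runs k
#' alternating Gibbs steps starting from a sampled hidden state, with
#' sampled states throughout except that the final visible reconstruction
#' is mean-field (probabilities, not samples) — a standard
#' variance-reduction choice.  Real-valued visibles in \eqn{[0,1]} are used
#' directly as Bernoulli means.  Deterministic given the RNG state.
#'
#' @param params an [rbm_params()].
#' @param batch matrix of visible vectors, one case per row, entries in
#'   \eqn{[0,1]}.
#' @param config a [train_config()] (only `cd_k` and `learning_rate` are
#'   used; the RNG is *not* reseeded here).
#' @return Updated `rbm_params`.
#' @export
cd_update <- function(params, batch, config) {
  if (!is.matrix(batch) || nrow(batch) == 0L) stop("'batch' must be a non-empty matrix")
  if (any(batch < 0 | batch > 1)) stop("batch entries must lie in [0,1]")
  n <- nrow(batch)
  ph0 <- prob_h_given_v(params, batch)        # data phase (probabilities)
  hs <- sample_bernoulli(ph0)
  for (k in seq_len(config$cd_k)) {
    pv <- prob_v_given_h(params, hs)
    vk <- if (k == config$cd_k) pv else sample_bernoulli(pv)
    phk <- prob_h_given_v(params, vk)
    if (k < config$cd_k) hs <- sample_bernoulli(phk)
  }
  lr <- config$learning_rate / n
  w_new <- params$w + lr * (t(ph0) %*% batch - t(phk) %*% vk)
  b_new <- params$b + lr * colSums(batch - vk)
  d_new <- params$d + lr * colSums(ph0 - phk)
  if (!all(is.finite(w_new), is.finite(b_new), is.finite(d_new)))
    stop("non-finite parameter update; reduce learning_rate")
  params$w <- w_new; params$b <- b_new; params$d <- d_new
  params
}

#' Train an RBM by contrastive divergence
#'
#' Runs `epochs` passes of minibatch CD-k over `data`.  The RNG is seeded
#' once from `config$seed`, then initialization (when `params_init` is
#' NULL), per-epoch row shuffling and all Gibbs draws consume that single
#' stream, so identical seed + config + data gives bit-identical
#' parameters.  The per-epoch mean-field reconstruction RMSE is recorded in
#' the `"recon_error"` attribute.
#'
#' @param data matrix of training vectors, one case per row, entries in
#'   \eqn{[0,1]}.
#' @param n_hidden hidden layer size (ignored when `params_init` given).
#' @param config a [train_config()].
#' @param params_init optional starting [rbm_params()].
#' @return Trained `rbm_params` with attribute `recon_error` (numeric
#'   vector, one entry per epoch).
#' @export
rbm_train <- function(data, n_hidden, config = train_config(),
                      params_init = NULL) {
  if (!is.matrix(data) || nrow(data) == 0L) stop("'data' must be a non-empty matrix")
  set.seed(config$seed)
  params <- if (is.null(params_init))
    rbm_params(ncol(data), n_hidden, config$init_scale)
  else params_init
  errs <- numeric(config$epochs)
  if (config$epochs >= 1L) for (e in seq_len(config$epochs)) {
    ord <- sample.int(nrow(data))
    starts <- seq(1L, nrow(data), by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, nrow(data))]
      params <- cd_update(params, data[idx, , drop = FALSE], config)
    }
    errs[e] <- reconstruction_rmse(params, data)
  }
  attr(params, "recon_error") <- errs
  params
}

#' Mean-field reconstruction RMSE of an RBM on a data matrix
#'
#' One deterministic up-down pass: \eqn{v \to P(h|v) \to P(v|h)}; returns
#' the root mean square deviation from the input.
#'
#' @param params an [rbm_params()].
#' @param data matrix of visible vectors, one case per row.
#' @return Scalar RMSE.
#' @export
reconstruction_rmse <- function(params, data) {
  recon <- prob_v_given_h(params, prob_h_given_v(params, data))
  sqrt(mean((data - recon)^2))
}

# All binary states of n units, one state per row (2^n x n), in binary
# counting order.
all_states <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 1L, 0L))
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, n:1, drop = FALSE]
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exact log-likelihood by state enumeration
#'
#' Computes \eqn{\log Z} by summing \eqn{e^{E(v,h)}} over all
#' \eqn{2^{|v|+|h|}} joint states and returns the mean exact
#' \eqn{\log P(v)} over the rows of `data`.  Only feasible for tiny
#' models (\eqn{|v| + |h| \le 20}); intended as a ground-truth check on
#' approximate training.
#'
#' @param params an [rbm_params()].
#' @param data matrix of visible vectors (one per row).
#' @return Scalar mean log-likelihood, with attribute `log_z`.
#' @export
exact_log_likelihood <- function(params, data) {
  nv <- ncol(params$w); nh <- nrow(params$w)
  if (nv + nh > 20L) stop("enumeration infeasible beyond |v| + |h| = 20")
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  vs <- all_states(nv)
  hs <- all_states(nh)
  # E over all (h, v) pairs: rows = hidden states, cols = visible states
  e_grid <- hs %*% params$w %*% t(vs) +
    as.numeric(hs %*% params$d) +
    matrix(as.numeric(vs %*% params$b), nrow(hs), nrow(vs), byrow = TRUE)
  log_z <- log_sum_exp(e_grid)
  ll <- vapply(seq_len(nrow(data)), function(i) {
    v <- data[i, ]
    e_v <- as.numeric(hs %*% params$w %*% v) + as.numeric(hs %*% params$d) +
      sum(params$b * v)
    log_sum_exp(e_v) - log_z
  }, numeric(1))
  structure(mean(ll), log_z = log_z)
}
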