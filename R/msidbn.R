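#' Greedy layer-wise pretraining of the per-source stacks
#'
#' Each timepoint network is one "source"; its training cases are the rows
#' of the (higher-order, rescaled, zero-diagonal) adjacency matrix — one
#' feature vector per protein.  For every source a two-layer stack is
#' trained greedily: layer 1 by contrastive divergence on the rows, layer 2
#' on layer 1's hidden activation probabilities.  Every stack uses the same
#' seed (layer 2 uses `seed + 1`), so identical sources yield identical
#' stacks and reordering identical sources only reorders them.
#'
#' @param series a [network_series()] whose matrices share one size.
#' @param sizes integer vector `c(n_h1, n_h2)`; sizes at or above the
#'   visible size trigger an over-completeness warning, not an error.
#' @param config a [train_config()].
#' @return List of `source_stack` objects, each with elements `t`,
#'   `layer1`, `layer2`.
#' @export
pretrain_stacks <- function(series, sizes, config = train_config()) {
  if (length(sizes) != 2L || any(sizes < 1L)) stop("'sizes' must be c(n_h1, n_h2), both >= 1")
  n <- length(series$protein_ids)
  if (any(sizes >= n))
    warning("hidden layer size >= visible size: over-complete representation")
  cfg1 <- config
  cfg2 <- config; cfg2$seed <- config$seed + 1L
  lapply(seq_along(series$matrices), function(t) {
    v <- series$matrices[[t]]
    layer1 <- rbm_train(v, sizes[1], cfg1)
    h1 <- prob_h_given_v(layer1, v)
    layer2 <- rbm_train(h1, sizes[2], cfg2)
    structure(list(t = t, layer1 = layer1, layer2 = layer2),
              class = "source_stack")
  })
}

# Mean-field upward pass through one stack: rows of v -> P(h2) probabilities.
stack_h2 <- function(stack, v) {
  prob_h_given_v(stack$layer2, prob_h_given_v(stack$layer1, v))
}

#' Train the shared joint top layer
#'
#' The joint layer is a single RBM whose visible layer is the concatenation
#' of every source's second-layer activation probabilities (per protein)
#' and whose hidden layer is the shared representation h of size `joint_size`.
#' Its conditionals factor per source:
#' \eqn{P(h_2^{(t)} \mid h) = \mathrm{sigmoid}(d_t + W_3^{(t)T} h)} and
#' \eqn{P(h \mid h_2^{(1..T)}) = \mathrm{sigmoid}(c + \sum_t W_3^{(t)}
#' h_2^{(t)})}.  Lower layers are frozen while the joint layer trains.
#'
#' @param stacks output of [pretrain_stacks()].
#' @param series the same [network_series()] the stacks were trained on.
#' @param joint_size shared hidden size J (>= 1).
#' @param config a [train_config()] (seeded with `config$seed + 2`
#'   internally so the stream is distinct from the stacks').
#' @return Object of class `joint_layer`: an RBM over the concatenated h2
#'   visibles plus the per-source block structure (`n_sources`, `block_size`).
#' @export
train_joint <- function(stacks, series, joint_size, config = train_config()) {
  if (joint_size < 1L) stop("'joint_size' must be >= 1")
  h2 <- do.call(cbind, lapply(seq_along(stacks), function(t)
    stack_h2(stacks[[t]], series$matrices[[t]])))
  cfg <- config; cfg$seed <- config$seed + 2L
  rbm <- rbm_train(h2, joint_size, cfg)
  structure(list(rbm = rbm, n_sources = length(stacks),
                 block_size = ncol(h2) / length(stacks)),
            class = "joint_layer")
}

#' Train a full multi-source integrated DBN
#'
#' Greedy schedule: per-source layer 1, per-source layer 2, then the shared
#' joint layer, each by contrastive divergence; no global fine-tuning.
#'
#' @param series a [network_series()] of T higher-order adjacency matrices.
#' @param sizes `c(n_h1, n_h2)` per-source layer sizes; defaults
#'   `min(256, N)` and `min(128, N)` for N proteins.
#' @param joint_size shared top-layer size J (default `64`).
#' @param config a [train_config()].
#' @return Object of class `msidbn_model` with elements `stacks`, `joint`,
#'   `layer_sizes`, `n_sources`, `n_visible`, `protein_ids`,
#'   `timepoint_labels` and a `training_log` of per-layer reconstruction
#'   error traces.
#' @export
msidbn_train <- function(series, sizes = NULL, joint_size = 64L,
                         config = train_config()) {
  n <- length(series$protein_ids)
  if (is.null(sizes)) sizes <- c(min(256L, n), min(128L, n))
  stacks <- pretrain_stacks(series, sizes, config)
  joint <- train_joint(stacks, series, joint_size, config)
  log <- list(
    layer1 = lapply(stacks, function(s) attr(s$layer1, "recon_error")),
    layer2 = lapply(stacks, function(s) attr(s$layer2, "recon_error")),
    joint = attr(joint$rbm, "recon_error"))
  structure(list(stacks = stacks, joint = joint,
                 layer_sizes = c(sizes, joint_size),
                 n_sources = length(series$matrices), n_visible = n,
                 protein_ids = series$protein_ids,
                 timepoint_labels = series$timepoint_labels,
                 training_log = log),
            class = "msidbn_model")
}

#' @export
print.msidbn_model <- function(x, ...) {
  cat(sprintf(
    "msidbn_model: %d sources, %d visible, layers %s, shared J = %d\n",
    x$n_sources, x$n_visible,
    paste(x$layer_sizes[1:2], collapse = "/"), x$layer_sizes[3]))
  invisible(x)
}

check_model_series <- function(model, series) {
  if (length(series$matrices) != model$n_sources)
    stop("series has ", length(series$matrices), " sources; model expects ",
         model$n_sources)
  if (length(series$protein_ids) != model$n_visible)
    stop("series has ", length(series$protein_ids),
         " proteins; model expects ", model$n_visible)
}

#' Shared encoding of a network series
#'
#' Deterministic mean-field upward pass
#' \eqn{v^{(t)} \to P(h_1^{(t)}) \to P(h_2^{(t)}) \to P(h)}: every protein
#' is mapped to its shared top-layer activation probabilities.
#'
#' @param model an `msidbn_model`.
#' @param series a [network_series()] of matching shape.
#' @return N x J matrix of probabilities, rownames = protein ids.
#' @export
msidbn_encode <- function(model, series) {
  check_model_series(model, series)
  h2 <- do.call(cbind, lapply(seq_along(model$stacks), function(t)
    stack_h2(model$stacks[[t]], series$matrices[[t]])))
  h <- prob_h_given_v(model$joint$rbm, h2)
  rownames(h) <- series$protein_ids
  h
}

#' Reconstruct a network series through the shared representation
#'
#' Deterministic mean-field autoencoding: the shared encoding
#' \eqn{P(h)} is propagated back down,
#' \eqn{P(h) \to P(h_2^{(t)} \mid h) \to P(h_1^{(t)}) \to P(v^{(t)})},
#' giving one reconstructed matrix per source with entries in (0, 1).
#' Proteins whose local structure is inconsistent across sources cannot be
#' recovered well from the shared code, which is what the downstream
#' ranking exploits.
#'
#' @param model an `msidbn_model`.
#' @param series a [network_series()] of matching shape.
#' @param sample reconstruct from Bernoulli samples of
#'   \eqn{P(h_2^{(t)} \mid h)} instead of mean-field probabilities
#'   (default FALSE; sampling makes downstream scores stochastic).
#' @param seed RNG seed used only when `sample = TRUE`.
#' @return A [network_series()] of reconstructed matrices (not exactly
#'   symmetric: the model reconstructs rows).
#' @export
msidbn_reconstruct <- function(model, series, sample = FALSE, seed = 1L) {
  check_model_series(model, series)
  h <- msidbn_encode(model, series)
  h2_rec <- prob_v_given_h(model$joint$rbm, h)
  if (sample) {
    set.seed(seed)
    h2_rec <- sample_bernoulli(h2_rec)
  }
  bs <- model$joint$block_size
  mats <- lapply(seq_along(model$stacks), function(t) {
    block <- h2_rec[, (t - 1L) * bs + seq_len(bs), drop = FALSE]
    h1 <- prob_v_given_h(model$stacks[[t]]$layer2, block)
    prob_v_given_h(model$stacks[[t]]$layer1, h1)
  })
  network_series(series$protein_ids, mats, series$timepoint_labels,
                 symmetric = FALSE)
}
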