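# Small fixtures built in code at test time.

# Expression matrix with prescribed per-gene values; vals is a list of
# timepoints x replicates matrices (or vectors for one replicate).
make_expr <- function(vals, ids = NULL) {
  vals <- lapply(vals, function(v) if (is.matrix(v)) v else matrix(v, ncol = 1))
  if (is.null(ids)) ids <- sprintf("G%02d", seq_along(vals))
  arr <- array(0, dim = c(length(vals), nrow(vals[[1]]), ncol(vals[[1]])))
  for (i in seq_along(vals)) arr[i, , ] <- vals[[i]]
  expression_matrix(ids, arr)
}

# A small random symmetric [0,1] network series.
make_series <- function(n = 6, t_n = 3, seed = 1) {
  set.seed(seed)
  mats <- lapply(seq_len(t_n), function(t) {
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  })
  network_series(sprintf("P%02d", seq_len(n)), mats)
}

# Seeded tiny RBM parameters.
make_rbm <- function(nv, nh, seed = 1, scale = 0.5) {
  set.seed(seed)
  p <- rbm_params(nv, nh, init_scale = scale)
  p$b <- rnorm(nv, sd = scale)
  p$d <- rnorm(nh, sd = scale)
  p
}
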