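# Independent brute-force oracles for the energy-based models.  Everything
# here is written with explicit loops and scalar arithmetic on purpose: the
# oracles must not share code paths with the package implementation.

# Energy of one (v, h) state under the P ~ exp(E) convention, scalar loops.
oracle_energy <- function(w, b, d, v, h) {
  e <- 0
  for (j in seq_along(h)) for (i in seq_along(v))
    e <- e + h[j] * w[j, i] * v[i]
  for (j in seq_along(h)) e <- e + d[j] * h[j]
  for (i in seq_along(v)) e <- e + b[i] * v[i]
  e
}

# All binary vectors of length n as a list.
oracle_states <- function(n) {
  if (n == 0L) return(list(numeric(0)))
  out <- list()
  for (k in 0:(2^n - 1)) {
    bits <- numeric(n)
    x <- k
    for (i in seq_len(n)) { bits[i] <- x %% 2; x <- x %/% 2 }
    out[[k + 1]] <- bits
  }
  out
}

# Full joint probability table over all (v, h) states by enumeration.
# Returns list(vs, hs, p) with p[i, j] = P(v = vs[[i]], h = hs[[j]]).
oracle_joint <- function(w, b, d) {
  vs <- oracle_states(ncol(w))
  hs <- oracle_states(nrow(w))
  e <- matrix(0, length(vs), length(hs))
  for (i in seq_along(vs)) for (j in seq_along(hs))
    e[i, j] <- oracle_energy(w, b, d, vs[[i]], hs[[j]])
  p <- exp(e)
  list(vs = vs, hs = hs, p = p / sum(p))
}

# P(h_j = 1 | v) for every hidden unit, from the enumerated joint.
oracle_cond_h <- function(joint, v) {
  vi <- which(vapply(joint$vs, function(x) all(x == v), logical(1)))
  pv <- joint$p[vi, ]
  nh <- length(joint$hs[[1]])
  vapply(seq_len(nh), function(j) {
    on <- vapply(joint$hs, function(h) h[j] == 1, logical(1))
    sum(pv[on]) / sum(pv)
  }, numeric(1))
}

# P(v_i = 1 | h), mirror of the above.
oracle_cond_v <- function(joint, h) {
  hi <- which(vapply(joint$hs, function(x) all(x == h), logical(1)))
  ph <- joint$p[, hi]
  nv <- length(joint$vs[[1]])
  vapply(seq_len(nv), function(i) {
    on <- vapply(joint$vs, function(v) v[i] == 1, logical(1))
    sum(ph[on]) / sum(ph)
  }, numeric(1))
}

# Exact log P(v) from the enumerated joint.
oracle_log_pv <- function(joint, v) {
  vi <- which(vapply(joint$vs, function(x) all(x == v), logical(1)))
  log(sum(joint$p[vi, ]))
}
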