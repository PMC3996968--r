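#' Specification for a synthetic benchmark dataset
#'
#' Describes a desk-scale dataset with the statistical structure the
#' pipeline assumes: genes grouped into modules with periodic,
#' phase-shifted expression over a cyclic time course (replicates are
#' successive cycles), a planted-partition static interactome that mirrors
#' the modules, and a planted subset of "critical" proteins that switch
#' module midway through the series — the ground truth the ranking should
#' recover.
#'
#' @param n_proteins number of proteins (default 100).
#' @param n_timepoints timepoints per cycle (default 12).
#' @param n_replicates replicate cycles (default 3).
#' @param n_modules phase modules (default 4).
#' @param n_critical planted structure-changing proteins (default 10).
#' @param rewiring_strength in \eqn{[0, 1]}: 0 leaves planted proteins
#'   untouched, 1 is a full module switch (default 1).
#' @param noise_sd Gaussian noise sd on expression (default 0.3).
#' @param edge_density overall static edge density (default 0.1);
#'   between-module edges are 10x rarer than within-module edges.
#' @param baseline,amplitude expression baseline and sinusoid amplitude
#'   (defaults 5 and 2; amplitude/noise_sd sets the activity
#'   signal-to-noise).
#' @param t_switch timepoint at which planted proteins change module
#'   (default `n_timepoints / 2 + 1`).
#' @param seed RNG seed; every generator below is deterministic given it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 100L, n_timepoints = 12L,
                           n_replicates = 3L, n_modules = 4L,
                           n_critical = 10L, rewiring_strength = 1,
                           noise_sd = 0.3, edge_density = 0.1,
                           baseline = 5, amplitude = 2,
                           t_switch = NULL, seed = 1L) {
  if (n_critical > n_proteins) stop("n_critical exceeds n_proteins")
  if (any(c(n_proteins, n_timepoints, n_replicates, n_modules) < 1L))
    stop("all counts must be positive")
  if (rewiring_strength < 0 || rewiring_strength > 1)
    stop("rewiring_strength must lie in [0, 1]")
  if (is.null(t_switch)) t_switch <- n_timepoints %/% 2L + 1L
  structure(list(n_proteins = as.integer(n_proteins),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 n_modules = as.integer(n_modules),
                 n_critical = as.integer(n_critical),
                 rewiring_strength = rewiring_strength,
                 noise_sd = noise_sd, edge_density = edge_density,
                 baseline = baseline, amplitude = amplitude,
                 t_switch = as.integer(t_switch),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_ids <- function(spec)
  sprintf("P%03d", seq_len(spec$n_proteins))

synthetic_modules <- function(spec)
  ((seq_len(spec$n_proteins) - 1L) %% spec$n_modules) + 1L

module_phase <- function(spec, m) 2 * pi * (m - 1) / spec$n_modules

# Noise-free periodic profile of module m over one cycle.
module_profile <- function(spec, m) {
  t <- seq_len(spec$n_timepoints)
  spec$baseline +
    spec$amplitude * cos(2 * pi * (t - 1) / spec$n_timepoints -
                           module_phase(spec, m))
}

#' Generate a periodic expression time course
#'
#' Every gene follows its module's sinusoid (modules peak at evenly spaced
#' phases across the cycle) plus i.i.d. Gaussian noise; replicates are
#' independently noisy copies of the same cycle.
#'
#' @param spec a [synthetic_spec()].
#' @return An [expression_matrix()] of shape
#'   `n_proteins x n_timepoints x n_replicates`.
#' @export
generate_expression <- function(spec) {
  set.seed(spec$seed)
  mods <- synthetic_modules(spec)
  vals <- array(0, dim = c(spec$n_proteins, spec$n_timepoints,
                           spec$n_replicates))
  for (i in seq_len(spec$n_proteins)) {
    clean <- module_profile(spec, mods[i])
    for (r in seq_len(spec$n_replicates))
      vals[i, , r] <- clean +
        stats::rnorm(spec$n_timepoints, sd = spec$noise_sd)
  }
  expression_matrix(synthetic_ids(spec), vals)
}

#' Generate a planted-partition static interactome
#'
#' Within-module pairs are connected with probability `p_in`, between-module
#' pairs with `p_in * inter_ratio`; `p_in` is solved so the expected overall
#' density matches `spec$edge_density`.
#'
#' @param spec a [synthetic_spec()].
#' @param inter_ratio between- to within-module edge probability ratio
#'   (default 0.1).
#' @return An [edge_list()], deterministic given `spec$seed`.
#' @export
generate_static_ppin <- function(spec, inter_ratio = 0.1) {
  set.seed(spec$seed + 1L)
  mods <- synthetic_modules(spec)
  ids <- synthetic_ids(spec)
  n <- spec$n_proteins
  pairs <- utils::combn(n, 2L)
  intra <- mods[pairs[1, ]] == mods[pairs[2, ]]
  f_in <- mean(intra)
  p_in <- spec$edge_density / (f_in + inter_ratio * (1 - f_in))
  p_in <- min(p_in, 1)
  p <- ifelse(intra, p_in, p_in * inter_ratio)
  keep <- stats::runif(ncol(pairs)) < p
  out <- edge_list(ids[pairs[1, keep]], ids[pairs[2, keep]])
  attr(out, "p_in") <- p_in
  out
}

#' Plant structure-changing critical proteins
#'
#' Selected proteins switch module membership midway through the cycle:
#' from `t_switch` onward their expression profile is blended toward the
#' phase of a target module (weight = `rewiring_strength`), and static
#' edges toward the target module are added with the within-module edge
#' probability scaled by `rewiring_strength`.  Their per-timepoint
#' higher-order adjacency rows therefore change sharply across the series
#' while unplanted proteins stay consistent.  Strength 0 returns the
#' inputs unchanged.
#'
#' @param spec a [synthetic_spec()].
#' @param expr expression from [generate_expression()].
#' @param ppin edges from [generate_static_ppin()].
#' @return List with elements `expr`, `ppin` (modified copies),
#'   `critical_ids` (ground-truth identifiers, length `spec$n_critical`)
#'   and `t_switch`.
#' @export
plant_critical <- function(spec, expr, ppin) {
  set.seed(spec$seed + 2L)
  mods <- synthetic_modules(spec)
  ids <- synthetic_ids(spec)
  # spread the planted set across modules, deterministically
  critical_idx <- seq_len(spec$n_critical)
  s <- spec$rewiring_strength
  if (s > 0 && spec$n_critical > 0L) {
    p_in <- attr(ppin, "p_in")
    if (is.null(p_in)) p_in <- spec$edge_density
    late <- spec$t_switch:spec$n_timepoints
    new_from <- character(0); new_to <- character(0)
    for (i in critical_idx) {
      # antiphase target: the new module's activity peak must fall in the
      # post-switch half of the series, or the new partnerships are never
      # observed active and the planted change is invisible downstream
      target <- ((mods[i] - 1L + spec$n_modules %/% 2L) %%
                   spec$n_modules) + 1L
      old_clean <- module_profile(spec, mods[i])[late]
      new_clean <- module_profile(spec, target)[late]
      for (r in seq_len(spec$n_replicates))
        expr$values[i, late, r] <- expr$values[i, late, r] +
          s * (new_clean - old_clean)
      members <- which(mods == target & seq_along(mods) != i)
      add <- members[stats::runif(length(members)) < p_in * s]
      new_from <- c(new_from, rep(ids[i], length(add)))
      new_to <- c(new_to, ids[add])
    }
    ppin <- edge_list(c(ppin[, 1], new_from), c(ppin[, 2], new_to))
  }
  list(expr = expr, ppin = ppin, critical_ids = ids[critical_idx],
       t_switch = spec$t_switch)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: expression + static interactome + planted critical
#' proteins, fully determined by `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `expr`, `ppin`, `critical_ids`, `t_switch`, `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  expr <- generate_expression(spec)
  ppin <- generate_static_ppin(spec)
  out <- plant_critical(spec, expr, ppin)
  out$spec <- spec
  out
}
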