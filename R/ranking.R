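#' Per-protein, per-timepoint reconstruction error
#'
#' For protein i at timepoint t, the root mean square error of its
#' adjacency row, \deqn{Er_i(t) = \sqrt{\tfrac{1}{N}\sum_j
#' (A^{(t)}_{ij} - A^{(R,t)}_{ij})^2}.}
#'
#' @param original,reconstructed two [network_series()] of identical shape.
#' @return N x T matrix; rownames protein ids, colnames timepoint labels.
#' @export
rmse_profile <- function(original, reconstructed) {
  if (length(original$matrices) != length(reconstructed$matrices) ||
      length(original$protein_ids) != length(reconstructed$protein_ids))
    stop("series shapes differ")
  er <- vapply(seq_along(original$matrices), function(t)
    sqrt(rowMeans((original$matrices[[t]] - reconstructed$matrices[[t]])^2)),
    numeric(length(original$protein_ids)))
  dimnames(er) <- list(original$protein_ids, original$timepoint_labels)
  er
}

#' Relative standard deviation of an error profile
#'
#' \eqn{RSD = \sigma / \mu} with the sample (n-1) standard deviation; a
#' zero-mean row (zero error everywhere — a perfectly explained protein)
#' is defined to have RSD 0 rather than NaN.
#'
#' @param er_row numeric vector of length >= 2 (one protein's per-timepoint
#'   errors).
#' @param sample_sd use the n-1 denominator (default) or n.
#' @return Scalar RSD >= 0.
#' @export
rsd <- function(er_row, sample_sd = TRUE) {
  if (length(er_row) < 2L) stop("need >= 2 timepoints")
  m <- mean(er_row)
  if (m == 0) return(0)
  s <- if (sample_sd) stats::sd(er_row)
  else sqrt(mean((er_row - m)^2))
  s / m
}

#' Rank proteins by reconstruction-error variability
#'
#' Proteins are ordered by descending RSD of their error profile; ties are
#' broken by descending mean error, then lexically by identifier, so the
#' ranking is fully deterministic.  High-RSD proteins are the candidates
#' for "critical" status: their local network structure is poorly and
#' unevenly explained by the shared representation across timepoints.
#'
#' @param er N x T error matrix from [rmse_profile()] (rownames = ids).
#' @param k size of the selected top set (default 150).
#' @param sample_sd passed to [rsd()].
#' @return Object of class `criticality_report` with elements
#'   `protein_ids`, `er`, `rsd`, `ranking` (all ids, best first) and
#'   `top_k`.
#' @export
rank_critical <- function(er, k = 150L, sample_sd = TRUE) {
  if (is.null(rownames(er))) stop("'er' must carry protein ids as rownames")
  ids <- rownames(er)
  scores <- apply(er, 1L, rsd, sample_sd = sample_sd)
  mean_er <- rowMeans(er)
  ord <- order(-scores, -mean_er, ids, method = "radix")
  ranking <- ids[ord]
  structure(list(protein_ids = ids, er = er,
                 rsd = stats::setNames(scores, ids),
                 ranking = ranking,
                 top_k = ranking[seq_len(min(k, length(ranking)))]),
            class = "criticality_report")
}

#' @export
print.criticality_report <- function(x, ...) {
  cat(sprintf("criticality_report: %d proteins x %d timepoints; top %d\n",
              nrow(x$er), ncol(x$er), length(x$top_k)))
  top <- utils::head(x$ranking, 5L)
  cat("  head of ranking:",
      paste(sprintf("%s (%.3f)", top, x$rsd[top]), collapse = ", "), "\n")
  invisible(x)
}
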