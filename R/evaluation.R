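#' Overlap score between a predicted cluster and a reference complex
#'
#' The default `squared` form is the neighborhood-affinity score
#' \eqn{OL(P, R) = |P \cap R|^2 / (|P| \cdot |R|)}, under which two
#' identical sets score 1 and the conventional match threshold 0.2 is
#' attainable at any size.  The `literal` form
#' \eqn{|P \cap R| / (|P| \cdot |R|)} is also provided; note that it makes
#' large identical sets unmatchable (two identical size-10 sets score
#' 0.1), which is why it is not the default.
#'
#' @param p,r non-empty character sets (predicted cluster, reference
#'   complex).
#' @param form `"squared"` or `"literal"`.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
overlap_score <- function(p, r, form = c("squared", "literal")) {
  form <- match.arg(form)
  p <- unique(p); r <- unique(r)
  if (length(p) == 0L || length(r) == 0L) stop("sets must be non-empty")
  i <- length(intersect(p, r))
  if (form == "squared") i^2 / (length(p) * length(r))
  else i / (length(p) * length(r))
}

#' Precision of predicted clusters against a complex catalog
#'
#' A predicted cluster counts as a true positive when its best overlap
#' score against any reference complex exceeds `threshold`; otherwise it is
#' a false positive, so \eqn{Prec = TP / (TP + FP)} with
#' \eqn{TP + FP} = number of predicted clusters.
#'
#' @param predicted list of non-empty character sets (predicted clusters),
#'   e.g. read from a one-cluster-per-line file.
#' @param reference a [complex_catalog()].
#' @param threshold match threshold on the overlap score (default 0.2).
#' @param form passed to [overlap_score()].
#' @return Object of class `match_result`: list with `per_cluster` (data
#'   frame of best score and matched complex), `tp`, `fp`, `prec`.
#' @export
complex_precision <- function(predicted, reference, threshold = 0.2,
                              form = c("squared", "literal")) {
  form <- match.arg(form)
  if (length(predicted) == 0L) stop("empty predicted cluster set")
  if (any(lengths(predicted) == 0L)) stop("empty cluster in predicted set")
  per <- lapply(predicted, function(p) {
    scores <- vapply(reference$complexes, overlap_score, numeric(1),
                     p = p, form = form)
    best <- which.max(scores)
    list(best_ol = scores[best], match = names(reference$complexes)[best])
  })
  best_ol <- vapply(per, `[[`, numeric(1), "best_ol")
  matched <- best_ol > threshold
  structure(list(
    per_cluster = data.frame(
      cluster = seq_along(predicted),
      best_ol = best_ol,
      match = ifelse(matched, vapply(per, `[[`, character(1), "match"), NA),
      stringsAsFactors = FALSE),
    tp = sum(matched), fp = sum(!matched),
    prec = mean(matched)), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d TP, %d FP, precision %.3f\n",
              x$tp, x$fp, x$prec))
  invisible(x)
}

#' Read predicted clusters (one cluster per line, tab-separated members)
#'
#' @param path file path; `#` comments and blank lines skipped.
#' @return List of character vectors.
#' @export
read_clusters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(strsplit(lines, "\t", fixed = TRUE), unique)
}

#' Precision of a ranked top list against a gold gene list
#'
#' @param top_k ordered character vector of selected protein ids.
#' @param gold character vector of gold-standard ids.
#' @return List with `matched` (overlap count) and `precision`
#'   (`matched / length(top_k)`).
#' @export
gold_list_precision <- function(top_k, gold) {
  if (length(top_k) == 0L) stop("'top_k' is empty")
  m <- length(intersect(top_k, gold))
  list(matched = m, precision = m / length(top_k))
}

#' AVG reconstruction baseline
#'
#' The time-constant baseline: every timepoint is "reconstructed" by the
#' element-wise mean matrix across sources — the exact minimizer of summed
#' squared error among reconstructions that do not vary with time.
#'
#' @param series a [network_series()].
#' @return A [network_series()] with the mean matrix at every timepoint.
#' @export
avg_baseline <- function(series) {
  m <- Reduce(`+`, series$matrices) / length(series$matrices)
  network_series(series$protein_ids,
                 rep(list(m), length(series$matrices)),
                 series$timepoint_labels, symmetric = FALSE)
}

#' Joint non-negative matrix factorization baseline
#'
#' A shallow common-structure baseline: one shared non-negative basis
#' \eqn{B} (N x r) with per-source coefficient matrices \eqn{H_t}
#' (r x N), fitted by multiplicative updates minimizing
#' \eqn{\sum_t \|A_t - B H_t\|_F^2}; the reconstruction of source t is
#' \eqn{B H_t}.  The objective is non-increasing across updates (its trace
#' is attached as the `"objective"` attribute).
#'
#' @param series a [network_series()] with non-negative matrices.
#' @param rank factorization rank; default 500 capped at N - 1.
#' @param iterations multiplicative update sweeps (default 100).
#' @param seed RNG seed for the uniform initialization.
#' @return A [network_series()] of reconstructions, with attribute
#'   `objective` (numeric vector of length `iterations`).
#' @export
jnmf_baseline <- function(series, rank = 500L, iterations = 100L,
                          seed = 1L) {
  n <- length(series$protein_ids)
  t_n <- length(series$matrices)
  if (any(vapply(series$matrices, min, numeric(1)) < 0))
    stop("JNMF requires non-negative inputs")
  r <- min(as.integer(rank), n - 1L)
  if (r < 1L) stop("rank must be >= 1")
  eps <- 1e-10
  set.seed(seed)
  b <- matrix(stats::runif(n * r), n, r)
  hs <- lapply(seq_len(t_n), function(t) matrix(stats::runif(r * n), r, n))
  obj <- numeric(iterations)
  for (it in seq_len(iterations)) {
    # per-source coefficients, shared basis fixed
    btb <- crossprod(b)
    hs <- lapply(seq_len(t_n), function(t)
      hs[[t]] * (crossprod(b, series$matrices[[t]])) /
        (btb %*% hs[[t]] + eps))
    # shared basis against all sources at once
    num <- Reduce(`+`, lapply(seq_len(t_n), function(t)
      series$matrices[[t]] %*% t(hs[[t]])))
    den <- b %*% Reduce(`+`, lapply(hs, tcrossprod)) + eps
    b <- b * num / den
    obj[it] <- sum(vapply(seq_len(t_n), function(t)
      sum((series$matrices[[t]] - b %*% hs[[t]])^2), numeric(1)))
  }
  out <- network_series(series$protein_ids,
                        lapply(hs, function(h) b %*% h),
                        series$timepoint_labels, symmetric = FALSE)
  attr(out, "objective") <- obj
  out
}

#' Overall reconstruction RMSE of a series pair
#'
#' Root mean square error pooled over every entry of every timepoint;
#' the single-number summary used to compare reconstruction methods.
#'
#' @param original,reconstructed two [network_series()] of equal shape.
#' @return Scalar RMSE.
#' @export
series_rmse <- function(original, reconstructed) {
  sqrt(mean(vapply(seq_along(original$matrices), function(t)
    mean((original$matrices[[t]] - reconstructed$matrices[[t]])^2),
    numeric(1))))
}
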