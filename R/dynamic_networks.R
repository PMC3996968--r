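#' Per-gene activity thresholds
#'
#' Computes, for every gene, the activity threshold (AcScore) against which
#' its expression is compared to decide whether the protein is active at a
#' timepoint.  Both statistics are taken over all of a gene's values
#' (every timepoint, every replicate cycle); supplying a `reference` series
#' pools its values with the main series for genes present in both, which
#' damps the bias of a single experiment on the mean and variance.
#'
#' Two functional forms are provided.  `range_consistent` (default) is the
#' three-sigma-style threshold
#' \deqn{AcScore(p) = \mu(p) + \alpha \frac{\sigma(p)^3}{1 + \sigma(p)^2},}
#' which keeps the score inside \eqn{(\mu, \mu + \alpha\sigma^3/(1+\sigma^2))}
#' and in which the tuning parameter \eqn{\alpha} (default 1.5) lives.
#' `eq1_literal` is the weighted-threshold form
#' \eqn{AcScore = thr_1 F + thr_2 (1 - F)} with \eqn{thr_1 = \mu},
#' \eqn{thr_2 = \mu\sigma} and \eqn{F = 1/(1+\sigma)}; it contains no
#' \eqn{\alpha} and is kept for comparison (see the package vignette for the
#' discrepancy between the two).
#'
#' Genes with zero variance get \eqn{AcScore = \mu} under either form.
#'
#' @param expr an [expression_matrix()].
#' @param alpha positive scalar weighting the variance term
#'   (`range_consistent` form only).
#' @param form `"range_consistent"` or `"eq1_literal"`.
#' @param reference optional second [expression_matrix()] whose values are
#'   pooled with `expr`'s, per gene, before computing mean and sd.
#' @return An object of class `activity_model`: a data frame with columns
#'   `gene_id`, `mu`, `sigma`, `f`, `thr1`, `thr2`, `ac_score`, plus
#'   attributes `alpha` and `form`.
#' @export
compute_activity_scores <- function(expr, alpha = 1.5,
                                    form = c("range_consistent",
                                             "eq1_literal"),
                                    reference = NULL) {
  form <- match.arg(form)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive scalar")
  ref_idx <- NULL
  if (!is.null(reference)) {
    ref_idx <- match(expr$gene_ids, reference$gene_ids)
    if (all(is.na(ref_idx)))
      stop("reference series shares no genes with 'expr'")
  }
  n <- length(expr$gene_ids)
  mu <- sigma <- numeric(n)
  for (i in seq_len(n)) {
    x <- as.numeric(expr$values[i, , ])
    if (!is.null(ref_idx) && !is.na(ref_idx[i]))
      x <- c(x, as.numeric(reference$values[ref_idx[i], , ]))
    mu[i] <- mean(x)
    sigma[i] <- stats::sd(x)
  }
  sigma[is.na(sigma)] <- 0  # single-observation genes
  f <- if (form == "eq1_literal") 1 / (1 + sigma) else 1 / (1 + sigma^2)
  ac <- if (form == "eq1_literal")
    mu * f + (mu * sigma) * (1 - f)
  else
    mu + alpha * sigma^3 / (1 + sigma^2)
  out <- data.frame(gene_id = expr$gene_ids, mu = mu, sigma = sigma, f = f,
                    thr1 = mu, thr2 = if (form == "eq1_literal") mu * sigma
                    else mu * sigma,
                    ac_score = ac, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "form") <- form
  class(out) <- c("activity_model", "data.frame")
  out
}

#' Binary activity vector at a timepoint
#'
#' A protein is active at timepoint `t` when its replicate-mean expression
#' \eqn{g_t(p)} meets or exceeds its activity threshold:
#' \eqn{\delta_t(p) = 1} iff \eqn{g_t(p) \ge AcScore(p)} (the comparison is
#' inclusive).
#'
#' @param expr an [expression_matrix()].
#' @param model an `activity_model` from [compute_activity_scores()]
#'   covering `expr`'s genes.
#' @param t timepoint index.
#' @return Integer 0/1 vector named by gene, one entry per gene of `expr`.
#' @export
binarize_activity <- function(expr, model, t) {
  t <- as.integer(t)
  if (t < 1L || t > dim(expr$values)[2]) stop("timepoint index out of range")
  idx <- match(expr$gene_ids, model$gene_id)
  if (anyNA(idx)) stop("activity model does not cover all genes")
  g <- rowMeans(expr$values[, t, , drop = FALSE], dims = 1L)
  stats::setNames(as.integer(g >= model$ac_score[idx]), expr$gene_ids)
}

#' Activity network at a timepoint
#'
#' The outer product \eqn{\delta_t \delta_t^T}: a binary, symmetric,
#' rank-at-most-one matrix whose (i, j) entry is 1 exactly when proteins i
#' and j are both active.
#'
#' @param delta binary activity vector (from [binarize_activity()]).
#' @return Binary symmetric matrix.
#' @export
activity_network <- function(delta) {
  if (!all(delta %in% c(0L, 1L))) stop("'delta' must be binary")
  outer(as.numeric(delta), as.numeric(delta))
}

#' Windowed co-expression matrix at a timepoint
#'
#' For each gene pair, the Pearson correlation over the samples in a
#' circular time window centered at `t` (timepoints `t - hw .. t + hw`,
#' wrapping at the series boundary, all replicate cycles pooled — up to
#' `(2 hw + 1) * replicates` values per gene), affinely mapped to
#' \eqn{[0, 1]} via \eqn{CoE = (r + 1)/2}.  Pairs where either gene is
#' constant over the window get \eqn{CoE = 0.5} (r defined as 0), including
#' the diagonal of a constant gene.
#'
#' @param expr an [expression_matrix()].
#' @param t timepoint index.
#' @param half_width window half-width (default 1, i.e. `t-1, t, t+1`).
#' @param circular wrap the window at the series boundary (default TRUE).
#' @return Symmetric matrix in \eqn{[0, 1]} with unit diagonal for
#'   non-constant genes.
#' @export
windowed_coexpression <- function(expr, t, half_width = 1L, circular = TRUE) {
  d <- dim(expr$values)
  t <- as.integer(t)
  if (t < 1L || t > d[2]) stop("timepoint index out of range")
  if (d[2] < 2L) stop("need >= 2 distinct timepoints")
  win <- (t - half_width):(t + half_width)
  if (circular) {
    win <- ((win - 1L) %% d[2]) + 1L
  } else {
    win <- win[win >= 1L & win <= d[2]]
  }
  x <- expr$values[, win, , drop = FALSE]
  x <- matrix(x, nrow = d[1])  # genes x (window * replicates) samples
  if (ncol(x) < 3L) stop("window contains fewer than 3 samples")
  sds <- apply(x, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(x)))
  r[!is.finite(r)] <- 0  # zero-variance genes: correlation defined as 0
  const <- sds == 0
  if (any(const)) {
    r[const, ] <- 0
    r[, const] <- 0
  }
  coe <- (r + 1) / 2
  dimnames(coe) <- list(expr$gene_ids, expr$gene_ids)
  coe
}

#' Combine co-expression, activity and static interactome
#'
#' Element-wise product \eqn{A_t = CoE_t \circ Act_t \circ Ppi}: an
#' interaction survives at timepoint t only if present in the static
#' network and between two simultaneously active proteins, and is then
#' weighted by their windowed co-expression.
#'
#' @param coe co-expression matrix in \eqn{[0,1]}.
#' @param act binary activity matrix.
#' @param ppi binary symmetric static adjacency with zero diagonal.
#' @return Symmetric matrix in \eqn{[0,1]}.
#' @export
combine_networks <- function(coe, act, ppi) {
  if (!all(dim(coe) == dim(act)) || !all(dim(coe) == dim(ppi)))
    stop("matrix shapes differ")
  if (!all(ppi %in% c(0, 1)) || any(diag(ppi) != 0) ||
      max(abs(ppi - t(ppi))) > 0)
    stop("'ppi' must be binary, symmetric, zero-diagonal")
  coe * act * ppi
}

#' Higher-order adjacency
#'
#' Raises a symmetric non-negative matrix to an integer matrix power
#' (mimicking multi-step random walks), zeroes the diagonal afterwards
#' (self-transitions are ignored), and optionally rescales by the global
#' maximum so entries lie in \eqn{[0,1]} and can be read as Bernoulli
#' means.
#'
#' @param a symmetric non-negative matrix.
#' @param order integer power >= 1 (default 2).
#' @param rescale `"max"` (divide by the maximum entry; an all-zero matrix
#'   is returned unchanged) or `"none"`.
#' @return Symmetric matrix with zero diagonal.
#' @export
higher_order <- function(a, order = 2L, rescale = c("max", "none")) {
  rescale <- match.arg(rescale)
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1")
  if (any(a < 0)) stop("'a' must be non-negative")
  if (max(abs(a - t(a))) > 1e-8) stop("'a' must be symmetric")
  m <- a
  if (order > 1L) for (k in seq_len(order - 1L)) m <- m %*% a
  diag(m) <- 0
  if (rescale == "max" && max(m) > 0) m <- m / max(m)
  m
}

#' Build the dynamic network series
#'
#' Full construction: restrict to the proteins shared by the expression
#' series and the static interactome, compute activity thresholds, then for
#' every timepoint assemble \eqn{A_t = CoE_t \circ \delta_t\delta_t^T \circ
#' Ppi} and take its higher-order form.  Per-timepoint active-protein and
#' edge counts are attached as the `"log"` attribute (a data frame) and
#' printed when `verbose`.
#'
#' @param expr an [expression_matrix()].
#' @param edges an [edge_list()] (the static interactome).
#' @param alpha,form,reference passed to [compute_activity_scores()].
#' @param order,rescale passed to [higher_order()].
#' @param half_width,circular passed to [windowed_coexpression()].
#' @param verbose print the per-timepoint counts.
#' @return A [network_series()] of higher-order matrices, with attributes
#'   `log` (counts per timepoint) and `raw` (the pre-higher-order series).
#' @export
build_series <- function(expr, edges, alpha = 1.5,
                         form = c("range_consistent", "eq1_literal"),
                         order = 2L, rescale = c("max", "none"),
                         half_width = 1L, circular = TRUE,
                         reference = NULL, verbose = FALSE) {
  form <- match.arg(form)
  rescale <- match.arg(rescale)
  common <- intersect(expr$gene_ids, edge_list_proteins(edges))
  if (length(common) == 0L) stop("empty protein intersection")
  expr <- subset_genes(expr, common)
  ppi <- adjacency_matrix(edges, common)
  model <- compute_activity_scores(expr, alpha = alpha, form = form,
                                   reference = reference)
  t_n <- dim(expr$values)[2]
  raw <- vector("list", t_n)
  ho <- vector("list", t_n)
  log <- data.frame(timepoint = expr$timepoint_labels,
                    active = integer(t_n), edges = integer(t_n))
  for (t in seq_len(t_n)) {
    delta <- binarize_activity(expr, model, t)
    act <- activity_network(delta)
    coe <- windowed_coexpression(expr, t, half_width = half_width,
                                 circular = circular)
    a <- combine_networks(coe, act, ppi)
    log$active[t] <- sum(delta)
    log$edges[t] <- sum(a > 0) / 2
    raw[[t]] <- a
    ho[[t]] <- higher_order(a, order = order, rescale = rescale)
  }
  if (verbose)
    for (t in seq_len(t_n))
      message(sprintf("%s: %d active proteins, %d edges",
                      log$timepoint[t], log$active[t], log$edges[t]))
  out <- network_series(common, ho, expr$timepoint_labels)
  attr(out, "log") <- log
  attr(out, "raw") <- network_series(common, raw, expr$timepoint_labels)
  attr(out, "activity_model") <- model
  out
}
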