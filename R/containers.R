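#' Expression matrix container
#'
#' Holds a gene-expression time course as a 3-dimensional array of
#' genes x timepoints x replicates, where replicates are the same
#' within-cycle timepoint observed across successive cycles (the layout of
#' metabolic/cell-cycle time-course series such as three cycles of twelve
#' timepoints each).
#'
#' @param gene_ids character vector of unique gene identifiers.
#' @param values numeric array of dimension
#'   `c(length(gene_ids), n_timepoints, n_replicates)`; all values finite.
#' @param timepoint_labels optional character labels, one per timepoint.
#' @return An object of class `expression_matrix` with elements `gene_ids`,
#'   `values` and `timepoint_labels`.
#' @export
expression_matrix <- function(gene_ids, values, timepoint_labels = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-d array (genes x timepoints x replicates)")
  if (dim(values)[1] != length(gene_ids))
    stop("first dimension of 'values' must match length(gene_ids)")
  if (dim(values)[3] < 1L) stop("need at least one replicate")
  if (!all(is.finite(values))) stop("all expression values must be finite")
  if (is.null(timepoint_labels))
    timepoint_labels <- paste0("t", seq_len(dim(values)[2]))
  if (length(timepoint_labels) != dim(values)[2])
    stop("timepoint_labels length must equal number of timepoints")
  dimnames(values) <- list(gene_ids, timepoint_labels, NULL)
  structure(list(gene_ids = gene_ids, values = values,
                 timepoint_labels = as.character(timepoint_labels)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_matrix: %d genes x %d timepoints x %d replicates\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene identifier
#'
#' @param expr an [expression_matrix()].
#' @param gene_ids identifiers to keep, in the order given.
#' @return An `expression_matrix` restricted to `gene_ids`.
#' @export
subset_genes <- function(expr, gene_ids) {
  idx <- match(gene_ids, expr$gene_ids)
  if (anyNA(idx))
    stop("unknown gene identifiers: ",
         paste(gene_ids[is.na(idx)], collapse = ", "))
  expression_matrix(expr$gene_ids[idx],
                    expr$values[idx, , , drop = FALSE],
                    expr$timepoint_labels)
}

#' Edge list container
#'
#' An undirected, simple edge list over protein identifiers: self-loops are
#' rejected, pairs are stored with the lexically smaller member first and
#' deduplicated.
#'
#' @param from,to character vectors of equal length.
#' @return Object of class `edge_list`: a two-column character matrix with
#'   one unordered pair per row.
#' @export
edge_list <- function(from = character(), to = character()) {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to)) stop("'from' and 'to' lengths differ")
  if (any(from == to)) stop("self-loops not allowed in edge_list")
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  structure(cbind(from = a[keep], to = b[keep]), class = "edge_list")
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("edge_list: %d interactions among %d proteins\n",
              nrow(x), length(unique(c(x[, 1], x[, 2])))))
  invisible(x)
}

#' Proteins covered by an edge list
#' @param edges an [edge_list()].
#' @return Sorted character vector of unique protein identifiers.
#' @export
edge_list_proteins <- function(edges) sort(unique(c(edges[, 1], edges[, 2])))

#' Binary adjacency matrix of an edge list
#'
#' @param edges an [edge_list()].
#' @param protein_ids node order for the matrix; edges whose endpoints fall
#'   outside this set are dropped.
#' @return Symmetric 0/1 matrix with zero diagonal and dimnames
#'   `protein_ids`.
#' @export
adjacency_matrix <- function(edges, protein_ids = edge_list_proteins(edges)) {
  n <- length(protein_ids)
  a <- matrix(0, n, n, dimnames = list(protein_ids, protein_ids))
  i <- match(edges[, 1], protein_ids)
  j <- match(edges[, 2], protein_ids)
  keep <- !is.na(i) & !is.na(j)
  a[cbind(i[keep], j[keep])] <- 1
  a[cbind(j[keep], i[keep])] <- 1
  a
}

#' Network series container
#'
#' An ordered list of T square symmetric matrices over one shared protein
#' index: the per-timepoint networks at any stage of the pipeline (activity,
#' co-expression, combined, or higher-order adjacency).
#'
#' @param protein_ids character identifiers shared by all matrices.
#' @param matrices list of square numeric matrices, all
#'   `length(protein_ids)` on a side.
#' @param timepoint_labels optional labels, one per matrix.
#' @param symmetric require symmetry (default TRUE; reconstructions from a
#'   row-wise model are not exactly symmetric and set this FALSE).
#' @return Object of class `network_series`.
#' @export
network_series <- function(protein_ids, matrices, timepoint_labels = NULL,
                           symmetric = TRUE) {
  protein_ids <- as.character(protein_ids)
  if (length(matrices) < 1L) stop("network series must contain >= 1 matrix")
  n <- length(protein_ids)
  for (k in seq_along(matrices)) {
    m <- matrices[[k]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop(sprintf("matrix %d is not %d x %d", k, n, n))
    if (!all(is.finite(m))) stop(sprintf("matrix %d has non-finite entries", k))
    if (symmetric && max(abs(m - t(m))) > 1e-8)
      stop(sprintf("matrix %d is not symmetric", k))
    dimnames(matrices[[k]]) <- list(protein_ids, protein_ids)
  }
  if (is.null(timepoint_labels))
    timepoint_labels <- paste0("t", seq_along(matrices))
  if (length(timepoint_labels) != length(matrices))
    stop("timepoint_labels length must equal number of matrices")
  structure(list(protein_ids = protein_ids, matrices = matrices,
                 timepoint_labels = as.character(timepoint_labels)),
            class = "network_series")
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf("network_series: %d timepoints, %d proteins\n",
              length(x$matrices), length(x$protein_ids)))
  invisible(x)
}

#' @export
length.network_series <- function(x) length(x$matrices)

#' Complex catalog container
#'
#' @param complexes named list of character vectors (member proteins); every
#'   complex must be non-empty.
#' @return Object of class `complex_catalog`.
#' @export
complex_catalog <- function(complexes) {
  if (is.null(names(complexes)) || any(names(complexes) == ""))
    names(complexes) <- paste0("complex", seq_along(complexes))
  if (any(lengths(complexes) == 0L)) stop("empty complex not allowed")
  complexes <- lapply(complexes, as.character)
  structure(list(complexes = complexes), class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("complex_catalog: %d complexes (sizes %d-%d)\n",
              length(x$complexes), min(lengths(x$complexes)),
              max(lengths(x$complexes))))
  invisible(x)
}
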