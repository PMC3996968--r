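#' Read a gene-expression time course
#'
#' Reads a genes x samples table and folds the sample columns into a
#' timepoints x replicates layout, where the replicates of a timepoint are
#' its observations in successive cycles.  Two layouts are supported:
#' `wide_tsv`, a plain tab-separated table whose first column is the gene
#' identifier, and `series_matrix`, a GEO-series-matrix-style file whose
#' expression table sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` lines with an ID_REF header row.
#'
#' @param path file path.
#' @param layout `"wide_tsv"` or `"series_matrix"`.
#' @param cycles number of replicate cycles the columns span; the column
#'   count must be divisible by it.
#' @param column_order `"cycle_major"` (cycle 1 timepoints 1..T, then cycle
#'   2, ...; the layout of cyclic GEO series) or `"timepoint_major"`
#'   (all cycles of timepoint 1 first).
#' @param impute_row_mean replace missing values by the row mean instead of
#'   failing (off by default; missing data are otherwise an error).
#' @return An [expression_matrix()] with `replicates = cycles`.
#' @export
read_expression <- function(path, layout = c("wide_tsv", "series_matrix"),
                            cycles = 1L,
                            column_order = c("cycle_major", "timepoint_major"),
                            impute_row_mean = FALSE) {
  layout <- match.arg(layout)
  column_order <- match.arg(column_order)
  cycles <- as.integer(cycles)
  if (cycles < 1L) stop("'cycles' must be a positive integer")
  if (!file.exists(path)) stop("file not found: ", path)

  lines <- readLines(path)
  if (layout == "series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("no series-matrix table found in ", path)
    lines <- lines[(beg + 2L):(end - 1L)]  # skip ID_REF header row
    offset <- beg + 1L
  } else {
    keep <- !grepl("^\\s*(#|$)", lines)
    offset_map <- which(keep)
    lines <- lines[keep]
    offset <- 0L
  }
  if (length(lines) == 0L) stop("no data rows in ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    line_no <- if (layout == "series_matrix") offset + 1L + bad else
      offset_map[bad]
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 line_no, nf[1], nf[bad]))
  }
  if (nf[1] < 2L) stop("expression table needs an id column plus values")

  gene_ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- t(vapply(fields, function(f) as.numeric(f[-1]),
                   numeric(nf[1] - 1L)))
  if (nf[1] == 2L) vals <- matrix(vals, ncol = 1L)

  if (anyNA(vals)) {
    if (!impute_row_mean)
      stop("missing expression values (set impute_row_mean = TRUE to impute)")
    for (i in seq_len(nrow(vals))) {
      miss <- is.na(vals[i, ])
      if (all(miss)) stop("gene ", gene_ids[i], " has no observed values")
      vals[i, miss] <- mean(vals[i, !miss])
    }
  }

  n_samples <- ncol(vals)
  if (n_samples %% cycles != 0L)
    stop(sprintf("column count %d not divisible by cycles = %d",
                 n_samples, cycles))
  n_t <- n_samples %/% cycles
  arr <- array(NA_real_, dim = c(nrow(vals), n_t, cycles))
  for (c in seq_len(cycles)) {
    cols <- if (column_order == "cycle_major")
      (c - 1L) * n_t + seq_len(n_t)
    else
      seq.int(c, by = cycles, length.out = n_t)
    arr[, , c] <- vals[, cols]
  }
  expression_matrix(gene_ids, arr)
}

#' Write an expression matrix as a wide TSV
#'
#' Inverse of [read_expression()] for the `wide_tsv`/`cycle_major` layout;
#' values are written with full double precision so that a read round-trip
#' is exact.
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  d <- dim(expr$values)
  wide <- matrix(NA_real_, d[1], d[2] * d[3])
  for (c in seq_len(d[3]))
    wide[, (c - 1L) * d[2] + seq_len(d[2])] <- expr$values[, , c]
  rows <- vapply(seq_len(d[1]), function(i)
    paste(c(expr$gene_ids[i], sprintf("%.17g", wide[i, ])), collapse = "\t"),
    character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Reads a tab-separated edge list (for example BioGRID-derived exports) and
#' returns a deduplicated, self-loop-free [edge_list()].  Lines starting
#' with `#` are skipped.
#'
#' @param path file path.
#' @param columns the two column indices holding the interactor
#'   identifiers (default the first two).
#' @return An [edge_list()]; an empty file yields an empty edge list with a
#'   warning.  Dropped self-loops are reported via [message()].
#' @export
read_edge_list <- function(path, columns = c(1L, 2L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_nos <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty edge list file: ", path)
    return(edge_list())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < max(columns))) {
    bad <- which(nf < max(columns))[1]
    stop(sprintf("parse error at line %d: need >= %d fields, found %d",
                 line_nos[bad], max(columns), nf[bad]))
  }
  from <- vapply(fields, `[[`, character(1), columns[1])
  to <- vapply(fields, `[[`, character(1), columns[2])
  loops <- from == to
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  edge_list(from[!loops], to[!loops])
}

#' Write an edge list as TSV
#' @param edges an [edge_list()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  writeLines(paste(edges[, 1], edges[, 2], sep = "\t"), path)
  invisible(path)
}

#' Read a protein-complex catalog
#'
#' One complex per line: a name field followed by tab-separated member
#' identifiers (the layout of curated complex catalogs such as CYC2008
#' exports).  Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return A [complex_catalog()].
#' @export
read_complex_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  line_nos <- which(!grepl("^\\s*(#|$)", lines))
  lines <- lines[line_nos]
  if (length(lines) == 0L) {
    warning("empty complex catalog: ", path)
    return(complex_catalog(stats::setNames(list(), character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1]
    stop(sprintf("empty complex at line %d (name with no members)",
                 line_nos[bad]))
  }
  complexes <- lapply(fields, function(f) unique(f[-1]))
  names(complexes) <- vapply(fields, `[[`, character(1), 1L)
  complex_catalog(complexes)
}

#' Read a gene list (one identifier per line)
#'
#' @param path file path; `#` comments and blank lines are skipped.
#' @return Character vector of unique identifiers, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  unique(lines[!grepl("^(#|$)", lines)])
}

#' Write / read a network series (versioned dense TSV container)
#'
#' The container is a plain-text file: `#%`-prefixed header lines carrying
#' the format version, protein index and timepoint labels, followed by one
#' dense block of tab-separated values per timepoint.  Values are written
#' with 17 significant digits, so doubles round-trip exactly.
#'
#' @param series a [network_series()].
#' @param path file path.
#' @return `write_network_series` returns `path` invisibly;
#'   `read_network_series` returns the [network_series()].
#' @export
write_network_series <- function(series, path) {
  if (length(series$matrices) == 0L) stop("cannot write an empty series")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#%format: network_series",
               "#%version: 1",
               paste0("#%n_proteins: ", length(series$protein_ids)),
               paste0("#%n_timepoints: ", length(series$matrices)),
               paste0("#%protein_ids: ",
                      paste(series$protein_ids, collapse = "\t")),
               paste0("#%timepoint_labels: ",
                      paste(series$timepoint_labels, collapse = "\t"))), con)
  for (k in seq_along(series$matrices)) {
    writeLines(paste0("#%matrix: ", series$timepoint_labels[k]), con)
    m <- series$matrices[[k]]
    writeLines(vapply(seq_len(nrow(m)), function(i)
      paste(sprintf("%.17g", m[i, ]), collapse = "\t"), character(1)), con)
  }
  invisible(path)
}

#' @rdname write_network_series
#' @export
read_network_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- function(key) {
    pat <- paste0("^#%", key, ": ")
    hit <- grep(pat, lines, value = TRUE)
    if (length(hit) == 0L) stop("malformed network series: missing ", key)
    sub(pat, "", hit[1])
  }
  if (!identical(hdr("format"), "network_series"))
    stop("not a network_series file: ", path)
  if (!identical(hdr("version"), "1"))
    stop("unsupported network_series version: ", hdr("version"))
  n <- as.integer(hdr("n_proteins"))
  t_n <- as.integer(hdr("n_timepoints"))
  ids <- strsplit(hdr("protein_ids"), "\t", fixed = TRUE)[[1]]
  labels <- strsplit(hdr("timepoint_labels"), "\t", fixed = TRUE)[[1]]
  starts <- grep("^#%matrix: ", lines)
  if (length(starts) != t_n)
    stop("expected ", t_n, " matrix blocks, found ", length(starts))
  mats <- lapply(starts, function(s) {
    block <- lines[(s + 1L):(s + n)]
    m <- do.call(rbind, lapply(strsplit(block, "\t", fixed = TRUE),
                               as.numeric))
    m
  })
  network_series(ids, mats, labels, symmetric = FALSE)
}

#' Save / load an msiDBN model checkpoint
#'
#' Checkpoints are RDS files carrying a format tag; all weight matrices,
#' biases and layer-size metadata are restored exactly.
#'
#' @param model an object of class `msidbn_model` (see [msidbn_train()]).
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "msidbn_model")) stop("not an msidbn_model")
  saveRDS(list(format = "msidbn_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "msidbn_model"))
    stop("not an msidbn model checkpoint: ", path)
  x$model
}

#' Write a criticality report as TSV
#'
#' Columns: protein, rank, rsd, mean_er, then one `er_<label>` column per
#' timepoint, in rank order.
#'
#' @param report a `criticality_report` (see [rank_critical()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  idx <- match(report$ranking, report$protein_ids)
  df <- data.frame(protein = report$ranking,
                   rank = seq_along(report$ranking),
                   rsd = report$rsd[idx],
                   mean_er = rowMeans(report$er)[idx],
                   report$er[idx, , drop = FALSE],
                   check.names = FALSE)
  names(df)[-(1:4)] <- paste0("er_", colnames(report$er))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
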