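#' Gene set constructor
#'
#' @param name Set name.
#' @param genes Character vector of member gene symbols.
#' @return A `gene_set` object (list with `name` and unique `genes`).
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop_mn("a gene set must be non-empty", "mn_bad_input")
  if (anyDuplicated(genes)) {
    rlang::warn(sprintf("gene set '%s': dropping %d duplicate members",
                        name, sum(duplicated(genes))))
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read and write GMT gene-set collections
#'
#' GMT is the tab-delimited format `name<TAB>description<TAB>gene1<TAB>...`,
#' one set per line.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop_mn("malformed GMT line (need name, description, >=1 gene)",
                                   "mn_malformed_gmt")
    gene_set(parts[1], parts[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' @param sets A list of [gene_set()] objects (or a single one).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "metaniche", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_id_table <- function(path, what) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tb) == 0) stop_mn(sprintf("empty %s table: %s", what, path), "mn_malformed_table")
  tb
}

#' Read a 10x-style MTX triplet bundle
#'
#' Loads a sparse gene x cell count matrix written in MatrixMarket coordinate
#' format together with its tab-delimited gene and cell tables, checks that
#' the three files describe the same dimensions and that identifiers are
#' unique, and returns the matrix keyed by gene symbol and cell id.  Gene
#' symbols that collide keep the row with the larger total count (with a
#' warning), matching symbol-keyed downstream matching.
#'
#' @param matrix_path Path to the MatrixMarket file.
#' @param genes_path Path to the gene table (columns `gene_id`, `symbol`, and
#'   optionally `chromosome`, `start`, `rank`).
#' @param cells_path Path to the cell table (column `cell_id`, and optionally
#'   `sample_id`, `condition`, `cell_type`, `doublet_score`).
#' @return A list with `counts` (dgCMatrix, symbols x cell ids), `genes` and
#'   `cells` tibbles.  `cells$total_umis` is (re)computed from the matrix.
#' @export
read_mtx_bundle <- function(matrix_path, genes_path, cells_path) {
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    stop_mn(sprintf("malformed MatrixMarket file %s: %s", matrix_path, conditionMessage(e)),
            "mn_malformed_mtx")
  })
  genes <- read_id_table(genes_path, "gene")
  cells <- read_id_table(cells_path, "cell")
  if (nrow(m) != nrow(genes)) {
    stop_mn(sprintf("matrix declares %d genes but gene table has %d rows",
                    nrow(m), nrow(genes)), "mn_dimension_mismatch")
  }
  if (ncol(m) != nrow(cells)) {
    stop_mn(sprintf("matrix declares %d cells but cell table has %d rows",
                    ncol(m), nrow(cells)), "mn_dimension_mismatch")
  }
  if (anyDuplicated(genes$gene_id)) stop_mn("duplicate gene_id in gene table", "mn_duplicate_ids")
  if (anyDuplicated(cells$cell_id)) stop_mn("duplicate cell_id in cell table", "mn_duplicate_ids")
  counts <- as_count_matrix(m)
  if (any(counts@x != round(counts@x))) {
    stop_mn("count matrix contains non-integer entries", "mn_bad_counts")
  }
  rownames(counts) <- genes$symbol
  colnames(counts) <- cells$cell_id
  if (anyDuplicated(genes$symbol)) {
    tot <- Matrix::rowSums(counts)
    keep <- !logical(nrow(counts))
    for (s in unique(genes$symbol[duplicated(genes$symbol)])) {
      idx <- which(genes$symbol == s)
      keep[idx[-which.max(tot[idx])]] <- FALSE
    }
    rlang::warn(sprintf("%d gene symbols collide; keeping the higher-total row of each",
                        sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
    genes <- genes[keep, , drop = FALSE]
  }
  cells$total_umis <- as.integer(Matrix::colSums(counts))
  list(counts = counts, genes = tibble::as_tibble(genes), cells = tibble::as_tibble(cells))
}

#' Write an MTX triplet bundle
#'
#' Inverse of [read_mtx_bundle()]: MatrixMarket coordinate file plus
#' tab-delimited gene and cell tables.  Integer matrices round-trip
#' bit-exactly.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param genes,cells Companion tibbles (`gene_id`/`symbol`, `cell_id`, ...).
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the three paths written.
#' @export
write_mtx_bundle <- function(counts, genes, cells, dir, prefix = "cohort") {
  if (nrow(counts) != nrow(genes) || ncol(counts) != nrow(cells)) {
    stop_mn("matrix dimensions do not match the companion tables", "mn_dimension_mismatch")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv", "_cells.tsv")))
  Matrix::writeMM(as_count_matrix(counts), paths[1])
  readr::write_tsv(tibble::as_tibble(genes), paths[2], progress = FALSE)
  readr::write_tsv(tibble::as_tibble(cells), paths[3], progress = FALSE)
  invisible(stats::setNames(paths, c("matrix", "genes", "cells")))
}
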