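#' Read a count matrix from disk
#'
#' Supports the MatrixMarket sparse coordinate dialect (1-based indices,
#' with `genes.tsv` and `barcodes.tsv` sidecars in the same directory) and
#' dense TSV with genes as rows and a header of cell ids.
#'
#' @param path For `format = "mtx"`, the `.mtx` file (sidecars are looked up
#'   next to it); for `format = "tsv"`, the TSV file.
#' @param format `"mtx"` or `"tsv"`.
#' @return A [count_matrix()].
#' @export
load_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    lines <- readLines(path, n = 100L)
    body <- grep("^%", lines, invert = TRUE)
    if (length(body) < 2L) stop("malformed MTX file: ", path)
    first_entry <- scan(text = lines[body[2L]], quiet = TRUE)
    if (length(first_entry) >= 2L && any(first_entry[1:2] < 1))
      stop("MTX indices must be 1-based (MatrixMarket coordinate dialect); ",
           "found a 0-based index in ", path)
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    genes <- utils::read.table(file.path(dir, "genes.tsv"),
                               sep = "\t", stringsAsFactors = FALSE)
    cells <- utils::read.table(file.path(dir, "barcodes.tsv"),
                               sep = "\t", stringsAsFactors = FALSE)
    if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m))
      stop("sidecar dimensions do not match the matrix")
    rownames(m) <- genes[[1L]]
    colnames(m) <- cells[[1L]]
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1L, check.names = FALSE)
    if (nrow(tab) == 0L || ncol(tab) == 0L) stop("empty matrix file: ", path)
    m <- as.matrix(tab)
  }
  count_matrix(m)
}

#' Write a count matrix to disk
#'
#' @param m A `CountMatrix`.
#' @param path Output `.mtx` file (sidecars written next to it) or TSV file.
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  m <- as_count_matrix(m)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    dir <- dirname(path)
    utils::write.table(data.frame(gene_ids(m)),
                       file.path(dir, "genes.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(cell_ids(m)),
                       file.path(dir, "barcodes.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(m$counts, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' Filter cells by coverage
#'
#' Retains cells having at least `min_genes` genes with at least
#' `min_reads_per_gene` reads each (defaults are the standard Smart-seq2
#' thresholds: 10 reads in each of at least 500 genes). Per-cell QC
#' statistics are computed before filtering.
#'
#' @param m A `CountMatrix`.
#' @param min_genes Minimum number of well-covered genes per retained cell.
#' @param min_reads_per_gene Reads required for a gene to count as covered.
#' @return A list with `counts` (the filtered `CountMatrix`) and `report`
#'   (a `QCReport`).
#' @export
filter_cells <- function(m, min_genes = 500L, min_reads_per_gene = 10L) {
  m <- as_count_matrix(m)
  covered <- colSums(m$counts >= min_reads_per_gene)
  keep <- covered >= min_genes
  report <- qc_report(m, keep_cells = keep)
  list(counts = m[, keep], report = report)
}

#' Filter genes by prevalence
#'
#' Retains genes expressed with at least `min_reads` reads in at least
#' `min_cells` cells (defaults: 10 reads in each of at least 5 cells).
#'
#' @param m A `CountMatrix`.
#' @param min_cells Minimum number of well-covered cells per retained gene.
#' @param min_reads Reads required for a cell to count.
#' @return The filtered `CountMatrix`.
#' @export
filter_genes <- function(m, min_cells = 5L, min_reads = 10L) {
  m <- as_count_matrix(m)
  keep <- rowSums(m$counts >= min_reads) >= min_cells
  m[keep, ]
}

qc_report <- function(m, keep_cells) {
  counts <- m$counts
  total <- colSums(counts)
  mito <- if (!is.null(m$gene_classes$mito)) {
    mg <- intersect(m$gene_classes$mito, rownames(counts))
    mr <- colSums(counts[mg, , drop = FALSE])
    ifelse(total > 0, mr / total, 0)
  } else rep(NA_real_, ncol(counts))
  structure(list(
    n_cells_in = ncol(counts),
    n_cells_out = sum(keep_cells),
    n_genes_in = nrow(counts),
    n_genes_out = nrow(counts),
    per_cell = data.frame(
      cell = colnames(counts),
      genes_observed = colSums(counts >= 1),
      total_reads = total,
      mito_fraction = mito,
      retained = keep_cells,
      row.names = NULL)),
    class = "QCReport")
}

#' @export
#' @method print QCReport
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d/%d cells retained, %d genes\n",
              x$n_cells_out, x$n_cells_in, x$n_genes_in))
  invisible(x)
}

#' Count Hox genes expressed per cell
#'
#' A cell "expresses" a Hox gene when it has at least `min_reads` reads of
#' it (default 1). Cells expressing none of the listed genes receive an
#' exclusion mask, since they cannot be mapped to an axis position.
#'
#' @param m A `CountMatrix`.
#' @param hox_genes Character vector of Hox gene ids (typically the seven
#'   *Drosophila* Hox genes lab, Dfd, Scr, Antp, Ubx, abd-A, Abd-B).
#' @param min_reads Reads required to call a gene expressed.
#' @return A data.frame with columns `cell`, `n_hox_expressed` and
#'   `masked` (TRUE when no listed gene is expressed). Gene ids absent from
#'   the matrix are reported in the `missing_genes` attribute.
#' @export
annotate_hox <- function(m, hox_genes, min_reads = 1L) {
  m <- as_count_matrix(m)
  if (length(hox_genes) == 0L) stop("empty Hox gene list")
  present <- intersect(hox_genes, gene_ids(m))
  missing <- setdiff(hox_genes, present)
  n_hox <- if (length(present))
    colSums(m$counts[present, , drop = FALSE] >= min_reads)
  else rep(0L, ncol(m$counts))
  out <- data.frame(cell = cell_ids(m),
                    n_hox_expressed = as.integer(n_hox),
                    masked = n_hox == 0L, row.names = NULL)
  attr(out, "missing_genes") <- missing
  out
}

#' Per-cell mitochondrial read fraction
#'
#' @param m A `CountMatrix` whose `gene_classes` annotation contains a
#'   `mito` entry listing mitochondrial genes.
#' @return Named numeric vector of fractions (0 for cells with no reads).
#' @export
mito_fraction <- function(m) {
  m <- as_count_matrix(m)
  if (is.null(m$gene_classes$mito))
    stop("no mitochondrial gene annotation (gene_classes$mito)")
  mg <- intersect(m$gene_classes$mito, gene_ids(m))
  total <- colSums(m$counts)
  mito <- colSums(m$counts[mg, , drop = FALSE])
  ifelse(total > 0, mito / total, 0)
}
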