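#' Construct a CountMatrix
#'
#' Light container for a genes x cells matrix of raw read counts, with
#' optional gene-class annotation. Counts must be nonnegative integers;
#' gene and cell identifiers must be unique.
#'
#' @param counts Integer matrix, genes in rows, cells in columns, with
#'   rownames (gene ids) and colnames (cell ids).
#' @param gene_classes Optional named list mapping a class label (e.g.
#'   `"homeobox"`, `"ig"`, `"hox"`, `"mito"`) to a character vector of gene
#'   ids belonging to that class.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   and `gene_classes`.
#' @export
count_matrix <- function(counts, gene_classes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- if (nrow(counts)) paste0("gene", seq_len(nrow(counts)))
                        else character(0)
  if (is.null(colnames(counts)))
    colnames(counts) <- if (ncol(counts)) paste0("cell", seq_len(ncol(counts)))
                        else character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("non-integer counts")
  storage.mode(counts) <- "double"
  if (!is.null(gene_classes)) {
    stopifnot(is.list(gene_classes), !is.null(names(gene_classes)))
    gene_classes <- lapply(gene_classes, as.character)
  }
  structure(list(counts = counts, gene_classes = gene_classes),
            class = "CountMatrix")
}

#' @export
#' @method print CountMatrix
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$gene_classes))
    cat("gene classes:",
        paste(sprintf("%s (%d)", names(x$gene_classes),
                      lengths(x$gene_classes)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Coerce to a CountMatrix
#'
#' @param x A `CountMatrix` or a plain matrix.
#' @param gene_classes Passed to [count_matrix()] when `x` is a matrix.
#' @return A `CountMatrix`.
#' @export
as_count_matrix <- function(x, gene_classes = NULL) {
  if (inherits(x, "CountMatrix")) return(x)
  count_matrix(x, gene_classes = gene_classes)
}

gene_ids <- function(m) rownames(m$counts)
cell_ids <- function(m) colnames(m$counts)

#' Subset a CountMatrix
#'
#' @param x A `CountMatrix`.
#' @param i,j Gene / cell indices (any form accepted by `[`).
#' @param ... Ignored.
#' @return A `CountMatrix` with gene-class annotation restricted to the
#'   retained genes.
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  if (is.null(dimnames(counts)))   # dropped on zero-extent subsets
    dimnames(counts) <- list(rownames(x$counts)[i][seq_len(nrow(counts))],
                             colnames(x$counts)[j][seq_len(ncol(counts))])
  gc <- x$gene_classes
  if (!is.null(gc))
    gc <- lapply(gc, function(g) intersect(g, rownames(counts)))
  count_matrix(counts, gene_classes = gc)
}
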