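# Cell clustering: major clusters from the top variable genes,
# homeodomain-code clusters on near-binary values, dorsal/ventral
# projection scoring from marker prevalence, and the sequencing-depth
# sanity check on cluster assignments.

#' Hierarchical clustering of cells on the most variable genes
#'
#' Ward-linkage, Euclidean-distance hierarchical clustering of cells on
#' scaled expression of the `n_genes` most variable genes (ranked by the
#' excess-variance test), cut at `n_clusters`. With the defaults this is
#' the 20-gene, 3-cluster major-cluster step.
#'
#' @param scaled_expr Matrix genes x cells of scaled expression.
#' @param hvg An `HVGResult` from [test_variable_genes()].
#' @param n_genes Number of top genes (default 20).
#' @param n_clusters Number of clusters (default 3).
#' @return List with `labels` (named integer per cell), `panel` (gene ids
#'   used) and `hclust` (the dendrogram).
#' @export
top_variable_clustering <- function(scaled_expr, hvg, n_genes = 20L,
                                    n_clusters = 3L) {
  stopifnot(n_clusters >= 1L)
  if (ncol(scaled_expr) < n_clusters) stop("fewer cells than clusters")
  ord <- order(hvg$p, -hvg$cv2)
  panel <- utils::head(hvg$gene[ord], n_genes)
  panel <- intersect(panel, rownames(scaled_expr))
  hc <- stats::hclust(stats::dist(t(scaled_expr[panel, , drop = FALSE])),
                      method = "ward.D2")
  labels <- stats::cutree(hc, k = n_clusters)
  list(labels = labels, panel = panel, hclust = hc)
}

#' Homeodomain-code clustering on near-binary values
#'
#' Ward-linkage, Euclidean-distance hierarchical clustering of cells on the
#' near-binary matrix of (variable) homeobox genes, after removing
#' Hox-negative cells, cut at `n_clusters` (60 in the motoneuron analysis,
#' matching the estimated number of cells per segment repeat). When
#' per-cell positions are supplied, cluster ids are renumbered by mean
#' inferred AP position so that cluster 1 is the most anterior.
#'
#' @param nb_expr Near-binary matrix (homeobox genes x cells) from
#'   [near_binary_matrix()].
#' @param hox_mask Optional logical per-cell vector; TRUE cells (no Hox
#'   expression) are excluded before clustering.
#' @param n_clusters Number of clusters.
#' @param positions Optional named per-cell positions used to order cluster
#'   ids along the axis.
#' @return List with `labels` (named integer per retained cell), `panel`
#'   and `hclust`.
#' @export
homeo_clustering <- function(nb_expr, hox_mask = NULL, n_clusters = 60L,
                             positions = NULL) {
  if (nrow(nb_expr) == 0L) stop("empty homeobox panel")
  if (!is.null(hox_mask)) {
    stopifnot(length(hox_mask) == ncol(nb_expr))
    nb_expr <- nb_expr[, !hox_mask, drop = FALSE]
  }
  if (ncol(nb_expr) < n_clusters)
    stop("n_clusters exceeds the number of cells")
  hc <- stats::hclust(stats::dist(t(nb_expr)), method = "ward.D2")
  labels <- stats::cutree(hc, k = n_clusters)
  if (!is.null(positions)) {
    mean_pos <- tapply(positions[colnames(nb_expr)], labels, mean,
                       na.rm = TRUE)
    remap <- integer(n_clusters)
    remap[as.integer(names(sort(mean_pos)))] <- seq_len(n_clusters)
    labels <- stats::setNames(remap[labels], names(labels))
  }
  list(labels = labels, panel = rownames(nb_expr), hclust = hc)
}

#' Score cells as dorsally or ventrally projecting motoneurons
#'
#' For each marker, its prevalence p is the fraction of all cells with at
#' least `min_reads` reads of it. A cell's dorsal (ventral) score is the
#' sum of -log(p) over the dorsal (ventral) markers it expresses: observing
#' a rare marker is strong evidence, a ubiquitous one none. The call is the
#' larger score, `ambiguous` on ties (including the all-zero case).
#'
#' @param m A `CountMatrix` or matrix.
#' @param dmn_markers,vmn_markers Character vectors of marker gene ids.
#' @param min_reads Reads required to call a marker observed (default 1).
#' @return data.frame: `cell`, `dmn_score`, `vmn_score`, `call`.
#' @export
subtype_score <- function(m, dmn_markers, vmn_markers, min_reads = 1L) {
  m <- as_count_matrix(m)
  if (length(dmn_markers) == 0L || length(vmn_markers) == 0L)
    stop("empty marker set")
  score_set <- function(markers) {
    markers <- intersect(markers, gene_ids(m))
    if (length(markers) == 0L) stop("no marker present in the matrix")
    obs <- m$counts[markers, , drop = FALSE] >= min_reads
    prev <- rowMeans(obs)
    if (any(prev == 0)) {
      warning("marker(s) never observed, excluded: ",
              paste(markers[prev == 0], collapse = ", "))
      obs <- obs[prev > 0, , drop = FALSE]
      prev <- prev[prev > 0]
    }
    colSums(obs * -log(prev))
  }
  dmn <- score_set(dmn_markers)
  vmn <- score_set(vmn_markers)
  call <- ifelse(dmn > vmn, "dMN", ifelse(vmn > dmn, "vMN", "ambiguous"))
  data.frame(cell = cell_ids(m), dmn_score = dmn, vmn_score = vmn,
             call = call, row.names = NULL)
}

#' Check cluster assignments against sequencing depth
#'
#' Per cluster, a two-sided Wilcoxon rank-sum test contrasting total reads
#' of cells in the cluster against all other cells. Clusters driven by
#' technical depth rather than biology show small p-values here.
#'
#' @param labels Named per-cell cluster labels.
#' @param depth Per-cell total read counts, aligned with `labels`.
#' @param alpha Significance level for the summary count (default 0.05).
#' @return data.frame (`cluster`, `n_cells`, `p`) with attribute
#'   `n_significant`.
#' @export
covariate_check <- function(labels, depth, alpha = 0.05) {
  stopifnot(length(labels) == length(depth))
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  cl <- sort(unique(labels))
  p <- vapply(cl, function(k) {
    inside <- depth[labels == k]; outside <- depth[labels != k]
    suppressWarnings(stats::wilcox.test(inside, outside)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  out <- data.frame(cluster = cl,
                    n_cells = as.integer(table(labels)[as.character(cl)]),
                    p = p, row.names = NULL)
  attr(out, "n_significant") <- sum(p < alpha)
  out
}
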