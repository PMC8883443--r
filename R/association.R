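# Association of gene expression with homeodomain-code cluster identity:
# per-gene one-way ANOVA F-tests, Fisher enrichment of gene classes among
# the associated genes, the Ig-by-cluster expression map, and the
# hypergeometric gene-set overlap statistic.

#' Per-gene F-test of association with cluster identity
#'
#' One-way ANOVA of scaled expression across cluster labels, per gene, with
#' Benjamini-Hochberg adjustment across genes. Computed from the
#' sum-of-squares decomposition; a gene with no between-cluster variation
#' has F = 0 and p = 1.
#'
#' @param scaled_expr Matrix genes x cells.
#' @param labels Per-cell cluster labels (at least 2 clusters, each with at
#'   least 2 cells).
#' @return data.frame: `gene`, `f_stat`, `p`, `p_adj`.
#' @export
cluster_association_ftest <- function(scaled_expr, labels) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  if (k < 2L) stop("all cells in one cluster")
  sizes <- table(labels)
  if (any(sizes < 2L)) stop("cluster with fewer than 2 cells")
  n <- length(labels)
  stopifnot(ncol(scaled_expr) == n)
  g_mat <- stats::model.matrix(~ labels - 1)        # cells x k indicator
  grp_sum <- scaled_expr %*% g_mat                  # genes x k
  grp_n <- matrix(as.numeric(sizes), nrow(scaled_expr), k, byrow = TRUE)
  grp_mean <- grp_sum / grp_n
  grand <- rowMeans(scaled_expr)
  ssb <- rowSums(grp_n * (grp_mean - grand)^2)
  sst <- rowSums((scaled_expr - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- ifelse(ssw > 0, (ssb / (k - 1)) / (ssw / (n - k)), ifelse(ssb > 0, Inf, 0))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssb == 0] <- 1
  data.frame(gene = rownames(scaled_expr), f_stat = f, p = p,
             p_adj = stats::p.adjust(p, "BH"), row.names = NULL)
}

#' Gene-class enrichment among cluster-associated genes
#'
#' Per class, a 2x2 Fisher exact test of (significant at `alpha`, after BH
#' adjustment) x (in class), plus a complementary two-sided Wilcoxon
#' rank-sum test contrasting the association p-values (as -log10 p) of
#' in-class versus out-of-class genes.
#'
#' @param results data.frame from [cluster_association_ftest()].
#' @param class_sets Named list of gene-id vectors (intersected with the
#'   tested genes).
#' @param alpha Significance level applied to `p_adj` (default 0.05).
#' @param use_adjusted Use `p_adj` (default) or raw `p` for the cut.
#' @return data.frame: `class`, `n_class`, `n_sig`, `overlap`, `fisher_p`,
#'   `wilcox_p`.
#' @export
class_association_fisher <- function(results, class_sets, alpha = 0.05,
                                     use_adjusted = TRUE) {
  pvec <- if (use_adjusted) results$p_adj else results$p
  sig <- results$gene[pvec < alpha]
  tested <- results$gene
  rows <- lapply(names(class_sets), function(cl) {
    cls <- intersect(class_sets[[cl]], tested)
    if (length(cls) == 0L) stop("class ", cl, " empty after intersection")
    in_class <- tested %in% cls
    is_sig <- tested %in% sig
    tab <- table(factor(is_sig, c(TRUE, FALSE)),
                 factor(in_class, c(TRUE, FALSE)))
    fp <- stats::fisher.test(tab)$p.value
    lp <- -log10(pmax(results$p, .Machine$double.xmin))
    wp <- if (all(in_class) || !any(in_class)) NA_real_ else
      suppressWarnings(stats::wilcox.test(lp[in_class], lp[!in_class])$p.value)
    data.frame(class = cl, n_class = length(cls), n_sig = length(sig),
               overlap = sum(in_class & is_sig), fisher_p = fp,
               wilcox_p = wp)
  })
  do.call(rbind, rows)
}

#' Mean and median Ig-gene expression per homeodomain cluster
#'
#' For each (cluster, Ig gene) pair, the mean and median of normalized
#' expression across the cluster's cells; rows ordered by the supplied
#' cluster order (typically mean inferred AP position, so the map reads
#' anterior to posterior).
#'
#' @param norm_expr Matrix genes x cells of normalized expression
#'   (size-factor-normalized log1p values).
#' @param labels Named per-cell cluster labels.
#' @param ig_genes Character vector of Ig-domain gene ids; ids absent from
#'   the matrix are reported via a warning, not an error.
#' @param cluster_order Optional vector of cluster ids in display order
#'   (default: sorted unique labels).
#' @return data.frame: `cluster`, `gene`, `mean_expr`, `median_expr`.
#' @export
ig_cluster_map <- function(norm_expr, labels, ig_genes,
                           cluster_order = NULL) {
  stopifnot(ncol(norm_expr) == length(labels))
  present <- intersect(ig_genes, rownames(norm_expr))
  missing <- setdiff(ig_genes, present)
  if (length(missing))
    warning("Ig gene(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(present) == 0L)
    return(data.frame(cluster = integer(0), gene = character(0),
                      mean_expr = numeric(0), median_expr = numeric(0)))
  if (is.null(cluster_order)) cluster_order <- sort(unique(labels))
  rows <- lapply(cluster_order, function(k) {
    idx <- which(labels == k)
    sub <- norm_expr[present, idx, drop = FALSE]
    data.frame(cluster = k, gene = present,
               mean_expr = rowMeans(sub),
               median_expr = apply(sub, 1L, stats::median))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two gene sets drawn from a universe of `universe_size` genes (default
#' 13,920, the number of protein-coding genes used as reference).
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Universe size (default 13920).
#' @return List with `overlap` and `p`.
#' @export
overlap_hypergeometric <- function(set_a, set_b, universe_size = 13920L) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size)
    stop("set larger than the universe")
  ov <- length(intersect(set_a, set_b))
  p <- stats::phyper(ov - 1, length(set_a),
                     universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = ov, p = p)
}
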