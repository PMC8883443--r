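# End-to-end orchestration: QC -> HVG -> normalization -> reference ->
# position mapping -> spatially variable genes -> clustering ->
# association, with every stage's output written as TSV plus a manifest of
# parameters, so a run is reproducible from its config and seed alone.

#' Pipeline configuration
#'
#' Defaults reproduce the standard analysis settings: QC thresholds 500
#' genes x 10 reads (cells) and 5 cells x 10 reads (genes), HVG FDR 0.1,
#' near-binary k = 1e6, background rate lambda = 0.1, a 201-point AP grid,
#' spline df 3, smoothing decay 10, 3 major clusters, 60 homeo clusters,
#' 10 pattern modules, association alpha 0.05.
#'
#' @param counts Optional path to a counts TSV/MTX; when NULL a synthetic
#'   dataset is generated (see [run_pipeline()]).
#' @param out_dir Output directory.
#' @param ... Parameter overrides (any of the names in the default list).
#'   `min_genes` defaults to 500 for real count files and to 10 for the
#'   synthetic default dataset, which has far fewer genes than a
#'   transcriptome.
#' @param seed Integer seed.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(counts = NULL, out_dir = tempfile("hoxpos_run"),
                            ..., seed = 1L) {
  cfg <- list(counts = counts, out_dir = out_dir, seed = as.integer(seed),
              min_genes = if (is.null(counts)) 10L else 500L,
              min_reads = 10L,
              gene_min_cells = 5L, gene_min_reads = 10L,
              fdr = 0.1, k = 1e6, lambda = 0.1, grid_size = 201L,
              df = 3L, decay = 10, n_major = 3L, n_homeo = 60L,
              n_patterns = 10L, alpha = 0.05,
              sim_n_cells = 500L, sim_r = 20, sim_n_spatial = 20L,
              sim_n_flat = 50L, sim_effect = 8)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Fields in the file override the defaults of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' When `config$counts` is NULL, a seeded synthetic dataset is generated
#' from the default seven-stripe Hox reference (plus planted spatial and
#' flat genes), so every stage runs without external inputs. Stages: cell
#' and gene QC filters, Hox positivity, size factors and the technical
#' noise fit, variable-gene test, near-binary normalization, position
#' mapping, spatially-variable-gene selection and pattern modules,
#' homeodomain clustering, depth check, and cluster-association tests.
#' All result tables are written to `config$out_dir` together with a
#' `manifest.yaml` of the parameters used.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ref <- make_reference(default_hox_specs(), grid_size = config$grid_size)
  if (is.null(config$counts)) {
    sim <- simulate_cells(ref, n_cells = config$sim_n_cells,
                          r = config$sim_r, lambda_bg = config$lambda,
                          depth_spread = 0.2, seed = config$seed)
    sim <- add_spatial_genes(sim$counts, sim$truth,
                             n_spatial = config$sim_n_spatial,
                             n_flat = config$sim_n_flat,
                             effect = config$sim_effect,
                             seed = config$seed + 1L)
    m <- sim$counts; truth <- sim$truth
  } else {
    fmt <- if (grepl("\\.mtx$", config$counts)) "mtx" else "tsv"
    m <- load_counts(config$counts, format = fmt)
    truth <- NULL
  }

  qc <- filter_cells(m, min_genes = min(config$min_genes, nrow(m$counts)),
                     min_reads_per_gene = config$min_reads)
  m2 <- filter_genes(qc$counts, min_cells = config$gene_min_cells,
                     min_reads = config$gene_min_reads)
  tsv(qc$report$per_cell, "qc_report.tsv")

  hox_genes <- if (!is.null(m2$gene_classes$hox))
    intersect(m2$gene_classes$hox, gene_ids(m2)) else character(0)
  hox <- if (length(hox_genes)) annotate_hox(m2, hox_genes) else NULL

  sf <- size_factors(m2)
  fit <- fit_technical_noise(m2, sf)
  hvg <- test_variable_genes(m2, fit, fdr = config$fdr)
  tsv(hvg, "hvg.tsv")
  scaled <- scale_expression(m2, fit)

  positions <- NULL
  if (length(hox_genes) >= 2L) {
    params <- mapping_params(estimate_rg(m2, hox_genes),
                             lambda_bg = config$lambda)
    est <- map_position(m2[hox_genes, ], ref, params)
    est$x_units <- axis_units(est$x_hat, "units")
    tsv(est, "positions.tsv")
    positions <- stats::setNames(est$x_hat, est$cell)
  }

  svg <- NULL
  if (!is.null(positions) && sum(!is.na(positions)) >= 10L) {
    svg <- select_spatial_genes(scaled, positions, df = config$df)
    spatial <- svg$gene[svg$is_spatial]
    if (length(spatial) >= config$n_patterns) {
      grid <- seq(0, 1, length.out = config$grid_size)
      prof <- t(vapply(spatial, function(g)
        smooth_profile(scaled[g, ], positions, decay = config$decay,
                       grid = grid)$values, numeric(config$grid_size)))
      svg$pattern_cluster <- NA_integer_
      svg$pattern_cluster[match(spatial, svg$gene)] <-
        cluster_patterns(prof, n_groups = config$n_patterns)
    }
    tsv(svg, "spatial_genes.tsv")
  }

  clusters <- NULL
  hb_panel <- if (!is.null(m2$gene_classes$homeobox))
    intersect(m2$gene_classes$homeobox, gene_ids(m2)) else hox_genes
  if (length(hb_panel) >= 2L) {
    nb <- near_binary_matrix(m2[hb_panel, ], sf = sf, k = config$k)
    mask <- if (!is.null(hox)) hox$masked else NULL
    n_cl <- min(config$n_homeo, ncol(nb) - 1L)
    clusters <- homeo_clustering(nb, hox_mask = mask, n_clusters = n_cl,
                                 positions = positions)
    tsv(data.frame(cell = names(clusters$labels),
                   homeo_cluster = clusters$labels), "clusters.tsv")
    depth <- colSums(m2$counts)[names(clusters$labels)]
    tsv(covariate_check(clusters$labels, depth), "depth_check.tsv")
  }

  assoc <- NULL
  if (!is.null(clusters)) {
    # singleton clusters carry no within-group variance; drop for the F-test
    sizes <- table(clusters$labels)
    ok <- clusters$labels %in% as.integer(names(sizes[sizes >= 2L]))
    cells <- names(clusters$labels)[ok]
    assoc <- cluster_association_ftest(scaled[, cells, drop = FALSE],
                                       clusters$labels[ok])
    tsv(assoc, "association.tsv")
    if (!is.null(m2$gene_classes$ig)) {
      cls <- class_association_fisher(
        assoc, m2$gene_classes["ig"], alpha = config$alpha)
      tsv(cls, "class_association.tsv")
      lognorm <- log1p(sweep(m2$counts, 2L, sf, `/`))
      igmap <- ig_cluster_map(lognorm[, cells, drop = FALSE],
                              clusters$labels, m2$gene_classes$ig)
      tsv(igmap, "ig_cluster_map.tsv")
    }
  }

  manifest <- c(unclass(config)[!vapply(config, is.null, logical(1))],
                list(n_cells_retained = ncol(m2$counts),
                     n_genes_retained = nrow(m2$counts)))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(config = config, counts = m2, truth = truth, qc = qc,
                 fit = fit, hvg = hvg, scaled = scaled, reference = ref,
                 positions = positions, svg = svg, clusters = clusters,
                 association = assoc))
}
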