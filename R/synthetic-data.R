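# Synthetic datasets with the generative structure the position-mapping
# model assumes: stripe/domain reference curves, Poisson counts with a
# background rate in non-expressing territory, planted spatially variable
# genes, and planted homeodomain-code clusters with linked Ig programs.

#' Stripe specification for a synthetic reference gene
#'
#' @param gene Gene identifier.
#' @param center Stripe center as an axis fraction in \[0,1\].
#' @param width Stripe width as an axis fraction (> 0). For `boxcar` this is
#'   the full support; for `gaussian` it is twice the standard deviation
#'   (support truncated at 3 sd); for `sigmoid-tail` it is the length scale
#'   of the posterior-rising sigmoid.
#' @param shape One of `"boxcar"`, `"gaussian"`, `"sigmoid-tail"`.
#' @param peak Peak intensity in (0,1\].
#' @return A `StripeSpec` (named list).
#' @export
stripe_spec <- function(gene, center, width,
                        shape = c("boxcar", "gaussian", "sigmoid-tail"),
                        peak = 1) {
  shape <- match.arg(shape)
  stopifnot(width > 0, peak > 0, peak <= 1, center >= 0, center <= 1)
  structure(list(gene = gene, center = center, width = width,
                 shape = shape, peak = peak), class = "StripeSpec")
}

#' Default seven-gene Hox stripe panel
#'
#' Mimics the *Drosophila* Hox arrangement: three anterior genes (lab, Dfd,
#' Scr) in non-overlapping discrete stripes and four posterior genes (Antp,
#' Ubx, abd-A, Abd-B) in broad, partially overlapping domains, Abd-B rising
#' toward the posterior end.
#'
#' @return List of seven [stripe_spec()] objects.
#' @export
default_hox_specs <- function() {
  list(
    stripe_spec("lab",  0.06, 0.08, "boxcar"),
    stripe_spec("Dfd",  0.17, 0.08, "boxcar"),
    stripe_spec("Scr",  0.28, 0.08, "boxcar"),
    stripe_spec("Antp", 0.45, 0.16, "gaussian"),
    stripe_spec("Ubx",  0.60, 0.16, "gaussian"),
    stripe_spec("abdA", 0.74, 0.16, "gaussian"),
    stripe_spec("AbdB", 0.85, 0.20, "sigmoid-tail"))
}

stripe_curve <- function(spec, grid) {
  with(spec, switch(shape,
    boxcar = ifelse(grid >= center - width / 2 & grid <= center + width / 2,
                    peak, 0),
    gaussian = {
      sd <- width / 2
      y <- peak * exp(-(grid - center)^2 / (2 * sd^2))
      y[abs(grid - center) > 3 * sd] <- 0
      y
    },
    `sigmoid-tail` = {
      y <- peak * stats::plogis((grid - center) / (width / 4))
      y[y < 0.01 * peak] <- 0
      y
    }))
}

#' Build a synthetic AP reference map from stripe specifications
#'
#' @param stripe_specs List of [stripe_spec()] objects (at least one).
#' @param grid_size Number of grid points on \[0,1\].
#' @param seed Unused (the construction is deterministic); kept so that all
#'   generator entry points share a signature.
#' @return A [reference_map()]. Overlapping boxcar stripes trigger a
#'   warning, not an error (posterior Hox domains are meant to overlap).
#' @export
make_reference <- function(stripe_specs, grid_size = 201L, seed = NULL) {
  if (length(stripe_specs) == 0L) stop("at least one stripe spec required")
  stopifnot(grid_size >= 2L)
  grid <- seq(0, 1, length.out = grid_size)
  curves <- t(vapply(stripe_specs, stripe_curve, numeric(grid_size), grid = grid))
  rownames(curves) <- vapply(stripe_specs, `[[`, character(1), "gene")
  boxcars <- which(vapply(stripe_specs, function(s) s$shape == "boxcar",
                          logical(1)))
  if (length(boxcars) >= 2L) {
    for (i in boxcars) for (j in boxcars) if (i < j) {
      if (sum(pmin(curves[i, ], curves[j, ])) > 0)
        warning("boxcar stripes ", rownames(curves)[i], " and ",
                rownames(curves)[j], " overlap")
    }
  }
  reference_map(grid, curves)
}

#' Simulate single cells from the Poisson observation model
#'
#' Each cell draws a uniform position \eqn{x_c} on \[0,1\]. Counts for gene
#' g are Poisson with mean \eqn{r_g Y_g(x_c)} where the reference is
#' positive and mean \eqn{\lambda} in non-expressing territory; an optional
#' per-cell lognormal depth factor (sd `depth_spread` on the log scale,
#' mean 1) scales all means.
#'
#' @param reference A `ReferenceMap`.
#' @param n_cells Number of cells (> 0).
#' @param r Per-gene expected count at full intensity; scalar or vector
#'   matching the reference genes.
#' @param lambda_bg Background Poisson rate (>= 0); default 0.1.
#' @param depth_spread Log-scale sd of the per-cell depth factor (0 = none).
#' @param seed Integer seed.
#' @return List with `counts` (a `CountMatrix`) and `truth` (list with
#'   `positions`, `depth`, `params`).
#' @export
simulate_cells <- function(reference, n_cells, r, lambda_bg = 0.1,
                           depth_spread = 0, seed = 1L) {
  stopifnot(inherits(reference, "ReferenceMap"), n_cells > 0,
            lambda_bg >= 0, depth_spread >= 0)
  genes <- rownames(reference$curves)
  r <- rep_len(r, length(genes))
  if (any(r <= 0)) stop("r must be positive for every reference gene")
  names(r) <- genes
  set.seed(seed)
  pos <- stats::runif(n_cells)
  depth <- if (depth_spread > 0)
    stats::rlnorm(n_cells, meanlog = -depth_spread^2 / 2,
                  sdlog = depth_spread)
  else rep(1, n_cells)
  y <- reference_at(reference, pos)                 # genes x cells
  mu <- ifelse(y > 0, r * y, lambda_bg)             # r recycles by row
  mu <- sweep(mu, 2L, depth, `*`)
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  dimnames(counts) <- list(genes, paste0("cell", seq_len(n_cells)))
  truth <- list(positions = stats::setNames(pos, colnames(counts)),
                depth = depth,
                spatial_gene_flags = stats::setNames(
                  rep(TRUE, length(genes)), genes),
                params = list(r = r, lambda_bg = lambda_bg,
                              depth_spread = depth_spread, seed = seed))
  list(counts = count_matrix(counts, gene_classes = list(hox = genes)),
       truth = truth)
}

#' Append planted spatially variable and flat genes
#'
#' Spatial genes follow a smooth Poisson mean over position (sigmoid or
#' single gaussian bump, alternating) with dynamic range `effect`; flat
#' genes have a position-independent mean. Depth factors recorded in
#' `truth` scale all appended means.
#'
#' @param counts A `CountMatrix` from [simulate_cells()].
#' @param truth Matching truth list (must contain `positions`).
#' @param n_spatial,n_flat Numbers of genes to append.
#' @param effect Fold change between the low and high end of a spatial
#'   gene's profile (> 1).
#' @param base_mean Poisson mean at the low end (default 5).
#' @param seed Integer seed.
#' @return List with updated `counts` and `truth` (flags extended).
#' @export
add_spatial_genes <- function(counts, truth, n_spatial, n_flat,
                              effect, base_mean = 5, seed = 1L) {
  if (effect <= 1) stop("effect must exceed 1")
  stopifnot(!is.null(truth$positions))
  counts <- as_count_matrix(counts)
  pos <- truth$positions
  n_cells <- length(pos)
  depth <- if (is.null(truth$depth)) rep(1, n_cells) else truth$depth
  set.seed(seed)
  sim_gene <- function(i, spatial) {
    if (spatial) {
      center <- stats::runif(1, 0.2, 0.8)
      f <- if (i %% 2L == 0L)
        stats::plogis((pos - center) / 0.05)
      else
        exp(-(pos - center)^2 / (2 * 0.1^2))
      if (stats::runif(1) < 0.5) f <- 1 - f   # anterior- or posterior-high
      mu <- base_mean * (1 + (effect - 1) * f)
    } else {
      mu <- rep(base_mean, n_cells)
    }
    stats::rpois(n_cells, mu * depth)
  }
  new <- rbind(
    if (n_spatial > 0)
      t(vapply(seq_len(n_spatial), sim_gene, numeric(n_cells), spatial = TRUE)),
    if (n_flat > 0)
      t(vapply(seq_len(n_flat), sim_gene, numeric(n_cells), spatial = FALSE)))
  rownames(new) <- c(if (n_spatial > 0) paste0("sv", seq_len(n_spatial)),
                     if (n_flat > 0) paste0("flat", seq_len(n_flat)))
  colnames(new) <- cell_ids(counts)
  flags <- stats::setNames(rep(c(TRUE, FALSE), c(n_spatial, n_flat)),
                           rownames(new))
  truth$spatial_gene_flags <- c(truth$spatial_gene_flags, flags)
  list(counts = count_matrix(rbind(counts$counts, new),
                             gene_classes = counts$gene_classes),
       truth = truth)
}

#' Simulate a population with planted homeodomain codes and Ig programs
#'
#' Each cluster receives a distinct random binary code over the homeobox
#' panel ("on" genes Poisson mean `on_mean`, "off" genes mean `lambda_bg`)
#' and a cluster-specific subset of Ig genes whose mean is raised by
#' `link_strength`. Clusters are placed at evenly spaced AP positions so
#' that cluster ordering by position is well defined.
#'
#' @param n_clusters Number of clusters (>= 2).
#' @param cells_per_cluster Cells per cluster.
#' @param n_homeobox,n_ig Panel sizes.
#' @param code_density Probability a homeobox gene is "on" in a cluster.
#' @param link_strength Fold change of the linked Ig subset (>= 1; 1 = no
#'   cluster signal in Ig genes).
#' @param on_mean Poisson mean of an "on" homeobox gene (default 20).
#' @param ig_mean Baseline Poisson mean of an Ig gene (default 5).
#' @param lambda_bg Background rate for "off" homeobox genes (default 0.1).
#' @param seed Integer seed.
#' @return List with `counts` (a `CountMatrix` with `homeobox` and `ig`
#'   gene classes) and `truth` (`cluster_labels`, `positions`, `codes`,
#'   `linked_ig`, `params`).
#' @export
simulate_homeo_population <- function(n_clusters, cells_per_cluster,
                                      n_homeobox, n_ig,
                                      code_density = 0.5,
                                      link_strength = 4,
                                      on_mean = 20, ig_mean = 5,
                                      lambda_bg = 0.1, seed = 1L) {
  stopifnot(n_clusters >= 2L, cells_per_cluster >= 1L, n_homeobox >= 1L,
            code_density > 0, code_density < 1, link_strength >= 1)
  if (n_clusters > 2^n_homeobox)
    stop("more distinct codes requested (", n_clusters,
         ") than exist for ", n_homeobox, " homeobox genes (",
         2^n_homeobox, ")")
  set.seed(seed)
  codes <- matrix(NA_integer_, n_clusters, n_homeobox)
  for (k in seq_len(n_clusters)) {
    for (attempt in seq_len(100L)) {
      cand <- stats::rbinom(n_homeobox, 1L, code_density)
      dup <- k > 1L &&
        any(apply(codes[seq_len(k - 1L), , drop = FALSE], 1L,
                  identical, y = cand))
      if (!dup) { codes[k, ] <- cand; break }
      if (attempt == 100L) stop("could not draw distinct codes")
    }
  }
  n_linked <- if (n_ig > 0) max(1L, round(0.2 * n_ig)) else 0L
  linked <- lapply(seq_len(n_clusters), function(k)
    if (n_linked > 0) sample.int(n_ig, n_linked) else integer(0))
  labels <- rep(seq_len(n_clusters), each = cells_per_cluster)
  n_cells <- length(labels)
  centers <- (seq_len(n_clusters) - 0.5) / n_clusters
  pos <- pmin(pmax(centers[labels] +
                     stats::rnorm(n_cells, sd = 0.5 / n_clusters / 3), 0), 1)
  hb <- matrix(0, n_homeobox, n_cells)
  ig <- matrix(0, max(n_ig, 0L), n_cells)
  for (k in seq_len(n_clusters)) {
    idx <- which(labels == k)
    mu_hb <- ifelse(codes[k, ] == 1L, on_mean, lambda_bg)
    hb[, idx] <- stats::rpois(n_homeobox * length(idx), mu_hb)
    if (n_ig > 0) {
      mu_ig <- rep(ig_mean, n_ig)
      mu_ig[linked[[k]]] <- ig_mean * link_strength
      ig[, idx] <- stats::rpois(n_ig * length(idx), mu_ig)
    }
  }
  hb_ids <- paste0("hbx", seq_len(n_homeobox))
  ig_ids <- if (n_ig > 0) paste0("ig", seq_len(n_ig)) else character(0)
  counts <- rbind(hb, if (n_ig > 0) ig)
  dimnames(counts) <- list(c(hb_ids, ig_ids),
                           paste0("cell", seq_len(n_cells)))
  truth <- list(cluster_labels = stats::setNames(labels, colnames(counts)),
                positions = stats::setNames(pos, colnames(counts)),
                codes = codes,
                linked_ig = lapply(linked, function(i) ig_ids[i]),
                params = list(code_density = code_density,
                              link_strength = link_strength,
                              on_mean = on_mean, ig_mean = ig_mean,
                              lambda_bg = lambda_bg, seed = seed))
  list(counts = count_matrix(counts,
                             gene_classes = list(homeobox = hb_ids,
                                                 ig = ig_ids)),
       truth = truth)
}

#' Write a simulation truth table to TSV
#'
#' @param truth Truth list from a generator.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  cells <- names(truth$positions)
  tab <- data.frame(cell = cells, position = unname(truth$positions))
  if (!is.null(truth$cluster_labels))
    tab$cluster <- unname(truth$cluster_labels[cells])
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
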