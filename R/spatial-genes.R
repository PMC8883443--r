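# Detection of genes whose expression varies along the inferred AP axis:
# per gene, a cubic B-spline regression of scaled expression on position is
# compared to an intercept-only null by BIC; significant profiles are
# smoothed with an absolute exponential kernel and grouped into pattern
# modules by hierarchical clustering.

#' Select spatially variable genes by B-spline/BIC model comparison
#'
#' Per gene, ordinary least squares of expression on a cubic B-spline basis
#' of position with `df` basis columns (plus intercept) is compared to an
#' intercept-only model by the Bayesian information criterion under a
#' Gaussian likelihood. A gene is called spatial when the spline model has
#' the lower BIC. No multiplicity correction is applied: BIC itself is the
#' selection rule.
#'
#' @param scaled_expr Matrix genes x cells of scaled expression.
#' @param positions Per-cell inferred positions in \[0,1\] (NA cells
#'   dropped).
#' @param df Spline degrees of freedom = number of basis columns
#'   (default 3).
#' @return data.frame: `gene`, `bic_spline`, `bic_null`, `delta_bic`
#'   (null minus spline), `is_spatial`.
#' @export
select_spatial_genes <- function(scaled_expr, positions, df = 3L) {
  keep <- !is.na(positions)
  positions <- positions[keep]
  scaled_expr <- scaled_expr[, keep, drop = FALSE]
  n <- length(positions)
  if (n < 10L) stop("fewer than 10 mapped cells")
  if (n <= df + 2L) stop("fewer cells than model parameters")
  stopifnot(all(positions >= 0), all(positions <= 1))
  basis <- splines::bs(positions, df = df)
  res <- lapply(rownames(scaled_expr), function(g) {
    y <- scaled_expr[g, ]
    if (stats::var(y) == 0) {
      # both models fit a constant perfectly; the spline only pays its
      # parameter penalty, so the null is preferred by construction
      return(data.frame(gene = g, bic_spline = NA_real_,
                        bic_null = NA_real_, delta_bic = -df * log(n),
                        is_spatial = FALSE))
    }
    fit1 <- stats::lm(y ~ basis)
    fit0 <- stats::lm(y ~ 1)
    b1 <- stats::BIC(fit1); b0 <- stats::BIC(fit0)
    data.frame(gene = g, bic_spline = b1, bic_null = b0,
               delta_bic = b0 - b1, is_spatial = b1 < b0)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Smooth expression along the axis with an exponential kernel
#'
#' Floating mean by 1-D convolution: at each grid point \eqn{x_0} the
#' smoothed value is the weighted mean of the per-cell values with weights
#' \eqn{\exp(-decay\,|x_c - x_0|)}, renormalized to sum 1. Positions are
#' axis fractions and the decay rate applies per unit axis (default 10,
#' kernel half-width about 0.07 of the axis).
#'
#' @param expr Per-cell expression values.
#' @param positions Per-cell positions in \[0,1\] (NA dropped together with
#'   the value).
#' @param decay Positive decay rate.
#' @param grid Grid points at which to evaluate (default 201 on \[0,1\]).
#' @return A `SmoothedProfile` list with `grid` and `values`.
#' @export
smooth_profile <- function(expr, positions, decay = 10,
                           grid = seq(0, 1, length.out = 201L)) {
  keep <- !is.na(positions) & !is.na(expr)
  expr <- expr[keep]; positions <- positions[keep]
  stopifnot(length(expr) >= 1L, decay > 0)
  w <- exp(-decay * abs(outer(grid, positions, `-`)))
  w <- w / rowSums(w)
  structure(list(grid = grid, values = as.vector(w %*% expr)),
            class = "SmoothedProfile")
}

#' Group smoothed spatial profiles into pattern modules
#'
#' Each profile is standardized (so the grouping reflects pattern shape,
#' not amplitude) and profiles are clustered by Ward-linkage hierarchical
#' clustering on Euclidean distance, cut at `n_groups`.
#'
#' @param profiles Matrix genes x grid of smoothed values, or a list of
#'   `SmoothedProfile` objects sharing one grid.
#' @param n_groups Number of pattern modules (default 10).
#' @return Named integer vector of module labels per gene.
#' @export
cluster_patterns <- function(profiles, n_groups = 10L) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      inherits(profiles[[1L]], "SmoothedProfile")) {
    mat <- t(vapply(profiles, `[[`, numeric(length(profiles[[1L]]$grid)),
                    "values"))
    rownames(mat) <- names(profiles)
  } else mat <- as.matrix(profiles)
  if (n_groups < 2L) stop("n_groups must be at least 2")
  if (nrow(mat) < n_groups) stop("fewer genes than groups")
  std <- t(apply(mat, 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  hc <- stats::hclust(stats::dist(std), method = "ward.D2")
  stats::cutree(hc, k = n_groups)
}
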