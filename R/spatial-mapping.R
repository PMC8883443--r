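# Maximum-likelihood inference of each cell's anterior-posterior position
# under a Poisson observation model: counts of Hox gene g in a cell at
# position x are Poisson with mean r_g * Y_g(x) where the reference curve
# is positive, and with a small background mean lambda where it is zero.
# Profiles are computed in log space; the raw product of Poisson
# probabilities over genes underflows.

#' Mapping parameters
#'
#' @param r Named per-gene rate \eqn{r_g}: expected read count in a cell at
#'   full reference intensity (> 0).
#' @param lambda_bg Background Poisson rate \eqn{\lambda} for reads of a
#'   gene in territory where its reference is zero (default 0.1).
#' @return A `MappingParams` list.
#' @export
mapping_params <- function(r, lambda_bg = 0.1) {
  stopifnot(all(r > 0), lambda_bg >= 0)
  structure(list(r = r, lambda_bg = lambda_bg), class = "MappingParams")
}

#' Estimate per-gene rates from expressing cells
#'
#' \eqn{r_g} = total counts of gene g over all cells divided by the number
#' of cells with at least one read of g (the mean expression in expressing
#' cells).
#'
#' @param m A `CountMatrix` or matrix.
#' @param genes Gene ids to estimate (default: the Hox panel from
#'   `gene_classes$hox`, else all genes).
#' @return Named numeric vector of rates.
#' @export
estimate_rg <- function(m, genes = NULL) {
  m <- as_count_matrix(m)
  if (is.null(genes))
    genes <- if (!is.null(m$gene_classes$hox)) m$gene_classes$hox
             else gene_ids(m)
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing)) stop("genes not in matrix: ",
                            paste(missing, collapse = ", "))
  sub <- m$counts[genes, , drop = FALSE]
  n_expr <- rowSums(sub > 0)
  if (any(n_expr == 0))
    stop("gene(s) with zero expressing cells: ",
         paste(genes[n_expr == 0], collapse = ", "))
  rowSums(sub) / n_expr
}

# mean matrix genes x grid under the observation model
model_means <- function(ref, params, genes) {
  y <- ref$curves[genes, , drop = FALSE]
  r <- params$r[genes]
  ifelse(y > 0, r * y, params$lambda_bg)
}

#' Log-likelihood profile of one cell over the AP grid
#'
#' At each grid point x, the sum over genes of the log Poisson probability
#' of the observed count with mean \eqn{r_g Y_g(x)} (reference positive) or
#' \eqn{\lambda} (reference zero). With \eqn{\lambda = 0}, a positive count
#' at a zero-support position contributes -Inf (never NaN).
#'
#' @param d Named per-gene counts for one cell (names matched to reference
#'   genes).
#' @param ref A `ReferenceMap`.
#' @param params A [mapping_params()] covering the genes of `d`.
#' @return Numeric vector of log-likelihoods, one per grid point.
#' @export
cell_log_likelihood <- function(d, ref, params) {
  stopifnot(inherits(ref, "ReferenceMap"), inherits(params, "MappingParams"))
  genes <- names(d)
  if (is.null(genes)) {
    stopifnot(length(d) == nrow(ref$curves))
    genes <- rownames(ref$curves)
    names(d) <- genes
  }
  missing <- setdiff(genes, rownames(ref$curves))
  if (length(missing)) stop("genes not in reference: ",
                            paste(missing, collapse = ", "))
  mu <- model_means(ref, params, genes)
  ll <- colSums(matrix(
    stats::dpois(rep(d, times = ncol(mu)), as.vector(mu), log = TRUE),
    nrow(mu), ncol(mu)))
  unname(ll)
}

#' Map cells to AP positions by maximum likelihood
#'
#' \eqn{\hat{x}_c = \arg\max_x \prod_g p(D_{g,c} \mid x)}, evaluated on the
#' reference grid in log space. Ties (plateaus of the profile, e.g. inside
#' a boxcar stripe) are broken deterministically at the median grid index
#' of the argmax set. Cells with no reads in any mapped gene cannot be
#' placed and are returned with `mapped = FALSE` when `require_hox` is
#' TRUE.
#'
#' @param m A `CountMatrix` or matrix restricted to (or containing) the
#'   reference genes.
#' @param ref A `ReferenceMap`.
#' @param params A [mapping_params()]; default estimates `r` by
#'   [estimate_rg()] with \eqn{\lambda = 0.1}.
#' @param require_hox Exclude cells with no reads in any mapped gene
#'   (default TRUE).
#' @param keep_profiles Attach the full cells x grid log-likelihood matrix
#'   as attribute `"profiles"` (default FALSE).
#' @return A `PositionEstimate` data.frame: `cell`, `x_hat` (axis
#'   fraction; NA when unmapped), `n_ties`, `mapped`, `max_loglik`.
#' @export
map_position <- function(m, ref, params = NULL, require_hox = TRUE,
                         keep_profiles = FALSE) {
  m <- as_count_matrix(m)
  genes <- intersect(rownames(ref$curves), gene_ids(m))
  if (length(genes) == 0L) stop("no reference genes in the matrix")
  if (is.null(params))
    params <- mapping_params(estimate_rg(m, genes), lambda_bg = 0.1)
  d <- m$counts[genes, , drop = FALSE]
  mu <- model_means(ref, params, genes)
  log_mu <- log(mu)                       # -Inf where mu = 0
  # loglik[c, x] = sum_g d[g,c]*log mu[g,x] - mu[g,x] - lgamma(d[g,c]+1)
  ll <- t(d) %*% ifelse(is.finite(log_mu), log_mu, 0) -
    matrix(colSums(mu), ncol(d), ncol(mu), byrow = TRUE) -
    colSums(lgamma(d + 1))
  # restore -Inf contributions: d > 0 where mu = 0
  if (any(!is.finite(log_mu))) {
    zero_mu <- !is.finite(log_mu)         # genes x grid
    pos_d <- d > 0                        # genes x cells
    bad <- t(pos_d) %*% zero_mu > 0       # cells x grid
    ll[bad] <- -Inf
  }
  n_cells <- ncol(d)
  out <- data.frame(cell = colnames(d), x_hat = NA_real_,
                    n_ties = NA_integer_, mapped = FALSE,
                    max_loglik = NA_real_, row.names = NULL)
  has_reads <- colSums(d) > 0
  for (c in seq_len(n_cells)) {
    if (require_hox && !has_reads[c]) next
    prof <- ll[c, ]
    mx <- max(prof)
    idx <- which(prof >= mx - 1e-9 * max(1, abs(mx)))
    out$x_hat[c] <- ref$grid[idx[(length(idx) + 1L) %/% 2L]]
    out$n_ties[c] <- length(idx)
    out$mapped[c] <- TRUE
    out$max_loglik[c] <- mx
  }
  class(out) <- c("PositionEstimate", "data.frame")
  if (keep_profiles) attr(out, "profiles") <- ll
  out
}

#' Robustness of the position estimate to parameter choice
#'
#' Latin hypercube sample over the background rate \eqn{\lambda} and a
#' global multiplier on the per-gene rates; positions are re-estimated for
#' every draw and all pairwise Spearman correlations between the resulting
#' position vectors are returned. Both parameters are positive scale
#' parameters and are sampled log-uniformly within their ranges.
#'
#' @param m A `CountMatrix` or matrix.
#' @param ref A `ReferenceMap`.
#' @param n_draws Number of parameter sets (>= 2).
#' @param lambda_range Length-2 positive interval for \eqn{\lambda}.
#' @param r_scale_range Length-2 positive interval for the r multiplier.
#' @param seed Integer seed for the hypercube.
#' @param base_r Per-gene rates to be scaled (default [estimate_rg()]).
#' @return List with `spearman` (n_draws x n_draws correlation matrix),
#'   `design` (data.frame of sampled `lambda`, `r_scale`) and `positions`
#'   (cells x draws matrix of x_hat).
#' @export
robustness_lhs <- function(m, ref, n_draws = 20L,
                           lambda_range = c(0.01, 1),
                           r_scale_range = c(0.2, 5),
                           seed = 1L, base_r = NULL) {
  stopifnot(n_draws >= 2L, all(lambda_range > 0), all(r_scale_range > 0))
  m <- as_count_matrix(m)
  genes <- intersect(rownames(ref$curves), gene_ids(m))
  if (is.null(base_r)) base_r <- estimate_rg(m, genes)
  set.seed(seed)
  u <- lhs::randomLHS(n_draws, 2L)
  expand <- function(u, rng) {
    if (rng[1] == rng[2]) rep(rng[1], length(u))
    else exp(log(rng[1]) + u * (log(rng[2]) - log(rng[1])))
  }
  design <- data.frame(lambda = expand(u[, 1L], lambda_range),
                       r_scale = expand(u[, 2L], r_scale_range))
  pos <- vapply(seq_len(n_draws), function(i) {
    est <- map_position(m, ref,
                        mapping_params(base_r * design$r_scale[i],
                                       lambda_bg = design$lambda[i]))
    est$x_hat
  }, numeric(ncol(m$counts)))
  keep <- stats::complete.cases(pos)
  sp <- stats::cor(pos[keep, , drop = FALSE], method = "spearman")
  list(spearman = sp, design = design, positions = pos)
}
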