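# Highly-variable-gene detection from the CV^2-versus-mean technical-noise
# trend: median-of-ratios size factors, an identity-link Gamma regression of
# CV^2 on 1/mean, a chi-square test of excess variance per gene, and
# hypergeometric enrichment of gene classes among the variable genes.

#' Median-of-ratios size factors
#'
#' Reference = per-gene geometric mean over genes with all-positive counts;
#' each cell's factor is the median ratio of its counts to the reference,
#' rescaled to geometric mean 1. When no gene is positive in every cell,
#' falls back to total counts divided by the mean total.
#'
#' @param m A `CountMatrix` or matrix.
#' @return Named positive numeric vector, one factor per cell.
#' @export
size_factors <- function(m) {
  m <- as_count_matrix(m)
  counts <- m$counts
  if (all(counts == 0)) stop("all-zero count matrix")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    sub <- counts[allpos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    sf <- apply(sub, 2L, function(col) stats::median(col / ref))
  } else {
    tot <- colSums(counts)
    if (any(tot == 0)) stop("cell with zero total counts and no reference gene")
    sf <- tot / mean(tot)
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Fit the technical CV^2-versus-mean trend
#'
#' Fits \eqn{CV^2 = a_1/\mu + a_0} across genes above a mean-expression
#' quantile, by an identity-link Gamma GLM of CV^2 on 1/mean (with an
#' ordinary least-squares fallback when the GLM does not converge). Means
#' and CV^2 are computed on size-factor-normalized counts.
#'
#' @param m A `CountMatrix` or matrix.
#' @param sf Per-cell size factors (default [size_factors()]).
#' @param min_mean_quantile Mean-expression quantile below which genes are
#'   excluded from the fit (default 0.4; low-mean genes have unstable CV^2).
#' @return A `NoiseFit`: list with `a0`, `a1`, `size_factors`,
#'   `fit_support` (gene ids used), `mean`, `cv2` (all genes), `method`.
#' @export
fit_technical_noise <- function(m, sf = size_factors(m),
                                min_mean_quantile = 0.4) {
  m <- as_count_matrix(m)
  norm <- sweep(m$counts, 2L, sf, `/`)
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
  thr <- stats::quantile(mu[mu > 0], min_mean_quantile)
  use <- which(mu >= thr & is.finite(cv2) & cv2 > 0)
  if (length(use) < 10L)
    stop("fewer than 10 genes above the mean-expression threshold")
  fit_df <- data.frame(cv2 = cv2[use], inv_mu = 1 / mu[use])
  coefs <- tryCatch({
    g <- suppressWarnings(stats::glm(cv2 ~ inv_mu, data = fit_df,
                                     family = stats::Gamma(link = "identity"),
                                     start = c(0.1, 1)))
    if (!g$converged) stop("glm did not converge")
    list(co = stats::coef(g), method = "gamma-glm")
  }, error = function(e) {
    list(co = stats::coef(stats::lm(cv2 ~ inv_mu, data = fit_df)),
         method = "ols")
  })
  a0 <- unname(coefs$co[1]); a1 <- unname(coefs$co[2])
  if (!is.finite(a0) || !is.finite(a1)) stop("degenerate noise fit")
  structure(list(a0 = a0, a1 = a1, size_factors = sf,
                 fit_support = rownames(m$counts)[use],
                 mean = mu, cv2 = cv2, method = coefs$method),
            class = "NoiseFit")
}

#' @export
#' @method print NoiseFit
print.NoiseFit <- function(x, ...) {
  cat(sprintf("NoiseFit (%s): CV^2 = %.3g/mu + %.3g  (%d genes in fit)\n",
              x$method, x$a1, x$a0, length(x$fit_support)))
  invisible(x)
}

#' Test genes for variance in excess of the technical trend
#'
#' Per gene, the observed variance of normalized counts is compared to the
#' fitted technical expectation \eqn{a_1\mu + a_0\mu^2} by the chi-square
#' statistic \eqn{(n-1)\, v_{obs}/v_{tech}} on n-1 degrees of freedom
#' (upper tail), with Benjamini-Hochberg adjustment across genes.
#'
#' @param m A `CountMatrix` or matrix.
#' @param fit A `NoiseFit`.
#' @param fdr False-discovery-rate level for the `is_variable` call
#'   (default 0.1).
#' @return An `HVGResult` data.frame: `gene`, `mean`, `cv2`, `p`, `p_adj`,
#'   `is_variable`, ordered as the input genes.
#' @export
test_variable_genes <- function(m, fit, fdr = 0.1) {
  stopifnot(inherits(fit, "NoiseFit"))
  m <- as_count_matrix(m)
  norm <- sweep(m$counts, 2L, fit$size_factors, `/`)
  n <- ncol(norm)
  mu <- rowMeans(norm)
  v_obs <- apply(norm, 1L, stats::var)
  v_tech <- fit$a1 * mu + fit$a0 * mu^2
  chi <- ifelse(v_tech > 0, (n - 1) * v_obs / v_tech, 0)
  p <- stats::pchisq(chi, df = n - 1, lower.tail = FALSE)
  p[v_obs == 0] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(norm), mean = mu,
                    cv2 = ifelse(mu > 0, v_obs / mu^2, NA_real_),
                    p = p, p_adj = p_adj,
                    is_variable = p_adj < fdr, row.names = NULL)
  class(out) <- c("HVGResult", "data.frame")
  out
}

#' Hypergeometric enrichment of gene classes among variable genes
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between the variable set and each class, within the universe.
#'
#' @param variable Character vector of variable gene ids (subset of
#'   `universe`).
#' @param class_sets Named list of character vectors (classes; intersected
#'   with the universe).
#' @param universe Character vector of all tested gene ids.
#' @return data.frame: `class`, `n_class`, `n_variable`, `overlap`, `p`.
#' @export
class_enrichment_hypergeometric <- function(variable, class_sets, universe) {
  if (length(universe) == 0L) stop("empty universe")
  variable <- intersect(variable, universe)
  rows <- lapply(names(class_sets), function(cl) {
    cls <- intersect(class_sets[[cl]], universe)
    ov <- length(intersect(variable, cls))
    p <- stats::phyper(ov - 1, length(cls),
                       length(universe) - length(cls),
                       length(variable), lower.tail = FALSE)
    data.frame(class = cl, n_class = length(cls),
               n_variable = length(variable), overlap = ov, p = p)
  })
  do.call(rbind, rows)
}

#' Scale expression to units of fitted total variance
#'
#' Size-factor-normalize, log1p-transform, center each gene, and divide by
#' the square root of the fitted total variance at that gene's mean: the
#' technical part \eqn{a_1\mu + a_0\mu^2} from the noise fit plus the
#' nonnegative biological excess of the observed variance over it. The fit
#' lives on the normalized-count scale while the values are logged, so the
#' variance is transferred to the log scale by the delta method
#' (\eqn{\mathrm{Var}\,\log(1+X) \approx \mathrm{Var}(X)/(1+\mu)^2}).
#' Constant genes scale to all zeros.
#'
#' @param m A `CountMatrix` or matrix.
#' @param fit A `NoiseFit`.
#' @return Numeric matrix of scaled expression, genes x cells.
#' @export
scale_expression <- function(m, fit) {
  stopifnot(inherits(fit, "NoiseFit"))
  m <- as_count_matrix(m)
  norm <- sweep(m$counts, 2L, fit$size_factors, `/`)
  mu <- rowMeans(norm)
  v_obs <- apply(norm, 1L, stats::var)
  v_tech <- pmax(fit$a1 * mu + fit$a0 * mu^2, 0)
  v_tot <- v_tech + pmax(v_obs - v_tech, 0)
  denom <- sqrt(v_tot) / (1 + mu)
  denom[denom == 0 | !is.finite(denom)] <- 1
  lg <- log1p(norm)
  scaled <- (lg - rowMeans(lg)) / denom
  scaled[v_obs == 0, ] <- 0
  scaled
}
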