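# Near-binarizing gene-wise log-k normalization used for homeodomain-code
# clustering. Library-size normalization over-weights absolute expression;
# strict binarization discards quantitative differences among expressing
# cells. The transform below interpolates: for large k, values are
# essentially presence/absence for lowly expressed genes while quantitative
# differences survive for highly expressed ones.

#' Near-binary transform of one gene's expression vector
#'
#' With \eqn{s_i = x_i / \sum_j x_j} the cell's share of the gene's total,
#' \deqn{N_i = \log_k(1 + k s_i) = \ln(1 + k s_i)/\ln k.}
#' \eqn{N_i = 0} exactly when \eqn{x_i = 0}; for any fixed share
#' \eqn{s > 0}, \eqn{N_i \to 1} as \eqn{k \to \infty}. Default
#' \eqn{k = 10^6}.
#'
#' @param x Nonnegative per-cell values of one gene (size-factor-normalized
#'   counts). All-zero vectors pass through as zeros.
#' @param k Gain parameter, > 1.
#' @param variant `"scaled"` (default) uses \eqn{\log_k(1 + k s_i)};
#'   `"plain"` uses the alternative reading \eqn{\log_k(s_i + 1)}, which
#'   collapses toward 0 for large k and is kept only for comparison.
#' @return Numeric vector of the same length, in
#'   \eqn{[0, \log_k(1 + k)]}.
#' @export
near_binary_transform <- function(x, k = 1e6,
                                  variant = c("scaled", "plain")) {
  variant <- match.arg(variant)
  if (k <= 1) stop("k must exceed 1")
  if (any(x < 0)) stop("negative expression values")
  tot <- sum(x)
  if (tot == 0) return(rep(0, length(x)))
  s <- x / tot
  if (variant == "scaled") log1p(k * s) / log(k) else log1p(s) / log(k)
}

#' Apply the near-binary transform gene-wise to a matrix
#'
#' @param m A `CountMatrix` or matrix (genes x cells); typically
#'   size-factor-normalized first.
#' @param sf Optional per-cell size factors to divide out before the
#'   transform.
#' @param k,variant Passed to [near_binary_transform()].
#' @return Numeric matrix of transformed values, genes x cells.
#' @export
near_binary_matrix <- function(m, sf = NULL, k = 1e6,
                               variant = c("scaled", "plain")) {
  variant <- match.arg(variant)
  m <- as_count_matrix(m)
  x <- m$counts
  if (!is.null(sf)) x <- sweep(x, 2L, sf, `/`)
  out <- t(apply(x, 1L, near_binary_transform, k = k, variant = variant))
  dimnames(out) <- dimnames(x)
  out
}
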