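#' Construct a ReferenceMap
#'
#' Container for per-gene expected-intensity curves \eqn{Y_g(x) \in [0,1]}
#' along a normalized anterior-posterior (AP) axis. The axis is stored as a
#' fraction in \[0,1\]; [axis_units()] converts to the 0-2000 unit and 0-100
#' percent scales used for reporting.
#'
#' @param grid Numeric vector of axis positions in \[0,1\], increasing.
#' @param curves Numeric matrix, one row per gene (rownames = gene ids),
#'   one column per grid point, values in \[0,1\].
#' @return An object of class `ReferenceMap` with elements `grid`, `curves`
#'   and `support` (logical matrix, `curves > 0`).
#' @export
reference_map <- function(grid, curves) {
  grid <- as.numeric(grid)
  curves <- as.matrix(curves)
  stopifnot(length(grid) >= 2L, ncol(curves) == length(grid),
            !is.unsorted(grid), all(grid >= 0), all(grid <= 1))
  if (is.null(rownames(curves))) stop("curves must have gene rownames")
  if (any(curves < 0) || any(curves > 1)) stop("curve values outside [0,1]")
  structure(list(grid = grid, curves = curves, support = curves > 0),
            class = "ReferenceMap")
}

#' @export
#' @method print ReferenceMap
print.ReferenceMap <- function(x, ...) {
  cat(sprintf("ReferenceMap: %d genes on a %d-point AP grid\n",
              nrow(x$curves), length(x$grid)))
  invisible(x)
}

#' Convert axis fractions to reporting scales
#'
#' @param x Axis positions as fractions in \[0,1\].
#' @param scale `"fraction"`, `"units"` (0-2000) or `"percent"` (0-100).
#' @return Rescaled positions.
#' @export
axis_units <- function(x, scale = c("fraction", "units", "percent")) {
  scale <- match.arg(scale)
  switch(scale, fraction = x, units = 2000 * x, percent = 100 * x)
}

#' Evaluate reference curves at arbitrary positions
#'
#' Linear interpolation between grid points; positions are clamped to the
#' grid range.
#'
#' @param ref A `ReferenceMap`.
#' @param x Axis positions in \[0,1\].
#' @return Matrix genes x length(x) of interpolated intensities.
#' @export
reference_at <- function(ref, x) {
  stopifnot(inherits(ref, "ReferenceMap"))
  x <- pmin(pmax(x, min(ref$grid)), max(ref$grid))
  out <- t(vapply(seq_len(nrow(ref$curves)), function(g)
    stats::approx(ref$grid, ref$curves[g, ], xout = x)$y,
    numeric(length(x))))
  dimnames(out) <- list(rownames(ref$curves), NULL)
  out
}

#' Build an AP reference map from immunofluorescence traces
#'
#' Per gene: raw positions are rescaled to \[0,1\]; intensities below the
#' `background_quantile` of that gene's trace are set to 0 (unspecific
#' staining background); the surviving intensities are min-max normalized to
#' \[0,1\]; the curve is resampled onto a common grid by linear
#' interpolation, optionally smoothed with an absolute exponential kernel;
#' replicate traces of a gene are averaged after normalization.
#'
#' @param traces data.frame with columns `gene`, `position`, `intensity` and
#'   optionally `replicate`.
#' @param grid_size Number of grid points on \[0,1\] (default 201,
#'   i.e. 10-unit steps on the 0-2000 scale).
#' @param background_quantile Per-gene intensity quantile treated as
#'   background (default 0.1).
#' @param smooth_decay Optional positive decay rate of an exponential
#'   smoothing kernel applied to the gridded curve (`NULL` = no smoothing).
#' @param allow_flat If TRUE, a trace with no dynamic range above background
#'   yields a constant curve Y = 1 instead of an error.
#' @return A [reference_map()].
#' @export
build_reference <- function(traces, grid_size = 201L,
                            background_quantile = 0.1,
                            smooth_decay = NULL, allow_flat = FALSE) {
  stopifnot(all(c("gene", "position", "intensity") %in% names(traces)),
            grid_size >= 2L)
  grid <- seq(0, 1, length.out = grid_size)
  if (is.null(traces$replicate)) traces$replicate <- 1L
  genes <- unique(as.character(traces$gene))
  curves <- matrix(0, length(genes), grid_size,
                   dimnames = list(genes, NULL))
  for (g in genes) {
    tr_g <- traces[traces$gene == g, ]
    reps <- unique(tr_g$replicate)
    rep_curves <- vapply(reps, function(r) {
      tr <- tr_g[tr_g$replicate == r, ]
      if (nrow(tr) < 2L) stop("gene ", g, ": fewer than 2 trace points")
      if (is.unsorted(tr$position, strictly = TRUE))
        stop("gene ", g, ": positions must be strictly increasing")
      pos <- (tr$position - min(tr$position)) /
        (max(tr$position) - min(tr$position))
      int <- tr$intensity
      thr <- stats::quantile(int, background_quantile)
      int[int < thr] <- 0
      if (all(int == 0))
        stop("gene ", g, ": entire trace below background")
      rng <- range(int)
      if (rng[1] == rng[2]) {
        if (!allow_flat)
          stop("gene ", g, ": no dynamic range for min-max normalization")
        int[] <- 1
      } else {
        int <- (int - rng[1]) / (rng[2] - rng[1])
      }
      y <- stats::approx(pos, int, xout = grid, rule = 2)$y
      pmin(pmax(y, 0), 1)
    }, numeric(grid_size))
    curves[g, ] <- rowMeans(rep_curves)
  }
  if (!is.null(smooth_decay)) {
    stopifnot(smooth_decay > 0)
    for (g in genes) {
      sm <- smooth_profile(curves[g, ], grid, decay = smooth_decay,
                           grid = grid)
      curves[g, ] <- pmin(pmax(sm$values, 0), 1)
    }
  }
  reference_map(grid, curves)
}

#' Resample a reference map onto a new grid
#'
#' @param ref A `ReferenceMap`.
#' @param new_grid_size Number of grid points (>= 2).
#' @return A `ReferenceMap` on the new grid (linear interpolation, clamped
#'   to \[0,1\]).
#' @export
resample_reference <- function(ref, new_grid_size) {
  stopifnot(inherits(ref, "ReferenceMap"), new_grid_size >= 2L)
  new_grid <- seq(0, 1, length.out = new_grid_size)
  curves <- t(vapply(seq_len(nrow(ref$curves)), function(g)
    pmin(pmax(stats::approx(ref$grid, ref$curves[g, ], xout = new_grid,
                            rule = 2)$y, 0), 1),
    numeric(new_grid_size)))
  rownames(curves) <- rownames(ref$curves)
  reference_map(new_grid, curves)
}
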