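# Principal coordinates analysis with signed-axis bookkeeping, and
# per-group centroid dispersion for scheme comparison.

#' Principal coordinates analysis (metric MDS)
#'
#' Gower-centres the squared dissimilarities, `G = -1/2 * J D^2 J` with
#' `J = I - 11'/n`, and eigendecomposes `G`. Coordinates are
#' eigenvectors scaled by `sqrt(|eigenvalue|)`; axes keep the sign of
#' their eigenvalue as metadata and no Lingoes/Cailliez correction is
#' applied, so the trace identity `sum(eigenvalues) = SS` from
#' [pseudo_variance()] holds exactly even when Bray-Curtis input yields
#' negative eigenvalues. Axis signs are fixed by making the
#' largest-magnitude loading positive, for reproducible output.
#'
#' @param d a `dist` or symmetric zero-diagonal dissimilarity matrix.
#' @param axis_tol axes with `|eigenvalue| <= axis_tol * max(|eigenvalue|)`
#'   carry no structure and are dropped from the coordinates (the full
#'   eigenvalue vector is always returned).
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (units x axes), `eigenvalues` (all n, descending), `axis_sign`
#'   (+1/-1 per retained axis), `proportion_explained` (per positive
#'   retained axis, relative to the sum of positive eigenvalues) and
#'   `trace` (sum of all eigenvalues).
#' @export
pcoa <- function(d, axis_tol = 1e-9) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (n < 2L) stop_coralmse("PCoA needs at least 2 units", "coralmse_input_error")
  m <- as.matrix(d)
  a <- -0.5 * m^2
  rm_ <- rowMeans(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  vals <- e$values
  scale_ref <- max(abs(vals), 0)
  keep <- if (scale_ref > 0) which(abs(vals) > axis_tol * scale_ref) else integer(0)
  coords <- e$vectors[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    v <- coords[, j]
    if (v[[which.max(abs(v))]] < 0) v <- -v
    coords[, j] <- v * sqrt(abs(vals[[keep[[j]]]]))
  }
  rownames(coords) <- labels(d) %||% rownames(m)
  colnames(coords) <- sprintf("Axis%d", seq_along(keep))
  pos <- vals[keep] > 0
  prop <- rep(NA_real_, length(keep))
  if (any(vals > 0)) prop[pos] <- vals[keep][pos] / sum(vals[vals > 0])
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 axis_sign = ifelse(vals[keep] > 0, 1, -1),
                 proportion_explained = prop,
                 trace = sum(vals)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  npos <- sum(x$eigenvalues > 0)
  cat(sprintf("PCoA: %d units, %d retained axes (%d positive eigenvalues), trace = %.4g\n",
              nrow(x$coordinates), ncol(x$coordinates), npos, x$trace))
  invisible(x)
}

#' Per-group centroid and dispersion in PCoA space
#'
#' For each group, the centroid (mean coordinate) and the standard
#' deviation of the coordinates along each retained positive axis, plus
#' a pooled dispersion (root mean per-axis variance). The overlap
#' diagnostic reports, for every pair of groups, whether the
#' centroid +/- 1 sd intervals intersect on both of the first two
#' positive axes — the criterion used to judge whether a denser
#' sampling scheme separates site centroids better.
#'
#' @param result a `pcoa_result`.
#' @param groups vector of group ids, one per unit (row of the
#'   coordinates).
#' @return list with `centroids` (groups x axes), `sd` (groups x axes),
#'   `pooled_sd` (per group) and `overlap` (data frame: group_a,
#'   group_b, overlap).
#' @export
centroid_dispersion <- function(result, groups) {
  stopifnot(inherits(result, "pcoa_result"))
  coords <- result$coordinates[, result$axis_sign > 0, drop = FALSE]
  groups <- as.character(groups)
  if (length(groups) != nrow(coords)) {
    stop_coralmse("groups must have one entry per unit", "coralmse_usage_error")
  }
  ids <- sort(unique(groups))
  n <- vapply(ids, function(g) sum(groups == g), integer(1))
  if (any(n < 2L)) {
    stop_coralmse(sprintf("group '%s' has fewer than 2 units", ids[n < 2L][[1L]]),
                  "coralmse_insufficient_units")
  }
  centroids <- t(vapply(ids, function(g)
    colMeans(coords[groups == g, , drop = FALSE]), numeric(ncol(coords))))
  sds <- t(vapply(ids, function(g)
    apply(coords[groups == g, , drop = FALSE], 2, stats::sd),
    numeric(ncol(coords))))
  dimnames(centroids) <- dimnames(sds) <- list(ids, colnames(coords))
  pooled <- sqrt(rowMeans(sds^2))
  k <- min(2L, ncol(coords))
  pairs <- if (length(ids) > 1L) utils::combn(ids, 2L) else matrix(character(0), 2, 0)
  overlap <- data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    overlap = vapply(seq_len(ncol(pairs)), function(p) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      all(vapply(seq_len(k), function(j) {
        lo_a <- centroids[a, j] - sds[a, j]; hi_a <- centroids[a, j] + sds[a, j]
        lo_b <- centroids[b, j] - sds[b, j]; hi_b <- centroids[b, j] + sds[b, j]
        lo_a <= hi_b && lo_b <= hi_a
      }, logical(1)))
    }, logical(1)),
    stringsAsFactors = FALSE)
  list(centroids = centroids, sd = sds, pooled_sd = pooled, overlap = overlap)
}
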