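# Pseudo multivariate dissimilarity-based standard error (MultSE).
#
# For n sampling units and a dissimilarity matrix d, the multivariate
# pseudo-variance is V = SS / (n - 1) with SS = (1/n) * sum_{i<j} d_ij^2,
# and MultSE = sqrt(V / n). With a Euclidean distance on a single
# variable, V is the classical sample variance and MultSE the classical
# standard error of the mean; with Bray-Curtis it measures the precision
# of the multivariate centroid of a community sample.

#' Quantitative Bray-Curtis dissimilarity
#'
#' `d(x, y) = 1 - 2 * sum_s min(x_s, y_s) / (sum_s x_s + sum_s y_s)` on
#' untransformed abundances ("quantitative" Bray-Curtis). Pairs where
#' both units are all-zero are undefined under the formula; they are set
#' to `zero_zero` (default 0), while an all-zero unit against a nonzero
#' one gets `zero_nonzero` (default 1). Both conventions are explicit
#' because empty sampling units are retained upstream.
#'
#' @param x units x species abundance matrix (e.g. percent cover),
#'   non-negative.
#' @param transform `"none"` (default; raw abundances) or `"sqrt"`.
#' @param zero_zero dissimilarity assigned to a pair of all-zero units.
#' @param zero_nonzero dissimilarity of an all-zero vs a nonzero unit.
#' @return a `stats::dist` object with unit labels.
#' @examples
#' bray_curtis(rbind(a = c(3, 1), b = c(1, 3)))  # d = 0.5
#' @export
bray_curtis <- function(x, transform = c("none", "sqrt"),
                        zero_zero = 0, zero_nonzero = 1) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  if (any(x < 0)) {
    stop_coralmse("abundances must be non-negative", "coralmse_domain_error")
  }
  if (transform == "sqrt") x <- sqrt(x)
  rs <- rowSums(x)
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (any(rs == 0)) {
    m <- as.matrix(d)
    zi <- which(rs == 0)
    m[zi, ] <- zero_nonzero
    m[, zi] <- zero_nonzero
    m[zi, zi] <- zero_zero
    diag(m) <- 0
    d <- stats::as.dist(m)
  }
  d
}

#' Multivariate pseudo-variance
#'
#' Returns `SS = (1/n) * sum_{i<j} d_ij^2` and `V = SS / (n - 1)` for a
#' dissimilarity matrix. `SS` equals the sum of squared distances of the
#' units to their centroid in the full signed principal-coordinate
#' embedding (see [pcoa()]), and `V` reduces to the classical sample
#' variance for a univariate Euclidean distance.
#'
#' @param d a `dist` object or symmetric dissimilarity matrix, n >= 2.
#' @return a list with components `ss` and `v`.
#' @export
pseudo_variance <- function(d) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  if (n < 2L) {
    stop_coralmse("pseudo-variance needs at least 2 units", "coralmse_insufficient_units")
  }
  ss <- sum(d^2) / n
  list(ss = ss, v = ss / (n - 1))
}

#' Pseudo multivariate dissimilarity-based standard error
#'
#' `MultSE = sqrt(V / n)` with `V` from [pseudo_variance()]. Measures
#' the precision of the multivariate sample centroid under the chosen
#' dissimilarity.
#'
#' @inheritParams pseudo_variance
#' @return a single non-negative number.
#' @examples
#' x <- rbind(a = c(3, 1), b = c(1, 3))
#' multse(bray_curtis(x))  # 0.25 = d/2 for two units
#' @export
multse <- function(d) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  sqrt(pseudo_variance(d)$v / n)
}

as_dist_checked <- function(d) {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12) ||
      any(abs(diag(m)) > 1e-12)) {
    stop_coralmse("d must be a symmetric matrix with zero diagonal",
                  "coralmse_input_error")
  }
  stats::as.dist(m)
}

#' Per-group MultSE with bias-corrected bootstrap percentile intervals
#'
#' For each group (typically a site), resamples its units with
#' replacement `n_boot` times, recomputes MultSE per resample, recentres
#' the bootstrap distribution on the observed value (shift by observed
#' minus bootstrap mean) and reports the requested percentiles of the
#' recentred distribution plus its 5%-95% interquantile range, the
#' statistic used to rank sites by estimation uncertainty. Resamples
#' that collapse onto few distinct units are kept (their MultSE is
#' computable, possibly 0). Deterministic given `seed`: each group gets
#' a child seed derived from the root seed and the group's position in
#' sorted group order.
#'
#' @param x units x species cover matrix (rows are sampling units).
#' @param groups vector of group ids, one per row of `x`.
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param percentiles pair of percentile levels in (0, 100), default
#'   `c(2.5, 97.5)`.
#' @param seed integer root seed (required for reproducibility).
#' @param transform passed to [bray_curtis()].
#' @return a `data.frame` (class `multse_estimates`) with one row per
#'   group: `group`, `n_units`, `multse`, `ss`, `v`, `q_low`, `q_high`,
#'   `iqr_5_95`, `n_boot`, `seed` (the group's child seed).
#' @export
bootstrap_multse <- function(x, groups, n_boot = 10000,
                             percentiles = c(2.5, 97.5), seed = 1,
                             transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) {
    stop_coralmse("groups must have one entry per row of x", "coralmse_usage_error")
  }
  if (length(percentiles) != 2L || any(percentiles <= 0) ||
      any(percentiles >= 100) || percentiles[1L] >= percentiles[2L]) {
    stop_coralmse("percentiles must be an increasing pair in (0, 100)",
                  "coralmse_usage_error")
  }
  if (n_boot < 1L) stop_coralmse("n_boot must be >= 1", "coralmse_usage_error")
  ids <- sort(unique(groups))
  rows <- vector("list", length(ids))
  for (gi in seq_along(ids)) {
    g <- ids[[gi]]
    idx <- which(groups == g)
    n <- length(idx)
    if (n < 2L) {
      stop_coralmse(sprintf("group '%s' has fewer than 2 units", g),
                    "coralmse_insufficient_units")
    }
    d <- bray_curtis(x[idx, , drop = FALSE], transform = transform)
    pv <- pseudo_variance(d)
    obs <- sqrt(pv$v / n)
    child <- derive_seed(seed, "bootstrap", gi)
    restore <- local_seed(child)
    d2 <- as.matrix(d)^2
    boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      id <- sample.int(n, n, replace = TRUE)
      ss_b <- sum(d2[id, id]) / (2 * n)
      boot[[b]] <- sqrt(ss_b / (n - 1) / n)
    }
    restore()
    centred <- boot - mean(boot) + obs
    q <- stats::quantile(centred, percentiles / 100, names = FALSE)
    iqr <- diff(stats::quantile(centred, c(0.05, 0.95), names = FALSE))
    rows[[gi]] <- data.frame(
      group = g, n_units = n, multse = obs, ss = pv$ss, v = pv$v,
      q_low = q[[1L]], q_high = q[[2L]], iqr_5_95 = iqr,
      n_boot = n_boot, seed = child, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("multse_estimates", class(out))
  out
}

#' Rank groups by bootstrap interquantile range
#'
#' Returns the `k` groups whose MultSE has the largest 5%-95%
#' interquantile range — the most uncertain estimates, hence the sites
#' worth re-annotating at higher point density. Ties are broken
#' lexicographically by group id.
#'
#' @param estimates a `multse_estimates` data frame from
#'   [bootstrap_multse()].
#' @param k number of groups to return.
#' @return character vector of `k` group ids, descending by IQR.
#' @export
rank_groups_by_iqr <- function(estimates, k) {
  if (k > nrow(estimates)) {
    stop_coralmse(sprintf("k = %d exceeds the %d available groups",
                          k, nrow(estimates)),
                  "coralmse_usage_error")
  }
  ord <- order(-estimates$iqr_5_95, estimates$group)
  estimates$group[ord][seq_len(k)]
}
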