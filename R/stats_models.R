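# Box-Cox transformed regression of MultSE on design parameters, plus
# the univariate correlates (SEM of total cover, species richness).

#' Box-Cox power transform
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` for
#' `lambda = 0`; monotone increasing in `y > 0` for every lambda.
#'
#' @param y positive numeric vector.
#' @param lambda power parameter.
#' @return transformed vector.
#' @export
bc_transform <- function(y, lambda) {
  if (any(y <= 0)) {
    stop_coralmse("Box-Cox requires strictly positive values", "coralmse_domain_error")
  }
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' Profile-likelihood Box-Cox fit
#'
#' Estimates the power parameter lambda by maximising the profile
#' log-likelihood of the normal model on the transformed scale,
#' `ll(lambda) = -n/2 * log(RSS(lambda)/n) + (lambda - 1) * sum(log y)`,
#' over a grid (default -2 to 2, step 0.01) followed by one quadratic
#' refinement through the best grid point and its neighbours.
#'
#' @param y strictly positive numeric vector.
#' @param lambda_grid grid of candidate lambdas.
#' @return object of class `boxcox_fit`: list with `lambda` (the
#'   estimate), `profile` (data frame lambda, loglik) and `transformed`
#'   (`bc_transform(y, lambda)`).
#' @examples
#' fit <- boxcox(exp(rnorm(500)))  # log-normal: lambda near 0
#' fit$lambda
#' @export
boxcox <- function(y, lambda_grid = seq(-2, 2, by = 0.01)) {
  if (any(y <= 0)) {
    stop_coralmse("Box-Cox requires strictly positive values", "coralmse_domain_error")
  }
  n <- length(y)
  slog <- sum(log(y))
  ll <- vapply(lambda_grid, function(l) {
    z <- bc_transform(y, l)
    rss <- sum((z - mean(z))^2)
    -n / 2 * log(rss / n) + (l - 1) * slog
  }, numeric(1))
  best <- which.max(ll)
  lambda <- lambda_grid[[best]]
  if (best > 1L && best < length(lambda_grid)) {
    # quadratic through (l-1, l, l+1): vertex of the fitted parabola
    x <- lambda_grid[(best - 1L):(best + 1L)]
    f <- ll[(best - 1L):(best + 1L)]
    denom <- (f[[1L]] - 2 * f[[2L]] + f[[3L]])
    if (denom < 0) {
      lambda <- x[[2L]] - (x[[2L]] - x[[1L]]) * (f[[3L]] - f[[1L]]) / (2 * denom)
    }
  }
  structure(list(lambda = lambda,
                 profile = data.frame(lambda = lambda_grid, loglik = ll),
                 transformed = bc_transform(y, lambda)),
            class = "boxcox_fit")
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf("Box-Cox fit: lambda = %.4f (profile over [%g, %g], n = %d)\n",
              x$lambda, min(x$profile$lambda), max(x$profile$lambda),
              length(x$transformed)))
  invisible(x)
}

#' Regress Box-Cox-transformed MultSE on the design parameters
#'
#' Ordinary least squares of the transformed MultSE on the numeric
#' predictors `nbt` (transects), `nbq` (quadrats) and `nbp` (points per
#' quadrat), main effects only, pooling sites and replicates. A negative
#' transect coefficient with the largest |t| is the signature that
#' adding transects is the most effective way to reduce the multivariate
#' error. Lambda is profiled once on the pooled response unless given.
#'
#' @param grid a `design_grid_result` from [evaluate_grid()] or a data
#'   frame with columns `nbt`, `nbq`, `nbp`, `multse`.
#' @param lambda fixed Box-Cox lambda; `NULL` (default) profiles it via
#'   [boxcox()].
#' @param by_site add site fixed effects (requires a `site` column).
#' @param drop_zero drop rows with `multse <= 0` instead of erroring.
#' @param offset constant added to `multse` before transforming
#'   (default 0; an alternative to `drop_zero` for zero rows).
#' @return object of class `design_model`: list with `lambda`,
#'   `coefficients` (term, estimate, se, t, p), `r_squared`,
#'   `df_residual` and the underlying `lm` fit.
#' @export
fit_design_model <- function(grid, lambda = NULL, by_site = FALSE,
                             drop_zero = FALSE, offset = 0) {
  df <- if (inherits(grid, "design_grid_result")) grid$results else as.data.frame(grid)
  needed <- c("nbt", "nbq", "nbp", "multse")
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop_coralmse(sprintf("grid lacks column '%s'", absent[[1L]]),
                  "coralmse_usage_error")
  }
  y <- df$multse + offset
  if (any(y <= 0)) {
    if (drop_zero) {
      keep <- y > 0
      df <- df[keep, , drop = FALSE]
      y <- y[keep]
    } else {
      stop_coralmse(paste0("MultSE values <= 0 cannot be Box-Cox transformed; ",
                           "set drop_zero = TRUE to exclude them or supply a ",
                           "positive offset"),
                    "coralmse_domain_error")
    }
  }
  lambda <- lambda %||% boxcox(y)$lambda
  df$.z <- bc_transform(y, lambda)
  form <- if (by_site) .z ~ nbt + nbq + nbp + factor(site) else .z ~ nbt + nbq + nbp
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  term_map <- c("(Intercept)" = "intercept", nbt = "transects",
                nbq = "quadrats", nbp = "points")
  terms <- rownames(co)
  coefficients <- data.frame(
    term = ifelse(terms %in% names(term_map), term_map[terms], terms),
    estimate = co[, 1L], se = co[, 2L], t = co[, 3L], p = co[, 4L],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(lambda = lambda, coefficients = coefficients,
                 r_squared = sm$r.squared, df_residual = fit$df.residual,
                 fit = fit),
            class = "design_model")
}

#' @export
print.design_model <- function(x, ...) {
  cat(sprintf("Box-Cox regression of MultSE on design (lambda = %.3f, R^2 = %.4f)\n",
              x$lambda, x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Per-group standard error of the mean total cover
#'
#' Total coral cover per unit is the row sum of the cover matrix; the
#' classical SEM `s / sqrt(n)` is computed per group. This is the
#' univariate precision measure MultSE is contrasted with.
#'
#' @param cover units x species percent-cover matrix.
#' @param groups vector of group ids, one per row.
#' @return data frame: group, n_units, mean_cover, se.
#' @export
univariate_se <- function(cover, groups) {
  cover <- as.matrix(cover)
  groups <- as.character(groups)
  if (length(groups) != nrow(cover)) {
    stop_coralmse("groups must have one entry per row", "coralmse_usage_error")
  }
  totals <- rowSums(cover)
  ids <- sort(unique(groups))
  n <- vapply(ids, function(g) sum(groups == g), integer(1))
  if (any(n < 2L)) {
    stop_coralmse(sprintf("group '%s' has fewer than 2 units", ids[n < 2L][[1L]]),
                  "coralmse_insufficient_units")
  }
  data.frame(
    group = ids,
    n_units = n,
    mean_cover = vapply(ids, function(g) mean(totals[groups == g]), numeric(1)),
    se = vapply(ids, function(g) {
      v <- totals[groups == g]
      stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Species richness per group
#'
#' Number of species with nonzero cover in at least one unit of the
#' group.
#'
#' @inheritParams univariate_se
#' @return data frame: group, richness.
#' @export
group_richness <- function(cover, groups) {
  cover <- as.matrix(cover)
  groups <- as.character(groups)
  ids <- sort(unique(groups))
  data.frame(
    group = ids,
    richness = vapply(ids, function(g)
      sum(colSums(cover[groups == g, , drop = FALSE]) > 0), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation of MultSE with a per-group covariate
#'
#' Thin wrapper around [stats::cor.test()]: product-moment r with the
#' two-sided t-based p-value.
#'
#' @param estimates numeric vector (e.g. per-site MultSE).
#' @param covariate numeric vector of the same length.
#' @return list with `r`, `p`, `n`.
#' @export
correlate <- function(estimates, covariate) {
  x <- as.numeric(estimates)
  y <- as.numeric(covariate)
  if (length(x) != length(y) || length(x) < 3L) {
    stop_coralmse("correlate needs two equal-length vectors with >= 3 groups",
                  "coralmse_usage_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_coralmse("non-finite values in correlation input", "coralmse_domain_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_coralmse("correlation undefined: zero variance", "coralmse_domain_error")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
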