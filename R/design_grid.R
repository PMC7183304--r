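# Factorial design-grid evaluation: MultSE per (site, nbT, nbQ, nbP).

#' Build the factorial grid of candidate sampling designs
#'
#' Defaults reproduce the simulated ranges of the study: 2 to 20
#' transects per site, 5 to 25 quadrats per transect and 25, 50 or 75
#' points per quadrat — 1197 designs. The transect floor is 2 because
#' MultSE is undefined for a single sampling unit.
#'
#' @param nbt integer vector of transect counts (all >= 2).
#' @param nbq integer vector of quadrat counts (all >= 1).
#' @param nbp integer vector of point counts (all >= 1).
#' @return a `data.frame` (class `design_grid`) with columns `nbt`,
#'   `nbq`, `nbp`, one row per design.
#' @export
default_grid <- function(nbt = 2:20, nbq = 5:25, nbp = c(25, 50, 75)) {
  if (any(nbt < 2)) {
    stop_coralmse("nbt must be >= 2: MultSE needs at least 2 transects",
                  "coralmse_usage_error")
  }
  if (any(nbq < 1) || any(nbp < 1)) {
    stop_coralmse("nbq and nbp must be >= 1", "coralmse_usage_error")
  }
  g <- expand.grid(nbt = as.integer(nbt), nbq = as.integer(nbq),
                   nbp = as.integer(nbp), KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("design_grid", class(g))
  g
}

grid_as_df <- function(specs) {
  if (is.data.frame(specs)) return(specs)
  if (inherits(specs, "design_spec")) specs <- list(specs)
  do.call(rbind, lapply(specs, function(s)
    data.frame(nbt = s$nbt, nbq = s$nbq, nbp = s$nbp)))
}

#' Evaluate MultSE over a design grid
#'
#' For every (site, design, replicate) combination: simulate the site
#' under the design (transect recycling, quadrat resampling, point
#' subsampling), aggregate the simulated points into a transect-level
#' percent-cover matrix, compute its Bray-Curtis dissimilarities and the
#' MultSE of the `nbt` simulated transects. One MultSE per simulated
#' dataset — replicate spread across a cell measures the Monte-Carlo
#' uncertainty, so no bootstrap is run inside cells. Child seeds derive
#' from `(seed, site, design, replicate)`, so every cell is individually
#' reproducible and re-running the grid is bit-identical.
#'
#' @param raw_sites a [site_raw_data] or list of them.
#' @param schema a [label_schema] identifying the species labels.
#' @param grid a `design_grid` data frame (default [default_grid()]) or
#'   list of [design_spec]s.
#' @param replicates simulated datasets per cell (default 10).
#' @param seed integer root seed.
#' @param transform passed to [bray_curtis()].
#' @return an object of class `design_grid_result`: list with `results`
#'   (long data frame: site, nbt, nbq, nbp, replicate, multse) and
#'   `summary` (per-cell mean and 2.5/97.5 percentiles over replicates).
#' @export
evaluate_grid <- function(raw_sites, schema, grid = default_grid(),
                          replicates = 10, seed = 1,
                          transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  if (inherits(raw_sites, "site_raw_data")) raw_sites <- list(raw_sites)
  stopifnot(inherits(schema, "label_schema"))
  g <- grid_as_df(grid)
  n_cells <- length(raw_sites) * nrow(g)
  res_site <- character(n_cells * replicates)
  res_mat <- matrix(0, nrow = n_cells * replicates, ncol = 4,
                    dimnames = list(NULL, c("nbt", "nbq", "nbp", "replicate")))
  res_ms <- numeric(n_cells * replicates)
  i <- 0L
  for (raw in raw_sites) {
    sp_idx <- which(raw$labels %in% schema$species)
    for (k in seq_len(nrow(g))) {
      spec <- design_spec(g$nbt[[k]], g$nbq[[k]], g$nbp[[k]])
      total <- spec$nbq * spec$nbp
      for (r in seq_len(replicates)) {
        child <- derive_seed(seed, raw$site, spec$nbt, spec$nbq, spec$nbp, r)
        counts <- tryCatch(
          sim_site_counts(raw, spec, seed = child),
          error = function(e) {
            stop_coralmse(
              sprintf("grid cell failed (site=%s nbt=%d nbq=%d nbp=%d rep=%d): %s",
                      raw$site, spec$nbt, spec$nbq, spec$nbp, r,
                      conditionMessage(e)),
              "coralmse_grid_error")
          })
        cover <- 100 * counts[, sp_idx, drop = FALSE] / total
        ms <- multse(bray_curtis(cover, transform = transform))
        i <- i + 1L
        res_site[[i]] <- raw$site
        res_mat[i, ] <- c(spec$nbt, spec$nbq, spec$nbp, r)
        res_ms[[i]] <- ms
      }
    }
  }
  results <- data.frame(site = res_site, res_mat, multse = res_ms,
                        stringsAsFactors = FALSE)
  summary <- stats::aggregate(
    multse ~ site + nbt + nbq + nbp, data = results,
    FUN = function(v) c(mean = mean(v),
                        q2.5 = stats::quantile(v, 0.025, names = FALSE),
                        q97.5 = stats::quantile(v, 0.975, names = FALSE)))
  summary <- cbind(summary[c("site", "nbt", "nbq", "nbp")],
                   as.data.frame(summary$multse))
  names(summary)[5:7] <- c("mean_multse", "q2.5", "q97.5")
  structure(list(results = results, summary = summary,
                 replicates = replicates, seed = seed),
            class = "design_grid_result")
}

#' @export
print.design_grid_result <- function(x, ...) {
  cat(sprintf("design grid: %d sites x %d cells x %d replicates (%d MultSE values)\n",
              length(unique(x$results$site)),
              nrow(unique(x$results[c("nbt", "nbq", "nbp")])),
              x$replicates, nrow(x$results)))
  invisible(x)
}

#' Plot mean MultSE against the number of transects
#'
#' One line per points-per-quadrat level, averaging cells over quadrat
#' counts and sites; a quick visual check that the error stabilises as
#' transects are added.
#'
#' @param x a `design_grid_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.design_grid_result <- function(x, ...) {
  agg <- stats::aggregate(mean_multse ~ nbt + nbp, data = x$summary, FUN = mean)
  wide <- stats::reshape(agg, idvar = "nbt", timevar = "nbp", direction = "wide")
  wide <- wide[order(wide$nbt), , drop = FALSE]
  graphics::matplot(wide$nbt, wide[, -1L, drop = FALSE], type = "b", pch = 16,
                    xlab = "transects per site (nbT)", ylab = "mean MultSE", ...)
  graphics::legend("topright", legend = sub("mean_multse\\.", "nbP = ",
                                            names(wide)[-1L]),
                   col = seq_len(ncol(wide) - 1L), lty = seq_len(ncol(wide) - 1L),
                   bty = "n")
  invisible(x)
}

#' Compare two sampling schemes site by site
#'
#' Evaluates both designs with [evaluate_grid()] and reports, per site,
#' the mean MultSE under each and their ratio (scheme A over scheme B).
#' A degenerate site with zero MultSE under both schemes yields a `NaN`
#' ratio with a warning.
#'
#' @param raw_sites a [site_raw_data] or list of them.
#' @param schema a [label_schema].
#' @param spec_a,spec_b [design_spec]s to compare.
#' @param replicates simulated datasets per scheme and site.
#' @param seed integer root seed.
#' @return data frame: site, mean_a, mean_b, ratio.
#' @export
compare_schemes <- function(raw_sites, schema, spec_a, spec_b,
                            replicates = 50, seed = 1) {
  ga <- evaluate_grid(raw_sites, schema, grid = list(spec_a),
                      replicates = replicates, seed = derive_seed(seed, "A"))
  gb <- evaluate_grid(raw_sites, schema, grid = list(spec_b),
                      replicates = replicates, seed = derive_seed(seed, "B"))
  a <- ga$summary[order(ga$summary$site), ]
  b <- gb$summary[order(gb$summary$site), ]
  ratio <- a$mean_multse / b$mean_multse
  if (any(!is.finite(ratio))) {
    warning("zero-variance site(s): scheme ratio undefined (NaN)")
  }
  data.frame(site = a$site, mean_a = a$mean_multse, mean_b = b$mean_multse,
             ratio = ratio, stringsAsFactors = FALSE)
}
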