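# Dirichlet-multinomial generator of synthetic point-annotation
# datasets with the sites > transects > quadrats > points hierarchy the
# analysis assumes, plus large-sample reference MultSE values for
# coverage and recovery tests.
#
# Composition model: each site draws a species relative-composition
# vector from Dirichlet(alpha_site * base) with a uniform base, each
# transect perturbs it by Dirichlet(alpha_T * site vector), each quadrat
# by Dirichlet(alpha_Q * transect vector); a point is substrate with
# probability 1 - coral_fraction, otherwise a species drawn from the
# quadrat vector. Larger concentrations mean less variability at that
# level; closed-form expectations make the hierarchy convenient for
# parameter-recovery tests.

SUBSTRATE_CODES <- c("MACROALGAE", "PAVEMENT", "RUBBLE", "SAND")

#' Configure the synthetic survey generator
#'
#' Defaults emulate the geometry of a Caribbean photo-quadrat survey:
#' 12 sites of 4 transects x 15 quadrats, re-annotated at 100 points per
#' quadrat, over a 43-species pool. Concentrations are Dirichlet
#' precision parameters (larger = less compositional variability at
#' that level); `coral_fraction` is the expected fraction of points
#' landing on coral rather than substrate.
#'
#' @param n_sites number of sites.
#' @param n_transects transects per site.
#' @param n_quadrats quadrats per transect.
#' @param n_points classified points per quadrat.
#' @param n_species size of the coral species pool.
#' @param site_concentration Dirichlet concentration of site
#'   compositions around the uniform base (> 0; small values give
#'   strongly differentiated, dominance-structured sites).
#' @param transect_concentration between-transect concentration (> 0).
#' @param quadrat_concentration between-quadrat concentration (> 0).
#' @param coral_fraction expected coral fraction of points, in (0, 1).
#' @param seed integer seed; all draws derive child seeds from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 12, n_transects = 4, n_quadrats = 15,
                             n_points = 100, n_species = 43,
                             site_concentration = 1.5,
                             transect_concentration = 100,
                             quadrat_concentration = 100,
                             coral_fraction = 0.35, seed = 1) {
  counts <- c(n_sites, n_transects, n_quadrats, n_points, n_species)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop_coralmse("counts must be integers >= 1", "coralmse_usage_error")
  }
  conc <- c(site_concentration, transect_concentration, quadrat_concentration)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop_coralmse("concentrations must be > 0", "coralmse_usage_error")
  }
  if (coral_fraction <= 0 || coral_fraction >= 1) {
    stop_coralmse("coral_fraction must be in (0, 1)", "coralmse_usage_error")
  }
  structure(list(
    n_sites = as.integer(n_sites), n_transects = as.integer(n_transects),
    n_quadrats = as.integer(n_quadrats), n_points = as.integer(n_points),
    n_species = as.integer(n_species),
    site_concentration = min(site_concentration, 1e9),
    transect_concentration = min(transect_concentration, 1e9),
    quadrat_concentration = min(quadrat_concentration, 1e9),
    coral_fraction = coral_fraction, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic survey: %d sites x %d transects x %d quadrats x ",
                     "%d points, %d species\n",
                     "concentrations site/transect/quadrat = %g/%g/%g, ",
                     "coral fraction = %g, seed = %d\n"),
              x$n_sites, x$n_transects, x$n_quadrats, x$n_points, x$n_species,
              x$site_concentration, x$transect_concentration,
              x$quadrat_concentration, x$coral_fraction, x$seed))
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0 || !is.finite(s)) {
    # numerically degenerate draw (all shapes ~ 0): fall back to the
    # normalised shape vector, the distribution's mean
    if (sum(alpha) > 0) return(alpha / sum(alpha))
    return(rep(1 / length(alpha), length(alpha)))
  }
  g / s
}

#' Species label schema of the synthetic generator
#'
#' @param config a [synthetic_config].
#' @return a [label_schema] with species `SP01..` and four substrate
#'   codes.
#' @export
synthetic_schema <- function(config) {
  label_schema(sprintf("SP%02d", seq_len(config$n_species)), SUBSTRATE_CODES)
}

site_latent <- function(config, i) {
  restore <- local_seed(derive_seed(config$seed, "site", i))
  on.exit(restore(), add = TRUE)
  base <- rep(1 / config$n_species, config$n_species)
  rdirichlet1(config$site_concentration * base)
}

# Draw the label sequence of one quadrat given its composition vector.
quadrat_labels <- function(qvec, n_points, coral_fraction, species_codes) {
  coral <- stats::runif(n_points) < coral_fraction
  out <- character(n_points)
  nc <- sum(coral)
  if (nc > 0) {
    out[coral] <- species_codes[sample.int(length(qvec), nc, replace = TRUE,
                                           prob = qvec)]
  }
  if (nc < n_points) {
    out[!coral] <- SUBSTRATE_CODES[sample.int(length(SUBSTRATE_CODES),
                                              n_points - nc, replace = TRUE)]
  }
  out
}

#' Generate a synthetic point-annotation dataset
#'
#' Draws the full hierarchy described in [synthetic_config()] and
#' returns the canonical annotation table together with a truth record
#' holding every latent composition vector, so parameter-recovery tests
#' need no re-derivation. Deterministic given the config seed; each
#' site uses an independent child stream, so subsets of sites are
#' reproducible in isolation.
#'
#' @param config a [synthetic_config].
#' @return list of class `synthetic_dataset`: `annotations` (data
#'   frame: site, transect, quadrat, point, label), `schema` (a
#'   [label_schema]) and `truth` (config, base vector, per-site /
#'   per-transect / per-quadrat latent vectors).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  species_codes <- sprintf("SP%02d", seq_len(config$n_species))
  site_ids <- sprintf("S%02d", seq_len(config$n_sites))
  per_site <- config$n_transects * config$n_quadrats * config$n_points
  tabs <- vector("list", config$n_sites)
  site_vectors <- matrix(NA_real_, config$n_species, config$n_sites,
                         dimnames = list(species_codes, site_ids))
  transect_vectors <- vector("list", config$n_sites)
  quadrat_vectors <- vector("list", config$n_sites)
  names(transect_vectors) <- names(quadrat_vectors) <- site_ids
  for (i in seq_len(config$n_sites)) {
    p_site <- site_latent(config, i)
    site_vectors[, i] <- p_site
    restore <- local_seed(derive_seed(config$seed, "draw", i))
    tv <- matrix(NA_real_, config$n_species, config$n_transects)
    qv <- vector("list", config$n_transects)
    labels <- character(per_site)
    at <- 0L
    for (t in seq_len(config$n_transects)) {
      p_tr <- rdirichlet1(config$transect_concentration * p_site)
      tv[, t] <- p_tr
      qm <- matrix(NA_real_, config$n_species, config$n_quadrats)
      for (q in seq_len(config$n_quadrats)) {
        p_q <- rdirichlet1(config$quadrat_concentration * p_tr)
        qm[, q] <- p_q
        labels[at + seq_len(config$n_points)] <-
          quadrat_labels(p_q, config$n_points, config$coral_fraction,
                         species_codes)
        at <- at + config$n_points
      }
      qv[[t]] <- qm
    }
    restore()
    transect_vectors[[i]] <- tv
    quadrat_vectors[[i]] <- qv
    tabs[[i]] <- data.frame(
      site = site_ids[[i]],
      transect = rep(sprintf("T%02d", seq_len(config$n_transects)),
                     each = config$n_quadrats * config$n_points),
      quadrat = rep(rep(sprintf("Q%02d", seq_len(config$n_quadrats)),
                        each = config$n_points), times = config$n_transects),
      point = rep(seq_len(config$n_points),
                  times = config$n_transects * config$n_quadrats),
      label = labels,
      stringsAsFactors = FALSE)
  }
  structure(list(
    annotations = do.call(rbind, tabs),
    schema = synthetic_schema(config),
    truth = list(config = config,
                 base = rep(1 / config$n_species, config$n_species),
                 site_vectors = site_vectors,
                 transect_vectors = transect_vectors,
                 quadrat_vectors = quadrat_vectors)),
    class = "synthetic_dataset")
}

#' Draw iid transect-level cover vectors from a site's latent composition
#'
#' Samples `n` fresh transects under site `site`'s latent composition
#' (the same one [generate()] uses for that site, reconstructed from the
#' config seed): per transect a Dirichlet perturbation, then
#' `n_quadrats` quadrat perturbations each contributing `n_points`
#' multinomial points, pooled into transect-level percent cover. These
#' are the exchangeable sampling units whose MultSE the pipeline
#' estimates.
#'
#' @param config a [synthetic_config].
#' @param site site index (1-based).
#' @param n number of transects to draw.
#' @param seed integer seed for the new draws (defaults to a child of
#'   the config seed).
#' @return n x n_species percent-cover matrix (substrate excluded from
#'   columns but counted in the denominator).
#' @export
sample_transect_cover <- function(config, site = 1, n, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  p_site <- site_latent(config, site)
  restore <- local_seed(seed %||% derive_seed(config$seed, "reference", site))
  on.exit(restore(), add = TRUE)
  total <- config$n_quadrats * config$n_points
  cover <- matrix(0, nrow = n, ncol = config$n_species,
                  dimnames = list(sprintf("ref%05d", seq_len(n)),
                                  sprintf("SP%02d", seq_len(config$n_species))))
  for (t in seq_len(n)) {
    p_tr <- rdirichlet1(config$transect_concentration * p_site)
    counts <- numeric(config$n_species)
    for (q in seq_len(config$n_quadrats)) {
      p_q <- rdirichlet1(config$quadrat_concentration * p_tr)
      nc <- stats::rbinom(1L, config$n_points, config$coral_fraction)
      if (nc > 0) {
        counts <- counts + stats::rmultinom(1L, nc, p_q)[, 1L]
      }
    }
    cover[t, ] <- 100 * counts / total
  }
  cover
}

#' Large-sample reference MultSE of the generator
#'
#' Estimates the asymptotic multivariate pseudo-variance `V` of the
#' generator's transect-level units at each site from `n_large` fresh
#' transects, and the implied MultSE `sqrt(V / n)` at a design with `n`
#' transects. Used as the "true" value in bootstrap-coverage and
#' design-recovery tests.
#'
#' @param config a [synthetic_config].
#' @param n_large transects used to estimate `V` (>= 1000).
#' @param sites site indices (default all).
#' @param at_n transect count at which to report MultSE (default the
#'   config's `n_transects`).
#' @param seed integer seed (defaults to a child of the config seed).
#' @return data frame: site, v, multse_at_n, n_large.
#' @export
reference_multse <- function(config, n_large = 5000, sites = NULL,
                             at_n = NULL, seed = NULL) {
  if (n_large < 1000) {
    stop_coralmse("n_large must be >= 1000 for a stable reference",
                  "coralmse_usage_error")
  }
  sites <- sites %||% seq_len(config$n_sites)
  at_n <- at_n %||% config$n_transects
  rows <- lapply(sites, function(i) {
    x <- sample_transect_cover(config, site = i, n = n_large,
                               seed = seed %||% derive_seed(config$seed, "reference", i))
    pv <- pseudo_variance(bray_curtis(x))
    data.frame(site = sprintf("S%02d", i), v = pv$v,
               multse_at_n = sqrt(pv$v / at_n), n_large = n_large)
  })
  do.call(rbind, rows)
}
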