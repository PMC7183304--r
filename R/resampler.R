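# Hierarchical resampler: build simulated datasets with nbT transects
# per site, nbQ quadrats per transect and nbP points per quadrat from
# densely re-annotated raw data.
#
# The algorithm, per simulated site:
#   1. simulated transects 1..nbT map onto the real transects by cyclic
#      recycling of the stored transect order (T1, T2, ..., T1, T2, ...);
#   2. each simulated transect draws nbQ quadrats from its real
#      transect's NQ observed quadrats — without replacement when
#      nbQ <= NQ, with replacement when nbQ > NQ;
#   3. each drawn quadrat contributes nbP of its observed points by
#      simple random sampling without replacement, so nbP can never
#      exceed the observed number of points per quadrat.

#' Index a site's raw annotations for resampling
#'
#' Reorganises a single site's point annotations into the nested
#' transect > quadrat > points structure the resampler draws from.
#' Transects and quadrats keep their order of first appearance; points
#' within a quadrat are ordered by point index.
#'
#' @param annotations annotation `data.frame` (one site, or use `site`
#'   to pick one).
#' @param site optional site id to extract when `annotations` spans
#'   several sites.
#' @return an object of class `site_raw_data`.
#' @export
site_raw_data <- function(annotations, site = NULL) {
  ann <- annotations
  if (!is.null(site)) ann <- ann[ann$site == site, , drop = FALSE]
  if (!nrow(ann)) stop_coralmse("no annotations for this site", "coralmse_input_error")
  sites <- unique(ann$site)
  if (length(sites) > 1L) {
    stop_coralmse("annotations span several sites; pass `site` to pick one",
                  "coralmse_usage_error")
  }
  labels <- sort(unique(ann$label))
  tr_ids <- unique(ann$transect)
  transects <- lapply(tr_ids, function(tid) {
    sub <- ann[ann$transect == tid, , drop = FALSE]
    q_ids <- unique(sub$quadrat)
    quadrats <- lapply(q_ids, function(qid) {
      qq <- sub[sub$quadrat == qid, , drop = FALSE]
      qq <- qq[order(qq$point), , drop = FALSE]
      list(point = qq$point,
           label = qq$label,
           code = match(qq$label, labels))
    })
    names(quadrats) <- q_ids
    quadrats
  })
  names(transects) <- tr_ids
  structure(list(site = sites, labels = labels, transects = transects),
            class = "site_raw_data")
}

#' @export
print.site_raw_data <- function(x, ...) {
  nq <- vapply(x$transects, length, integer(1))
  np <- unlist(lapply(x$transects, function(tr)
    vapply(tr, function(q) length(q$point), integer(1))))
  cat(sprintf("site '%s': %d transects, %s quadrats/transect, %d-%d points/quadrat\n",
              x$site, length(x$transects),
              paste(range(nq), collapse = "-"), min(np), max(np)))
  invisible(x)
}

#' Specify a simulated sampling design
#'
#' @param nbt transects per site (>= 1; MultSE needs >= 2).
#' @param nbq quadrats per transect (>= 1).
#' @param nbp points per quadrat (>= 1; must not exceed the observed
#'   points of any quadrat of the site it is applied to).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(nbt, nbq, nbp) {
  vals <- c(nbt = nbt, nbq = nbq, nbp = nbp)
  if (any(vals != round(vals)) || any(vals < 1)) {
    stop_coralmse("nbt, nbq and nbp must be integers >= 1", "coralmse_usage_error")
  }
  structure(list(nbt = as.integer(nbt), nbq = as.integer(nbq),
                 nbp = as.integer(nbp)), class = "design_spec")
}

check_spec_for_site <- function(raw, spec) {
  for (tid in names(raw$transects)) {
    npts <- vapply(raw$transects[[tid]], function(q) length(q$point), integer(1))
    bad <- which(npts < spec$nbp)
    if (length(bad)) {
      stop_coralmse(
        sprintf(paste0("nbp = %d could not be higher than the observed number ",
                       "of points per quadrat (%d in quadrat %s of transect %s)"),
                spec$nbp, npts[[bad[1L]]],
                names(raw$transects[[tid]])[bad[1L]], tid),
        "coralmse_design_error")
    }
  }
  invisible(TRUE)
}

# Core draw shared by simulate_site() and the fast cover path: consumes
# the current RNG stream, returns per simulated transect the source
# transect index, drawn quadrat indices and per-quadrat point indices.
draw_site <- function(raw, spec) {
  n_real <- length(raw$transects)
  src <- ((seq_len(spec$nbt) - 1L) %% n_real) + 1L
  lapply(seq_len(spec$nbt), function(t) {
    tr <- raw$transects[[src[[t]]]]
    nq_real <- length(tr)
    quads <- if (spec$nbq <= nq_real) {
      sample.int(nq_real, spec$nbq)
    } else {
      sample.int(nq_real, spec$nbq, replace = TRUE)
    }
    pts <- lapply(quads, function(q) sample.int(length(tr[[q]]$point), spec$nbp))
    list(src = src[[t]], quads = quads, points = pts)
  })
}

#' Simulate one site under a sampling design
#'
#' Draws a simulated dataset of `nbt` transects x `nbq` quadrats x
#' `nbp` points from a site's observed annotations, following the
#' transect-recycling / quadrat-resampling / point-subsampling scheme
#' described above. Output transects and quadrats get fresh simulated
#' ids; `source_transect`, `source_quadrat` and `source_point` columns
#' keep the provenance auditable (quadrats drawn with replacement show
#' up as repeated sources). Deterministic given `seed`.
#'
#' @param raw a [site_raw_data].
#' @param spec a [design_spec].
#' @param seed integer seed.
#' @return annotation `data.frame` with provenance columns.
#' @export
simulate_site <- function(raw, spec, seed) {
  stopifnot(inherits(raw, "site_raw_data"), inherits(spec, "design_spec"))
  check_spec_for_site(raw, spec)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  draws <- draw_site(raw, spec)
  per_tr <- spec$nbq * spec$nbp
  n_rows <- spec$nbt * per_tr
  lab <- character(n_rows)
  src_t <- character(n_rows)
  src_q <- character(n_rows)
  src_p <- integer(n_rows)
  at <- 0L
  for (t in seq_along(draws)) {
    dr <- draws[[t]]
    tr <- raw$transects[[dr$src]]
    for (j in seq_along(dr$quads)) {
      q <- tr[[dr$quads[[j]]]]
      sel <- dr$points[[j]]
      rng <- at + seq_len(spec$nbp)
      lab[rng] <- q$label[sel]
      src_t[rng] <- names(raw$transects)[dr$src]
      src_q[rng] <- names(tr)[dr$quads[[j]]]
      src_p[rng] <- q$point[sel]
      at <- at + spec$nbp
    }
  }
  data.frame(
    site = raw$site,
    transect = rep(sprintf("simT%02d", seq_len(spec$nbt)), each = per_tr),
    quadrat = rep(rep(sprintf("simQ%02d", seq_len(spec$nbq)), each = spec$nbp),
                  times = spec$nbt),
    point = rep(seq_len(spec$nbp), times = spec$nbt * spec$nbq),
    label = lab,
    source_transect = src_t,
    source_quadrat = src_q,
    source_point = src_p,
    stringsAsFactors = FALSE)
}

# Fast path: same draws as simulate_site (identical RNG stream via
# draw_site) but tabulated straight into a simulated-transect x label
# count matrix, skipping the annotation data frame. evaluate_grid()
# turns this into transect-level percent cover.
sim_site_counts <- function(raw, spec, seed) {
  check_spec_for_site(raw, spec)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  draws <- draw_site(raw, spec)
  n_lab <- length(raw$labels)
  counts <- matrix(0L, nrow = spec$nbt, ncol = n_lab,
                   dimnames = list(sprintf("simT%02d", seq_len(spec$nbt)),
                                   raw$labels))
  for (t in seq_along(draws)) {
    dr <- draws[[t]]
    tr <- raw$transects[[dr$src]]
    codes <- integer(spec$nbq * spec$nbp)
    at <- 0L
    for (j in seq_along(dr$quads)) {
      q <- tr[[dr$quads[[j]]]]
      codes[at + seq_len(spec$nbp)] <- q$code[dr$points[[j]]]
      at <- at + spec$nbp
    }
    counts[t, ] <- tabulate(codes, nbins = n_lab)
  }
  counts
}

#' Simulate a batch of (site x design x replicate) datasets
#'
#' Runs [simulate_site()] for every combination of sites, design specs
#' and replicates, with independent child seeds derived from the root
#' seed and the combination's identity — the stream is reproducible
#' regardless of iteration order. If `fun` is supplied it is applied to
#' each simulated table (with the combination metadata) and only its
#' results are kept, so large batches need not be materialised.
#'
#' @param raw_sites list of [site_raw_data] objects.
#' @param specs list of [design_spec]s.
#' @param replicates replicates per combination (>= 1).
#' @param seed integer root seed.
#' @param fun optional `function(site, spec, replicate, annotations)`.
#' @return a list, one element per combination in site-major order;
#'   each element is a list `(site, spec, replicate, annotations)` or,
#'   when `fun` is given, `(site, spec, replicate, value)`.
#' @export
simulate_batch <- function(raw_sites, specs, replicates, seed, fun = NULL) {
  if (replicates < 1L) stop_coralmse("replicates must be >= 1", "coralmse_usage_error")
  if (inherits(raw_sites, "site_raw_data")) raw_sites <- list(raw_sites)
  if (inherits(specs, "design_spec")) specs <- list(specs)
  out <- vector("list", length(raw_sites) * length(specs) * replicates)
  i <- 0L
  for (raw in raw_sites) {
    for (spec in specs) {
      for (r in seq_len(replicates)) {
        child <- derive_seed(seed, raw$site, spec$nbt, spec$nbq, spec$nbp, r)
        tab <- simulate_site(raw, spec, seed = child)
        i <- i + 1L
        out[[i]] <- if (is.null(fun)) {
          list(site = raw$site, spec = spec, replicate = r, annotations = tab)
        } else {
          list(site = raw$site, spec = spec, replicate = r,
               value = fun(raw$site, spec, r, tab))
        }
      }
    }
  }
  out
}
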