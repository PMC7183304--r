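# Point-annotation IO and aggregation into percent-cover matrices.
#
# The raw currency of a photo-quadrat survey is the classified point:
# one row per point, nested as site > transect > quadrat > point, with a
# label that is either a coral species code or a non-coral substrate
# code. Percent cover of a species in a sampling unit is the fraction of
# ALL classified points (coral and substrate alike) that carry its
# label, times 100 — the point-intercept definition. Rows of the
# resulting abundance matrix therefore sum to at most 100, the remainder
# being substrate.

ANNOTATION_COLUMNS <- c("site", "transect", "quadrat", "point", "label")

#' Define a label schema
#'
#' Declares which annotation labels are coral species (they become the
#' columns of abundance matrices) and which are non-coral substrate
#' (they count toward the cover denominator only). The two sets must be
#' disjoint.
#'
#' @param species character vector of coral species codes.
#' @param substrate character vector of non-coral substrate codes.
#' @return an object of class `label_schema`.
#' @examples
#' label_schema(c("OFAV", "PAST"), c("SAND", "TURF"))
#' @export
label_schema <- function(species, substrate) {
  species <- sort(unique(as.character(species)))
  substrate <- sort(unique(as.character(substrate)))
  if (any(species == "") || any(substrate == "")) {
    stop_coralmse("schema labels must be non-empty strings", "coralmse_schema_error")
  }
  overlap <- intersect(species, substrate)
  if (length(overlap)) {
    stop_coralmse(
      sprintf("labels cannot be both species and substrate: %s",
              paste(overlap, collapse = ", ")),
      "coralmse_schema_error")
  }
  structure(list(species = species, substrate = substrate),
            class = "label_schema")
}

#' Read a label schema from a YAML or JSON config file
#'
#' The file must hold two keys, `species` and `substrate`, each a list
#' of label codes.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [label_schema].
#' @export
read_label_schema <- function(path) {
  if (!file.exists(path)) {
    stop_coralmse(sprintf("schema file not found: %s", path), "coralmse_format_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$species) || is.null(cfg$substrate)) {
    stop_coralmse("schema config needs keys 'species' and 'substrate'",
                  "coralmse_format_error")
  }
  label_schema(cfg$species, cfg$substrate)
}

#' Read point annotations from CSV files
#'
#' Reads one or more long-format annotation CSVs (columns `site`,
#' `transect`, `quadrat`, `point`, `label`; other header names can be
#' adapted with `col_map`) and validates them against a schema.
#' Duplicate `(site, transect, quadrat, point)` keys are rejected, as
#' are labels absent from the schema unless `unknown_as_substrate` is
#' set, in which case unknown labels are kept and treated as substrate
#' downstream.
#'
#' @param paths character vector of CSV file paths.
#' @param schema a [label_schema].
#' @param col_map optional named character vector mapping canonical
#'   column names to the names used in the files, e.g.
#'   `c(site = "Station", label = "Code")`.
#' @param unknown_as_substrate accept labels missing from the schema and
#'   count them as substrate (default `FALSE`).
#' @return a `data.frame` of annotations with the five canonical columns.
#' @export
read_annotations <- function(paths, schema, col_map = NULL,
                             unknown_as_substrate = FALSE) {
  stopifnot(inherits(schema, "label_schema"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop_coralmse(sprintf("annotation file not found: %s", missing_files[[1L]]),
                  "coralmse_format_error")
  }
  tables <- lapply(paths, function(p) {
    tab <- utils::read.csv(p, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
    if (!is.null(col_map)) {
      for (canon in names(col_map)) {
        names(tab)[names(tab) == col_map[[canon]]] <- canon
      }
    }
    absent <- setdiff(ANNOTATION_COLUMNS, names(tab))
    if (length(absent)) {
      stop_coralmse(sprintf("file %s lacks required column '%s'", p, absent[[1L]]),
                    "coralmse_format_error")
    }
    tab[ANNOTATION_COLUMNS]
  })
  ann <- do.call(rbind, tables)
  ann$point <- as.integer(ann$point)
  validate_annotations(ann, schema, unknown_as_substrate)
}

validate_annotations <- function(ann, schema, unknown_as_substrate = FALSE) {
  if (anyNA(ann$point) || any(ann$point < 1L)) {
    stop_coralmse("point indices must be integers >= 1", "coralmse_format_error")
  }
  if (any(ann$label == "" | is.na(ann$label))) {
    stop_coralmse("labels must be non-empty", "coralmse_format_error")
  }
  key <- paste(ann$site, ann$transect, ann$quadrat, ann$point, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- ann[which(dup)[1L], ]
    stop_coralmse(
      sprintf("duplicate annotation key: site=%s transect=%s quadrat=%s point=%d",
              first$site, first$transect, first$quadrat, first$point),
      "coralmse_integrity_error")
  }
  known <- c(schema$species, schema$substrate)
  unknown <- setdiff(unique(ann$label), known)
  if (length(unknown) && !unknown_as_substrate) {
    stop_coralmse(
      sprintf("labels not in schema: %s (set unknown_as_substrate = TRUE to keep them)",
              paste(utils::head(unknown, 5L), collapse = ", ")),
      "coralmse_schema_error")
  }
  rownames(ann) <- NULL
  ann
}

#' Write point annotations to a CSV file
#'
#' @param annotations annotation `data.frame` as returned by
#'   [read_annotations()] or [simulate_site()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate point annotations into a percent-cover matrix
#'
#' Computes the cover of every coral species in every sampling unit
#' (quadrat or transect) as `100 * points labelled s / total points in
#' the unit`, with substrate points included in the denominator — the
#' point-intercept cover definition. At transect level, points are
#' pooled over the transect's quadrats, so the transect row equals the
#' point-count-weighted mean of its quadrat rows. Species columns are
#' the schema species observed anywhere in the data, in lexicographic
#' order.
#'
#' @param annotations annotation `data.frame`.
#' @param level `"transect"` (default) or `"quadrat"`; the sampling unit.
#' @param schema a [label_schema]; labels outside it count as substrate.
#' @return a numeric `cover_matrix` (units x species, percent) with a
#'   `units` attribute data frame holding the unit's site, transect,
#'   quadrat (at quadrat level), total point count and substrate cover.
#' @examples
#' ann <- data.frame(site = "A", transect = "T1", quadrat = "Q1",
#'                   point = 1:25,
#'                   label = c(rep("OFAV", 5), rep("SAND", 20)))
#' sch <- label_schema("OFAV", "SAND")
#' aggregate_cover(ann, level = "quadrat", schema = sch)
#' @export
aggregate_cover <- function(annotations, level = c("transect", "quadrat"),
                            schema) {
  level <- match.arg(level)
  stopifnot(inherits(schema, "label_schema"))
  ann <- annotations
  if (!nrow(ann)) stop_coralmse("no annotations to aggregate", "coralmse_computation_error")
  unit <- if (level == "quadrat") {
    paste(ann$site, ann$transect, ann$quadrat, sep = ":")
  } else {
    paste(ann$site, ann$transect, sep = ":")
  }
  species <- sort(intersect(schema$species, unique(ann$label)))
  units <- sort(unique(unit))
  n_points <- as.vector(table(factor(unit, levels = units)))
  counts <- matrix(0, nrow = length(units), ncol = length(species),
                   dimnames = list(units, species))
  if (length(species)) {
    is_sp <- ann$label %in% species
    if (any(is_sp)) {
      tab <- table(factor(unit[is_sp], levels = units),
                   factor(ann$label[is_sp], levels = species))
      counts <- counts + unclass(tab)
    }
  }
  cover <- 100 * counts / n_points
  zero_rows <- rowSums(cover) == 0
  if (any(zero_rows)) {
    message(sprintf("%d unit(s) have no coral points (all-substrate rows kept)",
                    sum(zero_rows)))
  }
  meta <- unique(ann[c("site", "transect", if (level == "quadrat") "quadrat")])
  meta_unit <- if (level == "quadrat") {
    paste(meta$site, meta$transect, meta$quadrat, sep = ":")
  } else {
    paste(meta$site, meta$transect, sep = ":")
  }
  meta <- meta[match(units, meta_unit), , drop = FALSE]
  meta$unit <- units
  meta$n_points <- n_points
  meta$substrate_cover <- 100 - rowSums(cover)
  rownames(meta) <- NULL
  structure(cover,
            units = meta,
            unit_level = level,
            class = c("cover_matrix", class(cover)))
}

#' Metadata of a cover matrix's sampling units
#'
#' @param cover a `cover_matrix` from [aggregate_cover()].
#' @return the `units` attribute data frame (site, transect, point
#'   counts, substrate cover per unit).
#' @export
cover_units <- function(cover) attr(cover, "units")

#' Write / read a percent-cover matrix as wide CSV
#'
#' The first column (`unit`) holds the unit identifier; remaining
#' columns are species percent covers.
#'
#' @param cover a `cover_matrix` (or plain units x species matrix).
#' @param path CSV path.
#' @return `write_cover`: `path` invisibly; `read_cover`: a numeric
#'   matrix with unit rownames.
#' @export
write_cover <- function(cover, path) {
  df <- data.frame(unit = rownames(cover), as.data.frame(unclass(cover)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cover
#' @export
read_cover <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
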