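# Shared fixture builders: everything is generated in code.

# Minimal annotation table: one site, `n_transects` transects of
# `n_quadrats` quadrats, `labels` recycled over `n_points` points.
make_annotations <- function(labels, n_transects = 1, n_quadrats = 1,
                             site = "A") {
  n_points <- length(labels)
  expand <- expand.grid(point = seq_len(n_points),
                        quadrat = sprintf("Q%d", seq_len(n_quadrats)),
                        transect = sprintf("T%d", seq_len(n_transects)),
                        stringsAsFactors = FALSE)
  data.frame(site = site, transect = expand$transect,
             quadrat = expand$quadrat, point = expand$point,
             label = rep(labels, times = n_transects * n_quadrats),
             stringsAsFactors = FALSE)
}

tiny_schema <- function() {
  label_schema(c("OFAV", "PAST", "MCAV"), c("SAND", "TURF"))
}

# Small synthetic survey used across modules: cheap but full hierarchy.
small_config <- function(seed = 42, ...) {
  args <- list(n_sites = 2, n_transects = 4, n_quadrats = 5, n_points = 25,
               n_species = 12, transect_concentration = 60,
               quadrat_concentration = 60, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
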