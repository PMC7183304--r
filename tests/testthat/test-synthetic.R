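# The Dirichlet-multinomial survey generator.

test_that("generated datasets have the configured dimensions and schema", {
  cfg <- small_config(seed = 61)
  ds <- generate(cfg)
  expect_equal(nrow(ds$annotations), 2 * 4 * 5 * 25)
  expect_identical(names(ds$annotations),
                   c("site", "transect", "quadrat", "point", "label"))
  expect_length(unique(ds$annotations$site), 2)
  expect_true(all(ds$annotations$label %in%
                    c(ds$schema$species, ds$schema$substrate)))
  # keys unique: the table validates against its own schema
  expect_silent(coralmse:::validate_annotations(ds$annotations, ds$schema))
  # truth record holds every latent vector
  expect_equal(dim(ds$truth$site_vectors), c(12, 2))
  expect_equal(dim(ds$truth$quadrat_vectors[["S01"]][[1]]), c(12, 5))
  expect_true(all(abs(colSums(ds$truth$site_vectors) - 1) < 1e-12))
})

test_that("generation is deterministic and site streams are independent", {
  cfg <- small_config(seed = 62)
  a <- generate(cfg)
  b <- generate(cfg)
  expect_identical(a$annotations, b$annotations)
  # site S01 is identical whether or not S02 exists
  solo <- generate(small_config(seed = 62, n_sites = 1))
  expect_equal(solo$annotations,
               a$annotations[a$annotations$site == "S01", ],
               ignore_attr = "row.names")
})

test_that("the degenerate-variance limit collapses to the site vector", {
  cfg <- small_config(seed = 63, n_sites = 1, n_transects = 6,
                      n_quadrats = 10, n_points = 100, n_species = 6,
                      site_concentration = 50,
                      transect_concentration = 1e9,
                      quadrat_concentration = 1e9,
                      coral_fraction = 0.999)
  ds <- generate(cfg)
  cov <- aggregate_cover(ds$annotations, "transect", ds$schema)
  p <- ds$truth$site_vectors[, 1]
  n_pts <- 10 * 100
  for (s in seq_along(p)) {
    phat <- cov[, sprintf("SP%02d", s)] / 100
    tol <- 3 * sqrt(p[[s]] * (1 - p[[s]]) / n_pts) + 1e-9
    expect_true(all(abs(phat - p[[s]] * 0.999) <= tol))
  }
})

test_that("single-species cover is binomial around coral_fraction", {
  cfg <- small_config(seed = 64, n_sites = 1, n_transects = 20,
                      n_quadrats = 4, n_points = 50, n_species = 1,
                      coral_fraction = 0.5)
  ds <- generate(cfg)
  cov <- aggregate_cover(ds$annotations, "transect", ds$schema)
  # per-transect cover ~ Binomial(200, 0.5)/200, in percent
  expect_equal(mean(cov[, 1]), 50, tolerance = 3 * 100 * sqrt(0.25 / (200 * 20)))
  expect_lt(sd(cov[, 1]) / 100, 3 * sqrt(0.25 / 200))
})

test_that("reference MultSE is reproducible and converges in n_large", {
  cfg <- small_config(seed = 65, n_sites = 1, n_quadrats = 4,
                      n_points = 25, n_species = 8)
  r1 <- reference_multse(cfg, n_large = 1000, sites = 1)
  r2 <- reference_multse(cfg, n_large = 1000, sites = 1)
  expect_identical(r1, r2)
  v2 <- reference_multse(cfg, n_large = 2000, sites = 1, seed = 7)$v
  v4 <- reference_multse(cfg, n_large = 4000, sites = 1, seed = 8)$v
  expect_lt(abs(v2 - v4) / v4, 0.05)
  expect_error(reference_multse(cfg, n_large = 10),
               class = "coralmse_usage_error")
})

test_that("lower between-transect variance lowers the site MultSE", {
  base <- small_config(seed = 66, n_sites = 1, n_quadrats = 4,
                       n_points = 25, n_species = 8,
                       transect_concentration = 10)
  tight <- small_config(seed = 66, n_sites = 1, n_quadrats = 4,
                        n_points = 25, n_species = 8,
                        transect_concentration = 300)
  ms <- function(cfg, r) {
    x <- sample_transect_cover(cfg, 1, 8, seed = 100 + r)
    multse(bray_curtis(x))
  }
  m_loose <- mean(vapply(1:60, function(r) ms(base, r), numeric(1)))
  m_tight <- mean(vapply(1:60, function(r) ms(tight, r), numeric(1)))
  expect_lt(m_tight, m_loose)
})

test_that("every stage runs end to end on generated data", {
  cfg <- small_config(seed = 67, n_points = 30)
  ds <- generate(cfg)
  cov <- aggregate_cover(ds$annotations, "transect", ds$schema)
  est <- bootstrap_multse(cov, cover_units(cov)$site, n_boot = 100, seed = 1)
  top <- rank_groups_by_iqr(est, 1)
  raw <- site_raw_data(ds$annotations, top)
  sim <- simulate_site(raw, design_spec(6, 4, 20), seed = 2)
  expect_equal(nrow(sim), 6 * 4 * 20)
  gr <- evaluate_grid(raw, ds$schema,
                      grid = default_grid(nbt = c(2, 4, 6), nbq = c(3, 4),
                                          nbp = c(15, 30)),
                      replicates = 3, seed = 3)
  fit <- fit_design_model(gr, drop_zero = TRUE)
  expect_true(all(c("transects", "quadrats", "points") %in%
                    fit$coefficients$term))
  ord <- pcoa(bray_curtis(cov))
  disp <- centroid_dispersion(ord, cover_units(cov)$site)
  expect_equal(nrow(disp$centroids), 2)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_sites = 0), class = "coralmse_usage_error")
  expect_error(synthetic_config(coral_fraction = 1), class = "coralmse_usage_error")
  expect_error(synthetic_config(transect_concentration = 0),
               class = "coralmse_usage_error")
})
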