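# Factorial design-grid evaluation.

test_that("the default grid enumerates the study's design ranges", {
  g <- default_grid()
  expect_equal(nrow(g), 19 * 21 * 3)   # nbT 2..20 x nbQ 5..25 x nbP {25,50,75}
  expect_equal(range(g$nbt), c(2, 20))
  expect_equal(range(g$nbq), c(5, 25))
  expect_setequal(unique(g$nbp), c(25, 50, 75))

  field <- default_grid(nbt = 4, nbq = 15, nbp = 25)
  expect_equal(nrow(field), 1)

  expect_error(default_grid(nbt = 1), class = "coralmse_usage_error")
})

test_that("grid evaluation yields one finite MultSE per cell and replicate", {
  cfg <- small_config(seed = 51, n_sites = 1)
  ds <- generate(cfg)
  raw <- site_raw_data(ds$annotations, "S01")
  gr <- evaluate_grid(raw, ds$schema,
                      grid = default_grid(nbt = c(2, 3), nbq = 5, nbp = 25),
                      replicates = 2, seed = 3)
  expect_equal(nrow(gr$results), 2 * 2)
  expect_true(all(is.finite(gr$results$multse)))
  expect_true(all(gr$results$multse >= 0))
  expect_equal(nrow(gr$summary), 2)

  # bit-identical under the same seed
  gr2 <- evaluate_grid(raw, ds$schema,
                       grid = default_grid(nbt = c(2, 3), nbq = 5, nbp = 25),
                       replicates = 2, seed = 3)
  expect_identical(gr$results, gr2$results)
})

test_that("a degenerate site with identical quadrats gives MultSE 0 everywhere", {
  labels <- c(rep("OFAV", 10), rep("SAND", 15))
  ann <- make_annotations(labels, n_transects = 4, n_quadrats = 6)
  raw <- site_raw_data(ann)
  sch <- tiny_schema()
  gr <- evaluate_grid(raw, sch,
                      grid = default_grid(nbt = c(2, 8), nbq = 6, nbp = 25),
                      replicates = 3, seed = 1)
  expect_true(all(gr$results$multse == 0))
})

test_that("cell means decay like 1/sqrt(nbT) when simulated transects are iid", {
  # a site whose composition is identical at every level concentrates
  # all resampling variance at the point-subsampling step, so each
  # simulated transect carries fresh iid noise and MultSE should scale
  # as 1/sqrt(nbT): ratio of cell means at nbT 16 vs 4 near 0.5
  cfg <- small_config(seed = 52, n_sites = 1, n_transects = 4,
                      n_quadrats = 15, n_points = 100, n_species = 8,
                      site_concentration = 1e6,
                      transect_concentration = 1e6,
                      quadrat_concentration = 1e6)
  ds <- generate(cfg)
  raw <- site_raw_data(ds$annotations, "S01")
  gr <- evaluate_grid(raw, ds$schema,
                      grid = default_grid(nbt = c(4, 16), nbq = 5, nbp = 25),
                      replicates = 200, seed = 8)
  m <- tapply(gr$results$multse, gr$results$nbt, mean)
  expect_gt(m[["16"]] / m[["4"]], 0.45)
  expect_lt(m[["16"]] / m[["4"]], 0.55)
  # monotone decay across the transect range
  gr2 <- evaluate_grid(raw, ds$schema,
                       grid = default_grid(nbt = seq(2, 16, 2), nbq = 5,
                                           nbp = 25),
                       replicates = 30, seed = 9)
  mm <- tapply(gr2$results$multse, gr2$results$nbt, mean)
  rho <- cor(as.numeric(names(mm)), mm, method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("scheme comparison reports paired means and sane ratios", {
  cfg <- small_config(seed = 53, n_sites = 2, n_points = 30)
  ds <- generate(cfg)
  raws <- lapply(c("S01", "S02"), function(s) site_raw_data(ds$annotations, s))
  spec <- design_spec(4, 4, 20)
  self <- compare_schemes(raws, ds$schema, spec, spec,
                          replicates = 80, seed = 12)
  expect_equal(nrow(self), 2)
  expect_true(all(abs(self$ratio - 1) < 0.25))   # Monte-Carlo error only

  # site with iid point-level noise only: schemes with equal
  # per-transect effort differ purely through 1/sqrt(nbT), so the
  # 10-vs-4-transect ratio approaches the closed-form limit sqrt(4/10)
  cfg2 <- small_config(seed = 54, n_sites = 1, n_quadrats = 15,
                       n_points = 100, n_species = 8,
                       site_concentration = 1e6,
                       transect_concentration = 1e6,
                       quadrat_concentration = 1e6)
  ds2 <- generate(cfg2)
  raw2 <- site_raw_data(ds2$annotations, "S01")
  cmp2 <- compare_schemes(raw2, ds2$schema,
                          design_spec(10, 10, 25), design_spec(4, 10, 25),
                          replicates = 120, seed = 13)
  expect_equal(cmp2$ratio, sqrt(4 / 10), tolerance = 0.1 / sqrt(4 / 10))
  # the denser 10/10/25 scheme beats the 4/15/25 field protocol outright
  cmp3 <- compare_schemes(raw2, ds2$schema,
                          design_spec(10, 10, 25), design_spec(4, 15, 25),
                          replicates = 120, seed = 14)
  expect_lt(cmp3$ratio, 1)

  # degenerate site with identical quadrats, resampled at full point
  # depth: both means 0, ratio NaN with warning
  labels <- c(rep("OFAV", 10), rep("SAND", 10))
  dann <- make_annotations(labels, n_transects = 4, n_quadrats = 5)
  expect_warning(
    cmp <- compare_schemes(site_raw_data(dann), tiny_schema(),
                           design_spec(3, 3, 20), design_spec(2, 2, 20),
                           replicates = 3, seed = 1),
    "NaN")
  expect_true(is.nan(cmp$ratio))
})
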