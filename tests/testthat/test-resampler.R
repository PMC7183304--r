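# The transect-recycling / quadrat-resampling / point-subsampling
# simulator.

raw_fixture <- function(n_transects = 4, n_quadrats = 5, n_points = 20,
                        seed = 33) {
  cfg <- small_config(seed = seed, n_sites = 1, n_transects = n_transects,
                      n_quadrats = n_quadrats, n_points = n_points)
  ds <- generate(cfg)
  list(raw = site_raw_data(ds$annotations, "S01"), schema = ds$schema)
}

test_that("simulated datasets have exact cardinalities and clean draws", {
  fx <- raw_fixture()
  spec <- design_spec(7, 3, 10)
  sim <- simulate_site(fx$raw, spec, seed = 4)
  expect_equal(nrow(sim), 7 * 3 * 10)
  expect_equal(length(unique(sim$transect)), 7)
  counts <- table(sim$transect, sim$quadrat)
  expect_true(all(counts == 10))
  # no duplicate source point inside one drawn quadrat
  key <- paste(sim$transect, sim$quadrat)
  expect_false(any(tapply(sim$source_point, key, anyDuplicated) > 0))
  # determinism
  expect_identical(sim, simulate_site(fx$raw, spec, seed = 4))
})

test_that("transect recycling is cyclic in stored order", {
  fx <- raw_fixture(n_transects = 4)
  sim <- simulate_site(fx$raw, design_spec(10, 2, 5), seed = 1)
  src <- unique(sim[c("transect", "source_transect")])$source_transect
  expect_identical(src, c("T01", "T02", "T03", "T04",
                          "T01", "T02", "T03", "T04", "T01", "T02"))
})

test_that("quadrat sampling flips from without to with replacement at NQ", {
  fx <- raw_fixture(n_quadrats = 5)
  # nbq = NQ: every real quadrat used exactly once per simulated transect
  sim <- simulate_site(fx$raw, design_spec(2, 5, 5), seed = 2)
  per_tr <- split(sim, sim$transect)
  for (tr in per_tr) {
    expect_setequal(unique(tr$source_quadrat), sprintf("Q%02d", 1:5))
  }
  # nbq < NQ: a subset, no duplicates
  sim2 <- simulate_site(fx$raw, design_spec(2, 3, 5), seed = 2)
  for (tr in split(sim2, sim2$transect)) {
    expect_equal(anyDuplicated(unique(tr[c("quadrat", "source_quadrat")])$source_quadrat), 0)
  }
  # nbq = NQ + 1: with replacement, a duplicate is forced by pigeonhole
  sim3 <- simulate_site(fx$raw, design_spec(1, 6, 5), seed = 2)
  srcs <- unique(sim3[c("quadrat", "source_quadrat")])$source_quadrat
  expect_gt(sum(duplicated(srcs)), 0)
})

test_that("with-replacement quadrat draws are uniform over NQ", {
  fx <- raw_fixture(n_quadrats = 3, n_points = 5)
  draws <- integer(0)
  for (s in 1:400) {
    sim <- simulate_site(fx$raw, design_spec(1, 8, 3), seed = s)
    draws <- c(draws, unique(sim[c("quadrat", "source_quadrat")])$source_quadrat)
  }
  tab <- table(factor(draws, levels = sprintf("Q%02d", 1:3)))
  p <- chisq.test(tab)$p.value   # 3200 uniform draws over 3 quadrats
  expect_gt(p, 0.001)
})

test_that("nbp above the observed points raises a design error", {
  fx <- raw_fixture(n_points = 20)
  expect_error(simulate_site(fx$raw, design_spec(2, 2, 21), seed = 1),
               class = "coralmse_design_error")
  expect_error(simulate_site(fx$raw, design_spec(2, 2, 21), seed = 1),
               "observed number of points")
})

test_that("recycled transects are generally non-identical", {
  fx <- raw_fixture(n_transects = 1, n_quadrats = 12, n_points = 30)
  identical_count <- 0L
  for (s in 1:50) {
    sim <- simulate_site(fx$raw, design_spec(2, 10, 25), seed = s)
    a <- sim[sim$transect == "simT01", c("source_quadrat", "source_point")]
    b <- sim[sim$transect == "simT02", c("source_quadrat", "source_point")]
    if (identical(a[order(a$source_quadrat, a$source_point), ],
                  b[order(b$source_quadrat, b$source_point), ])) {
      identical_count <- identical_count + 1L
    }
  }
  expect_lt(identical_count / 50, 0.01 + 1e-9)
})

test_that("batches enumerate site x spec x replicate with independent seeds", {
  fx <- raw_fixture()
  specs <- list(design_spec(2, 2, 5), design_spec(3, 2, 5))
  batch <- simulate_batch(fx$raw, specs, replicates = 3, seed = 9)
  expect_length(batch, 1 * 2 * 3)
  tabs <- lapply(batch, `[[`, "annotations")
  expect_gt(length(unique(vapply(tabs, function(t)
    paste(t$source_point, collapse = ","), character(1)))), 1)
  batch2 <- simulate_batch(fx$raw, specs, replicates = 3, seed = 9)
  expect_identical(batch, batch2)

  # callback form streams without keeping tables
  ms <- simulate_batch(fx$raw, specs, replicates = 2, seed = 9,
                       fun = function(site, spec, r, tab) nrow(tab))
  expect_equal(vapply(ms, `[[`, numeric(1), "value"),
               rep(c(2, 3), each = 2) * 2 * 5)
})

test_that("the fast count path reproduces simulate_site draw for draw", {
  fx <- raw_fixture(n_transects = 3, n_quadrats = 6, n_points = 15)
  spec <- design_spec(5, 8, 10)
  for (seed in c(1, 17, 400)) {
    sim <- simulate_site(fx$raw, spec, seed = seed)
    counts <- coralmse:::sim_site_counts(fx$raw, spec, seed = seed)
    tab <- table(sim$transect, factor(sim$label, levels = fx$raw$labels))
    expect_equal(unclass(counts), unclass(tab), ignore_attr = TRUE)
  }
})
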