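test_that("wavelength grid matches the instrument layout", {
  g <- wavelength_grid()
  expect_length(g, 125L)
  expect_equal(g[1], 400)
  expect_equal(g[125], 1000)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(range(diff(g))), 0, tolerance = 1e-12)  # uniform spacing
  expect_equal(diff(g)[1], 600 / 124, tolerance = 1e-12)    # ~4.84 nm
})

test_that("default archetypes are the seven study species, distinct and deterministic", {
  a1 <- default_archetypes()
  a2 <- default_archetypes()
  expect_identical(a1, a2)
  expect_length(a1, 7L)
  expect_setequal(vapply(a1, `[[`, "", "species_name"),
                  c("Medicago sativa", "Medicago ruthenica", "Elymus canadensis",
                    "Hordeum brevisubulatum", "Medicago varia",
                    "Onobrychis viciaefolia", "Bromus ciliatus"))
  # every pair of noise-free spectra differs
  curves <- vapply(a1, archetype_spectrum, numeric(125), phase = "2020-June")
  for (i in 1:6) for (j in (i + 1):7)
    expect_gt(mean(abs(curves[, i] - curves[, j])), 0)
})

test_that("phenology moves every archetype between June and August", {
  for (a in default_archetypes()) {
    jun <- archetype_spectrum(a, "2020-June")
    aug <- archetype_spectrum(a, "2020-August")
    expect_gt(max(abs(jun - aug)), 0.01)
  }
})

test_that("noise-free spectra have vegetation structure", {
  g <- wavelength_grid()
  i550 <- mhcgt:::band_index(g, 550)
  i670 <- mhcgt:::band_index(g, 670)
  i800 <- mhcgt:::band_index(g, 800)
  for (a in default_archetypes()) {
    r <- archetype_spectrum(a, "2021-June", g)
    expect_gt(r[i550], r[i670])  # green peak above the red chlorophyll well
    expect_gt(r[i800], r[i670])  # NIR plateau above the red well
  }
})

test_that("simulate_spectrum is deterministic, bounded, and honors degeneracy", {
  a <- default_archetypes()[[3]]
  s1 <- simulate_spectrum(a, "2020-June", seed = 7)
  s2 <- simulate_spectrum(a, "2020-June", seed = 7)
  expect_identical(s1, s2)
  expect_length(s1, 125L)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # degenerate flat archetype: constant at the continuum level
  flat <- flat_archetype(0.3)
  expect_equal(simulate_spectrum(flat, "2020-June", seed = 1), rep(0.3, 125),
               tolerance = 1e-12)
  expect_error(simulate_spectrum(a, "2019-May"), "2019-May")
})

test_that("generate_dataset honors the 7 x 4 design exactly", {
  ds <- tiny_dataset(1L)
  expect_equal(n_samples(ds), 28L)
  ds3 <- tiny_dataset(3L)
  expect_equal(n_samples(ds3), 84L)
  cells <- table(ds3$labels, mhcgt:::dataset_phases(ds3))
  expect_true(all(cells == 3L))
  expect_true(all(table(ds3$labels) == 12L))
  expect_error(generator_config(samples_per_class_phase = 0), "samples_per_class_phase")
})

test_that("generation is bit-identical from the seed and bounded", {
  d1 <- tiny_dataset(4L, seed = 5L)
  d2 <- tiny_dataset(4L, seed = 5L)
  expect_identical(d1$data, d2$data)
  expect_identical(d1$labels, d2$labels)
  expect_true(min(d1$data) >= 0 && max(d1$data) <= 1)
  d3 <- tiny_dataset(4L, seed = 6L)
  expect_false(identical(d1$data, d3$data))
})

test_that("within-class variance is non-decreasing in the noise level", {
  sigmas <- c(0.005, 0.02, 0.08)
  spread <- vapply(sigmas, function(s) {
    ds <- generate_dataset(generator_config(
      archetypes = default_archetypes(noise_sigma = s),
      samples_per_class_phase = 50L, seed = 31L))
    x <- spectra_matrix(ds)
    mean(vapply(levels(ds$labels), function(l)
      mean(apply(x[ds$labels == l, , drop = FALSE], 2L, stats::var)), 0))
  }, 0)
  expect_true(all(diff(spread) >= 0))
})

test_that("class_overlap shrinks between-class separation", {
  sep <- vapply(c(0, 0.5), function(ov) {
    ds <- generate_dataset(generator_config(samples_per_class_phase = 5L,
                                            seed = 8L, class_overlap = ov))
    x <- spectra_matrix(ds)
    mu <- t(vapply(levels(ds$labels), function(l)
      colMeans(x[ds$labels == l, , drop = FALSE]), numeric(125L)))
    mean(dist(mu))
  }, 0)
  expect_lt(sep[2], sep[1])
})

test_that("dataset container validates and subsets", {
  ds <- tiny_dataset(2L)
  expect_error(spectral_dataset(spectra_matrix(ds), ds$labels[-1], ds$year, ds$month),
               "one entry per sample")
  expect_error(spectral_dataset(spectra_matrix(ds) + 5, ds$labels, ds$year, ds$month),
               "\\[0,1\\]")
  sub <- ds[1:10]
  expect_equal(n_samples(sub), 10L)
  expect_identical(sub$ids, ds$ids[1:10])
})
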