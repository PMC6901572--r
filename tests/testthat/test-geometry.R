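test_that("largest-remainder apportionment reproduces the stage compositions", {
  c1 <- apportion_site_counts(area_ratios(0.30, 0.16, 0.54), 9, 100)
  expect_equal(c1$tsc, 30L)
  expect_equal(c1$vacancy, 16L)
  expect_equal(c1$axon, rep(6L, 9))
  c2 <- apportion_site_counts(area_ratios(1, 0, 0), 9, 50)
  expect_equal(c2$tsc, 50L)
  expect_equal(sum(c2$axon), 0L)
  c3 <- apportion_site_counts(area_ratios(0.57, 0.18, 0.25), 9, 100)
  expect_equal(c3$tsc, 57L)
  expect_equal(c3$vacancy, 18L)
  expect_equal(c3$axon, c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 2L, 2L))
})

test_that("apportionment minimises the total deviation from the quotas", {
  # exhaustive oracle: no integer 3-way split of 100 sites deviates less
  r <- c(0.57, 0.18, 0.25)
  cc <- apportion_site_counts(area_ratios(r), 9, 100)
  ours <- c(cc$tsc, cc$vacancy, sum(cc$axon))
  our_dev <- sum(abs(ours - r * 100))
  best <- Inf
  for (t in 0:100) for (v in 0:(100 - t)) {
    best <- min(best, sum(abs(c(t, v, 100 - t - v) - r * 100)))
  }
  expect_equal(our_dev, best)
  expect_true(all(abs(ours - r * 100) < 1))
})

test_that("apportionment rejects configurations starving axons", {
  expect_error(apportion_site_counts(area_ratios(0.30, 0.16, 0.54), 9, 12),
               "at least one site")
  expect_error(apportion_site_counts(stage_ratios("P0"), 9, 8), "too small")
})

test_that("placement respects the disc and the separation constraint", {
  counts <- apportion_site_counts(stage_ratios("P0"), 9, 100)
  lay <- place_sites(counts, region_diameter = 300, site_diameter = 30,
                     min_separation_factor = 0.8, seed = 1)
  expect_length(lay$occ, 100)
  d <- as.matrix(dist(cbind(lay$x, lay$y)))
  diag(d) <- Inf
  expect_gte(min(d), 0.8 * 30)
  expect_lte(max(sqrt(lay$x^2 + lay$y^2)), 135 + 1e-9)
  # composition preserved by the occupant shuffle
  expect_equal(sort(lay$occ), sort(nmjelim:::counts_to_occ(counts)))
})

test_that("placement is seed-reproducible and seed-sensitive", {
  counts <- apportion_site_counts(stage_ratios("P0"), 9, 40)
  a <- place_sites(counts, seed = 5)
  b <- place_sites(counts, seed = 5)
  c <- place_sites(counts, seed = 6)
  expect_identical(a[c("x", "y", "occ")], b[c("x", "y", "occ")])
  expect_false(identical(a$occ, c$occ) && identical(a$x, c$x))
})

test_that("degenerate and impossible placements behave as specified", {
  one <- structure(list(tsc = 1L, vacancy = 0L, axon = 0L),
                   class = "nmj_counts")
  lay1 <- place_sites(one, seed = 2)
  expect_length(lay1$occ, 1)
  expect_identical(lay1$adjacency[[1]], integer(0))
  many <- structure(list(tsc = 500L, vacancy = 0L, axon = 0L),
                    class = "nmj_counts")
  expect_error(place_sites(many, region_diameter = 300, site_diameter = 30,
                           seed = 3), "geometry error")
})

test_that("adjacency equals the brute-force threshold oracle", {
  lay <- manual_layout(x = c(0, 30, 90), y = c(0, 0, 0), occ = c(1, 0, -1),
                       neighbor_distance = 37.5)
  expect_identical(lay$adjacency, list(2L, 1L, integer(0)))
  rand <- small_layout(seed = 1, n_sites = 100)
  oracle <- adjacency_oracle(rand)
  expect_equal(lapply(rand$adjacency, as.integer), oracle)
  # symmetric and irreflexive
  for (i in seq_along(oracle)) {
    expect_false(i %in% oracle[[i]])
    for (j in oracle[[i]]) expect_true(i %in% oracle[[j]])
  }
})

test_that("layout ratios round-trip through apportionment", {
  lay <- small_layout(seed = 3, n_sites = 100,
                      ratios = area_ratios(0.57, 0.18, 0.25))
  lr <- layout_ratios(lay)
  expect_equal(as.numeric(lr$ratios), c(0.57, 0.18, 0.25))
  expect_equal(sum(lr$axon_fractions), 0.25)
  # per-category deviation below one site
  lay2 <- small_layout(seed = 4, n_sites = 30)
  lr2 <- layout_ratios(lay2)
  expect_true(all(abs(as.numeric(lr2$ratios) -
                        as.numeric(stage_ratios("P0"))) < 1 / 30))
  expect_error(layout_ratios(integer(0)), "empty")
})

test_that("layout snapshots round-trip through JSON", {
  lay <- small_layout(seed = 9, n_sites = 25)
  path <- tempfile(fileext = ".json")
  write_layout(lay, path)
  back <- read_layout(path)
  expect_equal(back$x, lay$x)
  expect_equal(back$y, lay$y)
  expect_identical(back$occ, lay$occ)
  expect_equal(back$adjacency, lay$adjacency)
  expect_equal(back$region_diameter, lay$region_diameter)
  unlink(path)
})
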