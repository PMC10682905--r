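test_that("layer generation is seed-deterministic and seed-sensitive", {
  g <- tiny_geom(10, 10)
  a <- make_env_layers(7, g, n_vars = 3)
  b <- make_env_layers(7, g, n_vars = 3)
  c <- make_env_layers(8, g, n_vars = 3)
  expect_identical(a$layers[[1]]$values, b$layers[[1]]$values)
  expect_false(identical(a$layers[[1]]$values, c$layers[[1]]$values))
})

test_that("cross-layer correlations track the target", {
  g <- grid_geometry(100, 100, -110, 25, 0.05)
  # identity target: uncorrelated layers
  st <- make_env_layers(3, g, n_vars = 2, correlation = diag(2))
  r <- cor(as.vector(st$layers[[1]]$values), as.vector(st$layers[[2]]$values))
  expect_lt(abs(r), 0.1)
  # strong positive target
  tgt <- matrix(c(1, 0.7, 0.7, 1), 2)
  st2 <- make_env_layers(4, g, n_vars = 2, correlation = tgt,
                         var_names = c("bio9", "bio5"))
  r2 <- cor(as.vector(st2$layers[[1]]$values), as.vector(st2$layers[[2]]$values))
  expect_lt(abs(r2 - 0.7), 0.1)
  expect_error(make_env_layers(1, g, 2, matrix(c(1, 2, 2, 1), 2)),
               class = "nichegrad_input_error")
})

test_that("the paper-scale default emits 9 bioclim-like layers", {
  st <- make_env_layers(1, tiny_geom(8, 8))
  expect_length(st$layers, 9)
  expect_setequal(stack_names(st),
                  c("bio2", "bio3", "bio4", "bio5", "bio9",
                    "bio14", "bio15", "bio18", "bio19"))
  kinds <- attr(st, "var_kinds")
  expect_equal(unname(kinds[c("bio9", "bio18", "bio15")]),
               c("temperature", "precipitation", "other"))
})

test_that("occurrence sampling follows the true suitability surface", {
  st <- tiny_stack(11, nr = 20, nc = 20)
  # huge breadth -> uniform density over valid cells (chi-square on quadrats)
  flat <- niche_spec("wild",
                     c(bio9 = 20, bio18 = 120, bio15 = 70),
                     c(bio9 = 1e6, bio18 = 1e6, bio15 = 1e6))
  occ <- sample_occurrences(5, st, flat, 2000)
  loc <- locate_cells(st$geometry, occ$lon, occ$lat)
  quad <- table(factor((loc$row - 1) %/% 5, 0:3),
                factor((loc$col - 1) %/% 5, 0:3))
  pval <- chisq.test(as.vector(quad))$p.value
  expect_gt(pval, 0.01)

  # frequency/suitability consistency at n = 5000 on a 50x50 grid (landrace:
  # its narrower niche gives enough suitability contrast for the check to be
  # informative against per-cell Poisson noise)
  st2 <- make_env_layers(12, grid_geometry(50, 50, -110, 25, 0.05), n_vars = 3,
                         var_names = c("bio9", "bio18", "bio15"))
  niche <- default_niches()$landrace
  occ2 <- sample_occurrences(6, st2, niche, 5000)
  loc2 <- locate_cells(st2$geometry, occ2$lon, occ2$lat)
  cell <- (loc2$col - 1) * 50 + loc2$row
  counts <- tabulate(cell, nbins = 2500)
  s <- true_suitability(st2, niche)$values
  expect_gt(cor(counts, as.vector(s)), 0.9)

  expect_error(sample_occurrences(1, st, flat, 0),
               class = "nichegrad_input_error")
})

test_that("nested design: landrace points fall inside the wild environmental hull", {
  st <- tiny_stack(13, nr = 25, nc = 25)
  niches <- default_niches()
  inside <- vapply(1:100, function(seed) {
    w <- extract_env(sample_occurrences(seed, st, niches$wild, 80), st)
    l <- extract_env(sample_occurrences(seed + 1000, st, niches$landrace, 40), st)
    hull <- convex_hull(cbind(w$bio9, w$bio18))
    mean(point_in_polygon(l$bio9, l$bio18, hull, tol = 1e-9))
  }, numeric(1))
  expect_gte(mean(inside >= 0.95), 0.95)
})

test_that("polygon proxies fall strictly inside their rings", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  pts <- make_polygon_proxies(3, list(sq), 100)
  expect_equal(nrow(pts), 100)
  expect_true(all(pts$lon > 0 & pts$lon < 1 & pts$lat > 0 & pts$lat < 1))
  expect_lt(abs(mean(pts$lon) - 0.5), 0.05)
  expect_lt(abs(mean(pts$lat) - 0.5), 0.05)

  sq2 <- cbind(c(3, 4, 4, 3), c(3, 3, 4, 4))
  two <- make_polygon_proxies(4, list(sq, sq2), 50)
  expect_equal(nrow(two), 100)
  expect_equal(sum(two$lon < 2), 50)
  expect_equal(sum(two$lon > 2), 50)

  expect_equal(nrow(make_polygon_proxies(1, list(sq), 0)), 0)
  degen <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(make_polygon_proxies(1, list(degen), 5),
               class = "nichegrad_input_error")
  # determinism
  expect_identical(make_polygon_proxies(9, list(sq), 20)$lon,
                   make_polygon_proxies(9, list(sq), 20)$lon)
})

test_that("scenario deltas transform layers as declared", {
  st <- tiny_stack(21, nr = 8, nc = 8)
  kinds <- default_var_kinds(stack_names(st))
  ident <- scenario_delta("g", 2050, "ssp245", 0, 1, 0)
  out <- make_future_stack(st, ident, kinds, seed = 1)
  expect_identical(out$layers[["bio9"]]$values, st$layers[["bio9"]]$values)

  g <- grid_geometry(4, 4, 0, 4, 1)
  const <- env_stack(list(env_layer("bio9", g, matrix(20, 4, 4))))
  warm <- make_future_stack(const, scenario_delta("g", 2070, "ssp585", 2, 1, 0),
                            c(bio9 = "temperature"), seed = 1)
  expect_equal(unique(as.vector(warm$layers[[1]]$values)), 22)

  wet <- make_future_stack(const, scenario_delta("g", 2070, "ssp585", 0, 1.5, 0),
                           c(bio9 = "precipitation"), seed = 1)
  expect_equal(unique(as.vector(wet$layers[[1]]$values)), 30)

  expect_error(make_future_stack(const, ident, c(other_var = "other"), 1),
               class = "nichegrad_input_error")
  expect_error(scenario_delta("g", 2050, "ssp245", precip_scale = 0),
               class = "nichegrad_input_error")
})

test_that("the default suite has 8 pseudo-GCMs per period-pathway", {
  st <- tiny_stack(22, nr = 6, nc = 6)
  suite <- make_scenario_suite(st, seed = 2, noise_sd = 0)
  expect_equal(nrow(suite$meta), 3 * 2 * 8)
  expect_length(suite$stacks, 48)
  expect_equal(length(unique(suite$meta$gcm)), 8)
  # warming grows with period within a pathway for each GCM
  m <- suite$meta[suite$meta$gcm == "gcm01" & suite$meta$pathway == "ssp585", ]
  expect_false(is.unsorted(m$temp_shift[order(m$period)]))
  # determinism
  suite2 <- make_scenario_suite(st, seed = 2, noise_sd = 0)
  expect_identical(suite$stacks[[1]]$layers[[1]]$values,
                   suite2$stacks[[1]]$layers[[1]]$values)
})
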