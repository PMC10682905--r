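test_that("thinning matches haversine oracles on hand-placed points", {
  # two points ~3 km apart (latitude offset): second dropped at 5 km
  d3 <- 3 / 111.19492  # degrees of latitude for ~3 km
  pts <- make_occ(c(0, 0), c(10, 10 + d3))
  expect_lt(abs(oracle_haversine(0, 10, 0, 10 + d3) - 3), 0.01)
  out <- thin(pts, 5)
  expect_equal(out$id, "wild_1")

  # three collinear points at 0, 4, 8 km: first and third kept
  d4 <- 4 / 111.19492
  pts3 <- make_occ(c(0, 0, 0), c(10, 10 + d4, 10 + 2 * d4))
  out3 <- thin(pts3, 5)
  expect_equal(out3$id, c("wild_1", "wild_3"))
  expect_gte(oracle_haversine(0, 10, 0, 10 + 2 * d4), 5)

  expect_identical(thin(pts3, 0), pts3)
  expect_equal(nrow(thin(pts3[0, ], 5)), 0)
})

test_that("thinning enforces the distance bound and is idempotent", {
  set.seed(31)
  for (k in 1:5) {
    pts <- make_occ(runif(60, -100, -99.5), runif(60, 19, 19.5))
    th <- thin(pts, 5)
    d <- as.matrix(stats::dist(cbind(th$lon, th$lat)))  # quick prefilter
    for (i in seq_len(nrow(th))) for (j in seq_len(nrow(th))) {
      if (i < j) {
        expect_gte(oracle_haversine(th$lon[i], th$lat[i],
                                    th$lon[j], th$lat[j]), 5)
      }
    }
    expect_identical(thin(th, 5), th)
    expect_true(all(th$id %in% pts$id))
  }
})

test_that("extraction uses cell centers with the half-open boundary rule", {
  g <- grid_geometry(3, 3, 0, 3, 1)
  const <- env_stack(list(env_layer("v", g, matrix(7, 3, 3))))
  at_center <- make_occ(0.5, 2.5)
  expect_equal(extract_env(at_center, const)$v, 7)

  vals <- matrix(1:9, 3, 3)  # column-major: cell (row, col) = row + 3(col-1)
  st <- env_stack(list(env_layer("v", g, vals)))
  # boundary x = 1 belongs to the right cell (x in [left, right));
  # boundary y = 2 belongs to the cell above (cell spans y in [bottom, top))
  b <- make_occ(c(1, 0.5, 1, 3 - 1e-12), c(2.5, 2, 2, 0.5))
  got <- extract_env(b, st)
  oracle_cell <- function(x, y) {
    col <- floor(x) + 1
    row <- if (y == 3) 1 else ceiling(3 - y)
    vals[row, col]
  }
  expect_equal(got$v, mapply(oracle_cell, b$lon, b$lat))

  off <- make_occ(c(0.5, 5), c(2.5, 2.5))
  expect_message(res <- extract_env(off, st), "excluded 1")
  expect_equal(nrow(res), 1)
  expect_equal(attr(res, "n_excluded"), 1)
})

test_that("extraction agrees with brute-force nearest-center lookup", {
  st <- tiny_stack(17, nr = 9, nc = 11)
  g <- st$geometry
  set.seed(5)
  pts <- make_occ(runif(40, g$x_origin, g$x_origin + g$n_cols * g$cell_size - 1e-9),
                  runif(40, g$y_origin - g$n_rows * g$cell_size + 1e-9, g$y_origin))
  got <- extract_env(pts, st)
  cc <- cell_centers(g)
  for (k in seq_len(nrow(got))) {
    i <- which.min(abs(cc$y - got$lat[k]))
    j <- which.min(abs(cc$x - got$lon[k]))
    expect_equal(got$bio9[k], st$layers[["bio9"]]$values[i, j])
  }
})

test_that("correlation filter removes collinear variables, not independent ones", {
  set.seed(8)
  a <- rnorm(200)
  x <- cbind(A = a, B = a + rnorm(200, sd = 1e-8), C = rnorm(200))
  kept <- correlation_filter(x, 0.8)
  expect_length(intersect(kept, c("A", "B")), 1)
  expect_true("C" %in% kept)
  # matches the exhaustive maximal-subset oracle size
  brute_best <- 0
  r <- abs(cor(x))
  for (sz in 3:1) {
    combs <- combn(colnames(x), sz, simplify = FALSE)
    ok <- Filter(function(s) all(r[s, s][upper.tri(diag(length(s)))] <= 0.8),
                 combs)
    if (length(ok)) { brute_best <- sz; break }
  }
  expect_equal(length(kept), brute_best)

  # identity when nothing exceeds the threshold
  y <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("p", "q", "s")))
  expect_equal(correlation_filter(y, 0.99), c("p", "q", "s"))
  # keep-list overrides the drop rule
  expect_true("B" %in% correlation_filter(x, 0.8, keep = "B"))
  # constant variable excluded with a warning
  expect_warning(kc <- correlation_filter(cbind(x, K = rep(1, 200)), 0.8),
                 "constant")
  expect_false("K" %in% kc)
})

test_that("train/test splits are sized, disjoint, exhaustive and seeded", {
  pts <- make_occ(runif(10), runif(10))
  sp <- split_train_test(pts, 0.3, seed = 4)
  expect_equal(nrow(sp$test), 3)
  expect_equal(nrow(sp$train), 7)
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  expect_setequal(c(sp$train$id, sp$test$id), pts$id)
  sp2 <- split_train_test(pts, 0.3, seed = 4)
  expect_identical(sp$test$id, sp2$test$id)
  expect_equal(nrow(split_train_test(pts, 0, seed = 1)$test), 0)
  expect_error(split_train_test(pts, 1, seed = 1),
               class = "nichegrad_input_error")
})

test_that("broad classes derive from fine classes by union", {
  pts <- occurrence_set(data.frame(
    id = as.character(1:6), lon = 1:6, lat = 1:6,
    class = c("wild", "semiwild", "landrace", "commercial",
              "cultivated_unassigned", "wild"),
    source = "t", stringsAsFactors = FALSE))
  expect_equal(nrow(as_broad_class(pts, "wild_sl")), 3)
  expect_equal(nrow(as_broad_class(pts, "cultivated")), 3)
  expect_true(all(as_broad_class(pts, "cultivated")$class == "cultivated"))
})

test_that("occurrence CSV round-trips with extracted environment", {
  st <- tiny_stack(3, nr = 6, nc = 6)
  occ <- extract_env(sample_occurrences(2, st, default_niches()$wild, 20), st)
  p <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, p)
  back <- read_occurrences(p)
  expect_equal(env_vars(back), env_vars(occ))
  expect_equal(back$bio9, occ$bio9)
  expect_equal(back$lon, occ$lon)
})
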