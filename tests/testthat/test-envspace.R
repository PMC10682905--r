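test_that("standardized PCA behaves on degenerate and isotropic inputs", {
  set.seed(2)
  a <- rnorm(50)
  two <- cbind(x = a, y = 2 * a + 3)  # r = 1
  p <- run_pca(two)
  expect_equal(p$explained_var_fraction[1], 1, tolerance = 1e-9)

  iso <- matrix(rnorm(20000), 10000, 2, dimnames = list(NULL, c("u", "v")))
  pi2 <- run_pca(iso)
  expect_equal(pi2$explained_var_fraction, c(0.5, 0.5), tolerance = 0.02)

  expect_error(run_pca(cbind(x = a, k = rep(1, 50))),
               class = "nichegrad_input_error")
  expect_error(run_pca(two[1:2, ]), class = "nichegrad_input_error")
})

test_that("scores have diagonal covariance with eigenvalue entries", {
  set.seed(3)
  x <- matrix(rnorm(600), 200, 3) %*% matrix(c(1, .5, 0, 0, 1, .3, 0, 0, 1), 3)
  colnames(x) <- c("a", "b", "c")
  p <- run_pca(x)
  cv <- cov(p$scores)
  ev <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(diag(cv), ev, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # sign convention: largest-magnitude loading entry positive
  for (k in 1:3) {
    l <- p$loadings[, k]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # explained fractions non-increasing and summing to 1
  expect_false(is.unsorted(rev(p$explained_var_fraction)))
  expect_equal(sum(p$explained_var_fraction), 1)
})

test_that("convex hulls match the gift-wrapping oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5), c(0.2, 0.8))
  h <- convex_hull(sq)
  expect_equal(nrow(h), 4)
  expect_equal(polygon_area(h), 1)
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(polygon_area(convex_hull(tri)), 2)
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(rnorm(200), 100, 2)
    h2 <- convex_hull(pts)
    o <- oracle_hull(pts)
    expect_equal(abs(polygon_area(h2)), abs(oracle_shoelace(o)),
                 tolerance = 1e-12)
    expect_setequal(apply(h2, 1, paste, collapse = ","),
                    apply(o, 1, paste, collapse = ","))
    expect_true(all(point_in_polygon(pts[, 1], pts[, 2], h2, tol = 1e-9)))
    expect_gt(polygon_area(h2), 0)  # counter-clockwise
  }
  expect_error(convex_hull(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "nichegrad_input_error")
})

test_that("hull overlap reproduces hand geometry and containment", {
  sqa <- convex_hull(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  ident <- hull_overlap(sqa, sqa, sqa, sqa)
  expect_equal(ident$frac_a, 1)
  expect_equal(ident$frac_b, 1)
  expect_equal(ident$frac_union, 1)
  expect_equal(ident$points_in_overlap_a, 1)

  sqb <- convex_hull(rbind(c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.5), c(0.5, 1.5)))
  off <- hull_overlap(sqa, sqb)
  expect_equal(off$area_intersection, 0.25, tolerance = 1e-12)
  expect_equal(off$frac_a, 0.25)
  expect_equal(off$frac_b, 0.25)
  expect_equal(off$frac_union, 0.25 / 1.75)

  inner <- convex_hull(rbind(c(0.3, 0.3), c(0.7, 0.3), c(0.7, 0.7), c(0.3, 0.7)))
  nest <- hull_overlap(sqa, inner, NULL, inner)
  expect_equal(nest$frac_b, 1, tolerance = 1e-12)
  expect_equal(nest$points_in_overlap_b, 1)

  far <- convex_hull(rbind(c(5, 5), c(6, 5), c(6, 6), c(5, 6)))
  disj <- hull_overlap(sqa, far)
  expect_equal(disj$area_intersection, 0)
  expect_equal(disj$frac_union, 0)
})

test_that("hull overlap is symmetric under argument swap", {
  for (seed in 1:4) {
    set.seed(seed)
    pa <- matrix(rnorm(60), 30, 2)
    pb <- matrix(rnorm(60, mean = 0.8), 30, 2)
    ha <- convex_hull(pa); hb <- convex_hull(pb)
    ab <- hull_overlap(ha, hb, pa, pb)
    ba <- hull_overlap(hb, ha, pb, pa)
    expect_equal(ab$area_intersection, ba$area_intersection, tolerance = 1e-9)
    expect_equal(ab$frac_a, ba$frac_b)
    expect_equal(ab$points_in_overlap_a, ba$points_in_overlap_b)
    expect_lte(ab$frac_union, min(ab$frac_a, ab$frac_b) + 1e-12)
    expect_lte(ab$area_intersection, min(ab$area_a, ab$area_b) + 1e-12)
  }
})

test_that("bootstrap CI defaults, degenerate input and determinism", {
  const <- rep(3.2, 10)
  ci <- bootstrap_ci(const, seed = 1)
  expect_equal(ci$ci_low, 3.2)
  expect_equal(ci$ci_high, 3.2)
  expect_equal(ci$estimate, 3.2)
  expect_equal(ci$n_boot, 1000)

  x <- rnorm(50)
  c1 <- bootstrap_ci(x, "median", seed = 9)
  c2 <- bootstrap_ci(x, "median", seed = 9)
  expect_identical(c1$ci_low, c2$ci_low)
  expect_lte(c1$ci_low, c1$estimate)
  expect_gte(c1$ci_high, c1$estimate)
  expect_error(bootstrap_ci(1), class = "nichegrad_input_error")
})

test_that("letter groups share letters exactly when intervals overlap", {
  mk <- function(lo, hi) list(estimate = (lo + hi) / 2, ci_low = lo, ci_high = hi)
  g1 <- ci_letter_groups(list(a = mk(0, 1), b = mk(2, 3)))
  expect_equal(unname(g1), c("a", "b"))
  g2 <- ci_letter_groups(list(x = mk(0, 2), y = mk(1, 3), z = mk(2.5, 4)))
  expect_equal(unname(g2), c("a", "ab", "b"))
  g3 <- ci_letter_groups(list(p = mk(1, 2), q = mk(1, 2), r = mk(1, 2)))
  expect_equal(unname(g3), c("a", "a", "a"))

  # property: shared letter iff intervals overlap (interval-graph oracle)
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    lo <- runif(n, 0, 10); hi <- lo + runif(n, 0.1, 4)
    cis <- lapply(seq_len(n), function(i) mk(lo[i], hi[i]))
    names(cis) <- letters[seq_len(n)]
    lab <- ci_letter_groups(cis)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      overlaps <- lo[i] <= hi[j] && lo[j] <= hi[i]
      shares <- length(intersect(strsplit(lab[i], "")[[1]],
                                 strsplit(lab[j], "")[[1]])) > 0
      expect_equal(shares, overlaps,
                   label = sprintf("rep %d pair %d-%d", rep, i, j))
    }
  }
})
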