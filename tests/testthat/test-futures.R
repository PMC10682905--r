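test_that("binarize implements the order-statistic threshold exactly", {
  m <- as_suit_map(matrix(seq(0.05, 1, length.out = 20), 4, 5))
  scores <- seq(0.1, 1, by = 0.1)
  b <- binarize(m, scores, percentile = 10)
  expect_equal(b$threshold_value, 0.2)  # k = floor(0.1*10)+1 = 2nd smallest
  expect_equal(sum(scores < b$threshold_value), 1)
  b0 <- binarize(m, scores, percentile = 0)
  expect_equal(b0$threshold_value, 0.1)
  expect_equal(sum(scores < b0$threshold_value), 0)
  # constant suitability above threshold: every valid cell retained
  const <- as_suit_map(matrix(0.9, 3, 3))
  expect_true(all(binarize(const, scores, 10)$mask))
  expect_error(binarize(m, numeric(0)), class = "nichegrad_input_error")
})

test_that("change metrics satisfy the conservation identities", {
  pres <- as_binary_map(matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  fut <- as_binary_map(matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
  cm <- change_metrics(pres, fut)
  expect_equal(cm$n_lost, 1)
  expect_equal(cm$n_retained, 1)
  expect_equal(cm$n_gained, 1)
  same <- change_metrics(pres, pres)
  expect_equal(same$n_lost, 0)
  expect_equal(same$n_gained, 0)
  empty <- change_metrics(pres, as_binary_map(matrix(FALSE, 2, 2)))
  expect_equal(empty$frac_lost, 1)
  set.seed(61)
  for (k in 1:50) {
    a <- as_binary_map(matrix(runif(48) < 0.5, 6, 8))
    b <- as_binary_map(matrix(runif(48) < 0.5, 6, 8))
    cm <- change_metrics(a, b)
    expect_equal(cm$n_present, cm$n_retained + cm$n_lost)
    expect_equal(cm$n_future, cm$n_retained + cm$n_gained)
  }
  off <- as_binary_map(matrix(TRUE, 3, 3))
  expect_error(change_metrics(pres, off), class = "nichegrad_input_error")
})

test_that("GCM intersection and union behave as set operations", {
  set.seed(62)
  maps <- lapply(1:5, function(k) as_binary_map(matrix(runif(40) < 0.6, 5, 8)))
  inter <- gcm_intersection(maps)
  uni <- gcm_union(maps)
  expect_identical(inter$mask, Reduce(`&`, lapply(maps, `[[`, "mask")))
  expect_identical(uni$mask, Reduce(`|`, lapply(maps, `[[`, "mask")))
  expect_identical(gcm_intersection(maps[1])$mask, maps[[1]]$mask)
  allfalse <- as_binary_map(matrix(FALSE, 5, 8))
  expect_equal(sum(gcm_intersection(c(maps, list(allfalse)))$mask), 0)
  # non-increasing as maps accumulate
  sizes <- vapply(seq_along(maps), function(k)
    sum(gcm_intersection(maps[seq_len(k)])$mask), numeric(1))
  expect_false(is.unsorted(rev(sizes)))
  expect_lte(sum(inter$mask), min(vapply(maps, function(m) sum(m$mask), 0)))
})

test_that("class overlap change reports intersection-over-union percents", {
  a <- as_binary_map(matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3))
  b <- as_binary_map(matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), 2, 3))
  # |A| = |B| = 3, shared = 1, union = 5 -> 20%
  ch <- class_overlap_change(a, a, b, b)
  expect_equal(ch$pct_overlap_present, 20)
  ident <- class_overlap_change(a, a, a, a)
  expect_equal(ident$pct_overlap_present, 100)
  disj <- as_binary_map(matrix(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), 2, 3))
  expect_equal(class_overlap_change(a, a, disj, disj)$pct_overlap_present, 0)
  # overlap lost when the future maps vanish
  none <- as_binary_map(matrix(FALSE, 2, 3))
  lost <- class_overlap_change(a, none, b, none)
  expect_equal(lost$n_overlap_lost, 1)
})

test_that("MESS reproduces the hand-worked similarity values", {
  train <- matrix(c(2, 4, 6, 8, 10), 5, 1, dimnames = list(NULL, "v"))
  g <- grid_geometry(1, 3, 0, 1, 1)
  proj <- env_stack(list(env_layer("v", g, matrix(c(6, 1, 6), 1, 3))))
  mm <- mess(proj, train)
  # p = 6: f = 40 (2 of 5 strictly below), similarity = 2f = 80
  expect_equal(mm$values$values[1, 1], 80)
  # p = 1 < min: (1-2)/(10-2)*100 = -12.5
  expect_equal(mm$values$values[1, 2], -12.5)
  expect_equal(mm$most_dissimilar_var[1, 2], "v")
  # f = 50 is the formula peak: train {1,2,3,4}, p = 2.5 -> similarity 100
  train2 <- matrix(1:4, 4, 1, dimnames = list(NULL, "v"))
  proj2 <- env_stack(list(env_layer("v", g, matrix(2.5, 1, 3))))
  mm2 <- mess(proj2, train2)
  expect_equal(mm2$values$values[1, 1], 100)
})

test_that("MESS negativity is exactly the out-of-training-range condition", {
  set.seed(63)
  for (k in 1:20) {
    nvar <- sample(2:4, 1)
    train <- matrix(rnorm(20 * nvar), 20, nvar,
                    dimnames = list(NULL, paste0("v", 1:nvar)))
    g <- grid_geometry(5, 5, 0, 5, 1)
    layers <- lapply(seq_len(nvar), function(j)
      env_layer(paste0("v", j), g, matrix(rnorm(25, sd = 2), 5, 5)))
    proj <- env_stack(layers)
    mm <- mess(proj, train)
    brute_out <- matrix(FALSE, 5, 5)
    for (j in seq_len(nvar)) {
      rng <- range(train[, j])
      v <- layers[[j]]$values
      brute_out <- brute_out | v < rng[1] | v > rng[2]
    }
    expect_identical(mm$values$values < 0, brute_out)
  }
})

test_that("MESS flags constant training variables", {
  train <- matrix(c(rep(5, 10), rnorm(10)), 10, 2,
                  dimnames = list(NULL, c("k", "v")))
  g <- grid_geometry(1, 2, 0, 1, 1)
  proj <- env_stack(list(env_layer("k", g, matrix(c(5, 6), 1, 2)),
                         env_layer("v", g, matrix(c(0, 0), 1, 2))))
  expect_warning(mm <- mess(proj, train), "constant")
  # p == constant -> 0 contribution from k; p != constant -> negative
  expect_lte(mm$values$values[1, 1], 0)
  expect_lt(mm$values$values[1, 2], 0)
})

test_that("scenario summary bookkeeping: rows, zero-delta identity", {
  st <- tiny_stack(71, nr = 12, nc = 12)
  occ <- extract_env(sample_occurrences(6, st, default_niches()$wild, 70), st)
  bg <- sample_background(st, 144, 5)
  fs <- build_features(bg, "L")
  mod <- fit_maxent(env_matrix(occ), bg, fs, reg_multiplier = 1, max_iter = 120)
  map <- predict_logistic(mod, st)
  pres_bin <- binarize(map, suitability_at_points(map, occ), 10)

  # zero-delta pseudo-GCMs: future identical to present, no loss anywhere
  suite0 <- make_scenario_suite(st, seed = 3, n_gcms = 2, noise_sd = 0)
  for (i in seq_along(suite0$stacks)) {
    suite0$stacks[[i]] <- st  # identity scenarios
  }
  summ0 <- scenario_summary(suite0, list(wild = mod), list(wild = pres_bin))
  expect_true(all(summ0$frac_lost == 0))
  expect_true(all(summ0$frac_gained == 0))
  # rows: 3 periods x 2 pathways x (2 GCMs + ALL)
  expect_equal(nrow(summ0), 3 * 2 * 3)
  expect_equal(sum(summ0$gcm == "ALL"), 6)
  # a missing scenario is listed absent, not an error
  suite0$stacks[[1]] <- NULL
  summ1 <- scenario_summary(suite0, list(wild = mod), list(wild = pres_bin))
  expect_equal(sum(summ1$absent), 1)
})
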