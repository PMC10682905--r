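bg3 <- function(n = 400, seed = 1, k = 3) {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k)
  colnames(m) <- paste0("v", seq_len(k))
  m
}

test_that("feature counts follow the combinatorics of LQHP", {
  b <- bg3(100, 1, 1)
  expect_equal(nrow(build_features(b, "L")$defs), 1)
  b3 <- bg3(100, 2, 3)
  expect_equal(nrow(build_features(b3, c("L", "Q", "P"))$defs), 3 + 3 + 3)
  b2 <- bg3(100, 3, 2)
  h <- build_features(b2, "H", hinge_knots_per_var = 5)
  expect_equal(nrow(h$defs), 2 * 5 * 2)
  # all features land in [0,1] on the training background
  fs <- build_features(b3, c("L", "Q", "H", "P"), 7)
  F <- evaluate_features(fs, b3)
  expect_gte(min(F), 0)
  expect_lte(max(F), 1)
  # hinge features come in forward/reverse pairs per knot
  expect_equal(sum(fs$defs$kind == "hinge_fwd"), sum(fs$defs$kind == "hinge_rev"))
  # constant variable: Q/H features dropped with a warning
  bc <- cbind(b2, const = 1)
  expect_warning(fc <- build_features(bc, c("L", "Q")), "constant")
  expect_equal(sum(fc$defs$var1 == "const" & fc$defs$kind == "quadratic"), 0)
})

test_that("a single-feature Gibbs tilt is recovered (lambda = 2)", {
  set.seed(101)
  bg <- matrix(runif(5000, -2, 2), ncol = 1, dimnames = list(NULL, "v1"))
  fs <- build_features(bg, "L")
  f_bg <- as.vector(evaluate_features(fs, bg))
  m <- 5000
  pick <- sample(nrow(bg), m, replace = TRUE, prob = exp(2 * f_bg))
  pres <- bg[pick, , drop = FALSE]
  mod <- fit_maxent(pres, bg, fs, reg_multiplier = 1e-6, max_iter = 500,
                    add_presence_to_background = FALSE)
  expect_lt(abs(mod$lambdas[1] - 2), 0.15)
  # independent oracle: grid-search MLE over lambda
  f_p <- as.vector(evaluate_features(fs, pres))
  grid <- seq(1, 3, by = 0.001)
  ll <- vapply(grid, function(l) mean(l * f_p) -
                 log(sum(exp(l * f_bg))), numeric(1))
  l_star <- grid[which.max(ll)]
  expect_lt(abs(l_star - 2), 0.15)
  expect_lt(abs(mod$lambdas[1] - l_star), 0.02)
})

test_that("full shrinkage gives the uniform model and logistic 0.5", {
  b <- bg3(300, 4, 2)
  set.seed(4)
  pres <- b[sample(300, 50), , drop = FALSE]
  fs <- build_features(b, c("L", "Q"))
  mod <- fit_maxent(pres, b, fs, reg_multiplier = 1e6)
  expect_true(all(mod$lambdas == 0))
  expect_equal(mod$entropy, log(mod$n_background), tolerance = 1e-6)
  sc <- predict_scores(mod, b)
  expect_equal(unique(round(sc$logistic, 12)), 0.5)
})

test_that("raw distribution sums to one and the objective ascends", {
  st <- tiny_stack(31, nr = 15, nc = 15)
  occ <- extract_env(sample_occurrences(3, st, default_niches()$wild, 120), st)
  bg <- sample_background(st, 200, 2)
  fs <- build_features(bg, c("L", "Q"))
  mod <- fit_maxent(env_matrix(occ), bg, fs, reg_multiplier = 1, max_iter = 300)
  # q reconstructed from stored lambdas and log Z must sum to 1
  train <- rbind(bg, env_matrix(occ)[, colnames(bg)])
  eta <- evaluate_features(fs, train) %*% mod$lambdas
  expect_lt(abs(sum(exp(eta - mod$log_z)) - 1), 1e-8)
  expect_false(is.unsorted(mod$objective_trace))
  expect_gte(mod$entropy, 0)
  # errors
  expect_error(fit_maxent(env_matrix(occ)[0, ], bg, fs),
               class = "nichegrad_input_error")
  bad <- env_matrix(occ); bad[1, 1] <- NaN
  expect_error(fit_maxent(bad, bg, fs), class = "nichegrad_input_error")
})

test_that("logistic projection matches a hand evaluation and clamps", {
  b <- bg3(200, 7, 2)
  set.seed(7)
  pres <- b[sample(200, 40), , drop = FALSE]
  fs <- build_features(b, "L")
  mod <- fit_maxent(pres, b, fs, reg_multiplier = 1)
  z <- b[5, , drop = FALSE]
  hand_f <- (z[, fs$vars] - fs$f_min) / (fs$f_max - fs$f_min)
  hand_raw <- exp(sum(mod$lambdas * hand_f) - mod$log_z)
  hand_logistic <- hand_raw * exp(mod$entropy) / (1 + hand_raw * exp(mod$entropy))
  expect_equal(predict_scores(mod, z)$logistic, hand_logistic,
               tolerance = 1e-12)

  beyond <- z; beyond[, 1] <- mod$clamp_max[1] + 10
  at_max <- z; at_max[, 1] <- mod$clamp_max[1]
  pb <- predict_scores(mod, beyond, clamp = TRUE)
  expect_equal(pb$logistic, predict_scores(mod, at_max)$logistic)
  expect_true(pb$clamped)
  expect_error(predict_scores(mod, z[, 1, drop = FALSE]),
               class = "nichegrad_input_error")
})

test_that("AUC equals brute-force pairwise counting", {
  expect_equal(auc(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(auc(rep(0.5, 4), rep(0.5, 6)), 0.5)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(15)
  for (k in 1:5) {
    p <- round(runif(sample(5:100, 1)), 2)  # rounding forces ties
    b <- round(runif(sample(5:100, 1)), 2)
    expect_equal(auc(p, b), oracle_auc(p, b))
  }
  expect_error(auc(numeric(0), 1), class = "nichegrad_input_error")
})

test_that("TSS matches hand counts and limiting thresholds", {
  perfect <- tss(c(0.9, 0.8), c(0.2, 0.1), 0.5)
  expect_equal(perfect$tss, 1)
  expect_equal(tss(c(0.9, 0.8), c(0.2, 0.1), 0)$tss, 0)  # sens 1, spec 0
  hand <- tss(c(0.8, 0.6, 0.2), c(0.7, 0.3, 0.1), 0.5)
  expect_equal(hand$tss, 2 / 3 + 2 / 3 - 1)
  expect_gte(hand$max_tss, hand$tss)
})

test_that("permutation importance concentrates on the informative variable", {
  set.seed(21)
  n <- 600
  b <- cbind(sig = rnorm(n), noise = rnorm(n))
  pres <- b[sample(n, 150, prob = exp(2 * b[, "sig"])), , drop = FALSE]
  fs <- build_features(b, "L")
  mod <- fit_maxent(pres, b, fs, reg_multiplier = 0.5)
  imp <- permutation_importance(mod, pres, b, seed = 3, n_perm = 5)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_gt(imp[["sig"]], 90)
  # variable not in the feature set gets zero raw importance
  fs1 <- build_features(b[, "sig", drop = FALSE], "L")
  mod1 <- fit_maxent(pres[, "sig", drop = FALSE], b[, "sig", drop = FALSE],
                     fs1, reg_multiplier = 0.5)
  imp1 <- permutation_importance(mod1, pres, b, seed = 3, n_perm = 5)
  expect_equal(imp1[["noise"]], 0)
  expect_equal(imp1[["sig"]], 100)
})

test_that("jackknife flags redundant and informative variables", {
  set.seed(22)
  n <- 500
  sig <- rnorm(n)
  b <- cbind(a = sig, b = sig + rnorm(n, sd = 0.01), c = rnorm(n))
  pres <- b[sample(n, 120, prob = exp(2 * sig)), , drop = FALSE]
  jk <- jackknife_contribution(pres, b, feature_classes = "L", seed = 5)
  full <- attr(jk, "full_auc")
  # duplicated pair: dropping one of them barely hurts
  expect_lt(abs(jk$without_gain[jk$variable == "a"] - full), 0.05)
  # the informative variable alone approaches the full model
  expect_lt(abs(jk$only_gain[jk$variable == "a"] - full), 0.05)
  # uninformative variable alone is near chance
  expect_lt(jk$only_gain[jk$variable == "c"], full - 0.05)
  jk2 <- jackknife_contribution(pres, b, feature_classes = "L", seed = 5)
  expect_identical(jk, jk2)
})

test_that("replicated CV aggregates median and SD maps coherently", {
  st <- tiny_stack(33, nr = 12, nc = 12)
  occ <- extract_env(sample_occurrences(4, st, default_niches()$landrace, 80), st)
  bg <- sample_background(st, 140, 3)
  cv <- replicate_cv(env_matrix(occ), bg, st, feature_classes = c("L", "Q"),
                     n_replicates = 3, test_fraction = 0.3, max_iter = 100,
                     seed = 11)
  expect_length(cv$replicates, 3)
  sd_vals <- cv$sd_map$layer$values[!cv$sd_map$layer$nodata_mask]
  expect_true(all(sd_vals >= 0))
  med_vals <- cv$median_map$layer$values[!cv$median_map$layer$nodata_mask]
  expect_true(all(med_vals >= 0 & med_vals <= 1))
  # with test_fraction 0 every replicate trains on the full set: the median
  # map equals each replicate's map
  cv0 <- replicate_cv(env_matrix(occ), bg, st, feature_classes = "L",
                      n_replicates = 2, test_fraction = 0, max_iter = 100,
                      seed = 12)
  r1 <- predict_logistic(cv0$replicates[[1]]$model, st)
  expect_equal(cv0$median_map$layer$values, r1$layer$values)
})

test_that("lambdas files round-trip models through structured text", {
  st <- tiny_stack(35, nr = 10, nc = 10)
  occ <- extract_env(sample_occurrences(5, st, default_niches()$wild, 60), st)
  bg <- sample_background(st, 120, 4)
  fs <- build_features(bg, c("L", "Q", "H"), 4)
  mod <- fit_maxent(env_matrix(occ), bg, fs, reg_multiplier = 2, max_iter = 150)
  p <- withr::local_tempfile(fileext = ".txt")
  write_maxent_model(mod, p)
  back <- read_maxent_model(p)
  expect_equal(back$lambdas, mod$lambdas)
  expect_equal(back$entropy, mod$entropy)
  m1 <- predict_logistic(mod, st)
  m2 <- predict_logistic(back, st)
  expect_equal(m2$layer$values, m1$layer$values, tolerance = 1e-12)
})
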