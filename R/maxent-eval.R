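# Model evaluation: AUC, TSS, permutation importance, jackknife variable
# contributions, and replicated cross-validated fitting with median/SD
# suitability surfaces.

#' Rank-based AUC (Mann-Whitney)
#'
#' Probability that a random presence scores above a random background
#' point, ties counted one half.
#'
#' @param presence_scores,background_scores numeric vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  p <- presence_scores[is.finite(presence_scores)]
  b <- background_scores[is.finite(background_scores)]
  if (length(p) == 0 || length(b) == 0) abort_input("auc needs non-empty scores")
  r <- rank(c(p, b))
  (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
    (length(p) * length(b))
}

#' True skill statistic at a threshold
#'
#' `sensitivity + specificity - 1`, with sensitivity the fraction of
#' presences scoring at or above the threshold and specificity the fraction
#' of background scoring below it.  The maximum TSS over all candidate
#' thresholds is reported alongside.
#'
#' @param presence_scores,background_scores numeric vectors.
#' @param threshold suitability threshold in `[0, 1]`.
#' @return list: `tss`, `sensitivity`, `specificity`, `threshold`,
#'   `max_tss`, `max_tss_threshold`.
#' @export
tss <- function(presence_scores, background_scores, threshold) {
  if (threshold < 0 || threshold > 1) abort_input("threshold must be in [0,1]")
  eval_at <- function(th) {
    mean(presence_scores >= th) + mean(background_scores < th) - 1
  }
  cands <- sort(unique(c(presence_scores, background_scores)))
  vals <- vapply(cands, eval_at, numeric(1))
  best <- which.max(vals)
  list(tss = eval_at(threshold),
       sensitivity = mean(presence_scores >= threshold),
       specificity = mean(background_scores < threshold),
       threshold = threshold,
       max_tss = vals[best], max_tss_threshold = cands[best])
}

#' Permutation importance of model variables
#'
#' For each variable, its values are shuffled jointly across the presence
#' and background rows, the fitted model is re-evaluated (no refit), and the
#' importance is the AUC drop `max(0, AUC_orig - mean(AUC_permuted))`,
#' normalized across variables to percentages summing to 100.
#'
#' @param model a [fit_maxent()] model.
#' @param presence_env,background_env the evaluation environment matrices.
#' @param seed integer seed.
#' @param n_perm permutations per variable (default 10).
#' @return named numeric vector of percentages (variables not in the feature
#'   set get 0).
#' @export
permutation_importance <- function(model, presence_env, background_env,
                                   seed = 1, n_perm = 10) {
  P <- as.matrix(presence_env); B <- as.matrix(background_env)
  vars <- colnames(P)
  all_env <- rbind(P, B[, colnames(P), drop = FALSE])
  is_p <- seq_len(nrow(all_env)) <= nrow(P)
  score <- function(X) {
    s <- predict_scores(model, X, clamp = TRUE)$logistic
    auc(s[is_p], s[!is_p])
  }
  auc0 <- score(all_env)
  raw <- with_seed(seed, vapply(vars, function(v) {
    if (!v %in% model$features$vars) return(0)
    drops <- vapply(seq_len(n_perm), function(k) {
      Xp <- all_env
      Xp[, v] <- Xp[sample(nrow(Xp)), v]
      score(Xp)
    }, numeric(1))
    max(0, auc0 - mean(drops))
  }, numeric(1)))
  tot <- sum(raw)
  if (tot == 0) {
    warning("all permutation importances are zero; returning uniform percentages")
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * raw / tot
}

#' Jackknife variable contributions
#'
#' Refits the model with each variable alone and with each variable
#' excluded, recording the held-out test AUC of every refit (a seeded
#' 70/30 split by default).
#'
#' @param presence_env,background_env training matrices.
#' @param feature_classes feature classes for the refits.
#' @param reg_multiplier,max_iter,hinge_knots fit configuration.
#' @param test_fraction held-out presence fraction.
#' @param seed integer seed.
#' @return data.frame with `variable`, `only_gain`, `without_gain` (test
#'   AUCs) and the full-model test AUC as the `full_auc` attribute.
#' @export
jackknife_contribution <- function(presence_env, background_env,
                                   feature_classes = c("L", "Q"),
                                   reg_multiplier = 1, max_iter = 200,
                                   hinge_knots = 10, test_fraction = 0.3,
                                   seed = 1) {
  P <- as.matrix(presence_env); B <- as.matrix(background_env)
  vars <- colnames(P)
  if (length(vars) < 2) abort_input("jackknife needs >= 2 variables")
  n_test <- round(nrow(P) * test_fraction)
  test_idx <- with_seed(seed, sample(nrow(P), n_test))
  P_tr <- P[setdiff(seq_len(nrow(P)), test_idx), , drop = FALSE]
  P_te <- P[test_idx, , drop = FALSE]
  fit_auc <- function(vs) {
    fs <- build_features(B[, vs, drop = FALSE], feature_classes, hinge_knots)
    mod <- fit_maxent(P_tr[, vs, drop = FALSE], B[, vs, drop = FALSE], fs,
                      reg_multiplier, max_iter = max_iter)
    auc(predict_scores(mod, P_te[, vs, drop = FALSE])$logistic,
        predict_scores(mod, B[, vs, drop = FALSE])$logistic)
  }
  out <- data.frame(
    variable = vars,
    only_gain = vapply(vars, function(v) fit_auc(v), numeric(1)),
    without_gain = vapply(vars, function(v) fit_auc(setdiff(vars, v)),
                          numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "full_auc") <- fit_auc(vars)
  out
}

#' Replicated cross-validated maxent fitting
#'
#' Runs `n_replicates` independent seeded 70/30 presence splits (the
#' "replicates with held-out test points" protocol), fits each, evaluates
#' train/test AUC and TSS-at-max, and aggregates the replicate logistic
#' projections into per-cell median and SD maps.
#'
#' @param presence_env presence records x variables matrix.
#' @param background_env background cells x variables matrix.
#' @param stack stack to project each replicate onto (or `NULL` to skip
#'   maps).
#' @param feature_classes subset of L/Q/H/P (analysis default: all four).
#' @param hinge_knots hinge knots per variable per direction.
#' @param reg_multiplier L1 multiplier.
#' @param n_replicates number of replicates (default 10).
#' @param test_fraction held-out presence fraction (default 0.3).
#' @param max_iter,tol optimizer settings.
#' @param seed integer seed; replicate k uses a derived child seed.
#' @param clamp clamp projections to the training range.
#' @return list: `replicates` (each with `model` and `eval`), `median_map`,
#'   `sd_map` (suitability maps or `NULL`), `features`.
#' @export
replicate_cv <- function(presence_env, background_env, stack = NULL,
                         feature_classes = c("L", "Q", "H", "P"),
                         hinge_knots = 30, reg_multiplier = 1,
                         n_replicates = 10, test_fraction = 0.3,
                         max_iter = 500, tol = 1e-6, seed = 1, clamp = TRUE) {
  P <- as.matrix(presence_env)
  fs <- build_features(background_env, feature_classes, hinge_knots)
  bg_scores_of <- function(mod) predict_scores(mod, background_env)$logistic
  reps <- vector("list", n_replicates)
  proj <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    n_test <- round(nrow(P) * test_fraction)
    te <- with_seed(child_seed(seed, k), sample(nrow(P), n_test))
    tr <- setdiff(seq_len(nrow(P)), te)
    mod <- fit_maxent(P[tr, , drop = FALSE], background_env, fs,
                      reg_multiplier, max_iter = max_iter, tol = tol)
    bg_s <- bg_scores_of(mod)
    tr_s <- predict_scores(mod, P[tr, , drop = FALSE])$logistic
    te_s <- if (length(te)) predict_scores(mod, P[te, , drop = FALSE])$logistic
            else numeric(0)
    ev <- list(
      auc_train = auc(tr_s, bg_s),
      auc_test = if (length(te_s)) auc(te_s, bg_s) else NA_real_,
      tss = tss(if (length(te_s)) te_s else tr_s, bg_s,
                threshold = stats::median(bg_s))
    )
    reps[[k]] <- list(model = mod, eval = ev, test_idx = te)
    if (!is.null(stack)) {
      proj[[k]] <- predict_logistic(mod, stack, clamp,
                                    model_id = sprintf("rep%02d", k))
    }
  }
  median_map <- sd_map <- NULL
  if (!is.null(stack)) {
    arr <- vapply(proj, function(m) m$layer$values,
                  matrix(0, stack$geometry$n_rows, stack$geometry$n_cols))
    med <- apply(arr, c(1, 2), stats::median)
    sdv <- apply(arr, c(1, 2), stats::sd)
    clamped_any <- Reduce(`|`, lapply(proj, function(m) m$clamped_mask))
    median_map <- structure(list(
      layer = env_layer("suitability_median", stack$geometry, med),
      model_id = "median", clamped_mask = clamped_any), class = "suitability_map")
    sd_map <- structure(list(
      layer = env_layer("suitability_sd", stack$geometry, sdv),
      model_id = "sd", clamped_mask = clamped_any), class = "suitability_map")
  }
  list(replicates = reps, median_map = median_map, sd_map = sd_map,
       features = fs)
}
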