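# Presence-background maximum-entropy fitting.
#
# The model is the Gibbs distribution q(z) = exp(lambda . f(z)) / Z over the
# background cells, fitted by maximizing the L1-penalized average presence
# log-likelihood
#
#   l(lambda) = mean_i lambda . f(x_i) - log Z(lambda) - sum_j beta_j |lambda_j|
#
# which is concave; we use proximal gradient ascent (soft-thresholding step)
# with backtracking line search, so the penalized objective is non-decreasing
# by construction.  beta_j = reg_multiplier * beta0(class_j, m) * s_j /
# sqrt(m), with s_j the background SD of feature j.

soft_threshold <- function(x, t) sign(x) * pmax(0, abs(x) - t)

# Core optimizer on precomputed feature matrices.  `F_bg` must already
# include the presence rows if the standard convention (presences in the
# partition function) is wanted.
fit_maxent_core <- function(pbar, F_bg, beta, max_iter = 500, tol = 1e-6) {
  J <- ncol(F_bg)
  lambda <- numeric(J)
  eta <- as.vector(F_bg %*% lambda)
  lz <- logsumexp(eta)
  obj <- sum(pbar * lambda) - lz - sum(beta * abs(lambda))
  trace <- numeric(max_iter)
  step <- 1
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    q <- exp(eta - lz)
    grad <- pbar - as.vector(crossprod(F_bg, q))
    step <- min(step * 2, 1e4)
    repeat {
      cand <- soft_threshold(lambda + step * grad, step * beta)
      eta_c <- as.vector(F_bg %*% cand)
      lz_c <- logsumexp(eta_c)
      obj_c <- sum(pbar * cand) - lz_c - sum(beta * abs(cand))
      if (obj_c >= obj || step < 1e-14) break
      step <- step / 2
    }
    if (obj_c < obj) { trace[it] <- obj; converged <- TRUE; break }
    improved <- obj_c - obj
    lambda <- cand; eta <- eta_c; lz <- lz_c; obj <- obj_c
    trace[it] <- obj
    if (improved < tol && it > 1) { converged <- TRUE; break }
  }
  q <- exp(eta - lz)
  list(lambda = lambda, log_z = lz, q = q,
       entropy = -sum(ifelse(q > 0, q * log(q), 0)),
       objective = obj, objective_trace = trace[seq_len(iter)],
       converged = converged, iterations = iter)
}

#' Fit a maximum-entropy niche model
#'
#' @param presence_env presence records x variables matrix.
#' @param background_env background cells x variables matrix.  By default the
#'   presence rows are appended to the background for the partition function
#'   (the standard convention for this model family).
#' @param features a [build_features()] result (typically built on
#'   `background_env`).
#' @param reg_multiplier positive scalar inflating all L1 penalties;
#'   the analysis uses 3 for wild-side classes and 1 for commercial and
#'   cultivated.
#' @param max_iter maximum optimizer iterations (default 500).
#' @param tol stop when the objective improves by less than this.
#' @param min_presences minimum presence records required (default 10).
#' @param add_presence_to_background logical, see above.
#' @return object of class `maxent_model` with `lambdas`, `betas`, `log_z`,
#'   `entropy`, clamp ranges, objective trace and training metadata.
#' @export
fit_maxent <- function(presence_env, background_env, features,
                       reg_multiplier = 1, max_iter = 500, tol = 1e-6,
                       min_presences = 10,
                       add_presence_to_background = TRUE) {
  P <- as.matrix(presence_env)
  B <- as.matrix(background_env)
  if (nrow(P) == 0) abort_input("no presence records")
  if (nrow(P) < min_presences) {
    abort_input("need >= %d presences, got %d", min_presences, nrow(P))
  }
  if (reg_multiplier <= 0) abort_input("reg_multiplier must be > 0")
  train <- if (add_presence_to_background) rbind(B, P[, colnames(B), drop = FALSE]) else B
  F_bg <- evaluate_features(features, train)
  F_p <- evaluate_features(features, P)
  if (!all(is.finite(F_bg)) || !all(is.finite(F_p))) {
    abort_input("non-finite feature values")
  }
  m <- nrow(P)
  s <- apply(F_bg, 2, stats::sd)
  beta <- reg_multiplier * beta0_for(features$defs$kind, m) * s / sqrt(m)
  fit <- fit_maxent_core(colMeans(F_p), F_bg, beta, max_iter, tol)
  structure(list(
    features = features,
    lambdas = fit$lambda,
    reg_multiplier = reg_multiplier,
    betas = beta,
    log_z = fit$log_z,
    entropy = fit$entropy,
    clamp_min = apply(train[, features$vars, drop = FALSE], 2, min),
    clamp_max = apply(train[, features$vars, drop = FALSE], 2, max),
    objective = fit$objective,
    objective_trace = fit$objective_trace,
    converged = fit$converged,
    iterations = fit$iterations,
    n_presence = m,
    n_background = nrow(train)
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model %d features, %d active; m=%d, N=%d; H=%.3f; %s after %d iter>\n",
    length(x$lambdas), sum(x$lambdas != 0), x$n_presence, x$n_background,
    x$entropy, if (x$converged) "converged" else "max_iter", x$iterations))
  invisible(x)
}

# Logistic scores for an environment matrix: raw r(z) = exp(lambda.f(z)) /
# Z_train, logistic = r e^H / (1 + r e^H) with H the training entropy.
predict_scores <- function(model, X, clamp = TRUE) {
  X <- as.matrix(X)
  missing <- setdiff(model$features$vars, colnames(X))
  if (length(missing)) abort_input("missing variables: %s",
                                   paste(missing, collapse = ", "))
  X <- X[, model$features$vars, drop = FALSE]
  clamped <- rep(FALSE, nrow(X))
  if (clamp) {
    for (v in model$features$vars) {
      lo <- model$clamp_min[v]; hi <- model$clamp_max[v]
      clamped <- clamped | X[, v] < lo | X[, v] > hi
      X[, v] <- pmin(pmax(X[, v], lo), hi)
    }
  }
  Fx <- evaluate_features(model$features, X)
  log_r <- as.vector(Fx %*% model$lambdas) - model$log_z
  list(logistic = stats::plogis(log_r + model$entropy),
       raw_log = log_r, clamped = clamped)
}

#' Project a fitted model over an environment stack
#'
#' Produces the logistic-output suitability surface.  When `clamp` is on
#' (the default, and the analysis configuration), projection-time variable
#' values are clamped to the training range and the affected cells are
#' flagged in `clamped_mask`.
#'
#' @param model a [fit_maxent()] model.
#' @param stack an [env_stack()] containing all model variables.
#' @param clamp logical.
#' @param model_id free-text id stored in the map.
#' @return object of class `suitability_map`: `layer` (an [env_layer()] in
#'   `[0, 1]`), `model_id`, `clamped_mask`.
#' @export
predict_logistic <- function(model, stack, clamp = TRUE, model_id = "maxent") {
  missing <- setdiff(model$features$vars, stack_names(stack))
  if (length(missing)) abort_input("stack lacks model variables: %s",
                                   paste(missing, collapse = ", "))
  cells <- which(stack$valid_mask)
  X <- stack_values(stack, cells)
  pr <- predict_scores(model, X, clamp)
  g <- stack$geometry
  vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  vals[cells] <- pr$logistic
  cl <- matrix(FALSE, g$n_rows, g$n_cols)
  cl[cells] <- pr$clamped
  structure(list(layer = env_layer(paste0("suitability_", model_id), g, vals),
                 model_id = model_id, clamped_mask = cl),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$layer$values[!x$layer$nodata_mask]
  cat(sprintf("<suitability_map '%s' mean %.3f, %d clamped cells>\n",
              x$model_id, mean(v), sum(x$clamped_mask)))
  invisible(x)
}

#' Suitability values at occurrence locations
#'
#' @param map a [predict_logistic()] map (or any `suitability_map`).
#' @param points an `occurrence_set`.
#' @return numeric vector (NA off-grid / on masked cells).
#' @export
suitability_at_points <- function(map, points) {
  g <- map$layer$geometry
  loc <- locate_cells(g, points$lon, points$lat)
  cell <- (loc$col - 1L) * g$n_rows + loc$row
  out <- rep(NA_real_, nrow(points))
  ok <- !is.na(cell)
  out[ok] <- map$layer$values[cell[ok]]
  out
}

#' Sample background cells from a stack
#'
#' Uniform sample without replacement from the valid (optionally cropped)
#' mask; if fewer valid cells than requested exist, all are used.
#'
#' @param stack an [env_stack()].
#' @param n target number of background cells (the analysis default is
#'   10000).
#' @param seed integer seed.
#' @return environment matrix (cells x variables) with a `cells` attribute.
#' @export
sample_background <- function(stack, n = 10000, seed = 1) {
  valid <- which(stack$valid_mask)
  if (length(valid) == 0) abort_input("stack has no valid cells")
  cells <- if (length(valid) <= n) valid else
    with_seed(seed, sort(sample(valid, n)))
  stack_values(stack, cells)
}
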