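# Niche similarity between suitability surfaces (Schoener's D, Warren's I,
# Spearman rank correlation) and the randomization tests built on them:
# niche equivalency (label-shuffling) and background similarity (random
# background draws), plus the occupancy-grid overlap in environmental space.

overlap_stats_vec <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) abort_input("overlap needs >= 2 shared valid cells")
  if (sum(a) <= 0 || sum(b) <= 0) abort_input("all-zero suitability surface")
  p <- a / sum(a); q <- b / sum(b)
  list(
    schoener_d = 1 - sum(abs(p - q)) / 2,
    warren_i = 1 - sum((sqrt(p) - sqrt(q))^2) / 2,
    spearman_rho = suppressWarnings(stats::cor(a, b, method = "spearman")),
    n_cells = length(a)
  )
}

#' Niche overlap statistics between two suitability surfaces
#'
#' Both surfaces are normalized to sum 1 over the shared valid cells;
#' Schoener's `D = 1 - 0.5 * sum|p - q|` and Warren's Hellinger-based
#' `I = 1 - 0.5 * sum(sqrt(p) - sqrt(q))^2` are computed on the normalized
#' surfaces, and the Spearman rank correlation (average ranks for ties) on
#' the raw values.  Both D and I are 1 exactly when the normalized surfaces
#' coincide.
#'
#' @param map_a,map_b co-registered `suitability_map`s (or `env_layer`s).
#' @return object of class `overlap_stats`: `schoener_d`, `warren_i`,
#'   `spearman_rho`, `n_cells`.
#' @export
overlap_stats <- function(map_a, map_b) {
  la <- if (inherits(map_a, "suitability_map")) map_a$layer else map_a
  lb <- if (inherits(map_b, "suitability_map")) map_b$layer else map_b
  stopifnot_coregistered(la$geometry, lb$geometry)
  shared <- !la$nodata_mask & !lb$nodata_mask
  out <- overlap_stats_vec(la$values[shared], lb$values[shared])
  structure(out, class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("<overlap D=%.3f I=%.3f rho=%.3f over %d cells>\n",
              x$schoener_d, x$warren_i, x$spearman_rho, x$n_cells))
  invisible(x)
}

#' Reduced model configuration for randomization tests
#'
#' Randomization tests refit models hundreds of times, so the default
#' configuration is deliberately light (no hinge features, 2000 background
#' cells, single fit); pass a custom list to restore the full configuration.
#'
#' @param feature_classes,hinge_knots,n_background,reg_multiplier,max_iter,tol,min_presences
#'   fit settings, see [fit_maxent()].
#' @return named list.
#' @export
overlap_enm_config <- function(feature_classes = c("L", "Q"),
                               hinge_knots = 10, n_background = 2000,
                               reg_multiplier = 1, max_iter = 200,
                               tol = 1e-6, min_presences = 10) {
  list(feature_classes = feature_classes, hinge_knots = hinge_knots,
       n_background = n_background, reg_multiplier = reg_multiplier,
       max_iter = max_iter, tol = tol, min_presences = min_presences)
}

# Shared machinery: precompute feature matrices once (background, candidate
# presence rows, projection cells); each (re)fit is then just the optimizer.
overlap_fit_context <- function(stack, config, seed, extra_env = NULL) {
  bg <- sample_background(stack, config$n_background, seed)
  fs <- build_features(bg, config$feature_classes, config$hinge_knots)
  cells <- which(stack$valid_mask)
  F_cells <- evaluate_features(fs, stack_values(stack, cells))
  list(stack = stack, config = config, fs = fs, bg = bg,
       F_bg = evaluate_features(fs, bg), F_cells = F_cells, cells = cells)
}

ctx_point_env <- function(ctx, points) {
  loc <- locate_cells(ctx$stack$geometry, points$lon, points$lat)
  cell <- (loc$col - 1L) * ctx$stack$geometry$n_rows + loc$row
  ok <- !is.na(cell)
  ok[ok] <- ctx$stack$valid_mask[cell[ok]]
  if (sum(ok) < ctx$config$min_presences) {
    abort_input("need >= %d on-grid presences, got %d",
                ctx$config$min_presences, sum(ok))
  }
  stack_values(ctx$stack, cell[ok])
}

# Fit on precomputed presence feature rows; returns the logistic suitability
# vector over the stack's valid cells.
ctx_fit_suitability <- function(ctx, F_pres) {
  m <- nrow(F_pres)
  F_train <- rbind(ctx$F_bg, F_pres)
  s <- apply(F_train, 2, stats::sd)
  beta <- ctx$config$reg_multiplier * beta0_for(ctx$fs$defs$kind, m) * s / sqrt(m)
  fit <- fit_maxent_core(colMeans(F_pres), F_train, beta,
                         ctx$config$max_iter, ctx$config$tol)
  log_r <- as.vector(ctx$F_cells %*% fit$lambda) - fit$log_z
  stats::plogis(log_r + fit$entropy)
}

finish_randomization <- function(observed, null_df, n_reps) {
  pval <- function(stat, side) {
    nv <- null_df[[stat]]
    obs <- observed[[stat]]
    if (side == "low") (sum(nv <= obs) + 1) / (n_reps + 1)
    else (sum(nv >= obs) + 1) / (n_reps + 1)
  }
  structure(list(
    observed = observed, null_values = null_df,
    p_low = c(schoener_d = pval("schoener_d", "low"),
              warren_i = pval("warren_i", "low")),
    p_high = c(schoener_d = pval("schoener_d", "high"),
               warren_i = pval("warren_i", "high")),
    n_reps = n_reps
  ), class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "<randomization D_obs=%.3f (p_low=%.3f, p_high=%.3f), %d reps>\n",
    x$observed$schoener_d, x$p_low["schoener_d"], x$p_high["schoener_d"],
    x$n_reps))
  invisible(x)
}

#' Niche equivalency test
#'
#' Observed statistic: overlap of the two classes' fitted suitability
#' surfaces.  Null: presences are pooled, class labels shuffled preserving
#' sample sizes, and both models refitted per repetition.  `p_low` small
#' means the observed overlap sits below the null distribution, i.e.
#' equivalency is rejected.
#'
#' @param points_a,points_b `occurrence_set`s.
#' @param stack an [env_stack()].
#' @param enm_config see [overlap_enm_config()].
#' @param n_reps null repetitions (`>= 1`).
#' @param seed integer seed.
#' @return a `randomization_result`.
#' @export
equivalency_test <- function(points_a, points_b, stack,
                             enm_config = overlap_enm_config(),
                             n_reps = 99, seed = 1) {
  if (n_reps < 1) abort_input("n_reps must be >= 1")
  ctx <- overlap_fit_context(stack, enm_config, child_seed(seed, 0))
  Ea <- ctx_point_env(ctx, points_a)
  Eb <- ctx_point_env(ctx, points_b)
  F_all <- evaluate_features(ctx$fs, rbind(Ea, Eb))
  na <- nrow(Ea); nb <- nrow(Eb)
  suit_of <- function(idx) ctx_fit_suitability(ctx, F_all[idx, , drop = FALSE])
  obs <- overlap_stats_vec(suit_of(seq_len(na)), suit_of(na + seq_len(nb)))
  null_df <- with_seed(child_seed(seed, 1), {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      perm <- sample(na + nb)
      st <- overlap_stats_vec(suit_of(perm[seq_len(na)]),
                              suit_of(perm[na + seq_len(nb)]))
      data.frame(schoener_d = st$schoener_d, warren_i = st$warren_i)
    }))
  })
  finish_randomization(obs, null_df, n_reps)
}

#' Background similarity test
#'
#' Observed statistic: overlap of model A and model B.  Null: class B's
#' presences are replaced by random cells from B's background region (same
#' sample size), B is refitted, and the overlap with the fixed model A is
#' recomputed.  `p_high` small: the two niches are *more* similar than
#' expected from B's available environment (e.g. nesting); `p_low` small:
#' *less* similar than random, i.e. divergent.  The test is asymmetric by
#' construction; run both directions to probe nesting.
#'
#' @param points_a,points_b `occurrence_set`s (B is randomized).
#' @param background_region_b integer cell indices defining B's available
#'   region, or `NULL` for all valid cells of the stack.
#' @param stack an [env_stack()].
#' @param enm_config see [overlap_enm_config()].
#' @param n_reps null repetitions.
#' @param seed integer seed.
#' @return a `randomization_result`.
#' @export
background_test <- function(points_a, points_b, background_region_b = NULL,
                            stack, enm_config = overlap_enm_config(),
                            n_reps = 99, seed = 1) {
  if (n_reps < 1) abort_input("n_reps must be >= 1")
  ctx <- overlap_fit_context(stack, enm_config, child_seed(seed, 0))
  region <- background_region_b %||% which(stack$valid_mask)
  Ea <- ctx_point_env(ctx, points_a)
  Eb <- ctx_point_env(ctx, points_b)
  nb <- nrow(Eb)
  if (length(region) < nb) {
    abort_input("background region (%d cells) smaller than class-b sample (%d)",
                length(region), nb)
  }
  suit_a <- ctx_fit_suitability(ctx, evaluate_features(ctx$fs, Ea))
  obs <- overlap_stats_vec(
    suit_a, ctx_fit_suitability(ctx, evaluate_features(ctx$fs, Eb)))
  null_df <- with_seed(child_seed(seed, 1), {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      cells <- sample(region, nb)
      Fb <- evaluate_features(ctx$fs, stack_values(ctx$stack, cells))
      st <- overlap_stats_vec(suit_a, ctx_fit_suitability(ctx, Fb))
      data.frame(schoener_d = st$schoener_d, warren_i = st$warren_i)
    }))
  })
  finish_randomization(obs, null_df, n_reps)
}

# Gaussian product-kernel density on a rectangular grid.
kde_grid <- function(px, py, xs, ys, hx, hy) {
  A <- stats::dnorm(outer(xs, px, "-") / hx) / hx
  B <- stats::dnorm(outer(ys, py, "-") / hy) / hy
  (A %*% t(B)) / length(px)
}

#' Occupancy-grid niche overlap in environmental space
#'
#' The standard environment-space variant: a PCA is fitted on the background
#' environment, occurrence and background densities are kernel-smoothed on a
#' `grid_res x grid_res` grid over PC1-PC2, and each class's occupancy is
#' its occurrence density divided by the background density (zero where the
#' background density vanishes), normalized to sum 1.  D and I are computed
#' on the two occupancy grids.
#'
#' @param points_a,points_b extracted `occurrence_set`s (>= 5 points each).
#' @param background_env background cells x variables matrix.
#' @param grid_res grid resolution per axis (default 100).
#' @param bandwidth kernel SD in PC units (scalar or length 2); default:
#'   normal-reference rule on the background scores.
#' @return an `overlap_stats` object (Spearman computed on occupancy
#'   values).
#' @export
envspace_density_overlap <- function(points_a, points_b, background_env,
                                     grid_res = 100, bandwidth = NULL) {
  if (nrow(points_a) < 5 || nrow(points_b) < 5) {
    abort_input("need >= 5 points per class")
  }
  pca <- run_pca(background_env)
  sb <- pca$scores[, 1:2, drop = FALSE]
  sa <- pca_project(pca, env_matrix(points_a))[, 1:2, drop = FALSE]
  sc <- pca_project(pca, env_matrix(points_b))[, 1:2, drop = FALSE]
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::bw.nrd0(sb[, 1]), stats::bw.nrd0(sb[, 2])) * 2
  }
  if (length(bandwidth) == 1) bandwidth <- rep(bandwidth, 2)
  xr <- range(sb[, 1], sa[, 1], sc[, 1])
  yr <- range(sb[, 2], sa[, 2], sc[, 2])
  xs <- seq(xr[1] - bandwidth[1], xr[2] + bandwidth[1], length.out = grid_res)
  ys <- seq(yr[1] - bandwidth[2], yr[2] + bandwidth[2], length.out = grid_res)
  dens_bg <- kde_grid(sb[, 1], sb[, 2], xs, ys, bandwidth[1], bandwidth[2])
  occupancy <- function(s) {
    d <- kde_grid(s[, 1], s[, 2], xs, ys, bandwidth[1], bandwidth[2])
    o <- ifelse(dens_bg > 1e-10 * max(dens_bg), d / dens_bg, 0)
    o / sum(o)
  }
  oa <- occupancy(sa); ob <- occupancy(sc)
  structure(overlap_stats_vec(as.vector(oa), as.vector(ob)),
            class = "overlap_stats")
}
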