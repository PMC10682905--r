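# PCA environmental envelopes, minimum-convex-hull overlap in PC space, and
# bootstrap comparison of per-variable distributions.

#' Standardized PCA of an environment table
#'
#' Principal components of the correlation matrix (variables are z-scored,
#' appropriate for heterogeneous units such as degrees C vs mm).  Sign
#' convention: each loading vector is flipped so its largest-magnitude entry
#' is positive, making output deterministic across BLAS implementations.
#'
#' @param env_table numeric records x variables matrix.
#' @return object of class `pca_result`: `loadings` (variables x
#'   components), `scores` (records x components), `explained_var_fraction`,
#'   `center`, `scale`.
#' @export
run_pca <- function(env_table) {
  x <- as.matrix(env_table)
  if (nrow(x) < ncol(x) + 1) abort_input("PCA needs more records than variables")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    abort_input("constant variable(s) in PCA input: %s",
                paste(colnames(x)[sds == 0 | !is.finite(sds)], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  structure(list(
    loadings = loadings,
    scores = scores,
    explained_var_fraction = pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center,
    scale = pc$scale
  ), class = "pca_result")
}

#' Project new records into an existing PCA space
#' @param pca a `pca_result`.
#' @param env_table records x variables matrix with the PCA's variables.
#' @return scores matrix.
#' @export
pca_project <- function(pca, env_table) {
  x <- as.matrix(env_table)[, names(pca$center), drop = FALSE]
  scale(x, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Overlap of two convex envelopes in PC space
#'
#' Areas are in squared PC units.  Two overlap conventions are reported
#' side by side, because envelope overlap can be quantified by area or, to
#' counter point clustering and uneven sampling, by point density:
#' `frac_a`/`frac_b` (intersection / own area), `frac_union`
#' (intersection / union), and `points_in_overlap_*` (proportion of each
#' class's points falling in the intersection polygon; boundary counts as
#' inside).
#'
#' @param hull_a,hull_b [convex_hull()] polygons.
#' @param points_a,points_b the 2-D point sets behind the hulls.
#' @return object of class `hull_overlap`.
#' @export
hull_overlap <- function(hull_a, hull_b, points_a = NULL, points_b = NULL) {
  area_a <- polygon_area(hull_a)
  area_b <- polygon_area(hull_b)
  inter <- clip_convex(hull_a, hull_b)
  area_i <- if (is.null(inter)) 0 else abs(polygon_area(inter))
  area_i <- min(area_i, area_a, area_b)  # guard float fuzz
  pts_frac <- function(p) {
    if (is.null(p) || nrow(p) == 0 || is.null(inter)) return(NA_real_)
    mean(point_in_polygon(p[, 1], p[, 2], inter, tol = 1e-9))
  }
  structure(list(
    area_a = area_a, area_b = area_b, area_intersection = area_i,
    frac_a = area_i / area_a, frac_b = area_i / area_b,
    frac_union = area_i / (area_a + area_b - area_i),
    points_in_overlap_a = pts_frac(points_a),
    points_in_overlap_b = pts_frac(points_b)
  ), class = "hull_overlap")
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the values with replacement `n_boot` times and takes the
#' 2.5/97.5 percentiles of the resampled statistic.
#'
#' @param values numeric vector, length >= 2.
#' @param statistic `"mean"` (default) or `"median"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return object of class `ci_result`: `statistic`, `estimate`, `ci_low`,
#'   `ci_high`, `n_boot`.
#' @export
bootstrap_ci <- function(values, statistic = c("mean", "median"),
                         n_boot = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  if (length(values) < 2) abort_input("bootstrap needs >= 2 values")
  fn <- match.fun(statistic)
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(length(values), length(values) * n_boot,
                             replace = TRUE), nrow = n_boot)
    apply(idx, 1, function(i) fn(values[i]))
  })
  q <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(statistic = statistic, estimate = fn(values),
                 ci_low = q[1], ci_high = q[2], n_boot = n_boot),
            class = "ci_result")
}

#' Compact letter display from confidence intervals
#'
#' Classes whose intervals overlap share at least one letter; classes with
#' disjoint intervals share none.  Letters are the maximal cliques of the
#' interval-overlap graph (for intervals, every maximal clique is the set of
#' intervals covering some point), ordered and labelled by ascending point
#' estimate.
#'
#' @param cis named list of [bootstrap_ci()] results (or any objects with
#'   `estimate`, `ci_low`, `ci_high`).
#' @return named character vector of letter labels, e.g. `c(a = "a", b =
#'   "ab", c = "b")`.
#' @export
ci_letter_groups <- function(cis) {
  if (length(cis) < 2) abort_input("letter groups need >= 2 classes")
  lo <- vapply(cis, function(c) c$ci_low, numeric(1))
  hi <- vapply(cis, function(c) c$ci_high, numeric(1))
  est <- vapply(cis, function(c) c$estimate, numeric(1))
  n <- length(cis)
  # candidate clique anchors: all interval endpoints
  pts <- sort(unique(c(lo, hi)))
  cliques <- unique(lapply(pts, function(p) which(lo <= p & hi >= p)))
  cliques <- Filter(function(cl) length(cl) > 0, cliques)
  # drop cliques contained in another
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  cliques <- cliques[keep]
  # order cliques by the smallest member estimate -> letters in rank order
  ord <- order(vapply(cliques, function(cl) min(est[cl]), numeric(1)))
  cliques <- cliques[ord]
  labels <- rep("", n)
  for (k in seq_along(cliques)) {
    labels[cliques[[k]]] <- paste0(labels[cliques[[k]]], letters[k])
  }
  stats::setNames(labels, names(cis))
}

#' Per-class environmental envelope summary in PC space
#'
#' Convenience wrapper used by the pipeline: runs the standardized PCA on
#' all records, then computes hulls and every pairwise [hull_overlap()] on
#' PC1-PC2.
#'
#' @param points an extracted `occurrence_set` covering >= 2 classes.
#' @param vars variables to use (default: all extracted).
#' @return list with `pca`, per-class `hulls`, and a data.frame `overlaps`
#'   of pairwise statistics.
#' @export
envelope_analysis <- function(points, vars = NULL) {
  vars <- vars %||% env_vars(points)
  x <- as.matrix(points[, vars, drop = FALSE])
  pca <- run_pca(x)
  sc <- pca$scores[, 1:2, drop = FALSE]
  classes <- unique(points$class)
  by_class <- lapply(stats::setNames(classes, classes),
                     function(cl) sc[points$class == cl, , drop = FALSE])
  hulls <- lapply(by_class, convex_hull)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    ov <- hull_overlap(hulls[[pr[1]]], hulls[[pr[2]]],
                       by_class[[pr[1]]], by_class[[pr[2]]])
    data.frame(class_a = pr[1], class_b = pr[2],
               area_a = ov$area_a, area_b = ov$area_b,
               area_intersection = ov$area_intersection,
               frac_a = ov$frac_a, frac_b = ov$frac_b,
               frac_union = ov$frac_union,
               points_in_overlap_a = ov$points_in_overlap_a,
               points_in_overlap_b = ov$points_in_overlap_b,
               stringsAsFactors = FALSE)
  })
  list(pca = pca, hulls = hulls, scores_by_class = by_class,
       overlaps = do.call(rbind, rows))
}
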