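# Seeded synthetic landscapes, class niches, occurrences, polygon proxies
# and future-scenario layers.  The generator states a fixed "world":
# bioclim-like correlated layers over a lon/lat grid, Gaussian (bell-shaped)
# true niches per domestication class with a nested/shifted design
# (landrace inside wild, commercial displaced toward dry / high-seasonality
# space), and future layers that are warmed / precipitation-scaled copies of
# the present layers per pseudo-GCM.

# Canonical 9 synthetic variables mirror the bioclim subset the analyses run
# on; kinds drive units and how scenario deltas apply.
SYNTH_VARS <- data.frame(
  name = c("bio2", "bio3", "bio4", "bio5", "bio9",
           "bio14", "bio15", "bio18", "bio19"),
  kind = c("temperature", "other", "other", "temperature", "temperature",
           "precipitation", "other", "precipitation", "precipitation"),
  mean = c(12, 55, 60, 32, 20, 30, 70, 120, 80),
  sd = c(3, 12, 18, 5, 5, 20, 25, 50, 40),
  stringsAsFactors = FALSE
)

#' Default variable kinds for synthetic layers
#'
#' @param names layer names.
#' @return named character vector mapping each layer to
#'   `"temperature"`, `"precipitation"` or `"other"`.
#' @export
default_var_kinds <- function(names) {
  kinds <- SYNTH_VARS$kind[match(names, SYNTH_VARS$name)]
  kinds[is.na(kinds)] <- "other"
  stats::setNames(kinds, names)
}

#' True-niche specification for a domestication class
#'
#' The synthetic truth is a Gaussian (bell) suitability surface in
#' environment space: `s(e) = exp(-0.5 * sum_v ((e_v - optimum_v) /
#' breadth_v)^2)`, in (0, 1].  Smooth, unimodal and nestable by construction,
#' which is exactly what the downstream envelope / overlap / recovery checks
#' need as a recovery target.
#'
#' @param class_label one of `"wild"`, `"semiwild"`, `"landrace"`,
#'   `"commercial"`.
#' @param optimum named numeric vector of per-variable optima (environment
#'   units; names must match layer names).
#' @param breadth named numeric vector of per-variable tolerances, `> 0`.
#' @param weight relative prevalence in `[0, 1]`.
#' @return object of class `niche_spec`.
#' @export
niche_spec <- function(class_label, optimum, breadth, weight = 1) {
  class_label <- match.arg(class_label,
                           c("wild", "semiwild", "landrace", "commercial"))
  if (is.null(names(optimum)) || is.null(names(breadth)) ||
      !identical(names(optimum), names(breadth))) {
    abort_input("optimum and breadth must be named identically")
  }
  if (any(breadth <= 0)) abort_input("breadth must be strictly positive")
  if (weight < 0 || weight > 1) abort_input("weight must be in [0,1]")
  structure(list(class_label = class_label, optimum = optimum,
                 breadth = breadth, weight = weight),
            class = "niche_spec")
}

#' Nested/shifted default niches for the four domestication classes
#'
#' Encodes the generator's stated design on the default synthetic layers:
#' landrace optimum equals the wild optimum with half the breadth (nested),
#' semiwild is a slightly narrowed, slightly shifted wild, and commercial is
#' displaced toward dry, high-seasonality conditions.
#'
#' @param vars variables the niches are defined over (must exist in the
#'   stack the niches are used with).
#' @return named list of [niche_spec()] objects.
#' @export
default_niches <- function(vars = c("bio9", "bio18", "bio15")) {
  opt_wild <- stats::setNames(c(20, 130, 65), vars)
  # tolerances ~ half the landscape SD of each variable: the study region
  # deliberately spans environments (deserts, high-seasonality zones) well
  # outside the wild class's niche, so nesting and divergence are
  # detectable properties of the world rather than border effects
  br_wild <- stats::setNames(c(2.6, 24, 12), vars)
  list(
    wild = niche_spec("wild", opt_wild, br_wild),
    semiwild = niche_spec("semiwild", opt_wild + c(-1, 10, -4),
                          0.7 * br_wild),
    landrace = niche_spec("landrace", opt_wild, 0.5 * br_wild),
    commercial = niche_spec("commercial",
                            opt_wild + c(2, -75, 35), 0.8 * br_wild)
  )
}

#' True suitability of a niche over a stack
#'
#' @param stack an [env_stack()] containing every variable of the niche.
#' @param niche a [niche_spec()].
#' @return an [env_layer()] with values in (0, 1] on valid cells.
#' @export
true_suitability <- function(stack, niche) {
  vars <- names(niche$optimum)
  missing <- setdiff(vars, stack_names(stack))
  if (length(missing)) abort_input("stack lacks niche variables: %s",
                                   paste(missing, collapse = ", "))
  cells <- which(stack$valid_mask)
  X <- stack_values(stack, cells)[, vars, drop = FALSE]
  z <- sweep(sweep(X, 2, niche$optimum[vars]), 2, niche$breadth[vars], "/")
  s <- exp(-0.5 * rowSums(z^2))
  vals <- matrix(NA_real_, stack$geometry$n_rows, stack$geometry$n_cols)
  vals[cells] <- s
  env_layer(paste0("suitability_", niche$class_label), stack$geometry, vals)
}

# Separable Gaussian smoothing with edge renormalization; `smoothness` is
# the kernel SD in cells.
smooth_field <- function(m, smoothness) {
  if (smoothness <= 0) return(m)
  half <- max(1L, ceiling(3 * smoothness))
  k <- stats::dnorm(seq(-half, half), sd = smoothness)
  smooth_vec <- function(v) {
    n <- length(v)
    out <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
    w <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
    (out / w)[(half + 1):(half + n)]
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(m, 1, smooth_vec))
}

#' Generate seeded synthetic environmental layers
#'
#' Each layer is a large-scale deterministic gradient plus a smoothed,
#' standardized Gaussian random field; fields are mixed across variables by a
#' Cholesky factor so empirical cross-layer correlations track the requested
#' target.  Layer 1 carries a north-south (temperature-like) gradient and
#' layer 2 an east-west (precipitation-like) gradient; the two are
#' empirically orthogonal over the grid, so they do not distort the target
#' correlations.  Identical seeds give bitwise-identical output.
#'
#' @param seed integer seed.
#' @param geometry a [grid_geometry()].
#' @param n_vars number of layers (default 9, the analysis scale).
#' @param correlation target correlation matrix (symmetric PSD, unit
#'   diagonal); default: 0.3 within same-kind blocks.
#' @param smoothness random-field kernel SD in cells.
#' @param var_names,var_kinds layer names and kinds; defaults to the
#'   canonical bioclim-like set.
#' @param gradient_weight fraction of raw-field variance carried by the
#'   deterministic gradients (layers 1-2).
#' @return an [env_stack()] with a `var_kinds` attribute.
#' @export
make_env_layers <- function(seed, geometry, n_vars = 9, correlation = NULL,
                            smoothness = 5, var_names = NULL,
                            var_kinds = NULL, gradient_weight = 0.5) {
  if (is.null(var_names)) {
    var_names <- if (n_vars <= nrow(SYNTH_VARS)) SYNTH_VARS$name[seq_len(n_vars)]
                 else paste0("var", seq_len(n_vars))
  }
  if (is.null(var_kinds)) var_kinds <- default_var_kinds(var_names)
  if (is.null(correlation)) {
    correlation <- diag(n_vars)
    same_kind <- outer(var_kinds, var_kinds, "==")
    correlation[same_kind & !diag(n_vars)] <- 0.3
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8)) ||
      any(abs(diag(correlation) - 1) > 1e-8)) {
    abort_input("correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort_input("correlation matrix is not PSD")

  nr <- geometry$n_rows; nc <- geometry$n_cols
  std <- function(m) (m - mean(m)) / stats::sd(as.vector(m))
  grad_ns <- std(matrix(seq(1, -1, length.out = nr), nr, nc))
  grad_ew <- std(matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE))
  with_seed(seed, {
    raw <- vapply(seq_len(n_vars), function(v) {
      noise <- std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc),
                                smoothness))
      g <- if (v == 1) grad_ns else if (v == 2) grad_ew else 0
      w <- if (v <= 2) gradient_weight else 0
      as.vector(sqrt(w) * g + sqrt(1 - w) * noise)
    }, numeric(nr * nc))
    # empirical whitening before mixing: the delivered layers then carry the
    # *exact* target correlation, not just its expectation
    raw <- scale(raw, center = TRUE, scale = FALSE)
    W <- chol(stats::cov(raw) + diag(1e-10, n_vars))
    L <- chol(correlation + diag(1e-10, n_vars))
    mixed <- raw %*% backsolve(W, diag(n_vars)) %*% L
    layers <- lapply(seq_len(n_vars), function(v) {
      info_row <- match(var_names[v], SYNTH_VARS$name)
      mu <- if (!is.na(info_row)) SYNTH_VARS$mean[info_row] else 0
      sdv <- if (!is.na(info_row)) SYNTH_VARS$sd[info_row] else 1
      vals <- matrix(mu + sdv * mixed[, v], nr, nc)
      if (var_kinds[[v]] == "precipitation") vals <- pmax(vals, 0)
      env_layer(var_names[v], geometry, vals)
    })
    out <- env_stack(layers)
    attr(out, "var_kinds") <- var_kinds
    out
  })
}

#' Sample occurrences from a true niche
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' true suitability of the niche at the cell; each occurrence is then placed
#' uniformly within its cell.
#'
#' @param seed integer seed.
#' @param stack an [env_stack()].
#' @param niche a [niche_spec()].
#' @param n number of occurrences, `>= 1`.
#' @param source source tag for the records.
#' @return an [occurrence_set()].
#' @export
sample_occurrences <- function(seed, stack, niche, n, source = "synthetic") {
  if (n < 1) abort_input("n must be >= 1")
  if (!any(stack$valid_mask)) abort_input("stack has no valid cells")
  s_layer <- true_suitability(stack, niche)
  cells <- which(!s_layer$nodata_mask)
  s <- s_layer$values[cells]
  g <- stack$geometry
  with_seed(seed, {
    pick <- sample(length(cells), n, replace = TRUE, prob = s)
    idx <- cells[pick]
    row <- (idx - 1) %% g$n_rows + 1
    col <- (idx - 1) %/% g$n_rows + 1
    lon <- g$x_origin + (col - 1 + stats::runif(n)) * g$cell_size
    lat <- g$y_origin - (row - 1 + stats::runif(n)) * g$cell_size
    occurrence_set(data.frame(
      id = sprintf("%s_%05d", niche$class_label, seq_len(n)),
      lon = lon, lat = lat, class = niche$class_label, source = source,
      stringsAsFactors = FALSE
    ))
  })
}

#' Random proxy points inside polygons
#'
#' Emulates the generation of coordinate proxies for cultivated occurrences
#' from agricultural polygons: points are drawn by rejection sampling in each
#' polygon's bounding box until they fall strictly inside it.
#'
#' @param seed integer seed.
#' @param polygons list of simple closed rings (2-column matrices; a repeated
#'   closing vertex is tolerated).
#' @param n_per_polygon points per polygon (0 gives an empty set).
#' @param class_label class assigned to the proxies.
#' @param source source tag.
#' @return an [occurrence_set()].
#' @export
make_polygon_proxies <- function(seed, polygons, n_per_polygon,
                                 class_label = "commercial",
                                 source = "polygon_proxy") {
  if (n_per_polygon < 0) abort_input("n_per_polygon must be >= 0")
  polys <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(unique(p)) < 3 || abs(polygon_area(p)) < 1e-300) {
      abort_input("degenerate polygon ring")
    }
    p
  })
  with_seed(seed, {
    pts <- lapply(seq_along(polys), function(k) {
      p <- polys[[k]]
      xr <- range(p[, 1]); yr <- range(p[, 2])
      got <- matrix(numeric(0), 0, 2)
      while (nrow(got) < n_per_polygon) {
        need <- n_per_polygon - nrow(got)
        cand_x <- stats::runif(2 * need + 8, xr[1], xr[2])
        cand_y <- stats::runif(2 * need + 8, yr[1], yr[2])
        ok <- point_in_polygon(cand_x, cand_y, p, tol = 0)
        got <- rbind(got, cbind(cand_x[ok], cand_y[ok]))
      }
      if (n_per_polygon == 0) matrix(numeric(0), 0, 3) else
        cbind(got[seq_len(n_per_polygon), , drop = FALSE], k)
    })
    pts <- do.call(rbind, pts)
    n <- nrow(pts)
    occurrence_set(data.frame(
      id = if (n) sprintf("proxy_%05d", seq_len(n)) else character(0),
      lon = pts[, 1], lat = pts[, 2],
      class = rep(class_label, n),
      source = if (n) paste0(source, "_", pts[, 3]) else character(0),
      stringsAsFactors = FALSE
    ))
  })
}

#' Scenario delta for a pseudo-GCM future
#'
#' @param gcm_id text id of the pseudo-GCM.
#' @param period one of 2050, 2070, 2090 (interval midpoints of the
#'   2041-2060, 2061-2080, 2081-2100 scenario averages).
#' @param pathway `"ssp245"` or `"ssp585"`.
#' @param temp_shift degrees added to temperature-kind layers.
#' @param precip_scale positive multiplier on precipitation-kind layers.
#' @param noise_sd SD of the smooth perturbation added to all layers.
#' @return object of class `scenario_delta`.
#' @export
scenario_delta <- function(gcm_id, period, pathway, temp_shift = 0,
                           precip_scale = 1, noise_sd = 0) {
  if (!period %in% c(2050, 2070, 2090)) abort_input("period must be 2050/2070/2090")
  pathway <- match.arg(pathway, c("ssp245", "ssp585"))
  if (precip_scale <= 0) abort_input("precip_scale must be > 0")
  structure(list(gcm_id = gcm_id, period = period, pathway = pathway,
                 temp_shift = temp_shift, precip_scale = precip_scale,
                 noise_sd = noise_sd),
            class = "scenario_delta")
}

#' Apply a scenario delta to a present-day stack
#'
#' Temperature-kind layers gain `temp_shift`; precipitation-kind layers are
#' multiplied by `precip_scale`; every layer then receives a smooth random
#' perturbation of SD `noise_sd`.  Geometry and masks are unchanged.
#'
#' @param stack present-day [env_stack()].
#' @param delta a [scenario_delta()].
#' @param var_kinds named map layer name -> kind; defaults to the stack's
#'   `var_kinds` attribute or [default_var_kinds()].
#' @param seed integer seed for the perturbation field.
#' @param smoothness perturbation kernel SD in cells.
#' @return a future [env_stack()].
#' @export
make_future_stack <- function(stack, delta, var_kinds = NULL, seed = 0,
                              smoothness = 5) {
  nms <- stack_names(stack)
  if (is.null(var_kinds)) var_kinds <- attr(stack, "var_kinds") %||%
      default_var_kinds(nms)
  missing <- setdiff(nms, names(var_kinds))
  if (length(missing)) abort_input("var_kinds missing for: %s",
                                   paste(missing, collapse = ", "))
  g <- stack$geometry
  with_seed(seed, {
    layers <- lapply(stack$layers, function(l) {
      v <- l$values
      kind <- var_kinds[[l$name]]
      if (kind == "temperature") v <- v + delta$temp_shift
      if (kind == "precipitation") v <- v * delta$precip_scale
      if (delta$noise_sd > 0) {
        f <- smooth_field(matrix(stats::rnorm(g$n_rows * g$n_cols),
                                 g$n_rows, g$n_cols), smoothness)
        v <- v + delta$noise_sd * f / stats::sd(as.vector(f))
      }
      env_layer(l$name, g, v, l$nodata_mask)
    })
    out <- env_stack(layers)
    attr(out, "var_kinds") <- var_kinds
    out
  })
}

# Stated warming (degrees C over present) by period x pathway; mid-range
# CMIP6-like ensemble values, fixed as part of the synthetic world.
SCENARIO_WARMING <- list(
  ssp245 = c(`2050` = 1.4, `2070` = 1.9, `2090` = 2.2),
  ssp585 = c(`2050` = 1.9, `2070` = 3.0, `2090` = 4.4)
)

#' Build a full future-scenario suite
#'
#' Emits `n_gcms` pseudo-GCMs for every period x pathway combination.  Each
#' pseudo-GCM has a fixed climate-sensitivity factor (0.75-1.25) and a
#' precipitation-response factor, both seeded, so warming and drying vary
#' across GCMs but are consistent for one GCM across scenarios, mirroring a
#' real ensemble's structure.
#'
#' @param stack present-day [env_stack()].
#' @param seed integer seed.
#' @param var_kinds layer kind map (see [make_future_stack()]).
#' @param periods,pathways scenario axes.
#' @param n_gcms pseudo-GCMs per combination (default 8, the ensemble size
#'   the analysis expects).
#' @param noise_sd perturbation SD per future layer.
#' @return object of class `scenario_suite`: list with `stacks` (named by
#'   `period_pathway_gcm`) and `meta` (one row per scenario).
#' @export
make_scenario_suite <- function(stack, seed, var_kinds = NULL,
                                periods = c(2050, 2070, 2090),
                                pathways = c("ssp245", "ssp585"),
                                n_gcms = 8, noise_sd = 0.15) {
  gcms <- sprintf("gcm%02d", seq_len(n_gcms))
  fac <- with_seed(child_seed(seed, 1), list(
    temp = stats::runif(n_gcms, 0.75, 1.25),
    precip = stats::runif(n_gcms, 0.5, 1.5)
  ))
  meta <- expand.grid(gcm = gcms, pathway = pathways, period = periods,
                      stringsAsFactors = FALSE)
  meta$scenario_id <- sprintf("%d_%s_%s", meta$period, meta$pathway, meta$gcm)
  stacks <- vector("list", nrow(meta))
  names(stacks) <- meta$scenario_id
  meta$temp_shift <- NA_real_
  meta$precip_scale <- NA_real_
  for (i in seq_len(nrow(meta))) {
    k <- match(meta$gcm[i], gcms)
    warm <- SCENARIO_WARMING[[meta$pathway[i]]][as.character(meta$period[i])]
    temp_shift <- warm * fac$temp[k]
    precip_scale <- max(0.5, 1 - 0.04 * warm * fac$precip[k])
    meta$temp_shift[i] <- temp_shift
    meta$precip_scale[i] <- precip_scale
    delta <- scenario_delta(meta$gcm[i], meta$period[i], meta$pathway[i],
                            temp_shift, precip_scale, noise_sd)
    stacks[[i]] <- make_future_stack(stack, delta, var_kinds,
                                     seed = child_seed(seed, 100 + i))
  }
  structure(list(stacks = stacks, meta = meta), class = "scenario_suite")
}

#' @export
print.scenario_suite <- function(x, ...) {
  cat(sprintf("<scenario_suite %d scenarios: %d periods x %d pathways x %d GCMs>\n",
              nrow(x$meta), length(unique(x$meta$period)),
              length(unique(x$meta$pathway)), length(unique(x$meta$gcm))))
  invisible(x)
}
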