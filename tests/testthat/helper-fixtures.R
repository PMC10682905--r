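# Shared fixtures and independent oracles.  Oracles are deliberately
# naive re-implementations (brute force / enumeration) kept separate from
# the package's code paths.

tiny_geom <- function(nr = 20, nc = 20, x0 = -100, y0 = 20, cs = 0.05) {
  grid_geometry(nr, nc, x0, y0, cs)
}

# 3-variable synthetic world on the niche-relevant variables
tiny_stack <- function(seed = 42, nr = 20, nc = 20, smoothness = 3) {
  make_env_layers(seed, tiny_geom(nr, nc), n_vars = 3,
                  var_names = c("bio9", "bio18", "bio15"),
                  smoothness = smoothness)
}

random_layer <- function(seed, nr = 7, nc = 5, mask_frac = 0.2) {
  set.seed(seed)
  v <- matrix(rnorm(nr * nc), nr, nc)
  mask <- matrix(runif(nr * nc) < mask_frac, nr, nc)
  env_layer("x", grid_geometry(nr, nc, -10, 5, 0.25), v, mask)
}

# Gift-wrapping (Jarvis march) convex hull oracle.
oracle_hull <- function(p) {
  p <- unique(as.matrix(p))
  n <- nrow(p)
  start <- which.min(p[, 1] + 1e-9 * p[, 2])
  hull_idx <- integer(0)
  cur <- start
  repeat {
    hull_idx <- c(hull_idx, cur)
    cand <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur) next
      cross <- (p[cand, 1] - p[cur, 1]) * (p[j, 2] - p[cur, 2]) -
        (p[cand, 2] - p[cur, 2]) * (p[j, 1] - p[cur, 1])
      d_cand <- sum((p[cand, ] - p[cur, ])^2)
      d_j <- sum((p[j, ] - p[cur, ])^2)
      if (cross < 0 || (cross == 0 && d_j > d_cand)) cand <- j
    }
    cur <- cand
    if (cur == start) break
  }
  p[hull_idx, , drop = FALSE]  # counter-clockwise from gift wrapping
}

oracle_shoelace <- function(poly) {
  n <- nrow(poly)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  s / 2
}

# Brute-force AUC: enumerate all presence x background pairs.
oracle_auc <- function(p, b) {
  wins <- 0
  for (x in p) for (y in b) {
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  wins / (length(p) * length(b))
}

# Independent haversine for thinning oracles.
oracle_haversine <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * 6371 * asin(sqrt(a))
}

# suitability_map wrapper around a plain value matrix (for overlap tests)
as_suit_map <- function(values, geom = NULL, id = "m") {
  values <- as.matrix(values)
  if (is.null(geom)) geom <- grid_geometry(nrow(values), ncol(values), 0,
                                           nrow(values), 1)
  structure(list(layer = env_layer(id, geom, values), model_id = id,
                 clamped_mask = matrix(FALSE, nrow(values), ncol(values))),
            class = "suitability_map")
}

as_binary_map <- function(mask, geom = NULL, threshold = 0.5, id = "m") {
  mask <- as.matrix(mask)
  if (is.null(geom)) geom <- grid_geometry(nrow(mask), ncol(mask), 0,
                                           nrow(mask), 1)
  structure(list(mask = mask, threshold_value = threshold, model_id = id,
                 scenario_id = id, geometry = geom), class = "binary_map")
}

keep_attrs_test <- function(new, old) {
  attr(new, "env_vars") <- attr(old, "env_vars")
  class(new) <- class(old)
  new
}

make_occ <- function(lon, lat, class = "wild", prefix = class) {
  occurrence_set(data.frame(
    id = paste0(prefix, "_", seq_along(lon)), lon = lon, lat = lat,
    class = class, source = "test", stringsAsFactors = FALSE))
}
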