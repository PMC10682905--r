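# Occurrence data model and preprocessing: class vocabulary, spatial
# thinning, environmental extraction, collinearity filtering and
# train/test splitting.

FINE_CLASSES <- c("wild", "semiwild", "landrace", "commercial")
BROAD_CLASSES <- c("wild_sl", "cultivated")

#' Georeferenced, class-labelled occurrence records
#'
#' A thin data.frame subclass with columns `id, lon, lat, class, source`;
#' extracted environment values, when present, are appended as additional
#' numeric columns whose names are recorded in the `env_vars` attribute.
#'
#' @param records data.frame with at least `id, lon, lat, class, source`.
#' @return object of class `occurrence_set` (still a data.frame).
#' @export
occurrence_set <- function(records) {
  need <- c("id", "lon", "lat", "class", "source")
  if (!all(need %in% names(records))) {
    abort_input("occurrence records need columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(records$id)) abort_input("occurrence ids must be unique")
  if (nrow(records) &&
      (any(records$lon < -180 | records$lon > 180) ||
       any(records$lat < -90 | records$lat > 90))) {
    abort_input("coordinates out of range")
  }
  bad <- setdiff(unique(records$class), c(FINE_CLASSES, BROAD_CLASSES,
                                          "cultivated_unassigned"))
  if (length(bad)) abort_input("unknown class labels: %s", paste(bad, collapse = ", "))
  structure(as.data.frame(records, stringsAsFactors = FALSE),
            class = c("occurrence_set", "data.frame"))
}

#' Names of extracted environment columns of an occurrence set
#' @param points an `occurrence_set`.
#' @return character vector (empty if not extracted).
#' @export
env_vars <- function(points) attr(points, "env_vars") %||% character(0)

#' Extracted environment matrix of an occurrence set
#' @param points an `occurrence_set` that went through [extract_env()].
#' @return numeric matrix records x variables.
#' @export
env_matrix <- function(points) {
  v <- env_vars(points)
  if (!length(v)) abort_input("occurrence set has no extracted environment")
  as.matrix(points[, v, drop = FALSE])
}

#' Combine occurrence sets (e.g. into broad classes)
#'
#' Broad labels derive from fine labels by the stated unions:
#' `wild_sl = wild + semiwild`; `cultivated = landrace + commercial`
#' (+ unassigned-cultivated records).
#'
#' @param points an `occurrence_set` with fine labels.
#' @param broad `"wild_sl"` or `"cultivated"`.
#' @return an `occurrence_set` relabelled to the broad class.
#' @export
as_broad_class <- function(points, broad = c("wild_sl", "cultivated")) {
  broad <- match.arg(broad)
  members <- if (broad == "wild_sl") c("wild", "semiwild")
             else c("landrace", "commercial", "cultivated_unassigned")
  sub <- points[points$class %in% members, , drop = FALSE]
  sub$class <- broad
  sub$id <- paste0(broad, "_", sub$id)
  keep_attrs(sub, points)
}

keep_attrs <- function(new, old) {
  attr(new, "env_vars") <- attr(old, "env_vars")
  class(new) <- class(old)
  new
}

#' Read / write occurrence CSV
#'
#' Schema: `id,lon,lat,class,source` plus any extracted variable columns.
#'
#' @param path CSV path.
#' @return an `occurrence_set`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) abort_input("occurrence file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("id", "lon", "lat", "class", "source"))
  out <- occurrence_set(df)
  if (length(extra)) attr(out, "env_vars") <- extra
  out
}

#' @rdname read_occurrences
#' @param points an `occurrence_set`.
#' @export
write_occurrences <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Spatial thinning at a minimum great-circle distance
#'
#' Greedy first-come pass in input order: a record is kept iff its haversine
#' distance to every already-kept record is at least `min_dist_km`.  Input
#' order defines priority, making the result deterministic; set
#' `shuffle_seed` to apply a seeded shuffle first for sensitivity checks.
#'
#' @param points an `occurrence_set`.
#' @param min_dist_km minimum pairwise distance in km (the pipeline default
#'   is 5); 0 is the identity.
#' @param shuffle_seed optional seed for a pre-thinning shuffle.
#' @return thinned `occurrence_set` (subset of the input).
#' @export
thin <- function(points, min_dist_km, shuffle_seed = NULL) {
  if (min_dist_km < 0) abort_input("min_dist_km must be >= 0")
  n <- nrow(points)
  if (n == 0 || min_dist_km == 0) return(points)
  ord <- seq_len(n)
  if (!is.null(shuffle_seed)) ord <- with_seed(shuffle_seed, sample(n))
  lon <- points$lon[ord]; lat <- points$lat[ord]
  kept <- integer(0)
  for (i in seq_len(n)) {
    if (length(kept) == 0 ||
        all(haversine_km(lon[kept], lat[kept], lon[i], lat[i]) >= min_dist_km)) {
      kept <- c(kept, i)
    }
  }
  out <- points[sort(ord[kept]), , drop = FALSE]
  keep_attrs(out, points)
}

#' Extract environmental values at occurrence locations
#'
#' Each record gains the stack's layer values at its containing cell (cell
#' assignment uses the documented half-open rule, see [locate_cells()]).
#' Records on masked cells or outside the grid are excluded, with the count
#' reported via a message and the `n_excluded` attribute.
#'
#' @param points an `occurrence_set`.
#' @param stack an [env_stack()].
#' @return `occurrence_set` with one column per layer appended.
#' @export
extract_env <- function(points, stack) {
  loc <- locate_cells(stack$geometry, points$lon, points$lat)
  cell <- (loc$col - 1L) * stack$geometry$n_rows + loc$row
  ok <- !is.na(cell)
  ok[ok] <- stack$valid_mask[cell[ok]]
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(sprintf("extract_env: excluded %d record(s) off-grid or on masked cells",
                    n_excluded))
  }
  out <- points[ok, , drop = FALSE]
  vals <- stack_values(stack, cell[ok])
  for (nm in colnames(vals)) out[[nm]] <- vals[, nm]
  out <- keep_attrs(out, points)
  attr(out, "env_vars") <- colnames(vals)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Greedy collinearity filter on environment variables
#'
#' Iterates variable pairs with `|Pearson r|` above the threshold in
#' descending `|r|`; at each step the member with the larger mean absolute
#' correlation to all remaining variables is dropped, unless it is protected
#' by `keep` (the expert-knowledge hook).  Constant variables are excluded
#' up front with a warning (their correlation is undefined).
#'
#' @param env_table numeric records x variables matrix (or data.frame).
#' @param threshold maximum tolerated `|r|` (default 0.8).
#' @param keep variable names never to drop.
#' @return character vector of retained variable names.
#' @export
correlation_filter <- function(env_table, threshold = 0.8, keep = character(0)) {
  x <- as.matrix(env_table)
  if (nrow(x) < 2) abort_input("correlation filter needs >= 2 records")
  const <- apply(x, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  vars <- colnames(x)
  if (length(vars) < 2) return(vars)
  r <- abs(stats::cor(x))
  diag(r) <- 0
  repeat {
    m <- max(r[vars, vars])
    if (m <= threshold) break
    idx <- which(r[vars, vars] == m, arr.ind = TRUE)[1, ]
    a <- vars[idx[1]]; b <- vars[idx[2]]
    mean_r <- function(v) mean(r[v, setdiff(vars, v)])
    drop <- if (a %in% keep && b %in% keep) NULL
            else if (a %in% keep) b
            else if (b %in% keep) a
            else if (mean_r(a) >= mean_r(b)) a else b
    if (is.null(drop)) { r[a, b] <- r[b, a] <- 0; next }  # both protected
    vars <- setdiff(vars, drop)
    if (length(vars) < 2) break
  }
  vars
}

#' Seeded train/test split of occurrences
#'
#' @param points an `occurrence_set`.
#' @param test_fraction proportion in `[0, 1)`; test size is
#'   `round(n * test_fraction)`.
#' @param seed integer seed.
#' @return list with `train` and `test` occurrence sets (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(points, test_fraction, seed) {
  if (test_fraction < 0 || test_fraction >= 1) {
    abort_input("test_fraction must be in [0, 1)")
  }
  n <- nrow(points)
  n_test <- round(n * test_fraction)
  test_idx <- with_seed(seed, sample(n, n_test))
  list(train = keep_attrs(points[setdiff(seq_len(n), test_idx), , drop = FALSE], points),
       test = keep_attrs(points[test_idx, , drop = FALSE], points))
}
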