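# Future-scenario bookkeeping: percentile thresholding into binary range
# maps, loss/gain/shift pixel accounting against the present, multi-GCM
# intersections, between-class overlap change, and MESS transferability
# surfaces.

#' Threshold a suitability map on training-presence scores
#'
#' The threshold is the k-th smallest training presence score with
#' `k = floor(percentile/100 * n) + 1`, so at most `floor(p * n)` training
#' presences fall strictly below it (exact on small n; no interpolation).
#' The same present-derived threshold is reused for all future projections
#' of a class.
#'
#' @param map a `suitability_map` (or `env_layer`).
#' @param training_presence_scores suitability of the training presences
#'   under the present model (non-empty).
#' @param percentile training-presence percentile (default 10, the analysis
#'   convention).
#' @param scenario_id label, `"present"` or `period_pathway_gcm`.
#' @return object of class `binary_map`: logical `mask`, `threshold_value`,
#'   `model_id`, `scenario_id`, `geometry`.
#' @export
binarize <- function(map, training_presence_scores, percentile = 10,
                     scenario_id = "present") {
  scores <- training_presence_scores[is.finite(training_presence_scores)]
  if (length(scores) == 0) abort_input("no training presence scores")
  layer <- if (inherits(map, "suitability_map")) map$layer else map
  k <- floor(percentile / 100 * length(scores)) + 1
  k <- min(k, length(scores))
  threshold <- sort(scores)[k]
  mask <- !layer$nodata_mask & !is.na(layer$values) & layer$values >= threshold
  structure(list(mask = mask, threshold_value = threshold,
                 model_id = if (inherits(map, "suitability_map")) map$model_id else layer$name,
                 scenario_id = scenario_id, geometry = layer$geometry),
            class = "binary_map")
}

#' Apply a precomputed threshold to a suitability map
#' @param map `suitability_map` or `env_layer`.
#' @param threshold suitability threshold.
#' @param scenario_id label.
#' @return a `binary_map`.
#' @export
binarize_at <- function(map, threshold, scenario_id = "present") {
  layer <- if (inherits(map, "suitability_map")) map$layer else map
  mask <- !layer$nodata_mask & !is.na(layer$values) & layer$values >= threshold
  structure(list(mask = mask, threshold_value = threshold,
                 model_id = if (inherits(map, "suitability_map")) map$model_id else layer$name,
                 scenario_id = scenario_id, geometry = layer$geometry),
            class = "binary_map")
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map '%s' threshold %.4f, %d suitable pixels>\n",
              x$scenario_id, x$threshold_value, sum(x$mask)))
  invisible(x)
}

#' Loss / gain / shift pixel accounting between two binary maps
#'
#' `lost = present & !future`, `gained = !present & future`, `retained =
#' present & future`; the conservation identities `n_present = n_retained +
#' n_lost` and `n_future = n_retained + n_gained` hold by construction.
#' "Shift" is reported as the (lost, gained) pair.
#'
#' @param present,future co-registered `binary_map`s.
#' @return object of class `change_metrics` with pixel counts and
#'   `frac_lost`/`frac_gained` relative to the present extent.
#' @export
change_metrics <- function(present, future) {
  stopifnot_coregistered(present$geometry, future$geometry)
  retained <- present$mask & future$mask
  lost <- present$mask & !future$mask
  gained <- !present$mask & future$mask
  n_present <- sum(present$mask)
  structure(list(
    n_present = n_present, n_future = sum(future$mask),
    n_retained = sum(retained), n_lost = sum(lost), n_gained = sum(gained),
    frac_lost = if (n_present > 0) sum(lost) / n_present else NA_real_,
    frac_gained = if (n_present > 0) sum(gained) / n_present else NA_real_,
    lost_mask = lost, gained_mask = gained
  ), class = "change_metrics")
}

#' Intersection / union of binary maps across a GCM ensemble
#'
#' The intersection keeps only pixels supported by every input map (the
#' stringent all-GCM criterion); the union variant is provided alongside.
#'
#' @param maps non-empty list of co-registered `binary_map`s.
#' @return a `binary_map` with `scenario_id` suffixed `_intersection` /
#'   `_union`.
#' @export
gcm_intersection <- function(maps) {
  combine_binary(maps, `&`, "intersection")
}

#' @rdname gcm_intersection
#' @export
gcm_union <- function(maps) {
  combine_binary(maps, `|`, "union")
}

combine_binary <- function(maps, op, tag) {
  if (length(maps) < 1) abort_input("need >= 1 binary map")
  g <- maps[[1]]$geometry
  for (m in maps) stopifnot_coregistered(g, m$geometry)
  mask <- Reduce(op, lapply(maps, function(m) m$mask))
  structure(list(mask = mask, threshold_value = maps[[1]]$threshold_value,
                 model_id = maps[[1]]$model_id,
                 scenario_id = paste0(sub("_[^_]*$", "", maps[[1]]$scenario_id),
                                      "_", tag),
                 geometry = g),
            class = "binary_map")
}

#' Between-class overlap and its future change
#'
#' Reports, for one class pair, the overlap pixel count and percent
#' (intersection / union convention) in the present and in the future, plus
#' the cells where present overlap is lost (suitable for both classes today
#' but not under the future maps).
#'
#' @param class_a_present,class_a_future,class_b_present,class_b_future
#'   co-registered `binary_map`s.
#' @return list with present/future overlap counts and percents and the
#'   `overlap_lost_mask`.
#' @export
class_overlap_change <- function(class_a_present, class_a_future,
                                 class_b_present, class_b_future) {
  g <- class_a_present$geometry
  for (m in list(class_a_future, class_b_present, class_b_future)) {
    stopifnot_coregistered(g, m$geometry)
  }
  pct <- function(a, b) {
    uni <- sum(a | b)
    if (uni == 0) 0 else 100 * sum(a & b) / uni
  }
  ov_present <- class_a_present$mask & class_b_present$mask
  ov_future <- class_a_future$mask & class_b_future$mask
  list(
    n_overlap_present = sum(ov_present),
    pct_overlap_present = pct(class_a_present$mask, class_b_present$mask),
    n_overlap_future = sum(ov_future),
    pct_overlap_future = pct(class_a_future$mask, class_b_future$mask),
    overlap_lost_mask = ov_present & !ov_future,
    n_overlap_lost = sum(ov_present & !ov_future)
  )
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Per cell and variable with projected value `p` and training fraction
#' `f = 100 * (fraction of training values < p)`: similarity is
#' `(p - min)/(max - min) * 100` when `f = 0`; `2f` when `0 < f <= 50`;
#' `2(100 - f)` when `50 < f < 100`; `(max - p)/(max - min) * 100` when
#' `f = 100`.  The cell's MESS value is the minimum over variables, and
#' negative values flag non-analog (out-of-training-range) conditions.
#' For a constant training variable, similarity is 0 where the projected
#' value equals the constant and strongly negative
#' (`-100 * |p - constant|`) elsewhere; such variables are flagged with a
#' warning.
#'
#' @param projection_env an [env_stack()] of projection-time layers.
#' @param training_env training records x variables matrix covering the
#'   stack's variables.
#' @return object of class `mess_map`: `values` (an [env_layer()], percent
#'   similarity units) and `most_dissimilar_var` (character matrix).
#' @export
mess <- function(projection_env, training_env) {
  Tm <- as.matrix(training_env)
  vars <- stack_names(projection_env)
  missing <- setdiff(vars, colnames(Tm))
  if (length(missing)) abort_input("training env lacks variables: %s",
                                   paste(missing, collapse = ", "))
  cells <- which(projection_env$valid_mask)
  X <- stack_values(projection_env, cells)
  sim <- matrix(NA_real_, length(cells), length(vars))
  for (j in seq_along(vars)) {
    v <- sort(Tm[, vars[j]])
    n <- length(v)
    lo <- v[1]; hi <- v[n]
    p <- X[, j]
    if (hi - lo <= 0) {
      warning("constant training variable in MESS: ", vars[j])
      sim[, j] <- ifelse(p == lo, 0, -100 * abs(p - lo))
      next
    }
    f <- 100 * findInterval(p, v, left.open = TRUE) / n
    s <- numeric(length(p))
    s[f == 0] <- (p[f == 0] - lo) / (hi - lo) * 100
    s[f == 100] <- (hi - p[f == 100]) / (hi - lo) * 100
    mid_lo <- f > 0 & f <= 50
    s[mid_lo] <- 2 * f[mid_lo]
    mid_hi <- f > 50 & f < 100
    s[mid_hi] <- 2 * (100 - f[mid_hi])
    sim[, j] <- s
  }
  mess_cell <- apply(sim, 1, min)
  worst <- vars[apply(sim, 1, which.min)]
  g <- projection_env$geometry
  vals <- matrix(NA_real_, g$n_rows, g$n_cols)
  vals[cells] <- mess_cell
  wm <- matrix(NA_character_, g$n_rows, g$n_cols)
  wm[cells] <- worst
  structure(list(values = env_layer("mess", g, vals),
                 most_dissimilar_var = wm),
            class = "mess_map")
}

#' Long change-accounting table across a scenario suite
#'
#' For each class and each scenario in the suite, the class's replicate
#' models are projected onto the scenario's layers, the per-cell median map
#' is thresholded with the class's *present-derived* threshold, and
#' [change_metrics()] against the class's present binary map are recorded.
#' One extra row per class, period and pathway holds the all-GCM
#' intersection (gcm = `"ALL"`).  Missing scenarios are listed as absent
#' (NA metrics), not errors.
#'
#' @param suite a [make_scenario_suite()] result.
#' @param models named list (per class) of lists of `maxent_model`
#'   replicates (a single model is accepted).
#' @param present_bins named list (per class) of present-day `binary_map`s.
#' @param clamp clamp projections to each model's training range.
#' @return data.frame keyed by class / period / pathway / gcm.
#' @export
scenario_summary <- function(suite, models, present_bins, clamp = TRUE) {
  classes <- names(models)
  rows <- list()
  bins_store <- list()
  for (cl in classes) {
    mods <- models[[cl]]
    if (inherits(mods, "maxent_model")) mods <- list(mods)
    pres <- present_bins[[cl]]
    for (i in seq_len(nrow(suite$meta))) {
      sid <- suite$meta$scenario_id[i]
      stack_f <- suite$stacks[[sid]]
      if (is.null(stack_f)) {
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, period = suite$meta$period[i],
          pathway = suite$meta$pathway[i], gcm = suite$meta$gcm[i],
          absent = TRUE, n_present = NA, n_future = NA, n_retained = NA,
          n_lost = NA, n_gained = NA, frac_lost = NA, frac_gained = NA,
          stringsAsFactors = FALSE)
        next
      }
      proj <- lapply(mods, function(m) predict_logistic(m, stack_f, clamp))
      arr <- vapply(proj, function(p) p$layer$values,
                    matrix(0, stack_f$geometry$n_rows, stack_f$geometry$n_cols))
      med <- if (length(proj) == 1) arr[, , 1] else apply(arr, c(1, 2), stats::median)
      med_layer <- env_layer("median", stack_f$geometry, med)
      fut_bin <- binarize_at(med_layer, pres$threshold_value, sid)
      bins_store[[paste(cl, sid, sep = ".")]] <- fut_bin
      cm <- change_metrics(pres, fut_bin)
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, period = suite$meta$period[i],
        pathway = suite$meta$pathway[i], gcm = suite$meta$gcm[i],
        absent = FALSE,
        n_present = cm$n_present, n_future = cm$n_future,
        n_retained = cm$n_retained, n_lost = cm$n_lost,
        n_gained = cm$n_gained, frac_lost = cm$frac_lost,
        frac_gained = cm$frac_gained, stringsAsFactors = FALSE)
    }
    # all-GCM intersection per period x pathway
    for (per in unique(suite$meta$period)) {
      for (pw in unique(suite$meta$pathway)) {
        sids <- suite$meta$scenario_id[suite$meta$period == per &
                                         suite$meta$pathway == pw]
        bins <- bins_store[paste(cl, sids, sep = ".")]
        bins <- Filter(Negate(is.null), bins)
        if (length(bins) == 0) next
        inter <- gcm_intersection(bins)
        cm <- change_metrics(pres, inter)
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, period = per, pathway = pw, gcm = "ALL",
          absent = FALSE,
          n_present = cm$n_present, n_future = cm$n_future,
          n_retained = cm$n_retained, n_lost = cm$n_lost,
          n_gained = cm$n_gained, frac_lost = cm$frac_lost,
          frac_gained = cm$frac_gained, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "future_bins") <- bins_store
  out
}
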