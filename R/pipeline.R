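# End-to-end pipeline: simulate -> thin -> extract -> variable filter ->
# PCA envelopes -> per-class maxent -> overlap suite -> futures suite ->
# report.  Everything is driven by one config object and one master seed;
# rerunning with the same config reproduces identical output files.

#' Pipeline configuration
#'
#' Defaults mirror the study design: 5-km thinning, 10000 background cells,
#' 30% test points, 10 replicates, 500 optimizer iterations, LQHP features,
#' 10th-percentile training threshold, 3-degree study-area buffer,
#' regularization multiplier 3 for wild, semiwild, wild-sl and landrace
#' models and 1 for commercial and cultivated, and a 3-period x 2-pathway x
#' 8-GCM future ensemble.  Override any field for desk-scale runs.
#'
#' @param seed master seed; every stage derives a child seed from it.
#' @param classes classes to model (fine and/or broad).
#' @param n_occurrences named per-fine-class occurrence counts for the
#'   synthetic world (defaults: the study's class sizes).
#' @param reg_multipliers named per-class regularization multipliers.
#' @param thin_km,buffer_deg,n_background,test_fraction,n_replicates,max_iter
#'   study-design scalars, see above.
#' @param threshold_percentile training-presence threshold percentile.
#' @param feature_classes,hinge_knots maxent feature configuration.
#' @param correlation_threshold collinearity filter cutoff.
#' @param grid list(n_rows, n_cols, x_origin, y_origin, cell_size) of the
#'   synthetic landscape.
#' @param n_vars synthetic layers to generate.
#' @param proxy_fraction fraction of commercial occurrences generated as
#'   polygon proxies instead of direct niche draws.
#' @param scenario list(periods, pathways, n_gcms, noise_sd).
#' @param n_null_reps repetitions for equivalency/background tests.
#' @param n_boot bootstrap resamples for envelope CIs.
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       classes = c("wild", "semiwild", "landrace",
                                   "commercial", "wild_sl", "cultivated"),
                       n_occurrences = c(wild = 302, semiwild = 86,
                                         landrace = 277, commercial = 2178),
                       reg_multipliers = c(wild = 3, semiwild = 3,
                                           wild_sl = 3, landrace = 3,
                                           commercial = 1, cultivated = 1),
                       thin_km = 5, buffer_deg = 3, n_background = 10000,
                       test_fraction = 0.3, n_replicates = 10,
                       max_iter = 500, threshold_percentile = 10,
                       feature_classes = c("L", "Q", "H", "P"),
                       hinge_knots = 30, correlation_threshold = 0.8,
                       grid = list(n_rows = 100, n_cols = 100,
                                   x_origin = -110, y_origin = 25,
                                   cell_size = 0.0416667),
                       n_vars = 9, proxy_fraction = 0.25,
                       scenario = list(periods = c(2050, 2070, 2090),
                                       pathways = c("ssp245", "ssp585"),
                                       n_gcms = 8, noise_sd = 0.15),
                       n_null_reps = 49, n_boot = 1000) {
  cfg <- as.list(environment())
  missing_reg <- setdiff(classes, names(reg_multipliers))
  if (length(missing_reg)) {
    abort_input("no reg_multiplier for class(es): %s",
                paste(missing_reg, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Executes simulate -> thin -> extract -> variable filter -> PCA/envelope
#' -> fit/project per class -> overlap suite -> futures suite -> report,
#' writing all artifacts (CSV summaries, ASCII rasters, lambdas files, a
#' JSON manifest and a log) under `out_dir`.  Any stage failure aborts with
#' a stage-tagged condition.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; key objects are returned as the
#'   `results` attribute.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) abort_input("config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "pipeline.log"), "wb")
  on.exit(close(log_con))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(
        list(message = sprintf("[stage %s] %s", name, conditionMessage(e)),
             call = NULL),
        class = c("nichegrad_stage_error", class(e))))
    })
  }
  seed <- config$seed
  fine <- intersect(config$classes, FINE_CLASSES)
  broad <- intersect(config$classes, BROAD_CLASSES)

  ## -- simulate ------------------------------------------------------------
  g <- do.call(grid_geometry, config$grid)
  stack <- stage("simulate", make_env_layers(child_seed(seed, 1), g,
                                             n_vars = config$n_vars))
  niches <- default_niches()
  occ_list <- list()
  stage("simulate", {
    need_fine <- union(fine, unlist(list(
      if ("wild_sl" %in% broad) c("wild", "semiwild"),
      if ("cultivated" %in% broad) c("landrace", "commercial"))))
    for (cl in need_fine) {
      n <- config$n_occurrences[[cl]]
      n_proxy <- if (cl == "commercial") round(n * config$proxy_fraction) else 0L
      occ <- sample_occurrences(child_seed(seed, 10 + match(cl, FINE_CLASSES)),
                                stack, niches[[cl]], n - n_proxy)
      if (n_proxy > 0) {
        poly <- proxy_polygon_for(stack, niches[[cl]])
        prox <- make_polygon_proxies(child_seed(seed, 20), list(poly),
                                     n_proxy, class_label = cl)
        occ <- keep_attrs(rbind(occ, prox), occ)
      }
      occ_list[[cl]] <- occ
    }
  })
  all_occ <- keep_attrs(do.call(rbind, occ_list), occ_list[[1]])
  write_occurrences(all_occ, file.path(out_dir, "occurrences_raw.csv"))
  pipeline_log(log_con, "simulate", sprintf("%d occurrences over %d classes",
                                            nrow(all_occ), length(occ_list)))

  ## -- thin / extract ------------------------------------------------------
  thinned <- stage("thin", {
    parts <- lapply(occ_list, thin, min_dist_km = config$thin_km)
    keep_attrs(do.call(rbind, parts), all_occ)
  })
  pipeline_log(log_con, "thin", sprintf("kept %d / %d records at %g km",
                                        nrow(thinned), nrow(all_occ),
                                        config$thin_km))
  extracted <- stage("extract", extract_env(thinned, stack))
  write_occurrences(extracted, file.path(out_dir, "occurrences_extracted.csv"))

  ## -- variable filter -----------------------------------------------------
  retained <- stage("filter", correlation_filter(env_matrix(extracted),
                                                 config$correlation_threshold))
  utils::write.csv(data.frame(variable = retained),
                   file.path(out_dir, "retained_variables.csv"),
                   row.names = FALSE, quote = FALSE)
  pipeline_log(log_con, "filter", sprintf("retained %d / %d variables",
                                          length(retained),
                                          length(env_vars(extracted))))

  ## -- PCA envelopes -------------------------------------------------------
  fine_pts <- extracted[extracted$class %in% fine, , drop = FALSE]
  fine_pts <- keep_attrs(fine_pts, extracted)
  envres <- stage("envelope", envelope_analysis(fine_pts, retained))
  utils::write.csv(cbind(variable = rownames(envres$pca$loadings),
                         as.data.frame(envres$pca$loadings)),
                   file.path(out_dir, "pca_loadings.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(envres$overlaps, file.path(out_dir, "envelope_overlaps.csv"),
                   row.names = FALSE, quote = FALSE)
  letters_rows <- stage("envelope", {
    rows <- list()
    for (v in retained) {
      cis <- lapply(stats::setNames(fine, fine), function(cl) {
        bootstrap_ci(fine_pts[[v]][fine_pts$class == cl],
                     n_boot = config$n_boot,
                     seed = child_seed(seed, 30 + match(v, retained)))
      })
      lab <- ci_letter_groups(cis)
      for (cl in fine) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, class = cl, estimate = cis[[cl]]$estimate,
          ci_low = cis[[cl]]$ci_low, ci_high = cis[[cl]]$ci_high,
          letters = lab[[cl]], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(letters_rows, file.path(out_dir, "envelope_ci_letters.csv"),
                   row.names = FALSE, quote = FALSE)

  ## -- study area + per-class models --------------------------------------
  cropped <- stage("crop", crop_to_hull(stack, thinned, config$buffer_deg))
  bg_full <- stage("fit", sample_background(cropped, config$n_background,
                                            child_seed(seed, 40)))
  bg <- bg_full[, retained, drop = FALSE]
  class_pts <- stats::setNames(lapply(config$classes, function(cl) {
    if (cl %in% BROAD_CLASSES) as_broad_class(extracted, cl)
    else keep_attrs(extracted[extracted$class == cl, , drop = FALSE], extracted)
  }), config$classes)
  models <- list(); present_bins <- list(); eval_rows <- list()
  median_maps <- list()
  stage("fit", {
    for (cl in config$classes) {
      pts <- class_pts[[cl]]
      P <- env_matrix(pts)[, retained, drop = FALSE]
      cv <- replicate_cv(P, bg, cropped,
                         feature_classes = config$feature_classes,
                         hinge_knots = config$hinge_knots,
                         reg_multiplier = config$reg_multipliers[[cl]],
                         n_replicates = config$n_replicates,
                         test_fraction = config$test_fraction,
                         max_iter = config$max_iter,
                         seed = child_seed(seed, 50 + match(cl, config$classes)))
      models[[cl]] <- cv
      median_maps[[cl]] <- cv$median_map
      write_raster(cv$median_map$layer,
                   file.path(out_dir, sprintf("suitability_median_%s.asc", cl)))
      write_maxent_model(cv$replicates[[1]]$model,
                         file.path(out_dir, sprintf("lambdas_%s.txt", cl)))
      train_scores <- suitability_at_points(cv$median_map, pts)
      present_bins[[cl]] <- binarize(cv$median_map, train_scores,
                                      config$threshold_percentile)
      for (k in seq_along(cv$replicates)) {
        ev <- cv$replicates[[k]]$eval
        eval_rows[[length(eval_rows) + 1]] <- data.frame(
          class = cl, replicate = k, auc_train = ev$auc_train,
          auc_test = ev$auc_test, max_tss = ev$tss$max_tss,
          stringsAsFactors = FALSE)
      }
      pipeline_log(log_con, "fit",
                   sprintf("%s: mean test AUC %.3f, threshold %.4f", cl,
                           mean(vapply(cv$replicates,
                                       function(r) r$eval$auc_test, 0)),
                           present_bins[[cl]]$threshold_value))
    }
  })
  utils::write.csv(do.call(rbind, eval_rows),
                   file.path(out_dir, "model_eval.csv"),
                   row.names = FALSE, quote = FALSE)

  ## -- overlap suite -------------------------------------------------------
  ov_rows <- stage("overlap", {
    prs <- utils::combn(config$classes, 2, simplify = FALSE)
    do.call(rbind, lapply(prs, function(pr) {
      st <- overlap_stats(median_maps[[pr[1]]], median_maps[[pr[2]]])
      data.frame(class_a = pr[1], class_b = pr[2],
                 schoener_d = st$schoener_d, warren_i = st$warren_i,
                 spearman_rho = st$spearman_rho, n_cells = st$n_cells,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(ov_rows, file.path(out_dir, "overlap_stats.csv"),
                   row.names = FALSE, quote = FALSE)
  rnd_rows <- stage("overlap", {
    rows <- list()
    test_pairs <- Filter(function(pr) all(pr %in% config$classes),
                         list(c("wild", "landrace"), c("wild", "commercial")))
    cfg_red <- overlap_enm_config(max_iter = min(config$max_iter, 200))
    for (pr in test_pairs) {
      bt <- background_test(class_pts[[pr[1]]], class_pts[[pr[2]]],
                            NULL, cropped, cfg_red,
                            n_reps = config$n_null_reps,
                            seed = child_seed(seed, 60 + match(pr[2], config$classes)))
      rows[[length(rows) + 1]] <- data.frame(
        test = "background", class_a = pr[1], class_b = pr[2],
        observed_d = bt$observed$schoener_d,
        p_low = bt$p_low[["schoener_d"]], p_high = bt$p_high[["schoener_d"]],
        n_reps = bt$n_reps, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  if (!is.null(rnd_rows)) {
    utils::write.csv(rnd_rows, file.path(out_dir, "randomization_tests.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  ## -- futures suite -------------------------------------------------------
  suite <- stage("futures", make_scenario_suite(
    cropped, child_seed(seed, 70),
    periods = config$scenario$periods, pathways = config$scenario$pathways,
    n_gcms = config$scenario$n_gcms, noise_sd = config$scenario$noise_sd))
  rep_models <- lapply(models, function(cv) {
    lapply(cv$replicates, function(r) r$model)
  })
  fut <- stage("futures", scenario_summary(suite, rep_models, present_bins))
  utils::write.csv(fut, file.path(out_dir, "futures_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  occ_change <- stage("futures", {
    if (!all(c("wild", "landrace") %in% config$classes)) NULL else {
      bins <- attr(fut, "future_bins")
      rows <- list()
      for (per in config$scenario$periods) {
        for (pw in config$scenario$pathways) {
          sids <- suite$meta$scenario_id[suite$meta$period == per &
                                           suite$meta$pathway == pw]
          w_bins <- Filter(Negate(is.null), bins[paste("wild", sids, sep = ".")])
          l_bins <- Filter(Negate(is.null), bins[paste("landrace", sids, sep = ".")])
          ch <- class_overlap_change(present_bins$wild,
                                     gcm_intersection(w_bins),
                                     present_bins$landrace,
                                     gcm_intersection(l_bins))
          rows[[length(rows) + 1]] <- data.frame(
            class_a = "wild", class_b = "landrace", period = per, pathway = pw,
            n_overlap_present = ch$n_overlap_present,
            pct_overlap_present = ch$pct_overlap_present,
            n_overlap_future = ch$n_overlap_future,
            pct_overlap_future = ch$pct_overlap_future,
            n_overlap_lost = ch$n_overlap_lost, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }
  })
  if (!is.null(occ_change)) {
    utils::write.csv(occ_change, file.path(out_dir, "class_overlap_change.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  mess_rows <- stage("mess", {
    rows <- list()
    for (per in config$scenario$periods) {
      for (pw in config$scenario$pathways) {
        sid <- suite$meta$scenario_id[suite$meta$period == per &
                                        suite$meta$pathway == pw][1]
        mm <- mess(suite$stacks[[sid]], bg_full)
        v <- mm$values$values[!mm$values$nodata_mask]
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sid, frac_novel = mean(v < 0), min_mess = min(v),
          median_mess = stats::median(v), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(mess_rows, file.path(out_dir, "mess_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  ## -- manifest ------------------------------------------------------------
  manifest <- config
  class(manifest) <- NULL
  manifest$stage_seeds <- list(
    env = child_seed(seed, 1), background = child_seed(seed, 40),
    scenarios = child_seed(seed, 70))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(log_con, "report", "pipeline complete")
  res <- list(stack = stack, cropped = cropped, occurrences = extracted,
              retained = retained, envelope = envres, models = models,
              present_bins = present_bins, overlaps = ov_rows,
              futures = fut, suite_meta = suite$meta)
  out <- out_dir
  attr(out, "results") <- res
  invisible(out)
}

# Rectangle proxy polygon around the high-suitability region of a niche:
# stands in for agricultural polygons from which cultivated proxy points
# are drawn.
proxy_polygon_for <- function(stack, niche, top_frac = 0.1) {
  s <- true_suitability(stack, niche)
  cells <- which(!s$nodata_mask)
  vals <- s$values[cells]
  top <- cells[vals >= stats::quantile(vals, 1 - top_frac)]
  g <- stack$geometry
  row <- (top - 1) %% g$n_rows + 1
  col <- (top - 1) %/% g$n_rows + 1
  cc <- cell_centers(g)
  xr <- range(cc$x[col]); yr <- range(cc$y[row])
  cbind(c(xr[1], xr[2], xr[2], xr[1]), c(yr[1], yr[1], yr[2], yr[2]))
}
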