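# Feature construction for the presence-background maximum-entropy model.
# Feature classes follow the LQHP vocabulary: Linear (identity), Quadratic
# (square), Hinge (piecewise-linear ramps, forward/reverse pairs per knot),
# Product (pairwise interactions).  All features are min-max scaled to [0,1]
# on the training background so the L1 penalties are comparable.

#' Build a feature set over training background values
#'
#' Hinge knots sit at evenly spaced quantiles (probabilities `k/(K+1)`) of
#' each variable's background values; each knot generates a forward hinge
#' `max(0, (x - k)/(max - k))` and a reverse hinge `max(0, (k - x)/(k -
#' min))`.  Constant variables keep their (degenerate, all-zero) linear
#' feature but their quadratic and hinge features are dropped with a
#' warning.
#'
#' @param bg_values background cells x variables numeric matrix (with
#'   column names).
#' @param classes subset of `c("L", "Q", "H", "P")`.
#' @param hinge_knots_per_var knots per variable per direction (default 30).
#' @return object of class `feature_set`.
#' @export
build_features <- function(bg_values, classes = c("L", "Q", "H", "P"),
                           hinge_knots_per_var = 30) {
  X <- as.matrix(bg_values)
  if (nrow(X) < 2) abort_input("feature construction needs >= 2 background cells")
  classes <- match.arg(classes, c("L", "Q", "H", "P"), several.ok = TRUE)
  vars <- colnames(X)
  if (is.null(vars)) abort_input("background matrix needs column names")
  var_min <- apply(X, 2, min)
  var_max <- apply(X, 2, max)
  const <- var_max - var_min <= 0
  if (any(const) && any(c("Q", "H") %in% classes)) {
    warning("constant variable(s), dropping their Q/H features: ",
            paste(vars[const], collapse = ", "))
  }
  defs <- list()
  add <- function(kind, var1, var2 = NA_character_, knot = NA_real_) {
    defs[[length(defs) + 1]] <<- data.frame(
      kind = kind, var1 = var1, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)
  }
  if ("L" %in% classes) for (v in vars) add("linear", v)
  if ("Q" %in% classes) for (v in vars[!const]) add("quadratic", v)
  if ("P" %in% classes && length(vars) >= 2) {
    for (pr in utils::combn(vars, 2, simplify = FALSE)) {
      add("product", pr[1], pr[2])
    }
  }
  if ("H" %in% classes && hinge_knots_per_var > 0) {
    probs <- seq_len(hinge_knots_per_var) / (hinge_knots_per_var + 1)
    for (v in vars[!const]) {
      knots <- unique(stats::quantile(X[, v], probs, names = FALSE, type = 7))
      for (k in knots) {
        if (k < var_max[v]) add("hinge_fwd", v, knot = k)
        if (k > var_min[v]) add("hinge_rev", v, knot = k)
      }
    }
  }
  defs <- do.call(rbind, defs)
  fs <- structure(list(defs = defs, vars = vars,
                       var_min = var_min, var_max = var_max,
                       classes = classes,
                       hinge_knots_per_var = hinge_knots_per_var,
                       f_min = NULL, f_max = NULL),
                  class = "feature_set")
  raw <- eval_features_raw(fs, X)
  fs$f_min <- apply(raw, 2, min)
  fs$f_max <- apply(raw, 2, max)
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %d features (%s) over %d variables>\n",
              nrow(x$defs), paste(x$classes, collapse = ""), length(x$vars)))
  invisible(x)
}

eval_features_raw <- function(fs, X) {
  d <- fs$defs
  n <- nrow(X)
  out <- matrix(0, n, nrow(d))
  for (j in seq_len(nrow(d))) {
    v <- X[, d$var1[j]]
    out[, j] <- switch(d$kind[j],
      linear = v,
      quadratic = v^2,
      product = v * X[, d$var2[j]],
      hinge_fwd = pmax(0, (v - d$knot[j]) / (fs$var_max[d$var1[j]] - d$knot[j])),
      hinge_rev = pmax(0, (d$knot[j] - v) / (d$knot[j] - fs$var_min[d$var1[j]]))
    )
  }
  out
}

#' Evaluate scaled features on an environment matrix
#'
#' @param fs a [build_features()] result.
#' @param X cells x variables matrix covering the feature set's variables.
#' @return cells x features matrix; each feature maps the training
#'   background into `[0, 1]` (values outside that range can occur when `X`
#'   leaves the training range and clamping is off).
#' @export
evaluate_features <- function(fs, X) {
  X <- as.matrix(X)
  missing <- setdiff(fs$vars, colnames(X))
  if (length(missing)) abort_input("missing variables: %s",
                                   paste(missing, collapse = ", "))
  raw <- eval_features_raw(fs, X[, fs$vars, drop = FALSE])
  span <- fs$f_max - fs$f_min
  span[span <= 0] <- 1  # constant feature -> stays 0 after centering
  sweep(sweep(raw, 2, fs$f_min), 2, span, "/")
}

# L1 base-penalty constants per feature class, interpolated on the presence
# count m.  These are this implementation's documented defaults (the common
# published defaults for maxent-style models): linear/quadratic/product
# interpolate (10, 1.0) -> (30, 0.2) -> (100, 0.05); hinge is 0.5 flat.
beta0_for <- function(kinds, m) {
  lqp <- stats::approx(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05),
                       xout = m, rule = 2)$y
  ifelse(kinds %in% c("hinge_fwd", "hinge_rev"), 0.5, lqp)
}
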