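# Structured-text (lambdas-file) serialization of fitted models, designed
# to be diffable: scalar header lines, then one CSV row per feature.

#' Write / read a fitted model as a structured-text lambdas file
#'
#' @param model a [fit_maxent()] model.
#' @param path output path.
#' @return `path` invisibly; `read_maxent_model` returns a `maxent_model`.
#' @export
write_maxent_model <- function(model, path) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  hdr <- c(
    "# nichegrad maxent lambdas v1",
    paste0("reg_multiplier=", num(model$reg_multiplier)),
    paste0("log_z=", num(model$log_z)),
    paste0("entropy=", num(model$entropy)),
    paste0("n_presence=", model$n_presence),
    paste0("n_background=", model$n_background),
    paste0("converged=", as.integer(model$converged)),
    paste0("iterations=", model$iterations),
    paste0("clamp_min=", paste(names(model$clamp_min), num(model$clamp_min),
                               sep = ":", collapse = ",")),
    paste0("clamp_max=", paste(names(model$clamp_max), num(model$clamp_max),
                               sep = ":", collapse = ",")),
    paste0("var_min=", paste(names(model$features$var_min),
                             num(model$features$var_min),
                             sep = ":", collapse = ",")),
    paste0("var_max=", paste(names(model$features$var_max),
                             num(model$features$var_max),
                             sep = ":", collapse = ","))
  )
  d <- model$features$defs
  tab <- data.frame(kind = d$kind, var1 = d$var1, var2 = d$var2,
                    knot = num(d$knot), lambda = num(model$lambdas),
                    beta = num(model$betas),
                    f_min = num(model$features$f_min),
                    f_max = num(model$features$f_max),
                    stringsAsFactors = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = ","), con)
  writeLines(do.call(paste, c(tab, sep = ",")), con)
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "# nichegrad maxent lambdas")) {
    abort_input("not a lambdas file: %s", path)
  }
  hdr_end <- which(startsWith(lines, "kind,"))[1]
  kv <- strsplit(lines[2:(hdr_end - 1)], "=", fixed = TRUE)
  hdr <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  parse_map <- function(s) {
    parts <- strsplit(strsplit(s, ",")[[1]], ":")
    stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                    vapply(parts, `[`, "", 1))
  }
  tab <- utils::read.csv(text = lines[hdr_end:length(lines)],
                         stringsAsFactors = FALSE)
  clamp_min <- parse_map(hdr$clamp_min)
  vars <- names(clamp_min)
  fs <- structure(list(
    defs = data.frame(kind = tab$kind, var1 = tab$var1, var2 = tab$var2,
                      knot = suppressWarnings(as.numeric(tab$knot)),
                      stringsAsFactors = FALSE),
    vars = vars,
    var_min = parse_map(hdr$var_min), var_max = parse_map(hdr$var_max),
    classes = NA_character_, hinge_knots_per_var = NA_integer_,
    f_min = as.numeric(tab$f_min), f_max = as.numeric(tab$f_max)
  ), class = "feature_set")
  structure(list(
    features = fs, lambdas = as.numeric(tab$lambda),
    reg_multiplier = as.numeric(hdr$reg_multiplier),
    betas = as.numeric(tab$beta),
    log_z = as.numeric(hdr$log_z), entropy = as.numeric(hdr$entropy),
    clamp_min = clamp_min, clamp_max = parse_map(hdr$clamp_max),
    objective = NA_real_, objective_trace = numeric(0),
    converged = hdr$converged == "1",
    iterations = as.integer(hdr$iterations),
    n_presence = as.integer(hdr$n_presence),
    n_background = as.integer(hdr$n_background)
  ), class = "maxent_model")
}
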