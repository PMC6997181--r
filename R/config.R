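#' Default pipeline configuration
#'
#' Sections: `parameters` (rate-parameter overrides), `stimulus` (shape,
#' onset, duration, amplitude), `solver` (rtol, atol, horizon, n_out),
#' `genotypes` (names to simulate), `qpcr` (alpha, ct_threshold), `paths`
#' (output directory) and `seed`.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    parameters = list(),
    stimulus = list(shape = "step", onset = 0, duration = 1, amplitude = 1),
    solver = list(rtol = 1e-8, atol = 1e-10, horizon = 50, n_out = 2001),
    genotypes = list(names = names(builtin_genotypes())),
    qpcr = list(alpha = 0.05, ct_threshold = 33),
    paths = list(out_dir = "synhomeo-output"),
    seed = 1L
  )
}

#' Load a pipeline configuration file
#'
#' Reads YAML or JSON, rejects unknown top-level keys and unknown keys
#' inside each section, and fills absent sections with defaults. An empty
#' file yields the all-defaults configuration.
#'
#' @param path Path to a YAML (.yml/.yaml) or JSON (.json) file.
#' @return Resolved configuration list of class `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must parse to a mapping", call. = FALSE)
  resolve_config(raw)
}

#' Resolve a raw configuration list against the defaults
#'
#' @param raw Possibly partial configuration list.
#' @return Resolved `pipeline_config`.
#' @export
resolve_config <- function(raw = list()) {
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- defaults
  for (section in names(raw)) {
    if (section == "seed") {
      s <- raw$seed
      if (length(s) != 1 || !is.finite(s) || s != as.integer(s)) {
        stop("config key 'seed' must be a single integer", call. = FALSE)
      }
      cfg$seed <- as.integer(s)
      next
    }
    sec <- raw[[section]]
    if (!is.list(sec)) stop("config section '", section, "' must be a mapping", call. = FALSE)
    if (section == "parameters") {
      bad <- setdiff(names(sec), names(default_parameters_template()))
      if (length(bad)) {
        stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
      cfg$parameters <- sec
      next
    }
    bad <- setdiff(names(sec), names(defaults[[section]]))
    if (length(bad)) {
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[[section]][names(sec)] <- sec
  }
  bad_geno <- setdiff(unlist(cfg$genotypes$names), names(builtin_genotypes()))
  if (length(bad_geno)) {
    stop("config references unregistered genotype(s): ",
         paste(bad_geno, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Save a resolved configuration
#'
#' @param config A `pipeline_config`.
#' @param path Output path (.yml/.yaml or .json).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates every configured genotype, writes the tidy normalized-curve
#' CSV and the metrics CSV; optionally calibrates against an observation
#' table and runs the synthetic-qPCR recovery for the built-in presets;
#' writes a JSON manifest carrying the resolved configuration hash, the
#' seed and the artifact list.
#'
#' @param config A `pipeline_config` (or raw list, resolved on entry).
#' @param observations Optional observation data frame for calibration.
#' @param run_qpcr If `TRUE`, generate one synthetic Ct dataset per
#'   built-in preset (seeded from the config seed) and quantify it.
#' @return Invisibly, a list with the output paths and in-memory results.
#' @export
run_full_pipeline <- function(config = resolve_config(), observations = NULL,
                              run_qpcr = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- resolve_config(config)
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- do.call(default_parameters, config$parameters)
  stim <- stimulus_spec(config$stimulus$shape, config$stimulus$onset,
                        config$stimulus$duration, config$stimulus$amplitude)
  horizon <- config$solver$horizon
  n_out <- config$solver$n_out
  genos <- unlist(config$genotypes$names)

  wt_tc <- simulate_genotype("wild-type", stim, horizon, params, n_out = n_out,
                             rtol = config$solver$rtol, atol = config$solver$atol)
  curves <- do.call(rbind, lapply(genos, function(g) {
    tc <- if (g == "wild-type") wt_tc else {
      simulate_genotype(g, stim, horizon, params, n_out = n_out,
                        rtol = config$solver$rtol, atol = config$solver$atol)
    }
    nr <- normalize_to_wildtype(tc, wt_tc)
    data.frame(genotype = g, time = nr$times, v_norm = nr$v_norm,
               stringsAsFactors = FALSE)
  }))
  curves_path <- file.path(out_dir, "curves.csv")
  utils::write.csv(curves, curves_path, row.names = FALSE)

  metrics <- genotype_metrics(genos, stim, horizon, params = params, n_out = n_out)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE)

  artifacts <- c(curves = curves_path, metrics = metrics_path)
  calibration <- NULL
  if (!is.null(observations)) {
    calibration <- fit_parameters(observations, params, seed = config$seed)
    calib_path <- file.path(out_dir, "calibration.json")
    jsonlite::write_json(
      list(loss = calibration$loss, converged = calibration$converged,
           parameters = as.list(calibration$parameters),
           residuals_log2 = calibration$residuals, seed = calibration$seed),
      calib_path, auto_unbox = TRUE, digits = NA, na = "null"
    )
    artifacts["calibration"] <- calib_path
  }
  quantification <- NULL
  if (isTRUE(run_qpcr)) {
    rows <- lapply(builtin_presets(), function(ps) {
      q <- delta_delta_ct(generate_ct_data(ps, seed = config$seed),
                          alpha = config$qpcr$alpha,
                          ct_threshold = config$qpcr$ct_threshold)
      data.frame(preset = ps$name, target_gene = q$target_gene,
                 true_fold_change = ps$true_fold_change,
                 fold_change = q$fold_change, p_value = q$p_value,
                 test_used = q$test_used, stars = q$stars,
                 stringsAsFactors = FALSE)
    })
    quantification <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    quant_path <- file.path(out_dir, "quantification.csv")
    utils::write.csv(quantification, quant_path, row.names = FALSE)
    artifacts["quantification"] <- quant_path
  }

  cfg_file <- tempfile(fileext = ".json")
  save_config(config, cfg_file)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("synhomeo")),
    artifacts = as.list(artifacts)
  )
  unlink(cfg_file)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  artifacts["manifest"] <- manifest_path

  invisible(list(artifacts = artifacts, curves = curves, metrics = metrics,
                 calibration = calibration, quantification = quantification))
}
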