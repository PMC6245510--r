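#' Write a trace to a two-column text file
#'
#' Tab-separated `time value` rows with a `#`-prefixed header; values are
#' written with 12 significant digits so round trips agree to better than
#' 1e-9 relative.
#'
#' @param path Output file path.
#' @param values Numeric series.
#' @param dt Sample interval (s).
#' @export
write_trace <- function(path, values, dt) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lnkadapt trace; dt = %.12g s; n = %d",
                     dt, length(values)), con)
  writeLines(sprintf("%.12g\t%.12g", (seq_along(values) - 1L) * dt, values),
             con)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Validates structure as it parses: every data line must hold exactly two
#' numeric fields and times must advance on a regular grid; truncated or
#' malformed files raise a parse error identifying the offending line.
#'
#' @param path Input file path.
#' @return A list with `values` and `dt`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(data_lines) < 2L) stop_invalid("trace file %s has < 2 data rows", path)
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop_invalid("parse error in %s at data line %d: expected 2 fields, found %d",
                 path, which(nf != 2L)[1L], nf[which(nf != 2L)[1L]])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2L,
              byrow = TRUE)
  if (anyNA(m)) {
    stop_invalid("parse error in %s at data line %d: non-numeric field",
                 path, which(rowSums(is.na(m)) > 0)[1L])
  }
  dts <- diff(m[, 1L])
  dt <- median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1e-12))) {
    stop_invalid("parse error in %s: time grid is not regular", path)
  }
  list(values = m[, 2L], dt = dt)
}

# ---- model (de)serialization ---------------------------------------------

LNK_SCHEMA_VERSION <- "1.0"

#' Serialize an LNK cell to JSON
#'
#' The document stores, per pathway, the filter taps and dt, the nonlinearity
#' parameters, the kinetics rates with their u-scaling set, the weight and
#' label, plus the cell's output scale/offset and a schema version.
#'
#' @param cell An [lnk_cell()].
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_lnk_cell <- function(cell, path = NULL) {
  doc <- list(
    schema_version = LNK_SCHEMA_VERSION,
    output_scale = cell$output_scale,
    output_offset = cell$output_offset,
    pathways = lapply(cell$pathways, function(p) {
      list(label = p$polarity_label, weight = p$weight,
           filter = list(taps = p$filter$taps, dt = p$filter$dt),
           nonlinearity = p$nonlinearity[c("a", "b1", "b2", "kappa")],
           kinetics = p$kinetics[c("k_a", "k_fi", "k_fr", "k_si", "k_sr",
                                   "u_scaled_rates")])
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Read an LNK cell from JSON
#'
#' @param path File path or a JSON string from [write_lnk_cell()].
#' @return An [lnk_cell()].
#' @export
read_lnk_cell <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.null(doc$schema_version)) stop_invalid("missing schema_version")
  pathways <- lapply(doc$pathways, function(p) {
    lnk_pathway(temporal_filter(p$filter$taps, p$filter$dt),
                sigmoid_nonlinearity(p$nonlinearity$a, p$nonlinearity$b1,
                                     p$nonlinearity$b2, p$nonlinearity$kappa),
                lnk_kinetics(p$kinetics$k_a, p$kinetics$k_fi, p$kinetics$k_fr,
                             p$kinetics$k_si, p$kinetics$k_sr,
                             p$kinetics$u_scaled_rates),
                weight = p$weight, polarity_label = p$label)
  })
  lnk_cell(pathways, doc$output_scale, doc$output_offset)
}

# ---- pipeline -------------------------------------------------------------

#' Default pipeline configuration
#'
#' A desk-scale demonstration configuration: a 60 s flicker record at five
#' contrasts, the reference cell, a light single-pathway fit, per-contrast
#' LN models with adaptation metrics, the component-exchange analysis, and a
#' small kinetics grid search.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts.
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = tempfile("lnkrun")) {
  list(seed = seed, out_dir = out_dir, dt = 0.002,
       stimulus = list(n_segments = 5, segment_duration = 12,
                       contrast_low = 0.05, contrast_high = 0.35),
       recording = list(noise_sd_fraction = 0.1, noise_cutoff = 50),
       fit = list(enabled = TRUE, n_pathways = 1, n_restarts = 2,
                  maxit_search = 40, maxit_polish = 60),
       metrics = list(contrasts = c(0.05, 0.125, 0.2, 0.275, 0.35),
                      epoch_length = 20),
       exchange = list(enabled = TRUE, epoch_length = 15,
                       contrasts = seq(0.05, 0.35, by = 0.075)),
       gridsearch = list(enabled = TRUE, n_grid = 3, grid_factor = 5,
                         epoch_length = 12))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: stimulus and reference-cell synthesis, a noisy
#' recording, an (optional) LNK fit, per-contrast LN models with adaptation
#' metrics, the component-exchange analysis, and the kinetics grid search.
#' All artifacts are written under `config$out_dir` as text/CSV/JSON and a
#' manifest records the seeds, parameters and stage list, so re-running an
#' identical configuration reproduces every numeric artifact.
#'
#' @param config A configuration list from [default_pipeline_config()], or a
#'   path to a YAML file holding one.
#' @return Invisibly, a list with the in-memory artifacts plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_invalid("config file %s not found", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dt <- config$dt
  stages <- character(0)

  # synth
  sched <- make_contrast_schedule(config$stimulus$n_segments,
                                  config$stimulus$segment_duration,
                                  config$stimulus$contrast_low,
                                  config$stimulus$contrast_high,
                                  rng_seed = config$seed)
  stim <- generate_flicker(sched, dt = dt, rng_seed = config$seed)
  cell <- make_reference_cell(config$seed, dt = dt)
  clean_sd <- sd(simulate_cell(cell, normalize_stimulus(stim), dt))
  rec <- synth_recording(cell, stim,
                         noise_sd = config$recording$noise_sd_fraction * clean_sd,
                         noise_cutoff = config$recording$noise_cutoff,
                         seed = config$seed)
  write_trace(file.path(config$out_dir, "recording.txt"), rec$noisy, dt)
  write_lnk_cell(cell, file.path(config$out_dir, "reference_cell.json"))
  stages <- c(stages, "synth")

  # fit
  fit <- NULL
  if (isTRUE(config$fit$enabled)) {
    cfg <- fit_config(n_restarts = config$fit$n_restarts,
                      maxit_search = config$fit$maxit_search,
                      maxit_polish = config$fit$maxit_polish,
                      rng_seed = config$seed)
    fit <- suppressWarnings(
      fit_lnk(normalize_stimulus(stim), rec$noisy, dt,
              n_pathways = config$fit$n_pathways, config = cfg))
    write_lnk_cell(fit$cell, file.path(config$out_dir, "fitted_cell.json"))
    utils::write.csv(fit$fold_table,
                     file.path(config$out_dir, "fit_folds.csv"),
                     row.names = FALSE)
    stages <- c(stages, "fit")
  }

  # per-contrast LN metrics
  summ <- adaptation_summary(cell, config$metrics$contrasts,
                             epoch_length = config$metrics$epoch_length,
                             dt = dt, rng_seed = config$seed)
  utils::write.csv(summ$per_contrast,
                   file.path(config$out_dir, "adaptation_summary.csv"),
                   row.names = FALSE)
  stages <- c(stages, "metrics")

  # exchange
  exch <- NULL
  if (isTRUE(config$exchange$enabled)) {
    exch <- exchange_analysis(cell, contrasts = config$exchange$contrasts,
                              epoch_length = config$exchange$epoch_length,
                              dt = dt, rng_seed = config$seed)
    jsonlite::write_json(exch, file.path(config$out_dir, "exchange.json"),
                         dataframe = "rows", digits = NA)
    stages <- c(stages, "exchange")
  }

  # grid search
  grid <- NULL
  if (isTRUE(config$gridsearch$enabled)) {
    grid <- bandwidth_grid_search(cell,
                                  grid_factor = config$gridsearch$grid_factor,
                                  n_grid = config$gridsearch$n_grid,
                                  epoch_length = config$gridsearch$epoch_length,
                                  dt = dt, rng_seed = config$seed)
    utils::write.csv(grid, file.path(config$out_dir, "bandwidth_grid.csv"),
                     row.names = FALSE)
    stages <- c(stages, "gridsearch")
  }

  manifest <- list(package_version = as.character(utils::packageVersion("lnkadapt")),
                   seed = config$seed, stages = stages, config = config,
                   created = format(Sys.time(), tz = "UTC"))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(stimulus = stim, cell = cell, recording = rec, fit = fit,
                 summary = summ, exchange = exch, grid = grid,
                 manifest_path = manifest_path))
}
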