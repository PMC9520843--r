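#' Default pipeline configuration
#'
#' A plain list (YAML-serializable) holding the channel-role map, detection
#' and classification parameters, marker roles, simulation presets and the
#' master seed. `markers$classify` are secondary markers classified on
#' every detected vesicle; `markers$screens` maps each screen channel to
#' the base markers that gate it.
#'
#' @param seed master seed recorded in the config.
#' @return nested list of class `PipelineConfig`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    channels = list(cav1 = 1L, endoglin = 2L, eea1 = 3L, smad1 = 4L),
    detection = c(list(channel = "cav1"), unclass(detection_params())),
    classification = unclass(classification_params()),
    markers = list(classify = "endoglin",
                   screens = list(smad1 = list(base = "endoglin"))),
    simulation = list(n_fields_per_condition = 10L,
                      field_shape = c(512L, 512L)),
    seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip losslessly; unknown keys are preserved.
#'
#' @param path YAML file path.
#' @param config a config list.
#' @return `read_config()` the config list; `write_config()` `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- modifyList(unclass(default_config()), yaml::read_yaml(path))
  structure(cfg, class = "PipelineConfig")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_detection_params <- function(config) {
  d <- config$detection
  detection_params(
    background_radius = d$background_radius, threshold_method = d$threshold_method,
    smoothing_sigma = d$smoothing_sigma, min_area = d$min_area,
    max_area = d$max_area, min_circularity = d$min_circularity,
    fill_holes = d$fill_holes, connectivity = d$connectivity,
    noise_floor_k = d$noise_floor_k %||% 4)
}

.config_classification_params <- function(config) {
  cl <- config$classification
  classification_params(f = cl$f, reference_scope = cl$reference_scope,
                        measure_on = cl$measure_on, strict = cl$strict,
                        overrides = cl$overrides %||% list())
}

#' Run the full analysis on one field of view
#'
#' detect -> measure -> classify -> screen -> summarize, as configured.
#'
#' @param field a `FieldOfView`.
#' @param config pipeline config (see [default_config()]).
#' @return list: `mask`, `table` (classified), `summary` (one row).
#' @export
process_field <- function(field, config = default_config()) {
  dp <- .config_detection_params(config)
  cp <- .config_classification_params(config)
  det_channel <- config$detection$channel
  det <- detect_vesicles(field, det_channel, dp)
  table <- det$table
  for (m in config$markers$classify)
    if (m %in% names(field$channels))
      table <- classify_vesicles(table, det$mask, field, m, cp)
  for (s in names(config$markers$screens %||% list())) {
    if (!s %in% names(field$channels)) next
    base <- unlist(config$markers$screens[[s]]$base)
    table <- screen_copositive(table, base, s, det$mask, field, cp)
  }
  attr(table, "condition_label") <- field$condition_label
  list(mask = det$mask, table = table,
       summary = summarize_field(table, field$condition_label))
}

#' Run the pipeline over many fields and compare conditions
#'
#' The end-to-end entry point. Inputs are either image files (a data.frame
#' with columns `path` and `condition`, read through the config's channel
#' map) or, with `simulate = TRUE`, synthetic fields generated from
#' [shear_presets()] under the config's seed. Per-file read or processing
#' errors are recorded and the run continues. When `out_dir` is given, all
#' products (masks, vesicle tables, per-field summary CSV, comparison
#' JSON, config snapshot, log) are written beneath it.
#'
#' @param config pipeline config.
#' @param images data.frame(path, condition) of input TIFFs, or NULL.
#' @param simulate logical; generate inputs with the simulator instead.
#' @param out_dir output directory (created), or NULL for no files.
#' @return list of class `PipelineResult`: `summaries` (data.frame),
#'   `comparisons` (list of `ConditionComparison` per metric), `tables`
#'   (per-field classified vesicle tables), `failures` (named list of
#'   error messages), `config`.
#' @export
run_pipeline <- function(config = default_config(), images = NULL,
                         simulate = is.null(images), out_dir = NULL) {
  .assert(simulate || (is.data.frame(images) && nrow(images) > 0 &&
                         all(c("path", "condition") %in% names(images))),
          "provide images (data.frame with path, condition) or simulate = TRUE")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  fields <- list(); names_out <- character(0); failures <- list()
  if (simulate) {
    presets <- shear_presets(field_shape = config$simulation$field_shape)
    sims <- simulate_experiment(presets$LSS, presets$HSS,
                                config$simulation$n_fields_per_condition,
                                seed = config$seed)
    fields <- lapply(sims, `[[`, "field")
    names_out <- vapply(fields, function(f)
      sprintf("%s_%s", f$condition_label, f$source_path), character(1))
    names_out <- make.unique(names_out)
  } else {
    for (i in seq_len(nrow(images))) {
      fo <- tryCatch(
        read_field(images$path[i], channels = unlist(config$channels),
                   condition_label = images$condition[i]),
        error = function(e) e)
      if (inherits(fo, "error")) {
        failures[[images$path[i]]] <- conditionMessage(fo)
        log("FAILED to read %s: %s", images$path[i], conditionMessage(fo))
      } else {
        fields[[length(fields) + 1L]] <- fo
        names_out <- c(names_out, basename(images$path[i]))
      }
    }
  }

  tables <- list(); summaries <- list()
  for (i in seq_along(fields)) {
    res <- tryCatch(process_field(fields[[i]], config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[names_out[i]]] <- conditionMessage(res)
      log("FAILED to process %s: %s", names_out[i], conditionMessage(res))
      next
    }
    tables[[names_out[i]]] <- res$table
    summaries[[length(summaries) + 1L]] <- res$summary
    log("%s [%s]: %d vesicles", names_out[i],
        fields[[i]]$condition_label, res$summary$n_vesicles)
    if (!is.null(out_dir)) {
      base <- file.path(out_dir, gsub("[^A-Za-z0-9_.-]", "_", names_out[i]))
      tiff::writeTIFF(res$mask$labels / 65535, paste0(base, "_mask.tif"),
                      bits.per.sample = 16L)
      write.csv(res$table, paste0(base, "_vesicles.csv"), row.names = FALSE)
    }
  }
  .assert(length(summaries) > 0, "no field processed successfully")
  summary_df <- summarize_fields(summaries)

  comparisons <- list()
  if (length(unique(summary_df$condition)) == 2L &&
      all(table(summary_df$condition) >= 2)) {
    metrics <- grep("^(n_vesicles$|n_pos|n_copos)", names(summary_df), value = TRUE)
    for (m in metrics)
      comparisons[[m]] <- compare_conditions(summary_df, m, test = "welch")
  }

  if (!is.null(out_dir)) {
    write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(comparisons, function(cmp) list(
        test = cmp$test, metric = cmp$metric, statistic = cmp$statistic,
        p_value = cmp$p_value, group_means = as.list(cmp$group_means),
        n = as.list(cmp$n))),
      file.path(out_dir, "comparisons.json"), auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }

  structure(list(summaries = summary_df, comparisons = comparisons,
                 tables = tables, failures = failures, config = config),
            class = "PipelineResult")
}
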