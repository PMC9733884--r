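#' Read an area-level CSV table with schema validation
#'
#' Reads a CSV and checks it against an expected schema: all named columns
#' present (extra columns reported), the id column unique, and numeric
#' columns parseable as numbers (the offending row and column are named
#' otherwise).
#'
#' @param path CSV file path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must be numeric.
#' @param id_col Column whose values must be unique (default `"area_id"`;
#'   `NULL` to skip).
#' @return Data frame.
#' @export
read_area_table <- function(path, required, numeric_cols = character(0),
                            id_col = "area_id") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  extra <- setdiff(names(tab), required)
  if (length(missing_cols)) {
    stop("read_area_table: '", basename(path), "' missing column(s): ",
         paste(missing_cols, collapse = ", "),
         if (length(extra)) paste0(" (extra: ",
                                   paste(extra, collapse = ", "), ")"),
         call. = FALSE)
  }
  if (!is.null(id_col) && id_col %in% names(tab) &&
      anyDuplicated(tab[[id_col]])) {
    stop("read_area_table: duplicate ", id_col, " in '", basename(path), "'",
         call. = FALSE)
  }
  for (col in numeric_cols) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop("read_area_table: non-numeric value in column '", col,
           "', row ", bad, " of '", basename(path), "'", call. = FALSE)
    }
  }
  tab
}

#' Write an area-level table as CSV
#'
#' @param table Data frame to write.
#' @param path Output CSV path; parent directories are created.
#' @return The path, invisibly.
#' @export
write_area_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' Parses a YAML pipeline configuration. The `synthetic:` section mirrors
#' [synthetic_config()] field names exactly; `transform:` carries the
#' exponential-transform constants; `orientation`, `strata` and `indices`
#' select the build options. Any omitted field takes its package default.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(synthetic = raw$synthetic, transform = raw$transform,
                  orientation = raw$orientation %||% "risk-high",
                  strata = raw$strata %||% c("all", "urban", "rural"),
                  indices = raw$indices %||%
                    c("simple", "complex", "compositional", "structural"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a pipeline configuration
#'
#' @param synthetic Named list of [synthetic_config()] arguments (or an
#'   already-built `synthetic_config`).
#' @param transform Named list of [exp_transform_params()] arguments.
#' @param orientation `"risk-high"` or `"risk-low"`; see [build_index()].
#' @param strata Validation strata, subset of `c("all","urban","rural")`.
#' @param indices Index variants to build.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, transform = NULL,
                            orientation = "risk-high",
                            strata = c("all", "urban", "rural"),
                            indices = c("simple", "complex",
                                        "compositional", "structural")) {
  syn <- if (inherits(synthetic, "synthetic_config")) {
    synthetic
  } else {
    do.call(synthetic_config, synthetic %||% list())
  }
  par <- do.call(exp_transform_params, transform %||% list())
  indices <- match.arg(indices,
                       c("simple", "complex", "compositional", "structural"),
                       several.ok = TRUE)
  structure(list(synthetic = syn, transform = par,
                 orientation = orientation, strata = strata,
                 indices = indices),
            class = "pipeline_config")
}

#' Run the full food-insecurity risk pipeline
#'
#' End-to-end orchestration: simulate the synthetic dataset, derive the
#' point-based structural indicators (bus-stop density, nearest-store
#' distance) from the generated point sets, build each requested index
#' variant, aggregate the Complex Index domains to MSOA level, validate
#' every index against the IMD-like criterion at area level (stratified by
#' urban/rural) and against the MSOA-level criteria, and summarise the
#' most-at-risk decile by region and urban/rural. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @param out_dir Optional directory: when given, every table is written as
#'   CSV and a plain-text run log (seed, stage row counts) is kept.
#' @return List with `data` (the synthetic bundle), `indices` (named list
#'   of [build_index()] results), `msoa_index`, `validation` (data frame of
#'   agreement statistics), `top_decile` summaries, and `log` (character).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
  }
  say("seed: ", config$synthetic$seed)

  data <- generate_synthetic_dataset(config$synthetic)
  say("simulate: ", nrow(data$geography), " areas, ",
      length(unique(data$geography$msoa_id)), " MSOAs")

  data$indicators <- derive_point_indicators(
    data$indicators, data$geography, data$store_points,
    data$bus_stop_points)
  say("derive: point-based indicators recomputed for ",
      nrow(data$indicators), " areas")

  indices <- list()
  for (which in config$indices) {
    indices[[which]] <- build_index(
      data$indicators, index_spec(which),
      params = config$transform,
      orientation = config$orientation)
    say("build ", which, ": ", nrow(indices[[which]]$index), " areas ranked")
  }

  msoa_index <- NULL
  if ("complex" %in% names(indices)) {
    bi <- indices$complex
    # aggregation always sums the risk-high transformed scores: under the
    # mirrored presentation a per-MSOA sum would offset by LSOA count
    exps <- lapply(bi$domains, `[[`, "domain_exp")
    if (config$orientation == "risk-low") {
      exps <- lapply(exps, function(e) config$transform$range_constant - e)
    }
    msoa_index <- aggregate_to_msoa(
      exps, bi$index$area_id, data$geography, bi$domain_weights,
      most_at_risk = "high")
    say("aggregate: ", nrow(msoa_index), " MSOAs")
  }

  # validate on rank order (orientation-independent): -rank puts the
  # most-at-risk area highest, as rank_worst_first expects
  reports <- list()
  for (which in names(indices)) {
    idx <- indices[[which]]$index
    reports[[length(reports) + 1L]] <- validate_index(
      data.frame(area_id = idx$area_id, combined_score = -idx$rank),
      data.frame(area_id = data$area_validation$area_id,
                 value = data$area_validation$imd_score),
      geography = data$geography, strata = config$strata,
      index_name = which, criterion_name = "imd")
  }
  if (!is.null(msoa_index)) {
    for (crit in c("fsm_pct", "obesity_pct")) {
      reports[[length(reports) + 1L]] <- validate_index(
        data.frame(msoa_id = msoa_index$msoa_id,
                   combined_score = -msoa_index$rank),
        data.frame(msoa_id = data$msoa_validation$msoa_id,
                   value = data$msoa_validation[[crit]]),
        geography = data$geography, strata = "all",
        index_name = "complex_msoa", criterion_name = crit,
        id_col = "msoa_id")
    }
  }
  validation <- do.call(rbind, c(reports, list(make.row.names = FALSE)))
  say("validate: ", nrow(validation), " index-criterion-stratum rows")

  top_decile <- lapply(indices, function(b) {
    if (!"decile" %in% names(b$index)) return(NULL)
    top_decile_summary(b$index, data$geography)
  })

  result <- list(data = data, indices = indices, msoa_index = msoa_index,
                 validation = validation, top_decile = top_decile,
                 log = log_lines, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# write every pipeline table plus log and config echo under out_dir
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- result$data
  write_area_table(d$geography, file.path(out_dir, "geography.csv"))
  write_area_table(d$indicators, file.path(out_dir, "indicators.csv"))
  write_area_table(d$store_points, file.path(out_dir, "store_points.csv"))
  write_area_table(d$bus_stop_points,
                   file.path(out_dir, "bus_stop_points.csv"))
  write_area_table(d$area_validation,
                   file.path(out_dir, "validation_area.csv"))
  write_area_table(d$msoa_validation,
                   file.path(out_dir, "validation_msoa.csv"))
  for (which in names(result$indices)) {
    b <- result$indices[[which]]
    tab <- b$index
    for (dn in names(b$domains)) {
      dd <- b$domains[[dn]]
      for (col in c("domain_score_raw", "domain_rank", "domain_scaled",
                    "domain_exp")) {
        tab[[paste0(dn, "_", col)]] <- dd[[col]][match(tab$area_id,
                                                       dd$area_id)]
      }
    }
    write_area_table(tab, file.path(out_dir, paste0("index_", which, ".csv")))
  }
  if (!is.null(result$msoa_index)) {
    write_area_table(result$msoa_index,
                     file.path(out_dir, "index_complex_msoa.csv"))
  }
  write_area_table(result$validation, file.path(out_dir, "validation.csv"))
  writeLines(result$log, file.path(out_dir, "run.log"))
  cfg <- result$config
  yaml::write_yaml(list(
    synthetic = lapply(unclass(cfg$synthetic), as.list),
    transform = unclass(cfg$transform),
    orientation = cfg$orientation,
    strata = cfg$strata,
    indices = cfg$indices), file.path(out_dir, "config_echo.yaml"))
  invisible(out_dir)
}
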