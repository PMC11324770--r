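# Configuration, validated table IO and the end-to-end workflow.

#' Default run configuration
#'
#' A compact demonstration configuration: one simulated compound on one
#' plate (9-point series, duplicate wells, 2 vehicle wells, 4 fields/well,
#' 64-cell 256x256 px fields), quantification with default parameters,
#' loglinear IC50 fitting, and a PBPK run with default morphometry mapped
#' onto the fitted curve. All values can be overridden from a YAML file
#' (see [load_run_config()]).
#'
#' @param seed master seed driving every stochastic stage
#' @return nested configuration list (class `run_config`)
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    plate = list(
      compound_id = "DEMO1",
      junction_ic50_um = 10, junction_hill = 1,
      viability_ec50_um = 400, viability_hill = 1,
      replicates = 2L, n_vehicle = 2L, fields_per_well = 4L),
    field = list(
      image_height_px = 256L, image_width_px = 256L, n_cells = 64L,
      pixel_size_um = 0.325, noise_sd = 100),
    doseresponse = list(method = "loglinear", min_response_le = 0.5),
    pbpk = list(
      total_dose_nmol = 1e5,
      deposition_fraction_tb = 0.70, deposition_fraction_alveolar = 0.30,
      formulation = "solid_particles",
      t_end_h = 24, dt_out_h = 0.1,
      compound = list(),   # overrides for compound_params()
      at_risk_fraction = 0.5)),
    class = "run_config")
}

#' Load / save a run configuration
#'
#' YAML round-trip: a saved configuration reloads unchanged. Unknown keys
#' are preserved.
#' @param path YAML file path
#' @return a `run_config` list
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  merged <- utils::modifyList(base, cfg)
  structure(merged, class = "run_config")
}

#' @rdname load_run_config
#' @param config a `run_config`
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Column type schemas for the tables the pipeline exchanges.
table_schemas <- list(
  manifest = c(plate = "character", well = "character", field = "numeric",
               compound = "character", concentration_um = "numeric",
               role = "character"),
  well_metrics = c(plate = "character", well = "character",
                   compound = "character", concentration_um = "numeric",
                   role = "character", n_fields = "numeric",
                   mean_nuclei_count = "numeric",
                   membrane_area_per_cell_um2 = "numeric",
                   junction_area_per_cell_um2 = "numeric"),
  truth = c(compound = "character", risk = "character"))

#' Read a CSV against a documented schema
#'
#' Required columns must exist and be coercible to their declared type;
#' violations are reported with row numbers. Unknown columns pass through
#' untouched.
#'
#' @param path CSV path
#' @param schema schema name (one of `r paste(names(table_schemas), collapse = ", ")`)
#'   or a named character vector of column types ("numeric"/"character")
#' @return validated data.frame
#' @export
load_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1) {
    schema <- table_schemas[[schema]] %||%
      stop("unknown schema: ", schema)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    stop("missing required columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in names(schema)) {
    if (schema[[cn]] == "numeric" && !is.numeric(df[[cn]])) {
      coerced <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(!is.na(df[[cn]]) & df[[cn]] != "" & is.na(coerced))
      if (length(bad)) {
        stop("column '", cn, "' in ", path, " is not numeric at rows: ",
             paste(utils::head(bad, 10), collapse = ", "))
      }
      df[[cn]] <- coerced
    }
    if (schema[[cn]] == "character") df[[cn]] <- as.character(df[[cn]])
  }
  df
}

#' @rdname load_table
#' @param df data.frame to write
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full pipeline: simulate, quantify, fit, simulate lung, map risk
#'
#' Chains simulate-plate, analyze-plate, normalization, IC50 fitting,
#' optional Cooper statistics against a truth table, the PBPK simulation
#' and the exposure-to-IC50 risk map. Deterministic for a fixed master
#' seed. When `out_dir` is given, writes the manifest, metrics, fit and
#' profile CSVs, the resolved configuration and a summary JSON next to
#' each other.
#'
#' @param config a [default_run_config()]-shaped list
#' @param out_dir optional output directory
#' @param truth optional truth data.frame (columns compound, risk) for
#'   Cooper statistics
#' @param write_images write the TIFF fields (default FALSE; metrics are
#'   computed in memory either way)
#' @return list with `manifest`, `well_table`, `responses`, `fit`,
#'   `region_summary`, `risk`, `summary` (the summary list written as JSON)
#' @export
run_end_to_end <- function(config = default_run_config(), out_dir = NULL,
                           truth = NULL, write_images = FALSE) {
  cfg <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  img_dir <- if (write_images && !is.null(out_dir)) file.path(out_dir, "images") else NULL

  layout <- stage("simulate-plate", plate_layout(
    compound_id = cfg$plate$compound_id, replicates = cfg$plate$replicates,
    n_vehicle = cfg$plate$n_vehicle))
  base_spec <- stage("simulate-plate", do.call(monolayer_spec, cfg$field))
  plate <- stage("simulate-plate", simulate_plate(
    layout,
    pharmacology = list(junction_ic50_um = cfg$plate$junction_ic50_um,
                        junction_hill = cfg$plate$junction_hill,
                        viability_ec50_um = cfg$plate$viability_ec50_um,
                        viability_hill = cfg$plate$viability_hill),
    base_spec = base_spec, fields_per_well = cfg$plate$fields_per_well,
    seed = cfg$seed, directory = img_dir))

  metrics <- stage("analyze-plate", analyze_plate(plate))
  responses <- stage("normalize", normalize_to_vehicle(metrics$well_table))
  fit <- stage("fit-dose-response", fit_ic50(
    responses$concentration_um, responses$response,
    method = cfg$doseresponse$method,
    min_response_le = cfg$doseresponse$min_response_le,
    compound_id = cfg$plate$compound_id,
    viability_responses = responses$viability_response))

  cooper <- NULL
  if (!is.null(truth)) {
    preds <- calls_from_ic50_table(
      data.frame(compound = truth$compound,
                 ic50_um = ifelse(truth$compound == cfg$plate$compound_id,
                                  fit$ic50_um, NA_real_)))
    cooper <- stage("cooper", cooper_statistics(preds, truth))
  }

  model <- stage("pbpk-simulate", build_lung_model(
    compound = do.call(compound_params, cfg$pbpk$compound)))
  dose <- stage("pbpk-simulate", dose_event(
    cfg$pbpk$total_dose_nmol,
    deposition_fraction_tb = cfg$pbpk$deposition_fraction_tb,
    deposition_fraction_alveolar = cfg$pbpk$deposition_fraction_alveolar,
    formulation = cfg$pbpk$formulation))
  sim <- stage("pbpk-simulate", simulate_lung(
    model, dose, t_end_h = cfg$pbpk$t_end_h, dt_out_h = cfg$pbpk$dt_out_h))
  regions <- stage("pbpk-simulate", elf_region_summary(sim))
  risk <- stage("risk-map", map_exposure_to_ic50(
    regions, fit, at_risk_fraction = cfg$pbpk$at_risk_fraction))

  summary <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("tjscreen")),
    compound = cfg$plate$compound_id,
    true_junction_ic50_um = cfg$plate$junction_ic50_um,
    fitted_ic50_um = fit$ic50_um,
    established = fit$established,
    classification = classify_compound(fit),
    region_cmax_um = stats::setNames(regions$cmax_um, regions$region),
    exposure_ratio = stats::setNames(risk$exposure_ratio, risk$region),
    at_risk_regions = risk$region[risk$at_risk])
  if (!is.null(cooper)) {
    summary$cooper <- list(sensitivity = cooper$sensitivity,
                           specificity = cooper$specificity,
                           accuracy = cooper$accuracy)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(plate$manifest, file.path(out_dir, "manifest.csv"))
    write_table(metrics$well_table, file.path(out_dir, "well_metrics.csv"))
    write_table(metrics$field_table, file.path(out_dir, "field_metrics.csv"))
    write_table(responses, file.path(out_dir, "responses.csv"))
    profiles <- data.frame(
      time_h = rep(sim$time_h, times = 24),
      generation = rep(1:24, each = length(sim$time_h)),
      compartment = "elf",
      concentration_um = as.vector(sim$elf_conc_um))
    write_table(profiles, file.path(out_dir, "elf_profiles.csv"))
    write_table(risk, file.path(out_dir, "risk_map.csv"))
    save_run_config(cfg, file.path(out_dir, "resolved_config.yaml"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(manifest = plate$manifest, well_table = metrics$well_table,
       responses = responses, fit = fit, cooper = cooper,
       region_summary = regions, risk = risk, summary = summary)
}
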