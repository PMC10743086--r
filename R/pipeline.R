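#' Run the full analysis on one plate
#'
#' Chains the pipeline stages for every non-empty layout well: nucleus
#' segmentation, bounded cell-region assignment, four-population scoring
#' (with positivity thresholds resolved once per plate from the pooled
#' per-cell statistics when set to `"auto"`), per-population dose-response
#' IC50 fitting, and Dunnett-gated induction calls. A well whose image is
#' missing or unreadable is skipped with a warning and is absent from all
#' downstream tables.
#'
#' @param images Either a directory containing one `<well>.tif` per
#'   non-empty well, or a named list of channel stacks keyed by well id.
#' @param layout A [plate_layout()] (or a path to a layout CSV).
#' @param config An [analysis_config()] (or a path to a YAML/JSON config).
#' @return List with data frames `cells`, `wells`, `dose_response`,
#'   `induction`, `calls`, the fitted `dose_response_results` and
#'   `induction_results` lists, and `thresholds`.
#' @export
analyze_plate <- function(images, layout, config = analysis_config()) {
  if (is.character(layout)) layout <- parse_layout(layout)
  if (is.character(config)) config <- read_analysis_config(config)
  lay <- layout$wells[layout$wells$role != "empty", , drop = FALSE]

  get_stack <- function(well) {
    if (is.list(images)) return(images[[well]])
    path <- file.path(images, paste0(well, ".tif"))
    if (!file.exists(path)) return(NULL)
    read_stack(path, config$channel_map)
  }
  if (!is.list(images) && !dir.exists(images)) {
    stop("image directory not found: ", images, call. = FALSE)
  }
  missing <- lay$well[vapply(lay$well, function(w) is.null(get_stack(w)),
                             logical(1))]
  if (length(missing) == nrow(lay)) {
    stop("no image found for any non-empty well (", length(missing),
         " wells): ", paste(utils::head(missing, 8), collapse = ", "),
         call. = FALSE)
  }

  seg <- list()
  stats_list <- list()
  for (well in lay$well) {
    res <- tryCatch({
      stack <- get_stack(well)
      if (is.null(stack)) stop("no image for well ", well)
      nuclei <- segment_nuclei(stack$nuclear, config$segmentation,
                               config$pixel_size)
      cells <- assign_cell_regions(nuclei, config$segmentation,
                                   config$pixel_size)
      list(stack = stack, nuclei = nuclei, cells = cells,
           stats = compute_cell_stats(stack, cells, nuclei, config))
    }, error = function(e) {
      warning("skipping well ", well, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      seg[[well]] <- res
      stats_list[[well]] <- res$stats
    }
  }
  if (!length(seg)) stop("no analyzable wells", call. = FALSE)

  pooled <- do.call(rbind, stats_list)
  thresholds <- resolve_thresholds(pooled, config)

  cell_rows <- list()
  well_rows <- list()
  for (well in names(seg)) {
    rec <- score_cells(seg[[well]]$stack, seg[[well]]$cells,
                       seg[[well]]$nuclei, config, well_id = well,
                       thresholds = thresholds)
    cell_rows[[well]] <- rec
    well_rows[[well]] <- summarize_well(rec, well)
  }
  cells_tab <- do.call(rbind, c(cell_rows, list(make.row.names = FALSE)))
  wells_tab <- do.call(rbind, c(well_rows, list(make.row.names = FALSE)))

  dr <- fit_dose_response(wells_tab, layout)
  ind <- compute_induction(wells_tab, layout, config)

  list(cells = cells_tab,
       wells = wells_tab,
       dose_response = attr(dr, "table"),
       induction = attr(ind, "table"),
       calls = call_matrix(ind),
       dose_response_results = dr,
       induction_results = ind,
       thresholds = thresholds)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(outdir, config, inputs, seed, timings, outputs) {
  manifest <- list(
    tool = "mdrhcs",
    version = as.character(utils::packageVersion("mdrhcs")),
    config_hash = .config_hash(config),
    inputs = inputs,
    seed = seed,
    timings_sec = lapply(timings, function(x) round(x, 3)),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a plate from files (CLI backend)
#'
#' Reads a scenario YAML and a layout CSV, simulates every non-empty well,
#' and writes per-well multi-page TIFFs, `truth.csv` and a run manifest.
#'
#' @param scenario_file Scenario YAML ([read_scenario()] format) or a preset
#'   name accepted by [scenario_preset()].
#' @param layout_file Layout CSV path.
#' @param outdir Output directory (created on demand).
#' @param seed Integer base seed.
#' @return The [simulate_plate()] result, invisibly.
#' @export
cmd_simulate <- function(scenario_file, layout_file, outdir, seed = 1L) {
  t0 <- proc.time()[["elapsed"]]
  scenarios <- if (file.exists(scenario_file)) {
    read_scenario(scenario_file)
  } else if (scenario_file %in% c("h460", "h460-coculture", "null")) {
    scenario_preset(scenario_file, seed = seed)
  } else {
    stop("scenario file not found: ", scenario_file, call. = FALSE)
  }
  layout <- parse_layout(layout_file)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_plate(scenarios, layout, outdir = outdir, base_seed = seed)
  .write_manifest(outdir, scenarios,
                  inputs = list(scenario = scenario_file,
                                layout = layout_file),
                  seed = seed,
                  timings = list(simulate = proc.time()[["elapsed"]] - t0),
                  outputs = c(file.path(outdir, paste0(names(sim$stacks),
                                                       ".tif")),
                              file.path(outdir, "truth.csv")))
  invisible(sim)
}

#' Analyze a plate from files (CLI backend)
#'
#' Runs [analyze_plate()] on an image directory and writes all result tables
#' plus a run manifest. Re-running with identical inputs and seed reproduces
#' bit-identical tables.
#'
#' @param images_dir Directory of per-well TIFFs.
#' @param layout_file Layout CSV path.
#' @param config_file Optional YAML/JSON analysis config.
#' @param outdir Output directory (created on demand).
#' @param seed Integer seed overriding the config seed.
#' @return The [analyze_plate()] result, invisibly.
#' @export
cmd_analyze <- function(images_dir, layout_file, config_file = NULL,
                        outdir = "results", seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  config <- if (is.null(config_file)) analysis_config()
            else read_analysis_config(config_file)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  layout <- parse_layout(layout_file)
  res <- analyze_plate(images_dir, layout, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- write_results(res, outdir)
  .write_manifest(outdir, config,
                  inputs = list(images = images_dir, layout = layout_file,
                                config = config_file),
                  seed = config$seed,
                  timings = list(analyze = proc.time()[["elapsed"]] - t0),
                  outputs = files)
  invisible(res)
}
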