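#' Convert a 384-well identifier to 0-based array indices
#'
#' Wells follow the 384-well convention: rows `A`--`P`, columns `1`--`24`.
#' Indexing is 0-based and row-major, so `"A1"` maps to `(0, 0)` and `"P24"`
#' to `(15, 23)`, matching image-array indexing.
#'
#' @param well_id Character vector of well identifiers (e.g. `"B2"`).
#' @return Integer matrix with columns `row` and `col` (0-based), one row per
#'   input identifier.
#' @seealso [index_to_well()] for the inverse.
#' @export
#' @examples
#' well_to_index(c("A1", "P24"))
well_to_index <- function(well_id) {
  if (length(well_id) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("row", "col"))))
  }
  ok <- grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", well_id)
  if (!all(ok)) {
    stop("invalid 384-well identifier(s): ",
         paste(unique(well_id[!ok]), collapse = ", "), call. = FALSE)
  }
  row <- match(substr(well_id, 1L, 1L), LETTERS[1:16]) - 1L
  col <- as.integer(substring(well_id, 2L)) - 1L
  cbind(row = row, col = col)
}

#' Convert 0-based (row, col) indices to 384-well identifiers
#'
#' @param row,col Integer vectors, 0-based; rows in `0:15`, columns in `0:23`.
#' @return Character vector of identifiers such as `"A1"`.
#' @export
index_to_well <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row > 15L | col < 0L | col > 23L)) {
    stop("indices out of 384-well range (rows 0-15, cols 0-23)", call. = FALSE)
  }
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Construct a validated plate layout
#'
#' A plate layout maps each well of a 384-well plate to a culture, a drug, a
#' molar concentration, a replicate number and a role. Vehicle controls are
#' encoded as `concentration = 0` (the drug column may be empty for them);
#' concentrations are stored in molar units throughout, display units are a
#' formatting concern.
#'
#' @param wells A `data.frame` with columns `well`, `culture`, `drug`,
#'   `concentration`, `replicate`, `role`.
#' @param plate_id Plate identifier string.
#' @return An object of class `plate_layout`: a list with `plate_id` and the
#'   validated `wells` data frame.
#' @export
plate_layout <- function(wells, plate_id = "plate1") {
  required <- c("well", "culture", "drug", "concentration", "replicate", "role")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("layout missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wells <- as.data.frame(wells)[required]
  if (nrow(wells) == 0L) stop("layout error: no wells", call. = FALSE)

  wells$well <- as.character(wells$well)
  wells$culture <- as.character(wells$culture)
  wells$drug <- as.character(wells$drug)
  wells$drug[!is.na(wells$drug) & wells$drug == ""] <- NA_character_
  wells$concentration <- suppressWarnings(as.numeric(wells$concentration))
  wells$concentration[is.na(wells$concentration)] <- 0
  wells$replicate <- as.integer(wells$replicate)
  wells$role <- as.character(wells$role)

  well_to_index(wells$well)  # validates identifiers
  dup <- wells$well[duplicated(wells$well)]
  if (length(dup)) {
    stop("layout error: duplicate well id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(wells$role %in% c("control", "treated", "empty"))) {
    stop("layout error: role must be one of control/treated/empty", call. = FALSE)
  }
  if (any(wells$concentration < 0, na.rm = TRUE)) {
    stop("layout error: negative concentration", call. = FALSE)
  }
  tr <- wells$role == "treated"
  if (any(tr & (is.na(wells$drug) | wells$concentration <= 0))) {
    bad <- wells$well[tr & (is.na(wells$drug) | wells$concentration <= 0)]
    stop("layout error: treated well(s) lacking drug or positive concentration: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ctl <- wells$role == "control"
  if (any(ctl & wells$concentration != 0)) {
    stop("layout error: control wells must have concentration 0", call. = FALSE)
  }
  if (any(tr & !is.na(wells$replicate) & wells$replicate < 1L)) {
    stop("layout error: replicate must be a positive integer", call. = FALSE)
  }
  # every (culture, drug) with treated wells needs >= 1 same-culture control
  need <- unique(wells$culture[tr])
  have <- unique(wells$culture[ctl])
  orphan <- setdiff(need, have)
  if (length(orphan)) {
    stop("layout error: no control well for culture(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(plate_id = plate_id, wells = wells), class = "plate_layout")
}

#' Read a plate-layout CSV
#'
#' Expects a comma-separated, UTF-8 table with header columns
#' `well,culture,drug,concentration,replicate,role`. Concentrations are molar.
#'
#' @param path Path to the layout CSV.
#' @param plate_id Plate identifier; defaults to the file name without
#'   extension.
#' @return A validated [plate_layout()] object.
#' @export
parse_layout <- function(path, plate_id = NULL) {
  if (!file.exists(path)) stop("layout file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(path))
  plate_layout(tab, plate_id = plate_id)
}

#' Write a plate layout back to CSV
#'
#' Inverse of [parse_layout()]: `parse_layout(write_layout(x, f))` reproduces
#' `x` on valid layouts.
#'
#' @param layout A `plate_layout`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  w <- layout$wells
  w$drug[is.na(w$drug)] <- ""
  utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.plate_layout <- function(x, ...) {
  w <- x$wells
  cat(sprintf("plate_layout '%s': %d wells (%d treated, %d control, %d empty)\n",
              x$plate_id, nrow(w), sum(w$role == "treated"),
              sum(w$role == "control"), sum(w$role == "empty")))
  cat("cultures:", paste(unique(w$culture), collapse = ", "), "\n")
  drugs <- unique(stats::na.omit(w$drug))
  if (length(drugs)) cat("drugs:", paste(drugs, collapse = ", "), "\n")
  invisible(x)
}

#' Segmentation parameter set
#'
#' Width gates are expressed in micrometres and applied to the equivalent
#' diameter (diameter of the circle with equal area), which is
#' rotation-invariant and matches "width" for round nuclei. These are
#' assay-calibration parameters: the defaults suit the bundled simulator and
#' typical 4x widefield NSCLC images, but real assays should calibrate them
#' against their own staining.
#'
#' @param nucleus_min_width,nucleus_max_width Accepted nuclear equivalent
#'   diameter range, in micrometres.
#' @param nuclear_threshold Absolute intensity threshold for the nuclear
#'   channel, or `"auto"` for a between-class-variance (Otsu) threshold.
#' @param cell_max_width Upper bound on the cell-region equivalent diameter,
#'   in micrometres.
#' @param cytoplasm_thresholds Named numeric vector of per-channel positivity
#'   thresholds on mean cytoplasmic intensity (names matching the channel
#'   map, e.g. `epithelial`, `marker`), or `"auto"` to derive each threshold
#'   from the per-cell intensity distribution.
#' @param split_touching Split touching nuclei by distance-transform
#'   watershed.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(nucleus_min_width = 6,
                                nucleus_max_width = 25,
                                nuclear_threshold = "auto",
                                cell_max_width = 40,
                                cytoplasm_thresholds = "auto",
                                split_touching = TRUE) {
  if (!(nucleus_min_width > 0 && nucleus_min_width < nucleus_max_width &&
        nucleus_max_width <= cell_max_width)) {
    stop("require 0 < nucleus_min_width < nucleus_max_width <= cell_max_width",
         call. = FALSE)
  }
  if (!identical(nuclear_threshold, "auto")) {
    stopifnot(is.numeric(nuclear_threshold), nuclear_threshold >= 0)
  }
  if (!identical(cytoplasm_thresholds, "auto")) {
    stopifnot(is.numeric(cytoplasm_thresholds), all(cytoplasm_thresholds >= 0),
              !is.null(names(cytoplasm_thresholds)))
  }
  structure(list(nucleus_min_width = nucleus_min_width,
                 nucleus_max_width = nucleus_max_width,
                 nuclear_threshold = nuclear_threshold,
                 cell_max_width = cell_max_width,
                 cytoplasm_thresholds = cytoplasm_thresholds,
                 split_touching = isTRUE(split_touching)),
            class = "segmentation_params")
}

#' Analysis configuration
#'
#' Bundles the knobs of the scoring and statistics stages. The induction
#' threshold defaults to a 20% relative increase of the marker-positive
#' percentage over control, the biological-relevance floor of the assay; the
#' significance level defaults to 0.05 on Dunnett-adjusted p-values.
#'
#' @param segmentation A [segmentation_params()] object.
#' @param channel_map Named list mapping channel roles to page indices of the
#'   image stack. `nuclear` and `epithelial` are required for the assay;
#'   `marker` is optional (cytotoxicity-only runs omit it).
#' @param induction_threshold Minimum increase of the marker-positive
#'   percentage, relative fraction in (0, 1) (or percentage points when
#'   `induction_metric = "absolute_points"`).
#' @param alpha Significance level in (0, 1) for the adjusted p-values.
#' @param induction_metric `"relative"` (default) or `"absolute_points"`.
#' @param intensity_stat Per-cell cytoplasmic statistic used for gating:
#'   `"mean"` (default) or `"integrated"` (sum over cytoplasmic pixels).
#' @param marker_name Marker label carried into result tables (e.g. `"ABCB1"`,
#'   `"ABCC1"`, `"ABCG2"`).
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param seed Integer seed for the seeded numerical stages.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(segmentation = segmentation_params(),
                            channel_map = list(nuclear = 1L, epithelial = 2L,
                                               marker = 3L),
                            induction_threshold = 0.20,
                            alpha = 0.05,
                            induction_metric = c("relative", "absolute_points"),
                            intensity_stat = c("mean", "integrated"),
                            marker_name = "ABCB1",
                            pixel_size = 1.7,
                            seed = 1L) {
  induction_metric <- match.arg(induction_metric)
  intensity_stat <- match.arg(intensity_stat)
  if (!(induction_threshold > 0 &&
        (induction_metric == "absolute_points" || induction_threshold < 1))) {
    stop("induction_threshold must lie in (0, 1) for the relative metric",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (is.null(channel_map$nuclear)) {
    stop("channel_map must include a nuclear channel", call. = FALSE)
  }
  if (anyDuplicated(names(channel_map))) {
    stop("channel_map names must be distinct", call. = FALSE)
  }
  if (!inherits(segmentation, "segmentation_params")) {
    segmentation <- do.call(segmentation_params, as.list(segmentation))
  }
  structure(list(segmentation = segmentation,
                 channel_map = lapply(channel_map, as.integer),
                 induction_threshold = induction_threshold,
                 alpha = alpha,
                 induction_metric = induction_metric,
                 intensity_stat = intensity_stat,
                 marker_name = marker_name,
                 pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys mirror the arguments of [analysis_config()]; `segmentation` is a
#' nested mapping with the arguments of [segmentation_params()]. Absent keys
#' take the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw),
                        names(formals(analysis_config)))]
  if (!is.null(args$segmentation)) {
    seg <- args$segmentation
    if (!is.null(seg$cytoplasm_thresholds) &&
        !identical(seg$cytoplasm_thresholds, "auto")) {
      seg$cytoplasm_thresholds <- unlist(seg$cytoplasm_thresholds)
    }
    args$segmentation <- do.call(segmentation_params, seg)
  }
  do.call(analysis_config, args)
}

## ---- result formatting -----------------------------------------------------

#' Format a possibly censored IC50 for tables
#'
#' Censored estimates render as `">cmax"` in the display unit, matching the
#' reporting convention of resistance panels (e.g. `">100"` for a drug that
#' never reaches 50% kill at a 100 µM top dose).
#'
#' @param ic50 Molar IC50, or `NA` when censored.
#' @param censored Logical; `TRUE` for a right-censored estimate.
#' @param cmax Highest tested molar concentration (the censoring bound).
#' @param unit Display unit, `"uM"` or `"nM"`.
#' @param digits Significant digits.
#' @return Character scalar such as `"5.705"` or `">100"`.
#' @export
format_ic50 <- function(ic50, censored = FALSE, cmax = NA_real_,
                        unit = c("uM", "nM"), digits = 4) {
  unit <- match.arg(unit)
  scale <- if (unit == "uM") 1e6 else 1e9
  if (isTRUE(censored)) {
    paste0(">", format(signif(cmax * scale, digits), trim = TRUE,
                       scientific = FALSE))
  } else {
    format(signif(ic50 * scale, digits), trim = TRUE, scientific = FALSE)
  }
}

#' Parse a table IC50 cell back into value/censoring
#'
#' @param x Character scalar like `"5.705"` or `">100"`.
#' @param unit Unit of the printed number, `"uM"` or `"nM"`.
#' @return List with `value` (molar; the bound when censored) and `censored`.
#' @export
parse_ic50 <- function(x, unit = c("uM", "nM")) {
  unit <- match.arg(unit)
  scale <- if (unit == "uM") 1e-6 else 1e-9
  x <- trimws(x)
  censored <- startsWith(x, ">")
  value <- as.numeric(sub("^>", "", x)) * scale
  list(value = value, censored = censored)
}

#' Write pipeline result tables
#'
#' Emits the standard result files into `dir`: `cells.csv` (one row per
#' scored cell), `wells.csv` (one row per well summary), `dose_response.csv`
#' (long form, IC50s with censored entries rendered as `">value"`),
#' `induction.csv` (per-concentration statistics) and `calls.csv` (wide
#' increase/no-change matrix, one block per marker). Empty components produce
#' headers-only files. Numeric columns are written to 6 significant digits
#' and round-trip through [utils::read.csv()].
#'
#' @param results A named list with any of `cells`, `wells`, `dose_response`,
#'   `induction`, `calls` (data frames, as produced by [analyze_plate()]).
#' @param dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output dir: ", dir,
                                      call. = FALSE)
  }
  files <- character(0)
  for (name in c("cells", "wells", "dose_response", "induction", "calls")) {
    tab <- results[[name]]
    if (is.null(tab)) next
    tab <- as.data.frame(tab)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 6)
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(tab, path, row.names = FALSE, na = "")
    files <- c(files, path)
  }
  invisible(files)
}
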