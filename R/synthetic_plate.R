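#' Scenario specification for the synthetic plate simulator
#'
#' Describes one culture's statistical and optical behaviour. Cell kill and
#' marker induction follow Hill curves: the surviving count in a well treated
#' at dose \eqn{c} is Poisson with mean
#' \eqn{n \cdot 1/(1+(c/\mathrm{IC50})^h)}, and the probability that a
#' survivor is marker-positive is
#' \eqn{p(c) = p_0 + (p_{max}-p_0)\, c^h/(c^h + \mathrm{EC50}^h)}.
#' Any smooth monotone dose model would serve; Hill curves are used so that
#' downstream fits can be checked for parameter recovery against the truth.
#'
#' The default field emulates a 4x widefield objective: 2048 x 2048 px at
#' 1.7 um/px, seeded at an expected 1000 cells per well; use `field = 512`
#' scaled presets for fast test runs.
#'
#' @param n_cells_mean Expected number of seeded cells per well.
#' @param cancer_fraction Fraction of cells that are cancer (epithelial);
#'   `0.5` emulates a 1:1 co-culture with stromal fibroblasts.
#' @param baseline_marker_pos Named fractions (`cancer`, `stromal`) of
#'   marker-positive cells at dose 0.
#' @param kill_ic50 Named molar IC50s of the kill curve per population.
#' @param kill_hill Hill slope of the kill curve (> 0).
#' @param induction_ec50 Molar EC50 of the marker-induction curve.
#' @param induction_hill Hill slope of the induction curve.
#' @param induction_max Named maximal marker-positive fractions (>= baseline).
#'   The simulator models the net observable positive fraction among
#'   survivors; it does not separate induction from selective survival.
#' @param nucleus_diameter_mean,nucleus_diameter_sd Nuclear diameter (um).
#' @param cell_diameter Whole-cell diameter (um); sets the cytoplasmic
#'   annulus.
#' @param intensity Per-channel emission levels (arbitrary counts): a list
#'   with `nuclear` (scalar) and `epithelial`/`marker` (named `pos`/`neg`).
#'   Per-cell brightness is lognormal around these levels (`sdlog`).
#' @param sdlog Lognormal sigma of per-cell brightness.
#' @param background Constant background offset (counts).
#' @param noise_sd Additive Gaussian read-noise sd (counts), on top of
#'   Poisson shot noise.
#' @param psf_sigma Gaussian blur sigma (px) standing in for the PSF.
#' @param pixel_size Pixel size (um/px).
#' @param field Field side length (px); the image is `field x field`.
#' @param seed Integer seed; `simulate_well()` is bit-reproducible given it.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(n_cells_mean = 1000,
                          cancer_fraction = 1,
                          baseline_marker_pos = c(cancer = 0.10, stromal = 0.05),
                          kill_ic50 = c(cancer = 1e-6, stromal = 5e-6),
                          kill_hill = 1,
                          induction_ec50 = 5e-7,
                          induction_hill = 1,
                          induction_max = NULL,
                          nucleus_diameter_mean = 12,
                          nucleus_diameter_sd = 1.5,
                          cell_diameter = 20,
                          intensity = list(nuclear = 3000,
                                           epithelial = c(pos = 2500, neg = 250),
                                           marker = c(pos = 2500, neg = 250)),
                          sdlog = 0.15,
                          background = 100,
                          noise_sd = 20,
                          psf_sigma = 1.2,
                          pixel_size = 1.7,
                          field = 2048,
                          seed = 1L) {
  baseline_marker_pos <- .per_pop(baseline_marker_pos)
  kill_ic50 <- .per_pop(kill_ic50)
  if (is.null(induction_max)) {
    # default: room for a 20-point induction above baseline
    induction_max <- pmin(baseline_marker_pos + 0.20, 1)
  }
  induction_max <- .per_pop(induction_max)
  stopifnot(n_cells_mean > 0,
            cancer_fraction >= 0, cancer_fraction <= 1,
            all(baseline_marker_pos >= 0), all(baseline_marker_pos <= 1),
            all(induction_max >= 0), all(induction_max <= 1),
            kill_hill > 0, induction_hill > 0,
            nucleus_diameter_mean > 0, cell_diameter > 0,
            pixel_size > 0, field >= 64)
  if (any(induction_max < baseline_marker_pos)) {
    stop("induction_max must be >= baseline_marker_pos per population",
         call. = FALSE)
  }
  structure(list(n_cells_mean = n_cells_mean,
                 cancer_fraction = cancer_fraction,
                 baseline_marker_pos = baseline_marker_pos,
                 kill_ic50 = kill_ic50, kill_hill = kill_hill,
                 induction_ec50 = induction_ec50,
                 induction_hill = induction_hill,
                 induction_max = induction_max,
                 nucleus_diameter_mean = nucleus_diameter_mean,
                 nucleus_diameter_sd = nucleus_diameter_sd,
                 cell_diameter = cell_diameter,
                 intensity = intensity, sdlog = sdlog,
                 background = background, noise_sd = noise_sd,
                 psf_sigma = psf_sigma, pixel_size = pixel_size,
                 field = as.integer(field), seed = as.integer(seed)),
            class = "scenario_spec")
}

.per_pop <- function(x) {
  if (is.null(names(x))) x <- c(cancer = x[[1]],
                                stromal = if (length(x) > 1) x[[2]] else x[[1]])
  x[c("cancer", "stromal")]
}

#' Hill survival fraction
#'
#' \eqn{f(c) = 1/(1+(c/\mathrm{IC50})^h)}; `f(0) = 1` and
#' `f(ic50) = 0.5` exactly.
#'
#' @param dose Molar dose(s).
#' @param ic50 Molar midpoint.
#' @param hill Slope (> 0).
#' @return Survival fraction(s) in (0, 1].
#' @export
hill_survival <- function(dose, ic50, hill = 1) {
  ifelse(dose <= 0, 1, 1 / (1 + (dose / ic50)^hill))
}

#' Hill marker-positive probability
#'
#' @param dose Molar dose(s).
#' @param p0 Baseline positive fraction.
#' @param pmax Maximal positive fraction.
#' @param ec50 Molar midpoint of the induction curve.
#' @param hill Slope (> 0).
#' @return Positive probability in \[p0, pmax\].
#' @export
hill_induction <- function(dose, p0, pmax, ec50, hill = 1) {
  ifelse(dose <= 0, p0,
         p0 + (pmax - p0) * dose^hill / (dose^hill + ec50^hill))
}

# Hard-core point process: uniform centres, sequential rejection below
# min_dist, bounded retries. Margin keeps whole cells inside the field.
.place_hardcore <- function(n, field, min_dist, margin, max_tries = 300L) {
  if (n == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  lo <- margin; hi <- field - margin
  if (hi <= lo) stop("field too small for the configured cell size",
                     call. = FALSE)
  pts <- matrix(NA_real_, nrow = n, ncol = 2)
  placed <- 0L
  tries <- 0L
  d2min <- min_dist^2
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries * n) {
      stop("hard-core placement failed after bounded retries; ",
           "use a larger field or fewer cells per well", call. = FALSE)
    }
    cand <- stats::runif(2, lo, hi)
    if (placed > 0L) {
      d2 <- (pts[seq_len(placed), 1] - cand[1])^2 +
            (pts[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < d2min) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  colnames(pts) <- c("row", "col")
  pts
}

# Accumulate a filled disk (or annulus when r_in > 0) of the given intensity
# into matrix `img` at centre (r0, c0) in 1-based pixel coordinates.
.draw_disk <- function(img, r0, c0, radius, value, r_in = 0) {
  n <- nrow(img)
  rr <- max(1L, floor(r0 - radius)):min(n, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(ncol(img), ceiling(c0 + radius))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  sel <- d2 <= radius^2 & d2 >= r_in^2
  img[rr, cc][sel] <- img[rr, cc][sel] + value
  img
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one well
#'
#' Draws surviving cancer and stromal cells from the kill model, assigns
#' marker positivity from the induction model, places nuclei by a hard-core
#' process (no two centres closer than 0.8 x the mean nuclear diameter) and,
#' unless `render = FALSE`, renders a three-channel stack: nuclear disks,
#' cytoplasmic annuli in the epithelial channel for cancer cells and in the
#' marker channel for marker-positive cells (negative cells emit a faint
#' annulus), Gaussian-blurred, with Poisson shot noise, constant background
#' and Gaussian read noise.
#'
#' @param spec A [scenario_spec()].
#' @param dose Molar dose (>= 0; 0 = vehicle control).
#' @param seed Seed for this well; defaults to `spec$seed`.
#' @param render If `FALSE`, skip image rendering and return truth only
#'   (fast path for statistical simulations).
#' @return List with `stack` (named list of `nuclear`, `epithelial`, `marker`
#'   count matrices, or `NULL`) and `truth` (data frame: one row per rendered
#'   cell with 0-based centroid, class, marker flag, nucleus radius in px).
#' @export
simulate_well <- function(spec, dose = 0, seed = spec$seed, render = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), dose >= 0)
  .with_seed(seed, {
    px <- spec$pixel_size
    f_c <- hill_survival(dose, spec$kill_ic50[["cancer"]], spec$kill_hill)
    f_s <- hill_survival(dose, spec$kill_ic50[["stromal"]], spec$kill_hill)
    n_cancer <- stats::rpois(1, spec$n_cells_mean * spec$cancer_fraction * f_c)
    n_stromal <- stats::rpois(1, spec$n_cells_mean * (1 - spec$cancer_fraction) * f_s)
    n <- n_cancer + n_stromal

    min_dist <- 0.8 * spec$nucleus_diameter_mean / px
    margin <- spec$cell_diameter / 2 / px + 1
    pts <- .place_hardcore(n, spec$field, min_dist, margin)

    cls <- rep(c("cancer", "stromal"), c(n_cancer, n_stromal))
    p_pos <- hill_induction(dose,
                            spec$baseline_marker_pos[cls],
                            spec$induction_max[cls],
                            spec$induction_ec50, spec$induction_hill)
    marker_pos <- stats::runif(n) < p_pos
    nuc_d_um <- stats::rnorm(n, spec$nucleus_diameter_mean,
                             spec$nucleus_diameter_sd)
    nuc_d_um <- pmax(nuc_d_um, 0.5 * spec$nucleus_diameter_mean)
    nuc_r <- nuc_d_um / 2 / px
    cell_r <- rep(spec$cell_diameter / 2 / px, n)

    truth <- data.frame(cell = seq_len(n),
                        class = cls,
                        marker_positive = marker_pos,
                        row = pts[, "row"] - 1,   # 0-based centroids
                        col = pts[, "col"] - 1,
                        nucleus_radius_px = nuc_r,
                        dose = rep(dose, n),
                        stringsAsFactors = FALSE)

    stack <- NULL
    if (render) {
      dim <- spec$field
      nuclear <- epithelial <- marker <- matrix(0, dim, dim)
      lv <- spec$intensity
      i_nuc <- stats::rlnorm(n, log(lv$nuclear), spec$sdlog)
      i_epi <- stats::rlnorm(n, log(ifelse(cls == "cancer",
                                           lv$epithelial[["pos"]],
                                           lv$epithelial[["neg"]])), spec$sdlog)
      i_mrk <- stats::rlnorm(n, log(ifelse(marker_pos,
                                           lv$marker[["pos"]],
                                           lv$marker[["neg"]])), spec$sdlog)
      for (k in seq_len(n)) {
        r0 <- pts[k, "row"]; c0 <- pts[k, "col"]
        nuclear <- .draw_disk(nuclear, r0, c0, nuc_r[k], i_nuc[k])
        epithelial <- .draw_disk(epithelial, r0, c0, cell_r[k], i_epi[k],
                                 r_in = nuc_r[k])
        marker <- .draw_disk(marker, r0, c0, cell_r[k], i_mrk[k],
                             r_in = nuc_r[k])
      }
      blur <- function(m) {
        if (spec$psf_sigma > 0) EBImage::gblur(m, sigma = spec$psf_sigma) else m
      }
      shotify <- function(m) {
        m <- blur(m)
        m <- stats::rpois(length(m), pmax(m, 0)) + spec$background +
          stats::rnorm(length(m), 0, spec$noise_sd)
        matrix(round(pmin(pmax(m, 0), 65535)), dim, dim)
      }
      stack <- list(nuclear = shotify(nuclear),
                    epithelial = shotify(epithelial),
                    marker = shotify(marker))
    }
    list(stack = stack, truth = truth)
  })
}

#' Simulate a whole plate from a layout
#'
#' Looks up a scenario for every non-empty well: first under the key
#' `"culture:drug"`, then under `"culture"`. Each well gets its own
#' deterministic seed derived from `base_seed` and the well's linear plate
#' index, so the output is reproducible and independent of well order.
#'
#' @param scenarios Named list of [scenario_spec()]s keyed by culture (or
#'   `"culture:drug"` for drug-specific kill/induction parameters).
#' @param layout A [plate_layout()].
#' @param outdir Optional directory: writes one multi-page 16-bit TIFF per
#'   well (page order nuclear, epithelial, marker) plus `truth.csv`.
#' @param base_seed Integer base seed (defaults to the first scenario's).
#' @param render Passed to [simulate_well()].
#' @return List with `stacks` (named list by well id, `NULL` entries when
#'   `render = FALSE`) and `truth` (combined data frame with a `well`
#'   column).
#' @export
simulate_plate <- function(scenarios, layout, outdir = NULL,
                           base_seed = NULL, render = TRUE) {
  stopifnot(inherits(layout, "plate_layout"))
  if (inherits(scenarios, "scenario_spec")) {
    scenarios <- stats::setNames(list(scenarios),
                                 unique(layout$wells$culture)[1])
  }
  if (is.null(base_seed)) base_seed <- scenarios[[1]]$seed
  w <- layout$wells[layout$wells$role != "empty", , drop = FALSE]
  stacks <- list()
  truths <- list()
  for (i in seq_len(nrow(w))) {
    key <- if (!is.na(w$drug[i])) paste0(w$culture[i], ":", w$drug[i]) else NA
    spec <- if (!is.na(key) && !is.null(scenarios[[key]])) {
      scenarios[[key]]
    } else scenarios[[w$culture[i]]]
    if (is.null(spec)) {
      stop("no scenario parameters for culture '", w$culture[i],
           "' (well ", w$well[i], ")", call. = FALSE)
    }
    idx <- well_to_index(w$well[i])
    lin <- idx[1, "row"] * 24L + idx[1, "col"]
    seed_i <- (as.numeric(base_seed) * 131071 + lin + 1) %% 2147483629
    sim <- simulate_well(spec, dose = w$concentration[i],
                         seed = as.integer(seed_i), render = render)
    if (render) stacks[[w$well[i]]] <- sim$stack
    if (nrow(sim$truth)) sim$truth$well <- w$well[i]
    truths[[w$well[i]]] <- sim$truth
  }
  truth <- if (length(truths)) {
    do.call(rbind, c(truths, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(truth)) {
    truth <- data.frame(cell = integer(0), class = character(0),
                        marker_positive = logical(0), row = numeric(0),
                        col = numeric(0), nucleus_radius_px = numeric(0),
                        dose = numeric(0), well = character(0))
  }
  if (!is.null(outdir) && render) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (well in names(stacks)) {
      write_stack(stacks[[well]], file.path(outdir, paste0(well, ".tif")))
    }
    utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  }
  list(stacks = stacks, truth = truth)
}

#' Write a channel stack as a multi-page 16-bit TIFF
#'
#' Page order is nuclear, epithelial, marker. Intensities are clipped to
#' `[0, 65535]` and rounded, so a write/read cycle is lossless.
#'
#' @param stack Named list of count matrices.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack, function(m) round(pmin(pmax(m, 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a named channel stack
#'
#' @param path `.tif` path (single- or multi-page).
#' @param channel_map Named list of page indices, as in [analysis_config()];
#'   channels whose page is absent from the file are dropped.
#' @return Named list of integer count matrices.
#' @export
read_stack <- function(path, channel_map = list(nuclear = 1L, epithelial = 2L,
                                                marker = 3L)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- list()
  for (ch in names(channel_map)) {
    i <- channel_map[[ch]]
    if (i <= length(pages)) out[[ch]] <- pages[[i]]
  }
  out
}

#' Simulate a viability response panel (statistical layer only)
#'
#' Generates percent-of-control viability readings straight from the Hill
#' kill model with multiplicative noise at a given coefficient of variation —
#' the per-well statistical behaviour of the imaging simulator without the
#' imaging. Used for dose-response fit validation.
#'
#' @param ic50 True molar IC50.
#' @param hill True Hill slope.
#' @param concentrations Molar doses (the treated panel).
#' @param n_replicates Replicate wells per dose.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param top,bottom Response asymptotes in percent.
#' @param seed Integer seed.
#' @return Data frame with `concentration` and `response` (one row per
#'   replicate well).
#' @export
simulate_viability_panel <- function(ic50, hill, concentrations,
                                     n_replicates = 4, cv = 0.10,
                                     top = 100, bottom = 0, seed = 1L) {
  .with_seed(seed, {
    conc <- rep(concentrations, each = n_replicates)
    mu <- bottom + (top - bottom) * hill_survival(conc, ic50, hill)
    resp <- pmax(mu * (1 + stats::rnorm(length(mu), 0, cv)), 0)
    data.frame(concentration = conc, response = resp)
  })
}

#' Built-in simulation presets
#'
#' `"h460"`: pure epithelial culture; `"h460-coculture"`: 1:1 cancer/stromal
#' co-culture; `"null"`: no kill and no induction within the tested range
#' (flat dose response). `field = 512` presets keep test runs fast; pass
#' `field = 2048` for full-scale wells.
#'
#' @param name Preset name.
#' @param field Field side (px).
#' @param n_cells_mean Expected cells per well (scaled down with the field).
#' @param seed Integer seed.
#' @return Named list of [scenario_spec()]s suitable for [simulate_plate()].
#' @export
scenario_preset <- function(name = c("h460", "h460-coculture", "null"),
                            field = 512, n_cells_mean = 150, seed = 1L) {
  name <- match.arg(name)
  base <- list(field = field, n_cells_mean = n_cells_mean, seed = seed)
  spec <- switch(name,
    "h460" = do.call(scenario_spec, c(base, list(cancer_fraction = 1))),
    "h460-coculture" = do.call(scenario_spec,
                               c(base, list(cancer_fraction = 0.5))),
    "null" = do.call(scenario_spec,
                     c(base, list(cancer_fraction = 1,
                                  kill_ic50 = c(cancer = 1, stromal = 1),
                                  induction_ec50 = 1))))
  stats::setNames(list(spec), name)
}

#' Read simulation scenarios from a YAML file
#'
#' The file maps scenario keys (culture or `"culture:drug"`) to
#' [scenario_spec()] arguments; named per-population values are given as
#' mappings (`kill_ic50: {cancer: 1.0e-6, stromal: 5.0e-6}`).
#'
#' @param path YAML file path.
#' @return Named list of `scenario_spec`s.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(args) {
    for (f in c("baseline_marker_pos", "kill_ic50", "induction_max")) {
      if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
    }
    if (!is.null(args$intensity)) {
      args$intensity <- lapply(args$intensity, unlist)
    }
    do.call(scenario_spec, args)
  })
}
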