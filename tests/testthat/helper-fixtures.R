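# Shared fixtures: all built in code at test time.

# Layout with one drug panel: n_conc x n_reps treated + n_controls controls,
# wells filled row-major from A1.
make_panel_layout <- function(concentrations = c(1, 2.5, 5, 7.5, 10) * 1e-6,
                              n_reps = 4, n_controls = 4,
                              culture = "h460", drug = "drugX",
                              plate_id = "testplate") {
  n <- length(concentrations) * n_reps + n_controls
  wells <- index_to_well((seq_len(n) - 1) %/% 24, (seq_len(n) - 1) %% 24)
  conc <- c(rep(concentrations, each = n_reps), rep(0, n_controls))
  rep_id <- c(rep(seq_len(n_reps), length(concentrations)),
              seq_len(n_controls))
  role <- c(rep("treated", length(concentrations) * n_reps),
            rep("control", n_controls))
  plate_layout(data.frame(well = wells, culture = culture,
                          drug = ifelse(role == "treated", drug, ""),
                          concentration = conc, replicate = rep_id,
                          role = role),
               plate_id = plate_id)
}

# Small, fast scenario for image-based tests.
tiny_spec <- function(...) {
  args <- list(field = 256, n_cells_mean = 40, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(scenario_spec, args)
}

# Flat-disk image with known centres/diameters (um) on a constant background.
disk_image <- function(centres, diam_um, pixel_size = 1.7, field = 256,
                       fg = 1000, bg = 0, noise_sd = 0) {
  img <- matrix(bg, field, field)
  r_px <- diam_um / 2 / pixel_size
  for (i in seq_len(nrow(centres))) {
    rr <- seq_len(field); cc <- seq_len(field)
    d2 <- outer((rr - centres[i, 1])^2, (cc - centres[i, 2])^2, "+")
    img[d2 <= r_px[min(i, length(r_px))]^2] <- fg
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(field^2, 0, noise_sd), field)
  img
}

# Hand-built cell records for scoring-logic tests.
make_records <- function(epi, mrk, well_id = "A1") {
  n <- length(epi)
  data.frame(cell_id = seq_len(n), row = seq_len(n), col = seq_len(n),
             nucleus_area = rep(10, n), cell_area = rep(30, n),
             well_id = rep(well_id, n),
             epithelial_positive = epi, marker_positive = mrk)
}

# Grouped percentage observations in the group_percentages() shape.
make_groups <- function(means, n = 4, sd = 1, seed = 1) {
  set.seed(seed)
  conc <- rep(seq_along(means) - 1, each = n) * 1e-6
  data.frame(concentration = conc,
             pct = rnorm(length(conc), rep(means, each = n), sd))
}
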