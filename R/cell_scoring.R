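#' Per-cell cytoplasmic intensity statistics
#'
#' For every labelled cell, computes the chosen statistic (mean by default,
#' or integrated = summed) of each channel over the cytoplasmic region —
#' the cell region excluding the nucleus. Cells whose region equals their
#' nucleus (no cytoplasmic pixels) fall back to the whole-cell region.
#'
#' @param stack Named list of channel matrices (from [read_stack()] or the
#'   simulator).
#' @param cells Cell-region label mask from [assign_cell_regions()].
#' @param nuclei Nucleus label mask from [segment_nuclei()]; label k is the
#'   nucleus of cell k.
#' @param config An [analysis_config()].
#' @return Data frame: `cell_id`, centroid `row`/`col` (0-based), areas, and
#'   one `cyto_<channel>` column per mapped channel present in the stack.
#' @export
compute_cell_stats <- function(stack, cells, nuclei, config = analysis_config()) {
  if (!identical(dim(cells), dim(nuclei))) {
    stop("cell and nucleus masks have different shapes", call. = FALSE)
  }
  k <- max(nuclei)
  cen <- label_centroids(nuclei)
  cell_area <- tabulate(cells[cells > 0L], nbins = k)
  out <- data.frame(cell_id = seq_len(k),
                    row = cen$row, col = cen$col,
                    nucleus_area = cen$area,
                    cell_area = cell_area)
  cyto <- cells > 0L & nuclei == 0L
  cyto_lab <- cells[cyto]
  cyto_n <- tabulate(cyto_lab, nbins = k)
  agg <- if (config$intensity_stat == "integrated") {
    function(v, lab, n) {
      s <- rep(0, k)
      if (length(lab)) s[sort(unique(lab))] <- rowsum(v, lab)[, 1]
      s
    }
  } else {
    function(v, lab, n) {
      s <- rep(NA_real_, k)
      if (length(lab)) s[sort(unique(lab))] <- rowsum(v, lab)[, 1]
      s / n
    }
  }
  for (ch in names(config$channel_map)) {
    img <- stack[[ch]]
    if (is.null(img)) next
    if (!identical(dim(img), dim(cells))) {
      stop("channel '", ch, "' shape does not match the masks", call. = FALSE)
    }
    val <- agg(img[cyto], cyto_lab, cyto_n)
    # fallback: whole-cell statistic where the cytoplasm is empty
    need <- which(cyto_n == 0L)
    if (length(need)) {
      fg <- cells > 0L
      lab_all <- cells[fg]
      tot <- rep(NA_real_, k)
      tot[sort(unique(lab_all))] <- rowsum(img[fg], lab_all)[, 1]
      val[need] <- if (config$intensity_stat == "integrated") {
        tot[need]
      } else tot[need] / cell_area[need]
    }
    out[[paste0("cyto_", ch)]] <- val
  }
  out
}

#' Resolve per-channel positivity thresholds
#'
#' Numeric thresholds in the configuration are taken as-is; `"auto"` derives
#' each channel's threshold from the distribution of per-cell cytoplasmic
#' statistics by between-class-variance splitting ([auto_threshold()]),
#' which assumes the scored cells contain both positive and negative
#' examples of that channel. Pool statistics across all wells of a plate
#' before resolving so single-class wells are gated consistently.
#'
#' @param stats Per-cell statistics (one or several [compute_cell_stats()]
#'   outputs row-bound together).
#' @param config An [analysis_config()].
#' @return Named numeric vector of thresholds for the non-nuclear channels
#'   present in `stats`.
#' @export
resolve_thresholds <- function(stats, config = analysis_config()) {
  chans <- setdiff(names(config$channel_map), "nuclear")
  chans <- chans[paste0("cyto_", chans) %in% names(stats)]
  cfg <- config$segmentation$cytoplasm_thresholds
  thr <- stats::setNames(numeric(length(chans)), chans)
  for (ch in chans) {
    if (!identical(cfg, "auto") && ch %in% names(cfg)) {
      thr[ch] <- cfg[[ch]]
    } else {
      v <- stats[[paste0("cyto_", ch)]]
      v <- v[is.finite(v)]
      thr[ch] <- if (length(unique(v)) < 2L) {
        if (length(v)) min(v) else 0   # degenerate: everything scores positive
      } else auto_threshold(v)
    }
  }
  thr
}

#' Score cells as epithelial/marker positive or negative
#'
#' Applies per-channel thresholds to the per-cell cytoplasmic statistic:
#' a cell is positive on a channel when its statistic is greater than or
#' equal to the threshold (ties score positive, deterministically). The
#' epithelial (CK8/18) flag separates cancer from stromal cells; the marker
#' flag (when a marker channel is mapped) separates MDR-marker positive from
#' negative cells, yielding the four scored populations.
#'
#' @param stack,cells,nuclei,config As in [compute_cell_stats()].
#' @param well_id Well identifier stamped on each record.
#' @param thresholds Optional named numeric vector of resolved thresholds;
#'   when `NULL` they are resolved from this well alone via
#'   [resolve_thresholds()].
#' @return Data frame of cell records: geometry, per-channel statistics,
#'   `epithelial_positive`, and `marker_positive` (`NA` when no marker
#'   channel is present).
#' @export
score_cells <- function(stack, cells, nuclei, config = analysis_config(),
                        well_id = "well", thresholds = NULL) {
  if (is.null(config$channel_map$epithelial) || is.null(stack$epithelial)) {
    stop("epithelial (CK8/18) channel is required to discriminate cancer ",
         "from stromal cells", call. = FALSE)
  }
  stats <- compute_cell_stats(stack, cells, nuclei, config)
  if (is.null(thresholds)) thresholds <- resolve_thresholds(stats, config)
  stats$well_id <- well_id
  stats$epithelial_positive <- stats$cyto_epithelial >= thresholds[["epithelial"]]
  stats$marker_positive <- if (!is.null(stats$cyto_marker) &&
                               "marker" %in% names(thresholds)) {
    stats$cyto_marker >= thresholds[["marker"]]
  } else NA
  stats
}

#' Summarize a well into the four scored populations
#'
#' Cross-tabulates cancer/stromal x marker-positive/negative and computes the
#' within-population marker-positive percentages. The four counts always sum
#' to the total. Percentages are `NA` (flagged undefined) when the
#' population denominator is zero or when no marker channel was scored.
#'
#' @param records Cell records from [score_cells()].
#' @param well_id Well identifier (checked against the records).
#' @return One-row data frame (`well_summary`): `well_id`, `n_total`, the
#'   four population counts, `n_cancer`, `n_stromal`, and
#'   `pct_marker_pos_cancer` / `pct_marker_pos_stromal`.
#' @export
summarize_well <- function(records, well_id = NULL) {
  if (is.null(well_id)) {
    well_id <- if (nrow(records)) records$well_id[1] else "well"
  }
  if (nrow(records) && !all(records$well_id == well_id)) {
    stop("records from a different well than '", well_id, "'", call. = FALSE)
  }
  epi <- records$epithelial_positive
  mrk <- records$marker_positive
  marker_scored <- nrow(records) > 0 && any(!is.na(mrk))
  mrk_eff <- !is.na(mrk) & mrk   # unscored marker counts as negative
  n_cmp <- sum(epi & mrk_eff)
  n_cmn <- sum(epi & !mrk_eff)
  n_smp <- sum(!epi & mrk_eff)
  n_smn <- sum(!epi & !mrk_eff)
  n_cancer <- n_cmp + n_cmn
  n_stromal <- n_smp + n_smn
  pct <- function(pos, denom) {
    if (!marker_scored || denom == 0L) NA_real_ else 100 * pos / denom
  }
  data.frame(well_id = well_id,
             n_total = nrow(records),
             n_cancer_marker_pos = n_cmp,
             n_cancer_marker_neg = n_cmn,
             n_stromal_marker_pos = n_smp,
             n_stromal_marker_neg = n_smn,
             n_cancer = n_cancer,
             n_stromal = n_stromal,
             pct_marker_pos_cancer = pct(n_cmp, n_cancer),
             pct_marker_pos_stromal = pct(n_smp, n_stromal),
             stringsAsFactors = FALSE)
}

.truth_class <- function(class, marker_positive) {
  paste0(class, ifelse(marker_positive, "_marker_pos", "_marker_neg"))
}

#' Confusion table of scored cells against simulation truth
#'
#' Matches scored cells to truth cells by nearest centroid within one true
#' nucleus radius (each object used once), then cross-tabulates the four
#' predicted classes against the four true classes.
#'
#' @param records Cell records from [score_cells()] for one simulated well.
#' @param truth The matching [simulate_well()] truth.
#' @return List with `confusion` (4 x 4 table, truth in rows), `per_class`
#'   (precision/recall per class; `NA` flagged when a class is absent),
#'   `accuracy` (over matched cells) and the `matching` summary.
#' @export
score_against_truth <- function(records, truth) {
  need <- c("class", "marker_positive", "row", "col", "nucleus_radius_px")
  if (!all(need %in% names(truth))) {
    stop("truth table lacks simulator columns; ",
         "score_against_truth requires simulated input", call. = FALSE)
  }
  det <- data.frame(label = records$cell_id, row = records$row,
                    col = records$col)
  m <- match_nuclei(det, truth)
  classes <- c("cancer_marker_pos", "cancer_marker_neg",
               "stromal_marker_pos", "stromal_marker_neg")
  pred_all <- .truth_class(ifelse(records$epithelial_positive,
                                  "cancer", "stromal"),
                           !is.na(records$marker_positive) &
                             records$marker_positive)
  true_all <- .truth_class(truth$class, truth$marker_positive)
  pred <- factor(pred_all[match(m$matches$label, records$cell_id)],
                 levels = classes)
  true <- factor(true_all[match(m$matches$truth_cell, truth$cell)],
                 levels = classes)
  confusion <- table(truth = true, predicted = pred)
  per_class <- data.frame(
    class = classes,
    n_truth = as.integer(rowSums(confusion)),
    n_predicted = as.integer(colSums(confusion)),
    recall = ifelse(rowSums(confusion) > 0,
                    diag(confusion) / rowSums(confusion), NA_real_),
    precision = ifelse(colSums(confusion) > 0,
                       diag(confusion) / colSums(confusion), NA_real_))
  list(confusion = confusion,
       per_class = per_class,
       accuracy = if (nrow(m$matches)) {
         sum(diag(confusion)) / nrow(m$matches)
       } else NA_real_,
       matching = m[c("precision", "recall", "n_detected", "n_truth")])
}
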