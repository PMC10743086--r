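#' Between-class-variance (Otsu) automatic threshold
#'
#' Picks the cut that maximizes the between-class variance of the two
#' resulting intensity classes, evaluated exactly over the distinct values of
#' the input (binned to 4096 levels only for near-continuous data). The
#' returned threshold is the midpoint between the optimal pair of adjacent
#' levels, so it shifts exactly with any constant offset added to the image.
#' Deterministic; the lowest maximizer wins on ties.
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @return A single threshold value; pixels strictly above it are foreground.
#' @export
auto_threshold <- function(image) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty image", call. = FALSE)
  vals <- sort(unique(x))
  if (length(vals) < 2L) {
    stop("constant image: no threshold exists", call. = FALSE)
  }
  if (length(vals) > 4096L) {
    br <- seq(vals[1], vals[length(vals)], length.out = 4097L)
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = 4096L)
    keep <- cnt > 0L
    vals <- ((br[-1L] + br[-4097L]) / 2)[keep]
    w <- cnt[keep]
  } else {
    w <- tabulate(match(x, vals), nbins = length(vals))
  }
  w <- as.numeric(w)
  W <- cumsum(w)
  S <- cumsum(w * vals)
  n <- W[length(W)]
  tot <- S[length(S)]
  i <- seq_len(length(vals) - 1L)
  w0 <- W[i]
  w1 <- n - w0
  mu0 <- S[i] / w0
  mu1 <- (tot - S[i]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(bcv)
  (vals[k] + vals[k + 1L]) / 2
}

# Relabel a mask so labels are consecutive 1..K (0 stays background).
.relabel <- function(mask, keep = NULL) {
  mx <- max(mask)
  if (mx == 0) return(mask)
  if (is.null(keep)) keep <- sort(unique(mask[mask > 0]))
  map <- integer(mx)
  map[keep] <- seq_along(keep)
  out <- mask
  fg <- mask > 0
  out[fg] <- map[mask[fg]]
  out
}

#' Segment nuclei in the nuclear channel
#'
#' Global threshold (absolute or automatic between-class variance), hole
#' filling, optional splitting of touching nuclei by distance-transform
#' watershed, then a width gate: only components whose equivalent diameter
#' (diameter of the equal-area circle) lies within
#' `[nucleus_min_width, nucleus_max_width]` are kept. Border-touching nuclei
#' are discarded because their intensity statistics are truncated. Fully
#' overlapped nuclei are not resolved and yield a single label.
#'
#' @param nuclear_image Numeric intensity matrix.
#' @param params A [segmentation_params()].
#' @param pixel_size Pixel size in um/px.
#' @return Integer label mask (same shape; 0 = background, labels 1..K).
#' @export
segment_nuclei <- function(nuclear_image, params = segmentation_params(),
                           pixel_size = 1.7) {
  stopifnot(inherits(params, "segmentation_params"),
            is.matrix(nuclear_image), length(nuclear_image) > 0,
            pixel_size > 0)
  empty <- matrix(0L, nrow(nuclear_image), ncol(nuclear_image))
  rng <- range(nuclear_image)
  if (rng[1] == rng[2]) {
    warning("constant (flat or saturated) nuclear image; returning empty mask")
    return(empty)
  }
  thr <- if (identical(params$nuclear_threshold, "auto")) {
    auto_threshold(nuclear_image)
  } else params$nuclear_threshold
  bw <- nuclear_image > thr
  if (mean(bw) > 0.9) {
    warning("nuclear channel nearly saturated above threshold; ",
            "returning empty mask")
    return(empty)
  }
  if (!any(bw)) return(empty)
  bw <- EBImage::fillHull(bw * 1)
  lab <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(bw), tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(bw)
  }
  lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
  k <- max(lab)
  if (k == 0L) return(empty)
  area <- tabulate(lab[lab > 0L], nbins = k)
  d_eq <- 2 * sqrt(area / pi) * pixel_size
  keep <- d_eq >= params$nucleus_min_width & d_eq <= params$nucleus_max_width
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep[border[border > 0L]] <- FALSE
  if (!any(keep)) return(empty)
  lab[!matrix(keep[pmax(lab, 1L)] & lab > 0L, nrow(lab))] <- 0L
  .relabel(lab, keep = which(keep))
}

# Minimum positive 8-neighbour label for every pixel (0 where none).
.neighbor_min_label <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  acc <- matrix(Inf, nr, nc)
  pad <- function(dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- L[rs - dr, cs - dc]
    out
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- pad(dr, dc)
    s[s == 0L] <- .Machine$integer.max
    acc <- pmin(acc, s)
  }
  acc[acc == .Machine$integer.max] <- 0
  matrix(as.integer(acc), nr, nc)
}

#' Expand nuclei into bounded cell regions
#'
#' Grows each nucleus outward by nearest-nucleus geodesic propagation in the
#' 8-connected (Chebyshev) metric: at each step every region claims the
#' unassigned pixels adjacent to it, contested pixels going to the
#' lowest-numbered adjacent region, so two regions meet at their equidistant
#' boundary. Growth of a region stops before the step that would push its
#' equivalent diameter above `cell_max_width` (the whole ring is skipped, so
#' an isolated nucleus ends up as an exact Chebyshev dilation of itself).
#' Regions are pairwise disjoint and each contains its own nucleus.
#'
#' @param nuclei Integer nucleus label mask (labels 1..K).
#' @param params A [segmentation_params()].
#' @param pixel_size Pixel size in um/px.
#' @return Integer cell-region label mask; label k is the region of
#'   nucleus k.
#' @export
assign_cell_regions <- function(nuclei, params = segmentation_params(),
                                pixel_size = 1.7) {
  stopifnot(inherits(params, "segmentation_params"), is.matrix(nuclei),
            pixel_size > 0)
  k <- max(nuclei)
  if (k == 0L) return(nuclei)
  labs <- sort(unique(nuclei[nuclei > 0L]))
  if (!identical(labs, seq_len(k))) {
    stop("nucleus labels must be consecutive 1..K", call. = FALSE)
  }
  a_max <- pi * (params$cell_max_width / 2 / pixel_size)^2
  L <- nuclei
  areas <- tabulate(L[L > 0L], nbins = k)
  frozen <- areas >= a_max
  repeat {
    cand <- .neighbor_min_label(L)
    sel <- L == 0L & cand > 0L
    sel[sel] <- !frozen[cand[sel]]
    if (!any(sel)) break
    ring <- tabulate(cand[sel], nbins = k)
    over <- ring > 0 & (areas + ring) > a_max
    if (any(over)) {
      frozen[over] <- TRUE
      sel[sel] <- !frozen[cand[sel]]
      if (!any(sel)) break
      ring <- tabulate(cand[sel], nbins = k)
    }
    L[sel] <- cand[sel]
    areas <- areas + ring
  }
  L
}

#' Centroids and areas of a label mask
#'
#' @param mask Integer label mask.
#' @return Data frame with `label`, 0-based `row`/`col` centroid, and `area`
#'   in pixels.
#' @export
label_centroids <- function(mask) {
  k <- max(mask)
  if (k == 0L) {
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                      area = integer(0)))
  }
  fg <- which(mask > 0L)
  lab <- mask[fg]
  rows <- (fg - 1L) %% nrow(mask)        # 0-based
  cols <- (fg - 1L) %/% nrow(mask)
  area <- tabulate(lab, nbins = k)
  data.frame(label = seq_len(k),
             row = rowsum(rows, lab)[, 1] / area,
             col = rowsum(cols, lab)[, 1] / area,
             area = area)
}

#' Match detected nuclei to simulation ground truth
#'
#' Greedy nearest-centroid matching: detections pair with truth cells when
#' their centroid distance is at most one true nucleus radius, closest pairs
#' first, each object used once. Reports detection precision and recall.
#'
#' @param mask Nucleus label mask (or a `label_centroids()` data frame).
#' @param truth Simulation truth for the same well (`row`, `col`,
#'   `nucleus_radius_px` columns).
#' @return List with `matches` (data frame `label`, `truth_cell`, `dist`),
#'   `precision`, `recall`, `n_detected`, `n_truth`.
#' @export
match_nuclei <- function(mask, truth) {
  det <- if (is.data.frame(mask)) mask else label_centroids(mask)
  n_det <- nrow(det)
  n_truth <- nrow(truth)
  if (n_det == 0L || n_truth == 0L) {
    return(list(matches = data.frame(label = integer(0),
                                     truth_cell = integer(0),
                                     dist = numeric(0)),
                precision = if (n_det) 0 else NA_real_,
                recall = if (n_truth) 0 else NA_real_,
                n_detected = n_det, n_truth = n_truth))
  }
  d <- sqrt(outer(det$row, truth$row, "-")^2 +
            outer(det$col, truth$col, "-")^2)
  lim <- matrix(truth$nucleus_radius_px, n_det, n_truth, byrow = TRUE)
  d[d > lim] <- Inf
  matches <- data.frame(label = integer(0), truth_cell = integer(0),
                        dist = numeric(0))
  while (any(is.finite(d))) {
    ij <- arrayInd(which.min(d), dim(d))
    matches <- rbind(matches,
                     data.frame(label = det$label[ij[1]],
                                truth_cell = truth$cell[ij[2]],
                                dist = d[ij[1], ij[2]]))
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  list(matches = matches,
       precision = nrow(matches) / n_det,
       recall = nrow(matches) / n_truth,
       n_detected = n_det, n_truth = n_truth)
}
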