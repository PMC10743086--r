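# Exhaustive-search oracle: best midpoint between adjacent distinct values
# by between-class variance, computed the slow way.
brute_otsu <- function(x) {
  v <- sort(unique(x))
  cands <- (v[-1] + v[-length(v)]) / 2
  bcv <- vapply(cands, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cands[which.max(bcv)]
}

test_that("auto threshold maximizes between-class variance", {
  set.seed(42)
  x <- c(rnorm(300, 10, 1), rnorm(300, 200, 10))
  thr <- auto_threshold(x)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_equal(thr, brute_otsu(x))
  for (s in 1:5) {
    set.seed(s)
    y <- sample(rep(1:6, times = sample(2:30, 6)))
    expect_equal(auto_threshold(y), brute_otsu(y))
  }
  expect_error(auto_threshold(matrix(5, 4, 4)), "constant")
})

test_that("auto threshold shifts exactly with a constant offset", {
  set.seed(1)
  x <- c(rnorm(200, 20, 3), rnorm(100, 150, 15))
  expect_equal(auto_threshold(x + 37.5), auto_threshold(x) + 37.5)
})

test_that("nucleus segmentation finds exactly the constructed disks", {
  set.seed(10)
  # 50 disks on a jittered grid, diameters inside the gate, SNR 10
  grid <- expand.grid(r = seq(20, 236, length.out = 8),
                      c = seq(20, 236, length.out = 8))[1:50, ]
  centres <- as.matrix(grid) + matrix(runif(100, -4, 4), ncol = 2)
  img <- disk_image(centres, diam_um = rep(12, 50), field = 256,
                    fg = 1000, bg = 0, noise_sd = 100)
  params <- segmentation_params(nucleus_min_width = 6, nucleus_max_width = 25)
  mask <- segment_nuclei(img, params, pixel_size = 1.7)
  expect_equal(max(mask), 50L)
  expect_equal(sort(unique(as.vector(mask))), 0:50)  # consecutive labels
})

test_that("the width gate rejects undersized objects and flat images", {
  params <- segmentation_params(nucleus_min_width = 6, nucleus_max_width = 25)
  expect_warning(m0 <- segment_nuclei(matrix(0, 64, 64), params, 1.7),
                 "constant")
  expect_equal(max(m0), 0L)
  # one disk at half the minimum width -> size-gated out
  img <- disk_image(cbind(32, 32), diam_um = 3, field = 64, fg = 1000, bg = 10)
  expect_equal(max(segment_nuclei(img, params, 1.7)), 0L)
})

test_that("nucleus counting is equivariant under 90-degree rotation", {
  spec <- tiny_spec(n_cells_mean = 30, seed = 9L)
  sim <- simulate_well(spec, dose = 0, seed = 9L)
  params <- segmentation_params()
  n1 <- max(segment_nuclei(sim$stack$nuclear, params, spec$pixel_size))
  rot <- t(sim$stack$nuclear)[ncol(sim$stack$nuclear):1, ]
  n2 <- max(segment_nuclei(rot, params, spec$pixel_size))
  expect_equal(n1, n2)
})

test_that("detection precision and recall reach 0.95 on simulator wells", {
  spec <- scenario_preset("h460", field = 512, n_cells_mean = 150,
                          seed = 21L)[[1]]
  sim <- simulate_well(spec, dose = 0, seed = 21L)
  mask <- segment_nuclei(sim$stack$nuclear, segmentation_params(),
                         spec$pixel_size)
  m <- match_nuclei(mask, sim$truth)
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)
})

test_that("cell regions stop growing at the equivalent-diameter bound", {
  # cap equal to the nucleus footprint: zero growth
  img <- disk_image(cbind(32, 32), diam_um = 12, field = 64, fg = 1000, bg = 10)
  nuc <- segment_nuclei(img, segmentation_params(), pixel_size = 1.7)
  d_eq <- 2 * sqrt(sum(nuc > 0) / pi) * 1.7
  tight <- segmentation_params(nucleus_min_width = 6, nucleus_max_width = d_eq,
                               cell_max_width = d_eq)
  expect_identical(assign_cell_regions(nuc, tight, 1.7), nuc)
})

test_that("an isolated nucleus grows to its Chebyshev dilation", {
  img <- disk_image(cbind(32, 32), diam_um = 10, field = 64, fg = 1000, bg = 10)
  params <- segmentation_params(nucleus_min_width = 6, nucleus_max_width = 25,
                                cell_max_width = 30)
  nuc <- segment_nuclei(img, params, 1.7)
  cells <- assign_cell_regions(nuc, params, 1.7)
  # brute-force oracle: Chebyshev distance of every pixel to the nucleus set,
  # dilated ring by ring while the area cap holds
  fg <- which(nuc > 0, arr.ind = TRUE)
  all_px <- expand.grid(r = 1:64, c = 1:64)
  cheb <- apply(all_px, 1, function(p) {
    min(pmax(abs(fg[, 1] - p[1]), abs(fg[, 2] - p[2])))
  })
  a_max <- pi * (params$cell_max_width / 2 / 1.7)^2
  r <- 0
  while (sum(cheb <= r + 1) <= a_max) r <- r + 1
  oracle <- matrix(as.integer(cheb <= r), 64, 64)
  expect_identical(unname(cells > 0), unname(oracle > 0))
})

test_that("two nearby nuclei partition the shared zone without overlap", {
  img <- matrix(0, 64, 64)
  img[disk_image(cbind(32, 22), 10, field = 64, fg = 1, bg = 0) > 0] <- 1000
  img[disk_image(cbind(32, 42), 10, field = 64, fg = 1, bg = 0) > 0] <- 1000
  params <- segmentation_params(cell_max_width = 30)
  nuc <- segment_nuclei(img, params, 1.7)
  expect_equal(max(nuc), 2L)
  cells <- assign_cell_regions(nuc, params, 1.7)
  # brute-force nearest-nucleus assignment in the growth metric
  cen <- label_centroids(nuc)
  for (px in sample(which(cells > 0), 200)) {
    r <- (px - 1) %% 64; c <- (px - 1) %/% 64
    d <- pmax(abs(cen$row - r), abs(cen$col - c))
    if (abs(d[1] - d[2]) > 1.5) {   # clearly closer to one nucleus
      expect_equal(cells[px], cen$label[which.min(d)])
    }
  }
  # each nucleus pixel belongs to its own region; regions disjoint by mask
  expect_true(all(cells[nuc > 0] == nuc[nuc > 0]))
})
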