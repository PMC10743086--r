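# Build one synthetic scored well shared by several tests.
scored_well <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- tiny_spec(n_cells_mean = 60, field = 384, seed = 4L,
                        cancer_fraction = 0.5,
                        baseline_marker_pos = c(cancer = 0.3, stromal = 0.2))
      sim <- simulate_well(spec, dose = 0, seed = 4L)
      cfg <- analysis_config()
      nuc <- segment_nuclei(sim$stack$nuclear, cfg$segmentation,
                            spec$pixel_size)
      cells <- assign_cell_regions(nuc, cfg$segmentation, spec$pixel_size)
      cache <<- list(sim = sim, cfg = cfg, nuc = nuc, cells = cells)
    }
    cache
  }
})

test_that("cytoplasmic means drive positivity with ties scoring positive", {
  # constructed 2-cell image: nucleus 3x3 at 500, cytoplasm ring at 100
  nuc <- matrix(0L, 16, 16); nuc[3:5, 3:5] <- 1L; nuc[10:12, 10:12] <- 2L
  cells <- matrix(0L, 16, 16); cells[2:6, 2:6] <- 1L; cells[9:13, 9:13] <- 2L
  img <- matrix(0, 16, 16)
  img[cells == 1 & nuc == 0] <- 100
  img[cells == 2 & nuc == 0] <- 150
  stack <- list(nuclear = matrix(500, 16, 16), epithelial = img,
                marker = img)
  cfg <- analysis_config()
  rec <- score_cells(stack, cells, nuc, cfg, well_id = "A1",
                     thresholds = c(epithelial = 150, marker = 150))
  expect_equal(rec$cyto_epithelial, c(100, 150))
  expect_equal(rec$epithelial_positive, c(FALSE, TRUE))  # tie is positive
  expect_equal(rec$marker_positive, c(FALSE, TRUE))
  # threshold 0: every cell positive
  rec0 <- score_cells(stack, cells, nuc, cfg, well_id = "A1",
                      thresholds = c(epithelial = 0, marker = 0))
  expect_true(all(rec0$epithelial_positive))
  # missing epithelial channel is an error: the assay needs CK8/18
  expect_error(score_cells(list(nuclear = stack$nuclear), cells, nuc, cfg),
               "epithelial")
  # shape mismatch
  expect_error(score_cells(list(nuclear = stack$nuclear,
                                epithelial = matrix(0, 8, 8)),
                           cells, nuc, cfg), "shape")
})

test_that("well summaries cross-tabulate the four populations", {
  rec <- make_records(epi = rep(c(TRUE, FALSE), c(6, 4)),
                      mrk = c(rep(TRUE, 4), FALSE, FALSE,
                              TRUE, FALSE, FALSE, FALSE))
  s <- summarize_well(rec, "A1")
  expect_equal(s$n_total, 10)
  expect_equal(s$n_cancer_marker_pos, 4)
  expect_equal(s$n_stromal_marker_pos, 1)
  expect_equal(s$pct_marker_pos_cancer, 100 * 4 / 6)
  expect_equal(s$pct_marker_pos_stromal, 25)

  s0 <- summarize_well(make_records(logical(0), logical(0)), "A1")
  expect_equal(s0$n_total, 0)
  expect_true(is.na(s0$pct_marker_pos_cancer))

  s1 <- summarize_well(make_records(rep(TRUE, 5), rep(FALSE, 5)), "A1")
  expect_equal(s1$n_stromal, 0)
  expect_true(is.na(s1$pct_marker_pos_stromal))
})

test_that("population counts always sum to the total (conservation)", {
  w <- scored_well()
  for (thr_mult in c(0.5, 1, 2)) {
    stats <- compute_cell_stats(w$sim$stack, w$cells, w$nuc, w$cfg)
    base <- resolve_thresholds(stats, w$cfg)
    rec <- score_cells(w$sim$stack, w$cells, w$nuc, w$cfg, "A1",
                       thresholds = base * thr_mult)
    s <- summarize_well(rec, "A1")
    expect_equal(s$n_cancer_marker_pos + s$n_cancer_marker_neg +
                   s$n_stromal_marker_pos + s$n_stromal_marker_neg,
                 s$n_total)
  }
})

test_that("positivity is monotone in the threshold", {
  w <- scored_well()
  stats <- compute_cell_stats(w$sim$stack, w$cells, w$nuc, w$cfg)
  base <- resolve_thresholds(stats, w$cfg)
  counts <- vapply(c(0.25, 0.5, 1, 2, 4), function(m) {
    rec <- score_cells(w$sim$stack, w$cells, w$nuc, w$cfg, "A1",
                       thresholds = base * m)
    sum(rec$marker_positive)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summaries are invariant to record order", {
  w <- scored_well()
  rec <- score_cells(w$sim$stack, w$cells, w$nuc, w$cfg, "A1")
  set.seed(1)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(summarize_well(shuf, "A1"), summarize_well(rec, "A1"))
})

test_that("scoring against truth recovers the simulated classes", {
  w <- scored_well()
  rec <- score_cells(w$sim$stack, w$cells, w$nuc, w$cfg, "A1")
  st <- score_against_truth(rec, w$sim$truth)
  # 10-fold intensity separation: rare errors only where annuli overlap
  expect_gte(st$accuracy, 0.95)
  expect_gte(st$matching$recall, 0.95)
  expect_error(score_against_truth(rec, data.frame(x = 1)), "simulated")
})

test_that("absent truth classes flag undefined recall", {
  rec <- make_records(epi = c(TRUE, FALSE), mrk = c(FALSE, FALSE))
  truth <- data.frame(cell = 1:2, class = c("cancer", "stromal"),
                      marker_positive = FALSE, row = 1:2, col = 1:2,
                      nucleus_radius_px = 5)
  st <- score_against_truth(rec, truth)
  pc <- st$per_class
  expect_true(is.na(pc$recall[pc$class == "cancer_marker_pos"]))
  expect_equal(st$accuracy, 1)
})
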