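test_that("group percentages aggregate replicate wells by concentration", {
  lay <- make_panel_layout(concentrations = c(1, 2) * 1e-6, n_reps = 4,
                           n_controls = 4)
  pcts <- c(rep(15, 8), 10, 12, 8, 10)   # treated x8, controls {10,12,8,10}
  wells <- data.frame(well_id = lay$wells$well,
                      pct_marker_pos_cancer = pcts,
                      pct_marker_pos_stromal = NA_real_)
  g <- group_percentages(wells, lay, "h460", "drugX", "cancer")
  gr <- attr(g, "groups")
  expect_equal(gr$n, rep(4L, 3))
  expect_equal(gr$mean[gr$concentration == 0], 10)
  expect_equal(gr$sem[gr$concentration == 0], sd(c(10, 12, 8, 10)) / 2)
  expect_equal(round(gr$sem[gr$concentration == 0], 3), 0.816)
  # stromal percentages undefined everywhere -> no usable groups
  expect_error(suppressWarnings(
    group_percentages(wells, lay, "h460", "drugX", "stromal")))
})

test_that("k = 1 Dunnett equals the pooled two-sample t-test", {
  g <- data.frame(concentration = rep(c(0, 1e-6), each = 4),
                  pct = c(10, 11, 9, 10, 12, 13, 11, 14))
  d <- dunnett_vs_control(g)
  tt <- t.test(g$pct[5:8], g$pct[1:4], var.equal = TRUE)
  expect_equal(d$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(unname(d$tstat), unname(tt$statistic), tolerance = 1e-10)
})

test_that("the quadrature matches mvtnorm and multcomp references", {
  # equal n
  p_mine <- dunnett_adjust(c(1.2, 2.5, 3.1), n = rep(4, 3), n0 = 4, df = 12)
  corr <- matrix(0.5, 3, 3); diag(corr) <- 1
  p_ref <- vapply(c(1.2, 2.5, 3.1), function(t) {
    set.seed(1)
    1 - as.numeric(mvtnorm::pmvt(lower = rep(-t, 3), upper = rep(t, 3),
                                 df = 12, corr = corr,
                                 algorithm = mvtnorm::GenzBretz(
                                   abseps = 1e-6, maxpts = 200000)))
  }, numeric(1))
  expect_equal(p_mine, p_ref, tolerance = 1e-4)

  # unequal n: exact correlation, checked against multcomp's Dunnett contrast
  set.seed(7)
  dat <- data.frame(g = factor(rep(0:3, times = c(6, 3, 4, 5))),
                    y = rnorm(18, rep(c(10, 11, 12, 10), c(6, 3, 4, 5)), 1.5))
  gdf <- data.frame(concentration = as.numeric(as.character(dat$g)) * 1e-6,
                    pct = dat$y)
  mine <- dunnett_vs_control(gdf)
  mc <- summary(multcomp::glht(stats::aov(y ~ g, dat),
                               linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(mine$p_adj, as.numeric(mc$test$pvalues), tolerance = 1e-3)
})

test_that("identical group means give adjusted p near 1", {
  g <- data.frame(concentration = rep(c(0, 1e-6, 2e-6), each = 3),
                  pct = rep(c(10, 11, 9), 3))
  d <- dunnett_vs_control(g)
  expect_true(all(d$p_adj > 0.999))
})

test_that("adjusted p-values are monotone in the family size", {
  for (k in 2:5) {
    p_small <- dunnett_adjust(2.2, n = 4, n0 = 4, df = 18)
    p_k <- dunnett_adjust(rep(2.2, k), n = rep(4, k), n0 = 4, df = 18)
    expect_gte(p_k[1] + 1e-9, p_small)
    if (k > 2) {
      p_prev <- dunnett_adjust(rep(2.2, k - 1), n = rep(4, k - 1), n0 = 4,
                               df = 18)
      expect_gte(p_k[1] + 1e-9, p_prev[1])
    }
  }
})

test_that("degenerate zero-variance families are flagged", {
  g <- data.frame(concentration = rep(c(0, 1e-6, 2e-6), each = 2),
                  pct = c(10, 10, 10, 10, 12, 12))
  d <- dunnett_vs_control(g)
  expect_true(all(d$degenerate))
  expect_equal(d$p_adj, c(1, 0))
  g2 <- data.frame(concentration = c(0, 0, 1e-6), pct = c(1, 2, 3))
  expect_error(dunnett_vs_control(g2), "n >= 2")
})

test_that("the induction call combines significance with relevance", {
  cfg <- analysis_config()
  groups <- data.frame(concentration = rep(c(0, 1e-6), each = 4),
                       pct = c(rep(10, 4), rep(13, 4)))
  fake_stats <- function(p) data.frame(concentration = 1e-6, n = 4,
                                       mean = 13, sem = 0.5, estimate = 3,
                                       tstat = 3, df = 6, p_adj = p,
                                       degenerate = FALSE)
  expect_equal(induction_call(groups, cfg, stats = fake_stats(0.01))$call,
               "increase")     # 30% relative, significant
  expect_equal(induction_call(groups, cfg, stats = fake_stats(0.20))$call,
               "no change")    # fails significance
  st <- fake_stats(0.001); st$mean <- 11.5; st$estimate <- 1.5
  expect_equal(induction_call(groups, cfg, stats = st)$call,
               "no change")    # 15% relative: fails relevance
  # decreases never call "increase"
  st2 <- fake_stats(1e-6); st2$mean <- 5; st2$estimate <- -5
  expect_equal(induction_call(groups, cfg, stats = st2)$call, "no change")
})

test_that("threshold extremes reduce the call to its components", {
  groups <- make_groups(c(10, 10, 14), n = 4, sd = 0.5, seed = 2)
  huge <- analysis_config(induction_threshold = 0.999999)
  tiny <- analysis_config(induction_threshold = 1e-9)
  expect_equal(induction_call(groups, huge)$call, "no change")
  res <- induction_call(groups, tiny)
  expect_equal(res$call,
               if (any(res$per_concentration$p_adj < tiny$alpha &
                       res$per_concentration$relative_increase > 0))
                 "increase" else "no change")
  expect_true(res$call == "increase")  # 40% jump at the top dose
})

test_that("a zero control mean demands the absolute metric", {
  groups <- data.frame(concentration = rep(c(0, 1e-6), each = 2),
                       pct = c(0, 0, 5, 6))
  expect_error(induction_call(groups, analysis_config()), "absolute_points")
  cfg_abs <- analysis_config(induction_metric = "absolute_points",
                             induction_threshold = 2)
  expect_equal(induction_call(groups, cfg_abs)$call, "increase")
})

test_that("calls are invariant to concentration ordering", {
  groups <- make_groups(c(10, 11, 15, 12), n = 4, sd = 1, seed = 3)
  cfg <- analysis_config()
  r1 <- induction_call(groups, cfg)
  set.seed(4)
  r2 <- induction_call(groups[sample(nrow(groups)), ], cfg)
  expect_equal(r1$call, r2$call)
  expect_equal(r1$per_concentration$p_adj, r2$per_concentration$p_adj)
})

test_that("the call matrix pivots to one block per marker", {
  expect_equal(nrow(call_matrix(list())), 0L)
  mk <- function(marker, culture, pop, drug, call) {
    structure(list(marker = marker, culture = culture, population = pop,
                   drug = drug, call = call), class = "induction_result")
  }
  res <- list(mk("ABCB1", "c1", "cancer", "cisplatin", "increase"),
              mk("ABCB1", "c1", "cancer", "etoposide", "no change"),
              mk("ABCC1", "c1", "cancer", "cisplatin", "no change"))
  cm <- call_matrix(res)
  expect_equal(dim(cm), c(2L, 5L))
  expect_equal(cm$cisplatin[cm$marker == "ABCB1"], "increase")
  expect_true(is.na(cm$etoposide[cm$marker == "ABCC1"]))
  expect_error(call_matrix(c(res, res[1])), "duplicate")
})
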