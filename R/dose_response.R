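#' Percent-of-control viability of a treated well
#'
#' Viability is the population count of the treated well expressed as a
#' percentage of the mean count of the same population across the control
#' wells of the same culture.
#'
#' @param treated One-row well summary ([summarize_well()]).
#' @param controls List (or row-bound data frame) of control well summaries.
#' @param population `"total"`, `"cancer"` or `"stromal"`.
#' @return Percent viability (a single number >= 0).
#' @export
viability <- function(treated, controls,
                      population = c("total", "cancer", "stromal")) {
  population <- match.arg(population)
  if (is.list(controls) && !is.data.frame(controls)) {
    controls <- do.call(rbind, controls)
  }
  if (is.null(controls) || nrow(controls) == 0L) {
    stop("at least one control well is required", call. = FALSE)
  }
  col <- switch(population, total = "n_total", cancer = "n_cancer",
                stromal = "n_stromal")
  ctl_mean <- mean(controls[[col]])
  if (!is.finite(ctl_mean) || ctl_mean <= 0) {
    stop("mean control count is zero for population '", population,
         "'; viability undefined", call. = FALSE)
  }
  100 * treated[[col]] / ctl_mean
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{R(c) = bottom + (top - bottom) / (1 + (c/\mathrm{ic50})^h)}
#' on log10 concentration (Levenberg-Marquardt), with constraints
#' `bottom >= 0`, `top <= 120`, `h > 0`, initialized from the data
#' (top = max response, bottom = min, midpoint = dose nearest 50%, h = 1).
#' Replicates are fitted jointly as individual points. The reported IC50 is
#' the concentration where the fitted curve crosses 50% of control; when the
#' curve never reaches 50% within the tested range, or the crossing exceeds
#' the highest tested concentration, the estimate is right-censored and
#' reported as `">cmax"`. A curve already below 50% over the whole range is
#' flagged `below_range`; a flat fit pinned near 50% is flagged `degenerate`.
#'
#' @param concentrations Molar doses, one per response (> 0); at least 4
#'   distinct values.
#' @param responses Percent-of-control viabilities, same length.
#' @param culture,drug,population Metadata carried into the result.
#' @return A `dose_response_result`: list with `ic50` (molar, `NA` when
#'   censored), `censored`, `cmax`, `hill`, `top`, `bottom`, `rss`, `flag`
#'   (`"ok"`, `"below_range"` or `"degenerate"`), `n_replicates`, the data,
#'   and the metadata.
#' @export
fit_curve <- function(concentrations, responses, culture = NA_character_,
                      drug = NA_character_, population = NA_character_) {
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must be paired", call. = FALSE)
  }
  keep <- is.finite(concentrations) & concentrations > 0
  concentrations <- concentrations[keep]
  responses <- responses[keep]
  if (any(!is.finite(responses))) {
    stop("non-finite responses", call. = FALSE)
  }
  doses <- sort(unique(concentrations))
  if (length(doses) < 4L) {
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  }
  ord <- order(concentrations)
  concentrations <- concentrations[ord]
  responses <- responses[ord]
  cmax <- max(doses)
  x <- log10(concentrations)

  means <- tapply(responses, concentrations, mean)
  start <- c(top = min(max(responses), 120),
             bottom = max(min(responses), 0),
             logmid = log10(doses[which.min(abs(means - 50))]),
             h = 1)
  if (start[["top"]] <= start[["bottom"]]) {
    start[["top"]] <- min(start[["bottom"]] + 1, 120)
    start[["bottom"]] <- max(start[["top"]] - 1, 0)
  }
  model <- function(par) {
    par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
      (1 + 10^(par[["h"]] * (x - par[["logmid"]])))
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(par) responses - model(par),
    lower = c(top = -Inf, bottom = 0, logmid = -Inf, h = 1e-3),
    upper = c(top = 120, bottom = Inf, logmid = Inf, h = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- as.list(fit$par)
  pred <- function(c) p$bottom + (p$top - p$bottom) /
    (1 + 10^(p$h * (log10(c) - p$logmid)))
  rng_pred <- pred(doses)

  flag <- "ok"
  censored <- FALSE
  ic50 <- NA_real_
  if (p$top > 50 && p$bottom < 50) {
    # absolute 50%-of-control crossing of the fitted curve
    ic50 <- 10^(p$logmid + log10((p$top - p$bottom) / (50 - p$bottom) - 1) / p$h)
  }
  if (all(abs(rng_pred - 50) < 1)) {
    flag <- "degenerate"   # flat at the midpoint: IC50 unidentifiable
    ic50 <- NA_real_
  } else if (!is.finite(ic50) || ic50 > cmax || min(rng_pred) > 50) {
    if (max(rng_pred) < 50) {
      flag <- "below_range"   # already past 50% kill at the lowest dose
      ic50 <- min(doses)
    } else {
      censored <- TRUE
      ic50 <- NA_real_
    }
  }
  structure(list(culture = culture, drug = drug, population = population,
                 ic50 = ic50, censored = censored, cmax = cmax,
                 hill = p$h, top = p$top, bottom = p$bottom,
                 rss = sum(fit$fvec^2), flag = flag,
                 n_replicates = length(responses) / length(doses),
                 concentrations = concentrations, responses = responses),
            class = "dose_response_result")
}

#' @export
print.dose_response_result <- function(x, ...) {
  lab <- format_ic50(x$ic50, x$censored, x$cmax)
  cat(sprintf("4PL fit%s: IC50 = %s uM (hill %.3g, top %.1f, bottom %.1f%s)\n",
              if (!is.na(x$drug)) paste0(" [", x$culture, "/", x$drug, "/",
                                         x$population, "]") else "",
              lab, x$hill, x$top, x$bottom,
              if (x$flag != "ok") paste0(", flag: ", x$flag) else ""))
  invisible(x)
}

.as_ic50 <- function(x) {
  if (inherits(x, "dose_response_result")) {
    list(value = if (x$censored) x$cmax else x$ic50, censored = x$censored)
  } else if (is.character(x)) {
    parse_ic50(x, unit = "uM")
  } else {
    list(value = as.numeric(x), censored = FALSE)
  }
}

#' Fold-resistance of a resistant line relative to its parental line
#'
#' The ratio of the resistant line's IC50 to the sensitive (parental) line's
#' IC50 for the same drug. A censored resistant IC50 (`">cmax"`) yields a
#' lower bound `"> cmax/sensitive"`; a censored sensitive IC50 leaves the
#' ratio undefined and is an error.
#'
#' @param ic50_resistant,ic50_sensitive `dose_response_result`s, molar
#'   numbers, or table strings in uM such as `">5"`.
#' @return A `fold_estimate`: list with `fold` (the ratio, or its lower
#'   bound), `lower_bound` (logical) and `label` (e.g. `"27.08"` or
#'   `"> 13.13"`); `round(x$fold)` gives the "n-fold" phrasing.
#' @export
fold_resistance <- function(ic50_resistant, ic50_sensitive) {
  r <- .as_ic50(ic50_resistant)
  s <- .as_ic50(ic50_sensitive)
  if (isTRUE(s$censored)) {
    stop("sensitive IC50 is censored; fold-resistance undefined", call. = FALSE)
  }
  fold <- r$value / s$value
  structure(list(fold = fold, lower_bound = isTRUE(r$censored),
                 label = paste0(if (isTRUE(r$censored)) "> " else "",
                                formatC(fold, format = "f", digits = 2))),
            class = "fold_estimate")
}

#' @export
print.fold_estimate <- function(x, ...) {
  cat(x$label, sprintf("(~%d-fold%s)\n", round(x$fold),
                       if (x$lower_bound) " or more" else ""))
  invisible(x)
}

#' Selectivity call between two IC50s for the same drug
#'
#' Flags the more sensitive member when the other member's IC50 (or its
#' censoring bound) is strictly greater; two results censored at the same
#' bound are indistinguishable and produce no call.
#'
#' @param ic50_a,ic50_b `dose_response_result`s for the same drug (or
#'   numbers / `">x"` strings in uM).
#' @return `"a"`, `"b"` (the selective, i.e. more sensitive, member) or
#'   `"none"`.
#' @export
selectivity_call <- function(ic50_a, ic50_b) {
  da <- inherits(ic50_a, "dose_response_result")
  db <- inherits(ic50_b, "dose_response_result")
  if (da && db && !identical(ic50_a$drug, ic50_b$drug)) {
    stop("selectivity compares the same drug across populations", call. = FALSE)
  }
  a <- .as_ic50(ic50_a)
  b <- .as_ic50(ic50_b)
  if (a$censored && b$censored) return("none")
  # a censored value is a lower bound: it exceeds an uncensored value that
  # is <= its bound, and comparisons between bounds are inconclusive
  if (a$censored) {
    return(if (b$value <= a$value) "b" else "none")
  }
  if (b$censored) {
    return(if (a$value <= b$value) "a" else "none")
  }
  if (a$value < b$value) "a" else if (b$value < a$value) "b" else "none"
}

#' Fit dose-response curves for every culture x drug x population series
#'
#' Computes per-well viability of each population against the same-culture
#' controls and fits one 4PL curve per (culture, drug, population) with at
#' least four distinct concentrations.
#'
#' @param wells Row-bound well summaries ([summarize_well()]).
#' @param layout The [plate_layout()] the wells came from.
#' @param populations Populations to fit.
#' @return List of `dose_response_result`s, plus attribute `"table"`: a long
#'   data frame (one row per fit) with the IC50s rendered as table strings.
#' @export
fit_dose_response <- function(wells, layout,
                              populations = c("total", "cancer", "stromal")) {
  lay <- layout$wells
  m <- merge(wells, lay, by.x = "well_id", by.y = "well")
  results <- list()
  rows <- list()
  for (culture in unique(m$culture)) {
    ctl <- m[m$culture == culture & m$role == "control", , drop = FALSE]
    trt <- m[m$culture == culture & m$role == "treated", , drop = FALSE]
    for (drug in unique(stats::na.omit(trt$drug))) {
      d <- trt[trt$drug == drug, , drop = FALSE]
      if (length(unique(d$concentration)) < 4L || nrow(ctl) == 0L) next
      for (pop in populations) {
        col <- switch(pop, total = "n_total", cancer = "n_cancer",
                      stromal = "n_stromal")
        if (mean(ctl[[col]]) <= 0) next
        resp <- vapply(seq_len(nrow(d)), function(i)
          viability(d[i, , drop = FALSE], ctl, pop), numeric(1))
        res <- fit_curve(d$concentration, resp, culture = culture,
                         drug = drug, population = pop)
        key <- paste(culture, drug, pop, sep = "|")
        results[[key]] <- res
        rows[[key]] <- data.frame(
          culture = culture, drug = drug, population = pop,
          ic50_uM = if (res$censored) NA_real_ else res$ic50 * 1e6,
          ic50 = format_ic50(res$ic50, res$censored, res$cmax),
          censored = res$censored, hill = res$hill, top = res$top,
          bottom = res$bottom, rss = res$rss, flag = res$flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(culture = character(0), drug = character(0),
               population = character(0), ic50_uM = numeric(0),
               ic50 = character(0), censored = logical(0), hill = numeric(0),
               top = numeric(0), bottom = numeric(0), rss = numeric(0),
               flag = character(0))
  }
  attr(results, "table") <- tab
  results
}
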