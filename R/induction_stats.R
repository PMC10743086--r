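#' Group marker-positive percentages by concentration
#'
#' Collects one observation per replicate well of the marker-positive
#' percentage within the chosen population, for one culture and drug.
#' Controls of the same culture form the concentration-0 group. Wells whose
#' population denominator is zero carry an undefined percentage and are
#' excluded with a warning.
#'
#' @param wells Row-bound well summaries.
#' @param layout The [plate_layout()].
#' @param culture,drug Series selectors.
#' @param population `"cancer"` or `"stromal"`.
#' @return Data frame with `well_id`, `concentration` (molar; 0 = control)
#'   and `pct` — plus attribute `"groups"`: per-concentration `n`, `mean`,
#'   `sem`.
#' @export
group_percentages <- function(wells, layout, culture, drug,
                              population = c("cancer", "stromal")) {
  population <- match.arg(population)
  col <- paste0("pct_marker_pos_", population)
  lay <- layout$wells
  m <- merge(wells, lay, by.x = "well_id", by.y = "well")
  m <- m[m$culture == culture &
           (m$role == "control" | (m$role == "treated" & !is.na(m$drug) &
                                     m$drug == drug)), , drop = FALSE]
  m$concentration[m$role == "control"] <- 0
  bad <- !is.finite(m[[col]])
  if (any(bad)) {
    warning(sum(bad), " well(s) excluded: ", population,
            " population absent (undefined percentage): ",
            paste(m$well_id[bad], collapse = ", "))
    m <- m[!bad, , drop = FALSE]
  }
  if (!any(m$concentration == 0)) {
    stop("no usable control group for ", culture, "/", drug, call. = FALSE)
  }
  if (!any(m$concentration > 0)) {
    stop("no usable treated group for ", culture, "/", drug, call. = FALSE)
  }
  out <- data.frame(well_id = m$well_id, concentration = m$concentration,
                    pct = m[[col]], stringsAsFactors = FALSE)
  out <- out[order(out$concentration), , drop = FALSE]
  g <- split(out$pct, out$concentration)
  attr(out, "groups") <- data.frame(
    concentration = as.numeric(names(g)),
    n = lengths(g),
    mean = vapply(g, mean, numeric(1)),
    sem = vapply(g, function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
    row.names = NULL)
  out
}

# Golub-Welsch: Gauss-Hermite nodes/weights for integrals against exp(-u^2).
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2 * sqrt(pi))
}

# Gauss-Legendre nodes/weights on (0, 1).
.gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = (e$values + 1) / 2, weights = e$vectors[1, ]^2)
}

.dunnett_quad <- local({
  cache <- NULL
  sgrid <- list()
  function(df = NULL) {
    if (is.null(cache)) {
      cache <<- list(gh = .gauss_hermite(64L), gl = .gauss_legendre01(64L))
    }
    if (is.null(df)) return(cache)
    key <- format(df)
    if (is.null(sgrid[[key]])) {
      sgrid[[key]] <<- sqrt(stats::qchisq(cache$gl$nodes, df) / df)
    }
    c(cache, list(s = sgrid[[key]]))
  }
})

# P(max_i |T_i| <= t) for the Dunnett many-to-one multivariate t:
# T_i = (lambda_i Z0 + sqrt(1-lambda_i^2) Z_i)/S, S^2 ~ chi^2_df/df.
# Evaluated by deterministic 64x64 Gauss quadrature over (Z0, S),
# accurate to ~1e-8.
.dunnett_prob <- function(t, lambda, df) {
  if (!is.finite(t)) return(if (t > 0) 1 else 0)
  if (t <= 0) return(0)
  q <- .dunnett_quad(df)
  z0 <- sqrt(2) * q$gh$nodes            # Z0 grid (standard normal)
  wz <- q$gh$weights / sqrt(pi)
  s <- q$s                              # equiprobable S grid (cached per df)
  ws <- q$gl$weights
  tau <- sqrt(1 - lambda^2)
  Z <- matrix(z0, length(z0), length(s))
  TS <- matrix(t * s, length(z0), length(s), byrow = TRUE)
  if (all(lambda == lambda[1])) {   # equal n: product is a single power
    pr <- (stats::pnorm((TS - lambda[1] * Z) / tau[1]) -
           stats::pnorm((-TS - lambda[1] * Z) / tau[1]))^length(lambda)
  } else {
    pr <- 1
    for (i in seq_along(lambda)) {
      pr <- pr * (stats::pnorm((TS - lambda[i] * Z) / tau[i]) -
                  stats::pnorm((-TS - lambda[i] * Z) / tau[i]))
    }
  }
  min(max(sum((wz %o% ws) * pr), 0), 1)
}

#' Dunnett family-wise adjustment of t statistics
#'
#' Given the pooled-variance t statistics of k treated-vs-control
#' comparisons, returns two-sided adjusted p-values
#' \eqn{p_i = P(\max_j |T_j| \ge |t_i|)} under the multivariate t with the
#' pooled error degrees of freedom and the exact Dunnett correlation matrix
#' \eqn{\rho_{ij} = \lambda_i \lambda_j},
#' \eqn{\lambda_i = \sqrt{n_i/(n_i+n_0)}} (the equicorrelated 0.5 case at
#' equal group sizes). The multivariate-t probability is evaluated by
#' deterministic Gauss quadrature over the shared control variate and the
#' pooled scale, so results are exactly reproducible; with k = 1 the
#' adjustment reduces to the ordinary two-sided t probability.
#'
#' @param tstats Vector of k t statistics.
#' @param n Vector of k treated group sizes.
#' @param n0 Control group size.
#' @param df Pooled error degrees of freedom.
#' @return Vector of adjusted p-values in (0, 1).
#' @export
dunnett_adjust <- function(tstats, n, n0, df) {
  k <- length(tstats)
  stopifnot(length(n) == k, n0 >= 1, df >= 1)
  lambda <- sqrt(n / (n + n0))
  if (k == 1L) {   # no multiplicity: exact two-sided t probability
    return(2 * stats::pt(-abs(tstats), df))
  }
  vapply(abs(tstats), function(t) {
    if (!is.finite(t)) return(0)
    min(max(1 - .dunnett_prob(t, lambda, df), 0), 1)
  }, numeric(1))
}

#' Dunnett's many-to-one comparisons against the control group
#'
#' Pooled-variance t tests of every treated concentration against the
#' concentration-0 control, with family-wise two-sided adjustment over the
#' family ([dunnett_adjust()]). Every group needs at least two replicate
#' wells. A zero pooled variance is degenerate: p is 0 where the means
#' differ and 1 where they coincide, and the result is flagged.
#'
#' @param groups Output of [group_percentages()] (or any data frame with
#'   `concentration` and a value column named `pct`).
#' @return Data frame, one row per treated concentration: `concentration`,
#'   `n`, `mean`, `sem`, `estimate` (mean difference vs control), `tstat`,
#'   `df`, `p_adj`, `degenerate`.
#' @export
dunnett_vs_control <- function(groups) {
  g <- split(groups$pct, groups$concentration)
  conc <- as.numeric(names(g))
  if (length(g) < 2L) stop("need a control and >= 1 treated group",
                           call. = FALSE)
  if (!any(conc == 0)) stop("no control (concentration 0) group", call. = FALSE)
  ns <- lengths(g)
  if (any(ns < 2L)) {
    stop("every group needs n >= 2 replicate wells for testing", call. = FALSE)
  }
  means <- vapply(g, mean, numeric(1))
  vars <- vapply(g, stats::var, numeric(1))
  if (any(!is.finite(vars))) stop("non-finite within-group variance",
                                  call. = FALSE)
  N <- sum(ns)
  df <- N - length(g)
  s2 <- sum((ns - 1) * vars) / df
  i0 <- which(conc == 0)
  it <- which(conc > 0)
  est <- means[it] - means[i0]
  degenerate <- s2 <= 0
  tstat <- if (degenerate) {
    ifelse(est == 0, 0, sign(est) * Inf)
  } else {
    est / sqrt(s2 * (1 / ns[it] + 1 / ns[i0]))
  }
  p_adj <- if (degenerate) {
    ifelse(est == 0, 1, 0)
  } else {
    dunnett_adjust(tstat, n = ns[it], n0 = ns[i0], df = df)
  }
  sem <- sqrt(vars / ns)
  data.frame(concentration = conc[it], n = as.integer(ns[it]),
             mean = means[it], sem = sem[it], estimate = est,
             tstat = tstat, df = df, p_adj = p_adj,
             degenerate = degenerate, row.names = NULL)
}

#' Increase / no-change induction call for one series
#'
#' A marker series is called `"increase"` when at least one concentration is
#' both statistically significant (Dunnett-adjusted p below `alpha`) and
#' biologically relevant: the marker-positive percentage rises by at least
#' `induction_threshold` over the control mean — relative by default
#' (`(mean_i - mean_0)/mean_0 >= threshold`), or in absolute percentage
#' points with `induction_metric = "absolute_points"`. Decreases never
#' produce an `"increase"`.
#'
#' @param groups Output of [group_percentages()].
#' @param config An [analysis_config()].
#' @param stats Optional precomputed [dunnett_vs_control()] table.
#' @param marker,culture,population Metadata carried into the result.
#' @return An `induction_result`: list with the per-concentration table
#'   (means, SEM, adjusted p, `relative_increase`, `relevant`,
#'   `significant`) and `call` (`"increase"` or `"no change"`).
#' @export
induction_call <- function(groups, config = analysis_config(), stats = NULL,
                           marker = config$marker_name,
                           culture = NA_character_,
                           population = NA_character_) {
  if (is.null(stats)) stats <- dunnett_vs_control(groups)
  control_mean <- mean(groups$pct[groups$concentration == 0])
  if (config$induction_metric == "relative" && control_mean == 0) {
    stop("control mean is 0%: the relative induction metric is undefined; ",
         "use induction_metric = 'absolute_points'", call. = FALSE)
  }
  increase <- if (config$induction_metric == "relative") {
    (stats$mean - control_mean) / control_mean
  } else {
    stats$mean - control_mean
  }
  stats$relative_increase <- increase
  stats$significant <- stats$p_adj < config$alpha
  stats$relevant <- increase >= config$induction_threshold
  call <- if (any(stats$significant & stats$relevant)) "increase" else "no change"
  structure(list(marker = marker, culture = culture, population = population,
                 control_mean = control_mean, per_concentration = stats,
                 call = call, metric = config$induction_metric,
                 threshold = config$induction_threshold,
                 alpha = config$alpha),
            class = "induction_result")
}

#' @export
print.induction_result <- function(x, ...) {
  cat(sprintf("induction [%s | %s | %s]: %s (control mean %.2f%%)\n",
              x$marker, x$culture, x$population, x$call, x$control_mean))
  print(x$per_concentration[, c("concentration", "mean", "sem", "p_adj",
                                "relative_increase")], row.names = FALSE)
  invisible(x)
}

#' Induction statistics for every culture x drug x population series
#'
#' Runs [group_percentages()], [dunnett_vs_control()] and [induction_call()]
#' for each (culture, drug, population) with usable groups; each such series
#' is one Dunnett family.
#'
#' @param wells Row-bound well summaries.
#' @param layout The [plate_layout()].
#' @param config An [analysis_config()].
#' @param populations Populations to test.
#' @param drug_of_marker Optional function(drug) -> marker name; defaults to
#'   the configured single marker.
#' @return List of `induction_result`s, with attribute `"table"`: the long
#'   per-concentration data frame.
#' @export
compute_induction <- function(wells, layout, config = analysis_config(),
                              populations = c("cancer", "stromal"),
                              drug_of_marker = NULL) {
  lay <- layout$wells
  results <- list()
  rows <- list()
  for (culture in unique(lay$culture)) {
    drugs <- unique(stats::na.omit(lay$drug[lay$culture == culture &
                                              lay$role == "treated"]))
    for (drug in drugs) {
      marker <- if (is.null(drug_of_marker)) config$marker_name
                else drug_of_marker(drug)
      for (pop in populations) {
        groups <- tryCatch(
          suppressWarnings(group_percentages(wells, layout, culture, drug, pop)),
          error = function(e) NULL)
        if (is.null(groups)) next
        res <- tryCatch(
          induction_call(groups, config, marker = marker, culture = culture,
                         population = pop),
          error = function(e) NULL)
        if (is.null(res)) next
        key <- paste(marker, culture, drug, pop, sep = "|")
        results[[key]] <- res
        tab <- res$per_concentration
        tab <- cbind(marker = marker, culture = culture, drug = drug,
                     population = pop, tab, call = res$call,
                     stringsAsFactors = FALSE)
        rows[[key]] <- tab
      }
    }
  }
  attr(results, "table") <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(marker = character(0), culture = character(0),
               drug = character(0), population = character(0))
  }
  results
}

#' Wide increase / no-change call matrix
#'
#' Pivots induction results into the reporting shape of a resistance panel:
#' one block per marker, rows = culture x population, one column per drug,
#' each cell `"increase"` or `"no change"`.
#'
#' @param results List of `induction_result`s (each needs `marker`,
#'   `culture`, `population`, `call` and a `drug` discoverable from the
#'   result or the list names `marker|culture|drug|population`).
#' @return Data frame with columns `marker`, `culture`, `population` and one
#'   column per drug. Empty input yields an empty frame.
#' @export
call_matrix <- function(results) {
  if (!length(results)) {
    return(data.frame(marker = character(0), culture = character(0),
                      population = character(0)))
  }
  meta <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    drug <- r$drug
    if (is.null(drug)) {
      parts <- strsplit(names(results)[i], "|", fixed = TRUE)[[1]]
      if (length(parts) == 4L) drug <- parts[3] else
        stop("cannot determine drug for result ", i, call. = FALSE)
    }
    data.frame(marker = r$marker, culture = r$culture,
               population = r$population, drug = drug, call = r$call,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, meta)
  if (anyDuplicated(long[c("marker", "culture", "population", "drug")])) {
    stop("duplicate grid cell(s) in induction results", call. = FALSE)
  }
  drugs <- unique(long$drug)
  keys <- unique(long[c("marker", "culture", "population")])
  keys <- keys[order(keys$marker, keys$culture, keys$population), ,
               drop = FALSE]
  out <- keys
  for (d in drugs) {
    sub <- long[long$drug == d, , drop = FALSE]
    idx <- match(paste(keys$marker, keys$culture, keys$population),
                 paste(sub$marker, sub$culture, sub$population))
    out[[d]] <- sub$call[idx]
  }
  rownames(out) <- NULL
  out
}
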