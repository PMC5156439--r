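#' Maximum specific growth rate from an OD600 time series
#'
#' Fits log-linear regressions of `ln(OD)` on time in sliding windows and
#' returns the steepest slope, the standard estimator of the maximum
#' specific growth rate during exponential growth.
#'
#' @param times Sampling times in hours.
#' @param od OD600 readings (> 0).
#' @param window_points Number of consecutive observations per window
#'   (default 4, minimum 3).
#' @return List with `mu_max` (per hour, floored at 0), `od_final` (last OD
#'   reading) and `window` (start/end time of the steepest window).
#' @export
estimate_growth <- function(times, od, window_points = 4L) {
  if (length(times) != length(od)) stop("times and od must have equal length")
  if (any(od <= 0)) stop("all OD values must be positive")
  window_points <- as.integer(window_points)
  if (window_points < 3L) stop("window_points must be >= 3")
  if (length(od) < window_points) stop("fewer observations than window_points")
  o <- order(times)
  times <- times[o]; od <- od[o]
  y <- log(od)
  n <- length(y)
  best <- -Inf; best_win <- c(times[1L], times[window_points])
  for (i in seq_len(n - window_points + 1L)) {
    idx <- i:(i + window_points - 1L)
    tt <- times[idx]
    slope <- stats::cov(tt, y[idx]) / stats::var(tt)
    if (slope > best) {
      best <- slope
      best_win <- c(tt[1L], tt[window_points])
    }
  }
  list(mu_max = max(best, 0), od_final = od[n],
       window = c(t_start = best_win[1L], t_end = best_win[2L]))
}

#' Percent survival and log10 reduction from CFU counts
#'
#' Technical duplicate CFU counts are averaged on the count scale before
#' taking the ratio; robustness is the log10 difference of viable counts
#' after (N_t) and before (N_0) the stress exposure.
#'
#' @param n0 CFU/ml before stress (vector of technical duplicates, all > 0).
#' @param nt CFU/ml after stress (vector of technical duplicates).
#' @return List with `survival_pct` and `robustness` (log10 units, equal to
#'   `log10(survival_pct / 100)`).
#' @export
compute_survival <- function(n0, nt) {
  if (!length(n0) || !length(nt)) stop("empty CFU vectors")
  if (any(n0 <= 0)) stop("all n0 counts must be positive")
  if (any(nt < 0)) stop("negative nt counts")
  if (all(nt == 0)) {
    stop(structure(
      class = c("robustsig_censored", "error", "condition"),
      list(message = "all post-stress counts are zero: survival below detection limit",
           call = sys.call(-1))))
  }
  m0 <- mean(n0); mt <- mean(nt)
  list(survival_pct = 100 * mt / m0,
       robustness = log10(mt) - log10(m0))
}

#' Dynamic range of survival across conditions
#'
#' @param survival_pcts Positive percent-survival values, length >= 2.
#' @return `log10(max / min)` in log10 units.
#' @export
dynamic_range <- function(survival_pcts) {
  survival_pcts <- survival_pcts[!is.na(survival_pcts)]
  if (length(survival_pcts) < 2L) stop("need at least 2 survival values")
  if (any(survival_pcts <= 0)) stop("survival values must be positive")
  log10(max(survival_pcts) / min(survival_pcts))
}

#' Select the assay timepoint with the largest dynamic range
#'
#' The analysis timepoint of a stress assay is the one whose survival values
#' span the largest log10 range across fermentations; ties break toward the
#' earlier timepoint.
#'
#' @param per_timepoint_survival Named list mapping timepoint (minutes, as
#'   names) to vectors of positive percent survival.
#' @return The selected timepoint in minutes (numeric).
#' @export
select_timepoint <- function(per_timepoint_survival) {
  if (!length(per_timepoint_survival)) stop("no timepoints supplied")
  tps <- as.numeric(names(per_timepoint_survival))
  if (anyNA(tps)) stop("timepoint names must be numeric (minutes)")
  rng <- vapply(per_timepoint_survival, function(v) {
    if (length(v) < 2L) return(0)
    dynamic_range(v)
  }, 0)
  o <- order(-rng, tps)
  tps[o[1L]]
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper used for growth-versus-survival correlations;
#' survival enters on the log10 scale (see the phenotype report helpers).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance input")
  stats::cor(x, y)
}

#' Welch two-sample t-test for a fermentation parameter contrast
#'
#' Compares a response (growth characteristic or log10 robustness) between
#' the two levels of a binary fermentation factor using the unequal-variance
#' (Welch) t-test, the default of `t.test` in R. Degenerate inputs with zero
#' pooled standard error and equal means return t = 0, p = 1.
#'
#' @param values Numeric response vector.
#' @param grouping Factor (or coercible) with exactly 2 levels.
#' @return List with `t`, `p`, `df` and `group_means` (named by level).
#' @export
parameter_effect_ttest <- function(values, grouping) {
  grouping <- factor(grouping)
  if (nlevels(grouping) != 2L) stop("grouping must have exactly 2 levels")
  if (length(values) != length(grouping)) stop("length mismatch")
  sp <- split(values, grouping)
  if (any(vapply(sp, length, 0L) < 2L)) stop("each group needs >= 2 observations")
  n <- vapply(sp, length, 0L)
  m <- vapply(sp, mean, 0)
  v <- vapply(sp, stats::var, 0)
  se2 <- v[1L] / n[1L] + v[2L] / n[2L]
  d <- m[1L] - m[2L]
  if (se2 == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
    df <- sum(n) - 2
  } else {
    t <- d / sqrt(se2)
    df <- se2^2 / ((v[1L] / n[1L])^2 / (n[1L] - 1L) + (v[2L] / n[2L])^2 / (n[2L] - 1L))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = unname(t), p = unname(p), df = unname(df), group_means = m)
}

#' Robustness columns for a phenotype table
#'
#' Converts every `<stress>_<minutes>min_pct` column to log10 fractional
#' survival (`log10(pct / 100)`), the robustness scale used for all
#' correlation and t-test work. Equivalent up to an additive constant to
#' the log CFU difference N_t - N_0.
#'
#' @param pheno Phenotype data.frame.
#' @return data.frame of robustness values, one column per survival column
#'   (named `<stress>_<minutes>min`), rows aligned with `pheno`.
#' @export
robustness_values <- function(pheno) {
  sc <- survival_columns(pheno)
  if (!nrow(sc)) stop("no survival columns found")
  out <- lapply(sc$column, function(cl) {
    v <- pheno[[cl]]
    if (any(v <= 0, na.rm = TRUE)) stop("non-positive survival in column ", cl)
    log10(v / 100)
  })
  names(out) <- sub("_pct$", "", sc$column)
  as.data.frame(out, check.names = FALSE)
}

#' Phenotype-layer report for one strain
#'
#' Computes, from a phenotype table: the dynamic range per stress assay
#' timepoint, the selected analysis timepoint per stress, Pearson
#' correlations of growth rate and final OD with log10 survival, and Welch
#' t-tests of every fermentation parameter against every response
#' (growth characteristics and per-stress robustness). Temperature (three
#' levels) is tested as the three pairwise contrasts.
#'
#' @param pheno Phenotype data.frame including `mu` and `od_final`.
#' @param alpha Significance level for flagging (default 0.05).
#' @return List with `dynamic_ranges`, `selected_timepoints`,
#'   `correlations`, `parameter_tests` data.frames.
#' @export
phenotype_report <- function(pheno, alpha = 0.05) {
  sc <- survival_columns(pheno)
  if (!nrow(sc)) stop("no survival columns found")
  rob <- robustness_values(pheno)

  sc$dynamic_range <- vapply(sc$column, function(cl) dynamic_range(pheno[[cl]]), 0)

  sel <- do.call(rbind, lapply(split(sc, sc$stress), function(s) {
    pt <- stats::setNames(lapply(s$column, function(cl) pheno[[cl]]),
                          s$timepoint_min)
    data.frame(stress = s$stress[1L], timepoint_min = select_timepoint(pt),
               stringsAsFactors = FALSE)
  }))
  rownames(sel) <- NULL

  corr <- NULL
  if (all(c("mu", "od_final") %in% names(pheno))) {
    corr <- do.call(rbind, lapply(seq_len(nrow(sc)), function(i) {
      r <- rob[[i]]
      data.frame(
        stress = sc$stress[i], timepoint_min = sc$timepoint_min[i],
        pearson_mu = pearson(pheno$mu, r),
        pearson_od_final = pearson(pheno$od_final, r),
        stringsAsFactors = FALSE
      )
    }))
  }

  responses <- c(
    if ("mu" %in% names(pheno)) list(mu = pheno$mu),
    if ("od_final" %in% names(pheno)) list(od_final = pheno$od_final),
    as.list(rob)
  )
  contrasts <- list(
    salt      = list(values = pheno$salt_mM, a = 0, b = 100),
    initial_pH = list(values = pheno$initial_pH, a = 6.0, b = 6.5),
    oxygen    = list(values = pheno$oxygen, a = "low", b = "high"),
    temperature_27v30 = list(values = pheno$temperature_C, a = 27, b = 30),
    temperature_30v35 = list(values = pheno$temperature_C, a = 30, b = 35),
    temperature_27v35 = list(values = pheno$temperature_C, a = 27, b = 35)
  )
  rows <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    keep <- ct$values %in% c(ct$a, ct$b)
    g <- factor(ct$values[keep], levels = c(ct$a, ct$b))
    for (rn in names(responses)) {
      tt <- parameter_effect_ttest(responses[[rn]][keep], g)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = cn, response = rn, t = tt$t, p = tt$p,
        mean_low = tt$group_means[1L], mean_high = tt$group_means[2L],
        significant = tt$p < alpha, stringsAsFactors = FALSE
      )
    }
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL

  list(dynamic_ranges = sc, selected_timepoints = sel,
       correlations = corr, parameter_tests = tests)
}
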