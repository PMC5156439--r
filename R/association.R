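#' Linear fit of one gene's expression against robustness
#'
#' Ordinary least squares of 2-log expression on log10 robustness across
#' fermentations, with a two-sided P-value for the slope from its
#' t-statistic on n - 2 degrees of freedom.
#'
#' @param expr 2-log expression values, one per fermentation.
#' @param robustness Matching log10 robustness values (nonzero variance,
#'   length >= 4).
#' @return List with `slope`, `intercept`, `p_value`, `direction`
#'   ("positive"/"negative").
#' @export
fit_gene_linear <- function(expr, robustness) {
  if (length(expr) != length(robustness)) stop("length mismatch")
  if (length(expr) < 4L) stop("need at least 4 paired observations")
  if (stats::var(robustness) == 0) stop("zero-variance robustness")
  res <- fit_all_genes(matrix(expr, nrow = 1L,
                              dimnames = list("g", NULL)), robustness)
  list(slope = res$slope, intercept = res$intercept, p_value = res$p_value,
       direction = res$direction)
}

#' Vectorised per-gene linear fits
#'
#' Closed-form OLS of every row of an expression matrix on a robustness
#' vector; algebraically identical to `lm(expr ~ robustness)` per gene but
#' computed with the normal equations for speed on thousands of genes.
#'
#' @param expr Genes-by-fermentations matrix of 2-log expression.
#' @param robustness Robustness values, one per column of `expr`.
#' @return data.frame: `gene_id`, `slope`, `intercept`, `t`, `p_value`,
#'   `direction`.
#' @export
fit_all_genes <- function(expr, robustness) {
  if (ncol(expr) != length(robustness)) stop("length mismatch")
  keep <- !is.na(robustness)
  expr <- expr[, keep, drop = FALSE]
  x <- as.numeric(robustness[keep])
  n <- length(x)
  if (n < 4L) stop("need at least 4 fermentations with robustness values")
  if (stats::var(x) == 0) stop("zero-variance robustness")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- rowMeans(expr)
  slope <- as.numeric(expr %*% xc) / sxx
  intercept <- ym - slope * mean(x)
  fitted_dev <- outer(slope, xc)                 # fitted minus row mean
  rss <- rowSums((expr - ym - fitted_dev)^2)
  sigma2 <- rss / (n - 2L)
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf * sign(slope)))
  p <- 2 * stats::pt(-abs(tstat), n - 2L)
  data.frame(
    gene_id = rownames(expr), slope = slope, intercept = intercept,
    t = tstat, p_value = p,
    direction = ifelse(slope >= 0, "positive", "negative"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-strain robustness signature from two assay timepoints
#'
#' Keeps the genes whose expression correlates significantly
#' (p < `alpha`) with robustness at both timepoints of the stress assay
#' with a consistent direction, ranks them by the product of the two
#' P-values (most significant first), and flags the subset below
#' `product_threshold`.
#'
#' @param results_t1,results_t2 Per-gene fit results (from
#'   [fit_all_genes()]) at the two timepoints; same gene universe.
#' @param alpha Per-timepoint significance level (default 0.05).
#' @param product_threshold P-value product cutoff for the
#'   "most significant" flag (default 5e-5).
#' @return data.frame ranked ascending by `p_product`: `gene_id`,
#'   `direction`, `avg_slope` (signed mean of the two slopes),
#'   `abs_avg_slope`, `p_t1`, `p_t2`, `p_product`, `most_significant`,
#'   plus informational BH-adjusted columns `bh_t1`, `bh_t2`.
#' @export
strain_signature <- function(results_t1, results_t2, alpha = 0.05,
                             product_threshold = 5e-5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (product_threshold <= 0 || product_threshold >= 1)
    stop("product_threshold must be in (0, 1)")
  if (!setequal(results_t1$gene_id, results_t2$gene_id))
    stop("the two timepoints must cover the same gene universe")
  m <- merge(results_t1, results_t2, by = "gene_id",
             suffixes = c("_t1", "_t2"))
  m$bh_t1 <- stats::p.adjust(m$p_value_t1, "BH")
  m$bh_t2 <- stats::p.adjust(m$p_value_t2, "BH")
  keep <- m$p_value_t1 < alpha & m$p_value_t2 < alpha &
    m$direction_t1 == m$direction_t2
  sig <- m[keep, , drop = FALSE]
  out <- data.frame(
    gene_id = sig$gene_id,
    direction = sig$direction_t1,
    avg_slope = (sig$slope_t1 + sig$slope_t2) / 2,
    p_t1 = sig$p_value_t1, p_t2 = sig$p_value_t2,
    p_product = sig$p_value_t1 * sig$p_value_t2,
    bh_t1 = sig$bh_t1, bh_t2 = sig$bh_t2,
    stringsAsFactors = FALSE
  )
  out$abs_avg_slope <- abs(out$avg_slope)
  out$most_significant <- out$p_product < product_threshold
  out <- out[order(out$p_product, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rowwise Welch t-test of matrix columns split by a 2-level factor.
row_welch <- function(Y, grouping) {
  grouping <- factor(grouping)
  stopifnot(nlevels(grouping) == 2L)
  i1 <- grouping == levels(grouping)[1L]
  i2 <- grouping == levels(grouping)[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each level needs >= 2 fermentations")
  m1 <- rowMeans(Y[, i1, drop = FALSE]); m2 <- rowMeans(Y[, i2, drop = FALSE])
  v1 <- rowSums((Y[, i1, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((Y[, i2, drop = FALSE] - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & m1 == m2] <- 1
  data.frame(t = t, df = df, p_value = p, row.names = NULL)
}

#' Differential expression by individual fermentation parameter
#'
#' Welch t-tests of every gene between the two levels of each fermentation
#' parameter (salt 0 vs 100 mM, oxygen low vs high, initial pH 6.0 vs 6.5,
#' temperature extreme levels 27 vs 35 degrees C), plus the pairwise overlap
#' of the significant gene sets.
#'
#' @param expr Genes-by-fermentations matrix (columns named by
#'   fermentation id).
#' @param design Fermentation design covering those ids.
#' @param alpha Significance level (default 0.05).
#' @return List with `sets` (named list of significant gene-id vectors),
#'   `counts`, `overlap_counts` (matrix, diagonal = set sizes) and
#'   `overlap_pct` (Jaccard percentage of each pair; NA when both sets are
#'   empty).
#' @export
parameter_differential_expression <- function(expr, design, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  design <- design[match(colnames(expr), as.character(design$fermentation_id)), ]
  if (anyNA(design$fermentation_id))
    stop("expression columns missing from the design")
  params <- list(
    salt = list(v = design$salt_mM, lv = c(0, 100)),
    oxygen = list(v = design$oxygen, lv = c("low", "high")),
    pH = list(v = design$initial_pH, lv = c(6.0, 6.5)),
    temperature = list(v = design$temperature_C, lv = c(27, 35))
  )
  sets <- list()
  for (pn in names(params)) {
    p <- params[[pn]]
    if (length(unique(p$v)) < 2L)
      stop("parameter ", pn, " has a single level in this design")
    keep <- p$v %in% p$lv
    w <- row_welch(expr[, keep, drop = FALSE],
                   factor(p$v[keep], levels = p$lv))
    sets[[pn]] <- rownames(expr)[w$p_value < alpha]
  }
  k <- length(sets)
  oc <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  op <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    oc[i, j] <- inter
    op[i, j] <- if (uni > 0) 100 * inter / uni else NA_real_
  }
  list(sets = sets, counts = vapply(sets, length, 0L),
       overlap_counts = oc, overlap_pct = op)
}
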