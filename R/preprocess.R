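#' MA transformation of two-color intensities
#'
#' @param cy5,cy3 Positive channel intensities (vectors of equal length).
#' @return data.frame with `M` (log2 cy5/cy3) and `A` (mean log2 intensity).
#' @export
ma_transform <- function(cy5, cy3) {
  if (length(cy5) != length(cy3)) stop("cy5 and cy3 must have equal length")
  if (any(cy5 <= 0) || any(cy3 <= 0)) stop("intensities must be positive")
  data.frame(M = log2(cy5 / cy3), A = (log2(cy5) + log2(cy3)) / 2)
}

#' Raise non-positive intensities to a floor
#'
#' Raw fluorescence after background handling can be zero or negative; the
#' log transform requires positivity, so such values are raised to `floor`
#' and the count is reported via a message.
#'
#' @param x Intensity vector.
#' @param floor Replacement value (default 1).
#' @return Floored vector; number floored in `attr(, "n_floored")`.
#' @export
floor_intensities <- function(x, floor = 1) {
  n <- sum(x <= 0)
  if (n > 0) {
    message("floored ", n, " non-positive intensities to ", floor)
    x[x <= 0] <- floor
  }
  structure(x, n_floored = n)
}

#' Lowess normalization of M against A
#'
#' Removes intensity-dependent dye bias by subtracting a robust local
#' regression fit of M on A (local quadratic, robustness-weighted — classic
#' degree-1 lowess leaves visible lack of fit at curvature comparable to
#' the span window), then median-centers the corrected M per array (the
#' scaling step).
#'
#' @param M Log2 ratios.
#' @param A Mean log2 intensities, same length as `M` (>= 20, non-degenerate).
#' @param span Smoother span in (0, 1] (default 0.3).
#' @return Corrected M vector with per-array median 0.
#' @export
lowess_normalize <- function(M, A, span = 0.3) {
  if (length(M) != length(A)) stop("M and A must have equal length")
  if (length(M) < 20L) stop("need at least 20 spots for lowess normalization")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (diff(range(A)) == 0) stop("degenerate A values (all equal)")
  if (stats::var(M) == 0) return(M - stats::median(M))
  # robustness iterations break down when > half the residuals are exactly 0
  # (MAD = 0); fall back to plain local least squares in that case
  fit <- tryCatch(
    stats::loess(M ~ A, span = span, degree = 2, family = "symmetric"),
    error = function(e) stats::loess(M ~ A, span = span, degree = 2))
  Mc <- M - stats::predict(fit, A)
  Mc - stats::median(Mc)
}

#' Place samples on one relative expression scale from loop ratios
#'
#' Solves, per probe, the least-squares system `x[cy5] - x[cy3] = M` over
#' all hybridizations of a connected design. The per-probe gauge freedom (a
#' common additive constant) is fixed by the minimum-norm solution, which
#' makes each probe's sample values sum to zero.
#'
#' @param normalized Long data.frame with `array_id`, `probe_id`, `M`
#'   (normalized log2 ratios), or a hybridization-by-probe matrix with
#'   rownames = array ids.
#' @param design Hybridization design (`array_id`, `cy5`, `cy3`).
#' @return Matrix probes x samples of relative log2 expression (columns
#'   named by fermentation id; each row sums to ~0).
#' @export
loop_to_sample_expression <- function(normalized, design) {
  if (!design_connected(design))
    stop("hybridization design graph is not connected; samples cannot be placed on one scale")
  if (is.data.frame(normalized)) {
    Mmat <- stats::xtabs(M ~ array_id + probe_id, data = normalized)
    Mmat <- matrix(as.numeric(Mmat), nrow(Mmat), ncol(Mmat),
                   dimnames = dimnames(Mmat))
  } else {
    Mmat <- normalized
  }
  Mmat <- Mmat[as.character(design$array_id), , drop = FALSE]
  samples <- as.character(sort(unique(c(design$cy5, design$cy3))))
  X <- matrix(0, nrow(design), length(samples),
              dimnames = list(design$array_id, samples))
  for (h in seq_len(nrow(design))) {
    X[h, as.character(design$cy5[h])] <- X[h, as.character(design$cy5[h])] + 1
    X[h, as.character(design$cy3[h])] <- X[h, as.character(design$cy3[h])] - 1
  }
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
  Xplus <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  out <- t(Xplus %*% Mmat)           # probes x samples
  rownames(out) <- colnames(Mmat)
  colnames(out) <- samples
  out
}

#' Median aggregation of probe signals to ORF expression
#'
#' @param probe_expression Probe-by-sample matrix of relative log2 values.
#' @param probe_map data.frame `probe_id`, `orf_id`; every probe must map to
#'   exactly one ORF.
#' @return ORF-by-sample matrix (median over each ORF's probes).
#' @export
aggregate_probes <- function(probe_expression, probe_map) {
  probes <- rownames(probe_expression)
  if (anyDuplicated(probe_map$probe_id)) stop("probe map assigns a probe to multiple ORFs")
  idx <- match(probes, probe_map$probe_id)
  if (anyNA(idx)) stop("unmapped probe ids: ",
                       paste(utils::head(probes[is.na(idx)], 5L), collapse = ", "))
  orf <- probe_map$orf_id[idx]
  orfs <- unique(orf)
  out <- matrix(NA_real_, length(orfs), ncol(probe_expression),
                dimnames = list(orfs, colnames(probe_expression)))
  groups <- split(seq_along(orf), orf)
  for (g in names(groups)) {
    rows <- groups[[g]]
    out[g, ] <- if (length(rows) == 1L) probe_expression[rows, ]
                else apply(probe_expression[rows, , drop = FALSE], 2L, stats::median)
  }
  out[orfs[order(orfs)], , drop = FALSE]
}

#' Full probe-to-gene preprocessing chain
#'
#' Floors and MA-transforms the raw channel intensities, lowess-normalizes M
#' against A per array (optionally with a single global lowess fit),
#' unfolds the loop design into per-sample relative expression, and
#' aggregates probes into ORF-level values.
#'
#' @param intensities data.frame `array_id`, `probe_id`, `cy5`, `cy3`.
#' @param probe_map data.frame `probe_id`, `orf_id`.
#' @param design Hybridization design.
#' @param span Lowess span (default 0.3).
#' @param global_scale Normalize per array (FALSE, default) or with one
#'   global fit across arrays (TRUE).
#' @return ORF-by-sample matrix of relative log2 expression.
#' @export
preprocess_arrays <- function(intensities, probe_map, design, span = 0.3,
                              global_scale = FALSE) {
  intensities$cy5 <- floor_intensities(intensities$cy5)
  intensities$cy3 <- floor_intensities(intensities$cy3)
  ma <- ma_transform(intensities$cy5, intensities$cy3)
  intensities$A <- ma$A
  if (global_scale) {
    intensities$M <- lowess_normalize(ma$M, ma$A, span)
  } else {
    intensities$M <- ma$M
    for (a in unique(intensities$array_id)) {
      i <- intensities$array_id == a
      intensities$M[i] <- lowess_normalize(ma$M[i], ma$A[i], span)
    }
  }
  probe_expr <- loop_to_sample_expression(
    intensities[, c("array_id", "probe_id", "M")], design)
  aggregate_probes(probe_expr, probe_map)
}
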