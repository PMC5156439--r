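#' Cross-strain generic signature over orthologous groups
#'
#' Screens the orthologous groups (OGs) that are complete across all
#' strains for those whose member genes show a same-direction association
#' of expression with robustness at the selected timepoint in every strain
#' (per-strain p < `p_threshold`), ranks them on the average per-strain
#' P-value, and returns the top of the ranking with the average and maximum
#' P-value per OG.
#'
#' @param per_strain_results Named list (one entry per strain) of per-gene
#'   fit results (from [fit_all_genes()]) at that strain's selected
#'   timepoint.
#' @param og_map data.frame `og_id` plus one gene-id column per strain
#'   (NA = absent); at most one gene per strain per OG.
#' @param p_threshold Per-strain screening threshold (default 0.2).
#' @param top_k Number of ranked entries returned (default 10).
#' @return data.frame ranked ascending by `avg_p` (ties broken by `max_p`,
#'   then `og_id`): `og_id`, one `locus_<strain>` column per strain, one
#'   `p_<strain>` column per strain, `direction`, `avg_p`, `max_p`.
#' @export
generic_rank <- function(per_strain_results, og_map, p_threshold = 0.2,
                         top_k = 10L) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  strains <- names(per_strain_results)
  if (length(strains) < 2L) stop("need results for at least 2 strains")
  if (!all(strains %in% names(og_map)))
    stop("og_map lacks columns for strains: ",
         paste(setdiff(strains, names(og_map)), collapse = ", "))
  for (s in strains) {
    r <- per_strain_results[[s]]
    if (is.null(r) || !nrow(r)) stop("empty results for strain ", s)
    dup <- og_map[[s]][!is.na(og_map[[s]])]
    if (anyDuplicated(dup))
      stop("og_map assigns one ", s, " gene to multiple OGs")
  }
  complete <- stats::complete.cases(og_map[, strains, drop = FALSE])
  og <- og_map[complete, , drop = FALSE]
  if (!nrow(og)) {
    return(data.frame(og_id = character(0)))
  }
  pm <- matrix(NA_real_, nrow(og), length(strains),
               dimnames = list(og$og_id, strains))
  dm <- matrix(NA_character_, nrow(og), length(strains),
               dimnames = list(og$og_id, strains))
  for (s in strains) {
    r <- per_strain_results[[s]]
    idx <- match(og[[s]], r$gene_id)
    pm[, s] <- r$p_value[idx]
    dm[, s] <- r$direction[idx]
  }
  if (anyNA(pm))
    stop("OG member genes missing from strain results: ",
         paste(utils::head(og$og_id[rowSums(is.na(pm)) > 0], 5L), collapse = ", "))
  pass <- rowSums(pm < p_threshold) == length(strains) &
    apply(dm, 1L, function(d) length(unique(d)) == 1L)
  og <- og[pass, , drop = FALSE]
  pm <- pm[pass, , drop = FALSE]
  dm <- dm[pass, , drop = FALSE]
  out <- data.frame(og_id = og$og_id, stringsAsFactors = FALSE)
  for (s in strains) out[[paste0("locus_", s)]] <- og[[s]]
  for (s in strains) out[[paste0("p_", s)]] <- pm[, s]
  out$direction <- if (nrow(dm)) dm[, 1L] else character(0)
  out$avg_p <- rowMeans(pm)
  out$max_p <- if (nrow(pm)) apply(pm, 1L, max) else numeric(0)
  out <- out[order(out$avg_p, out$max_p, out$og_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
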