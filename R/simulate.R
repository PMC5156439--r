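#' Gene identifiers used by the synthetic generators
#' @param n_genes Number of genes.
#' @return Character vector `g0001`-style, zero-padded to the width of `n_genes`.
#' @export
gene_ids <- function(n_genes) sprintf("g%0*d", nchar(as.character(n_genes)), seq_len(n_genes))

#' Default per-stress factor effects (log10 robustness units)
#'
#' Additive effects of each fermentation factor on log10 robustness:
#' `salt` (100 vs 0 mM), `ph` (6.5 vs 6.0), `temp_per_C` (per degree above
#' 27) and `oxygen` (high vs low). The heat profile is dominated by a
#' +1.8 log10 oxygen effect, mirroring the strongest single-parameter
#' contrast seen in the real phenotype tables; oxidative robustness gets a
#' weaker, partly opposing profile so the two stresses are distinct.
#'
#' @return Named list with `heat` and `oxidative` effect vectors.
#' @export
default_response_profile <- function() {
  list(
    heat      = c(salt = 0.2, ph = 0.3, temp_per_C = 0.12, oxygen = 1.8),
    oxidative = c(salt = 0.3, ph = 0.2, temp_per_C = 0.08, oxygen = -1.0)
  )
}

.linear_predictor <- function(design, eff) {
  g <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  g("salt") * (design$salt_mM == 100) +
    g("ph") * (design$initial_pH == 6.5) +
    g("temp_per_C") * (design$temperature_C - 27) +
    g("oxygen") * (design$oxygen == "high")
}

#' Simulate stress-survival phenotypes with duplicate CFU counts
#'
#' Builds a true log10 robustness value per fermentation, stress and assay
#' timepoint additively from factor effects plus Gaussian noise, then draws
#' paired technical-duplicate CFU counts by Poisson sampling consistent with
#' that robustness (N0 fixed, Nt mean = N0 * 10^robustness).
#'
#' @param design Fermentation design (default [fermentation_design()]).
#' @param response_profile Per-stress factor effects in log10 units, see
#'   [default_response_profile()].
#' @param dynamic_range_target Noise-free log10 spread the factor effects are
#'   rescaled to (default 5). `NULL` keeps the profile's native scale.
#' @param timepoints Named list: stress -> at least two assay timepoints in
#'   minutes.
#' @param noise_sd Gaussian noise on log10 robustness (default 0.3).
#' @param n0 True pre-stress count, CFU/ml (default 1e8).
#' @param n_duplicates Technical duplicates per CFU measurement (default 2).
#' @param seed Integer seed; same seed gives identical output.
#' @return List with `table` (per fermentation/stress/timepoint: true and
#'   CFU-derived survival and robustness), `cfu` (duplicate-level counts),
#'   `true_robustness` (named list per stress: the shared noise-free
#'   fermentation effect, the quantity expression is planted against),
#'   `design`, `seed`.
#' @export
generate_phenotypes <- function(design = fermentation_design(),
                                response_profile = default_response_profile(),
                                dynamic_range_target = 5,
                                timepoints = list(heat = c(10, 30),
                                                  oxidative = c(30, 60)),
                                noise_sd = 0.3,
                                n0 = 1e8,
                                n_duplicates = 2L,
                                seed = 1L) {
  if (!is.null(dynamic_range_target) && dynamic_range_target <= 0)
    stop("dynamic_range_target must be positive")
  if (any(vapply(timepoints, length, 0L) < 2L))
    stop("each stress needs at least 2 timepoints")
  set.seed(seed)
  nf <- nrow(design)
  rows <- list(); cfu_rows <- list(); truth <- list()
  for (stress in names(timepoints)) {
    eta <- .linear_predictor(design, response_profile[[stress]])
    spread <- diff(range(eta))
    if (!is.null(dynamic_range_target) && spread > 0)
      eta <- eta * dynamic_range_target / spread
    tps <- sort(timepoints[[stress]])
    base1 <- -0.2 - max(eta)          # most robust condition ~63% survival
    truth[[stress]] <- stats::setNames(base1 + eta, design$fermentation_id)
    for (k in seq_along(tps)) {
      base_k <- base1 - 0.5 * (k - 1L)  # later timepoints kill more
      r_true <- base_k + eta + stats::rnorm(nf, 0, noise_sd)
      lam_t <- n0 * 10^r_true
      for (f in seq_len(nf)) {
        n0_dup <- stats::rpois(n_duplicates, n0)
        nt_dup <- stats::rpois(n_duplicates, lam_t[f])
        surv <- tryCatch(compute_survival(n0_dup, nt_dup),
                         robustsig_censored = function(e) list(survival_pct = NA_real_,
                                                               robustness = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          fermentation_id = design$fermentation_id[f],
          stress = stress, timepoint_min = tps[k],
          true_robustness = r_true[f],
          true_survival_pct = 100 * 10^r_true[f],
          survival_pct = surv$survival_pct,
          robustness = surv$robustness,
          censored = is.na(surv$survival_pct),
          stringsAsFactors = FALSE
        )
        cfu_rows[[length(cfu_rows) + 1L]] <- data.frame(
          fermentation_id = design$fermentation_id[f],
          stress = stress, timepoint_min = tps[k],
          replicate = seq_len(n_duplicates),
          n0 = n0_dup, nt = nt_dup, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(table = do.call(rbind, rows),
       cfu = do.call(rbind, cfu_rows),
       true_robustness = truth,
       design = design, seed = seed)
}

#' Simulate a 2-log expression matrix with planted robustness signal
#'
#' Planted genes follow `a_g + slope_g * robustness + N(0, noise_sd)`;
#' the remaining genes are noise around their baseline, independent of the
#' phenotype.
#'
#' @param robustness One (true) robustness value per fermentation; names are
#'   used as column names.
#' @param n_genes Total genes (>= number planted).
#' @param n_planted Number of planted genes (ignored when `planted_slopes`
#'   is given).
#' @param slope_range Absolute slope range for planted genes (expression
#'   units per log10 robustness); signs are drawn at random.
#' @param noise_sd Gaussian expression noise (2-log units).
#' @param baseline_range Range of per-gene baselines `a_g` (2-log units).
#' @param planted_slopes Optional named vector gene_id -> signed slope,
#'   overriding random planting.
#' @param seed Integer seed.
#' @return List with `expr` (genes x fermentations matrix) and `truth`
#'   (data.frame gene_id, slope for planted genes).
#' @export
generate_expression <- function(robustness, n_genes,
                                n_planted = 20L,
                                slope_range = c(1.5, 3),
                                noise_sd = 0.5,
                                baseline_range = c(6, 12),
                                planted_slopes = NULL,
                                seed = 1L) {
  set.seed(seed)
  ids <- gene_ids(n_genes)
  nf <- length(robustness)
  if (is.null(planted_slopes)) {
    if (n_genes < n_planted) stop("n_genes must be >= n_planted")
    planted <- if (n_planted > 0L) sort(sample.int(n_genes, n_planted)) else integer(0)
    slopes <- stats::runif(length(planted), slope_range[1L], slope_range[2L]) *
      sample(c(-1, 1), length(planted), replace = TRUE)
    planted_slopes <- stats::setNames(slopes, ids[planted])
  } else {
    if (!all(names(planted_slopes) %in% ids))
      stop("planted_slopes names outside the gene universe")
    if (any(planted_slopes == 0)) stop("planted slopes must be nonzero")
  }
  a <- stats::runif(n_genes, baseline_range[1L], baseline_range[2L])
  expr <- matrix(a, n_genes, nf) +
    matrix(stats::rnorm(n_genes * nf, 0, noise_sd), n_genes, nf)
  rownames(expr) <- ids
  colnames(expr) <- if (!is.null(names(robustness))) names(robustness) else seq_len(nf)
  if (length(planted_slopes)) {
    pg <- names(planted_slopes)
    expr[pg, ] <- expr[pg, ] + outer(unname(planted_slopes), as.numeric(robustness))
  }
  list(expr = expr,
       truth = data.frame(gene_id = names(planted_slopes),
                          slope = unname(planted_slopes),
                          stringsAsFactors = FALSE))
}

#' Two-loop hybridization design
#'
#' Default microarray co-hybridization layout: one loop over the day-1
#' samples, one loop over the day-2 samples, plus a single bridging
#' hybridization between the replicated fermentations, giving one connected
#' graph over all samples. Arrowheads (Cy5) point from each sample to the
#' next in its loop.
#'
#' @param day_loops List of integer vectors of fermentation ids, one loop
#'   per day.
#' @param bridge Length-2 vector: one hybridization connecting the loops
#'   (Cy3 first element, Cy5 second). `NULL` for no bridge.
#' @return data.frame with `array_id`, `cy5`, `cy3` (fermentation ids).
#' @export
loop_design <- function(day_loops = list(1:6, 7:13), bridge = c(6, 13)) {
  edges <- list()
  for (loop in day_loops) {
    if (length(loop) < 2L) stop("each loop needs >= 2 samples")
    nxt <- c(loop[-1L], loop[1L])
    edges[[length(edges) + 1L]] <- data.frame(cy5 = nxt, cy3 = loop)
  }
  if (!is.null(bridge)) {
    if (length(bridge) != 2L) stop("bridge must name exactly 2 samples")
    edges[[length(edges) + 1L]] <- data.frame(cy5 = bridge[2L], cy3 = bridge[1L])
  }
  d <- do.call(rbind, edges)
  d <- data.frame(array_id = sprintf("A%02d", seq_len(nrow(d))), d,
                  stringsAsFactors = FALSE)
  d
}

#' Check that a hybridization design connects all its samples
#'
#' @param design data.frame with `cy5`, `cy3` sample columns.
#' @return TRUE if the undirected co-hybridization graph is connected.
#' @export
design_connected <- function(design) {
  samples <- unique(c(design$cy5, design$cy3))
  if (length(samples) <= 1L) return(TRUE)
  idx <- stats::setNames(seq_along(samples), samples)
  parent <- seq_along(samples)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(design))) {
    a <- find(idx[[as.character(design$cy5[k])]])
    b <- find(idx[[as.character(design$cy3[k])]])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(samples), find, 0L))) == 1L
}

#' Simulate probe-level two-color intensities under a loop design
#'
#' Each gene gets `probes_per_gene` probes with probe-specific affinities.
#' Per hybridization, the true log2 ratio of a probe equals the expression
#' difference of the co-hybridized samples; an intensity-dependent dye bias
#' `dye_bias(A)` and Gaussian noise are added in M, and the two channel
#' intensities are reconstructed from (M, A).
#'
#' @param expr Gene-by-fermentation 2-log expression matrix (column names =
#'   fermentation ids).
#' @param probes_per_gene Probes designed per ORF (>= 1).
#' @param design Hybridization design (see [loop_design()]).
#' @param dye_bias Function of mean log2 intensity A returning the M offset.
#' @param noise_sd Gaussian M noise (log2 units).
#' @param affinity_range Range of per-probe affinity offsets (log2 units).
#' @param seed Integer seed.
#' @return List with `intensities` (array_id, probe_id, cy5, cy3),
#'   `probe_map` (probe_id, orf_id) and `design`.
#' @export
generate_probe_intensities <- function(expr, probes_per_gene = 3L,
                                       design = loop_design(),
                                       dye_bias = function(A) 0,
                                       noise_sd = 0,
                                       affinity_range = c(0, 6),
                                       seed = 1L) {
  if (probes_per_gene < 1L) stop("probes_per_gene must be >= 1")
  known <- colnames(expr)
  bad <- setdiff(as.character(c(design$cy5, design$cy3)), known)
  if (length(bad)) stop("design references unknown fermentation ids: ",
                        paste(unique(bad), collapse = ", "))
  set.seed(seed)
  genes <- rownames(expr)
  probe_map <- data.frame(
    probe_id = paste0(rep(genes, each = probes_per_gene), "_p",
                      rep(seq_len(probes_per_gene), length(genes))),
    orf_id = rep(genes, each = probes_per_gene),
    stringsAsFactors = FALSE
  )
  affinity <- stats::runif(nrow(probe_map), affinity_range[1L], affinity_range[2L])
  out <- vector("list", nrow(design))
  for (h in seq_len(nrow(design))) {
    s5 <- as.character(design$cy5[h]); s3 <- as.character(design$cy3[h])
    e5 <- expr[probe_map$orf_id, s5]; e3 <- expr[probe_map$orf_id, s3]
    A <- affinity + (e5 + e3) / 2
    M <- (e5 - e3) + dye_bias(A) + stats::rnorm(nrow(probe_map), 0, noise_sd)
    out[[h]] <- data.frame(
      array_id = design$array_id[h],
      probe_id = probe_map$probe_id,
      cy5 = 2^(A + M / 2), cy3 = 2^(A - M / 2),
      stringsAsFactors = FALSE
    )
  }
  list(intensities = do.call(rbind, out), probe_map = probe_map, design = design)
}

#' Simulate an orthologous-group map across strains
#'
#' One candidate OG per gene index; each OG holds at most one gene per
#' strain (a random gene of that strain, without replacement). A fraction of
#' the OGs is complete (members in every strain); the rest lack at least one
#' strain.
#'
#' @param strains Character vector of strain ids (>= 2).
#' @param n_genes Genes per strain.
#' @param fraction_shared Fraction of OGs complete in all strains.
#' @param seed Integer seed.
#' @return data.frame: `og_id` plus one gene-id column per strain
#'   (NA = absent).
#' @export
generate_og_map <- function(strains, n_genes, fraction_shared = 1, seed = 1L) {
  if (length(strains) < 2L) stop("need at least 2 strains")
  if (fraction_shared < 0 || fraction_shared > 1)
    stop("fraction_shared must be in [0, 1]")
  set.seed(seed)
  ids <- gene_ids(n_genes)
  og <- data.frame(og_id = sprintf("OG%0*d", nchar(as.character(n_genes)),
                                   seq_len(n_genes)),
                   stringsAsFactors = FALSE)
  for (s in strains) og[[s]] <- sample(ids)
  n_shared <- round(fraction_shared * n_genes)
  incomplete <- if (n_shared < n_genes)
    sort(sample.int(n_genes, n_genes - n_shared)) else integer(0)
  for (i in incomplete) {
    drop <- sample(strains, sample.int(length(strains) - 1L, 1L))
    og[i, drop] <- NA
  }
  og
}
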