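#' Pipeline configuration
#'
#' Collects the tunable thresholds and input locations of the end-to-end
#' pipeline. Defaults follow the analysis conventions used throughout the
#' package: per-timepoint significance 0.05, P-value product cutoff 5e-5,
#' cross-strain screening threshold 0.2, lowess span 0.3, top 10 generic
#' entries.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer master seed for all simulation stages.
#' @param alpha Per-timepoint significance level.
#' @param product_threshold P-value product cutoff for the most-significant
#'   flag.
#' @param generic_p_threshold Per-strain screening threshold of the generic
#'   signature.
#' @param lowess_span Lowess smoother span for dye-bias normalization.
#' @param ttest_alpha Significance level for fermentation-parameter t-tests.
#' @param top_k Entries returned by the generic ranking.
#' @param n_genes,n_planted,probes_per_gene,noise_sd Synthetic-data sizes.
#' @param strains Strain ids simulated (and expected in the OG map).
#' @param phenotype_paths Optional named vector strain -> phenotype TSV; when
#'   unset, the simulate stage's outputs (or the packaged strain fixtures,
#'   for the phenotype stage alone) are used.
#' @param expression_paths Optional named vector strain -> expression TSV.
#' @param og_path Optional OG map TSV.
#' @return A list of class `robustsig_config`.
#' @export
pipeline_config <- function(out_dir = "robustsig_out", seed = 1L,
                            alpha = 0.05, product_threshold = 5e-5,
                            generic_p_threshold = 0.2, lowess_span = 0.3,
                            ttest_alpha = 0.05, top_k = 10L,
                            n_genes = 1000L, n_planted = 20L,
                            probes_per_gene = 3L, noise_sd = 0.5,
                            strains = c("strainA", "strainB", "strainC", "strainD"),
                            phenotype_paths = NULL, expression_paths = NULL,
                            og_path = NULL) {
  for (th in c(alpha, product_threshold, generic_p_threshold, ttest_alpha))
    if (th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  if (lowess_span <= 0 || lowess_span > 1) stop("lowess_span must be in (0, 1]")
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
    product_threshold = product_threshold,
    generic_p_threshold = generic_p_threshold, lowess_span = lowess_span,
    ttest_alpha = ttest_alpha, top_k = as.integer(top_k),
    n_genes = as.integer(n_genes), n_planted = as.integer(n_planted),
    probes_per_gene = as.integer(probes_per_gene), noise_sd = noise_sd,
    strains = strains, phenotype_paths = phenotype_paths,
    expression_paths = expression_paths, og_path = og_path
  ), class = "robustsig_config")
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; values are coerced to
#' numeric where possible, comma-separated values become vectors.
#'
#' @param path Config file path.
#' @return A `robustsig_config` built from the file's settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed config line ", which(bad)[1L], ": ", lines[bad][1L])
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2L], "\\s*,\\s*")[[1L]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(vals) <- vapply(kv, `[`, "", 1L)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

.log <- function(stage, ...) message(sprintf("[%s] ", stage), ...)

.pheno_wide <- function(sim, strain) {
  tab <- sim$table
  wide <- sim$design
  for (stress in unique(tab$stress)) {
    for (tp in sort(unique(tab$timepoint_min[tab$stress == stress]))) {
      sel <- tab$stress == stress & tab$timepoint_min == tp
      col <- sprintf("%s_%dmin_pct", stress, tp)
      wide[[col]] <- tab$survival_pct[sel][match(wide$fermentation_id,
                                                 tab$fermentation_id[sel])]
    }
  }
  wide
}

.simulate_strain <- function(cfg, strain, strain_seed) {
  sim <- generate_phenotypes(seed = strain_seed, noise_sd = 0.3)
  # synthetic growth characteristics: temperature speeds growth, higher
  # initial pH raises final biomass (the dominant real-data contrasts)
  set.seed(strain_seed + 1L)
  d <- sim$design
  mu <- pmax(0.05, 0.35 + 0.025 * (d$temperature_C - 27) +
               0.1 * (d$initial_pH == 6.5) + stats::rnorm(nrow(d), 0, 0.05))
  od <- pmax(0.2, 1.5 + 0.8 * (d$initial_pH == 6.5) + stats::rnorm(nrow(d), 0, 0.12))
  pheno <- .pheno_wide(sim, strain)
  pheno <- cbind(pheno[, 1:6], mu = round(mu, 3), od_final = round(od, 3),
                 pheno[, -(1:6), drop = FALSE])
  ge <- generate_expression(sim$true_robustness$heat, n_genes = cfg$n_genes,
                            n_planted = cfg$n_planted, noise_sd = cfg$noise_sd,
                            seed = strain_seed + 2L)
  pr <- generate_probe_intensities(ge$expr, probes_per_gene = cfg$probes_per_gene,
                                   dye_bias = function(A) 0.3 * sin(A / 2),
                                   noise_sd = 0.1, seed = strain_seed + 3L)
  list(sim = sim, pheno = pheno, expr = ge$expr, truth = ge$truth, probes = pr)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages, writing each stage's TSV outputs into
#' `config$out_dir` and logging configuration, seed and row counts to
#' stderr. With the `simulate` stage, every downstream input is generated
#' synthetically; without it, phenotype/expression/OG inputs are taken from
#' the configured paths (the packaged strain phenotype fixtures serve as the
#' default for a standalone `phenotype` stage).
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of
#'   `c("simulate", "phenotype", "preprocess", "associate", "generic")`,
#'   or `"all"`.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  all_stages <- c("simulate", "phenotype", "preprocess", "associate", "generic")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  meta <- c(seed = config$seed)
  sims <- NULL

  if ("simulate" %in% stages) {
    .log("simulate", "seed=", config$seed, " strains=",
         paste(config$strains, collapse = ","))
    sims <- list()
    for (i in seq_along(config$strains)) {
      s <- config$strains[i]
      sims[[s]] <- .simulate_strain(config, s, config$seed + 100L * i)
      write_tsv(sims[[s]]$pheno,
                file.path(config$out_dir, sprintf("phenotypes_%s.tsv", s)),
                meta = c(meta, strain = s))
      write_expression(sims[[s]]$expr,
                       file.path(config$out_dir, sprintf("expression_%s.tsv", s)),
                       meta = c(meta, strain = s))
      write_tsv(cbind(sims[[s]]$truth, stress = "heat"),
                file.path(config$out_dir, sprintf("truth_%s.tsv", s)),
                meta = c(meta, strain = s))
      write_tsv(sims[[s]]$probes$intensities,
                file.path(config$out_dir, sprintf("probe_intensities_%s.tsv", s)),
                meta = c(meta, strain = s))
      write_tsv(sims[[s]]$probes$probe_map,
                file.path(config$out_dir, sprintf("probe_map_%s.tsv", s)),
                meta = c(meta, strain = s))
      write_tsv(sims[[s]]$probes$design,
                file.path(config$out_dir, sprintf("loop_design_%s.tsv", s)),
                meta = c(meta, strain = s))
      .log("simulate", s, ": ", nrow(sims[[s]]$pheno), " fermentations, ",
           nrow(sims[[s]]$expr), " genes")
    }
    og <- generate_og_map(config$strains, config$n_genes, fraction_shared = 1,
                          seed = config$seed)
    write_tsv(og, file.path(config$out_dir, "og_map.tsv"), meta = meta)
    res$simulate <- sims
    res$og_map <- og
  }

  read_pheno_inputs <- function() {
    if (!is.null(sims)) {
      lapply(sims, `[[`, "pheno")
    } else if (!is.null(config$phenotype_paths)) {
      lapply(config$phenotype_paths, read_phenotypes)
    } else {
      stats::setNames(lapply(strain_names(), strain_phenotypes), strain_names())
    }
  }

  if ("phenotype" %in% stages) {
    phenos <- read_pheno_inputs()
    rep_rows <- list()
    reports <- list()
    for (s in names(phenos)) {
      rp <- phenotype_report(phenos[[s]], alpha = config$ttest_alpha)
      reports[[s]] <- rp
      .log("phenotype", s, ": max dynamic range ",
           round(max(rp$dynamic_ranges$dynamic_range), 2), " log10 units")
      write_tsv(cbind(strain = s, rp$dynamic_ranges),
                file.path(config$out_dir, sprintf("dynamic_ranges_%s.tsv", s)))
      if (!is.null(rp$correlations))
        write_tsv(cbind(strain = s, rp$correlations),
                  file.path(config$out_dir, sprintf("correlations_%s.tsv", s)))
      write_tsv(cbind(strain = s, rp$parameter_tests),
                file.path(config$out_dir, sprintf("parameter_tests_%s.tsv", s)))
      rep_rows[[s]] <- cbind(strain = s, rp$selected_timepoints)
    }
    write_tsv(do.call(rbind, rep_rows),
              file.path(config$out_dir, "selected_timepoints.tsv"))
    res$phenotype <- reports
  }

  if ("preprocess" %in% stages) {
    if (is.null(sims)) stop("preprocess stage needs simulate outputs or probe inputs")
    derived <- list()
    for (s in names(sims)) {
      pr <- sims[[s]]$probes
      ex <- preprocess_arrays(pr$intensities, pr$probe_map, pr$design,
                              span = config$lowess_span)
      derived[[s]] <- ex
      write_expression(ex, file.path(config$out_dir,
                                     sprintf("expression_derived_%s.tsv", s)),
                       meta = c(meta, strain = s, source = "preprocess"))
      .log("preprocess", s, ": ", nrow(ex), " ORFs x ", ncol(ex), " samples")
    }
    res$preprocess <- derived
  }

  if ("associate" %in% stages || "generic" %in% stages) {
    if (is.null(sims)) stop("associate/generic stages need simulate outputs")
    assoc <- list(); selected <- list()
    for (s in names(sims)) {
      pheno <- sims[[s]]$pheno
      expr <- sims[[s]]$expr[, as.character(pheno$fermentation_id)]
      rob <- robustness_values(pheno)
      assoc[[s]] <- list()
      for (stress in c("heat", "oxidative")) {
        cols <- grep(paste0("^", stress, "_"), names(rob), value = TRUE)
        fits <- lapply(cols, function(cl) fit_all_genes(expr, rob[[cl]]))
        names(fits) <- sub(".*_(\\d+)min$", "\\1", cols)
        sig <- strain_signature(fits[[1L]], fits[[2L]], alpha = config$alpha,
                                product_threshold = config$product_threshold)
        assoc[[s]][[stress]] <- list(fits = fits, signature = sig)
        if ("associate" %in% stages) {
          write_tsv(sig, file.path(config$out_dir,
                                   sprintf("signature_%s_%s.tsv", s, stress)),
                    meta = c(meta, strain = s, stress = stress))
          .log("associate", s, "/", stress, ": ", nrow(sig),
               " signature genes (", sum(sig$most_significant), " most significant)")
        }
        sc <- survival_columns(pheno)
        sc <- sc[sc$stress == stress, ]
        pt <- stats::setNames(lapply(sc$column, function(cl) pheno[[cl]]),
                              sc$timepoint_min)
        selected[[s]][[stress]] <- as.character(select_timepoint(pt))
      }
    }
    res$associate <- assoc

    if ("generic" %in% stages) {
      og <- if (!is.null(res$og_map)) res$og_map else read_tsv(config$og_path)
      gen <- list()
      for (stress in c("heat", "oxidative")) {
        per_strain <- lapply(names(assoc), function(s)
          assoc[[s]][[stress]]$fits[[selected[[s]][[stress]]]])
        names(per_strain) <- names(assoc)
        gr <- generic_rank(per_strain, og,
                           p_threshold = config$generic_p_threshold,
                           top_k = config$top_k)
        gen[[stress]] <- gr
        write_tsv(gr, file.path(config$out_dir,
                                sprintf("generic_signature_%s.tsv", stress)),
                  meta = c(meta, stress = stress))
        .log("generic", stress, ": ", nrow(gr), " OGs ranked")
      }
      res$generic <- gen
    }
  }
  invisible(res)
}

#' Command-line entry point
#'
#' Verbs: `simulate`, `phenotype`, `preprocess`, `associate`, `generic`,
#' `all`. Flags: `--config=FILE`, `--seed=N`, `--out-dir=DIR`,
#' `--alpha=X`, `--product-threshold=X`, `--generic-p-threshold=X`,
#' `--lowess-span=X`, `--top-k=N`. Results go to files, logs to stderr.
#'
#' @param args Character vector of CLI arguments (default: the process
#'   command line).
#' @return Exit status, invisibly (0 = success).
#' @export
robustsig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: robustsig <simulate|phenotype|preprocess|associate|generic|all>",
    "[--config=FILE] [--seed=N] [--out-dir=DIR] [--alpha=X]",
    "[--product-threshold=X] [--generic-p-threshold=X] [--lowess-span=X] [--top-k=N]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  verbs <- c("simulate", "phenotype", "preprocess", "associate", "generic", "all")
  verb <- args[1L]
  if (!verb %in% verbs) {
    message("unknown verb: ", verb, "\n", usage)
    return(invisible(1L))
  }
  flags <- args[-1L]
  opt <- list()
  for (f in flags) {
    m <- regmatches(f, regexec("^--([a-z-]+)=(.*)$", f))[[1L]]
    if (length(m) != 3L) { message("bad flag: ", f, "\n", usage); return(invisible(1L)) }
    opt[[gsub("-", "_", m[2L])]] <- m[3L]
  }
  cfg_args <- list()
  if (!is.null(opt$config)) cfg_args <- as.list(read_config(opt$config))[
    names(formals(pipeline_config))]
  cfg_args <- Filter(Negate(is.null), cfg_args)
  num_flags <- c(seed = "seed", alpha = "alpha",
                 product_threshold = "product_threshold",
                 generic_p_threshold = "generic_p_threshold",
                 lowess_span = "lowess_span", top_k = "top_k")
  for (nf in names(num_flags))
    if (!is.null(opt[[nf]])) cfg_args[[num_flags[[nf]]]] <- as.numeric(opt[[nf]])
  if (!is.null(opt$out_dir)) cfg_args$out_dir <- opt$out_dir
  status <- tryCatch({
    config <- do.call(pipeline_config, cfg_args)
    run_pipeline(config, stages = if (verb == "all") "all" else verb)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
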