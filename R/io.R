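#' Read a tab-separated table with `#` metadata header lines
#'
#' All pipeline tables are plain TSV with optional leading `# key=value`
#' comment lines (seed, strain, ...). Decimal separator is always `.`.
#'
#' @param path File path.
#' @return A data.frame; parsed header metadata is attached as
#'   `attr(x, "meta")` (a named character vector).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- character(0)
  if (length(hdr)) {
    kv <- regmatches(hdr, regexec("^#\\s*([^=]+)=(.*)$", hdr))
    kv <- Filter(function(m) length(m) == 3L, kv)
    meta <- stats::setNames(vapply(kv, `[`, "", 3L), trimws(vapply(kv, `[`, "", 2L)))
  }
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  attr(x, "meta") <- meta
  x
}

#' Write a tab-separated table with `#` metadata header lines
#'
#' @param x A data.frame or matrix (matrices are written with a leading
#'   id column named by `id_col` holding the rownames).
#' @param path Output path.
#' @param meta Named character/numeric vector written as `# key=value` lines.
#' @param id_col Name for the rownames column when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, meta = NULL, id_col = "id") {
  if (is.matrix(x)) {
    x <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
    names(x)[1L] <- id_col
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' The phenotype layout mirrors the published fermentation table: design
#' columns (`fermentation_id`, `salt_mM`, `initial_pH`, `temperature_C`,
#' `oxygen`, `day`), growth columns (`mu`, `od_final`) and one percent
#' survival column per stress assay timepoint, named
#' `<stress>_<minutes>min_pct`.
#'
#' @param path Path to a phenotype TSV.
#' @return Validated data.frame with `meta` attribute.
#' @export
read_phenotypes <- function(path) {
  x <- read_tsv(path)
  need <- c("fermentation_id", "salt_mM", "initial_pH", "temperature_C", "oxygen")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("phenotype table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$fermentation_id))
    stop("duplicated fermentation_id in ", path)
  x
}

#' List the survival columns of a phenotype table
#'
#' @param pheno Phenotype data.frame.
#' @return data.frame with `column`, `stress`, `timepoint_min`.
#' @export
survival_columns <- function(pheno) {
  cols <- grep("^(heat|oxidative)_[0-9]+min_pct$", names(pheno), value = TRUE)
  m <- regmatches(cols, regexec("^(heat|oxidative)_([0-9]+)min_pct$", cols))
  data.frame(
    column = cols,
    stress = vapply(m, `[`, "", 2L),
    timepoint_min = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Read / write a gene-by-fermentation expression matrix
#'
#' Expression TSVs carry one row per gene, one column per fermentation id,
#' values on the 2-log scale; the first column (`gene_id`) holds gene ids.
#'
#' @param path File path.
#' @return Numeric matrix, rownames = gene ids, colnames = fermentation ids.
#' @export
read_expression <- function(path) {
  x <- read_tsv(path)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing expression values in ", path)
  m
}

#' @rdname read_expression
#' @param expr Numeric matrix (genes x fermentations).
#' @param meta Named vector of header metadata (e.g. seed).
#' @export
write_expression <- function(expr, path, meta = NULL) {
  write_tsv(expr, path, meta = meta, id_col = "gene_id")
}
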