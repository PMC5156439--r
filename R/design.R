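#' The 13-fermentation fractional factorial design
#'
#' Returns the fixed experimental design used throughout the package: twelve
#' fermentations varying sodium chloride (0 or 100 mM), initial pH (6.0 or
#' 6.5), temperature (27, 30 or 35 degrees C) and oxygen level (high =
#' shaken, low = static), run on two days, plus a thirteenth fermentation
#' replicating the factor settings of fermentation 6 on day 2.
#'
#' @return A data.frame with columns `fermentation_id`, `salt_mM`,
#'   `initial_pH`, `temperature_C`, `oxygen` (factor levels "high"/"low")
#'   and `day`.
#' @examples
#' d <- fermentation_design()
#' stopifnot(nrow(d) == 13)
#' @export
fermentation_design <- function() {
  data.frame(
    fermentation_id = 1:13,
    salt_mM        = c(0, 100, 0, 100, 0, 100, 0, 100, 0, 100, 0, 100, 100),
    initial_pH     = c(6.0, 6.5, 6.5, 6.0, 6.0, 6.5, 6.5, 6.0, 6.0, 6.5, 6.5, 6.0, 6.5),
    temperature_C  = c(27, 27, 27, 27, 30, 30, 30, 30, 35, 35, 35, 35, 30),
    oxygen         = c("high", "high", "low", "low", "low", "low", "high", "high",
                       "high", "high", "low", "low", "low"),
    day            = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Packaged strain phenotype tables
#'
#' Loads the packaged per-strain fermentation phenotype fixture (growth rate,
#' final OD and percent survival under heat and oxidative stress at the
#' published assay timepoints) for one of the three strains.
#'
#' @param strain One of "IL1403", "KF147", "SK11".
#' @return A data.frame in the standard phenotype layout (see
#'   [read_phenotypes()]).
#' @export
strain_phenotypes <- function(strain = c("IL1403", "KF147", "SK11")) {
  strain <- match.arg(strain)
  path <- system.file("extdata", sprintf("phenotypes_%s.tsv", strain),
                      package = "robustsig", mustWork = TRUE)
  read_phenotypes(path)
}

#' @rdname strain_phenotypes
#' @export
strain_names <- function() c("IL1403", "KF147", "SK11")
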