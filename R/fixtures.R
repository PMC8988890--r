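#' Packaged summary tables
#'
#' Small plain-text tables shipped with the package: published summary
#' statistics of the germplasm screening and feeding study that several
#' analyses take as inputs (per-accession and per-subject raw data were not
#' deposited).
#'
#' Available tables:
#' \describe{
#'   \item{`trait_ranges`}{19 quantitative traits: range, mean, variance and
#'     mean-comparison p-value in the core collection (n = 623) and the
#'     selected diversity panel (n = 350).}
#'   \item{`gpa_descriptives`}{Grain phytic acid descriptive statistics by
#'     season and accession set.}
#'   \item{`genetic_parameters`}{Printed variance components (GV/PV/EV) and
#'     derived statistics by season and accession set.}
#'   \item{`subject_baseline`}{Baseline characteristics (mean, SD, range) of
#'     the 10 feeding-study subjects.}
#'   \item{`meal_composition`}{Grain composition and test-meal iron of the
#'     two selected accessions (GE 2358 low, GE 1004 high phytic acid).}
#'   \item{`absorption_summary`}{Geometric mean and range of fractional iron
#'     absorption for the two test meals.}
#' }
#'
#' @param name Table name (see above).
#' @return data.frame.
#' @export
millet_table <- function(name = c("trait_ranges", "gpa_descriptives",
                                  "genetic_parameters", "subject_baseline",
                                  "meal_composition", "absorption_summary")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "phytofer",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
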