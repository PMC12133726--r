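# Bundled per-subject reference index tables from a published 14-subject
# lower-limb motor-imagery cohort, used to validate the summary-table and
# correlation machinery and as calibration targets for the synthetic
# generator defaults.

#' Reference cohort index tables
#'
#' Per-subject attention-index values (alpha ERD at Cz paired with either
#' the F4 alpha-modulation index or the theta/beta ratio, per condition)
#' from a 14-subject lower-limb motor-imagery study. These are the group
#' statistics the synthetic generator defaults are calibrated to, and the
#' standard inputs for exercising [summary_stats()], [pearson_r()] and
#' [build_summary_table()].
#'
#' Note the two tables' quirks, reproduced as printed: the ERD columns
#' differ for subjects S11-S14 between the tables, and the second table's
#' published ERD group mean matches the first table's column rather than
#' its own; [build_summary_table()] recomputes summary rows from the
#' per-subject values it is given.
#'
#' @param metrics `c("erd", "ami")` or `c("erd", "tbr")`, selecting the
#'   table.
#' @return A tidy tibble: `subject`, `condition`, and the two metric
#'   columns (suitable for [build_summary_table()]).
#' @export
reference_indices <- function(metrics = c("erd", "ami")) {
  metrics <- match.arg(paste(metrics, collapse = "_"),
                       c("erd_ami", "erd_tbr"))
  path <- system.file("extdata", paste0("reference_", metrics, ".tsv"),
                      package = "attnmi", mustWork = TRUE)
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  tidyr::pivot_longer(tibble::as_tibble(wide), -"subject",
                      names_to = c(".value", "condition"),
                      names_sep = "_")
}
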