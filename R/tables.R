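#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory; empty to
#'   list the directory.
#' @return A file path.
#' @export
metacrispr_extdata <- function(file = "") {
  system.file("extdata", file, package = "metacrispr", mustWork = nzchar(file))
}

#' Bundled spacer copy-number survey
#'
#' Copies/uL of the CRISPR3 and CRISPR1 spacers, plus bacterial and human
#' DNA concentrations, for a typing survey of 10 individuals: 22 hypothenar
#' skin swabs, 11 saliva samples and 4 keyboard ("object") swabs. Sub-LOQ
#' values are flagged (`below_loq`) and one skin sample shows no CRISPR1
#' amplification (`nd`).
#'
#' @param loq Limit of quantification passed to [read_copy_table()].
#' @return A long tibble, one row per sample x locus.
#' @export
#' @examples
#' summarize_copies(survey_copy_table(), "skin", "CRISPR3")
survey_copy_table <- function(loq = 100) {
  read_copy_table(metacrispr_extdata("spacer_copy_survey.tsv"), loq = loq)
}

#' Bundled typing-vs-STR comparison tables
#'
#' Per-sample Bray-Curtis distances of eight neat (or 1:10 diluted)
#' hypothenar skin swabs to the donor's reference saliva, at both CRISPR
#' loci, together with the number of correctly typed loci out of the
#' 21-locus autosomal STR panel.
#'
#' @param dilution `"neat"` or `"diluted"`.
#' @return A tibble with columns `sample_id`, `individual`, `site`,
#'   `bc_crispr3`, `bc_crispr1`, `correct_loci`.
#' @export
typing_comparison_table <- function(dilution = c("neat", "diluted")) {
  dilution <- match.arg(dilution)
  file <- if (dilution == "neat") "typing_neat_comparison.tsv"
          else "typing_diluted_comparison.tsv"
  readr::read_tsv(metacrispr_extdata(file), show_col_types = FALSE,
                  progress = FALSE)
}

#' Household membership of the survey individuals
#'
#' Three cohabiting couples shared households; the remaining donors are
#' single-member households.
#'
#' @return A tibble with `individual` and `household`.
#' @export
survey_households <- function() {
  tibble(
    individual = c("P04", "P07", "P08", "P09", "P11", "P12",
                   "P01", "P03", "P06", "P10"),
    household = c("H1", "H1", "H2", "H2", "H3", "H3",
                  "H4", "H5", "H6", "H7")
  )
}
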