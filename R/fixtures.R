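#' Path to a bundled data file
#'
#' @param file File name under the package's \code{extdata} directory;
#'   with no argument, lists the available files.
#' @return Full path (or vector of file names).
#' @export
palrank_extdata <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "palrank")))
  path <- system.file("extdata", file, package = "palrank")
  if (!nzchar(path)) stop("no bundled file '", file, "'", call. = FALSE)
  path
}

#' Worked-example clinical table: first-line targeted therapies
#'
#' Returns the bundled cohort of 21 first-line targeted-therapy records from
#' an advanced colorectal cancer study: per line, the administered targeted
#' drug, RECIST response, progression-free survival in months, the drug's
#' balanced efficiency score (BES) and its rank among the full drug database
#' evaluated for that patient, plus TNM staging and RAS mutation status.
#' All records are marked as observed progression events; the source did not
#' publish censoring flags, and this assumption is documented in the methods
#' vignette.
#'
#' @return Therapy-record \code{data.frame} (see \code{\link{read_clinical}}).
#' @export
first_line_therapy_records <- function() {
  read_clinical(palrank_extdata("table1_clinical.csv"))
}

#' Worked-example targeted drug database
#'
#' The nine targeted drugs administered in the worked-example cohort
#' (bevacizumab, aflibercept, bortezomib, cabozantinib, cetuximab,
#' crizotinib, panitumumab, regorafenib, denosumab) with their literature
#' molecular targets, translated to HGNC symbols through the bundled alias
#' table.
#'
#' @return Named list of \code{\link{drug}} objects.
#' @export
example_drug_db <- function() {
  load_drug_db(palrank_extdata("table3_drugs.tsv"))
}
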