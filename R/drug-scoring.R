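#' Construct a targeted drug
#'
#' @param name Drug name (unique within a database).
#' @param targets Character vector of HGNC target gene symbols, non-empty.
#' @param status \code{"approved"} or \code{"off_label"}.
#' @return Object of class \code{Drug}. Only inhibitor-type drugs (including
#'   neutralizing antibodies) are modeled; high target expression and target
#'   pathway activation predict benefit.
#' @export
drug <- function(name, targets, status = c("approved", "off_label")) {
  status <- match.arg(status)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  targets <- unique(targets[nzchar(targets)])
  if (length(targets) == 0L)
    stop("drug '", name, "' has an empty target list", call. = FALSE)
  structure(list(name = name, targets = targets, status = status,
                 action = "inhibitor"), class = "Drug")
}

#' Read a target-gene alias table
#'
#' Drug databases often name targets by protein (VEGF, TIE2, TrkA, ...) while
#' expression profiles are keyed by HGNC symbol. The alias table is a
#' two-column TSV (\code{alias}, \code{hgnc_symbol}); the bundled copy covers
#' the aliases used by the shipped drug database and can be replaced.
#'
#' @param path Path to the alias TSV; defaults to the bundled table.
#' @return Named character vector alias -> HGNC symbol.
#' @export
read_alias_table <- function(path = palrank_extdata("target_aliases.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$hgnc_symbol, tab$alias)
}

#' Load a targeted-drug database
#'
#' Reads a tab-delimited file with header columns \code{drug},
#' \code{targets} (comma-separated) and \code{status}, applies the alias
#' table to translate protein names to HGNC symbols, and returns one
#' \code{\link{drug}} per row. Duplicate drug names and empty target lists
#' are errors.
#'
#' @param path Path to the drug database TSV.
#' @param aliases Named character vector alias -> HGNC symbol, or \code{NULL}
#'   to skip aliasing.
#' @return Named list of \code{Drug} objects.
#' @export
load_drug_db <- function(path, aliases = read_alias_table()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$drug))
    stop("duplicate drug name in ", path, ": '",
         tab$drug[duplicated(tab$drug)][1], "'", call. = FALSE)
  drugs <- lapply(seq_len(nrow(tab)), function(i) {
    spec <- as.character(tab$targets[i])
    if (is.na(spec)) spec <- ""
    targets <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
    if (!is.null(aliases)) {
      hit <- targets %in% names(aliases)
      targets[hit] <- aliases[targets[hit]]
    }
    drug(tab$drug[i], targets, tab$status[i])
  })
  stats::setNames(drugs, tab$drug)
}

#' Balanced efficiency score for one drug
#'
#' Combines the two ingredients of expression-based drug scoring for
#' inhibitor drugs: expression of the drug's target genes, and activation of
#' the molecular pathways containing those targets. With weights
#' \code{alpha}, \code{beta}:
#' \deqn{BES = \alpha \sum_{g \in targets} \log_{10}(CNR_g) +
#'       \beta \sum_{p : targets \cap p \neq \emptyset}
#'       PAL_p \cdot |targets \cap p| / |p|}
#' Only targets measured in the CNR vector enter the first sum; the pathway
#' term weighs each target-containing pathway's PAL by the fraction of its
#' member genes that are targets. Positive scores predict clinical benefit.
#' The scorer is deliberately pluggable: pass a different function as
#' \code{scorer} to \code{\link{bes_table}} to swap the formula.
#'
#' @param cnr A \code{CnrVector} for the patient.
#' @param pals Named numeric vector of PAL values for the patient (one row of
#'   \code{\link{pal_matrix}} works).
#' @param pathways List of \code{Pathway} objects matching \code{names(pals)}.
#' @param dr A \code{Drug}.
#' @param weights Numeric \code{c(alpha, beta)}, default \code{c(1, 1)}.
#' @return Numeric BES; \code{NA} with attribute \code{undefined = TRUE} when
#'   no target is measured and no pathway contains a target.
#' @export
compute_bes <- function(cnr, pals, pathways, dr, weights = c(1, 1)) {
  stopifnot(inherits(cnr, "CnrVector"), inherits(dr, "Drug"),
            length(weights) == 2L)
  alpha <- weights[1]; beta <- weights[2]
  measured <- intersect(dr$targets, names(cnr$cnr))
  expr_term <- if (length(measured)) sum(log10(cnr$cnr[measured])) else 0
  pw_term <- 0
  any_pathway <- FALSE
  for (pw in pathways) {
    hit <- intersect(dr$targets, names(pw$members))
    if (length(hit) == 0L) next
    any_pathway <- TRUE
    if (!pw$pathway_id %in% names(pals)) next
    pal <- pals[[pw$pathway_id]]
    if (is.na(pal)) next
    pw_term <- pw_term + pal * length(hit) / length(pw$members)
  }
  if (length(measured) == 0L && !any_pathway) {
    warning("BES undefined for drug '", dr$name, "': no measured target and ",
            "no target-containing pathway", call. = FALSE)
    return(structure(NA_real_, undefined = TRUE))
  }
  alpha * expr_term + beta * pw_term
}

#' BES for every drug in a database
#'
#' @param cnr A \code{CnrVector}.
#' @param pals Named numeric PAL vector for the same sample.
#' @param pathways List of \code{Pathway} objects.
#' @param drugs List of \code{Drug} objects (see \code{\link{load_drug_db}}).
#' @param weights Passed to the scorer.
#' @param scorer Scoring function with the signature of
#'   \code{\link{compute_bes}}.
#' @return Named numeric vector of scores (NA where undefined).
#' @export
bes_table <- function(cnr, pals, pathways, drugs, weights = c(1, 1),
                      scorer = compute_bes) {
  vapply(drugs, function(d)
    as.numeric(suppressWarnings(scorer(cnr, pals, pathways, d, weights))),
    numeric(1))
}

#' Rank drugs by balanced efficiency score
#'
#' Rank 1 is the highest BES; ties are broken lexicographically by drug name
#' so the ranking is a strict total order. A drug is predicted effective only
#' for strictly positive BES (the threshold is strict: BES = 0 is predicted
#' ineffective). Undefined (NA) scores are dropped with a warning.
#'
#' @param scores Named numeric vector of BES values.
#' @param sample_id Optional sample identifier stored in the card.
#' @return A \code{DrugScoreCard}: \code{data.frame} with columns
#'   \code{sample_id}, \code{drug}, \code{bes}, \code{rank},
#'   \code{predicted_effective}, sorted by rank.
#' @export
rank_drugs <- function(scores, sample_id = NA_character_) {
  if (length(scores) == 0L) stop("no scored drug to rank", call. = FALSE)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be named by drug", call. = FALSE)
  if (anyNA(scores)) {
    warning(sum(is.na(scores)), " undefined score(s) dropped from ranking",
            call. = FALSE)
    scores <- scores[!is.na(scores)]
    if (length(scores) == 0L) stop("no defined score to rank", call. = FALSE)
  }
  ord <- order(-scores, names(scores), method = "radix")
  card <- data.frame(sample_id = sample_id,
                     drug = names(scores)[ord],
                     bes = unname(scores[ord]),
                     rank = seq_along(ord),
                     predicted_effective = unname(scores[ord] > 0),
                     stringsAsFactors = FALSE)
  class(card) <- c("DrugScoreCard", "data.frame")
  card
}

#' Write a per-sample drug score card as CSV
#'
#' @param card A \code{DrugScoreCard}.
#' @param path Output path.
#' @export
write_score_card <- function(card, path) {
  utils::write.csv(as.data.frame(card), path, row.names = FALSE)
  invisible(path)
}
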