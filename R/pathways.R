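#' Construct a pathway with signed gene roles
#'
#' A pathway is a named gene set in which each member gene carries an
#' activator/repressor role (ARR): +1 for a clear activator of the pathway,
#' -1 for a clear inhibitor, +0.5 / -0.5 for genes that are rather activators
#' or rather inhibitors, and 0 for members with ambiguous or unknown role.
#'
#' @param pathway_id Single character identifier.
#' @param name Human-readable pathway name (defaults to the id).
#' @param members Named numeric vector of ARR values, names are gene symbols.
#' @return An object of class \code{Pathway}.
#' @export
pathway <- function(pathway_id, members, name = pathway_id) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  if (length(members) == 0L)
    stop("pathway '", pathway_id, "' has no member genes", call. = FALSE)
  if (is.null(names(members)) || any(!nzchar(names(members))))
    stop("pathway members must be named by gene symbol", call. = FALSE)
  if (anyDuplicated(names(members)))
    stop("duplicate member gene in pathway '", pathway_id, "'", call. = FALSE)
  if (!all(members %in% c(-1, -0.5, 0, 0.5, 1)))
    stop("ARR values must lie in {-1, -0.5, 0, 0.5, 1} (pathway '",
         pathway_id, "')", call. = FALSE)
  structure(list(pathway_id = pathway_id, name = name,
                 members = stats::setNames(as.numeric(members), names(members))),
            class = "Pathway")
}

#' @export
print.Pathway <- function(x, ...) {
  cat(sprintf("<Pathway> %s: %d genes (%d activators, %d repressors, %d neutral)\n",
              x$pathway_id, length(x$members), sum(x$members > 0),
              sum(x$members < 0), sum(x$members == 0)))
  invisible(x)
}

#' Read pathway definitions
#'
#' Two formats are accepted. The extended tab-delimited format has a header
#' and columns \code{pathway_id}, \code{pathway_name}, \code{gene_symbol},
#' \code{arr}, one member gene per row. Plain GMT
#' (\code{name<TAB>description<TAB>gene...}) is also accepted, in which case
#' every member receives ARR = +1.
#'
#' @param path Path to the pathway file.
#' @return List of \code{\link{pathway}} objects, in file order.
#' @export
read_pathways <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  cols <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (identical(tolower(cols[1:2]), c("pathway_id", "pathway_name"))) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    split_rows <- split(tab, factor(tab$pathway_id, levels = unique(tab$pathway_id)))
    lapply(split_rows, function(rows)
      pathway(rows$pathway_id[1],
              stats::setNames(rows$arr, rows$gene_symbol),
              name = rows$pathway_name[1]))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      if (length(f) < 3L)
        stop("GMT line needs name, description and at least one gene", call. = FALSE)
      genes <- f[-(1:2)]
      pathway(f[1], stats::setNames(rep(1, length(genes)), genes), name = f[1])
    })
  }
}

#' Write pathways in the extended tab-delimited format
#'
#' @param pathways List of \code{Pathway} objects.
#' @param path Output path.
#' @export
write_pathways <- function(pathways, path) {
  rows <- do.call(rbind, lapply(pathways, function(p)
    data.frame(pathway_id = p$pathway_id, pathway_name = p$name,
               gene_symbol = names(p$members), arr = unname(p$members))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
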