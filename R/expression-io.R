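#' Construct an expression profile
#'
#' An \code{ExpressionProfile} holds one sample's gene-level expression as a
#' named non-negative numeric vector keyed by gene symbol, together with the
#' sample's role in a tumor-versus-normal design and optional library QC
#' metadata.
#'
#' @param sample_id Single character string identifying the sample.
#' @param values Named numeric vector of non-negative expression values; names
#'   are gene symbols and must be unique.
#' @param role One of \code{"tumor"}, \code{"normal"} or \code{NA}.
#' @param qc Optional list with elements \code{total_reads} and
#'   \code{uniquely_gene_mapped_reads}.
#' @return An object of class \code{ExpressionProfile}.
#' @export
expression_profile <- function(sample_id, values, role = NA_character_, qc = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("expression values must be named by gene symbol", call. = FALSE)
  if (anyDuplicated(names(values)))
    stop("duplicate gene symbols in profile '", sample_id, "'", call. = FALSE)
  values <- stats::setNames(as.numeric(values), names(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0 in profile '", sample_id, "'",
         call. = FALSE)
  if (!is.na(role) && !role %in% c("tumor", "normal"))
    stop("role must be 'tumor', 'normal' or NA", call. = FALSE)
  structure(list(sample_id = sample_id, values = values, role = role, qc = qc),
            class = "ExpressionProfile")
}

#' @export
print.ExpressionProfile <- function(x, ...) {
  cat(sprintf("<ExpressionProfile> %s (%s), %d genes\n", x$sample_id,
              ifelse(is.na(x$role), "role unknown", x$role), length(x$values)))
  invisible(x)
}

#' Read an Ensembl-to-HGNC gene identifier map
#'
#' Reads a two-column tab-delimited file (\code{ensembl_id}, \code{hgnc_symbol});
#' a header row is accepted and detected by name. Many Ensembl identifiers may
#' map to the same symbol; counts for those are summed at mapping time.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping Ensembl identifier to HGNC symbol.
#' @export
read_gene_id_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("gene map must have two tab-delimited columns", call. = FALSE)
  if (tolower(tab[1, 1]) %in% c("ensembl_id", "ensembl"))
    tab <- tab[-1L, , drop = FALSE]
  if (any(!nzchar(tab[[2]])))
    stop("gene map contains empty HGNC symbols", call. = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("gene map assigns multiple symbols to one Ensembl id", call. = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}

# Collapse Ensembl-keyed counts onto HGNC symbols, summing collisions.
# Unmapped ids are dropped; the dropped count is attached as an attribute.
map_to_hgnc <- function(values, id_map) {
  sym <- id_map[names(values)]
  keep <- !is.na(sym)
  n_unmapped <- sum(!keep)
  if (n_unmapped > 0L)
    warning(n_unmapped, " gene id(s) absent from the id map were dropped",
            call. = FALSE)
  out <- vapply(split(values[keep], sym[keep]), sum, numeric(1))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Read gene-level count tables
#'
#' Accepts two dialects: the per-sample STAR \code{ReadsPerGene.out.tab} format
#' (four columns, no header, leading \code{N_*} summary rows) and a plain
#' genes-by-samples count matrix (header row of sample names, first column of
#' gene identifiers). STAR summary rows are stripped from the expression values
#' and folded into the profile's QC metadata; the uniquely-gene-mapped read
#' count is the sum over gene rows of the selected strand column.
#'
#' @param path Path to the count file.
#' @param id_map Optional named character vector (see
#'   \code{\link{read_gene_id_map}}); when supplied, counts of Ensembl ids
#'   sharing an HGNC symbol are summed.
#' @param star_strand Which STAR GeneCounts column to use:
#'   \code{"unstranded"} (default), \code{"forward"} or \code{"reverse"}.
#' @param role Role assigned to the returned profiles.
#' @return List of \code{\link{expression_profile}} objects, one per sample.
#' @export
read_gene_counts <- function(path, id_map = NULL,
                             star_strand = c("unstranded", "forward", "reverse"),
                             role = NA_character_) {
  star_strand <- match.arg(star_strand)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty count file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_star <- length(fields[[1]]) == 4L &&
    any(grepl("^N_", vapply(fields, `[`, "", 1L)))
  profiles <- if (is_star) {
    list(read_star_counts(fields, path, star_strand, role))
  } else {
    read_matrix_counts(fields, path, role)
  }
  if (!is.null(id_map)) {
    profiles <- lapply(profiles, function(p) {
      mapped <- map_to_hgnc(p$values, id_map)
      expression_profile(p$sample_id, c(mapped), role = p$role, qc = p$qc)
    })
  }
  profiles
}

read_star_counts <- function(fields, path, star_strand, role) {
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop("malformed STAR row ", bad[1], " in ", path, ": '",
         paste(fields[[bad[1]]], collapse = "\t"), "'", call. = FALSE)
  col <- c(unstranded = 2L, forward = 3L, reverse = 4L)[[star_strand]]
  ids <- vapply(fields, `[`, "", 1L)
  counts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", col)))
  if (anyNA(counts)) {
    bad <- which(is.na(counts))[1]
    stop("non-numeric count at row ", bad, " in ", path, ": '",
         paste(fields[[bad]], collapse = "\t"), "'", call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0)[1]
    stop("negative count at row ", bad, " in ", path, call. = FALSE)
  }
  summary_rows <- grepl("^N_", ids)
  qc_extra <- as.list(counts[summary_rows])
  names(qc_extra) <- ids[summary_rows]
  gene_counts <- stats::setNames(counts[!summary_rows], ids[!summary_rows])
  if (anyDuplicated(names(gene_counts)))
    stop("duplicate gene id in ", path, call. = FALSE)
  mapped <- sum(gene_counts)
  qc <- c(list(total_reads = mapped + sum(counts[summary_rows]),
               uniquely_gene_mapped_reads = mapped), qc_extra)
  sample_id <- sub("\\.[^.]*$", "", basename(path))
  expression_profile(sample_id, gene_counts, role = role, qc = qc)
}

read_matrix_counts <- function(fields, path, role) {
  header <- fields[[1]]
  if (length(header) < 2L)
    stop("count matrix needs a gene-id column and at least one sample column in ",
         path, call. = FALSE)
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample names in header of ", path, call. = FALSE)
  body <- fields[-1L]
  bad <- which(lengths(body) != length(header))
  if (length(bad))
    stop("malformed row ", bad[1] + 1L, " in ", path, ": expected ",
         length(header), " fields", call. = FALSE)
  ids <- vapply(body, `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate gene id in ", path, call. = FALSE)
  mat <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(body, `[`, -1L)))), ncol = length(samples), byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[1]
    stop("non-numeric count at row ", bad + 1L, " in ", path, ": '",
         paste(body[[bad]], collapse = "\t"), "'", call. = FALSE)
  }
  if (any(mat < 0)) {
    bad <- which(apply(mat < 0, 1L, any))[1]
    stop("negative count at row ", bad + 1L, " in ", path, call. = FALSE)
  }
  lapply(seq_along(samples), function(j)
    expression_profile(samples[j], stats::setNames(mat[, j], ids), role = role))
}

#' Write profiles as a genes-by-samples count matrix
#'
#' Inverse of the matrix dialect of \code{\link{read_gene_counts}}: a
#' read-write-read round trip is the identity on values.
#'
#' @param profiles List of \code{ExpressionProfile} objects sharing a gene
#'   universe.
#' @param path Output path (tab-delimited, UTF-8).
#' @export
write_gene_counts <- function(profiles, path) {
  stopifnot(length(profiles) >= 1L)
  genes <- names(profiles[[1]]$values)
  mat <- vapply(profiles, function(p) {
    if (!identical(sort(names(p$values)), sort(genes)))
      stop("profiles do not share a gene universe", call. = FALSE)
    p$values[genes]
  }, numeric(length(genes)))
  df <- data.frame(gene_id = genes, mat, check.names = FALSE)
  colnames(df) <- c("gene_id", vapply(profiles, `[[`, "", "sample_id"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Library-quality check on uniquely gene-mapped reads
#'
#' A library passes when its uniquely gene-mapped read count reaches
#' \code{min_mapped}; the boundary is inclusive. Profiles lacking QC metadata
#' return status \code{"unknown"}, never a silent pass.
#'
#' @param profile An \code{ExpressionProfile}.
#' @param min_mapped Minimum uniquely gene-mapped reads (default 2.5 million).
#' @return Character scalar \code{"pass"}, \code{"fail"} or \code{"unknown"},
#'   with a \code{"reason"} attribute.
#' @export
qc_check_library <- function(profile, min_mapped = 2500000L) {
  qc <- profile$qc
  if (is.null(qc) || is.null(qc$uniquely_gene_mapped_reads)) {
    return(structure("unknown",
                     reason = "no uniquely_gene_mapped_reads in QC metadata"))
  }
  mapped <- qc$uniquely_gene_mapped_reads
  if (mapped >= min_mapped) {
    structure("pass", reason = sprintf("%.0f uniquely gene-mapped reads >= %.0f",
                                       mapped, min_mapped))
  } else {
    structure("fail", reason = sprintf("%.0f uniquely gene-mapped reads < %.0f",
                                       mapped, min_mapped))
  }
}

#' Median-of-ratios size-factor normalization
#'
#' Computes per-sample size factors against the per-gene geometric mean across
#' samples, using only genes with strictly positive counts in every sample
#' (genes whose geometric-mean reference would otherwise be zero are ignored
#' for factor estimation but retained in the output). Each profile is divided
#' by its factor. Genes present in some profiles only are treated as zero
#' where absent, with a warning.
#'
#' @param profiles List of at least two \code{ExpressionProfile} objects.
#' @return List of normalized profiles, with the numeric size factors attached
#'   as attribute \code{"size_factors"}.
#' @export
size_factor_normalize <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  universes <- lapply(profiles, function(p) names(p$values))
  genes <- sort(unique(unlist(universes)))
  if (!all(vapply(universes, function(u) length(u) == length(genes), logical(1))))
    warning("profiles differ in gene universe; missing genes treated as 0",
            call. = FALSE)
  mat <- matrix(vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(genes)), genes)
    v[names(p$values)] <- p$values
    v
  }, numeric(length(genes))), nrow = length(genes),
  dimnames = list(genes, NULL))
  usable <- apply(mat > 0, 1L, all)
  if (!any(usable))
    stop("no gene with positive counts in every sample; cannot normalize",
         call. = FALSE)
  log_ref <- rowMeans(log(mat[usable, , drop = FALSE]))
  factors <- apply(mat[usable, , drop = FALSE], 2L, function(col)
    stats::median(exp(log(col) - log_ref)))
  out <- lapply(seq_along(profiles), function(j) {
    p <- profiles[[j]]
    expression_profile(p$sample_id, p$values / factors[j], role = p$role, qc = p$qc)
  })
  attr(out, "size_factors") <- stats::setNames(
    factors, vapply(profiles, `[[`, "", "sample_id"))
  out
}
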