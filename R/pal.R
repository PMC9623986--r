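#' Build the geometric-mean normal reference profile
#'
#' The reference against which case-to-normal ratios are taken is the per-gene
#' geometric mean over the control (normal tissue) profiles, computed on the
#' offset-shifted scale: each control value has \code{offset} added before the
#' geometric mean, so that zero counts never produce a zero reference. Genes
#' whose shifted geometric mean is still not strictly positive (possible only
#' with \code{offset = 0}) are dropped with a warning.
#'
#' @param controls List of at least one \code{ExpressionProfile}; profiles
#'   must share a gene universe (the intersection is used, with a warning when
#'   universes differ).
#' @param offset Non-negative pseudo-expression added before ratios; default 1.
#' @return Object of class \code{ReferenceProfile}: a list with \code{values}
#'   (named positive numerics) and \code{n_controls}.
#' @export
build_reference <- function(controls, offset = 1) {
  if (length(controls) < 1L) stop("need at least one control profile", call. = FALSE)
  stopifnot(offset >= 0)
  genes <- Reduce(intersect, lapply(controls, function(p) names(p$values)))
  if (length(genes) == 0L)
    stop("control profiles share no genes", call. = FALSE)
  if (any(vapply(controls, function(p) length(p$values), integer(1)) != length(genes)))
    warning("control profiles differ in gene universe; using the intersection",
            call. = FALSE)
  mat <- vapply(controls, function(p) p$values[genes] + offset,
                numeric(length(genes)))
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, NULL))
  positive <- apply(mat > 0, 1L, all)
  if (!all(positive)) {
    warning(sum(!positive), " gene(s) with zero shifted expression dropped ",
            "from the reference", call. = FALSE)
    mat <- mat[positive, , drop = FALSE]
  }
  if (nrow(mat) == 0L)
    stop("no gene with positive shifted expression in all controls", call. = FALSE)
  values <- exp(rowMeans(log(mat)))
  structure(list(values = values, n_controls = length(controls), offset = offset),
            class = "ReferenceProfile")
}

#' Case-to-normal expression ratios for one tumor
#'
#' For each gene measured in both the tumor profile and the reference, the
#' case-to-normal ratio (CNR) is the tumor's offset-shifted expression divided
#' by the reference value. The offset is applied symmetrically: the reference
#' was built on the same shifted scale. Genes absent from either side are
#' omitted and counted.
#'
#' @param tumor An \code{ExpressionProfile}.
#' @param reference A \code{ReferenceProfile} from \code{\link{build_reference}}.
#' @param offset Non-negative offset; should match the one used for the
#'   reference (defaults to the reference's own offset).
#' @return Object of class \code{CnrVector}: list with \code{sample_id},
#'   \code{cnr} (named positive numerics) and \code{n_dropped}.
#' @export
compute_cnr <- function(tumor, reference, offset = reference$offset) {
  stopifnot(inherits(reference, "ReferenceProfile"), offset >= 0)
  genes <- intersect(names(tumor$values), names(reference$values))
  if (length(genes) == 0L)
    stop("no gene overlap between tumor '", tumor$sample_id,
         "' and the reference", call. = FALSE)
  cnr <- (tumor$values[genes] + offset) / reference$values[genes]
  nonpos <- cnr <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " gene(s) with non-positive ratio dropped for '",
            tumor$sample_id, "'", call. = FALSE)
    cnr <- cnr[!nonpos]
  }
  n_dropped <- length(tumor$values) - length(cnr)
  structure(list(sample_id = tumor$sample_id, cnr = cnr, n_dropped = n_dropped),
            class = "CnrVector")
}

#' Pathway activation level
#'
#' The pathway activation level (PAL) is the signed, role-weighted mean of
#' log10 case-to-normal ratios over a pathway's member genes:
#' \deqn{PAL_p = \sum_n ARR_{np} \log_{10}(CNR_n) / \sum_n |ARR_{np}|}
#' where ARR is the activator/repressor role. Members with ARR = 0 contribute
#' to neither sum; members not measured in the CNR vector are dropped from
#' both sums. When no measured member has a non-zero role the PAL is
#' undefined; 0 is returned with attribute \code{undefined = TRUE} so that
#' cohort-level matrix computations never abort, and a warning is emitted.
#'
#' @param cnr A \code{CnrVector}.
#' @param pw A \code{Pathway}.
#' @return Numeric PAL with attributes \code{coverage} (fraction of pathway
#'   members measured) and \code{undefined}.
#' @export
compute_pal <- function(cnr, pw) {
  stopifnot(inherits(cnr, "CnrVector"), inherits(pw, "Pathway"))
  arr <- pw$members
  measured <- names(arr)[names(arr) %in% names(cnr$cnr)]
  coverage <- length(measured) / length(arr)
  arr_m <- arr[measured]
  arr_m <- arr_m[arr_m != 0]
  if (length(arr_m) == 0L) {
    warning("PAL undefined for pathway '", pw$pathway_id, "' in sample '",
            cnr$sample_id, "' (no measured member with non-zero role)",
            call. = FALSE)
    return(structure(0, coverage = coverage, undefined = TRUE))
  }
  lg <- log10(cnr$cnr[names(arr_m)])
  structure(sum(arr_m * lg) / sum(abs(arr_m)),
            coverage = coverage, undefined = FALSE)
}

#' PAL matrix over a tumor cohort
#'
#' Applies \code{\link{compute_cnr}} and \code{\link{compute_pal}} to every
#' tumor and pathway. Row order follows the tumor list, column order the
#' pathway list.
#'
#' @param tumors List of \code{ExpressionProfile} objects.
#' @param reference A \code{ReferenceProfile}.
#' @param pathways List of \code{Pathway} objects.
#' @param offset Offset passed to \code{\link{compute_cnr}}.
#' @return Numeric matrix samples x pathways with attributes \code{coverage}
#'   and \code{undefined} (same shape).
#' @export
pal_matrix <- function(tumors, reference, pathways, offset = reference$offset) {
  ids <- vapply(tumors, `[[`, "", "sample_id")
  pids <- vapply(pathways, `[[`, "", "pathway_id")
  pal <- matrix(NA_real_, length(tumors), length(pathways),
                dimnames = list(ids, pids))
  cov <- pal
  undef <- matrix(FALSE, length(tumors), length(pathways),
                  dimnames = list(ids, pids))
  for (i in seq_along(tumors)) {
    cnr <- compute_cnr(tumors[[i]], reference, offset)
    for (j in seq_along(pathways)) {
      v <- suppressWarnings(compute_pal(cnr, pathways[[j]]))
      pal[i, j] <- as.numeric(v)
      cov[i, j] <- attr(v, "coverage")
      undef[i, j] <- attr(v, "undefined")
    }
  }
  structure(pal, coverage = cov, undefined = undef)
}

#' Rank pathways by mean PAL difference between outcome groups
#'
#' Computes, per pathway, the difference between the mean PAL in the poor
#' prognosis group and the mean PAL in the favorable prognosis group, and
#' sorts pathways by the signed difference (most poor-prognosis-activated
#' first). Swapping the group labels flips every sign.
#'
#' @param pal Matrix from \code{\link{pal_matrix}} (samples x pathways).
#' @param groups Named character vector mapping sample id to \code{"poor"} or
#'   \code{"favorable"}; both groups must be non-empty.
#' @param top_k Optional integer: return only the \code{top_k} most positive
#'   and \code{top_k} most negative pathways.
#' @return \code{data.frame} with columns \code{pathway_id},
#'   \code{mean_pal_poor}, \code{mean_pal_favorable}, \code{difference},
#'   sorted by decreasing difference.
#' @export
pal_group_difference <- function(pal, groups, top_k = NULL) {
  groups <- groups[rownames(pal)]
  if (anyNA(groups)) stop("groups missing for some samples", call. = FALSE)
  if (!all(groups %in% c("poor", "favorable")))
    stop("groups must be 'poor' or 'favorable'", call. = FALSE)
  poor <- pal[groups == "poor", , drop = FALSE]
  fav <- pal[groups == "favorable", , drop = FALSE]
  if (nrow(poor) == 0L || nrow(fav) == 0L)
    stop("both prognosis groups must be non-empty", call. = FALSE)
  out <- data.frame(pathway_id = colnames(pal),
                    mean_pal_poor = colMeans(poor),
                    mean_pal_favorable = colMeans(fav),
                    row.names = NULL)
  out$difference <- out$mean_pal_poor - out$mean_pal_favorable
  out <- out[order(-out$difference), ]
  rownames(out) <- NULL
  if (!is.null(top_k) && nrow(out) > 2L * top_k)
    out <- out[c(seq_len(top_k), nrow(out) - rev(seq_len(top_k)) + 1L), ]
  out
}

#' Write a PAL matrix as CSV
#'
#' @param pal Matrix from \code{\link{pal_matrix}}.
#' @param path Output path (samples in rows, pathways in columns).
#' @export
write_pal_matrix <- function(pal, path) {
  utils::write.csv(data.frame(sample_id = rownames(pal), pal,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
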