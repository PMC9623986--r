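#' Dichotomize RECIST response into responder / non-responder
#'
#' Progressive disease is a non-responder; stable disease, partial response
#' and complete response count as responders (control over disease).
#' Abbreviations PD/SD/PR/CR are accepted alongside the full names.
#'
#' @param response Character vector of RECIST categories.
#' @return Character vector of \code{"responder"} / \code{"non_responder"}.
#' @export
dichotomize_response <- function(response) {
  key <- tolower(trimws(response))
  map <- c("progressive disease" = "non_responder", "pd" = "non_responder",
           "stable disease" = "responder", "sd" = "responder",
           "partial response" = "responder", "pr" = "responder",
           "complete response" = "responder", "cr" = "responder")
  out <- map[key]
  if (anyNA(out))
    stop("unknown RECIST category: '", response[is.na(out)][1], "'",
         call. = FALSE)
  unname(out)
}

#' ROC area under the curve by pairwise comparison
#'
#' Computes the probability that a randomly chosen responder outscores a
#' randomly chosen non-responder, with tied pairs credited 0.5 — the
#' Mann-Whitney U statistic divided by the number of pairs. For rank-based
#' evaluation pass negated ranks (lower rank = better prediction).
#'
#' @param scores Numeric vector.
#' @param labels Logical vector (TRUE = responder) or the output of
#'   \code{\link{dichotomize_response}}.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "responder"
  stopifnot(is.logical(labels), length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both responder and non-responder classes are required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kaplan-Meier curves with group medians
#'
#' Product-limit estimates per group. The median survival reported is the
#' first time at which the estimated survival drops to 0.5 or below, and is
#' undefined (NA) when the curve never reaches 0.5.
#'
#' @param records \code{data.frame} with columns \code{pfs_months} and
#'   \code{event_observed} (logical or 0/1).
#' @param groups Vector of group labels, one per record; every group must be
#'   non-empty.
#' @return Object of class \code{km_curve}: named list per group with a step
#'   \code{data.frame(time, n_risk, n_event, n_censor, surv)} and element
#'   \code{median}.
#' @export
km_curve <- function(records, groups) {
  stopifnot(nrow(records) == length(groups))
  groups <- as.character(groups)
  fit <- survival::survfit(
    survival::Surv(records$pfs_months, as.integer(records$event_observed)) ~ g,
    data = data.frame(g = groups))
  out <- list()
  if (is.null(fit$strata)) {
    strata_id <- rep(unique(groups), length(fit$time))
  } else {
    strata_id <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  for (g in unique(groups)) {
    sel <- strata_id == g
    steps <- data.frame(time = fit$time[sel], n_risk = fit$n.risk[sel],
                        n_event = fit$n.event[sel], n_censor = fit$n.censor[sel],
                        surv = fit$surv[sel])
    reached <- steps$time[steps$surv <= 0.5]
    out[[g]] <- list(steps = steps,
                     median = if (length(reached)) min(reached) else NA_real_)
  }
  structure(out, class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square comparing two survival
#' samples; invariant under swapping the group labels.
#'
#' @param group_a,group_b \code{data.frame}s (or 2-column matrices) with
#'   columns \code{time} and \code{event}.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
logrank_test <- function(group_a, group_b) {
  ga <- as.data.frame(group_a); gb <- as.data.frame(group_b)
  colnames(ga) <- colnames(gb) <- c("time", "event")
  if (nrow(ga) == 0L || nrow(gb) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(ga$event) + sum(gb$event) == 0)
    stop("log-rank test requires at least one event", call. = FALSE)
  d <- rbind(cbind(ga, g = 0L), cbind(gb, g = 1L))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit with convergence flagging
#'
#' Partial-likelihood maximum-likelihood fit (Efron tie handling by default)
#' for one or more covariates. Perfect separation / monotone likelihood is
#' detected from the coxph infinite-coefficient diagnostic and flagged in the
#' result rather than returned silently.
#'
#' @param time Numeric event/censoring times.
#' @param event Logical or 0/1 event indicators.
#' @param covariates \code{data.frame} (or vector, coerced to one column) of
#'   covariates; constant covariates are an error.
#' @param ties Tie handling, \code{"efron"} (default) or \code{"breslow"}.
#' @return \code{data.frame} with one row per coefficient: \code{term},
#'   \code{coef}, \code{hr}, \code{ci_lo}, \code{ci_hi}, \code{p}; attribute
#'   \code{converged} is FALSE when the fit is degenerate.
#' @export
cox_ph <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (!is.data.frame(covariates))
    covariates <- data.frame(group = covariates)
  stopifnot(length(time) == nrow(covariates), length(event) == length(time))
  if (sum(as.integer(event)) == 0)
    stop("Cox fit requires at least one observed event", call. = FALSE)
  constant <- vapply(covariates, function(v) length(unique(v)) < 2L, logical(1))
  if (any(constant))
    stop("constant covariate(s): ", paste(names(covariates)[constant],
                                          collapse = ", "), call. = FALSE)
  d <- cbind(data.frame(.time = time, .event = as.integer(event)), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lo = s$conf.int[, "lower .95"],
                    ci_hi = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  if (!converged)
    warning("Cox fit did not converge (monotone likelihood / separation); ",
            "result flagged", call. = FALSE)
  attr(out, "converged") <- converged
  out
}

#' Median-split survival screen over a feature matrix
#'
#' For each feature (gene expression or pathway activation), samples are
#' split at the feature's median — values strictly greater than the median go
#' to the high group, values equal to the median to the low group — and the
#' two groups are compared with a univariate Cox model and a log-rank test.
#' Constant features are skipped with a flag. Following common practice for
#' such screens, raw log-rank p-values are thresholded without multiplicity
#' correction.
#'
#' @param feature_matrix Numeric matrix samples x features, rownames matching
#'   \code{records} order is the caller's responsibility (row i of the matrix
#'   is record i).
#' @param records \code{data.frame} with \code{pfs_months} and
#'   \code{event_observed}; at least 4 rows.
#' @param p_threshold Significance threshold for the \code{significant}
#'   attribute subset (default 0.05).
#' @return \code{data.frame} with columns \code{feature}, \code{hr},
#'   \code{logrank_p}, \code{n_high}, \code{n_low}, \code{skipped}; attribute
#'   \code{significant} holds the non-skipped rows with
#'   \code{logrank_p < p_threshold}.
#' @export
median_split_screen <- function(feature_matrix, records, p_threshold = 0.05) {
  stopifnot(nrow(feature_matrix) == nrow(records), nrow(records) >= 4L)
  time <- records$pfs_months
  event <- as.integer(records$event_observed)
  res <- lapply(colnames(feature_matrix), function(f) {
    x <- feature_matrix[, f]
    high <- x > stats::median(x)
    if (all(high) || !any(high))
      return(data.frame(feature = f, hr = NA_real_, logrank_p = NA_real_,
                        n_high = sum(high), n_low = sum(!high), skipped = TRUE))
    fit <- suppressWarnings(cox_ph(time, event, data.frame(high = as.integer(high))))
    lr <- logrank_test(data.frame(time = time[!high], event = event[!high]),
                       data.frame(time = time[high], event = event[high]))
    data.frame(feature = f, hr = fit$hr[1], logrank_p = lr$p_value,
               n_high = sum(high), n_low = sum(!high), skipped = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "significant") <-
    out[!out$skipped & out$logrank_p < p_threshold, , drop = FALSE]
  out
}

#' Random permutation test for multi-set overlap
#'
#' Tests whether the overlap among several observed gene or pathway sets is
#' larger than expected by chance. In each iteration, a random subset of the
#' same size as each observed set is drawn without replacement from that
#' set's universe; the sampled sets are intersected; the p-value is the
#' fraction of iterations whose intersection is at least as large as the
#' observed one (so an observed overlap of 0 gives p = 1).
#'
#' @param observed_sets List of character vectors (typically 3), each a
#'   subset of the corresponding universe.
#' @param universes List of character vectors, same length as
#'   \code{observed_sets}.
#' @param n_iterations Number of random intersections (default 10000).
#' @param seed Optional integer seed, recorded in the result.
#' @return Object of class \code{OverlapTestResult}: list with
#'   \code{observed_overlap}, \code{n_iterations}, \code{n_at_least_as_large},
#'   \code{p_value} and \code{seed}.
#' @export
permutation_overlap_test <- function(observed_sets, universes,
                                     n_iterations = 10000L, seed = NULL) {
  stopifnot(length(observed_sets) == length(universes),
            length(observed_sets) >= 2L)
  for (i in seq_along(observed_sets)) {
    if (!all(observed_sets[[i]] %in% universes[[i]]))
      stop("observed set ", i, " is not a subset of its universe", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  observed <- length(Reduce(intersect, observed_sets))
  sizes <- lengths(observed_sets)
  hits <- 0L
  for (it in seq_len(n_iterations)) {
    draw <- Reduce(intersect, lapply(seq_along(universes), function(i)
      sample(universes[[i]], sizes[i])))
    if (length(draw) >= observed) hits <- hits + 1L
  }
  structure(list(observed_overlap = observed, n_iterations = n_iterations,
                 n_at_least_as_large = hits, p_value = hits / n_iterations,
                 seed = seed),
            class = "OverlapTestResult")
}

#' @export
print.OverlapTestResult <- function(x, ...) {
  cat(sprintf("Permutation overlap test: observed %d, p = %.4g (%d/%d draws)\n",
              x$observed_overlap, x$p_value, x$n_at_least_as_large,
              x$n_iterations))
  invisible(x)
}

#' Read therapy records from a clinical CSV
#'
#' Expected columns: \code{patient_id}, \code{sample_id}, \code{line_number},
#' \code{drug}, \code{response} (RECIST vocabulary), \code{pfs_months},
#' \code{event_observed}; optional \code{bes}, \code{rank} and covariates.
#'
#' @param path CSV path.
#' @return \code{data.frame} of therapy records with a
#'   \code{dichotomized} column added.
#' @export
read_clinical <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "sample_id", "line_number", "drug", "response",
              "pfs_months", "event_observed")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(rec$pfs_months <= 0))
    stop("pfs_months must be positive", call. = FALSE)
  rec$dichotomized <- dichotomize_response(rec$response)
  rec
}

#' Evaluate drug score cards against clinical outcomes
#'
#' Joins therapy records to score-card entries (by sample and drug), applies
#' an optional subset filter, and summarizes predictive performance: class
#' counts, ROC AUC of the BES and of the negated rank, a univariate Cox model
#' and log-rank test comparing the BES > 0 and BES <= 0 groups, and
#' Kaplan-Meier medians per group. Records whose \code{bes}/\code{rank}
#' columns are already filled (as in archival clinical tables) need no cards.
#'
#' @param cards List of \code{DrugScoreCard}s, or \code{NULL} when the
#'   records already carry \code{bes} and \code{rank}.
#' @param records Therapy records (see \code{\link{read_clinical}}).
#' @param subset Optional named list of filters applied before evaluation,
#'   e.g. \code{list(line_number = 1, drug = "bevacizumab")}.
#' @param bes_threshold Threshold separating predicted-effective from
#'   predicted-ineffective (default 0, strict).
#' @return Object of class \code{drug_eval_report} (a list).
#' @export
evaluate_score_card <- function(cards = NULL, records, subset = NULL,
                                bes_threshold = 0) {
  rec <- records
  if (!is.null(cards)) {
    allcards <- do.call(rbind, lapply(cards, as.data.frame))
    idx <- match(paste(rec$sample_id, rec$drug),
                 paste(allcards$sample_id, allcards$drug))
    if (anyNA(idx))
      stop("record(s) with no matching score-card entry: ",
           paste(utils::head(paste0(rec$sample_id[is.na(idx)], "/",
                                    rec$drug[is.na(idx)]), 5L),
                 collapse = ", "), call. = FALSE)
    rec$bes <- allcards$bes[idx]
    rec$rank <- allcards$rank[idx]
  }
  if (is.null(rec$bes) || is.null(rec$rank))
    stop("records carry no bes/rank and no cards were supplied", call. = FALSE)
  for (f in names(subset)) {
    if (!f %in% names(rec)) stop("unknown subset field '", f, "'", call. = FALSE)
    rec <- rec[rec[[f]] %in% subset[[f]], , drop = FALSE]
  }
  if (nrow(rec) == 0L)
    stop("subset selects no therapy record", call. = FALSE)
  if (is.null(rec$dichotomized)) rec$dichotomized <- dichotomize_response(rec$response)
  lab <- rec$dichotomized == "responder"
  grp <- ifelse(rec$bes > bes_threshold, "bes_positive", "bes_nonpositive")
  both_classes <- length(unique(lab)) == 2L
  auc_bes <- if (both_classes) roc_auc(rec$bes, lab) else NA_real_
  auc_rank <- if (both_classes) roc_auc(-rec$rank, lab) else NA_real_
  cox <- km <- lr <- NULL
  if (length(unique(grp)) == 2L) {
    cox <- cox_ph(rec$pfs_months, rec$event_observed,
                  data.frame(bes_positive = as.integer(grp == "bes_positive")))
    km <- km_curve(rec, grp)
    pos <- grp == "bes_positive"
    lr <- logrank_test(
      data.frame(time = rec$pfs_months[!pos],
                 event = as.integer(rec$event_observed[!pos])),
      data.frame(time = rec$pfs_months[pos],
                 event = as.integer(rec$event_observed[pos])))
  }
  structure(list(
    n = nrow(rec),
    n_responders = sum(lab),
    n_non_responders = sum(!lab),
    auc_bes = auc_bes,
    auc_rank = auc_rank,
    bes_threshold = bes_threshold,
    n_bes_positive = sum(grp == "bes_positive"),
    n_bes_nonpositive = sum(grp == "bes_nonpositive"),
    cox_bes_positive = cox,
    logrank = lr,
    km_median = if (!is.null(km)) lapply(km, `[[`, "median") else NULL,
    subset = subset,
    records = rec
  ), class = "drug_eval_report")
}

#' @export
print.drug_eval_report <- function(x, ...) {
  cat(sprintf("Drug score evaluation (n = %d therapy lines)\n", x$n))
  cat(sprintf("  responders / non-responders: %d / %d\n",
              x$n_responders, x$n_non_responders))
  if (!is.na(x$auc_rank))
    cat(sprintf("  ROC AUC (negated rank): %.3f\n", x$auc_rank))
  if (!is.na(x$auc_bes))
    cat(sprintf("  ROC AUC (BES):          %.3f\n", x$auc_bes))
  if (!is.null(x$cox_bes_positive))
    cat(sprintf("  Cox HR, BES > %g vs <=: %.3f [%.3f, %.3f], logrank p = %.2g\n",
                x$bes_threshold, x$cox_bes_positive$hr[1],
                x$cox_bes_positive$ci_lo[1], x$cox_bes_positive$ci_hi[1],
                x$logrank$p_value))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report A \code{drug_eval_report}.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  out <- report[c("n", "n_responders", "n_non_responders", "auc_bes",
                  "auc_rank", "bes_threshold", "n_bes_positive",
                  "n_bes_nonpositive")]
  if (!is.null(report$cox_bes_positive)) {
    out$cox_hr <- report$cox_bes_positive$hr[1]
    out$cox_ci <- c(report$cox_bes_positive$ci_lo[1],
                    report$cox_bes_positive$ci_hi[1])
    out$cox_p <- report$cox_bes_positive$p[1]
    out$logrank_p <- report$logrank$p_value
    out$km_median <- report$km_median
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
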