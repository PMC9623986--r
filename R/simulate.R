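#' Configuration for synthetic tumor/normal cohorts
#'
#' The generator emulates a small tumor-versus-normal RNA-seq study: each
#' gene's log10 expression is a shared baseline plus independent Gaussian
#' biological noise, tumors additionally receive planted log10 fold-changes
#' on genes selected per pathway, treatment response is drawn from a logistic
#' link on the per-patient drug score, and progression-free survival follows
#' a proportional-hazards exponential model on the score group with optional
#' independent exponential censoring.
#'
#' Defaults mirror a small archival-tissue cohort: 6 normal references, 21
#' treated tumors, baseline expression 100 counts, a responder fraction near
#' 43 percent at score zero, a 5-month median progression-free survival in
#' the unfavorable group, no censoring (progression observed for every
#' line), and a strong protective hazard ratio for the favorable score group.
#'
#' @param n_genes Number of simulated genes (pathway genes are always
#'   included in the universe).
#' @param n_normals,n_tumors Cohort sizes, strictly positive.
#' @param baseline_mean_log10_expr Mean log10 expression of every gene.
#' @param biological_sd_log10 SD of the per-sample log10 expression noise.
#' @param planted_effects List of effects, each a list with elements
#'   \code{pathway_id}, \code{rule} (\code{"activators"}, \code{"repressors"},
#'   \code{"all"}, or a character vector of gene symbols) and \code{lfc}
#'   (log10 fold-change added to tumor profiles).
#' @param response_link_slope,response_link_intercept Logistic-link
#'   parameters: P(responder) = plogis(intercept + slope * score).
#' @param baseline_hazard Events per month in the score-nonpositive group.
#' @param true_log_hazard_ratio_per_score Log hazard ratio applied to the
#'   favorable (score > 0) group.
#' @param censoring_rate Target fraction of censored records in [0, 1].
#' @param rng_seed Integer seed; one RNG stream per cohort, with per-stage
#'   sub-streams derived deterministically from it.
#' @return Object of class \code{SimulationConfig}.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_normals = 6L,
                              n_tumors = 21L,
                              baseline_mean_log10_expr = 2,
                              biological_sd_log10 = 0.25,
                              planted_effects = list(),
                              response_link_slope = 1,
                              response_link_intercept = stats::qlogis(9 / 21),
                              baseline_hazard = log(2) / 5,
                              true_log_hazard_ratio_per_score = log(0.14),
                              censoring_rate = 0,
                              rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_normals = as.integer(n_normals),
              n_tumors = as.integer(n_tumors),
              baseline_mean_log10_expr = baseline_mean_log10_expr,
              biological_sd_log10 = biological_sd_log10,
              planted_effects = planted_effects,
              response_link_slope = response_link_slope,
              response_link_intercept = response_link_intercept,
              baseline_hazard = baseline_hazard,
              true_log_hazard_ratio_per_score = true_log_hazard_ratio_per_score,
              censoring_rate = censoring_rate,
              rng_seed = as.integer(rng_seed))
  if (cfg$n_genes < 1L || cfg$n_normals < 1L || cfg$n_tumors < 1L)
    stop("cohort and gene counts must be strictly positive", call. = FALSE)
  if (cfg$biological_sd_log10 < 0)
    stop("biological_sd_log10 must be >= 0", call. = FALSE)
  if (cfg$baseline_hazard <= 0)
    stop("baseline_hazard must be > 0", call. = FALSE)
  if (is.na(cfg$censoring_rate) || cfg$censoring_rate < 0 || cfg$censoring_rate > 1)
    stop("censoring_rate must lie in [0, 1]", call. = FALSE)
  for (eff in cfg$planted_effects) {
    if (!all(c("pathway_id", "rule", "lfc") %in% names(eff)))
      stop("each planted effect needs pathway_id, rule and lfc", call. = FALSE)
  }
  structure(cfg, class = "SimulationConfig")
}

# Deterministic per-stage sub-seeds from the cohort seed.
stage_seeds <- function(cfg) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$rng_seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("expression", "response", "survival", "covariates"))
}

planted_genes <- function(eff, pathways) {
  ids <- vapply(pathways, `[[`, "", "pathway_id")
  hit <- match(eff$pathway_id, ids)
  if (is.na(hit))
    stop("planted effect references unknown pathway '", eff$pathway_id, "'",
         call. = FALSE)
  members <- pathways[[hit]]$members
  if (is.character(eff$rule) && length(eff$rule) == 1L &&
      eff$rule %in% c("activators", "repressors", "all")) {
    switch(eff$rule,
           activators = names(members)[members > 0],
           repressors = names(members)[members < 0],
           all = names(members))
  } else {
    unknown <- setdiff(eff$rule, names(members))
    if (length(unknown))
      stop("planted effect genes not in pathway '", eff$pathway_id, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    eff$rule
  }
}

# Total planted log10 fold-change per gene, summed over effects.
planted_lfc <- function(cfg, pathways, universe) {
  lfc <- stats::setNames(numeric(length(universe)), universe)
  for (eff in cfg$planted_effects) {
    g <- planted_genes(eff, pathways)
    lfc[g] <- lfc[g] + eff$lfc
  }
  lfc
}

#' Simulate tumor and normal expression profiles
#'
#' Draws \code{n_normals + n_tumors} profiles over a gene universe consisting
#' of all pathway member genes padded with filler genes up to \code{n_genes}.
#' Every value is \code{10^(baseline + noise)}, with the planted log10
#' fold-changes added to tumor profiles only, so expression is strictly
#' positive and planted effects stay interpretable on the log10-ratio scale
#' that pathway activation scoring uses.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param pathways List of \code{Pathway} objects the planted effects refer to.
#' @return Object of class \code{SyntheticCohort}: list with
#'   \code{normal_profiles}, \code{tumor_profiles}, \code{true_pal} (tumors x
#'   pathways matrix of noise-free PAL implied by the planted fold-changes),
#'   and the \code{config}.
#' @export
simulate_expression <- function(config, pathways = list()) {
  stopifnot(inherits(config, "SimulationConfig"))
  seeds <- stage_seeds(config)
  pw_genes <- unique(unlist(lapply(pathways, function(p) names(p$members))))
  n_fill <- max(0L, config$n_genes - length(pw_genes))
  universe <- c(pw_genes, sprintf("FILLER%05d", seq_len(n_fill)))
  lfc <- planted_lfc(config, pathways, universe)
  set.seed(seeds[["expression"]])
  draw <- function(id, role, shift) {
    lg <- config$baseline_mean_log10_expr +
      stats::rnorm(length(universe), 0, config$biological_sd_log10) + shift
    expression_profile(id, stats::setNames(10^lg, universe), role = role)
  }
  normals <- lapply(seq_len(config$n_normals), function(i)
    draw(sprintf("NORM%02d", i), "normal", 0))
  tumors <- lapply(seq_len(config$n_tumors), function(i)
    draw(sprintf("TUMOR%02d", i), "tumor", lfc))
  true_pal <- vapply(pathways, function(p) {
    arr <- p$members[p$members != 0]
    if (length(arr) == 0L) return(0)
    sum(arr * lfc[names(arr)]) / sum(abs(arr))
  }, numeric(1))
  true_pal <- matrix(rep(true_pal, each = config$n_tumors),
                     nrow = config$n_tumors,
                     dimnames = list(vapply(tumors, `[[`, "", "sample_id"),
                                     vapply(pathways, `[[`, "", "pathway_id")))
  structure(list(normal_profiles = normals, tumor_profiles = tumors,
                 true_pal = true_pal, config = config),
            class = "SyntheticCohort")
}

#' Simulate clinical outcomes from per-patient drug scores
#'
#' Responder status is Bernoulli with success probability
#' \code{plogis(intercept + slope * score)}; responders are recorded as
#' stable disease and non-responders as progressive disease. PFS is
#' exponential with hazard \code{baseline_hazard * exp(log_HR * (score > 0))},
#' i.e. the proportional-hazards effect applies to the predicted-effective
#' group. Censoring is independent exponential, with rate calibrated so the
#' expected censored fraction equals \code{censoring_rate}. Covariates (age,
#' sex, stage, RAS mutation) are drawn to resemble an advanced colorectal
#' cancer cohort and carry no outcome effect.
#'
#' @param scores Named numeric vector: one score per tumor sample.
#' @param config A \code{\link{simulation_config}}.
#' @param drug Drug name recorded in the therapy records.
#' @return \code{data.frame} of therapy records (one line per tumor).
#' @export
simulate_outcomes <- function(scores, config, drug = "simdrug") {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(names(scores)) || anyNA(scores))
    stop("scores must be a complete named vector (one per tumor)", call. = FALSE)
  seeds <- stage_seeds(config)
  n <- length(scores)
  set.seed(seeds[["response"]])
  p_resp <- stats::plogis(config$response_link_intercept +
                            config$response_link_slope * scores)
  responder <- stats::runif(n) < p_resp
  set.seed(seeds[["survival"]])
  rate <- config$baseline_hazard *
    exp(config$true_log_hazard_ratio_per_score * (scores > 0))
  t_event <- stats::rexp(n, rate)
  if (config$censoring_rate > 0 && config$censoring_rate < 1) {
    c_rate <- rate * config$censoring_rate / (1 - config$censoring_rate)
    t_cens <- stats::rexp(n, c_rate)
  } else if (config$censoring_rate == 0) {
    t_cens <- rep(Inf, n)
  } else {
    t_cens <- rep(0, n)
  }
  event <- t_event <= t_cens
  pfs <- pmin(t_event, t_cens)
  pfs <- pmax(pfs, 1e-6)  # strictly positive survival times
  set.seed(seeds[["covariates"]])
  data.frame(patient_id = names(scores),
             sample_id = names(scores),
             line_number = 1L,
             drug = drug,
             response = ifelse(responder, "stable disease", "progressive disease"),
             dichotomized = ifelse(responder, "responder", "non_responder"),
             pfs_months = pfs,
             event_observed = event,
             age = pmin(pmax(round(stats::rnorm(n, 55, 10)), 30), 85),
             sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.78, 0.22)),
             stage = sample(c("II", "III", "IV"), n, replace = TRUE,
                            prob = c(0.1, 0.21, 0.69)),
             ras_mutant = stats::runif(n) < 0.39,
             bes = unname(scores),
             score_group = unname(scores > 0),
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort and score it end to end
#'
#' Convenience wrapper: simulates expression, builds the geometric-mean
#' reference from the synthetic normals, computes case-to-normal ratios, PAL
#' and BES through the standard pipeline, assigns every tumor the requested
#' drug, and simulates outcomes from the realized BES. This is the
#' configuration used for parameter-recovery testing: the outcome-generating
#' score is exactly the score the pipeline later evaluates.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param pathways List of \code{Pathway} objects.
#' @param drugs Named list of \code{Drug} objects; outcomes are simulated for
#'   \code{drug_name}.
#' @param drug_name Which drug's BES drives the outcome link (defaults to the
#'   first drug).
#' @param offset CNR offset (default 1).
#' @param weights BES weights \code{c(alpha, beta)}.
#' @return List with the \code{SyntheticCohort}, the \code{pal} matrix, the
#'   per-tumor \code{bes} matrix (tumors x drugs), the \code{score_cards}
#'   list and the clinical \code{records}.
#' @export
simulate_cohort <- function(config, pathways, drugs,
                            drug_name = names(drugs)[1], offset = 1,
                            weights = c(1, 1)) {
  cohort <- simulate_expression(config, pathways)
  reference <- build_reference(cohort$normal_profiles, offset = offset)
  pal <- pal_matrix(cohort$tumor_profiles, reference, pathways)
  vals <- vapply(cohort$tumor_profiles, function(tm) {
    cnr <- compute_cnr(tm, reference)
    pals <- stats::setNames(pal[tm$sample_id, ], colnames(pal))
    bes_table(cnr, pals, pathways, drugs, weights)
  }, numeric(length(drugs)))
  bes <- t(matrix(vals, nrow = length(drugs),
                  dimnames = list(names(drugs),
                                  vapply(cohort$tumor_profiles, `[[`, "",
                                         "sample_id"))))
  cards <- lapply(rownames(bes), function(s)
    suppressWarnings(rank_drugs(stats::setNames(bes[s, ], colnames(bes)), s)))
  records <- simulate_outcomes(bes[, drug_name], config, drug = drug_name)
  list(cohort = cohort, pal = pal, bes = bes, score_cards = cards,
       records = records)
}
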