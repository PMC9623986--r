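#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file with two blocks: \code{paths} (counts,
#' normal_counts, gene_map, pathways, drug_db, clinical, output_dir) and
#' \code{parameters} (offset, alpha, beta, qc_min_mapped, bes_threshold,
#' permutation_iterations, seed), plus an optional \code{simulation} block
#' forwarded to \code{\link{simulation_config}}. Missing parameters take the
#' defaults below; the seed is recorded in every output manifest.
#'
#' @param path YAML file path, or \code{NULL} for an all-defaults config.
#' @param overrides Named list merged over the file contents (CLI flags).
#' @return Object of class \code{RunConfig}.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    paths = list(output_dir = "palrank_out"),
    parameters = list(offset = 1, alpha = 1, beta = 1,
                      qc_min_mapped = 2500000, bes_threshold = 0,
                      permutation_iterations = 10000L, seed = 1L))
  cfg <- utils::modifyList(defaults, cfg)
  cfg <- utils::modifyList(cfg, overrides)
  if (!is.null(cfg$simulation))
    cfg$simulation_config <- do.call(
      simulation_config,
      utils::modifyList(cfg$simulation, list(rng_seed = cfg$parameters$seed)))
  structure(cfg, class = "RunConfig")
}

config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, stage, out_dir, outputs) {
  manifest <- list(stage = stage,
                   seed = config$parameters$seed,
                   config_md5 = config_fingerprint(config),
                   outputs = outputs,
                   parameters = config$parameters)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
}

require_artifact <- function(path, stage) {
  if (is.null(path) || !file.exists(path))
    stop("missing input '", path %||% "<unset>", "'; run the '", stage,
         "' stage (or point the config at an existing file) first",
         call. = FALSE)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort to disk
#'
#' Writes the synthetic normal and tumor count tables (same TSV dialect the
#' reader consumes), the clinical CSV, and a manifest carrying the seed and
#' parameters. Requires a \code{simulation} block and a \code{pathways} path
#' in the config.
#'
#' @param config A \code{RunConfig}.
#' @return Invisible named vector of written paths.
#' @export
run_simulate <- function(config) {
  if (is.null(config$simulation_config))
    stop("config has no simulation block", call. = FALSE)
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pathways <- read_pathways(require_artifact(config$paths$pathways, "setup"))
  drugs <- if (!is.null(config$paths$drug_db))
    load_drug_db(config$paths$drug_db) else example_drug_db()
  sim <- simulate_cohort(config$simulation_config, pathways, drugs,
                         offset = config$parameters$offset,
                         weights = c(config$parameters$alpha,
                                     config$parameters$beta))
  paths <- c(normal_counts = file.path(out_dir, "normal_counts.tsv"),
             tumor_counts = file.path(out_dir, "tumor_counts.tsv"),
             clinical = file.path(out_dir, "clinical.csv"))
  write_gene_counts(sim$cohort$normal_profiles, paths[["normal_counts"]])
  write_gene_counts(sim$cohort$tumor_profiles, paths[["tumor_counts"]])
  utils::write.csv(sim$records, paths[["clinical"]], row.names = FALSE)
  write_manifest(config, "simulate", out_dir, as.list(paths))
  invisible(paths)
}

#' Compute the PAL matrix for a configured cohort
#'
#' Reads tumor and normal count tables and the pathway file, normalizes the
#' pooled cohort with median-of-ratios size factors, builds the
#' geometric-mean reference from the normals and writes the samples-by-
#' pathways PAL matrix as CSV.
#'
#' @param config A \code{RunConfig}.
#' @return Invisible path of the written PAL matrix.
#' @export
run_pal <- function(config) {
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id_map <- if (!is.null(config$paths$gene_map))
    read_gene_id_map(config$paths$gene_map)
  tumors <- read_gene_counts(require_artifact(config$paths$counts, "simulate"),
                             id_map, role = "tumor")
  normals <- read_gene_counts(
    require_artifact(config$paths$normal_counts, "simulate"),
    id_map, role = "normal")
  norm <- size_factor_normalize(c(normals, tumors))
  normals <- norm[seq_along(normals)]
  tumors <- norm[length(normals) + seq_along(tumors)]
  pathways <- read_pathways(require_artifact(config$paths$pathways, "setup"))
  reference <- build_reference(normals, offset = config$parameters$offset)
  pal <- pal_matrix(tumors, reference, pathways)
  out <- file.path(out_dir, "pal_matrix.csv")
  write_pal_matrix(pal, out)
  write_manifest(config, "pal", out_dir, list(pal_matrix = out))
  invisible(out)
}

#' Score and rank drugs for every tumor in a configured cohort
#'
#' @param config A \code{RunConfig}.
#' @return Invisible path of the written score-card CSV (all samples stacked).
#' @export
run_score <- function(config) {
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id_map <- if (!is.null(config$paths$gene_map))
    read_gene_id_map(config$paths$gene_map)
  tumors <- read_gene_counts(require_artifact(config$paths$counts, "simulate"),
                             id_map, role = "tumor")
  normals <- read_gene_counts(
    require_artifact(config$paths$normal_counts, "simulate"),
    id_map, role = "normal")
  norm <- size_factor_normalize(c(normals, tumors))
  normals <- norm[seq_along(normals)]
  tumors <- norm[length(normals) + seq_along(tumors)]
  pathways <- read_pathways(require_artifact(config$paths$pathways, "setup"))
  drugs <- if (!is.null(config$paths$drug_db))
    load_drug_db(config$paths$drug_db) else example_drug_db()
  reference <- build_reference(normals, offset = config$parameters$offset)
  pal <- pal_matrix(tumors, reference, pathways)
  weights <- c(config$parameters$alpha, config$parameters$beta)
  cards <- lapply(tumors, function(tm) {
    cnr <- compute_cnr(tm, reference)
    pals <- stats::setNames(pal[tm$sample_id, ], colnames(pal))
    suppressWarnings(rank_drugs(bes_table(cnr, pals, pathways, drugs, weights),
                                tm$sample_id))
  })
  out <- file.path(out_dir, "score_cards.csv")
  utils::write.csv(do.call(rbind, lapply(cards, as.data.frame)), out,
                   row.names = FALSE)
  write_manifest(config, "score", out_dir, list(score_cards = out))
  invisible(out)
}

#' Evaluate scores against clinical outcomes
#'
#' Joins the clinical table to the score cards (or uses the bundled
#' worked-example cohort when \code{fixture = "table1"}, whose records carry
#' their published BES and rank) and writes the evaluation report as JSON.
#'
#' @param config A \code{RunConfig}.
#' @param fixture \code{NULL}, or \code{"table1"} for the bundled first-line
#'   worked example.
#' @param subset Optional named list of record filters, e.g.
#'   \code{list(drug = "bevacizumab", line_number = 1)}.
#' @return The \code{drug_eval_report}, invisibly; JSON written to the output
#'   directory.
#' @export
run_evaluate <- function(config, fixture = NULL, subset = NULL) {
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (identical(fixture, "table1")) {
    records <- first_line_therapy_records()
    cards <- NULL
  } else {
    records <- read_clinical(require_artifact(config$paths$clinical, "simulate"))
    cards_path <- require_artifact(file.path(out_dir, "score_cards.csv"), "score")
    stacked <- utils::read.csv(cards_path, stringsAsFactors = FALSE)
    cards <- split(stacked, stacked$sample_id)
  }
  report <- evaluate_score_card(cards, records, subset = subset,
                                bes_threshold = config$parameters$bes_threshold)
  out <- file.path(out_dir, "evaluation_report.json")
  write_eval_report(report, out)
  write_manifest(config, "evaluate", out_dir, list(report = out))
  invisible(report)
}
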