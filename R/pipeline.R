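# Orchestration: a validated configuration object and an end-to-end run
# over either user files or a simulated cohort, writing every stage's table
# with a provenance header and a machine-readable JSON report.

#' Pipeline configuration
#'
#' @param scenario "simulate" (generate a synthetic cohort) or "user-data"
#'   (read the supplied files).
#' @param out_dir output directory; created if absent.
#' @param counts,metadata,annotation,enrichment,grouping,gmt input paths
#'   (user-data mode; enrichment/grouping/gmt optional in both modes).
#' @param lfc_threshold,alpha DEG thresholds.
#' @param batch_in_design unused placeholder flag recorded in the report
#'   (batch correction is applied to the log-expression used by the
#'   signature, never to the count-level test).
#' @param sig_batch,k_max signature selection parameters.
#' @param log_input correlate/classify on log2 normalised expression
#'   (default) rather than linear.
#' @param absolute_band use absolute distances for the decision band.
#' @param seed integer seed for the simulate scenario.
#' @param cohort optional \code{\link{cohort_config}} overriding the
#'   simulate-scenario default (\code{study_mimic_config(seed)}).
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = c("simulate", "user-data"),
                            out_dir = tempfile("cmsig_run_"),
                            counts = NULL, metadata = NULL, annotation = NULL,
                            enrichment = NULL, grouping = NULL, gmt = NULL,
                            lfc_threshold = 2, alpha = 0.05,
                            batch_in_design = FALSE, sig_batch = 5,
                            k_max = 50, log_input = TRUE,
                            absolute_band = FALSE, seed = 1, cohort = NULL) {
  scenario <- match.arg(scenario)
  if (lfc_threshold <= 0 || alpha <= 0 || alpha >= 1 || sig_batch < 1)
    stop("invalid thresholds", call. = FALSE)
  if (scenario == "user-data") {
    for (p in c(counts, metadata)) {
      if (is.null(p) || !file.exists(p))
        stop("user-data mode requires existing counts and metadata paths",
             call. = FALSE)
    }
  }
  cfg <- list(scenario = scenario, out_dir = out_dir, counts = counts,
              metadata = metadata, annotation = annotation,
              enrichment = enrichment, grouping = grouping, gmt = gmt,
              lfc_threshold = lfc_threshold, alpha = alpha,
              batch_in_design = batch_in_design, sig_batch = sig_batch,
              k_max = k_max, log_input = log_input,
              absolute_band = absolute_band, seed = as.integer(seed),
              cohort = cohort)
  class(cfg) <- "pipeline_config"
  cfg
}

provenance_of <- function(cfg) {
  list(package = "cmsig",
       version = as.character(utils::packageVersion("cmsig")),
       scenario = cfg$scenario, seed = cfg$seed)
}

#' Run the full analysis pipeline
#'
#' Stage order: gene filtering, size factors, tumour-vs-control DE, DEG
#' lists, optional over-representation analysis, poor-vs-good DE within
#' tumours, signature selection with classification and decision band,
#' optional TME comparisons, and the clinical subgroup score tests. All
#' stage tables are written to \code{cfg$out_dir} with provenance comment
#' headers; a JSON run report summarises counts per stage. Deterministic
#' given the seed.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return the run report, invisibly (a named list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_of(cfg)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)

  ann <- NULL; emx <- NULL; grouping <- NULL; sets <- NULL
  if (cfg$scenario == "simulate") {
    cohort_cfg <- if (is.null(cfg$cohort)) study_mimic_config(seed = cfg$seed)
                  else cfg$cohort
    cohort <- generate_cohort(cohort_cfg)
    counts <- cohort$counts; st <- cohort$samples
    write_counts(counts, file.path(cfg$out_dir, "counts.tsv"), prov)
    write_metadata(st, file.path(cfg$out_dir, "metadata.tsv"), prov)
    write_tsv_raw(cohort$truth$genes, file.path(cfg$out_dir, "truth_genes.tsv"),
                  prov)
    ecfg <- enrichment_config(seed = cfg$seed + 1L)
    enr <- generate_enrichment(ecfg, st)
    emx <- enr$scores; grouping <- enr$grouping
    write_enrichment(emx, file.path(cfg$out_dir, "enrichment.tsv"), prov)
  } else {
    counts <- read_counts(cfg$counts)
    st <- read_metadata(cfg$metadata)
    if (!is.null(cfg$annotation)) ann <- read_annotation(cfg$annotation)
    if (!is.null(cfg$enrichment)) emx <- read_enrichment(cfg$enrichment)
    if (!is.null(cfg$grouping)) {
      grouping <- read_tsv_raw(cfg$grouping)
      if (!all(c("cell_type", "category") %in% names(grouping)))
        stop("grouping file needs cell_type and category columns", call. = FALSE)
    }
  }
  if (!is.null(cfg$gmt)) sets <- read_gmt(cfg$gmt)

  genes_in <- nrow(counts)
  counts <- filter_genes(counts, ann)
  genes_filtered <- nrow(counts)

  # tumour vs control DE
  de_tc <- nb_wald_test(counts, st, contrast = c("control", "tumor"),
                        lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha)
  write_tsv_raw(as.data.frame(de_tc), file.path(cfg$out_dir, "de_tumor_vs_control.tsv"),
                prov)
  deg_tc <- filter_deg(de_tc, cfg$lfc_threshold, cfg$alpha)

  ora <- NULL
  if (!is.null(sets)) {
    universe <- de_tc$gene_id[!is.na(de_tc$p)]
    hits <- intersect(deg_tc$all, universe)
    if (length(hits) > 0) {
      ora <- ora_hypergeom(hits, universe, sets)
      write_tsv_raw(ora, file.path(cfg$out_dir, "ora.tsv"), prov)
    } else note("no DEG for over-representation analysis")
  }

  # poor vs good within tumours
  tum_ids <- st$sample_id[st$group == "tumor"]
  de_pg <- nb_wald_test(counts[, tum_ids, drop = FALSE], st,
                        contrast = c("good", "poor"),
                        lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha)
  write_tsv_raw(as.data.frame(de_pg), file.path(cfg$out_dir, "de_poor_vs_good.tsv"),
                prov)
  deg_pg <- filter_deg(de_pg, cfg$lfc_threshold, cfg$alpha)

  # expression input for the signature
  sf <- size_factors(counts)
  em <- normalize_counts(counts, sf, log = cfg$log_input)
  if (length(unique(st$batch)) > 1)
    em <- remove_batch(em, st$batch[match(colnames(em), st$sample_id)])

  model <- NULL; sig_k <- NA; sig_auc <- NA
  if (length(deg_pg$all) >= cfg$sig_batch) {
    model <- select_signature(em, st, deg_pg$all, batch = cfg$sig_batch,
                              k_max = cfg$k_max)
    if (cfg$absolute_band) {
      band <- decision_band(model$records, absolute = TRUE)
      model$records <- band$records; model$sigma <- band$sigma
    }
    sig_k <- model$k; sig_auc <- model$auc
    write_tsv_raw(model$ranking, file.path(cfg$out_dir, "signature_ranking.tsv"),
                  prov)
    write_tsv_raw(model$records, file.path(cfg$out_dir, "classification.tsv"),
                  prov)
    write_tsv_raw(data.frame(k = as.integer(names(model$auc_trace)),
                             auc = unname(model$auc_trace)),
                  file.path(cfg$out_dir, "auc_trace.tsv"), prov)
    hm <- export_signature_heatmap(em, st, model)
    write_expression(hm$matrix, file.path(cfg$out_dir, "signature_heatmap.tsv"),
                     prov)
  } else {
    note("too few poor-vs-good DEG for signature selection")
  }

  tme <- NULL; subgroups <- NULL; n_sig_types <- NA
  if (!is.null(emx) && !is.null(grouping)) {
    tme <- compare_cell_types(emx, st, contrast = c("tumor", "control"))
    n_sig_types <- sum(tme$significant)
    write_tsv_raw(tme, file.path(cfg$out_dir, "tme_comparisons.tsv"), prov)
    comp <- composite_scores(emx, grouping)
    write_tsv_raw(comp, file.path(cfg$out_dir, "composite_scores.tsv"), prov)
    subgroups <- withCallingHandlers(
      subgroup_score_tests(emx, st, grouping),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    write_tsv_raw(subgroups, file.path(cfg$out_dir, "subgroup_tests.tsv"), prov)
  }

  report <- list(
    config = prov,
    parameters = list(lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha,
                      sig_batch = cfg$sig_batch, k_max = cfg$k_max,
                      log_input = cfg$log_input, seed = cfg$seed),
    stages = list(genes_in = genes_in, genes_after_filter = genes_filtered,
                  deg_tumor_up = length(deg_tc$up),
                  deg_tumor_down = length(deg_tc$down),
                  deg_outcome = length(deg_pg$all),
                  signature_k = sig_k, signature_auc = sig_auc,
                  significant_cell_types = n_sig_types),
    warnings = warnings_log)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(report)
}
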