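# Synthetic cohorts with planted effects. The generator emulates the
# count-level statistical structure of a small FFPE bulk RNA-seq study of
# conjunctival melanoma: 12 tumours (6 poor / 6 good outcome), 8 healthy
# conjunctival controls, overdispersed negative-binomial counts, planted
# tumour-vs-control and poor-vs-good fold changes, and ground-truth tables
# for recovery tests.

#' Cohort simulation configuration
#'
#' Counts are drawn from a negative binomial with variance mu + alpha * mu^2
#' (dispersion alpha). Per-gene baseline means are log2-uniform, dispersions
#' log-uniform, library size factors log-normal. A set of tumour genes
#' carries a planted tumour-vs-control log2 fold change; a disjoint (by
#' default) set of outcome genes carries a planted poor-vs-good log2 fold
#' change within tumours.
#'
#' @param n_genes number of genes.
#' @param n_control,n_poor,n_good sample sizes per group.
#' @param base_log2_range range of the uniform baseline log2 mean.
#' @param dispersion_range range of the log-uniform NB dispersion alpha.
#' @param n_tumor_deg number of planted tumour-vs-control genes.
#' @param tumor_lfc_range range of planted |log2FC| for tumour genes.
#' @param n_outcome_genes number of planted poor-vs-good genes.
#' @param outcome_lfc_range range of planted |log2FC| for outcome genes.
#' @param libsize_sdlog sdlog of the log-normal library size factors.
#' @param allow_overlap allow outcome genes to overlap tumour genes.
#' @param batch_effect additive log2-scale offset applied to the second of
#'   two alternating batches (0 disables batch structure).
#' @param seed integer RNG seed; the same seed reproduces the cohort exactly.
#' @return validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_genes = 2000, n_control = 8, n_poor = 6,
                          n_good = 6, base_log2_range = c(2, 10),
                          dispersion_range = c(0.05, 0.5),
                          n_tumor_deg = 150, tumor_lfc_range = c(2, 4),
                          n_outcome_genes = 20, outcome_lfc_range = c(2, 3),
                          libsize_sdlog = 0.3, allow_overlap = FALSE,
                          batch_effect = 0, seed = 1) {
  cfg <- list(n_genes = n_genes, n_control = n_control, n_poor = n_poor,
              n_good = n_good, base_log2_range = base_log2_range,
              dispersion_range = dispersion_range, n_tumor_deg = n_tumor_deg,
              tumor_lfc_range = tumor_lfc_range,
              n_outcome_genes = n_outcome_genes,
              outcome_lfc_range = outcome_lfc_range,
              libsize_sdlog = libsize_sdlog, allow_overlap = allow_overlap,
              batch_effect = batch_effect, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param cfg object to validate.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with(cfg, {
    if (n_genes < 1 || n_control < 0 || n_poor < 1 || n_good < 1)
      stop("invalid sample/gene counts", call. = FALSE)
    planted <- n_tumor_deg + (if (allow_overlap) 0 else n_outcome_genes)
    if (planted > n_genes)
      stop("more planted genes than genes", call. = FALSE)
    if (any(dispersion_range <= 0) || libsize_sdlog < 0)
      stop("dispersion and size-factor parameters must be positive", call. = FALSE)
  })
  invisible(cfg)
}

#' Configuration mirroring the study layout
#'
#' 12 tumours (6 poor, 6 good outcome) and 8 healthy controls — 20 samples in
#' total — with the generator defaults for everything else.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to \code{\link{cohort_config}}.
#' @export
study_mimic_config <- function(seed = 1, ...) {
  cohort_config(n_control = 8, n_poor = 6, n_good = 6, seed = seed, ...)
}

#' Generate a synthetic cohort
#'
#' Draws counts K_ij ~ NB(mu_ij, alpha_i) with
#' mu_ij = s_j * q_i * 2^(tumour effect) * 2^(outcome effect), where the
#' tumour effect applies to tumour samples of planted tumour genes and the
#' outcome effect to poor-outcome samples of planted outcome genes. Clinical
#' flags follow the study's mix: among the poor-outcome tumours, five carry
#' local recurrence and two systemic metastasis (one sample both).
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @return list with \code{counts} (matrix), \code{samples} (sample table),
#'   and \code{truth} (list with per-gene data.frame \code{genes}, per-sample
#'   \code{size_factors}, and the config).
#' @export
generate_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  set.seed(cfg$seed)
  G <- cfg$n_genes
  n <- cfg$n_control + cfg$n_poor + cfg$n_good
  gene_ids <- sprintf("gene%05d", seq_len(G))

  group <- c(rep("control", cfg$n_control), rep("tumor", cfg$n_poor + cfg$n_good))
  outcome <- c(rep("none", cfg$n_control), rep("poor", cfg$n_poor),
               rep("good", cfg$n_good))
  sample_ids <- c(sprintf("ctrl%02d", seq_len(cfg$n_control)),
                  sprintf("tumP%02d", seq_len(cfg$n_poor)),
                  sprintf("tumG%02d", seq_len(cfg$n_good)))

  q <- 2^stats::runif(G, cfg$base_log2_range[1], cfg$base_log2_range[2])
  alpha <- exp(stats::runif(G, log(cfg$dispersion_range[1]),
                            log(cfg$dispersion_range[2])))
  s <- stats::rlnorm(n, 0, cfg$libsize_sdlog)

  tumor_idx <- sample.int(G, cfg$n_tumor_deg)
  pool <- if (cfg$allow_overlap) seq_len(G) else setdiff(seq_len(G), tumor_idx)
  outcome_idx <- sample(pool, cfg$n_outcome_genes)

  tumor_lfc <- numeric(G)
  tumor_lfc[tumor_idx] <- stats::runif(cfg$n_tumor_deg, cfg$tumor_lfc_range[1],
                                       cfg$tumor_lfc_range[2]) *
    sample(c(-1, 1), cfg$n_tumor_deg, replace = TRUE)
  outcome_lfc <- numeric(G)
  outcome_lfc[outcome_idx] <- stats::runif(cfg$n_outcome_genes,
                                           cfg$outcome_lfc_range[1],
                                           cfg$outcome_lfc_range[2]) *
    sample(c(-1, 1), cfg$n_outcome_genes, replace = TRUE)

  batch <- rep("b1", n)
  if (cfg$batch_effect != 0) batch <- rep(c("b1", "b2"), length.out = n)

  is_tumor <- group == "tumor"
  is_poor <- outcome == "poor"
  log2mu <- outer(log2(q), log2(s), "+") +
    outer(tumor_lfc, as.numeric(is_tumor)) +
    outer(outcome_lfc, as.numeric(is_poor))
  if (cfg$batch_effect != 0)
    log2mu <- log2mu + matrix(cfg$batch_effect * (batch == "b2"), G, n,
                              byrow = TRUE)
  mu <- 2^log2mu

  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / alpha, n)),
                   nrow = G, ncol = n,
                   dimnames = list(gene_ids, sample_ids))
  storage.mode(counts) <- "double"

  recurrence <- ifelse(group == "control", NA, FALSE)
  metastasis <- ifelse(group == "control", NA, FALSE)
  poor_pos <- which(outcome == "poor")
  recurrence[poor_pos[seq_len(min(5, length(poor_pos)))]] <- TRUE
  metastasis[poor_pos[seq(to = length(poor_pos),
                          length.out = min(2, length(poor_pos)))]] <- TRUE

  samples <- data.frame(sample_id = sample_ids, group = group,
                        outcome = outcome, recurrence = recurrence,
                        metastasis = metastasis, batch = batch,
                        stringsAsFactors = FALSE)
  validate_sample_table(samples)

  truth_genes <- data.frame(
    gene_id = gene_ids,
    is_tumor_deg = seq_len(G) %in% tumor_idx,
    tumor_log2fc = tumor_lfc,
    is_outcome_gene = seq_len(G) %in% outcome_idx,
    outcome_log2fc = outcome_lfc,
    dispersion = alpha,
    baseline_mean = q,
    stringsAsFactors = FALSE)
  truth_sf <- data.frame(sample_id = sample_ids, size_factor = s,
                         stringsAsFactors = FALSE)

  list(counts = counts, samples = samples,
       truth = list(genes = truth_genes, size_factors = truth_sf,
                    config = cfg,
                    rng = list(kind = RNGkind()[1], seed = cfg$seed)))
}

#' Enrichment simulation configuration
#'
#' Cell-type scores are Beta(2, 20) at baseline (mean about 0.09, the sparse
#' regime typical of xCell output), with a designated set of types shifted by
#' +delta in tumour samples and another set by -delta, clamped to [0, 1].
#' The 64 default types are partitioned into immune, stroma and other.
#'
#' @param n_cell_types number of cell types.
#' @param n_immune,n_stroma number of immune and stroma types; the remainder
#'   are labelled "other".
#' @param n_enriched,n_depleted numbers of tumour-shifted types (enriched
#'   types are drawn from the immune partition, depleted from stroma/other).
#' @param delta shift added to (subtracted from) tumour scores of enriched
#'   (depleted) types.
#' @param beta_shape1,beta_shape2 baseline Beta parameters.
#' @param seed RNG seed.
#' @return list of class \code{enrichment_config}.
#' @export
enrichment_config <- function(n_cell_types = 64, n_immune = 40, n_stroma = 14,
                              n_enriched = 8, n_depleted = 4, delta = 0.15,
                              beta_shape1 = 2, beta_shape2 = 20, seed = 1) {
  if (n_immune + n_stroma > n_cell_types)
    stop("immune + stroma partition exceeds the number of cell types",
         call. = FALSE)
  if (n_enriched > n_immune || n_depleted > n_cell_types - n_enriched)
    stop("more shifted types than available types", call. = FALSE)
  cfg <- list(n_cell_types = n_cell_types, n_immune = n_immune,
              n_stroma = n_stroma, n_enriched = n_enriched,
              n_depleted = n_depleted, delta = delta,
              beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
              seed = as.integer(seed))
  class(cfg) <- "enrichment_config"
  cfg
}

#' Generate a synthetic cell-type enrichment matrix
#'
#' @param cfg an \code{\link{enrichment_config}}.
#' @param st sample table defining which samples are tumours.
#' @return list with \code{scores} (cell types x samples, in [0,1]),
#'   \code{grouping} (data.frame cell_type, category), and \code{truth}
#'   (enriched/depleted type ids and the config).
#' @export
generate_enrichment <- function(cfg, st) {
  stopifnot(inherits(cfg, "enrichment_config"))
  validate_sample_table(st)
  if (nrow(st) == 0) stop("sample table is empty", call. = FALSE)
  set.seed(cfg$seed)
  types <- sprintf("celltype%02d", seq_len(cfg$n_cell_types))
  category <- rep("other", cfg$n_cell_types)
  category[seq_len(cfg$n_immune)] <- "immune"
  if (cfg$n_stroma > 0)
    category[cfg$n_immune + seq_len(cfg$n_stroma)] <- "stroma"

  enriched <- sample(which(category == "immune"), cfg$n_enriched)
  depl_pool <- setdiff(seq_len(cfg$n_cell_types), enriched)
  depleted <- if (cfg$n_depleted > 0) sample(depl_pool, cfg$n_depleted) else integer(0)

  n <- nrow(st)
  scores <- matrix(stats::rbeta(cfg$n_cell_types * n, cfg$beta_shape1,
                                cfg$beta_shape2),
                   nrow = cfg$n_cell_types, ncol = n,
                   dimnames = list(types, st$sample_id))
  tum <- st$group == "tumor"
  scores[enriched, tum] <- scores[enriched, tum] + cfg$delta
  scores[depleted, tum] <- scores[depleted, tum] - cfg$delta
  scores <- pmin(pmax(scores, 0), 1)

  list(scores = scores,
       grouping = data.frame(cell_type = types, category = category,
                             stringsAsFactors = FALSE),
       truth = list(enriched = types[enriched], depleted = types[depleted],
                    config = cfg))
}
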