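#' Configuration for the synthetic multi-omics cohort generator
#'
#' Collects every simulation parameter with validated defaults. The defaults
#' define the package's standard study conditions: 3 cancer types of 100
#' samples, 1100 genes over 22 autosomes, one planted whole-chromosome
#' aneuploidy per type at carrier fraction 0.6 over a 0.05 background
#' alteration rate, a log2(1.5) transcript dosage effect attenuated by half
#' at the protein level, partner co-abundance correlation 0.6 for
#' compensated pairs, and a survival hazard ratio of 3 on the planted
#' deviation state.
#'
#' @param n_samples_per_type,n_cancer_types,n_genes,n_chromosomes Cohort
#'   dimensions.
#' @param planted_aneuploidies data.frame(cancer_type, chromosome,
#'   direction, carrier_fraction). Types are labelled "CT1", "CT2", ...
#' @param background_alteration_rate Per sample-chromosome probability of a
#'   background whole-chromosome alteration.
#' @param arm_missing_rate,arm_discordance_rate Rates of missing arm calls
#'   and of single-arm (conflicting) measurement noise.
#' @param dosage_effect Log2 fold change added to transcript means on
#'   altered chromosomes (times the alteration direction).
#' @param attenuation Multiplier in [0,1] scaling the dosage effect at the
#'   protein level.
#' @param compensation_rho Target co-abundance correlation for compensated
#'   partner pairs.
#' @param noise_sd_transcript,noise_sd_protein Log-scale noise SDs.
#' @param protein_missing_rate MCAR missingness in the protein matrix.
#' @param protein_coverage Fraction of protein-coding genes quantified at
#'   the protein level.
#' @param frac_protein_coding Fraction of genes flagged protein-coding.
#' @param n_complexes,complex_size_range Complex database shape (random
#'   complexes; a few large ribosomal complexes are added on top).
#' @param n_ppi_edges,n_tfs,targets_per_tf Network and TF-map sizes.
#' @param frac_aggregation_prone Fraction of proteins labelled
#'   aggregation-prone (candidate aneuploid complex proteins are enriched
#'   for the label so compensation recovery is testable).
#' @param frac_ribosomal,frac_degradation Fractions of genes labelled
#'   ribosomal / degradation-machinery.
#' @param deg_coupling Abundance increment of degradation-machinery
#'   proteins per unit of planted deviation.
#' @param ubiq_rate_compensated,ubiq_rate_background Poisson rates for
#'   ubiquitination-site counts.
#' @param meth_shift Promoter-methylation beta shift added for genes on
#'   planted deleted chromosomes in carrier samples (default 0).
#' @param survival_hazard_ratio Hazard ratio per unit planted deviation.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_samples_per_type = 100,
                          n_cancer_types = 3,
                          n_genes = 1100,
                          n_chromosomes = 22,
                          planted_aneuploidies = NULL,
                          background_alteration_rate = 0.05,
                          arm_missing_rate = 0.01,
                          arm_discordance_rate = 0.01,
                          dosage_effect = log2(1.5),
                          attenuation = 0.5,
                          compensation_rho = 0.6,
                          noise_sd_transcript = 0.5,
                          noise_sd_protein = 0.5,
                          protein_missing_rate = 0.1,
                          protein_coverage = 0.7,
                          frac_protein_coding = 0.9,
                          n_complexes = 100,
                          complex_size_range = c(3, 8),
                          n_ppi_edges = 3000,
                          n_tfs = 30,
                          targets_per_tf = 40,
                          frac_aggregation_prone = 0.1,
                          frac_ribosomal = 0.03,
                          frac_degradation = 0.03,
                          deg_coupling = 0.5,
                          ubiq_rate_compensated = 6,
                          ubiq_rate_background = 2,
                          meth_shift = 0,
                          survival_hazard_ratio = 3,
                          seed = 1) {
  if (is.null(planted_aneuploidies)) {
    planted_aneuploidies <- data.frame(
      cancer_type = paste0("CT", seq_len(min(3, n_cancer_types))),
      chromosome = c(7L, 10L, 12L)[seq_len(min(3, n_cancer_types))],
      direction = c(1L, -1L, 1L)[seq_len(min(3, n_cancer_types))],
      carrier_fraction = 0.6,
      stringsAsFactors = FALSE)
    planted_aneuploidies <- planted_aneuploidies[
      planted_aneuploidies$chromosome <= n_chromosomes, , drop = FALSE]
  }
  cfg <- list(
    n_samples_per_type = as.integer(n_samples_per_type),
    n_cancer_types = as.integer(n_cancer_types),
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    planted_aneuploidies = planted_aneuploidies,
    background_alteration_rate = background_alteration_rate,
    arm_missing_rate = arm_missing_rate,
    arm_discordance_rate = arm_discordance_rate,
    dosage_effect = dosage_effect,
    attenuation = attenuation,
    compensation_rho = compensation_rho,
    noise_sd_transcript = noise_sd_transcript,
    noise_sd_protein = noise_sd_protein,
    protein_missing_rate = protein_missing_rate,
    protein_coverage = protein_coverage,
    frac_protein_coding = frac_protein_coding,
    n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    n_ppi_edges = as.integer(n_ppi_edges),
    n_tfs = as.integer(n_tfs),
    targets_per_tf = as.integer(targets_per_tf),
    frac_aggregation_prone = frac_aggregation_prone,
    frac_ribosomal = frac_ribosomal,
    frac_degradation = frac_degradation,
    deg_coupling = deg_coupling,
    ubiq_rate_compensated = ubiq_rate_compensated,
    ubiq_rate_background = ubiq_rate_background,
    meth_shift = meth_shift,
    survival_hazard_ratio = survival_hazard_ratio,
    seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_samples_per_type >= 1, cfg$n_cancer_types >= 1,
            cfg$n_genes >= cfg$n_chromosomes,
            cfg$n_chromosomes >= 1, cfg$n_chromosomes <= 22)
  pa <- cfg$planted_aneuploidies
  if (nrow(pa)) {
    if (!all(pa$direction %in% c(-1L, 1L))) {
      stop("planted directions must be -1 or +1")
    }
    if (!all(pa$chromosome >= 1 & pa$chromosome <= cfg$n_chromosomes)) {
      stop("planted chromosome outside the simulated genome")
    }
    type_idx <- as.integer(sub("^CT", "", pa$cancer_type))
    if (any(is.na(type_idx)) || any(type_idx > cfg$n_cancer_types)) {
      stop("planted cancer types must be CT1..CTk within n_cancer_types")
    }
    if (any(pa$carrier_fraction <= cfg$background_alteration_rate)) {
      stop("carrier_fraction must exceed background_alteration_rate")
    }
    if (any(pa$carrier_fraction > 1 | pa$carrier_fraction <= 0)) {
      stop("carrier_fraction must lie in (0, 1]")
    }
  }
  stopifnot(cfg$attenuation >= 0, cfg$attenuation <= 1,
            abs(cfg$compensation_rho) < 1,
            cfg$noise_sd_transcript > 0, cfg$noise_sd_protein > 0,
            length(cfg$complex_size_range) == 2L,
            cfg$complex_size_range[1] >= 2L,
            cfg$complex_size_range[2] >= cfg$complex_size_range[1],
            cfg$ubiq_rate_compensated >= 0, cfg$ubiq_rate_background >= 0,
            cfg$survival_hazard_ratio > 0)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("cohort_config: %d types x %d samples, %d genes on %d ",
                     "chromosomes, %d planted aneuploidies, seed %d\n"),
              x$n_cancer_types, x$n_samples_per_type, x$n_genes,
              x$n_chromosomes, nrow(x$planted_aneuploidies), x$seed))
  invisible(x)
}
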