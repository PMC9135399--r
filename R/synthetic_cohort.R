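#' Generate a synthetic multi-omics cohort with recorded ground truth
#'
#' Emulates the data landscape of an aneuploid tumor proteogenomics study:
#' per-sample arm-level aneuploidy calls with planted recurrent
#' whole-chromosome alterations, a TPM transcript matrix with dosage effects
#' on altered chromosomes, a log-scale protein matrix with attenuated dosage
#' effects and planted partner co-abundance for compensated pairs, a complex
#' database with functional-term labels, an undirected PPI network enriched
#' between aneuploid proteins and their partners, promoter methylation,
#' TF-target associations, ubiquitination-site counts elevated for
#' compensated partners, and survival times whose hazard follows the planted
#' per-sample deviation state.
#'
#' Compensated pairs couple an aggregation-prone aneuploid-chromosome
#' protein to a co-complex partner on another chromosome at the target
#' Spearman correlation; per-sample residual noise around that coupling is
#' scaled by the planted deviation state, so the downstream stoichiometry
#' deviation score has a recoverable ground truth.
#'
#' @param config A [cohort_config()].
#' @return An object of class \code{stoich_cohort}: a list with elements
#'   \code{config}, \code{sample_info}, \code{arm_scores}, \code{transcript},
#'   \code{protein}, \code{annotation}, \code{complex_db}, \code{network},
#'   \code{methylation}, \code{promoter_map}, \code{tf_targets},
#'   \code{ubiquitination}, \code{survival} and \code{ground_truth}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cfg <- config
  block_seed <- function(k) set.seed(derive_seed(cfg$seed, k))

  ## genome annotation -------------------------------------------------
  block_seed(1L)
  n <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  chromosome <- sort(rep_len(seq_len(cfg$n_chromosomes), n))
  protein_coding <- rep(FALSE, n)
  protein_coding[sample.int(n, round(cfg$frac_protein_coding * n))] <- TRUE
  ribosomal <- rep(FALSE, n)
  rib_pool <- which(protein_coding)
  ribosomal[sample(rib_pool, max(10L, round(cfg$frac_ribosomal * n)))] <- TRUE
  annotation <- data.frame(gene = genes, chromosome = chromosome,
                           protein_coding = protein_coding,
                           ribosomal = ribosomal,
                           stringsAsFactors = FALSE)

  ## samples ------------------------------------------------------------
  n_samples <- cfg$n_samples_per_type * cfg$n_cancer_types
  samples <- sprintf("S%04d", seq_len(n_samples))
  cancer_type <- rep(paste0("CT", seq_len(cfg$n_cancer_types)),
                     each = cfg$n_samples_per_type)
  sample_info <- data.frame(sample = samples, cancer_type = cancer_type,
                            stringsAsFactors = FALSE)

  ## true chromosome states + arm scores --------------------------------
  block_seed(2L)
  chromosomes <- seq_len(cfg$n_chromosomes)
  true_states <- matrix(0L, n_samples, cfg$n_chromosomes,
                        dimnames = list(samples, as.character(chromosomes)))
  bg <- matrix(stats::runif(n_samples * cfg$n_chromosomes) <
                 cfg$background_alteration_rate,
               n_samples, cfg$n_chromosomes)
  true_states[bg] <- sample(c(-1L, 1L), sum(bg), replace = TRUE)
  pa <- cfg$planted_aneuploidies
  for (i in seq_len(nrow(pa))) {
    in_type <- which(cancer_type == pa$cancer_type[i])
    carriers <- sample(in_type, round(pa$carrier_fraction[i] * length(in_type)))
    true_states[carriers, as.character(pa$chromosome[i])] <- pa$direction[i]
  }
  acro <- intersect(acrocentric_chromosomes(), chromosomes)
  arm_cols <- c(rbind(paste0(chromosomes, "p"), paste0(chromosomes, "q")))
  arm_cols <- setdiff(arm_cols, paste0(acro, "p"))
  arm_scores <- matrix(NA_real_, n_samples, length(arm_cols),
                       dimnames = list(samples, arm_cols))
  for (chr in chromosomes) {
    qcol <- paste0(chr, "q")
    arm_scores[, qcol] <- true_states[, as.character(chr)]
    pcol <- paste0(chr, "p")
    if (pcol %in% arm_cols) arm_scores[, pcol] <- true_states[, as.character(chr)]
  }
  # measurement noise: single-arm discordance, then missing calls
  for (chr in setdiff(chromosomes, acro)) {
    hit <- stats::runif(n_samples) < cfg$arm_discordance_rate
    if (any(hit)) {
      arm <- paste0(chr, sample(c("p", "q"), sum(hit), replace = TRUE))
      for (j in seq_along(which(hit))) {
        s <- which(hit)[j]
        cur <- arm_scores[s, arm[j]]
        arm_scores[s, arm[j]] <- sample(setdiff(c(-1, 0, 1), cur), 1)
      }
    }
  }
  arm_scores[matrix(stats::runif(length(arm_scores)) < cfg$arm_missing_rate,
                    nrow(arm_scores))] <- NA_real_

  ## transcripts (log-normal -> TPM) ------------------------------------
  block_seed(3L)
  mu <- stats::rnorm(n, mean = 6, sd = 1.2)
  dosage <- cfg$dosage_effect * true_states[, as.character(chromosome), drop = FALSE]
  logval <- matrix(mu, n, n_samples) + t(dosage) +
    matrix(stats::rnorm(n * n_samples, sd = cfg$noise_sd_transcript), n, n_samples)
  transcript <- 2^logval
  transcript <- sweep(transcript, 2, colSums(transcript), "/") * 1e6
  dimnames(transcript) <- list(genes, samples)

  ## complexes ----------------------------------------------------------
  block_seed(4L)
  coding_genes <- genes[protein_coding]
  terms_pool <- c("cell_cycle", "dna_repair", "rna_splicing", "rna_processing",
                  "chromatin_remodeling", "protein_transport", "signalling",
                  "metabolism", "protein_complex_assembly", "proteolysis",
                  "transcription", "membrane_trafficking")
  # promiscuous hub subunits recur across complexes (as in curated complex
  # databases); one hub is placed on every planted chromosome so the
  # promiscuity analyses are exercised for each aneuploidy case
  pa <- cfg$planted_aneuploidies
  hubs <- character(0)
  for (chr in unique(pa$chromosome)) {
    on_chr <- setdiff(coding_genes[chromosome[match(coding_genes, genes)] == chr],
                      hubs)
    if (length(on_chr)) hubs <- c(hubs, sample(on_chr, 1))
  }
  free <- setdiff(coding_genes, hubs)
  hubs <- c(hubs, sample(free, max(0L, 12L - length(hubs))))
  sizes <- sample(seq(cfg$complex_size_range[1], cfg$complex_size_range[2]),
                  cfg$n_complexes, replace = TRUE)
  cx <- lapply(sizes, function(k) {
    members <- sample(setdiff(coding_genes, hubs), k - 1L)
    if (stats::runif(1) < 0.8) c(sample(hubs, 1), members) else
      c(sample(setdiff(coding_genes, hubs), 1), members)
  })
  ann_terms <- lapply(seq_len(cfg$n_complexes), function(i)
    sample(terms_pool, sample(1:2, 1)))
  rib_genes <- genes[ribosomal]
  n_rib_cx <- if (length(rib_genes) >= 12) 3L else 0L
  for (i in seq_len(n_rib_cx)) {
    cx[[cfg$n_complexes + i]] <- unique(c(
      sample(rib_genes, min(13, length(rib_genes))),
      sample(coding_genes, 2)))
    ann_terms[[cfg$n_complexes + i]] <- c("translation", "ribosome_biogenesis")
  }
  names(cx) <- names(ann_terms) <- sprintf("CPX%03d", seq_along(cx))
  db <- complex_db(cx, ann_terms)

  ## protein matrix with compensation ----------------------------------
  block_seed(5L)
  prot_genes <- sort(union(hubs,
                           sample(coding_genes, round(cfg$protein_coverage *
                                                        length(coding_genes)))))
  np <- length(prot_genes)
  nu <- stats::rnorm(np)
  names(nu) <- prot_genes
  prot_chr <- chromosome[match(prot_genes, genes)]
  prot_dosage <- cfg$attenuation * cfg$dosage_effect *
    t(true_states[, as.character(prot_chr), drop = FALSE])
  protein <- matrix(nu, np, n_samples) + prot_dosage +
    matrix(stats::rnorm(np * n_samples, sd = cfg$noise_sd_protein), np, n_samples)
  dimnames(protein) <- list(prot_genes, samples)

  # planted per-sample deviation state (0 = compensating, 1 = failing)
  deviation <- stats::rbinom(n_samples, 1L, 0.5)
  names(deviation) <- samples
  noise_mult <- 1 + deviation        # residual-noise multiplier in {1, 2}
  mult_norm <- noise_mult / sqrt(mean(noise_mult^2))

  # aggregation-prone labels: half of the candidate aneuploid complex
  # proteins (promiscuous hubs excluded -- their partner abundances are left
  # unregulated), then random background proteins up to the global fraction
  planted_chrs <- unique(pa$chromosome)
  n_complexes_of <- vapply(prot_genes, function(g)
    length(db$membership[[g]] %||% character(0)), integer(1))
  promiscuous <- prot_genes[n_complexes_of > 5L]
  candidates <- lapply(seq_len(nrow(pa)), function(i) {
    on_chr <- prot_genes[prot_chr == pa$chromosome[i]]
    on_chr <- setdiff(intersect(on_chr, names(db$membership)), promiscuous)
    on_chr[vapply(on_chr, function(g)
      length(setdiff(co_complex_partners(g, db), genes[chromosome %in% planted_chrs])) > 0,
      logical(1))]
  })
  cand_all <- unique(unlist(candidates))
  aggregation_prone <- character(0)
  if (length(cand_all)) {
    aggregation_prone <- sort(sample(cand_all, ceiling(length(cand_all) / 2)))
  }
  n_target <- round(cfg$frac_aggregation_prone * np)
  extra <- max(0L, n_target - length(aggregation_prone))
  bg_pool <- setdiff(prot_genes, cand_all)
  if (extra > 0L && length(bg_pool)) {
    aggregation_prone <- sort(c(aggregation_prone,
                                sample(bg_pool, min(extra, length(bg_pool)))))
  }

  # compensated pairs: aggregation-prone aneuploid protein x up to 3
  # measured partners on non-planted chromosomes
  pair_rows <- list()
  used_partners <- character(0)
  for (i in seq_len(nrow(pa))) {
    for (ap in intersect(candidates[[i]], aggregation_prone)) {
      partners <- co_complex_partners(ap, db)
      partners <- intersect(partners, prot_genes)
      partners <- partners[!chromosome[match(partners, genes)] %in% planted_chrs]
      partners <- setdiff(partners, used_partners)
      partners <- utils::head(sort(partners), 3)
      if (!length(partners)) next
      used_partners <- c(used_partners, partners)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        aneuploid_protein = ap, partner = partners,
        cancer_type = pa$cancer_type[i], chromosome = pa$chromosome[i],
        direction = pa$direction[i], stringsAsFactors = FALSE)
    }
  }
  compensated_pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(aneuploid_protein = character(), partner = character(),
               cancer_type = character(), chromosome = integer(),
               direction = integer(), stringsAsFactors = FALSE)
  rho <- cfg$compensation_rho
  for (i in seq_len(nrow(compensated_pairs))) {
    ap <- compensated_pairs$aneuploid_protein[i]
    pp <- compensated_pairs$partner[i]
    z <- as.numeric(scale(protein[ap, ]))
    eps <- stats::rnorm(n_samples)
    protein[pp, ] <- nu[pp] + cfg$noise_sd_protein *
      (rho * z + sqrt(1 - rho^2) * mult_norm * eps)
  }

  # degradation machinery coupled to the planted deviation state
  block_seed(6L)
  deg_pool <- setdiff(prot_genes, c(compensated_pairs$partner,
                                    compensated_pairs$aneuploid_protein))
  deg_pool <- deg_pool[!prot_chr[match(deg_pool, prot_genes)] %in% planted_chrs]
  degradation <- sort(sample(deg_pool,
                             max(10L, round(cfg$frac_degradation * np))))
  for (g in degradation) {
    protein[g, ] <- protein[g, ] + cfg$deg_coupling * deviation
  }
  protein[matrix(stats::runif(length(protein)) < cfg$protein_missing_rate,
                 nrow(protein))] <- NA_real_

  ## PPI network --------------------------------------------------------
  block_seed(7L)
  planted_edges <- unique(compensated_pairs[, c("aneuploid_protein", "partner")])
  names(planted_edges) <- c("a", "b")
  # cross-wiring inside the compensation module: co-complex modules are
  # densely interconnected, so compensated aneuploid proteins also contact
  # partners of the other compensated pairs of their case
  cross <- do.call(rbind, lapply(split(compensated_pairs,
                                       compensated_pairs$cancer_type),
                                 function(cp) {
    aps <- unique(cp$aneuploid_protein)
    pps <- unique(cp$partner)
    if (length(aps) < 2L) return(NULL)
    grid <- cbind(rep(aps, each = length(pps)), rep(pps, length(aps)))
    grid[stats::runif(nrow(grid)) < 0.3, , drop = FALSE]
  }))
  if (!is.null(cross) && nrow(cross)) {
    planted_edges <- unique(rbind(as.matrix(planted_edges),
                                  unname(cross)))
  }
  cocx <- do.call(rbind, lapply(db$complexes, function(s) {
    s <- intersect(s, prot_genes)
    if (length(s) < 2) return(NULL)
    pr <- t(utils::combn(sort(s), 2))
    pr[stats::runif(nrow(pr)) < 0.3, , drop = FALSE]
  }))
  edges <- rbind(as.matrix(planted_edges),
                 if (!is.null(cocx)) cocx else NULL)
  n_random <- max(0L, cfg$n_ppi_edges - nrow(edges))
  rnd <- cbind(sample(prot_genes, n_random, replace = TRUE),
               sample(prot_genes, n_random, replace = TRUE))
  rnd <- rnd[rnd[, 1] != rnd[, 2], , drop = FALSE]
  edges <- rbind(edges, rnd)
  network <- suppressWarnings(interaction_network(edges))

  ## methylation --------------------------------------------------------
  block_seed(8L)
  promoters <- paste0("P_", genes)
  promoter_map <- stats::setNames(promoters, genes)
  base_beta <- stats::rbeta(n, 2, 5)
  meth <- matrix(base_beta, n, n_samples) +
    matrix(stats::rnorm(n * n_samples, sd = 0.05), n, n_samples)
  if (cfg$meth_shift != 0) {
    for (i in which(pa$direction == -1L)) {
      on_chr <- chromosome == pa$chromosome[i]
      carr <- true_states[, as.character(pa$chromosome[i])] == -1L
      meth[on_chr, carr] <- meth[on_chr, carr] + cfg$meth_shift
    }
  }
  meth <- pmin(pmax(meth, 0), 1)
  dimnames(meth) <- list(promoters, samples)

  ## TF -> target map ---------------------------------------------------
  block_seed(9L)
  tfs <- sample(coding_genes, cfg$n_tfs)
  tf_targets <- stats::setNames(lapply(tfs, function(tf)
    sort(sample(setdiff(genes, tf), cfg$targets_per_tf))), tfs)

  ## ubiquitination counts ----------------------------------------------
  block_seed(10L)
  covered <- sort(sample(prot_genes, round(0.9 * np)))
  ubiq <- stats::rpois(length(covered), cfg$ubiq_rate_background)
  names(ubiq) <- covered
  comp_cov <- intersect(unique(compensated_pairs$partner), covered)
  ubiq[comp_cov] <- stats::rpois(length(comp_cov), cfg$ubiq_rate_compensated)

  ## survival -----------------------------------------------------------
  block_seed(11L)
  make_endpoint <- function(label, base_rate) {
    rate <- base_rate * cfg$survival_hazard_ratio^deviation
    t_event <- stats::rexp(n_samples, rate)
    censor <- 20
    data.frame(sample = samples, time = pmin(t_event, censor),
               event = as.integer(t_event <= censor), endpoint = label,
               stringsAsFactors = FALSE)
  }
  survival_tab <- rbind(make_endpoint("overall", 0.08),
                        make_endpoint("disease_free", 0.10))

  ground_truth <- list(
    planted = pa,
    compensated_pairs = compensated_pairs,
    aggregation_prone = aggregation_prone,
    degradation = degradation,
    deviation = deviation,
    true_states = true_states)

  structure(list(config = cfg, sample_info = sample_info,
                 arm_scores = arm_scores, transcript = transcript,
                 protein = protein, annotation = annotation,
                 complex_db = db, network = network, methylation = meth,
                 promoter_map = promoter_map, tf_targets = tf_targets,
                 ubiquitination = ubiq, survival = survival_tab,
                 ground_truth = ground_truth),
            class = "stoich_cohort")
}

#' @export
print.stoich_cohort <- function(x, ...) {
  cat(sprintf(paste0("stoich_cohort: %d samples (%d types), %d genes, ",
                     "%d proteins, %d complexes, %d PPI edges, ",
                     "%d compensated pairs\n"),
              nrow(x$sample_info), x$config$n_cancer_types,
              nrow(x$transcript), nrow(x$protein), length(x$complex_db),
              nrow(x$network$edges), nrow(x$ground_truth$compensated_pairs)))
  invisible(x)
}
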