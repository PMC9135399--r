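#' Promoter methylation shift between aneuploid and diploid samples
#'
#' For each gene the mean promoter methylation is computed separately across
#' aneuploid and diploid samples; the per-gene group means are then compared
#' with a Wilcoxon test (paired per gene by default, pooled optionally).
#' Run separately for up- and downregulated gene sets: higher methylation in
#' aneuploid samples for downregulated genes (or lower for upregulated) is
#' the "consistent" epigenetic-silencing pattern.
#'
#' @param meth Promoters x samples matrix of beta-like values in [0, 1].
#' @param promoter_map Named character vector mapping gene -> promoter row
#'   (the most upstream promoter).
#' @param genes Gene set to test (e.g. downregulated DE genes).
#' @param aneuploid,diploid Sample ID vectors.
#' @param paired Paired per-gene test (default TRUE) or pooled.
#' @return list(p, median_shift (aneuploid - diploid), n_genes).
#' @export
methylation_shift_test <- function(meth, promoter_map, genes, aneuploid,
                                   diploid, paired = TRUE) {
  if (!length(genes)) stop("empty gene set")
  if (!length(aneuploid) || !length(diploid)) stop("both sample groups must be non-empty")
  genes <- unique(as.character(genes))
  has_prom <- genes %in% names(promoter_map) &
    promoter_map[genes] %in% rownames(meth)
  if (any(!has_prom)) {
    warning(sprintf("%d gene(s) without promoter dropped", sum(!has_prom)),
            call. = FALSE)
    genes <- genes[has_prom]
  }
  if (!length(genes)) stop("no genes with promoter data")
  rowsel <- promoter_map[genes]
  a <- rowMeans(meth[rowsel, intersect(aneuploid, colnames(meth)), drop = FALSE],
                na.rm = TRUE)
  d <- rowMeans(meth[rowsel, intersect(diploid, colnames(meth)), drop = FALSE],
                na.rm = TRUE)
  diff <- a - d
  p <- if (paired) {
    if (all(diff == 0)) 1 else
      suppressWarnings(stats::wilcox.test(a, d, paired = TRUE)$p.value)
  } else {
    rank_sum_p(a, d)
  }
  list(p = p, median_shift = stats::median(diff), n_genes = length(genes))
}

#' Randomization test for TF-target enrichment
#'
#' Counts targets of differentially expressed TFs on the aneuploid
#' chromosome among differentially expressed genes on other chromosomes,
#' against a null of size-matched random TF sets (default 100 iterations).
#' The two-tailed empirical p-value doubles the smaller tail. The default
#' "midp" method counts the observed value half in each tail (a mid-p), which
#' is close to uniform under the null even with the discrete target counts;
#' "conservative" counts the observed value fully in both tails with
#' pseudocounts, 2 * min((1 + #\{null >= obs\}), (1 + #\{null <= obs\})) /
#' (n_iter + 1), which never understates the p but is biased upward.
#'
#' @param tf_map Named list TF -> character vector of target genes.
#' @param de_tfs Differentially expressed TFs on the aneuploid chromosome.
#' @param de_genes_other Differentially expressed genes on other chromosomes.
#' @param all_tfs Pool of TFs to draw random sets from (default: all TFs in
#'   \code{tf_map}).
#' @param n_iter Number of random TF sets (default 100; raise for a finer,
#'   more stable p).
#' @param seed Optional integer seed.
#' @param p_method "midp" (default, calibrated) or "conservative".
#' @return list(status, observed, expected, diff = observed - expected, p,
#'   null). status is "skipped" when \code{de_tfs} is empty.
#' @export
tf_target_randomization <- function(tf_map, de_tfs, de_genes_other,
                                    all_tfs = names(tf_map), n_iter = 100,
                                    seed = NULL,
                                    p_method = c("midp", "conservative")) {
  p_method <- match.arg(p_method)
  de_tfs <- intersect(de_tfs, names(tf_map))
  if (!length(de_tfs)) {
    return(list(status = "skipped", observed = NA_real_, expected = NA_real_,
                diff = NA_real_, p = NA_real_, null = numeric(0)))
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(de_tfs)
  if (length(all_tfs) < k) stop("random TF pool smaller than required set size")
  count_targets <- function(tfs) {
    length(intersect(de_genes_other,
                     unique(unlist(tf_map[tfs], use.names = FALSE))))
  }
  observed <- count_targets(de_tfs)
  null <- vapply(seq_len(n_iter), function(i)
    count_targets(sample(all_tfs, k)), numeric(1))
  if (p_method == "midp") {
    p_hi <- (0.5 + sum(null > observed) + 0.5 * sum(null == observed)) /
      (n_iter + 1)
    p_lo <- (0.5 + sum(null < observed) + 0.5 * sum(null == observed)) /
      (n_iter + 1)
  } else {
    p_hi <- (1 + sum(null >= observed)) / (n_iter + 1)
    p_lo <- (1 + sum(null <= observed)) / (n_iter + 1)
  }
  list(status = "ok", observed = observed, expected = mean(null),
       diff = observed - mean(null), p = min(1, 2 * min(p_hi, p_lo)),
       null = null)
}

#' Chi-square enrichment of a single TF's targets among DE genes
#'
#' 2x2 chi-square over a gene universe crossing target status with DE
#' status (the per-TF control analysis, e.g. for MYC-like regulators).
#'
#' @param tf TF identifier (must be in \code{tf_map}).
#' @param tf_map Named list TF -> target genes.
#' @param de_genes DE gene set.
#' @param universe Gene universe.
#' @return list(std_residual, p, observed, expected) or NULL on degenerate
#'   margins / no targets in the universe.
#' @export
target_enrichment_chisq <- function(tf, tf_map, de_genes, universe) {
  if (!tf %in% names(tf_map)) stop(sprintf("unknown TF %s", tf))
  targets <- intersect(tf_map[[tf]], universe)
  if (!length(targets)) return(NULL)
  association_2x2(de_genes, targets, universe)
}

#' Ubiquitination-site comparison across correlation groups
#'
#' Compares total ubiquitination-site counts between (i) all proteins with
#' counts, (ii) complex subunits, (iii) top positively correlated partners
#' (rho >= threshold) and (iv) top negatively correlated partners
#' (rho <= -threshold), with pairwise rank-sum tests. Proteins not covered
#' by the ubiquitination data are removed.
#'
#' @param table Pooled correlation table ([pool_correlations()]); the
#'   partner column provides the correlated-protein groups.
#' @param counts Named nonnegative integer vector: protein -> total sites.
#' @param db A [complex_db()] (defines the complex-subunit group).
#' @param threshold Top-correlation band edge (default 0.4, inclusive).
#' @param min_group Minimum proteins per group for a contrast (default 3).
#' @return list(groups = named list of count vectors, contrasts =
#'   data.frame(group1, group2, p)).
#' @export
ubiquitination_comparison <- function(table, counts, db, threshold = 0.4,
                                      min_group = 3) {
  stopifnot(!is.null(names(counts)))
  if (any(counts < 0)) stop("ubiquitination counts must be nonnegative")
  covered <- names(counts)
  groups <- list(
    all = counts,
    complex_subunits = counts[intersect(covered, names(db$membership))],
    top_positive = counts[intersect(covered,
      unique(table$partner[table$rho >= threshold]))],
    top_negative = counts[intersect(covered,
      unique(table$partner[table$rho <= -threshold]))]
  )
  combos <- utils::combn(names(groups), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
    g1 <- groups[[combos[1, j]]]
    g2 <- groups[[combos[2, j]]]
    data.frame(group1 = combos[1, j], group2 = combos[2, j],
               p = if (length(g1) >= min_group && length(g2) >= min_group)
                 rank_sum_p(g1, g2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(groups = groups, contrasts = contrasts)
}
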