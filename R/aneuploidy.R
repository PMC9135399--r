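#' Whole-chromosome aneuploidy score from arm-level calls
#'
#' Collapses p/q arm calls into a whole-chromosome state. For the
#' metacentric/submetacentric autosomes (1-12 and 16-20) the chromosome is
#' called amplified (+1), deleted (-1) or diploid (0) only when both arms
#' agree and neither is missing; conflicting or incomplete arms give NA.
#' For the acrocentric autosomes (13-15, 21, 22) the q arm is taken as
#' representative of the whole chromosome.
#'
#' @param p_score,q_score Integer vectors with values in {-1, 0, +1} or NA
#'   (missing).
#' @param chromosome Integer vector of autosome numbers (1-22), recycled
#'   against the scores.
#' @return Integer vector of whole-chromosome scores in {-1, 0, +1, NA}.
#' @examples
#' whole_chromosome_score(1, 1, 5)    # +1
#' whole_chromosome_score(1, 0, 2)    # NA (conflicting arms)
#' whole_chromosome_score(NA, -1, 13) # -1 (acrocentric: q arm representative)
#' @export
whole_chromosome_score <- function(p_score, q_score, chromosome) {
  n <- max(length(p_score), length(q_score), length(chromosome))
  p <- rep_len(as.integer(p_score), n)
  q <- rep_len(as.integer(q_score), n)
  chr <- rep_len(as.integer(chromosome), n)
  ok <- function(v) all(is.na(v) | v %in% c(-1L, 0L, 1L))
  if (!ok(p) || !ok(q)) stop("arm scores must be -1, 0, +1 or NA")
  if (any(is.na(chr)) || any(chr < 1L | chr > 22L)) {
    stop("chromosome must be an autosome number in 1..22")
  }
  acro <- chr %in% acrocentric_chromosomes()
  out <- rep(NA_integer_, n)
  out[acro] <- q[acro]
  both <- !acro & !is.na(p) & !is.na(q) & p == q
  out[both] <- p[both]
  out
}

#' @rdname whole_chromosome_score
#' @export
acrocentric_chromosomes <- function() c(13L, 14L, 15L, 21L, 22L)

#' Derive the sample-by-chromosome score matrix from arm-level calls
#'
#' @param arm_scores Numeric matrix, samples in rows; columns named like
#'   \code{"1p"}, \code{"1q"}, ..., \code{"22q"}. Acrocentric p-arm columns
#'   may be absent. Values in {-1, 0, +1, NA}.
#' @return Integer matrix samples x 22 with columns "1".."22".
#' @export
chromosome_scores <- function(arm_scores) {
  stopifnot(is.matrix(arm_scores))
  out <- matrix(NA_integer_, nrow = nrow(arm_scores), ncol = 22L,
                dimnames = list(rownames(arm_scores), as.character(1:22)))
  for (chr in 1:22) {
    pcol <- paste0(chr, "p")
    qcol <- paste0(chr, "q")
    q <- if (qcol %in% colnames(arm_scores)) arm_scores[, qcol] else
      rep(NA_real_, nrow(arm_scores))
    p <- if (pcol %in% colnames(arm_scores)) arm_scores[, pcol] else
      rep(NA_real_, nrow(arm_scores))
    out[, chr] <- whole_chromosome_score(p, q, chr)
  }
  out
}

#' Detect recurrent cancer-type-specific whole-chromosome aneuploidies
#'
#' For every (cancer type, chromosome, direction) the occurrence of the
#' alteration within the type is tested against the remaining types with a
#' 2x2 Pearson chi-square (no continuity correction). P-values are corrected
#' with Holm's method across all tests; a case is called when the adjusted
#' p-value is at most \code{alpha} and the standard residual of the
#' (this type, altered) cell is at least \code{min_residual}. Samples with an
#' NA score for a chromosome are excluded from that chromosome's tests.
#'
#' @param chrom_scores Integer matrix samples x chromosomes (see
#'   [chromosome_scores()]).
#' @param cancer_types Character/factor vector of per-sample type labels,
#'   aligned with the rows of \code{chrom_scores}.
#' @param alpha Holm-adjusted significance level (default 0.05).
#' @param min_residual Minimum standard residual (default 2).
#' @param min_type_size Types with fewer samples are not tested (default 10).
#' @param correct Apply the Yates continuity correction to the chi-square
#'   p-value (default TRUE; the standard residuals are raw Pearson
#'   components either way). The uncorrected tail is anticonservative on
#'   2x2 tables at Holm-level thresholds and breaks family-wise error
#'   control; the corrected p keeps the Holm guarantee. Set FALSE for the
#'   plain Pearson p.
#' @return data.frame of selected cases (cancer_type, chromosome, direction,
#'   n_altered, n_type, chi2_p, adj_p, std_residual) with the full test table
#'   attached as attribute \code{"all_tests"}.
#' @export
detect_recurrent <- function(chrom_scores, cancer_types, alpha = 0.05,
                             min_residual = 2, min_type_size = 10,
                             correct = TRUE) {
  stopifnot(is.matrix(chrom_scores), nrow(chrom_scores) == length(cancer_types))
  types <- as.character(cancer_types)
  tab_types <- table(types)
  use_types <- names(tab_types)[tab_types >= min_type_size]
  if (length(use_types) < 2L) stop("need at least two cancer types with enough samples")
  rows <- list()
  for (chr in colnames(chrom_scores)) {
    sc <- chrom_scores[, chr]
    keep <- !is.na(sc)
    sc <- sc[keep]
    ty <- types[keep]
    for (ct in use_types) {
      in_type <- ty == ct
      for (dir in c(1L, -1L)) {
        altered <- sc == dir
        tab <- matrix(c(sum(in_type & altered), sum(in_type & !altered),
                        sum(!in_type & altered), sum(!in_type & !altered)),
                      nrow = 2, byrow = TRUE)
        ht <- chisq_2x2(tab, correct = correct)
        if (is.null(ht)) next
        if (any(ht$expected < 1)) {
          warning(sprintf("expected cell < 1 for %s chr%s dir%+d; skipped",
                          ct, chr, dir), call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cancer_type = ct, chromosome = as.integer(chr), direction = dir,
          n_altered = tab[1, 1], n_type = sum(in_type),
          chi2_p = ht$p, std_residual = ht$residuals[1, 1],
          stringsAsFactors = FALSE)
      }
    }
  }
  all_tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cancer_type = character(), chromosome = integer(),
               direction = integer(), n_altered = integer(), n_type = integer(),
               chi2_p = numeric(), std_residual = numeric())
  all_tests$adj_p <- stats::p.adjust(all_tests$chi2_p, method = "holm")
  sel <- all_tests[all_tests$adj_p <= alpha & all_tests$std_residual >= min_residual, ,
                   drop = FALSE]
  rownames(sel) <- NULL
  structure(sel, all_tests = all_tests)
}

#' Detect chromosome co-amplifications within amplification cases
#'
#' Within each amplification case's cancer type, tests the co-occurrence of
#' amplification of the case chromosome with amplification of every other
#' chromosome (2x2 chi-square, Holm correction across all pairs). A pair is
#' retained when its adjusted p-value is strictly below \code{alpha}.
#'
#' @inheritParams detect_recurrent
#' @param cases data.frame of cases from [detect_recurrent()]; only rows with
#'   direction +1 are used.
#' @param alpha Adjusted p-value threshold (default 0.01, strict).
#' @param correct Yates continuity correction for the p-value (default TRUE,
#'   as in [detect_recurrent()]).
#' @return data.frame (cancer_type, chromosome, partner_chromosome, p, adj_p,
#'   significant); significant rows form the co-amplification list.
#' @export
detect_coamplifications <- function(chrom_scores, cancer_types, cases,
                                    alpha = 0.01, correct = TRUE) {
  types <- as.character(cancer_types)
  amp <- cases[cases$direction == 1L, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(amp))) {
    ct <- amp$cancer_type[i]
    chr <- as.character(amp$chromosome[i])
    in_type <- types == ct
    for (other in setdiff(colnames(chrom_scores), chr)) {
      a <- chrom_scores[in_type, chr]
      b <- chrom_scores[in_type, other]
      keep <- !is.na(a) & !is.na(b)
      if (!any(keep)) next
      tab <- table(factor(a[keep] == 1L, c(TRUE, FALSE)),
                   factor(b[keep] == 1L, c(TRUE, FALSE)))
      ht <- chisq_2x2(unclass(tab), correct = correct)
      if (is.null(ht)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cancer_type = ct, chromosome = as.integer(chr),
        partner_chromosome = as.integer(other), p = ht$p,
        std_residual = ht$residuals[1, 1], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(cancer_type = character(), chromosome = integer(),
                      partner_chromosome = integer(), p = numeric(),
                      std_residual = numeric(), adj_p = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "holm")
  out$significant <- out$adj_p < alpha
  rownames(out) <- NULL
  out
}

#' Per-chromosome contribution to transcriptional dysregulation
#'
#' Fraction of each chromosome's annotated genes that are differentially
#' expressed.
#'
#' @param de_genes Character vector of differentially expressed gene IDs.
#' @param gene_annotation data.frame with columns \code{gene} and
#'   \code{chromosome}.
#' @return Named numeric vector of fractions in [0, 1], one per chromosome
#'   with at least one annotated gene.
#' @export
chromosome_contribution <- function(de_genes, gene_annotation) {
  stopifnot(all(c("gene", "chromosome") %in% names(gene_annotation)))
  missing <- setdiff(de_genes, gene_annotation$gene)
  if (length(missing)) {
    stop(sprintf("%d DE genes missing from the annotation", length(missing)))
  }
  totals <- table(gene_annotation$chromosome)
  de <- table(factor(gene_annotation$chromosome[gene_annotation$gene %in% de_genes],
                     levels = names(totals)))
  frac <- as.numeric(de) / as.numeric(totals)
  names(frac) <- names(totals)
  frac
}

#' Compare contributions of co-amplified vs other chromosomes
#'
#' Paired Wilcoxon test across cases of the mean per-chromosome DE
#' contribution of co-amplified chromosomes against that of the remaining
#' chromosomes.
#'
#' @param case_fractions List (one element per case) of named fraction
#'   vectors from [chromosome_contribution()].
#' @param case_coamplified List (same length) of co-amplified chromosome
#'   labels for each case; the case's own chromosome should not be included.
#' @return list(p, mean_coamplified, mean_other) where the means are the
#'   per-case means used in the paired test.
#' @export
compare_contributions <- function(case_fractions, case_coamplified) {
  stopifnot(length(case_fractions) == length(case_coamplified))
  co <- other <- numeric(0)
  for (i in seq_along(case_fractions)) {
    f <- case_fractions[[i]]
    cc <- intersect(as.character(case_coamplified[[i]]), names(f))
    if (!length(cc) || length(cc) == length(f)) next
    co <- c(co, mean(f[cc]))
    other <- c(other, mean(f[setdiff(names(f), cc)]))
  }
  if (!length(co)) return(list(p = NA_real_, mean_coamplified = co, mean_other = other))
  d <- co - other
  p <- if (all(d == 0)) 1 else
    suppressWarnings(stats::wilcox.test(co, other, paired = TRUE)$p.value)
  list(p = p, mean_coamplified = co, mean_other = other)
}
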