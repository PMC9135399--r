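#' Convert FPKM values to TPM
#'
#' TPM_gs = FPKM_gs / sum_g FPKM_gs * 1e6, so every sample column sums to one
#' million. Features with zero values in all samples are removed; an optional
#' exclusion list (e.g. mitochondrial genes) is dropped first.
#'
#' @param mat Nonnegative numeric matrix, features x samples.
#' @param exclude Optional character vector of feature IDs to drop before
#'   scaling (mitochondrial filtering hook).
#' @return Matrix on the TPM scale.
#' @export
fpkm_to_tpm <- function(mat, exclude = NULL) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0, na.rm = TRUE)) stop("FPKM values must be nonnegative")
  if (!is.null(exclude)) mat <- mat[!rownames(mat) %in% exclude, , drop = FALSE]
  mat <- mat[rowSums(mat, na.rm = TRUE) > 0, , drop = FALSE]
  cs <- colSums(mat)
  if (any(cs == 0)) {
    stop(sprintf("all-zero sample column(s): %s",
                 paste(colnames(mat)[cs == 0], collapse = ", ")))
  }
  sweep(mat, 2, cs, "/") * 1e6
}

#' Quantile normalization followed by log2 transform
#'
#' Maps every sample column onto the mean-of-order-statistics reference
#' profile (average ranks for ties, interpolating the reference at
#' half-integer ranks), then applies log2(x + pseudocount). Within-column
#' rank order is preserved.
#'
#' @param mat Nonnegative numeric matrix, features x samples.
#' @param pseudocount Added before the log (default 1).
#' @return Normalized log2-scale matrix of the same shape.
#' @export
quantile_normalize_log2 <- function(mat, pseudocount = 1) {
  stopifnot(is.matrix(mat))
  if (any(mat < 0, na.rm = TRUE)) stop("values must be nonnegative")
  ref <- rowMeans(apply(mat, 2, sort))
  n <- nrow(mat)
  out <- apply(mat, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_len(n), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(mat)
  log2(out + pseudocount)
}

#' Split samples into aneuploid and diploid groups for a case
#'
#' Restricts to the case's cancer type, then partitions samples into those
#' whose whole-chromosome score equals the case direction (aneuploid group)
#' and those diploid (score 0). Samples with the opposite alteration or an NA
#' score are excluded.
#'
#' @param chrom_scores Samples x chromosomes matrix ([chromosome_scores()]).
#' @param cancer_types Per-sample type labels aligned with the rows.
#' @param case A list or one-row data.frame with \code{cancer_type},
#'   \code{chromosome} and \code{direction}.
#' @param min_group Minimum size of each group (default 5); smaller cases are
#'   skipped (NULL with a warning).
#' @return list(aneuploid = sample IDs, diploid = sample IDs) or NULL.
#' @export
split_by_case <- function(chrom_scores, cancer_types, case, min_group = 5) {
  ids <- rownames(chrom_scores)
  in_type <- as.character(cancer_types) == case$cancer_type
  sc <- chrom_scores[, as.character(case$chromosome)]
  aneuploid <- ids[in_type & !is.na(sc) & sc == case$direction]
  diploid <- ids[in_type & !is.na(sc) & sc == 0L]
  if (length(aneuploid) < min_group || length(diploid) < min_group) {
    warning(sprintf("case %s chr%s dir%+d skipped: group sizes %d/%d below %d",
                    case$cancer_type, case$chromosome, case$direction,
                    length(aneuploid), length(diploid), min_group), call. = FALSE)
    return(NULL)
  }
  list(aneuploid = aneuploid, diploid = diploid)
}

#' Differential features between aneuploid and diploid groups
#'
#' Two-sided Wilcoxon rank-sum test per feature. In transcript mode p-values
#' are Benjamini-Hochberg adjusted and features are significant at adjusted
#' p < 0.1; when fewer than \code{fallback_n} protein-coding features pass,
#' the call is re-made at raw p < 0.05 so enough genes remain for enrichment
#' testing. In protein mode the raw p < 0.1 rule is used without adjustment.
#' Direction is the sign of the median difference (aneuploid - diploid).
#'
#' @param mat Features x samples matrix. Transcript mode: TPM, no missing
#'   values (features zero in all retained samples are dropped). Protein
#'   mode: log-scale abundances, NA allowed (pairwise exclusion).
#' @param groups list(aneuploid=, diploid=) of sample IDs ([split_by_case()]).
#' @param mode "transcript" or "protein".
#' @param protein_coding Optional character vector of protein-coding feature
#'   IDs; only these count toward the fallback rule. Default: all features.
#' @param min_obs Protein mode: minimum non-missing values per group for a
#'   feature to be tested (default 3).
#' @param adj_alpha,fallback_n,fallback_alpha,protein_alpha Threshold
#'   parameters (defaults 0.1, 250, 0.05, 0.1).
#' @return data.frame (feature, raw_p, adj_p, median_diff, log2_fc,
#'   direction, significant, constant) with attribute \code{"rule"} in
#'   {"adj_p_0.1", "raw_p_0.05", "raw_p_0.1"}.
#' @export
differential_test <- function(mat, groups, mode = c("transcript", "protein"),
                              protein_coding = NULL, min_obs = 3,
                              adj_alpha = 0.1, fallback_n = 250,
                              fallback_alpha = 0.05, protein_alpha = 0.1) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat))
  a_ids <- intersect(groups$aneuploid, colnames(mat))
  d_ids <- intersect(groups$diploid, colnames(mat))
  if (!length(a_ids) || !length(d_ids)) stop("both groups must be non-empty")
  sub <- mat[, c(a_ids, d_ids), drop = FALSE]
  if (mode == "transcript") {
    sub <- sub[rowSums(sub, na.rm = TRUE) > 0, , drop = FALSE]
  }
  na_idx <- seq_along(a_ids)
  raw_p <- med <- rep(NA_real_, nrow(sub))
  constant <- tested <- rep(FALSE, nrow(sub))
  for (i in seq_len(nrow(sub))) {
    x <- sub[i, na_idx]
    y <- sub[i, -na_idx]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (mode == "protein" && (length(x) < min_obs || length(y) < min_obs)) next
    tested[i] <- TRUE
    med[i] <- stats::median(x) - stats::median(y)
    if (length(unique(c(x, y))) == 1L) {
      raw_p[i] <- 1
      constant[i] <- TRUE
    } else {
      raw_p[i] <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
  }
  res <- data.frame(feature = rownames(sub), raw_p = raw_p,
                    adj_p = NA_real_, median_diff = med,
                    direction = NA_character_, significant = FALSE,
                    constant = constant, stringsAsFactors = FALSE)
  res <- res[tested, , drop = FALSE]
  res$adj_p <- stats::p.adjust(res$raw_p, method = "BH")
  if (mode == "transcript") {
    res$log2_fc <- {
      m <- match(res$feature, rownames(sub))
      log2((apply(sub[m, na_idx, drop = FALSE], 1, stats::median) + 1) /
           (apply(sub[m, -na_idx, drop = FALSE], 1, stats::median) + 1))
    }
    sig <- res$adj_p < adj_alpha
    coding <- if (is.null(protein_coding)) rep(TRUE, nrow(res)) else
      res$feature %in% protein_coding
    if (sum(sig & coding, na.rm = TRUE) < fallback_n) {
      sig <- res$raw_p < fallback_alpha
      rule <- "raw_p_0.05"
    } else {
      rule <- "adj_p_0.1"
    }
  } else {
    sig <- res$raw_p < protein_alpha
    rule <- "raw_p_0.1"
  }
  res$significant <- !is.na(sig) & sig
  res$direction[res$significant] <-
    ifelse(res$median_diff[res$significant] >= 0, "up", "down")
  rownames(res) <- NULL
  structure(res, rule = rule)
}

#' Annotate differential features with chromosome location
#'
#' Marks each feature as lying on the case's aneuploid chromosome or on
#' another chromosome. Unannotated features are excluded with a warning.
#'
#' @param result data.frame from [differential_test()].
#' @param gene_annotation data.frame with \code{gene}, \code{chromosome}.
#' @param case_chromosome The case's chromosome.
#' @return \code{result} with a \code{location} column in
#'   {"aneuploid_chromosome", "other_chromosome"}.
#' @export
locate_features <- function(result, gene_annotation, case_chromosome) {
  m <- match(result$feature, gene_annotation$gene)
  if (anyNA(m)) {
    warning(sprintf("%d unannotated features excluded", sum(is.na(m))),
            call. = FALSE)
    result <- result[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  chr <- gene_annotation$chromosome[m]
  result$location <- ifelse(chr == as.integer(case_chromosome),
                            "aneuploid_chromosome", "other_chromosome")
  result
}

#' Fraction of detected features that are differential, by location class
#'
#' @param result Located result from [locate_features()].
#' @return Named numeric: fraction of tested features significant on the
#'   aneuploid chromosome and on other chromosomes.
#' @export
location_fractions <- function(result) {
  stopifnot("location" %in% names(result))
  vapply(split(result$significant, result$location), mean, numeric(1))
}
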