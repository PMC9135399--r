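#' Protein complex database
#'
#' Container for a set of named protein complexes (subunit sets) with
#' optional functional-term annotations, plus a protein -> complex
#' membership index. The same shape as a CORUM-style GMT file.
#'
#' @param complexes Named list of character vectors (subunit IDs). Duplicate
#'   subunits are removed; complexes with fewer than two distinct subunits
#'   are dropped with a warning.
#' @param annotations Optional named list of character vectors of
#'   functional-term labels, keyed by complex ID.
#' @return An object of class \code{complex_db}.
#' @export
complex_db <- function(complexes, annotations = NULL) {
  stopifnot(is.list(complexes), !is.null(names(complexes)))
  complexes <- lapply(complexes, function(s) unique(as.character(s)))
  sizes <- lengths(complexes)
  if (any(sizes < 2L)) {
    warning(sprintf("%d complexes with < 2 subunits dropped", sum(sizes < 2L)),
            call. = FALSE)
    complexes <- complexes[sizes >= 2L]
  }
  if (is.null(annotations)) annotations <- setNames(vector("list", length(complexes)),
                                                    names(complexes))
  annotations <- annotations[names(complexes)]
  names(annotations) <- names(complexes)
  membership <- split(rep(names(complexes), lengths(complexes)),
                      unlist(complexes, use.names = FALSE))
  structure(list(complexes = complexes, annotations = annotations,
                 membership = membership),
            class = "complex_db")
}

#' @export
print.complex_db <- function(x, ...) {
  cat(sprintf("complex_db: %d complexes, %d distinct proteins\n",
              length(x$complexes), length(x$membership)))
  invisible(x)
}

#' @export
length.complex_db <- function(x) length(x$complexes)

#' Read / write a complex database in GMT format
#'
#' One complex per line: ID, description (semicolon-separated functional
#' terms), then subunit IDs, all tab-separated. Duplicate subunits within a
#' line are removed with a warning.
#'
#' @param path File path.
#' @return \code{read_gmt}: a [complex_db()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields", bad[1], path))
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  subunits <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(subunits, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning(sprintf("duplicate subunits deduplicated in %d GMT line(s)", sum(dup)),
            call. = FALSE)
  }
  ann <- lapply(desc, function(d) {
    if (identical(d, "") || identical(d, "NA")) character(0) else
      strsplit(d, ";", fixed = TRUE)[[1]]
  })
  names(subunits) <- names(ann) <- ids
  complex_db(subunits, ann)
}

#' @rdname read_gmt
#' @param db A [complex_db()].
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "complex_db"))
  desc <- vapply(db$annotations, function(a)
    if (length(a)) paste(a, collapse = ";") else "NA", character(1))
  lines <- vapply(seq_along(db$complexes), function(i)
    paste(c(names(db$complexes)[i], desc[i], db$complexes[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Co-complex partners of a protein set
#'
#' All proteins sharing at least one complex with any input protein, minus
#' the input set itself. Unknown proteins contribute no partners.
#'
#' @param proteins Character vector of protein IDs.
#' @param db A [complex_db()].
#' @return Character vector of partner IDs.
#' @export
co_complex_partners <- function(proteins, db) {
  stopifnot(inherits(db, "complex_db"))
  cx <- unique(unlist(db$membership[intersect(proteins, names(db$membership))],
                      use.names = FALSE))
  out <- setdiff(unique(unlist(db$complexes[cx], use.names = FALSE)), proteins)
  as.character(out)
}

# Shared 2x2 association machinery: predicate membership vs DA status over a
# universe, Pearson residual of the (DA, in-set) cell.
association_2x2 <- function(da, set, universe) {
  u <- unique(universe)
  da <- intersect(da, u)
  set <- intersect(set, u)
  is_da <- u %in% da
  in_set <- u %in% set
  tab <- matrix(c(sum(is_da & in_set), sum(is_da & !in_set),
                  sum(!is_da & in_set), sum(!is_da & !in_set)),
                nrow = 2, byrow = TRUE)
  ht <- chisq_2x2(tab)
  if (is.null(ht)) return(NULL)
  list(std_residual = ht$residuals[1, 1], p = ht$p, table = tab,
       observed = tab[1, 1], expected = ht$expected[1, 1])
}

#' Partner enrichment among differentially abundant proteins
#'
#' Tests whether differentially abundant (DA) proteins on other,
#' non-aneuploid chromosomes are enriched for co-complex partners of DA
#' proteins on the aneuploid chromosome: a 2x2 chi-square over the universe
#' of quantified other-chromosome proteins, crossing DA status with partner
#' status. Enrichment is claimed when the standard residual of the
#' (DA, partner) cell is at least 2 and p < 0.05.
#'
#' @param da_other DA proteins on other chromosomes.
#' @param da_aneuploid DA proteins on the aneuploid chromosome (direction
#'   consistent with the case).
#' @param universe All quantified proteins on other chromosomes.
#' @param db A [complex_db()].
#' @return list(std_residual, p, enriched, observed, expected, n_partners,
#'   partner_fraction) or NULL when the partner set is empty (skipped with a
#'   warning). \code{partner_fraction} is the share of DA other-chromosome
#'   proteins that are partners.
#' @export
partner_enrichment_test <- function(da_other, da_aneuploid, universe, db) {
  if (!length(da_aneuploid)) {
    warning("empty aneuploid DA set; test skipped", call. = FALSE)
    return(NULL)
  }
  partners <- intersect(co_complex_partners(da_aneuploid, db), universe)
  if (!length(partners)) {
    warning("no co-complex partners in the universe; test skipped", call. = FALSE)
    return(NULL)
  }
  ht <- association_2x2(da_other, partners, universe)
  if (is.null(ht)) return(NULL)
  da_u <- intersect(da_other, universe)
  c(ht, list(enriched = ht$std_residual >= 2 && ht$p < 0.05,
             n_partners = length(partners),
             partner_fraction = if (length(da_u))
               length(intersect(da_u, partners)) / length(da_u) else NA_real_))
}

#' Complex-subunit association among differentially abundant proteins
#'
#' As [partner_enrichment_test()] but with the predicate "is a subunit of
#' any known complex". The residual sign distinguishes depletion (negative)
#' from enrichment (positive).
#'
#' @inheritParams partner_enrichment_test
#' @return list(std_residual, p, observed, expected) or NULL when no subunit
#'   lies in the universe.
#' @export
subunit_association_test <- function(da_other, universe, db) {
  subunits <- intersect(names(db$membership), universe)
  if (!length(subunits)) {
    warning("no complex subunits in the universe; test skipped", call. = FALSE)
    return(NULL)
  }
  association_2x2(da_other, subunits, universe)
}

#' Spearman co-abundance correlations for protein pairs across cohorts
#'
#' Per (pair, cohort): Spearman rho (average-rank ties) over pairwise
#' complete samples. Pairs with fewer than \code{min_n} complete samples or
#' a constant vector in a cohort are dropped there (flagged via the
#' \code{dropped} attribute).
#'
#' @param pairs data.frame with columns \code{aneuploid_protein},
#'   \code{partner}; extra columns (e.g. case direction) are carried
#'   through.
#' @param matrices Named list of protein matrices (proteins x samples), one
#'   per cohort / cancer type.
#' @param min_n Minimum pairwise-complete sample count (default 3).
#' @return data.frame (pair columns..., cohort, rho, n_samples).
#' @export
abundance_correlations <- function(pairs, matrices, min_n = 3) {
  stopifnot(is.data.frame(pairs),
            all(c("aneuploid_protein", "partner") %in% names(pairs)),
            is.list(matrices), !is.null(names(matrices)))
  out <- list()
  dropped <- 0L
  for (cohort in names(matrices)) {
    m <- matrices[[cohort]]
    keep <- pairs$aneuploid_protein %in% rownames(m) & pairs$partner %in% rownames(m)
    pk <- pairs[keep, , drop = FALSE]
    if (!nrow(pk)) next
    for (i in seq_len(nrow(pk))) {
      x <- m[pk$aneuploid_protein[i], ]
      y <- m[pk$partner[i], ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        dropped <- dropped + 1L
        next
      }
      row <- pk[i, , drop = FALSE]
      row$cohort <- cohort
      row$rho <- stats::cor(x[ok], y[ok], method = "spearman")
      row$n_samples <- sum(ok)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    cbind(pairs[0, , drop = FALSE],
          data.frame(cohort = character(), rho = numeric(), n_samples = integer()))
  rownames(res) <- NULL
  structure(res, dropped = dropped)
}

#' Pool a correlation table across cohorts (one row per unordered pair)
#'
#' For pairs measured in more than one cohort the maximum correlation is
#' kept: the maximum signed rho by default, or the row with the largest
#' absolute rho.
#'
#' @param table data.frame from [abundance_correlations()].
#' @param method "signed" (default) or "absolute".
#' @return Pooled data.frame, one row per unordered protein pair.
#' @export
pool_correlations <- function(table, method = c("signed", "absolute")) {
  method <- match.arg(method)
  if (!nrow(table)) return(table)
  key <- vapply(seq_len(nrow(table)), function(i)
    paste(sort(c(table$aneuploid_protein[i], table$partner[i])), collapse = "|"),
    character(1))
  score <- if (method == "signed") table$rho else abs(table$rho)
  ord <- order(key, -score, table$cohort)
  t2 <- table[ord, , drop = FALSE]
  res <- t2[!duplicated(key[ord]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare correlation distributions between two pair groups
#'
#' Two-sided Wilcoxon rank-sum test on rho values, e.g. co-complex vs
#' non-complex partners, aggregation-prone vs non-prone aneuploid proteins,
#' or promiscuous vs non-promiscuous.
#'
#' @param table Correlation table (typically pooled).
#' @param group Logical vector aligned with the rows of \code{table}
#'   (TRUE = first group).
#' @param min_group Minimum rows per group (default 3).
#' @return list(p, median_in, median_out, n_in, n_out).
#' @export
compare_correlation_groups <- function(table, group, min_group = 3) {
  stopifnot(nrow(table) == length(group))
  a <- table$rho[group]
  b <- table$rho[!group]
  if (length(a) < min_group || length(b) < min_group) {
    stop(sprintf("correlation groups too small (%d vs %d)", length(a), length(b)))
  }
  list(p = rank_sum_p(a, b),
       median_in = stats::median(a), median_out = stats::median(b),
       n_in = length(a), n_out = length(b))
}

#' Promiscuity classification of proteins
#'
#' A protein is promiscuous when it participates in more than five complexes.
#'
#' @param proteins Character vector of protein IDs.
#' @param db A [complex_db()].
#' @param threshold Complex-count threshold (default 5, strict "more than").
#' @return Character vector in {"promiscuous", "non_promiscuous"}.
#' @export
promiscuity <- function(proteins, db, threshold = 5) {
  n <- vapply(as.character(proteins), function(p)
    length(db$membership[[p]] %||% character(0)), integer(1))
  ifelse(n > threshold, "promiscuous", "non_promiscuous")
}

#' Co-occurrence frequency of two proteins across complexes
#'
#' Number of complexes containing both proteins divided by the number of
#' complexes containing at least one of them. Undefined (NA, with warning)
#' when neither protein occurs in any complex.
#'
#' @param a,b Protein IDs (vectors are processed elementwise).
#' @param db A [complex_db()].
#' @return Numeric vector of fractions in [0, 1] (NA where undefined).
#' @export
co_occurrence_frequency <- function(a, b, db) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ca <- db$membership[[a[i]]] %||% character(0)
    cb <- db$membership[[b[i]]] %||% character(0)
    u <- union(ca, cb)
    if (!length(u)) {
      warning(sprintf("neither %s nor %s occurs in any complex", a[i], b[i]),
              call. = FALSE)
      out[i] <- NA_real_
    } else {
      out[i] <- length(intersect(ca, cb)) / length(u)
    }
  }
  out
}

#' Co-occurrence frequency by correlation class
#'
#' Classifies pairs of a correlation table as positively correlated,
#' negatively correlated or non-correlated (within the \code{band}), and
#' compares co-occurrence frequency distributions between classes with
#' rank-sum tests.
#'
#' @param table Pooled correlation table.
#' @param db A [complex_db()].
#' @param band Half-width of the non-correlated band (default 0.2; positive
#'   means rho > band, negative rho < -band).
#' @return list(class = per-row factor, frequency = per-row co-occurrence,
#'   contrasts = data.frame(group1, group2, p)).
#' @export
co_occurrence_by_correlation_class <- function(table, db, band = 0.2) {
  cls <- cut(table$rho, breaks = c(-Inf, -band, band, Inf),
             labels = c("negative", "non_correlated", "positive"))
  freq <- suppressWarnings(
    co_occurrence_frequency(table$aneuploid_protein, table$partner, db))
  combos <- utils::combn(levels(cls), 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
    g1 <- freq[cls == combos[1, j] & !is.na(freq)]
    g2 <- freq[cls == combos[2, j] & !is.na(freq)]
    data.frame(group1 = combos[1, j], group2 = combos[2, j],
               p = if (length(g1) && length(g2)) rank_sum_p(g1, g2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(class = cls, frequency = freq, contrasts = contrasts)
}
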