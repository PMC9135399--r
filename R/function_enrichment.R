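#' Select top-correlated and background pairs from a correlation table
#'
#' Top pairs are the 20 strongest positive plus the 20 strongest negative
#' correlations (40 in total when available); the background is the
#' non-correlated band rho in [-band, band], with top pairs removed so the
#' two groups are disjoint. Boundary ties are broken by pair ID so the
#' selection is deterministic.
#'
#' @param table Pooled correlation table ([pool_correlations()]).
#' @param n_top Pairs taken from each tail (default 20).
#' @param band Half-width of the background band (default 0.2, inclusive).
#' @return list(top, background (row subsets of \code{table}), flags
#'   (character vector: "short_positive_side", "short_negative_side",
#'   "weak_top" when the top set had to be drawn from inside the band)).
#' @export
select_top_and_background <- function(table, n_top = 20, band = 0.2) {
  if (!nrow(table)) stop("empty correlation table")
  pair_id <- paste(table$aneuploid_protein, table$partner, sep = "|")
  flags <- character(0)
  ord_pos <- order(-table$rho, pair_id)
  ord_neg <- order(table$rho, pair_id)
  pos_avail <- which(table$rho > 0)
  neg_avail <- which(table$rho < 0)
  take_pos <- head(ord_pos[ord_pos %in% pos_avail], n_top)
  take_neg <- head(ord_neg[ord_neg %in% neg_avail], n_top)
  if (length(take_pos) < n_top) flags <- c(flags, "short_positive_side")
  if (length(take_neg) < n_top) flags <- c(flags, "short_negative_side")
  top_idx <- union(take_pos, take_neg)
  if (!length(top_idx)) {
    # degenerate: all rho at zero; take extremes by magnitude
    top_idx <- head(order(-abs(table$rho), pair_id), 2 * n_top)
    flags <- c(flags, "short_positive_side", "short_negative_side")
  }
  if (any(abs(table$rho[top_idx]) <= band)) flags <- c(flags, "weak_top")
  bg_idx <- setdiff(which(table$rho >= -band & table$rho <= band), top_idx)
  if (!length(bg_idx)) stop("background band is empty: no null reference")
  list(top = table[top_idx, , drop = FALSE],
       background = table[bg_idx, , drop = FALSE],
       flags = unique(flags))
}

#' Complexes containing the partner proteins of a pair set
#'
#' @param pairs Rows of a correlation table (needs a \code{partner} column).
#' @param db A [complex_db()].
#' @return Character vector of complex IDs (duplicates collapsed).
#' @export
complexes_of <- function(pairs, db) {
  unique(unlist(db$membership[intersect(unique(pairs$partner),
                                        names(db$membership))],
                use.names = FALSE))
}

#' Functional-term enrichment of top-correlated complexes
#'
#' For each functional term annotating any complex in either group, a 2x2
#' chi-square crosses group membership (top vs background) with term
#' annotation. The enrichment score is the standard residual
#' (O - E)/sqrt(E) of the (top, annotated) cell; terms with p < 0.05 are
#' significant (no multiple-testing correction by default, optionally BH).
#'
#' @param top_complexes,background_complexes Character vectors of complex
#'   IDs (non-empty, as produced by [complexes_of()]).
#' @param db A [complex_db()] carrying the annotations.
#' @param alpha Significance level on p (default 0.05).
#' @param bh Apply Benjamini-Hochberg across terms before thresholding
#'   (default FALSE).
#' @return data.frame (term, observed, expected, enrichment_score, p,
#'   significant) sorted by p. Terms with degenerate tables are skipped.
#' @export
term_enrichment <- function(top_complexes, background_complexes, db,
                            alpha = 0.05, bh = FALSE) {
  top <- setdiff(unique(top_complexes), NULL)
  bg <- unique(background_complexes)
  if (!length(top) || !length(bg)) stop("both complex groups must be non-empty")
  bg <- setdiff(bg, top)
  if (!length(bg)) stop("background complexes all overlap the top set")
  ann <- db$annotations
  terms <- sort(unique(unlist(ann[c(top, bg)], use.names = FALSE)))
  rows <- lapply(terms, function(term) {
    has <- vapply(ann[c(top, bg)], function(a) term %in% a, logical(1))
    in_top <- c(rep(TRUE, length(top)), rep(FALSE, length(bg)))
    tab <- matrix(c(sum(in_top & has), sum(in_top & !has),
                    sum(!in_top & has), sum(!in_top & !has)),
                  nrow = 2, byrow = TRUE)
    ht <- chisq_2x2(tab)
    if (is.null(ht)) return(NULL)
    data.frame(term = term, observed = tab[1, 1], expected = ht$expected[1, 1],
               enrichment_score = standard_residual(tab[1, 1], ht$expected[1, 1]),
               p = ht$p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), observed = integer(),
                      expected = numeric(), enrichment_score = numeric(),
                      p = numeric(), significant = logical()))
  }
  res <- do.call(rbind, rows)
  pv <- if (bh) stats::p.adjust(res$p, method = "BH") else res$p
  res$significant <- pv < alpha
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter a complex database for sensitivity re-runs
#'
#' \code{drop_ribosomal} removes the listed ribosomal genes from all subunit
#' sets (complexes left with fewer than two subunits are dropped);
#' \code{drop_large_complexes} removes complexes with more than
#' \code{max_size} subunits.
#'
#' @param db A [complex_db()].
#' @param variant "none", "drop_ribosomal" or "drop_large_complexes".
#' @param ribosomal_genes Character vector (required for drop_ribosomal).
#' @param max_size Large-complex threshold (default 10; complexes with more
#'   than this many subunits are removed, size-10 complexes are retained).
#' @return A filtered [complex_db()].
#' @export
filter_complex_db <- function(db, variant = c("none", "drop_ribosomal",
                                              "drop_large_complexes"),
                              ribosomal_genes = NULL, max_size = 10) {
  variant <- match.arg(variant)
  if (variant == "none") return(db)
  cx <- db$complexes
  if (variant == "drop_ribosomal") {
    if (is.null(ribosomal_genes)) stop("ribosomal gene list required")
    cx <- lapply(cx, setdiff, y = ribosomal_genes)
  } else {
    cx <- cx[lengths(cx) <= max_size]
  }
  suppressWarnings(complex_db(cx, db$annotations[names(cx)]))
}

#' Full functional-enrichment analysis of a correlation table
#'
#' Runs top/background selection, complex lookup and term enrichment; the
#' sensitivity variants repeat the analysis on a filtered database.
#'
#' @inheritParams select_top_and_background
#' @inheritParams filter_complex_db
#' @param db A [complex_db()].
#' @param ... Passed to [term_enrichment()].
#' @return list(enrichment (data.frame), top_complexes, background_complexes,
#'   selection_flags, variant).
#' @export
functional_enrichment <- function(table, db, variant = "none",
                                  ribosomal_genes = NULL, n_top = 20,
                                  band = 0.2, ...) {
  db_used <- filter_complex_db(db, variant, ribosomal_genes)
  sel <- select_top_and_background(table, n_top = n_top, band = band)
  top_cx <- complexes_of(sel$top, db_used)
  bg_cx <- complexes_of(sel$background, db_used)
  if (!length(top_cx)) stop("filtering left no complexes for the top pairs")
  list(enrichment = term_enrichment(top_cx, bg_cx, db_used, ...),
       top_complexes = top_cx, background_complexes = bg_cx,
       selection_flags = sel$flags, variant = variant)
}
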