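#' Select the top 30 strongest amplification-case correlation pairs
#'
#' Restricts a pooled correlation table to pairs from amplification cases
#' and keeps the \code{n} with the largest absolute rho (signed-positive
#' optionally), with deterministic tie-breaking by pair ID.
#'
#' @param table Pooled correlation table; a \code{direction} column (+1/-1)
#'   marks the case type of each pair, when present. Rows without it are
#'   assumed to come from amplification cases.
#' @param n Number of pairs (default 30).
#' @param use_abs Rank by |rho| (default) or by signed rho.
#' @return Row subset of \code{table}; attribute \code{"short"} is TRUE when
#'   fewer than \code{n} pairs were available.
#' @export
select_top30_pairs <- function(table, n = 30, use_abs = TRUE) {
  if ("direction" %in% names(table)) {
    table <- table[table$direction == 1L, , drop = FALSE]
  }
  table <- table[!is.na(table$rho), , drop = FALSE]
  if (!nrow(table)) stop("no amplification-case pairs with valid correlations")
  pair_id <- paste(table$aneuploid_protein, table$partner, sep = "|")
  score <- if (use_abs) abs(table$rho) else table$rho
  out <- table[order(-score, pair_id), , drop = FALSE]
  short <- nrow(out) < n
  out <- utils::head(out, n)
  rownames(out) <- NULL
  structure(out, short = short)
}

#' Fit per-pair linear models (partner on aneuploid protein)
#'
#' Ordinary least squares of partner abundance on aneuploid-protein
#' abundance over all pairwise-complete samples.
#'
#' @param pairs data.frame with \code{aneuploid_protein}, \code{partner}.
#' @param protein_mat Proteins x samples matrix (NA allowed).
#' @param min_n Minimum complete samples per pair (default 3).
#' @return List of models: each list(aneuploid_protein, partner, slope,
#'   intercept, n, samples). Pairs with a constant predictor or too few
#'   samples are skipped with a warning.
#' @export
fit_pair_models <- function(pairs, protein_mat, min_n = 3) {
  models <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    ap <- pairs$aneuploid_protein[i]
    pp <- pairs$partner[i]
    if (!ap %in% rownames(protein_mat) || !pp %in% rownames(protein_mat)) {
      skipped <- skipped + 1L
      next
    }
    x <- protein_mat[ap, ]
    y <- protein_mat[pp, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n || stats::sd(x[ok]) == 0) {
      skipped <- skipped + 1L
      next
    }
    fit <- stats::lm.fit(cbind(1, x[ok]), y[ok])
    models[[length(models) + 1L]] <- list(
      aneuploid_protein = ap, partner = pp,
      intercept = unname(fit$coefficients[1]),
      slope = unname(fit$coefficients[2]),
      n = sum(ok), samples = colnames(protein_mat)[ok])
  }
  if (skipped) {
    warning(sprintf("%d pair(s) skipped (missing protein, constant predictor or too few samples)",
                    skipped), call. = FALSE)
  }
  models
}

#' Per-sample stoichiometry deviation scores
#'
#' The deviation score of a sample is the mean of absolute residuals across
#' the fitted pair models for which both proteins are measured in that
#' sample. High scores mark samples failing to keep partner abundances on
#' the cohort-wide regression line, i.e. failing stoichiometric
#' compensation.
#'
#' @param models List of models from [fit_pair_models()].
#' @param protein_mat Proteins x samples matrix.
#' @param min_fraction Minimum fraction of models a sample must be scorable
#'   in (default 0.5); samples below it are excluded with a warning.
#' @return data.frame (sample, score, n_models).
#' @export
deviation_scores <- function(models, protein_mat, min_fraction = 0.5) {
  if (!length(models)) stop("at least one model is required")
  samples <- colnames(protein_mat)
  resid <- matrix(NA_real_, nrow = length(models), ncol = length(samples),
                  dimnames = list(NULL, samples))
  for (k in seq_along(models)) {
    m <- models[[k]]
    x <- protein_mat[m$aneuploid_protein, ]
    y <- protein_mat[m$partner, ]
    resid[k, ] <- abs(y - (m$intercept + m$slope * x))
  }
  n_models <- as.integer(colSums(!is.na(resid)))
  names(n_models) <- samples
  score <- colMeans(resid, na.rm = TRUE)
  keep <- n_models >= max(1L, ceiling(min_fraction * length(models)))
  if (any(!keep)) {
    warning(sprintf("%d sample(s) excluded: scorable in too few models",
                    sum(!keep)), call. = FALSE)
  }
  data.frame(sample = samples[keep], score = unname(score[keep]),
             n_models = unname(n_models[keep]), stringsAsFactors = FALSE)
}

# Standardized log-rank statistic |z| for the two groups score <= cut vs
# score > cut; NA when survdiff degenerates (e.g. no events).
logrank_z <- function(time, event, low) {
  if (length(unique(low)) < 2L) return(NA_real_)
  sd <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ low),
                 error = function(e) NULL)
  if (is.null(sd) || !is.finite(sd$chisq)) return(NA_real_)
  sqrt(sd$chisq)
}

#' Stratify survival by stoichiometry deviation score
#'
#' Chooses the cutpoint maximizing the absolute standardized log-rank
#' statistic over the observed scores inside the [10%, 90%] score-quantile
#' window (a maximally selected rank statistic scan), assigns samples with
#' score <= cutpoint to the low group, and reports Kaplan-Meier curves and
#' the log-rank p at the chosen cutpoint. The naive p does not account for
#' cutpoint selection; a permutation-adjusted p is available.
#'
#' @param scores data.frame from [deviation_scores()].
#' @param surv SurvivalTable data.frame (sample, time, event, optional
#'   endpoint column).
#' @param endpoint Endpoint to use when an endpoint column is present
#'   (default "overall").
#' @param quantile_range Candidate-cutpoint window (default c(0.1, 0.9)).
#' @param min_samples,min_event_frac Preconditions (defaults 20 and 0.1).
#' @param adjusted_p Also compute a selection-adjusted permutation p
#'   (default FALSE).
#' @param n_perm Permutations for the adjusted p (default 1000).
#' @param seed Optional seed for the permutation p.
#' @return list(cutpoint, groups (named factor low/high), p, statistic,
#'   adjusted_p (or NA), fit (survfit), curves (data.frame time, surv,
#'   group), n, n_events).
#' @export
survival_stratify <- function(scores, surv, endpoint = "overall",
                              quantile_range = c(0.1, 0.9),
                              min_samples = 20, min_event_frac = 0.1,
                              adjusted_p = FALSE, n_perm = 1000, seed = NULL) {
  if ("endpoint" %in% names(surv)) {
    surv <- surv[surv$endpoint == endpoint, , drop = FALSE]
  }
  m <- merge(scores, surv, by = "sample")
  if (nrow(m) < min_samples) stop("too few samples with both score and survival")
  if (mean(m$event) < min_event_frac) stop("too few events for a log-rank scan")
  if (length(unique(m$score)) == 1L) stop("all deviation scores identical: no cutpoint")
  qs <- stats::quantile(m$score, quantile_range, names = FALSE)
  cand <- sort(unique(m$score[m$score >= qs[1] & m$score <= qs[2]]))
  cand <- cand[cand < max(m$score)] # both groups non-empty
  if (!length(cand)) cand <- sort(unique(m$score))[1]
  zs <- vapply(cand, function(cut)
    logrank_z(m$time, m$event, m$score <= cut), numeric(1))
  if (all(is.na(zs))) {
    cutpoint <- cand[1]
    statistic <- NA_real_
    p <- 1
  } else {
    best <- which.max(zs)
    cutpoint <- cand[best]
    statistic <- zs[best]
    sd <- survival::survdiff(survival::Surv(m$time, m$event) ~ (m$score <= cutpoint))
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  groups <- factor(ifelse(m$score <= cutpoint, "low", "high"),
                   levels = c("low", "high"))
  names(groups) <- m$sample
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = data.frame(time = m$time, event = m$event,
                                             group = groups))
  curves <- data.frame(
    time = fit$time, surv = fit$surv,
    group = rep(sub("^group=", "", names(fit$strata)), fit$strata),
    stringsAsFactors = FALSE)
  adj <- NA_real_
  if (adjusted_p && is.finite(statistic)) {
    if (!is.null(seed)) set.seed(seed)
    perm_max <- vapply(seq_len(n_perm), function(i) {
      s <- sample(m$score)
      max(vapply(cand, function(cut) logrank_z(m$time, m$event, s <= cut),
                 numeric(1)), na.rm = TRUE)
    }, numeric(1))
    adj <- (1 + sum(perm_max >= statistic)) / (n_perm + 1)
  }
  list(cutpoint = cutpoint, groups = groups, p = p, statistic = statistic,
       adjusted_p = adj, fit = fit, curves = curves, n = nrow(m),
       n_events = sum(m$event))
}

#' Correlation of protein abundances with deviation scores
#'
#' Spearman correlation of every protein's abundance with the per-sample
#' deviation scores, and a rank-sum comparison of the degradation-machinery
#' set's rho distribution (proteasome/ubiquitin-binding proteins) against
#' the all-protein rho distribution. Optionally repeated within sample
#' subsets (e.g. amplification and deletion carriers).
#'
#' @param scores data.frame from [deviation_scores()].
#' @param protein_mat Proteins x samples matrix.
#' @param degradation_set Character vector of degradation-machinery protein
#'   IDs (non-empty intersection with the matrix required).
#' @param sample_groups Optional named list of sample ID vectors; the
#'   analysis is repeated within each.
#' @param min_n Minimum pairwise-complete samples per protein (default 5).
#' @return list(rho (data.frame protein, rho, degradation), p,
#'   median_degradation, median_all, subsets (named list of the same shape)).
#' @export
degradation_correlation <- function(scores, protein_mat, degradation_set,
                                    sample_groups = NULL, min_n = 5) {
  degradation_set <- intersect(degradation_set, rownames(protein_mat))
  if (!length(degradation_set)) stop("degradation set empty in the protein matrix")
  run_once <- function(samples) {
    sc <- scores[scores$sample %in% samples, , drop = FALSE]
    sub <- protein_mat[, sc$sample, drop = FALSE]
    rho <- vapply(rownames(sub), function(pr) {
      x <- sub[pr, ]
      ok <- !is.na(x)
      if (sum(ok) < min_n || stats::sd(x[ok]) == 0 || stats::sd(sc$score[ok]) == 0)
        return(NA_real_)
      stats::cor(x[ok], sc$score[ok], method = "spearman")
    }, numeric(1))
    df <- data.frame(protein = rownames(sub), rho = unname(rho),
                     degradation = rownames(sub) %in% degradation_set,
                     stringsAsFactors = FALSE)
    df <- df[!is.na(df$rho), , drop = FALSE]
    list(rho = df,
         p = rank_sum_p(df$rho[df$degradation], df$rho),
         median_degradation = stats::median(df$rho[df$degradation]),
         median_all = stats::median(df$rho))
  }
  main <- run_once(colnames(protein_mat))
  subsets <- NULL
  if (!is.null(sample_groups)) {
    subsets <- lapply(sample_groups, run_once)
  }
  c(main, list(subsets = subsets))
}
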