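#' Default pipeline configuration
#'
#' Documented thresholds for every stage; values follow the analysis
#' conventions used throughout the package (Holm-adjusted p <= 0.05 and
#' residual >= 2 for aneuploidy calls, adjusted p < 0.01 for
#' co-amplifications, BH-adjusted p < 0.1 with the 250-gene raw p < 0.05
#' fallback for transcripts, raw p < 0.1 for proteins, promiscuity above 5
#' complexes, +/-0.4 top-correlation band, +/-0.2 non-correlated band,
#' 20+20 top pairs, top-30 deviation pairs, 100 TF randomizations, and the
#' 10-90% score-quantile cutpoint window).
#'
#' @return Named list of defaults; override any entry through the
#'   \code{config} argument of [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(alpha = 0.05, min_residual = 2, coamp_alpha = 0.01,
       min_type_size = 10, min_group = 5,
       de_adj_alpha = 0.1, fallback_n = 250, fallback_alpha = 0.05,
       protein_alpha = 0.1, min_obs = 3,
       promiscuity_threshold = 5, ubiq_threshold = 0.4,
       corr_band = 0.2, n_top = 20, top_pairs = 30,
       ppi_iters = 200, tf_iters = 100,
       quantile_range = c(0.1, 0.9), adjusted_survival_p = FALSE,
       max_cases = Inf, seed = NULL)
}

stage_result <- function(expr) {
  tryCatch(list(status = "ok", value = suppressWarnings(expr), reason = NULL),
           error = function(e)
             list(status = "skipped", value = NULL, reason = conditionMessage(e)))
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(utils::capture.output(utils::str(cfg)), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full stoichiometry-compensation pipeline on a cohort
#'
#' Executes, in order: whole-chromosome scoring, recurrent-aneuploidy and
#' co-amplification detection, per-case differential transcript/protein
#' calling, co-complex partner and subunit association tests, co-abundance
#' correlations, degree-preserving PPI randomization, regulatory-layer
#' attribution (methylation, TF targets, ubiquitination), per-case
#' functional-term enrichment, and the pooled stoichiometry deviation /
#' survival stage. Stage failures are recorded as skips, not fatal errors,
#' and the whole run is deterministic given the seed.
#'
#' @param cohort A \code{stoich_cohort} (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config Named list overriding entries of [pipeline_defaults()].
#' @return A \code{pipeline_report} list: \code{cases} (per-case stage
#'   results), \code{aneuploidy}, \code{coamplification},
#'   \code{correlations}, \code{comparisons}, \code{stoichiometry} and a
#'   \code{provenance} block (config hash, seed, package version).
#' @export
run_pipeline <- function(cohort, config = list()) {
  stopifnot(inherits(cohort, "stoich_cohort"))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  seed <- cfg$seed %||% cohort$config$seed
  t0 <- proc.time()[["elapsed"]]
  note <- function(fmt, ...) message(sprintf(
    "[%6.1fs] %s", proc.time()[["elapsed"]] - t0, sprintf(fmt, ...)))

  ann <- cohort$annotation
  types <- cohort$sample_info$cancer_type
  names(types) <- cohort$sample_info$sample

  note("scoring chromosomes")
  chrom <- chromosome_scores(cohort$arm_scores)

  note("detecting recurrent aneuploidies")
  detection <- stage_result(detect_recurrent(
    chrom, types, alpha = cfg$alpha, min_residual = cfg$min_residual,
    min_type_size = cfg$min_type_size))
  cases <- detection$value
  report_cases <- list()
  corr_rows <- list()
  de_gene_sets <- list()

  if (!is.null(cases) && nrow(cases)) {
    n_run <- min(nrow(cases), cfg$max_cases)
    for (i in seq_len(n_run)) {
      case <- as.list(cases[i, ])
      case_id <- sprintf("%s_chr%d_%+d", case$cancer_type, case$chromosome,
                         case$direction)
      note("case %s", case_id)
      entry <- list(case = case)
      groups <- suppressWarnings(split_by_case(chrom, types, case,
                                               min_group = cfg$min_group))
      if (is.null(groups)) {
        entry$expression <- list(status = "skipped", value = NULL,
                                 reason = "group sizes below minimum")
        report_cases[[case_id]] <- entry
        next
      }
      entry$groups <- lengths(groups)

      entry$expression <- stage_result({
        de <- differential_test(
          cohort$transcript, groups, mode = "transcript",
          protein_coding = ann$gene[ann$protein_coding],
          adj_alpha = cfg$de_adj_alpha, fallback_n = cfg$fallback_n,
          fallback_alpha = cfg$fallback_alpha)
        de <- locate_features(de, ann, case$chromosome)
        list(result = de, rule = attr(de, "rule"),
             fractions = location_fractions(de))
      })
      if (entry$expression$status == "ok") {
        der <- entry$expression$value$result
        de_gene_sets[[case_id]] <- der$feature[der$significant]
      }

      entry$proteome <- stage_result({
        dp <- differential_test(cohort$protein, groups, mode = "protein",
                                min_obs = cfg$min_obs,
                                protein_alpha = cfg$protein_alpha)
        dp <- locate_features(dp, ann, case$chromosome)
        list(result = dp, fractions = location_fractions(dp))
      })

      if (entry$proteome$status == "ok") {
        dp <- entry$proteome$value$result
        da_aneu_dir <- dp$feature[dp$significant &
                                    dp$location == "aneuploid_chromosome" &
                                    dp$direction == (if (case$direction == 1L)
                                                       "up" else "down")]
        da_other <- dp$feature[dp$significant & dp$location == "other_chromosome"]
        universe <- dp$feature[dp$location == "other_chromosome"]

        entry$partner_association <- stage_result({
          r <- partner_enrichment_test(da_other, da_aneu_dir, universe,
                                       cohort$complex_db)
          if (is.null(r)) stop("empty partner set") else r[names(r) != "table"]
        })
        entry$subunit_association <- stage_result({
          r <- subunit_association_test(da_other, universe, cohort$complex_db)
          if (is.null(r)) stop("no subunits in universe") else r[names(r) != "table"]
        })

        entry$correlations <- stage_result({
          if (!length(da_aneu_dir))
            stop("no direction-consistent aneuploid proteins with partners")
          partner_sets <- lapply(stats::setNames(nm = da_aneu_dir), function(a)
            intersect(co_complex_partners(a, cohort$complex_db), universe))
          partner_sets <- partner_sets[lengths(partner_sets) > 0]
          if (!length(partner_sets))
            stop("no direction-consistent aneuploid proteins with partners")
          pairs <- data.frame(
            aneuploid_protein = rep(names(partner_sets), lengths(partner_sets)),
            partner = unlist(partner_sets, use.names = FALSE),
            stringsAsFactors = FALSE)
          pairs$direction <- case$direction
          pairs$case_id <- case_id
          mat <- cohort$protein[, names(types)[types == case$cancer_type],
                                drop = FALSE]
          tab <- abundance_correlations(pairs,
                                        stats::setNames(list(mat),
                                                        case$cancer_type))
          if (!nrow(tab)) stop("no correlations computable")
          tab
        })
        if (entry$correlations$status == "ok") {
          corr_rows[[case_id]] <- entry$correlations$value
        }

        entry$ppi <- stage_result({
          if (!length(da_aneu_dir) || !length(da_other))
            stop("empty DA protein sets")
          degree_preserving_test(da_aneu_dir, da_other, cohort$network,
                                 n_iter = cfg$ppi_iters,
                                 seed = derive_seed(seed, 100L + i))
        })
        if (entry$ppi$status == "ok") entry$ppi$value$null <- NULL

        entry$functional <- stage_result({
          fe <- functional_enrichment(entry$correlations$value,
                                      cohort$complex_db,
                                      n_top = cfg$n_top, band = cfg$corr_band)
          fe[c("enrichment", "selection_flags")]
        })
      }

      if (entry$expression$status == "ok") {
        der <- entry$expression$value$result
        de_other_up <- der$feature[der$significant & der$direction == "up" &
                                     der$location == "other_chromosome"]
        de_other_down <- der$feature[der$significant & der$direction == "down" &
                                       der$location == "other_chromosome"]
        entry$methylation <- stage_result({
          lapply(list(up = de_other_up, down = de_other_down), function(g) {
            if (!length(g)) return(list(status = "skipped"))
            methylation_shift_test(cohort$methylation, cohort$promoter_map,
                                   g, groups$aneuploid, groups$diploid)
          })
        })
        entry$tf <- stage_result({
          de_all <- der$feature[der$significant]
          de_tfs <- intersect(de_all[der$location[match(de_all, der$feature)] ==
                                       "aneuploid_chromosome"],
                              names(cohort$tf_targets))
          tf_target_randomization(cohort$tf_targets, de_tfs,
                                  c(de_other_up, de_other_down),
                                  n_iter = cfg$tf_iters,
                                  seed = derive_seed(seed, 200L + i))
        })
      }
      report_cases[[case_id]] <- entry
    }
  }

  note("co-amplification analysis")
  coamp <- stage_result({
    if (is.null(cases) || !nrow(cases)) stop("no detected cases")
    ca <- detect_coamplifications(chrom, types, cases, alpha = cfg$coamp_alpha)
    sig <- ca[ca$significant, , drop = FALSE]
    contribs <- list()
    coamp_sets <- list()
    for (cid in names(de_gene_sets)) {
      case <- report_cases[[cid]]$case
      if (case$direction != 1L) next
      partners <- sig$partner_chromosome[sig$cancer_type == case$cancer_type &
                                           sig$chromosome == case$chromosome]
      if (!length(partners)) next
      f <- chromosome_contribution(de_gene_sets[[cid]], ann)
      f <- f[names(f) != as.character(case$chromosome)]
      contribs[[cid]] <- f
      coamp_sets[[cid]] <- as.character(partners)
    }
    list(tests = ca, significant = sig,
         contribution_comparison = if (length(contribs))
           compare_contributions(contribs, coamp_sets)
         else list(p = NA_real_))
  })

  note("pooling correlations")
  pooled_stage <- stage_result({
    if (!length(corr_rows)) stop("no per-case correlation tables")
    pool_correlations(do.call(rbind, corr_rows))
  })
  pooled <- pooled_stage$value

  comparisons <- list(status = "skipped", reason = "no pooled correlations")
  if (!is.null(pooled) && nrow(pooled)) {
    note("group comparisons")
    agg <- cohort$ground_truth$aggregation_prone
    amp <- pooled[pooled$direction == 1L, , drop = FALSE]
    comparisons <- list(
      status = "ok",
      aggregation = stage_result(compare_correlation_groups(
        amp, amp$aneuploid_protein %in% agg)),
      promiscuity = stage_result(compare_correlation_groups(
        amp, promiscuity(amp$aneuploid_protein, cohort$complex_db,
                         cfg$promiscuity_threshold) == "promiscuous")),
      co_occurrence = stage_result(co_occurrence_by_correlation_class(
        pooled, cohort$complex_db, band = cfg$corr_band)),
      ubiquitination = stage_result(ubiquitination_comparison(
        pooled, cohort$ubiquitination, cohort$complex_db,
        threshold = cfg$ubiq_threshold))
    )
  }

  note("stoichiometry deviation and survival")
  stoich <- stage_result({
    if (is.null(pooled) || !nrow(pooled)) stop("no pooled correlations")
    top <- select_top30_pairs(pooled, n = cfg$top_pairs)
    models <- suppressWarnings(fit_pair_models(top, cohort$protein))
    scores <- suppressWarnings(deviation_scores(models, cohort$protein))
    surv <- lapply(stats::setNames(nm = unique(cohort$survival$endpoint)),
                   function(ep) stage_result({
      s <- survival_stratify(scores, cohort$survival, endpoint = ep,
                             quantile_range = cfg$quantile_range,
                             adjusted_p = cfg$adjusted_survival_p,
                             seed = derive_seed(seed, 300L))
      s[c("cutpoint", "p", "statistic", "adjusted_p", "n", "n_events",
          "curves")]
    }))
    amp_samples <- rownames(chrom)[apply(chrom == 1L, 1, any, na.rm = TRUE)]
    del_samples <- rownames(chrom)[apply(chrom == -1L, 1, any, na.rm = TRUE)]
    degr <- stage_result({
      d <- degradation_correlation(
        scores, cohort$protein, cohort$ground_truth$degradation,
        sample_groups = list(amplification = amp_samples,
                             deletion = del_samples))
      d$rho <- NULL
      d$subsets <- lapply(d$subsets, function(s) s[names(s) != "rho"])
      d
    })
    list(n_models = length(models), scores = scores, survival = surv,
         degradation = degr)
  })

  note("done")
  structure(list(
    cases = report_cases,
    aneuploidy = list(detection = detection,
                      n_cases = if (is.null(cases)) 0L else nrow(cases)),
    coamplification = coamp,
    correlations = pooled_stage,
    comparisons = comparisons,
    stoichiometry = stoich,
    provenance = list(config_hash = config_hash(list(cfg, cohort$config)),
                      seed = seed,
                      package_version = as.character(utils::packageVersion("stoichcomp")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d aneuploidy cases, %d stages at top level\n",
              x$aneuploidy$n_cases, length(x) - 1L))
  invisible(x)
}
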