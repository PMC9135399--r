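# Full-precision TSV matrix IO: %.17g formatting guarantees that doubles
# survive the text round trip bit-for-bit; missing values are written "NA".
write_matrix_tsv <- function(m, path, id_col = "feature") {
  chr <- matrix(sprintf("%.17g", m), nrow(m))
  chr[is.na(m)] <- "NA"
  df <- data.frame(rownames(m), chr, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) {
    v <- sprintf("%.17g", df[[j]])
    v[is.na(df[[j]])] <- "NA"
    df[[j]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' TSV matrices (features in rows, first column the feature ID, "NA" for
#' missing), a GMT complex file, TSV edge list, TSV survival and
#' ground-truth sidecar tables, and the configuration as JSON. Numeric
#' values are written at full precision so [read_cohort()] restores them
#' exactly.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "stoich_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  write_tsv(cohort$sample_info, p("samples.tsv"))
  write_matrix_tsv(cohort$arm_scores, p("arm_scores.tsv"), "sample_arm")
  write_matrix_tsv(cohort$transcript, p("transcript.tsv"), "gene")
  write_matrix_tsv(cohort$protein, p("protein.tsv"), "protein")
  write_matrix_tsv(cohort$methylation, p("methylation.tsv"), "promoter")
  write_tsv(cohort$annotation, p("annotation.tsv"))
  write_gmt(cohort$complex_db, p("complexes.gmt"))
  write_tsv(data.frame(protein_a = cohort$network$edges[, 1],
                       protein_b = cohort$network$edges[, 2],
                       stringsAsFactors = FALSE), p("ppi_edges.tsv"))
  write_tsv(data.frame(gene = names(cohort$promoter_map),
                       promoter = unname(cohort$promoter_map),
                       stringsAsFactors = FALSE), p("promoter_map.tsv"))
  write_tsv(data.frame(tf = rep(names(cohort$tf_targets),
                                lengths(cohort$tf_targets)),
                       target = unlist(cohort$tf_targets, use.names = FALSE),
                       stringsAsFactors = FALSE), p("tf_targets.tsv"))
  write_tsv(data.frame(protein = names(cohort$ubiquitination),
                       n_sites = unname(cohort$ubiquitination),
                       stringsAsFactors = FALSE), p("ubiquitination.tsv"))
  write_tsv(cohort$survival, p("survival.tsv"))
  gt <- cohort$ground_truth
  write_tsv(gt$planted, p("ground_truth_planted.tsv"))
  write_tsv(gt$compensated_pairs, p("ground_truth_pairs.tsv"))
  write_tsv(data.frame(sample = names(gt$deviation),
                       deviation = unname(gt$deviation),
                       stringsAsFactors = FALSE), p("ground_truth_samples.tsv"))
  write_tsv(data.frame(
    protein = c(gt$aggregation_prone, gt$degradation),
    label = c(rep("aggregation_prone", length(gt$aggregation_prone)),
              rep("degradation", length(gt$degradation))),
    stringsAsFactors = FALSE), p("ground_truth_labels.tsv"))
  write_matrix_tsv(gt$true_states, p("ground_truth_states.tsv"), "sample")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Validates the edge list (self-loops rejected with file and line) and the
#' GMT file (duplicate subunits deduplicated with a warning) on the way in.
#'
#' @param dir Cohort directory.
#' @return A \code{stoich_cohort} equal to the one written.
#' @export
read_cohort <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop(sprintf("missing cohort file: %s", fp))
    fp
  }
  cfg_raw <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  pa <- as.data.frame(cfg_raw$planted_aneuploidies, stringsAsFactors = FALSE)
  pa$chromosome <- as.integer(pa$chromosome)
  pa$direction <- as.integer(pa$direction)
  cfg_args <- cfg_raw[setdiff(names(cfg_raw), "planted_aneuploidies")]
  config <- do.call(cohort_config, c(cfg_args, list(planted_aneuploidies = pa)))
  rd <- function(f) utils::read.delim(p(f), stringsAsFactors = FALSE,
                                      check.names = FALSE)
  sample_info <- rd("samples.tsv")
  arm_scores <- read_matrix_tsv(p("arm_scores.tsv"))
  transcript <- read_matrix_tsv(p("transcript.tsv"))
  protein <- read_matrix_tsv(p("protein.tsv"))
  methylation <- read_matrix_tsv(p("methylation.tsv"))
  annotation <- rd("annotation.tsv")
  db <- read_gmt(p("complexes.gmt"))
  network <- read_edge_list(p("ppi_edges.tsv"))
  pm <- rd("promoter_map.tsv")
  promoter_map <- stats::setNames(pm$promoter, pm$gene)
  tft <- rd("tf_targets.tsv")
  tf_targets <- split(tft$target, tft$tf)
  tf_targets <- tf_targets[unique(tft$tf)]
  ub <- rd("ubiquitination.tsv")
  ubiquitination <- stats::setNames(as.integer(ub$n_sites), ub$protein)
  survival_tab <- rd("survival.tsv")
  survival_tab$event <- as.integer(survival_tab$event)
  gt_planted <- rd("ground_truth_planted.tsv")
  gt_planted$chromosome <- as.integer(gt_planted$chromosome)
  gt_planted$direction <- as.integer(gt_planted$direction)
  gt_pairs <- rd("ground_truth_pairs.tsv")
  if (nrow(gt_pairs)) {
    gt_pairs$chromosome <- as.integer(gt_pairs$chromosome)
    gt_pairs$direction <- as.integer(gt_pairs$direction)
  }
  gt_samples <- rd("ground_truth_samples.tsv")
  gt_labels <- rd("ground_truth_labels.tsv")
  true_states <- read_matrix_tsv(p("ground_truth_states.tsv"))
  mode(true_states) <- "integer"
  ground_truth <- list(
    planted = gt_planted,
    compensated_pairs = gt_pairs,
    aggregation_prone = gt_labels$protein[gt_labels$label == "aggregation_prone"],
    degradation = gt_labels$protein[gt_labels$label == "degradation"],
    deviation = stats::setNames(as.integer(gt_samples$deviation),
                                gt_samples$sample),
    true_states = true_states)
  structure(list(config = config, sample_info = sample_info,
                 arm_scores = arm_scores, transcript = transcript,
                 protein = protein, annotation = annotation,
                 complex_db = db, network = network, methylation = methylation,
                 promoter_map = promoter_map, tf_targets = tf_targets,
                 ubiquitination = ubiquitination, survival = survival_tab,
                 ground_truth = ground_truth),
            class = "stoich_cohort")
}
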