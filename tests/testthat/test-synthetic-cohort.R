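test_that("generation is deterministic given config and seed", {
  cfg <- small_config(seed = 3)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(planted_aneuploidies = data.frame(
    cancer_type = "CT1", chromosome = 7L, direction = 1L,
    carrier_fraction = 0.04)), "carrier_fraction")
  expect_error(cohort_config(planted_aneuploidies = data.frame(
    cancer_type = "CT9", chromosome = 7L, direction = 1L,
    carrier_fraction = 0.5)), "cancer types")
  expect_error(cohort_config(planted_aneuploidies = data.frame(
    cancer_type = "CT1", chromosome = 30L, direction = 1L,
    carrier_fraction = 0.5)), "chromosome")
  expect_error(cohort_config(n_genes = 5, n_chromosomes = 22))
})

test_that("cohort matrices satisfy their structural invariants", {
  co <- generate_cohort(small_config(seed = 4))
  expect_true(all(co$arm_scores %in% c(-1, 0, 1) | is.na(co$arm_scores)))
  # acrocentric chromosomes carry no p-arm columns
  expect_false(any(paste0(c(13, 14, 15, 21, 22), "p") %in%
                     colnames(co$arm_scores)))
  expect_equal(colSums(co$transcript), rep(1e6, ncol(co$transcript)),
               ignore_attr = TRUE)
  expect_false(anyNA(co$transcript))
  expect_true(all(co$methylation >= 0 & co$methylation <= 1))
  expect_true(anyNA(co$protein))
  expect_true(all(co$ubiquitination >= 0))
  # every compensated pair has both members in the database and the matrix
  gt <- co$ground_truth$compensated_pairs
  expect_true(all(gt$aneuploid_protein %in% rownames(co$protein)))
  expect_true(all(gt$partner %in% rownames(co$protein)))
  expect_true(all(gt$aneuploid_protein %in% names(co$complex_db$membership)))
  expect_true(all(gt$partner %in% names(co$complex_db$membership)))
  expect_true(all(gt$aneuploid_protein %in% co$ground_truth$aggregation_prone))
  # carriers in the truth matrix match the planted fractions
  pa <- co$ground_truth$planted
  for (i in seq_len(nrow(pa))) {
    in_type <- co$sample_info$cancer_type == pa$cancer_type[i]
    carriers <- sum(co$ground_truth$true_states[in_type,
                    as.character(pa$chromosome[i])] == pa$direction[i])
    expect_gte(carriers, round(pa$carrier_fraction[i] * sum(in_type)))
  }
})

test_that("null configuration produces no carrier/non-carrier transcript difference", {
  cfg <- small_config(seed = 5, dosage_effect = 0, compensation_rho = 0,
                      deg_coupling = 0)
  co <- generate_cohort(cfg)
  pa <- co$ground_truth$planted[1, ]
  st <- co$ground_truth$true_states[, as.character(pa$chromosome)]
  in_type <- co$sample_info$cancer_type == pa$cancer_type
  carrier <- co$sample_info$sample[in_type & st == pa$direction]
  dip <- co$sample_info$sample[in_type & st == 0]
  on_chr <- co$annotation$gene[co$annotation$chromosome == pa$chromosome]
  lg <- log2(co$transcript[on_chr, ] + 1)
  d <- rowMeans(lg[, carrier]) - rowMeans(lg[, dip])
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("carrier transcript shift grows strictly with the dosage effect", {
  shifts <- vapply(c(0.3, 0.6, 1.0), function(eff) {
    co <- generate_cohort(small_config(seed = 6, dosage_effect = eff))
    pa <- co$ground_truth$planted[1, ]
    st <- co$ground_truth$true_states[, as.character(pa$chromosome)]
    in_type <- co$sample_info$cancer_type == pa$cancer_type
    carrier <- co$sample_info$sample[in_type & st == pa$direction]
    dip <- co$sample_info$sample[in_type & st == 0]
    on_chr <- co$annotation$gene[co$annotation$chromosome == pa$chromosome]
    lg <- log2(co$transcript[on_chr, ] + 1)
    mean(rowMeans(lg[, carrier]) - rowMeans(lg[, dip]))
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("planted compensation correlation is recovered within 0.1", {
  cfg <- cohort_config(n_samples_per_type = 200, n_genes = 440,
                       n_complexes = 40, n_ppi_edges = 1200, seed = 7)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth$compensated_pairs
  expect_gt(nrow(gt), 10)
  mats <- lapply(split(co$sample_info$sample, co$sample_info$cancer_type),
                 function(s) co$protein[, s, drop = FALSE])
  tab <- abundance_correlations(gt, mats)
  own <- tab[tab$cohort == tab$cancer_type, ]
  expect_lt(abs(mean(own$rho) - cfg$compensation_rho), 0.1)
})

test_that("cohort round-trips through the directory format", {
  co <- generate_cohort(small_config(seed = 8))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$arm_scores, co$arm_scores)
  expect_identical(back$transcript, co$transcript)
  expect_identical(back$protein, co$protein)
  expect_identical(back$methylation, co$methylation)
  expect_equal(back$sample_info, co$sample_info)
  expect_equal(back$annotation, co$annotation)
  expect_equal(back$complex_db$complexes, co$complex_db$complexes)
  expect_equal(back$complex_db$annotations, co$complex_db$annotations)
  expect_identical(back$network$edges, co$network$edges)
  expect_equal(back$promoter_map, co$promoter_map)
  expect_equal(back$tf_targets, co$tf_targets)
  expect_equal(back$ubiquitination, co$ubiquitination)
  expect_equal(back$survival, co$survival)
  expect_equal(back$ground_truth$planted, co$ground_truth$planted)
  expect_equal(back$ground_truth$compensated_pairs,
               co$ground_truth$compensated_pairs)
  expect_equal(back$ground_truth$deviation, co$ground_truth$deviation)
  expect_identical(back$ground_truth$true_states, co$ground_truth$true_states)
  expect_equal(back$config, co$config)
  unlink(dir, recursive = TRUE)
})

test_that("reading rejects malformed inputs", {
  co <- generate_cohort(small_config(seed = 9))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  # inject a self-loop into the edge list
  edges <- readLines(file.path(dir, "ppi_edges.tsv"))
  writeLines(c(edges, "G0001\tG0001"), file.path(dir, "ppi_edges.tsv"))
  expect_error(read_cohort(dir), "self-loop")
  unlink(file.path(dir, "ppi_edges.tsv"))
  expect_error(read_cohort(dir), "missing cohort file")
  unlink(dir, recursive = TRUE)
})
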