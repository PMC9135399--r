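test_that("FPKM to TPM conversion normalizes every sample to one million", {
  m <- matrix(c(1, 2, 5, 4, 0, 16), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  tpm <- fpkm_to_tpm(m)
  expect_equal(colSums(tpm), c(s1 = 1e6, s2 = 1e6))
  # hand-computed ratios for the toy matrix
  expect_equal(tpm["g1", "s1"], 1 / 8 * 1e6)
  expect_equal(tpm["g3", "s2"], 16 / 20 * 1e6)
  # uniform column: every entry 1e6 / G
  u <- matrix(7, 4, 1, dimnames = list(paste0("g", 1:4), "s1"))
  expect_true(all(fpkm_to_tpm(u) == 1e6 / 4))
  # all-zero feature removed; all-zero sample is an error naming it
  z <- rbind(m, g4 = c(0, 0))
  expect_identical(rownames(fpkm_to_tpm(z)), rownames(m))
  bad <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(fpkm_to_tpm(bad), "s2")
})

test_that("quantile normalization maps columns onto the mean order-statistic profile", {
  m <- matrix(c(2, 4, 6, 8, 3, 1, 7, 5), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  qn <- quantile_normalize_log2(m, pseudocount = 1)
  ref <- c(1.5, 3.5, 5.5, 7.5)
  expect_equal(qn[, "s1"], log2(ref + 1), ignore_attr = TRUE)
  expect_equal(qn[, "s2"], log2(ref[c(2, 1, 4, 3)] + 1), ignore_attr = TRUE)
  # identical columns are a fixed point up to the log transform
  ident <- cbind(s1 = c(5, 1, 3), s2 = c(5, 1, 3))
  expect_equal(quantile_normalize_log2(ident), log2(ident + 1),
               ignore_attr = TRUE)
  # rank order within each column is preserved
  set.seed(5)
  r <- matrix(rexp(200), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  qr <- quantile_normalize_log2(r)
  for (j in 1:4) expect_equal(cor(r[, j], qr[, j], method = "spearman"), 1)
})

test_that("quantile normalization matches the limma reference implementation", {
  set.seed(9)
  m <- matrix(round(rexp(300, 0.1)), 60, 5)
  mine <- quantile_normalize_log2(m, pseudocount = 0.5)
  ref <- log2(limma::normalizeQuantiles(m, ties = TRUE) + 0.5)
  expect_equal(mine, ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("case splitting partitions samples by chromosome state", {
  m <- matrix(NA_integer_, 5, 22,
              dimnames = list(paste0("s", 1:5), as.character(1:22)))
  m[, "3"] <- c(1L, 0L, 0L, NA, -1L)
  case <- list(cancer_type = "CT1", chromosome = 3, direction = 1L)
  g <- split_by_case(m, rep("CT1", 5), case, min_group = 1)
  expect_identical(g$aneuploid, "s1")
  expect_identical(g$diploid, c("s2", "s3"))
  # all-diploid case is skipped
  m[, "3"] <- 0L
  expect_warning(g2 <- split_by_case(m, rep("CT1", 5), case, min_group = 1),
                 "skipped")
  expect_null(g2)
})

test_that("rank-sum p-values match the independent normal-approximation oracle", {
  set.seed(21)
  for (k in 1:60) {
    x <- round(rnorm(30, sd = 2), 1)  # rounding forces ties -> normal approx
    y <- round(rnorm(30, sd = 2), 1)
    expect_equal(suppressWarnings(wilcox.test(x, y)$p.value),
                 oracle_wilcox_p(x, y), tolerance = 1e-8)
  }
})

test_that("differential transcript calling applies the fallback threshold rules", {
  set.seed(31)
  samples <- sprintf("s%02d", 1:40)
  groups <- list(aneuploid = samples[1:20], diploid = samples[21:40])
  # large planted-effect case: >= 250 adjusted-significant genes, no fallback
  big <- matrix(rexp(600 * 40, 0.01), 600, 40,
                dimnames = list(sprintf("g%03d", 1:600), samples))
  big[1:300, 1:20] <- big[1:300, 1:20] * 8
  r1 <- differential_test(big, groups, mode = "transcript")
  expect_identical(attr(r1, "rule"), "adj_p_0.1")
  expect_gte(sum(r1$significant), 250)
  # small case: fallback to raw p < 0.05
  small <- big[1:100, ]
  r2 <- differential_test(small, groups, mode = "transcript")
  expect_identical(attr(r2, "rule"), "raw_p_0.05")
  expect_identical(r2$significant, !is.na(r2$raw_p) & r2$raw_p < 0.05)
  # invariants: BH-adjusted p never below raw p, monotone in raw-p order,
  # direction defined exactly for significant features
  expect_true(all(r1$adj_p >= r1$raw_p - 1e-12))
  o <- order(r1$raw_p)
  expect_true(all(diff(r1$adj_p[o]) >= -1e-12))
  expect_identical(!is.na(r1$direction), r1$significant)
  up <- r1$significant & r1$median_diff > 0
  expect_true(all(r1$direction[up] == "up"))
})

test_that("differential protein calling uses raw p < 0.1 and tolerates missingness", {
  set.seed(41)
  samples <- sprintf("s%02d", 1:30)
  groups <- list(aneuploid = samples[1:15], diploid = samples[16:30])
  m <- matrix(rnorm(50 * 30), 50, 30, dimnames = list(sprintf("p%02d", 1:50),
                                                      samples))
  m[1:5, 1:15] <- m[1:5, 1:15] + 3          # planted shift
  m[sample(length(m), 150)] <- NA            # 10% missing
  m[6, 1:13] <- NA                           # feature with < 3 obs in a group
  m[7, ] <- 1                                # constant feature
  r <- differential_test(m, groups, mode = "protein", min_obs = 3)
  expect_identical(attr(r, "rule"), "raw_p_0.1")
  expect_false("p06" %in% r$feature)         # skipped, not zero-filled
  expect_true(all(r$significant[r$feature %in% sprintf("p%02d", 1:5)]))
  expect_equal(r$raw_p[r$feature == "p07"], 1)
  expect_true(r$constant[r$feature == "p07"])
})

test_that("feature location and per-class fractions follow the annotation", {
  ann <- data.frame(gene = paste0("g", 1:10), chromosome = rep(1:2, each = 5))
  res <- data.frame(feature = paste0("g", 1:10),
                    raw_p = seq(0.01, 0.1, length.out = 10),
                    significant = rep(c(TRUE, FALSE), 5))
  loc <- locate_features(res, ann, case_chromosome = 1)
  expect_identical(loc$location,
                   rep(c("aneuploid_chromosome", "other_chromosome"), each = 5))
  f <- location_fractions(loc)
  expect_equal(unname(f["aneuploid_chromosome"]), 3 / 5)
  expect_equal(unname(f["other_chromosome"]), 2 / 5)
  res2 <- rbind(res, data.frame(feature = "unknown", raw_p = 0.5,
                                significant = FALSE))
  expect_warning(loc2 <- locate_features(res2, ann, 1), "unannotated")
  expect_identical(nrow(loc2), 10L)
})
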