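test_that("partner lookup matches exhaustive enumeration", {
  db <- tiny_db()
  expect_setequal(co_complex_partners("a", db), c("b", "c"))
  expect_identical(co_complex_partners("zz", db), character(0))
  expect_identical(co_complex_partners(c("a", "b", "c", "d"), db), character(0))
  set.seed(51)
  for (k in 1:30) {
    cx <- random_complexes()
    db2 <- suppressWarnings(complex_db(cx))
    input <- sample(letters[1:12], sample(1:3, 1))
    expect_setequal(co_complex_partners(input, db2),
                    oracle_partners(input, db2$complexes))
  }
})

test_that("promiscuity uses the more-than-five-complexes rule", {
  cx <- lapply(1:6, function(i) c("hub", paste0("x", i)))
  names(cx) <- paste0("C", 1:6)
  db6 <- complex_db(cx)
  expect_identical(unname(promiscuity("hub", db6)), "promiscuous")
  db5 <- complex_db(cx[1:5])
  expect_identical(unname(promiscuity("hub", db5)), "non_promiscuous")
  expect_identical(unname(promiscuity("absent", db5)), "non_promiscuous")
})

test_that("co-occurrence frequency is the both/either complex ratio and symmetric", {
  together <- complex_db(list(C1 = c("a", "b"), C2 = c("a", "b", "x"),
                              C3 = c("a", "b", "y")))
  expect_equal(co_occurrence_frequency("a", "b", together), 1)
  apart <- complex_db(list(C1 = c("a", "x"), C2 = c("a", "y"),
                           C3 = c("b", "x"), C4 = c("b", "y")))
  expect_equal(co_occurrence_frequency("a", "b", apart), 0)
  mixed <- complex_db(list(C1 = c("a", "b"), C2 = c("a", "x"),
                           C3 = c("a", "y"), C4 = c("b", "z")))
  expect_equal(co_occurrence_frequency("a", "b", mixed), 0.25)
  expect_warning(out <- co_occurrence_frequency("q1", "q2", mixed), "complex")
  expect_true(is.na(out))
  set.seed(61)
  for (k in 1:30) {
    db <- suppressWarnings(complex_db(random_complexes()))
    pair <- sample(letters[1:12], 2)
    f_ab <- suppressWarnings(co_occurrence_frequency(pair[1], pair[2], db))
    f_ba <- suppressWarnings(co_occurrence_frequency(pair[2], pair[1], db))
    expect_identical(f_ab, f_ba)
    expect_equal(f_ab, oracle_cooccur(pair[1], pair[2], db$complexes))
  }
})

test_that("Spearman correlations match the brute-force rank formula", {
  x_inc <- c(1, 2, 3, 5, 8)
  m <- rbind(a = x_inc, b = x_inc * 2 + 1, c = rev(x_inc))
  colnames(m) <- paste0("s", 1:5)
  pairs <- data.frame(aneuploid_protein = c("a", "a"), partner = c("b", "c"))
  tab <- abundance_correlations(pairs, list(T1 = m))
  expect_equal(tab$rho[tab$partner == "b"], 1)
  expect_equal(tab$rho[tab$partner == "c"], -1)
  # tie-rich 8-sample pair against the oracle
  x <- c(1, 1, 2, 3, 3, 3, 4, 5)
  y <- c(2, 1, 1, 3, 3, 4, 4, 4)
  m2 <- rbind(a = x, b = y)
  colnames(m2) <- paste0("s", 1:8)
  tab2 <- abundance_correlations(data.frame(aneuploid_protein = "a",
                                            partner = "b"), list(T1 = m2))
  expect_equal(tab2$rho, oracle_spearman(x, y), tolerance = 1e-10)
  # constant vectors are dropped with the flag
  m3 <- rbind(a = rep(1, 5), b = 1:5)
  colnames(m3) <- paste0("s", 1:5)
  tab3 <- abundance_correlations(data.frame(aneuploid_protein = "a",
                                            partner = "b"), list(T1 = m3))
  expect_identical(nrow(tab3), 0L)
  expect_identical(attr(tab3, "dropped"), 1L)
})

test_that("pooling keeps one row per unordered pair at the maximum correlation", {
  tab <- data.frame(
    aneuploid_protein = c("a", "a", "b", "a"),
    partner = c("b", "b", "a", "c"),
    cohort = c("T1", "T2", "T3", "T1"),
    rho = c(0.2, 0.7, 0.5, -0.4),
    n_samples = 10L)
  pooled <- pool_correlations(tab)
  expect_identical(nrow(pooled), 2L)
  expect_equal(pooled$rho[paste0(pooled$aneuploid_protein,
                                 pooled$partner) %in% c("ab", "ba")], 0.7)
  pooled_abs <- pool_correlations(tab, method = "absolute")
  expect_equal(sort(pooled_abs$rho), c(-0.4, 0.7))
})

test_that("partner enrichment matches brute force in the extreme and is calibrated under the null", {
  cx <- list(C1 = c("ap1", paste0("d", 1:10)))
  db <- complex_db(cx)
  universe <- c(paste0("d", 1:10), paste0("n", 1:30))
  r <- partner_enrichment_test(da_other = paste0("d", 1:10),
                               da_aneuploid = "ap1", universe = universe, db = db)
  tab <- matrix(c(10, 0, 0, 30), 2, byrow = TRUE)
  expect_equal(r$std_residual, oracle_residuals(tab)[1, 1], tolerance = 1e-10)
  expect_true(r$enriched)
  expect_equal(r$partner_fraction, 1)
  expect_warning(r0 <- partner_enrichment_test("d1", character(0), universe, db),
                 "skipped")
  expect_null(r0)
  # independence null: residual exceeds 2 rarely
  set.seed(71)
  universe_big <- sprintf("u%03d", 1:200)
  cx2 <- complex_db(list(C1 = c("ap", sample(universe_big, 40))))
  exceed <- replicate(100, {
    da_other <- sample(universe_big, 50)
    rr <- partner_enrichment_test(da_other, "ap", universe_big, cx2)
    abs(rr$std_residual) >= 2
  })
  expect_lte(mean(exceed), 0.05)
})

test_that("subunit association distinguishes enrichment from depletion", {
  db <- complex_db(list(C1 = c("s1", "s2"), C2 = c("s3", "s4")))
  universe <- c(paste0("s", 1:4), paste0("n", 1:20))
  enr <- subunit_association_test(paste0("s", 1:4), universe, db)
  expect_gt(enr$std_residual, 2)
  dep <- subunit_association_test(paste0("n", 1:10), universe, db)
  expect_lt(dep$std_residual, 0)
  expect_warning(none <- subunit_association_test("n1", paste0("n", 1:5), db),
                 "skipped")
  expect_null(none)
})

test_that("correlation-group comparison detects planted contrasts and guards small groups", {
  set.seed(81)
  tab <- data.frame(
    aneuploid_protein = sprintf("a%03d", 1:200),
    partner = sprintf("p%03d", 1:200),
    rho = c(rnorm(100, 0.55, 0.1), rnorm(100, 0, 0.1)))
  grp <- seq_len(200) <= 100
  r <- compare_correlation_groups(tab, grp)
  expect_lt(r$p, 0.01)
  expect_gt(r$median_in, r$median_out)
  expect_error(compare_correlation_groups(tab, rep(TRUE, 200)), "small")
})

test_that("co-occurrence by correlation class recovers planted co-membership structure", {
  set.seed(91)
  # high-rho pairs co-occur in complexes; low-rho pairs never do
  cx <- c(
    lapply(1:20, function(i) c(paste0("ha", i), paste0("hp", i))),
    lapply(1:20, function(i) c(paste0("la", i), paste0("x", i))),
    lapply(1:20, function(i) c(paste0("lp", i), paste0("y", i))))
  names(cx) <- paste0("C", seq_along(cx))
  db <- complex_db(cx)
  tab <- data.frame(
    aneuploid_protein = c(paste0("ha", 1:20), paste0("la", 1:20)),
    partner = c(paste0("hp", 1:20), paste0("lp", 1:20)),
    rho = c(runif(20, 0.5, 0.9), runif(20, -0.1, 0.1)))
  r <- co_occurrence_by_correlation_class(tab, db)
  expect_true(all(r$frequency >= 0 & r$frequency <= 1, na.rm = TRUE))
  pos_non <- r$contrasts$p[r$contrasts$group1 == "non_correlated" &
                             r$contrasts$group2 == "positive"]
  expect_lt(pos_non, 0.05)
})

test_that("GMT round trip preserves complexes and deduplicates with a warning", {
  db <- complex_db(list(A = c("p1", "p2", "p3"), B = c("p2", "p4")),
                   annotations = list(A = c("t1", "t2"), B = "t3"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(db, path)
  back <- read_gmt(path)
  expect_equal(back$complexes, db$complexes)
  expect_equal(back$annotations, db$annotations)
  writeLines("D\tterm\tp1\tp1\tp2", path)
  expect_warning(dup <- read_gmt(path), "dedup")
  expect_identical(dup$complexes$D, c("p1", "p2"))
})
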