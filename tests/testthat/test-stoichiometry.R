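test_that("top-30 selection keeps the strongest amplification-case pairs", {
  set.seed(181)
  tab <- data.frame(aneuploid_protein = sprintf("a%03d", 1:60),
                    partner = sprintf("p%03d", 1:60),
                    rho = seq(-0.95, 0.95, length.out = 60),
                    direction = c(rep(1L, 40), rep(-1L, 20)))
  top <- select_top30_pairs(tab)
  expect_identical(nrow(top), 30L)
  expect_true(all(top$direction == 1L))
  amp_rho <- abs(tab$rho[tab$direction == 1L])
  expect_equal(sort(abs(top$rho)),
               sort(sort(amp_rho, decreasing = TRUE)[1:30]))
  short <- select_top30_pairs(tab[c(1:10, 41:60), ])
  expect_true(attr(short, "short"))
  expect_identical(nrow(short), 10L)  # only the amplification rows remain
  expect_error(select_top30_pairs(tab[tab$direction == -1L, ]),
               "no amplification")
})

test_that("pair models reproduce exact linear relations and the closed-form OLS oracle", {
  x <- c(1, 2, 3, 4, 5)
  m <- rbind(a = x, b = 2 * x + 1)
  colnames(m) <- paste0("s", 1:5)
  mods <- fit_pair_models(data.frame(aneuploid_protein = "a", partner = "b"), m)
  expect_equal(mods[[1]]$slope, 2)
  expect_equal(mods[[1]]$intercept, 1)
  set.seed(191)
  for (k in 1:40) {
    xx <- rnorm(5)
    yy <- rnorm(5)
    mm <- rbind(a = xx, b = yy)
    colnames(mm) <- paste0("s", 1:5)
    fit <- fit_pair_models(data.frame(aneuploid_protein = "a", partner = "b"),
                           mm)[[1]]
    o <- oracle_ols(xx, yy)
    expect_equal(fit$intercept, unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(fit$slope, unname(o["slope"]), tolerance = 1e-10)
    # least-squares residuals sum to zero
    expect_lt(abs(sum(yy - (fit$intercept + fit$slope * xx))), 1e-8)
  }
  const <- rbind(a = rep(1, 5), b = x)
  colnames(const) <- paste0("s", 1:5)
  expect_warning(none <- fit_pair_models(
    data.frame(aneuploid_protein = "a", partner = "b"), const), "skipped")
  expect_identical(length(none), 0L)
})

test_that("deviation scores are means of absolute residuals", {
  # two models with residuals +0.4 and -0.2 for one sample -> score 0.3
  m <- rbind(x1 = c(0, 1), y1 = c(0.4, 1), x2 = c(0, 1), y2 = c(-0.2, 1))
  colnames(m) <- c("sA", "sB")
  models <- list(
    list(aneuploid_protein = "x1", partner = "y1", intercept = 0, slope = 1),
    list(aneuploid_protein = "x2", partner = "y2", intercept = 0, slope = 1))
  sc <- deviation_scores(models, m)
  expect_equal(sc$score[sc$sample == "sA"], 0.3)
  expect_equal(sc$score[sc$sample == "sB"], 0)
  expect_identical(sc$n_models, c(2L, 2L))
  # adding an all-zero-residual model can only decrease or keep the score
  m2 <- rbind(m, x3 = c(1, 2), y3 = c(1, 2))
  models3 <- c(models, list(list(aneuploid_protein = "x3", partner = "y3",
                                 intercept = 0, slope = 1)))
  sc3 <- deviation_scores(models3, m2)
  expect_true(all(sc3$score <= sc$score + 1e-12))
  # invariant to model ordering
  sc_rev <- deviation_scores(rev(models), m)
  expect_equal(sc_rev$score, sc$score)
  expect_error(deviation_scores(list(), m), "at least one")
})

test_that("samples with doubled residual noise score significantly higher", {
  set.seed(201)
  n <- 200
  samples <- sprintf("s%03d", 1:n)
  noisy <- seq_len(n) > 100
  mats <- lapply(1:15, function(k) {
    x <- rnorm(n)
    y <- 0.8 * x + rnorm(n, sd = ifelse(noisy, 0.8, 0.4))
    rbind(x, y)
  })
  m <- do.call(rbind, mats)
  rownames(m) <- paste0(rep(c("x", "y"), 15), rep(1:15, each = 2))
  colnames(m) <- samples
  pairs <- data.frame(aneuploid_protein = paste0("x", 1:15),
                      partner = paste0("y", 1:15))
  sc <- deviation_scores(fit_pair_models(pairs, m), m)
  p <- wilcox.test(sc$score[noisy], sc$score[!noisy],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("survival stratification finds the planted cutpoint between score clusters", {
  set.seed(211)
  n <- 120
  score <- c(runif(60, 0.1, 0.3), runif(60, 0.7, 0.9))
  hazard <- 0.08 * 3^(score > 0.5)
  time <- pmin(rexp(n, hazard), 20)
  surv <- data.frame(sample = sprintf("s%03d", 1:n),
                     time = time, event = as.integer(time < 20))
  scores <- data.frame(sample = surv$sample, score = score, n_models = 10L)
  st <- survival_stratify(scores, surv)
  # the chosen cutpoint separates the clusters (up to a few edge samples)
  expect_gt(st$cutpoint, 0.3 - 1e-9)
  expect_lt(st$cutpoint, 0.75)
  expect_gt(mean(score[st$groups == "high"]), mean(score[st$groups == "low"]))
  expect_true(st$cutpoint %in% score)          # cutpoint is an observed score
  expect_lt(st$p, 0.05)
  grp <- st$groups
  expect_identical(sort(unique(as.character(grp))), c("high", "low"))
  expect_true(all(as.character(grp[score <= st$cutpoint]) == "low"))
  expect_true(all(as.character(grp[score > st$cutpoint]) == "high"))
  expect_identical(length(grp), as.integer(n)) # exhaustive partition
  # the low group survives better at median follow-up
  tm <- median(time)
  expect_gt(km_at(st$curves, "low", tm), km_at(st$curves, "high", tm))
  expect_error(survival_stratify(transform(scores, score = 1), surv),
               "identical")
})

test_that("selection-adjusted permutation p is available and conservative under the null", {
  set.seed(221)
  n <- 80
  score <- runif(n)
  time <- pmin(rexp(n, 0.1), 15)
  surv <- data.frame(sample = sprintf("s%02d", 1:n), time = time,
                     event = as.integer(time < 15))
  scores <- data.frame(sample = surv$sample, score = score, n_models = 5L)
  st <- survival_stratify(scores, surv, adjusted_p = TRUE, n_perm = 200,
                          seed = 9)
  expect_gte(st$adjusted_p, st$p)  # selection makes the naive p optimistic
  expect_lte(st$adjusted_p, 1)
})

test_that("degradation-machinery coupling with deviation scores is recovered", {
  set.seed(231)
  n <- 150
  samples <- sprintf("s%03d", 1:n)
  dev <- runif(n)
  scores <- data.frame(sample = samples, score = dev, n_models = 10L)
  prot <- matrix(rnorm(80 * n), 80, n,
                 dimnames = list(sprintf("p%02d", 1:80), samples))
  deg <- sprintf("p%02d", 1:10)
  prot[deg, ] <- prot[deg, ] + 2 * rep(dev, each = 10)
  r <- degradation_correlation(scores, prot, deg)
  expect_lt(r$p, 0.05)
  expect_gt(r$median_degradation, r$median_all)
  expect_error(degradation_correlation(scores, prot, "absent"), "empty")
  # subsets run the same analysis within sample groups
  r2 <- degradation_correlation(scores, prot, deg,
                                sample_groups = list(first = samples[1:75]))
  expect_identical(names(r2$subsets), "first")
  expect_true(is.numeric(r2$subsets$first$p))
})
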