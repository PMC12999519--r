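test_that("low-expression filter applies the inclusive 30% boundary", {
  set.seed(1)
  counts <- matrix(rpois(50 * 10, 50), 50, 10)
  counts[1, ] <- 0                              # all zeros
  counts[2, ] <- c(rep(15, 3), rep(0, 7))       # 3/10 supporting: kept
  counts[3, ] <- c(rep(15, 2), rep(0, 8))       # 2/10: removed
  counts[4, ] <- c(rep(9, 10))                  # below min_reads everywhere
  cc <- toy_cohort(counts)
  f <- filter_low_expressed(cc, group_by = NULL)
  expect_false("g001" %in% f$genes)
  expect_true("g002" %in% f$genes)
  expect_false("g003" %in% f$genes)
  expect_false("g004" %in% f$genes)
  # idempotence
  f2 <- filter_low_expressed(f, group_by = NULL)
  expect_identical(f2$counts, f$counts)
  expect_error(filter_low_expressed(cc, min_frac = 0), "min_frac")
})

test_that("TMM factors match a from-scratch implementation of the formula", {
  set.seed(42)
  counts <- matrix(rnbinom(400 * 8, mu = 100, size = 5), 400, 8)
  # composition shift: half the genes 4x in sample 1
  counts[1:200, 1] <- counts[1:200, 1] * 4
  cc <- toy_cohort(counts)
  e <- tmm_normalize(cc)
  expect_equal(unname(e$norm_factors), unname(tmm_oracle(counts)),
               tolerance = 1e-8)
  expect_equal(exp(mean(log(e$norm_factors))), 1, tolerance = 1e-9)
})

test_that("TMM factors ignore pure depth differences", {
  set.seed(7)
  counts <- matrix(rnbinom(300 * 6, mu = 80, size = 10), 300, 6)
  # a pair of columns that are exact 2x copies: all M values are zero
  # after library scaling, so both factors are one
  two <- toy_cohort(cbind(counts[, 1], counts[, 1] * 2))
  expect_equal(unname(tmm_normalize(two)$norm_factors), c(1, 1),
               tolerance = 1e-10)
  counts[, 2] <- counts[, 1] * 2
  f1 <- tmm_normalize(toy_cohort(counts))$norm_factors
  # global depth rescaling of a column moves its factor only through the
  # asymptotic-variance weights (second decimal at most)
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 2
  f2 <- tmm_normalize(toy_cohort(counts2))$norm_factors
  expect_equal(unname(f1), unname(f2), tolerance = 0.01)
  # identical columns give unit factors
  same <- toy_cohort(matrix(rep(counts[, 1], 5), ncol = 5))
  expect_equal(unname(tmm_normalize(same)$norm_factors), rep(1, 5))
  zero <- counts; zero[, 2] <- 0
  expect_error(tmm_normalize(toy_cohort(zero)), "all-zero")
})

test_that("outlier detection flags the independent-noise sample and standardizes", {
  set.seed(3)
  base <- rnorm(200)
  vals <- sapply(1:9, function(i) base + rnorm(200, 0, 0.05))
  vals <- cbind(vals, rnorm(200))   # sample 10 is unrelated noise
  cc <- toy_cohort(matrix(rpois(200 * 10, 50), 200, 10))
  e <- tmm_normalize(cc)
  e$values <- vals
  colnames(e$values) <- e$samples$sample_id
  rep10 <- detect_outliers(e, group_by = "day")
  expect_true(rep10$removed[10])
  expect_false(any(rep10$removed[1:9]))
  expect_equal(mean(rep10$z), 0, tolerance = 1e-8)
  expect_equal(sd(rep10$z), 1, tolerance = 1e-8)
  # identical samples: sd 0 path, warning, no outliers
  e$values <- matrix(rep(base, 10), ncol = 10,
                     dimnames = dimnames(e$values))
  e$values <- e$values + matrix(rnorm(2000, 0, 1e-12), 200, 10)
  expect_warning(repid <- detect_outliers(e, group_by = "day"),
                 "zero connectivity")
  expect_false(any(repid$removed))
  # group of two errors
  e2 <- e
  e2$values <- e$values[, 1:2]
  e2$samples <- e$samples[1:2, ]
  expect_error(detect_outliers(e2, group_by = "day"), "fewer than 3")
})

test_that("covariate regression matches the normal-equations oracle", {
  set.seed(11)
  n <- 30
  meta <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     x1 = rnorm(n), x2 = rnorm(n))
  vals <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), meta$sample_id))
  e <- structure(list(values = vals, norm_factors = rep(1, n),
                      offset = 0.5, samples = meta), class = "expr_matrix")
  r <- regress_covariates(e, covariates = c("x1", "x2"))
  X <- cbind(1, meta$x1, meta$x2)
  for (g in 1:5) {
    beta <- solve(crossprod(X), crossprod(X, vals[g, ]))
    oracle <- vals[g, ] - X %*% beta + mean(vals[g, ])
    expect_equal(unname(r$values[g, ]), drop(oracle), tolerance = 1e-8)
    expect_lt(abs(cor(r$values[g, ], meta$x1)), 1e-8)
  }
  # gene that is an exact linear function of a covariate
  e$values[1, ] <- 2 * meta$x1 + 3
  r2 <- regress_covariates(e, covariates = c("x1", "x2"))
  expect_lt(var(r2$values[1, ]), 1e-20)
  meta$x3 <- meta$x1
  e$samples <- meta
  expect_error(regress_covariates(e, covariates = c("x1", "x3")),
               "collinear")
})

test_that("reproducibility pairs, counts and labels match a hand enumeration", {
  counts <- matrix(rpois(100 * 6, 60), 100, 6)
  cc <- toy_cohort(counts)
  cc$samples$individual_id <- c("I1", "I1", "I1", "I2", "I2", "I3")
  cc$samples$line_id <- c("L1", "L1", "L2", "L3", "L4", "L5")
  e <- tmm_normalize(cc)
  rep_ <- reproducibility_correlations(e)
  expect_equal(nrow(rep_), choose(6, 2))
  lab <- function(s1, s2) rep_$label[rep_$sample1 == s1 & rep_$sample2 == s2]
  expect_equal(lab("S01", "S02"), "same line")
  expect_equal(lab("S01", "S03"), "same individual")
  expect_equal(lab("S01", "S04"), "different individuals")
  # duplicated sample correlates at 1
  e$values[, 2] <- e$values[, 1]
  rep2 <- reproducibility_correlations(e)
  expect_equal(rep2$rho[rep2$sample1 == "S01" & rep2$sample2 == "S02"], 1)
})

test_that("variance fractions recover dominant terms and match a REML oracle", {
  set.seed(21)
  n <- 60
  meta <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     day = factor(rep(c(25, 50, 75, 100), each = 15)),
                     batch = factor(rep_len(c("a", "b", "c", "d", "e", "f"),
                                            n)))
  vals <- rbind(
    dayonly = as.numeric(meta$day) * 2 + rnorm(n, 0, 0.01),
    noise = rnorm(n),
    mixed = rnorm(4)[as.integer(meta$day)] * 1.5 +
      rnorm(6)[as.integer(meta$batch)] + rnorm(n, 0, 0.5))
  colnames(vals) <- meta$sample_id
  e <- structure(list(values = vals, norm_factors = rep(1, n),
                      offset = 0.5, samples = meta), class = "expr_matrix")
  vf <- variance_fractions(e, terms = c("day", "batch"))
  expect_true(all(abs(rowSums(vf) - 1) < 1e-6))
  expect_gt(vf["dayonly", "day"], 0.95)
  expect_gt(vf["noise", "residual"], 0.8)
  oracle <- reml_two_way_oracle(vals["mixed", ], meta$day, meta$batch)
  expect_equal(unname(vf["mixed", c("day", "batch", "residual")]),
               unname(oracle), tolerance = 0.02)
  meta$one <- factor("x")
  e$samples <- meta
  expect_error(variance_fractions(e, terms = "one"), "single level")
})
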