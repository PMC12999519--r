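# build a small expression matrix + metadata directly for the mixed model
lmm_toy <- function(n_ind = 8, per_ind = 2, n_genes = 20, group_sd = 0.5,
                    resid_sd = 0.3, effect = 0, seed = 1) {
  set.seed(seed)
  n <- n_ind * per_ind
  meta <- data.frame(
    sample_id = sprintf("S%02d", 1:n),
    individual_id = rep(sprintf("I%02d", 1:n_ind), each = per_ind),
    form = rep(rep(c("control", "caseA"), each = n_ind / 2 * per_ind)),
    day = rep(25, n), stringsAsFactors = FALSE)
  u <- rnorm(n_ind, 0, group_sd)
  vals <- t(vapply(seq_len(n_genes), function(g)
    effect * (meta$form == "caseA") +
      u[as.integer(factor(meta$individual_id))] + rnorm(n, 0, resid_sd),
    numeric(n)))
  dimnames(vals) <- list(sprintf("g%03d", seq_len(n_genes)), meta$sample_id)
  list(vals = vals, meta = meta)
}

test_that("zero group variance collapses the mixed model to OLS", {
  toy <- lmm_toy(group_sd = 0, resid_sd = 1, seed = 4)
  fits <- fit_gene_lmm(toy$vals, toy$meta, fixed = ~ form)
  for (g in c(1, 7, 20)) {
    ols <- lm(toy$vals[g, ] ~ relevel(factor(toy$meta$form), "control"))
    expect_equal(unname(fits$coef[g, ]), unname(coef(ols)),
                 tolerance = 1e-6)
  }
})

test_that("the REML fit agrees with lmer on data with real group variance", {
  toy <- lmm_toy(group_sd = 0.8, resid_sd = 0.3, effect = 1, seed = 9)
  fits <- fit_gene_lmm(toy$vals, toy$meta, fixed = ~ form)
  for (g in 1:5) {
    dat <- cbind(data.frame(y = toy$vals[g, ]), toy$meta)
    dat$form <- relevel(factor(dat$form), "control")
    lf <- lme4::lmer(y ~ form + (1 | individual_id), data = dat,
                     REML = TRUE)
    expect_equal(unname(fits$coef[g, 2]),
                 unname(lme4::fixef(lf)[2]), tolerance = 1e-3)
  }
})

test_that("correlated within-individual replicates widen SEs over naive OLS", {
  # two replicates per individual sharing a strong individual intercept:
  # treating them as independent understates the contrast SE
  toy <- lmm_toy(n_ind = 10, per_ind = 2, n_genes = 50, group_sd = 0.6,
                 resid_sd = 0.2, effect = 0.5, seed = 5)
  fits <- fit_gene_lmm(toy$vals, toy$meta, fixed = ~ form)
  de <- contrast_form_vs_control(fits, "caseA", 25)
  se_naive <- vapply(seq_len(nrow(toy$vals)), function(g)
    summary(lm(toy$vals[g, ] ~ factor(toy$meta$form)))$coefficients[2, 2],
    numeric(1))
  expect_gt(mean(de$se > se_naive), 0.9)
})

test_that("a planted log2 fold change is recovered on average", {
  toy <- lmm_toy(n_ind = 16, per_ind = 1, n_genes = 200, group_sd = 0,
                 resid_sd = 0.3, effect = 1, seed = 7)
  fits <- fit_gene_lmm(toy$vals, toy$meta, fixed = ~ form)
  de <- contrast_form_vs_control(fits, "caseA", 25)
  expect_lt(abs(mean(de$logFC) - 1), 0.1)
})

test_that("contrasts error on missing levels and are zero for self-contrast", {
  toy <- lmm_toy(seed = 2)
  fits <- fit_gene_lmm(toy$vals, toy$meta, fixed = ~ form)
  expect_error(contrast_form_vs_control(fits, "nosuch", 25),
               "missing form")
  expect_error(contrast_form_vs_control(fits, "caseA", 99), "missing day")
  # the contrast of control against itself is identically zero
  L <- convorg:::contrast_vector(fits, "control", 25)
  expect_true(all(L == 0))
})

test_that("fixed-effect meta-analysis matches the closed form and metafor", {
  rows <- data.frame(gene = "g1", form = c("f1", "f2"), day = 25,
                     logFC = c(1, 3), se = c(1, 1), stat = 0, p = 0.5,
                     fdr = 0.5)
  m <- meta_fixed_effect(rows)
  expect_equal(m$beta, 2)
  expect_equal(m$se, 0.7071, tolerance = 1e-4)
  expect_equal(m$z, 2.8284, tolerance = 1e-4)
  # k identical studies: beta unchanged, se shrinks by sqrt(k)
  k <- 4
  rows_k <- data.frame(gene = "g1", form = paste0("f", 1:k), day = 25,
                       logFC = 0.7, se = 0.2, stat = 0, p = 0.5, fdr = 0.5)
  mk <- meta_fixed_effect(rows_k)
  expect_equal(mk$beta, 0.7)
  expect_equal(mk$se, 0.2 / sqrt(k))
  # single study violates the precondition
  expect_error(meta_fixed_effect(rows[1, ]), "at least 2")
  expect_error(meta_fixed_effect(transform(rows, se = c(1, 0))),
               "positive")
  # meta beta lies within the range of input betas
  set.seed(3)
  rnd <- data.frame(gene = "g1", form = paste0("f", 1:5), day = 25,
                    logFC = rnorm(5), se = runif(5, 0.1, 1), stat = 0,
                    p = 0.5, fdr = 0.5)
  mr <- meta_fixed_effect(rnd)
  expect_gte(mr$beta, min(rnd$logFC))
  expect_lte(mr$beta, max(rnd$logFC))
  # independent oracle: metafor fixed-effect fit
  or <- metafor::rma(yi = rnd$logFC, sei = rnd$se, method = "FE")
  expect_equal(mr$beta, unname(or$beta[, 1]), tolerance = 1e-10)
  expect_equal(mr$se, unname(or$se), tolerance = 1e-10)
})

test_that("CNV summary fractions match a brute-force count", {
  set.seed(8)
  de <- data.frame(gene = sprintf("g%02d", 1:40),
                   form = rep(c("del", "dup"), each = 20), day = 25,
                   logFC = rnorm(40), se = 0.1, stat = 0,
                   p = runif(40, 1e-5, 1), fdr = runif(40, 1e-4, 1))
  sets <- list(del = sprintf("g%02d", 1:10), dup = sprintf("g%02d", 21:30))
  dos <- c(del = 0.5, dup = 1.5)
  cs <- cnv_dosage_summary(de, sets, dos)
  del_rows <- de[de$form == "del" & de$gene %in% sets$del, ]
  expect_equal(cs$frac_expected_direction[cs$form == "del"],
               mean(del_rows$logFC < 0))
  expect_equal(cs$frac_strict_fdr[cs$form == "del"],
               mean(del_rows$fdr < 0.005))
  expect_error(cnv_dosage_summary(de, list(zz = "g01"), dos), "unknown")
  empty <- cnv_dosage_summary(de, list(del = "not_tested"), dos)
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$frac_expected_direction))
})

test_that("peak expression day follows the argmax with earliest-day ties", {
  n <- 12
  meta <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     day = rep(c(25, 50, 75), each = 4))
  vals <- rbind(up = rep(c(1, 2, 3), each = 4),
                tie = rep(1, n),
                rnd = rnorm(n))
  colnames(vals) <- meta$sample_id
  e <- structure(list(values = vals, norm_factors = rep(1, n),
                      offset = 0.5, samples = meta), class = "expr_matrix")
  pk <- peak_expression_day(e)
  expect_equal(pk$peak_day[pk$gene == "up"], 75)
  expect_equal(pk$peak_day[pk$gene == "tie"], 25)
  means <- vapply(c(25, 50, 75), function(d)
    mean(vals["rnd", meta$day == d]), numeric(1))
  expect_equal(pk$peak_day[pk$gene == "rnd"],
               c(25, 50, 75)[which.max(means)])
})

test_that("BH adjustment is monotone and fixes equal-p vectors", {
  expect_equal(adjust_bh(rep(0.2, 6)), rep(0.2, 6))
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_bh(p), rep(0.04, 4))
  set.seed(1)
  pr <- runif(50)
  adj <- adjust_bh(pr)
  expect_true(all(diff(adj[order(pr)]) >= -1e-12))
  expect_true(all(adj >= pr))
})
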