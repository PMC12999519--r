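# vectors with exact pairwise correlations for adjacency checks
exact_cor_pair <- function(r, n = 50) {
  x <- scale(rnorm(n))[, 1]
  y0 <- scale(rnorm(n))[, 1]
  y0 <- scale(y0 - x * sum(x * y0) / sum(x * x))[, 1]
  rbind(x = x, y = r * x + sqrt(1 - r^2) * y0)
}

test_that("signed adjacency maps correlations through the soft power", {
  set.seed(1)
  p1 <- exact_cor_pair(1)
  expect_equal(signed_adjacency(p1, 6)["x", "y"], 1, tolerance = 1e-10)
  pm <- exact_cor_pair(-1)
  expect_equal(signed_adjacency(pm, 6)["x", "y"], 0, tolerance = 1e-10)
  p0 <- exact_cor_pair(0)
  expect_equal(signed_adjacency(p0, 2)["x", "y"], 0.25, tolerance = 1e-10)
  const <- rbind(a = rep(1, 10), b = rnorm(10))
  expect_error(signed_adjacency(const, 6), "constant")
})

test_that("TOM dissimilarity matches the triple-loop oracle", {
  # two genes, a = 0.5: no shared neighbours, k = 0.5
  A2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  d2 <- tom_dissimilarity(A2)
  expect_equal(d2[1, 2], 0.5)
  # identity adjacency: no overlap at all
  dI <- tom_dissimilarity(diag(5))
  expect_true(all(dI[upper.tri(dI)] == 1))
  set.seed(3)
  C <- cor(matrix(rnorm(30 * 20), 30, 20))
  A <- ((1 + C) / 2)^4
  diag(A) <- 1
  expect_equal(tom_dissimilarity(A), tom_oracle(A), tolerance = 1e-10,
               ignore_attr = TRUE)
  bad <- A; bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(tom_dissimilarity(bad), "symmetric")
})

test_that("consensus is the element-wise median and respects form balance", {
  m1 <- matrix(0.2, 3, 3); m2 <- matrix(0.4, 3, 3); m3 <- matrix(0.9, 3, 3)
  med <- convorg:::.matrix_list_median(list(m1, m2, m3))
  expect_equal(med[1, 1], 0.4)
  # permutation invariance in iteration order
  med2 <- convorg:::.matrix_list_median(list(m3, m1, m2))
  expect_identical(med, med2)
  # even count: midpoint
  med4 <- convorg:::.matrix_list_median(list(m1, m2, m3, m3))
  expect_equal(med4[1, 1], 0.65)

  set.seed(2)
  counts <- matrix(rnbinom(60 * 12, mu = 100, size = 5), 60, 12)
  cc <- toy_cohort(counts, forms = rep(c("control", "caseA"), each = 6))
  e <- tmm_normalize(cc)
  np <- network_params(beta = 4, resamples = 3, min_per_form = 4, seed = 3)
  plain <- consensus_resampled_tom(e, params = np, resample = FALSE)
  expect_equal(plain, tom_dissimilarity(signed_adjacency(e, 4)))
  cons <- consensus_resampled_tom(e, params = np)
  expect_true(all(cons >= 0 & cons <= 1))
  cons2 <- consensus_resampled_tom(e, params = np)
  expect_identical(cons, cons2)   # seeded determinism
  small <- toy_cohort(counts, forms = c(rep("control", 9), rep("tiny", 3)))
  es <- tmm_normalize(small)
  expect_error(consensus_resampled_tom(es, params = np), "tiny")
})

test_that("soft threshold scan prefers the smallest power hitting the target", {
  set.seed(5)
  # modular data reaches scale-free-ish fits
  f <- matrix(rnorm(4 * 60), 4, 60)
  loads <- matrix(0, 120, 4)
  for (m in 1:4) loads[((m - 1) * 30 + 1):(m * 30), m] <- runif(30, .6, 1)
  vals <- loads %*% f + matrix(rnorm(120 * 60, 0, 0.6), 120, 60)
  rownames(vals) <- sprintf("g%03d", 1:120)
  ps <- pick_soft_threshold(vals, candidate_betas = 1:12, target_r2 = 0.2)
  expect_true(ps$reached_target)
  reached <- ps$fit_table$beta[ps$fit_table$r2 >= 0.2]
  expect_equal(ps$beta, min(reached))
  # mean connectivity strictly decreases with the power
  expect_true(all(diff(ps$fit_table$mean_connectivity) < 0))
  # white noise cannot reach a strict target
  noise <- matrix(rnorm(60 * 40), 60, 40,
                  dimnames = list(sprintf("n%02d", 1:60), NULL))
  expect_warning(pw <- pick_soft_threshold(noise, candidate_betas = 1:6,
                                           target_r2 = 0.99),
                 "not reached")
  expect_false(pw$reached_target)
})

test_that("planted correlation blocks become modules and noise stays unassigned", {
  set.seed(11)
  n_samp <- 80
  f <- matrix(rnorm(3 * n_samp), 3, n_samp)
  vals <- rbind(
    do.call(rbind, lapply(1:3, function(m)
      outer(runif(60, 0.8, 1.2), f[m, ]) +
        matrix(rnorm(60 * n_samp, 0, 0.5), 60, n_samp))),
    matrix(rnorm(100 * n_samp), 100, n_samp))
  rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
  truth <- c(rep(1:3, each = 60), rep(0, 100))
  np <- network_params(beta = 6, min_module_size = 30, seed = 1)
  diss <- tom_dissimilarity(signed_adjacency(vals, 6))
  lab <- detect_modules(diss, np, expr = vals)
  expect_equal(max(lab), 3)
  planted <- truth > 0
  expect_gte(mclust::adjustedRandIndex(truth[planted], lab[planted]), 0.9)
  # noise majority unassigned
  expect_gt(mean(lab[!planted] == 0), 0.5)
  expect_error(detect_modules(diss, network_params(min_module_size = 1e4)),
               "exceeds")
})

test_that("near-duplicate modules merge at the eigengene step", {
  set.seed(13)
  n_samp <- 60
  f1 <- rnorm(n_samp)
  f2 <- f1 + rnorm(n_samp, 0, 0.2)   # eigengene correlation ~0.98
  f3 <- rnorm(n_samp)
  vals <- rbind(
    outer(rep(1, 40), f1) + matrix(rnorm(40 * n_samp, 0, 0.3), 40),
    outer(rep(1, 40), f2) + matrix(rnorm(40 * n_samp, 0, 0.3), 40),
    outer(rep(1, 40), f3) + matrix(rnorm(40 * n_samp, 0, 0.3), 40))
  rownames(vals) <- sprintf("g%03d", 1:120)
  np <- network_params(beta = 6, min_module_size = 20,
                       cut_height_merge = 0.1, seed = 1)
  diss <- tom_dissimilarity(signed_adjacency(vals, 6))
  lab <- detect_modules(diss, np, expr = vals)
  # f1/f2 blocks merge; f3 stays apart
  expect_equal(max(lab), 2)
  expect_equal(length(unique(lab[1:80][lab[1:80] > 0])), 1)
})

test_that("eigengenes carry the sign convention and SVD variance share", {
  set.seed(17)
  n_samp <- 40
  prof <- rnorm(n_samp)
  vals <- rbind(outer(rep(1, 10), prof),
                matrix(rnorm(10 * n_samp), 10)) +
    matrix(rnorm(20 * n_samp, 0, 1e-3), 20)
  rownames(vals) <- sprintf("g%02d", 1:20)
  lab <- setNames(c(rep(1, 10), rep(0, 10)), rownames(vals))
  ms <- module_eigengenes_kme(vals, lab)
  expect_equal(unname(ms$kme[1:10, "1"]), rep(1, 10), tolerance = 1e-4)
  # sign flip of all module genes flips the eigengene, not |kME|
  vflip <- vals; vflip[1:10, ] <- -vflip[1:10, ]
  msf <- module_eigengenes_kme(vflip, lab)
  expect_equal(abs(msf$kme[1:10, "1"]), abs(ms$kme[1:10, "1"]),
               tolerance = 1e-6)
  expect_equal(unname(msf$eigengenes[, "1"]), -unname(ms$eigengenes[, "1"]),
               tolerance = 1e-6)
  # own-module mean kME is positive under the orientation rule
  expect_gt(mean(ms$kme[1:10, "1"]), 0)
  expect_gt(mean(msf$kme[1:10, "1"]), 0)
  # variance share equals the SVD top eigenvalue share
  sub <- vals[1:10, ]
  Z <- t(scale(t(sub)))
  sv <- svd(Z)
  expect_equal(unname(ms$var_explained["1"]),
               sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-8)
})

test_that("module-trait association recovers planted eigengene shifts", {
  set.seed(19)
  n <- 80
  meta <- data.frame(
    sample_id = sprintf("S%02d", 1:n),
    form = rep(c("control", "fA", "fB", "fC"), each = 20),
    stringsAsFactors = FALSE)
  meta$diagnosis <- ifelse(meta$form == "control", "control", "affected")
  me <- cbind(m1 = rnorm(n, 0, 0.1) - (meta$form == "fA") * 1,
              m2 = rnorm(n, 0, 0.1),
              m3 = rnorm(n, 0, 0.1) - (meta$form != "control") * 0.5)
  rownames(me) <- meta$sample_id
  assoc <- module_trait_association(me, meta)
  a1 <- assoc[assoc$module == "m1" & assoc$term == "form:fA", ]
  expect_equal(a1$beta, -1, tolerance = 0.12)
  a2 <- assoc[assoc$module == "m2" & assoc$term == "diagnosis", ]
  expect_lt(abs(a2$beta), 0.15)
  expect_lt(abs(a2$signed_adjusted_R), 0.3)
  a3 <- assoc[assoc$module == "m3" & assoc$term == "diagnosis", ]
  expect_equal(a3$beta, -0.5, tolerance = 0.12)
  expect_lt(a3$signed_adjusted_R, 0)
})

test_that("trajectory test flags a planted divergent form", {
  set.seed(23)
  n <- 96
  meta <- data.frame(
    sample_id = sprintf("S%02d", 1:n),
    day = rep(rep(c(25, 50, 75, 100), each = 8), 3),
    form = rep(c("control", "fA", "fB"), each = 32),
    stringsAsFactors = FALSE)
  base <- 0.01 * meta$day
  me <- cbind(flat = base + rnorm(n, 0, 0.1),
              diverge = base + (meta$form == "fA") * 0.015 * meta$day +
                rnorm(n, 0, 0.1))
  rownames(me) <- meta$sample_id
  tt <- module_trajectory_test(me, meta)
  expect_lt(tt$p[tt$module == "diverge" & tt$form == "fA"], 0.05)
  expect_gt(tt$p[tt$module == "flat" & tt$form == "fB"], 0.05)
  # spline basis has exactly df columns
  expect_equal(ncol(splines::bs(meta$day, df = 2, degree = 2)), 2)
  expect_error(module_trajectory_test(me, transform(meta, day = 25)),
               "3 distinct days")
})

test_that("module preservation separates real structure from noise", {
  set.seed(29)
  n_samp <- 50
  f <- matrix(rnorm(2 * n_samp), 2, n_samp)
  mkdata <- function(fmat) {
    v <- rbind(outer(runif(40, .7, 1), fmat[1, ]),
               outer(runif(40, .7, 1), fmat[2, ]),
               matrix(rnorm(40 * n_samp), 40)) +
      matrix(rnorm(120 * n_samp, 0, 0.4), 120)
    rownames(v) <- sprintf("g%03d", 1:120)
    v
  }
  ref <- mkdata(f)
  lab <- setNames(c(rep(1, 40), rep(2, 40), rep(0, 40)), rownames(ref))
  # same data: strong preservation
  zs <- module_preservation_lite(ref, lab, ref, n_perm = 50, seed = 1)
  expect_true(all(zs$z_summary > 10))
  # independent noise: no preservation
  noise <- matrix(rnorm(120 * n_samp), 120,
                  dimnames = list(rownames(ref), NULL))
  zn <- module_preservation_lite(ref, lab, noise, n_perm = 50, seed = 1)
  expect_true(all(abs(zn$z_summary) < 3))
  # random labels on real data: null by construction
  set.seed(2)
  rl <- setNames(sample(lab), names(lab))
  zr <- module_preservation_lite(ref, rl, mkdata(f), n_perm = 50, seed = 1)
  expect_true(all(abs(zr$z_summary) < 3))
})
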