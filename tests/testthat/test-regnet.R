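# hand-built module set: labels plus a controlled kME matrix
hand_modules <- function(labels, kme) {
  structure(list(labels = labels, kme = kme,
                 eigengenes = matrix(0, 2, ncol(kme),
                                     dimnames = list(NULL, colnames(kme))),
                 var_explained = setNames(rep(1, ncol(kme)),
                                          colnames(kme))),
            class = "module_set")
}

toy_modules <- function() {
  genes <- c(paste0("u", 1:3), paste0("v", 1:4))
  labels <- setNames(c(1, 1, 1, 2, 2, 2, 2), genes)
  kme <- matrix(0.5, length(genes), 2,
                dimnames = list(genes, c("1", "2")))
  kme[c("v1", "v2"), "2"] <- c(0.9, 0.7)
  hand_modules(labels, kme)
}

test_that("the regulation score is the kME-weighted regulated fraction", {
  ms <- toy_modules()
  annot <- data.frame(regulator = c("u1", "u2", "u1"),
                      target = c("v1", "v2", "v1"),  # v1 hit twice
                      high_confidence = TRUE)
  # (0.9 + 0.7) / 4, counting v1 once despite two regulators
  expect_equal(module_regulation_score(ms, annot, 1, 2), 0.4)
  # no regulators in U
  none <- annot[0, ]
  expect_equal(module_regulation_score(ms, none, 1, 2), 0)
  # everything targeted at kME 1 reaches the upper bound
  full <- data.frame(regulator = "u1", target = paste0("v", 1:4),
                     high_confidence = TRUE)
  ms1 <- ms; ms1$kme[, "2"] <- 1
  expect_equal(module_regulation_score(ms1, full, 1, 2), 1)
  # low-confidence annotations are ignored
  lc <- transform(annot, high_confidence = FALSE)
  expect_equal(module_regulation_score(ms, lc, 1, 2), 0)
  expect_error(module_regulation_score(ms, annot, 2, 2), "differ")
})

test_that("the score grows when another positively weighted target is added", {
  ms <- toy_modules()
  a1 <- data.frame(regulator = "u1", target = "v1",
                   high_confidence = TRUE)
  a2 <- rbind(a1, data.frame(regulator = "u1", target = "v2",
                             high_confidence = TRUE))
  expect_gt(module_regulation_score(ms, a2, 1, 2),
            module_regulation_score(ms, a1, 1, 2))
})

test_that("the edge threshold is mean + one population SD, strictly exceeded", {
  # engineer scores {0, 0.1, 0.2, 0.3, 0.4} over 5 ordered pairs is not
  # directly possible with modules; check the arithmetic on the scores
  x <- c(0, 0.1, 0.2, 0.3, 0.4)
  thr <- mean(x) + sd(x) * sqrt(4 / 5)
  expect_equal(thr, 0.3414, tolerance = 1e-4)
  expect_equal(sum(x > thr), 1)

  # and the graph machinery end-to-end on a planted design
  genes <- c(paste0("u", 1:4), paste0("a", 1:4), paste0("b", 1:4))
  labels <- setNames(rep(1:3, each = 4), genes)
  kme <- matrix(0.1, 12, 3, dimnames = list(genes, as.character(1:3)))
  kme[paste0("a", 1:4), "2"] <- 0.8
  kme[paste0("b", 1:4), "3"] <- 0.8
  ms <- hand_modules(labels, kme)
  annot <- data.frame(regulator = rep(paste0("u", 1:2), each = 4),
                      target = c(paste0("a", 1:4), paste0("b", 1:4)),
                      high_confidence = TRUE)
  g <- regulation_graph(ms, annot)
  edges <- g$scores[g$scores$is_edge, ]
  expect_setequal(paste(edges$from, edges$to), c("1 2", "1 3"))
  expect_equal(g$out_degree$out_degree[g$out_degree$module == 1], 2)
  expect_equal(g$out_degree$frac_modules_regulated[g$out_degree$module == 1],
               1)
  single <- hand_modules(setNames(rep(1, 4), paste0("u", 1:4)),
                         matrix(1, 4, 1, dimnames = list(paste0("u", 1:4),
                                                         "1")))
  expect_error(regulation_graph(single, annot), "at least 2")
})

test_that("regulator-target correlations report the negative fraction", {
  set.seed(3)
  n <- 60
  reg <- rnorm(n)
  vals <- rbind(r1 = reg,
                t1 = -0.8 * reg + rnorm(n, 0, 0.3),
                t2 = 0.8 * reg + rnorm(n, 0, 0.3),
                flat = rep(1, n))
  annot <- data.frame(regulator = "r1", target = c("t1", "t2", "flat"),
                      high_confidence = TRUE)
  rc <- regulator_target_correlations(vals, annot)
  expect_equal(rc$skipped, 1L)
  expect_lt(rc$pairs$rho[rc$pairs$target == "t1"], 0)
  expect_equal(rc$fraction_negative, mean(rc$pairs$rho < 0))
  self <- data.frame(regulator = "r1", target = "r1",
                     high_confidence = TRUE)
  expect_equal(regulator_target_correlations(vals, self)$pairs$rho, 1)
})

test_that("risk-gene table enumerates downstream regulated risk genes once", {
  genes <- c("u1", "u2", "v1", "v2", "v3", "w1", "w2")
  labels <- setNames(c(1, 1, 2, 2, 2, 3, 3), genes)
  kme <- matrix(0.9, 7, 3, dimnames = list(genes, as.character(1:3)))
  ms <- hand_modules(labels, kme)
  annot <- data.frame(regulator = c("u1", "u2", "u1"),
                      target = c("v1", "v1", "v2"),
                      high_confidence = TRUE)
  g <- regulation_graph(ms, annot)
  expect_true(any(g$scores$is_edge))
  risk <- list(riskA = c("v1", "w1"), riskB = c("v1", "v3"))
  tab <- regulated_riskgene_table(g, ms, annot, risk)
  expect_equal(nrow(tab[tab$gene == "v1", ]), 1)
  expect_equal(tab$regulators[tab$gene == "v1"], "u1,u2")
  expect_equal(tab$risk_sets[tab$gene == "v1"], "riskA,riskB")
  expect_false("v3" %in% tab$gene)   # not a target
  expect_false("w1" %in% tab$gene)   # module 3 is not downstream
  # no risk genes downstream -> empty
  tab2 <- regulated_riskgene_table(g, ms, annot, list(r = "w2"))
  expect_equal(nrow(tab2), 0)
})

test_that("graph edges ignore gene order within modules", {
  set.seed(5)
  genes <- c(paste0("u", 1:4), paste0("a", 1:4), paste0("b", 1:4))
  labels <- setNames(rep(1:3, each = 4), genes)
  kme <- matrix(runif(36, 0, 0.4), 12, 3,
                dimnames = list(genes, as.character(1:3)))
  kme[paste0("a", 1:4), "2"] <- 0.9
  ms <- hand_modules(labels, kme)
  annot <- data.frame(regulator = "u1", target = paste0("a", 1:4),
                      high_confidence = TRUE)
  g1 <- regulation_graph(ms, annot)
  perm <- sample(genes)
  ms2 <- hand_modules(labels[perm], kme[perm, ])
  g2 <- regulation_graph(ms2, annot)
  expect_equal(g1$scores[order(g1$scores$from, g1$scores$to), "score"],
               g2$scores[order(g2$scores$from, g2$scores$to), "score"])
})

test_that("annotation harmonization drops duplicates and foreign genes", {
  annot <- data.frame(regulator = c("r1", "r1", "r2"),
                      target = c("t1", "t1", "zz"),
                      high_confidence = TRUE)
  h <- harmonize_annotation(annot, c("r1", "r2", "t1"))
  expect_equal(nrow(h), 1)
  expect_equal(attr(h, "dropped"), 1L)
})
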