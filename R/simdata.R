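#' Simulation configuration for a multi-form organoid cohort
#'
#' Collects every tunable of the cohort generator. Defaults emulate the
#' structure of a multi-form stem-cell cohort: nine disorder forms plus a
#' control group, four differentiation days, a handful of individuals per
#' form with nested lines and differentiations, planted co-expression
#' modules, a per-day convergence schedule that mixes form-specific and
#' shared differential-expression effects, CNV dosage genes, and a set of
#' repressive transcriptional regulators residing in the first module.
#'
#' The per-day form effect for gene g, form f, day d is
#' `(1 - s_d) * specific(g, f) + s_d * shared(g)` where `s_d` is
#' `convergence_schedule[d]`. The expected cross-form correlation of the
#' planted effect vectors is therefore monotone in `s_d`.
#'
#' @param n_genes number of genes.
#' @param n_forms number of forms including the control group.
#' @param days strictly increasing numeric day labels.
#' @param individuals_per_form,lines_per_individual,diffs_per_line nesting
#'   counts; every differentiation is profiled at every day.
#' @param n_modules number of planted co-expression modules.
#' @param module_size_range length-2 integer range of module sizes (>= 3).
#' @param nb_dispersion negative-binomial dispersion alpha in
#'   `Var = mu + alpha * mu^2`; values below 1e-8 fall back to Poisson.
#' @param convergence_schedule per-day shared fraction `s_d` in \[0, 1\].
#' @param form_effect_sd,shared_effect_sd log2 SDs of the form-specific and
#'   shared effect components.
#' @param cnv_genes_per_form number of dosage-affected genes per non-control
#'   form (disjoint across forms).
#' @param cnv_dosage dosage multiplier (0.5 deletion, 1.5 duplication);
#'   scalar or one value per non-control form.
#' @param n_regulators number of regulator genes planted in module 1.
#' @param regulator_effect log2 effect of upstream module activity on each
#'   regulated target (targets are repressed: higher module-1 activity
#'   lowers target expression).
#' @param target_fraction fraction of each downstream module targeted by
#'   the planted regulators.
#' @param downstream_modules module ids regulated by the module-1 regulators.
#' @param intercept_sd named numeric: log2 SDs of the nested random
#'   intercepts (individual, line, differentiation).
#' @param baseline_log2_mean,baseline_log2_sd log-normal baseline of gene
#'   abundance on the log2 scale.
#' @param day_trend_sd per-gene SD of the linear maturation trend.
#' @param module_loading_range uniform range of module factor loadings.
#' @param covariate_effect_sd log2 SD of per-gene sex and batch effects.
#' @param pc_effect_sd log2 SD of per-gene ancestry/sequencing PC effects.
#' @param n_seq_pcs number of technical sequencing PCs simulated.
#' @param libsize_sdlog log-normal SD of per-sample depth factors.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_forms = 10,
                       days = c(25, 50, 75, 100),
                       individuals_per_form = 4,
                       lines_per_individual = 1,
                       diffs_per_line = 1,
                       n_modules = 8,
                       module_size_range = c(40, 80),
                       nb_dispersion = 0.1,
                       convergence_schedule = c(0.1, 0.3, 0.6, 0.9),
                       form_effect_sd = 0.5,
                       shared_effect_sd = 0.5,
                       cnv_genes_per_form = 20,
                       cnv_dosage = 0.5,
                       n_regulators = 10,
                       regulator_effect = 0.25,
                       target_fraction = 0.6,
                       downstream_modules = 2:4,
                       intercept_sd = c(individual = 0.3, line = 0.15,
                                        differentiation = 0.15),
                       baseline_log2_mean = 6,
                       baseline_log2_sd = 1.5,
                       day_trend_sd = 0.3,
                       module_loading_range = c(0.4, 0.8),
                       covariate_effect_sd = 0.1,
                       pc_effect_sd = 0.05,
                       n_seq_pcs = 2,
                       libsize_sdlog = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(days) < 1 || is.unsorted(days, strictly = TRUE))
    stop("days must be strictly increasing")
  if (length(convergence_schedule) != length(days))
    stop("invalid schedule: convergence_schedule must have one entry per day")
  if (any(convergence_schedule < 0 | convergence_schedule > 1))
    stop("invalid schedule: entries must lie in [0, 1]")
  if (n_forms < 2) stop("need at least one form besides control")
  if (any(module_size_range < 3)) stop("module sizes must be >= 3")
  if (any(cnv_dosage <= 0)) stop("cnv dosage must be positive")
  if (nb_dispersion < 0) stop("nb_dispersion must be non-negative")
  if (n_modules > 0 && max(downstream_modules) > n_modules)
    cfg$downstream_modules <- downstream_modules[downstream_modules <= n_modules]
  class(cfg) <- "sim_config"
  cfg
}

form_names <- function(n_forms) {
  c("control", sprintf("form%02d", seq_len(n_forms - 1)))
}

#' Simulate a multi-form organoid cohort with ground truth
#'
#' Generates negative-binomial counts whose log2 means combine a per-gene
#' baseline, a maturation trend over days, planted module latent factors,
#' per-day form effects mixing form-specific and shared components
#' according to the convergence schedule, CNV dosage shifts, nested random
#' intercepts (individual, line, differentiation), sex/batch/PC covariate
#' effects and per-sample depth. Every planted parameter is recorded in the
#' returned truth object for recovery testing.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `cohort` (a `cohort_counts`) and `truth`
#'   (a `sim_truth` list: `module_labels`, `form_effects` (gene x form x
#'   day), `shared_effect` (gene x day), `cnv_genes`, `regulators`,
#'   `regulator_targets` (signed), `module_factors`, `log2_mean`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  forms <- form_names(cfg$n_forms)
  aff_forms <- forms[-1]
  n_days <- length(cfg$days)

  ## ---- sample metadata (nested individual / line / differentiation) ----
  meta <- do.call(rbind, lapply(seq_along(forms), function(fi) {
    f <- forms[fi]
    do.call(rbind, lapply(seq_len(cfg$individuals_per_form), function(ii) {
      ind <- sprintf("%s_I%02d", f, ii)
      do.call(rbind, lapply(seq_len(cfg$lines_per_individual), function(li) {
        lin <- sprintf("%s_L%d", ind, li)
        do.call(rbind, lapply(seq_len(cfg$diffs_per_line), function(di) {
          dif <- sprintf("%s_D%d", lin, di)
          data.frame(individual_id = ind, line_id = lin,
                     differentiation_id = dif, day = cfg$days,
                     form = f, stringsAsFactors = FALSE)
        }))
      }))
    }))
  }))
  meta$sample_id <- sprintf("%s_day%03d", meta$differentiation_id, meta$day)
  meta$diagnosis <- ifelse(meta$form == "control", "control", "affected")
  n_ind <- length(unique(meta$individual_id))
  ind_sex <- setNames(sample(c("F", "M"), n_ind, replace = TRUE),
                      unique(meta$individual_id))
  meta$sex <- unname(ind_sex[meta$individual_id])
  meta$batch <- sample(paste0("B", 1:2), nrow(meta), replace = TRUE)
  meta$ancestry_pc1 <- rnorm(nrow(meta))
  meta$ancestry_pc2 <- rnorm(nrow(meta))
  for (k in seq_len(cfg$n_seq_pcs))
    meta[[paste0("seq_pc", k)]] <- rnorm(nrow(meta))
  meta <- meta[, c("sample_id", "individual_id", "line_id",
                   "differentiation_id", "day", "form", "diagnosis", "sex",
                   "batch", "ancestry_pc1", "ancestry_pc2",
                   paste0("seq_pc", seq_len(cfg$n_seq_pcs)))]
  n_samp <- nrow(meta)

  ## ---- module structure ----
  module_labels <- integer(cfg$n_genes)
  if (cfg$n_modules > 0) {
    sizes <- sample(seq(cfg$module_size_range[1], cfg$module_size_range[2]),
                    cfg$n_modules, replace = TRUE)
    if (sum(sizes) > cfg$n_genes)
      stop("module sizes exceed gene count; increase n_genes")
    idx <- sample(cfg$n_genes, sum(sizes))
    module_labels[idx] <- rep(seq_len(cfg$n_modules), times = sizes)
  }
  loadings <- runif(cfg$n_genes, cfg$module_loading_range[1],
                    cfg$module_loading_range[2])
  module_factors <- if (cfg$n_modules > 0)
    matrix(rnorm(cfg$n_modules * n_samp), cfg$n_modules, n_samp,
           dimnames = list(NULL, meta$sample_id)) else NULL

  ## ---- form effects with convergence schedule ----
  shared <- rnorm(cfg$n_genes, 0, cfg$shared_effect_sd)
  specific <- matrix(rnorm(cfg$n_genes * length(aff_forms), 0,
                           cfg$form_effect_sd),
                     cfg$n_genes, length(aff_forms),
                     dimnames = list(genes, aff_forms))
  s <- cfg$convergence_schedule
  form_effects <- array(0, dim = c(cfg$n_genes, length(aff_forms), n_days),
                        dimnames = list(genes, aff_forms, cfg$days))
  shared_effect <- outer(shared, s)
  dimnames(shared_effect) <- list(genes, cfg$days)
  for (d in seq_len(n_days))
    form_effects[, , d] <- (1 - s[d]) * specific + s[d] * shared

  ## ---- CNV genes (disjoint across forms) ----
  dosage <- rep_len(cfg$cnv_dosage, length(aff_forms))
  names(dosage) <- aff_forms
  cnv_genes <- list()
  if (cfg$cnv_genes_per_form > 0) {
    pool <- sample(genes, cfg$cnv_genes_per_form * length(aff_forms))
    cnv_genes <- split(pool, rep(aff_forms, each = cfg$cnv_genes_per_form))
  }

  ## ---- regulators in module 1 repressing downstream-module targets ----
  regulators <- character(0)
  regulator_targets <- list()
  reg_effect_gene <- numeric(cfg$n_genes)
  if (cfg$n_regulators > 0 && cfg$n_modules >= 2) {
    m1 <- which(module_labels == 1)
    if (length(m1) < cfg$n_regulators)
      stop("module 1 too small to host the requested regulators")
    regulators <- genes[sample(m1, cfg$n_regulators)]
    down <- cfg$downstream_modules
    targ <- genes[module_labels %in% down]
    targ <- sample(targ, round(cfg$target_fraction * length(targ)))
    reg_of_target <- sample(regulators, length(targ), replace = TRUE)
    regulator_targets <- lapply(setNames(regulators, regulators), function(r)
      data.frame(target = targ[reg_of_target == r],
                 sign = -1L, stringsAsFactors = FALSE))
    reg_effect_gene[match(targ, genes)] <- cfg$regulator_effect
  }

  ## ---- per-gene nuisance effects ----
  baseline <- rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  day_trend <- rnorm(cfg$n_genes, 0, cfg$day_trend_sd)
  day_span <- diff(range(cfg$days))
  day_scaled <- if (day_span > 0)
    (meta$day - mean(cfg$days)) / day_span else rep(0, nrow(meta))
  sex_eff <- rnorm(cfg$n_genes, 0, cfg$covariate_effect_sd)
  batch_eff <- rnorm(cfg$n_genes, 0, cfg$covariate_effect_sd)
  pc_cols <- c("ancestry_pc1", "ancestry_pc2",
               paste0("seq_pc", seq_len(cfg$n_seq_pcs)))
  pc_eff <- matrix(rnorm(cfg$n_genes * length(pc_cols), 0, cfg$pc_effect_sd),
                   cfg$n_genes, length(pc_cols))

  rand_int <- function(ids, sd) {
    u <- unique(ids)
    eff <- matrix(rnorm(cfg$n_genes * length(u), 0, sd), cfg$n_genes,
                  length(u), dimnames = list(NULL, u))
    eff[, ids, drop = FALSE]
  }
  isd <- cfg$intercept_sd
  re <- rand_int(meta$individual_id, isd[["individual"]]) +
    rand_int(meta$line_id, isd[["line"]]) +
    rand_int(meta$differentiation_id, isd[["differentiation"]])

  ## ---- assemble log2 means ----
  log2mu <- matrix(baseline, cfg$n_genes, n_samp) +
    outer(day_trend, day_scaled) + re +
    outer(sex_eff, as.numeric(meta$sex == "M")) +
    outer(batch_eff, as.numeric(meta$batch == "B2")) +
    pc_eff %*% t(as.matrix(meta[, pc_cols]))
  if (cfg$n_modules > 0) {
    L <- matrix(0, cfg$n_genes, cfg$n_modules)
    L[cbind(which(module_labels > 0), module_labels[module_labels > 0])] <-
      loadings[module_labels > 0]
    log2mu <- log2mu + L %*% module_factors
  }
  day_idx <- match(meta$day, cfg$days)
  form_idx <- match(meta$form, aff_forms)  # NA for control
  for (j in seq_len(n_samp)) {
    if (!is.na(form_idx[j]))
      log2mu[, j] <- log2mu[, j] + form_effects[, form_idx[j], day_idx[j]]
  }
  for (f in names(cnv_genes)) {
    cols <- meta$form == f
    log2mu[match(cnv_genes[[f]], genes), cols] <-
      log2mu[match(cnv_genes[[f]], genes), cols] + log2(dosage[[f]])
  }
  if (length(regulators) && cfg$n_modules > 0) {
    # repression: target log2 mean decreases with upstream module-1 activity
    log2mu <- log2mu - outer(reg_effect_gene, module_factors[1, ])
  }

  ## ---- sample counts ----
  lib <- rlnorm(n_samp, 0, cfg$libsize_sdlog)
  mu <- 2^log2mu * rep(lib, each = cfg$n_genes)
  counts <- if (cfg$nb_dispersion < 1e-8) {
    matrix(rpois(length(mu), mu), cfg$n_genes, n_samp)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           cfg$n_genes, n_samp)
  }
  dimnames(counts) <- list(genes, meta$sample_id)

  cohort <- cohort_counts(counts, meta)
  tab <- table(meta$form)
  if (any(tab < 4)) {
    attr(cohort, "low_form_warning") <- names(tab)[tab < 4]
    warning("some forms have fewer than 4 samples; ",
            "balanced network resampling downstream will fail")
  }

  truth <- structure(list(
    module_labels = setNames(module_labels, genes),
    form_effects = form_effects,
    shared_effect = shared_effect,
    cnv_genes = cnv_genes,
    cnv_dosage = dosage,
    regulators = regulators,
    regulator_targets = regulator_targets,
    module_factors = module_factors,
    log2_mean = log2mu,
    config = unclass(cfg)), class = "sim_truth")

  list(cohort = cohort, truth = truth)
}

#' Simulate a single-cell reference with planted marker genes
#'
#' Per-cell counts follow a negative binomial around cell-type mean
#' profiles in which each type's marker genes are elevated by `marker_fc`.
#' Marker sets are disjoint across types, so markers have maximal
#' specificity in their own type by construction.
#'
#' @param genes gene identifiers (the bulk gene universe).
#' @param n_celltypes number of cell types (>= 2).
#' @param cells_per_type cells per type (>= 3).
#' @param markers_per_type markers per type (>= 5).
#' @param marker_fc fold elevation of a marker in its own type.
#' @param depth expected per-cell library size.
#' @param nb_dispersion negative-binomial dispersion.
#' @param seed RNG seed.
#' @return list with `reference` (class `reference_profiles`: `counts`
#'   gene x cell, `celltypes`, `markers`) and `specificity` (gene x type
#'   expression shares, rows sum to 1).
#' @export
simulate_single_cell_reference <- function(genes,
                                           n_celltypes = 4,
                                           cells_per_type = 50,
                                           markers_per_type = 25,
                                           marker_fc = 8,
                                           depth = 5000,
                                           nb_dispersion = 0.3,
                                           seed = 1L) {
  if (n_celltypes < 2) stop("need at least 2 cell types")
  if (markers_per_type < 5) stop("need at least 5 marker genes per type")
  set.seed(seed)
  n_genes <- length(genes)
  types <- paste0("type", seq_len(n_celltypes))
  if (markers_per_type * n_celltypes > n_genes)
    stop("marker sets would overlap: not enough genes")
  marker_pool <- sample(genes, markers_per_type * n_celltypes)
  markers <- split(marker_pool, rep(types, each = markers_per_type))

  base <- rlnorm(n_genes, log(10), 1)
  profiles <- matrix(base, n_genes, n_celltypes,
                     dimnames = list(genes, types))
  for (t in types)
    profiles[markers[[t]], t] <- profiles[markers[[t]], t] * marker_fc
  rel <- sweep(profiles, 2, colSums(profiles), "/")

  celltypes <- rep(types, each = cells_per_type)
  mu <- rel[, celltypes, drop = FALSE] * depth
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                   n_genes, length(celltypes),
                   dimnames = list(genes,
                                   paste0("cell", seq_along(celltypes))))
  specificity <- sweep(rel, 1, rowSums(rel), "/")
  list(reference = structure(list(counts = counts,
                                  celltypes = factor(celltypes),
                                  markers = markers),
                             class = "reference_profiles"),
       specificity = specificity)
}

#' Simulate an IP-MS bait x prey logFC table with planted edges
#'
#' True bait-prey edges receive `logfc ~ Normal(effect, sigma)`, non-edges
#' `Normal(0, sigma)`; each (bait, prey) cell is independently zeroed with
#' probability `1 - detection_prob`, emulating undetected interactors that
#' are zero-imputed downstream.
#'
#' @param n_baits number of bait proteins (members of the planted clique).
#' @param universe_size total detected-protein universe (> clique size).
#' @param clique_size proteins in the planted connected set (>= n_baits);
#'   the first `n_baits` of them are the baits.
#' @param effect mean logFC on planted edges.
#' @param sigma logFC noise SD.
#' @param detection_prob probability a cell is detected at all.
#' @param seed RNG seed.
#' @return list with `table` (class `ipms_table`) and `truth` (planted
#'   member set and edge pairs).
#' @export
simulate_ipms <- function(n_baits = 6,
                          universe_size = 300,
                          clique_size = 15,
                          effect = 2,
                          sigma = 0.5,
                          detection_prob = 0.8,
                          seed = 1L) {
  if (universe_size <= clique_size)
    stop("universe must be larger than the planted network")
  set.seed(seed)
  prot <- sprintf("P%04d", seq_len(universe_size))
  members <- prot[seq_len(clique_size)]
  baits <- members[seq_len(n_baits)]
  logfc <- matrix(rnorm(n_baits * universe_size, 0, sigma),
                  n_baits, universe_size, dimnames = list(baits, prot))
  for (b in baits) {
    tgt <- setdiff(members, b)
    logfc[b, tgt] <- rnorm(length(tgt), effect, sigma)
  }
  det <- matrix(runif(length(logfc)) < detection_prob,
                n_baits, universe_size)
  logfc[!det] <- 0
  logfc[cbind(seq_len(n_baits), match(baits, prot))] <- 0  # self entries
  edges <- do.call(rbind, lapply(baits, function(b)
    data.frame(bait = b, prey = setdiff(members, b),
               stringsAsFactors = FALSE)))
  list(table = ipms_table(baits, prot, logfc),
       truth = list(members = members, edges = edges, effect = effect))
}

#' Simulate a CROP-seq style screen (cells, gRNA UMIs, knockdown)
#'
#' Cell-by-gene counts follow a negative binomial; in cells truly carrying
#' a target's guide the target gene's mean is multiplied by
#' `1 - knockdown_fraction`. The gRNA UMI table includes sub-threshold and
#' multi-guide cells so the assignment rules are exercised.
#'
#' @param genes gene identifiers; targets are drawn from these.
#' @param n_targets number of knockdown target genes.
#' @param targets optional explicit target genes (overrides `n_targets`).
#' @param guides_per_target guides designed per target.
#' @param n_ntc_guides non-targeting control guides.
#' @param cells_per_guide cells truly carrying each guide.
#' @param knockdown_fraction fraction of target expression removed, in
#'   (0, 1); scalar or one value per target.
#' @param downstream_targets optional named list (target gene ->
#'   character vector of downstream genes) describing repressive
#'   regulator-target relationships: in cells carrying a target's guide
#'   the downstream genes are de-repressed by `downstream_fc`.
#' @param downstream_fc fold elevation of de-repressed downstream genes.
#' @param n_replicates replicate libraries cells are split across.
#' @param umi_mean mean gRNA UMI count in a carrying cell.
#' @param sub_threshold_frac fraction of cells whose guide UMI is forced
#'   below the assignment threshold.
#' @param multi_guide_frac fraction of cells receiving a second guide of a
#'   different target above threshold.
#' @param depth expected per-cell library size.
#' @param nb_dispersion negative-binomial dispersion.
#' @param mito_frac_genes number of genes renamed `MT-*` to exercise QC.
#' @param seed RNG seed.
#' @return list with `counts` (gene x cell), `grna_umi` (long data frame:
#'   cell, guide, umi), `guide_map` (guide, target, is_ntc), `replicates`
#'   (cell to replicate), and `truth` (per-cell true guide/target and
#'   per-target knockdown fraction).
#' @export
simulate_cropseq <- function(genes,
                             n_targets = 6,
                             targets = NULL,
                             guides_per_target = 3,
                             n_ntc_guides = 4,
                             cells_per_guide = 60,
                             knockdown_fraction = 0.75,
                             downstream_targets = NULL,
                             downstream_fc = 1.5,
                             n_replicates = 6,
                             umi_mean = 40,
                             sub_threshold_frac = 0.1,
                             multi_guide_frac = 0.05,
                             depth = 20000,
                             nb_dispersion = 0.2,
                             mito_frac_genes = 10,
                             seed = 1L) {
  if (n_targets < 1 || n_ntc_guides < 1)
    stop("need at least 1 target and 1 non-targeting control guide")
  if (any(knockdown_fraction <= 0 | knockdown_fraction >= 1))
    stop("knockdown_fraction must lie in (0, 1)")
  set.seed(seed)
  n_genes <- length(genes)
  if (mito_frac_genes > 0) {
    mito_idx <- seq_len(mito_frac_genes)
    genes[mito_idx] <- sprintf("MT-%s", genes[mito_idx])
  }
  if (is.null(targets)) {
    targets <- sample(setdiff(genes, grep("^MT-", genes, value = TRUE)),
                      n_targets)
  } else {
    stopifnot(all(targets %in% genes))
    n_targets <- length(targets)
  }
  kd <- setNames(rep_len(knockdown_fraction, n_targets), targets)
  guide_map <- rbind(
    data.frame(guide = sprintf("%s_g%d", rep(targets, each = guides_per_target),
                               seq_len(guides_per_target)),
               target = rep(targets, each = guides_per_target),
               is_ntc = FALSE, stringsAsFactors = FALSE),
    data.frame(guide = sprintf("NTC_g%d", seq_len(n_ntc_guides)),
               target = "NTC", is_ntc = TRUE, stringsAsFactors = FALSE))

  n_cells <- cells_per_guide * nrow(guide_map)
  cells <- sprintf("C%05d", seq_len(n_cells))
  true_guide <- rep(guide_map$guide, each = cells_per_guide)
  true_target <- guide_map$target[match(true_guide, guide_map$guide)]
  replicates <- setNames(sample(paste0("rep", seq_len(n_replicates)),
                                n_cells, replace = TRUE), cells)

  ## gRNA UMI table
  umi <- pmax(1L, rnbinom(n_cells, mu = umi_mean, size = 2))
  sub <- runif(n_cells) < sub_threshold_frac
  umi[sub] <- sample(1:9, sum(sub), replace = TRUE)
  grna <- data.frame(cell = cells, guide = true_guide, umi = umi,
                     stringsAsFactors = FALSE)
  multi <- which(runif(n_cells) < multi_guide_frac)
  if (length(multi)) {
    other <- vapply(true_guide[multi], function(g)
      sample(setdiff(guide_map$guide,
                     guide_map$guide[guide_map$target ==
                                       guide_map$target[guide_map$guide == g]]),
             1), character(1))
    grna <- rbind(grna, data.frame(cell = cells[multi], guide = other,
                                   umi = pmax(10L, rnbinom(length(multi),
                                                           mu = umi_mean,
                                                           size = 2)),
                                   stringsAsFactors = FALSE))
  }

  ## expression counts
  base <- rlnorm(n_genes, log(5), 1.2)
  rel <- base / sum(base)
  mu <- matrix(rel * depth, n_genes, n_cells,
               dimnames = list(genes, cells))
  for (t in targets) {
    carrier <- true_target == t
    mu[t, carrier] <- mu[t, carrier] * (1 - kd[[t]])
    down <- intersect(downstream_targets[[t]], genes)
    if (length(down))
      mu[down, carrier] <- mu[down, carrier] * downstream_fc
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                   n_genes, n_cells, dimnames = list(genes, cells))

  list(counts = counts, grna_umi = grna, guide_map = guide_map,
       replicates = replicates,
       truth = list(true_guide = setNames(true_guide, cells),
                    true_target = setNames(true_target, cells),
                    knockdown_fraction = kd))
}

#' Derive a regulator-to-target annotation table from simulation truth
#'
#' Emulates the output of a motif-database scan: the true planted
#' regulator-target pairs plus false-positive pairs added at rate `fpr`
#' over the remaining (regulator, gene) candidate space. All planted
#' regulators are flagged high-confidence.
#'
#' @param truth a `sim_truth` from [simulate_cohort()].
#' @param fpr false-positive pair rate in \[0, 1).
#' @param seed RNG seed.
#' @return data frame (regulator, target, high_confidence); class
#'   `regulator_annotation`.
#' @export
simulate_regulator_annotations <- function(truth, fpr = 0, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (fpr < 0 || fpr >= 1) stop("fpr must lie in [0, 1)")
  set.seed(seed)
  regs <- truth$regulators
  if (!length(regs))
    return(structure(data.frame(regulator = character(0),
                                target = character(0),
                                high_confidence = logical(0)),
                     class = c("regulator_annotation", "data.frame")))
  true_pairs <- do.call(rbind, lapply(regs, function(r) {
    tt <- truth$regulator_targets[[r]]
    if (!nrow(tt)) return(NULL)
    data.frame(regulator = r, target = tt$target, stringsAsFactors = FALSE)
  }))
  genes <- names(truth$module_labels)
  annot <- true_pairs
  if (fpr > 0) {
    key <- paste(true_pairs$regulator, true_pairs$target)
    cand <- expand.grid(regulator = regs, target = genes,
                        stringsAsFactors = FALSE)
    cand <- cand[!(paste(cand$regulator, cand$target) %in% key) &
                   cand$regulator != cand$target, ]
    keep <- runif(nrow(cand)) < fpr
    annot <- rbind(true_pairs, cand[keep, ])
  }
  annot$high_confidence <- TRUE
  annot <- annot[!duplicated(paste(annot$regulator, annot$target)), ]
  rownames(annot) <- NULL
  class(annot) <- c("regulator_annotation", "data.frame")
  annot
}
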