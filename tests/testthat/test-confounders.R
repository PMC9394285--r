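# ---- ASCA decomposition ------------------------------------------------------

test_that("a balanced two-factor design gives orthogonal effect matrices", {
  withr::with_seed(81, {
    f1 <- rep(c("u", "v"), each = 20)
    f2 <- rep(c("x", "y"), 20)
    m <- matrix(rnorm(40 * 6), 40, 6)
    m[f1 == "u", 1] <- m[f1 == "u", 1] + 2
    m[f2 == "x", 2] <- m[f2 == "x", 2] + 1
  })
  dec <- asca_decompose(m, list(a = f1, b = f2), with_interaction = TRUE)
  ip <- function(x, y) sum(x * y)
  expect_lt(abs(ip(dec$effects$a, dec$effects$b)), 1e-8)
  expect_lt(abs(ip(dec$effects$a, dec$effects$`a:b`)), 1e-8)
  expect_lt(abs(ip(dec$effects$b, dec$effects$`a:b`)), 1e-8)
})

test_that("a null factor takes a negligible share of the variance", {
  # a 2-level null factor absorbs ||E||/||Xc|| ~ sqrt(1/n) of the norm
  withr::with_seed(82, {
    m <- matrix(rnorm(200 * 10), 200, 10)
    cl <- rep(c("c1", "c2"), each = 100)
  })
  dec <- asca_decompose(m, list(cluster = cl))
  xc <- scale(m, center = TRUE, scale = FALSE)
  ratio <- sqrt(sum(dec$effects$cluster^2)) / sqrt(sum(xc^2))
  expect_lt(ratio, 2 * sqrt(1 / 200))

  withr::with_seed(182, {
    m8 <- matrix(rnorm(800 * 10), 800, 10)
    cl8 <- rep(c("c1", "c2"), each = 400)
  })
  dec8 <- asca_decompose(m8, list(cluster = cl8))
  xc8 <- scale(m8, center = TRUE, scale = FALSE)
  expect_lt(sqrt(sum(dec8$effects$cluster^2)) / sqrt(sum(xc8^2)), 0.05)
})

test_that("a 3-sample one-factor toy equals the hand computation", {
  m <- matrix(c(1, 2, 6,
                2, 4, 9), 3, 2)
  f <- c("a", "a", "b")
  dec <- asca_decompose(m, list(g = f))
  # grand means: (3, 5); centered: col1 = (-2, -1, 3), col2 = (-3, -1, 4)
  # level a mean = (-1.5, -2); level b mean = (3, 4)
  expect_equal(dec$effects$g[1, ], c(-1.5, -2))
  expect_equal(dec$effects$g[2, ], c(-1.5, -2))
  expect_equal(dec$effects$g[3, ], c(3, 4))
  expect_equal(dec$residuals[1, ], c(-2, -3) - c(-1.5, -2))
})

test_that("reconstruction and removal idempotence hold across random designs", {
  withr::with_seed(83, {
    for (rep in 1:5) {
      n <- 24
      m <- matrix(rnorm(n * 5), n, 5)
      f1 <- sample(c("p", "q"), n, replace = TRUE)
      f2 <- rep(c("s", "t"), n / 2)
      wi <- rep %% 2 == 0
      dec <- tryCatch(asca_decompose(m, list(a = f1, b = f2),
                                     with_interaction = wi),
                      error = function(e) NULL)
      if (is.null(dec)) next  # a draw with an empty cell
      xc <- scale(m, center = TRUE, scale = FALSE)
      recon <- Reduce(`+`, dec$effects) + dec$residuals
      expect_lt(max(abs(recon - xc)), 1e-10)
      for (e in dec$effects) expect_lt(max(abs(colMeans(e))), 1e-12)
      # removing an effect then re-decomposing finds nothing left
      corr <- asca_correct(dec, "a")
      dec2 <- asca_decompose(corr, list(a = f1))
      expect_lt(sqrt(sum(dec2$effects$a^2)), 1e-8)
    }
  })
})

test_that("an empty design cell fails naming the cell", {
  m <- matrix(rnorm(30), 10, 3)
  f1 <- rep(c("c1", "c2"), 5)
  f2 <- c(rep("CS", 4), rep("PA", 6))
  f1[f2 == "CS"] <- "c2"  # no CS in cluster c1
  expect_error(asca_decompose(m, list(cluster = f1, disease = f2),
                              with_interaction = TRUE),
               "c1:CS")
  # without the interaction the decomposition is fine
  expect_silent(asca_decompose(m, list(cluster = f1, disease = f2)))
})

test_that("asca_correct validates its arguments", {
  m <- matrix(rnorm(40), 10, 4)
  dec <- asca_decompose(m, list(g = rep(c("a", "b"), 5)))
  xc <- scale(m, center = TRUE, scale = FALSE)
  expect_equal(unname(asca_correct(dec, character())), unname(xc),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(asca_correct(dec, "bogus"), "unknown effect")
  expect_error(asca_correct(dec, c("g", "residuals")), "nothing")
})

# ---- deconfounding through CV2 ----------------------------------------------

make_confounded <- function(seed, n = 60, disease_peaks = NULL, d = 1,
                            cluster_scale = 0.5) {
  cfg <- sim_config(
    n_per_cell = tibble::tibble(center = rep(c("A1", "B1"), each = 2),
                                disease = rep(c("PHT", "PA"), 2), n = n / 2),
    centers = tibble::tibble(center = c("A1", "B1"), cluster = c(1, 2)),
    cluster_effect_scale = cluster_scale, lod = 0, noise_sd = 0.3,
    disease_effects = if (is.null(disease_peaks)) list() else
      list(PA = list(peaks = disease_peaks, shift = d)),
    sample_age_model = list(range = list(PHT = c(100, 110), PA = c(100, 110)),
                            age_slope = 0, cluster_corr = 0),
    batch_sd = 0, run_order_slope = 0, n_qc = 2, n_hv = 2, seed = seed)
  sim <- simulate_cohort(cfg)
  m <- log(peaks_to_matrix(sim$peaks))
  study <- sim$meta[sim$meta$role == "STUDY", ]
  m <- m[rownames(m) %in% study$sample_id, ]
  study <- study[match(rownames(m), study$sample_id), ]
  list(x = m, cluster = paste0("c", study$cluster), disease = study$disease)
}

test_that("fold-internal effect removal brings the removed factor to chance", {
  dat <- make_confounded(seed = 84)
  cfg <- cv_config(outer_repeats = 10, max_ncomp = 3, seed = 7)
  r0 <- cv2_evaluate(dat$x, dat$cluster, "plsda", cfg)
  ba0 <- dplyr::filter(glance(r0), metric == "balanced_accuracy")$mean
  expect_gt(ba0, 90)  # the confounder is strongly learnable before correction
  r1 <- cv2_evaluate(dat$x, dat$cluster, "plsda", cfg,
                     correction = list(factors = tibble::tibble(cluster = dat$cluster),
                                       remove = "cluster"))
  ba1 <- dplyr::filter(glance(r1), metric == "balanced_accuracy")$mean
  expect_lt(abs(ba1 - 50), 5)
})

test_that("an orthogonal disease effect survives the correction", {
  peaks5 <- c("1.457", "4.041", "2.695", "8.441", "0.981")  # off the template
  dat <- make_confounded(seed = 85, n = 100, disease_peaks = peaks5, d = 1)
  cfg <- cv_config(outer_repeats = 10, max_ncomp = 3, seed = 8)
  before <- cv2_evaluate(dat$x, dat$disease, "plsda", cfg)
  after <- cv2_evaluate(dat$x, dat$disease, "plsda", cfg,
                        correction = list(factors = tibble::tibble(cluster = dat$cluster),
                                          remove = "cluster"))
  ba_b <- dplyr::filter(glance(before), metric == "balanced_accuracy")$mean
  ba_a <- dplyr::filter(glance(after), metric == "balanced_accuracy")$mean
  expect_lte(abs(ba_b - ba_a), 3)
})

# ---- confounder signatures ---------------------------------------------------

test_that("the cluster signature recovers the injected template", {
  hits <- vapply(1:10, function(s) {
    dat <- make_confounded(seed = 900 + s, n = 120, cluster_scale = 0.5)
    sig <- confounder_signature(dat$x, dat$cluster,
                                cv_config(outer_repeats = 5, max_ncomp = 3,
                                          seed = s))
    ns <- default_peak_namespace()
    tpl <- table4_template()
    template_peaks <- ns$ppm[ns$metabolite %in% names(tpl)]
    n_tpl <- length(intersect(sig$feature, template_peaks))
    n_extra <- length(setdiff(sig$feature, template_peaks))
    # directions must match the template for recovered peaks
    sgn <- tpl[ns$metabolite[match(sig$feature, ns$ppm)]]
    ok_dir <- all(sig$direction == unname(sgn), na.rm = TRUE)
    (n_tpl >= 12) && (n_extra <= 3) && ok_dir
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("without confounding the cluster signature is nearly empty", {
  small <- vapply(1:10, function(s) {
    dat <- make_confounded(seed = 950 + s, n = 80, cluster_scale = 0)
    sig <- confounder_signature(dat$x, dat$cluster,
                                cv_config(outer_repeats = 5, max_ncomp = 2,
                                          seed = s))
    nrow(sig) <= 0.1 * ncol(dat$x)
  }, logical(1))
  expect_gte(mean(small), 0.9)
})

test_that("the small-group PCA contrast finds the delayed-storage pattern", {
  ns <- default_peak_namespace()
  glu_up <- ns$ppm[ns$metabolite == "Glutamate"]
  gln_dn <- ns$ppm[ns$metabolite == "Glutamine"]
  hits <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      p <- nrow(ns)
      m <- matrix(rnorm(40 * p, 0, 0.3), 40, p)
      colnames(m) <- ns$ppm
      rownames(m) <- sprintf("S%03d", 1:40)
      flag <- rep(c(TRUE, FALSE), c(8, 32))
      m[flag, colnames(m) %in% glu_up] <- m[flag, colnames(m) %in% glu_up] + 0.8
      m[flag, colnames(m) %in% gln_dn] <- m[flag, colnames(m) %in% gln_dn] - 0.8
    })
    sig <- frpa1_pca_contrast(m, flag)
    got_glu <- any(glu_up %in% sig$feature) &&
      all(sig$direction[sig$feature %in% glu_up] == 1)
    got_gln <- any(gln_dn %in% sig$feature) &&
      all(sig$direction[sig$feature %in% gln_dn] == -1)
    got_glu && got_gln
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a flag independent of the data yields little or nothing", {
  spurious <- vapply(1:10, function(s) {
    withr::with_seed(1100 + s, {
      m <- matrix(rnorm(40 * 20), 40, 20)
      colnames(m) <- sprintf("%.3f", seq(1.001, by = 0.01, length.out = 20))
      flag <- rep(c(TRUE, FALSE), c(6, 34))
    })
    sig <- quiet(frpa1_pca_contrast(m, flag))
    nrow(sig) <= 2
  }, logical(1))
  expect_gte(mean(spurious), 0.9)

  withr::with_seed(7, m <- matrix(rnorm(40 * 8), 40, 8))
  colnames(m) <- sprintf("%.3f", seq(1.001, by = 0.01, length.out = 8))
  always_empty <- quiet(frpa1_pca_contrast(m, rep(c(TRUE, FALSE), c(5, 35)),
                                           cor_cutoff = 1.01))
  expect_identical(nrow(always_empty), 0L)
  expect_error(frpa1_pca_contrast(m, rep(c(TRUE, FALSE), c(2, 38))), "3 samples")
})

# ---- approach runs -----------------------------------------------------------

sim_for_approaches <- function(seed = 86, n = 40, cluster_scale = 0.5,
                               disease_peaks = c("1.457", "4.041", "2.695"),
                               d = 1.2) {
  cfg <- sim_config(
    n_per_cell = tibble::tibble(center = rep(c("GYDR", "GBGL2"), each = 2),
                                disease = rep(c("PHT", "PA"), 2), n = n),
    centers = tibble::tibble(center = c("GYDR", "GBGL2"), cluster = c(1, 2)),
    cluster_effect_scale = cluster_scale, noise_sd = 0.3,
    disease_effects = list(PA = list(peaks = disease_peaks, shift = d)),
    sample_age_model = list(range = list(PHT = c(100, 2000), PA = c(100, 2000)),
                            age_slope = 0.1, cluster_corr = 0.5),
    n_qc = 12, n_hv = 12, seed = seed)
  simulate_cohort(cfg)
}

test_that("peak exclusion deconfounds while a disease signal survives", {
  sim <- sim_for_approaches(seed = 87)
  cfg <- cv_config(outer_repeats = 4, max_ncomp = 3, seed = 10)
  res <- quiet(approach_b_run(sim$peaks, sim$meta, "PA-PHT", cfg,
                              preprocess_config(outlier_pass = FALSE),
                              namespace = default_peak_namespace()))
  # the exclusion list is dominated by template peaks
  ns <- default_peak_namespace()
  template_peaks <- ns$ppm[ns$metabolite %in% names(table4_template())]
  expect_gt(length(intersect(res$peaks_excluded, template_peaks)), 8)
  # cluster separation on the reduced matrix collapses to chance
  pre2 <- preprocess_pipeline(sim$peaks, sim$meta,
                              preprocess_config(outlier_pass = FALSE,
                                                exclude_peaks = res$peaks_excluded))
  study <- sim$meta[sim$meta$role == "STUDY", ]
  m2 <- peaks_to_matrix(pre2$peaks)
  m2 <- m2[rownames(m2) %in% study$sample_id, ]
  cl <- paste0("c", study$cluster[match(rownames(m2), study$sample_id)])
  rc <- cv2_evaluate(m2, cl, "plsda", cv_config(outer_repeats = 5,
                                                max_ncomp = 3, seed = 11))
  ba <- dplyr::filter(glance(rc), metric == "balanced_accuracy")$mean
  expect_lt(abs(ba - 50), 5)
  # the disease contrast is still learnable (its peaks are off the template)
  ba_dis <- dplyr::filter(glance(res$cv2), metric == "balanced_accuracy")$mean
  expect_gt(ba_dis, 75)
})

test_that("center exclusion evaluates retained samples and predicts the rest", {
  # a label-correlated artifact confined to the retained center: the model
  # learns it, and it does not transfer to the excluded center
  sim <- sim_for_approaches(seed = 88, cluster_scale = 0.3,
                            disease_peaks = c("1.457", "4.041", "2.695"),
                            d = 0.3)
  artifact_peaks <- c("2.997", "7.168", "2.91")  # off the disease/template sets
  pk <- peaks_to_matrix(sim$peaks)
  study <- sim$meta[sim$meta$role == "STUDY", ]
  hit <- rownames(pk) %in% study$sample_id[study$center == "GYDR" &
                                             study$disease == "PA"]
  pk[hit, artifact_peaks] <- pk[hit, artifact_peaks] * exp(1.5)
  peaks2 <- matrix_to_peaks(pk)

  cfg <- cv_config(outer_repeats = 4, max_ncomp = 3, seed = 12)
  res <- quiet(approach_c_run(peaks2, sim$meta, "GYDR", "PA-PHT", cfg,
                              preprocess_config(outlier_pass = FALSE)))
  expect_identical(res$retained_counts$n[res$retained_counts$disease == "PA"], 40)
  expect_identical(nrow(res$external), 3L)
  acc <- res$external$value[res$external$metric == "accuracy"]
  ba_in <- dplyr::filter(glance(res$cv2), metric == "balanced_accuracy")$mean
  expect_gt(ba_in - acc, 5)
})

test_that("keeping every center reduces approach C to the initial analysis", {
  sim <- sim_for_approaches(seed = 89, n = 25)
  cfg <- cv_config(outer_repeats = 3, max_ncomp = 2, seed = 13)
  pre_cfg <- preprocess_config(outlier_pass = FALSE)
  res <- quiet(approach_c_run(sim$peaks, sim$meta, c("GYDR", "GBGL2"),
                              "PA-PHT", cfg, pre_cfg))
  expect_identical(nrow(res$external), 0L)
  pre <- preprocess_pipeline(sim$peaks, sim$meta, pre_cfg)
  study <- sim$meta[sim$meta$role == "STUDY", ]
  m <- peaks_to_matrix(pre$peaks)
  m <- m[rownames(m) %in% study$sample_id, ]
  y <- study$disease[match(rownames(m), study$sample_id)]
  direct <- cv2_evaluate(m, y, "splsda", cfg)
  expect_identical(res$cv2$metrics, direct$metrics)

  expect_error(quiet(approach_c_run(sim$peaks, sim$meta, character(),
                                    "PA-PHT", cfg, pre_cfg)), "non-empty")
  sim_no_pa <- sim
  sim_no_pa$meta$disease[sim_no_pa$meta$center == "GYDR" &
                           !is.na(sim_no_pa$meta$disease) &
                           sim_no_pa$meta$disease == "PA"] <- "PPGL"
  expect_error(quiet(approach_c_run(sim_no_pa$peaks, sim_no_pa$meta, "GYDR",
                                    "PA-PHT", cfg, pre_cfg)), "PA")
})

# ---- signature comparison ----------------------------------------------------

test_that("cross-approach comparison reproduces the printed contrasts", {
  cmp <- compare_signatures(table3_signature(),
                            c("initial", "approach_a", "approach_c"))
  gl <- cmp[cmp$metabolite %in% c("Glutamine", "Glutamate"), ]
  expect_true(all(gl$selected_by == "initial,approach_a"))
  lact <- cmp[cmp$metabolite == "Lactate", ]
  expect_false(lact$sign_agreement)
  expect_true(cmp$sign_agreement[cmp$metabolite == "Pyruvate"])
})

test_that("identical signatures agree everywhere", {
  sig <- tibble::tibble(metabolite = c("m1", "m2", "m3"),
                        a = c(0.5, 0, -0.2), b = c(0.5, 0, -0.2))
  cmp <- compare_signatures(sig)
  expect_true(all(cmp$sign_agreement[cmp$n_selected > 0]))
  expect_true(all(is.na(cmp$only_in)))
  expect_identical(cmp$selected_by, c("a,b", "", "a,b"))
})

test_that("cluster assignment from PC1 is deterministic and correct", {
  dat <- make_confounded(seed = 91, n = 80, cluster_scale = 1)
  meta <- tibble::tibble(sample_id = rownames(dat$x),
                         center = ifelse(dat$cluster == "c1", "AA", "BB"))
  cl <- assign_clusters(dat$x, meta)
  expect_identical(cl$cluster[cl$center == "AA"], 1)
  expect_identical(cl$cluster[cl$center == "BB"], 2)
})
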