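# scenario -> (labels, sample ids) over STUDY samples
.scenario_labels <- function(meta, scenario) {
  study <- dplyr::filter(meta, .data$role == "STUDY")
  sc <- toupper(scenario)
  if (sc == "ALL-ALL") {
    return(tibble::tibble(sample_id = study$sample_id, label = study$disease))
  }
  parts <- strsplit(sc, "-")[[1]]
  if (length(parts) != 2) abort(paste0("unknown scenario '", scenario, "'"))
  pick <- function(code) if (code == "EHT") c("PA", "PPGL", "CS") else code
  g1 <- pick(parts[1]); g2 <- pick(parts[2])
  out <- study |>
    dplyr::filter(.data$disease %in% c(g1, g2)) |>
    dplyr::transmute(sample_id = .data$sample_id,
                     label = ifelse(.data$disease %in% g1, parts[1], parts[2]))
  for (side in parts) {
    if (!side %in% out$label) {
      abort(paste0("scenario ", scenario, ": class ", side, " has no samples"))
    }
  }
  out
}

#' Assign center clusters from the first principal component
#'
#' For cohorts without a pre-assigned clustering, centers are grouped by
#' 2-means on the per-center mean PC1 score of the STUDY samples. Cluster 1
#' is the group containing the alphabetically lowest center code, making
#' labels deterministic.
#'
#' @param x Preprocessed feature data for the STUDY samples.
#' @param meta Metadata with matching `sample_id` and `center`.
#' @return A tibble `center`, `cluster`.
#' @export
assign_clusters <- function(x, meta) {
  m <- .as_feature_matrix(x)
  pc1 <- pca_fit(m, 1)$scores[, 1]
  ctr <- meta$center[match(rownames(m), meta$sample_id)]
  km <- stats::kmeans(matrix(pc1, ncol = 1),
                      centers = matrix(range(pc1), 2, 1))
  # per-center majority vote over the sample partition
  vote <- tapply(km$cluster, ctr, function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    as.integer(names(tb)[1])  # ties resolved by the lower k-means label
  })
  centers <- sort(names(vote))  # ties across centers: lower code first
  first <- vote[[centers[1]]]
  tibble::tibble(center = centers,
                 cluster = as.numeric(ifelse(vote[centers] == first, 1, 2)))
}

#' Confounder signature by PLS-DA under double cross-validation
#'
#' Runs the classifier on groups defined by a confounder (center cluster 1
#' without the flagged FRPA1-PHT subgroup vs cluster 2, or sample age below
#' vs above the global median) and returns the peaks with median outer-loop
#' VIP above 1, each with the direction of its group difference.
#'
#' A VIP list is only meaningful when the grouping is actually learnable:
#' about a third of the features of a random direction exceed VIP 1, so an
#' unpredictive model would always "find" a signature. The list is
#' therefore returned empty when the mean cross-validated balanced accuracy
#' stays below `min_accuracy` (the reported confounder models classify far
#' above chance).
#'
#' @param x Preprocessed feature data.
#' @param confounder_labels Binary labels aligned with the rows of `x`.
#' @param cfg A [cv_config()].
#' @param threshold Median-VIP cutoff.
#' @param min_accuracy Minimum mean balanced accuracy (percent) for a
#'   non-empty signature.
#' @return A tibble `feature`, `median_vip`, `direction` (+1 where the mean
#'   is higher in the second sorted label), plus the `cv2_result` as
#'   attribute `cv2`.
#' @export
confounder_signature <- function(x, confounder_labels, cfg = cv_config(),
                                 threshold = 1, min_accuracy = 60) {
  m <- .as_feature_matrix(x)
  lab <- as.character(confounder_labels)
  lev <- sort(unique(lab))
  if (length(lev) != 2) abort("confounder grouping must be binary")
  res <- cv2_evaluate(m, lab, "plsda", cfg)
  ba <- mean(res$metrics$value[res$metrics$metric == "balanced_accuracy"])
  med <- apply(res$vip, 2, median)
  sel <- med > threshold
  if (ba < min_accuracy) {
    inform(paste0("confounder grouping not learnable (balanced accuracy ",
                  round(ba, 1), "%): empty signature"))
    sel[] <- FALSE
  }
  dir <- sign(colMeans(m[lab == lev[2], sel, drop = FALSE]) -
                colMeans(m[lab == lev[1], sel, drop = FALSE]))
  out <- tibble::tibble(feature = colnames(m)[sel],
                        median_vip = unname(med[sel]),
                        direction = unname(dir))
  attr(out, "cv2") <- res
  out
}

#' Small-group contrast by PCA component correlation
#'
#' For a subgroup too small for reliable supervised modelling (the
#' delayed-storage FRPA1-PHT samples within cluster 1), finds the principal
#' component whose scores correlate most with the group flag and returns the
#' peaks whose correlation with that component exceeds the cutoff, signed by
#' their association with the flag.
#'
#' @param x Feature data for the pooled comparison samples.
#' @param flag Logical (or 0/1) vector marking the subgroup; needs at least
#'   3 flagged samples.
#' @param cor_cutoff Peak-component correlation cutoff (default 0.5).
#' @param max_comp Components searched.
#' @return A tibble `feature`, `correlation`, `direction`; empty with a
#'   warning when no component reaches |r| > 0.3 with the flag.
#' @export
frpa1_pca_contrast <- function(x, flag, cor_cutoff = 0.5, max_comp = 10) {
  m <- .as_feature_matrix(x)
  flag <- as.numeric(flag)
  if (sum(flag) < 3) abort("flagged group needs at least 3 samples")
  pc <- pca_fit(m, min(max_comp, nrow(m) - 1, ncol(m)))
  rs <- suppressWarnings(apply(pc$scores, 2, cor, y = flag))
  rs[is.na(rs)] <- 0
  best <- which.max(abs(rs))
  empty <- tibble::tibble(feature = character(), correlation = numeric(),
                          direction = numeric())
  if (abs(rs[best]) <= 0.3) {
    warn("no component correlates with the flag (|r| <= 0.3): empty contrast")
    return(empty)
  }
  pr <- suppressWarnings(apply(m, 2, cor, y = pc$scores[, best]))
  pr[is.na(pr)] <- 0
  sel <- abs(pr) > cor_cutoff
  tibble::tibble(feature = colnames(m)[sel],
                 correlation = unname(pr[sel]),
                 direction = sign(unname(pr[sel]) * rs[best]))
}

# union exclusion list from the three confounder probes, on a preprocessed
# STUDY matrix
.build_confounder_exclusion <- function(m, study, cfg) {
  cl_keep <- !is.na(study$cluster) & !(study$frpa1_pht %||% FALSE)
  cl_lab <- paste0("cluster", study$cluster[cl_keep])
  sig_cluster <- confounder_signature(m[cl_keep, , drop = FALSE], cl_lab, cfg)
  med_age <- median(study$sample_age_days)
  age_lab <- ifelse(study$sample_age_days > med_age, "above", "below")
  sig_age <- confounder_signature(m, age_lab, cfg)
  in_cl1 <- !is.na(study$cluster) & study$cluster == 1
  sig_frpa1 <- if (sum(study$frpa1_pht[in_cl1], na.rm = TRUE) >= 3) {
    frpa1_pca_contrast(m[in_cl1, , drop = FALSE], study$frpa1_pht[in_cl1])
  } else {
    tibble::tibble(feature = character())
  }
  list(features = union(union(sig_cluster$feature, sig_age$feature),
                        sig_frpa1$feature),
       cluster = sig_cluster, sample_age = sig_age, frpa1 = sig_frpa1)
}

#' Confounder-peak-exclusion analysis (Approach B)
#'
#' Builds the inclusive confounder peak list (cluster PLS-DA signature,
#' sample-age PLS-DA signature, and the small-group PCA contrast for the
#' flagged FRPA1-PHT samples), re-runs the preprocessing chain with those
#' peaks excluded up front, then evaluates the disease scenario by double
#' cross-validation and extracts the sparse signature on the reduced matrix.
#'
#' Because VIP ranks features relative to one another, a single probe keeps
#' weaker confounder peaks hidden behind stronger ones. The aim is an
#' inclusive list of *all* related peaks, not the most predictive subset,
#' so the probe is iterated: peaks found are excluded, the reduced matrix
#' is probed again, and the loop stops when the confounder groupings are no
#' longer learnable (or after `max_iter` rounds). When a peak-to-metabolite
#' `namespace` is supplied, a hit on any peak of a metabolite excludes all
#' of that metabolite's peaks, mirroring how the exclusion list is built
#' per metabolite.
#'
#' @param peaks Raw peak table.
#' @param meta Sample metadata (with a logical `frpa1_pht` column when the
#'   flagged subgroup exists).
#' @param scenario One of `"EHT-PHT"`, `"PA-PHT"`, `"CS-PHT"`,
#'   `"PPGL-PHT"`, `"ALL-ALL"`.
#' @param cfg A [cv_config()].
#' @param pre_cfg A [preprocess_config()].
#' @param namespace Optional tibble (`ppm`, `metabolite`) for
#'   metabolite-level expansion of the exclusion list.
#' @param max_iter Maximum probe/exclude rounds.
#' @return A list: `exclusion` (the first-round probe results),
#'   `peaks_excluded` (the accumulated list), `iterations`, `cv2` (the
#'   scenario `cv2_result` on the reduced data) and `signature`.
#' @export
approach_b_run <- function(peaks, meta, scenario, cfg = cv_config(),
                           pre_cfg = preprocess_config(),
                           namespace = NULL, max_iter = 4) {
  study_all <- dplyr::filter(meta, .data$role == "STUDY")
  if (!"frpa1_pht" %in% names(study_all)) study_all$frpa1_pht <- FALSE
  excluded <- character()
  first <- NULL
  iterations <- 0
  for (it in seq_len(max_iter)) {
    pre_cfg_i <- pre_cfg
    pre_cfg_i$exclude_peaks <- union(pre_cfg$exclude_peaks, excluded)
    pre <- preprocess_pipeline(peaks, meta, pre_cfg_i)
    m <- peaks_to_matrix(dplyr::filter(pre$peaks,
                                       .data$sample_id %in% study_all$sample_id))
    study <- study_all[match(rownames(m), study_all$sample_id), ]
    excl <- .build_confounder_exclusion(m, study, cfg)
    if (is.null(first)) first <- excl
    found <- excl$features
    if (!is.null(namespace)) {
      hit_met <- unique(namespace$metabolite[namespace$ppm %in% found])
      found <- union(found, namespace$ppm[namespace$metabolite %in% hit_met])
    }
    new_peaks <- setdiff(found, excluded)
    iterations <- it
    if (length(new_peaks) == 0) break
    excluded <- union(excluded, new_peaks)
  }
  pre_cfg2 <- pre_cfg
  pre_cfg2$exclude_peaks <- union(pre_cfg$exclude_peaks, excluded)
  pre2 <- preprocess_pipeline(peaks, meta, pre_cfg2)
  if (ncol(pre2$peaks) <= 1) abort("confounder exclusion removed every peak")
  sl <- .scenario_labels(meta, scenario)
  m2 <- peaks_to_matrix(dplyr::filter(pre2$peaks, .data$sample_id %in% sl$sample_id))
  lab <- sl$label[match(rownames(m2), sl$sample_id)]
  list(exclusion = first,
       peaks_excluded = excluded,
       iterations = iterations,
       cv2 = cv2_evaluate(m2, lab, "splsda", cfg),
       signature = signature_from_splsda(m2, lab, cfg))
}

#' Whole-center-exclusion analysis (Approach C)
#'
#' Restricts the cohort to the retained centers (the tight cluster),
#' evaluates the disease scenario there by double cross-validation and
#' extracts the sparse signature; additionally refits a model with the
#' modal CV2 hyperparameters on all retained samples and predicts the
#' disease group of every excluded STUDY sample of the scenario's classes,
#' reporting external accuracy, sensitivity and specificity.
#'
#' @inheritParams approach_b_run
#' @param keep_centers Centers to retain.
#' @return A list: `cv2`, `signature`, `external` (tibble of external
#'   prediction metrics on the percent scale; zero rows when nothing was
#'   excluded) and `retained_counts`.
#' @export
approach_c_run <- function(peaks, meta, keep_centers, scenario,
                           cfg = cv_config(), pre_cfg = preprocess_config()) {
  if (length(keep_centers) == 0) abort("keep_centers must be non-empty")
  pre <- preprocess_pipeline(peaks, meta, pre_cfg)
  sl <- .scenario_labels(meta, scenario)
  keep_ids <- meta$sample_id[meta$role == "STUDY" & meta$center %in% keep_centers]
  sl_in <- dplyr::filter(sl, .data$sample_id %in% keep_ids)
  sl_out <- dplyr::filter(sl, !.data$sample_id %in% keep_ids)
  missing_cls <- setdiff(unique(sl$label), unique(sl_in$label))
  if (length(missing_cls) > 0) {
    abort(paste0("scenario ", scenario, ": class ",
                 paste(missing_cls, collapse = ", "),
                 " has no samples in the retained centers"))
  }
  mx <- peaks_to_matrix(pre$peaks)
  m_in <- mx[rownames(mx) %in% sl_in$sample_id, , drop = FALSE]
  lab_in <- sl_in$label[match(rownames(m_in), sl_in$sample_id)]
  res <- cv2_evaluate(m_in, lab_in, "splsda", cfg)
  sig <- signature_from_splsda(m_in, lab_in, cfg)
  external <- tibble::tibble(metric = character(), value = numeric())
  if (nrow(sl_out) > 0) {
    ncomp <- .modal_min(res$chosen$ncomp)
    keepX <- .modal_min(res$chosen$keepX)
    fit <- suppressWarnings(.pls_core(m_in, lab_in, ncomp, keepX = rep(keepX, ncomp)))
    m_out <- mx[rownames(mx) %in% sl_out$sample_id, , drop = FALSE]
    truth <- sl_out$label[match(rownames(m_out), sl_out$sample_id)]
    pred <- .predict_labels(fit, m_out, fit$ncomp)
    lev <- sort(unique(sl$label))
    tp <- .per_class_tp(truth, pred, lev)
    external <- tibble::tibble(metric = "accuracy", value = mean(pred == truth) * 100)
    if (length(lev) == 2) {
      control <- if (cfg$control %in% lev) cfg$control else lev[1]
      case <- setdiff(lev, control)
      external <- dplyr::bind_rows(external, tibble::tibble(
        metric = c("sensitivity", "specificity"),
        value = c(tp[case], tp[control]) * 100))
    }
  }
  list(cv2 = res, signature = sig, external = external,
       retained_counts = count_after_center_filter(meta, keep_centers))
}

#' Compare signatures across approaches
#'
#' Aligns per-approach signatures over a shared metabolite namespace and
#' reports, per metabolite, which approaches selected it (nonzero
#' coefficient; `NA` means excluded before the analysis) and whether the
#' nonzero coefficients agree in sign.
#'
#' @param sigs A wide signature table (as [table3_signature()]): a
#'   `metabolite` column plus one coefficient column per approach.
#' @param approaches Coefficient columns to compare; defaults to every
#'   column except `metabolite` and `ppm`.
#' @return A tibble: `metabolite`, `selected_by` (comma-joined approaches),
#'   `n_selected`, `sign_agreement`, and `only_in` (the approach name when a
#'   metabolite is unique to one approach).
#' @export
compare_signatures <- function(sigs, approaches = NULL) {
  sigs <- tibble::as_tibble(sigs)
  approaches <- approaches %||% setdiff(names(sigs), c("metabolite", "ppm"))
  sel <- purrr::map(approaches, function(a) {
    co <- sigs[[a]]
    !is.na(co) & co != 0
  })
  names(sel) <- approaches
  purrr::map_dfr(seq_len(nrow(sigs)), function(i) {
    hit <- approaches[vapply(sel, function(s) s[i], logical(1))]
    co <- vapply(approaches, function(a) sigs[[a]][i], numeric(1))
    nz <- co[!is.na(co) & co != 0]
    tibble::tibble(
      metabolite = sigs$metabolite[i],
      selected_by = paste(hit, collapse = ","),
      n_selected = length(hit),
      sign_agreement = if (length(nz) == 0) NA else length(unique(sign(nz))) == 1,
      only_in = if (length(hit) == 1) hit else NA_character_)
  })
}
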