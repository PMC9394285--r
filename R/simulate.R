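#' Confounder direction template
#'
#' The fixed 14-metabolite sign map of the preanalytical confounder panel:
#' the direction in which each metabolite shifts in samples affected by the
#' center-cluster / sample-age confounders (+1 = higher in cluster 2 /
#' high-sample-age / delayed-storage samples, -1 = lower). Lactate, ornithine
#' and glutamate rise with a pre-centrifugation or pre-storage delay while
#' glucose, pyruvate and glutamine fall, the pattern expected from ongoing
#' red-blood-cell glycolysis and glutaminase activity.
#'
#' @return A named numeric vector of +1/-1 with 14 entries.
#' @export
table4_template <- function() {
  c("Acetylcarnitine" = -1, "Creatine" = +1, "Dimethyl sulfone" = +1,
    "Glucose" = -1, "Glutamate" = +1, "Glutamine" = -1, "Glycerol" = +1,
    "Glycine" = -1, "Lactate" = +1, "Methanol" = -1, "Methionine" = -1,
    "Ornithine" = +1, "Pyruvate" = -1, "Unknown 3.284" = +1)
}

#' Default peak namespace for simulation
#'
#' The signature-table peaks plus the additional confounder-panel peaks
#' (ornithine, acetylcarnitine, a second creatine/glucose/glycerol/lactate/
#' glutamate/glutamine signal) and a handful of pure-noise unknowns: 40
#' peaks in total, each mapped to a metabolite name where one is known.
#'
#' @return A tibble with columns `ppm` (3-decimal label) and `metabolite`.
#' @export
default_peak_namespace <- function() {
  base <- table3_signature()[, c("ppm", "metabolite")]
  extra <- tibble::tribble(
    ~ppm,    ~metabolite,
    "3.041", "Ornithine",
    "3.057", "Ornithine",
    "3.177", "Acetylcarnitine",
    "3.021", "Creatine",
    "5.227", "Glucose",
    "3.567", "Glycerol",
    "1.321", "Lactate",
    "2.047", "Glutamate",
    "2.460", "Glutamine",
    "0.855", "Unknown 0.855",
    "1.048", "Unknown 1.048",
    "6.902", "Unknown 6.902",
    "7.532", "Unknown 7.532",
    "8.120", "Unknown 8.120")
  dplyr::bind_rows(base, extra)
}

#' Simulation configuration
#'
#' Defines a synthetic multicenter plasma-NMR cohort. Intensities are
#' log-normal with additive structure on the log scale:
#' \deqn{\log x = \mu_j + \delta_{disease} + s \cdot g_j \, [cluster\,2]
#'   + \beta_{age} g_j \, age/1000 + b_{batch} + r \cdot run
#'   + \varepsilon}
#' where \eqn{g_j} is the confounder template sign of peak j (0 off the
#' panel), so cluster membership, sample age, batch and run order act
#' multiplicatively on intensities. Values below `lod` become non-detects.
#' QC samples are technical replicates of the pooled study mean; HV samples
#' are biological draws from one designated center's baseline.
#'
#' @param n_per_cell Tibble with columns `center`, `disease`, `n` giving
#'   STUDY sample counts per cell.
#' @param centers Tibble with columns `center`, `cluster` assigning each
#'   center to center-cluster 1 or 2.
#' @param peaks Peak namespace tibble (`ppm`, `metabolite`); defaults to
#'   [default_peak_namespace()].
#' @param baseline_log_mean,baseline_log_sd Per-peak baseline log-intensity
#'   means and noise standard deviations; scalars are recycled. The sd
#'   defaults to `noise_sd`.
#' @param noise_sd Default per-peak log-scale residual sd (biological +
#'   unexplained technical), 0.3.
#' @param disease_effects Named list: disease -> `list(peaks =, shift =)`
#'   giving a log-scale shift on a set of ppm labels.
#' @param cluster_effect_scale Multiplier `s` on the template signs applied
#'   to cluster-2 samples (log units).
#' @param frpa1_effect_scale Scale of the delayed-storage sub-template
#'   (glutamate up, glutamine down, no glycolysis shift) applied to the
#'   flagged FRPA1-PHT subgroup.
#' @param sample_age_model List with `range` (named list disease ->
#'   `c(lo, hi)` days), `age_slope` (log-intensity per 1000 days applied to
#'   template peaks with the template sign) and `cluster_corr` in `[0, 1]`
#'   (how strongly cluster-2 samples skew towards the old end of their
#'   disease's range).
#' @param batch_sd Sd of the per-batch log offset.
#' @param run_order_slope Log-intensity drift per run-order position.
#' @param lod Absolute intensity below which a value becomes a non-detect.
#' @param n_qc,n_hv Number of QC replicate and healthy-volunteer samples.
#' @param qc_cv Technical coefficient of variation of QC replicates
#'   (log-scale sd, a good approximation for small values).
#' @param hv_center Center whose baseline the HV samples are drawn from
#'   (also the default PQN reference pool).
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_cell,
                       centers = NULL,
                       peaks = default_peak_namespace(),
                       baseline_log_mean = NULL,
                       baseline_log_sd = NULL,
                       noise_sd = 0.3,
                       disease_effects = list(),
                       cluster_effect_scale = 0.5,
                       frpa1_effect_scale = cluster_effect_scale,
                       sample_age_model = list(
                         range = list(PHT = c(127, 6418), PA = c(52, 2280),
                                      PPGL = c(11, 3442), CS = c(19, 1186)),
                         age_slope = 0.15, cluster_corr = 0.6),
                       batch_sd = 0.05,
                       run_order_slope = 0.002,
                       lod = 8,
                       n_qc = 20, n_hv = 20,
                       qc_cv = 0.05,
                       hv_center = "GYDR",
                       seed = 1L) {
  n_per_cell <- tibble::as_tibble(n_per_cell)
  stopifnot(all(c("center", "disease", "n") %in% names(n_per_cell)))
  if (is.null(centers)) {
    centers <- tibble::tibble(center = unique(n_per_cell$center), cluster = 1)
  }
  p <- nrow(peaks)
  if (is.null(baseline_log_mean)) {
    # deterministic spread of baselines over ~ exp(2.5)..exp(5.5)
    baseline_log_mean <- 2.5 + 3 * ((seq_len(p) * 7) %% 11) / 10
  }
  baseline_log_mean <- rep_len(baseline_log_mean, p)
  baseline_log_sd <- rep_len(baseline_log_sd %||% noise_sd, p)
  if (any(baseline_log_sd < 0) || batch_sd < 0 || lod < 0 || qc_cv < 0) {
    abort("standard deviations and lod must be nonnegative")
  }
  for (d in disease_effects) {
    if (!all(d$peaks %in% peaks$ppm)) abort("disease effect peaks outside the peak namespace")
  }
  structure(list(
    n_per_cell = n_per_cell, centers = centers, peaks = peaks,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    noise_sd = noise_sd, disease_effects = disease_effects,
    cluster_effect_scale = cluster_effect_scale,
    frpa1_effect_scale = frpa1_effect_scale,
    sample_age_model = sample_age_model, batch_sd = batch_sd,
    run_order_slope = run_order_slope, lod = lod,
    n_qc = n_qc, n_hv = n_hv, qc_cv = qc_cv, hv_center = hv_center,
    seed = as.integer(seed)), class = "sim_config")
}

#' Study-layout simulation scenario
#'
#' A [sim_config()] whose center-by-disease STUDY counts equal the printed
#' cohort table, with the observed center clustering (GYDR, GYLU, GYMU,
#' GYWU, ITTU3, NLNI and PLWW in cluster 1; FRPA1 non-PHT, FRPA2, GBGL2,
#' IRGA, ITPD/ITPD3 in cluster 2; the FRPA1 PHT subgroup in cluster 1 with
#' its own delayed-storage flag) and per-disease sample-age ranges matching
#' the printed ranges.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
default_study_scenario <- function(...) {
  counts <- table1_counts()
  cl1 <- c("GYDR", "GYLU", "GYMU", "GYWU", "ITTU3", "NLNI", "PLWW")
  centers <- tibble::tibble(center = unique(counts$center)) |>
    dplyr::mutate(cluster = ifelse(.data$center %in% cl1, 1, 2))
  sim_config(n_per_cell = counts, centers = centers, ...)
}

#' Simulate a multicenter cohort
#'
#' Draws a peak table and matching metadata from a [sim_config()]. See that
#' help page for the generative model. The caller's RNG state is saved and
#' restored, so simulation is reproducible from `config$seed` alone.
#'
#' @param config A `sim_config`.
#' @return A list with elements `peaks` (peak-table tibble, `NA` =
#'   non-detect) and `meta` (sample metadata tibble).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (sum(config$n_per_cell$n) == 0) abort("n_per_cell is all zero: nothing to simulate")
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed)

  pk <- config$peaks
  p <- nrow(pk)
  template <- table4_template()
  sign_j <- unname(template[pk$metabolite])
  sign_j[is.na(sign_j)] <- 0
  frpa1_sub <- c("Glutamate" = +1, "Glutamine" = -1)
  frpa1_j <- unname(frpa1_sub[pk$metabolite])
  frpa1_j[is.na(frpa1_j)] <- 0

  cells <- dplyr::filter(config$n_per_cell, .data$n > 0)
  cluster_of <- setNames(config$centers$cluster, config$centers$center)
  study <- purrr::pmap_dfr(cells, function(center, disease, n) {
    tibble::tibble(center = center, disease = disease,
                   frpa1_pht = center == "FRPA1" & disease == "PHT",
                   cluster = ifelse(center == "FRPA1" & disease == "PHT",
                                    1, cluster_of[[center]]),
                   idx = seq_len(n))
  })
  n_study <- nrow(study)
  study$sample_id <- sprintf("S%03d", seq_len(n_study))
  study$role <- "STUDY"

  # sample age: within the disease range, cluster-2 samples skew old
  am <- config$sample_age_model
  rng <- am$range
  corr <- am$cluster_corr %||% 0
  u <- runif(n_study)
  u <- (1 - corr) * u + corr * ifelse(study$cluster == 2, 0.75 + 0.25 * u, 0.25 * u)
  lims <- t(vapply(study$disease,
                   function(d) rng[[d]] %||% c(30, 3000), numeric(2)))
  study$sample_age_days <- round(lims[, 1] + u * (lims[, 2] - lims[, 1]))
  study$sex <- sample(c("F", "M"), n_study, replace = TRUE)
  study$patient_age <- round(runif(n_study, 25, 75))

  qc <- tibble::tibble(sample_id = sprintf("QC%02d", seq_len(config$n_qc)),
                       role = "QC", disease = NA_character_, center = NA_character_,
                       cluster = NA_real_, frpa1_pht = FALSE,
                       sample_age_days = 0, sex = NA_character_, patient_age = NA_real_)
  hv_cluster <- if (config$hv_center %in% names(cluster_of)) cluster_of[[config$hv_center]] else 1
  hv <- tibble::tibble(sample_id = sprintf("HV%02d", seq_len(config$n_hv)),
                       role = "HV", disease = NA_character_, center = config$hv_center,
                       cluster = hv_cluster, frpa1_pht = FALSE,
                       sample_age_days = 0, sex = NA_character_, patient_age = NA_real_)
  meta <- dplyr::bind_rows(
    dplyr::select(study, "sample_id", "role", "disease", "center", "cluster",
                  "frpa1_pht", "sample_age_days", "sex", "patient_age"),
    qc, hv)

  # batch layout: shuffled run, at most 15 samples per batch
  meta$batch <- NA_real_
  meta$run_order <- NA_real_
  ord <- sample.int(nrow(meta))
  meta$batch[ord] <- ceiling(seq_len(nrow(meta)) / 15)
  meta$run_order[ord] <- ((seq_len(nrow(meta)) - 1) %% 15) + 1
  n_batch <- max(meta$batch)
  batch_off <- rnorm(n_batch, 0, config$batch_sd)

  # expected log intensity per STUDY sample x peak (before noise)
  mu <- matrix(config$baseline_log_mean, n_study, p, byrow = TRUE)
  for (d in names(config$disease_effects)) {
    eff <- config$disease_effects[[d]]
    jj <- match(eff$peaks, pk$ppm)
    ii <- which(study$disease == d)
    if (length(ii) > 0) mu[ii, jj] <- mu[ii, jj] + eff$shift
  }
  mu <- mu + (study$cluster == 2) %o% (config$cluster_effect_scale * sign_j)
  mu <- mu + study$frpa1_pht %o% (config$frpa1_effect_scale * frpa1_j)
  mu <- mu + (study$sample_age_days / 1000) %o% (am$age_slope * sign_j)

  tech <- function(ids) {
    b <- meta$batch[match(ids, meta$sample_id)]
    r <- meta$run_order[match(ids, meta$sample_id)]
    batch_off[b] + config$run_order_slope * r
  }
  noise <- matrix(rnorm(n_study * p, 0, 1), n_study, p) *
    matrix(config$baseline_log_sd, n_study, p, byrow = TRUE)
  log_study <- mu + tech(study$sample_id) + noise

  qc_mu <- colMeans(mu)  # pooled study mean, technical noise only on top
  log_qc <- matrix(qc_mu, config$n_qc, p, byrow = TRUE) + tech(qc$sample_id) +
    matrix(rnorm(config$n_qc * p, 0, config$qc_cv), config$n_qc, p)

  hv_mu <- config$baseline_log_mean +
    (hv_cluster == 2) * config$cluster_effect_scale * sign_j
  log_hv <- matrix(hv_mu, config$n_hv, p, byrow = TRUE) + tech(hv$sample_id) +
    matrix(rnorm(config$n_hv * p, 0, 1), config$n_hv, p) *
    matrix(config$baseline_log_sd, config$n_hv, p, byrow = TRUE)

  x <- exp(rbind(log_study, log_qc, log_hv))
  x[x < config$lod] <- NA_real_
  rownames(x) <- c(study$sample_id, qc$sample_id, hv$sample_id)
  colnames(x) <- pk$ppm

  peaks <- matrix_to_peaks(x)
  meta <- meta[match(peaks$sample_id, meta$sample_id), ]
  list(peaks = validate_peak_table(peaks),
       meta = validate_sample_meta(dplyr::select(
         meta, "sample_id", "role", "disease", "center", "cluster",
         "sample_age_days", "batch", "run_order", "sex", "patient_age",
         "frpa1_pht")))
}
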