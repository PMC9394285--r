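# shared fixture builders; everything is generated in code

# a peak table from a plain matrix, inventing valid ppm labels if needed
as_peaks <- function(m, ids = NULL) {
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("%.3f", seq(0.501, by = 0.01, length.out = ncol(m)))
  }
  rownames(m) <- ids %||% sprintf("S%03d", seq_len(nrow(m)))
  matrix_to_peaks(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal metadata for a set of study samples (+ optional QC/HV blocks)
make_meta <- function(study_ids, disease, center = "GYDR", cluster = 1,
                      qc_ids = character(), hv_ids = character(),
                      sample_age = 100, sex = "F", patient_age = 50) {
  n <- length(study_ids)
  study <- tibble::tibble(
    sample_id = study_ids, role = "STUDY",
    disease = rep_len(disease, n), center = rep_len(center, n),
    cluster = rep_len(cluster, n),
    sample_age_days = rep_len(sample_age, n),
    sex = rep_len(sex, n), patient_age = rep_len(patient_age, n))
  extras <- tibble::tibble(
    sample_id = c(qc_ids, hv_ids),
    role = rep(c("QC", "HV"), c(length(qc_ids), length(hv_ids))),
    disease = NA_character_,
    center = c(rep(NA_character_, length(qc_ids)), rep("GYDR", length(hv_ids))),
    cluster = NA_real_, sample_age_days = 0,
    sex = NA_character_, patient_age = NA_real_)
  out <- dplyr::bind_rows(study, extras)
  out$batch <- ceiling(seq_len(nrow(out)) / 15)
  out$run_order <- ((seq_len(nrow(out)) - 1) %% 15) + 1
  out
}

# two-class Gaussian toy: `informative` features carry a mean shift `d`
two_class_toy <- function(n_per = 30, p = 10, informative = 1:2, d = 3,
                          sd = 1, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(2 * n_per * p, 0, sd), 2 * n_per, p)
    m[seq_len(n_per), informative] <- m[seq_len(n_per), informative] + d
    colnames(m) <- sprintf("%.3f", seq(1.001, by = 0.01, length.out = p))
    rownames(m) <- sprintf("S%03d", seq_len(2 * n_per))
    list(x = m, y = rep(c("PA", "PHT"), each = n_per))
  })
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# independent kNN-imputation oracle: exhaustive neighbour search with
# explicit loops (root-mean-square distance over mutually detected peaks,
# 1/distance weights, exact matches dominate)
knn_oracle <- function(m, k) {
  n <- nrow(m)
  out <- m
  for (i in seq_len(n)) for (j in seq_len(ncol(m))) {
    if (!is.na(m[i, j])) next
    d <- rep(NA_real_, n)
    for (l in seq_len(n)) {
      if (l == i) next
      shared <- !is.na(m[i, ]) & !is.na(m[l, ])
      if (!any(shared)) next
      d[l] <- sqrt(mean((m[i, shared] - m[l, shared])^2))
    }
    cand <- order(d, na.last = NA)
    cand <- cand[!is.na(m[cand, j])]
    nb <- cand[seq_len(min(k, length(cand)))]
    w <- 1 / d[nb]
    out[i, j] <- if (any(d[nb] == 0)) mean(m[nb[d[nb] == 0], j]) else
      sum(w * m[nb, j]) / sum(w)
  }
  out
}
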