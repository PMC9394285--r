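#' Preprocessing configuration
#'
#' Parameters of the feature-processing chain that turns a raw peak table
#' into an analysis-ready matrix. The chain runs in the order: peak
#' exclusion, presence filter, probabilistic quotient normalization, QC
#' coefficient-of-variation filter, k-nearest-neighbour imputation,
#' generalized-log transform, and (optionally) a robust-PCA outlier pass on
#' the QC/HV groups followed by a re-run of the normalization and transform
#' with the outliers removed.
#'
#' @param presence_threshold Minimum detection fraction in the QC *or* HV
#'   group for a peak to be kept (default 0.80). Set 0 to disable.
#' @param cv_threshold Maximum coefficient of variation over detected QC
#'   values (default 0.30). Set `Inf` to disable.
#' @param knn_k Number of neighbours for imputation (default 10).
#' @param glog_lambda `"auto"` to fit the transform parameter on QC
#'   replicates, or a positive number.
#' @param outlier_pass Run the robust-PCA outlier pass and re-run the
#'   normalization/transform without the flagged QC/HV samples?
#' @param pqn_reference List with `role` and `center` selecting the
#'   reference pool for quotient normalization (default: HV samples from
#'   GYDR; falls back to all HV samples if that center has none).
#' @param cv_before_pqn The chain applies the CV filter after normalization
#'   (its position in the stated order); set `TRUE` for the alternative
#'   pre-normalization variant.
#' @param exclude_peaks ppm labels removed up front (the peak-exclusion
#'   step; this is where confounder-related peaks are dropped under the
#'   exclusion approach).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(presence_threshold = 0.80,
                              cv_threshold = 0.30,
                              knn_k = 10,
                              glog_lambda = "auto",
                              outlier_pass = TRUE,
                              pqn_reference = list(role = "HV", center = "GYDR"),
                              cv_before_pqn = FALSE,
                              exclude_peaks = character()) {
  if (presence_threshold < 0 || presence_threshold > 1) {
    abort("presence_threshold must be in [0, 1]")
  }
  if (knn_k < 1) abort("knn_k must be >= 1")
  structure(list(presence_threshold = presence_threshold,
                 cv_threshold = cv_threshold, knn_k = knn_k,
                 glog_lambda = glog_lambda, outlier_pass = outlier_pass,
                 pqn_reference = pqn_reference, cv_before_pqn = cv_before_pqn,
                 exclude_peaks = exclude_peaks),
            class = "preprocess_config")
}

#' Presence filter
#'
#' Keeps a peak iff it is detected in at least `threshold` of QC samples
#' *or* at least `threshold` of HV samples (the reference groups define
#' what a reliably measurable feature is).
#'
#' @param peaks Peak table.
#' @param meta Sample metadata.
#' @param threshold Detection fraction in (0, 1].
#' @return The reduced peak table; removed peaks are recorded in the
#'   `removed` attribute as a tibble with a reason per peak.
#' @export
presence_filter <- function(peaks, meta, threshold = 0.80) {
  qc_ids <- meta$sample_id[meta$role == "QC"]
  hv_ids <- meta$sample_id[meta$role == "HV"]
  if (length(qc_ids) == 0 && length(hv_ids) == 0) {
    abort("presence filter needs QC or HV samples")
  }
  m <- peaks_to_matrix(peaks)
  frac <- function(ids) {
    if (length(ids) == 0) return(rep(0, ncol(m)))
    colMeans(!is.na(m[rownames(m) %in% ids, , drop = FALSE]))
  }
  keep <- frac(qc_ids) >= threshold | frac(hv_ids) >= threshold
  removed <- tibble::tibble(peak = colnames(m)[!keep], reason = "presence")
  out <- peaks[c("sample_id", colnames(m)[keep])]
  attr(out, "removed") <- removed
  out
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution. The reference spectrum is the per-peak
#' median over the reference samples, ignoring non-detects; each sample's
#' dilution factor is the median of its detected-intensity quotients
#' against the reference, and the sample is divided by it. Non-detects are
#' preserved.
#'
#' @param peaks Peak table.
#' @param reference_samples Character vector of sample ids forming the
#'   reference pool (typically healthy-volunteer samples from one center).
#' @return A list with `peaks` (normalized table) and `factors` (tibble
#'   `sample_id`, `dilution`). Errors if a sample shares no detected peak
#'   with the reference.
#' @export
pqn_normalize <- function(peaks, reference_samples) {
  m <- peaks_to_matrix(peaks)
  ref <- m[rownames(m) %in% reference_samples, , drop = FALSE]
  if (nrow(ref) == 0) abort("reference set is empty")
  r <- apply(ref, 2, median, na.rm = TRUE)
  usable <- !is.na(r) & r > 0
  if (!any(usable)) abort("reference spectrum has no positive detected peak")
  q <- sweep(m[, usable, drop = FALSE], 2, r[usable], "/")
  f <- apply(q, 1, median, na.rm = TRUE)
  bad <- rownames(m)[is.na(f)]
  if (length(bad) > 0) {
    abort(paste0("sample(s) share no detected peak with the reference: ",
                 paste(bad, collapse = ", ")))
  }
  out <- matrix_to_peaks(m / f)
  list(peaks = out,
       factors = tibble::tibble(sample_id = rownames(m), dilution = unname(f)))
}

#' QC coefficient-of-variation filter
#'
#' Removes peaks whose relative technical variability over the detected QC
#' replicate values exceeds `threshold`; peaks with fewer than 3 detected
#' QC values are removed as unsupported.
#'
#' @param peaks Peak table.
#' @param meta Sample metadata (QC rows are used).
#' @param threshold Maximum sd/mean over detected QC values.
#' @return The reduced peak table with a `removed` attribute.
#' @export
cv_filter <- function(peaks, meta, threshold = 0.30) {
  qc_ids <- meta$sample_id[meta$role == "QC"]
  if (length(qc_ids) < 3) abort("cv filter needs at least 3 QC samples")
  m <- peaks_to_matrix(peaks)
  qc <- m[rownames(m) %in% qc_ids, , drop = FALSE]
  n_det <- colSums(!is.na(qc))
  cv <- apply(qc, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3) return(NA_real_)
    sd(x) / mean(x)
  })
  unsupported <- n_det < 3
  high <- !unsupported & cv > threshold
  removed <- dplyr::bind_rows(
    tibble::tibble(peak = colnames(m)[unsupported], reason = "insufficient QC support"),
    tibble::tibble(peak = colnames(m)[high], reason = "qc_cv"))
  keep <- !(unsupported | high)
  out <- peaks[c("sample_id", colnames(m)[keep])]
  attr(out, "removed") <- removed
  out
}

# pairwise root-mean-square distance over mutually detected peaks
.shared_rms_dist <- function(m) {
  mask <- (!is.na(m)) * 1
  s <- m; s[is.na(s)] <- 0
  cross <- tcrossprod(s)
  a <- tcrossprod(s^2, mask)
  d2 <- a + t(a) - 2 * cross
  cnt <- tcrossprod(mask)
  d <- sqrt(pmax(d2, 0) / ifelse(cnt > 0, cnt, NA))
  diag(d) <- NA
  d
}

#' k-nearest-neighbour imputation
#'
#' Replaces each non-detect by a distance-weighted average of the peak's
#' detected values in the `k` nearest samples. Distance between two samples
#' is the root-mean-square difference over the peaks detected in both, so
#' samples with different amounts of missingness are comparable; neighbour
#' weights are 1/distance, and exact duplicates (distance 0) take over
#' entirely. Neighbours without a detected value for the target peak are
#' skipped in favour of the next nearest.
#'
#' @param peaks Peak table; every peak must have at least one detected value.
#' @param k Number of neighbours; values `>= n - 1` are clipped with a
#'   warning.
#' @return A complete peak table.
#' @export
knn_impute <- function(peaks, k = 10) {
  m <- peaks_to_matrix(peaks)
  if (!anyNA(m)) return(peaks)
  empty <- colSums(!is.na(m)) == 0
  if (any(empty)) {
    abort(paste0("peak(s) with no detected value: ",
                 paste(colnames(m)[empty], collapse = ", ")))
  }
  n <- nrow(m)
  if (k > n - 1) {
    warn(paste0("k = ", k, " clipped to n - 1 = ", n - 1))
    k <- n - 1
  }
  d <- .shared_rms_dist(m)
  out <- m
  for (i in seq_len(n)) {
    miss <- which(is.na(m[i, ]))
    if (length(miss) == 0) next
    ord <- order(d[i, ], na.last = NA)  # stable: ties resolved by index
    for (j in miss) {
      cand <- ord[!is.na(m[ord, j])]
      if (length(cand) == 0) next  # unreachable: every peak has a detection
      nb <- cand[seq_len(min(k, length(cand)))]
      dist <- d[i, nb]
      if (any(dist == 0)) {
        out[i, j] <- mean(m[nb[dist == 0], j])
      } else {
        w <- 1 / dist
        out[i, j] <- sum(w * m[nb, j]) / sum(w)
      }
    }
  }
  matrix_to_peaks(out)
}

#' Fit the generalized-log transform parameter
#'
#' Chooses the transform offset lambda that makes the technical variance of
#' QC replicates as homogeneous as possible across peaks: a grid search
#' minimizing the variance of the per-peak replicate variances of
#' `g(x) = ln(x + sqrt(x^2 + lambda))`, after dividing by their mean so the
#' criterion is scale-free. With purely multiplicative noise the objective
#' decreases towards small lambda (g approaches an ordinary log); additive
#' noise at low intensities pushes lambda up.
#'
#' @param qc_peaks Complete (imputed) peak table of QC replicates.
#' @param lambda_grid Grid of candidate lambdas (default 25 log-spaced
#'   points over 1e-2..1e8).
#' @return The selected lambda, with the grid and objective values attached
#'   as attributes. If the objective is flat (variance already homogeneous)
#'   the smallest grid value is returned with a message.
#' @export
glog_fit <- function(qc_peaks, lambda_grid = 10^seq(-2, 8, length.out = 25)) {
  m <- peaks_to_matrix(qc_peaks)
  if (nrow(m) < 3) abort("glog fit needs at least 3 QC replicates")
  if (anyNA(m)) abort("glog fit needs a complete (imputed) QC table")
  obj <- vapply(lambda_grid, function(l) {
    v <- apply(.glog(m, l), 2, var)
    mv <- mean(v)
    if (mv == 0) return(0)
    var(v / mv)
  }, numeric(1))
  if (diff(range(obj)) < 1e-12) {
    inform("QC variance already homogeneous; returning the smallest grid lambda")
    lam <- lambda_grid[1]
  } else {
    lam <- lambda_grid[which.min(obj)]
  }
  structure(lam, grid = lambda_grid, objective = obj)
}

.glog <- function(x, lambda) log(x + sqrt(x^2 + lambda))

#' Apply the generalized-log transform
#'
#' `g(x) = ln(x + sqrt(x^2 + lambda))`, strictly increasing in `x`; at
#' lambda = 0 it is `ln(2x)`, and for `x >> sqrt(lambda)` it approaches
#' `ln(2x)`.
#'
#' @param peaks Peak table with nonnegative intensities.
#' @param lambda Nonnegative transform parameter.
#' @return The transformed peak table.
#' @export
glog_apply <- function(peaks, lambda) {
  if (lambda < 0) abort("lambda must be nonnegative")
  m <- peaks_to_matrix(peaks)
  if (any(m < 0, na.rm = TRUE)) abort("negative intensity: glog is defined for x >= 0")
  matrix_to_peaks(.glog(m, lambda))
}

# robust score/orthogonal-distance outlier detection on one group
.robust_outliers <- function(m, var_target = 0.80, alpha = 0.975) {
  scale <- apply(m, 2, mad)
  scale[scale == 0] <- apply(m[, scale == 0, drop = FALSE], 2, sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(m, 2, apply(m, 2, median)), 2, scale, "/")
  pc <- prcomp(z, center = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-10)
  q <- min(which(cumsum(ev) / sum(ev) >= var_target), rank, 10)
  t_s <- pc$x[, seq_len(q), drop = FALSE]
  sd2 <- rowSums(sweep(t_s^2, 2, ev[seq_len(q)], "/"))
  flag_sd <- sd2 > qchisq(alpha, df = q)
  recon <- t_s %*% t(pc$rotation[, seq_len(q), drop = FALSE])
  od <- sqrt(rowSums((z - recon)^2))
  flag_od <- rep(FALSE, nrow(m))
  if (q < rank && any(od > 1e-10)) {
    od23 <- od^(2 / 3)
    cut <- (median(od23) + mad(od23) * stats::qnorm(alpha))^(3 / 2)
    flag_od <- od > cut
  }
  rownames(m)[flag_sd | flag_od]
}

#' Robust-PCA outlier pass on the QC and HV groups
#'
#' Flags samples whose robust score distance or orthogonal distance on a
#' PCA of median-centered, MAD-scaled data exceeds the 0.975 chi-square /
#' normal-quantile cutoffs. Each role group is screened separately; groups
#' with fewer than 10 samples are skipped with a warning.
#'
#' @param peaks Complete, transformed peak table.
#' @param meta Sample metadata; rows with `role` in `roles` are screened.
#' @param roles Roles to screen (default QC and HV).
#' @return Character vector of flagged sample ids.
#' @export
robust_outlier_pass <- function(peaks, meta, roles = c("QC", "HV")) {
  m <- peaks_to_matrix(peaks)
  out <- character()
  for (rl in roles) {
    ids <- meta$sample_id[meta$role == rl]
    ids <- intersect(ids, rownames(m))
    if (length(ids) == 0) next
    if (length(ids) < 10) {
      warn(paste0("outlier pass skipped for ", rl, ": fewer than 10 samples"))
      next
    }
    out <- c(out, .robust_outliers(m[ids, , drop = FALSE]))
  }
  out
}

#' Run the full preprocessing chain
#'
#' Executes, in order: peak exclusion, presence filter, quotient
#' normalization, QC CV filter, k-NN imputation and generalized-log
#' transform; when `outlier_pass` is on, QC/HV samples flagged by robust
#' PCA are removed and the normalization reference and transform parameter
#' are re-estimated and re-applied. STUDY samples are never dropped here.
#'
#' @param peaks Raw peak table.
#' @param meta Sample metadata.
#' @param config A [preprocess_config()].
#' @return A `preprocess_result` list: `peaks` (the analysis-ready,
#'   complete, transformed table), and `report` with the removed peaks per
#'   step (each removed peak appears exactly once), flagged outliers, the
#'   fitted lambda, dilution factors and the executed stage order.
#' @export
preprocess_pipeline <- function(peaks, meta, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  meta <- validate_sample_meta(meta)
  removed <- tibble::tibble(peak = character(), reason = character())
  steps <- character()

  tbl <- validate_peak_table(peaks)
  if (length(config$exclude_peaks) > 0) {
    drop <- intersect(names(tbl), config$exclude_peaks)
    tbl <- tbl[setdiff(names(tbl), drop)]
    removed <- dplyr::bind_rows(removed, tibble::tibble(peak = drop, reason = "excluded"))
    steps <- c(steps, "exclusion")
  }
  if (config$presence_threshold > 0) {
    tbl <- presence_filter(tbl, meta, config$presence_threshold)
    removed <- dplyr::bind_rows(removed, attr(tbl, "removed"))
    steps <- c(steps, "presence_filter")
  }

  run_core <- function(tbl, meta_eff, removed, steps) {
    ref_ids <- .pqn_reference_ids(meta_eff, config$pqn_reference)
    do_cv <- is.finite(config$cv_threshold)
    if (do_cv && config$cv_before_pqn) {
      tbl <- cv_filter(tbl, meta_eff, config$cv_threshold)
      removed <- dplyr::bind_rows(removed, attr(tbl, "removed"))
      steps <- c(steps, "cv_filter")
    }
    pq <- pqn_normalize(tbl, ref_ids)
    tbl <- pq$peaks
    steps <- c(steps, "pqn")
    if (do_cv && !config$cv_before_pqn) {
      tbl <- cv_filter(tbl, meta_eff, config$cv_threshold)
      removed <- dplyr::bind_rows(removed, attr(tbl, "removed"))
      steps <- c(steps, "cv_filter")
    }
    if (anyNA(peaks_to_matrix(tbl))) {
      tbl <- knn_impute(tbl, config$knn_k)
      steps <- c(steps, "knn_impute")
    }
    qc_ids <- meta_eff$sample_id[meta_eff$role == "QC"]
    lambda <- if (identical(config$glog_lambda, "auto")) {
      as.numeric(glog_fit(dplyr::filter(tbl, .data$sample_id %in% qc_ids)))
    } else {
      config$glog_lambda
    }
    tbl <- glog_apply(tbl, lambda)
    steps <- c(steps, "glog")
    list(tbl = tbl, removed = removed, steps = steps,
         factors = pq$factors, lambda = lambda)
  }

  res <- run_core(tbl, meta, removed, steps)
  outliers <- character()
  if (config$outlier_pass) {
    outliers <- robust_outlier_pass(res$tbl, meta)
    steps <- c(res$steps, "outlier_pass")
    if (length(outliers) > 0) {
      meta_eff <- dplyr::filter(meta, !.data$sample_id %in% outliers)
      tbl2 <- dplyr::filter(tbl, !.data$sample_id %in% outliers)
      res <- run_core(tbl2, meta_eff, removed, steps)
      res$steps <- c(res$steps, "rerun_after_outliers")
    } else {
      res$steps <- steps
    }
  }

  structure(list(
    peaks = res$tbl,
    report = list(removed = res$removed, outliers = outliers,
                  lambda = res$lambda, dilution = res$factors,
                  steps = res$steps)),
    class = "preprocess_result")
}

.pqn_reference_ids <- function(meta, ref) {
  ids <- meta$sample_id[meta$role == ref$role & !is.na(meta$center) &
                          meta$center == ref$center]
  if (length(ids) == 0) ids <- meta$sample_id[meta$role == ref$role]
  if (length(ids) == 0) {
    abort(paste0("no ", ref$role, " samples available as normalization reference"))
  }
  ids
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result>\n")
  cat("  samples:", nrow(x$peaks), " peaks:", ncol(x$peaks) - 1, "\n")
  cat("  stages: ", paste(x$report$steps, collapse = " -> "), "\n")
  cat("  peaks removed:", nrow(x$report$removed),
      " outliers:", length(x$report$outliers),
      " lambda:", format(x$report$lambda, digits = 4), "\n")
  invisible(x)
}
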