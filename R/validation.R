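#' Cross-validation configuration
#'
#' Settings of the double (nested) cross-validation: the outer loop
#' estimates prediction performance, the inner loop selects the model size.
#' Defaults follow the stratified 8-fold outer / 7-fold inner scheme with
#' 50 outer repeats and a single inner repeat; scenarios with higher class
#' imbalance use smaller k (7/6 for the CS-vs-PHT contrast, 6/5 for the
#' reduced center-filtered cohorts), exposed through `scenario_override`.
#'
#' @param outer_k,inner_k Fold counts of the outer and inner loops.
#' @param outer_repeats Number of outer-loop repeats (folds re-randomized
#'   per repeat).
#' @param inner_repeats Inner-loop repeats (1, as in the reference scheme).
#' @param max_ncomp Largest number of latent components searched.
#' @param keepX_grid Candidate per-component variable counts for the sparse
#'   model (`Inf` = all variables; capped at p at fit time).
#' @param control Class treated as the negative/control label for
#'   sensitivity/specificity (used when present among the labels).
#' @param scenario Optional scenario name; when it matches an entry of
#'   `scenario_override` the fold counts are replaced.
#' @param scenario_override Named list: scenario -> `c(outer_k, inner_k)`.
#' @param se_tol Parsimony tolerance of the inner selection: the smallest
#'   model within `se_tol` binomial standard errors of the maximum inner
#'   accuracy is chosen (the one-standard-error rule at the default 1);
#'   0 gives the strict minimum-at-maximum rule.
#' @param seed Integer seed driving all fold randomization.
#' @return A `cv_config` list.
#' @export
cv_config <- function(outer_k = 8, inner_k = 7, outer_repeats = 50,
                      inner_repeats = 1, max_ncomp = 10,
                      keepX_grid = c(1, 2, 5, 10, 15, 20, Inf),
                      control = "PHT",
                      scenario = NULL,
                      scenario_override = list("CS-PHT" = c(7, 6),
                                               "approach_c" = c(6, 5)),
                      se_tol = 1,
                      seed = 1L) {
  if (!is.null(scenario) && scenario %in% names(scenario_override)) {
    kk <- scenario_override[[scenario]]
    outer_k <- kk[1]; inner_k <- kk[2]
  }
  stopifnot(outer_repeats >= 1, inner_repeats >= 1, inner_k >= 2, outer_k >= 2)
  structure(list(outer_k = outer_k, inner_k = inner_k,
                 outer_repeats = outer_repeats, inner_repeats = inner_repeats,
                 max_ncomp = max_ncomp, keepX_grid = keepX_grid,
                 control = control, se_tol = se_tol, seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified k-fold assignment
#'
#' Assigns samples to k folds so that every fold holds an equal share of
#' each class (sizes differing by at most one per class). `k` larger than
#' the smallest class count is reduced with a warning so no training split
#' can lose a class.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @return Integer vector of fold ids in 1..k, with the (possibly reduced)
#'   `k` as attribute `k`. Uses the current RNG state; seed upstream for
#'   reproducibility.
#' @export
stratified_kfold <- function(labels, k) {
  labels <- as.character(labels)
  min_n <- min(table(labels))
  if (k > min_n) {
    warn(paste0("k reduced from ", k, " to smallest class count ", min_n))
    k <- min_n
  }
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- which(labels == l)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  structure(fold, k = k)
}

# accuracy of each (ncomp, keepX) cell under one k-fold pass
.cv_accuracy_grid <- function(m, y, k, max_a, keepx_grid, sparse) {
  folds <- suppressWarnings(stratified_kfold(y, k))
  k <- attr(folds, "k")
  nkx <- length(keepx_grid)
  correct <- matrix(0, max_a, nkx)
  for (f in seq_len(k)) {
    tr <- folds != f
    a_max <- min(max_a, sum(tr) - 1, ncol(m))
    for (ik in seq_len(nkx)) {
      fit <- suppressWarnings(tryCatch(
        if (sparse) .pls_core(m[tr, , drop = FALSE], y[tr], a_max,
                              keepX = rep(keepx_grid[ik], a_max))
        else .pls_core(m[tr, , drop = FALSE], y[tr], a_max, keepX = NULL),
        error = function(e) NULL))
      if (is.null(fit)) next
      for (a in seq_len(max_a)) {
        ae <- min(a, fit$ncomp)
        pred <- .predict_labels(fit, m[!tr, , drop = FALSE], ae)
        correct[a, ik] <- correct[a, ik] + sum(pred == y[!tr])
      }
    }
  }
  correct / length(y)
}

# smallest model (min ncomp, then min keepX) within `se_tol` binomial
# standard errors of the maximum inner accuracy; se_tol = 0 is the strict
# minimum-at-maximum rule
.pick_hyper <- function(acc, keepx_grid, n = NULL, se_tol = 1) {
  best <- max(acc)
  tol <- 1e-12
  if (!is.null(n) && se_tol > 0) {
    tol <- tol + se_tol * sqrt(max(best * (1 - best), 1e-12) / n)
  }
  hit <- which(acc >= best - tol, arr.ind = TRUE)
  a <- min(hit[, 1])
  kx <- keepx_grid[min(hit[hit[, 1] == a, 2])]
  list(ncomp = a, keepX = kx)
}

.per_class_tp <- function(truth, pred, levels) {
  vapply(levels, function(l) {
    n <- sum(truth == l)
    if (n == 0) NA_real_ else sum(pred == l & truth == l) / n
  }, numeric(1))
}

#' Double cross-validation of a PLS-DA classifier
#'
#' For each outer repeat, samples are split into stratified outer folds;
#' within each outer-training set a single inner k-fold pass scores every
#' candidate model size (components, and variable count for the sparse
#' family), the smallest model attaining the maximum inner accuracy is
#' chosen, refit on the outer-training set and used to predict the held-out
#' fold by Mahalanobis distance. Per-repeat confusion matrices, balanced
#' accuracy (mean per-class true-positive rate), sensitivity/specificity
#' (binary), chosen hyperparameters and the VIP vector of every refit
#' outer-training model are retained.
#'
#' When `correction` is supplied, an ASCA effect removal is estimated on
#' each outer-training fold and applied out-of-sample to the held-out fold
#' (see [asca_correct_oos()]); correcting train and test jointly would make
#' the held-out group means anti-correlated with the training means and
#' push the removed factor's apparent accuracy far below chance.
#'
#' @param x Feature data (peak table, data frame or matrix).
#' @param y Class labels.
#' @param model_family `"plsda"` or `"splsda"`.
#' @param cfg A [cv_config()].
#' @param correction Optional fold-internal confounder correction: a list
#'   with `factors` (data frame of design factors aligned with the rows of
#'   `x`), `remove` (effect names to subtract) and optionally
#'   `with_interaction`.
#' @return A `cv2_result`: `metrics` (long tibble, percent scale),
#'   `confusion` (one matrix per repeat), `chosen` (hyperparameters per
#'   outer fold), `vip` (models x features matrix), plus label metadata.
#' @export
cv2_evaluate <- function(x, y, model_family = c("plsda", "splsda"),
                         cfg = cv_config(), correction = NULL) {
  model_family <- match.arg(model_family)
  sparse <- model_family == "splsda"
  m <- .as_feature_matrix(x)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) < 2) abort("need at least 2 classes")
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  p <- ncol(m)
  keepx_grid <- if (sparse) sort(unique(pmin(cfg$keepX_grid, p))) else NA_real_
  control <- if (cfg$control %in% lev) cfg$control else lev[1]
  case <- if (length(lev) == 2) setdiff(lev, control) else NA_character_

  metrics <- list(); confusion <- list(); chosen <- list(); vips <- list()
  for (r in seq_len(cfg$outer_repeats)) {
    folds <- suppressWarnings(stratified_kfold(y, cfg$outer_k))
    ko <- attr(folds, "k")
    truth <- character(0); pred <- character(0)
    for (f in seq_len(ko)) {
      tr <- folds != f
      m_tr <- m[tr, , drop = FALSE]
      m_te <- m[!tr, , drop = FALSE]
      if (!is.null(correction)) {
        fac <- tibble::as_tibble(correction$factors)
        dec <- asca_decompose(m_tr, fac[tr, , drop = FALSE],
                              with_interaction = isTRUE(correction$with_interaction))
        m_tr <- asca_correct(dec, correction$remove)
        m_te <- suppressWarnings(
          asca_correct_oos(dec, m_te, fac[!tr, , drop = FALSE], correction$remove))
      }
      max_a <- min(cfg$max_ncomp, sum(tr) - 1, p)
      acc <- 0
      for (ir in seq_len(cfg$inner_repeats)) {
        acc <- acc + .cv_accuracy_grid(m_tr, y[tr],
                                       cfg$inner_k, max_a, keepx_grid, sparse)
      }
      hp <- .pick_hyper(acc, keepx_grid, n = sum(tr), se_tol = cfg$se_tol %||% 1)
      fit <- suppressWarnings(tryCatch(
        if (sparse) .pls_core(m_tr, y[tr], hp$ncomp,
                              keepX = rep(hp$keepX, hp$ncomp))
        else .pls_core(m_tr, y[tr], hp$ncomp, keepX = NULL),
        error = function(e) NULL))
      if (is.null(fit)) {
        # degenerate training fold (no class covariance left): null model,
        # predicting the majority training label
        tb <- table(y[tr])
        pf <- rep(names(tb)[which.max(tb)], sum(!tr))
        chosen[[length(chosen) + 1]] <- tibble::tibble(
          repeat_id = r, fold = f, ncomp = 0, keepX = NA_real_)
        vips[[length(vips) + 1]] <- setNames(rep(0, p), colnames(m))
      } else {
        pf <- .predict_labels(fit, m_te, fit$ncomp)
        chosen[[length(chosen) + 1]] <- tibble::tibble(
          repeat_id = r, fold = f, ncomp = fit$ncomp,
          keepX = if (sparse) hp$keepX else NA_real_)
        vips[[length(vips) + 1]] <- vip(fit)
      }
      truth <- c(truth, y[!tr]); pred <- c(pred, pf)
    }
    cm <- table(factor(truth, lev), factor(pred, lev))
    confusion[[r]] <- cm
    tp <- .per_class_tp(truth, pred, lev)
    vals <- c(balanced_accuracy = mean(tp, na.rm = TRUE) * 100)
    if (length(lev) == 2) {
      vals <- c(vals, sensitivity = unname(tp[case]) * 100,
                specificity = unname(tp[control]) * 100)
    } else {
      vals <- c(vals, setNames(tp * 100, paste0("tp_rate_", lev)))
    }
    metrics[[r]] <- tibble::tibble(repeat_id = r, metric = names(vals),
                                   value = unname(vals))
  }
  structure(list(metrics = dplyr::bind_rows(metrics),
                 confusion = confusion,
                 chosen = dplyr::bind_rows(chosen),
                 vip = do.call(rbind, vips),
                 levels = lev, control = control, case = case,
                 family = model_family, config = cfg),
            class = "cv2_result")
}

#' @export
print.cv2_result <- function(x, ...) {
  cat("<cv2_result> ", x$family, ", classes: ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Mean and 95% confidence interval over repeats
#'
#' One-sample t interval across the per-repeat metric values:
#' mean +/- t(0.975, r-1) * sd / sqrt(r). A zero-variance input yields a
#' degenerate interval equal to the mean.
#'
#' @param values Numeric vector of per-repeat values (at least 2).
#' @return A tibble with `mean`, `ci_lo`, `ci_hi`.
#' @export
metrics_ci <- function(values) {
  r <- length(values)
  if (r < 2) abort("need at least 2 repeats")
  m <- mean(values)
  half <- qt(0.975, r - 1) * sd(values) / sqrt(r)
  if (!is.finite(half)) half <- 0
  tibble::tibble(mean = m, ci_lo = m - half, ci_hi = m + half)
}

#' Signature by outer-loop VIP
#'
#' Features whose median VIP score across all outer-fold refit models
#' exceeds the threshold (strictly).
#'
#' @param result A [cv2_evaluate()] result.
#' @param threshold VIP cutoff (default 1).
#' @return Character vector of feature labels.
#' @export
signature_from_vip <- function(result, threshold = 1) {
  stopifnot(inherits(result, "cv2_result"))
  if (is.null(result$vip) || nrow(result$vip) == 0) abort("result holds no VIP vectors")
  med <- apply(result$vip, 2, median)
  names(med)[med > threshold]
}

.modal_min <- function(v) {
  tb <- table(v)
  as.numeric(names(tb)[tb == max(tb)])[1]  # names sorted ascending: ties -> smaller
}

#' Sparse PLS-DA signature on the full sample set
#'
#' Chooses the model size by repeated single cross-validation on all
#' samples (same fold counts and number of repeats as the outer CV loop):
#' each repeat picks the smallest (components, keepX) attaining its maximum
#' accuracy, the modal values across repeats (ties to the smaller) are
#' retained, and the final model is fit on all samples. The regression
#' coefficients of that model are the reported signature; never-selected
#' features carry an exact zero.
#'
#' @param x Feature data.
#' @param y Class labels.
#' @param cfg A [cv_config()]; `outer_k` folds, `outer_repeats` repeats.
#' @return An `spls_signature`: the final model, chosen `ncomp`/`keepX`,
#'   and a `coefficients` tibble (feature, one column per class for
#'   multiclass or a single `coefficient` column for the case class in a
#'   binary contrast).
#' @export
signature_from_splsda <- function(x, y, cfg = cv_config()) {
  m <- .as_feature_matrix(x)
  y <- as.character(y)
  lev <- sort(unique(y))
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  p <- ncol(m)
  keepx_grid <- sort(unique(pmin(cfg$keepX_grid, p)))
  max_a <- min(cfg$max_ncomp, nrow(m) - 1, p)
  picks <- purrr::map_dfr(seq_len(cfg$outer_repeats), function(r) {
    acc <- .cv_accuracy_grid(m, y, cfg$outer_k, max_a, keepx_grid, sparse = TRUE)
    tibble::as_tibble(.pick_hyper(acc, keepx_grid, n = nrow(m), se_tol = cfg$se_tol %||% 1))
  })
  ncomp <- .modal_min(picks$ncomp)
  keepX <- .modal_min(picks$keepX)
  fit <- suppressWarnings(.pls_core(m, y, ncomp, keepX = rep(keepX, ncomp)))
  control <- if (cfg$control %in% lev) cfg$control else lev[1]
  coefs <- if (length(lev) == 2) {
    case <- setdiff(lev, control)
    tibble::tibble(feature = fit$features, coefficient = fit$B[, case])
  } else {
    dplyr::bind_cols(tibble::tibble(feature = fit$features),
                     tibble::as_tibble(fit$B))
  }
  structure(list(model = fit, ncomp = fit$ncomp, keepX = keepX,
                 coefficients = coefs, picks = picks, levels = lev,
                 control = control),
            class = "spls_signature")
}

#' @export
print.spls_signature <- function(x, ...) {
  cat("<spls_signature> ncomp =", x$ncomp, ", keepX =", x$keepX, "\n")
  nz <- if ("coefficient" %in% names(x$coefficients)) {
    sum(x$coefficients$coefficient != 0)
  } else {
    sum(rowSums(as.matrix(x$coefficients[-1]) != 0) > 0)
  }
  cat("  nonzero features:", nz, "of", nrow(x$coefficients), "\n")
  invisible(x)
}
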