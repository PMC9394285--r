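# ---- internal helpers --------------------------------------------------

# accept a peak table, data frame or matrix of features
.as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  x <- tibble::as_tibble(x)
  if ("sample_id" %in% names(x)) return(peaks_to_matrix(x))
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

# centered indicator (dummy) response, one column per class
.dummy_y <- function(y, levels) {
  yd <- outer(as.character(y), levels, "==") * 1
  colnames(yd) <- levels
  list(raw = yd, centered = scale(yd, center = TRUE, scale = FALSE),
       means = colMeans(yd))
}

# ---- PLS-DA ------------------------------------------------------------

#' Fit a (sparse) PLS discriminant model
#'
#' Partial least squares discriminant analysis on mean-centered, unscaled
#' data with a centered indicator column per class. Components are
#' extracted iteratively: the weight vector is the dominant singular
#' direction of the X'Y covariance (truncated to its `keepX`
#' largest-magnitude entries and renormalized for the sparse variant), X is
#' deflated by the score-loading outer product, and Y is left undeflated.
#' The component sign is fixed by forcing the largest-magnitude weight
#' entry positive, so fits are reproducible across platforms.
#'
#' @param x Feature data: a peak table, data frame or numeric matrix
#'   (samples x features).
#' @param y Class labels (character or factor); at least two classes with
#'   two samples each. Class order is the sorted label order (CS < PA <
#'   PHT < PPGL for the disease codes), used for deterministic tie-breaks.
#' @param ncomp Number of latent components; clipped to `min(n - 1, p)`
#'   with a warning, and truncated early if X runs out of covariance with Y.
#' @param keepX For [splsda_fit()]: number of variables retained per
#'   component (recycled; `Inf` means all).
#' @return An object of class `nmr_pls` (and `nmr_spls` when sparse):
#'   weights `W`, loadings `P`, Y-loadings `C`, scores `T`, per-component
#'   explained Y sum of squares `ssy`, feature/class metadata, regression
#'   coefficients `B` (features x classes) and everything needed to project
#'   new samples.
#' @export
plsda_fit <- function(x, y, ncomp = 2) {
  .pls_core(x, y, ncomp, keepX = NULL)
}

#' @rdname plsda_fit
#' @export
splsda_fit <- function(x, y, ncomp = 2, keepX) {
  if (any(keepX == 0)) abort("keepX must be >= 1")
  .pls_core(x, y, ncomp, keepX = keepX)
}

.pls_core <- function(x, y, ncomp, keepX) {
  m <- .as_feature_matrix(x)
  y <- as.character(y)
  if (anyNA(m)) abort("PLS-DA needs a complete matrix; impute first")
  lev <- sort(unique(y))
  if (length(lev) < 2) abort("need at least 2 classes")
  if (any(table(y) < 2)) abort("every class needs at least 2 samples")
  n <- nrow(m); p <- ncol(m); g <- length(lev)
  max_a <- min(n - 1, p)
  if (ncomp > max_a) {
    warn(paste0("ncomp reduced to ", max_a))
    ncomp <- max_a
  }
  sparse <- !is.null(keepX)
  if (sparse) {
    keepX <- pmin(rep_len(keepX, ncomp), p)
  }
  dm <- .dummy_y(y, lev)
  x_mean <- colMeans(m)
  xd <- sweep(m, 2, x_mean)
  yc <- dm$centered
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, g, ncomp); TT <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  a_done <- 0
  for (a in seq_len(ncomp)) {
    M <- crossprod(xd, yc)
    if (max(abs(M)) < 1e-12) {
      if (a == 1) abort("X carries no covariance with the class labels")
      break
    }
    w <- svd(M, nu = 1, nv = 0)$u[, 1]
    if (sparse) {
      ka <- keepX[a]
      keep <- rank(-abs(w), ties.method = "first") <= ka
      w[!keep] <- 0
      w <- w / sqrt(sum(w^2))
    }
    w <- w * sign(w[which.max(abs(w))])
    t_a <- drop(xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(xd, t_a)) / tt
    c_a <- drop(crossprod(yc, t_a)) / tt
    W[, a] <- w; P[, a] <- p_a; C[, a] <- c_a; TT[, a] <- t_a
    ssy[a] <- tt * sum(c_a^2)
    xd <- xd - tcrossprod(t_a, p_a)
    a_done <- a
  }
  idx <- seq_len(a_done)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  C <- C[, idx, drop = FALSE]; TT <- TT[, idx, drop = FALSE]
  ssy <- ssy[idx]
  rstar <- W %*% solve(crossprod(P, W))
  B <- rstar %*% t(C)
  dimnames(B) <- list(colnames(m), lev)
  fit <- list(ncomp = a_done, W = W, P = P, C = C, T = TT, ssy = ssy,
              ssy_total = sum(yc^2), x_mean = x_mean, y_means = dm$means,
              levels = lev, y = y, n = n, p = p,
              features = colnames(m), rstar = rstar, B = B,
              keepX = if (sparse) keepX[idx] else NULL,
              selected = if (sparse) colnames(m)[rowSums(W != 0) > 0] else NULL)
  class(fit) <- c(if (sparse) "nmr_spls", "nmr_pls")
  fit
}

#' @export
print.nmr_pls <- function(x, ...) {
  cat("<", if (inherits(x, "nmr_spls")) "sparse " else "", "PLS-DA model> ",
      x$n, " samples, ", x$p, " features, ", x$ncomp, " component(s)\n", sep = "")
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  if (!is.null(x$keepX)) cat("  keepX:", paste(x$keepX, collapse = ", "), "\n")
  invisible(x)
}

#' Variable importance in the projection
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where SSY_a is the Y sum of squares explained by component a. The mean
#' of VIP^2 over features is exactly 1, so features above 1 are more
#' influential than average.
#'
#' @param model A fitted [plsda_fit()]/[splsda_fit()] model.
#' @return A named numeric vector, one score per feature.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "nmr_pls"))
  if (sum(model$ssy) <= 0) abort("model explains no Y variance: VIP undefined")
  wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  v <- sqrt(model$p * drop(wn^2 %*% model$ssy) / sum(model$ssy))
  names(v) <- model$features
  v
}

# reorder new-data columns to the training feature order when both are named
.align_features <- function(model, m) {
  if (!is.null(model$features) && !is.null(colnames(m))) {
    miss <- setdiff(model$features, colnames(m))
    if (length(miss) > 0) {
      abort(paste0("new data lacks feature(s): ", paste(miss, collapse = ", ")))
    }
    m <- m[, model$features, drop = FALSE]
  }
  m
}

# score-space projection of new samples; leading `a` components
.project_scores <- function(model, m, a) {
  r <- if (a == model$ncomp) model$rstar else
    model$W[, 1:a, drop = FALSE] %*%
      solve(crossprod(model$P[, 1:a, drop = FALSE], model$W[, 1:a, drop = FALSE]))
  sweep(m, 2, model$x_mean) %*% r
}

# class means and pooled within-class covariance of training scores
.score_space_stats <- function(model, a) {
  ts <- model$T[, 1:a, drop = FALSE]
  lev <- model$levels
  mu <- vapply(lev, function(l) colMeans(ts[model$y == l, , drop = FALSE]),
               numeric(a))
  mu <- t(matrix(mu, nrow = a))  # classes x components
  cen <- ts - mu[match(model$y, lev), , drop = FALSE]
  s <- crossprod(cen) / (model$n - length(lev))
  ok <- tryCatch({solve(s); TRUE}, error = function(e) FALSE)
  if (!ok || kappa(s) > 1e12) {
    warn("singular pooled score covariance: ridge-regularized")
    s <- s + diag(1e-8 * sum(diag(s)) / a, a)
  }
  list(mu = mu, sinv = solve(s))
}

#' Predict class labels by Mahalanobis distance in score space
#'
#' Projects new samples into the latent score space and assigns each to the
#' class whose training score mean is nearest under the pooled within-class
#' score covariance. Ties break to the first class in sorted label order.
#'
#' @param model A fitted PLS-DA model.
#' @param new_data New samples over the same feature space.
#' @param ncomp Number of leading components to use (default: all fitted).
#' @return A tibble with `sample` (row identifier), the predicted `.pred`
#'   label, and one score column per component.
#' @export
predict_mahalanobis <- function(model, new_data, ncomp = model$ncomp) {
  m <- .align_features(model, .as_feature_matrix(new_data))
  lab <- .predict_labels(model, m, ncomp)
  ts <- .project_scores(model, m, ncomp)
  out <- tibble::tibble(sample = rownames(m) %||% as.character(seq_len(nrow(m))),
                        .pred = lab)
  for (a in seq_len(ncomp)) out[[paste0("comp", a)]] <- ts[, a]
  out
}

.predict_labels <- function(model, m, a) {
  ts <- .project_scores(model, m, a)
  st <- .score_space_stats(model, a)
  d2 <- vapply(seq_along(model$levels), function(k) {
    dif <- sweep(ts, 2, st$mu[k, ])
    rowSums((dif %*% st$sinv) * dif)
  }, numeric(nrow(ts)))
  d2 <- matrix(d2, nrow = nrow(ts))
  # ties break to the first (sorted) class label
  model$levels[apply(d2, 1, which.min)]
}

#' @export
predict.nmr_pls <- function(object, new_data, ncomp = object$ncomp,
                            type = c("class", "scores"), ...) {
  type <- match.arg(type)
  m <- .align_features(object, .as_feature_matrix(new_data))
  if (type == "scores") return(.project_scores(object, m, ncomp))
  .predict_labels(object, m, ncomp)
}

# ---- PCA ---------------------------------------------------------------

#' Principal component analysis
#'
#' Thin wrapper around the singular value decomposition of the centered
#' matrix, returning orthonormal loadings, scores and explained-variance
#' fractions. Used as the unsupervised view of the data (trend and outlier
#' discovery, center-cluster geometry).
#'
#' @param x Feature data (peak table, data frame or matrix).
#' @param ncomp Number of components; reduced to the matrix rank with a
#'   warning if larger.
#' @return An `nmr_pca` list with `scores`, `loadings`, `var_fraction`,
#'   `center`.
#' @export
pca_fit <- function(x, ncomp = 2) {
  m <- .as_feature_matrix(x)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (ncomp > rank) {
    warn(paste0("ncomp reduced to rank ", rank))
    ncomp <- rank
  }
  structure(list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
                 loadings = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 var_fraction = ev[seq_len(ncomp)] / sum(ev),
                 center = pc$center, ncomp = ncomp),
            class = "nmr_pca")
}

# ---- L1 logistic regression --------------------------------------------

#' L1-regularized logistic regression
#'
#' Lasso-penalized logistic fit (via coordinate descent as implemented in
#' glmnet) for a binary contrast, with the penalty chosen by k-fold
#' cross-validated misclassification rate; the alternative, regression-based
#' route to a sparse signature. Metabolite intensities enter unscaled;
#' set `standardize = TRUE` when mixing in clinical covariates on other
#' scales.
#'
#' @param x Feature data.
#' @param y Binary class labels.
#' @param lambda_grid Optional decreasing penalty grid; glmnet's default
#'   path when `NULL`.
#' @param cv_folds Folds for the penalty search.
#' @param standardize Autoscale columns before fitting?
#' @return An `nmr_l1log` list: the glmnet path, the chosen `lambda`,
#'   `coefficients` (named, intercept excluded), `intercept` and the path
#'   of nonzero counts.
#' @export
l1_logistic_fit <- function(x, y, lambda_grid = NULL, cv_folds = 10,
                            standardize = FALSE) {
  m <- .as_feature_matrix(x)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2) abort("l1 logistic regression needs exactly 2 classes")
  yb <- as.integer(y == lev[2])
  cvfit <- glmnet::cv.glmnet(m, yb, family = "binomial", alpha = 1,
                             lambda = lambda_grid, nfolds = cv_folds,
                             type.measure = "class", standardize = standardize)
  co <- coef(cvfit, s = "lambda.min")
  structure(list(path = cvfit$glmnet.fit, cv = cvfit,
                 lambda = cvfit$lambda.min,
                 coefficients = setNames(as.numeric(co)[-1], rownames(co)[-1]),
                 intercept = as.numeric(co)[1],
                 lambda_path = cvfit$lambda,
                 nonzero_path = cvfit$nzero,
                 levels = lev),
            class = "nmr_l1log")
}

# ---- serialization -------------------------------------------------------

#' Serialize a fitted PLS-DA model to JSON
#'
#' Writes every stored model field (weights, loadings, scores, explained-Y
#' sums of squares, centering vectors, class metadata, sparsity pattern and
#' regression coefficients) to a JSON document, so fits can be archived or
#' exchanged without R serialization.
#'
#' @param model A fitted [plsda_fit()]/[splsda_fit()] model.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The file path (invisibly) or a JSON string.
#' @export
pls_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "nmr_pls"))
  payload <- model[c("ncomp", "W", "P", "C", "T", "ssy", "ssy_total",
                     "x_mean", "y_means", "levels", "y", "n", "p",
                     "features", "B", "keepX", "selected")]
  payload$sparse <- inherits(model, "nmr_spls")
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                            matrix = "rowmajor", null = "null"))
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Restore a PLS-DA model from its JSON form
#'
#' @param x A JSON string or file path produced by [pls_to_json()].
#' @return A fitted-model object equivalent to the serialized one.
#' @export
pls_from_json <- function(x) {
  payload <- jsonlite::fromJSON(x)
  as_mat <- function(v) if (is.null(v)) NULL else as.matrix(v)
  fit <- list(ncomp = payload$ncomp,
              W = as_mat(payload$W), P = as_mat(payload$P),
              C = as_mat(payload$C), T = as_mat(payload$T),
              ssy = as.numeric(payload$ssy), ssy_total = payload$ssy_total,
              x_mean = setNames(as.numeric(payload$x_mean), payload$features),
              y_means = setNames(as.numeric(payload$y_means), payload$levels),
              levels = payload$levels, y = payload$y,
              n = payload$n, p = payload$p, features = payload$features,
              B = as_mat(payload$B), keepX = payload$keepX,
              selected = payload$selected)
  dimnames(fit$B) <- list(fit$features, fit$levels)
  fit$rstar <- fit$W %*% solve(crossprod(fit$P, fit$W))
  class(fit) <- c(if (isTRUE(payload$sparse)) "nmr_spls", "nmr_pls")
  fit
}
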