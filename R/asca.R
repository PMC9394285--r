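#' ANOVA-simultaneous-component-analysis decomposition
#'
#' Splits a (column-)centered data matrix into additive effect matrices for
#' categorical design factors plus residuals: each main-effect matrix holds
#' the per-level column means of the centered data, the optional interaction
#' holds the cell means minus the main effects, and the residual matrix is
#' the remainder, so the centered data are reconstructed exactly as the sum
#' of all parts.
#'
#' @param x Feature data (peak table, data frame or matrix).
#' @param factors Named list (or data frame) of categorical vectors, one
#'   entry per sample.
#' @param with_interaction Include the all-factor interaction term? Requires
#'   every combination of observed levels to be populated; an empty cell is
#'   an error naming the cell (this is what makes the correction impossible
#'   when a class exists in only one cluster).
#' @return An `asca_decomp`: `grand_mean`, `effects` (named list of
#'   matrices, interaction named `"f1:f2"`), `residuals`, per-effect sums of
#'   squares `ss`, and the design.
#' @export
asca_decompose <- function(x, factors, with_interaction = FALSE) {
  m <- .as_feature_matrix(x)
  factors <- lapply(tibble::as_tibble(factors), as.character)
  if (length(factors) < 1) abort("need at least one design factor")
  if (is.null(names(factors)) || any(names(factors) == "")) {
    names(factors) <- paste0("factor", seq_along(factors))
  }
  n <- nrow(m)
  stopifnot(all(lengths(factors) == n))
  grand <- colMeans(m)
  xc <- sweep(m, 2, grand)
  effects <- list()
  level_means <- list()
  for (nm in names(factors)) {
    f <- factors[[nm]]
    e <- matrix(0, n, ncol(m))
    lm <- list()
    for (l in unique(f)) {
      idx <- f == l
      mu <- colMeans(xc[idx, , drop = FALSE])
      lm[[l]] <- mu
      e[idx, ] <- matrix(mu, sum(idx), ncol(m), byrow = TRUE)
    }
    effects[[nm]] <- e
    level_means[[nm]] <- lm
  }
  if (with_interaction) {
    if (length(factors) < 2) abort("interaction needs at least two factors")
    cell <- do.call(paste, c(factors, sep = ":"))
    full <- do.call(paste, c(expand.grid(lapply(factors, unique),
                                         stringsAsFactors = FALSE), sep = ":"))
    missing_cells <- setdiff(full, unique(cell))
    if (length(missing_cells) > 0) {
      abort(paste0("empty design cell(s): ", paste(missing_cells, collapse = ", "),
                   "; the interaction effect cannot be estimated"))
    }
    main_sum <- Reduce(`+`, effects)
    resid_main <- xc - main_sum
    e <- matrix(0, n, ncol(m))
    lm <- list()
    for (l in unique(cell)) {
      idx <- cell == l
      mu <- colMeans(resid_main[idx, , drop = FALSE])
      lm[[l]] <- mu
      e[idx, ] <- matrix(mu, sum(idx), ncol(m), byrow = TRUE)
    }
    inm <- paste(names(factors), collapse = ":")
    effects[[inm]] <- e
    level_means[[inm]] <- lm
  }
  resid <- xc - Reduce(`+`, effects)
  ss <- c(vapply(effects, function(e) sum(e^2), numeric(1)),
          residuals = sum(resid^2))
  structure(list(grand_mean = grand, effects = effects, residuals = resid,
                 ss = ss, factors = factors, features = colnames(m),
                 level_means = level_means, sample_ids = rownames(m), n = n),
            class = "asca_decomp")
}

#' @export
print.asca_decomp <- function(x, ...) {
  cat("<asca_decomp> ", x$n, " samples, effects: ",
      paste(names(x$effects), collapse = ", "), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Remove estimated effects from the data
#'
#' Subtracts the named effect matrices from the centered data: the
#' residualization route to confounder correction (remove the cluster main
#' effect and, when estimable, the cluster-by-disease interaction, retaining
#' the disease effect for downstream classification).
#'
#' @param decomp An [asca_decompose()] result.
#' @param remove Character vector of effect names to subtract; `character(0)`
#'   returns the centered data unchanged. Removing every effect *and*
#'   `"residuals"` is an error (nothing would remain).
#' @return The corrected matrix (same dimnames as the input).
#' @export
asca_correct <- function(decomp, remove = character()) {
  stopifnot(inherits(decomp, "asca_decomp"))
  known <- c(names(decomp$effects), "residuals")
  bad <- setdiff(remove, known)
  if (length(bad) > 0) {
    abort(paste0("unknown effect(s): ", paste(bad, collapse = ", "),
                 "; available: ", paste(known, collapse = ", ")))
  }
  if (all(known %in% remove)) abort("removing all effects and residuals leaves nothing")
  out <- decomp$residuals + Reduce(
    `+`, decomp$effects[setdiff(names(decomp$effects), remove)],
    init = matrix(0, nrow(decomp$residuals), ncol(decomp$residuals)))
  if ("residuals" %in% remove) out <- out - decomp$residuals
  dimnames(out) <- list(decomp$sample_ids, decomp$features)
  out
}

#' Apply an estimated effect removal to new samples
#'
#' Out-of-sample counterpart of [asca_correct()]: centers new samples with
#' the training grand mean and subtracts, for each removed effect, the
#' training-estimated level mean matching each new sample's factor level.
#' Used inside cross-validation so that held-out samples are corrected with
#' training information only (correcting train and test jointly makes the
#' held-out group means anti-correlated with the training means and drives
#' the apparent accuracy of the removed factor far below chance).
#' Levels unseen in training contribute no adjustment (with a warning).
#'
#' @param decomp An [asca_decompose()] result (the training decomposition).
#' @param x New feature data over the same features.
#' @param factors Named list/data frame of factor values for the new
#'   samples (names matching the training design).
#' @param remove Effect names to subtract.
#' @return The corrected matrix on the centered scale of the training data.
#' @export
asca_correct_oos <- function(decomp, x, factors, remove) {
  stopifnot(inherits(decomp, "asca_decomp"))
  m <- .as_feature_matrix(x)
  if (!is.null(decomp$features)) m <- m[, decomp$features, drop = FALSE]
  factors <- lapply(tibble::as_tibble(factors), as.character)
  out <- sweep(m, 2, decomp$grand_mean)
  for (nm in remove) {
    if (!nm %in% names(decomp$level_means)) {
      abort(paste0("unknown effect '", nm, "'"))
    }
    vals <- if (grepl(":", nm, fixed = TRUE)) {
      do.call(paste, c(factors[strsplit(nm, ":", fixed = TRUE)[[1]]], sep = ":"))
    } else {
      factors[[nm]]
    }
    lm <- decomp$level_means[[nm]]
    unseen <- setdiff(unique(vals), names(lm))
    if (length(unseen) > 0) {
      warn(paste0("level(s) unseen in training for '", nm, "': ",
                  paste(unseen, collapse = ", "), "; no adjustment applied"))
    }
    for (l in intersect(unique(vals), names(lm))) {
      idx <- vals == l
      out[idx, ] <- sweep(out[idx, , drop = FALSE], 2, lm[[l]])
    }
  }
  out
}
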