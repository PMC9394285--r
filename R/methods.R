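# broom-style accessors and ggplot2 autoplot methods for the fitted objects

#' @export
tidy.nmr_pls <- function(x, ...) {
  out <- tibble::tibble(feature = x$features, vip = unname(vip(x)))
  dplyr::bind_cols(out, tibble::as_tibble(x$B))
}

#' @export
glance.nmr_pls <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, ncomp = x$ncomp,
                 classes = length(x$levels),
                 explained_y_variance = sum(x$ssy) / x$ssy_total,
                 sparse = inherits(x, "nmr_spls"))
}

#' @export
tidy.cv2_result <- function(x, ...) x$metrics

#' @export
glance.cv2_result <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(metrics_ci(.data$value), .groups = "drop")
}

#' @export
tidy.asca_decomp <- function(x, ...) {
  tibble::tibble(effect = names(x$ss), ss = unname(x$ss),
                 fraction = unname(x$ss) / sum(x$ss))
}

#' @export
tidy.spls_signature <- function(x, ...) x$coefficients

#' @export
glance.spls_signature <- function(x, ...) {
  nz <- if ("coefficient" %in% names(x$coefficients)) {
    sum(x$coefficients$coefficient != 0)
  } else {
    sum(rowSums(as.matrix(x$coefficients[-1]) != 0) > 0)
  }
  tibble::tibble(ncomp = x$ncomp, keepX = x$keepX,
                 n_features = nrow(x$coefficients), n_nonzero = nz)
}

#' Score plot of a fitted PLS-DA model
#'
#' @param object A [plsda_fit()] model.
#' @param ... Unused.
#' @return A ggplot: samples in the space of the first two latent
#'   components, coloured by class.
#' @export
autoplot.nmr_pls <- function(object, ...) {
  a <- min(2, object$ncomp)
  df <- tibble::tibble(comp1 = object$T[, 1],
                       comp2 = if (a > 1) object$T[, 2] else 0,
                       class = object$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$comp1, .data$comp2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "component 1", y = if (a > 1) "component 2" else "",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Per-repeat metric distribution of a double-cross-validation run
#'
#' @param object A [cv2_evaluate()] result.
#' @param ... Unused.
#' @return A ggplot: boxplots of the per-repeat metric values (percent).
#' @export
autoplot.cv2_result <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 50, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "per-repeat value (%)") +
    ggplot2::theme_minimal()
}

#' Variance decomposition of an ASCA model
#'
#' @param object An [asca_decompose()] result.
#' @param ... Unused.
#' @return A ggplot: sum-of-squares fraction per effect.
#' @export
autoplot.asca_decomp <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$effect, .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of sum of squares") +
    ggplot2::theme_minimal()
}
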