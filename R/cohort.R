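#' Transcribed printed tables
#'
#' Accessors for the three printed tables shipped with the package so that
#' the in-cohort count checks run without any patient-level data:
#' `table1_counts()` gives the per-center, per-disease STUDY sample counts;
#' `table3_signature()` the sparse PLS-DA regression coefficients of the
#' EHT-vs-PHT signature under each analysis approach (an empty Approach-B
#' cell, read as `NA`, means the peak was excluded before that analysis and
#' is distinct from a zero coefficient); `table4_exclusion()` the
#' confounder-related metabolites with their peaks, reason tags and the
#' direction of the shift in the affected samples.
#'
#' @return A tibble.
#' @name printed_tables
NULL

#' @rdname printed_tables
#' @export
table1_counts <- function() {
  readr::read_csv(system.file("extdata", "tables", "table1_counts.csv",
                              package = "nmrconfound", mustWork = TRUE),
                  col_types = "ccd", progress = FALSE)
}

#' @rdname printed_tables
#' @export
table3_signature <- function() {
  readr::read_csv(system.file("extdata", "tables", "table3_signature.csv",
                              package = "nmrconfound", mustWork = TRUE),
                  col_types = "ccdddd", progress = FALSE)
}

#' @rdname printed_tables
#' @export
table4_exclusion <- function() {
  readr::read_csv(system.file("extdata", "tables", "table4_exclusion.csv",
                              package = "nmrconfound", mustWork = TRUE),
                  col_types = "ccccc", progress = FALSE)
}

#' Cohort summary with group-vs-control tests
#'
#' Summarises STUDY samples per contrast the way multicenter cohort tables
#' are reported: each continuous variable (patient age, sample age, batch,
#' run order) as mean or median with range -- mean when a Shapiro-Wilk test
#' at alpha = 0.05 does not reject normality in *both* groups, median
#' otherwise -- with a two-sided t or Wilcoxon test accordingly; each
#' categorical variable (sex, center) with a Fisher exact test. Tables
#' larger than 2x2 use a Monte-Carlo Fisher p-value.
#'
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @param contrasts Named list; each element is a list with `group` and
#'   `control` character vectors of disease codes. A pooled group such as
#'   EHT is expressed as `c("PA", "PPGL", "CS")`.
#' @param fisher_b Number of Monte-Carlo table draws for r x c Fisher tests.
#' @param mc_seed Seed used for the Monte-Carlo draw, restoring the caller's
#'   RNG state afterwards, so reported p-values are reproducible.
#' @return A tibble with one row per contrast x variable: the formatted
#'   group and control summaries, the test used and its p-value. Groups with
#'   fewer than 3 samples report counts only (statistics suppressed).
#' @export
cohort_summary <- function(meta, contrasts, fisher_b = 1e5, mc_seed = 1) {
  meta <- validate_sample_meta(meta)
  study <- dplyr::filter(meta, .data$role == "STUDY")
  cont_vars <- c("patient_age", "sample_age_days", "batch", "run_order")
  cat_vars <- c("sex", "center")
  if (is.null(names(contrasts))) {
    names(contrasts) <- vapply(contrasts, function(ct)
      paste0(paste(ct$group, collapse = "+"), "-vs-", paste(ct$control, collapse = "+")),
      character(1))
  }
  purrr::imap_dfr(contrasts, function(ct, nm) {
    g <- dplyr::filter(study, .data$disease %in% ct$group)
    c0 <- dplyr::filter(study, .data$disease %in% ct$control)
    if (nrow(c0) == 0) abort(paste0("contrast '", nm, "': control group is empty"))
    small <- nrow(g) < 3 || nrow(c0) < 3
    rows_cont <- purrr::map_dfr(cont_vars, function(v) {
      x <- g[[v]][!is.na(g[[v]])]
      y <- c0[[v]][!is.na(c0[[v]])]
      if (small || length(x) < 3 || length(y) < 3) {
        return(tibble::tibble(contrast = nm, variable = v, type = "continuous",
                              group_summary = paste0("n=", length(x)),
                              control_summary = paste0("n=", length(y)),
                              test = NA_character_, p_value = NA_real_))
      }
      normal <- .shapiro_ok(x) && .shapiro_ok(y)
      if (normal) {
        p <- t.test(x, y)$p.value
        fmt <- function(z) sprintf("%.3g [%.3g-%.3g]", mean(z), min(z), max(z))
        test <- "t"
      } else {
        p <- suppressWarnings(wilcox.test(x, y)$p.value)
        fmt <- function(z) sprintf("%.3g [%.3g-%.3g]", median(z), min(z), max(z))
        test <- "wilcoxon"
      }
      tibble::tibble(contrast = nm, variable = v, type = "continuous",
                     group_summary = fmt(x), control_summary = fmt(y),
                     test = test, p_value = p)
    })
    rows_cat <- purrr::map_dfr(cat_vars, function(v) {
      x <- g[[v]][!is.na(g[[v]])]
      y <- c0[[v]][!is.na(c0[[v]])]
      if (small || length(x) == 0 || length(y) == 0) {
        return(tibble::tibble(contrast = nm, variable = v, type = "categorical",
                              group_summary = paste0("n=", length(x)),
                              control_summary = paste0("n=", length(y)),
                              test = NA_character_, p_value = NA_real_))
      }
      lev <- sort(unique(c(x, y)))
      tab <- rbind(table(factor(x, lev)), table(factor(y, lev)))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      p <- if (ncol(tab) > 2 || nrow(tab) > 2) {
        old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
        set.seed(mc_seed)
        fisher.test(tab, simulate.p.value = TRUE, B = fisher_b)$p.value
      } else if (ncol(tab) < 2) {
        1
      } else {
        fisher.test(tab)$p.value
      }
      fmt <- function(z) paste(vapply(lev, function(l) sum(z == l), 0), collapse = "/")
      tibble::tibble(contrast = nm, variable = v, type = "categorical",
                     group_summary = fmt(x), control_summary = fmt(y),
                     test = "fisher", p_value = p)
    })
    dplyr::bind_rows(rows_cont, rows_cat)
  })
}

.shapiro_ok <- function(x) {
  if (length(unique(x)) < 3) return(FALSE)
  x <- if (length(x) > 5000) sample(x, 5000) else x
  shapiro.test(x)$p.value >= 0.05
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' STUDY sample counts after restricting to a set of centers
#'
#' Applies a center filter (as in the whole-center-exclusion correction,
#' where only the centers of the tight cluster are retained) and counts
#' STUDY samples per disease group, adding the pooled EHT count
#' (PA + PPGL + CS).
#'
#' Disease groups whose retained count falls below `min_per_group` are
#' dropped from the table (count set to zero and excluded from the EHT
#' pool): a handful of samples cannot support a classification contrast,
#' which is why the retained-cohort table carries no Cushing column.
#'
#' @param x Either a per-sample metadata table or a per-center count table
#'   with columns `center`, `disease`, `n` (the shape of the printed cohort
#'   table).
#' @param keep_centers Character vector of center codes to retain. An empty
#'   intersection yields zero counts, not an error.
#' @param min_per_group Minimum retained samples for a disease group to stay
#'   in the cohort (default 5).
#' @return A tibble with columns `disease` (PHT, PA, PPGL, CS, EHT) and `n`.
#' @export
count_after_center_filter <- function(x, keep_centers, min_per_group = 5) {
  x <- tibble::as_tibble(x)
  counts <-
    if ("n" %in% names(x)) {
      x |>
        dplyr::filter(.data$center %in% keep_centers) |>
        dplyr::group_by(.data$disease) |>
        dplyr::summarise(n = sum(.data$n), .groups = "drop")
    } else {
      validate_sample_meta(x) |>
        dplyr::filter(.data$role == "STUDY", .data$center %in% keep_centers) |>
        dplyr::count(.data$disease)
    }
  out <- tibble::tibble(disease = c("PHT", "PA", "PPGL", "CS")) |>
    dplyr::left_join(counts, by = "disease") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0),
                  n = ifelse(.data$n < min_per_group, 0, .data$n))
  dplyr::bind_rows(out, tibble::tibble(
    disease = "EHT",
    n = sum(out$n[out$disease %in% c("PA", "PPGL", "CS")])))
}

#' Cohort exclusion arithmetic
#'
#' Subtracts a list of disjoint exclusion counts (spectral-quality and
#' eligibility exclusions) from an enrolment count.
#'
#' @param initial_n Enrolled sample count.
#' @param exclusion_counts Numeric vector of nonnegative exclusion counts.
#' @return The remaining count. Errors if the result would be negative.
#' @export
apply_exclusion_arithmetic <- function(initial_n, exclusion_counts = numeric()) {
  if (length(exclusion_counts) > 0 && any(exclusion_counts < 0)) {
    abort("exclusion counts must be nonnegative")
  }
  out <- initial_n - sum(exclusion_counts)
  if (out < 0) {
    abort(paste0("exclusions (", sum(exclusion_counts),
                 ") exceed the initial count (", initial_n, ")"))
  }
  out
}

#' Overlap between a disease signature and the confounder exclusion list
#'
#' Counts how many metabolites carrying a nonzero coefficient under a given
#' analysis approach also appear on the confounder-related exclusion list.
#' `NA` coefficients (peaks excluded before the analysis) never count as
#' selected.
#'
#' @param sig Signature table in the shape of [table3_signature()]: a
#'   `metabolite` column plus one coefficient column per approach.
#' @param excl Exclusion list in the shape of [table4_exclusion()].
#' @param approach Name of the coefficient column to use, e.g. `"initial"`
#'   or `"approach_c"`.
#' @return A list with `overlap` (count), `size` (signature size) and
#'   `metabolites` (the overlapping names).
#' @export
signature_confounder_overlap <- function(sig, excl, approach = "initial") {
  if (!approach %in% names(sig)) {
    abort(paste0("unknown approach column '", approach, "'; available: ",
                 paste(setdiff(names(sig), c("metabolite", "ppm")), collapse = ", ")))
  }
  coefs <- sig[[approach]]
  selected <- sig$metabolite[!is.na(coefs) & coefs != 0]
  overlap <- intersect(selected, excl$metabolite)
  list(overlap = length(overlap), size = length(selected), metabolites = overlap)
}
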