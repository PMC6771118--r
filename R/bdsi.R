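# Age-adjusted Best's Disease Severity Index (BDSI).
#
# BDSI expresses loss of vision as a percentage: the two-eye logMAR sum is
# normalized by 2.6 (both eyes at the 1.3 logMAR blindness limit), scaled
# to percent and weighted by the age factor exp(-age/100), which discounts
# severity observed late in life.

#' Age-adjustment factor of the severity index
#'
#' Returns \code{exp(-age/100)}, the multiplicative factor that discounts
#' visual-acuity loss observed at a later age: roughly 1 for a child and
#' about 0.368 at age 100.
#'
#' @param age_years Age in years (vectorized, non-negative; age 0 is the
#'   exact-unity limit).
#' @return Numeric vector in (0, 1], strictly decreasing in age.
#' @examples
#' age_adjustment_factor(c(0, 40, 100))
#' @export
age_adjustment_factor <- function(age_years) {
  if (!is.numeric(age_years) || any(is.na(age_years)))
    stop("age_years must be numeric and non-missing", call. = FALSE)
  if (any(age_years < 0))
    stop("age_years must be non-negative", call. = FALSE)
  exp(-age_years / 100)
}

#' Per-proband Best's Disease Severity Index
#'
#' Computes \code{100 * (bcva_le + bcva_re) / 2.6 * exp(-age/100)}, the
#' percent loss of vision adjusted for the proband's age at evaluation.
#' Both eyes' best-corrected visual acuities are required; records missing
#' an eye must be excluded upstream, never zero-imputed. If the two-eye
#' logMAR sum exceeds the 2.6 full scale it is clamped with a warning so
#' the index stays within [0, 100].
#'
#' @param bcva_le,bcva_re Per-eye best-corrected visual acuity in logMAR,
#'   each in [0, 2.6] (vectorized).
#' @param age_years Age at last clinical evaluation, in years.
#' @return Numeric vector of severity percentages in [0, 100]; full double
#'   precision (round only for presentation).
#' @examples
#' proband_bdsi(0.4, 0.6, 40)  # about 25.78, rounds to 26
#' proband_bdsi(0, 0, 100)     # 0: no symptoms over a lifetime
#' @export
proband_bdsi <- function(bcva_le, bcva_re, age_years) {
  if (any(is.na(bcva_le)) || any(is.na(bcva_re)))
    stop("missing BCVA: records without both eyes must be excluded, ",
         "not imputed", call. = FALSE)
  if (any(bcva_le < 0 | bcva_le > 2.6) || any(bcva_re < 0 | bcva_re > 2.6))
    stop("BCVA values must lie in [0, 2.6] logMAR", call. = FALSE)
  total <- bcva_le + bcva_re
  if (any(total > 2.6)) {
    warning("two-eye logMAR sum exceeds the 2.6 full scale; clamping",
            call. = FALSE)
    total <- pmin(total, 2.6)
  }
  total / 2.6 * 100 * age_adjustment_factor(age_years)
}

#' Mean severity index of a variant group
#'
#' Averages the per-proband severity index over all probands carrying the
#' same protein variant. Probands lacking BCVA for either eye are dropped
#' before averaging (and listed in the result); a group with no
#' BCVA-complete proband is a missing-data error.
#'
#' @param group A data frame of proband records for one variant, with
#'   columns \code{proband_id}, \code{age_years}, \code{bcva_le},
#'   \code{bcva_re} (e.g. one element of \code{\link{group_by_variant}}).
#' @return An object of class \code{bdsi_value}: list with \code{value}
#'   (percent), \code{n_probands} (contributors only),
#'   \code{contributing_ids} and \code{dropped_ids}.
#' @export
mean_bdsi <- function(group) {
  if (nrow(group) == 0L) stop("empty proband group", call. = FALSE)
  complete <- !is.na(group$bcva_le) & !is.na(group$bcva_re)
  if (!any(complete))
    stop("no BCVA-complete proband in group; mean severity is missing",
         call. = FALSE)
  g <- group[complete, , drop = FALSE]
  vals <- proband_bdsi(g$bcva_le, g$bcva_re, g$age_years)
  structure(
    list(value = mean(vals),
         n_probands = nrow(g),
         contributing_ids = g$proband_id,
         dropped_ids = group$proband_id[!complete]),
    class = "bdsi_value")
}

#' @export
print.bdsi_value <- function(x, ...) {
  cat(sprintf("mean BDSI %.2f%% over %d proband(s): %s\n", x$value,
              x$n_probands, paste(x$contributing_ids, collapse = ", ")))
  if (length(x$dropped_ids))
    cat("dropped (missing BCVA):", paste(x$dropped_ids, collapse = ", "),
        "\n")
  invisible(x)
}

#' Severity indices for a whole cohort
#'
#' Convenience wrapper: per-proband severity for every BCVA-complete
#' record, and the per-variant mean over probands sharing the same
#' amino-acid replacement (variants whose probands all lack BCVA get a
#' missing mean, as in the source tables).
#'
#' @param cohort A \code{bv_cohort} data frame.
#' @return List with two data frames: \code{per_proband} (columns
#'   \code{proband_id}, \code{variant}, \code{bdsi}) and
#'   \code{per_variant} (columns \code{variant}, \code{mean_bdsi},
#'   \code{n_probands}, \code{contributing_ids}).
#' @examples
#' res <- cohort_bdsi(read_cohort(bestqspr_example("probands.csv")))
#' head(res$per_variant)
#' @export
cohort_bdsi <- function(cohort) {
  ok <- cohort$bcva_complete
  per_proband <- data.frame(
    proband_id = cohort$proband_id[ok],
    variant = cohort$variant[ok],
    bdsi = proband_bdsi(cohort$bcva_le[ok], cohort$bcva_re[ok],
                        cohort$age_years[ok]),
    stringsAsFactors = FALSE)
  groups <- group_by_variant(cohort)
  rows <- lapply(names(groups), function(v) {
    bv <- tryCatch(mean_bdsi(groups[[v]]), error = function(e) NULL)
    data.frame(
      variant = v,
      mean_bdsi = if (is.null(bv)) NA_real_ else bv$value,
      n_probands = if (is.null(bv)) 0L else bv$n_probands,
      contributing_ids = if (is.null(bv)) NA_character_ else
        paste(bv$contributing_ids, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  list(per_proband = per_proband,
       per_variant = do.call(rbind, rows))
}
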