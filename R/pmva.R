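# Predicted mean visual acuity (PMVA) and pathogenicity classification.
#
# PMVA inverts the severity index back onto the logMAR scale: it is the
# predicted two-eye average best-corrected visual acuity of a carrier of a
# variant with a given |ddE_dim| at a chosen age,
#   PMVA = (2.6/200) * (slope * |ddE_dim| + intercept) * exp(age/100).
# Note the positive exponent: severity observed at a later age was
# discounted by exp(-age/100), so predicting acuity at a later age scales
# it back up.  A variant whose PMVA at the reference age of 40 years
# reaches the 0.5 logMAR low-vision cut is classified likely pathogenic.

#' The published regression coefficients as a reference model
#'
#' A minimal \code{qspr_model} carrying the regression coefficients of the
#' packaged dataset (slope 0.24935 percent per kcal/mol, intercept 6.56527
#' percent), used as the default model for prediction and classification.
#'
#' @return A \code{qspr_model} with \code{slope} and \code{intercept} only.
#' @export
reference_qspr_model <- function() {
  structure(
    list(slope = 0.24935, intercept = 6.56527,
         r2 = NA_real_, r2_xv = NA_real_, f_stat = NA_real_,
         significant = NA, n_used = NA_integer_,
         outlier_ids = character(0), source = "reference coefficients"),
    class = "qspr_model")
}

#' Predicted mean visual acuity
#'
#' Forward prediction of the two-eye average logMAR acuity at a given age
#' from the modulus of the relative dimerization energy.
#'
#' @param abs_dde_dim Modulus of the relative dimerization energy,
#'   kcal/mol (non-negative; vectorized).
#' @param age_years Age in years at which acuity is predicted (default 40,
#'   the reference age; vectorized).
#' @param model A \code{qspr_model}; defaults to the packaged reference
#'   coefficients.
#' @return Predicted mean visual acuity in logMAR (full precision; round
#'   to 2 decimals for presentation).
#' @examples
#' round(predict_pmva(96, 40), 2)  # 0.59
#' round(predict_pmva(34, 40), 2)  # 0.29
#' @export
predict_pmva <- function(abs_dde_dim, age_years = 40,
                         model = reference_qspr_model()) {
  if (any(is.na(abs_dde_dim)) || any(abs_dde_dim < 0))
    stop("abs_dde_dim must be a non-negative modulus", call. = FALSE)
  if (any(is.na(age_years)) || any(age_years < 0))
    stop("age_years must be non-negative", call. = FALSE)
  (2.6 / 200) * (model$slope * abs_dde_dim + model$intercept) *
    exp(age_years / 100)
}

#' Classify variant pathogenicity from the dimerization-energy modulus
#'
#' A variant is likely pathogenic when its predicted mean visual acuity at
#' the reference age, rounded to \code{digits} decimals, reaches the
#' low-vision cut \code{pmva_cut} (0.5 logMAR per the WHO criterion). The
#' rounding rule makes the 0.5 logMAR cut coincide with an integer
#' energy bound of 77 kcal/mol under the reference coefficients.
#' Truncating variants (stop gains) carry no dimerization energy and are
#' reported as not scorable.
#'
#' @inheritParams predict_pmva
#' @param pmva_cut Low-vision cut in logMAR.
#' @param digits Decimals used by the rounding rule.
#' @param truncating Logical (vectorized); \code{TRUE} marks a stop-gain
#'   variant that cannot be scored.
#' @return Character vector: \code{"likely-pathogenic"},
#'   \code{"likely-non-pathogenic"} or \code{"not-scorable"}.
#' @examples
#' classify_pathogenicity(c(96, 34, 77))
#' @export
classify_pathogenicity <- function(abs_dde_dim,
                                   model = reference_qspr_model(),
                                   age_years = 40, pmva_cut = 0.5,
                                   digits = 2, truncating = FALSE) {
  n <- max(length(abs_dde_dim), length(truncating))
  truncating <- rep_len(truncating, n)
  out <- rep(NA_character_, n)
  out[truncating] <- "not-scorable"
  idx <- which(!truncating)
  if (length(idx)) {
    pm <- predict_pmva(rep_len(abs_dde_dim, n)[idx], age_years, model)
    out[idx] <- ifelse(round(pm, digits) >= pmva_cut,
                       "likely-pathogenic", "likely-non-pathogenic")
  }
  out
}

#' Energy modulus at the pathogenicity threshold
#'
#' Inverts the acuity predictor for |ddE_dim| at the low-vision cut:
#' returns the exact real solution and the smallest integer modulus
#' classified likely pathogenic under the rounding rule (77 kcal/mol with
#' the reference coefficients at age 40 and a 0.5 logMAR cut, where the
#' exact real root is about 77.07).
#'
#' @inheritParams classify_pathogenicity
#' @return List with \code{real_root} (kcal/mol) and
#'   \code{smallest_pathogenic_integer}.
#' @export
pathogenic_energy_threshold <- function(model = reference_qspr_model(),
                                        age_years = 40, pmva_cut = 0.5,
                                        digits = 2) {
  if (is.na(model$slope) || model$slope <= 0)
    stop("no finite threshold: model slope must be positive", call. = FALSE)
  root <- (pmva_cut * (200 / 2.6) * exp(-age_years / 100) -
             model$intercept) / model$slope
  # smallest integer whose rounded PMVA reaches the cut: start just below
  # the root of the rounding boundary and scan upward
  lower <- max(0L, as.integer(floor(root)) - 2L)
  m <- lower
  while (classify_pathogenicity(m, model, age_years, pmva_cut,
                                digits) != "likely-pathogenic") {
    m <- m + 1L
    if (m > lower + 1e6) stop("threshold search failed", call. = FALSE)
  }
  list(real_root = root, smallest_pathogenic_integer = m)
}

#' Predicted acuity progression over age
#'
#' Evaluates the acuity predictor over a grid of ages for a fixed energy
#' modulus; the curve is strictly increasing in age (acuity worsens).
#'
#' @inheritParams predict_pmva
#' @param ages Positive ages in years, sorted increasingly.
#' @return Data frame with columns \code{age} and \code{pmva}.
#' @examples
#' bcva_progression(96, c(20, 40, 60))
#' @export
bcva_progression <- function(abs_dde_dim, ages,
                             model = reference_qspr_model()) {
  if (length(abs_dde_dim) != 1L)
    stop("abs_dde_dim must be a single modulus", call. = FALSE)
  if (any(is.na(ages)) || any(ages <= 0))
    stop("ages must be positive", call. = FALSE)
  if (is.unsorted(ages, strictly = TRUE))
    stop("ages must be sorted strictly increasing", call. = FALSE)
  data.frame(age = ages,
             pmva = predict_pmva(abs_dde_dim, ages, model))
}
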