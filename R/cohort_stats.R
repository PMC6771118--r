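# Cohort-level descriptive statistics: genetic test positivity and
# penetrance among variant carriers.

#' Genetic test positivity rate
#'
#' @param positive Number of probands testing positive.
#' @param tested Number of probands tested (> 0).
#' @return List with \code{percent} (exact, e.g. 63.2 for 36/57) and
#'   \code{percent_rounded} (nearest integer percent).
#' @examples
#' positivity_rate(36, 57)
#' @export
positivity_rate <- function(positive, tested) {
  if (tested <= 0) stop("tested must be positive", call. = FALSE)
  if (positive < 0 || positive > tested)
    stop("positive must lie in [0, tested]", call. = FALSE)
  p <- 100 * positive / tested
  list(percent = p, percent_rounded = round(p))
}

#' Carrier counts for penetrance estimation
#'
#' Affected and clinically healthy carriers of a disease variant,
#' optionally broken down by sex. Probands count as affected carriers:
#' penetrance is estimated over everyone carrying the variant, and every
#' proband is by definition a symptomatic carrier.
#'
#' @param affected,unaffected Non-negative carrier counts.
#' @param by_sex Optional named list, one entry per sex, each a length-2
#'   vector \code{c(affected, unaffected)}; sums must match the totals.
#' @return An object of class \code{carrier_counts}.
#' @examples
#' carrier_counts(21, 8, by_sex = list(F = c(10, 4), M = c(11, 4)))
#' @export
carrier_counts <- function(affected, unaffected, by_sex = NULL) {
  if (affected < 0 || unaffected < 0)
    stop("carrier counts must be non-negative", call. = FALSE)
  if (!is.null(by_sex)) {
    sums <- Reduce(`+`, by_sex)
    if (!isTRUE(all.equal(unname(sums), c(affected, unaffected))))
      stop("per-sex counts must sum to the overall totals", call. = FALSE)
  }
  structure(list(affected = affected, unaffected = unaffected,
                 by_sex = by_sex),
            class = "carrier_counts")
}

#' Penetrance among variant carriers
#'
#' \code{100 * affected / (affected + unaffected)}; per-sex penetrances
#' are reported when the breakdown is available.
#'
#' @param counts A \code{\link{carrier_counts}} object.
#' @return List with \code{overall} (percent) and \code{by_sex} (named
#'   numeric vector, or \code{NULL}).
#' @examples
#' penetrance(carrier_counts(21, 8))  # 72.4 percent
#' @export
penetrance <- function(counts) {
  stopifnot(inherits(counts, "carrier_counts"))
  total <- counts$affected + counts$unaffected
  if (total <= 0) stop("no carriers", call. = FALSE)
  overall <- 100 * counts$affected / total
  by_sex <- NULL
  if (!is.null(counts$by_sex))
    by_sex <- vapply(counts$by_sex,
                     function(v) 100 * v[1] / sum(v), numeric(1))
  list(overall = overall, by_sex = by_sex)
}
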