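# Linear quantitative structure-pathogenicity regression (QSPR).
#
# Mean severity index (percent) is regressed on the modulus of the relative
# dimerization energy |ddE_dim| by unweighted ordinary least squares.
# Validation uses leave-one-out (LOO) cross-validation: a point's LOO
# residual is its error when predicted by the model fitted on all other
# points.  An outlier is a point whose |LOO residual| is more than twice
# the scale of the LOO residuals; flagging, removal and refitting iterate
# until no point is flagged.

#' Assemble a QSPR dataset
#'
#' @param ids Unique point identifiers (variant or proband-group labels).
#' @param x Modulus of the relative dimerization energy, kcal/mol
#'   (non-negative).
#' @param y Mean severity index, percent in [0, 100].
#' @param provenance \code{"fixture"}, \code{"synthetic"} or \code{"user"}.
#' @return A data frame of class \code{qspr_dataset} with columns
#'   \code{id}, \code{x}, \code{y}.
#' @examples
#' qspr_dataset(letters[1:4], c(0, 10, 20, 30), c(6, 9, 11, 14))
#' @export
qspr_dataset <- function(ids, x, y, provenance = "user") {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("point ids must be unique", call. = FALSE)
  if (any(is.na(x)) || any(x < 0))
    stop("x must be a non-negative modulus", call. = FALSE)
  if (any(is.na(y)) || any(y < 0 | y > 100))
    stop("y must be a severity percent in [0, 100]", call. = FALSE)
  structure(
    data.frame(id = ids, x = as.numeric(x), y = as.numeric(y),
               stringsAsFactors = FALSE),
    provenance = provenance,
    class = c("qspr_dataset", "data.frame"))
}

#' The packaged 20-point regression dataset
#'
#' Builds the (|ddE_dim|, mean BDSI) dataset from the packaged per-variant
#' energy table: the 20 variants with an observed mean severity index and
#' computed energies, labelled by their proband group.
#'
#' @return A \code{\link{qspr_dataset}} with 20 points,
#'   provenance \code{"fixture"}.
#' @export
qspr_fixture_dataset <- function() {
  et <- read_variant_energies(bestqspr_example("variant_energies.csv"))
  keep <- !is.na(et$mean_bdsi) & !is.na(et$dde_dim)
  et <- et[keep, , drop = FALSE]
  qspr_dataset(et$group_id, abs(et$dde_dim), et$mean_bdsi,
               provenance = "fixture")
}

.check_dataset <- function(dataset, min_n = 3L) {
  if (!is.data.frame(dataset) || !all(c("id", "x", "y") %in% names(dataset)))
    stop("dataset must have columns id, x, y", call. = FALSE)
  if (nrow(dataset) < min_n)
    stop("need at least ", min_n, " points, got ", nrow(dataset),
         call. = FALSE)
  if (length(unique(dataset$x)) < 2L)
    stop("degenerate dataset: all x values equal, fit is singular",
         call. = FALSE)
  invisible(dataset)
}

.ols <- function(dataset) stats::lm(y ~ x, data = dataset)

#' Leave-one-out residuals
#'
#' For each point i, the residual \code{y_i - yhat_i} where \code{yhat_i}
#' is predicted by the model fitted on all points except i. Computed with
#' the closed-form leverage shortcut \code{e_i / (1 - h_ii)} from the full
#' fit, which is algebraically identical to n separate drop-one refits.
#'
#' @param dataset A \code{\link{qspr_dataset}} with at least 4 points.
#' @return Named numeric vector of LOO residuals, in the units of y.
#' @export
loo_residuals <- function(dataset) {
  .check_dataset(dataset, min_n = 4L)
  fit <- .ols(dataset)
  r <- stats::resid(fit) / (1 - stats::hatvalues(fit))
  names(r) <- dataset$id
  r
}

# Scale of the LOO residuals used in the 2-sigma outlier rule.
# "residual-df": sqrt(PRESS / (n - p)), the cross-validated analogue of the
# residual standard error (p = 2 coefficients); "population" and "sample"
# are the centred SDs with denominators n and n - 1.
.loo_scale <- function(r, method) {
  n <- length(r)
  switch(method,
         "residual-df" = sqrt(sum(r^2) / (n - 2)),
         "population" = sqrt(mean((r - mean(r))^2)),
         "sample" = stats::sd(r),
         stop("unknown loo_scale '", method, "'", call. = FALSE))
}

#' Flag regression outliers by the leave-one-out rule
#'
#' A point is an outlier when the absolute value of its LOO residual is
#' strictly more than twice the scale of the LOO residuals of the current
#' dataset. The default scale is \code{sqrt(PRESS / (n - 2))}, the
#' cross-validated residual standard error; the centred population and
#' sample standard deviations are available for comparison.
#'
#' @param dataset A \code{\link{qspr_dataset}} with at least 5 points.
#' @param loo_scale Scale estimator: \code{"residual-df"} (default),
#'   \code{"population"} or \code{"sample"}.
#' @return Character vector of flagged point ids (possibly empty).
#' @export
flag_outliers <- function(dataset, loo_scale = "residual-df") {
  .check_dataset(dataset, min_n = 5L)
  r <- loo_residuals(dataset)
  s <- .loo_scale(r, loo_scale)
  # numerical floor: an exact fit leaves only rounding noise, not outliers
  floor_tol <- 1e-8 * (max(abs(dataset$y)) + 1)
  names(r)[abs(r) > pmax(2 * s, floor_tol)]
}

.model_stats <- function(fit, dataset) {
  n <- nrow(dataset)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((dataset$y - mean(dataset$y))^2)
  r2 <- 1 - ss_res / ss_tot
  lr <- stats::resid(fit) / (1 - stats::hatvalues(fit))
  press <- sum(lr^2)
  r2_xv <- 1 - press / ss_tot
  f_stat <- if (r2 >= 1) Inf else r2 / (1 - r2) * (n - 2)
  f_crit <- stats::qf(0.95, 1, n - 2)
  list(r2 = r2, r2_xv = r2_xv, f_stat = f_stat,
       significant = f_stat > f_crit,
       loo_residuals = stats::setNames(lr, dataset$id))
}

#' Fit the severity-versus-energy regression
#'
#' Unweighted ordinary least squares of mean severity index on |ddE_dim|,
#' optionally with iterative leave-one-out outlier removal: flag outliers
#' (see \code{\link{flag_outliers}}), drop them, refit, and repeat until no
#' point is flagged or \code{max_iter} is reached. Group sizes are not
#' used as weights.
#'
#' @param dataset A \code{\link{qspr_dataset}} (at least 3 points; at least
#'   5 when removing outliers).
#' @param remove_outliers Logical; iterate the flag-and-refit procedure.
#' @param max_iter Maximum flag-and-refit iterations.
#' @param loo_scale Scale estimator passed to \code{\link{flag_outliers}}.
#' @return An object of class \code{qspr_model}: slope and intercept
#'   (percent per kcal/mol and percent), \code{r2}, PRESS-based
#'   \code{r2_xv}, \code{f_stat} (with \code{significant} at the 95 percent
#'   F criterion), \code{n_used}, cumulative \code{outlier_ids},
#'   \code{loo_residuals} on the survivor set, the survivor \code{data} and
#'   the \code{removed} points.
#' @examples
#' fit <- fit_qspr(qspr_fixture_dataset())
#' fit$outlier_ids
#' coef(fit)
#' @export
fit_qspr <- function(dataset, remove_outliers = TRUE, max_iter = 10L,
                     loo_scale = "residual-df") {
  .check_dataset(dataset)
  cur <- dataset
  removed <- cur[0, , drop = FALSE]
  if (remove_outliers) {
    for (i in seq_len(max_iter)) {
      if (nrow(cur) < 5L) break  # too few points to validate further
      flagged <- flag_outliers(cur, loo_scale = loo_scale)
      if (!length(flagged)) break
      if (nrow(cur) - length(flagged) < 3L)
        stop("outlier removal would leave fewer than 3 points; refusing",
             call. = FALSE)
      removed <- rbind(removed, cur[cur$id %in% flagged, , drop = FALSE])
      cur <- cur[!cur$id %in% flagged, , drop = FALSE]
    }
  }
  fit <- .ols(cur)
  st <- .model_stats(fit, cur)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = st$r2, r2_xv = st$r2_xv, f_stat = st$f_stat,
         significant = st$significant,
         n_used = nrow(cur),
         outlier_ids = removed$id,
         loo_residuals = st$loo_residuals,
         residuals = stats::setNames(stats::resid(fit), cur$id),
         data = cur, removed = removed,
         loo_scale = loo_scale,
         call = match.call()),
    class = "qspr_model")
}

#' Validation statistics of a fitted regression
#'
#' Recomputes, on the model's survivor set, the squared correlation
#' coefficient \code{R2 = 1 - SS_res/SS_tot}, the PRESS-based
#' cross-validated \code{R2_xv = 1 - PRESS/SS_tot}, the F statistic
#' \code{R2/(1-R2) * (n-2)} (reported as \code{Inf} for a perfect fit) and
#' whether it exceeds the 95 percent critical value on (1, n-2) degrees of
#' freedom.
#'
#' @param model A \code{qspr_model}.
#' @return Named list \code{r2}, \code{r2_xv}, \code{f_stat},
#'   \code{significant}.
#' @export
model_statistics <- function(model) {
  stopifnot(inherits(model, "qspr_model"))
  st <- .model_stats(.ols(model$data), model$data)
  st[c("r2", "r2_xv", "f_stat", "significant")]
}

#' @export
coef.qspr_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.qspr_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  if (any(x < 0, na.rm = TRUE))
    stop("|ddE_dim| must be non-negative", call. = FALSE)
  object$slope * x + object$intercept
}

#' @export
print.qspr_model <- function(x, ...) {
  cat("QSPR linear model: severity = slope * |ddE_dim| + intercept\n")
  cat(sprintf("  slope     %.5f %% per kcal/mol\n", x$slope))
  cat(sprintf("  intercept %.5f %%\n", x$intercept))
  cat(sprintf("  n = %d, R2 = %.3f, R2_xv = %.3f, F = %.3f (%ssignificant at 95%%)\n",
              x$n_used, x$r2, x$r2_xv, x$f_stat,
              if (x$significant) "" else "not "))
  if (length(x$outlier_ids))
    cat("  outliers removed:", paste(x$outlier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a fitted severity-versus-energy regression
#'
#' Scatter of the survivor points with the fitted line; removed outliers,
#' if any, are shown as open triangles.
#'
#' @param x A \code{qspr_model}.
#' @param ... Further arguments passed to \code{plot.default}.
#' @return Invisibly, the model.
#' @export
plot.qspr_model <- function(x, ...) {
  xs <- c(x$data$x, x$removed$x); ys <- c(x$data$y, x$removed$y)
  plot(x$data$x, x$data$y, pch = 19,
       xlim = range(xs), ylim = range(ys),
       xlab = "|ddE_dim| [kcal/mol]", ylab = "mean BDSI [%]", ...)
  if (nrow(x$removed))
    graphics::points(x$removed$x, x$removed$y, pch = 2)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
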