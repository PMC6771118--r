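test_that("ordinary least squares recovers exact lines", {
  fit <- fit_qspr(line_dataset(10, slope = 2, intercept = 1),
                  remove_outliers = FALSE)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_equal(fit$r2_xv, 1)
  expect_identical(fit$f_stat, Inf)

  # three points interpolate a line exactly (two-parameter model)
  d3 <- qspr_dataset(c("a", "b", "c"), c(0, 10, 20), c(5, 10, 15))
  f3 <- fit_qspr(d3, remove_outliers = FALSE)
  expect_equal(unname(f3$residuals), rep(0, 3), tolerance = 1e-12)

  expect_error(fit_qspr(qspr_dataset("a", 1, 1)), "at least 3")
  expect_error(
    fit_qspr(qspr_dataset(c("a", "b", "c"), c(5, 5, 5), c(1, 2, 3))),
    "singular")
})

test_that("residuals on the survivor set sum to zero", {
  set.seed(21)
  for (i in 1:5) {
    fit <- fit_qspr(random_dataset(15), remove_outliers = TRUE)
    expect_lt(abs(sum(fit$residuals)), 1e-9)
  }
})

test_that("leverage-shortcut LOO residuals equal brute-force refits", {
  set.seed(42)
  for (i in 1:50) {
    d <- random_dataset(sample(5:12, 1), noise_sd = runif(1, 0.5, 8))
    expect_equal(unname(loo_residuals(d)), loo_brute_force(d),
                 tolerance = 1e-9)
  }
})

test_that("LOO residuals vanish on a line and expose a displaced point", {
  expect_equal(max(abs(loo_residuals(line_dataset(8)))), 0,
               tolerance = 1e-9)
  d <- qspr_dataset(paste0("v", 1:5), c(0, 10, 20, 30, 40),
                    c(1, 21, 41, 61, 95))  # last point displaced from y=2x+1
  r <- loo_residuals(d)
  expect_equal(names(which.max(abs(r))), "v5")
})

test_that("the outlier rule flags planted gross outliers and only stops there", {
  expect_length(flag_outliers(line_dataset(10)), 0)

  set.seed(7)
  d <- random_dataset(20, noise_sd = 2)
  d$y[13] <- min(100, d$y[13] + 40)  # one gross outlier, 20x the noise SD
  expect_identical(flag_outliers(d), "v13")

  # strictness: a residual exactly at twice the scale is not flagged
  r <- loo_residuals(d)
  expect_false(any(abs(r) == 2 * sqrt(sum(r^2) / (length(r) - 2)) &
                     abs(r) > 0))
})

test_that("iterative removal on the packaged dataset reproduces the published model", {
  ds <- qspr_fixture_dataset()
  expect_equal(nrow(ds), 20L)
  fit <- fit_qspr(ds)
  expect_setequal(fit$outlier_ids, expected_fixture_outliers)
  expect_equal(fit$n_used, 15L)
  expect_equal(fit$slope, 0.24935, tolerance = 1e-5 / 0.24935)
  expect_equal(fit$intercept, 6.56527, tolerance = 1e-5 / 6.56527)
  expect_equal(fit$r2, 0.854, tolerance = 0.001)
  expect_equal(fit$f_stat, 76.164, tolerance = 0.001)
  expect_true(fit$significant)
  # accounting: survivors plus outliers partition the input
  expect_equal(fit$n_used + length(fit$outlier_ids), nrow(ds))

  # idempotence: refitting the survivor set removes nothing
  again <- fit_qspr(qspr_dataset(fit$data$id, fit$data$x, fit$data$y))
  expect_length(again$outlier_ids, 0)
  expect_equal(again$slope, fit$slope, tolerance = 1e-12)
})

test_that("model statistics recompute from the survivor set", {
  fit <- fit_qspr(qspr_fixture_dataset())
  st <- model_statistics(fit)
  expect_equal(st$r2, fit$r2, tolerance = 1e-12)
  expect_equal(st$r2_xv, fit$r2_xv, tolerance = 1e-12)
  expect_equal(st$f_stat, fit$r2 / (1 - fit$r2) * (fit$n_used - 2),
               tolerance = 1e-12)
  # PRESS identity: r2_xv = 1 - PRESS/SS_tot
  press <- sum(fit$loo_residuals^2)
  ss_tot <- sum((fit$data$y - mean(fit$data$y))^2)
  expect_equal(fit$r2_xv, 1 - press / ss_tot, tolerance = 1e-12)
  expect_lte(fit$r2_xv, fit$r2)
})

test_that("alternative LOO scale estimators remove more points on the packaged data", {
  ds <- qspr_fixture_dataset()
  for (sc in c("population", "sample")) {
    fit <- fit_qspr(ds, loo_scale = sc)
    expect_true(all(expected_fixture_outliers %in% fit$outlier_ids))
    expect_gt(length(fit$outlier_ids), 5)
  }
})

test_that("removal never leaves fewer than three survivors", {
  set.seed(31)
  for (i in 1:20) {
    d <- random_dataset(sample(5:8, 1), noise_sd = runif(1, 1, 15))
    fit <- tryCatch(fit_qspr(d), error = function(e) e)
    if (inherits(fit, "error")) {
      expect_match(conditionMessage(fit), "fewer than 3")
    } else {
      expect_gte(fit$n_used, 3L)
    }
  }
})
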