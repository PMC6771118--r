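test_that("age factor matches its closed form and is decreasing", {
  expect_equal(age_adjustment_factor(100), exp(-1), tolerance = 1e-12)
  expect_equal(round(age_adjustment_factor(100), 5), 0.36788)
  expect_equal(age_adjustment_factor(0), 1)
  expect_equal(round(age_adjustment_factor(1), 5), 0.99005)
  ages <- seq(0, 100, by = 5)
  expect_true(all(diff(age_adjustment_factor(ages)) < 0))
  expect_error(age_adjustment_factor(-1), "non-negative")
})

test_that("per-proband severity reproduces the worked examples", {
  expect_equal(proband_bdsi(0, 0, 100), 0)
  expect_equal(round(proband_bdsi(0.4, 0.6, 40), 2), 25.78)
  expect_equal(round(proband_bdsi(0.4, 0.6, 40)), 26)
  expect_equal(proband_bdsi(1.3, 1.3, 0), 100)
  expect_equal(round(proband_bdsi(0, 0.6, 27), 2), 17.62)
  # closed form: (le+re)/2.6 * 100 * exp(-age/100)
  expect_equal(proband_bdsi(0.1, 1, 26),
               1.1 / 2.6 * 100 * exp(-0.26), tolerance = 1e-12)
})

test_that("severity is monotone, linear in acuity and bounded", {
  # strictly increasing in each eye, strictly decreasing in age
  expect_true(all(diff(proband_bdsi(seq(0, 1.3, 0.1), 0.5, 40)) > 0))
  expect_true(all(diff(proband_bdsi(0.5, seq(0, 1.3, 0.1), 40)) > 0))
  expect_true(all(diff(proband_bdsi(0.5, 0.5, seq(1, 90, 5))) < 0))
  # numerator linearity: scaling both eyes scales the index
  for (s in c(0.25, 0.5, 0.75)) {
    expect_equal(proband_bdsi(s * 0.8, s * 1.0, 33),
                 s * proband_bdsi(0.8, 1.0, 33), tolerance = 1e-12)
  }
  # bounds for admissible inputs
  set.seed(11)
  le <- runif(50, 0, 1.3); re <- runif(50, 0, 1.3)
  v <- proband_bdsi(le, re, runif(50, 1, 90))
  expect_true(all(v >= 0 & v <= 100))
})

test_that("missing and out-of-scale acuities are rejected or clamped", {
  expect_error(proband_bdsi(NA, 0.3, 40), "missing BCVA")
  expect_error(proband_bdsi(0.3, 0.3, NA), "non-missing")
  expect_error(proband_bdsi(-0.1, 0.3, 40), "\\[0, 2.6\\]")
  expect_warning(v <- proband_bdsi(2.0, 2.0, 0), "clamping")
  expect_equal(v, 100)
})

test_that("group means average contributors only", {
  g <- data.frame(proband_id = c("P32", "P33"),
                  age_years = c(39, 41),
                  bcva_le = c(0.1, 0.3), bcva_re = c(0.3, 0.3))
  bv <- mean_bdsi(g)
  # closed-form mean of the two per-proband indices
  expected <- mean(c(0.4 / 2.6 * 100 * exp(-0.39),
                     0.6 / 2.6 * 100 * exp(-0.41)))
  expect_equal(bv$value, expected, tolerance = 1e-12)
  expect_equal(round(bv$value, 2), 12.87)
  expect_equal(bv$n_probands, 2L)

  # singleton equals its proband index; ties average to the common value
  one <- g[1, , drop = FALSE]
  expect_equal(mean_bdsi(one)$value, proband_bdsi(0.1, 0.3, 39))
  three <- one[rep(1, 3), ]
  three$proband_id <- c("a", "b", "c")
  expect_equal(mean_bdsi(three)$value, proband_bdsi(0.1, 0.3, 39))

  # incomplete records are dropped and reported, never imputed
  g2 <- rbind(g, data.frame(proband_id = "PX", age_years = 30,
                            bcva_le = NA, bcva_re = 0.2))
  bv2 <- mean_bdsi(g2)
  expect_equal(bv2$value, expected, tolerance = 1e-12)
  expect_equal(bv2$dropped_ids, "PX")
  expect_error(mean_bdsi(g2[4, , drop = FALSE]), "no BCVA-complete")
})

test_that("cohort-wide severity matches the published per-variant values", {
  coh <- read_cohort(bestqspr_example("probands.csv"))
  pv <- cohort_bdsi(coh)$per_variant
  get <- function(v) pv$mean_bdsi[pv$variant == v]
  # variants whose printed means recompute exactly from the cohort table
  expect_equal(round(get("p.(Val9Gly)"), 1), 17.6)
  expect_equal(round(get("p.(Ser16Phe)"), 1), 17.6)
  expect_equal(round(get("p.(Glu292Gln)"), 1), 70.3)
  expect_equal(round(get("p.(Tyr29Cys)"), 1), 0)
  expect_equal(round(get("p.(Ser108Arg)"), 1), 32.6)
  # all-missing groups surface as missing means, not zeros
  expect_true(is.na(get("p.(Arg92Cys)")))
  expect_true(is.na(get("p.(Arg200*)")))
})
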