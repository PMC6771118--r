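# Shared test fixtures and independent oracles.

# exact line y = slope*x + intercept on an x grid
line_dataset <- function(n = 10, slope = 2, intercept = 1,
                         x = seq(0, 40, length.out = n)) {
  qspr_dataset(paste0("v", seq_along(x)), x, intercept + slope * x)
}

# brute-force leave-one-out residuals: n separate refits
loo_brute_force <- function(dataset) {
  vapply(seq_len(nrow(dataset)), function(i) {
    fit <- lm(y ~ x, data = dataset[-i, ])
    dataset$y[i] - unname(predict(fit, newdata = dataset[i, , drop = FALSE]))
  }, numeric(1))
}

# small random regression dataset with y kept inside [0, 100]
random_dataset <- function(n, noise_sd = 3) {
  x <- runif(n, 0, 96)
  y <- pmin(pmax(0.24935 * x + 6.56527 + rnorm(n, 0, noise_sd), 0), 100)
  qspr_dataset(paste0("v", seq_len(n)), x, y)
}

expected_fixture_outliers <- c("P13", "P24", "P25", "P27", "P31")
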