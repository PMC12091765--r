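# QSPR regression fits, correlations, the study policies and predictions

test_that("linear fit matches closed-form OLS on tiny cases", {
  perfect <- qspr_fit(c(0, 1, 2), c(0, 1, 2))
  expect_equal(unname(coef(perfect)), c(0, 1), tolerance = 1e-12)
  expect_equal(perfect$R2, 1)
  f <- qspr_fit(c(0, 1, 2), c(0, 1, 1))
  expect_equal(coef(f)[["A"]], 1 / 6, tolerance = 1e-12)
  expect_equal(coef(f)[["B"]], 0.5, tolerance = 1e-12)
  expect_equal(f$R2, 0.75, tolerance = 1e-12)
  expect_equal(f$F, 3, tolerance = 1e-12)
  expect_equal(f$SE, sqrt(sum(residuals(f)^2) / 1), tolerance = 1e-12)
})

test_that("cubic fit recovers an exact cubic and beats the linear R2", {
  x <- c(-2, -1, 0, 1, 2)
  f <- qspr_fit(x, x^3, "cubic")
  expect_equal(unname(coef(f)), c(0, 0, 0, 1), tolerance = 1e-8)
  expect_equal(f$R2, 1, tolerance = 1e-12)
  set.seed(4)
  x <- runif(12, 0, 10); y <- 2 + 0.5 * x - 0.02 * x^2 + rnorm(12)
  expect_gte(qspr_fit(x, y, "cubic")$R2, qspr_fit(x, y, "linear")$R2)
})

test_that("degenerate and insufficient inputs are rejected", {
  expect_error(qspr_fit(c(1, 2), c(1, 2)), "insufficient data")
  expect_error(qspr_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(qspr_fit(c(1, 2, 3, 4), c(1, 2, 3, 4), "cubic"),
               "insufficient data")
  expect_error(qspr_fit(c(1, 1, 2, 2, 3), c(1, 2, 3, 4, 5), "cubic"),
               "degenerate")
  expect_error(qspr_fit(c(1, NA, 3), c(1, 2, 3)), "missing")
})

test_that("fitted coefficients are recovered on simulated data within 3 SE", {
  set.seed(2026)
  n <- 50
  x <- runif(n, 0, 100)
  a_true <- 40; b_true <- 2.5; sigma <- 8
  y <- a_true + b_true * x + rnorm(n, 0, sigma)
  f <- qspr_fit(x, y)
  # closed-form coefficient standard errors
  sxx <- sum((x - mean(x))^2)
  se_b <- f$SE / sqrt(sxx)
  se_a <- f$SE * sqrt(1 / n + mean(x)^2 / sxx)
  expect_lt(abs(coef(f)[["A"]] - a_true), 3 * se_a)
  expect_lt(abs(coef(f)[["B"]] - b_true), 3 * se_b)
})

test_that("pearson correlation handles missing pairs and degenerate input", {
  expect_equal(pearson_correlation(1:5, 1:5), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  x <- c(1, 2, 3, 4, NA); y <- c(2, 4, 6, 8, 100)
  expect_equal(pearson_correlation(x, y), 1)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(c(1, NA, NA, 4), c(1, 2, 3, 4)),
               "insufficient")
})

test_that("study policies select the documented sample sizes", {
  fx <- drug_fixtures()
  idx <- index_table(lapply(fx, `[[`, "partition"))
  props <- drug_properties()
  st <- qspr_study(idx, props, kind = "linear", policy = "paper-mixed")
  f <- st$fits
  expect_true(all(f$n == 7))                       # complete-case fits
  st2 <- qspr_study(idx, props, kind = "linear", policy = "pairwise")
  f2 <- st2$fits
  expect_true(all(f2$n[f2$property %in% c("BP", "E", "FP")] == 7))
  expect_true(all(f2$n[!f2$property %in% c("BP", "E", "FP")] == 8))
  # pairwise correlation uses all 8 drugs where possible
  expect_equal(st$correlations["NE1", "MW"], 0.968, tolerance = 5e-4)
  st3 <- qspr_study(idx, props, kind = "linear", policy = "complete-case")
  expect_equal(st3$correlations["NE1", "MW"], 0.966, tolerance = 5e-4)
})

test_that("sqrt of the complete-case linear R2 equals the complete-case correlation", {
  fx <- drug_fixtures()
  idx <- index_table(lapply(fx, `[[`, "partition"))
  props <- drug_properties()
  st <- qspr_study(idx, props, kind = "linear", policy = "complete-case")
  for (k in seq_len(nrow(st$fits))) {
    f <- st$fits[k, ]
    expect_equal(sqrt(f$R2), abs(st$correlations[f$index, f$property]),
                 tolerance = 1e-9)
  }
})

test_that("prediction tables apply the model to all drugs, with optional coefficient rounding", {
  x <- c(a = 1, b = 2, c = 3)
  f <- qspr_fit(c(0, 1, 2), c(0, 1, 2))        # y = x
  pt <- prediction_table(f, x)
  expect_equal(pt$predicted, c(1, 2, 3))
  f2 <- qspr_fit(c(0, 10, 20), c(0.04, 1, 2.04))
  full <- prediction_table(f2, x)
  rounded <- prediction_table(f2, x, coef_digits = 0)
  expect_false(isTRUE(all.equal(full$predicted, rounded$predicted)))
  # simulate() is centred on the fitted values
  set.seed(1)
  sims <- simulate(f2, nsim = 200)
  expect_equal(rowMeans(as.matrix(sims)), f2$fitted, tolerance = 0.2)
})

test_that("mismatched or degenerate study inputs raise informative errors", {
  idx <- data.frame(NE1 = 1:3, row.names = c("a", "b", "c"))
  props <- data.frame(MW = 1:3, row.names = c("a", "b", "d"))
  expect_error(qspr_study(idx, props), "mismatched drug sets")
  props2 <- data.frame(MW = c(5, 5, 5), row.names = c("a", "b", "c"))
  expect_error(qspr_study(idx, props2, kind = "linear"), "zero variance")
})
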