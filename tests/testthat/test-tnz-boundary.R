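test_that("breusch_pagan matches the auxiliary-regression identity", {
  set.seed(101)
  x <- runif(60, 10, 35)
  y <- 2 - 0.1 * x + rnorm(60, 0, 0.2)
  bp <- breusch_pagan(x, y)
  # independent two-pass OLS oracle: n * R^2 of squared residuals on x
  r <- resid(lm(y ~ x))
  aux <- lm(I(r^2) ~ x)
  expect_equal(bp$statistic, 60 * summary(aux)$r.squared, tolerance = 1e-10)
  expect_equal(bp$p_value, pchisq(bp$statistic, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("breusch_pagan separates homo- from heteroscedastic scatter", {
  set.seed(203)
  x <- runif(200, 0, 30)
  y_hom <- 5 - 0.1 * x + rnorm(200, 0, 0.3)
  expect_gt(breusch_pagan(x, y_hom)$p_value, 0.05)
  y_het <- 5 - 0.1 * x + rnorm(200, 0, 0.05 * x)
  expect_lt(breusch_pagan(x, y_het)$p_value, 0.05)
})

test_that("breusch_pagan degrades gracefully on perfect fits", {
  x <- 1:20
  expect_warning(bp <- breusch_pagan(x, 2 + 3 * x), "residual variance")
  expect_equal(bp$p_value, 1)
})

test_that("tlc_low search underestimates the lower critical temperature", {
  fx <- default_fixtures(n = 100, seed = 7)
  d <- generate_dataset(fx$homeotherm)
  b <- find_tlc_low(d)
  expect_s3_class(b, "tnz_boundary")
  expect_lte(b$tlc_low, attr(d, "truth")$t_lc)
  expect_true(b$tlc_low %in% d$ta)
  # every window before the trigger passed both tests
  n_win <- nrow(b$diagnostics)
  if (n_win > 1)
    expect_false(any(b$diagnostics$trigger[-n_win]))
  # heterotherm data trip the search too
  dh <- generate_dataset(default_fixtures(n = 100, seed = 7)$deep_hibernator)
  bh <- find_tlc_low(dh)
  expect_lte(bh$tlc_low, attr(dh, "truth")$t_lc)
})

test_that("tlc_low search is deterministic", {
  d <- generate_dataset(default_fixtures(n = 100, seed = 3)$deep_hibernator)
  b1 <- find_tlc_low(d)
  b2 <- find_tlc_low(d)
  expect_identical(b1$tlc_low, b2$tlc_low)
  expect_identical(b1$diagnostics, b2$diagnostics)
})

test_that("pure-thermoneutral data never trigger", {
  set.seed(5)
  d <- as_metabolic_dataset(
    data.frame(ta = runif(40, 28, 36), m = rnorm(40, 1, 0.04)))
  b <- find_tlc_low(d)
  expect_false(b$triggered)
  expect_equal(b$tlc_low, min(d$ta))
})

test_that("a significantly positive slope aborts the search", {
  set.seed(6)
  ta <- runif(60, 5, 35)
  d <- as_metabolic_dataset(data.frame(ta = ta, m = 0.2 + 0.05 * ta +
                                         rnorm(60, 0, 0.05)))
  expect_error(find_tlc_low(d), "positive slope")
})

test_that("tied temperatures enter a window together", {
  set.seed(8)
  ta <- c(rep(35, 6), rep(34, 6), rep(33, 6), seq(32, 20, length.out = 30))
  m <- ifelse(ta > 30, rnorm(length(ta), 1, 0.04),
              1 + 0.125 * (30 - ta) + rnorm(length(ta), 0, 0.04))
  b <- find_tlc_low(as_metabolic_dataset(data.frame(ta = ta, m = m)))
  # the first window must absorb the whole 12-record tie block
  expect_gte(b$diagnostics$window[1], 12)
})
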