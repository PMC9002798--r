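test_that("kernel-density overlap is calibrated", {
  set.seed(21)
  a <- rnorm(50000)
  expect_equal(ppo(a, a), 100, tolerance = 0.02)          # identical samples
  b <- rnorm(50000, mean = 1)
  # closed form for two unit-variance Gaussians one SD apart: 2 * pnorm(-1/2)
  expect_equal(ppo(a, b), 100 * 2 * pnorm(-0.5), tolerance = 0.033)
  expect_equal(ppo(a, b), ppo(b, a))                       # symmetry
  far <- rnorm(50000, mean = 50)
  expect_lt(ppo(a, far), 2)                                # disjoint supports
  expect_error(ppo(rep(1, 2000), a), "zero-variance")
  expect_error(ppo(a[1:10], b), "1,000 draws")
})

test_that("joint prior draws honour every truncation bound", {
  spec <- build_priors(1, "step23", tlc = 30, l95 = 29)
  pr <- sample_priors(spec, n = 10000)
  expect_true(all(pr$tmr > 0 & pr$tmr <= 0.8))
  expect_true(all(pr$mr >= pr$tmr & pr$mr <= 1))
  expect_true(all(pr$tbe > 30 & pr$tbe <= 50))
  expect_true(all(pr$tbt >= -5))
  beta_r <- -1 / (pr$tbe - 30)
  tt <- pr$tbt + pr$tmr / beta_r
  expect_true(all(tt < 29))                         # below the t_lc CI floor
  q10 <- exp(10 * log(pr$mr / pr$tmr) / (30 - tt))
  expect_true(all(q10 <= 5 + 1e-9))
  expect_true(all(pr$sd_c >= pr$sd_r / 5 & pr$sd_c <= pr$sd_r))
  expect_true(all(pr$sd_tnz >= pr$sd_r / 2 & pr$sd_tnz <= pr$sd_r))
})

test_that("prior construction rejects impossible supports", {
  expect_error(build_priors(-1, "step23", tlc = 30, l95 = 29), "positive")
  expect_error(build_priors(1, "step1", tlc_low = 35, ta_max = 30),
               "empty t_lc prior support")
  expect_error(build_priors(1, "step23", tlc = 30), "l95")
})

test_that("state log likelihood matches the Gaussian mixture terms", {
  p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                     tmr = 0.05, m_r = 0.8, sd_r = 0.1, sd_c = 0.05,
                     sd_tnz = 0.06)
  # value exactly on the euthermic line: the Gaussian mode
  ta <- 20
  expect_equal(log_likelihood(ta, predict_euthermic(ta, p), p, "euthermy"),
               -log(p$sd_r * sqrt(2 * pi)))
  # density integrates to one over m (quadrature)
  f <- function(m) exp(log_likelihood(25, m, p, "torpor"))
  expect_equal(integrate(f, -Inf, Inf)$value, 1, tolerance = 1e-6)
  # scatter switches with the torpor branch
  expect_equal(log_likelihood(0, p$tmr, p, "torpor"),   # regulated side
               dnorm(p$tmr, predict_torpor(0, p), p$sd_r, log = TRUE))
  expect_equal(log_likelihood(20, p$m_r, p, "torpor"),  # conforming side
               dnorm(p$m_r, predict_torpor(20, p), p$sd_c, log = TRUE))
  # a point on the euthermic line far above the torpor curve
  m <- predict_euthermic(15, p)
  expect_gt(log_likelihood(15, m, p, "euthermy"),
            log_likelihood(15, m, p, "torpor"))
})

test_that("the sampler honours the run protocol and truncations", {
  set.seed(31)
  d <- generate_dataset(default_fixtures(n = 60, seed = 5)$deep_hibernator)
  cfg <- mcmc_config(chains = 2, iterations = 3000, burnin = 1500,
                     adapt = 300, thin = 5, seed = 9)
  below <- d$ta <= 30
  jd <- list(Tab = d$ta[below], Mb = d$m[below] / mean(d$m), Nb = sum(below),
             Ma = d$m[!below] / mean(d$m), Na = sum(!below),
             Mtnz = mean(d$m[!below]) / mean(d$m), Tlc = 30, L95 = 29.5,
             conc = c(1, 1))
  run <- suppressWarnings(
    run_mcmc("step23", jd, monitors = c("Tbe", "Tbt", "TMR", "Mr", "Tt",
                                        "SDr", "SDc", "SDtnz", "p", "s"),
             config = cfg))
  expect_length(run$samples, 2)                       # chains
  expect_equal(nrow(run$samples[[1]]), (3000 - 1500) / 5)
  spec <- build_priors(jd$Mtnz, "step23", tlc = 30, l95 = 29.5)
  expect_true(isTRUE(check_truncation(run$samples, spec)))
  expect_true(all(is.na(run$rhat) | run$rhat > 0))
  expect_false(any(grepl("^s\\[", names(run$rhat))))  # indicators excluded
})

test_that("identical seeds reproduce the sampler exactly", {
  d <- generate_dataset(default_fixtures(n = 60, seed = 5)$deep_hibernator)
  cfg <- mcmc_config(chains = 2, iterations = 2000, burnin = 1000,
                     adapt = 200, thin = 5, seed = 13)
  below <- d$ta <= 30
  jd <- list(Tab = d$ta[below], Mb = d$m[below] / mean(d$m), Nb = sum(below),
             Ma = d$m[!below] / mean(d$m), Na = sum(!below),
             Mtnz = mean(d$m[!below]) / mean(d$m), Tlc = 30, L95 = 29.5,
             conc = c(1, 1))
  mons <- c("Tbe", "TMR", "Mr")
  r1 <- suppressWarnings(run_mcmc("step23", jd, mons, cfg))
  r2 <- suppressWarnings(run_mcmc("step23", jd, mons, cfg))
  expect_identical(as.matrix(r1$samples), as.matrix(r2$samples))
})
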