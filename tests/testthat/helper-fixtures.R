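# Shared fixtures.  The two full-protocol pipeline fits are expensive, so
# they are computed once per test run and cached for every block that needs
# them.

.fit_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(name, n = 120L, data_seed = 7L, mcmc_seed = 11L) {
  key <- paste(name, n, data_seed, mcmc_seed, sep = "_")
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  fx <- default_fixtures(n = n, seed = data_seed)
  d <- generate_dataset(fx[[name]])
  fit <- suppressWarnings(fit_thermo(d, mcmc_config(seed = mcmc_seed)))
  res <- list(data = d, fit = fit, truth = attr(d, "truth"))
  assign(key, res, envir = .fit_cache)
  res
}

# Random admissible parameter sets for property-style tests: rejection
# sampling over plausible ranges until every constructor invariant holds.
random_thermo_params <- function(n, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    sd_r <- stats::runif(1, 0.02, 0.2)
    p <- try(thermo_params(
      m_tnz = stats::runif(1, 0.5, 3),
      t_lc = stats::runif(1, 25, 35),
      t_be = stats::runif(1, 36, 45),
      t_bt = stats::runif(1, -4, 20),
      tmr = stats::runif(1, 0.02, 0.6),
      m_r = stats::runif(1, 0.1, 1.5),
      sd_r = sd_r,
      sd_c = stats::runif(1, sd_r / 5, sd_r),
      sd_tnz = stats::runif(1, sd_r / 2, sd_r),
      p_t = stats::runif(1, 0.2, 0.8)), silent = TRUE)
    if (inherits(p, "try-error")) next
    i <- i + 1L
    out[[i]] <- p
  }
  out
}

# Independent oracle for the regulated/conforming threshold: bisection of
# |beta_r| * (t_bt - x) - tmr, never using the closed form under test.
tt_bisection_oracle <- function(params, tol = 1e-10) {
  f <- function(x) abs(params$beta_r) * (params$t_bt - x) - params$tmr
  lo <- params$t_bt - 1000
  hi <- params$t_bt
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}
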