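# Synthetic respirometry-like datasets with known ground truth under the
# extended Scholander-Irving model, for tests and parameter-recovery checks.

#' Configure a synthetic dataset generator
#'
#' @param params A [thermo_params] ground truth (natural units; its `p_t`,
#'   `p_e` are the below-`t_lc` state mixing fractions).
#' @param n Number of records.
#' @param ta_range Sampling range of ambient temperature; default
#'   `c(t_bt - 5, t_lc + 8)`, which keeps a thermoneutral segment wide
#'   enough for the step-1 ten-record window.
#' @param scheme `"uniform"` draws temperatures uniformly over `ta_range`;
#'   `"grid"` uses an evenly spaced fixed grid.
#' @param mode `"heterotherm"` keeps the configured torpor fraction;
#'   `"homeotherm"` forces it to zero.
#' @param seed Integer seed; identical configurations produce identical
#'   datasets.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(params, n = 120L,
                             ta_range = NULL,
                             scheme = c("uniform", "grid"),
                             mode = c("heterotherm", "homeotherm"),
                             seed = 1L) {
  stopifnot(inherits(params, "thermo_params"), n >= 10)
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (is.null(ta_range)) ta_range <- c(params$t_bt - 5, params$t_lc + 8)
  stopifnot(length(ta_range) == 2, ta_range[1] < ta_range[2])
  if (mode == "homeotherm") {
    params$p_t <- 0
    params$p_e <- 1
  }
  structure(list(params = params, n = as.integer(n), ta_range = ta_range,
                 scheme = scheme, mode = mode, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic metabolic dataset
#'
#' Ambient temperatures are drawn per the configured scheme; each record
#' above the true lower critical temperature is thermoneutral, each record
#' below is assigned torpor or euthermy by the mixing fractions.  Metabolic
#' rate is Gaussian around the state's model curve with the state's scatter
#' (`sd_tnz` in the thermoneutral zone, `sd_r` on the linear euthermic and
#' regulated-torpor branches, `sd_c` on the conforming branch); draws are
#' redrawn until positive, and the generating state is retained both in
#' `state_true` and as the `state_ref` reference label.
#'
#' @param config A [generator_config()].
#' @return A `metabolic_dataset` with columns `ta`, `m`, `state_ref`,
#'   `state_true`; the ground-truth `thermo_params` is attached as
#'   attribute `"truth"`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$params
  set.seed(config$seed)
  ta <- switch(config$scheme,
               uniform = stats::runif(config$n, config$ta_range[1],
                                      config$ta_range[2]),
               grid = seq(config$ta_range[1], config$ta_range[2],
                          length.out = config$n))
  state <- ifelse(ta > p$t_lc, "tnz",
                  ifelse(stats::runif(config$n) < p$p_t, "torpor", "euthermy"))
  mu <- numeric(config$n)
  sd <- numeric(config$n)
  for (st in unique(state)) {
    i <- state == st
    mu[i] <- predict_state(ta[i], p, st)
    sd[i] <- switch(st,
                    tnz = p$sd_tnz,
                    euthermy = p$sd_r,
                    torpor = ifelse(ta[i] < p$t_t, p$sd_r, p$sd_c))
  }
  m <- stats::rnorm(config$n, mu, sd)
  while (any(bad <- m <= 0))        # positivity by redraw, not truncation
    m[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  out <- data.frame(ta = ta, m = m, state_ref = state, state_true = state)
  out <- as_metabolic_dataset(out)
  attr(out, "truth") <- p
  out
}

#' Reference fixture configurations
#'
#' Four named generator configurations spanning the method's regimes:
#' \describe{
#'   \item{deep_hibernator}{Large euthermy-torpor separation, regulated
#'     torpor defended near 2 degrees C -- the easy, deep-hibernation case.}
#'   \item{shallow_daily}{Small separation with the torpor line reaching
#'     zero near 25 degrees C -- the hard case of daily heterotherms whose
#'     torpid body temperature sits only slightly below the euthermic one.}
#'   \item{homeotherm}{No torpor at all; the torpor-curve parameters exist
#'     only as (unidentifiable) priors.}
#'   \item{inhibited}{Strong additional metabolic inhibition,
#'     `m_r / m_tnz < 0.5`.}
#' }
#'
#' @param n Records per dataset (default 120).
#' @param seed Base seed; each fixture offsets it deterministically.
#' @return Named list of `generator_config` objects.
#' @export
default_fixtures <- function(n = 120L, seed = 1L) {
  deep <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                        tmr = 0.05, m_r = 0.7,
                        sd_tnz = 0.04, sd_r = 0.06, sd_c = 0.03,
                        p_t = 0.5)
  shallow <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 25,
                           tmr = 0.55, m_r = 0.85,
                           sd_tnz = 0.04, sd_r = 0.06, sd_c = 0.03,
                           p_t = 0.5)
  inhibited <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
                             tmr = 0.06, m_r = 0.35,
                             sd_tnz = 0.04, sd_r = 0.06, sd_c = 0.03,
                             p_t = 0.5)
  list(
    deep_hibernator = generator_config(deep, n = n, seed = seed),
    shallow_daily = generator_config(shallow, n = n, seed = seed + 1L),
    homeotherm = generator_config(deep, n = n, mode = "homeotherm",
                                  ta_range = c(10, 38), seed = seed + 2L),
    inhibited = generator_config(inhibited, n = n, seed = seed + 3L))
}
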