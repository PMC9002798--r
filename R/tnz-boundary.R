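#' Breusch-Pagan test for heteroscedastic metabolic scatter
#'
#' Studentized (Koenker) Breusch-Pagan test of the regression of `y` on `x`:
#' the statistic is n times the R-squared of the auxiliary regression of the
#' squared OLS residuals on `x`, referred to a chi-square distribution with
#' one degree of freedom.  Used on rolling windows of measurements sorted
#' from the warm end of the dataset: the appearance of a second (torpid)
#' metabolic level below the thermoneutral zone inflates residual spread and
#' trips this test.
#'
#' @param x Ambient temperatures.
#' @param y Metabolic rates.
#' @return List with `statistic` and `p_value`.  When the residual variance
#'   is numerically zero no heteroscedasticity is detectable: the test is
#'   reported non-significant with a warning.
#' @export
breusch_pagan <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  if (mean(stats::resid(fit)^2) < .Machine$double.eps * max(1, mean(y^2))) {
    warning("zero residual variance: heteroscedasticity not detectable")
    return(list(statistic = 0, p_value = 1))
  }
  bt <- lmtest::bptest(fit, studentize = TRUE)
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value))
}

# One-sided OLS slope p-values (negative and positive directions).
slope_pvalues <- function(x, y) {
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2 || !is.finite(cf[2, 3]))
    return(list(slope = NA_real_, p_neg = 1, p_pos = 1))
  tval <- cf[2, 3]
  df <- fit$df.residual
  list(slope = cf[2, 1],
       p_neg = stats::pt(tval, df),               # H1: slope < 0
       p_pos = stats::pt(tval, df, lower.tail = FALSE))  # H1: slope > 0
}

#' Locate the conservative lower bound of the thermoneutral zone
#'
#' Step 1a of the three-step method.  Starting from the ten measurements at
#' the highest ambient temperatures, ordinary least-squares regressions of
#' metabolic rate on temperature are run on windows that grow one record (one
#' tie group of equal `ta`) at a time towards lower temperatures.  A window
#' "triggers" when its slope is significantly negative (one-sided, level
#' `alpha_slope`) or its Breusch-Pagan test is significant (level
#' `alpha_bp`): either signals that the window has grown past the lower
#' critical temperature.  `tlc_low` is the minimum temperature of the last
#' window that passed both tests, so it still underestimates the true lower
#' critical temperature.  A significantly positive slope reveals insufficient
#' euthermic data below the thermoneutral zone and aborts the search.
#'
#' @param data A `metabolic_dataset` (see [as_metabolic_dataset()]).
#' @param alpha_bp Significance level of the Breusch-Pagan test (default 0.05).
#' @param alpha_slope Significance level of the one-sided slope tests
#'   (default 0.01).
#' @return An object of class `tnz_boundary`: list with `tlc_low` and a
#'   `diagnostics` data.frame (one row per window: size, minimum `ta`, slope,
#'   one-sided slope p-value, BP p-value, trigger flag).
#' @export
find_tlc_low <- function(data, alpha_bp = 0.05, alpha_slope = 0.01) {
  data <- as_metabolic_dataset(as.data.frame(data))
  ord <- order(data$ta, decreasing = TRUE)
  ta <- data$ta[ord]
  m <- data$m[ord]
  n <- length(ta)

  # window end indices: grow by whole tie groups, never splitting equal ta
  ends <- integer(0)
  i <- 10L
  while (i <= n) {
    while (i < n && ta[i + 1L] == ta[i]) i <- i + 1L
    ends <- c(ends, i)
    i <- i + 1L
  }
  if (!length(ends)) ends <- n

  diag_rows <- vector("list", length(ends))
  last_pass <- NA_integer_
  triggered <- FALSE
  for (k in seq_along(ends)) {
    idx <- seq_len(ends[k])
    sp <- slope_pvalues(ta[idx], m[idx])
    if (is.finite(sp$slope) && sp$p_pos < alpha_slope)
      stop("insufficient euthermic data below the thermoneutral zone: ",
           "significantly positive slope at window size ", ends[k],
           " makes tlc_low undefinable", call. = FALSE)
    bp <- if (stats::sd(ta[idx]) > 0)
      suppressWarnings(breusch_pagan(ta[idx], m[idx]))
    else list(statistic = NA_real_, p_value = 1)
    trig <- (is.finite(sp$slope) && sp$p_neg < alpha_slope) ||
      bp$p_value < alpha_bp
    diag_rows[[k]] <- data.frame(
      window = ends[k], min_ta = ta[ends[k]], slope = sp$slope,
      p_slope_neg = sp$p_neg, p_bp = bp$p_value, trigger = trig)
    if (trig) { triggered <- TRUE; break }
    last_pass <- ends[k]
  }
  diagnostics <- do.call(rbind, diag_rows[!vapply(diag_rows, is.null, logical(1))])
  if (is.na(last_pass))
    stop("the initial window already shows a negative slope or ",
         "heteroscedasticity: no homoscedastic flat segment at the highest ",
         "temperatures, tlc_low undefinable", call. = FALSE)
  structure(list(tlc_low = ta[last_pass], triggered = triggered,
                 diagnostics = diagnostics),
            class = "tnz_boundary")
}

#' @export
print.tnz_boundary <- function(x, ...) {
  cat(sprintf("TNZ boundary search: tlc_low = %.3f C (%s)\n", x$tlc_low,
              if (x$triggered) "trigger reached" else "no trigger; dataset floor"))
  cat(sprintf("  %d window(s) examined\n", nrow(x$diagnostics)))
  invisible(x)
}

#' Estimate the lower critical temperature and thermoneutral metabolic rate
#'
#' Step 1b of the three-step method.  The Bayesian mixture model is run on
#' the measurements at `ta <= tlc_low` with the lower critical temperature
#' `t_lc` as a free parameter, its prior truncated to
#' `[tlc_low, max(ta)]`.  The thermoneutral rate supplied to that run is the
#' mean of the (mean-normalised) metabolic rates measured above `tlc_low`;
#' after sampling, `m_tnz` is recalculated as the mean of the rates measured
#' above the posterior median `t_lc`.
#'
#' @param data A `metabolic_dataset`.
#' @param boundary A `tnz_boundary` from [find_tlc_low()], or a single
#'   numeric `tlc_low`.
#' @param config An [mcmc_config()].
#' @return List of class `tlc_estimate`: `tlc_draws` (pooled posterior
#'   draws), `tlc_median`, `tlc_ci` (95% credible interval), `m_tnz`
#'   (natural units), `m_tnz_norm`, `m_mean` (the normalisation constant),
#'   `samples` (the full `mcmc.list`), `rhat`, and `converged`.
#' @export
estimate_tlc <- function(data, boundary, config = mcmc_config()) {
  data <- as_metabolic_dataset(as.data.frame(data))
  tlc_low <- if (inherits(boundary, "tnz_boundary")) boundary$tlc_low
  else as.numeric(boundary)
  m_mean <- mean(data$m)
  mn <- data$m / m_mean
  above <- data$ta > tlc_low
  if (!any(above))
    stop("no measurements above tlc_low to initialise m_tnz", call. = FALSE)
  mtnz0 <- mean(mn[above])
  sub <- data$ta <= tlc_low
  if (sum(sub) < 3)
    stop("too few measurements at or below tlc_low for the mixture model",
         call. = FALSE)

  run <- run_mcmc(
    stage = "step1",
    jags_data = list(Tab = data$ta[sub], Mb = mn[sub], Nb = sum(sub),
                     Mtnz = mtnz0, Tlclow = tlc_low, Tamax = max(data$ta),
                     conc = c(1, 1)),
    monitors = c("Tlc", "Tbe", "Tbt", "TMR", "Mr", "Tt",
                 "SDr", "SDc", "SDtnz", "p", "s"),
    config = config)

  tlc_draws <- pooled_param(run$samples, "Tlc")
  tlc_median <- stats::median(tlc_draws)
  above2 <- data$ta > tlc_median
  m_tnz_norm <- if (any(above2)) mean(mn[above2]) else {
    warning("no measurements above the posterior median t_lc; ",
            "keeping the tlc_low-based m_tnz")
    mtnz0
  }
  structure(list(tlc_draws = tlc_draws,
                 tlc_median = tlc_median,
                 tlc_ci = unname(stats::quantile(tlc_draws, c(0.025, 0.975))),
                 m_tnz = m_tnz_norm * m_mean,
                 m_tnz_norm = m_tnz_norm,
                 m_tnz0_norm = mtnz0,
                 m_mean = m_mean,
                 tlc_low = tlc_low,
                 ta_max = max(data$ta),
                 samples = run$samples,
                 rhat = run$rhat,
                 converged = run$converged),
            class = "tlc_estimate")
}

#' @export
print.tlc_estimate <- function(x, ...) {
  cat(sprintf("Step 1: T_lc = %.2f C [%.2f, %.2f], M_TNZ = %.4g%s\n",
              x$tlc_median, x$tlc_ci[1], x$tlc_ci[2], x$m_tnz,
              if (x$converged) "" else "  (convergence warning)"))
  invisible(x)
}
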