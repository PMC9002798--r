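# Steps 2 and 3: probabilistic pre-assignment, automatic assignment rules,
# final (clamped) run, per-measurement confidence and validity.

STATE_TORPOR <- 1L    # mixture component codes used by the sampler
STATE_EUTHERMY <- 2L

# Evaluate one state's curve at temperatures `ta` for every retained draw.
# Returns a draws x length(ta) matrix on the normalised scale.
posterior_curves <- function(samples, m_tnz, tlc, ta,
                             state = c("euthermy", "torpor")) {
  state <- match.arg(state)
  tbe <- pooled_param(samples, "Tbe")
  beta <- -m_tnz / (tbe - tlc)
  if (state == "euthermy") {
    outer(beta, ta - tlc) + m_tnz
  } else {
    tmr <- pooled_param(samples, "TMR")
    mr <- pooled_param(samples, "Mr")
    tbt <- pooled_param(samples, "Tbt")
    tt <- tbt + tmr / beta
    beta_c <- log(mr / tmr) / (tlc - tt)
    out <- matrix(NA_real_, length(beta), length(ta))
    for (j in seq_along(ta)) {
      regulated <- ta[j] < tt
      out[, j] <- ifelse(regulated,
                         -beta * tbt + beta * ta[j],
                         mr * exp(beta_c * (ta[j] - tlc)))
    }
    out
  }
}

#' Pre-assign measurements to physiological states (step 2)
#'
#' Records above the fixed lower critical temperature are automatically
#' assigned to thermoneutral rest with membership probability one.  For each
#' record below it, the state-indicator draws of the mixture run give the
#' membership probabilities of torpor and euthermic rest.  If at least one
#' record was assigned to torpor, two automatic overrides then apply:
#' records above the posterior-median euthermic curve are fixed to euthermy,
#' records below the posterior-median torpor curve are fixed to torpor, each
#' with membership probability one.
#'
#' @param data A `metabolic_dataset`.
#' @param run A [run_mcmc()] result for stage `"step23"` on this dataset.
#' @param tlc Fixed lower critical temperature (step-1 posterior median).
#' @param m_tnz_norm Thermoneutral rate on the mean-normalised scale.
#' @param m_mean Normalisation constant (dataset mean of `m`).
#' @return Data.frame of class `assignment_table`: `ta`, `m`, `state`,
#'   `membership_torpor`, `membership_euthermy`, `membership`, `auto`.
#' @export
preassign <- function(data, run, tlc, m_tnz_norm, m_mean) {
  data <- as.data.frame(data)
  n <- nrow(data)
  below <- data$ta <= tlc
  state <- rep("tnz", n)
  memb_t <- memb_e <- rep(0, n)
  membership <- rep(1, n)
  auto <- rep(TRUE, n)          # above-t_lc records are automatic

  if (any(below)) {
    s <- pooled_states(run$samples, sum(below))
    memb_t[below] <- colMeans(s == STATE_TORPOR)
    memb_e[below] <- colMeans(s == STATE_EUTHERMY)
    # tie -> euthermy (the conservative, non-torpor reading)
    state[below] <- ifelse(memb_t[below] > memb_e[below], "torpor", "euthermy")
    membership[below] <- pmax(memb_t[below], memb_e[below])
    auto[below] <- FALSE

    if (any(state[below] == "torpor")) {
      ta_b <- data$ta[below]
      mn_b <- data$m[below] / m_mean
      me_med <- apply(posterior_curves(run$samples, m_tnz_norm, tlc, ta_b,
                                       "euthermy"), 2, stats::median)
      mt_med <- apply(posterior_curves(run$samples, m_tnz_norm, tlc, ta_b,
                                       "torpor"), 2, stats::median)
      hi <- mn_b > me_med
      lo <- mn_b < mt_med
      idx <- which(below)
      state[idx[hi]] <- "euthermy"
      memb_e[idx[hi]] <- 1; memb_t[idx[hi]] <- 0
      state[idx[lo]] <- "torpor"
      memb_t[idx[lo]] <- 1; memb_e[idx[lo]] <- 0
      membership[idx[hi | lo]] <- 1
      auto[idx[hi | lo]] <- TRUE
    }
  }
  structure(data.frame(ta = data$ta, m = data$m, state = state,
                       membership_torpor = memb_t,
                       membership_euthermy = memb_e,
                       membership = membership, auto = auto),
            class = c("assignment_table", "data.frame"))
}

#' Finalise assignments and curve parameters (step 3)
#'
#' Re-runs the mixture model with the states of automatically assigned
#' records clamped (their indicators observed); only records lying between
#' the predicted euthermic and torpor curves keep sampled indicators.
#' Returns the final assignment table -- including per-record predicted
#' metabolic rate with a 95% credible interval, assignment confidence and
#' the binomial validity flag -- and the final parameter posterior.
#'
#' @param data A `metabolic_dataset`.
#' @param pre The step-2 `assignment_table` from [preassign()].
#' @param step1 The `tlc_estimate` from [estimate_tlc()].
#' @param config An [mcmc_config()].
#' @return List of class `final_assignment`: `table` (assignment table with
#'   `confidence`, `valid`, `pred_median`, `pred_lo95`, `pred_hi95` in
#'   natural units), `run` (the step-3 sampler result), `spec` (its
#'   `prior_spec`).
#' @export
final_assign <- function(data, pre, step1, config = mcmc_config()) {
  data <- as.data.frame(data)
  tlc <- step1$tlc_median
  m_mean <- step1$m_mean
  m_tnz_norm <- step1$m_tnz_norm
  below <- data$ta <= tlc
  n_below <- sum(below)
  if (n_below == 0)
    stop("no measurements below the estimated t_lc: nothing to assign",
         call. = FALSE)

  s_clamp <- rep(NA_integer_, n_below)
  pre_b <- pre[below, , drop = FALSE]
  s_clamp[pre_b$auto & pre_b$state == "torpor"] <- STATE_TORPOR
  s_clamp[pre_b$auto & pre_b$state == "euthermy"] <- STATE_EUTHERMY

  jd <- list(Tab = data$ta[below], Mb = data$m[below] / m_mean, Nb = n_below,
             Ma = data$m[!below] / m_mean, Na = sum(!below),
             Mtnz = m_tnz_norm, Tlc = tlc, L95 = step1$tlc_ci[1],
             conc = c(1, 1))
  if (any(!is.na(s_clamp))) jd$s <- s_clamp
  run <- run_mcmc("step23", jd,
                  monitors = c("Tbe", "Tbt", "TMR", "Mr", "Tt",
                               "SDr", "SDc", "SDtnz", "p", "s"),
                  config = config)

  tab <- pre
  if (n_below > 0) {
    s <- pooled_states(run$samples, n_below)
    idx <- which(below)
    free <- is.na(s_clamp)
    memb_t <- colMeans(s == STATE_TORPOR)
    memb_e <- colMeans(s == STATE_EUTHERMY)
    tab$membership_torpor[idx[free]] <- memb_t[free]
    tab$membership_euthermy[idx[free]] <- memb_e[free]
    tab$state[idx[free]] <- ifelse(memb_t[free] > memb_e[free],
                                   "torpor", "euthermy")
    tab$membership[idx[free]] <- pmax(memb_t[free], memb_e[free])
  }

  # predicted M (posterior median + 95% CI) of the assigned state's curve
  pred <- matrix(NA_real_, nrow(tab), 3)
  for (st in c("euthermy", "torpor")) {
    rows <- which(tab$state == st)
    if (!length(rows)) next
    cur <- posterior_curves(run$samples, m_tnz_norm, tlc, tab$ta[rows], st)
    pred[rows, ] <- t(apply(cur, 2, stats::quantile,
                            probs = c(0.5, 0.025, 0.975)))
  }
  rows <- which(tab$state == "tnz")        # fixed level: degenerate interval
  if (length(rows)) pred[rows, ] <- m_tnz_norm
  tab$pred_median <- pred[, 1] * m_mean
  tab$pred_lo95 <- pred[, 2] * m_mean
  tab$pred_hi95 <- pred[, 3] * m_mean

  tab$confidence <- assignment_confidence(tab$ta, tab$state, tab$membership,
                                          step1$tlc_draws)
  n_draws <- config$chains * (config$iterations - config$burnin) / config$thin
  tab$valid <- assignment_validity(tab$confidence, n_draws,
                                   threshold = config$validity_threshold,
                                   alpha = config$validity_alpha)
  class(tab) <- c("assignment_table", "data.frame")

  spec <- build_priors(m_tnz_norm, "step23", tlc = tlc, l95 = step1$tlc_ci[1])
  structure(list(table = tab, run = run, spec = spec),
            class = "final_assignment")
}

#' Assignment confidence
#'
#' The product of the record's highest state-membership probability and the
#' probability that its temperature lies on the assigned side of the lower
#' critical temperature: the posterior CDF of `t_lc` evaluated at `ta` for
#' thermoneutral assignments, one minus it for euthermy and torpor.
#'
#' @param ta Ambient temperature(s) of the record(s).
#' @param state Assigned state(s) (`"tnz"`, `"euthermy"`, `"torpor"`).
#' @param membership Highest membership probability per record.
#' @param tlc_draws Posterior draws of the lower critical temperature.
#' @return Confidence value(s) in `[0, 1]`.
#' @export
assignment_confidence <- function(ta, state, membership, tlc_draws) {
  stopifnot(length(ta) == length(state), length(ta) == length(membership),
            length(tlc_draws) > 0)
  cdf <- vapply(ta, function(t) mean(tlc_draws <= t), numeric(1))
  side <- ifelse(state == "tnz", cdf, 1 - cdf)
  membership * side
}

#' Binomial validity test of an assignment
#'
#' Treats the retained posterior draws as Bernoulli trials supporting the
#' assignment (success count = `round(confidence * n_draws)`) and tests
#' H0: success probability <= `threshold` against the one-sided "greater"
#' alternative with an exact binomial test.  The assignment is valid when
#' the null is rejected at level `alpha`; a confidence at or below the
#' threshold can never be valid.
#'
#' @param confidence Confidence value(s) in `[0, 1]`.
#' @param n_draws Number of retained posterior draws (> 0).
#' @param threshold Validity threshold (default 0.8).
#' @param alpha Test level (default 0.05).
#' @return Logical vector of validity flags.
#' @export
assignment_validity <- function(confidence, n_draws, threshold = 0.8,
                                alpha = 0.05) {
  if (length(n_draws) != 1 || !is.finite(n_draws) || n_draws <= 0)
    stop("n_draws must be a single positive count", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  vapply(confidence, function(cf) {
    x <- round(min(max(cf, 0), 1) * n_draws)
    stats::binom.test(x, n_draws, p = threshold,
                      alternative = "greater")$p.value < alpha
  }, logical(1))
}
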