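#' Thermoregulatory curve parameters
#'
#' Constructs and validates one coherent parameter vector of the extended
#' Scholander-Irving model: a flat thermoneutral segment at `m_tnz` above the
#' lower critical temperature `t_lc`, a linear euthermic segment below `t_lc`
#' reaching zero at the extrapolated body temperature `t_be`, and a two-piece
#' torpor curve -- linear ("regulated torpor") below the threshold temperature
#' `t_t`, exponential ("conforming torpor") between `t_t` and `t_lc`.  The
#' regulated-torpor line shares the euthermic slope and reaches zero at
#' `t_bt`; the conforming branch runs from the minimal torpid rate `tmr` at
#' `t_t` up to `m_r` at `t_lc`.
#'
#' All derived quantities (slopes, intercepts, `t_t`, the conforming exponent)
#' are computed from the anchor conditions and never stored independently.
#'
#' @param m_tnz Mean resting metabolic rate within the thermoneutral zone
#'   (any consistent metabolic unit; must be > 0).
#' @param t_lc Lower critical temperature of the thermoneutral zone (degrees C).
#' @param t_be Extrapolated ambient temperature at which the euthermic line
#'   reaches zero (degrees C); must exceed `t_lc`.
#' @param t_bt Extrapolated ambient temperature at which the regulated-torpor
#'   line reaches zero (degrees C); must be >= -5.
#' @param tmr Minimal torpid metabolic rate, reached at `t_t`; must satisfy
#'   0 < `tmr` <= 0.8 * `m_tnz`.
#' @param m_r Torpid metabolic rate at `t_lc`; must satisfy
#'   `tmr` <= `m_r` <= `m_tnz`.
#' @param sd_tnz,sd_r,sd_c Gaussian scatter of the thermoneutral, linear
#'   (euthermic / regulated-torpor) and conforming segments.  The ratio
#'   constraints `sd_r/5 <= sd_c <= sd_r` and `sd_r/2 <= sd_tnz <= sd_r`
#'   are enforced (they are scale-free); the absolute bound `sd_r < 3`
#'   applies on the mean-normalised metabolic scale used during sampling.
#' @param p_t,p_e Dataset-level fractions of below-`t_lc` measurements in
#'   torpor and euthermic rest; must sum to 1.
#'
#' @return An object of class `thermo_params`: a named list of the stored
#'   parameters plus derived `alpha_e`, `beta_e`, `alpha_r`, `beta_r`,
#'   `alpha_c`, `beta_c` and `t_t`.
#' @examples
#' p <- thermo_params(m_tnz = 1, t_lc = 30, t_be = 38, t_bt = 2,
#'                    tmr = 0.05, m_r = 0.8)
#' p$beta_e   # -0.125
#' p$t_t      # 1.6
#' @export
thermo_params <- function(m_tnz, t_lc, t_be, t_bt, tmr, m_r,
                          sd_tnz = 0.04, sd_r = 0.06, sd_c = 0.03,
                          p_t = 0.5, p_e = 1 - p_t) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg, call. = FALSE)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("invalid parameters: ", nm, " must be a finite scalar", call. = FALSE)
  }
  for (nm in c("m_tnz", "t_lc", "t_be", "t_bt", "tmr", "m_r",
               "sd_tnz", "sd_r", "sd_c", "p_t", "p_e"))
    num1(get(nm), nm)

  chk(m_tnz > 0, "m_tnz must be positive")
  chk(t_be > t_lc, "t_be must exceed t_lc (degenerate euthermic geometry)")
  chk(t_bt >= -5, "t_bt must be >= -5 degrees C")
  chk(tmr > 0 && tmr <= 0.8 * m_tnz, "tmr must lie in (0, 0.8 * m_tnz]")
  chk(m_r >= tmr && m_r <= m_tnz, "m_r must lie in [tmr, m_tnz]")
  chk(sd_r > 0, "sd_r must be positive")
  chk(sd_c >= sd_r / 5 && sd_c <= sd_r, "sd_c must lie in [sd_r/5, sd_r]")
  chk(sd_tnz >= sd_r / 2 && sd_tnz <= sd_r, "sd_tnz must lie in [sd_r/2, sd_r]")
  chk(abs(p_t + p_e - 1) < 1e-12 && p_t >= 0 && p_e >= 0,
      "p_t and p_e must be non-negative and sum to 1")

  beta_e <- -m_tnz / (t_be - t_lc)
  alpha_e <- m_tnz - beta_e * t_lc
  beta_r <- beta_e                       # shared slope of the linear branches
  alpha_r <- -beta_r * t_bt
  t_t <- t_bt + tmr / beta_r             # regulated line reaches tmr here
  chk(t_t < t_lc, "t_t must fall below t_lc (conforming segment collapsed)")
  beta_c <- log(m_r / tmr) / (t_lc - t_t)
  alpha_c <- m_r * exp(-beta_c * t_lc)
  q10 <- exp(10 * beta_c)
  chk(q10 <= 5 + 1e-9, sprintf("Q10 of the conforming segment is %.3f (> 5)", q10))

  structure(
    list(m_tnz = m_tnz, t_lc = t_lc, t_be = t_be, t_bt = t_bt,
         tmr = tmr, m_r = m_r,
         sd_tnz = sd_tnz, sd_r = sd_r, sd_c = sd_c,
         p_t = p_t, p_e = p_e,
         alpha_e = alpha_e, beta_e = beta_e,
         alpha_r = alpha_r, beta_r = beta_r,
         alpha_c = alpha_c, beta_c = beta_c,
         t_t = t_t),
    class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Extended Scholander-Irving parameters\n")
  cat(sprintf("  M_TNZ = %.4g   T_lc = %.4g C   T_be = %.4g C\n",
              x$m_tnz, x$t_lc, x$t_be))
  cat(sprintf("  TMR   = %.4g   M_r  = %.4g     T_bt = %.4g C   T_t = %.4g C\n",
              x$tmr, x$m_r, x$t_bt, x$t_t))
  cat(sprintf("  slopes: beta_e = beta_r = %.4g; conforming Q10 = %.3f\n",
              x$beta_e, q10_conforming(x)))
  invisible(x)
}

#' Euthermic line intercept and slope
#'
#' The euthermic segment passes through (`t_lc`, `m_tnz`) and (`t_be`, 0),
#' which determines its slope `beta_e = -m_tnz / (t_be - t_lc)` and intercept
#' `alpha_e = m_tnz - beta_e * t_lc`.
#'
#' @param params A [thermo_params] object.
#' @return Named numeric vector `c(alpha_e, beta_e)`.
#' @export
derive_euthermic_line <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  c(alpha_e = params$alpha_e, beta_e = params$beta_e)
}

#' Threshold temperature between regulated and conforming torpor
#'
#' `t_t` is the ambient temperature at which the regulated-torpor line
#' (through (`t_bt`, 0) with slope `beta_r`) takes the value `tmr`:
#' `t_t = t_bt + tmr / beta_r`.
#'
#' @param params A [thermo_params] object.
#' @return The threshold temperature `t_t` (degrees C), always below `t_bt`.
#' @export
derive_tt <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  params$t_t
}

#' Predict euthermic resting metabolic rate
#'
#' Evaluates the euthermic line `alpha_e + beta_e * ta`.  The line is defined
#' for `ta <= t_lc` (it extrapolates outside that range; callers enforce the
#' domain when assigning states).
#'
#' @param ta Ambient temperature(s), degrees C.
#' @param params A [thermo_params] object.
#' @return Predicted metabolic rate(s), same unit as `m_tnz`.
#' @export
predict_euthermic <- function(ta, params) {
  stopifnot(inherits(params, "thermo_params"), is.numeric(ta))
  params$alpha_e + params$beta_e * ta
}

#' Predict torpid metabolic rate
#'
#' Below `t_t` the regulated-torpor line `alpha_r + beta_r * ta` applies;
#' from `t_t` up to `t_lc` the conforming-torpor exponential
#' `alpha_c * exp(beta_c * ta)` applies.  The two branches agree at `t_t`
#' (both equal `tmr`) and the conforming branch equals `m_r` at `t_lc`.
#'
#' @inheritParams predict_euthermic
#' @return Predicted torpid metabolic rate(s).
#' @export
predict_torpor <- function(ta, params) {
  stopifnot(inherits(params, "thermo_params"), is.numeric(ta))
  ifelse(ta < params$t_t,
         params$alpha_r + params$beta_r * ta,
         params$alpha_c * exp(params$beta_c * ta))
}

#' Predict metabolic rate for a named physiological state
#'
#' @inheritParams predict_euthermic
#' @param state One of `"tnz"`, `"euthermy"`, `"torpor"`.
#' @return Predicted metabolic rate(s) for that state's curve.
#' @export
predict_state <- function(ta, params, state) {
  state <- match.arg(state, c("tnz", "euthermy", "torpor"))
  switch(state,
         tnz = rep(params$m_tnz, length(ta)),
         euthermy = predict_euthermic(ta, params),
         torpor = predict_torpor(ta, params))
}

#' Q10 of the conforming-torpor segment
#'
#' The factor by which conforming torpid metabolic rate changes over a 10
#' degree C change in temperature, `exp(10 * beta_c)`.  Admissible parameter
#' sets keep this at or below 5.
#'
#' @param params A [thermo_params] object.
#' @return The Q10 value (>= 1 whenever `m_r >= tmr`).
#' @export
q10_conforming <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  exp(10 * params$beta_c)
}
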