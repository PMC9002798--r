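#' Fit the three-step state-assignment model
#'
#' End-to-end analysis of a metabolic dataset:
#' \enumerate{
#'   \item Rolling-regression search for the conservative thermoneutral
#'     boundary `tlc_low` ([find_tlc_low()]), then a mixture run with the
#'     lower critical temperature free ([estimate_tlc()]) giving the `t_lc`
#'     posterior and `m_tnz`.
#'   \item Pre-assignment mixture run at fixed `t_lc` ([preassign()]) with
#'     the automatic euthermy/torpor overrides.
#'   \item Final run with automatically assigned states clamped
#'     ([final_assign()]), yielding the curve-parameter posteriors, the
#'     per-record assignments with confidence and validity, and the
#'     prior-posterior-overlap identifiability report.
#' }
#' All sampling happens on the mean-normalised metabolic scale; reported
#' rates (`m_tnz`, `tmr`, `m_r`, scatter parameters, predictions) are in the
#' input's natural units.
#'
#' @param data A `metabolic_dataset` (see [as_metabolic_dataset()]).
#' @param config An [mcmc_config()]; its `seed` drives every chain.
#' @return An object of class `thermo_fit`: list with `boundary`, `step1`,
#'   `assignment` (final table), `parameters` (named vector of posterior
#'   medians, natural units), `parameter_ci` (95% credible intervals),
#'   `posteriors` (named list of pooled draws, natural units), `rhat`,
#'   `converged`, `ppo` (identifiability report), `config`, `data`.
#' @export
fit_thermo <- function(data, config = mcmc_config()) {
  data <- as_metabolic_dataset(as.data.frame(data))
  boundary <- find_tlc_low(data, alpha_bp = config$bp_alpha,
                           alpha_slope = config$slope_alpha)
  step1 <- estimate_tlc(data, boundary, config)

  tlc <- step1$tlc_median
  m_mean <- step1$m_mean
  below <- data$ta <= tlc
  if (sum(below) < 2)
    stop("fewer than 2 measurements below the estimated t_lc; ",
         "nothing to assign", call. = FALSE)

  jd2 <- list(Tab = data$ta[below], Mb = data$m[below] / m_mean,
              Nb = sum(below),
              Ma = data$m[!below] / m_mean, Na = sum(!below),
              Mtnz = step1$m_tnz_norm, Tlc = tlc, L95 = step1$tlc_ci[1],
              conc = c(1, 1))
  run2 <- run_mcmc("step23", jd2,
                   monitors = c("Tbe", "Tbt", "TMR", "Mr", "Tt",
                                "SDr", "SDc", "SDtnz", "p", "s"),
                   config = config)
  pre <- preassign(data, run2, tlc, step1$m_tnz_norm, m_mean)
  fin <- final_assign(data, pre, step1, config)

  scale_of <- c(Tbe = 1, Tbt = 1, Tt = 1, TMR = m_mean, Mr = m_mean,
                SDr = m_mean, SDc = m_mean, SDtnz = m_mean,
                `p[1]` = 1, `p[2]` = 1)
  posteriors <- lapply(names(scale_of), function(v)
    pooled_param(fin$run$samples, v) * scale_of[[v]])
  names(posteriors) <- names(scale_of)
  med <- vapply(posteriors, stats::median, numeric(1))
  ci <- t(vapply(posteriors, stats::quantile, numeric(2),
                 probs = c(0.025, 0.975)))
  parameters <- c(m_tnz = step1$m_tnz, t_lc = tlc,
                  t_be = unname(med["Tbe"]), t_bt = unname(med["Tbt"]),
                  tmr = unname(med["TMR"]), m_r = unname(med["Mr"]),
                  t_t = unname(med["Tt"]),
                  sd_tnz = unname(med["SDtnz"]), sd_r = unname(med["SDr"]),
                  sd_c = unname(med["SDc"]),
                  p_t = unname(med["p[1]"]), p_e = unname(med["p[2]"]))

  rhat <- c(step1 = max(step1$rhat, na.rm = TRUE),
            step2 = max(run2$rhat, na.rm = TRUE),
            step3 = max(fin$run$rhat, na.rm = TRUE))
  report <- ppo_report(fin$run$samples, fin$spec,
                       threshold = config$ppo_threshold)

  structure(list(boundary = boundary, step1 = step1,
                 final = fin,
                 assignment = fin$table,
                 parameters = parameters, parameter_ci = ci,
                 posteriors = posteriors,
                 rhat_by_param = fin$run$rhat, rhat = rhat,
                 converged = step1$converged && run2$converged &&
                   fin$run$converged,
                 ppo = report, config = config, data = data),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat("Three-step Bayesian state assignment\n")
  cat(sprintf("  n = %d records; tlc_low = %.2f C\n",
              nrow(x$data), x$boundary$tlc_low))
  cat(sprintf("  T_lc = %.2f C [%.2f, %.2f]   M_TNZ = %.4g\n",
              x$parameters["t_lc"], x$step1$tlc_ci[1], x$step1$tlc_ci[2],
              x$parameters["m_tnz"]))
  cat(sprintf("  TMR = %.4g   M_r = %.4g   T_be = %.2f C   T_bt = %.2f C   T_t = %.2f C\n",
              x$parameters["tmr"], x$parameters["m_r"], x$parameters["t_be"],
              x$parameters["t_bt"], x$parameters["t_t"]))
  tab <- table(factor(x$assignment$state,
                      levels = c("tnz", "euthermy", "torpor")))
  cat(sprintf("  states: tnz %d / euthermy %d / torpor %d; valid %d/%d\n",
              tab["tnz"], tab["euthermy"], tab["torpor"],
              sum(x$assignment$valid), nrow(x$assignment)))
  cat(sprintf("  max R-hat: %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  unid <- x$ppo$parameter[!x$ppo$identifiable]
  if (length(unid))
    cat("  unidentifiable (PPO >= threshold): ",
        paste(unid, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write fit artifacts
#'
#' Writes the assignment table as CSV and a JSON summary (parameter medians,
#' 95% credible intervals, R-hat, prior-posterior overlaps, the full run
#' configuration and seed) into a directory.
#'
#' @param fit A `thermo_fit`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "thermo_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "assignment.csv")
  utils::write.csv(as.data.frame(fit$assignment), csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  summary <- list(
    parameters = as.list(fit$parameters),
    credible_intervals = apply(fit$parameter_ci, 1, as.list),
    rhat = as.list(fit$rhat),
    rhat_by_param = as.list(fit$rhat_by_param),
    converged = fit$converged,
    ppo = fit$ppo,
    tlc_low = fit$boundary$tlc_low,
    config = unclass(fit$config))
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  diag <- file.path(dir, "boundary_diagnostics.csv")
  utils::write.csv(fit$boundary$diagnostics, diag, row.names = FALSE)
  invisible(c(csv, js, diag))
}
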