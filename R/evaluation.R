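# Method-evaluation utilities: corroboration against reference labels,
# paired parameter comparison, metabolic-inhibition fraction.

#' Corroboration index against reference labels
#'
#' Fraction of validly assigned records whose model state matches an
#' independent reference labelling.  Only records flagged valid enter the
#' numerator and denominator.  When the reference distinguishes only
#' torpor from not-torpor (`collapse_tnz = TRUE`, the default), the model's
#' thermoneutral and euthermic assignments are pooled into one non-torpor
#' class before matching, which isolates the torpor/euthermy decision from
#' disagreements about where the lower critical temperature sits.
#'
#' @param model_states Character vector of model assignments
#'   (`"tnz"`, `"euthermy"`, `"torpor"`).
#' @param reference_states Character vector of reference labels (same
#'   values; `"none"` entries are treated as unlabelled and dropped).
#' @param valid_mask Logical vector of validity flags.
#' @param collapse_tnz Pool `tnz` and `euthermy` into one class (default
#'   `TRUE`); set `FALSE` to count lower-critical-temperature placement
#'   disagreements as mismatches too.
#' @return Fraction of matches in `[0, 1]`.
#' @export
corroboration_index <- function(model_states, reference_states, valid_mask,
                                collapse_tnz = TRUE) {
  stopifnot(length(model_states) == length(reference_states),
            length(model_states) == length(valid_mask))
  keep <- valid_mask & reference_states != "none"
  if (!any(keep))
    stop("no valid, labelled records: corroboration undefined", call. = FALSE)
  ms <- model_states[keep]
  rs <- reference_states[keep]
  if (collapse_tnz) {
    ms <- ifelse(ms == "torpor", "torpor", "not_torpor")
    rs <- ifelse(rs == "torpor", "torpor", "not_torpor")
  }
  mean(ms == rs)
}

#' Additional-metabolic-inhibition fraction
#'
#' Torpid metabolic rate at the lower critical temperature relative to the
#' thermoneutral rate, `m_r / m_tnz`: values below one indicate metabolic
#' inhibition beyond the mere suspension of thermogenesis.  The estimate is
#' the posterior median of `m_r`; it is flagged unreliable when the
#' prior-posterior overlap of `m_r` is at or above the identifiability
#' threshold (too few conforming-torpor measurements to pin the parameter).
#'
#' @param mr_draws Posterior draws of `m_r` (same unit as `m_tnz`).
#' @param m_tnz Thermoneutral metabolic rate (> 0).
#' @param ppo_mr Prior-posterior overlap of `m_r`, percent.
#' @param threshold Identifiability threshold (default 75).
#' @return List with `fraction` and logical `reliable`.
#' @export
inhibition_fraction <- function(mr_draws, m_tnz, ppo_mr, threshold = 75) {
  if (m_tnz <= 0) stop("m_tnz must be positive", call. = FALSE)
  list(fraction = unname(stats::median(mr_draws) / m_tnz),
       reliable = unname(is.finite(ppo_mr) && ppo_mr < threshold))
}

#' Paired comparison of estimated and reference parameters
#'
#' Pearson correlation per parameter between model estimates and values
#' reported by the original data sources, across datasets.  Pairs whose
#' estimated threshold temperature (`parameter == "tt"`) falls outside the
#' dataset's measured temperature range are excluded before testing, as the
#' threshold is then unidentifiable.  Parameters with fewer than 3 usable
#' pairs are reported with `NA` correlation.
#'
#' @param comparisons Data.frame with columns `parameter`, `estimate`,
#'   `reference`, and (used for `tt` only) `ta_min`, `ta_max`.
#' @return Data.frame: `parameter`, `n`, `r`, `p_value`.
#' @export
compare_parameters <- function(comparisons) {
  need <- c("parameter", "estimate", "reference")
  miss <- setdiff(need, names(comparisons))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- lapply(split(comparisons, comparisons$parameter), function(d) {
    if (d$parameter[1] == "tt" &&
        all(c("ta_min", "ta_max") %in% names(d))) {
      inside <- d$estimate >= d$ta_min & d$estimate <= d$ta_max
      d <- d[inside, , drop = FALSE]
    }
    if (nrow(d) < 3)
      return(data.frame(parameter = if (nrow(d)) d$parameter[1] else NA,
                        n = nrow(d), r = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(d$estimate, d$reference, method = "pearson")
    data.frame(parameter = d$parameter[1], n = nrow(d),
               r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Evaluate a fitted assignment against reference labels
#'
#' @param fit A `thermo_fit` from [fit_thermo()].
#' @param reference_states Optional reference labels; defaults to the
#'   dataset's `state_ref` column.
#' @param collapse_tnz Passed to [corroboration_index()].
#' @return List of class `evaluation_report`: `corroboration`,
#'   `valid_fraction`, `inhibition` (fraction + reliability),
#'   `n_valid`, `n_labelled`.
#' @export
evaluate_fit <- function(fit, reference_states = NULL, collapse_tnz = TRUE) {
  stopifnot(inherits(fit, "thermo_fit"))
  tab <- fit$assignment
  if (is.null(reference_states)) reference_states <- fit$data$state_ref
  corr <- corroboration_index(tab$state, reference_states, tab$valid,
                              collapse_tnz = collapse_tnz)
  inh <- inhibition_fraction(fit$posteriors$Mr, fit$parameters["m_tnz"],
                             ppo_mr = fit$ppo$overlap[fit$ppo$parameter == "Mr"])
  structure(list(corroboration = corr,
                 valid_fraction = mean(tab$valid),
                 inhibition = inh,
                 n_valid = sum(tab$valid),
                 n_labelled = sum(reference_states != "none")),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Corroboration index: %.3f over %d valid records\n",
              x$corroboration, x$n_valid))
  cat(sprintf("Valid-assignment proportion: %.3f\n", x$valid_fraction))
  cat(sprintf("Inhibition fraction M_r/M_TNZ: %.3f (%s)\n",
              x$inhibition$fraction,
              if (x$inhibition$reliable) "identifiable" else "unreliable: M_r PPO >= threshold"))
  invisible(x)
}
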