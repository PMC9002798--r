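#' Construct a metabolic dataset
#'
#' Validates a table of paired measurements of ambient temperature (`ta`,
#' degrees C) and resting/torpid metabolic rate (`m`, any consistent unit),
#' optionally carrying reference state labels (`state_ref`) supplied by the
#' original authors for evaluation.  Measurements taken above the upper
#' critical temperature must be excluded by the caller before analysis.
#'
#' @param x A data.frame with numeric columns `ta` and `m`, and optionally a
#'   character column `state_ref` with values in
#'   `c("torpor", "euthermy", "tnz", "none")`.
#' @return The validated data.frame with class `metabolic_dataset`.
#' @export
as_metabolic_dataset <- function(x) {
  if (!is.data.frame(x)) stop("expected a data.frame", call. = FALSE)
  miss <- setdiff(c("ta", "m"), names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(x$ta) | !is.finite(x$m))
  if (length(bad))
    stop("non-finite ta or m in row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(x$m <= 0)
  if (length(bad))
    stop("non-positive metabolic rate in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(x) < 10)
    stop("at least 10 records are required (the initial regression window)",
         call. = FALSE)
  if (is.null(x$state_ref)) {
    x$state_ref <- "none"
  } else {
    x$state_ref <- as.character(x$state_ref)
    ok <- x$state_ref %in% c("torpor", "euthermy", "tnz", "none")
    if (!all(ok))
      stop("state_ref values must be torpor/euthermy/tnz/none; offending row(s): ",
           paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  class(x) <- c("metabolic_dataset", "data.frame")
  x
}

#' Read a metabolic dataset from CSV
#'
#' Expects a header row with columns `ta` and `m`; an optional `state_ref`
#' column carries reference labels.  Rows with missing or non-finite values
#' are rejected with row-numbered messages.
#'
#' @param path Path to a CSV file.
#' @return A `metabolic_dataset`.
#' @export
read_metabolic_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_metabolic_dataset(x)
}

#' Write a metabolic dataset to CSV
#'
#' @param data A `metabolic_dataset` (or compatible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metabolic_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' MCMC and threshold configuration
#'
#' Bundles the sampling protocol and decision thresholds.  Defaults are the
#' method's reference settings: three chains of 50,000 iterations, the first
#' 30,000 dropped, thinning by 10 (2,000 retained draws per chain), an R-hat
#' convergence threshold of 1.1, a Breusch-Pagan level of 0.05 and a slope
#' level of 0.01 for the rolling boundary search, a prior-posterior-overlap
#' identifiability threshold of 75%, and an assignment-validity threshold of
#' 0.8 tested at level 0.05.
#'
#' @param chains Number of Markov chains.
#' @param iterations Total iterations per chain.
#' @param burnin Iterations dropped from the start of each chain (the rjags
#'   adaptation phase, `adapt` iterations, is counted inside this budget).
#' @param thin Thinning factor applied after burn-in.
#' @param adapt Adaptation iterations (part of `burnin`).
#' @param seed Integer seed controlling all chain RNGs.
#' @param rhat_threshold Convergence flag threshold for the
#'   Brooks-Gelman-Rubin statistic.
#' @param bp_alpha,slope_alpha Significance levels of the rolling-window
#'   Breusch-Pagan and slope tests.
#' @param ppo_threshold Prior-posterior overlap (%) at or above which a
#'   parameter is reported unidentifiable.
#' @param validity_threshold,validity_alpha Confidence threshold and level of
#'   the one-sided binomial validity test.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, iterations = 50000L, burnin = 30000L,
                        thin = 10L, adapt = 1000L, seed = 1L,
                        rhat_threshold = 1.1,
                        bp_alpha = 0.05, slope_alpha = 0.01,
                        ppo_threshold = 75,
                        validity_threshold = 0.8, validity_alpha = 0.05) {
  stopifnot(chains >= 1, iterations > burnin, burnin >= adapt, thin >= 1,
            validity_threshold > 0, validity_threshold < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 thin = as.integer(thin),
                 adapt = as.integer(adapt),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 bp_alpha = bp_alpha, slope_alpha = slope_alpha,
                 ppo_threshold = ppo_threshold,
                 validity_threshold = validity_threshold,
                 validity_alpha = validity_alpha),
            class = "mcmc_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Any field of [mcmc_config()] may be overridden; unknown fields are an
#' error.  Format is chosen by file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path Path to the configuration file.
#' @return An `mcmc_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(mcmc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(mcmc_config, vals)
}
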