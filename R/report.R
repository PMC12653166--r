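#' Correlations of person-level EAPs with external measures
#'
#' Pearson correlations between the EAP estimates of the person-level
#' random-effect parameters (ability plus each random practice component)
#' and each external measure, with two-tailed p-values from the exact t
#' transform (`t = r sqrt((n-2)/(1-r^2))`, n-2 df) and significance flags at
#' .05 / .01. EAP point estimates are used as-is (shrinkage attenuates the
#' correlations; this matches the reference reporting and is documented,
#' not corrected).
#'
#' @param fit An [oslm_fit()].
#' @param external Data frame with a `person` column matching the fit's
#'   person ids plus one numeric column per measure.
#' @return Data frame of class `oslm_correlations`: `measure, parameter, r,
#'   p, sig` (`""`, `"*"`, `"**"`).
#' @export
correlate_effects <- function(fit, external) {
  stopifnot(is.data.frame(external), "person" %in% names(external))
  ids <- fit$data$person_ids
  idx <- match(ids, external$person)
  if (anyNA(idx))
    stop("external table is missing persons: ",
         paste(utils::head(ids[is.na(idx)]), collapse = ", "))
  external <- external[idx, , drop = FALSE]
  n <- length(ids)
  eaps <- list(theta = colMeans(stack_draws(fit,
                                            brkt("theta", seq_len(n)))))
  rand <- fit$spec$components[fit$spec$practice_mode == "random"]
  for (m in rand)
    eaps[[paste0("delta_", m)]] <- classify_individuals(fit, m)$eap
  if (any(fit$spec$difficulty_mode == "random")) {
    for (m in fit$spec$components)
      eaps[[paste0("eta_", m)]] <-
        colMeans(stack_draws(fit, brkt("eta", seq_len(n), m)))
  }
  measures <- setdiff(names(external), "person")
  out <- expand.grid(measure = measures, parameter = names(eaps),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (k in seq_len(nrow(out))) {
    x <- external[[out$measure[k]]]
    y <- eaps[[out$parameter[k]]]
    r <- cor(x, y)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    out$r[k] <- r
    out$p[k] <- 2 * pt(-abs(tt), df = n - 2)
  }
  out$sig <- ifelse(out$p < 0.01, "**", ifelse(out$p < 0.05, "*", ""))
  class(out) <- c("oslm_correlations", "data.frame")
  out
}

#' Rasch item difficulties
#'
#' Item difficulties as EAPs from a Rasch model, fitted as the special case
#' of the package's own family: structure matrix `W = identity(J)` (one
#' pseudo-component per item), no practice terms (LLTM variant).
#'
#' @param data An [response_data()].
#' @param config Sampler configuration (default a fast profile).
#' @return Named numeric vector of J item difficulties (logit units), with
#'   the fit attached as attribute `fit`.
#' @export
rasch_difficulties <- function(data, config = fast_profile()) {
  J <- data$J
  pbar <- colMeans(data$X)
  if (any(pbar == 0) || any(pbar == 1))
    stop("degenerate item(s) with all-0 or all-1 responses: ",
         paste(which(pbar %in% c(0, 1)), collapse = ", "))
  comps <- data.frame(name = paste0("item_", seq_len(J)), kind = "rule",
                      stringsAsFactors = FALSE)
  design <- test_design(diag(J), comps)
  spec <- model_spec("LLTM", components = comps$name)
  fit <- oslm_fit(spec, design, data, config)
  sm <- summary(fit, pars = "global")
  d <- setNames(sm$EAP[match(brkt("alpha", comps$name), sm$parameter)],
                paste0("item_", seq_len(J)))
  attr(d, "fit") <- fit
  d
}

#' Variance in item difficulty explained by the design components
#'
#' Ordinary least squares of item difficulties on the structure-matrix
#' columns (with intercept) gives the component R-squared; adding item
#' position tests whether position explains difficulty beyond the
#' components (incremental R-squared with an F test).
#'
#' @param difficulties Numeric vector of J item difficulties (e.g. from
#'   [rasch_difficulties()]).
#' @param design The [test_design()].
#' @param positions Item positions (default `1:J`).
#' @return List of class `oslm_varexp`: `r_squared`,
#'   `r_squared_with_position`, `incremental_r_squared`, `F`, `p_position`,
#'   `difficulties`.
#' @export
variance_explained <- function(difficulties, design,
                               positions = seq_len(design$J)) {
  J <- design$J
  stopifnot(length(difficulties) == J, length(positions) == J)
  if (J <= design$M + 2)
    stop("need J > M + 2 items for the position test")
  df <- data.frame(d = difficulties, design$W, .position = positions,
                   check.names = TRUE)
  base <- lm(d ~ . - .position, data = df)
  if (any(is.na(coef(base))))
    stop("rank-deficient regression matrix: components are collinear")
  full <- lm(d ~ ., data = df)
  a <- anova(base, full)
  tss <- sum((difficulties - mean(difficulties))^2)
  r2 <- 1 - sum(residuals(base)^2) / tss
  r2p <- 1 - sum(residuals(full)^2) / tss
  structure(list(r_squared = r2,
                 r_squared_with_position = r2p,
                 incremental_r_squared = max(r2p - r2, 0),
                 F = a$F[2], p_position = a$`Pr(>F)`[2],
                 difficulties = difficulties),
            class = "oslm_varexp")
}

#' @export
print.oslm_varexp <- function(x, ...) {
  cat(sprintf("Components explain %.1f%% of item-difficulty variance;",
              100 * x$r_squared),
      sprintf("position adds %.2f%% (F = %.2f, p = %.3f)\n",
              100 * x$incremental_r_squared, x$F, x$p_position))
  invisible(x)
}

num_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write report files for a fitted analysis
#'
#' Writes the standard table-shaped CSVs (posterior summary, model
#' comparison, external correlations), a tidy trajectory table, and a
#' markdown run report with configuration, seeds, versions and diagnostics.
#' Regenerating from the same fit is byte-identical (no timestamps).
#'
#' @param fit An [oslm_fit()].
#' @param out_dir Output directory (created if needed).
#' @param comparison Optional [compare_models()] result.
#' @param correlations Optional [correlate_effects()] result.
#' @param trajectory_persons Persons for the trajectory table (default:
#'   none, shared curves only).
#' @return Named vector of file paths, invisibly.
#' @export
render_reports <- function(fit, out_dir, comparison = NULL,
                           correlations = NULL, trajectory_persons = integer(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(summary = file.path(out_dir, "posterior_summary.csv"),
             trajectories = file.path(out_dir, "trajectories.csv"),
             report = file.path(out_dir, "report.md"))
  sm <- summary(fit, pars = "global")
  num_csv(as.data.frame(sm), files["summary"])
  tr <- trajectories(fit, persons = trajectory_persons)
  num_csv(tr, files["trajectories"])
  if (!is.null(comparison)) {
    files["comparison"] <- file.path(out_dir, "model_comparison.csv")
    num_csv(as.data.frame(comparison), files["comparison"])
  }
  if (!is.null(correlations)) {
    files["correlations"] <- file.path(out_dir, "external_correlations.csv")
    num_csv(as.data.frame(correlations), files["correlations"])
  }
  rl <- c(
    "# Analysis run report", "",
    paste0("- model: ", fit$spec$variant),
    paste0("- persons: ", fit$data$n, ", items: ", fit$data$J,
           ", components: ", fit$design$M),
    paste0("- sampler: ", fit$config$chains, " chains x ", fit$config$iter,
           " iterations (", fit$config$warmup, " warmup), seed ",
           fit$config$seed),
    paste0("- adapt_delta: ", fit$config$adapt_delta,
           ", max_treedepth: ", fit$config$max_treedepth),
    paste0("- divergences: ", fit$diagnostics$divergences),
    paste0("- max R-hat (reported parameters): ",
           formatC(max(sm$Rhat, na.rm = TRUE), digits = 4, format = "f")),
    paste0("- R-hat < 1.01 for all reported parameters: ",
           isTRUE(attr(sm, "rhat_ok"))),
    paste0("- oslm version: ",
           as.character(utils::packageVersion("oslm"))),
    "",
    "## Files", "",
    paste0("- ", basename(files)))
  if (is.null(comparison)) rl <- c(rl, "", "(no model-comparison / PPMC section: not requested)")
  writeLines(rl, files["report"])
  invisible(files)
}

#' End-to-end synthetic demonstration study
#'
#' `simulate -> fit -> compare -> report` on the packaged synthetic study:
#' generates an ART-like data set, fits the constrained random-weights
#' practice model and the practice-free LLTM, compares them (WAIC, LOO,
#' PPMC), correlates the person EAPs with the generated external measures,
#' and writes all table-shaped outputs. Deterministic given `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n,J Study size before exclusion.
#' @param config Sampler configuration (default a small fast profile).
#' @param ppmc_replicates Replicates for the posterior predictive check.
#' @return List with the study, fits, comparison, correlations and the file
#'   paths written.
#' @export
run_demo_study <- function(out_dir, seed = 1, n = 120, J = 34,
                           config = fast_profile(seed = seed, iter = 400,
                                                 warmup = 200),
                           ppmc_replicates = 100) {
  study <- simulate_study(n = n, J = J, seed = seed)
  spec_full <- gen_model_spec(study$generating)
  spec_lltm <- model_spec("LLTM", components = study$generating$components)
  fit_full <- oslm_fit(spec_full, study$design, study$data, config)
  fit_lltm <- oslm_fit(spec_lltm, study$design, study$data, config)
  comparison <- compare_models(list(RWOSLM_const = fit_full,
                                    LLTM = fit_lltm),
                               ppmc_replicates = ppmc_replicates,
                               seed = seed)
  correlations <- correlate_effects(fit_full, study$external)
  files <- render_reports(fit_full, out_dir, comparison = comparison,
                          correlations = correlations,
                          trajectory_persons = seq_len(min(5, fit_full$data$n)))
  ex_path <- file.path(out_dir, "exclusions.csv")
  num_csv(data.frame(n_before = study$raw_data$n,
                     n_excluded = study$filter$n_excluded,
                     fraction_excluded = study$filter$fraction_excluded,
                     threshold_seconds = study$filter$threshold_seconds),
          ex_path)
  files["exclusions"] <- ex_path
  invisible(list(study = study, fits = list(RWOSLM_const = fit_full,
                                            LLTM = fit_lltm),
                 comparison = comparison, correlations = correlations,
                 files = files))
}
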