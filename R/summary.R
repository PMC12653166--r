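#' Rank-normalized split R-hat
#'
#' The modern convergence diagnostic: chains are split in half, pooled draws
#' are rank-normalized through the standard-normal quantile function, and
#' the classic potential-scale-reduction statistic is computed on the
#' normalized ranks. The larger of the bulk statistic and the tail (folded)
#' statistic is returned. Constant draws give `NA` with a warning.
#'
#' @param chains List of numeric vectors (or a single vector), one per
#'   chain, post-warmup draws of a single parameter.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  halves <- list()
  for (ch in chains) {
    m <- length(ch) %/% 2
    halves <- c(halves, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  if (length(unique(unlist(halves))) == 1L) {
    warning("constant draws: R-hat undefined")
    return(NA_real_)
  }
  rhat_basic <- function(parts) {
    m <- length(parts); nn <- length(parts[[1]])
    means <- vapply(parts, mean, 0)
    vars <- vapply(parts, var, 0)
    B <- nn * var(means)
    Wv <- mean(vars)
    if (Wv == 0) return(NA_real_)
    sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
  }
  znorm <- function(parts) {
    x <- unlist(parts)
    z <- qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
    split(z, rep(seq_along(parts), lengths(parts)))
  }
  bulk <- rhat_basic(znorm(halves))
  folded <- rhat_basic(znorm(lapply(halves, function(x) abs(x - stats::median(unlist(halves))))))
  max(bulk, folded, na.rm = TRUE)
}

#' Posterior summary table
#'
#' EAP (posterior mean), posterior SD, central 2.5/97.5% interval and
#' rank-normalized split R-hat per parameter, in the layout of the reference
#' reporting format. Invariant to chain order.
#'
#' @param object An [oslm_fit()].
#' @param pars `"global"` (default: everything except person-level theta,
#'   eta, delta), `"all"`, or a character vector of parameter names.
#' @param ... Unused.
#' @return A data frame with columns `parameter, EAP, SD, q2.5, q97.5, Rhat`.
#' @export
summary.oslm_fit <- function(object, pars = "global", ...) {
  nm <- object$param_names
  if (identical(pars, "global")) {
    sel <- nm[!grepl("^(theta|eta|delta)\\[[0-9]+[],]", nm)]
  } else if (identical(pars, "all")) {
    sel <- nm
  } else {
    missing_p <- setdiff(pars, nm)
    if (length(missing_p))
      stop("unknown parameter(s): ", paste(missing_p, collapse = ", "))
    sel <- pars
  }
  per_chain <- lapply(object$draws, function(D) D[, sel, drop = FALSE])
  pooled <- do.call(rbind, per_chain)
  qs <- apply(pooled, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  rh <- vapply(seq_along(sel), function(k) {
    suppressWarnings(split_rhat(lapply(per_chain, function(D) D[, k])))
  }, 0)
  out <- data.frame(parameter = sel,
                    EAP = colMeans(pooled),
                    SD = apply(pooled, 2, sd),
                    q2.5 = qs[1, ], q97.5 = qs[2, ],
                    Rhat = rh,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "rhat_ok") <- all(is.na(out$Rhat) | out$Rhat < 1.01)
  class(out) <- c("oslm_summary", "data.frame")
  out
}

#' Posterior probability of a parameter event
#'
#' Fraction of post-warmup draws in which the named parameter exceeds (or
#' falls below) a threshold, e.g. `P(delta_D3 > 0 | x)`.
#'
#' @param fit An [oslm_fit()].
#' @param parameter Parameter name as printed by [summary.oslm_fit()], e.g.
#'   `"delta[D3]"` or `"mu_delta[distortion]"`.
#' @param direction `">"` or `"<"`.
#' @param threshold Numeric threshold (default 0).
#' @return Probability in `[0, 1]`.
#' @export
posterior_probability <- function(fit, parameter, direction = c(">", "<"),
                                  threshold = 0) {
  direction <- match.arg(direction)
  if (!parameter %in% fit$param_names)
    stop("unknown parameter: ", parameter)
  x <- stack_draws(fit, parameter)
  if (direction == ">") mean(x > threshold) else mean(x < threshold)
}

#' Individual-level practice-effect classification
#'
#' Per-person EAP of the random practice effect for one component and the
#' proportion of persons whose EAP is positive (i.e. whose estimated
#' difficulty for that component decreases with practice).
#'
#' @param fit An [oslm_fit()].
#' @param component Name of a random-practice component.
#' @return List with `eap` (named per-person vector), `proportion_positive`,
#'   and `component`.
#' @export
classify_individuals <- function(fit, component) {
  rc <- fit$spec$components[fit$spec$practice_mode == "random"]
  if (!component %in% rc)
    stop("component '", component, "' does not have random practice effects")
  cols <- brkt("delta", seq_len(fit$data$n), component)
  eap <- colMeans(stack_draws(fit, cols))
  names(eap) <- fit$data$person_ids
  list(component = component, eap = eap,
       proportion_positive = mean(eap > 0))
}

#' Difficulty-by-practice trajectories
#'
#' Evaluates, at the posterior EAPs, the difficulty of each component as a
#' function of item position: `alpha_ijm = alpha_m - delta_im *
#' cumulative prior weight`. Fixed-practice components give one shared
#' curve; random-practice components give one curve per requested person.
#'
#' @param fit An [oslm_fit()].
#' @param persons Person indices for the person-specific curves (default all).
#' @param components Components to include (default all).
#' @return Tidy data frame: `component, person (NA for shared curves), item,
#'   accumulated_weight, difficulty`.
#' @export
trajectories <- function(fit, persons = NULL, components = NULL) {
  spec <- fit$spec; design <- fit$design
  if (is.null(components)) components <- spec$components
  if (is.null(persons)) persons <- seq_len(fit$data$n)
  sm <- summary(fit, pars = "all")
  eap <- setNames(sm$EAP, sm$parameter)
  out <- list()
  for (m in components) {
    wcol <- design$W[, m]
    acc <- c(0, cumsum(wcol))[seq_len(design$J)]
    a_m <- if (any(spec$difficulty_mode == "random"))
      eap[brkt("mu_eta", m)] else eap[brkt("alpha", m)]
    pm <- spec$practice_mode[[m]]
    if (pm == "random") {
      for (i in persons) {
        d_im <- eap[brkt("delta", i, m)]
        out[[length(out) + 1L]] <- data.frame(
          component = m, person = i, item = seq_len(design$J),
          accumulated_weight = acc,
          difficulty = rule_difficulty_trajectory(a_m, d_im, wcol,
                                                  seq_len(design$J)))
      }
    } else {
      d_m <- if (pm == "fixed") eap[brkt("delta", m)] else 0
      out[[length(out) + 1L]] <- data.frame(
        component = m, person = NA_integer_, item = seq_len(design$J),
        accumulated_weight = acc,
        difficulty = rule_difficulty_trajectory(a_m, d_m, wcol,
                                                seq_len(design$J)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
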