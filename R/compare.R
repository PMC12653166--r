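logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

as_loglik_matrix <- function(x, thin = 1L) {
  if (inherits(x, "oslm_fit")) pointwise_loglik(x, thin = thin)
  else as.matrix(x)
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log mean_s exp(ll_si)` (log-sum-exp stabilized),
#' `p_waic = sum_i var_s(ll_si)`, `elpd_waic = lppd - p_waic`,
#' `waic = -2 elpd_waic`.
#'
#' @param x An [oslm_fit()] or an S x N matrix of pointwise log-likelihood
#'   draws (S draws, N observations).
#' @return List of class `oslm_ic` with `elpd_waic`, `p_waic`, `waic`,
#'   per-observation contributions, and `n_obs`, `n_draws`.
#' @export
waic <- function(x) {
  ll <- as_loglik_matrix(x)
  if (nrow(ll) < 2) stop("need at least 2 draws for WAIC")
  S <- nrow(ll)
  lppd_i <- apply(ll, 2, logsumexp) - log(S)
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  structure(list(elpd_waic = sum(elpd_i), p_waic = sum(p_i),
                 waic = -2 * sum(elpd_i),
                 pointwise = data.frame(lppd = lppd_i, p_waic = p_i,
                                        elpd_waic = elpd_i),
                 n_obs = ncol(ll), n_draws = S),
            class = "oslm_ic")
}

# Generalized Pareto fit by the Zhang-Stephens (2009) quadrature estimator,
# with the weak prior shrinkage of the shape toward 1/2 used by standard
# PSIS implementations.
gpd_fit <- function(x) {
  x <- sort(x)
  N <- length(x)
  m <- 30 + floor(sqrt(N))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(N / 4 + 0.5))]
  theta <- 1 / x[N] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  profile <- vapply(theta, function(th) {
    k <- mean(log1p(-th * x))
    N * (log(-th / k) - k - 1)
  }, 0)
  w <- exp(profile - logsumexp(profile))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (k * N + 0.5 * 10) / (N + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma / k * ((1 - p)^(-k) - 1)
}

# smooth one vector of log importance weights; returns smoothed lw and khat
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(exc) <= 0) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  if (!is.finite(fit$k)) return(list(lw = lw, k = NA_real_))
  qq <- qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma) + exp(cutoff)
  smoothed <- log(qq)
  smoothed <- pmin(smoothed, 0)   # truncate at the raw maximum (= 0 after centering)
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  list(lw = lw, k = fit$k)
}

#' Pareto-smoothed importance-sampling LOO
#'
#' Leave-one-out expected log predictive density estimated by importance
#' sampling with generalized-Pareto smoothing of the largest weights;
#' reports the per-observation Pareto k diagnostic.
#'
#' @inheritParams waic
#' @return List of class `oslm_ic` with `elpd_loo`, `p_loo`, `looic`,
#'   per-observation contributions and Pareto `k` values.
#' @export
psis_loo <- function(x) {
  ll <- as_loglik_matrix(x)
  if (nrow(ll) < 2) stop("need at least 2 draws for LOO")
  S <- nrow(ll)
  N <- ncol(ll)
  elpd_i <- numeric(N); khat <- numeric(N)
  lppd_i <- apply(ll, 2, logsumexp) - log(S)
  for (i in seq_len(N)) {
    lli <- ll[, i]
    if (!all(is.finite(lli))) stop("non-finite log-likelihood draws")
    sm <- psis_smooth(-lli)
    lw <- sm$lw
    khat[i] <- sm$k
    elpd_i[i] <- logsumexp(lw + lli) - logsumexp(lw)
  }
  structure(list(elpd_loo = sum(elpd_i), p_loo = sum(lppd_i - elpd_i),
                 looic = -2 * sum(elpd_i),
                 pointwise = data.frame(elpd_loo = elpd_i, k = khat),
                 n_obs = N, n_draws = S),
            class = "oslm_ic")
}

#' @export
print.oslm_ic <- function(x, ...) {
  if (!is.null(x$elpd_waic))
    cat(sprintf("WAIC: elpd %.1f, p_waic %.1f, waic %.1f (%d obs, %d draws)\n",
                x$elpd_waic, x$p_waic, x$waic, x$n_obs, x$n_draws))
  if (!is.null(x$elpd_loo))
    cat(sprintf("LOO:  elpd %.1f, p_loo %.1f, looic %.1f (%d obs, %d draws)\n",
                x$elpd_loo, x$p_loo, x$looic, x$n_obs, x$n_draws))
  invisible(x)
}

#' Pairwise odds-ratio statistic
#'
#' Measure of association between item pairs: for each unordered pair
#' (j, k) the 2x2 success table is formed and its odds ratio
#' `n11 n00 / (n10 n01)` computed, with 0.5 added to every cell of a table
#' containing a zero. The statistic is the sum over all J(J-1)/2 pairs.
#' (The aggregation into one scalar is a documented package choice; the
#' pairwise values are available via `pairwise = TRUE`.)
#'
#' @param X An [response_data()] object or binary n x J matrix.
#' @param pairwise Return the per-pair matrix instead of the sum.
#' @return Scalar sum of pairwise odds ratios (or a J x J symmetric matrix
#'   with `NA` diagonal when `pairwise = TRUE`).
#' @export
or_statistic <- function(X, pairwise = FALSE) {
  if (inherits(X, "oslm_responses")) X <- X$X
  X <- as.matrix(X)
  J <- ncol(X)
  if (J < 2 || nrow(X) < 1) stop("need at least 2 items and 1 person")
  # all pairwise 2x2 tables at once
  N11 <- crossprod(X)
  N10 <- crossprod(X, 1 - X)
  N01 <- t(N10)
  N00 <- crossprod(1 - X)
  zero <- pmin(N11, pmin(N10, pmin(N01, N00))) == 0
  cc <- ifelse(zero, 0.5, 0)
  OR <- ((N11 + cc) * (N00 + cc)) / ((N10 + cc) * (N01 + cc))
  diag(OR) <- NA_real_
  if (pairwise) OR else sum(OR[upper.tri(OR)])
}

#' Posterior predictive check with the odds-ratio statistic
#'
#' For a subsample of posterior draws, simulates a replicate response matrix
#' from the model and computes [or_statistic()]; the posterior predictive
#' p-value is the fraction of replicates at least as large as the realized
#' value (`p_post = P(T_rep >= T_obs)`), so models that underpredict item
#' association give p_post near 0.
#'
#' @param fit An [oslm_fit()].
#' @param n_replicates Number of replicate data sets (default up to 500,
#'   thinned to every 5th draw).
#' @param seed RNG seed for the replicate simulation.
#' @param thin Draw thinning interval (default 5).
#' @return List of class `oslm_ppmc` with `realized`, `replicates`,
#'   `simulated_mean`, `simulated_sd`, `p_post`, `n_replicates`.
#' @export
ppmc <- function(fit, n_replicates = 500, seed = 1, thin = 5L) {
  D <- stack_draws(fit)
  idx <- seq(1, nrow(D), by = thin)
  if (n_replicates > length(idx)) {
    if (n_replicates > nrow(D))
      stop("n_replicates exceeds the number of post-warmup draws")
    idx <- seq_len(nrow(D))
  }
  idx <- idx[seq_len(min(length(idx), n_replicates))]
  realized <- or_statistic(fit$data)
  set.seed(seed)
  reps <- vapply(idx, function(s) {
    par <- draw_params(fit, D[s, ])
    P1 <- plogis(logit_matrix(par, fit$design, fit$practice, fit$spec))
    Xrep <- matrix(rbinom(length(P1), 1, as.vector(P1)), nrow(P1), ncol(P1))
    or_statistic(Xrep)
  }, 0)
  structure(list(realized = realized, replicates = reps,
                 simulated_mean = mean(reps), simulated_sd = sd(reps),
                 p_post = mean(reps >= realized),
                 n_replicates = length(reps)),
            class = "oslm_ppmc")
}

#' @export
print.oslm_ppmc <- function(x, ...) {
  cat(sprintf("PPMC (OR): observed %.2f, simulated %.2f (%.2f), p_post = %.3f [%d replicates]\n",
              x$realized, x$simulated_mean, x$simulated_sd, x$p_post,
              x$n_replicates))
  invisible(x)
}

data_fingerprint <- function(data) {
  X <- data$X
  c(dim(X), sum(X), sum(X * seq_along(X)) %% 1e9)
}

#' Compare fitted models
#'
#' WAIC and PSIS-LOO (optionally PPMC) for several fits of the same data,
#' sorted by LOOIC; the best model (lowest LOOIC = best fit-parsimony
#' balance) is flagged. Also reports the standard error of the elpd_loo
#' difference to the best model, computed from the pointwise contributions.
#'
#' @param fits Named list of [oslm_fit()] objects on identical data.
#' @param ppmc_replicates If > 0, run [ppmc()] with this many replicates.
#' @param seed Seed for the PPMC replicates.
#' @param thin Thinning for the pointwise log-likelihood (default 1).
#' @return Data frame of class `oslm_comparison` with one row per model:
#'   `model, elpd_waic, p_waic, waic, elpd_loo, p_loo, looic,
#'   elpd_diff, se_diff, best` and, with PPMC, `or_observed, or_simulated,
#'   or_sd, p_post`.
#' @export
compare_models <- function(fits, ppmc_replicates = 0, seed = 1, thin = 1L) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f) f$spec$variant, "")
  fps <- lapply(fits, function(f) data_fingerprint(f$data))
  if (length(unique(lapply(fps, paste, collapse = ","))) != 1)
    stop("fits were not computed on identical data")
  lls <- lapply(fits, pointwise_loglik, thin = thin)
  w <- lapply(lls, waic)
  l <- lapply(lls, psis_loo)
  out <- data.frame(
    model = names(fits),
    elpd_waic = vapply(w, `[[`, 0, "elpd_waic"),
    p_waic = vapply(w, `[[`, 0, "p_waic"),
    waic = vapply(w, `[[`, 0, "waic"),
    elpd_loo = vapply(l, `[[`, 0, "elpd_loo"),
    p_loo = vapply(l, `[[`, 0, "p_loo"),
    looic = vapply(l, `[[`, 0, "looic"),
    stringsAsFactors = FALSE, row.names = NULL)
  best <- which.min(out$looic)
  ptbest <- l[[best]]$pointwise$elpd_loo
  out$elpd_diff <- out$elpd_loo - out$elpd_loo[best]
  out$se_diff <- vapply(seq_along(l), function(k) {
    d <- l[[k]]$pointwise$elpd_loo - ptbest
    sqrt(length(d) * var(d))
  }, 0)
  out$best <- seq_len(nrow(out)) == best
  if (ppmc_replicates > 0) {
    pp <- lapply(fits, ppmc, n_replicates = ppmc_replicates, seed = seed)
    out$or_observed <- vapply(pp, `[[`, 0, "realized")
    out$or_simulated <- vapply(pp, `[[`, 0, "simulated_mean")
    out$or_sd <- vapply(pp, `[[`, 0, "simulated_sd")
    out$p_post <- vapply(pp, `[[`, 0, "p_post")
  }
  out <- out[order(out$looic), , drop = FALSE]
  rownames(out) <- NULL
  if (sum(abs(out$looic - min(out$looic)) < 1e-8) > 1)
    attr(out, "tie") <- TRUE
  class(out) <- c("oslm_comparison", "data.frame")
  out
}
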