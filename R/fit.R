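#' Sampler configuration
#'
#' Defaults mirror the reference analysis: four chains of 5000 iterations
#' each, first half discarded as warmup. [fast_profile()] is a desk-scale
#' preset (2 chains x 1000) for tests and demos.
#'
#' @param chains Number of chains (>= 1).
#' @param iter Total iterations per chain (warmup included).
#' @param warmup Warmup iterations discarded per chain; default half.
#' @param seed Integer seed; every chain derives its own stream from it.
#' @param adapt_delta Dual-averaging target acceptance statistic.
#' @param max_treedepth NUTS tree-depth cap.
#' @return A list of class `oslm_sampler_config`.
#' @export
sampler_config <- function(chains = 4, iter = 5000, warmup = floor(iter / 2),
                           seed = 1, adapt_delta = 0.8, max_treedepth = 10) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 20)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 adapt_delta = adapt_delta,
                 max_treedepth = as.integer(max_treedepth)),
            class = "oslm_sampler_config")
}

#' @rdname sampler_config
#' @param ... Passed on to [sampler_config()].
#' @export
fast_profile <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(chains = 2, iter = 1000, seed = seed)
  do.call(sampler_config, utils::modifyList(defaults, args))
}

# 0-based unconstrained-parameter layout shared with the C++ sampler.
build_layout <- function(spec, n, M) {
  diff_random <- any(spec$difficulty_mode == "random")
  fixd <- which(spec$practice_mode == "fixed")
  rand <- which(spec$practice_mode == "random")
  F <- length(fixd); R <- length(rand)
  off <- list(theta = 0L, alpha = 0L, mu_e = 0L, ls_e = 0L, y_e = 0L,
              z_e = 0L, df = 0L, mu_d = 0L, ls_d = 0L, y_d = 0L, z_d = 0L)
  p <- n
  if (diff_random) {
    off$mu_e <- p; p <- p + M
    off$ls_e <- p; p <- p + M
    off$y_e <- p; p <- p + M * (M - 1) / 2
    off$z_e <- p; p <- p + n * M
  } else {
    off$alpha <- p; p <- p + M
  }
  if (F > 0) { off$df <- p; p <- p + F }
  if (R > 0) {
    off$mu_d <- p; p <- p + R
    off$ls_d <- p; p <- p + R
    off$y_d <- p; p <- p + R * (R - 1) / 2
    off$z_d <- p; p <- p + n * R
  }
  list(offsets = lapply(off, as.integer), P = as.integer(p),
       diff_random = diff_random, fixed_idx = fixd, rand_idx = rand,
       F = F, R = R, n = n, M = M)
}

# model list consumed by the C++ evaluator
build_model_list <- function(spec, design, practice, data, exclude = NULL) {
  n <- data$n; J <- design$J; M <- design$M
  lay <- build_layout(spec, n, M)
  mask <- matrix(1, n, J)
  if (!is.null(exclude)) {
    exclude <- as.matrix(exclude)
    stopifnot(ncol(exclude) == 2)
    mask[exclude] <- 0
  }
  list(X = data$X, mask = mask, W = design$W, V = practice$V,
       Vf = practice$V[, lay$fixed_idx, drop = FALSE],
       Vr = practice$V[, lay$rand_idx, drop = FALSE],
       n = as.integer(n), J = as.integer(J), M = as.integer(M),
       F = as.integer(lay$F), R = as.integer(lay$R),
       diff_random = lay$diff_random,
       offsets = lay$offsets, P = lay$P)
}

brkt <- function(name, ...) paste0(name, "[", paste(..., sep = ","), "]")

# user-scale parameter names in draw-column order
param_names <- function(spec, lay, person_ids) {
  comps <- spec$components
  nm <- character(0)
  if (lay$n > 0) nm <- c(nm, brkt("theta", seq_len(lay$n)))
  if (lay$diff_random) {
    nm <- c(nm, brkt("mu_eta", comps), brkt("sigma_eta", comps))
    if (lay$M > 1) {
      pr <- which(lower.tri(diag(lay$M)), arr.ind = TRUE)
      pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
      nm <- c(nm, brkt("Omega_eta", comps[pr[, 2]], comps[pr[, 1]]))
    }
    if (lay$n > 0)
      nm <- c(nm, as.vector(outer(seq_len(lay$n), comps,
                                  function(i, m) brkt("eta", i, m))))
  } else {
    nm <- c(nm, brkt("alpha", comps))
  }
  if (lay$F > 0) nm <- c(nm, brkt("delta", comps[lay$fixed_idx]))
  if (lay$R > 0) {
    rc <- comps[lay$rand_idx]
    nm <- c(nm, brkt("mu_delta", rc), brkt("sigma_delta", rc))
    if (lay$R > 1) {
      pr <- which(lower.tri(diag(lay$R)), arr.ind = TRUE)
      pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
      nm <- c(nm, brkt("Omega_delta", rc[pr[, 2]], rc[pr[, 1]]))
    }
    if (lay$n > 0)
      nm <- c(nm, as.vector(outer(seq_len(lay$n), rc,
                                  function(i, m) brkt("delta", i, m))))
  }
  nm
}

# transform one chain of unconstrained draws (S x P) to the user scale
transform_draws <- function(Q, spec, lay) {
  S <- nrow(Q); n <- lay$n; M <- lay$M; off <- lay$offsets
  out <- list()
  if (n > 0) out$theta <- Q[, off$theta + seq_len(n), drop = FALSE]
  block <- function(o_mu, o_ls, o_y, o_z, K) {
    mu <- Q[, o_mu + seq_len(K), drop = FALSE]
    sig <- exp(Q[, o_ls + seq_len(K), drop = FALSE])
    ny <- K * (K - 1) / 2
    omg <- if (ny > 0) matrix(0, S, ny) else NULL
    eff <- if (n > 0) matrix(0, S, n * K) else NULL
    for (s in seq_len(S)) {
      L <- if (ny > 0) oslm_corr_chol(Q[s, o_y + seq_len(ny)], K) else diag(K)
      if (ny > 0) {
        Om <- L %*% t(L)
        omg[s, ] <- Om[lower.tri(Om)][order_lowtri(K)]
      }
      if (n > 0) {
        Z <- matrix(Q[s, o_z + seq_len(n * K)], n, K)
        D <- sweep(Z %*% t(L), 2, sig[s, ], `*`)
        D <- sweep(D, 2, mu[s, ], `+`)
        eff[s, ] <- as.vector(D)
      }
    }
    list(mu = mu, sig = sig, omg = omg, eff = eff)
  }
  if (lay$diff_random) {
    b <- block(off$mu_e, off$ls_e, off$y_e, off$z_e, M)
    out$mu_eta <- b$mu; out$sigma_eta <- b$sig
    if (!is.null(b$omg)) out$Omega_eta <- b$omg
    if (!is.null(b$eff)) out$eta <- b$eff
  } else {
    out$alpha <- Q[, off$alpha + seq_len(M), drop = FALSE]
  }
  if (lay$F > 0) out$delta_fixed <- Q[, off$df + seq_len(lay$F), drop = FALSE]
  if (lay$R > 0) {
    b <- block(off$mu_d, off$ls_d, off$y_d, off$z_d, lay$R)
    out$mu_delta <- b$mu; out$sigma_delta <- b$sig
    if (!is.null(b$omg)) out$Omega_delta <- b$omg
    if (!is.null(b$eff)) out$delta <- b$eff
  }
  # exact [[ ]] indexing: $ would partial-match "delta" to "delta_fixed"
  cols <- list()
  if (!is.null(out[["theta"]])) cols <- c(cols, list(out[["theta"]]))
  if (lay$diff_random) {
    cols <- c(cols, list(out[["mu_eta"]], out[["sigma_eta"]]))
    if (!is.null(out[["Omega_eta"]])) cols <- c(cols, list(out[["Omega_eta"]]))
    if (!is.null(out[["eta"]])) cols <- c(cols, list(out[["eta"]]))
  } else cols <- c(cols, list(out[["alpha"]]))
  if (lay$F > 0) cols <- c(cols, list(out[["delta_fixed"]]))
  if (lay$R > 0) {
    cols <- c(cols, list(out[["mu_delta"]], out[["sigma_delta"]]))
    if (!is.null(out[["Omega_delta"]])) cols <- c(cols, list(out[["Omega_delta"]]))
    if (!is.null(out[["delta"]])) cols <- c(cols, list(out[["delta"]]))
  }
  do.call(cbind, cols)
}

# row order of lower.tri entries sorted by (row, col)
order_lowtri <- function(K) {
  pr <- which(lower.tri(diag(K)), arr.ind = TRUE)
  order(order(pr[, 1], pr[, 2]))
}

#' Fit a model by NUTS
#'
#' Samples the joint posterior of the selected model variant with the
#' package's built-in No-U-Turn sampler (multinomial tree sampling,
#' dual-averaging step size, windowed diagonal metric adaptation).
#' Person-varying effects use a non-centred parameterization; the
#' correlation matrix of random effects is sampled through its Cholesky
#' factor under the LKJ(2) prior. Draws are returned on the user scale
#' (including realized per-person random effects), post-warmup only.
#' Identical seed and configuration give identical draws.
#'
#' @param spec A [model_spec()].
#' @param design An [test_design()].
#' @param data An [response_data()].
#' @param config A [sampler_config()].
#' @param practice Optional precomputed [build_practice_matrix()] output.
#' @param exclude Optional two-column matrix of (person, item) cells removed
#'   from the likelihood (used by the exact-LOO refit oracle).
#' @param check Run [check_identification()] first (default `TRUE`; fits
#'   with a failing report are refused).
#' @return An object of class `oslm_fit`: `draws` (list of per-chain
#'   iterations x parameters matrices, named columns), `diagnostics`
#'   (divergences, step sizes, tree-depth saturation per chain), plus the
#'   inputs.
#' @export
oslm_fit <- function(spec, design, data, config = sampler_config(),
                     practice = NULL, exclude = NULL, check = TRUE) {
  stopifnot(inherits(spec, "oslm_spec"), inherits(design, "oslm_design"),
            inherits(data, "oslm_responses"),
            inherits(config, "oslm_sampler_config"))
  if (data$J != design$J) stop("data and design disagree on item count")
  if (is.null(practice)) practice <- build_practice_matrix(design)
  if (check && data$n > 0) {
    rep_ <- check_identification(design, practice, spec)
    if (!rep_$pass)
      stop("identification check failed: ",
           paste(rep_$messages, collapse = "; "))
  }
  model <- build_model_list(spec, design, practice, data, exclude)
  lay <- build_layout(spec, data$n, design$M)
  nm <- param_names(spec, lay, data$person_ids)

  draws <- vector("list", config$chains)
  diag_list <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    chain_seed <- (config$seed %% 100000L) * 1000L + 7919L * ch
    set.seed(chain_seed)
    init <- runif(lay$P, -1, 1)
    res <- oslm_nuts(model, config$iter, config$warmup, init,
                     config$adapt_delta, config$max_treedepth, chain_seed)
    D <- transform_draws(res$draws, spec, lay)
    colnames(D) <- nm
    draws[[ch]] <- D
    diag_list[[ch]] <- list(stepsize = res$stepsize,
                            divergences = res$divergences,
                            max_depth_hits = res$max_depth_hits,
                            n_grad = res$n_grad)
  }
  ndiv <- sum(vapply(diag_list, `[[`, 0, "divergences"))
  if (ndiv > 0)
    warning(sprintf("%d divergent transitions after warmup; treat estimates with care", ndiv))
  structure(list(spec = spec, design = design, practice = practice,
                 data = data, config = config, draws = draws,
                 param_names = nm, layout = lay,
                 diagnostics = list(chains = diag_list, divergences = ndiv),
                 exclude = exclude),
            class = "oslm_fit")
}

#' @export
print.oslm_fit <- function(x, ...) {
  cat("oslm fit:", x$spec$variant, "|", x$data$n, "persons x", x$data$J,
      "items |", x$config$chains, "chains x", x$config$iter, "iter (",
      x$config$warmup, "warmup) |", x$diagnostics$divergences,
      "divergences\n")
  invisible(x)
}

# all post-warmup draws of selected columns, chains stacked
stack_draws <- function(fit, cols = NULL) {
  D <- do.call(rbind, fit$draws)
  if (is.null(cols)) D else D[, cols, drop = FALSE]
}

#' Pointwise log-likelihood draws
#'
#' Recomputes the n x J Bernoulli log likelihood for every post-warmup draw.
#' Observations are ordered person-fastest (column-major in the n x J
#' matrix).
#'
#' @param fit An [oslm_fit()] object.
#' @param thin Keep every `thin`-th draw (default 1 = all).
#' @return S x (n*J) matrix.
#' @export
pointwise_loglik <- function(fit, thin = 1L) {
  D <- stack_draws(fit)
  keep <- seq(1, nrow(D), by = thin)
  D <- D[keep, , drop = FALSE]
  S <- nrow(D)
  n <- fit$data$n; J <- fit$data$J
  out <- matrix(0, S, n * J)
  X <- fit$data$X
  for (s in seq_len(S)) {
    par <- draw_params(fit, D[s, ])
    Lg <- logit_matrix(par, fit$design, fit$practice, fit$spec)
    sp <- ifelse(Lg > 30, Lg, log1p(exp(Lg)))
    out[s, ] <- as.vector(X * Lg - sp)
  }
  out
}

# reconstruct a parameter list from one named draw row
draw_params <- function(fit, row) {
  spec <- fit$spec; lay <- fit$layout
  comps <- spec$components; n <- lay$n
  par <- list(theta = unname(row[brkt("theta", seq_len(n))]))
  if (lay$diff_random) {
    par$eta <- matrix(row[as.vector(outer(seq_len(n), comps,
                                          function(i, m) brkt("eta", i, m)))],
                      n, lay$M, dimnames = list(NULL, comps))
  } else {
    par$alpha <- setNames(row[brkt("alpha", comps)], comps)
  }
  if (lay$F > 0) {
    fc <- comps[lay$fixed_idx]
    par$delta_fixed <- setNames(row[brkt("delta", fc)], fc)
  }
  if (lay$R > 0) {
    rc <- comps[lay$rand_idx]
    par$delta <- matrix(row[as.vector(outer(seq_len(n), rc,
                                            function(i, m) brkt("delta", i, m)))],
                        n, lay$R, dimnames = list(NULL, rc))
  }
  par
}
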