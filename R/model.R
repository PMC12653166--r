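#' Model specification
#'
#' The unified model family covers five variants of the linear logistic test
#' model with operation-specific practice terms. The logit of a correct
#' response is
#' \deqn{logit P(X_{ij}=1) = \theta_i - \sum_m w_{jm} a_m + \sum_m v_{jm} d_{im}}
#' where the difficulty term `a` is fixed across persons (LLTM, OSLM,
#' RWOSLM) or a person-varying random effect (RWLLTM), and the practice term
#' `d` per component is absent (LLTM/RWLLTM), a shared fixed effect (OSLM),
#' or a person-varying multivariate-normal random effect (RWOSLM; mixed in
#' the constrained `RWOSLM_const`).
#'
#' @param variant One of `"LLTM"`, `"RWLLTM"`, `"OSLM"`, `"RWOSLM"`,
#'   `"RWOSLM_const"`.
#' @param components Character vector of component names (defaults to the
#'   ART components).
#' @param random_practice For `RWOSLM_const` only: component names whose
#'   practice effects are person-varying; the rest get shared fixed effects.
#'   Default `c("A/S", "distortion")`.
#' @return An object of class `oslm_spec` with `variant`, `difficulty_mode`
#'   (per component, `"fixed"`/`"random"`) and `practice_mode` (per
#'   component, `"none"`/`"fixed"`/`"random"`).
#' @export
model_spec <- function(variant = c("LLTM", "RWLLTM", "OSLM", "RWOSLM",
                                   "RWOSLM_const"),
                       components = art_components()$name,
                       random_practice = c("A/S", "distortion")) {
  variant <- match.arg(variant)
  M <- length(components)
  dmode <- rep(if (variant == "RWLLTM") "random" else "fixed", M)
  pmode <- switch(variant,
    LLTM = , RWLLTM = rep("none", M),
    OSLM = rep("fixed", M),
    RWOSLM = rep("random", M),
    RWOSLM_const = ifelse(components %in% random_practice, "random", "fixed"))
  if (variant == "RWOSLM_const") {
    if (!all(random_practice %in% components))
      stop("unknown component(s) in random_practice: ",
           paste(setdiff(random_practice, components), collapse = ", "))
    if (!any(pmode == "random"))
      stop("RWOSLM_const needs at least one random practice component")
  }
  structure(list(variant = variant,
                 components = components,
                 difficulty_mode = setNames(dmode, components),
                 practice_mode = setNames(pmode, components)),
            class = "oslm_spec")
}

#' @export
print.oslm_spec <- function(x, ...) {
  cat("Model:", x$variant, "\n")
  cat("  difficulty:", paste0(x$components, "(",
                              substr(x$difficulty_mode, 1, 1), ")",
                              collapse = " "), "\n")
  cat("  practice:  ", paste0(x$components, "(",
                              substr(x$practice_mode, 1, 1), ")",
                              collapse = " "), "\n")
  invisible(x)
}

#' Response data container
#'
#' @param X n x J matrix of binary outcomes (0/1), columns in administration
#'   order matching the design.
#' @param person_ids Optional person identifiers (default `1:n`).
#' @param latencies Optional n x J matrix of response latencies in seconds
#'   (used only by the exclusion filter, never modelled).
#' @return An object of class `oslm_responses`.
#' @export
response_data <- function(X, person_ids = NULL, latencies = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing responses are not supported")
  if (!all(X %in% c(0, 1))) stop("responses must be binary 0/1")
  n <- nrow(X)
  if (is.null(person_ids)) person_ids <- seq_len(n)
  if (length(person_ids) != n) stop("person_ids length must equal nrow(X)")
  if (anyDuplicated(person_ids)) stop("person_ids must be unique")
  if (!is.null(latencies)) {
    latencies <- as.matrix(latencies)
    if (!identical(dim(latencies), dim(X)))
      stop("latencies must have the same shape as X")
  }
  structure(list(X = X, person_ids = person_ids, latencies = latencies,
                 n = n, J = ncol(X)),
            class = "oslm_responses")
}

#' @export
print.oslm_responses <- function(x, ...) {
  cat("Responses:", x$n, "persons x", x$J, "items;",
      sprintf("mean correct %.3f", mean(x$X)),
      if (!is.null(x$latencies)) "(latencies present)" else "", "\n")
  invisible(x)
}

#' Read / write response data
#'
#' Wide CSV: `person,<item_1..item_J>` with 0/1 cells. Long CSV:
#' `person,item,response[,latency]`; items must form a complete rectangle.
#'
#' @param path File path.
#' @param format `"wide"` or `"long"`.
#' @return An [response_data()] object.
#' @export
read_responses <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE)
  if (format == "wide") {
    if (!"person" %in% names(df)) stop("wide response CSV needs a 'person' column")
    X <- as.matrix(df[, setdiff(names(df), "person"), drop = FALSE])
    response_data(X, person_ids = df$person)
  } else {
    need <- c("person", "item", "response")
    if (!all(need %in% names(df)))
      stop("long response CSV needs columns person,item,response")
    persons <- unique(df$person)
    items <- sort(unique(df$item))
    X <- matrix(NA_real_, length(persons), length(items))
    idx <- cbind(match(df$person, persons), match(df$item, items))
    X[idx] <- df$response
    if (anyNA(X)) stop("long response CSV is not a complete person x item rectangle")
    lat <- NULL
    if ("latency" %in% names(df)) {
      lat <- matrix(NA_real_, length(persons), length(items))
      lat[idx] <- df$latency
    }
    response_data(X, person_ids = persons, latencies = lat)
  }
}

#' @rdname read_responses
#' @param data An [response_data()] object.
#' @export
write_responses <- function(data, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(data, "oslm_responses"))
  if (format == "wide") {
    df <- data.frame(person = data$person_ids, check.names = FALSE)
    X <- data$X
    colnames(X) <- paste0("item_", seq_len(ncol(X)))
    write.csv(cbind(df, X), path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(
      person = rep(data$person_ids, times = data$J),
      item = rep(seq_len(data$J), each = data$n),
      response = as.vector(data$X))
    if (!is.null(data$latencies)) df$latency <- as.vector(data$latencies)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Success logit for one person-item pair
#'
#' Direct evaluation of the model logit
#' `theta_i - sum_m w[j,m] * a_m + sum_m v[j,m] * d_m` where for each
#' component the difficulty entry `a_m` is `alpha[m]` and the practice entry
#' `d_m` is taken from `delta_i` (random components), `delta_fixed` (fixed
#' components) or 0 (no practice), according to `spec`.
#'
#' @param theta_i Person ability (logit units).
#' @param alpha Named difficulty vector, one entry per component (for
#'   RWLLTM pass the person's realized random difficulties).
#' @param delta_i Named vector of the person's practice effects for
#'   random-practice components (may be `NULL`).
#' @param delta_fixed Named vector of shared practice effects for
#'   fixed-practice components (may be `NULL`).
#' @param w_row,v_row Item j's rows of `W` and `V`.
#' @param spec A [model_spec()].
#' @return The logit (scalar).
#' @export
success_logit <- function(theta_i, alpha, delta_i = NULL, delta_fixed = NULL,
                          w_row, v_row, spec) {
  stopifnot(inherits(spec, "oslm_spec"))
  M <- length(spec$components)
  if (length(alpha) != M || length(w_row) != M || length(v_row) != M)
    stop("alpha, w_row, v_row must have one entry per component")
  d <- numeric(M)
  names(d) <- spec$components
  rand <- spec$components[spec$practice_mode == "random"]
  fixd <- spec$components[spec$practice_mode == "fixed"]
  if (length(rand)) {
    if (is.null(delta_i) || !all(rand %in% names(delta_i)))
      stop("delta_i must name every random-practice component")
    d[rand] <- delta_i[rand]
  }
  if (length(fixd)) {
    if (is.null(delta_fixed) || !all(fixd %in% names(delta_fixed)))
      stop("delta_fixed must name every fixed-practice component")
    d[fixd] <- delta_fixed[fixd]
  }
  as.numeric(theta_i - sum(w_row * alpha) + sum(v_row * d))
}

#' Component difficulty as a function of practice
#'
#' The practice reformulation of the model: the difficulty of component m
#' for person i at item j is its initial difficulty minus the practice
#' effect times the accumulated prior weight,
#' `alpha_ijm = alpha_m - delta_im * sum(W[1:(j-1), m])`.
#'
#' @param alpha_m Initial component difficulty.
#' @param delta_im Practice effect (positive = difficulty decreases).
#' @param W_column The component's column of `W` (length J).
#' @param j Item position, 1-based.
#' @return `alpha_ijm` (scalar, or vector if `j` is a vector).
#' @export
rule_difficulty_trajectory <- function(alpha_m, delta_im, W_column, j) {
  stopifnot(all(j >= 1), all(j <= length(W_column)))
  prior <- c(0, cumsum(W_column))[j]
  alpha_m - delta_im * prior
}

# Full n x J logit matrix from a parameter list:
#   params$theta (n), params$alpha (M) or params$eta (n x M),
#   params$delta_fixed (named, fixed comps), params$delta (n x R, named cols)
logit_matrix <- function(params, design, practice, spec) {
  W <- design$W; V <- practice$V
  n <- length(params$theta)
  comps <- spec$components
  if (all(spec$difficulty_mode == "fixed")) {
    base <- -as.vector(W %*% params$alpha[comps])
  } else {
    base <- 0
  }
  Lg <- matrix(params$theta, n, design$J) +
    matrix(base, n, design$J, byrow = TRUE)
  if (any(spec$difficulty_mode == "random"))
    Lg <- Lg - params$eta[, comps, drop = FALSE] %*% t(W)
  fixd <- comps[spec$practice_mode == "fixed"]
  if (length(fixd))
    Lg <- Lg + matrix(as.vector(V[, fixd, drop = FALSE] %*%
                                  params$delta_fixed[fixd]),
                      n, design$J, byrow = TRUE)
  rand <- comps[spec$practice_mode == "random"]
  if (length(rand))
    Lg <- Lg + params$delta[, rand, drop = FALSE] %*% t(V[, rand, drop = FALSE])
  Lg
}

#' Pointwise Bernoulli log likelihood
#'
#' @param data An [response_data()] object.
#' @param params Named list of parameter values: `theta` (length n), and per
#'   spec `alpha` (named length M) or `eta` (n x M), `delta_fixed` (named),
#'   `delta` (n x R with named columns).
#' @param design,practice,spec Design, practice matrix and model spec.
#' @return List with `pointwise` (n x J matrix of log-likelihood
#'   contributions) and `total`. Numerically stable for extreme logits.
#' @export
log_likelihood <- function(data, params, design, practice = NULL, spec) {
  stopifnot(inherits(data, "oslm_responses"), inherits(spec, "oslm_spec"))
  if (data$J != design$J) stop("data and design disagree on item count")
  if (is.null(practice)) practice <- build_practice_matrix(design)
  Lg <- logit_matrix(params, design, practice, spec)
  # X*l - log(1 + e^l), stable via softplus
  sp <- ifelse(Lg > 30, Lg, log1p(exp(Lg)))
  pw <- data$X * Lg - sp
  list(pointwise = pw, total = sum(pw))
}

#' Log density of the LKJ correlation prior
#'
#' `log p(Omega) = log C(eta, K) + (eta - 1) * log det(Omega)` with the
#' exact normalizing constant.
#'
#' @param Omega Correlation matrix.
#' @param eta Shape parameter (> 0); `eta = 1` is uniform over correlation
#'   matrices, larger values concentrate near the identity.
#' @return Log density (scalar, including the normalizer).
#' @export
lkj_log_density <- function(Omega, eta = 2) {
  K <- nrow(Omega)
  if (K != ncol(Omega) || any(abs(diag(Omega) - 1) > 1e-8))
    stop("Omega must be a correlation matrix")
  # normalizer c(K, eta) = prod_{k=1}^{K-1} pi^{k/2}
  #   Gamma(eta + (K-1-k)/2) / Gamma(eta + (K-1)/2)
  # (K = 2 reduces to sqrt(pi) Gamma(eta) / Gamma(eta + 1/2), the integral of
  # (1 - rho^2)^(eta-1) over [-1, 1]; general K validated by Monte Carlo
  # integration in the test suite)
  logc <- 0
  for (k in seq_len(K - 1)) {
    a <- eta + (K - 1 - k) / 2
    logc <- logc + (k / 2) * log(pi) + lgamma(a) - lgamma(a + k / 2)
  }
  ld <- determinant(Omega, logarithm = TRUE)
  if (ld$sign <= 0) stop("Omega is not positive definite")
  as.numeric(-logc + (eta - 1) * ld$modulus)
}

#' Practice-effect hyperparameters
#'
#' Builds and validates the covariance `Sigma = diag(sigma) Omega
#' diag(sigma)` of the random practice (or random difficulty) effects.
#'
#' @param mu Mean vector.
#' @param sigma SD vector (elementwise > 0).
#' @param Omega Correlation matrix (symmetric, unit diagonal, positive
#'   definite); default identity.
#' @return List with `mu`, `sigma`, `Omega`, `Sigma`.
#' @export
practice_hyper <- function(mu, sigma, Omega = diag(length(mu))) {
  K <- length(mu)
  stopifnot(length(sigma) == K, all(dim(Omega) == K))
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(abs(Omega - t(Omega)) > 1e-10) || any(abs(diag(Omega) - 1) > 1e-10))
    stop("Omega must be symmetric with unit diagonal")
  Sigma <- diag(sigma, K) %*% Omega %*% diag(sigma, K)
  ok <- tryCatch({ chol(Sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("implied covariance is not positive definite")
  list(mu = mu, sigma = sigma, Omega = Omega, Sigma = Sigma)
}

#' Joint log prior
#'
#' Sums the log prior densities the spec activates: `theta ~ N(0,1)`; fixed
#' difficulty/practice effects `~ N(0, 100)` (100 = variance, SD 10); random
#' effects `~ MVN(mu, Sigma)`; hyper-priors `mu ~ N(0,1)`,
#' `sigma ~ half-Cauchy(0,5)`, `Omega ~ LKJ(2)`. All densities include
#' their normalizing constants.
#'
#' @param params Parameter list as in [log_likelihood()].
#' @param hyper A [practice_hyper()] list for the active random block (or
#'   `NULL` when no random effects).
#' @param spec A [model_spec()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, hyper = NULL, spec) {
  stopifnot(inherits(spec, "oslm_spec"))
  lp <- sum(stats::dnorm(params$theta, 0, 1, log = TRUE))
  comps <- spec$components
  if (all(spec$difficulty_mode == "fixed")) {
    lp <- lp + sum(stats::dnorm(params$alpha[comps], 0, 10, log = TRUE))
  }
  fixd <- comps[spec$practice_mode == "fixed"]
  if (length(fixd))
    lp <- lp + sum(stats::dnorm(params$delta_fixed[fixd], 0, 10, log = TRUE))
  rand_block <- NULL
  if (any(spec$difficulty_mode == "random")) rand_block <- params$eta
  rand <- comps[spec$practice_mode == "random"]
  if (length(rand)) rand_block <- params$delta[, rand, drop = FALSE]
  if (!is.null(rand_block)) {
    if (is.null(hyper)) stop("hyper must be supplied for random-effect models")
    if (any(hyper$sigma <= 0)) stop("sigma must be positive (half-Cauchy support)")
    Sigma <- hyper$Sigma
    Kd <- ncol(rand_block)
    ch <- chol(Sigma)
    centered <- sweep(rand_block, 2, hyper$mu)
    z2 <- rowSums((centered %*% solve(ch))^2)
    lp <- lp + sum(-0.5 * z2 - sum(log(diag(ch))) - 0.5 * Kd * log(2 * pi))
    # hyper-priors
    lp <- lp + sum(stats::dnorm(hyper$mu, 0, 1, log = TRUE))
    lp <- lp + sum(stats::dcauchy(hyper$sigma, 0, 5, log = TRUE) + log(2))
    lp <- lp + lkj_log_density(hyper$Omega, eta = 2)
  }
  lp
}
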