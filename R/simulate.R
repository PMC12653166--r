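#' Default generating parameters for ART-like simulations
#'
#' Realistic effect magnitudes for the 8-component Carpenter-rule design:
#' initial component difficulties, per-component practice configuration
#' (fixed shared effects for CR, PP, D3, D2, overlay, fusion; person-varying
#' random effects for A/S and distortion with their prior means and SDs),
#' standard-normal ability, and an identity correlation between the two
#' random effects (no reported value exists; independence is the package
#' default, see the methods vignette). Values are packaged as a versioned
#' plain-text fixture under `inst/extdata/`.
#'
#' @param path Optional path to an alternative JSON fixture with fields
#'   `components`, `alpha`, `practice_mode`, `delta_fixed`, `mu_delta`,
#'   `sigma_delta`, `Omega_delta`.
#' @return List of class `oslm_generating`: `components`, `alpha` (named),
#'   `practice_mode` (named), `delta_fixed` (named, fixed components),
#'   `mu_delta`, `sigma_delta` (named, random components), `Omega_delta`.
#' @export
art_generating_parameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "art_generating_parameters.json",
                        package = "oslm")
  obj <- jsonlite::fromJSON(path)
  comps <- obj$components
  gen <- list(
    components = comps,
    alpha = setNames(as.numeric(obj$alpha), comps),
    practice_mode = setNames(as.character(obj$practice_mode), comps),
    delta_fixed = setNames(as.numeric(obj$delta_fixed),
                           names(obj$delta_fixed)),
    mu_delta = setNames(as.numeric(obj$mu_delta), names(obj$mu_delta)),
    sigma_delta = setNames(as.numeric(obj$sigma_delta),
                           names(obj$sigma_delta)),
    Omega_delta = as.matrix(obj$Omega_delta))
  dimnames(gen$Omega_delta) <- list(names(gen$mu_delta), names(gen$mu_delta))
  class(gen) <- "oslm_generating"
  gen
}

#' Construct generating parameters
#'
#' @param alpha Named vector of true initial component difficulties.
#' @param practice_mode Named vector over the same components:
#'   `"none"`, `"fixed"` or `"random"`.
#' @param delta_fixed Named true practice effects for the fixed components.
#' @param mu_delta,sigma_delta Named prior mean / SD of the random effects.
#' @param Omega_delta Correlation matrix of the random effects (default
#'   identity).
#' @return List of class `oslm_generating`.
#' @export
generating_parameters <- function(alpha, practice_mode,
                                  delta_fixed = NULL, mu_delta = NULL,
                                  sigma_delta = NULL, Omega_delta = NULL) {
  comps <- names(alpha)
  stopifnot(!is.null(comps), identical(sort(comps), sort(names(practice_mode))))
  practice_mode <- practice_mode[comps]
  fixd <- comps[practice_mode == "fixed"]
  rand <- comps[practice_mode == "random"]
  if (length(fixd) && !all(fixd %in% names(delta_fixed)))
    stop("delta_fixed must name every fixed-practice component")
  if (length(rand)) {
    if (!all(rand %in% names(mu_delta)) || !all(rand %in% names(sigma_delta)))
      stop("mu_delta and sigma_delta must name every random-practice component")
    if (is.null(Omega_delta)) Omega_delta <- diag(length(rand))
    dimnames(Omega_delta) <- list(rand, rand)
    practice_hyper(mu_delta[rand], sigma_delta[rand], Omega_delta)  # validates
  }
  structure(list(components = comps, alpha = alpha,
                 practice_mode = practice_mode,
                 delta_fixed = if (length(fixd)) delta_fixed[fixd],
                 mu_delta = if (length(rand)) mu_delta[rand],
                 sigma_delta = if (length(rand)) sigma_delta[rand],
                 Omega_delta = if (length(rand)) Omega_delta),
            class = "oslm_generating")
}

gen_model_spec <- function(gen) {
  comps <- gen$components
  rand <- comps[gen$practice_mode == "random"]
  if (all(gen$practice_mode == "none")) model_spec("LLTM", components = comps)
  else if (!length(rand)) model_spec("OSLM", components = comps)
  else if (all(gen$practice_mode == "random"))
    model_spec("RWOSLM", components = comps)
  else model_spec("RWOSLM_const", components = comps, random_practice = rand)
}

#' Generate an ART-like test design
#'
#' Draws small-integer component weights (0-2 applications per rule, 0-1
#' per figural property, 1-3 rules per item, emulating Carpenter-style item
#' structures), orders items by predicted difficulty (sum of weighted true
#' component difficulties, easiest first, as in a difficulty-ordered test
#' administration), and rejection-resamples until the identification check
#' passes.
#'
#' @param J Number of items (must satisfy `2M + 1 <= J` for practice
#'   modelling).
#' @param components Component data frame (default [art_components()]).
#' @param seed RNG seed; the generator is seed-deterministic.
#' @param alpha_true Named true difficulties used for the difficulty
#'   ordering (default: the packaged generating fixture when the component
#'   names match, otherwise standard-normal draws).
#' @param max_tries Retry budget for the identification rejection loop.
#' @return An [test_design()] with attribute `provenance` (seed and
#'   generator settings).
#' @export
generate_design <- function(J = 34, components = art_components(), seed = 1,
                            alpha_true = NULL, max_tries = 200) {
  M <- nrow(components)
  if (J < 2 * M + 1)
    stop("J = ", J, " items cannot identify 2M + 1 = ", 2 * M + 1, " effects")
  set.seed(seed)
  if (is.null(alpha_true)) {
    fix <- art_generating_parameters()
    alpha_true <- if (all(components$name %in% names(fix$alpha)))
      fix$alpha[components$name]
    else setNames(rnorm(M), components$name)
  }
  rules <- which(components$kind == "rule")
  figs <- which(components$kind == "figural")
  for (try in seq_len(max_tries)) {
    W <- matrix(0, J, M)
    for (j in seq_len(J)) {
      k <- sample(1:min(3, length(rules)), 1)
      sel <- sample(rules, k)
      W[j, sel] <- sample(1:2, k, replace = TRUE)
      if (length(figs))
        W[j, figs] <- rbinom(length(figs), 1, 0.4)
    }
    if (any(colSums(W) == 0)) next
    diff_pred <- as.vector(W %*% alpha_true[components$name])
    W <- W[order(diff_pred), , drop = FALSE]
    d <- tryCatch(test_design(W, components), error = function(e) NULL)
    if (is.null(d)) next
    idr <- check_identification(d, build_practice_matrix(d),
                                model_spec("RWOSLM"))
    if (idr$pass) {
      attr(d, "provenance") <- list(seed = seed, J = J, try = try)
      return(d)
    }
  }
  stop("no identified design found within ", max_tries, " tries")
}

#' Generate true person parameters
#'
#' Abilities are i.i.d. standard normal; random practice effects are i.i.d.
#' multivariate normal with mean `mu_delta` and covariance
#' `diag(sigma) Omega diag(sigma)`.
#'
#' @param n Number of persons.
#' @param generating An [generating_parameters()] list.
#' @param seed RNG seed.
#' @return List of class `oslm_persons`: `theta` (length n), `delta`
#'   (n x R matrix, columns named after the random components; `NULL` when
#'   none), `provenance`.
#' @export
generate_persons <- function(n, generating = art_generating_parameters(),
                             seed = 1) {
  set.seed(seed)
  theta <- rnorm(n)
  delta <- NULL
  rand <- names(generating$mu_delta)
  if (length(rand)) {
    R <- length(rand)
    Sigma <- diag(generating$sigma_delta, R) %*% generating$Omega_delta %*%
      diag(generating$sigma_delta, R)
    ch <- tryCatch(chol(Sigma), error = function(e)
      stop("generating covariance is not positive definite"))
    Z <- matrix(rnorm(n * R), n, R)
    delta <- sweep(Z %*% ch, 2, generating$mu_delta, `+`)
    colnames(delta) <- rand
  }
  structure(list(theta = theta, delta = delta, n = n,
                 provenance = list(seed = seed)),
            class = "oslm_persons")
}

#' Simulate binary responses (and latencies)
#'
#' Forward simulation from the model: `X_ij ~ Bernoulli(plogis(l_ij))` with
#' the logit built from the true person and component parameters. Latencies
#' are drawn lognormal (median ~5 s) purely to exercise the exclusion
#' filter; a `contamination` fraction of persons receives at least one
#' sub-second "involuntary" response latency.
#'
#' @param design,practice Design and its practice matrix (practice derived
#'   if `NULL`).
#' @param persons A [generate_persons()] object.
#' @param generating The [generating_parameters()] used.
#' @param seed RNG seed.
#' @param latencies Generate a latency matrix (default `TRUE`).
#' @param contamination Fraction of persons given sub-second latencies
#'   (default 0.065, the reference exclusion rate).
#' @return An [response_data()] with attribute `provenance`.
#' @export
simulate_responses <- function(design, persons,
                               generating = art_generating_parameters(),
                               practice = NULL, seed = 1, latencies = TRUE,
                               contamination = 0.065) {
  if (is.null(practice)) practice <- build_practice_matrix(design)
  set.seed(seed)
  n <- persons$n; J <- design$J
  comps <- design$components$name
  stopifnot(identical(comps, generating$components))
  spec <- gen_model_spec(generating)
  par <- list(theta = persons$theta, alpha = generating$alpha,
              delta_fixed = generating$delta_fixed,
              delta = persons$delta)
  Lg <- logit_matrix(par, design, practice, spec)
  X <- matrix(rbinom(n * J, 1, plogis(as.vector(Lg))), n, J)
  lat <- NULL
  if (latencies) {
    lat <- matrix(rlnorm(n * J, meanlog = log(5), sdlog = 0.5), n, J)
    bad <- which(rbinom(n, 1, contamination) == 1)
    for (i in bad) {
      k <- sample(J, 1 + rbinom(1, 2, 0.3))
      lat[i, k] <- runif(length(k), 0.2, 0.99)
    }
  }
  out <- response_data(X, latencies = lat)
  attr(out, "provenance") <- list(seed = seed, contamination = contamination)
  out
}

#' Latency-based exclusion filter
#'
#' Excludes every person with at least one response latency below the
#' threshold (interpreted as involuntary responses from computerized
#' administration).
#'
#' @param data An [response_data()] with latencies.
#' @param threshold_seconds Exclusion threshold (default 1 s).
#' @return List: `data` (filtered [response_data()]), `excluded_ids`,
#'   `n_excluded`, `fraction_excluded`, `threshold_seconds`.
#' @export
latency_filter <- function(data, threshold_seconds = 1.0) {
  stopifnot(inherits(data, "oslm_responses"))
  if (is.null(data$latencies))
    stop("no latencies present; re-run without the latency filter (--no-filter)")
  bad <- apply(data$latencies < threshold_seconds, 1, any)
  keep <- which(!bad)
  filtered <- response_data(data$X[keep, , drop = FALSE],
                            person_ids = data$person_ids[keep],
                            latencies = data$latencies[keep, , drop = FALSE])
  list(data = filtered,
       excluded_ids = data$person_ids[bad],
       n_excluded = sum(bad),
       fraction_excluded = mean(bad),
       threshold_seconds = threshold_seconds)
}

#' External-measure specification
#'
#' Target correlations of each external measure with ability and with each
#' random practice effect; defaults emulate the reference magnitudes for a
#' general cognitive battery and two personality scales.
#'
#' @param targets Numeric matrix: rows = measures (named), columns =
#'   `theta` plus the random components.
#' @return Matrix of class `oslm_external_spec`.
#' @export
external_measure_spec <- function(targets = NULL) {
  if (is.null(targets)) {
    targets <- rbind(
      GTB = c(0.513, 0.254, 0.221),
      Openness = c(0.175, 0.075, 0.097),
      Conscientiousness = c(-0.098, -0.103, -0.079))
    colnames(targets) <- c("theta", "A/S", "distortion")
  }
  stopifnot(is.matrix(targets), !is.null(rownames(targets)),
            colnames(targets)[1] == "theta")
  class(targets) <- c("oslm_external_spec", class(targets))
  targets
}

#' Generate external person-level measures
#'
#' Each measure is a weighted sum of the standardized true person parameters
#' plus Gaussian noise, with the weights solved from the latent correlation
#' structure so that the population correlations equal the targets
#' (`b = R^-1 r`, noise variance `1 - r' R^-1 r`). Ability is independent
#' of the random practice effects in the generator; the practice effects
#' are correlated by `Omega`.
#'
#' @param persons A [generate_persons()] object.
#' @param spec An [external_measure_spec()] target matrix.
#' @param generating The generating parameters (for standardization and
#'   `Omega`).
#' @param seed RNG seed.
#' @return Data frame: `person` plus one column per measure.
#' @export
generate_external_measures <- function(persons,
                                       spec = external_measure_spec(),
                                       generating = art_generating_parameters(),
                                       seed = 1) {
  rand <- names(generating$mu_delta)
  need <- c("theta", rand)
  if (!all(colnames(spec) %in% need) || !all(need %in% colnames(spec)))
    stop("spec columns must be 'theta' plus the random components: ",
         paste(need, collapse = ", "))
  spec <- spec[, need, drop = FALSE]
  S <- cbind(theta = persons$theta)
  if (length(rand)) {
    Dstd <- sweep(sweep(persons$delta[, rand, drop = FALSE], 2,
                        generating$mu_delta[rand]),
                  2, generating$sigma_delta[rand], `/`)
    S <- cbind(S, Dstd)
  }
  K <- ncol(S)
  Rlat <- diag(K)
  if (length(rand) > 1)
    Rlat[-1, -1] <- generating$Omega_delta[rand, rand]
  set.seed(seed)
  out <- data.frame(person = seq_len(persons$n))
  for (m in rownames(spec)) {
    r <- as.numeric(spec[m, ])
    b <- solve(Rlat, r)
    v <- 1 - sum(r * b)
    if (v < -1e-8)
      stop("infeasible target correlations for measure '", m,
           "' (implied joint correlation not positive definite)")
    v <- max(v, 0)
    out[[m]] <- as.vector(S %*% b) + rnorm(persons$n, 0, sqrt(v))
  }
  out
}

#' One-call synthetic study
#'
#' Generates a design, persons, responses with latencies and external
#' measures, then applies the latency filter: the full stated world of the
#' simulator in administration order.
#'
#' @param n Persons before exclusion.
#' @param J Items.
#' @param generating Generating parameters.
#' @param seed Master seed (sub-seeds are derived from it).
#' @param external Generate external measures (default `TRUE`).
#' @return List: `design`, `practice`, `persons`, `raw_data`, `filter`
#'   (latency-filter report), `data` (filtered responses), `persons_kept`
#'   (true parameters of retained persons), `external` (filtered rows),
#'   `generating`, `seed`.
#' @export
simulate_study <- function(n = 765, J = 34,
                           generating = art_generating_parameters(),
                           seed = 1, external = TRUE) {
  comps <- data.frame(name = generating$components,
                      kind = ifelse(generating$components %in%
                                      c("overlay", "distortion", "fusion"),
                                    "figural", "rule"),
                      stringsAsFactors = FALSE)
  design <- generate_design(J = J, components = comps, seed = seed,
                            alpha_true = generating$alpha)
  practice <- build_practice_matrix(design)
  persons <- generate_persons(n, generating, seed = seed + 1L)
  raw <- simulate_responses(design, persons, generating, practice,
                            seed = seed + 2L)
  flt <- latency_filter(raw)
  keep <- match(flt$data$person_ids, seq_len(n))
  persons_kept <- structure(list(theta = persons$theta[keep],
                                 delta = if (!is.null(persons$delta))
                                   persons$delta[keep, , drop = FALSE],
                                 n = length(keep),
                                 provenance = persons$provenance),
                            class = "oslm_persons")
  ext <- NULL
  if (external) {
    ext <- generate_external_measures(persons, seed = seed + 3L,
                                      generating = generating)
    ext <- ext[keep, , drop = FALSE]
  }
  list(design = design, practice = practice, persons = persons,
       raw_data = raw, filter = flt, data = flt$data,
       persons_kept = persons_kept, external = ext,
       generating = generating, seed = seed)
}
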