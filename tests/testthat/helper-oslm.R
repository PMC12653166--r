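# Shared fixtures, built in code.

# deterministic 4-component mini design used across tests
mini_components <- function() {
  data.frame(name = c("r1", "r2", "r3", "f1"),
             kind = c("rule", "rule", "rule", "figural"),
             stringsAsFactors = FALSE)
}

mini_design <- function(J = 16, seed = 3) {
  generate_design(J = J, components = mini_components(), seed = seed,
                  alpha_true = c(r1 = -1, r2 = 0.8, r3 = 0.2, f1 = -0.4))
}

# generating parameters for the mini design (strong random effects so that
# model-selection and misfit signals are present at small n)
mini_generating <- function(sigma_scale = 1) {
  generating_parameters(
    alpha = c(r1 = -1, r2 = 0.8, r3 = 0.2, f1 = -0.4),
    practice_mode = c(r1 = "fixed", r2 = "random", r3 = "fixed",
                      f1 = "random"),
    delta_fixed = c(r1 = -0.05, r3 = 0.04),
    mu_delta = c(r2 = -0.05, f1 = 0.03),
    sigma_delta = c(r2 = 0.0548, f1 = 0.2049) * sigma_scale)
}

mini_spec <- function() {
  model_spec("RWOSLM_const", components = mini_components()$name,
             random_practice = c("r2", "f1"))
}

# brute-force double-loop practice-matrix oracle
practice_oracle <- function(W) {
  J <- nrow(W); M <- ncol(W)
  V <- matrix(0, J, M)
  for (j in seq_len(J))
    for (m in seq_len(M)) {
      s <- 0
      if (j > 1) for (k in seq_len(j - 1)) s <- s + W[k, m]
      V[j, m] <- W[j, m] * s
    }
  V
}

# one small cached fit reused by summary/reporting tests
.fit_cache <- new.env(parent = emptyenv())
cached_mini_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    d <- mini_design()
    gen <- mini_generating(sigma_scale = 3)
    persons <- generate_persons(80, gen, seed = 51)
    data <- simulate_responses(d, persons, gen, seed = 52, latencies = FALSE)
    .fit_cache$fit <- oslm_fit(mini_spec(), d, data,
                               sampler_config(chains = 2, iter = 500,
                                              warmup = 250, seed = 5))
    .fit_cache$persons <- persons
    .fit_cache$gen <- gen
  }
  .fit_cache$fit
}

# random parameter list conforming to a spec (for likelihood-level tests)
random_params <- function(spec, n, design, seed = 1) {
  set.seed(seed)
  comps <- spec$components
  M <- length(comps)
  par <- list(theta = rnorm(n))
  if (all(spec$difficulty_mode == "fixed")) {
    par$alpha <- setNames(rnorm(M), comps)
  } else {
    par$eta <- matrix(rnorm(n * M), n, M, dimnames = list(NULL, comps))
  }
  fixd <- comps[spec$practice_mode == "fixed"]
  if (length(fixd)) par$delta_fixed <- setNames(rnorm(length(fixd), 0, 0.1), fixd)
  rand <- comps[spec$practice_mode == "random"]
  if (length(rand))
    par$delta <- matrix(rnorm(n * length(rand), 0, 0.1), n, length(rand),
                        dimnames = list(NULL, rand))
  par
}
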