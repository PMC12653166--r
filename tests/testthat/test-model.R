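test_that("success_logit reproduces direct arithmetic", {
  spec <- model_spec("RWOSLM", components = c("a", "b"))
  # null model
  expect_equal(success_logit(0, c(a = 0, b = 0),
                             delta_i = c(a = 0, b = 0),
                             w_row = c(1, 1), v_row = c(1, 1), spec = spec), 0)
  # published-magnitude arithmetic: -(-1.585 + 1.017) + (2*(-0.090) + 0.095)
  lg <- success_logit(0, c(a = -1.585, b = 1.017),
                      delta_i = c(a = -0.090, b = 0.095),
                      w_row = c(1, 1), v_row = c(2, 1), spec = spec)
  expect_equal(lg, 0.483, tolerance = 1e-12)
})

test_that("difficulty trajectory evaluates the practice reformulation", {
  W_col <- c(1, 1, 1, 2)
  expect_equal(rule_difficulty_trajectory(1.5, 0.3, W_col, 1), 1.5)
  # alpha 1.017, delta 0.095, accumulated weight 3 -> 0.732
  expect_equal(rule_difficulty_trajectory(1.017, 0.095, c(1, 2, 5), 3), 0.732,
               tolerance = 1e-12)
  # negative delta: difficulty increases with practice
  expect_equal(rule_difficulty_trajectory(-1.585, -0.090, c(2, 4), 2), -1.405,
               tolerance = 1e-12)
})

test_that("direct and trajectory-based logits agree on random draws", {
  # algebraic identity checked to 1e-10 over random designs and parameters
  set.seed(7)
  for (rep in 1:25) {
    J <- sample(4:10, 1); M <- sample(2:4, 1)
    W <- matrix(rpois(J * M, 1), J, M); W[, colSums(W) == 0] <- 1
    comps <- paste0("c", seq_len(M))
    colnames(W) <- comps
    d <- test_design(W, data.frame(name = comps, kind = "rule"))
    V <- build_practice_matrix(d)$V
    spec <- model_spec("RWOSLM", components = comps)
    theta <- rnorm(1); alpha <- setNames(rnorm(M), comps)
    delta <- setNames(rnorm(M, 0, 0.2), comps)
    for (j in seq_len(J)) {
      direct <- success_logit(theta, alpha, delta_i = delta,
                              w_row = W[j, ], v_row = V[j, ], spec = spec)
      a_ijm <- vapply(comps, function(m)
        rule_difficulty_trajectory(alpha[m], delta[m], W[, m], j), 0)
      expect_equal(direct, theta - sum(W[j, ] * a_ijm), tolerance = 1e-10)
    }
  }
})

test_that("pointwise log likelihood matches a hand oracle and saturates safely", {
  comps <- c("a", "b")
  W <- cbind(a = c(1, 0, 1, 2), b = c(0, 1, 1, 1))
  d <- test_design(W, data.frame(name = comps, kind = "rule"))
  pr <- build_practice_matrix(d)
  spec <- model_spec("OSLM", components = comps)
  set.seed(2)
  X <- matrix(rbinom(12, 1, 0.5), 3, 4)
  data <- response_data(X)
  par <- list(theta = c(-0.5, 0, 1), alpha = c(a = 0.3, b = -0.2),
              delta_fixed = c(a = 0.05, b = -0.1))
  ll <- log_likelihood(data, par, d, pr, spec)
  # independent direct evaluation, scalar loops
  tot <- 0
  for (i in 1:3) for (j in 1:4) {
    l <- par$theta[i] - sum(W[j, ] * par$alpha) + sum(pr$V[j, ] * par$delta_fixed)
    p <- 1 / (1 + exp(-l))
    li <- if (X[i, j] == 1) log(p) else log(1 - p)
    expect_equal(ll$pointwise[i, j], li, tolerance = 1e-12)
    tot <- tot + li
  }
  expect_equal(ll$total, tot, tolerance = 1e-10)

  # saturation: logit +30 with X = 1 is ~0, finite, no overflow
  par2 <- list(theta = 30, alpha = c(a = 0, b = 0),
               delta_fixed = c(a = 0, b = 0))
  d1 <- response_data(matrix(1, 1, 4))
  ll2 <- log_likelihood(d1, par2, d, pr, spec)
  expect_true(all(is.finite(ll2$pointwise)))
  expect_true(all(ll2$pointwise > -1e-10))
  # X = 1 with logit 0 -> log 0.5
  par3 <- list(theta = 0, alpha = c(a = 0, b = 0),
               delta_fixed = c(a = 0, b = 0))
  expect_equal(log_likelihood(d1, par3, d, pr, spec)$pointwise[1, 1],
               log(0.5), tolerance = 1e-12)
})

test_that("practice models nest the practice-free and shared-effect models", {
  d <- mini_design(J = 12)
  pr <- build_practice_matrix(d)
  comps <- d$components$name
  set.seed(9)
  X <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12)
  data <- response_data(X)
  theta <- rnorm(8); alpha <- setNames(rnorm(4), comps)

  lltm <- log_likelihood(data, list(theta = theta, alpha = alpha), d, pr,
                         model_spec("LLTM", components = comps))
  # OSLM with all delta = 0 equals LLTM pointwise
  oslm0 <- log_likelihood(data, list(theta = theta, alpha = alpha,
                                     delta_fixed = setNames(rep(0, 4), comps)),
                          d, pr, model_spec("OSLM", components = comps))
  expect_equal(oslm0$pointwise, lltm$pointwise, tolerance = 1e-12)
  # RWOSLM with all person rows = 0 equals LLTM pointwise
  rw0 <- log_likelihood(data, list(theta = theta, alpha = alpha,
                                   delta = matrix(0, 8, 4,
                                                  dimnames = list(NULL, comps))),
                        d, pr, model_spec("RWOSLM", components = comps))
  expect_equal(rw0$pointwise, lltm$pointwise, tolerance = 1e-12)
  # RWOSLM with shared rows delta_i = delta equals OSLM conditionally
  del <- setNames(rnorm(4, 0, 0.2), comps)
  oslmd <- log_likelihood(data, list(theta = theta, alpha = alpha,
                                     delta_fixed = del), d, pr,
                          model_spec("OSLM", components = comps))
  rwd <- log_likelihood(data, list(theta = theta, alpha = alpha,
                                   delta = matrix(del, 8, 4, byrow = TRUE,
                                                  dimnames = list(NULL, comps))),
                        d, pr, model_spec("RWOSLM", components = comps))
  expect_equal(rwd$pointwise, oslmd$pointwise, tolerance = 1e-12)
})

test_that("success probability is monotone in ability and practice", {
  d <- mini_design(J = 12)
  pr <- build_practice_matrix(d)
  comps <- d$components$name
  spec <- model_spec("RWOSLM", components = comps)
  alpha <- setNames(rnorm(4), comps)
  set.seed(4)
  delta <- setNames(rep(0, 4), comps)
  for (j in seq_len(d$J)) {
    l1 <- success_logit(0, alpha, delta_i = delta, w_row = d$W[j, ],
                        v_row = pr$V[j, ], spec = spec)
    l2 <- success_logit(0.5, alpha, delta_i = delta, w_row = d$W[j, ],
                        v_row = pr$V[j, ], spec = spec)
    expect_gt(l2, l1)   # strictly increasing in theta
    dplus <- delta; dplus[2] <- 0.3
    l3 <- success_logit(0, alpha, delta_i = dplus, w_row = d$W[j, ],
                        v_row = pr$V[j, ], spec = spec)
    if (pr$V[j, 2] > 0) expect_gt(l3, l1) else expect_equal(l3, l1)
  }
})

test_that("LKJ density and hyperparameter validation are correct", {
  # K = 2 identity: log density = -log integral of (1-rho^2)^(eta-1)
  expect_equal(lkj_log_density(diag(2), eta = 2), -log(4 / 3),
               tolerance = 1e-12)
  # K = 3 identity, eta = 2: normalizer validated by grid integration of
  # det(Omega) over the PD region (frozen value from that oracle)
  expect_equal(lkj_log_density(diag(3), eta = 2), -log(1.85055),
               tolerance = 1e-4)
  # density ratio between two matrices equals the det ratio
  Om <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(lkj_log_density(Om, 2) - lkj_log_density(diag(2), 2),
               log(det(Om)), tolerance = 1e-12)
  expect_error(practice_hyper(c(0, 0), c(0.5, -1)), "positive")
  h <- practice_hyper(c(0, 0), c(0.5, 2), matrix(c(1, 0.3, 0.3, 1), 2))
  expect_equal(h$Sigma, diag(c(0.5, 2)) %*% h$Omega %*% diag(c(0.5, 2)))
  expect_silent(chol(h$Sigma))
})

test_that("log prior activates exactly the spec'd densities", {
  comps <- c("a", "b")
  spec_o <- model_spec("OSLM", components = comps)
  par <- list(theta = c(0.3, -1), alpha = c(a = 1, b = -2),
              delta_fixed = c(a = 0.1, b = 0))
  lp <- log_prior(par, spec = spec_o)
  expect_equal(lp,
               sum(dnorm(par$theta, log = TRUE)) +
                 sum(dnorm(c(par$alpha, par$delta_fixed), 0, 10, log = TRUE)),
               tolerance = 1e-12)
  # random-effect model: MVN + hyper-priors, and sigma <= 0 errors
  spec_r <- model_spec("RWOSLM", components = comps)
  parr <- list(theta = 0.3, alpha = c(a = 1, b = -2),
               delta = matrix(c(0.1, -0.2), 1, 2,
                              dimnames = list(NULL, comps)))
  h <- practice_hyper(c(0, 0), c(1, 1))
  lpr <- log_prior(parr, h, spec_r)
  byhand <- dnorm(0.3, log = TRUE) + sum(dnorm(parr$alpha, 0, 10, log = TRUE)) +
    sum(dnorm(c(0.1, -0.2), 0, 1, log = TRUE)) +
    sum(dnorm(h$mu, 0, 1, log = TRUE)) +
    sum(dcauchy(h$sigma, 0, 5, log = TRUE) + log(2)) +
    lkj_log_density(diag(2), 2)
  expect_equal(lpr, byhand, tolerance = 1e-10)
  hbad <- h; hbad$sigma <- c(-1, 1)
  expect_error(log_prior(parr, hbad, spec_r), "half-Cauchy")
})

test_that("responses round-trip through wide and long CSV", {
  set.seed(11)
  data <- response_data(matrix(rbinom(20, 1, 0.5), 5, 4),
                        latencies = matrix(rlnorm(20), 5, 4))
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  write_responses(data, wide, "wide")
  write_responses(data, long, "long")
  expect_equal(read_responses(wide, "wide")$X, data$X, ignore_attr = TRUE)
  rl <- read_responses(long, "long")
  expect_equal(rl$X, data$X, ignore_attr = TRUE)
  expect_equal(rl$latencies, data$latencies, ignore_attr = TRUE)
  expect_error(response_data(matrix(c(0, 1, 2, 1), 2)), "binary")
  expect_error(response_data(matrix(c(0, 1, NA, 1), 2)), "missing")
})
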