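test_that("generated ART-like designs are identified, ordered and deterministic", {
  d <- generate_design(J = 34, seed = 1)
  expect_equal(d$J, 34); expect_equal(d$M, 8)
  expect_true(check_identification(d, build_practice_matrix(d),
                                   model_spec("RWOSLM"))$pass)
  # ordered by predicted difficulty (easiest first)
  gen <- art_generating_parameters()
  pred <- as.vector(d$W %*% gen$alpha[d$components$name])
  expect_true(all(diff(pred) >= 0))
  # seed-determinism, and provenance recorded
  expect_identical(generate_design(J = 34, seed = 1)$W, d$W)
  expect_false(identical(generate_design(J = 34, seed = 2)$W, d$W))
  expect_equal(attr(d, "provenance")$seed, 1)
  # too few items for 2M + 1 effects
  expect_error(generate_design(J = 5), "identify")
})

test_that("generated persons have the stated distribution", {
  gen <- art_generating_parameters()
  p <- generate_persons(50000, gen, seed = 2)
  expect_lt(abs(mean(p$theta)), 3 / sqrt(50000))
  expect_lt(abs(sd(p$theta) - 1), 0.02)
  # sample covariance of delta within 5% (Frobenius) of Sigma
  Sig <- diag(gen$sigma_delta) %*% gen$Omega_delta %*% diag(gen$sigma_delta)
  S <- cov(p$delta)
  expect_lt(norm(S - Sig, "F") / norm(Sig, "F"), 0.05)
  # degenerate limit: sigma -> 0 gives delta = mu for everyone
  gen0 <- gen
  gen0$sigma_delta[] <- 1e-12
  p0 <- generate_persons(5, gen0, seed = 3)
  expect_equal(unname(p0$delta[1, ]), unname(gen$mu_delta), tolerance = 1e-6)
})

test_that("simulated responses follow the forward model", {
  gen <- art_generating_parameters()
  d <- generate_design(J = 34, seed = 4)
  pr <- build_practice_matrix(d)
  # saturation
  psat <- structure(list(theta = rep(30, 5),
                         delta = matrix(0, 5, 2, dimnames =
                                          list(NULL, names(gen$mu_delta))),
                         n = 5), class = "oslm_persons")
  Xsat <- simulate_responses(d, psat, gen, pr, seed = 5, latencies = FALSE)
  expect_true(all(Xsat$X == 1))
  # empirical item means track model probabilities at n = 20000
  p <- generate_persons(20000, gen, seed = 6)
  data <- simulate_responses(d, p, gen, pr, seed = 7, latencies = FALSE)
  spec <- oslm:::gen_model_spec(gen)
  par <- list(theta = p$theta, alpha = gen$alpha,
              delta_fixed = gen$delta_fixed, delta = p$delta)
  probs <- colMeans(plogis(oslm:::logit_matrix(par, d, pr, spec)))
  expect_lt(max(abs(colMeans(data$X) - probs)), 0.015)
  # seed-determinism
  data2 <- simulate_responses(d, p, gen, pr, seed = 7, latencies = FALSE)
  expect_identical(data$X, data2$X)
})

test_that("latency filter excludes exactly the sub-threshold persons", {
  lat <- rbind(c(0.5, 2.0, 3.1), c(1.2, 5, 2), c(9, 9, 0.99))
  data <- response_data(matrix(1, 3, 3) * cbind(c(1, 0, 1), c(0, 1, 1), 1),
                        latencies = lat)
  fl <- latency_filter(data)
  expect_equal(fl$n_excluded, 2)             # persons 1 and 3
  expect_equal(fl$excluded_ids, c(1, 3))
  expect_equal(fl$data$n, 1)
  # all latencies >= 1: zero exclusions
  ok <- response_data(matrix(1, 2, 3), latencies = matrix(2, 2, 3))
  expect_equal(latency_filter(ok)$n_excluded, 0)
  expect_error(latency_filter(response_data(matrix(1, 2, 3))), "no-filter")
  # exclusion fraction tracks the contamination rate on synthetic data
  gen <- art_generating_parameters()
  d <- generate_design(J = 34, seed = 8)
  p <- generate_persons(3000, gen, seed = 9)
  data <- simulate_responses(d, p, gen, seed = 10, contamination = 0.065)
  fr <- latency_filter(data)$fraction_excluded
  expect_lt(abs(fr - 0.065), 0.02)
})

test_that("external measures hit their target correlations", {
  gen <- art_generating_parameters()
  p <- generate_persons(50000, gen, seed = 11)
  ext <- generate_external_measures(p, seed = 12, generating = gen)
  expect_lt(abs(cor(ext$GTB, p$theta) - 0.513), 0.02)
  expect_lt(abs(cor(ext$GTB, p$delta[, "A/S"]) - 0.254), 0.02)
  expect_lt(abs(cor(ext$GTB, p$delta[, "distortion"]) - 0.221), 0.02)
  # all-zero targets: independence
  null_spec <- external_measure_spec(
    matrix(0, 1, 3, dimnames = list("null", c("theta", "A/S", "distortion"))))
  e0 <- generate_external_measures(p, null_spec, gen, seed = 13)
  expect_lt(abs(cor(e0$null, p$theta)), 3 / sqrt(50000))
  # target r = 1 with zero noise: affine transform of theta
  one_spec <- external_measure_spec(
    matrix(c(1, 0, 0), 1, 3,
           dimnames = list("copy", c("theta", "A/S", "distortion"))))
  e1 <- generate_external_measures(p, one_spec, gen, seed = 14)
  expect_equal(cor(e1$copy, p$theta), 1, tolerance = 1e-12)
  # infeasible targets rejected
  bad <- external_measure_spec(
    matrix(c(0.9, 0.9, 0.9), 1, 3,
           dimnames = list("bad", c("theta", "A/S", "distortion"))))
  expect_error(generate_external_measures(p, bad, gen, seed = 15),
               "infeasible")
})

test_that("simulate_study wires the pieces together with provenance", {
  st <- simulate_study(n = 200, J = 34, seed = 21)
  expect_equal(st$raw_data$n, 200)
  expect_equal(st$data$n, 200 - st$filter$n_excluded)
  expect_equal(nrow(st$external), st$data$n)
  expect_equal(length(st$persons_kept$theta), st$data$n)
  expect_equal(attr(st$raw_data, "provenance")$seed, 23)
  # deterministic
  st2 <- simulate_study(n = 200, J = 34, seed = 21)
  expect_identical(st$data$X, st2$data$X)
})
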