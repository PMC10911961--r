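test_that("model specs reproduce the pooling/covariate grid", {
  flags <- t(vapply(0:6, function(m) {
    s <- hmm_spec(m)
    c(s$pool_state, s$pool_obs, s$cov_state, s$cov_obs)
  }, logical(4)))
  expect_equal(flags[, 1], c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(flags[, 2], c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(flags[, 3], c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(flags[, 4], c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("forward likelihood, Viterbi and posteriors match exhaustive enumeration", {
  set.seed(10)
  for (i in 1:40) {
    T_ <- sample(2:8, 1)
    inst <- rand_instance(T_)
    fit <- manual_hmm(inst$delta, inst$Gamma, inst$mu, inst$sigma,
                      inst$rho, inst$kappa)
    oracle <- enum_hmm(inst$delta, inst$Gamma, inst$L)
    ll <- log_likelihood(list(delta = inst$delta, Gamma = inst$Gamma,
                              mu = inst$mu, sigma = inst$sigma,
                              rho = inst$rho, kappa = inst$kappa),
                         inst$steps)
    expect_equal(ll, oracle$loglik, tolerance = 1e-10)
    expect_equal(viterbi_decode(fit, inst$steps)[[1]],
                 unname(oracle$path))
    post <- local_probabilities(fit, inst$steps)[[1]]
    expect_lt(max(abs(post - oracle$posterior)), 1e-10)
  }
})

test_that("single-point edge cases follow Bayes' rule", {
  inst <- rand_instance(1)
  # T = 1: likelihood is the state-mixture density, posterior is Bayes
  ll <- log_likelihood(list(delta = inst$delta, Gamma = inst$Gamma,
                            mu = inst$mu, sigma = inst$sigma,
                            rho = inst$rho, kappa = inst$kappa), inst$steps)
  mix <- logsumexp(log(inst$delta) + inst$L[1, ])
  expect_equal(ll, mix, tolerance = 1e-12)
  fit <- manual_hmm(inst$delta, inst$Gamma, inst$mu, inst$sigma,
                    inst$rho, inst$kappa)
  post <- local_probabilities(fit, inst$steps)[[1]]
  expected <- exp(log(inst$delta) + inst$L[1, ] - mix)
  expect_equal(as.numeric(post), expected, tolerance = 1e-12)
  expect_equal(viterbi_decode(fit, inst$steps)[[1]],
               which.max(log(inst$delta) + inst$L[1, ]))
})

test_that("likelihood is invariant under joint state relabelling", {
  set.seed(11)
  inst <- rand_instance(6)
  p1 <- list(delta = inst$delta, Gamma = inst$Gamma, mu = inst$mu,
             sigma = inst$sigma, rho = inst$rho, kappa = inst$kappa)
  p2 <- list(delta = rev(inst$delta),
             Gamma = inst$Gamma[2:1, 2:1],
             mu = rev(inst$mu), sigma = rev(inst$sigma),
             rho = rev(inst$rho), kappa = rev(inst$kappa))
  expect_equal(log_likelihood(p1, inst$steps), log_likelihood(p2, inst$steps),
               tolerance = 1e-12)
})

test_that("smoothing rows sum to 1 and agree with filtering at the last point", {
  set.seed(12)
  inst <- rand_instance(30)
  fit <- manual_hmm(inst$delta, inst$Gamma, inst$mu, inst$sigma,
                    inst$rho, inst$kappa)
  sm <- local_probabilities(fit, inst$steps)[[1]]
  fl <- local_probabilities(fit, inst$steps, type = "filtered")[[1]]
  expect_equal(rowSums(sm), rep(1, 30), tolerance = 1e-12)
  expect_equal(rowSums(fl), rep(1, 30), tolerance = 1e-12)
  expect_equal(sm[30, ], fl[30, ], tolerance = 1e-10)
})

test_that("Viterbi breaks exact ties toward the lower state index", {
  # identical emissions and a symmetric chain: every sequence is equally
  # likely, so the decoded path must collapse to state 1 throughout
  steps <- data.frame(track_id = "tie", t = 1:5,
                      step_km = rep(0.01, 5),
                      angle_rad = c(NA, rep(0.2, 4)),
                      dist_colony_km = rep(1, 5),
                      behaviour = NA_character_, stringsAsFactors = FALSE)
  class(steps) <- c("step_series", "data.frame")
  fit <- manual_hmm(c(0.5, 0.5), matrix(0.5, 2, 2),
                    mu = c(0.01, 0.01), sigma = c(0.005, 0.005),
                    rho = c(0, 0), kappa = c(2, 2))
  expect_equal(viterbi_decode(fit, steps)[[1]], rep(1L, 5))
})

test_that("with near-uniform transitions Viterbi is the pointwise max-density state", {
  set.seed(13)
  inst <- rand_instance(50)
  fit <- manual_hmm(c(0.5, 0.5), matrix(0.5, 2, 2), inst$mu, inst$sigma,
                    inst$rho, inst$kappa)
  v <- viterbi_decode(fit, inst$steps)[[1]]
  expect_equal(v, unname(apply(inst$L, 1, which.max)))
})

test_that("fitting recovers parameters and dominates the truth on a small run", {
  ds <- small_dataset(n_tracks = 3, track_length_s = 600, seed = 21)
  steps <- lapply(ds$tern_tracks, track_to_steps)
  fit <- fit_hmm(0, steps, n_restarts = 2, seed = 1, compute_se = FALSE)
  expect_equal(fit$n_params, 11)
  expect_true(is.finite(fit$loglik))
  truth <- list(delta = c(0.5, 0.5),
                Gamma = matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE),
                mu = c(0.005, 0.020), sigma = c(0.003, 0.008),
                rho = c(0, 0), kappa = c(1, 20))
  expect_gte(fit$loglik, log_likelihood(truth, steps))
  st <- fit$par$step[[1]]
  expect_lt(max(abs(st$mu - truth$mu) / truth$mu), 0.25)
  # determinism given the seed
  fit2 <- fit_hmm(0, steps, n_restarts = 2, seed = 1, compute_se = FALSE)
  expect_identical(fit$theta, fit2$theta)
})

test_that("per-track model variants demand at least two tracks and add parameters", {
  ds <- small_dataset(n_tracks = 2, track_length_s = 400, seed = 22)
  steps <- lapply(ds$tern_tracks, track_to_steps)
  expect_error(fit_hmm(1, steps[1], n_restarts = 1, seed = 1), "at least 2")
  expect_error(fit_hmm(3, steps[1], n_restarts = 1, seed = 1), "at least 2")
  f1 <- fit_hmm(1, steps, n_restarts = 1, seed = 1, compute_se = FALSE,
                maxit = 150)
  # Model 1, 2 tracks: 2 deltas + 2x2 transition + 4 step + 4 angle = 14
  expect_equal(f1$n_params, 14)
  f2 <- fit_hmm(2, steps, n_restarts = 1, seed = 1, compute_se = FALSE,
                maxit = 150)
  # Model 2, 2 tracks: 1 delta + 2 transition + 2x4 step + 4 angle = 15
  expect_equal(f2$n_params, 15)
})

test_that("state labelling picks the smaller-mean state as foraging", {
  fit <- manual_hmm(c(0.5, 0.5), matrix(0.5, 2, 2), mu = c(0.005, 0.02),
                    sigma = c(0.003, 0.008), rho = c(0, 0), kappa = c(1, 20))
  expect_equal(unname(label_states(fit)), c("foraging", "not_foraging"))
  fit$par$step[[1]]$mu <- c(0.02, 0.005)
  expect_equal(unname(label_states(fit)), c("not_foraging", "foraging"))
  fit$par$step[[1]]$mu <- c(0.01, 0.01)
  expect_error(label_states(fit), "ambiguous")
})

test_that("AIC follows 2k - 2logLik", {
  fake <- structure(list(n_params = 11, loglik = 0), class = "fitted_hmm")
  expect_equal(aic(fake), 22)
  fake$loglik <- -10; fake$n_params <- 12
  expect_equal(aic(fake), 44)
})

test_that("decode emits aligned per-step rows with foraging probabilities", {
  ds <- small_dataset(n_tracks = 2, track_length_s = 300, seed = 23)
  steps <- lapply(ds$tern_tracks, track_to_steps)
  fit <- fit_hmm(0, steps, n_restarts = 1, seed = 2, compute_se = FALSE)
  dec <- decode(fit, steps)
  expect_equal(nrow(dec), sum(vapply(steps, nrow, integer(1))))
  expect_true(all(dec$prob_foraging >= 0 & dec$prob_foraging <= 1))
  expect_setequal(unique(dec$label), c("foraging", "not_foraging"))
  expect_equal(unique(dec$track_id),
               vapply(steps, function(s) s$track_id[1], character(1)))
})

test_that("fitted models serialise to JSON with their key quantities", {
  ds <- small_dataset(n_tracks = 2, track_length_s = 200, seed = 24)
  steps <- lapply(ds$tern_tracks, track_to_steps)
  fit <- fit_hmm(0, steps, n_restarts = 1, seed = 3, compute_se = FALSE)
  f <- tempfile(fileext = ".json")
  write_fitted_json(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$model_id, 0)
  expect_equal(back$n_params, 11)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(unlist(back$theta), fit$theta, tolerance = 1e-12)
})
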