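#' Model specifications 0-6
#'
#' The model suite varies (i) whether the state process (initial
#' distribution and transition probabilities) and the observed process
#' (gamma step-length parameters) are pooled across tracks or estimated
#' per track, and (ii) whether the distance-to-colony covariate enters the
#' transition probabilities and/or the step-length mean and sd:
#'
#' | model | state pooled | step pooled | covariate on state | on step |
#' |------:|:---:|:---:|:---:|:---:|
#' | 0 | yes | yes | no | no |
#' | 1 | no  | yes | no | no |
#' | 2 | yes | no  | no | no |
#' | 3 | no  | no  | no | no |
#' | 4 | yes | yes | yes | no |
#' | 5 | yes | yes | no | yes |
#' | 6 | yes | yes | yes | yes |
#'
#' Turning-angle parameters are always pooled. The number of states is 2
#' by default (foraging = shorter steps, not-foraging = longer steps).
#'
#' @param model_id integer 0-6.
#' @param N number of states (the model suite is designed for 2).
#' @return an object of class `hmm_spec`.
#' @export
hmm_spec <- function(model_id, N = 2) {
  stopifnot(length(model_id) == 1, model_id %in% 0:6)
  pool_state <- !(model_id %in% c(1, 3))
  pool_obs <- !(model_id %in% c(2, 3))
  cov_state <- model_id %in% c(4, 6)
  cov_obs <- model_id %in% c(5, 6)
  structure(list(model_id = model_id, N = N,
                 pool_state = pool_state, pool_obs = pool_obs,
                 cov_state = cov_state, cov_obs = cov_obs),
            class = "hmm_spec")
}

#' Short human-readable model description
#' @param model_id integer 0-6.
#' @return character.
#' @export
model_description <- function(model_id) {
  c("Complete pool", "No pool on transition", "No pool on step",
    "No pool on transition and step", "Covariate on transition",
    "Covariate on step", "Covariate on transition and step")[model_id + 1]
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("<hmm_spec> Model", x$model_id, "-", model_description(x$model_id),
      paste0("(N = ", x$N, ")\n"))
  invisible(x)
}

# ---- working-parameter layout ----------------------------------------------

# The likelihood is maximised over an unconstrained working vector:
#   delta   : multinomial logit, N-1 per block
#   trans   : beta0 (and beta1 when the covariate is on) per off-diagonal
#   step    : log mu, log sigma per state, or free (beta0, beta1) pairs for
#             the log-linear covariate model
#   angle   : rho free (wrapped on use), log kappa
# Per-track blocks repeat the delta/trans and/or step blocks K times.
.layout <- function(spec, K) {
  N <- spec$N
  n_off <- N * (N - 1)
  kd <- if (spec$pool_state) 1 else K
  ko <- if (spec$pool_obs) 1 else K
  len_delta <- N - 1
  len_trans <- n_off * (1 + spec$cov_state)
  len_step <- 2 * N * (1 + spec$cov_obs)
  len_angle <- 2 * N
  sizes <- c(rep(len_delta, kd), rep(len_trans, kd), rep(len_step, ko),
             len_angle)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  idx <- Map(seq, starts, ends)
  list(N = N, K = K, kd = kd, ko = ko, n_off = n_off,
       delta = idx[seq_len(kd)],
       trans = idx[kd + seq_len(kd)],
       step = idx[2 * kd + seq_len(ko)],
       angle = idx[[2 * kd + ko + 1]],
       n_par = ends[length(ends)])
}

.theta_names <- function(spec, lay) {
  N <- lay$N
  off <- character(0)
  for (i in seq_len(N)) for (j in seq_len(N)) if (i != j)
    off <- c(off, paste0(i, j))
  nm <- character(lay$n_par)
  for (b in seq_len(lay$kd)) {
    pre <- if (lay$kd == 1) "" else paste0("tr", b, ".")
    nm[lay$delta[[b]]] <- paste0(pre, "delta", seq_len(N - 1))
    tn <- paste0(pre, "beta0.", off)
    if (spec$cov_state) tn <- c(tn, paste0(pre, "beta1.", off))
    nm[lay$trans[[b]]] <- tn
  }
  for (b in seq_len(lay$ko)) {
    pre <- if (lay$ko == 1) "" else paste0("tr", b, ".")
    if (spec$cov_obs) {
      sn <- c(paste0(pre, "mu.beta0.", seq_len(N)),
              paste0(pre, "mu.beta1.", seq_len(N)),
              paste0(pre, "sd.beta0.", seq_len(N)),
              paste0(pre, "sd.beta1.", seq_len(N)))
    } else {
      sn <- c(paste0(pre, "logmu", seq_len(N)),
              paste0(pre, "logsigma", seq_len(N)))
    }
    nm[lay$step[[b]]] <- sn
  }
  nm[lay$angle] <- c(paste0("rho", seq_len(N)), paste0("logkappa", seq_len(N)))
  nm
}

.softmax_delta <- function(w) {
  e <- exp(c(0, w))
  e / sum(e)
}

.unpack <- function(theta, spec, lay) {
  N <- lay$N
  delta <- lapply(lay$delta, function(ix) .softmax_delta(theta[ix]))
  trans <- lapply(lay$trans, function(ix) {
    v <- theta[ix]
    b0 <- v[seq_len(lay$n_off)]
    b1 <- if (spec$cov_state) v[lay$n_off + seq_len(lay$n_off)] else
      rep(0, lay$n_off)
    transition_model(b0, b1, N)
  })
  step <- lapply(lay$step, function(ix) {
    v <- theta[ix]
    if (spec$cov_obs) {
      list(cov = TRUE,
           mu_b0 = v[seq_len(N)], mu_b1 = v[N + seq_len(N)],
           sd_b0 = v[2 * N + seq_len(N)], sd_b1 = v[3 * N + seq_len(N)])
    } else {
      list(cov = FALSE, mu = exp(v[seq_len(N)]), sigma = exp(v[N + seq_len(N)]))
    }
  })
  av <- theta[lay$angle]
  list(delta = delta, trans = trans, step = step,
       rho = wrap_angle(av[seq_len(N)]), kappa = exp(av[N + seq_len(N)]))
}

# ---- likelihood machinery ---------------------------------------------------

# T x N matrix of log f_j(x_t); missing leading angle contributes the step
# factor only.
.emission_ldens <- function(r, psi, stepp, rho, kappa, cvec) {
  N <- length(rho)
  T_ <- length(r)
  L <- matrix(0, T_, N)
  for (j in seq_len(N)) {
    if (isTRUE(stepp$cov)) {
      mu <- exp(stepp$mu_b0[j] + stepp$mu_b1[j] * cvec)
      sg <- exp(stepp$sd_b0[j] + stepp$sd_b1[j] * cvec)
    } else {
      mu <- stepp$mu[j]
      sg <- stepp$sigma[j]
    }
    # working parameters can under/overflow during line search; signal an
    # invalid point with -Inf rather than erroring
    if (any(!is.finite(mu)) || any(!is.finite(sg)) ||
        any(mu <= 0) || any(sg <= 0) || !is.finite(kappa[j])) {
      L[] <- -Inf
      return(L)
    }
    ld <- suppressWarnings(
      stats::dgamma(r, shape = (mu / sg)^2, rate = mu / sg^2, log = TRUE))
    la <- vonmises_logpdf(psi, rho[j], kappa[j])
    la[is.na(psi)] <- 0
    L[, j] <- ld + la
  }
  L
}

# Transition structure for one track: either a constant matrix or per-time
# off-diagonal probabilities (2-state fast path) / an array (general N).
# The transition into time t is evaluated at the covariate of time t - 1.
.gamma_struct <- function(tm, cvec, N) {
  if (is.matrix(tm)) return(list(const = TRUE, G = tm))
  if (!tm$covariate_enabled) {
    return(list(const = TRUE, G = transition_matrix(tm, 0)))
  }
  if (N == 2) {
    gp <- .trans_probs_2state(tm$beta0, tm$beta1, cvec)
    list(const = FALSE, g12 = gp[, 1], g21 = gp[, 2])
  } else {
    T_ <- length(cvec)
    A <- array(NA_real_, c(N, N, T_))
    for (t in seq_len(T_)) A[, , t] <- transition_matrix(tm, cvec[t])
    list(const = FALSE, A = A)
  }
}

# Scaled forward recursion; returns the log-likelihood. With store = TRUE
# also returns the scaled forward variables and scale factors for smoothing.
.forward <- function(L, delta, gs, store = FALSE) {
  T_ <- nrow(L); N <- ncol(L)
  m <- apply(L, 1, max)
  E <- exp(L - m)
  ll <- 0
  if (T_ == 1) {
    v <- delta * E[1, ]
    s <- sum(v)
    ll <- log(s) + m[1]
    if (!store) return(ll)
    return(list(ll = ll, phi = matrix(v / s, 1, N), scl = s, E = E, m = m))
  }
  if (N == 2 && !store) {
    e1 <- E[, 1]; e2 <- E[, 2]
    p1 <- delta[1] * e1[1]; p2 <- delta[2] * e2[1]
    s <- p1 + p2
    ll <- log(s) + m[1]
    p1 <- p1 / s; p2 <- p2 / s
    if (gs$const) {
      g11 <- gs$G[1, 1]; g12 <- gs$G[1, 2]
      g21 <- gs$G[2, 1]; g22 <- gs$G[2, 2]
      for (t in 2:T_) {
        a1 <- (p1 * g11 + p2 * g21) * e1[t]
        a2 <- (p1 * g12 + p2 * g22) * e2[t]
        s <- a1 + a2
        ll <- ll + log(s) + m[t]
        p1 <- a1 / s; p2 <- a2 / s
      }
    } else {
      g12 <- gs$g12; g21 <- gs$g21
      for (t in 2:T_) {
        a1 <- (p1 * (1 - g12[t - 1]) + p2 * g21[t - 1]) * e1[t]
        a2 <- (p1 * g12[t - 1] + p2 * (1 - g21[t - 1])) * e2[t]
        s <- a1 + a2
        ll <- ll + log(s) + m[t]
        p1 <- a1 / s; p2 <- a2 / s
      }
    }
    return(ll)
  }
  phi <- matrix(NA_real_, T_, N)
  scl <- numeric(T_)
  v <- delta * E[1, ]
  scl[1] <- sum(v)
  phi[1, ] <- v / scl[1]
  ll <- log(scl[1]) + m[1]
  for (t in 2:T_) {
    G <- if (gs$const) gs$G else if (N == 2) {
      matrix(c(1 - gs$g12[t - 1], gs$g21[t - 1],
               gs$g12[t - 1], 1 - gs$g21[t - 1]), 2, 2)
    } else gs$A[, , t - 1]
    v <- (phi[t - 1, ] %*% G) * E[t, ]
    scl[t] <- sum(v)
    phi[t, ] <- v / scl[t]
    ll <- ll + log(scl[t]) + m[t]
  }
  if (store) list(ll = ll, phi = phi, scl = scl, E = E, m = m) else ll
}

# Natural-parameter set for one track; `tm` may be a transition_model or a
# fixed matrix.
.track_ll <- function(steps, delta, tm, stepp, rho, kappa, cvec) {
  L <- .emission_ldens(steps$step_km, steps$angle_rad, stepp, rho, kappa, cvec)
  gs <- .gamma_struct(tm, cvec, length(delta))
  .forward(L, delta, gs)
}

#' HMM log-likelihood at given parameters
#'
#' Evaluates the (scaled-forward) log-likelihood of one or more step/angle
#' series under explicit natural parameters, summing over tracks. Mostly
#' useful for checking fitted models or computing the likelihood at known
#' (e.g. simulation) parameters; [fit_hmm()] maximises this internally.
#'
#' @param params list with elements `delta` (length-N simplex), `Gamma`
#'   (N x N matrix) or `trans` (a [transition_model()]), `mu`, `sigma`,
#'   `rho`, `kappa` (length-N vectors).
#' @param data a `step_series` or list of them.
#' @param cov_centre,cov_scale standardisation of the distance-to-colony
#'   covariate used when `trans` has non-zero slopes.
#' @return log-likelihood (scalar).
#' @export
log_likelihood <- function(params, data, cov_centre = 0, cov_scale = 1) {
  if (inherits(data, "step_series")) data <- list(data)
  tm <- if (!is.null(params$Gamma)) params$Gamma else params$trans
  stepp <- list(cov = FALSE, mu = params$mu, sigma = params$sigma)
  ll <- 0
  for (steps in data) {
    cvec <- (steps$dist_colony_km - cov_centre) / cov_scale
    ll <- ll + .track_ll(steps, params$delta, tm, stepp,
                         params$rho, params$kappa, cvec)
  }
  ll
}

# ---- fitting ----------------------------------------------------------------

.init_theta <- function(spec, lay, data, restart, rng_perturb) {
  r <- unlist(lapply(data, function(s) s$step_km))
  psi <- unlist(lapply(data, function(s) s$angle_rad))
  psi <- psi[!is.na(psi)]
  med <- stats::median(r)
  lo <- r[r <= med]; hi <- r[r > med]
  mu0 <- c(mean(lo), mean(hi))
  sg0 <- c(stats::sd(lo), stats::sd(hi))
  sg0[!is.finite(sg0) | sg0 <= 0] <- mu0[!is.finite(sg0) | sg0 <= 0] / 2
  rbar <- sqrt(mean(cos(psi))^2 + mean(sin(psi))^2)
  khat <- .kappa_from_rbar(rbar)
  k0 <- c(max(0.3, 0.4 * khat), max(1.5, 1.8 * khat))
  N <- lay$N
  if (N != 2) { # generic spread over N quantile bins
    qs <- stats::quantile(r, probs = (seq_len(N) - 0.5) / N)
    mu0 <- as.numeric(qs); sg0 <- rep(stats::sd(r), N)
    k0 <- rep(max(0.5, khat), N)
  }
  theta <- numeric(lay$n_par)
  for (b in seq_len(lay$kd)) {
    theta[lay$delta[[b]]] <- 0
    tv <- rep(stats::qlogis(0.1), lay$n_off)
    if (spec$cov_state) tv <- c(tv, rep(0, lay$n_off))
    theta[lay$trans[[b]]] <- tv
  }
  for (b in seq_len(lay$ko)) {
    if (spec$cov_obs) {
      theta[lay$step[[b]]] <- c(log(mu0), rep(0, N), log(sg0), rep(0, N))
    } else {
      theta[lay$step[[b]]] <- c(log(mu0), log(sg0))
    }
  }
  theta[lay$angle] <- c(rep(0, N), log(k0))
  if (restart > 1) theta <- theta + rng_perturb(length(theta))
  theta
}

#' Fit a movement HMM by maximum likelihood
#'
#' Maximises the scaled-forward log-likelihood of gamma step-length /
#' von Mises turning-angle observations over unconstrained working
#' parameters (log scale for mu, sigma, kappa; multinomial logit for the
#' initial distribution; free coefficients for the transition and
#' log-linear step covariate models), using quasi-Newton optimisation with
#' multiple data-driven, seed-perturbed starting values. The best restart
#' by log-likelihood is returned.
#'
#' @param spec an [hmm_spec()] or a model id 0-6.
#' @param data a `step_series` or list of them (per-track models require at
#'   least two tracks).
#' @param n_restarts number of starting values (the first is data-driven,
#'   the rest are perturbations of it).
#' @param seed integer seed controlling the perturbations; the fit is
#'   deterministic given the seed.
#' @param standardise_covariate centre/scale the distance-to-colony
#'   covariate by its pooled mean/sd before it enters the linear predictors.
#' @param cov_centre,cov_scale explicit standardisation constants
#'   (overriding the pooled empirical ones); useful when the covariate
#'   scale is known by design.
#' @param compute_se compute standard errors from the numerical Hessian at
#'   the optimum.
#' @param maxit,reltol optimiser control.
#' @return an object of class `fitted_hmm` with elements `spec`, `theta`
#'   (named working parameters), `par` (natural parameters), `loglik`,
#'   `n_params`, `se`, `convergence`, `restart_best`, `cov_centre`,
#'   `cov_scale`, `cov_median`.
#' @export
fit_hmm <- function(spec, data, n_restarts = 25, seed = 1,
                    standardise_covariate = TRUE,
                    cov_centre = NULL, cov_scale = NULL,
                    compute_se = TRUE, maxit = 500, reltol = 1e-8) {
  if (!inherits(spec, "hmm_spec")) spec <- hmm_spec(spec)
  if (inherits(data, "step_series")) data <- list(data)
  stopifnot(length(data) >= 1)
  K <- length(data)
  if ((!spec$pool_state || !spec$pool_obs) && K < 2) {
    stop("Model ", spec$model_id,
         " estimates per-track parameters and requires at least 2 tracks")
  }
  dall <- unlist(lapply(data, function(s) s$dist_colony_km))
  if (is.null(cov_centre)) {
    cov_centre <- if (standardise_covariate) mean(dall) else 0
  }
  if (is.null(cov_scale)) {
    cov_scale <- if (standardise_covariate) max(stats::sd(dall), 1e-8) else 1
  }
  cvecs <- lapply(data, function(s) (s$dist_colony_km - cov_centre) / cov_scale)
  lay <- .layout(spec, K)
  nms <- .theta_names(spec, lay)

  nll <- function(theta) {
    p <- .unpack(theta, spec, lay)
    ll <- 0
    for (k in seq_len(K)) {
      kd <- if (spec$pool_state) 1 else k
      ko <- if (spec$pool_obs) 1 else k
      lk <- .track_ll(data[[k]], p$delta[[kd]], p$trans[[kd]], p$step[[ko]],
                      p$rho, p$kappa, cvecs[[k]])
      if (!is.finite(lk)) return(1e10)
      ll <- ll + lk
    }
    -ll
  }

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, n_restarts)
  fits <- vector("list", n_restarts)
  for (rs in seq_len(n_restarts)) {
    set.seed(seeds[rs])
    theta0 <- .init_theta(spec, lay, data, rs,
                          function(n) stats::rnorm(n, 0, 0.4))
    fits[[rs]] <- tryCatch(
      stats::optim(theta0, nll, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  ok <- ok & vapply(fits, function(f) isTRUE(is.finite(f$value)) &&
                      f$value < 1e9, logical(1))
  if (!any(ok)) stop("all ", n_restarts, " restarts failed to converge")
  vals <- vapply(fits, function(f) if (is.null(f)) Inf else f$value, numeric(1))
  vals[!ok] <- Inf
  best <- which.min(vals)
  opt <- fits[[best]]
  theta <- stats::setNames(opt$par, nms)
  se <- rep(NA_real_, length(theta))
  if (compute_se) {
    H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V)) {
        dg <- diag(V)
        se <- ifelse(dg > 0, sqrt(dg), NA_real_)
      }
    }
  }
  names(se) <- nms
  structure(
    list(spec = spec, K = K, theta = theta,
         par = .unpack(opt$par, spec, lay),
         loglik = -opt$value, n_params = lay$n_par, se = se,
         convergence = opt$convergence, restart_best = best,
         restart_seeds = seeds, seed = seed,
         cov_centre = cov_centre, cov_scale = cov_scale,
         cov_median = stats::median((dall - cov_centre) / cov_scale),
         track_ids = vapply(data, function(s) s$track_id[1], character(1))),
    class = "fitted_hmm")
}

#' Build a fitted-model object from explicit parameters
#'
#' Wraps known natural parameters (e.g. simulation truth) in a
#' `fitted_hmm` so the decoding functions ([viterbi_decode()],
#' [local_probabilities()], [decode()]) can be used without fitting.
#'
#' @param delta initial state distribution.
#' @param Gamma N x N transition matrix, or a [transition_model()].
#' @param mu,sigma,rho,kappa state-dependent distribution parameters.
#' @param cov_centre,cov_scale covariate standardisation (used only with a
#'   covariate-enabled transition model).
#' @return a `fitted_hmm` (with `loglik` and `se` unset).
#' @export
manual_hmm <- function(delta, Gamma, mu, sigma, rho, kappa,
                       cov_centre = 0, cov_scale = 1) {
  N <- length(delta)
  structure(
    list(spec = hmm_spec(0, N = N), K = 1,
         theta = NULL,
         par = list(delta = list(delta),
                    trans = list(Gamma),
                    step = list(list(cov = FALSE, mu = mu, sigma = sigma)),
                    rho = rho, kappa = kappa),
         loglik = NA_real_, n_params = NA_integer_, se = NULL,
         convergence = NA_integer_, restart_best = NA_integer_,
         seed = NA_integer_,
         cov_centre = cov_centre, cov_scale = cov_scale, cov_median = 0,
         track_ids = character(0)),
    class = "fitted_hmm")
}

#' @export
print.fitted_hmm <- function(x, ...) {
  cat("<fitted_hmm> Model", x$spec$model_id, "-",
      model_description(x$spec$model_id), "\n")
  cat("  tracks:", x$K, " logLik:", format(x$loglik, digits = 8),
      " params:", x$n_params, " AIC:", format(aic(x), digits = 8), "\n")
  st <- x$par$step[[1]]
  if (!st$cov) {
    cat("  mu:", format(st$mu, digits = 4),
        " sigma:", format(st$sigma, digits = 4), "\n")
  }
  cat("  rho:", format(x$par$rho, digits = 3),
      " kappa:", format(x$par$kappa, digits = 4), "\n")
  invisible(x)
}

#' Akaike information criterion of a fitted HMM
#' @param fitted a `fitted_hmm`.
#' @return AIC = 2 * n_params - 2 * loglik.
#' @export
aic <- function(fitted) 2 * fitted$n_params - 2 * fitted$loglik

# Per-track parameter pieces and covariate vector for decoding.
.track_pieces <- function(fitted, data) {
  spec <- fitted$spec
  K <- length(data)
  lapply(seq_len(K), function(k) {
    kd <- if (spec$pool_state) 1 else k
    ko <- if (spec$pool_obs) 1 else k
    cvec <- (data[[k]]$dist_colony_km - fitted$cov_centre) / fitted$cov_scale
    list(delta = fitted$par$delta[[kd]], tm = fitted$par$trans[[kd]],
         stepp = fitted$par$step[[ko]], cvec = cvec)
  })
}

#' Viterbi (global) decoding
#'
#' Most likely joint state sequence per track, computed in log space. Ties
#' are broken toward the lower state index.
#'
#' @param fitted a `fitted_hmm`.
#' @param data the `step_series` (or list) the model was fitted to.
#' @return list of integer state vectors, one per track.
#' @export
viterbi_decode <- function(fitted, data) {
  if (inherits(data, "step_series")) data <- list(data)
  pieces <- .track_pieces(fitted, data)
  lapply(seq_along(data), function(k) {
    pc <- pieces[[k]]
    steps <- data[[k]]
    L <- .emission_ldens(steps$step_km, steps$angle_rad, pc$stepp,
                         fitted$par$rho, fitted$par$kappa, pc$cvec)
    gs <- .gamma_struct(pc$tm, pc$cvec, length(pc$delta))
    .viterbi_path(L, pc$delta, gs)
  })
}

.viterbi_path <- function(L, delta, gs) {
  T_ <- nrow(L); N <- ncol(L)
  lG <- if (gs$const) log(gs$G) else NULL
  v <- log(delta) + L[1, ]
  if (T_ == 1) return(which.max(v))
  bp <- matrix(0L, T_, N)
  for (t in 2:T_) {
    G <- if (gs$const) lG else if (N == 2) {
      log(matrix(c(1 - gs$g12[t - 1], gs$g21[t - 1],
                   gs$g12[t - 1], 1 - gs$g21[t - 1]), 2, 2))
    } else log(gs$A[, , t - 1])
    vn <- numeric(N)
    for (j in seq_len(N)) {
      cand <- v + G[, j]
      b <- which.max(cand)   # first max = lowest state index on ties
      bp[t, j] <- b
      vn[j] <- cand[b] + L[t, j]
    }
    v <- vn
  }
  path <- integer(T_)
  path[T_] <- which.max(v)
  for (t in T_:2) path[t - 1] <- bp[t, path[t]]
  path
}

#' Local (forward-backward) state probabilities
#'
#' Per-time-point posterior state probabilities. `type = "smoothed"`
#' conditions on the whole track, P(S_t = j | x_(1:T)); `"filtered"`
#' conditions on the past only, P(S_t = j | x_(1:t)).
#'
#' @inheritParams viterbi_decode
#' @param type `"smoothed"` (default) or `"filtered"`.
#' @return list of T x N matrices with rows summing to 1.
#' @export
local_probabilities <- function(fitted, data, type = c("smoothed", "filtered")) {
  type <- match.arg(type)
  if (inherits(data, "step_series")) data <- list(data)
  pieces <- .track_pieces(fitted, data)
  lapply(seq_along(data), function(k) {
    pc <- pieces[[k]]
    steps <- data[[k]]
    L <- .emission_ldens(steps$step_km, steps$angle_rad, pc$stepp,
                         fitted$par$rho, fitted$par$kappa, pc$cvec)
    gs <- .gamma_struct(pc$tm, pc$cvec, length(pc$delta))
    fw <- .forward(L, pc$delta, gs, store = TRUE)
    if (type == "filtered") return(fw$phi)
    T_ <- nrow(L); N <- ncol(L)
    if (T_ == 1) return(fw$phi)
    beta <- matrix(NA_real_, T_, N)
    beta[T_, ] <- 1
    for (t in (T_ - 1):1) {
      G <- if (gs$const) gs$G else if (N == 2) {
        matrix(c(1 - gs$g12[t], gs$g21[t], gs$g12[t], 1 - gs$g21[t]), 2, 2)
      } else gs$A[, , t]
      beta[t, ] <- (G %*% (fw$E[t + 1, ] * beta[t + 1, ])) / fw$scl[t + 1]
    }
    post <- fw$phi * beta
    post / rowSums(post)
  })
}

#' Label the fitted states as foraging / not-foraging
#'
#' The state with the smaller fitted mean step length is labelled foraging
#' (slow, tortuous flight); the other not-foraging. With the covariate on
#' the step mean, means are compared at the median (standardised)
#' covariate value; with per-track step parameters, per-track means are
#' averaged first.
#'
#' @param fitted a `fitted_hmm` with 2 states.
#' @return named character vector mapping state index to label.
#' @export
label_states <- function(fitted) {
  stopifnot(fitted$spec$N == 2)
  mus <- vapply(fitted$par$step, function(st) {
    if (st$cov) exp(st$mu_b0 + st$mu_b1 * fitted$cov_median) else st$mu
  }, numeric(2))
  mu <- rowMeans(matrix(mus, nrow = 2))
  if (mu[1] == mu[2]) {
    stop("states have identical mean step lengths; labelling is ambiguous")
  }
  f <- which.min(mu)
  out <- c("not_foraging", "not_foraging")
  out[f] <- "foraging"
  stats::setNames(out, paste0("state", 1:2))
}

#' Decode tracks into a tidy table
#'
#' Runs Viterbi and local decoding and returns one row per step with the
#' decoded state, its foraging/not-foraging label, and the local
#' probability of the foraging-labelled state.
#'
#' @inheritParams viterbi_decode
#' @param type local-probability type passed to [local_probabilities()].
#' @return data.frame `track_id, t, viterbi_state, label, prob_foraging`.
#' @export
decode <- function(fitted, data, type = "smoothed") {
  if (inherits(data, "step_series")) data <- list(data)
  vit <- viterbi_decode(fitted, data)
  lp <- local_probabilities(fitted, data, type = type)
  labs <- label_states(fitted)
  f_state <- which(labs == "foraging")
  do.call(rbind, lapply(seq_along(data), function(k) {
    data.frame(track_id = data[[k]]$track_id[1],
               t = data[[k]]$t,
               viterbi_state = vit[[k]],
               label = unname(labs[vit[[k]]]),
               prob_foraging = lp[[k]][, f_state],
               stringsAsFactors = FALSE)
  }))
}

#' Serialise a fitted HMM to JSON
#' @param fitted a `fitted_hmm`.
#' @param path output path.
#' @export
write_fitted_json <- function(fitted, path) {
  obj <- list(model_id = fitted$spec$model_id,
              N = fitted$spec$N, K = fitted$K,
              theta = as.list(fitted$theta),
              se = as.list(fitted$se),
              loglik = fitted$loglik, n_params = fitted$n_params,
              aic = aic(fitted), convergence = fitted$convergence,
              seed = fitted$seed, restart_best = fitted$restart_best,
              cov_centre = fitted$cov_centre, cov_scale = fitted$cov_scale,
              track_ids = fitted$track_ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
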