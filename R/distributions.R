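#' Gamma log-density, mean/sd parametrisation
#'
#' Step lengths are modelled by a gamma distribution parametrised by its
#' mean `mu` and standard deviation `sigma`, the usual convention in
#' movement HMMs. Internally shape = (mu/sigma)^2 and rate = mu/sigma^2.
#'
#' @param r step length(s), km, > 0.
#' @param mu,sigma mean and sd, > 0.
#' @return log-density, vectorised.
#' @export
gamma_logpdf_meansd <- function(r, mu, sigma) {
  if (any(r <= 0) || any(mu <= 0) || any(sigma <= 0)) {
    stop("gamma_logpdf_meansd requires r, mu, sigma > 0")
  }
  shape <- (mu / sigma)^2
  rate <- mu / sigma^2
  stats::dgamma(r, shape = shape, rate = rate, log = TRUE)
}

#' von Mises log-density
#'
#' Turning angles are modelled by a von Mises distribution with mean
#' direction `rho` and concentration `kappa`:
#' log f = kappa*cos(psi - rho) - log(2*pi*I0(kappa)). Evaluated with the
#' exponentially scaled Bessel function so large concentrations do not
#' overflow. `kappa = 0` gives the circular uniform density.
#'
#' @param psi angle(s), radians in (-pi, pi].
#' @param rho mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return log-density, vectorised.
#' @export
vonmises_logpdf <- function(psi, rho, kappa) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  kappa * cos(psi - rho) - log(2 * pi) - log_i0
}

#' Build a transition model
#'
#' Off-diagonal transition probabilities follow a multinomial-logit link
#' with linear predictors eta_ij = beta0_ij + beta1_ij * c (eta_ii = 0),
#' where `c` is the (standardised) distance-to-colony covariate. For two
#' states this is exactly the per-off-diagonal logistic model
#' gamma_12 = logistic(beta0_12 + beta1_12 c), etc. With the covariate
#' disabled, beta1 is fixed at zero and the matrix is constant.
#'
#' @param beta0 numeric vector of intercepts for the off-diagonal entries,
#'   in row-major order (for N = 2: `c(eta12, eta21)`).
#' @param beta1 covariate slopes, same layout; default all zero.
#' @param N number of states.
#' @return an object of class `transition_model`.
#' @export
transition_model <- function(beta0, beta1 = NULL, N = 2) {
  n_off <- N * (N - 1)
  stopifnot(length(beta0) == n_off)
  if (is.null(beta1)) beta1 <- rep(0, n_off)
  stopifnot(length(beta1) == n_off)
  structure(list(N = N, beta0 = beta0, beta1 = beta1,
                 covariate_enabled = any(beta1 != 0)),
            class = "transition_model")
}

#' Evaluate the transition probability matrix at a covariate value
#'
#' @param tm a [transition_model()], or a numeric vector of intercepts.
#' @param c covariate value (ignored when slopes are all zero); scalar.
#' @return N x N row-stochastic matrix.
#' @export
transition_matrix <- function(tm, c = 0) {
  if (!inherits(tm, "transition_model")) tm <- transition_model(tm)
  N <- tm$N
  eta <- matrix(0, N, N)
  k <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) {
      k <- k + 1
      eta[i, j] <- tm$beta0[k] + tm$beta1[k] * c
    }
  }
  ex <- exp(eta)
  ex / rowSums(ex)
}

# Vectorised 2-state off-diagonal transition probabilities over a covariate
# vector; returns cbind(gamma12, gamma21).
.trans_probs_2state <- function(beta0, beta1, cvec) {
  cbind(stats::plogis(beta0[1] + beta1[1] * cvec),
        stats::plogis(beta0[2] + beta1[2] * cvec))
}

# Inverse of the mean-resultant-length function A(kappa) = I1/I0, the
# standard series approximation; used only for data-driven starting values.
.kappa_from_rbar <- function(rbar) {
  if (is.na(rbar) || rbar <= 0) return(0.1)
  if (rbar >= 0.999) rbar <- 0.999
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}
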