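# Independent brute-force oracles for the HMM recursions: enumerate all N^T
# state sequences and sum/maximise their joint densities directly.

# log-densities computed straight from the distribution formulas (not via
# the package's emission builder)
oracle_ldens <- function(r, psi, mu, sigma, rho, kappa) {
  N <- length(mu)
  L <- matrix(0, length(r), N)
  for (j in seq_len(N)) {
    ld <- dgamma(r, shape = (mu[j] / sigma[j])^2, rate = mu[j] / sigma[j]^2,
                 log = TRUE)
    la <- kappa[j] * cos(psi - rho[j]) - log(2 * pi * besselI(kappa[j], 0))
    la[is.na(psi)] <- 0
    L[, j] <- ld + la
  }
  L
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Enumerate all sequences; returns loglik, the MAP path and the smoothed
# posterior matrix.
enum_hmm <- function(delta, Gamma, L) {
  T_ <- nrow(L); N <- ncol(L)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  logp <- apply(seqs, 1, function(s) {
    lp <- log(delta[s[1]]) + L[1, s[1]]
    if (T_ > 1) for (t in 2:T_) {
      lp <- lp + log(Gamma[s[t - 1], s[t]]) + L[t, s[t]]
    }
    lp
  })
  loglik <- logsumexp(logp)
  post <- matrix(0, T_, N)
  w <- exp(logp - loglik)
  for (t in seq_len(T_)) for (j in seq_len(N)) {
    post[t, j] <- sum(w[seqs[, t] == j])
  }
  list(loglik = loglik, path = seqs[which.max(logp), ],
       posterior = post / rowSums(post))
}

# Random 2-state instance: parameters plus synthetic step/angle data in a
# step_series data.frame (first angle missing, as in real tracks).
rand_instance <- function(T_) {
  mu <- sort(exp(runif(2, log(0.002), log(0.05))))
  sigma <- mu * runif(2, 0.3, 1)
  rho <- runif(2, -pi, pi)
  kappa <- runif(2, 0, 10)
  delta <- as.numeric(rdirichlet2())
  Gamma <- rbind(rdirichlet2(), rdirichlet2())
  r <- exp(runif(T_, log(0.001), log(0.06)))
  psi <- c(NA, runif(T_ - 1, -pi, pi))
  if (T_ == 1) psi <- NA_real_
  steps <- data.frame(track_id = "toy", t = seq_len(T_), step_km = r,
                      angle_rad = psi, dist_colony_km = rep(1, T_),
                      behaviour = NA_character_, stringsAsFactors = FALSE)
  class(steps) <- c("step_series", "data.frame")
  list(delta = delta, Gamma = Gamma, mu = mu, sigma = sigma, rho = rho,
       kappa = kappa, steps = steps,
       L = oracle_ldens(r, psi, mu, sigma, rho, kappa))
}

rdirichlet2 <- function() {
  g <- rgamma(2, 1) + 0.05
  g / sum(g)
}
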