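#' Simulation configuration
#'
#' Defaults emulate the visual-tracking study conditions: 1 s fixes, a
#' two-state switching flight (state 1 foraging: short tortuous steps;
#' state 2 not-foraging: long directionally persistent steps), a colony on
#' the UK east coast, and a following boat kept roughly 50-200 m from the
#' bird. The default movement regime (mu = 5 and 20 m per second, sd 3 and
#' 8 m, kappa = 1 and 20, switching probability 0.05 giving ~20 s dwell
#' times) spans realistic tern flight speeds of ~5-20 m/s with clearly
#' separated states; it is a design choice, not an estimate from field
#' data.
#'
#' @param n_tracks number of tracks.
#' @param track_length_s track duration, seconds.
#' @param cadence_s sampling cadence, seconds (nominal 1).
#' @param delta initial state distribution.
#' @param trans_beta0 logit intercepts for (gamma12, gamma21).
#' @param trans_beta1 covariate slopes on the standardised
#'   distance-to-colony (0 disables the covariate effect).
#' @param mu,sigma gamma step mean and sd per state, km (foraging mean must
#'   be the smaller).
#' @param rho,kappa von Mises turning-angle mean and concentration per state.
#' @param colony_lon,colony_lat colony coordinates, degrees.
#' @param start_dist_km distance from the colony at which tracks start.
#' @param cov_centre_km,cov_scale_km standardisation of distance-to-colony
#'   used inside the generator's covariate effect (so the generating slope
#'   is on a known standardised scale).
#' @param boat_target_km standoff distance the boat tries to keep, km.
#' @param boat_smooth heading-smoothing weight in \[0, 1): 0 = pure
#'   pursuit, larger = smoother boat turning.
#' @param boat_speed_cap_km maximum boat step per second, km.
#' @param boat_jitter_sd_km sd of positional jitter added to boat fixes, km.
#' @param label_noise_rate probability an observed label is flipped.
#' @param seed default seed for [make_dataset()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tracks = 10, track_length_s = 2000, cadence_s = 1,
                       delta = c(0.5, 0.5),
                       trans_beta0 = stats::qlogis(c(0.05, 0.05)),
                       trans_beta1 = c(0, 0),
                       mu = c(0.005, 0.020), sigma = c(0.003, 0.008),
                       rho = c(0, 0), kappa = c(1, 20),
                       colony_lon = -1.533, colony_lat = 55.333,
                       start_dist_km = 1,
                       cov_centre_km = 5, cov_scale_km = 3,
                       boat_target_km = 0.1, boat_smooth = 0.7,
                       boat_speed_cap_km = 0.04, boat_jitter_sd_km = 0,
                       label_noise_rate = 0, seed = 1) {
  cfg <- list(n_tracks = n_tracks, track_length_s = track_length_s,
              cadence_s = cadence_s, delta = delta,
              trans_beta0 = trans_beta0, trans_beta1 = trans_beta1,
              mu = mu, sigma = sigma, rho = rho, kappa = kappa,
              colony_lon = colony_lon, colony_lat = colony_lat,
              start_dist_km = start_dist_km,
              cov_centre_km = cov_centre_km, cov_scale_km = cov_scale_km,
              boat_target_km = boat_target_km, boat_smooth = boat_smooth,
              boat_speed_cap_km = boat_speed_cap_km,
              boat_jitter_sd_km = boat_jitter_sd_km,
              label_noise_rate = label_noise_rate, seed = seed)
  if (any(cfg$mu <= 0) || any(cfg$sigma <= 0) || any(cfg$kappa < 0)) {
    stop("mu and sigma must be positive and kappa non-negative")
  }
  if (cfg$mu[1] >= cfg$mu[2]) {
    stop("the foraging state (1) must have the smaller mean step length")
  }
  if (cfg$label_noise_rate < 0 || cfg$label_noise_rate >= 0.5) {
    stop("label_noise_rate must be in [0, 0.5)")
  }
  if (cfg$boat_smooth < 0 || cfg$boat_smooth >= 1) {
    stop("boat_smooth must be in [0, 1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) wrapped-Cauchy rejection sampler; `kappa = 0`
#' falls back to the circular uniform.
#'
#' @param n number of draws.
#' @param rho mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, rho = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa)) return(rep(wrap_angle(rho), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0
  while (got < n) {
    need <- n - got
    u1 <- stats::runif(need); u2 <- stats::runif(need); u3 <- stats::runif(need)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nf <- sum(ok)
    if (nf > 0) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[got + seq_len(nf)] <- th
      got <- got + nf
    }
  }
  wrap_angle(out + rho)
}

#' Simulate one bird track from the two-state movement model
#'
#' Runs the state process (Markov chain, optionally with the
#' distance-to-colony covariate on the transition probabilities), draws
#' gamma step lengths and von Mises turning angles conditional on the
#' state, and advances positions on the sphere with
#' [destination_point()]: heading(t) = heading(t-1) + angle(t), first
#' heading uniform. The transition into step t is evaluated at the
#' standardised distance-to-colony of the previous step's starting fix,
#' matching the fitting convention.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (NULL = continue the current RNG stream).
#' @param track_id identifier.
#' @return list with `track` (a [geo_track()] whose fix behaviours are the
#'   true state labels) and `states` (integer vector, one per step).
#' @export
simulate_tern_track <- function(config, seed = NULL, track_id = "sim1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_fix <- floor(config$track_length_s / config$cadence_s) + 1
  n_step <- n_fix - 1
  lon <- numeric(n_fix); lat <- numeric(n_fix)
  start_bearing <- stats::runif(1, 0, 2 * pi)
  p0 <- destination_point(config$colony_lon, config$colony_lat,
                          start_bearing, config$start_dist_km)
  lon[1] <- p0[1]; lat[1] <- p0[2]
  states <- integer(n_step)
  heading <- stats::runif(1, 0, 2 * pi)
  covariate_on <- any(config$trans_beta1 != 0)
  G0 <- transition_matrix(transition_model(config$trans_beta0), 0)
  states[1] <- sample(1:2, 1, prob = config$delta)
  prev_c <- NA_real_
  for (t in seq_len(n_step)) {
    if (t > 1) {
      if (covariate_on) {
        gp <- .trans_probs_2state(config$trans_beta0, config$trans_beta1,
                                  prev_c)
        G <- matrix(c(1 - gp[1], gp[2], gp[1], 1 - gp[2]), 2, 2)
      } else G <- G0
      states[t] <- sample(1:2, 1, prob = G[states[t - 1], ])
    }
    j <- states[t]
    r <- stats::rgamma(1, shape = (config$mu[j] / config$sigma[j])^2,
                       rate = config$mu[j] / config$sigma[j]^2)
    # turning angles are counter-clockwise positive; compass headings
    # clockwise, so a positive turn decreases the heading
    if (t > 1) heading <- heading - rvonmises(1, config$rho[j], config$kappa[j])
    prev_c <- (great_circle_km(lon[t], lat[t],
                               config$colony_lon, config$colony_lat) -
               config$cov_centre_km) / config$cov_scale_km
    p <- destination_point(lon[t], lat[t], heading %% (2 * pi), r)
    lon[t + 1] <- p[1]; lat[t + 1] <- p[2]
  }
  beh <- c("foraging", "not_foraging")[c(states, states[n_step])]
  fixes <- data.frame(time = (seq_len(n_fix) - 1) * config$cadence_s,
                      lon = lon, lat = lat, behaviour = beh,
                      stringsAsFactors = FALSE)
  list(track = geo_track(track_id, fixes, config$colony_lon,
                         config$colony_lat, period = "chick_rearing"),
       states = states)
}

#' Simulate a boat following a bird track
#'
#' The boat pursues a standoff point at `boat_target_km` from the bird
#' (on the bird-to-boat side), with its heading a weighted circular mean
#' of the previous heading (weight `boat_smooth`) and the bearing to the
#' standoff point, and its speed capped at `boat_speed_cap_km` per fix.
#' The smoothed heading makes the boat's turning-angle distribution more
#' concentrated than the bird's, as an observer platform's would be. The
#' recorded `bearing` and `distance` columns are the exact boat-to-bird
#' bearing and great-circle distance at each fix, so
#' [reconstruct_track()] recovers the bird's positions.
#'
#' @param tern_track a [geo_track()] from [simulate_tern_track()].
#' @param config a [sim_config()].
#' @param seed integer seed (NULL = continue the current RNG stream).
#' @return a [geo_track()] for the boat with `bearing` and `distance`
#'   columns (behaviour labels copied from the bird track).
#' @export
simulate_boat_follow <- function(tern_track, config, seed = NULL) {
  stopifnot(inherits(tern_track, "geo_track"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  tl <- tern_track$fixes$lon; tt <- tern_track$fixes$lat
  n <- length(tl)
  w <- config$boat_smooth
  cap <- config$boat_speed_cap_km
  jsd <- config$boat_jitter_sd_km
  blon <- numeric(n); blat <- numeric(n)
  off_bearing <- stats::runif(1, 0, 2 * pi)
  p0 <- destination_point(tl[1], tt[1], off_bearing, config$boat_target_km)
  blon[1] <- p0[1]; blat[1] <- p0[2]
  heading <- initial_bearing(blon[1], blat[1], tl[1], tt[1])
  for (t in seq_len(n - 1)) {
    # standoff goal: boat_target_km from the bird's next position, on the
    # side the boat currently is
    if (tl[t + 1] == blon[t] && tt[t + 1] == blat[t]) {
      goal <- c(blon[t], blat[t])
    } else {
      btb <- initial_bearing(tl[t + 1], tt[t + 1], blon[t], blat[t])
      goal <- destination_point(tl[t + 1], tt[t + 1], btb,
                                config$boat_target_km)
    }
    d <- great_circle_km(blon[t], blat[t], goal[1], goal[2])
    align <- 1
    if (d > 0) {
      raw <- initial_bearing(blon[t], blat[t], goal[1], goal[2])
      heading <- atan2(w * sin(heading) + (1 - w) * sin(raw),
                       w * cos(heading) + (1 - w) * cos(raw)) %% (2 * pi)
      # throttle down when the smoothed heading points away from the goal
      # (a skipper slows in turns); full speed only when aligned
      align <- max(cos(heading - raw), 0)
    }
    p <- destination_point(blon[t], blat[t], heading, min(cap, d) * align)
    if (jsd > 0) {
      p <- destination_point(p[1], p[2], stats::runif(1, 0, 2 * pi),
                             abs(stats::rnorm(1, 0, jsd)))
    }
    blon[t + 1] <- p[1]; blat[t + 1] <- p[2]
  }
  same <- blon == tl & blat == tt
  bearing <- rep(0, n)
  bearing[!same] <- initial_bearing(blon[!same], blat[!same],
                                    tl[!same], tt[!same])
  distance <- great_circle_km(blon, blat, tl, tt)
  fixes <- data.frame(time = tern_track$fixes$time,
                      lon = blon, lat = blat,
                      behaviour = tern_track$fixes$behaviour,
                      bearing = bearing, distance = distance,
                      stringsAsFactors = FALSE)
  geo_track(paste0(tern_track$track_id, "_boat"), fixes,
            tern_track$colony_lon, tern_track$colony_lat,
            tern_track$colony, tern_track$species, tern_track$period)
}

#' Flip true state labels with independent observer noise
#'
#' @param true_states integer states (1 = foraging) or binary labels.
#' @param noise_rate flip probability in \[0, 0.5).
#' @param seed integer seed (NULL = continue the current RNG stream).
#' @return character labels over `{"foraging", "not_foraging"}`.
#' @export
simulate_labels <- function(true_states, noise_rate = 0, seed = NULL) {
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must be in [0, 0.5)")
  }
  if (!is.null(seed)) set.seed(seed)
  f <- .as_foraging(if (is.numeric(true_states)) true_states == 1 else
    true_states)
  flip <- stats::runif(length(f)) < noise_rate
  ifelse(xor(f, flip), "foraging", "not_foraging")
}

#' Generate a full synthetic dataset
#'
#' End-to-end generation of bird tracks, following-boat tracks and
#' observed behaviour labels, reproducible from `config$seed`. When
#' `out_dir` is given, writes `tern_tracks.csv`, `boat_tracks.csv` (with
#' bearing/distance columns) and a `manifest.json` with the seed and
#' generating parameters.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list of class `synthetic_dataset`: `tern_tracks`, `boat_tracks`
#'   (lists of [geo_track()]), `true_states` (list of integer vectors,
#'   one per step), `config`.
#' @export
make_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tern <- vector("list", config$n_tracks)
  boat <- vector("list", config$n_tracks)
  states <- vector("list", config$n_tracks)
  for (i in seq_len(config$n_tracks)) {
    sim <- simulate_tern_track(config, seed = NULL,
                               track_id = sprintf("sim%02d", i))
    labels <- simulate_labels(sim$states, config$label_noise_rate)
    tr <- sim$track
    tr$fixes$behaviour <- c(labels, labels[length(labels)])
    tern[[i]] <- tr
    boat[[i]] <- simulate_boat_follow(tr, config, seed = NULL)
    states[[i]] <- sim$states
  }
  out <- structure(list(tern_tracks = tern, boat_tracks = boat,
                        true_states = states, config = config),
                   class = "synthetic_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tracks(tern, file.path(out_dir, "tern_tracks.csv"))
    write_tracks(boat, file.path(out_dir, "boat_tracks.csv"))
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", length(x$tern_tracks), "tracks x",
      x$config$track_length_s, "s (seed", paste0(x$config$seed, ")\n"))
  invisible(x)
}
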