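# Spherical earth radius (km). The reconstruction and step-length formulas
# are written in terms of d/R; all distances in this package are km.
EARTH_RADIUS_KM <- 6371

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Great-circle (haversine) distance
#'
#' Distance between two points on a sphere of radius `radius_km`
#' (default 6371 km). Vectorised over all four coordinates.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @param radius_km sphere radius in km.
#' @return distance in km, non-negative and symmetric in its endpoints.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2, radius_km = EARTH_RADIUS_KM) {
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Initial bearing from point 1 to point 2, measured clockwise from due
#' north, in radians in \[0, 2*pi).
#'
#' @inheritParams great_circle_km
#' @return bearing in radians; coincident points are an error (the bearing
#'   is undefined there).
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  if (any(lon1 == lon2 & lat1 == lat2)) {
    stop("initial_bearing is undefined for coincident points")
  }
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  atan2(y, x) %% (2 * pi)
}

#' Destination point along a great circle
#'
#' Position reached from a start point after travelling `distance_km` along
#' the great circle with the given initial bearing. This is the formula used
#' to reconstruct the animal's position from the observer platform's
#' position plus the recorded bearing and distance to the animal:
#' \deqn{lat' = \arcsin(\sin lat \cos(d/R) + \cos lat \sin(d/R) \cos b)}
#' \deqn{lon' = lon + \mathrm{atan2}(\sin b \sin(d/R) \cos lat,\;
#'   \cos(d/R) - \sin lat \sin lat')}
#'
#' @param lon,lat start point, decimal degrees.
#' @param bearing initial bearing in radians, 0 = due north, clockwise.
#' @param distance_km great-circle distance to travel, km, >= 0.
#' @param radius_km sphere radius in km.
#' @return named numeric vector `c(lon =, lat =)`, longitude normalised to
#'   \[-180, 180\].
#' @export
destination_point <- function(lon, lat, bearing, distance_km,
                              radius_km = EARTH_RADIUS_KM) {
  if (any(distance_km < 0)) stop("distance_km must be >= 0")
  phi1 <- .deg2rad(lat)
  lam1 <- .deg2rad(lon)
  dr <- distance_km / radius_km
  sphi2 <- sin(phi1) * cos(dr) + cos(phi1) * sin(dr) * cos(bearing)
  sphi2 <- pmin(pmax(sphi2, -1), 1)
  phi2 <- asin(sphi2)
  y <- sin(bearing) * sin(dr) * cos(phi1)
  x <- cos(dr) - sin(phi1) * sphi2
  lam2 <- lam1 + atan2(y, x)
  lon2 <- .rad2deg(lam2)
  lon2 <- ((lon2 + 180) %% 360) - 180
  # keep +180 rather than -180 for the boundary case
  lon2 <- ifelse(lon2 == -180, 180, lon2)
  c(lon = unname(lon2), lat = unname(.rad2deg(phi2)))
}

#' Construct a GPS track object
#'
#' A `geo_track` bundles the timestamped fixes of one tracked individual
#' with the colony location and grouping metadata (colony, species,
#' breeding period). Fix times must be strictly increasing.
#'
#' @param track_id character identifier.
#' @param fixes data.frame with columns `time` (seconds since track start),
#'   `lon`, `lat`, and optionally `behaviour`, `bearing` (radians to the
#'   animal) and `distance` (km to the animal).
#' @param colony_lon,colony_lat colony coordinates, decimal degrees.
#' @param colony,species character grouping labels.
#' @param period `"chick_rearing"` or `"incubation"`.
#' @return an object of class `geo_track`.
#' @export
geo_track <- function(track_id, fixes, colony_lon, colony_lat,
                      colony = "colony", species = "species",
                      period = c("chick_rearing", "incubation")) {
  period <- match.arg(period)
  stopifnot(is.data.frame(fixes), nrow(fixes) >= 2,
            all(c("time", "lon", "lat") %in% names(fixes)))
  if (any(diff(fixes$time) <= 0)) {
    stop("fix times must be strictly increasing in track ", track_id)
  }
  if (any(fixes$lat < -90 | fixes$lat > 90) ||
      any(fixes$lon < -180 | fixes$lon > 180)) {
    stop("coordinates out of bounds in track ", track_id)
  }
  structure(
    list(track_id = as.character(track_id), fixes = fixes,
         colony_lon = colony_lon, colony_lat = colony_lat,
         colony = colony, species = species, period = period),
    class = "geo_track")
}

#' @export
print.geo_track <- function(x, ...) {
  cat("<geo_track>", x$track_id, "-", nrow(x$fixes), "fixes,",
      x$species, "@", x$colony, paste0("(", x$period, ")\n"))
  invisible(x)
}

#' Map ethogram labels to binary behaviour classes
#'
#' Observer-recorded flight behaviours collapse to a binary classification:
#' active search is foraging; transit search and direct flight are
#' not-foraging. Already-binary labels pass through unchanged.
#'
#' @param label character vector of ethogram or binary labels.
#' @return character vector over `{"foraging", "not_foraging"}`.
#' @export
map_ethogram <- function(label) {
  out <- character(length(label))
  known <- c(active_search = "foraging",
             transit_search = "not_foraging",
             direct_flight = "not_foraging",
             foraging = "foraging",
             not_foraging = "not_foraging")
  bad <- !is.na(label) & !(label %in% names(known))
  if (any(bad)) {
    stop("unknown behaviour label(s): ",
         paste(unique(label[bad]), collapse = ", "))
  }
  out <- unname(known[label])
  out[is.na(label)] <- NA_character_
  out
}

#' Convert a track to step lengths and turning angles
#'
#' Computes, for each pair of consecutive fixes, the great-circle step
#' length (km) and, from the second step on, the signed turning angle
#' (radians, counter-clockwise positive, wrapped to (-pi, pi\]; the first
#' angle of a track is undefined and stored as `NA`). The distance from the
#' step's starting fix to the colony is carried as a covariate, and the
#' behaviour label of the starting fix is carried per step. Exact-zero
#' steps are replaced by `zero_step_eps` km (the gamma step distribution
#' has strictly positive support) and counted.
#'
#' @param track a [geo_track()].
#' @param zero_step_eps replacement length for exact-zero steps, km.
#' @return a data.frame of class `step_series` with columns `track_id`,
#'   `t`, `step_km`, `angle_rad`, `dist_colony_km`, `behaviour`, and
#'   attributes `cadence_s` and `n_zero_steps`.
#' @export
track_to_steps <- function(track, zero_step_eps = 1e-6) {
  stopifnot(inherits(track, "geo_track"))
  fx <- track$fixes
  n <- nrow(fx)
  if (n < 3) stop("track ", track$track_id, " too short: need >= 3 fixes")
  lon <- fx$lon; lat <- fx$lat
  step <- great_circle_km(lon[-n], lat[-n], lon[-1], lat[-1])
  n_zero <- sum(step == 0)
  # zero steps have no bearing; substitute before computing headings using
  # the previous heading (a stationary fix keeps the old heading)
  step[step == 0] <- zero_step_eps
  head_ok <- !(lon[-n] == lon[-1] & lat[-n] == lat[-1])
  heading <- rep(NA_real_, n - 1)
  heading[head_ok] <- initial_bearing(lon[-n][head_ok], lat[-n][head_ok],
                                      lon[-1][head_ok], lat[-1][head_ok])
  for (i in seq_len(n - 1)[-1]) {
    if (is.na(heading[i])) heading[i] <- heading[i - 1]
  }
  # compass headings increase clockwise; negate so a left turn is positive
  angle <- c(NA_real_, wrap_angle(-diff(heading)))
  # wrap_angle maps an exact pi difference correctly; NA heading at t=1
  # (stationary first step with nothing before it) keeps angle NA
  dist_col <- great_circle_km(lon[-n], lat[-n],
                              track$colony_lon, track$colony_lat)
  beh <- if ("behaviour" %in% names(fx)) map_ethogram(fx$behaviour[-n]) else
    rep(NA_character_, n - 1)
  out <- data.frame(track_id = track$track_id,
                    t = seq_len(n - 1),
                    step_km = step,
                    angle_rad = angle,
                    dist_colony_km = dist_col,
                    behaviour = beh,
                    stringsAsFactors = FALSE)
  attr(out, "cadence_s") <- stats::median(diff(fx$time))
  attr(out, "n_zero_steps") <- n_zero
  class(out) <- c("step_series", "data.frame")
  out
}

#' Filter tracks by duration and behavioural variety
#'
#' Drops tracks whose total tracking time does not exceed `min_duration_s`
#' (default 60 s) and tracks over which a single observed behaviour was
#' recorded throughout, returning both the kept tracks and an audit list of
#' dropped tracks with reasons.
#'
#' @param tracks list of [geo_track()] objects.
#' @param min_duration_s minimum total duration in seconds (exclusive).
#' @return list with elements `kept` (list of tracks) and `dropped`
#'   (data.frame `track_id`, `reason`).
#' @export
filter_tracks <- function(tracks, min_duration_s = 60) {
  keep <- list(); drop_id <- character(); drop_why <- character()
  for (tr in tracks) {
    dur <- max(tr$fixes$time) - min(tr$fixes$time)
    beh <- tr$fixes$behaviour
    if (dur <= min_duration_s) {
      drop_id <- c(drop_id, tr$track_id); drop_why <- c(drop_why, "too_short")
    } else if (!is.null(beh) &&
               length(unique(map_ethogram(beh[!is.na(beh)]))) <= 1) {
      drop_id <- c(drop_id, tr$track_id)
      drop_why <- c(drop_why, "single_behaviour")
    } else {
      keep[[length(keep) + 1]] <- tr
    }
  }
  list(kept = keep,
       dropped = data.frame(track_id = drop_id, reason = drop_why,
                            stringsAsFactors = FALSE))
}

#' Reconstruct the animal's track from observer bearing and distance
#'
#' Applies [destination_point()] fix-by-fix to an observer-platform track
#' carrying `bearing` (radians to the animal) and `distance` (km) columns,
#' returning a new `geo_track` at the animal's (approximate) positions.
#'
#' @param boat_track a [geo_track()] whose fixes have `bearing` and
#'   `distance` columns.
#' @return a [geo_track()] for the animal, same times and metadata.
#' @export
reconstruct_track <- function(boat_track) {
  fx <- boat_track$fixes
  if (!all(c("bearing", "distance") %in% names(fx))) {
    stop("track ", boat_track$track_id,
         " has no bearing/distance columns; cannot reconstruct")
  }
  phi1 <- .deg2rad(fx$lat); lam1 <- .deg2rad(fx$lon)
  dr <- fx$distance / EARTH_RADIUS_KM
  sphi2 <- sin(phi1) * cos(dr) + cos(phi1) * sin(dr) * cos(fx$bearing)
  sphi2 <- pmin(pmax(sphi2, -1), 1)
  y <- sin(fx$bearing) * sin(dr) * cos(phi1)
  x <- cos(dr) - sin(phi1) * sphi2
  lon2 <- .rad2deg(lam1 + atan2(y, x))
  lon2 <- ((lon2 + 180) %% 360) - 180
  fx2 <- fx
  fx2$lon <- lon2
  fx2$lat <- .rad2deg(asin(sphi2))
  fx2$bearing <- NULL; fx2$distance <- NULL
  out <- boat_track
  out$fixes <- fx2
  out$track_id <- paste0(boat_track$track_id, "_animal")
  out
}

#' Read tracks from CSV
#'
#' Reads a fix-per-row CSV with header
#' `track_id,time,lon,lat,behaviour[,bearing,distance]` into a list of
#' [geo_track()] objects. `time` may be numeric seconds or ISO-8601;
#' ISO-8601 times are converted to seconds since each track's first fix.
#'
#' @param path CSV path.
#' @param colony_lon,colony_lat colony coordinates applied to all tracks.
#' @param colony,species,period metadata applied to all tracks.
#' @return list of `geo_track`.
#' @export
read_tracks <- function(path, colony_lon, colony_lat,
                        colony = "colony", species = "species",
                        period = "chick_rearing") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("track_id", "time", "lon", "lat") %in% names(df)))
  if (!is.numeric(df$time)) {
    tm <- as.POSIXct(df$time, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    df$time <- as.numeric(tm)
  }
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    d$time <- d$time - d$time[1]
    keep <- intersect(c("time", "lon", "lat", "behaviour",
                        "bearing", "distance"), names(d))
    geo_track(d$track_id[1], d[, keep, drop = FALSE],
              colony_lon, colony_lat, colony, species, period)
  })
}

#' Write tracks to CSV
#'
#' Inverse of [read_tracks()]: one row per fix, numeric-seconds time.
#'
#' @param tracks list of [geo_track()].
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    d <- tr$fixes
    cbind(data.frame(track_id = tr$track_id, stringsAsFactors = FALSE), d)
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) {
    for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA
    d[, all_cols, drop = FALSE]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a step series to CSV
#' @param steps a `step_series` (or rbind of several).
#' @param path output path.
#' @export
write_step_series <- function(steps, path) {
  utils::write.csv(as.data.frame(steps), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a step series from CSV
#' @param path CSV written by [write_step_series()].
#' @param cadence_s sampling cadence to attach, seconds.
#' @return a `step_series` data.frame.
#' @export
read_step_series <- function(path, cadence_s = 1) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(out, "cadence_s") <- cadence_s
  class(out) <- c("step_series", "data.frame")
  out
}
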