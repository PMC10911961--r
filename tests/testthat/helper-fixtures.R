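# Shared small fixtures built in code.

# A hand-made track: fixes on a simple dog-leg east then north, 1 s cadence.
toy_track <- function(behaviour = c("active_search", "active_search",
                                    "direct_flight", "direct_flight"),
                      lat0 = 0, lon0 = 0, d_deg = 0.001) {
  fixes <- data.frame(
    time = 0:3,
    lon = c(lon0, lon0 + d_deg, lon0 + 2 * d_deg, lon0 + 2 * d_deg),
    lat = c(lat0, lat0, lat0, lat0 + d_deg),
    behaviour = behaviour,
    stringsAsFactors = FALSE)
  geo_track("toy", fixes, colony_lon = lon0, colony_lat = lat0)
}

# Small default-regime dataset reused by several fitting tests (module-level
# so it is built once per test file that needs it).
small_dataset <- function(n_tracks = 3, track_length_s = 400, seed = 42, ...) {
  make_dataset(sim_config(n_tracks = n_tracks, track_length_s = track_length_s,
                          seed = seed, ...))
}
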