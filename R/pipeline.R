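#' Run the full per-group analysis
#'
#' For each colony x species x period group of tracks: applies the track
#' filters, converts tracks to step/angle series, fits the requested model
#' variants, validates each against the observed behaviours (pooling time
#' points across the group's tracks), selects the optimal model by
#' log-loss (ties to fewer parameters; AIC is reported but not used for
#' selection unless `select_by = "aic"`), and runs the foraging-event
#' coverage analysis under the optimal model. Deterministic given `seed`.
#'
#' @param tracks list of [geo_track()] objects with behaviour labels.
#' @param model_ids model variants to fit, subset of 0:6.
#' @param seed base seed; each model's fit uses `seed + model_id`.
#' @param n_restarts restarts per fit, passed to [fit_hmm()].
#' @param min_duration_s track-duration filter threshold, seconds.
#' @param select_by `"logloss"` (default) or `"aic"` (comparison studies).
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param ... further arguments to [fit_hmm()].
#' @return list of class `run_report`: per group a list with `table`
#'   (ranked metrics), `optimal_id`, `optimal`, `decoded`, `coverage`,
#'   `per_track`, `dropped`, `fit_failures`.
#' @export
run_group_analysis <- function(tracks, model_ids = 0:6, seed = 1,
                               n_restarts = 25, min_duration_s = 60,
                               select_by = c("logloss", "aic"),
                               out_dir = NULL, ...) {
  select_by <- match.arg(select_by)
  stopifnot(length(model_ids) >= 1, all(model_ids %in% 0:6))
  keys <- vapply(tracks, function(tr)
    paste(tr$colony, tr$species, tr$period, sep = "/"), character(1))
  groups <- split(tracks, keys)
  report <- list()
  for (g in names(groups)) {
    flt <- filter_tracks(groups[[g]], min_duration_s = min_duration_s)
    if (length(flt$kept) == 0) {
      report[[g]] <- list(skipped = TRUE, reason = "no tracks passed filters",
                          dropped = flt$dropped)
      message("group ", g, " skipped: no tracks passed filters")
      next
    }
    steps <- lapply(flt$kept, track_to_steps)
    observed <- unlist(lapply(steps, function(s) s$behaviour))
    fits <- list()
    failures <- character(0)
    for (m in model_ids) {
      f <- tryCatch(
        fit_hmm(m, steps, n_restarts = n_restarts, seed = seed + m, ...),
        error = function(e) {
          failures[[length(failures) + 1]] <<-
            paste0("model ", m, ": ", conditionMessage(e))
          NULL
        })
      if (!is.null(f)) fits[[paste0("model", m)]] <- f
    }
    if (length(fits) == 0) {
      report[[g]] <- list(skipped = TRUE, reason = "all fits failed",
                          dropped = flt$dropped, fit_failures = failures)
      next
    }
    sel <- select_model(fits, steps, observed)
    if (select_by == "aic") {
      ord <- order(sel$table$aic)
      sel$table <- sel$table[ord, , drop = FALSE]
      sel$optimal_id <- sel$table$model_id[1]
      sel$optimal <- fits[[paste0("model", sel$optimal_id)]]
    }
    dec <- decode(sel$optimal, steps)
    cadence <- attr(steps[[1]], "cadence_s")
    events <- do.call(rbind, lapply(steps, function(s)
      extract_foraging_events(s$behaviour, cadence, s$track_id[1])))
    dec_by_track <- split(dec$label, dec$track_id)
    cov <- event_coverage(events, dec_by_track)
    per_track <- do.call(rbind, lapply(steps, function(s) {
      dl <- dec$label[dec$track_id == s$track_id[1]]
      cbind(data.frame(track_id = s$track_id[1], stringsAsFactors = FALSE),
            validation_metrics(s$behaviour, dl))
    }))
    grp <- strsplit(g, "/")[[1]]
    tab <- cbind(data.frame(colony = grp[1], species = grp[2],
                            period = grp[3], stringsAsFactors = FALSE),
                 sel$table)
    report[[g]] <- list(skipped = FALSE, table = tab,
                        optimal_id = sel$optimal_id, optimal = sel$optimal,
                        decoded = dec, coverage = cov, per_track = per_track,
                        dropped = flt$dropped, fit_failures = failures)
  }
  report <- structure(report, class = "run_report", seed = seed,
                      model_ids = model_ids, select_by = select_by)
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write a run report's tables to disk
#'
#' Emits `metrics.csv` (all groups, percentages), per-group decoded-state
#' CSVs, `event_coverage.csv`, and `summary.json` (optimal models, missed
#' events, seeds).
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  done <- !vapply(report, function(x) isTRUE(x$skipped), logical(1))
  tabs <- do.call(rbind, lapply(report[done], function(x) x$table))
  write_metrics_csv(tabs, file.path(out_dir, "metrics.csv"))
  ev <- do.call(rbind, lapply(names(report)[done], function(g) {
    pe <- report[[g]]$coverage$per_event
    if (nrow(pe) == 0) return(NULL)
    cbind(group = g, pe)
  }))
  if (!is.null(ev)) {
    utils::write.csv(ev, file.path(out_dir, "event_coverage.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (g in names(report)[done]) {
    fn <- file.path(out_dir, paste0("decoded_", gsub("/", "_", g), ".csv"))
    utils::write.csv(report[[g]]$decoded, fn, row.names = FALSE, quote = FALSE)
  }
  summ <- lapply(report, function(x) {
    if (isTRUE(x$skipped)) return(list(skipped = TRUE, reason = x$reason))
    list(optimal_model = x$optimal_id,
         logloss = x$table$logloss[1],
         f1_pct = 100 * x$table$f1[1],
         missed_events = x$coverage$missed_count,
         median_missed_s = x$coverage$median_missed_s,
         dropped_tracks = x$dropped$track_id,
         fit_failures = x$fit_failures)
  })
  summ$seed <- attr(report, "seed")
  summ$model_ids <- attr(report, "model_ids")
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  for (g in names(x)) {
    if (isTRUE(x[[g]]$skipped)) {
      cat(g, ": skipped (", x[[g]]$reason, ")\n", sep = "")
    } else {
      cat(g, ": optimal model ", x[[g]]$optimal_id, ", F1 = ",
          round(100 * x[[g]]$table$f1[1], 2), "%, log-loss = ",
          round(x[[g]]$table$logloss[1], 4), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Assess observer-platform tracks as proxies for the animal's track
#'
#' Reconstructs the animal's track from each boat track's bearing/distance
#' columns, fits the same model variant(s) independently to the
#' boat-derived and animal-derived step/angle series, decodes both with
#' Viterbi, aligns state labels via [label_states()], and cross-tabulates
#' the decoded behaviours (FF, FN, NF, NN; F = foraging from the boat
#' fit). Also returns step/turning-angle distribution summaries for both
#' track sets.
#'
#' @param boat_tracks list of [geo_track()] with `bearing` and `distance`
#'   fix columns.
#' @param model_ids model variants to compare, subset of 0:6.
#' @param seed base seed.
#' @param n_restarts restarts per fit.
#' @param ... further arguments to [fit_hmm()].
#' @return list of class `proxy_assessment`, one element per model:
#'   `confusion` (FF/FN/NF/NN), `agreement`, plus `summaries` (mean/sd of
#'   steps, circular variance of angles, per track set).
#' @export
run_proxy_assessment <- function(boat_tracks, model_ids = 0, seed = 1,
                                 n_restarts = 25, ...) {
  for (tr in boat_tracks) {
    if (!all(c("bearing", "distance") %in% names(tr$fixes))) {
      stop("track ", tr$track_id, " lacks bearing/distance columns; ",
           "proxy assessment needs the animal's recorded position offset")
    }
  }
  animal_tracks <- lapply(boat_tracks, reconstruct_track)
  boat_steps <- lapply(boat_tracks, track_to_steps)
  animal_steps <- lapply(animal_tracks, track_to_steps)
  circ_var <- function(steps) {
    a <- unlist(lapply(steps, function(s) s$angle_rad))
    a <- a[!is.na(a)]
    1 - sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  }
  summ <- function(steps) {
    r <- unlist(lapply(steps, function(s) s$step_km))
    list(step_mean_km = mean(r), step_sd_km = stats::sd(r),
         angle_circular_variance = circ_var(steps))
  }
  out <- list()
  for (m in model_ids) {
    fb <- fit_hmm(m, boat_steps, n_restarts = n_restarts,
                  seed = seed + m, ...)
    fa <- fit_hmm(m, animal_steps, n_restarts = n_restarts,
                  seed = seed + m, ...)
    db <- decode(fb, boat_steps)
    da <- decode(fa, animal_steps)
    b <- .as_foraging(db$label)
    a <- .as_foraging(da$label)
    conf <- c(FF = sum(b & a), FN = sum(b & !a),
              NF = sum(!b & a), NN = sum(!b & !a))
    out[[paste0("model", m)]] <- list(
      confusion = conf,
      agreement = (conf[["FF"]] + conf[["NN"]]) / sum(conf),
      boat_fit = fb, animal_fit = fa)
  }
  structure(list(models = out,
                 summaries = list(boat = summ(boat_steps),
                                  animal = summ(animal_steps))),
            class = "proxy_assessment")
}

#' @export
print.proxy_assessment <- function(x, ...) {
  for (m in names(x$models)) {
    cat(m, ": agreement ", round(100 * x$models[[m]]$agreement, 2), "% (",
        paste(names(x$models[[m]]$confusion),
              x$models[[m]]$confusion, collapse = ", "), ")\n", sep = "")
  }
  cat("boat step mean:",
      format(x$summaries$boat$step_mean_km, digits = 4), "km, circ var:",
      format(x$summaries$boat$angle_circular_variance, digits = 3), "\n")
  cat("animal step mean:",
      format(x$summaries$animal$step_mean_km, digits = 4), "km, circ var:",
      format(x$summaries$animal$angle_circular_variance, digits = 3), "\n")
  invisible(x)
}
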