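#' Confusion counts for binary foraging classification
#'
#' Cross-tabulates aligned observed and decoded binary sequences; the
#' positive class is foraging.
#'
#' @param observed,decoded equal-length character vectors over
#'   `{"foraging", "not_foraging"}` (or logicals, TRUE = foraging).
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(observed, decoded) {
  if (length(observed) != length(decoded)) {
    stop("observed (", length(observed), ") and decoded (", length(decoded),
         ") sequences differ in length")
  }
  o <- .as_foraging(observed)
  d <- .as_foraging(decoded)
  structure(list(tp = sum(o & d), fp = sum(!o & d),
                 fn = sum(o & !d), tn = sum(!o & !d)),
            class = "confusion_counts")
}

.as_foraging <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x == 1)
  x == "foraging"
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion> tp:", x$tp, " fp:", x$fp, " fn:", x$fn, " tn:", x$tn, "\n")
  invisible(x)
}

#' Positive predictive value (precision)
#'
#' Proportion of decoded-foraging points that are observed foraging,
#' tp / (tp + fp). Undefined (NA) when nothing is decoded as foraging.
#'
#' @param counts a [confusion()] result.
#' @return proportion in \[0, 1\], or NA when the denominator is zero.
#' @export
ppv <- function(counts) {
  den <- counts$tp + counts$fp
  if (den == 0) return(NA_real_)
  counts$tp / den
}

#' True positive rate (recall)
#'
#' Proportion of observed-foraging points decoded as foraging,
#' tp / (tp + fn).
#'
#' @inheritParams ppv
#' @return proportion in \[0, 1\], or NA when the denominator is zero.
#' @export
tpr <- function(counts) {
  den <- counts$tp + counts$fn
  if (den == 0) return(NA_real_)
  counts$tp / den
}

#' Negative predictive value
#'
#' Proportion of decoded-not-foraging points that are observed
#' not-foraging, tn / (tn + fn).
#'
#' @inheritParams ppv
#' @return proportion in \[0, 1\], or NA when the denominator is zero.
#' @export
npv <- function(counts) {
  den <- counts$tn + counts$fn
  if (den == 0) return(NA_real_)
  counts$tn / den
}

#' F1 score
#'
#' Harmonic mean of precision and recall, 2 * PPV * TPR / (PPV + TPR);
#' defined as 0 when both are 0.
#'
#' @param ppv,tpr proportions in \[0, 1\] (both on the same scale; passing
#'   percentages returns a percentage).
#' @return harmonic mean on the input scale.
#' @export
f1_score <- function(ppv, tpr) {
  ifelse(ppv + tpr == 0, 0, 2 * ppv * tpr / (ppv + tpr))
}

#' Logarithmic loss
#'
#' Mean negative log-likelihood of the observed binary labels under the
#' predicted foraging probabilities,
#' -mean(y * log q + (1 - y) * log(1 - q)), with probabilities clipped to
#' \[1e-12, 1 - 1e-12\].
#'
#' @param observed binary labels (character foraging/not_foraging, logical,
#'   or 0/1).
#' @param prob_foraging predicted probabilities of foraging, in \[0, 1\].
#' @param clip clipping bound.
#' @return non-negative scalar.
#' @export
log_loss <- function(observed, prob_foraging, clip = 1e-12) {
  if (length(observed) != length(prob_foraging)) {
    stop("observed and prob_foraging differ in length")
  }
  y <- as.numeric(.as_foraging(observed))
  q <- pmin(pmax(prob_foraging, clip), 1 - clip)
  -mean(y * log(q) + (1 - y) * log(1 - q))
}

#' Validation metrics for one decoded model
#'
#' @param observed observed binary labels aligned with `decoded`.
#' @param decoded decoded binary labels (e.g. Viterbi + [label_states()]).
#' @param prob_foraging local probabilities of the foraging state.
#' @param fitted optional `fitted_hmm` supplying AIC.
#' @return one-row data.frame with `ppv`, `tpr`, `npv`, `f1` (proportions),
#'   `logloss`, `aic`, `n`.
#' @export
validation_metrics <- function(observed, decoded, prob_foraging = NULL,
                               fitted = NULL) {
  cc <- confusion(observed, decoded)
  p <- ppv(cc); t <- tpr(cc)
  data.frame(
    ppv = p, tpr = t, npv = npv(cc),
    f1 = if (is.na(p) || is.na(t)) NA_real_ else f1_score(p, t),
    logloss = if (is.null(prob_foraging)) NA_real_ else
      log_loss(observed, prob_foraging),
    aic = if (is.null(fitted)) NA_real_ else aic(fitted),
    n = cc$tp + cc$fp + cc$fn + cc$tn)
}

#' Select the optimal model by log-loss
#'
#' Ranks fitted models by ascending log-loss of their local foraging
#' probabilities against the observed behaviours; the minimiser is
#' optimal, with ties broken by fewer parameters. AIC is reported
#' alongside but never used for selection.
#'
#' @param fits named list of `fitted_hmm` objects fitted to the same data.
#' @param data the common `step_series` list.
#' @param observed observed binary labels pooled across the tracks, aligned
#'   with the decoded output.
#' @return list with `optimal` (the chosen fit), `optimal_id`, and
#'   `table` (per-model metrics, ranked).
#' @export
select_model <- function(fits, data, observed) {
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop("no converged fits to select from")
  rows <- lapply(fits, function(f) {
    dec <- decode(f, data)
    cbind(data.frame(model_id = f$spec$model_id,
                     model_description = model_description(f$spec$model_id),
                     stringsAsFactors = FALSE),
          validation_metrics(observed, dec$label, dec$prob_foraging, f))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  npar <- vapply(fits, function(f) f$n_params, numeric(1))
  ord <- order(tab$logloss, npar)
  tab <- tab[ord, , drop = FALSE]
  list(optimal = fits[[ord[1]]], optimal_id = tab$model_id[1], table = tab)
}

#' Extract observed foraging events
#'
#' A foraging event is a maximal contiguous run of observed-foraging
#' labels within one track.
#'
#' @param observed binary labels of one track.
#' @param cadence_s sampling cadence, seconds per point.
#' @param track_id identifier carried into the output.
#' @return data.frame `track_id, start_index, end_index, duration_s` (one
#'   row per event; zero rows when no foraging is observed).
#' @export
extract_foraging_events <- function(observed, cadence_s = 1,
                                    track_id = "track") {
  o <- .as_foraging(observed)
  rl <- rle(o)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  keep <- rl$values
  data.frame(track_id = rep(track_id, sum(keep)),
             start_index = starts[keep],
             end_index = ends[keep],
             duration_s = rl$lengths[keep] * cadence_s,
             stringsAsFactors = FALSE)
}

#' Foraging-event coverage by the decoded states
#'
#' For each observed foraging event, the proportion of its time points
#' decoded as foraging, binned as: missed (exactly 0), (0, 25%),
#' \[25, 50%), \[50, 75%), \[75, 100%\] (an exact 25/50/75% falls in the
#' upper bin). Completely missed events are summarised by their median
#' duration.
#'
#' @param events events from [extract_foraging_events()] (possibly rbind
#'   of several tracks, in which case `decoded` must be the matching
#'   per-track list).
#' @param decoded decoded binary labels for the same track (vector), or a
#'   named list keyed by track_id.
#' @return list of class `event_coverage`: `per_event` data.frame with
#'   `prop_correct` and `bin`, `histogram` (named counts), `missed_count`,
#'   `missed_durations`, `median_missed_s`.
#' @export
event_coverage <- function(events, decoded) {
  bins <- c("missed", "(0,25%)", "[25,50%)", "[50,75%)", "[75,100%]")
  prop <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    dec <- if (is.list(decoded) && !is.null(names(decoded))) {
      decoded[[events$track_id[i]]]
    } else decoded
    win <- .as_foraging(dec[events$start_index[i]:events$end_index[i]])
    prop[i] <- mean(win)
  }
  bin <- ifelse(prop == 0, "missed",
         ifelse(prop < 0.25, "(0,25%)",
         ifelse(prop < 0.50, "[25,50%)",
         ifelse(prop < 0.75, "[50,75%)", "[75,100%]"))))
  per_event <- cbind(events, prop_correct = prop, bin = bin)
  hist <- stats::setNames(vapply(bins, function(b) sum(bin == b), integer(1)),
                          bins)
  missed <- events$duration_s[bin == "missed"]
  structure(list(per_event = per_event, histogram = hist,
                 missed_count = length(missed), missed_durations = missed,
                 median_missed_s = if (length(missed)) stats::median(missed)
                                   else NA_real_),
            class = "event_coverage")
}

#' @export
print.event_coverage <- function(x, ...) {
  cat("<event_coverage>", nrow(x$per_event), "events;",
      x$missed_count, "completely missed")
  if (x$missed_count > 0) cat(" (median", x$median_missed_s, "s)")
  cat("\n")
  print(x$histogram)
  invisible(x)
}

#' Write a validation metrics table to CSV
#'
#' Columns mirror the per-group validation-table layout:
#' `colony,species,period,model_id,model_description,ppv,tpr,npv,f1,logloss,aic`
#' with proportions reported as percentages.
#'
#' @param tab metrics table (from [select_model()], plus grouping columns).
#' @param path output path.
#' @export
write_metrics_csv <- function(tab, path) {
  out <- tab
  for (cc in intersect(c("ppv", "tpr", "npv", "f1"), names(out))) {
    out[[cc]] <- round(100 * out[[cc]], 2)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
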