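#' Extract (day, score) anchors for one scale from an assessment table
#' @keywords internal
anchor_points <- function(assessments, participant, scale_id) {
  a <- as.data.table(assessments)[participant_id == participant]
  if (!scale_id %in% names(a)) stop_alstrack("unknown scale: ", scale_id)
  a <- a[order(day)]
  list(day = a$day, score = as.numeric(a[[scale_id]]),
       date = if ("date" %in% names(a)) a$date else NULL)
}

new_pseudolabel_series <- function(participant, scale_id, method, day,
                                   value, anchors, start_date = NULL) {
  out <- data.table(participant_id = participant, scale_id = scale_id,
                    method = method, day = day, value = value)
  if (!is.null(start_date)) out[, date := start_date + day]
  setattr(out, "scale_id", scale_id)
  setattr(out, "method", method)
  setattr(out, "anchor_days", anchors$day)
  out[]
}

#' Piecewise-linear daily pseudo-labels
#'
#' Interpolates linearly between consecutive assessment anchors; before the
#' first and after the last anchor the nearest anchor value is extended
#' constantly. At every anchor day the pseudo-label equals the observed
#' score exactly.
#'
#' @param assessments assessment table (from [emit_assessments()] or
#'   equivalent, wide with one column per scale)
#' @param daily_index integer vector of day indices to label
#' @param participant participant id
#' @param scale_id scale to interpolate ("speech", ..., "composite")
#' @param start_date optional calendar date of day 0 (adds a `date` column)
#' @return a pseudo-label series data.table
#' @export
interpolate_linear <- function(assessments, daily_index, participant,
                               scale_id, start_date = NULL) {
  an <- anchor_points(assessments, participant, scale_id)
  if (length(an$day) < 2L) stop_alstrack("insufficient anchors (need >= 2)")
  v <- approx(an$day, an$score, xout = daily_index, method = "linear",
              rule = 2)$y
  rng <- scale_range(scale_id)
  new_pseudolabel_series(participant, scale_id, "linear", daily_index,
                         clip(v, rng[1], rng[2]), an, start_date)
}

#' Natural cubic spline daily pseudo-labels
#'
#' Fits a natural cubic spline through the assessment anchors (with exactly
#' two anchors this degenerates to the linear interpolant), evaluates it on
#' the daily index, extends constantly outside the anchor range and clips to
#' the scale's domain.
#'
#' @inheritParams interpolate_linear
#' @return a pseudo-label series data.table
#' @export
interpolate_cubic <- function(assessments, daily_index, participant,
                              scale_id, start_date = NULL) {
  an <- anchor_points(assessments, participant, scale_id)
  if (length(an$day) < 2L) stop_alstrack("insufficient anchors (need >= 2)")
  xq <- clip(daily_index, min(an$day), max(an$day)) # constant extension
  v <- spline(an$day, an$score, xout = xq, method = "natural")$y
  rng <- scale_range(scale_id)
  new_pseudolabel_series(participant, scale_id, "cubic", daily_index,
                         clip(v, rng[1], rng[2]), an, start_date)
}

#' Average per-channel attention estimates into one pseudo-label series
#'
#' Pointwise arithmetic mean over member series sharing one daily index.
#'
#' @param series_list list of numeric vectors (or pseudo-label series) on a
#'   common daily index
#' @param participant,scale_id,daily_index,start_date metadata for the
#'   resulting series
#' @return a pseudo-label series with method tag "attention"
#' @export
ensemble_attention <- function(series_list, participant, scale_id,
                               daily_index, start_date = NULL) {
  if (length(series_list) == 0L) stop_alstrack("empty ensemble")
  vecs <- lapply(series_list, function(s) {
    if (is.data.frame(s)) s$value else as.numeric(s)
  })
  len <- unique(vapply(vecs, length, integer(1)))
  if (length(len) != 1L || len != length(daily_index)) {
    stop_alstrack("ensemble members must share the daily index")
  }
  v <- Reduce(`+`, vecs) / length(vecs)
  an <- list(day = integer(0))
  new_pseudolabel_series(participant, scale_id, "attention", daily_index,
                         v, an, start_date)
}

#' Ensembled self-attention pseudo-labels across per-channel feature tables
#'
#' Trains one shallow self-attention interpolator per sensor channel (its
#' day/night summary statistics form the feature table) against the observed
#' scores on anchor days, evaluates each on all days, and ensembles by
#' averaging.
#'
#' @param feature_tables named list of per-channel daily feature tables
#'   (each: `date` + feature columns covering the daily index)
#' @param assessments wide assessment table
#' @param participant,scale_id target cell
#' @param daily_index day indices to label
#' @param config an [attention_config()]
#' @param start_date optional calendar date of day 0
#' @return a pseudo-label series with method tag "attention"
#' @export
interpolate_attention <- function(feature_tables, assessments, participant,
                                  scale_id, daily_index, config = attention_config(),
                                  start_date = NULL) {
  an <- anchor_points(assessments, participant, scale_id)
  if (length(an$day) < 2L) stop_alstrack("insufficient anchors (need >= 2)")
  members <- vector("list", length(feature_tables))
  for (i in seq_along(feature_tables)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, "attention", participant, scale_id,
                              names(feature_tables)[i] %||% i)
    members[[i]] <- fit_attention_interpolator(
      feature_tables[[i]], assessments, participant, scale_id, daily_index,
      cfg_i)$estimates
  }
  out <- ensemble_attention(members, participant, scale_id, daily_index,
                            start_date)
  setattr(out, "anchor_days", an$day)
  out
}
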