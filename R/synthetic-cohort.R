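#' Sensor channels emitted by the synthetic cohort generator
#'
#' Three bed-sensor (ballistocardiogram-derived) channels sampled at high
#' frequency and four passive-infrared room-motion channels recorded as
#' hourly activity counts.
#' @export
SENSOR_CHANNELS <- c(
  "respiration", "pulse", "restlessness",
  "motion_bedroom", "motion_living", "motion_kitchen", "motion_bathroom"
)

BED_CHANNELS <- c("respiration", "pulse", "restlessness")

# channel baselines are the fully-declined (latent = 0) daily means; loadings
# are per unit of the coupling latent (composite scale, 0-48 by default)
default_coupling <- function() {
  c(respiration = -0.12, pulse = -0.40, restlessness = -0.50,
    motion_bedroom = 0.15, motion_living = 0.35,
    motion_kitchen = 0.30, motion_bathroom = 0.15)
}

default_baselines <- function() {
  c(respiration = 18, pulse = 82, restlessness = 28,
    motion_bedroom = 4, motion_living = 3, motion_kitchen = 2,
    motion_bathroom = 2)
}

default_day_amplitude <- function() {
  c(respiration = 1.5, pulse = 6, restlessness = -8,
    motion_bedroom = -3, motion_living = 6, motion_kitchen = 4,
    motion_bathroom = 2)
}

#' Configuration for a synthetic ALS monitoring cohort
#'
#' Defines the study conditions the generator emulates: a small case series
#' (three participants by default) monitored continuously at home for 150-600
#' days, with ALSFRS-R assessments collected every 30 days (every third one
#' flagged as a clinic visit) and in-home sensor channels whose daily means
#' are linearly coupled to the participant's latent functional level.
#'
#' Per-scale progression profiles:
#' \describe{
#'   \item{homogeneous}{all participants share one decline rate; they differ
#'     only by a starting-level offset.}
#'   \item{heterogeneous}{participant-specific decline rates, spread over a
#'     4-fold range around the scale template.}
#'   \item{plateau-drop}{periods of stability punctuated by sudden unit
#'     drops, the shape seen in rapidly progressing functional domains.}
#' }
#'
#' @param n_participants number of participants (>= 1)
#' @param enrollment_days integer vector of per-participant monitoring
#'   lengths in days; recycled/truncated to `n_participants`. Defaults match
#'   the case-series enrollment lengths (599, 236, 219).
#' @param assessment_cadence days between ALSFRS-R assessments (default 30);
#'   day 0 (enrollment) is always assessed
#' @param clinic_every every k-th assessment is flagged as a clinic visit
#' @param profile named character vector mapping subscale name to profile;
#'   unnamed scalar applies to all subscales
#' @param rates optional named numeric: fixed template decline rate
#'   (units/day) per subscale, overriding the seeded draw
#' @param drop_days optional named list: fixed drop days per plateau-drop
#'   subscale
#' @param coupling named numeric loadings of each channel's daily mean on the
#'   coupling latent
#' @param coupling_scale which latent drives the sensors (default
#'   "composite")
#' @param baselines named numeric channel baselines (daily mean at latent 0)
#' @param noise_sd per-channel Gaussian noise SD (scalar or named); applied
#'   both to the daily mean and to intra-day samples
#' @param day_amplitude named numeric day-minus-night additive modulation per
#'   channel (mean-preserving within a day)
#' @param jitter amplitude of uniform day-to-day jitter added to latent
#'   trajectories (trajectories are monotone nonincreasing up to this)
#' @param dropout fraction of days dropped from the sensor record (default
#'   0.05), emulating gaps between enrollment length and usable days
#' @param bed_samples_per_day intra-day samples for bed channels (default
#'   1440, i.e. one per minute)
#' @param motion_samples_per_day hourly count samples for motion channels
#' @param start_date calendar date of day 0
#' @param seed master integer seed
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_participants = 3,
                          enrollment_days = c(599, 236, 219),
                          assessment_cadence = 30,
                          clinic_every = 3,
                          profile = NULL,
                          rates = NULL,
                          drop_days = NULL,
                          coupling = default_coupling(),
                          coupling_scale = "composite",
                          baselines = default_baselines(),
                          noise_sd = 1,
                          day_amplitude = default_day_amplitude(),
                          jitter = 0.05,
                          dropout = 0.05,
                          bed_samples_per_day = 1440,
                          motion_samples_per_day = 24,
                          start_date = as.Date("2023-01-01"),
                          seed = 1L) {
  if (n_participants < 1) stop_alstrack("n_participants must be >= 1")
  if (assessment_cadence < 1) stop_alstrack("assessment_cadence must be >= 1")
  if (bed_samples_per_day < 1 || motion_samples_per_day < 1) {
    stop_alstrack("sampling frequency must be positive")
  }
  enrollment_days <- rep_len(as.integer(enrollment_days), n_participants)

  # default profile mix: respiratory-domain scales and speech progress in
  # patient-specific ways, salivation shows plateau-drop shapes, the rest
  # follow cohort-level trends
  prof <- setNames(rep("homogeneous", 12L), ALSFRS_SUBSCALES)
  prof[c("speech", "dyspnea", "orthopnea", "respiratory")] <- "heterogeneous"
  prof["salivation"] <- "plateau-drop"
  if (!is.null(profile)) {
    if (is.null(names(profile)) && length(profile) == 1L) {
      prof[] <- profile
    } else {
      prof[names(profile)] <- profile
    }
  }
  bad <- setdiff(prof, c("homogeneous", "heterogeneous", "plateau-drop"))
  if (length(bad)) stop_alstrack("unknown profile: ", paste(bad, collapse = ", "))

  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    noise_sd <- setNames(rep(noise_sd, length(SENSOR_CHANNELS)), SENSOR_CHANNELS)
  }
  stopifnot(all(is.finite(coupling)), all(is.finite(noise_sd)))

  structure(list(
    n_participants = n_participants,
    participant_ids = sprintf("P%d", seq_len(n_participants)),
    enrollment_days = enrollment_days,
    assessment_cadence = as.integer(assessment_cadence),
    clinic_every = as.integer(clinic_every),
    profile = prof,
    rates = rates,
    drop_days = drop_days,
    coupling = coupling,
    coupling_scale = coupling_scale,
    baselines = baselines,
    noise_sd = noise_sd,
    day_amplitude = day_amplitude,
    jitter = jitter,
    dropout = dropout,
    bed_samples_per_day = as.integer(bed_samples_per_day),
    motion_samples_per_day = as.integer(motion_samples_per_day),
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate daily latent functional trajectories
#'
#' One trajectory per participant x scale (12 subscales plus the composite,
#' which is the subscale sum). Subscale values live on \[0, 4\] and are
#' monotone nonincreasing up to the configured jitter amplitude.
#'
#' @param config a [cohort_config()]
#' @return data.table with columns participant_id, scale_id, day, value
#' @export
simulate_latent_trajectories <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  short <- config$enrollment_days < 2 * config$assessment_cadence
  if (any(short)) {
    stop_alstrack("enrollment too short for two assessments (participants: ",
                  paste(config$participant_ids[short], collapse = ", "), ")")
  }
  n <- config$n_participants

  # per-scale template decline rates (units/day); fixed rates override
  # template decline rates calibrated so assessment-score variances over
  # study-length enrollments span the observed 0.0-2.4 range
  set.seed(derive_seed(config$seed, "latent", "templates"))
  template <- setNames(runif(12L, 0.004, 0.020), ALSFRS_SUBSCALES)
  start0 <- setNames(runif(12L, 2.8, 4.0), ALSFRS_SUBSCALES)
  if (!is.null(config$rates)) template[names(config$rates)] <- config$rates

  out <- vector("list", n * 12L)
  k <- 0L
  for (i in seq_len(n)) {
    pid <- config$participant_ids[i]
    days <- seq_len(config$enrollment_days[i]) - 1L
    D <- length(days)
    for (s in ALSFRS_SUBSCALES) {
      set.seed(derive_seed(config$seed, "latent", pid, s))
      # one participant-specific starting-level offset per scale
      start <- clip(start0[[s]] + runif(1, -0.4, 0.4), 2.0, 4.0)
      prof <- config$profile[[s]]
      if (prof == "heterogeneous") {
        # participant rates spread over a 4x range around the template;
        # capped at full-range decline over ~220 days — faster progressors
        # leave the study before declining further, and uncapped rates
        # produce bimodal score mixes with unrealistic variance
        spread <- exp(seq(-log(2), log(2), length.out = max(n, 2L)))[i]
        rate <- min(template[[s]] * spread * exp(runif(1, -0.15, 0.15)),
                    0.0205)
      } else {
        rate <- template[[s]]
      }
      if (prof == "plateau-drop") {
        # at most 3 unit drops, spread across the record: clustered drops
        # produce bimodal 4-vs-low score mixes whose variance exceeds what
        # case-series assessments show
        ndrop <- min(max(1L, round(rate * D)), 3L)
        fixed <- config$drop_days[[s]]
        drop_at <- if (!is.null(fixed)) fixed else {
          centers <- D * (0.15 + 0.7 * (seq_len(ndrop) - 0.5) / ndrop)
          sort(round(centers + runif(ndrop, -0.05 * D, 0.05 * D)))
        }
        base <- start - vapply(days, function(t) sum(drop_at <= t), numeric(1))
      } else {
        base <- start - rate * days
      }
      jit <- runif(D, -config$jitter, config$jitter)
      vals <- clip(base + jit, 0, 4)
      k <- k + 1L
      out[[k]] <- data.table(participant_id = pid, scale_id = s,
                             day = days, value = vals)
    }
  }
  traj <- rbindlist(out)
  comp <- traj[, .(scale_id = "composite", value = clip(sum(value), 0, 48)),
               by = .(participant_id, day)]
  setcolorder(comp, c("participant_id", "scale_id", "day", "value"))
  res <- rbind(traj, comp)
  setkey(res, participant_id, scale_id, day)
  res[]
}

#' Emit sparse ALSFRS-R assessment series from latent trajectories
#'
#' Assessments occur at day 0 and every `assessment_cadence` days thereafter;
#' every `clinic_every`-th assessment is flagged as a pre-clinic visit.
#' Subscale scores are the latent value clipped to \[0, 4\] then rounded
#' half-up to an integer; the composite is recomputed as the subscale sum.
#'
#' @param latent output of [simulate_latent_trajectories()]
#' @param config the [cohort_config()] used to generate it
#' @return wide data.table: participant_id, day, date, clinic, one integer
#'   column per subscale, composite
#' @export
emit_assessments <- function(latent, config) {
  subs <- latent[scale_id != "composite"]
  out <- list()
  for (i in seq_len(config$n_participants)) {
    pid <- config$participant_ids[i]
    adays <- seq(0L, config$enrollment_days[i] - 1L, by = config$assessment_cadence)
    cell <- subs[participant_id == pid & day %in% adays]
    if (!all(adays %in% cell$day)) {
      stop_alstrack("latent trajectories do not cover all assessment dates")
    }
    cell[, score := as.integer(round_half_up(clip(value, 0, 4)))]
    w <- dcast(cell, day ~ scale_id, value.var = "score")
    setcolorder(w, c("day", ALSFRS_SUBSCALES))
    w[, composite := rowSums(.SD), .SDcols = ALSFRS_SUBSCALES]
    w[, participant_id := pid]
    w[, date := config$start_date + day]
    idx <- seq_along(adays)
    w[, clinic := ((idx - 1L) %% config$clinic_every) == (config$clinic_every - 1L)]
    out[[i]] <- w
  }
  res <- rbindlist(out)
  setcolorder(res, c("participant_id", "day", "date", "clinic",
                     ALSFRS_SUBSCALES, "composite"))
  res[]
}

#' Emit high-frequency sensor streams coupled to the latent trajectories
#'
#' Each channel's daily sample mean is `baseline + loading * latent + noise`
#' where `latent` is the coupling scale's value that day and the noise is
#' Gaussian with the channel's `noise_sd`. Within a day, samples in the day
#' window are shifted up and night samples down by a mean-preserving
#' amplitude so day/night segmentation is informative, and per-sample noise
#' (same SD) is added. A seeded dropout mask removes whole days.
#'
#' @param latent output of [simulate_latent_trajectories()]
#' @param config the [cohort_config()]
#' @return data.table: participant_id, channel_id, timestamp (POSIXct UTC),
#'   value
#' @export
emit_sensor_streams <- function(latent, config) {
  cs <- config$coupling_scale
  lat <- latent[scale_id == cs]
  if (nrow(lat) == 0L) stop_alstrack("coupling scale not present in latent set")
  origin <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  out <- list()
  k <- 0L
  for (i in seq_len(config$n_participants)) {
    pid <- config$participant_ids[i]
    D <- config$enrollment_days[i]
    lv <- lat[participant_id == pid][order(day)]$value
    set.seed(derive_seed(config$seed, "dropout", pid))
    keep <- runif(D) >= config$dropout
    for (ch in SENSOR_CHANNELS) {
      nper <- if (ch %in% BED_CHANNELS) config$bed_samples_per_day else config$motion_samples_per_day
      sd_ch <- config$noise_sd[[ch]]
      set.seed(derive_seed(config$seed, "stream", pid, ch))
      mu <- config$baselines[[ch]] + config$coupling[[ch]] * lv +
        rnorm(D, 0, sd_ch)
      # sample clock times, equally spaced across the 24h day
      frac <- (seq_len(nper) - 1L) / nper
      hour <- frac * 24
      is_day <- hour >= 6 & hour < 22
      n_day <- sum(is_day)
      amp <- config$day_amplitude[[ch]]
      # mean-preserving day/night split of the modulation amplitude
      offs <- ifelse(is_day, amp * (nper - n_day) / nper, -amp * n_day / nper)
      vals <- rep(mu, each = nper) + rep(offs, times = D) +
        rnorm(D * nper, 0, sd_ch)
      dayrep <- rep(seq_len(D) - 1L, each = nper)
      ts <- origin + dayrep * 86400 + rep(frac * 86400, times = D)
      ok <- rep(keep, each = nper)
      k <- k + 1L
      out[[k]] <- data.table(participant_id = pid, channel_id = ch,
                             timestamp = ts[ok], value = vals[ok])
    }
  }
  res <- rbindlist(out)
  setkey(res, participant_id, channel_id, timestamp)
  res[]
}

#' Generate a full synthetic cohort bundle
#'
#' Composes the latent-trajectory, assessment and sensor-stream generators;
#' optionally writes the CSV fixtures plus a sidecar JSON recording the seed
#' and a config hash.
#'
#' @param config a [cohort_config()]
#' @param out_dir optional directory for `sensors.csv`, `assessments.csv`,
#'   `latent.csv` and `cohort_meta.json`
#' @return list of class `als_cohort` with elements `streams`,
#'   `assessments`, `latent`, `config`
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  latent <- simulate_latent_trajectories(config)
  assessments <- emit_assessments(latent, config)
  streams <- emit_sensor_streams(latent, config)
  cohort <- structure(list(streams = streams, assessments = assessments,
                           latent = latent, config = config),
                      class = "als_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(streams, file.path(out_dir, "sensors.csv"))
    fwrite(assessments, file.path(out_dir, "assessments.csv"))
    fwrite(latent, file.path(out_dir, "latent.csv"))
    jsonlite::write_json(
      list(seed = config$seed, config_hash = config_hash(config)),
      file.path(out_dir, "cohort_meta.json"), auto_unbox = TRUE)
  }
  cohort
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Named synthetic fixture presets
#'
#' \describe{
#'   \item{tiny}{2 participants, 60 days, 14-day cadence; generates in well
#'     under 5 seconds (reduced intra-day sampling).}
#'   \item{homogeneous}{3 participants, ~200 days, all subscales share
#'     cohort-level decline rates (participant offsets only).}
#'   \item{heterogeneous}{3 participants, ~200 days, participant-specific
#'     decline rates on every subscale (>= 2-fold spread by construction).}
#'   \item{plateau-drop}{3 participants, ~200 days, stability punctuated by
#'     sudden unit drops on every subscale.}
#' }
#'
#' @param name preset name
#' @param seed master seed
#' @param out_dir optional fixture output directory (CSV bundle)
#' @return an `als_cohort` bundle
#' @export
make_fixture <- function(name, seed = 1L, out_dir = NULL) {
  presets <- c("tiny", "homogeneous", "heterogeneous", "plateau-drop")
  if (!name %in% presets) {
    stop_alstrack("unknown preset '", name, "'; available: ",
                  paste(presets, collapse = ", "))
  }
  cfg <- switch(name,
    tiny = cohort_config(n_participants = 2, enrollment_days = 60,
                         assessment_cadence = 14,
                         bed_samples_per_day = 96, motion_samples_per_day = 24,
                         seed = seed),
    homogeneous = cohort_config(n_participants = 3,
                                enrollment_days = c(211, 181, 241),
                                profile = "homogeneous",
                                bed_samples_per_day = 144,
                                motion_samples_per_day = 24, seed = seed),
    heterogeneous = cohort_config(n_participants = 3,
                                  enrollment_days = c(211, 181, 241),
                                  profile = "heterogeneous",
                                  bed_samples_per_day = 144,
                                  motion_samples_per_day = 24, seed = seed),
    `plateau-drop` = cohort_config(n_participants = 3,
                                   enrollment_days = c(211, 181, 241),
                                   profile = "plateau-drop",
                                   bed_samples_per_day = 144,
                                   motion_samples_per_day = 24, seed = seed)
  )
  generate_cohort(cfg, out_dir = out_dir)
}
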