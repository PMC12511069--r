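test_that("latent trajectories are seeded, bounded and monotone up to jitter", {
  cfg <- cohort_config(n_participants = 3, enrollment_days = c(150, 180, 200),
                       bed_samples_per_day = 48, seed = 7)
  a <- simulate_latent_trajectories(cfg)
  b <- simulate_latent_trajectories(cfg)
  expect_identical(a, b)
  subs <- a[scale_id != "composite"]
  expect_true(all(subs$value >= 0 & subs$value <= 4))
  # nonincreasing up to twice the jitter amplitude
  incr <- subs[, max(c(diff(value), 0)), by = .(participant_id, scale_id)]$V1
  expect_true(all(incr <= 2 * cfg$jitter + 1e-9))
})

test_that("zero decline rate with no jitter gives constant trajectories", {
  cfg <- cohort_config(n_participants = 1, enrollment_days = 100,
                       profile = "homogeneous",
                       rates = setNames(rep(0, 12), ALSFRS_SUBSCALES),
                       jitter = 0, seed = 3)
  lat <- simulate_latent_trajectories(cfg)
  rngs <- lat[scale_id != "composite",
              diff(range(value)), by = scale_id]$V1
  expect_true(all(rngs == 0))
})

test_that("plateau-drop produces an abrupt step dominating daily change", {
  cfg <- cohort_config(n_participants = 1, enrollment_days = 200,
                       profile = "plateau-drop",
                       drop_days = setNames(rep(list(100), 12),
                                            ALSFRS_SUBSCALES),
                       jitter = 0.002, seed = 5)
  lat <- simulate_latent_trajectories(cfg)[scale_id == "speech"]
  step <- abs(lat[day == 101]$value - lat[day == 99]$value)
  med <- median(abs(diff(lat$value)))
  expect_gt(step, 10 * max(med, 1e-6))
})

test_that("enrollment shorter than two cadences errors", {
  cfg <- cohort_config(n_participants = 1, enrollment_days = 45,
                       assessment_cadence = 30)
  expect_error(simulate_latent_trajectories(cfg), "too short")
})

test_that("assessment schedule matches the monthly cadence with day 0 included", {
  # 219 days at a 30-day cadence gives 8 assessments: days 0, 30, ..., 210
  cfg <- cohort_config(n_participants = 1, enrollment_days = 219, seed = 2)
  lat <- simulate_latent_trajectories(cfg)
  a <- emit_assessments(lat, cfg)
  expect_equal(nrow(a), 8L)
  expect_equal(a$day, seq(0L, 210L, by = 30L))
  # every third assessment is the pre-clinic one
  expect_equal(which(a$clinic), c(3L, 6L))
})

test_that("scores are rounded half-up, clipped, and composite is the subscale sum", {
  cfg <- cohort_config(n_participants = 1, enrollment_days = 100,
                       profile = "homogeneous",
                       rates = setNames(rep(0, 12), ALSFRS_SUBSCALES),
                       jitter = 0, seed = 11)
  lat <- simulate_latent_trajectories(cfg)
  lat[scale_id != "composite", value := 4.0]
  a <- emit_assessments(lat, cfg)
  expect_true(all(as.matrix(a[, ALSFRS_SUBSCALES, with = FALSE]) == 4L))
  expect_true(all(a$composite == 48L))
  lat[scale_id == "speech", value := 2.4]
  lat[scale_id == "walking", value := 2.5]
  a2 <- emit_assessments(lat, cfg)
  expect_true(all(a2$speech == 2L))
  expect_true(all(a2$walking == 3L))
  expect_equal(a2$composite,
               rowSums(as.matrix(a2[, ALSFRS_SUBSCALES, with = FALSE])))
})

test_that("sensor daily means follow baseline + loading x latent exactly at zero noise", {
  cfg <- cohort_config(n_participants = 1, enrollment_days = 60,
                       noise_sd = 0, dropout = 0,
                       coupling = setNames(c(1, rep(0, 6)), SENSOR_CHANNELS),
                       bed_samples_per_day = 24, motion_samples_per_day = 24,
                       seed = 4)
  lat <- simulate_latent_trajectories(cfg)
  st <- emit_sensor_streams(lat, cfg)
  comp <- lat[scale_id == "composite"][order(day)]$value
  dm <- st[channel_id == "respiration",
           .(m = mean(value)), by = .(d = as.Date(timestamp, tz = "UTC"))]
  expect_equal(dm$m, cfg$baselines[["respiration"]] + 1 * comp,
               tolerance = 1e-10)
})

test_that("a zero loading decouples the channel from the latent trajectory", {
  cfg <- cohort_config(n_participants = 1, enrollment_days = 200,
                       dropout = 0,
                       coupling = setNames(rep(0, 7), SENSOR_CHANNELS),
                       bed_samples_per_day = 24, seed = 9)
  lat <- simulate_latent_trajectories(cfg)
  st <- emit_sensor_streams(lat, cfg)
  comp <- lat[scale_id == "composite"][order(day)]$value
  dm <- st[channel_id == "pulse",
           .(m = mean(value)), by = .(d = as.Date(timestamp, tz = "UTC"))]
  expect_lt(abs(cor(dm$m, comp)), 0.2)
})

test_that("streams are bit-identical under the same seed", {
  cfg <- cohort_config(n_participants = 2, enrollment_days = 70,
                       bed_samples_per_day = 24, seed = 13)
  lat <- simulate_latent_trajectories(cfg)
  expect_identical(emit_sensor_streams(lat, cfg),
                   emit_sensor_streams(lat, cfg))
})

test_that("OLS on daily means recovers the coupling loading within 3 SE", {
  cfg <- cohort_config(n_participants = 1, enrollment_days = 250,
                       dropout = 0, noise_sd = 1,
                       coupling = setNames(c(0.5, rep(0, 6)), SENSOR_CHANNELS),
                       bed_samples_per_day = 24, seed = 21)
  lat <- simulate_latent_trajectories(cfg)
  st <- emit_sensor_streams(lat, cfg)
  comp <- lat[scale_id == "composite"][order(day)]$value
  dm <- st[channel_id == "respiration",
           .(m = mean(value)), by = .(d = as.Date(timestamp, tz = "UTC"))]
  fit <- summary(lm(dm$m ~ comp))$coefficients
  expect_lt(abs(fit["comp", "Estimate"] - 0.5), 3 * fit["comp", "Std. Error"])
})

test_that("default study conditions give subscale score variances in the observed range", {
  cfg <- cohort_config(seed = 17)
  lat <- simulate_latent_trajectories(cfg)
  a <- emit_assessments(lat, cfg)
  v <- a[, lapply(.SD, var), by = participant_id,
         .SDcols = ALSFRS_SUBSCALES]
  vals <- unlist(v[, !"participant_id"])
  expect_true(all(vals >= 0 & vals <= 2.5))
})

test_that("homogeneous profiles share decline rates while heterogeneous spread them", {
  rate_spread <- function(profile, seed) {
    cfg <- cohort_config(n_participants = 3, enrollment_days = 200,
                         profile = profile, seed = seed)
    lat <- simulate_latent_trajectories(cfg)[scale_id == "swallowing"]
    rates <- lat[, -coef(lm(value ~ day))[["day"]], by = participant_id]$V1
    var(rates)
  }
  wins <- sum(vapply(1:10, function(s) {
    rate_spread("homogeneous", s) < rate_spread("heterogeneous", s)
  }, logical(1)))
  expect_gte(wins, 8)
})

test_that("generate_cohort composes the bundle and n_participants = 1 is allowed", {
  co <- make_fixture("tiny", seed = 1)
  expect_s3_class(co, "als_cohort")
  expect_equal(length(unique(co$latent$scale_id)), 13L)
  expect_equal(sort(unique(co$streams$participant_id)), c("P1", "P2"))
  one <- generate_cohort(cohort_config(n_participants = 1,
                                       enrollment_days = 70,
                                       bed_samples_per_day = 24, seed = 5))
  expect_equal(unique(one$assessments$participant_id), "P1")
})

test_that("fixture presets are deterministic and heterogeneous rates differ >= 2-fold", {
  t0 <- Sys.time()
  a <- make_fixture("tiny", seed = 4)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  b <- make_fixture("tiny", seed = 4)
  expect_identical(a$streams, b$streams)
  expect_identical(a$assessments, b$assessments)
  expect_error(make_fixture("nope"), "tiny")

  het <- make_fixture("heterogeneous", seed = 6)
  lat <- het$latent[scale_id == "respiratory"]
  rates <- lat[, -coef(lm(value ~ day))[["day"]], by = participant_id]$V1
  expect_gte(max(rates) / max(min(rates), 1e-12), 2)
})
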