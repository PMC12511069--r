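test_that("sequential splits use floor(f * N) earliest observations", {
  mk <- function(N) data.table(date = as.Date("2023-01-01") + seq_len(N))
  s10 <- split_sequential(mk(10))
  expect_equal(c(s10$n_train, s10$n_test), c(8L, 2L))
  expect_true(max(s10$train_dates) < min(s10$test_dates))
  # the case-series splits: 487 -> 389/98, 161 -> 128/33, 196 -> 156/40
  for (case in list(c(487, 389, 98), c(161, 128, 33), c(196, 156, 40))) {
    s <- split_sequential(mk(case[1]))
    expect_equal(c(s$n_train, s$n_test), case[2:3])
  }
  expect_error(split_sequential(mk(4)), "at least 5")
})

test_that("variance screening distinguishes zero, near-zero and modelable targets", {
  z <- screen_variance(rep(4, 20))
  expect_equal(z$decision, "skip")
  expect_equal(z$reason, "zero variance")
  expect_true(z$static)
  nz <- screen_variance(rnorm(20, sd = sqrt(1e-6)), epsilon = 0.01)
  expect_equal(nz$decision, "skip")
  expect_match(nz$reason, "near-zero")
  expect_false(nz$static)
  ok <- screen_variance(rnorm(20, sd = sqrt(0.5)))
  expect_equal(ok$decision, "model")
})

test_that("hyperparameter draws come only from the candidate lists, reproducibly", {
  sp <- hyperparam_space()
  d1 <- sample_hyperparams(sp, 40, seed = 3)
  d2 <- sample_hyperparams(sp, 40, seed = 3)
  expect_identical(d1, d2)
  for (nm in names(sp)) expect_true(all(d1[[nm]] %in% sp[[nm]]))
})

test_that("precision rounding grows subsets with precision and caps at the limit", {
  imp <- c(a = 0.5, b = 4e-7, c = 0)
  ps <- precision_subsets(imp)
  expect_equal(ps$subsets[[1]], "a")          # p = 6: round(4e-7, 6) == 0
  expect_equal(sort(ps$subsets[[2]]), c("a", "b")) # p = 7 admits b
  expect_false("c" %in% unlist(ps$subsets))   # zero importance never enters
  set.seed(5)
  big <- setNames(runif(250, 1e-4, 1), paste0("f", 1:250))
  cap <- precision_subsets(big, max_features = 200)
  expect_true(all(vapply(cap$subsets, length, integer(1)) <= 200))
  expect_equal(length(cap$subsets[[length(cap$subsets)]]), 200L)
})

test_that("tuning returns a screener trace and is seed-deterministic", {
  tab <- make_supervised_table(n = 60, seed = 1)
  r1 <- tune_and_select(tab, paste0("f", 1:6), n_draws = 4, seed = 11)
  r2 <- tune_and_select(tab, paste0("f", 1:6), n_draws = 4, seed = 11)
  expect_identical(r1$hyperparameters, r2$hyperparameters)
  expect_identical(r1$features, r2$features)
  expect_true(sum(r1$trace$chosen) == 1L)
  expect_true(all(diff(r1$trace$n_features) >= 0))
  expect_true("f1" %in% r1$features) # the signal feature survives screening
})

test_that("individual batch fitting learns a separable signal and refuses static targets", {
  tab <- make_supervised_table(n = 80, seed = 2, noise_sd = 0)
  art <- fit_individual_batch(tab, paste0("f", 1:6),
                              default_hp(n_estimators = 256), seed = 1)
  expect_lt(rmse(tab$label, predict_artifact(art, tab)), 0.05)
  art2 <- fit_individual_batch(tab, paste0("f", 1:6),
                               default_hp(n_estimators = 256), seed = 1)
  expect_identical(predict_artifact(art, tab), predict_artifact(art2, tab))
  flat <- copy(tab)[, label := 4]
  expect_error(fit_individual_batch(flat, paste0("f", 1:6), default_hp()),
               "zero variance")
})

test_that("cohort base training excludes the holdout and records provenance", {
  t1 <- make_supervised_table(n = 40, seed = 3, participant = "P2")
  t2 <- make_supervised_table(n = 40, seed = 4, participant = "P3")
  hold <- make_supervised_table(n = 40, seed = 5, participant = "P1")
  expect_error(fit_cohort_base(list(P2 = t1), paste0("f", 1:6), default_hp()),
               "LOPO")
  base <- fit_cohort_base(list(P2 = t1, P3 = t2), paste0("f", 1:6),
                          default_hp(), seed = 9, fold_id = "P1")
  expect_equal(base$provenance$fold, "P1")
  expect_true(verify_lopo(base, hold))
  # injecting a holdout row must fail the audit
  poisoned <- fit_cohort_base(list(P2 = rbind(t1, hold[1]), P3 = t2),
                              paste0("f", 1:6), default_hp(), seed = 9,
                              fold_id = "PX")
  expect_error(verify_lopo(poisoned, hold), "LOPO violation")
  base2 <- fit_cohort_base(list(P2 = t1, P3 = t2), paste0("f", 1:6),
                           default_hp(), seed = 9, fold_id = "P1")
  expect_identical(predict_artifact(base, hold),
                   predict_artifact(base2, hold))
})

test_that("batch fine-tuning adapts to a shifted holdout and is identity at 0 rounds", {
  t1 <- make_supervised_table(n = 50, seed = 6, participant = "P2")
  t2 <- make_supervised_table(n = 50, seed = 7, participant = "P3")
  base <- fit_cohort_base(list(P2 = t1, P3 = t2), paste0("f", 1:6),
                          default_hp(), seed = 2, fold_id = "P1")
  hold <- make_supervised_table(n = 60, seed = 8, participant = "P1")
  hold[, label := label + 3] # constant shift away from the cohort
  sp <- split_sequential(hold)
  tr <- hold[date %in% sp$train_dates]; te <- hold[date %in% sp$test_dates]
  ft0 <- finetune_batch(base, tr, rounds = 0)
  expect_identical(predict_artifact(ft0, te), predict_artifact(base, te))
  expect_equal(ft0$provenance$parent, alstrack:::artifact_hash(base))
  ft <- finetune_batch(base, tr, rounds = 64, seed = 3)
  expect_lt(rmse(te$label, predict_artifact(ft, te)),
            rmse(te$label, predict_artifact(base, te)))
  bad <- copy(tr)
  setnames(bad, "f1", "g1")
  expect_error(finetune_batch(base, bad), "mismatch")
})

test_that("incremental fine-tuning is prequentially causal", {
  t1 <- make_supervised_table(n = 40, seed = 9, participant = "P2")
  t2 <- make_supervised_table(n = 40, seed = 10, participant = "P3")
  base <- fit_cohort_base(list(P2 = t1, P3 = t2), paste0("f", 1:6),
                          default_hp(n_estimators = 32), seed = 4,
                          fold_id = "P1")
  hold <- make_supervised_table(n = 20, seed = 11, participant = "P1")
  full <- finetune_incremental(base, hold, k = 1, window = 7, seed = 5)
  # prediction at step t must not depend on rows after t
  for (t in c(5, 12)) {
    trunc <- finetune_incremental(base, hold[1:t], k = 1, window = 7, seed = 5)
    expect_equal(full$prequential$prediction[1:t],
                 trunc$prequential$prediction)
  }
  # k = 0 leaves the model untouched and predicts with the base throughout
  none <- finetune_incremental(base, hold, k = 0)
  expect_identical(none$artifact$booster_raw, base$booster_raw)
  expect_equal(none$prequential$prediction, predict_artifact(base, hold))
  shuffled <- hold[c(2, 1, 3:20)]
  expect_error(finetune_incremental(base, shuffled, k = 1), "date order")
})

test_that("incremental adaptation reduces prequential error on a stationary stream", {
  wins <- 0L
  for (s in 1:10) {
    t1 <- make_supervised_table(n = 40, seed = 100 + s, participant = "P2")
    t2 <- make_supervised_table(n = 40, seed = 200 + s, participant = "P3")
    base <- fit_cohort_base(list(P2 = t1, P3 = t2), paste0("f", 1:6),
                            default_hp(n_estimators = 32), seed = s,
                            fold_id = "P1")
    hold <- make_supervised_table(n = 40, seed = 300 + s, participant = "P1")
    hold[, label := label + 2] # stationary but offset from the cohort
    inc <- finetune_incremental(base, hold, k = 2, window = 14, seed = s)
    e <- (inc$prequential$label - inc$prequential$prediction)^2
    q <- length(e) %/% 4
    if (mean(e[(length(e) - q + 1):length(e)]) <= mean(e[1:q])) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("checkpoints round-trip exactly and detect corruption", {
  tab <- make_supervised_table(n = 50, seed = 12)
  art <- fit_individual_batch(tab, paste0("f", 1:6), default_hp(), seed = 1,
                              provenance = list(fold = "P1", scale = "speech",
                                                interpolation = "linear"))
  path <- tempfile(fileext = ".ubj")
  save_checkpoint(art, path)
  back <- load_checkpoint(path)
  probe <- make_supervised_table(n = 100, seed = 13)
  expect_identical(predict_artifact(back, probe), predict_artifact(art, probe))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$provenance$scale, "speech")
  expect_equal(side$provenance$paradigm, "individual_batch")
  # corrupt the binary: checksum must catch it
  raw <- readBin(path, "raw", file.size(path))
  raw[100] <- as.raw(bitwXor(as.integer(raw[100]), 255L))
  writeBin(raw, path)
  expect_error(load_checkpoint(path), "checksum")
  # unrecognized sidecar schema
  path2 <- tempfile()
  save_checkpoint(art, path2)
  jsonlite::write_json(list(foo = 1), paste0(path2, ".json"),
                       auto_unbox = TRUE)
  expect_error(load_checkpoint(path2), "schema")
})
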