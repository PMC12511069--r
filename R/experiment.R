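#' Experiment configuration for the end-to-end pipeline
#'
#' Gathers every knob of the pipeline: cohort source, interpolations,
#' paradigms, scales, splitting, tuning, fine-tuning, evaluation and output
#' location. One master `seed` derives every stage seed through
#' [derive_seed()], so identical config + seed reproduces the run exactly.
#'
#' @param cohort a [cohort_config()], or a preset name understood by
#'   [make_fixture()]
#' @param interpolations subset of c("linear", "cubic", "attention")
#' @param paradigms subset of c("individual_batch", "transfer_batch",
#'   "transfer_incremental")
#' @param scales scales to model (default all 12 subscales + composite)
#' @param seed master integer seed
#' @param out_dir optional output directory for CSV artifacts
#' @param paper_faithful select screener iterations on the held-out test set
#'   (the leakage-prone historical behaviour) instead of an internal
#'   validation slice; also fits min-max normalization on all rows
#' @param train_fraction sequential split fraction (default 0.8)
#' @param n_draws randomized-search draws per tuning (default 8 here; the
#'   full search in [tune_and_select()] defaults to 50)
#' @param cv_folds cross-validation folds in tuning
#' @param k_rounds boosting rounds per incremental step
#' @param window_days incremental refit window
#' @param finetune_rounds rounds for batch fine-tuning
#' @param epsilon_variance near-zero-variance screening threshold
#' @param collinearity_threshold absolute-correlation drop threshold
#' @param day_window day-period clock window (hours)
#' @param bootstrap_B RMSE bootstrap resamples per evaluated cell
#' @param attention named list of [attention_config()] overrides
#' @return an `experiment_config` list
#' @export
experiment_config <- function(cohort = cohort_config(),
                              interpolations = c("linear", "cubic", "attention"),
                              paradigms = c("individual_batch",
                                            "transfer_batch",
                                            "transfer_incremental"),
                              scales = ALSFRS_SCALES,
                              seed = 1L,
                              out_dir = NULL,
                              paper_faithful = FALSE,
                              train_fraction = 0.8,
                              n_draws = 8L,
                              cv_folds = 3L,
                              k_rounds = 1L,
                              window_days = 14L,
                              finetune_rounds = 32L,
                              epsilon_variance = 0.01,
                              collinearity_threshold = 0.95,
                              day_window = c(6, 22),
                              bootstrap_B = 1000L,
                              attention = list()) {
  if (length(interpolations) == 0L) stop_alstrack("need at least one interpolation")
  if (length(paradigms) == 0L) stop_alstrack("need at least one paradigm")
  if (length(scales) == 0L) stop_alstrack("need at least one scale")
  bad <- setdiff(interpolations, c("linear", "cubic", "attention"))
  if (length(bad)) stop_alstrack("unknown interpolation: ", paste(bad, collapse = ", "))
  bad <- setdiff(paradigms, c("individual_batch", "transfer_batch",
                              "transfer_incremental"))
  if (length(bad)) stop_alstrack("unknown paradigm: ", paste(bad, collapse = ", "))
  bad <- setdiff(scales, ALSFRS_SCALES)
  if (length(bad)) stop_alstrack("unknown scale: ", paste(bad, collapse = ", "))
  structure(list(cohort = cohort, interpolations = interpolations,
                 paradigms = paradigms, scales = scales,
                 seed = as.integer(seed), out_dir = out_dir,
                 paper_faithful = isTRUE(paper_faithful),
                 train_fraction = train_fraction,
                 n_draws = as.integer(n_draws),
                 cv_folds = as.integer(cv_folds),
                 k_rounds = as.integer(k_rounds),
                 window_days = as.integer(window_days),
                 finetune_rounds = as.integer(finetune_rounds),
                 epsilon_variance = epsilon_variance,
                 collinearity_threshold = collinearity_threshold,
                 day_window = day_window,
                 bootstrap_B = as.integer(bootstrap_B),
                 attention = attention),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the [experiment_config()] arguments; a `cohort:`
#' mapping is passed to [cohort_config()] (or, if a string, treated as a
#' fixture preset name).
#'
#' @param path YAML file path
#' @return an `experiment_config`
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort) && is.list(y$cohort)) {
    y$cohort <- do.call(cohort_config, y$cohort)
  }
  do.call(experiment_config, y)
}

# group feature columns of a wide daily matrix by sensor channel
channel_tables <- function(daily_wide) {
  cols <- setdiff(names(daily_wide), c("date", "day"))
  ch <- sub("__.*$", "", cols)
  lapply(split(cols, ch), function(cc) {
    daily_wide[, c("date", "day", cc), with = FALSE]
  })
}

build_pseudolabels <- function(cohort, cfg, daily_norm_all) {
  ccfg <- cohort$config
  att_cfg <- do.call(attention_config,
                     c(cfg$attention, list(seed = derive_seed(cfg$seed, "att"))))
  labels <- list()
  for (pid in ccfg$participant_ids) {
    D <- ccfg$enrollment_days[match(pid, ccfg$participant_ids)]
    idx <- seq_len(D) - 1L
    for (s in cfg$scales) {
      for (m in cfg$interpolations) {
        key <- paste(pid, s, m, sep = "|")
        labels[[key]] <- switch(m,
          linear = interpolate_linear(cohort$assessments, idx, pid, s,
                                      ccfg$start_date),
          cubic = interpolate_cubic(cohort$assessments, idx, pid, s,
                                    ccfg$start_date),
          attention = interpolate_attention(
            channel_tables(daily_norm_all[[pid]]), cohort$assessments, pid,
            s, idx, att_cfg, ccfg$start_date)
        )
      }
    }
  }
  labels
}

#' Run the full pipeline: generate, featurize, pseudo-label, fit, evaluate
#'
#' Stages: synthetic cohort (or supplied bundle) -> day/night daily summary
#' features -> pseudo-labels (per interpolation) -> leave-one-participant-out
#' folds with sequential 80/20 splits -> the three learning paradigms with
#' randomized tuning and the precision-rounding screener -> metric reports,
#' Taylor coordinates and contrast tables. Identical config + seed yields
#' identical outputs (byte-identical CSVs when `out_dir` is set).
#'
#' @param cfg an [experiment_config()]
#' @param cohort optional pre-generated `als_cohort` (otherwise generated
#'   from `cfg$cohort` with a derived seed)
#' @return list of class `als_experiment`: metrics, contrasts_rmse,
#'   contrasts_r, screened, splits, dropped_columns, labels, cohort
#' @export
run_experiment <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(cohort)) {
    if (is.character(cfg$cohort)) {
      cohort <- make_fixture(cfg$cohort, seed = derive_seed(cfg$seed, "cohort"))
    } else {
      ccfg <- cfg$cohort
      ccfg$seed <- derive_seed(cfg$seed, "cohort")
      cohort <- generate_cohort(ccfg)
    }
  }
  ccfg <- cohort$config
  pids <- ccfg$participant_ids

  tagged <- segment_day_night(cohort$streams, cfg$day_window)
  daily <- summarize_daily(tagged)
  for (pid in names(daily)) {
    daily[[pid]][, day := as.integer(date - ccfg$start_date)]
    setcolorder(daily[[pid]], c("date", "day"))
  }

  # per-participant sequential splits on the days with sensor coverage
  splits <- lapply(pids, function(pid) {
    split_sequential(daily[[pid]], cfg$train_fraction, pid)
  })
  names(splits) <- pids

  # participant-own full-row normalization feeds the attention interpolator
  norm_all <- lapply(pids, function(pid) {
    feat <- daily[[pid]][, !"day"]
    nm <- minmax_normalize(feat)$matrix
    nm[, day := daily[[pid]]$day]
    nm
  })
  names(norm_all) <- pids

  labels <- build_pseudolabels(cohort, cfg, norm_all)

  metrics <- list()
  screened <- list()
  dropped <- list()
  lopo_audits <- list()
  need_transfer <- any(c("transfer_batch", "transfer_incremental") %in%
                         cfg$paradigms)
  can_lopo <- length(pids) >= 3L # a cohort base needs >= 2 leave-in

  for (h in pids) {
    sp <- splits[[h]]
    train_idx_h <- which(daily[[h]]$date %in% sp$train_dates)
    dc <- drop_collinear(daily[[h]][, !"day"], cfg$collinearity_threshold,
                         fit_rows = train_idx_h)
    kept <- dc$kept
    dropped[[h]] <- copy(dc$report)[, fold := h]

    # fold-aligned normalized features: the identical protocol for every
    # participant (ranges fit on the earliest train_fraction of their rows)
    # keeps the normalized scale comparable across participants; in
    # paper-faithful mode ranges are fit on all rows instead
    feats <- list()
    for (pid in pids) {
      mat <- daily[[pid]][, c("date", kept), with = FALSE]
      fit_rows <- if (cfg$paper_faithful) seq_len(nrow(mat)) else
        seq_len(floor(cfg$train_fraction * nrow(mat)))
      nm <- minmax_normalize(mat, fit_rows = fit_rows)$matrix
      nm[, participant_id := pid]
      feats[[pid]] <- nm
    }

    for (s in cfg$scales) {
      for (m in cfg$interpolations) {
        tab_h <- assemble_supervised_table(
          feats[[h]][, !"participant_id"],
          labels[[paste(h, s, m, sep = "|")]])
        tab_h[, participant_id := h]
        tr <- tab_h[date %in% sp$train_dates]
        te <- tab_h[date %in% sp$test_dates]
        scr <- screen_variance(tr$label, cfg$epsilon_variance)
        run_individual <- "individual_batch" %in% cfg$paradigms &&
          scr$decision == "model"
        run_transfer <- need_transfer && can_lopo && !scr$static
        if (!run_individual && "individual_batch" %in% cfg$paradigms) {
          screened[[length(screened) + 1L]] <- data.table(
            fold = h, scale_id = s, method = m,
            paradigm = "individual_batch", reason = scr$reason)
        }
        if (!run_transfer && need_transfer) {
          screened[[length(screened) + 1L]] <- data.table(
            fold = h, scale_id = s, method = m, paradigm = "transfer",
            reason = if (!can_lopo) "too few participants for LOPO" else
              scr$reason)
        }

        cell_seed <- derive_seed(cfg$seed, "cell", h, s, m)
        if (run_individual) {
          tune_i <- tune_and_select(
            tr, kept, n_draws = cfg$n_draws, cv_folds = cfg$cv_folds,
            chronological = TRUE,
            selection_table = if (cfg$paper_faithful) te else NULL,
            seed = derive_seed(cell_seed, "tune_ind"))
          art_i <- fit_individual_batch(
            tr, tune_i$features, tune_i$hyperparameters,
            seed = derive_seed(cell_seed, "fit_ind"),
            provenance = list(fold = h, scale = s, interpolation = m),
            epsilon = cfg$epsilon_variance)
          metrics[[length(metrics) + 1L]] <- evaluate_cell(
            te$label, predict_artifact(art_i, te), B = cfg$bootstrap_B,
            seed = derive_seed(cell_seed, "boot_ind"),
            cell = list(participant_id = h, scale_id = s, method = m,
                        paradigm = "individual_batch"))
        }
        if (run_transfer) {
          leavein <- lapply(setdiff(pids, h), function(pid) {
            ti <- assemble_supervised_table(
              feats[[pid]][, !"participant_id"],
              labels[[paste(pid, s, m, sep = "|")]])
            ti[, participant_id := pid]
            ti
          })
          names(leavein) <- setdiff(pids, h)
          pooled <- rbindlist(leavein)
          tune_c <- tune_and_select(
            pooled, kept, n_draws = cfg$n_draws, cv_folds = cfg$cv_folds,
            chronological = FALSE,
            selection_table = if (cfg$paper_faithful) te else NULL,
            seed = derive_seed(cell_seed, "tune_coh"))
          base <- fit_cohort_base(
            leavein, tune_c$features, tune_c$hyperparameters,
            seed = derive_seed(cell_seed, "base"), fold_id = h)
          verify_lopo(base, tab_h)
          lopo_audits[[length(lopo_audits) + 1L]] <- data.table(
            fold = h, scale_id = s, method = m,
            train_row_hash = base$provenance$train_row_hash,
            n_train = base$provenance$n_train, holdout_overlap = 0L)
          if ("transfer_batch" %in% cfg$paradigms) {
            art_b <- finetune_batch(base, tr, rounds = cfg$finetune_rounds,
                                    seed = derive_seed(cell_seed, "ftb"))
            metrics[[length(metrics) + 1L]] <- evaluate_cell(
              te$label, predict_artifact(art_b, te), B = cfg$bootstrap_B,
              seed = derive_seed(cell_seed, "boot_ftb"),
              cell = list(participant_id = h, scale_id = s, method = m,
                          paradigm = "transfer_batch"))
          }
          if ("transfer_incremental" %in% cfg$paradigms) {
            inc <- finetune_incremental(base, tr, k = cfg$k_rounds,
                                        window = cfg$window_days,
                                        seed = derive_seed(cell_seed, "fti"))
            metrics[[length(metrics) + 1L]] <- evaluate_cell(
              te$label, predict_artifact(inc$artifact, te),
              B = cfg$bootstrap_B,
              seed = derive_seed(cell_seed, "boot_fti"),
              cell = list(participant_id = h, scale_id = s, method = m,
                          paradigm = "transfer_incremental"))
          }
        }
      }
    }
  }

  metrics <- if (length(metrics)) rbindlist(metrics) else data.table()
  screened <- if (length(screened)) rbindlist(screened) else
    data.table(fold = character(0), scale_id = character(0),
               method = character(0), paradigm = character(0),
               reason = character(0))
  dropped <- rbindlist(dropped)
  contrasts_rmse <- if (nrow(metrics)) {
    contrast_table(metrics, c("participant_id", "scale_id", "method"))
  } else data.table()
  contrasts_r <- if (nrow(metrics)) {
    contrast_table(metrics, c("participant_id", "scale_id", "method"),
                   metric = "r")
  } else data.table()

  lopo_audits <- if (length(lopo_audits)) rbindlist(lopo_audits) else
    data.table()
  res <- structure(list(metrics = metrics, contrasts_rmse = contrasts_rmse,
                        contrasts_r = contrasts_r, screened = screened,
                        splits = splits, dropped_columns = dropped,
                        lopo_audits = lopo_audits,
                        labels = labels, cohort = cohort, config = cfg),
                   class = "als_experiment")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(metrics, file.path(cfg$out_dir, "metrics.csv"))
    taylor_cols <- intersect(c("participant_id", "scale_id", "method",
                               "paradigm", "sigma_ref", "sigma_pred", "r",
                               "e_prime", "taylor_x", "taylor_y"),
                             names(metrics))
    fwrite(metrics[, taylor_cols, with = FALSE],
           file.path(cfg$out_dir, "taylor.csv"))
    fwrite(contrasts_rmse, file.path(cfg$out_dir, "contrasts.csv"))
    fwrite(dropped, file.path(cfg$out_dir, "dropped_columns.csv"))
    writeLines(
      vapply(seq_len(nrow(screened)), function(i) {
        jsonlite::toJSON(as.list(screened[i]), auto_unbox = TRUE)
      }, character(1)),
      file.path(cfg$out_dir, "screened.jsonl"))
    jsonlite::write_json(list(seed = cfg$seed),
                         file.path(cfg$out_dir, "run_meta.json"),
                         auto_unbox = TRUE)
  }
  res
}
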