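#' Randomized-search hyperparameter space for the boosted-tree learner
#'
#' Candidate lists for the nine tuned hyperparameters. Draws during tuning
#' come only from these lists.
#'
#' @return named list of candidate vectors
#' @export
hyperparam_space <- function() {
  list(
    eta = c(0.001, 0.01, 0.1, 0.3, 0.5),
    n_estimators = c(32, 64, 128, 192, 256, 384, 512),
    gamma = c(0, 0.25, 0.5, 1),
    max_depth = c(2, 3, 4, 6, 8, 10, 12, 16, 24),
    min_child_weight = c(0.5, 1, 3, 5, 7, 10),
    subsample = c(0.8, 0.9, 1.0),
    colsample_bytree = c(0.6, 0.7, 0.8, 0.9),
    lambda = c(0.01, 0.1, 1, 5, 10, 50, 100),
    alpha = c(0, 0.001, 0.01, 0.1)
  )
}

#' Draw random hyperparameter configurations from the search space
#' @param space output of [hyperparam_space()]
#' @param n_draws number of random configurations
#' @param seed integer seed
#' @return data.table, one row per draw
#' @export
sample_hyperparams <- function(space = hyperparam_space(), n_draws = 50L,
                               seed = 1L) {
  set.seed(seed)
  as.data.table(lapply(space, function(v) v[sample.int(length(v), n_draws,
                                                       replace = TRUE)]))
}

#' Chronological train/test split of a supervised table
#'
#' The earliest `train_fraction` of observations (by date) form the training
#' partition; the remainder is the unseen test set. Train size is
#' `floor(train_fraction * N)`.
#'
#' @param table supervised table with a `date` column
#' @param train_fraction fraction of rows assigned to training (default 0.8)
#' @param participant optional participant id recorded in the spec
#' @return list of class `split_spec`: train_dates, test_dates, n_train,
#'   n_test
#' @export
split_sequential <- function(table, train_fraction = 0.8, participant = NA) {
  dts <- sort(as.data.table(table)$date)
  N <- length(dts)
  if (N < 5L) stop_alstrack("need at least 5 observations to split")
  n_train <- floor(train_fraction * N)
  structure(list(participant_id = participant,
                 train_dates = dts[seq_len(n_train)],
                 test_dates = dts[(n_train + 1L):N],
                 train_fraction = train_fraction,
                 n_train = n_train, n_test = N - n_train),
            class = "split_spec")
}

#' Decide whether a target has enough training variance to model
#'
#' Targets with training variance below `epsilon` are not modeled with
#' individual batch learning; targets with exactly zero variance (static
#' scores) are additionally excluded from transfer fine-tuning.
#'
#' @param train_labels numeric training-partition labels
#' @param epsilon near-zero variance threshold (default 0.01)
#' @return list: decision ("model" | "skip"), reason, static (zero variance)
#' @export
screen_variance <- function(train_labels, epsilon = 0.01) {
  v <- var(train_labels)
  if (!is.finite(v)) v <- 0
  if (v == 0) {
    list(decision = "skip", reason = "zero variance", static = TRUE,
         variance = v)
  } else if (v < epsilon) {
    list(decision = "skip", reason = "near-zero variance", static = FALSE,
         variance = v)
  } else {
    list(decision = "model", reason = NA_character_, static = FALSE,
         variance = v)
  }
}

xgb_params <- function(hp, seed) {
  list(eta = hp$eta, gamma = hp$gamma, max_depth = as.integer(hp$max_depth),
       min_child_weight = hp$min_child_weight, subsample = hp$subsample,
       colsample_bytree = hp$colsample_bytree, lambda = hp$lambda,
       alpha = hp$alpha, objective = "reg:squarederror", nthread = 1L,
       seed = as.integer(seed %% .Machine$integer.max))
}

fit_booster <- function(X, y, hp, seed, xgb_model = NULL, nrounds = NULL) {
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  xgboost::xgb.train(params = xgb_params(hp, seed), data = d,
                     nrounds = as.integer(nrounds %||% hp$n_estimators),
                     verbose = 0, xgb_model = xgb_model)
}

feature_matrix <- function(table, features) {
  tab <- as.data.table(table)
  missing <- setdiff(features, names(tab))
  if (length(missing)) {
    stop_alstrack("feature columns absent from table: ",
                  paste(head(missing, 5), collapse = ", "))
  }
  X <- as.matrix(tab[, features, with = FALSE])
  X[!is.finite(X)] <- 0
  storage.mode(X) <- "double"
  X
}

new_artifact <- function(booster, features, hp, provenance) {
  structure(list(booster_raw = xgboost::xgb.save.raw(booster),
                 features = features, hyperparameters = hp,
                 provenance = provenance),
            class = "model_artifact")
}

artifact_booster <- function(artifact) xgboost::xgb.load.raw(artifact$booster_raw)

#' Predict from a model artifact
#' @param artifact a `model_artifact`
#' @param table supervised table (or any table holding the feature columns)
#' @return numeric predictions
#' @export
predict_artifact <- function(artifact, table) {
  X <- feature_matrix(table, artifact$features)
  predict(artifact_booster(artifact),
          xgboost::xgb.DMatrix(X, nthread = 1L))
}

row_ids <- function(table) {
  tab <- as.data.table(table)
  pid <- if ("participant_id" %in% names(tab)) tab$participant_id else "?"
  paste(pid, as.character(tab$date), sep = "::")
}

hash_strings <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sort(x), f)
  unname(tools::md5sum(f))
}

#' Precision-rounding feature subsets from an importance vector
#'
#' At precision level p (starting at 6 decimal places and increasing), the
#' candidate subset holds the features whose importance, rounded to p
#' decimals, is still positive - so finer precision admits smaller
#' importances and subsets grow with p. Each subset is capped at the
#' `max_features` largest importances; zero-importance features never enter.
#' Levels that repeat the previous subset are collapsed.
#'
#' @param importance named numeric importance vector
#' @param max_features subset size cap (default 200)
#' @param precisions decimal levels scanned (default 6:12)
#' @return list: subsets (list of feature-name vectors), precisions
#' @export
precision_subsets <- function(importance, max_features = 200L,
                              precisions = 6:12) {
  ord <- names(sort(importance, decreasing = TRUE))
  nz <- sum(importance > 0)
  subsets <- list(); kept_p <- integer(0)
  for (p in precisions) {
    sel <- names(importance)[round(importance, p) > 0]
    sel <- intersect(ord, sel)[seq_len(min(length(sel), max_features))]
    if (length(sel) == 0L) next
    if (length(subsets) == 0L || !identical(sel, subsets[[length(subsets)]])) {
      subsets[[length(subsets) + 1L]] <- sel
      kept_p <- c(kept_p, p)
    }
    if (length(sel) >= min(nz, max_features)) break
  }
  list(subsets = subsets, precisions = kept_p)
}

#' Randomized hyperparameter search plus precision-rounding feature screening
#'
#' Stage 1 draws `n_draws` configurations from the search space and scores
#' each by cross-validated RMSE over the training rows (chronological blocks
#' by default, shuffled folds for cohort-level tuning). Stage 2 fits the best
#' configuration on all training rows, extracts split-frequency feature
#' importances, and iterates precision levels p = 6, 7, 8, ... decimals: the
#' candidate subset at p holds the features whose importance rounded at p
#' decimals is still positive, capped at the top 200 by importance. Each
#' subset is refit and scored on `selection_rows`; the configuration with the
#' lowest selection RMSE wins (ties go to the smaller subset).
#'
#' @param table training-partition supervised table (date, features, label)
#' @param feature_cols candidate feature names
#' @param space candidate lists, see [hyperparam_space()]
#' @param n_draws number of random draws (default 50)
#' @param cv_folds cross-validation folds for stage 1 (default 3)
#' @param chronological use contiguous chronological CV blocks (TRUE, for
#'   within-participant tuning) or shuffled folds (FALSE, cohort-level)
#' @param selection_rows row indices of `table` used to score screener
#'   iterations; default is the last 20 percent of rows (an internal
#'   validation slice). Under `paper_faithful` pass the test rows via
#'   `selection_table` instead.
#' @param selection_table optional separate table scored instead of
#'   `selection_rows` (used by the paper-faithful mode, which selects on the
#'   held-out test set)
#' @param max_features cap on the selected subset size (default 200)
#' @param seed integer seed
#' @return list: hyperparameters (one-row data.table), features (selected
#'   names), trace (`screener_trace` data.table), cv (per-draw CV RMSE)
#' @export
tune_and_select <- function(table, feature_cols, space = hyperparam_space(),
                            n_draws = 50L, cv_folds = 3L,
                            chronological = TRUE, selection_rows = NULL,
                            selection_table = NULL, max_features = 200L,
                            seed = 1L) {
  tab <- as.data.table(table)[order(date)]
  N <- nrow(tab)
  X <- feature_matrix(tab, feature_cols)
  y <- tab$label
  draws <- sample_hyperparams(space, n_draws, derive_seed(seed, "draws"))

  if (chronological) {
    fold_id <- ceiling(seq_len(N) / (N / cv_folds))
  } else {
    set.seed(derive_seed(seed, "cvshuffle"))
    fold_id <- sample(rep_len(seq_len(cv_folds), N))
  }
  cv_rmse <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    hp <- draws[i]
    errs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold_id != f
      if (sum(tr) < 2L || sum(!tr) < 1L) return(NA_real_)
      m <- fit_booster(X[tr, , drop = FALSE], y[tr], hp,
                       derive_seed(seed, "cv", i, f))
      p <- predict(m, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], nthread = 1L))
      sqrt(mean((y[!tr] - p)^2))
    }, numeric(1))
    cv_rmse[i] <- mean(errs, na.rm = TRUE)
  }
  best_hp <- draws[which.min(cv_rmse)]

  if (is.null(selection_table)) {
    if (is.null(selection_rows)) {
      selection_rows <- seq.int(max(1L, floor(0.8 * N) + 1L), N)
    }
    sel_X <- X[selection_rows, , drop = FALSE]
    sel_y <- y[selection_rows]
    fit_rows <- setdiff(seq_len(N), selection_rows)
  } else {
    sel_tab <- as.data.table(selection_table)
    sel_X <- feature_matrix(sel_tab, feature_cols)
    sel_y <- sel_tab$label
    fit_rows <- seq_len(N)
  }

  full <- fit_booster(X[fit_rows, , drop = FALSE], y[fit_rows], best_hp,
                      derive_seed(seed, "screener", 0))
  imp_dt <- xgboost::xgb.importance(model = full)
  imp <- setNames(rep(0, length(feature_cols)), feature_cols)
  if (!is.null(imp_dt) && nrow(imp_dt)) imp[imp_dt$Feature] <- imp_dt$Frequency

  if (all(imp == 0)) {
    warning("all feature importances are zero; keeping all features")
    subsets <- list(feature_cols)
    precisions <- NA_integer_
  } else {
    ps <- precision_subsets(imp, max_features)
    subsets <- ps$subsets
    precisions <- ps$precisions
  }

  trace <- data.table(precision = precisions,
                      n_features = vapply(subsets, length, integer(1)),
                      rmse = NA_real_)
  for (j in seq_along(subsets)) {
    fs <- subsets[[j]]
    m <- fit_booster(X[fit_rows, fs, drop = FALSE], y[fit_rows], best_hp,
                     derive_seed(seed, "screener", j))
    p <- predict(m, xgboost::xgb.DMatrix(sel_X[, fs, drop = FALSE],
                                         nthread = 1L))
    trace[j, rmse := sqrt(mean((sel_y - p)^2))]
  }
  # lowest selection RMSE wins; ties resolved toward the smaller subset
  pick <- order(trace$rmse, trace$n_features)[1]
  trace[, chosen := seq_len(.N) == pick]
  setattr(trace, "class", c("screener_trace", class(trace)))

  list(hyperparameters = best_hp, features = subsets[[pick]],
       trace = trace, cv = data.table(draw = seq_len(n_draws),
                                      cv_rmse = cv_rmse))
}

#' Fit an individual batch-learning model on one participant's training data
#'
#' @param train_table the holdout participant's training partition
#' @param features selected feature names
#' @param hyperparameters one-row data.table of tuned hyperparameters
#' @param seed integer seed
#' @param provenance named list merged into the artifact provenance
#' @param epsilon near-zero variance threshold passed to [screen_variance()]
#' @return a `model_artifact`
#' @export
fit_individual_batch <- function(train_table, features, hyperparameters,
                                 seed = 1L, provenance = list(),
                                 epsilon = 0.01) {
  tab <- as.data.table(train_table)[order(date)]
  scr <- screen_variance(tab$label, epsilon)
  if (scr$decision == "skip") {
    stop_alstrack("target screened out for individual batch learning (",
                  scr$reason, ")")
  }
  m <- fit_booster(feature_matrix(tab, features), tab$label, hyperparameters,
                   derive_seed(seed, "individual"))
  new_artifact(m, features, hyperparameters,
               c(list(paradigm = "individual_batch", seed = seed,
                      n_train = nrow(tab),
                      train_row_hash = hash_strings(row_ids(tab))),
                 provenance))
}

#' Train the cohort base model on the leave-in participants
#'
#' Rows from all leave-in participants are concatenated, shuffled with the
#' derived seed, and fit in one batch. The holdout participant's rows are
#' provably absent: the sorted training row ids are hashed into the artifact
#' provenance and [verify_lopo()] audits the exclusion.
#'
#' @param leavein_tables named list (by participant) of supervised tables
#' @param features,hyperparameters,seed as in [fit_individual_batch()]
#' @param fold_id holdout participant id recorded in provenance
#' @return a `model_artifact` (checkpointable cohort base)
#' @export
fit_cohort_base <- function(leavein_tables, features, hyperparameters,
                            seed = 1L, fold_id = NA_character_) {
  if (length(leavein_tables) < 2L) {
    stop_alstrack("LOPO requires >= 2 leave-in participants")
  }
  tabs <- mapply(function(tb, nm) {
    tb <- as.data.table(tb)
    if (!"participant_id" %in% names(tb)) tb[, participant_id := nm]
    tb
  }, leavein_tables, names(leavein_tables), SIMPLIFY = FALSE)
  pooled <- rbindlist(tabs, fill = TRUE)
  if (fold_id %in% pooled$participant_id) {
    stop_alstrack("holdout participant present in leave-in tables")
  }
  set.seed(derive_seed(seed, "shuffle", fold_id))
  pooled <- pooled[sample.int(nrow(pooled))]
  ids <- row_ids(pooled)
  m <- fit_booster(feature_matrix(pooled, features), pooled$label,
                   hyperparameters, derive_seed(seed, "cohort", fold_id))
  new_artifact(m, features, hyperparameters,
               list(paradigm = "cohort_base", fold = fold_id, seed = seed,
                    n_train = nrow(pooled),
                    train_row_ids = ids,
                    train_row_hash = hash_strings(ids)))
}

#' Audit leave-one-participant-out integrity of a cohort base model
#'
#' Checks that none of the holdout rows entered the base model's training
#' set, and that the stored training-row hash matches the stored ids.
#'
#' @param artifact a cohort base `model_artifact`
#' @param holdout_table the holdout participant's full supervised table
#' @return TRUE invisibly; errors on violation
#' @export
verify_lopo <- function(artifact, holdout_table) {
  ids <- artifact$provenance$train_row_ids
  if (is.null(ids)) stop_alstrack("artifact carries no training row ids")
  if (!identical(hash_strings(ids), artifact$provenance$train_row_hash)) {
    stop_alstrack("training row hash mismatch")
  }
  overlap <- intersect(ids, row_ids(holdout_table))
  if (length(overlap)) {
    stop_alstrack("LOPO violation: ", length(overlap),
                  " holdout rows found in the cohort base training set")
  }
  invisible(TRUE)
}

#' Batch fine-tuning of a cohort base model on the holdout training set
#'
#' Boosting resumes from the base checkpoint for `rounds` additional rounds,
#' fit on the full holdout training partition in a single pass.
#' Hyperparameters are held constant from the base model. With `rounds = 0`
#' the base model is returned unchanged (identity).
#'
#' @param base cohort base `model_artifact`
#' @param train_table holdout training partition
#' @param rounds additional boosting rounds (default 32)
#' @param seed integer seed
#' @return a fine-tuned `model_artifact` whose provenance records the parent
#'   checkpoint hash
#' @export
finetune_batch <- function(base, train_table, rounds = 32L, seed = 1L) {
  tab <- as.data.table(train_table)[order(date)]
  miss <- setdiff(base$features, names(tab))
  if (length(miss)) {
    stop_alstrack("feature-name mismatch with base model: ",
                  paste(head(miss, 5), collapse = ", "))
  }
  prov <- list(paradigm = "transfer_batch", fold = base$provenance$fold,
               seed = seed, n_train = nrow(tab), rounds = rounds,
               parent = artifact_hash(base))
  if (rounds == 0L) {
    return(structure(list(booster_raw = base$booster_raw,
                          features = base$features,
                          hyperparameters = base$hyperparameters,
                          provenance = prov), class = "model_artifact"))
  }
  m <- fit_booster(feature_matrix(tab, base$features), tab$label,
                   base$hyperparameters, derive_seed(seed, "ftbatch"),
                   xgb_model = artifact_booster(base), nrounds = rounds)
  new_artifact(m, base$features, base$hyperparameters, prov)
}

#' Incremental (prequential) fine-tuning of a cohort base model
#'
#' Walks the holdout training rows in date order. At each step the current
#' model state predicts the incoming observation *before* seeing it (the
#' prequential prediction), then boosting resumes for `k` rounds on a window
#' of the most recent `window` rows including the new one, simulating
#' between-visit adaptation. With `k = 0` no update occurs and the
#' prequential predictions equal the base model's.
#'
#' @param base cohort base `model_artifact`
#' @param train_table holdout training partition, strictly date-ordered
#' @param k boosting rounds per step (default 1)
#' @param window number of most recent rows refit at each step (default 14)
#' @param seed integer seed
#' @return list: `artifact` (final adapted model), `prequential`
#'   (data.table date, label, prediction)
#' @export
finetune_incremental <- function(base, train_table, k = 1L, window = 14L,
                                 seed = 1L) {
  tab <- as.data.table(train_table)
  if (is.unsorted(tab$date, strictly = FALSE)) {
    stop_alstrack("rows must be in nondecreasing date order")
  }
  miss <- setdiff(base$features, names(tab))
  if (length(miss)) stop_alstrack("feature-name mismatch with base model")
  X <- feature_matrix(tab, base$features)
  y <- tab$label
  # state is carried as the serialized booster: handing xgb.train a live
  # handle across many continuation steps can hit a disposed-handle error
  state_raw <- base$booster_raw
  booster <- xgboost::xgb.load.raw(state_raw)
  preds <- numeric(nrow(tab))
  for (t in seq_len(nrow(tab))) {
    preds[t] <- predict(booster, xgboost::xgb.DMatrix(
      X[t, , drop = FALSE], nthread = 1L))
    if (k > 0L) {
      w0 <- max(1L, t - window + 1L)
      dtr <- xgboost::xgb.DMatrix(X[w0:t, , drop = FALSE], label = y[w0:t],
                                  nthread = 1L)
      booster <- xgboost::xgb.train(
        params = xgb_params(base$hyperparameters,
                            derive_seed(seed, "inc", t)),
        data = dtr, nrounds = as.integer(k), verbose = 0,
        xgb_model = state_raw)
      state_raw <- xgboost::xgb.save.raw(booster)
    }
  }
  prov <- list(paradigm = "transfer_incremental", fold = base$provenance$fold,
               seed = seed, n_train = nrow(tab), k = k, window = window,
               parent = artifact_hash(base))
  art <- if (k == 0L) {
    structure(list(booster_raw = base$booster_raw, features = base$features,
                   hyperparameters = base$hyperparameters,
                   provenance = prov), class = "model_artifact")
  } else {
    new_artifact(booster, base$features, base$hyperparameters, prov)
  }
  list(artifact = art,
       prequential = data.table(date = tab$date, label = y,
                                prediction = preds))
}

artifact_hash <- function(artifact) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(artifact$booster_raw, f)
  unname(tools::md5sum(f))
}

#' Serialize a model artifact to a checkpoint file pair
#'
#' Writes the booster binary to `path` and a sidecar JSON
#' (`<path>.json`) holding provenance, feature list, hyperparameters,
#' format version and the booster content hash.
#'
#' @param artifact a `model_artifact`
#' @param path checkpoint file path
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(artifact, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeBin(artifact$booster_raw, path)
  side <- list(version = 1L,
               content_hash = artifact_hash(artifact),
               features = artifact$features,
               hyperparameters = as.list(artifact$hyperparameters),
               provenance = artifact$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model artifact from a checkpoint file pair
#'
#' Verifies the sidecar's content hash against the binary (corrupt files
#' error with a checksum report) and the schema version.
#'
#' @param path checkpoint file path written by [save_checkpoint()]
#' @return a `model_artifact` that predicts identically to the saved one
#' @export
load_checkpoint <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side_path)) {
    stop_alstrack("checkpoint files missing at ", path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  if (is.null(side$version) || is.null(side$features)) {
    stop_alstrack("checkpoint sidecar has an unrecognized schema")
  }
  raw <- readBin(path, what = "raw", n = file.size(path))
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, side$content_hash)) {
    stop_alstrack("checkpoint checksum mismatch: expected ",
                  side$content_hash, ", found ", actual)
  }
  hp <- as.data.table(side$hyperparameters)
  structure(list(booster_raw = raw, features = side$features,
                 hyperparameters = hp, provenance = side$provenance),
            class = "model_artifact")
}
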