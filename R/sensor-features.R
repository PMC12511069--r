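#' The 17 daily summary statistics computed per channel and period
#' @export
SUMMARY_STATS <- c("count", "min", "max", "mean", "median", "mode",
                   "variance", "range", "skew", "kurtosis",
                   "q10", "q25", "q75", "q90", "iqr", "cv", "entropy")

#' Tag sensor samples as day or night
#'
#' The day window is half-open on the clock: a sample is "day" when its
#' local clock time lies in `[day_start, day_end)`, otherwise "night". The
#' partition is exhaustive and disjoint.
#'
#' @param stream data.table with participant_id, channel_id, timestamp, value
#' @param day_window numeric length-2, start and end hour of the day period
#'   (default `c(6, 22)`, i.e. 06:00-22:00)
#' @return the stream with added `date` and `period` columns
#' @export
segment_day_night <- function(stream, day_window = c(6, 22)) {
  if (length(day_window) != 2L || day_window[1] >= day_window[2]) {
    stop_alstrack("day_window must be an increasing (start, end) hour pair")
  }
  tagged <- copy(as.data.table(stream))
  hr <- as.numeric(format(tagged$timestamp, "%H")) +
    as.numeric(format(tagged$timestamp, "%M")) / 60 +
    as.numeric(format(tagged$timestamp, "%S")) / 3600
  tagged[, date := as.Date(timestamp, tz = "UTC")]
  tagged[, period := ifelse(hr >= day_window[1] & hr < day_window[2],
                            "day", "night")]
  tagged[]
}

# all 17 statistics for one cell of samples; constants must behave (variance,
# range, iqr, skew, kurtosis, entropy and cv all 0), and n = 1 degenerates
# the same way
cell_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- if (n < 2L) 0 else var(x)
  s <- sqrt(s2)
  qs <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  sk <- if (s2 > 0) e1071::skewness(x, type = 1) else 0
  ku <- if (s2 > 0) e1071::kurtosis(x, type = 1) else 0
  list(count = as.numeric(n), min = min(x), max = max(x), mean = m,
       median = median(x), mode = mode_value(x), variance = s2,
       range = max(x) - min(x), skew = sk, kurtosis = ku,
       q10 = qs[1], q25 = qs[2], q75 = qs[3], q90 = qs[4],
       iqr = qs[3] - qs[2],
       cv = if (abs(m) < 1e-12) 0 else s / m,
       entropy = shannon_entropy(x))
}

# modal value after rounding to 2 decimals; ties broken toward the smallest
mode_value <- function(x) {
  r <- round(x, 2)
  u <- sort(unique(r))
  u[which.max(tabulate(match(r, u)))] # first max in ascending value order
}

# Shannon entropy (natural log) of a 10-bin histogram over the cell's range
shannon_entropy <- function(x, bins = 10L) {
  if (length(unique(x)) == 1L) return(0)
  h <- findInterval(x, seq(min(x), max(x), length.out = bins + 1L),
                    rightmost.closed = TRUE)
  p <- tabulate(h, nbins = bins)
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

#' Build the daily day/night summary-statistic feature matrix
#'
#' Computes the 17 summary statistics per channel x period x date and spreads
#' them into wide columns named `<channel>__<period>__<stat>`. Skew and
#' kurtosis are the standardized third/fourth moments (kurtosis as excess);
#' entropy is the Shannon entropy (natural log) of a 10-bin histogram over
#' the cell's values; CV is sd/mean guarded at zero mean; the mode is the
#' modal 2-decimal-rounded value with ties broken toward the smallest.
#' Non-finite samples are excluded before aggregation and counted in the
#' `n_nonfinite` attribute. Cells with no samples yield `count = 0` and
#' missing statistics.
#'
#' @param tagged output of [segment_day_night()]
#' @return list of per-participant wide data.tables (date + feature columns),
#'   named by participant
#' @export
summarize_daily <- function(tagged) {
  dt <- as.data.table(tagged)
  bad <- !is.finite(dt$value)
  if (any(bad)) {
    message(sum(bad), " non-finite sensor samples excluded")
    dt <- dt[!bad]
  }
  stats_long <- dt[, cell_stats(value),
                   by = .(participant_id, date, channel_id, period)]
  long <- melt(stats_long, id.vars = c("participant_id", "date",
                                       "channel_id", "period"),
               variable.name = "stat", value.name = "value")
  long[, col := paste(channel_id, period, stat, sep = "__")]
  res <- list()
  for (pid in sort(unique(long$participant_id))) {
    w <- dcast(long[participant_id == pid], date ~ col, value.var = "value")
    cnt <- grep("__count$", names(w), value = TRUE)
    for (cc in cnt) set(w, which(is.na(w[[cc]])), cc, 0)
    setattr(w, "n_nonfinite", sum(bad))
    res[[pid]] <- w
  }
  res
}

#' Remove collinear (and constant) feature columns
#'
#' Greedy scan in fixed column order over the training rows: a column is
#' dropped when its absolute Pearson correlation with any earlier retained
#' column exceeds the threshold; zero-variance columns are dropped with
#' reason "constant". Decisions depend only on `fit_rows`.
#'
#' @param mat wide feature data.table (a `date` column plus feature columns)
#' @param threshold absolute correlation above which a column is dropped
#'   (default 0.95)
#' @param fit_rows integer row indices of the training partition (default all
#'   rows)
#' @return list with `matrix` (reduced), `report` (data.table of dropped
#'   columns with the retained column and correlation responsible), and
#'   `kept` (retained feature names)
#' @export
drop_collinear <- function(mat, threshold = 0.95, fit_rows = seq_len(nrow(mat))) {
  mat <- as.data.table(mat)
  cols <- setdiff(names(mat), "date")
  fit <- mat[fit_rows]
  kept <- character(0)
  rep_list <- list()
  for (cn in cols) {
    x <- fit[[cn]]
    x <- x[is.finite(x)]
    if (length(x) < 2L || var(x) == 0) {
      rep_list[[length(rep_list) + 1L]] <-
        data.table(dropped = cn, kept = NA_character_, r = NA_real_,
                   reason = "constant")
      next
    }
    clash <- NA_character_; rclash <- NA_real_
    for (kn in kept) {
      r <- suppressWarnings(cor(fit[[cn]], fit[[kn]],
                                use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > threshold) { clash <- kn; rclash <- r; break }
    }
    if (is.na(clash)) {
      kept <- c(kept, cn)
    } else {
      rep_list[[length(rep_list) + 1L]] <-
        data.table(dropped = cn, kept = clash, r = rclash,
                   reason = "collinear")
    }
  }
  report <- if (length(rep_list)) rbindlist(rep_list) else
    data.table(dropped = character(0), kept = character(0), r = numeric(0),
               reason = character(0))
  list(matrix = mat[, c("date", kept), with = FALSE], report = report,
       kept = kept)
}

#' Min-max normalize feature columns using training-row statistics
#'
#' `x' = (x - min) / (max - min)` with the per-column min/max computed on
#' `fit_rows` only; constant columns map to 0. The same transform is applied
#' unchanged to the remaining rows, so test values may fall outside \[0, 1\]
#' (no clipping).
#'
#' @param mat wide feature data.table (`date` + feature columns)
#' @param fit_rows training row indices used to fit the per-column ranges
#' @param ranges optional previously fitted ranges (data.table col/min/max);
#'   when supplied, `fit_rows` is ignored and the stored transform is applied
#' @return list with `matrix` (normalized) and `ranges`
#' @export
minmax_normalize <- function(mat, fit_rows = seq_len(nrow(mat)), ranges = NULL) {
  mat <- as.data.table(mat)
  cols <- setdiff(names(mat), "date")
  if (is.null(ranges)) {
    if (length(fit_rows) == 0L) stop_alstrack("fit_rows must be non-empty")
    fit <- mat[fit_rows]
    ranges <- data.table(
      col = cols,
      min = vapply(cols, function(cn) suppressWarnings(min(fit[[cn]], na.rm = TRUE)), numeric(1)),
      max = vapply(cols, function(cn) suppressWarnings(max(fit[[cn]], na.rm = TRUE)), numeric(1))
    )
  }
  out <- copy(mat)
  for (i in seq_len(nrow(ranges))) {
    cn <- ranges$col[i]
    if (!cn %in% names(out)) next
    lo <- ranges$min[i]; hi <- ranges$max[i]
    v <- out[[cn]]
    set(out, j = cn, value = if (!is.finite(lo) || !is.finite(hi) || hi == lo)
      rep(0, length(v)) else (v - lo) / (hi - lo))
  }
  list(matrix = out, ranges = ranges)
}

#' Join a daily feature matrix with a pseudo-label series
#'
#' Inner join by exact date; rows lacking either side are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param features wide feature data.table (`date` + feature columns)
#' @param labels a pseudo-label series (data.table with date, value)
#' @return a supervised table: date, features, and a `label` column, with
#'   `scale_id` and `method` attributes carried from the label series
#' @export
assemble_supervised_table <- function(features, labels) {
  features <- as.data.table(features)
  labels <- as.data.table(labels)
  if (anyDuplicated(features$date)) stop_alstrack("no duplicate dates allowed in features")
  if (anyDuplicated(labels$date)) stop_alstrack("no duplicate dates allowed in labels")
  lab <- labels[, .(date, label = value)]
  joined <- merge(features, lab, by = "date")
  if (nrow(joined) == 0L) stop_alstrack("no overlapping dates between features and labels")
  setattr(joined, "n_dropped",
          (nrow(features) - nrow(joined)) + (nrow(lab) - nrow(joined)))
  setattr(joined, "scale_id", attr(labels, "scale_id"))
  setattr(joined, "method", attr(labels, "method"))
  joined[]
}
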