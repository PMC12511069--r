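# population (1/n) standard deviation: the Taylor-diagram convention, under
# which rmse^2 = e_prime^2 + mean-bias^2 exactly
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Root mean square error
#' @param y true values
#' @param y_hat predictions
#' @return sqrt(mean((y - y_hat)^2))
#' @export
rmse <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1L)
  sqrt(mean((y - y_hat)^2))
}

#' Pearson correlation with a degenerate-variance convention
#'
#' When either side has zero variance the correlation is undefined; it is
#' reported as 0 with `degenerate = TRUE` (rendered "0 (0-0)" in tables).
#'
#' @param y,y_hat paired values (n >= 2)
#' @return list: r, degenerate
#' @export
pearson_r <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  if (sd(y) == 0 || sd(y_hat) == 0) {
    return(list(r = 0, degenerate = TRUE))
  }
  list(r = cor(y, y_hat), degenerate = FALSE)
}

#' Fisher z confidence interval for a Pearson correlation
#'
#' `z = atanh(r)`, `se = 1/sqrt(n - 3)`, limits `tanh(z +- z_level * se)`.
#' With fewer than four points the interval is marked missing; |r| = 1
#' yields the degenerate interval (r, r) with a flag.
#'
#' @param r sample correlation
#' @param n number of paired points
#' @param level confidence level (default 0.95)
#' @return list: lo, hi, missing, degenerate
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4L) return(list(lo = NA_real_, hi = NA_real_, missing = TRUE,
                          degenerate = FALSE))
  if (abs(r) >= 1) return(list(lo = r, hi = r, missing = FALSE,
                               degenerate = TRUE))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(lo = tanh(z - q * se), hi = tanh(z + q * se), missing = FALSE,
       degenerate = FALSE)
}

#' Bootstrap confidence interval for the RMSE
#'
#' Non-parametric bootstrap over the paired (y, y_hat) values: each of the
#' `B` resamples (default 1,000) recomputes the error as
#' `sqrt(sd(y)^2 + sd(y_hat)^2 - 2 sd(y) sd(y_hat) |r|)` - the centered
#' (law-of-cosines) form built from the two standard deviations and the
#' absolute correlation - and the 2.5/97.5 empirical percentiles (linear
#' interpolation) of the resampled errors are the bounds. Resamples in which
#' either side collapses to zero variance contribute with |r| treated as 0.
#' `method = "residual"` instead recomputes the plain RMSE per resample.
#'
#' @param y,y_hat paired values (n >= 2)
#' @param B resamples (default 1000)
#' @param seed integer seed
#' @param level confidence level (default 0.95)
#' @param method "centered" (default) or "residual"
#' @return list: lo, hi, n_degenerate (zero-variance resamples)
#' @export
bootstrap_rmse_ci <- function(y, y_hat, B = 1000L, seed = 1L, level = 0.95,
                              method = c("centered", "residual")) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(n >= 2L, length(y_hat) == n, B >= 1L)
  set.seed(seed)
  stat <- numeric(B)
  n_deg <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]; pb <- y_hat[idx]
    if (method == "residual") {
      stat[b] <- sqrt(mean((yb - pb)^2))
    } else {
      s1 <- sd_pop(yb); s2 <- sd_pop(pb)
      if (s1 == 0 || s2 == 0) {
        ar <- 0
        n_deg <- n_deg + 1L
      } else {
        ar <- abs(cor(yb, pb))
        if (!is.finite(ar)) { ar <- 0; n_deg <- n_deg + 1L }
        if (ar > 1 - 1e-12) ar <- 1 # avoid fp residue for perfect pairs
      }
      stat[b] <- sqrt(max(s1^2 + s2^2 - 2 * s1 * s2 * ar, 0))
    }
  }
  a <- (1 - level) / 2
  qs <- quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
  list(lo = qs[1], hi = qs[2], n_degenerate = n_deg)
}

#' Taylor-diagram coordinates for one prediction cell
#'
#' The reference (true) series sits at `(sigma_ref, 0)`; a model sits at
#' polar radius `sigma_pred` and angle `arccos(r)`, i.e. Cartesian
#' `(sigma_pred * r, sigma_pred * sqrt(1 - r^2))`. The centered RMSE obeys
#' `E'^2 = sigma_ref^2 + sigma_pred^2 - 2 sigma_ref sigma_pred r`. A
#' zero-variance prediction sits at the origin (SD = 0, r = 0).
#'
#' @param y,y_hat paired values (n >= 2)
#' @return list: sigma_ref, sigma_pred, r, e_prime, x, y (plot coordinates)
#' @export
taylor_point <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  s_ref <- sd_pop(y)
  s_pred <- sd_pop(y_hat)
  pr <- pearson_r(y, y_hat)
  r <- if (pr$degenerate) 0 else pr$r
  e2 <- s_ref^2 + s_pred^2 - 2 * s_ref * s_pred * r
  list(sigma_ref = s_ref, sigma_pred = s_pred, r = r,
       e_prime = sqrt(max(e2, 0)),
       x = s_pred * r, y = s_pred * sqrt(max(1 - r^2, 0)))
}

#' Cross-participant mean with a t-distribution confidence interval
#'
#' `mean +- t(level, n-1) * sd / sqrt(n)`; with a single value the interval
#' is missing (never fabricated).
#'
#' @param values per-participant metric values
#' @param level confidence level (default 0.95)
#' @return list: mean, lo, hi, n, missing
#' @export
aggregate_mean_tci <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  stopifnot(n >= 1L)
  m <- mean(values)
  if (n < 2L) {
    return(list(mean = m, lo = NA_real_, hi = NA_real_, n = n,
                missing = TRUE))
  }
  half <- qt(1 - (1 - level) / 2, df = n - 1L) * sd(values) / sqrt(n)
  list(mean = m, lo = m - half, hi = m + half, n = n, missing = FALSE)
}

#' Evaluate one prediction cell into a metric report row
#'
#' @param y,y_hat paired test values and predictions
#' @param B bootstrap resamples for the RMSE interval
#' @param seed integer seed
#' @param cell named list of identifiers (participant, scale, method,
#'   paradigm) prepended to the row
#' @return one-row data.table: rmse, rmse_lo, rmse_hi, r, r_lo, r_hi, n,
#'   r_degenerate, r_ci_missing, plus Taylor coordinates
#' @export
evaluate_cell <- function(y, y_hat, B = 1000L, seed = 1L, cell = list()) {
  n <- length(y)
  rm <- rmse(y, y_hat)
  ci <- if (n >= 2L) bootstrap_rmse_ci(y, y_hat, B = B, seed = seed) else
    list(lo = NA_real_, hi = NA_real_)
  pr <- if (n >= 2L) pearson_r(y, y_hat) else list(r = NA_real_, degenerate = TRUE)
  rci <- if (pr$degenerate) list(lo = 0, hi = 0, missing = n < 4L) else
    fisher_ci(pr$r, n)
  tp <- if (n >= 2L) taylor_point(y, y_hat) else
    list(sigma_ref = NA_real_, sigma_pred = NA_real_, r = NA_real_,
         e_prime = NA_real_, x = NA_real_, y = NA_real_)
  cbind(as.data.table(cell),
        data.table(rmse = rm, rmse_lo = ci$lo, rmse_hi = ci$hi,
                   r = if (pr$degenerate) 0 else pr$r,
                   r_lo = rci$lo, r_hi = rci$hi, n = n,
                   r_degenerate = pr$degenerate,
                   r_ci_missing = isTRUE(rci$missing),
                   sigma_ref = tp$sigma_ref, sigma_pred = tp$sigma_pred,
                   e_prime = tp$e_prime, taylor_x = tp$x, taylor_y = tp$y))
}

#' Best-per-row contrast table with CI-disjointness significance flags
#'
#' For each row (a participant x scale cell, or any grouping) the method
#' with the lowest RMSE (or highest r, with `metric = "r"`) is marked best;
#' a method is flagged significantly better than another when their 95%
#' intervals are disjoint in the favorable direction. Unmodeled cells are
#' rendered with the dash convention; exact ties are reported as ties.
#'
#' @param reports metric-report data.table (rows from [evaluate_cell()])
#' @param row_cols columns identifying a row (default participant + scale)
#' @param method_col column naming the compared methods (default "paradigm")
#' @param metric "rmse" (lower is better) or "r" (higher is better)
#' @return long data.table: row ids, method, formatted cell, best, tie, and
#'   `sig_better_than` (comma list of methods this one significantly beats)
#' @export
contrast_table <- function(reports, row_cols = c("participant_id", "scale_id"),
                           method_col = "paradigm", metric = c("rmse", "r")) {
  metric <- match.arg(metric)
  rep_dt <- as.data.table(reports)
  lo_col <- paste0(metric, "_lo"); hi_col <- paste0(metric, "_hi")
  out <- rep_dt[, {
    v <- get(metric); lo <- get(lo_col); hi <- get(hi_col)
    meth <- as.character(get(method_col))
    ok <- is.finite(v)
    best <- rep(FALSE, .N); tie <- rep(FALSE, .N)
    if (any(ok)) {
      opt <- if (metric == "rmse") min(v[ok]) else max(v[ok])
      best <- ok & v == opt
      tie <- best & sum(best) > 1L
    }
    sig <- vapply(seq_len(.N), function(i) {
      if (!ok[i] || !is.finite(lo[i]) || !is.finite(hi[i])) return("")
      beats <- vapply(seq_len(.N), function(j) {
        if (j == i || !ok[j] || !is.finite(lo[j]) || !is.finite(hi[j])) {
          return(FALSE)
        }
        if (metric == "rmse") hi[i] < lo[j] else lo[i] > hi[j]
      }, logical(1))
      paste(meth[beats], collapse = ",")
    }, character(1))
    fmt <- ifelse(ok,
                  sprintf("%.2f (%.2f–%.2f)", v, lo, hi),
                  "—")
    list(method = meth, value = v, lo = lo, hi = hi, cell = fmt,
         best = best, tie = tie, sig_better_than = sig)
  }, by = row_cols]
  out[]
}
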