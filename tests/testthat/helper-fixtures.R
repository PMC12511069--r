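library(data.table)

# small supervised table: date-indexed features with a known signal column
make_supervised_table <- function(n = 60, n_features = 6, seed = 1,
                                  signal = function(x) 2 * x[, 1],
                                  noise_sd = 0.1, participant = "PX",
                                  start = as.Date("2023-01-01")) {
  set.seed(seed)
  X <- matrix(runif(n * n_features), n, n_features)
  colnames(X) <- paste0("f", seq_len(n_features))
  tab <- as.data.table(X)
  tab[, date := start + seq_len(n) - 1L]
  tab[, label := signal(X) + rnorm(n, 0, noise_sd)]
  tab[, participant_id := participant]
  setcolorder(tab, c("participant_id", "date"))
  tab[]
}

default_hp <- function(eta = 0.1, n_estimators = 64, max_depth = 3) {
  data.table(eta = eta, n_estimators = n_estimators, gamma = 0,
             max_depth = max_depth, min_child_weight = 1, subsample = 1,
             colsample_bytree = 1, lambda = 1, alpha = 0)
}

# a wide assessment table built directly from (day, score) anchors
make_assessments <- function(days, scores_by_scale, participant = "P1",
                             start = as.Date("2023-01-01")) {
  a <- data.table(participant_id = participant, day = as.integer(days),
                  date = start + days)
  for (s in alstrack::ALSFRS_SUBSCALES) {
    a[, (s) := as.integer(scores_by_scale[[s]] %||% rep(4L, length(days)))]
  }
  a[, composite := rowSums(.SD), .SDcols = alstrack::ALSFRS_SUBSCALES]
  a[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent natural cubic spline by the classic tridiagonal second-
# derivative solve (oracle for interpolate_cubic)
natural_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  if (n == 2) return(approx(x, y, xout)$y)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b) # second derivatives at the knots
  vapply(xout, function(xx) {
    i <- max(1, min(findInterval(xx, x), n - 1))
    t1 <- x[i + 1] - xx; t2 <- xx - x[i]
    (M[i] * t1^3 + M[i + 1] * t2^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t2
  }, numeric(1))
}

# naive reimplementations of the 17 summary statistics (oracle for
# summarize_daily's cell statistics)
naive_cell_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  sv <- if (n < 2) 0 else sum((x - mu)^2) / (n - 1)
  xs <- sort(x)
  qn <- function(p) { # type-7 linear interpolation, written out
    hidx <- (n - 1) * p + 1
    lo <- floor(hidx); hi <- ceiling(hidx)
    xs[lo] + (hidx - lo) * (xs[hi] - xs[lo])
  }
  ent <- if (min(x) == max(x)) 0 else {
    br <- seq(min(x), max(x), length.out = 11)
    cnt <- vapply(1:10, function(b) {
      if (b < 10) sum(x >= br[b] & x < br[b + 1]) else sum(x >= br[10])
    }, numeric(1))
    p <- cnt[cnt > 0] / n
    -sum(p * log(p))
  }
  r2 <- round(x, 2)
  md <- min(as.numeric(names(which(table(r2) == max(table(r2))))))
  list(count = n, min = min(x), max = max(x), mean = mu,
       median = qn(0.5), mode = md, variance = sv, range = max(x) - min(x),
       skew = if (m2 > 0) m3 / m2^1.5 else 0,
       kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0,
       q10 = qn(0.10), q25 = qn(0.25), q75 = qn(0.75), q90 = qn(0.90),
       iqr = qn(0.75) - qn(0.25),
       cv = if (abs(mu) < 1e-12) 0 else sqrt(sv) / mu,
       entropy = ent)
}
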