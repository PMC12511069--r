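test_that("rmse follows the direct formula", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(1, 2, 3), c(2, 4, 6)), sqrt(14 / 3))
})

test_that("pearson_r handles perfect and degenerate correlation", {
  y <- c(1, 2, 3, 5)
  expect_equal(pearson_r(y, 2 * y)$r, 1)
  expect_equal(pearson_r(y, -y)$r, -1)
  d <- pearson_r(y, rep(2, 4))
  expect_equal(d$r, 0)
  expect_true(d$degenerate)
})

test_that("fisher intervals match the closed form and go missing below n = 4", {
  m <- fisher_ci(0.8, 3)
  expect_true(m$missing)
  expect_true(is.na(m$lo))
  ci <- fisher_ci(0.5, 20)
  z <- atanh(0.5); se <- 1 / sqrt(17); q <- qnorm(0.975)
  expect_equal(ci$lo, tanh(z - q * se), tolerance = 1e-12)
  expect_equal(ci$hi, tanh(z + q * se), tolerance = 1e-12)
  expect_equal(c(ci$lo, ci$hi), c(0.0738, 0.7716), tolerance = 1e-3)
  s <- fisher_ci(0, 30)
  expect_equal(s$lo, -s$hi, tolerance = 1e-12) # symmetric about 0
  dg <- fisher_ci(1, 10)
  expect_true(dg$degenerate)
  expect_equal(c(dg$lo, dg$hi), c(1, 1))
  # width shrinks monotonically with n at fixed r
  widths <- sapply(c(5, 10, 20, 50, 200), function(n) {
    ci <- fisher_ci(0.4, n); ci$hi - ci$lo
  })
  expect_true(all(diff(widths) < 0))
})

test_that("bootstrap RMSE interval collapses for perfect predictions and is seeded", {
  y <- c(1, 2, 3, 4, 5)
  ci <- bootstrap_rmse_ci(y, y, B = 200, seed = 1)
  expect_equal(c(ci$lo, ci$hi), c(0, 0))
  set.seed(99)
  y2 <- rnorm(30); p2 <- y2 + rnorm(30, 0, 0.5)
  a <- bootstrap_rmse_ci(y2, p2, B = 500, seed = 7)
  b <- bootstrap_rmse_ci(y2, p2, B = 500, seed = 7)
  expect_identical(a, b)
})

test_that("the centered bootstrap matches an independent high-B oracle", {
  set.seed(5)
  y <- rnorm(40, 2, 1); p <- 0.7 * y + rnorm(40, 0, 0.6)
  got <- bootstrap_rmse_ci(y, p, B = 1000, seed = 3)
  # independent oracle: vectorized resampling, same statistic definition
  set.seed(1234)
  oracle <- replicate(10000, {
    i <- sample(40, 40, replace = TRUE)
    sy <- sqrt(mean((y[i] - mean(y[i]))^2))
    sp <- sqrt(mean((p[i] - mean(p[i]))^2))
    ar <- if (sy == 0 || sp == 0) 0 else abs(cor(y[i], p[i]))
    sqrt(max(sy^2 + sp^2 - 2 * sy * sp * ar, 0))
  })
  expect_lt(abs(got$lo - quantile(oracle, 0.025, names = FALSE)), 0.02)
  expect_lt(abs(got$hi - quantile(oracle, 0.975, names = FALSE)), 0.02)
})

test_that("bootstrap interval usually covers the point statistic", {
  set.seed(21)
  hits <- 0L
  for (i in 1:40) {
    y <- rnorm(25); p <- 0.5 * y + rnorm(25, 0, 0.7)
    tp <- taylor_point(y, p)
    ci <- bootstrap_rmse_ci(y, p, B = 300, seed = i)
    if (tp$e_prime >= ci$lo && tp$e_prime <= ci$hi) hits <- hits + 1L
  }
  expect_gte(hits, 36L)
})

test_that("taylor points satisfy the law-of-cosines identity", {
  set.seed(17)
  for (i in 1:50) {
    y <- rnorm(30, 1, 2); p <- 0.4 * y + rnorm(30)
    tp <- taylor_point(y, p)
    expect_equal(tp$e_prime^2,
                 tp$sigma_ref^2 + tp$sigma_pred^2 -
                   2 * tp$sigma_ref * tp$sigma_pred * tp$r,
                 tolerance = 1e-9)
    # direct residual computation of the centered error
    direct <- sqrt(mean(((y - mean(y)) - (p - mean(p)))^2))
    expect_equal(tp$e_prime, direct, tolerance = 1e-9)
    expect_gte(rmse(y, p) + 1e-12, tp$e_prime) # bias term is nonnegative
    expect_equal(c(tp$x, tp$y),
                 c(tp$sigma_pred * tp$r, tp$sigma_pred * sqrt(1 - tp$r^2)),
                 tolerance = 1e-12)
  }
  # perfect prediction coincides with the reference
  y <- rnorm(20)
  tp <- taylor_point(y, y)
  expect_equal(tp$e_prime, 0, tolerance = 1e-12)
  expect_equal(tp$sigma_pred, tp$sigma_ref)
  # sigma_ref = sigma_pred = 1, r = 0 gives E' = sqrt(2)
  tp2 <- list(sigma_ref = 1, sigma_pred = 1, r = 0)
  expect_equal(sqrt(tp2$sigma_ref^2 + tp2$sigma_pred^2), sqrt(2))
  flat <- taylor_point(y, rep(1, 20))
  expect_equal(c(flat$sigma_pred, flat$r, flat$x, flat$y), c(0, 0, 0, 0))
})

test_that("cross-participant aggregation uses the t interval and never fabricates one", {
  one <- aggregate_mean_tci(3.2)
  expect_equal(one$mean, 3.2)
  expect_true(one$missing)
  agg <- aggregate_mean_tci(c(1, 2, 3))
  expect_equal(agg$mean, 2)
  half <- qt(0.975, df = 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(c(agg$lo, agg$hi), c(2 - half, 2 + half), tolerance = 1e-12)
  same <- aggregate_mean_tci(c(2, 2, 2))
  expect_equal(c(same$lo, same$hi), c(2, 2))
})

test_that("contrast tables bold the best cell and flag disjoint intervals", {
  rep_dt <- data.table(
    participant_id = "P1", scale_id = "speech",
    paradigm = c("individual_batch", "transfer_batch", "transfer_incremental"),
    rmse = c(0.20, 0.08, 0.04), rmse_lo = c(0.14, 0.04, 0.03),
    rmse_hi = c(0.28, 0.10, 0.04),
    r = c(-0.05, -0.02, 0.22), r_lo = c(-0.15, -0.04, 0.00),
    r_hi = c(0.00, 0.00, 0.66), n = 39)
  ct <- contrast_table(rep_dt)
  expect_equal(ct[best == TRUE]$method, "transfer_incremental")
  # (0.03-0.04) is disjoint below (0.14-0.28): significantly better
  expect_match(ct[method == "transfer_incremental"]$sig_better_than,
               "individual_batch")
  # overlapping intervals are not flagged
  expect_false(grepl("transfer_batch",
                     ct[method == "transfer_incremental"]$sig_better_than))
  # unmodeled rows render with the dash convention
  na_row <- data.table(participant_id = "P1", scale_id = "salivation",
                       paradigm = c("a", "b"), rmse = NA_real_,
                       rmse_lo = NA_real_, rmse_hi = NA_real_, r = NA_real_,
                       r_lo = NA_real_, r_hi = NA_real_, n = 0)
  ctna <- contrast_table(na_row)
  expect_true(all(ctna$cell == "—"))
  # exact ties are reported as ties
  tie <- copy(rep_dt)[, rmse := 0.1][, rmse_lo := 0.05][, rmse_hi := 0.15]
  expect_true(all(contrast_table(tie)$tie))
})

test_that("evaluate_cell assembles a coherent metric row", {
  set.seed(2)
  y <- rnorm(25, 3, 1); p <- y + rnorm(25, 0, 0.4)
  row <- evaluate_cell(y, p, B = 200, seed = 1,
                       cell = list(participant_id = "P1",
                                   scale_id = "speech",
                                   method = "linear",
                                   paradigm = "individual_batch"))
  expect_equal(row$n, 25L)
  expect_true(row$rmse_lo <= row$rmse_hi)
  expect_true(row$r_lo <= row$r & row$r <= row$r_hi)
  expect_equal(row$e_prime^2,
               row$sigma_ref^2 + row$sigma_pred^2 -
                 2 * row$sigma_ref * row$sigma_pred * row$r,
               tolerance = 1e-9)
  # degenerate predictions render as 0 (0-0)
  drow <- evaluate_cell(y, rep(1, 25), B = 50, seed = 1)
  expect_equal(c(drow$r, drow$r_lo, drow$r_hi), c(0, 0, 0))
  expect_true(drow$r_degenerate)
})
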