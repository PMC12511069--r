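#' Configuration of the shallow self-attention interpolator
#'
#' A deliberately small transformer encoder: date-indexed sensor feature
#' vectors (plus a normalized day-index positional input) pass through a
#' linear embedding, `n_layers` blocks of multi-head scaled dot-product
#' self-attention with residual connections and a two-layer ReLU feed-forward
#' net, and a linear read-out. It is trained full-batch by Adam against the
#' observed scores on anchor days only (mean squared error on standardized
#' targets), then evaluated on all days. Keeping it shallow yields smooth,
#' continuous estimates rather than crisp label predictions.
#'
#' @param d_model embedding width (default 32; must be divisible by n_heads)
#' @param n_heads attention heads (default 2)
#' @param n_layers encoder blocks (default 1)
#' @param ff_dim feed-forward hidden width (default 64)
#' @param epochs full-batch training epochs (default 200; no early stopping,
#'   for determinism)
#' @param learning_rate Adam step size (default 1e-3)
#' @param seed integer seed for the parameter initialization
#' @param target_mode "score" regresses the observed score directly;
#'   "delta" regresses per-day change and integrates it forward from the most
#'   recent anchor
#' @return an `attention_config` list
#' @export
attention_config <- function(d_model = 32L, n_heads = 2L, n_layers = 1L,
                             ff_dim = 64L, epochs = 200L,
                             learning_rate = 1e-3, seed = 1L,
                             target_mode = c("score", "delta")) {
  target_mode <- match.arg(target_mode)
  if (d_model %% n_heads != 0L) stop_alstrack("d_model must be divisible by n_heads")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), ff_dim = as.integer(ff_dim),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed), target_mode = target_mode),
            class = "attention_config")
}

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

init_attention_params <- function(n_features, cfg) {
  set.seed(cfg$seed)
  d <- cfg$d_model; ff <- cfg$ff_dim
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
         Wo = glorot(d, d), bo = numeric(d),
         Wf1 = glorot(d, ff), bf1 = numeric(ff),
         Wf2 = glorot(ff, d), bf2 = numeric(d))
  })
  # zero-initialized read-out: the model starts at the target mean, which
  # keeps early training stable and makes constant targets exact
  list(Win = glorot(n_features, d), bin = numeric(d),
       layers = layers,
       wout = matrix(0, d, 1L), bout = 0)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# forward pass; returns predictions and the caches needed for backprop
attention_forward <- function(params, X, cfg) {
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  H <- X %*% params$Win + matrix(params$bin, nrow(X), d, byrow = TRUE)
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    p <- params$layers[[l]]
    Q <- H %*% p$Wq; K <- H %*% p$Wk; V <- H %*% p$Wv
    Z <- matrix(0, nrow(X), d)
    A_list <- vector("list", nh)
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dh)
      A <- softmax_rows(S)
      A_list[[h]] <- A
      Z[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    O <- Z %*% p$Wo + matrix(p$bo, nrow(X), d, byrow = TRUE)
    H1 <- H + O
    P <- H1 %*% p$Wf1 + matrix(p$bf1, nrow(X), cfg$ff_dim, byrow = TRUE)
    U <- pmax(P, 0)
    H2 <- H1 + U %*% p$Wf2 + matrix(p$bf2, nrow(X), d, byrow = TRUE)
    caches[[l]] <- list(H = H, Q = Q, K = K, V = V, A = A_list, Z = Z,
                        H1 = H1, P = P, U = U)
    H <- H2
  }
  yhat <- as.numeric(H %*% params$wout + params$bout)
  list(yhat = yhat, H_final = H, caches = caches)
}

# backprop of dL/dyhat through the encoder; returns grads mirroring params
attention_backward <- function(params, X, fwd, dy, cfg) {
  d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  g <- list(Win = NULL, bin = NULL, layers = vector("list", cfg$n_layers),
            wout = NULL, bout = NULL)
  dy <- matrix(dy, ncol = 1L)
  g$wout <- crossprod(fwd$H_final, dy)
  g$bout <- sum(dy)
  dH <- dy %*% t(params$wout)
  for (l in rev(seq_len(cfg$n_layers))) {
    p <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    dH1 <- dH                            # residual branch of H2 = H1 + FF
    dFF <- dH
    g$layers[[l]]$Wf2 <- crossprod(cc$U, dFF)
    g$layers[[l]]$bf2 <- colSums(dFF)
    dU <- dFF %*% t(p$Wf2)
    dP <- dU * (cc$P > 0)
    g$layers[[l]]$Wf1 <- crossprod(cc$H1, dP)
    g$layers[[l]]$bf1 <- colSums(dP)
    dH1 <- dH1 + dP %*% t(p$Wf1)
    dO <- dH1
    dHres <- dH1                         # residual branch of H1 = H + O
    g$layers[[l]]$Wo <- crossprod(cc$Z, dO)
    g$layers[[l]]$bo <- colSums(dO)
    dZ <- dO %*% t(p$Wo)
    dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
    for (h in seq_len(nh)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dZh <- dZ[, idx, drop = FALSE]
      dA <- tcrossprod(dZh, cc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dZh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% cc$K[, idx, drop = FALSE] / sqrt(dh)
      dK[, idx] <- crossprod(dS, cc$Q[, idx, drop = FALSE]) / sqrt(dh)
    }
    g$layers[[l]]$Wq <- crossprod(cc$H, dQ)
    g$layers[[l]]$Wk <- crossprod(cc$H, dK)
    g$layers[[l]]$Wv <- crossprod(cc$H, dV)
    dH <- dHres + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  g$Win <- crossprod(X, dH)
  g$bin <- colSums(dH)
  g
}

# MSE on masked rows plus gradients; the unit checked by finite differences
attention_loss_grads <- function(params, X, z, mask, cfg) {
  fwd <- attention_forward(params, X, cfg)
  resid <- (fwd$yhat - z) * mask
  n <- sum(mask)
  loss <- sum(resid^2) / n
  dy <- 2 * resid / n
  list(loss = loss, grads = attention_backward(params, X, fwd, dy, cfg))
}

# flatten/rebuild helpers so Adam state can be kept per tensor
param_walk <- function(params, grads, state, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  upd <- function(w, gw, st) {
    if (is.null(st)) st <- list(m = w * 0, v = w * 0)
    st$m <- b1 * st$m + (1 - b1) * gw
    st$v <- b2 * st$v + (1 - b2) * gw^2
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    list(w = w - lr * mhat / (sqrt(vhat) + eps), st = st)
  }
  for (nm in c("Win", "bin", "wout", "bout")) {
    r <- upd(params[[nm]], grads[[nm]], state[[nm]])
    params[[nm]] <- r$w; state[[nm]] <- r$st
  }
  for (l in seq_along(params$layers)) {
    for (nm in names(params$layers[[l]])) {
      r <- upd(params$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$layers[[l]][[nm]])
      params$layers[[l]][[nm]] <- r$w
      state$layers[[l]][[nm]] <- r$st
    }
  }
  list(params = params, state = state)
}

#' Fit the shallow self-attention interpolator on one feature table
#'
#' Builds the date-indexed input matrix (feature columns plus a normalized
#' day-index positional column), standardizes the anchor scores, trains by
#' full-batch Adam on anchor days only, and returns clipped daily estimates
#' on the requested index. Days absent from the feature table (sensor
#' dropout) are filled by linear interpolation of the estimates.
#'
#' @param features daily feature table: a `day` column (or `date`, from
#'   which day indices are derived) plus numeric feature columns
#' @param assessments wide assessment table with observed scores
#' @param participant,scale_id target cell
#' @param daily_index day indices on which estimates are required
#' @param config an [attention_config()]
#' @return list with `estimates` (numeric, on `daily_index`), `params`,
#'   `loss` (final training loss), `anchor_days`
#' @export
fit_attention_interpolator <- function(features, assessments, participant,
                                       scale_id, daily_index,
                                       config = attention_config()) {
  feats <- as.data.table(features)
  if (!"day" %in% names(feats)) {
    if (!"date" %in% names(feats)) stop_alstrack("features need a day or date column")
    feats[, day := as.integer(date - min(date))]
  }
  fcols <- setdiff(names(feats), c("day", "date"))
  an <- anchor_points(assessments, participant, scale_id)
  if (length(an$day) < 2L) stop_alstrack("insufficient anchors (need >= 2)")

  X <- as.matrix(feats[, ..fcols])
  X[!is.finite(X)] <- 0
  X <- cbind(X, pos = feats$day / max(max(daily_index), 1L))
  rows_anchor <- match(an$day, feats$day)
  covered <- !is.na(rows_anchor)
  if (sum(covered) < 2L) stop_alstrack("fewer than two anchor days have sensor coverage")
  mask <- rep(0, nrow(X))
  mask[rows_anchor[covered]] <- 1

  if (config$target_mode == "delta") {
    # per-day change between consecutive anchors, integrated at prediction
    sc <- an$score[covered]; dd <- an$day[covered]
    slope <- c(diff(sc) / diff(dd), 0)
    tgt_at_anchor <- slope[findInterval(dd, dd)]
  } else {
    tgt_at_anchor <- an$score[covered]
  }
  mu <- mean(tgt_at_anchor)
  sdz <- sd(tgt_at_anchor)
  if (!is.finite(sdz) || sdz == 0) sdz <- 1
  z <- rep(0, nrow(X))
  z[rows_anchor[covered]] <- (tgt_at_anchor - mu) / sdz

  params <- init_attention_params(ncol(X), config)
  state <- list(layers = vector("list", config$n_layers))
  loss <- NA_real_
  for (t in seq_len(config$epochs)) {
    lg <- attention_loss_grads(params, X, z, mask, config)
    loss <- lg$loss
    r <- param_walk(params, lg$grads, state, config$learning_rate, t)
    params <- r$params; state <- r$state
  }
  raw <- attention_forward(params, X, config)$yhat * sdz + mu

  if (config$target_mode == "delta") {
    # integrate predicted per-day change forward from the latest anchor
    est_days <- feats$day
    sc <- an$score[covered]; dd <- an$day[covered]
    pred <- numeric(length(est_days))
    for (i in seq_along(est_days)) {
      t0 <- est_days[i]
      k <- findInterval(t0, dd)
      if (k == 0L) { pred[i] <- sc[1]; next }
      span <- which(est_days > dd[k] & est_days <= t0)
      pred[i] <- sc[k] + sum(raw[span])
    }
    raw <- pred
  }
  rng <- scale_range(scale_id)
  raw <- clip(raw, rng[1], rng[2])
  est <- approx(feats$day, raw, xout = daily_index, rule = 2)$y
  list(estimates = clip(est, rng[1], rng[2]), params = params, loss = loss,
       anchor_days = an$day[covered])
}
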