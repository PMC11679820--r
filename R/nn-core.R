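# Numerical core for the sequence classifiers: layer primitives with
# explicit forward/backward passes, parameter initialisation, optimizers
# and the learning-rate schedule. All activations flow through plain
# matrices; a batch of B clips of T frames is a (B*T) x d matrix with
# clip rows contiguous.

glorot_uniform <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

dense_fw <- function(X, W, b) {
  sweep(X %*% W, 2L, b, "+")
}

# returns list(dX, dW, db)
dense_bw <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

relu <- function(X) {
  X * (X > 0)
}

layernorm_fw <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bw <- function(cache, g, dY) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  e <- exp(X - m)
  e / rowSums(e)
}

dropout_fw <- function(X, rate, train) {
  if (!train || rate <= 0) {
    return(list(out = X, mask = NULL))
  }
  keep <- 1 - rate
  mask <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X)) / keep
  list(out = X * mask, mask = mask)
}

dropout_bw <- function(mask, dY) {
  if (is.null(mask)) dY else dY * mask
}

# source-row index for a temporal shift of `off` frames within each clip;
# out-of-clip positions map to the zero row BT + 1
conv_idx <- function(B, T_len, off) {
  t <- rep(seq_len(T_len), B)
  r <- seq_len(B * T_len)
  src <- r + off
  src[t + off < 1L | t + off > T_len] <- B * T_len + 1L
  src
}

# 1-D convolution over time ('same' zero padding, odd kernel).
# W: array [k, d_in, filters]; X: (BT) x d_in.
conv1d_fw <- function(X, W, b, B, T_len) {
  k <- dim(W)[1]
  half <- (k - 1L) %/% 2L
  Xz <- rbind(X, 0)
  out <- matrix(rep(b, each = nrow(X)), nrow(X), dim(W)[3])
  idx <- vector("list", k)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    idx[[j]] <- conv_idx(B, T_len, off)
    out <- out + Xz[idx[[j]], , drop = FALSE] %*% W[j, , ]
  }
  list(out = out, idx = idx)
}

conv1d_bw <- function(X, W, dY, idx) {
  k <- dim(W)[1]
  n <- nrow(X)
  Xz <- rbind(X, 0)
  dXz <- matrix(0, n + 1L, ncol(X))
  dW <- array(0, dim = dim(W))
  for (j in seq_len(k)) {
    Xs <- Xz[idx[[j]], , drop = FALSE]
    dW[j, , ] <- crossprod(Xs, dY)
    back <- dY %*% t(W[j, , ])
    dXz[idx[[j]], ] <- dXz[idx[[j]], , drop = FALSE] + back
    # rows mapped to the zero row accumulate there and are dropped
  }
  list(dX = dXz[seq_len(n), , drop = FALSE], dW = dW, db = colSums(dY))
}

sinusoidal_encoding <- function(T_len, d) {
  pe <- matrix(0, T_len, d)
  pos <- seq_len(T_len) - 1L
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pe[, 2L * i - 1L] <- sin(pos * freq)
    if (2L * i <= d) pe[, 2L * i] <- cos(pos * freq)
  }
  pe
}

#' Cosine-decay learning rate
#'
#' @param epoch Zero-based epoch index.
#' @param base Base learning rate (the rate at epoch 0).
#' @param max_epochs Decay horizon; the rate reaches `floor` there.
#' @param floor Terminal learning rate.
#' @return The learning rate for `epoch`.
#' @export
cosine_decay_lr <- function(epoch, base, max_epochs, floor = 0) {
  frac <- min(max(epoch / max_epochs, 0), 1)
  floor + (base - floor) * 0.5 * (1 + cos(pi * frac))
}

# ---- optimizers -----------------------------------------------------------

opt_init <- function(kind, params, weight_decay = 1e-4, momentum = 0) {
  zeros <- lapply(params, function(p) array(0, dim = dim(as.array(p))))
  list(
    kind = kind, t = 0L, m = zeros, v = zeros,
    weight_decay = weight_decay, momentum = momentum,
    beta1 = 0.9, beta2 = 0.999, eps = 1e-7
  )
}

opt_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    p <- params[[nm]]
    if (opt$kind == "sgd") {
      if (opt$momentum > 0) {
        opt$m[[nm]] <- opt$momentum * opt$m[[nm]] + g
        g <- opt$m[[nm]]
      }
      params[[nm]] <- p - lr * g
    } else { # adam / adamw
      opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
      opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
      mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
      vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
      step <- lr * mhat / (sqrt(vhat) + opt$eps)
      if (opt$kind == "adamw" && length(dim(as.array(p))) >= 2L) {
        step <- step + lr * opt$weight_decay * p # decoupled decay on weight matrices
      }
      params[[nm]] <- p - step
    }
  }
  list(opt = opt, params = params)
}

# cross-entropy over softmax probs; Y is a B x K one-hot matrix
xent_loss <- function(probs, Y) {
  -mean(log(rowSums(probs * Y) + 1e-12))
}
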