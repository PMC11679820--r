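#' Recurrent baseline configuration
#'
#' LSTM / GRU baselines: stacked recurrent layers whose final hidden
#' state feeds, through dropout, a dense softmax over the classes.
#'
#' @param kind `"lstm"` or `"gru"`.
#' @param units Hidden units per layer (>= 1).
#' @param num_layers Stacked recurrent layers.
#' @param dropout_rate Dropout on the final hidden state, in \[0, 1).
#' @param l2_weight L2 penalty on the output dense weights.
#' @param num_classes Output classes.
#' @return A `recurrent_config` list.
#' @export
recurrent_config <- function(kind = c("lstm", "gru"), units = 64L,
                             num_layers = 1L, dropout_rate = 0.2,
                             l2_weight = 1e-4, num_classes = 7L) {
  kind <- match.arg(kind)
  if (units < 1L) stop("invalid config: units must be >= 1")
  if (num_layers < 1L) stop("invalid config: num_layers must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("invalid config: dropout_rate must be in [0, 1)")
  structure(
    list(
      kind = kind, units = units, num_layers = num_layers,
      dropout_rate = dropout_rate, l2_weight = l2_weight,
      num_classes = num_classes
    ),
    class = "recurrent_config"
  )
}

#' Build a recurrent (LSTM/GRU) sequence classifier
#'
#' @param d_in Input channel count.
#' @param T_len Sequence length.
#' @param cfg A [recurrent_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `fall_classifier` object (untrained).
#' @export
build_recurrent <- function(d_in, T_len, cfg = recurrent_config(), seed = 0L) {
  stopifnot(d_in >= 1L, T_len >= 1L)
  with_preserved_seed(seed, {
    u <- cfg$units
    ng <- if (cfg$kind == "lstm") 4L else 3L
    p <- list()
    din <- d_in
    for (l in seq_len(cfg$num_layers)) {
      pre <- sprintf("l%d_", l)
      p[[paste0(pre, "W")]] <- glorot_uniform(din, ng * u)
      p[[paste0(pre, "U")]] <- glorot_uniform(u, ng * u)
      b <- rep(0, ng * u)
      if (cfg$kind == "lstm") b[(u + 1L):(2L * u)] <- 1 # forget-gate bias
      p[[paste0(pre, "b")]] <- b
      din <- u
    }
    p$Wout <- glorot_uniform(u, cfg$num_classes)
    p$bout <- rep(0, cfg$num_classes)
    structure(
      list(
        kind = cfg$kind, cfg = cfg, d_in = d_in, T_len = T_len, params = p,
        classes = posture_classes()[seq_len(cfg$num_classes)],
        channels = NULL, history = NULL
      ),
      class = c("fall_recurrent", "fall_classifier")
    )
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward; X is B x T x d array
recurrent_fw <- function(model, Xarr, train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  B <- dim(Xarr)[1]
  T_len <- dim(Xarr)[2]
  u <- cfg$units
  layers <- vector("list", cfg$num_layers)
  inp <- Xarr
  for (l in seq_len(cfg$num_layers)) {
    pre <- sprintf("l%d_", l)
    W <- p[[paste0(pre, "W")]]
    U <- p[[paste0(pre, "U")]]
    b <- p[[paste0(pre, "b")]]
    h <- matrix(0, B, u)
    cst <- matrix(0, B, u)
    Hs <- array(0, dim = c(B, T_len, u))
    gates <- vector("list", T_len)
    for (t in seq_len(T_len)) {
      Xt <- matrix(inp[, t, ], B)
      if (cfg$kind == "lstm") {
        Z <- sweep(Xt %*% W + h %*% U, 2L, b, "+")
        i <- sigmoid(Z[, 1:u, drop = FALSE])
        f <- sigmoid(Z[, (u + 1):(2 * u), drop = FALSE])
        gg <- tanh(Z[, (2 * u + 1):(3 * u), drop = FALSE])
        o <- sigmoid(Z[, (3 * u + 1):(4 * u), drop = FALSE])
        c_prev <- cst
        cst <- f * c_prev + i * gg
        tc <- tanh(cst)
        h <- o * tc
        gates[[t]] <- list(i = i, f = f, g = gg, o = o, c_prev = c_prev, c = cst, tc = tc, Xt = Xt)
      } else {
        Zzr <- sweep(Xt %*% W[, 1:(2 * u), drop = FALSE] + h %*% U[, 1:(2 * u), drop = FALSE],
          2L, b[1:(2 * u)], "+"
        )
        z <- sigmoid(Zzr[, 1:u, drop = FALSE])
        r <- sigmoid(Zzr[, (u + 1):(2 * u), drop = FALSE])
        rh <- r * h
        n <- tanh(sweep(Xt %*% W[, (2 * u + 1):(3 * u), drop = FALSE] +
          rh %*% U[, (2 * u + 1):(3 * u), drop = FALSE], 2L, b[(2 * u + 1):(3 * u)], "+"))
        h_prev <- h
        h <- (1 - z) * n + z * h_prev
        gates[[t]] <- list(z = z, r = r, n = n, h_prev = h_prev, rh = rh, Xt = Xt)
      }
      Hs[, t, ] <- h
    }
    layers[[l]] <- list(Hs = Hs, gates = gates, inp = inp)
    inp <- Hs
  }
  h_last <- matrix(Hs[, T_len, ], B)
  drp <- dropout_fw(h_last, cfg$dropout_rate, train)
  logits <- dense_fw(drp$out, p$Wout, p$bout)
  list(
    probs = softmax_rows(logits),
    cache = list(layers = layers, h_last = h_last, head_mask = drp$mask, head_in = drp$out, B = B, T_len = T_len)
  )
}

recurrent_bw <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- model$params
  u <- cfg$units
  B <- cache$B
  T_len <- cache$T_len
  g <- list()
  bw <- dense_bw(cache$head_in, p$Wout, dlogits)
  g$Wout <- bw$dW + 2 * cfg$l2_weight * p$Wout
  g$bout <- bw$db
  dh_top <- dropout_bw(cache$head_mask, bw$dX)

  # gradient w.r.t. every timestep output of the topmost layer: only the
  # last step receives head gradient; lower layers receive full sequences
  dHs_next <- array(0, dim = c(B, T_len, u))
  dHs_next[, T_len, ] <- dh_top

  for (l in rev(seq_len(cfg$num_layers))) {
    pre <- sprintf("l%d_", l)
    W <- p[[paste0(pre, "W")]]
    U <- p[[paste0(pre, "U")]]
    lay <- cache$layers[[l]]
    din <- dim(lay$inp)[3]
    dW <- array(0, dim = dim(W))
    dU <- array(0, dim = dim(U))
    db <- rep(0, length(p[[paste0(pre, "b")]]))
    dInp <- array(0, dim = dim(lay$inp))
    dh <- matrix(0, B, u)
    dc <- matrix(0, B, u)
    for (t in rev(seq_len(T_len))) {
      dh <- dh + matrix(dHs_next[, t, ], B)
      gt <- lay$gates[[t]]
      h_prev <- if (t > 1L) matrix(lay$Hs[, t - 1L, ], B) else matrix(0, B, u)
      if (cfg$kind == "lstm") {
        do_ <- dh * gt$tc * gt$o * (1 - gt$o)
        dc <- dc + dh * gt$o * (1 - gt$tc^2)
        di <- dc * gt$g * gt$i * (1 - gt$i)
        df <- dc * gt$c_prev * gt$f * (1 - gt$f)
        dg <- dc * gt$i * (1 - gt$g^2)
        dZ <- cbind(di, df, dg, do_)
        dW <- dW + crossprod(gt$Xt, dZ)
        dU <- dU + crossprod(h_prev, dZ)
        db <- db + colSums(dZ)
        dInp[, t, ] <- dZ %*% t(W)
        dh <- dZ %*% t(U)
        dc <- dc * gt$f
      } else {
        dz <- dh * (h_prev - gt$n) * gt$z * (1 - gt$z)
        dn <- dh * (1 - gt$z) * (1 - gt$n^2)
        dh_prev <- dh * gt$z
        Wn <- W[, (2 * u + 1):(3 * u), drop = FALSE]
        Un <- U[, (2 * u + 1):(3 * u), drop = FALSE]
        drh <- dn %*% t(Un)
        dr <- drh * gt$h_prev * gt$r * (1 - gt$r)
        dh_prev <- dh_prev + drh * gt$r
        dZzr <- cbind(dz, dr)
        dW[, 1:(2 * u)] <- dW[, 1:(2 * u)] + crossprod(gt$Xt, dZzr)
        dU[, 1:(2 * u)] <- dU[, 1:(2 * u)] + crossprod(gt$h_prev, dZzr)
        db[1:(2 * u)] <- db[1:(2 * u)] + colSums(dZzr)
        dW[, (2 * u + 1):(3 * u)] <- dW[, (2 * u + 1):(3 * u)] + crossprod(gt$Xt, dn)
        dU[, (2 * u + 1):(3 * u)] <- dU[, (2 * u + 1):(3 * u)] + crossprod(gt$rh, dn)
        db[(2 * u + 1):(3 * u)] <- db[(2 * u + 1):(3 * u)] + colSums(dn)
        dInp[, t, ] <- dZzr %*% t(W[, 1:(2 * u), drop = FALSE]) + dn %*% t(Wn)
        dh <- dh_prev + dZzr %*% t(U[, 1:(2 * u), drop = FALSE])
      }
    }
    g[[paste0(pre, "W")]] <- dW
    g[[paste0(pre, "U")]] <- dU
    g[[paste0(pre, "b")]] <- db
    dHs_next <- dInp
  }
  g$dX <- dHs_next # gradient w.r.t. the input array (for checks)
  g
}

recurrent_l2 <- function(model) {
  model$cfg$l2_weight * sum(model$params$Wout^2)
}
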