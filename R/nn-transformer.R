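#' Transformer classifier configuration
#'
#' Architecture hyperparameters for the transformer encoder sequence
#' classifier. Each encoder block is: LayerNorm, multi-head
#' self-attention, dropout, residual add, LayerNorm, a 1-D convolutional
#' position-wise feed-forward (ReLU) projected back to the model width,
#' and a second residual add. Blocks are followed by global average
#' pooling over time, a ReLU MLP with dropout and L2 weight penalties,
#' and a softmax output over the seven classes.
#'
#' @param num_blocks Number of encoder blocks.
#' @param num_heads Attention heads per block.
#' @param key_dim Per-head query/key/value width.
#' @param d_model Model (embedding) width after the input projection.
#' @param ff_conv_filters Filters in the feed-forward convolution;
#'   default 4 x `d_model`.
#' @param ff_conv_kernel Odd kernel size of the feed-forward convolution.
#' @param dropout_rate Dropout rate in \[0, 1).
#' @param mlp_units Hidden widths of the classification MLP.
#' @param l2_weight L2 penalty on the dense (MLP and output) weights.
#' @param num_classes Output classes (the seven-posture vocabulary).
#' @param positional_encoding `"sinusoidal"`, `"learned"` or `"none"`.
#' @return A `transformer_config` list.
#' @export
transformer_config <- function(num_blocks = 2L, num_heads = 4L, key_dim = 32L,
                               d_model = 64L, ff_conv_filters = NULL,
                               ff_conv_kernel = 1L, dropout_rate = 0.1,
                               mlp_units = 128L, l2_weight = 1e-4,
                               num_classes = 7L,
                               positional_encoding = c("sinusoidal", "learned", "none")) {
  positional_encoding <- match.arg(positional_encoding)
  if (is.null(ff_conv_filters)) ff_conv_filters <- 4L * d_model
  fields <- list(
    num_blocks = num_blocks, num_heads = num_heads, key_dim = key_dim,
    d_model = d_model, ff_conv_filters = ff_conv_filters,
    ff_conv_kernel = ff_conv_kernel, dropout_rate = dropout_rate,
    mlp_units = mlp_units, l2_weight = l2_weight, num_classes = num_classes,
    positional_encoding = positional_encoding
  )
  for (nm in c("num_blocks", "num_heads", "key_dim", "d_model", "ff_conv_filters")) {
    if (fields[[nm]] < 1L) stop("invalid config: ", nm, " must be >= 1")
  }
  if (ff_conv_kernel %% 2L != 1L) stop("invalid config: ff_conv_kernel must be odd")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("invalid config: dropout_rate must be in [0, 1)")
  if (l2_weight < 0) stop("invalid config: l2_weight must be >= 0")
  structure(fields, class = "transformer_config")
}

#' Build a transformer sequence classifier
#'
#' Initialises the weights of the architecture described in
#' [transformer_config()] for inputs of `T` frames and `d_in` channels.
#'
#' @param d_in Input channel count.
#' @param T_len Sequence length (frames per clip).
#' @param cfg A [transformer_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `fall_classifier` object (untrained).
#' @export
build_transformer <- function(d_in, T_len, cfg = transformer_config(), seed = 0L) {
  stopifnot(d_in >= 1L, T_len >= 1L)
  with_preserved_seed(seed, {
    d <- cfg$d_model
    hk <- cfg$num_heads * cfg$key_dim
    f <- cfg$ff_conv_filters
    k <- cfg$ff_conv_kernel
    p <- list(
      Wp = glorot_uniform(d_in, d), bp = rep(0, d)
    )
    for (i in seq_len(cfg$num_blocks)) {
      pre <- sprintf("b%d_", i)
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- rep(0, d)
      p[[paste0(pre, "Wq")]] <- glorot_uniform(d, hk)
      p[[paste0(pre, "bq")]] <- rep(0, hk)
      p[[paste0(pre, "Wk")]] <- glorot_uniform(d, hk)
      p[[paste0(pre, "bk")]] <- rep(0, hk)
      p[[paste0(pre, "Wv")]] <- glorot_uniform(d, hk)
      p[[paste0(pre, "bv")]] <- rep(0, hk)
      p[[paste0(pre, "Wo")]] <- glorot_uniform(hk, d)
      p[[paste0(pre, "bo")]] <- rep(0, d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- rep(0, d)
      p[[paste0(pre, "Wc1")]] <- glorot_uniform(k * d, f, dims = c(k, d, f))
      p[[paste0(pre, "bc1")]] <- rep(0, f)
      p[[paste0(pre, "Wc2")]] <- glorot_uniform(f, d)
      p[[paste0(pre, "bc2")]] <- rep(0, d)
    }
    prev <- d
    for (j in seq_along(cfg$mlp_units)) {
      p[[sprintf("mlp%d_W", j)]] <- glorot_uniform(prev, cfg$mlp_units[j])
      p[[sprintf("mlp%d_b", j)]] <- rep(0, cfg$mlp_units[j])
      prev <- cfg$mlp_units[j]
    }
    p$Wout <- glorot_uniform(prev, cfg$num_classes)
    p$bout <- rep(0, cfg$num_classes)
    if (cfg$positional_encoding == "learned") {
      p$PE <- 0.02 * matrix(stats::rnorm(T_len * d), T_len, d)
    }
    structure(
      list(
        kind = "transformer", cfg = cfg, d_in = d_in, T_len = T_len,
        params = p,
        pe = if (cfg$positional_encoding == "sinusoidal") sinusoidal_encoding(T_len, d) else NULL,
        classes = posture_classes()[seq_len(cfg$num_classes)],
        channels = NULL, history = NULL
      ),
      class = c("fall_transformer", "fall_classifier")
    )
  })
}

# forward pass; Xm is (B*T) x d_in with clip rows contiguous
transformer_fw <- function(model, Xm, B, train = FALSE) {
  p <- model$params
  cfg <- model$cfg
  T_len <- model$T_len
  d <- cfg$d_model
  dk <- cfg$key_dim
  h <- cfg$num_heads
  cache <- list(Xm = Xm, B = B)

  H <- dense_fw(Xm, p$Wp, p$bp)
  pe <- switch(cfg$positional_encoding,
    sinusoidal = model$pe,
    learned = p$PE,
    none = NULL
  )
  if (!is.null(pe)) H <- H + pe[rep(seq_len(T_len), B), , drop = FALSE]
  cache$H0 <- H

  for (i in seq_len(cfg$num_blocks)) {
    pre <- sprintf("b%d_", i)
    bl <- list(H_in = H)
    ln1 <- layernorm_fw(H, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    bl$ln1 <- ln1
    N1 <- ln1$out
    Q <- dense_fw(N1, p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- dense_fw(N1, p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    V <- dense_fw(N1, p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    O <- matrix(0, nrow(N1), h * dk)
    Pattn <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T_len + 1L):(b * T_len)
      Pb <- vector("list", cfg$num_heads)
      for (hh in seq_len(h)) {
        hc <- ((hh - 1L) * dk + 1L):(hh * dk)
        S <- Q[rb, hc, drop = FALSE] %*% t(K[rb, hc, drop = FALSE]) / sqrt(dk)
        Pm <- softmax_rows(S)
        O[rb, hc] <- Pm %*% V[rb, hc, drop = FALSE]
        Pb[[hh]] <- Pm
      }
      Pattn[[b]] <- Pb
    }
    bl$N1 <- N1
    bl$Q <- Q
    bl$K <- K
    bl$V <- V
    bl$O <- O
    bl$Pattn <- Pattn
    A <- dense_fw(O, p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    drp <- dropout_fw(A, cfg$dropout_rate, train)
    bl$attn_mask <- drp$mask
    H2 <- H + drp$out
    bl$H2 <- H2
    ln2 <- layernorm_fw(H2, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    bl$ln2 <- ln2
    N2 <- ln2$out
    bl$N2 <- N2
    cv <- conv1d_fw(N2, p[[paste0(pre, "Wc1")]], p[[paste0(pre, "bc1")]], B, T_len)
    bl$F1pre <- cv$out
    bl$conv_idx <- cv$idx
    F1 <- relu(cv$out)
    bl$F1 <- F1
    F2 <- dense_fw(F1, p[[paste0(pre, "Wc2")]], p[[paste0(pre, "bc2")]])
    H <- H2 + F2
    cache[[paste0("block", i)]] <- bl
  }
  cache$Henc <- H

  # global average pooling over time
  G <- matrix(0, B, d)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * T_len + 1L):(b * T_len)
    G[b, ] <- colMeans(H[rb, , drop = FALSE])
  }
  cache$G <- G
  Z <- G
  for (j in seq_along(cfg$mlp_units)) {
    Zpre <- dense_fw(Z, p[[sprintf("mlp%d_W", j)]], p[[sprintf("mlp%d_b", j)]])
    cache[[sprintf("mlp%d_in", j)]] <- Z
    cache[[sprintf("mlp%d_pre", j)]] <- Zpre
    Za <- relu(Zpre)
    drp <- dropout_fw(Za, cfg$dropout_rate, train)
    cache[[sprintf("mlp%d_mask", j)]] <- drp$mask
    Z <- drp$out
  }
  cache$head_in <- Z
  logits <- dense_fw(Z, p$Wout, p$bout)
  cache$logits <- logits
  list(probs = softmax_rows(logits), cache = cache)
}

# backward pass from d(loss)/d(logits); returns named gradient list
transformer_bw <- function(model, cache, dlogits) {
  p <- model$params
  cfg <- model$cfg
  T_len <- model$T_len
  B <- cache$B
  dk <- cfg$key_dim
  h <- cfg$num_heads
  g <- list()

  bw <- dense_bw(cache$head_in, p$Wout, dlogits)
  g$Wout <- bw$dW + 2 * cfg$l2_weight * p$Wout
  g$bout <- bw$db
  dZ <- bw$dX
  for (j in rev(seq_along(cfg$mlp_units))) {
    dZ <- dropout_bw(cache[[sprintf("mlp%d_mask", j)]], dZ)
    dZ <- dZ * (cache[[sprintf("mlp%d_pre", j)]] > 0)
    bw <- dense_bw(cache[[sprintf("mlp%d_in", j)]], p[[sprintf("mlp%d_W", j)]], dZ)
    g[[sprintf("mlp%d_W", j)]] <- bw$dW + 2 * cfg$l2_weight * p[[sprintf("mlp%d_W", j)]]
    g[[sprintf("mlp%d_b", j)]] <- bw$db
    dZ <- bw$dX
  }

  # un-pool: every frame of clip b receives dG[b, ] / T
  dH <- matrix(0, B * T_len, cfg$d_model)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * T_len + 1L):(b * T_len)
    dH[rb, ] <- matrix(dZ[b, ] / T_len, T_len, cfg$d_model, byrow = TRUE)
  }

  for (i in rev(seq_len(cfg$num_blocks))) {
    pre <- sprintf("b%d_", i)
    bl <- cache[[paste0("block", i)]]
    # H = H2 + F2
    dH2 <- dH
    dF2 <- dH
    bw <- dense_bw(bl$F1, p[[paste0(pre, "Wc2")]], dF2)
    g[[paste0(pre, "Wc2")]] <- bw$dW
    g[[paste0(pre, "bc2")]] <- bw$db
    dF1 <- bw$dX * (bl$F1pre > 0)
    cb <- conv1d_bw(bl$N2, p[[paste0(pre, "Wc1")]], dF1, bl$conv_idx)
    g[[paste0(pre, "Wc1")]] <- cb$dW
    g[[paste0(pre, "bc1")]] <- cb$db
    lb <- layernorm_bw(bl$ln2, p[[paste0(pre, "ln2_g")]], cb$dX)
    g[[paste0(pre, "ln2_g")]] <- lb$dg
    g[[paste0(pre, "ln2_b")]] <- lb$db
    dH2 <- dH2 + lb$dX
    # H2 = H_in + dropout(A)
    dA <- dropout_bw(bl$attn_mask, dH2)
    bw <- dense_bw(bl$O, p[[paste0(pre, "Wo")]], dA)
    g[[paste0(pre, "Wo")]] <- bw$dW
    g[[paste0(pre, "bo")]] <- bw$db
    dO <- bw$dX
    dQ <- matrix(0, nrow(dO), h * dk)
    dK <- matrix(0, nrow(dO), h * dk)
    dV <- matrix(0, nrow(dO), h * dk)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T_len + 1L):(b * T_len)
      for (hh in seq_len(h)) {
        hc <- ((hh - 1L) * dk + 1L):(hh * dk)
        Pm <- bl$Pattn[[b]][[hh]]
        dOb <- dO[rb, hc, drop = FALSE]
        Vb <- bl$V[rb, hc, drop = FALSE]
        dP <- dOb %*% t(Vb)
        dV[rb, hc] <- crossprod(Pm, dOb)
        dS <- Pm * (dP - rowSums(dP * Pm))
        dQ[rb, hc] <- dS %*% bl$K[rb, hc, drop = FALSE] / sqrt(dk)
        dK[rb, hc] <- crossprod(dS, bl$Q[rb, hc, drop = FALSE]) / sqrt(dk)
      }
    }
    dN1 <- matrix(0, nrow(dO), cfg$d_model)
    bw <- dense_bw(bl$N1, p[[paste0(pre, "Wq")]], dQ)
    g[[paste0(pre, "Wq")]] <- bw$dW
    g[[paste0(pre, "bq")]] <- bw$db
    dN1 <- dN1 + bw$dX
    bw <- dense_bw(bl$N1, p[[paste0(pre, "Wk")]], dK)
    g[[paste0(pre, "Wk")]] <- bw$dW
    g[[paste0(pre, "bk")]] <- bw$db
    dN1 <- dN1 + bw$dX
    bw <- dense_bw(bl$N1, p[[paste0(pre, "Wv")]], dV)
    g[[paste0(pre, "Wv")]] <- bw$dW
    g[[paste0(pre, "bv")]] <- bw$db
    dN1 <- dN1 + bw$dX
    lb <- layernorm_bw(bl$ln1, p[[paste0(pre, "ln1_g")]], dN1)
    g[[paste0(pre, "ln1_g")]] <- lb$dg
    g[[paste0(pre, "ln1_b")]] <- lb$db
    dH <- dH2 + lb$dX
  }

  if (cfg$positional_encoding == "learned") {
    dPE <- matrix(0, T_len, cfg$d_model)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * T_len + 1L):(b * T_len)
      dPE <- dPE + dH[rb, , drop = FALSE]
    }
    g$PE <- dPE
  }
  bw <- dense_bw(cache$Xm, p$Wp, dH)
  g$Wp <- bw$dW
  g$bp <- bw$db
  g
}

# L2 penalty term included in the training objective (dense head weights)
transformer_l2 <- function(model) {
  p <- model$params
  w2 <- sum(p$Wout^2)
  for (j in seq_along(model$cfg$mlp_units)) {
    w2 <- w2 + sum(p[[sprintf("mlp%d_W", j)]]^2)
  }
  model$cfg$l2_weight * w2
}
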