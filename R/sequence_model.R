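# Configurable-scale transformer over topological sequences, implemented
# natively with analytic backpropagation: per-step convolutional (1x1)
# projection plus trainable multiscale (positional) embedding, multi-head
# self-attention encoder, an asymmetric (smaller) decoder for masked
# reconstruction pretraining, a regression head on the first position for
# affinity fine-tuning, and attention-score / gradient-saliency extraction.

#' Model configuration
#'
#' The `"paper"` preset mirrors the published scale (512-dimensional
#' embeddings; encoder/decoder depths are placeholders pending the reference
#' supplementary settings). The `"tiny"` preset is sized for desk-scale
#' training and testing.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param ... Named overrides of any field: `d_model`, `n_heads`,
#'   `n_encoder_layers`, `n_decoder_layers` (must not exceed the encoder
#'   depth), `d_ff`, `seq_len`, `n_combos`, `n_stats`, `lr`, `loss`
#'   (`"mse"` or `"mae"`), `mask_ratio`, `activation` (`"relu"` or
#'   `"identity"`), `seed`.
#' @return Named list of class `"pthl_model_config"`.
#' @export
model_config <- function(preset = c("tiny", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "tiny") {
    list(d_model = 32, n_heads = 4, n_encoder_layers = 2,
         n_decoder_layers = 1, d_ff = 64, seq_len = 50,
         n_combos = 143, n_stats = 6, lr = 1e-3, loss = "mse",
         mask_ratio = 0.5, activation = "relu", seed = 1)
  } else {
    list(d_model = 512, n_heads = 8, n_encoder_layers = 6,
         n_decoder_layers = 2, d_ff = 2048, seq_len = 100,
         n_combos = 143, n_stats = 6, lr = 1e-4, loss = "mse",
         mask_ratio = 0.5, activation = "relu", seed = 1)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$d_model %% cfg$n_heads != 0)
    stop("d_model must be divisible by n_heads")
  if (cfg$n_decoder_layers > cfg$n_encoder_layers)
    stop("asymmetric design: decoder depth must not exceed encoder depth")
  if (!cfg$loss %in% c("mse", "mae")) stop("loss must be 'mse' or 'mae'")
  if (!cfg$activation %in% c("relu", "identity"))
    stop("activation must be 'relu' or 'identity'")
  structure(cfg, class = "pthl_model_config")
}

new_layer <- function(d, dff, gen) {
  list(Wq = gen(d, d), Wk = gen(d, d), Wv = gen(d, d),
       Wo = gen(d, d), bo = numeric(d),
       W1 = gen(d, dff), b1 = numeric(dff),
       W2 = gen(dff, d), b2 = numeric(d))
}

#' Initialize a topological transformer
#'
#' @param config A [model_config()].
#' @return Object of class `"topoformer"`: list with `config`, `params`,
#'   `trained` flags. Initialization is deterministic in `config$seed`.
#' @export
topoformer <- function(config = model_config()) {
  stopifnot(inherits(config, "pthl_model_config"))
  withr_seed(config$seed)
  d <- config$d_model
  nf <- config$n_combos * config$n_stats
  gen <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  params <- list(
    W_in = gen(nf, d), b_in = numeric(d),
    pos = gen(config$seq_len, d),
    mask_token = stats::rnorm(nf, 0, 0.02),
    enc = lapply(seq_len(config$n_encoder_layers), function(i)
      new_layer(d, config$d_ff, gen)),
    dec = lapply(seq_len(config$n_decoder_layers), function(i)
      new_layer(d, config$d_ff, gen)),
    W_out = gen(d, nf), b_out = numeric(nf),
    w_reg = stats::rnorm(d, 0, 0.02), b_reg = 0
  )
  structure(list(config = config, params = params,
                 pretrained = FALSE, finetuned = FALSE),
            class = "topoformer")
}

#' @export
print.topoformer <- function(x, ...) {
  cfg <- x$config
  cat("<topoformer> d_model=", cfg$d_model, ", heads=", cfg$n_heads,
      ", enc/dec layers=", cfg$n_encoder_layers, "/", cfg$n_decoder_layers,
      ", seq_len=", cfg$seq_len,
      if (x$pretrained) ", pretrained" else "",
      if (x$finetuned) ", finetuned" else "", "\n", sep = "")
  invisible(x)
}

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / scale) V`; every row of the weight matrix sums to 1.
#'
#' @param Q,K,V Conforming matrices (`ncol(Q) == ncol(K)`,
#'   `nrow(K) == nrow(V)`).
#' @param scale Scalar divisor; defaults to `sqrt(ncol(K))`, the square root
#'   of the key dimension.
#' @return List with `output` (`nrow(Q) x ncol(V)`) and `weights`
#'   (`nrow(Q) x nrow(K)`, rows summing to 1).
#' @export
attention <- function(Q, K, V, scale = sqrt(ncol(K))) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension")
  if (nrow(K) != nrow(V)) stop("K and V must have matching rows")
  A <- row_softmax(Q %*% t(K) / scale)
  list(output = A %*% V, weights = A)
}

# ---- forward/backward building blocks (caches carried alongside) ----------

mha_forward <- function(H, ly, n_heads) {
  d <- ncol(H); dh <- d / n_heads; s <- sqrt(dh)
  Q <- H %*% ly$Wq; K <- H %*% ly$Wk; V <- H %*% ly$Wv
  O <- matrix(0, nrow(H), d)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A[[h]] <- row_softmax(Q[, idx, drop = FALSE] %*%
                            t(K[, idx, drop = FALSE]) / s)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  Y <- O %*% ly$Wo + matrix(ly$bo, nrow(H), d, byrow = TRUE)
  list(Y = Y, cache = list(H = H, Q = Q, K = K, V = V, O = O, A = A,
                           s = s, n_heads = n_heads, dh = dh))
}

mha_backward <- function(dY, cache, ly) {
  H <- cache$H; s <- cache$s; dh <- cache$dh
  g <- list(Wo = crossprod(cache$O, dY), bo = colSums(dY))
  dO <- dY %*% t(ly$Wo)
  dQ <- matrix(0, nrow(H), ncol(H)); dK <- dQ; dV <- dQ
  for (h in seq_len(cache$n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- (dA - rowSums(dA * A)) * A
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / s
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) / s
  }
  g$Wq <- crossprod(H, dQ); g$Wk <- crossprod(H, dK); g$Wv <- crossprod(H, dV)
  dH <- dQ %*% t(ly$Wq) + dK %*% t(ly$Wk) + dV %*% t(ly$Wv)
  list(dH = dH, grads = g)
}

block_forward <- function(H, ly, n_heads) {
  att <- mha_forward(H, ly, n_heads)
  H1 <- H + att$Y
  Z <- H1 %*% ly$W1 + matrix(ly$b1, nrow(H1), ncol(ly$W1), byrow = TRUE)
  R <- pmax(Z, 0)
  H2 <- H1 + R %*% ly$W2 + matrix(ly$b2, nrow(H1), ncol(ly$W2), byrow = TRUE)
  list(H = H2, cache = list(att = att$cache, H1 = H1, Z = Z, R = R))
}

block_backward <- function(dH2, cache, ly, n_heads) {
  dF <- dH2
  g <- list(W2 = crossprod(cache$R, dF), b2 = colSums(dF))
  dR <- dF %*% t(ly$W2)
  dZ <- dR * (cache$Z > 0)
  g$W1 <- crossprod(cache$H1, dZ); g$b1 <- colSums(dZ)
  dH1 <- dH2 + dZ %*% t(ly$W1)
  mb <- mha_backward(dH1, cache$att, ly)
  # keep the gradient tree in the same field order as new_layer(): the
  # optimizer pairs parameter and gradient leaves positionally
  grads <- list(Wq = mb$grads$Wq, Wk = mb$grads$Wk, Wv = mb$grads$Wv,
                Wo = mb$grads$Wo, bo = mb$grads$bo,
                W1 = g$W1, b1 = g$b1, W2 = g$W2, b2 = g$b2)
  list(dH = dH1 + mb$dH, grads = grads)
}

act_forward <- function(Z, activation) {
  if (activation == "relu") pmax(Z, 0) else Z
}
act_grad <- function(Z, activation) {
  if (activation == "relu") (Z > 0) * 1 else 1
}

encoder_forward <- function(model, X, mask = integer(0)) {
  cfg <- model$config; p <- model$params
  if (nrow(X) != cfg$seq_len)
    stop("sequence length ", nrow(X), " does not match config seq_len ",
         cfg$seq_len)
  Xin <- X
  if (length(mask) > 0)
    Xin[mask, ] <- matrix(p$mask_token, length(mask), ncol(X), byrow = TRUE)
  Zp <- Xin %*% p$W_in + matrix(p$b_in, nrow(X), cfg$d_model, byrow = TRUE)
  H <- act_forward(Zp, cfg$activation) + p$pos
  blocks <- vector("list", length(p$enc))
  for (i in seq_along(p$enc)) {
    bf <- block_forward(H, p$enc[[i]], cfg$n_heads)
    H <- bf$H
    blocks[[i]] <- bf$cache
  }
  list(H = H, cache = list(Xin = Xin, Zp = Zp, mask = mask, blocks = blocks))
}

# Backward through the encoder; returns grads for encoder params, the input
# projection, the positional table and the mask token, plus dX.
encoder_backward <- function(model, dH, cache) {
  cfg <- model$config; p <- model$params
  genc <- vector("list", length(p$enc))
  for (i in rev(seq_along(p$enc))) {
    bb <- block_backward(dH, cache$blocks[[i]], p$enc[[i]], cfg$n_heads)
    dH <- bb$dH
    genc[[i]] <- bb$grads
  }
  dpos <- dH
  dZp <- dH * act_grad(cache$Zp, cfg$activation)
  gW_in <- crossprod(cache$Xin, dZp)
  gb_in <- colSums(dZp)
  dXin <- dZp %*% t(p$W_in)
  gmask <- numeric(length(p$mask_token))
  if (length(cache$mask) > 0) {
    gmask <- colSums(dXin[cache$mask, , drop = FALSE])
    dXin[cache$mask, ] <- 0
  }
  list(dX = dXin,
       grads = list(W_in = gW_in, b_in = gb_in, pos = dpos,
                    mask_token = gmask, enc = genc))
}

decoder_forward <- function(model, Henc) {
  cfg <- model$config; p <- model$params
  H <- Henc
  blocks <- vector("list", length(p$dec))
  for (i in seq_along(p$dec)) {
    bf <- block_forward(H, p$dec[[i]], cfg$n_heads)
    H <- bf$H
    blocks[[i]] <- bf$cache
  }
  Y <- H %*% p$W_out + matrix(p$b_out, nrow(H), ncol(p$W_out), byrow = TRUE)
  list(Y = Y, cache = list(blocks = blocks, Hdec = H))
}

decoder_backward <- function(model, dY, cache) {
  cfg <- model$config; p <- model$params
  gW_out <- crossprod(cache$Hdec, dY)
  gb_out <- colSums(dY)
  dH <- dY %*% t(p$W_out)
  gdec <- vector("list", length(p$dec))
  for (i in rev(seq_along(p$dec))) {
    bb <- block_backward(dH, cache$blocks[[i]], p$dec[[i]], cfg$n_heads)
    dH <- bb$dH
    gdec[[i]] <- bb$grads
  }
  list(dHenc = dH, grads = list(W_out = gW_out, b_out = gb_out, dec = gdec))
}

# Convert a topo_sequence / (T x 143 x 6) array / matrix to the T x 858
# flattened input (column-major over the 143 x 6 step matrix).
sequence_matrix <- function(seq, config) {
  x <- if (inherits(seq, "topo_sequence")) seq$tensor else seq
  nf <- config$n_combos * config$n_stats
  if (is.matrix(x)) {
    if (ncol(x) != nf) stop("feature matrix has wrong width")
    return(x)
  }
  d <- dim(x)
  if (length(d) != 3 || d[2] != config$n_combos || d[3] != config$n_stats)
    stop("expected a (T x ", config$n_combos, " x ", config$n_stats,
         ") tensor")
  matrix(x, d[1], nf)
}

#' Per-step convolutional projection
#'
#' The 1x1 convolution that flattens one filtration step's 143 x 6 feature
#' matrix into a `d_model` vector: a linear map followed by the configured
#' nonlinearity. (In the full forward pass the trainable multiscale embedding
#' for the step's position is then added.)
#'
#' @param model A [topoformer()].
#' @param step_features `n_combos x n_stats` matrix (or its flattened vector).
#' @return Numeric vector of length `d_model`.
#' @export
project_step <- function(model, step_features) {
  p <- model$params; cfg <- model$config
  x <- as.numeric(step_features)
  if (length(x) != nrow(p$W_in)) stop("step feature shape mismatch")
  drop(act_forward(rbind(x) %*% p$W_in + rbind(p$b_in), cfg$activation))
}

# ---- losses ---------------------------------------------------------------

recon_loss_grad <- function(Y, X, loss) {
  n <- length(X)
  if (loss == "mse") {
    list(loss = mean((Y - X)^2), dY = 2 * (Y - X) / n)
  } else {
    list(loss = mean(abs(Y - X)), dY = sign(Y - X) / n)
  }
}

# ---- parameter-tree utilities (Adam) --------------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps))
  list(params = tree_map2(params, upd, function(p, u) p - u), state = state)
}

tree_add <- function(a, b) tree_map2(a, b, `+`)
tree_scale <- function(a, s) tree_map(a, function(x) x * s)

# ---- training -------------------------------------------------------------

# One reconstruction pass; returns loss and, when wanted, full grads.
recon_pass <- function(model, X, mask, with_grads = TRUE) {
  ef <- encoder_forward(model, X, mask)
  df <- decoder_forward(model, ef$H)
  lg <- recon_loss_grad(df$Y, X, model$config$loss)
  if (!with_grads) return(list(loss = lg$loss))
  db <- decoder_backward(model, lg$dY, df$cache)
  eb <- encoder_backward(model, db$dHenc, ef$cache)
  grads <- model$params
  grads$W_in <- eb$grads$W_in; grads$b_in <- eb$grads$b_in
  grads$pos <- eb$grads$pos; grads$mask_token <- eb$grads$mask_token
  grads$enc <- eb$grads$enc
  grads$dec <- db$grads$dec
  grads$W_out <- db$grads$W_out; grads$b_out <- db$grads$b_out
  grads$w_reg <- model$params$w_reg * 0; grads$b_reg <- 0
  list(loss = lg$loss, grads = grads)
}

sample_mask <- function(T_, ratio) {
  k <- round(ratio * T_)
  if (k <= 0) integer(0) else sort(sample.int(T_, k))
}

#' Masked-reconstruction pretraining
#'
#' Self-supervised training: a random half (by default) of the filtration
#' steps is replaced by a learned mask token, the encoder-decoder
#' reconstructs the full topological sequence, and the reconstruction loss
#' (MSE by default) is minimized with Adam. Deterministic given the config
#' seed.
#'
#' @param model A [topoformer()].
#' @param sequences List of `"topo_sequence"` objects or `(T x 143 x 6)`
#'   arrays.
#' @param steps Number of optimization steps.
#' @param batch_size Sequences per step.
#' @param lr Learning rate (defaults to the config value).
#' @param mask_ratio Fraction of positions masked (config default).
#' @return The trained model, with a numeric `history` of per-step losses.
#' @export
pretrain <- function(model, sequences, steps = 200, batch_size = 8,
                     lr = model$config$lr,
                     mask_ratio = model$config$mask_ratio) {
  stopifnot(inherits(model, "topoformer"), length(sequences) >= 1)
  cfg <- model$config
  Xs <- lapply(sequences, sequence_matrix, config = cfg)
  withr_seed(cfg$seed + 1)
  state <- adam_init(model$params)
  history <- numeric(steps)
  for (s in seq_len(steps)) {
    pick <- sample.int(length(Xs), min(batch_size, length(Xs)))
    acc <- NULL; loss <- 0
    for (i in pick) {
      mask <- sample_mask(cfg$seq_len, mask_ratio)
      rp <- recon_pass(model, Xs[[i]], mask)
      loss <- loss + rp$loss
      acc <- if (is.null(acc)) rp$grads else tree_add(acc, rp$grads)
    }
    loss <- loss / length(pick)
    if (!is.finite(loss))
      stop("pretraining diverged at step ", s, " (loss = ", loss, ")")
    acc <- tree_scale(acc, 1 / length(pick))
    st <- adam_step(model$params, acc, state, lr)
    model$params <- st$params; state <- st$state
    history[s] <- loss
  }
  model$pretrained <- TRUE
  model$history <- history
  model
}

#' Reconstruction loss on held-out sequences
#'
#' Evaluates the masked-reconstruction objective without updating the model;
#' the mask draw is deterministic in `seed`.
#'
#' @inheritParams pretrain
#' @param seed Seed for the mask draw.
#' @return Mean loss over the sequences.
#' @export
reconstruction_loss <- function(model, sequences,
                                mask_ratio = model$config$mask_ratio,
                                seed = model$config$seed) {
  cfg <- model$config
  Xs <- lapply(sequences, sequence_matrix, config = cfg)
  withr_seed(seed)
  mean(vapply(Xs, function(X) {
    mask <- sample_mask(cfg$seq_len, mask_ratio)
    recon_pass(model, X, mask, with_grads = FALSE)$loss
  }, numeric(1)))
}

#' Supervised fine-tuning for affinity regression
#'
#' Trains the scalar head on the encoder output at the first filtration
#' position (the foremost embedded vector) against the labels with squared
#' error, updating the whole encoder.
#'
#' @param model A [topoformer()] (pretrained or fresh).
#' @param sequences List of sequences (as in [pretrain()]).
#' @param labels Numeric vector of binding affinities (-log Kd/Ki), one per
#'   sequence.
#' @param steps,batch_size,lr Training hyperparameters.
#' @return The fine-tuned model with a `history` of per-step losses.
#' @export
finetune <- function(model, sequences, labels, steps = 200, batch_size = 8,
                     lr = model$config$lr) {
  stopifnot(inherits(model, "topoformer"))
  if (length(labels) != length(sequences))
    stop("labels must match sequences")
  if (any(!is.finite(labels))) stop("labels must be finite")
  cfg <- model$config
  Xs <- lapply(sequences, sequence_matrix, config = cfg)
  withr_seed(cfg$seed + 2)
  state <- adam_init(model$params)
  history <- numeric(steps)
  for (s in seq_len(steps)) {
    pick <- sample.int(length(Xs), min(batch_size, length(Xs)))
    acc <- NULL; loss <- 0
    for (i in pick) {
      ef <- encoder_forward(model, Xs[[i]])
      h1 <- ef$H[1, ]
      yhat <- sum(h1 * model$params$w_reg) + model$params$b_reg
      err <- yhat - labels[i]
      loss <- loss + err^2
      dH <- matrix(0, cfg$seq_len, cfg$d_model)
      dH[1, ] <- 2 * err * model$params$w_reg
      eb <- encoder_backward(model, dH, ef$cache)
      g <- model$params
      g$W_in <- eb$grads$W_in; g$b_in <- eb$grads$b_in
      g$pos <- eb$grads$pos; g$mask_token <- eb$grads$mask_token
      g$enc <- eb$grads$enc
      g$dec <- tree_scale(model$params$dec, 0)
      g$W_out <- model$params$W_out * 0; g$b_out <- model$params$b_out * 0
      g$w_reg <- 2 * err * h1; g$b_reg <- 2 * err
      acc <- if (is.null(acc)) g else tree_add(acc, g)
    }
    loss <- loss / length(pick)
    if (!is.finite(loss))
      stop("fine-tuning diverged at step ", s, " (loss = ", loss, ")")
    acc <- tree_scale(acc, 1 / length(pick))
    st <- adam_step(model$params, acc, state, lr)
    model$params <- st$params; state <- st$state
    history[s] <- loss
  }
  model$finetuned <- TRUE
  model$history <- history
  model
}

#' Predict binding affinity for topological sequences
#'
#' @param object A fine-tuned (or fresh) [topoformer()].
#' @param newdata A single sequence or a list of sequences.
#' @param ... Unused.
#' @return Numeric vector of predicted scalars, one per sequence.
#' @export
predict.topoformer <- function(object, newdata, ...) {
  cfg <- object$config
  if (inherits(newdata, "topo_sequence") || !is.list(newdata))
    newdata <- list(newdata)
  vapply(newdata, function(s) {
    X <- sequence_matrix(s, cfg)
    h1 <- encoder_forward(object, X)$H[1, ]
    sum(h1 * object$params$w_reg) + object$params$b_reg
  }, numeric(1))
}

#' Attention score over filtration scales
#'
#' The mean of the attention weights over all encoder layers, heads and
#' query positions, as a distribution over key positions (filtration steps):
#' non-negative entries summing to 1. Its argmax identifies the dominant
#' interaction scale of the input complex.
#'
#' @param model A [topoformer()].
#' @param seq A sequence (see [pretrain()]).
#' @return Numeric vector of length `seq_len` summing to 1, with attribute
#'   `"argmax"` (the dominant step index).
#' @export
attention_score <- function(model, seq) {
  cfg <- model$config
  X <- sequence_matrix(seq, cfg)
  ef <- encoder_forward(model, X)
  acc <- numeric(cfg$seq_len)
  n <- 0
  for (blk in ef$cache$blocks) {
    for (A in blk$att$A) {
      acc <- acc + colMeans(A)
      n <- n + 1
    }
  }
  if (n == 0) stop("model has no encoder layers")
  score <- acc / n
  attr(score, "argmax") <- which.max(score)
  score
}

#' Gradient saliency map
#'
#' Absolute gradient of the scalar regression output with respect to every
#' input feature, reshaped to the input layout
#' `(filtration steps x combinations x statistics)`.
#'
#' @param model A [topoformer()].
#' @param seq A sequence.
#' @return Array of shape `(seq_len, n_combos, n_stats)`.
#' @export
saliency <- function(model, seq) {
  cfg <- model$config
  X <- sequence_matrix(seq, cfg)
  ef <- encoder_forward(model, X)
  dH <- matrix(0, cfg$seq_len, cfg$d_model)
  dH[1, ] <- model$params$w_reg
  eb <- encoder_backward(model, dH, ef$cache)
  array(abs(eb$dX), dim = c(cfg$seq_len, cfg$n_combos, cfg$n_stats))
}
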