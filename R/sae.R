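# Tied-weight autoencoders and their stacking. One autoencoder maps an input
# x to a hidden activation y = g(W x + b1) and reconstructs z = g(W' y + b2)
# with the decoder weight matrix tied to the transpose of the encoder's; the
# reconstruction loss over m samples is J = (1/2m) sum_i ||z_i - x_i||^2.
# A stacked autoencoder trains each layer greedily on the previous layer's
# encodings, then (optionally) fine-tunes the whole encoder plus a linear
# head against measured SSC.

activation_fns <- function(name) {
  switch(name,
    sigmoid = list(f = function(a) 1 / (1 + exp(-a)),
                   # derivative expressed through the output y = f(a)
                   dfy = function(a, y) y * (1 - y)),
    relu = list(f = function(a) pmax(a, 0),
                dfy = function(a, y) (a > 0) * 1),
    linear = list(f = function(a) a,          # diagnostic/test hook
                  dfy = function(a, y) 1),
    invalid_parameter(sprintf("unknown activation '%s'", name)))
}

#' Autoencoder layer
#'
#' @param w weight matrix, `hidden x input`; the decoder uses `t(w)` (tied
#'   weights).
#' @param b1 hidden-layer offsets (length = hidden units).
#' @param b2 output-layer offsets (length = input dim).
#' @param activation `"sigmoid"` (default), `"relu"`, or `"linear"` (a
#'   diagnostic hook used to test exact linear-manifold recovery).
#' @return object of class `ae_layer`.
#' @export
ae_layer <- function(w, b1, b2, activation = "sigmoid") {
  w <- as.matrix(w)
  if (length(b1) != nrow(w)) invalid_input("length(b1) must equal hidden dim")
  if (length(b2) != ncol(w)) invalid_input("length(b2) must equal input dim")
  activation_fns(activation)  # validates the name
  structure(list(w = w, b1 = as.numeric(b1), b2 = as.numeric(b2),
                 activation = activation),
            class = "ae_layer")
}

as_sample_matrix <- function(x, d, what) {
  if (is.null(dim(x))) {
    if (length(x) != d)
      invalid_input(sprintf("%s has %d values, layer expects %d",
                            what, length(x), d))
    matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != d)
      invalid_input(sprintf("%s has %d columns, layer expects %d",
                            what, ncol(x), d))
    x
  }
}

#' Encode: hidden activations of an autoencoder layer
#'
#' Computes `y = g(w x + b1)` per sample.
#'
#' @param layer an [ae_layer()].
#' @param x numeric vector (one sample) or `samples x input` matrix.
#' @return hidden activations, same sample arrangement as `x`.
#' @export
encode <- function(layer, x) {
  vec <- is.null(dim(x))
  xm <- as_sample_matrix(x, ncol(layer$w), "input")
  act <- activation_fns(layer$activation)
  y <- act$f(xm %*% t(layer$w) +
               matrix(layer$b1, nrow(xm), nrow(layer$w), byrow = TRUE))
  if (vec) as.vector(y) else y
}

#' Decode: reconstruction from hidden activations
#'
#' Computes `z = g(t(w) y + b2)` per sample, with the same `w` as [encode()]
#' transposed (tied weights).
#'
#' @param layer an [ae_layer()].
#' @param y numeric vector or `samples x hidden` matrix of activations.
#' @return reconstructions, same sample arrangement as `y`.
#' @export
decode <- function(layer, y) {
  vec <- is.null(dim(y))
  ym <- as_sample_matrix(y, nrow(layer$w), "activation")
  act <- activation_fns(layer$activation)
  z <- act$f(ym %*% layer$w +
               matrix(layer$b2, nrow(ym), ncol(layer$w), byrow = TRUE))
  if (vec) as.vector(z) else z
}

#' Mean reconstruction loss
#'
#' `J = (1/2m) * sum_i ||z_i - x_i||^2` over `m` samples.
#'
#' @param x original samples (vector or `samples x dim` matrix).
#' @param z reconstructions, same shape.
#' @return nonnegative scalar loss.
#' @export
reconstruction_loss <- function(x, z) {
  xm <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  zm <- if (is.null(dim(z))) matrix(z, nrow = 1L) else as.matrix(z)
  if (!identical(dim(xm), dim(zm)))
    invalid_input("x and z must have identical shapes")
  if (nrow(xm) == 0L) invalid_input("at least one sample required")
  sum((zm - xm)^2) / (2 * nrow(xm))
}

#' Training configuration for (stacked) autoencoders
#'
#' @param epochs unsupervised pretraining epochs per layer (default 200).
#' @param learning_rate fixed gradient-descent step size (default 0.1).
#' @param batch_size mini-batch size (default 16).
#' @param seed integer RNG seed governing initialization and batch order.
#' @param finetune_epochs supervised fine-tuning epochs (default 100).
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 0.1, batch_size = 16L,
                         seed = 1L, finetune_epochs = 100L) {
  if (epochs < 1L || finetune_epochs < 0L || batch_size < 1L ||
      learning_rate <= 0)
    invalid_parameter("epochs/batch_size must be >= 1, learning_rate > 0")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 finetune_epochs = as.integer(finetune_epochs)),
            class = "train_config")
}

glorot_init <- function(hidden, input) {
  r <- sqrt(6 / (hidden + input))
  matrix(stats::runif(hidden * input, -r, r), hidden, input)
}

#' Pretrain one autoencoder layer
#'
#' Minimizes the reconstruction loss by mini-batch gradient descent on the
#' tied weights and both offset vectors. Deterministic given `cfg$seed`.
#'
#' @param x training payloads, `samples x dim` matrix with values nominally in
#'   `[0, 1]`.
#' @param hidden_dim number of hidden units (>= 1).
#' @param cfg a [train_config()].
#' @param activation activation name (see [ae_layer()]).
#' @return an [ae_layer()] with attribute `training_log`: per-epoch full-data
#'   loss, element 1 being the pre-training (epoch 0) loss.
#' @export
pretrain_layer <- function(x, hidden_dim, cfg = train_config(),
                           activation = "sigmoid") {
  x <- as.matrix(x)
  if (nrow(x) == 0L) invalid_input("x must be non-empty")
  if (!all(is.finite(x))) invalid_input("x contains non-finite values")
  if (hidden_dim < 1L) invalid_parameter("hidden_dim must be >= 1")
  act <- activation_fns(activation)
  m <- nrow(x)
  d <- ncol(x)
  set.seed(cfg$seed)
  w <- glorot_init(hidden_dim, d)
  b1 <- numeric(hidden_dim)
  b2 <- numeric(d)
  full_loss <- function() {
    y <- act$f(x %*% t(w) + matrix(b1, m, hidden_dim, byrow = TRUE))
    z <- act$f(y %*% w + matrix(b2, m, d, byrow = TRUE))
    sum((z - x)^2) / (2 * m)
  }
  log_j <- numeric(cfg$epochs + 1L)
  log_j[1L] <- full_loss()
  lr <- cfg$learning_rate
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(m)
    starts <- seq(1L, m, by = cfg$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, m)]
      xb <- x[idx, , drop = FALSE]
      nb <- length(idx)
      a1 <- xb %*% t(w) + matrix(b1, nb, hidden_dim, byrow = TRUE)
      y <- act$f(a1)
      a2 <- y %*% w + matrix(b2, nb, d, byrow = TRUE)
      z <- act$f(a2)
      d2 <- ((z - xb) / nb) * act$dfy(a2, z)
      d1 <- (d2 %*% t(w)) * act$dfy(a1, y)
      gw <- t(d1) %*% xb + t(y) %*% d2  # tied weights: encode + decode terms
      w <- w - lr * gw
      b1 <- b1 - lr * colSums(d1)
      b2 <- b2 - lr * colSums(d2)
    }
    log_j[ep + 1L] <- full_loss()
  }
  layer <- ae_layer(w, b1, b2, activation)
  attr(layer, "training_log") <- log_j
  layer
}

parse_structure <- function(structure) {
  if (is.character(structure))
    structure <- as.numeric(strsplit(structure, "-", fixed = TRUE)[[1L]])
  structure <- as.integer(structure)
  if (length(structure) < 2L || anyNA(structure) || any(structure < 1L))
    invalid_parameter("structure must list input dim and >= 1 hidden dims")
  structure
}

structure_string <- function(dims) paste(dims, collapse = "-")

#' Fit a stacked autoencoder
#'
#' Greedy layer-wise pretraining: layer k is trained to reconstruct the
#' encodings produced by layers 1..k-1; the last hidden layer's output is the
#' deep feature. If SSC targets are supplied, a linear head is attached and
#' the encoder + head are fine-tuned end-to-end against squared error
#' (targets standardized internally; predictions returned in degrees Brix).
#'
#' @param x training payloads, `samples x dim` matrix in `[0, 1]`.
#' @param structure dims as vector or string, e.g. `"1237-650-310-130"`:
#'   input dim followed by the hidden widths of each stacked autoencoder.
#' @param targets optional SSC vector (degrees Brix) aligned with rows of `x`;
#'   enables supervised fine-tuning.
#' @param cfg a [train_config()].
#' @param activation activation name for all layers.
#' @param finetune_scope `"all"` (update every encoder layer and the head,
#'   default) or `"head"` (frozen encoder).
#' @return object of class `sae_model`: `layers`, `structure`, optional
#'   `head`, and `training_log` (`pretrain` per layer, `finetune` per epoch).
#' @export
fit_sae <- function(x, structure, targets = NULL, cfg = train_config(),
                    activation = "sigmoid",
                    finetune_scope = c("all", "head")) {
  finetune_scope <- match.arg(finetune_scope)
  x <- as.matrix(x)
  dims <- parse_structure(structure)
  if (dims[1L] != ncol(x))
    invalid_parameter(sprintf("structure input dim %d != payload dim %d",
                              dims[1L], ncol(x)))
  if (!is.null(targets) && length(targets) != nrow(x))
    invalid_parameter("targets must align with rows of x")
  layers <- vector("list", length(dims) - 1L)
  logs <- vector("list", length(dims) - 1L)
  h <- x
  for (k in seq_along(layers)) {
    lcfg <- cfg
    lcfg$seed <- cfg$seed + k
    layers[[k]] <- pretrain_layer(h, dims[k + 1L], lcfg, activation)
    logs[[k]] <- attr(layers[[k]], "training_log")
    h <- encode(layers[[k]], h)
  }
  model <- structure(list(layers = layers, structure = dims,
                          structure_string = structure_string(dims),
                          activation = activation, head = NULL,
                          training_log = list(pretrain = logs,
                                              finetune = numeric(0))),
                     class = "sae_model")
  if (!is.null(targets))
    model <- finetune_sae(model, x, targets, cfg, finetune_scope)
  model
}

# Supervised fine-tuning: linear head on the deep features, squared-error
# loss on standardized targets, backprop through the encoder stack.
finetune_sae <- function(model, x, targets, cfg, scope) {
  act <- activation_fns(model$activation)
  mu <- mean(targets)
  sdv <- stats::sd(targets)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  t_std <- (targets - mu) / sdv
  m <- nrow(x)
  nl <- length(model$layers)
  feats <- deep_features(model, x)
  # ridge-stabilized least squares start for the head
  a_mat <- cbind(1, feats)
  beta <- solve(crossprod(a_mat) + 1e-3 * diag(ncol(a_mat)),
                crossprod(a_mat, t_std))
  bh <- beta[1L]
  wh <- beta[-1L, , drop = FALSE]  # last_dim x 1
  ws <- lapply(model$layers, `[[`, "w")
  b1s <- lapply(model$layers, `[[`, "b1")
  lr <- cfg$learning_rate
  set.seed(cfg$seed + 1000L)
  forward <- function(xb) {
    acts <- vector("list", nl + 1L)
    pre <- vector("list", nl)
    acts[[1L]] <- xb
    for (l in seq_len(nl)) {
      pre[[l]] <- acts[[l]] %*% t(ws[[l]]) +
        matrix(b1s[[l]], nrow(xb), length(b1s[[l]]), byrow = TRUE)
      acts[[l + 1L]] <- act$f(pre[[l]])
    }
    list(acts = acts, pre = pre)
  }
  log_j <- numeric(cfg$finetune_epochs)
  for (ep in seq_len(cfg$finetune_epochs)) {
    ord <- sample.int(m)
    for (s in seq(1L, m, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1L, m)]
      xb <- x[idx, , drop = FALSE]
      nb <- length(idx)
      fw <- forward(xb)
      pred <- fw$acts[[nl + 1L]] %*% wh + bh
      err <- (pred - t_std[idx]) / nb
      g_wh <- crossprod(fw$acts[[nl + 1L]], err)
      g_bh <- sum(err)
      if (scope == "all") {
        delta <- (err %*% t(wh)) * act$dfy(fw$pre[[nl]], fw$acts[[nl + 1L]])
        for (l in rev(seq_len(nl))) {
          gw <- crossprod(delta, fw$acts[[l]])
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% ws[[l]]) *
              act$dfy(fw$pre[[l - 1L]], fw$acts[[l]])
          ws[[l]] <- ws[[l]] - lr * gw
          b1s[[l]] <- b1s[[l]] - lr * gb
        }
      }
      wh <- wh - lr * g_wh
      bh <- bh - lr * g_bh
    }
    fw <- forward(x)
    pred <- fw$acts[[nl + 1L]] %*% wh + bh
    log_j[ep] <- sum((pred - t_std)^2) / (2 * m)
  }
  for (l in seq_len(nl)) {
    model$layers[[l]]$w <- ws[[l]]
    model$layers[[l]]$b1 <- b1s[[l]]
  }
  model$head <- list(w = wh, b = bh, target_mean = mu, target_sd = sdv,
                     scope = scope)
  model$training_log$finetune <- log_j
  model
}

#' Deep features: the last hidden layer's output
#'
#' Applies the encoder stack row-wise; sample order does not influence any
#' row's value.
#'
#' @param model an [sae_model][fit_sae()].
#' @param x payload vector or `samples x dim` matrix; dim must match the
#'   model's input width.
#' @return `samples x last_dim` matrix of deep features.
#' @export
deep_features <- function(model, x) {
  if (!inherits(model, "sae_model")) invalid_input("`model` must be an sae_model")
  h <- as_sample_matrix(x, model$structure[1L], "payload")
  for (layer in model$layers) h <- encode(layer, h)
  h
}

#' Predict SSC with a fine-tuned stacked autoencoder
#'
#' @param object a fine-tuned [sae_model][fit_sae()] (head present).
#' @param newdata payload matrix or vector.
#' @param ... unused.
#' @return predicted SSC in degrees Brix.
#' @export
predict.sae_model <- function(object, newdata, ...) {
  if (is.null(object$head))
    incompatible_model("model has no supervised head; fit with targets")
  f <- deep_features(object, newdata)
  as.vector(f %*% object$head$w + object$head$b) * object$head$target_sd +
    object$head$target_mean
}

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf("<sae_model> %s (%d stacked autoencoders, %s activation)%s\n",
              x$structure_string, length(x$layers), x$activation,
              if (is.null(x$head)) "" else ", fine-tuned"))
  invisible(x)
}

#' Save / load a stacked autoencoder model
#'
#' Single-file serialization of the weight stack, head and training log.
#'
#' @param model an `sae_model`.
#' @param path file path.
#' @return `save_sae` returns `path` invisibly; `load_sae` the model.
#' @export
save_sae <- function(model, path) {
  if (!inherits(model, "sae_model")) invalid_input("not an sae_model")
  tryCatch(saveRDS(model, path),
           error = function(e) io_error(conditionMessage(e)))
  invisible(path)
}

#' @rdname save_sae
#' @export
load_sae <- function(path) {
  if (!file.exists(path)) io_error(sprintf("no such file: '%s'", path))
  model <- readRDS(path)
  if (!inherits(model, "sae_model")) format_error("file is not an sae_model")
  model
}
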