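# Network specifications and thin R wrappers over the compiled MLP engine.

#' Network specifications for the two surrogate families
#'
#' `build_mapping_net()` is the small design-parameters-to-field-code net of
#' the autoencoder-based model: input 3, two hidden layers of 16 Softplus
#' units, and `code_dim` (default 8) linear outputs. `build_decoder()` is
#' the field decoder: `code_dim` inputs, 512 Softplus hidden units, and
#' `field_dim` (default 4143) linear outputs. `build_autoencoder()` stacks
#' an encoder (Softplus hidden layer, linear layer to `code_dim`, then a
#' per-sample L2 normalization of the code) on the decoder.
#' `build_direct_net()` is the direct feedforward model: input 3, hidden
#' layers of 32, 64 and 256 Softplus units, `field_dim` linear outputs.
#'
#' @param code_dim field-code length (default 8).
#' @param field_dim flattened field length (default 4143 = 1381 x 3).
#' @param encoder_hidden Softplus width of the encoder's hidden layer
#'   (default 512, mirroring the decoder).
#' @return A `tav_net_spec`: list with `dims` (layer widths, input first)
#'   and `acts` (activation per layer, one of `"softplus"`, `"linear"`,
#'   `"l2norm"`), plus bookkeeping fields.
#' @export
build_mapping_net <- function(code_dim = 8L) {
  new_net_spec(c(3L, 16L, 16L, code_dim),
               c("softplus", "softplus", "linear"), kind = "mapping")
}

#' @rdname build_mapping_net
#' @export
build_decoder <- function(field_dim = 4143L, code_dim = 8L) {
  new_net_spec(c(code_dim, 512L, field_dim),
               c("softplus", "linear"), kind = "decoder")
}

#' @rdname build_mapping_net
#' @export
build_autoencoder <- function(field_dim = 4143L, code_dim = 8L,
                              encoder_hidden = 512L) {
  spec <- new_net_spec(
    c(field_dim, encoder_hidden, code_dim, 512L, field_dim),
    c("softplus", "l2norm", "softplus", "linear"), kind = "autoencoder")
  spec$encoder_layers <- 2L  # layers 1..2 form the encoder
  spec
}

#' @rdname build_mapping_net
#' @export
build_direct_net <- function(field_dim = 4143L) {
  new_net_spec(c(3L, 32L, 64L, 256L, field_dim),
               c("softplus", "softplus", "softplus", "linear"),
               kind = "direct")
}

new_net_spec <- function(dims, acts, kind) {
  stopifnot(length(dims) == length(acts) + 1L, all(dims >= 1L),
            all(acts %in% c("softplus", "linear", "l2norm")))
  structure(list(dims = as.integer(dims), acts = acts, kind = kind),
            class = "tav_net_spec")
}

#' @export
print.tav_net_spec <- function(x, ...) {
  cat(sprintf("Network spec (%s): %s\n", x$kind,
              paste0(x$dims[1], " -> ",
                     paste(sprintf("%d[%s]", x$dims[-1], x$acts),
                           collapse = " -> "))))
  invisible(x)
}

#' Initialize network weights
#'
#' Glorot-uniform initialization with a dedicated deterministic RNG stream;
#' identical seeds give bitwise-identical weights.
#'
#' @param spec a `tav_net_spec`.
#' @param seed integer seed.
#' @return A `tav_net`: weight/bias lists plus the activation schedule.
#' @export
init_net <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "tav_net_spec"))
  net <- .mlp_init(spec$dims, spec$acts, as.integer(seed))
  structure(list(W = net$W, b = net$b, act = net$act, spec = spec),
            class = "tav_net")
}

#' @export
print.tav_net <- function(x, ...) {
  np <- sum(vapply(x$W, length, 0)) + sum(vapply(x$b, length, 0))
  cat(sprintf("Trained network (%s), %d layers, %s parameters\n",
              x$spec$kind, length(x$W), format(np, big.mark = ",")))
  invisible(x)
}

net_core <- function(net) list(W = net$W, b = net$b, act = net$act)

#' Forward pass of a network
#'
#' @param net a `tav_net`.
#' @param X matrix of inputs, one row per sample.
#' @param upto evaluate only the first `upto` layers (used to run the
#'   encoder part of an autoencoder); default all layers.
#' @return matrix of outputs.
#' @export
net_forward <- function(net, X, upto = -1L) {
  .mlp_forward(net_core(net), as.matrix(X), as.integer(upto))
}

#' Train a network with Adamax on MSE loss
#'
#' Minibatch Adamax with the Keras-documented defaults
#' (lr = 0.002, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7). With
#' `cfg$refit_output = TRUE` the gradient phase is followed by a ridge
#' least-squares refit of the final linear layer given the learned hidden
#' features ("output-layer refinement"), which exactly minimizes the
#' training MSE over that layer; it is off by default, so the default
#' recipe is the plain optimizer schedule. Fully deterministic per seed.
#'
#' @param net a `tav_net`.
#' @param X,Y training inputs and targets (rows = samples).
#' @param cfg a [train_config()].
#' @param epochs override of `cfg$epochs`.
#' @return the trained `tav_net` with a `history` attribute (per-epoch mean
#'   minibatch loss).
#' @export
net_train <- function(net, X, Y, cfg = train_config(), epochs = NULL) {
  stopifnot(inherits(net, "tav_net"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 2L) stop("net_train: need at least 2 training samples", call. = FALSE)
  ep <- as.integer(if (is.null(epochs)) cfg$epochs else epochs)
  res <- .mlp_train(net_core(net), X, Y, ep, as.integer(cfg$batch_size),
                    cfg$lr, cfg$beta1, cfg$beta2, cfg$epsilon,
                    as.integer(cfg$seed))
  out <- net
  out$W <- res$net$W; out$b <- res$net$b
  if (isTRUE(cfg$refit_output)) {
    refit <- .mlp_refit_output(net_core(out), X, Y, cfg$ridge)
    out$W <- refit$W; out$b <- refit$b
  }
  attr(out, "history") <- as.numeric(res$history)
  out
}

#' Training-set mean squared error of a network
#' @inheritParams net_train
#' @return scalar MSE (mean over samples and outputs).
#' @export
net_mse <- function(net, X, Y) {
  .mlp_mse(net_core(net), as.matrix(X), as.matrix(Y))
}

#' Training configuration
#'
#' Adamax with library-default hyperparameters and MSE loss. Epoch counts
#' and batch size are package defaults (2000 epochs, batch 32), configurable
#' per call; cross-validation drivers typically pass shorter schedules.
#'
#' @param epochs gradient epochs.
#' @param batch_size minibatch size (use `Inf` or the sample count for
#'   full-batch).
#' @param lr,beta1,beta2,epsilon Adamax hyperparameters (Keras defaults).
#' @param seed integer seed controlling shuffling (and, via [init_net()],
#'   weight initialization in the higher-level training drivers).
#' @param refit_output logical; run the final-layer least-squares
#'   refinement after the gradient phase.
#' @param ridge relative ridge of the refinement.
#' @return An object of class `tav_train_config`.
#' @export
train_config <- function(epochs = 2000L, batch_size = 32L, lr = 0.002,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         seed = 0L, refit_output = FALSE, ridge = 1e-8) {
  stopifnot(epochs >= 1, batch_size >= 1)
  structure(list(optimizer = "adamax", loss = "mse",
                 epochs = as.integer(epochs),
                 batch_size = as.integer(min(batch_size, .Machine$integer.max)),
                 lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed), refit_output = isTRUE(refit_output),
                 ridge = ridge),
            class = "tav_train_config")
}
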