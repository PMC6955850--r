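# The two surrogate families and their training schedules.
#
# model-a (autoencoder-based): an autoencoder learns an 8-number field code
# by unsupervised reconstruction; a small mapping net learns design
# parameters -> code; the decoder is copied behind the mapping net and the
# composite is fine-tuned end to end.
# model-d (direct): one feedforward net from design parameters to the field.
#
# Inputs are min-max scaled to [0,1] with the design-space bounds; fields
# are standardized per feature with training-set statistics stored on the
# model.

derive_seed <- function(seed, k) {
  x <- bitwXor(as.integer(seed) %% 2147483647L,
               as.integer((k * 2654435761) %% 2147483647))
  abs(x) %% 2147483647L
}

scale_designs <- function(designs, space = design_space()) {
  designs <- as_design_df(designs)
  b <- space$bounds
  X <- as.matrix(designs[, c("a", "b", "ssl")])
  sweep(sweep(X, 2L, b[, "min"], `-`), 2L, b[, "max"] - b[, "min"], `/`)
}

make_field_scaler <- function(fields) {
  center <- colMeans(fields)
  scale <- apply(fields, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

apply_field_scaler <- function(fields, sc) {
  sweep(sweep(fields, 2L, sc$center, `-`), 2L, sc$scale, `/`)
}

invert_field_scaler <- function(z, sc) {
  sweep(sweep(z, 2L, sc$scale, `*`), 2L, sc$center, `+`)
}

#' Train an autoencoder on a field matrix
#'
#' Unsupervised phase of the autoencoder-based surrogate: minimizes the MSE
#' between each (standardized) field and its reconstruction through the
#' 8-number code bottleneck.
#'
#' @param fields n x field_dim matrix of standardized training fields.
#' @param cfg a [train_config()].
#' @param code_dim field-code length.
#' @param encoder_hidden encoder Softplus width.
#' @return An object of class `tav_autoencoder` (fields `net`, `history`,
#'   `code_dim`).
#' @export
train_autoencoder <- function(fields, cfg = train_config(), code_dim = 8L,
                              encoder_hidden = 512L) {
  fields <- as.matrix(fields)
  if (nrow(fields) < 2L) stop("train_autoencoder: need >= 2 samples", call. = FALSE)
  spec <- build_autoencoder(ncol(fields), code_dim, encoder_hidden)
  net <- init_net(spec, derive_seed(cfg$seed, 11L))
  cfg$seed <- derive_seed(cfg$seed, 12L)
  net <- net_train(net, fields, fields, cfg)
  structure(list(net = net, history = attr(net, "history"),
                 code_dim = as.integer(code_dim)),
            class = "tav_autoencoder")
}

#' Encode fields to field codes
#'
#' Runs the encoder half of a trained autoencoder; codes have length 8 (or
#' the configured `code_dim`) and unit Euclidean norm (the encoder ends in a
#' per-sample L2 normalization).
#'
#' @param ae a [train_autoencoder()] result.
#' @param fields standardized field matrix.
#' @return n x code_dim matrix of field codes.
#' @export
encode_fields <- function(ae, fields) {
  stopifnot(inherits(ae, "tav_autoencoder"))
  net_forward(ae$net, as.matrix(fields), upto = ae$net$spec$encoder_layers)
}

#' Decode field codes back to fields
#' @inheritParams encode_fields
#' @param codes n x code_dim matrix.
#' @return n x field_dim matrix of (standardized) reconstructions.
#' @export
decode_codes <- function(ae, codes) {
  stopifnot(inherits(ae, "tav_autoencoder"))
  dec <- decoder_net(ae)
  net_forward(dec, as.matrix(codes))
}

decoder_net <- function(ae) {
  enc_l <- ae$net$spec$encoder_layers
  L <- length(ae$net$W)
  spec <- new_net_spec(
    c(ae$code_dim, ae$net$spec$dims[(enc_l + 2L):(L + 1L)]),
    ae$net$spec$acts[(enc_l + 1L):L], kind = "decoder")
  structure(list(W = ae$net$W[(enc_l + 1L):L],
                 b = ae$net$b[(enc_l + 1L):L],
                 act = ae$net$act[(enc_l + 1L):L],
                 spec = spec),
            class = "tav_net")
}

#' Train the design-parameters-to-code mapping net
#'
#' Supervised phase: fits the small 3 -> 16 -> 16 -> 8 net to the codes the
#' trained encoder assigned to the training fields.
#'
#' @param designs_scaled n x 3 matrix of min-max scaled design parameters.
#' @param codes n x code_dim matrix of encoder outputs for the same samples.
#' @param cfg a [train_config()].
#' @return a trained `tav_net`.
#' @export
train_mapping <- function(designs_scaled, codes, cfg = train_config()) {
  codes <- as.matrix(codes)
  net <- init_net(build_mapping_net(ncol(codes)), derive_seed(cfg$seed, 21L))
  cfg$seed <- derive_seed(cfg$seed, 22L)
  net_train(net, designs_scaled, codes, cfg)
}

#' Assemble the autoencoder-based surrogate from its trained parts
#'
#' Copies the decoder of the trained autoencoder behind the mapping net.
#' Until fine-tuning the composite output is exactly
#' `decode(mapping(design))`.
#'
#' @param mapping trained mapping `tav_net`.
#' @param ae trained [train_autoencoder()] (its decoder is copied).
#' @param kind `"model_a_shape"` or `"model_a_stress"`.
#' @param y_scaler field standardization constants (training-set
#'   per-feature center/scale).
#' @param space the design space used for input scaling.
#' @return An object of class `tav_surrogate`.
#' @export
assemble_model_a <- function(mapping, ae, kind = "model_a_shape",
                             y_scaler, space = design_space()) {
  stopifnot(inherits(mapping, "tav_net"), inherits(ae, "tav_autoencoder"))
  dec <- decoder_net(ae)
  if (utils::tail(mapping$spec$dims, 1L) != dec$spec$dims[1L]) {
    stop("assemble_model_a: mapping output dimension does not match decoder input",
         call. = FALSE)
  }
  comp_spec <- new_net_spec(c(mapping$spec$dims, dec$spec$dims[-1L]),
                            c(mapping$spec$acts, dec$spec$acts),
                            kind = "model_a_composite")
  net <- structure(list(W = c(mapping$W, dec$W), b = c(mapping$b, dec$b),
                        act = c(mapping$act, dec$act), spec = comp_spec),
                   class = "tav_net")
  new_surrogate(kind, net, y_scaler, space,
                extra = list(mapping_layers = length(mapping$W)))
}

new_surrogate <- function(kind, net, y_scaler, space, extra = list()) {
  structure(c(list(kind = kind, net = net, y_scaler = y_scaler,
                   space = space, trained = TRUE), extra),
            class = "tav_surrogate")
}

#' @export
print.tav_surrogate <- function(x, ...) {
  cat(sprintf("TAV surrogate model (%s), output dimension %d\n",
              x$kind, surrogate_dim(x)))
  invisible(x)
}

surrogate_dim <- function(model) {
  if (model$kind == "mean_baseline") length(model$mean_field)
  else utils::tail(model$net$spec$dims, 1L)
}

#' Fine-tune the assembled autoencoder-based surrogate end to end
#'
#' Warm-start Adamax on the composite net against the training fields
#' (plus the output-layer refinement when `cfg$refit_output` is set). The
#' result is guaranteed not to have higher training MSE than the assembled
#' composite: if the gradient phase ends worse (possible with a fixed-epoch
#' schedule), the initial composite is kept instead.
#'
#' @param model an [assemble_model_a()] result.
#' @param designs design data frame (training set).
#' @param fields n x field_dim raw field matrix (training set).
#' @param cfg a [train_config()].
#' @return the fine-tuned `tav_surrogate`.
#' @export
finetune_model_a <- function(model, designs, fields, cfg = train_config()) {
  stopifnot(inherits(model, "tav_surrogate"),
            startsWith(model$kind, "model_a"))
  X <- scale_designs(designs, model$space)
  Yz <- apply_field_scaler(as.matrix(fields), model$y_scaler)
  cfg$seed <- derive_seed(cfg$seed, 31L)
  # reference: the assembled composite with its own output-layer refinement
  ref <- model$net
  if (isTRUE(cfg$refit_output)) {
    r <- .mlp_refit_output(net_core(ref), X, Yz, cfg$ridge)
    ref$W <- r$W; ref$b <- r$b
  }
  tuned <- net_train(model$net, X, Yz, cfg)
  pre <- net_mse(ref, X, Yz)
  post <- net_mse(tuned, X, Yz)
  model$net <- if (post <= pre) tuned else ref
  model$finetune_history <- attr(tuned, "history")
  model
}

#' Train the direct surrogate
#'
#' Single-phase supervised training of the 3 -> 32 -> 64 -> 256 -> field_dim
#' feedforward net.
#'
#' @inheritParams finetune_model_a
#' @param kind `"model_d_shape"` or `"model_d_stress"`.
#' @param space design space for input scaling.
#' @return a `tav_surrogate`.
#' @export
train_direct <- function(designs, fields, cfg = train_config(),
                         kind = "model_d_shape", space = design_space()) {
  fields <- as.matrix(fields)
  if (nrow(fields) < 2L) stop("train_direct: need >= 2 samples", call. = FALSE)
  X <- scale_designs(designs, space)
  ysc <- make_field_scaler(fields)
  Yz <- apply_field_scaler(fields, ysc)
  net <- init_net(build_direct_net(ncol(fields)), derive_seed(cfg$seed, 41L))
  cfg$seed <- derive_seed(cfg$seed, 42L)
  net <- net_train(net, X, Yz, cfg)
  m <- new_surrogate(kind, net, ysc, space)
  m$history <- attr(net, "history")
  m
}

#' Fit a surrogate of a given family on training data
#'
#' One-call driver used by cross-validation. For `"model_a"` it runs the
#' three phases (autoencoder, mapping, fine-tune); for `"model_d"` a single
#' supervised fit; `"mean_baseline"` simply stores the training-mean field
#' and predicts it for every design.
#'
#' @param designs training design data frame.
#' @param fields n x field_dim raw field matrix.
#' @param family `"model_a"`, `"model_d"`, or `"mean_baseline"`.
#' @param target `"shape"` or `"stress"` (recorded in the model kind).
#' @param cfg a [train_config()]; `cfg$epochs` is used for `model_d`.
#' @param epochs_a named epochs for the three model-a phases.
#' @param space design space for input scaling.
#' @return a `tav_surrogate`.
#' @export
fit_surrogate <- function(designs, fields,
                          family = c("model_a", "model_d", "mean_baseline"),
                          target = c("shape", "stress"),
                          cfg = train_config(),
                          epochs_a = c(ae = cfg$epochs, map = cfg$epochs,
                                       finetune = cfg$epochs),
                          space = design_space()) {
  family <- match.arg(family)
  target <- match.arg(target)
  fields <- as.matrix(fields)
  if (family == "mean_baseline") {
    m <- structure(list(kind = paste0("mean_baseline_", target),
                        mean_field = colMeans(fields), space = space,
                        trained = TRUE),
                   class = "tav_surrogate")
    return(m)
  }
  if (family == "model_d") {
    return(train_direct(designs, fields, cfg,
                        kind = paste0("model_d_", target), space = space))
  }
  ysc <- make_field_scaler(fields)
  Yz <- apply_field_scaler(fields, ysc)
  cfg_ae <- cfg; cfg_ae$epochs <- as.integer(epochs_a[["ae"]])
  ae <- train_autoencoder(Yz, cfg_ae)
  codes <- encode_fields(ae, Yz)
  X <- scale_designs(designs, space)
  cfg_map <- cfg; cfg_map$epochs <- as.integer(epochs_a[["map"]])
  mapping <- train_mapping(X, codes, cfg_map)
  model <- assemble_model_a(mapping, ae, kind = paste0("model_a_", target),
                            y_scaler = ysc, space = space)
  cfg_ft <- cfg; cfg_ft$epochs <- as.integer(epochs_a[["finetune"]])
  finetune_model_a(model, designs, fields, cfg_ft)
}

#' Predict fields for new designs
#'
#' Deterministic inference: scales the design parameters, runs the net, and
#' de-standardizes the output. Single-design latency is well under a second
#' on one CPU.
#'
#' @param object a trained `tav_surrogate`.
#' @param newdata design data frame (or named vector).
#' @param ... unused.
#' @return n x field_dim matrix of predicted flattened fields.
#' @export
predict.tav_surrogate <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop("predict: model is not trained", call. = FALSE)
  newdata <- as_design_df(newdata)
  if (object$kind %in% c("mean_baseline_shape", "mean_baseline_stress")) {
    out <- matrix(object$mean_field, nrow(newdata), length(object$mean_field),
                  byrow = TRUE)
    return(out)
  }
  X <- scale_designs(newdata, object$space)
  Z <- net_forward(object$net, X)
  invert_field_scaler(Z, object$y_scaler)
}
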