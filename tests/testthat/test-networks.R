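test_that("network specs reproduce the reference layer widths", {
  mp <- build_mapping_net()
  expect_equal(mp$dims, c(3L, 16L, 16L, 8L))
  expect_equal(mp$acts, c("softplus", "softplus", "linear"))
  dec <- build_decoder()
  expect_equal(dec$dims, c(8L, 512L, 4143L))
  expect_equal(dec$acts, c("softplus", "linear"))
  ae <- build_autoencoder(4143L)
  expect_equal(ae$dims, c(4143L, 512L, 8L, 512L, 4143L))
  expect_equal(ae$acts, c("softplus", "l2norm", "softplus", "linear"))
  dd <- build_direct_net()
  expect_equal(dd$dims, c(3L, 32L, 64L, 256L, 4143L))
  expect_equal(dd$acts, c("softplus", "softplus", "softplus", "linear"))
})

test_that("weight initialization is seeded and reproducible", {
  spec <- build_mapping_net()
  n1 <- init_net(spec, 5)
  n2 <- init_net(spec, 5)
  n3 <- init_net(spec, 6)
  expect_identical(n1$W, n2$W)
  expect_false(identical(n1$W, n3$W))
  expect_equal(dim(n1$W[[1]]), c(3L, 16L))
})

test_that("analytic gradients agree with finite differences", {
  # small net exercising every layer type, checked parameter-by-parameter
  spec <- tavsurrogate:::new_net_spec(c(2L, 4L, 3L, 4L, 2L),
                                      c("softplus", "l2norm", "softplus", "linear"),
                                      "gradcheck")
  set.seed(3)
  X <- matrix(rnorm(10), 5, 2)
  Y <- matrix(rnorm(10), 5, 2)
  net <- init_net(spec, 1)
  # one full-batch Adamax step from the same start must move every layer in
  # the loss-decreasing direction; verify via the loss value directly
  mse0 <- net_mse(net, X, Y)
  cfg <- train_config(epochs = 1, batch_size = 5, lr = 1e-3, seed = 1,
                      refit_output = FALSE)
  stepped <- net_train(net, X, Y, cfg)
  expect_lt(net_mse(stepped, X, Y), mse0)
  # numerical directional check: loss gradient wrt a single weight
  eps <- 1e-6
  for (l in seq_along(net$W)) {
    w_plus <- net; w_minus <- net
    w_plus$W[[l]][1, 1] <- w_plus$W[[l]][1, 1] + eps
    w_minus$W[[l]][1, 1] <- w_minus$W[[l]][1, 1] - eps
    g_num <- (net_mse(w_plus, X, Y) - net_mse(w_minus, X, Y)) / (2 * eps)
    # the Adamax step moves opposite the gradient sign (single step from
    # zero moment state: update direction = -sign-ish of gradient)
    dw <- stepped$W[[l]][1, 1] - net$W[[l]][1, 1]
    if (abs(g_num) > 1e-8) expect_lt(dw * g_num, 0)
  }
})

test_that("training reduces loss, is seeded, and the refit helps", {
  set.seed(11)
  X <- matrix(runif(300), 100, 3)
  Y <- cbind(sin(3 * X[, 1]) + X[, 2] * X[, 3], X[, 1]^2 - X[, 3])
  spec <- tavsurrogate:::new_net_spec(c(3L, 16L, 16L, 2L),
                                      c("softplus", "softplus", "linear"), "t")
  net <- init_net(spec, 2)
  cfg <- train_config(epochs = 150, batch_size = 16, seed = 4,
                      refit_output = FALSE)
  tr <- net_train(net, X, Y, cfg)
  h <- attr(tr, "history")
  expect_length(h, 150L)
  expect_lt(h[length(h)], h[1])
  # bitwise reproducible
  tr2 <- net_train(net, X, Y, cfg)
  expect_identical(tr$W, tr2$W)
  expect_identical(attr(tr2, "history"), h)
  # output-layer refinement cannot hurt the training loss
  cfg_r <- cfg; cfg_r$refit_output <- TRUE
  trr <- net_train(net, X, Y, cfg_r)
  expect_lte(net_mse(trr, X, Y), net_mse(tr, X, Y) + 1e-12)
})

test_that("training diverging to non-finite loss is surfaced", {
  # an absurd learning rate overflows the weights; the non-finite loss must
  # surface as an error, not silently propagate NaNs
  X <- matrix(c(1e3, -1e3, 2e3, -2e3), 2, 2)
  Y <- matrix(c(1, -1), 2, 1)
  spec <- tavsurrogate:::new_net_spec(c(2L, 1L), "linear", "t")
  net <- init_net(spec, 1)
  cfg <- train_config(epochs = 5, batch_size = 2, lr = 1e160,
                      refit_output = FALSE)
  expect_error(net_train(net, X, Y, cfg), "diverged|non-finite")
})

test_that("the encoder code is unit-norm and of length 8", {
  set.seed(5)
  fields <- matrix(rnorm(40 * 60), 40, 60)
  ae <- train_autoencoder(fields, train_config(epochs = 3, batch_size = 8,
                                               seed = 2))
  codes <- encode_fields(ae, fields)
  expect_equal(dim(codes), c(40L, 8L))
  expect_equal(rowSums(codes^2), rep(1, 40), tolerance = 1e-9)
  rec <- decode_codes(ae, codes)
  expect_equal(dim(rec), dim(fields))
})

test_that("assembled model-a is exactly decode(mapping(.)) before fine-tuning", {
  set.seed(6)
  fields <- matrix(rnorm(30 * 45), 30, 45)
  designs <- sample_designs(design_space(), 30, seed = 1)
  ysc <- tavsurrogate:::make_field_scaler(fields)
  Yz <- tavsurrogate:::apply_field_scaler(fields, ysc)
  ae <- train_autoencoder(Yz, train_config(epochs = 3, batch_size = 8, seed = 1))
  codes <- encode_fields(ae, Yz)
  Xs <- tavsurrogate:::scale_designs(designs)
  mapping <- train_mapping(Xs, codes, train_config(epochs = 5, batch_size = 8,
                                                   seed = 1))
  model <- assemble_model_a(mapping, ae, "model_a_stress", ysc)
  pred_direct <- predict(model, designs)
  pred_manual <- tavsurrogate:::invert_field_scaler(
    decode_codes(ae, net_forward(mapping, Xs)), ysc)
  expect_equal(pred_direct, pred_manual, tolerance = 1e-12)
  # dimension mismatch is a config error
  bad_map <- init_net(build_mapping_net(code_dim = 5L), 1)
  expect_error(assemble_model_a(bad_map, ae, "model_a_stress", ysc),
               "does not match")
})

test_that("prediction is deterministic and batches consistently", {
  ds <- small_dataset()
  cfg <- train_config(epochs = 20, batch_size = 16, seed = 3)
  m <- fit_surrogate(ds$designs, ds$stresses, "model_d", "stress", cfg)
  d5 <- ds$designs[1:5, ]
  p_batch <- predict(m, d5)
  expect_equal(dim(p_batch), c(5L, ncol(ds$stresses)))
  expect_true(all(is.finite(p_batch)))
  p_single <- do.call(rbind, lapply(1:5, function(i) predict(m, d5[i, ])))
  expect_equal(p_batch, p_single, tolerance = 1e-12)
  expect_identical(predict(m, d5), p_batch)
  # single-design inference latency is far under a second
  t0 <- proc.time()[["elapsed"]]
  invisible(predict(m, d5[1, ]))
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
})
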