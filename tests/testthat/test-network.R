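test_that("network architecture follows the layer-sizing rule", {
  protocol <- test_protocol()
  net <- build_network(network_config(10), protocol, seed = 1)
  expect_equal(net$sizes, c(10, 10, 10, 10, 4))
  # 3 x (10*10 + 10) weights+biases in the hidden stack, 10*4 + 4 out
  expect_equal(n_weights(net), 3 * (10 * 10 + 10) + (10 * 4 + 4))
  expect_equal(n_weights(net), 374)
  expect_error(build_network(network_config(8), protocol), "n_inputs")
})

test_that("forward pass honours shape and bound contracts", {
  protocol <- test_protocol()
  net <- build_network(network_config(10), protocol, seed = 2)
  set.seed(3)
  M <- matrix(runif(70, 0.1, 1.2), 7)
  pred <- predict(net, M)
  expect_equal(dim(as.matrix(pred$params[, 1:4])), c(7, 4))
  expect_equal(dim(pred$signals), c(7, 10))
  for (nm in names(net$bounds)) {
    expect_true(all(pred$params[[nm]] > net$bounds[[nm]][1]))
    expect_true(all(pred$params[[nm]] < net$bounds[[nm]][2]))
  }
  # empty batch: empty table, no error
  empty <- predict(net, matrix(numeric(0), 0, 10))
  expect_equal(nrow(empty$params), 0)
  # protocol mismatch (Nz differs) is an error
  expect_error(predict(net, matrix(1, 3, 9)), "Nz differs")
})

test_that("backpropagated weight gradients match finite differences", {
  protocol <- test_protocol()
  net <- build_network(network_config(10), protocol, seed = 4)
  set.seed(5)
  M <- matrix(runif(40, 0.2, 1.1), 4)
  tc <- training_config("NLR", sigma = 0.1)
  loss_at <- function(n) {
    fwd <- ricianfit:::net_forward(n, M)
    ricianfit:::batch_loss_grad(M, fwd$A, tc)$value
  }
  fwd <- ricianfit:::net_forward(net, M)
  lg <- ricianfit:::batch_loss_grad(M, fwd$A, tc)
  grads <- ricianfit:::net_backward(net, fwd, lg$grad)
  eps <- 1e-6
  for (l in c(1, 4)) {
    for (ij in list(c(1, 1), c(2, 3))) {
      np <- net; np$W[[l]][ij[1], ij[2]] <- np$W[[l]][ij[1], ij[2]] + eps
      nm <- net; nm$W[[l]][ij[1], ij[2]] <- nm$W[[l]][ij[1], ij[2]] - eps
      fd <- (loss_at(np) - loss_at(nm)) / (2 * eps)
      expect_equal(grads$gW[[l]][ij[1], ij[2]], fd, tolerance = 1e-5,
                   label = sprintf("layer %d W[%d,%d]", l, ij[1], ij[2]))
    }
  }
})

test_that("training is deterministic and improves the loss", {
  ds <- tiny_dataset(sigma = 0.1, reps = 2, seed = 21)
  val <- tiny_dataset(sigma = 0.1, reps = 1, seed = 22)
  cfg <- network_config(10)
  tc <- training_config("MSE", batch_size = 32, max_epochs = 8, patience = 8,
                        seed = 77)
  run <- function() {
    net <- build_network(cfg, test_protocol(), seed = 55)
    train_network(net, ds, val, tc)
  }
  a <- run()
  b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$W, b$W)
  expect_lt(a$history$train_loss[nrow(a$history)], a$history$train_loss[1])
  expect_true(all(is.finite(a$history$val_loss)))
})

test_that("NLR training requires sigma and records a full history", {
  expect_error(training_config("NLR"), "sigma")
  ds <- tiny_dataset(sigma = 0.2, reps = 1, seed = 31)
  net <- build_network(network_config(10), test_protocol(), seed = 6)
  tc <- training_config("NLR", sigma = 0.2, max_epochs = 3, patience = 3,
                        seed = 8)
  net <- train_network(net, ds, NULL, tc)
  expect_equal(net$n_epochs, 3)
  expect_named(net$history, c("epoch", "train_loss", "val_loss"))
})

test_that("predict re-scored with the training loss reproduces the final loss", {
  ds <- tiny_dataset(sigma = 0.1, reps = 2, seed = 41)
  net <- build_network(network_config(10), test_protocol(), seed = 9)
  tc <- training_config("MSE", max_epochs = 5, patience = 5, seed = 10)
  net <- train_network(net, ds, NULL, tc)
  pred <- predict(net, ds)
  expect_equal(mse_loss(ds$M, pred$signals)$value, net$final_train_loss,
               tolerance = 1e-12)
})

test_that("networks serialize to JSON and restore bit-exactly", {
  ds <- tiny_dataset(sigma = 0.1, reps = 1, seed = 51)
  net <- build_network(network_config(10), test_protocol(), seed = 12)
  tc <- training_config("MSE", max_epochs = 2, patience = 2, seed = 13)
  net <- train_network(net, ds, NULL, tc)
  path <- tempfile(fileext = ".json")
  save_network(net, path)
  net2 <- load_network(path)
  expect_equal(net2$W, net$W, tolerance = 0)
  expect_identical(predict(net2, ds)$params, predict(net, ds)$params)
})

test_that("common initialisation returns the best of the repetitions", {
  ds <- tiny_dataset(sigma = 0.1, reps = 2, seed = 61)
  val <- tiny_dataset(sigma = 0.1, reps = 1, seed = 62)
  tc <- training_config("NLR", sigma = 0.1, max_epochs = 2, patience = 2,
                        init_repetitions = 3, seed = 14)
  init <- common_initialisation(network_config(10), test_protocol(), ds, val,
                                tc)
  expect_length(init$init_manifest$val_losses, 3)
  expect_equal(init$final_val_loss, min(init$init_manifest$val_losses))
})
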