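test_that("composite loss reproduces hand-computed values", {
  # perfect prediction: both terms vanish (up to the SD epsilon guard)
  expect_equal(composite_loss(c(1, 2, 3), c(1, 2, 3), 0.8), 0,
               tolerance = 1e-6)
  expect_equal(composite_loss(c(1, 2, 3), c(1, 2, 3), 0.3), 0,
               tolerance = 1e-6)
  # anti-correlated: MAE 1, PCC -1 -> 0.8*1 + 0.2*2 = 1.2
  expect_equal(composite_loss(c(0, 1), c(1, 0), 0.8), 1.2, tolerance = 1e-7)
  # shifted: MAE 1, PCC 1 -> 0.8
  expect_equal(composite_loss(c(1, 2, 3), c(2, 3, 4), 0.8), 0.8,
               tolerance = 1e-7)
  # alpha weighting
  expect_equal(composite_loss(c(0, 1), c(1, 0), 0.5), 0.5 + 0.5 * 2,
               tolerance = 1e-7)
  expect_error(composite_loss(1:3, 1:2, 0.8))
})

test_that("composite loss is permutation invariant and guards zero variance", {
  set.seed(2)
  k <- rnorm(9); kh <- rnorm(9)
  p <- sample(9)
  expect_equal(composite_loss(k, kh, 0.8), composite_loss(k[p], kh[p], 0.8))
  # constant predictions: Pearson term ~ 1 (maximally penalized), not NaN
  l <- composite_loss(c(1, 2, 3), c(2, 2, 2), 0)
  expect_true(is.finite(l))
  expect_equal(l, 1, tolerance = 1e-4)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(3)
  for (alpha in c(0, 0.5, 0.8, 1)) {
    k <- rnorm(8)
    kh <- rnorm(8)
    ga <- cleavenet:::composite_loss_grad(k, kh, alpha)
    eps <- 1e-6
    fd <- vapply(1:8, function(i) {
      kp <- kh; kp[i] <- kp[i] + eps
      km <- kh; km[i] <- km[i] - eps
      (composite_loss(k, kp, alpha) - composite_loss(k, km, alpha)) / (2 * eps)
    }, numeric(1))
    expect_equal(ga, fd, tolerance = 1e-5)
  }
})

test_that("rate normalization round-trips and uses training data only", {
  nm <- normalize_rates(c(2, 4))
  expect_equal(nm$mean, 3)
  expect_equal(nm$sd, sd(c(2, 4)))
  expect_equal(normalize_apply(nm, nm$mean), 0)
  x <- c(0.3, 1.7, 9)
  expect_equal(normalize_invert(nm, normalize_apply(nm, x)), x)
  expect_error(normalize_rates(c(5, 5, 5)), "constant")
  expect_error(normalize_rates(7), "length")
})

test_that("evaluation metrics are the sample PCC and raw-unit MAE", {
  ev <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$pcc, 1)
  expect_equal(ev$mae, 0)
  expect_equal(evaluate(-c(1, 2, 3) + 10, c(1, 2, 3))$pcc, -1)
  # hand value: cor((1,2,4),(1,2,3)) = 0.9819805
  expect_equal(evaluate(c(1, 2, 4), c(1, 2, 3))$pcc, 0.981981,
               tolerance = 1e-5)
  expect_true(is.na(evaluate(c(2, 2, 2), c(1, 2, 3))$pcc))
})

test_that("paired t-test conventions match the textbook formula", {
  expect_equal(repeat_and_compare(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p = 1, df = 2L, mean_diff = 0))
  # nonzero constant difference: degenerate, reported as p -> 0
  r <- repeat_and_compare(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r$p, 0)
  expect_true(is.infinite(r$t) && r$t > 0)
  # hand oracle: d = (0.10, 0.07, 0.13), t = mean(d)/(sd(d)/sqrt(3))
  r2 <- repeat_and_compare(c(0.50, 0.62, 0.71), c(0.40, 0.55, 0.58))
  expect_equal(r2$t, 5.7735027, tolerance = 1e-6)
  expect_equal(r2$p, 0.028713, tolerance = 1e-4)
})

test_that("training is bit-reproducible given the seed", {
  bench <- tiny_dataset()
  mcfg <- tiny_config(L = 8L)
  tcfg <- train_config(lr = 3e-3, max_epochs = 3, batch_size = 32)
  sp <- cleavenet:::val_split_indices(length(bench$data), 0.15, 5)
  f1 <- train_model(bench$data[sp$train], bench$data[sp$val], mcfg, tcfg,
                    seed = 9)
  f2 <- train_model(bench$data[sp$train], bench$data[sp$val], mcfg, tcfg,
                    seed = 9)
  expect_identical(f1$model$par, f2$model$par)
  expect_identical(f1$history, f2$history)
  f3 <- train_model(bench$data[sp$train], bench$data[sp$val], mcfg, tcfg,
                    seed = 10)
  expect_false(identical(f1$model$par, f3$model$par))
})

test_that("training reduces the loss on a small benchmark", {
  bench <- tiny_dataset()
  mcfg <- tiny_config(L = 8L)
  tcfg <- train_config(lr = 5e-3, max_epochs = 8, batch_size = 32)
  sp <- cleavenet:::val_split_indices(length(bench$data), 0.15, 5)
  fit <- train_model(bench$data[sp$train], bench$data[sp$val], mcfg, tcfg,
                     seed = 1)
  h <- fit$history
  expect_lt(mean(tail(h$train_loss, 2)), h$train_loss[1])
  expect_true(fit$best_epoch >= 1 && fit$best_epoch <= nrow(h))
})

test_that("normalization and epoch selection never see held-out rates", {
  bench <- tiny_dataset()
  groups <- guide_groups(bench$data)
  tr_idx <- groups[[1]]
  te_idx <- groups[[2]]
  sp <- cleavenet:::val_split_indices(length(tr_idx), 0.15, 3)
  mcfg <- tiny_config(L = 8L)
  tcfg <- train_config(lr = 3e-3, max_epochs = 2, batch_size = 32)
  fit1 <- train_model(bench$data[tr_idx[sp$train]], bench$data[tr_idx[sp$val]],
                      mcfg, tcfg, seed = 4)
  # perturb the held-out rates: nothing about the fit may change
  pert <- bench$data
  pert$k[te_idx] <- pert$k[te_idx] * 10
  fit2 <- train_model(pert[tr_idx[sp$train]], pert[tr_idx[sp$val]],
                      mcfg, tcfg, seed = 4)
  expect_identical(fit1$model$par, fit2$model$par)
  expect_identical(fit1$model$norm, fit2$model$norm)
})

test_that("the scheduler halves the rate after a validation plateau", {
  bench <- tiny_dataset()
  mcfg <- tiny_config(L = 8L)
  # a learning rate this small cannot move the validation loss, forcing a
  # plateau; the scheduler must cut the rate every `patience` epochs
  tcfg <- train_config(lr = 1e-12, max_epochs = 7, batch_size = 64,
                       scheduler_patience = 3L, lr_min = 1e-20)
  sp <- cleavenet:::val_split_indices(length(bench$data), 0.15, 5)
  fit <- train_model(bench$data[sp$train], bench$data[sp$val], mcfg, tcfg,
                     seed = 2)
  lrs <- fit$history$lr
  # epoch 1 sets the baseline; epochs 2-4 stall -> cut at epoch 4, again
  # after three further stalled epochs at epoch 7
  expect_equal(lrs[1:3], rep(1e-12, 3))
  expect_equal(lrs[4], 1e-12 * 0.5)
  expect_equal(lrs[7], 1e-12 * 0.25)
})

test_that("size-1 trailing minibatches are merged", {
  b <- cleavenet:::make_batches(1:9, 4L)
  expect_equal(lengths(b), c(4L, 5L))
  b2 <- cleavenet:::make_batches(1:8, 4L)
  expect_equal(lengths(b2), c(4L, 4L))
  b3 <- cleavenet:::make_batches(1:10, 4L)
  expect_equal(lengths(b3), c(4L, 4L, 2L))
})

test_that("the retrain pass reproduces the two-stage protocol", {
  bench <- tiny_dataset()
  mcfg <- tiny_config(L = 8L)
  tcfg <- train_config(lr = 3e-3, max_epochs = 3, batch_size = 32,
                       retrain = TRUE)
  sp <- cleavenet:::val_split_indices(length(bench$data), 0.15, 5)
  fit <- train_model(bench$data[sp$train], bench$data[sp$val], mcfg, tcfg,
                     seed = 6)
  expect_true(all(is.finite(
    model_forward(fit$model, cleavenet:::dataset_encodings(bench$data)))))
  expect_identical(
    fit$model$par,
    train_model(bench$data[sp$train], bench$data[sp$val], mcfg, tcfg,
                seed = 6)$model$par)
})
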