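ENCODING_KINDS <- c("interaction", "concat_onehot", "kmer", "cnn_embed")
BASELINE_MODELS <- c("knn", "ridge", "random_forest", "extra_trees",
                     "bagging", "adaboost", "gradient_boosting", "xgboost",
                     "mlp", "ffnn")

#' Fit a classic regressor baseline on a chosen encoding
#'
#' The benchmarking harness that pits the interaction-centric encoding
#' against sequence-based strategies (concatenated one-hot, k-mer counts,
#' and a small trained convolutional feature extractor) under off-the-shelf
#' regressors. Rates are z-scored on the training set; reported metrics are
#' on de-normalized predictions.
#'
#' @param encoding_kind one of \code{"interaction"} (flattened
#'   interaction-centric features), \code{"concat_onehot"}, \code{"kmer"}
#'   (k = 3 by default), \code{"cnn_embed"}.
#' @param model_kind one of knn, ridge, random_forest, extra_trees,
#'   bagging, adaboost, gradient_boosting, xgboost, mlp, ffnn.
#' @param train,test \code{cleavage_dataset}s.
#' @param seed integer seed (tree ensembles, network initialization).
#' @param kmer_k k-mer size for the kmer encoding.
#' @return list with \code{eval} (an \code{\link{evaluate}} result on
#'   test), \code{predictions}, \code{encoding_kind}, \code{model_kind}.
#' @export
fit_baseline <- function(encoding_kind, model_kind, train, test, seed = 1L,
                         kmer_k = 3L) {
  if (!encoding_kind %in% ENCODING_KINDS) {
    stop("unknown encoding '", encoding_kind, "'; valid: ",
         paste(ENCODING_KINDS, collapse = ", "))
  }
  if (!model_kind %in% BASELINE_MODELS) {
    stop("unknown model '", model_kind, "'; valid: ",
         paste(BASELINE_MODELS, collapse = ", "))
  }
  stopifnot(inherits(train, "cleavage_dataset"),
            inherits(test, "cleavage_dataset"))
  feats <- baseline_features(encoding_kind, train, test, seed, kmer_k)
  norm <- normalize_rates(train$k)
  y <- normalize_apply(norm, train$k)
  set.seed(seed)
  pred_z <- baseline_fit_predict(model_kind, feats$train, y, feats$test, seed)
  pred <- normalize_invert(norm, pred_z)
  list(eval = evaluate(pred, test$k), predictions = pred,
       encoding_kind = encoding_kind, model_kind = model_kind)
}

# Feature matrices for train and test under one encoding; the cnn_embed
# extractor is fitted on the training records only.
baseline_features <- function(encoding_kind, train, test, seed, kmer_k) {
  fe <- function(data) {
    switch(encoding_kind,
      interaction = t(vapply(seq_len(n_records(data)), function(i) {
        flatten_interaction(encode_interaction(
          data$guides[[data$guide_id[i]]], data$specs[[i]]))
      }, numeric(train$guides[[1]]$L * 11L + train$guides[[1]]$L + 1L))),
      concat_onehot = t(vapply(seq_len(n_records(data)), function(i) {
        g <- data$guides[[data$guide_id[i]]]
        encode_concat_onehot(g, target_from_spec(g, data$specs[[i]]))
      }, numeric(train$guides[[1]]$L * 8L))),
      kmer = t(vapply(seq_len(n_records(data)), function(i) {
        g <- data$guides[[data$guide_id[i]]]
        encode_kmer(g, target_from_spec(g, data$specs[[i]]), kmer_k)
      }, numeric(2L * 4L^kmer_k))),
      cnn_embed = NULL)
  }
  if (encoding_kind == "cnn_embed") {
    cnn_embed_features(train, test, seed)
  } else {
    list(train = fe(train), test = fe(test))
  }
}

baseline_fit_predict <- function(model_kind, X, y, Xtest, seed) {
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("baseline '", model_kind, "' needs package '", pkg, "'")
    }
  }
  switch(model_kind,
    knn = {
      need("caret")
      fit <- caret::knnreg(X, y, k = 5L)
      as.numeric(stats::predict(fit, Xtest))
    },
    ridge = {
      need("glmnet")
      fit <- glmnet::glmnet(X, y, alpha = 0, lambda = 1e-4)
      as.numeric(stats::predict(fit, Xtest, s = 1e-4))
    },
    random_forest = {
      need("randomForest")
      fit <- randomForest::randomForest(X, y, ntree = 300L)
      as.numeric(stats::predict(fit, Xtest))
    },
    extra_trees = {
      need("ranger")
      df <- as.data.frame(X); df$.y <- y
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = 300L,
                            splitrule = "extratrees", replace = FALSE,
                            sample.fraction = 1, seed = seed)
      as.numeric(stats::predict(fit, as.data.frame(Xtest))$predictions)
    },
    bagging = {
      # bagged regression trees = random forest with mtry = p
      need("randomForest")
      fit <- randomForest::randomForest(X, y, ntree = 300L, mtry = ncol(X))
      as.numeric(stats::predict(fit, Xtest))
    },
    adaboost = adaboost_r2(X, y, Xtest, n_estimators = 50L),
    gradient_boosting = {
      # classic slow-learning GBM settings (shrinkage 0.1, depth-3 trees)
      xgb_fit_predict(X, y, Xtest, nrounds = 300L, eta = 0.1, max_depth = 3L)
    },
    xgboost = {
      xgb_fit_predict(X, y, Xtest, nrounds = 100L, eta = 0.3, max_depth = 6L)
    },
    mlp = {
      need("nnet")
      fit <- nnet::nnet(X, y, size = 32L, linout = TRUE, decay = 1e-4,
                        maxit = 300L, MaxNWts = 100000L, trace = FALSE)
      as.numeric(stats::predict(fit, Xtest))
    },
    ffnn = ffnn_fit_predict(X, y, Xtest, seed))
}

xgb_fit_predict <- function(X, y, Xtest, nrounds, eta, max_depth) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("this baseline needs package 'xgboost'")
  }
  fit <- xgboost::xgb.train(
    params = list(eta = eta, max_depth = max_depth, nthread = 1L,
                  objective = "reg:squarederror"),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = nrounds, verbose = 0)
  as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(Xtest)))
}

# AdaBoost.R2 (Drucker 1997) over shallow regression trees: reweighted
# bootstrap fits, linear loss, weighted-median aggregation. Hand-written
# because no installed package offers AdaBoost regression.
adaboost_r2 <- function(X, y, Xtest, n_estimators = 50L, maxdepth = 8L) {
  if (!requireNamespace("rpart", quietly = TRUE)) {
    stop("baseline 'adaboost' needs package 'rpart'")
  }
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- as.data.frame(X); df$.y <- y
  dftest <- as.data.frame(Xtest)
  fits <- list(); betas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, xval = 0,
                          minsplit = 4L, minbucket = 2L))
    pred <- stats::predict(fit, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax == 0) { fits <- c(fits, list(fit)); betas <- c(betas, 1e-10); break }
    lvec <- err / emax
    ebar <- sum(w * lvec)
    if (ebar >= 0.5) break
    beta <- ebar / (1 - ebar)
    w <- w * beta^(1 - lvec)
    w <- w / sum(w)
    fits <- c(fits, list(fit)); betas <- c(betas, beta)
  }
  if (length(fits) == 0L) stop("adaboost failed to fit any estimator")
  preds <- vapply(fits, function(f) stats::predict(f, dftest),
                  numeric(nrow(Xtest)))
  preds <- matrix(preds, nrow = nrow(Xtest))
  lw <- log(1 / betas)
  apply(preds, 1L, function(p) {
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1]]
  })
}

# Small feed-forward network (two ReLU hidden layers) trained with AdamW on
# MSE over standardized features; reuses the package's optimizer.
ffnn_fit_predict <- function(X, y, Xtest, seed, hidden = c(32L, 16L),
                             epochs = 80L, lr = 1e-3, batch_size = 64L,
                             weight_decay = 5e-3) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1  # train-constant columns pass through unscaled
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xt <- sweep(sweep(Xtest, 2, mu), 2, sdv, "/")
  set.seed(seed)
  par <- list(W1 = init_mat(ncol(Xs), hidden[1]), b1 = numeric(hidden[1]),
              W2 = init_mat(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
              W3 = init_mat(hidden[2], 1L), b3 = 0)
  theta <- flatten_params(par)
  opt <- adamw_init(length(theta))
  n <- nrow(Xs)
  fwd <- function(par, X) {
    A1 <- relu_fwd(linear_fwd(X, par$W1, par$b1))
    A2 <- relu_fwd(linear_fwd(A1, par$W2, par$b2))
    list(pred = as.numeric(A2 %*% par$W3) + par$b3, A1 = A1, A2 = A2)
  }
  for (ep in seq_len(epochs)) {
    for (idx in make_batches(sample.int(n), batch_size)) {
      par <- unflatten_params(par, theta)
      f <- fwd(par, Xs[idx, , drop = FALSE])
      d <- 2 * (f$pred - y[idx]) / length(idx)
      g <- list()
      g$W3 <- crossprod(f$A2, matrix(d)); g$b3 <- sum(d)
      dA2 <- relu_bwd(matrix(d) %*% t(par$W3), f$A2)
      l2 <- linear_bwd(dA2, f$A1, par$W2)
      g$W2 <- l2$dW; g$b2 <- l2$db
      dA1 <- relu_bwd(l2$dX, f$A1)
      l1 <- linear_bwd(dA1, Xs[idx, , drop = FALSE], par$W1)
      g$W1 <- l1$dW; g$b1 <- l1$db
      stepped <- adamw_step(theta, flatten_like(par, g), opt, lr,
                            weight_decay)
      theta <- stepped$theta; opt <- stepped$state
    }
  }
  par <- unflatten_params(par, theta)
  fwd(par, Xt)$pred
}

# Trained convolutional feature extractor for the cnn_embed baseline: one
# convolution (16 filters, width 3) over the stacked guide/target one-hot,
# ReLU, global max-pool over positions, fitted end-to-end with a linear
# head on the training records, then frozen as a feature map.
cnn_embed_features <- function(train, test, seed, filters = 16L,
                               epochs = 60L, lr = 1e-2) {
  L <- train$guides[[1]]$L
  stack8 <- function(data) {
    B <- n_records(data)
    X <- matrix(0, B * L, 8L)
    for (i in seq_len(B)) {
      g <- data$guides[[data$guide_id[i]]]
      tg <- strsplit(target_from_spec(g, data$specs[[i]]), "")[[1]]
      rows <- (i - 1L) * L + seq_len(L)
      X[rows, 1:4] <- matrix(onehot_vec(g$seq), L, 4L, byrow = TRUE)
      X[rows, 5:8] <- matrix(onehot_vec(tg), L, 4L, byrow = TRUE)
    }
    X
  }
  Xtr <- stack8(train); Xte <- stack8(test)
  Btr <- n_records(train)
  norm <- normalize_rates(train$k)
  y <- normalize_apply(norm, train$k)
  set.seed(seed)
  par <- list(W = lapply(1:3, function(j) init_mat(8L, filters)),
              b = numeric(filters),
              Wh = init_mat(filters, 1L), bh = 0)
  theta <- flatten_params(par)
  opt <- adamw_init(length(theta))
  pool <- function(H, B) {
    # global max over the L rows of each record, per channel
    grp <- rep(seq_len(B), each = L)
    vals <- matrix(0, B, ncol(H)); amax <- matrix(0L, B, ncol(H))
    for (c in seq_len(ncol(H))) {
      hc <- matrix(H[, c], L, B)
      amax[, c] <- max.col(t(hc), ties.method = "first")
      vals[, c] <- hc[cbind(amax[, c], seq_len(B))]
    }
    list(vals = vals, amax = amax)
  }
  for (ep in seq_len(epochs)) {
    par <- unflatten_params(par, theta)
    Hpre <- conv1d_fwd(Xtr, par$W, par$b, L, Btr)
    H <- relu_fwd(Hpre)
    pl <- pool(H, Btr)
    pred <- as.numeric(pl$vals %*% par$Wh) + par$bh
    d <- 2 * (pred - y) / Btr
    g <- list()
    dvals <- matrix(d) %*% t(par$Wh)
    g$Wh <- crossprod(pl$vals, matrix(d)); g$bh <- sum(d)
    dH <- matrix(0, nrow(H), ncol(H))
    for (c in seq_len(ncol(H))) {
      rows <- (seq_len(Btr) - 1L) * L + pl$amax[, c]
      dH[cbind(rows, c)] <- dvals[, c]
    }
    cb <- conv1d_bwd(relu_bwd(dH, Hpre), Xtr, par$W, L, Btr)
    g$W <- cb$dW; g$b <- cb$db
    stepped <- adamw_step(theta, flatten_like(par, g), opt, lr, 1e-4)
    theta <- stepped$theta; opt <- stepped$state
  }
  par <- unflatten_params(par, theta)
  featurize <- function(X, B) {
    pool(relu_fwd(conv1d_fwd(X, par$W, par$b, L, B)), B)$vals
  }
  list(train = featurize(Xtr, Btr), test = featurize(Xte, n_records(test)))
}

#' Run the encoding-by-model benchmark grid
#'
#' Evaluates every requested encoding/regressor combination on one
#' train/test split and tabulates test PCC and MAE — the experiment shape
#' used to show that interaction-centric features dominate sequence-only
#' encodings regardless of the downstream model.
#'
#' @param train,test \code{cleavage_dataset}s.
#' @param encodings,models character vectors of kinds (defaults: all).
#' @param seed integer seed.
#' @return data frame with columns encoding, model, pcc, mae.
#' @export
benchmark_grid <- function(train, test, encodings = ENCODING_KINDS,
                           models = BASELINE_MODELS, seed = 1L) {
  rows <- list()
  for (enc in encodings) {
    for (mod in models) {
      fb <- fit_baseline(enc, mod, train, test, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        encoding = enc, model = mod, pcc = fb$eval$pcc, mae = fb$eval$mae,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
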