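#' Training configuration
#'
#' Optimization settings. Reference defaults: composite-loss weight
#' alpha = 0.8, AdamW with learning rate 1e-4 and decoupled weight decay
#' 0.1, batch size 128, learning rate halved after 5 epochs without
#' validation-loss improvement, 10 evaluation seeds. \code{max_epochs}
#' defaults to 200 with early stop once the learning rate decays below
#' \code{lr_min}. Small synthetic benchmarks in this package's examples and
#' tests use a larger learning rate and fewer epochs (see the methods
#' vignette); the defaults here are the reference protocol.
#'
#' @param alpha MAE weight of the composite loss, in [0, 1].
#' @param lr initial AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param batch_size minibatch size (>= 2; the Pearson term needs at least
#'   two points, and a trailing size-1 batch is merged into its
#'   predecessor).
#' @param scheduler_factor multiplicative learning-rate reduction on
#'   plateau.
#' @param scheduler_patience epochs without validation improvement before a
#'   reduction.
#' @param max_epochs maximum training epochs.
#' @param lr_min stop training once the learning rate falls below this.
#' @param n_seeds replicate seeds used by repeated evaluations.
#' @param val_fraction fraction of training records held out as the inner
#'   validation split for epoch selection.
#' @param retrain if TRUE, after selecting the best epoch on the inner
#'   validation split, retrain on the full training set for that many
#'   epochs (the two-stage protocol); if FALSE (default) return the
#'   best-epoch weights directly.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(alpha = 0.8, lr = 1e-4, weight_decay = 0.1,
                         batch_size = 128L, scheduler_factor = 0.5,
                         scheduler_patience = 5L, max_epochs = 200L,
                         lr_min = 1e-6, n_seeds = 10L, val_fraction = 0.1,
                         retrain = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, lr > 0, weight_decay >= 0,
            batch_size >= 2L, scheduler_factor > 0, scheduler_factor < 1,
            scheduler_patience >= 1L, max_epochs >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(list(alpha = alpha, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 max_epochs = as.integer(max_epochs), lr_min = lr_min,
                 n_seeds = as.integer(n_seeds), val_fraction = val_fraction,
                 retrain = isTRUE(retrain)),
            class = "train_config")
}

# ---- flat parameter vector utilities -------------------------------------

flatten_params <- function(x) {
  if (is.list(x)) {
    unlist(lapply(x, flatten_params), use.names = FALSE)
  } else {
    as.numeric(x)
  }
}

# Flatten `x` following the structure/names of skeleton `sk` (used to align
# the gradient list, which is assembled in backward order, with the
# parameter list).
flatten_like <- function(sk, x) {
  if (is.list(sk)) {
    nms <- names(sk)
    parts <- lapply(seq_along(sk), function(i) {
      xi <- if (!is.null(nms) && nzchar(nms[i])) x[[nms[i]]] else x[[i]]
      flatten_like(sk[[i]], xi)
    })
    unlist(parts, use.names = FALSE)
  } else {
    as.numeric(x)
  }
}

unflatten_params <- function(sk, vec) {
  pos <- 0L
  rebuild <- function(s) {
    if (is.list(s)) {
      out <- lapply(s, rebuild)
      names(out) <- names(s)
      out
    } else {
      n <- length(s)
      v <- vec[pos + seq_len(n)]
      pos <<- pos + n
      if (!is.null(dim(s))) dim(v) <- dim(s)
      v
    }
  }
  rebuild(sk)
}

# ---- AdamW ---------------------------------------------------------------

adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(theta, grad, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

# ---- dataset stacking ----------------------------------------------------

# Encode an entire dataset once into the dense batch layout; minibatches
# are then row subsets.
stack_dataset <- function(data, simple_pairing = FALSE) {
  st <- stack_encodings(dataset_encodings(data), simple_pairing)
  st
}

subset_stack <- function(st, idx) {
  L <- st$L
  rows <- rep((idx - 1L) * L, each = L) + seq_len(L)
  list(X = st$X[rows, , drop = FALSE],
       Imat = st$Imat[idx, , drop = FALSE],
       B = length(idx), L = L)
}

# ---- training loop -------------------------------------------------------

#' Train a predictor on a train/validation split
#'
#' Minibatch AdamW optimization of the composite MAE-Pearson loss on
#' z-score-normalized rates (normalization fitted on the training records
#' only). The learning rate is multiplied by \code{scheduler_factor}
#' whenever the validation loss fails to improve for
#' \code{scheduler_patience} consecutive epochs; training stops at
#' \code{max_epochs} or when the rate falls below \code{lr_min}. The
#' returned model carries the parameters of the epoch with the lowest
#' validation MAE; with \code{tcfg$retrain = TRUE} a second pass retrains
#' on train+validation for that many epochs. Fully reproducible given
#' \code{seed}.
#'
#' @param train,val disjoint \code{cleavage_dataset}s (val nonempty, >= 2
#'   records).
#' @param mcfg a \code{\link{model_config}}.
#' @param tcfg a \code{\link{train_config}}.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return list with \code{model} (a trained \code{predictor} carrying the
#'   normalization), \code{history} (per-epoch data frame), and
#'   \code{best_epoch}.
#' @export
train_model <- function(train, val, mcfg, tcfg, seed = 1L) {
  stopifnot(inherits(train, "cleavage_dataset"),
            inherits(val, "cleavage_dataset"))
  if (n_records(val) < 2L) {
    stop("validation set needs >= 2 records for the Pearson term")
  }
  norm <- normalize_rates(train$k)
  simple <- mcfg$ablation == "SIMPLE_PAIRING"
  st_train <- stack_dataset(train, simple)
  st_val <- stack_dataset(val, simple)
  k_train <- normalize_apply(norm, train$k)
  k_val <- normalize_apply(norm, val$k)
  fit <- run_optimization(st_train, k_train, st_val, k_val, mcfg, tcfg, seed)
  model <- fit$model
  if (tcfg$retrain && fit$best_epoch >= 1L) {
    full <- list(X = rbind(st_train$X, st_val$X),
                 Imat = rbind(st_train$Imat, st_val$Imat),
                 B = st_train$B + st_val$B, L = st_train$L)
    k_full <- c(k_train, k_val)
    refit <- run_optimization(full, k_full, st_val = NULL, k_val = NULL,
                              mcfg, tcfg, seed, fixed_epochs = fit$best_epoch)
    model <- refit$model
  }
  model$norm <- norm
  list(model = model, history = fit$history, best_epoch = fit$best_epoch)
}

# Core loop; st_val = NULL runs a fixed number of epochs with no epoch
# selection (used by the retrain pass).
run_optimization <- function(st_train, k_train, st_val, k_val, mcfg, tcfg,
                             seed, fixed_epochs = NULL) {
  model <- build_model(mcfg, seed)
  theta <- flatten_params(model$par)
  opt <- adamw_init(length(theta))
  lr <- tcfg$lr
  set.seed(seed + 1L)
  N <- st_train$B
  n_epochs <- if (is.null(fixed_epochs)) tcfg$max_epochs else fixed_epochs
  best_val_mae <- Inf
  best_theta <- theta
  best_epoch <- 0L
  plateau <- 0L
  best_sched_loss <- Inf
  hist <- vector("list", n_epochs)
  for (epoch in seq_len(n_epochs)) {
    ord <- sample.int(N)
    batches <- make_batches(ord, tcfg$batch_size)
    epoch_loss <- 0
    nb <- 0L
    for (idx in batches) {
      batch <- subset_stack(st_train, idx)
      model$par <- unflatten_params(model$par, theta)
      fw <- nn_forward(model, batch, training = TRUE)
      loss <- composite_loss(k_train[idx], fw$pred, tcfg$alpha)
      dpred <- composite_loss_grad(k_train[idx], fw$pred, tcfg$alpha)
      bw <- nn_backward(model, fw$cache, dpred)
      grad <- flatten_like(model$par, bw$grads)
      stepped <- adamw_step(theta, grad, opt, lr, tcfg$weight_decay)
      theta <- stepped$theta
      opt <- stepped$state
      epoch_loss <- epoch_loss + loss
      nb <- nb + 1L
    }
    model$par <- unflatten_params(model$par, theta)
    if (!is.null(st_val)) {
      val_pred <- nn_forward(model, st_val, training = FALSE)$pred
      val_loss <- composite_loss(k_val, val_pred, tcfg$alpha)
      val_mae <- mean(abs(k_val - val_pred))
      if (val_mae < best_val_mae) {
        best_val_mae <- val_mae
        best_theta <- theta
        best_epoch <- epoch
      }
      if (val_loss < best_sched_loss - 1e-9) {
        best_sched_loss <- val_loss
        plateau <- 0L
      } else {
        plateau <- plateau + 1L
        if (plateau >= tcfg$scheduler_patience) {
          lr <- lr * tcfg$scheduler_factor
          plateau <- 0L
        }
      }
    } else {
      val_loss <- NA_real_
      val_mae <- NA_real_
    }
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = epoch_loss / max(nb, 1L),
                                val_loss = val_loss, val_mae = val_mae,
                                lr = lr)
    if (lr < tcfg$lr_min) break
  }
  if (is.null(st_val)) {
    best_theta <- theta
    best_epoch <- n_epochs
  }
  model$par <- unflatten_params(model$par, best_theta)
  list(model = model, history = do.call(rbind, hist), best_epoch = best_epoch)
}

# Split a shuffled index vector into minibatches; the last incomplete batch
# is kept, except that a size-1 tail is merged into the previous batch so
# the Pearson term stays defined.
make_batches <- function(ord, batch_size) {
  N <- length(ord)
  starts <- seq.int(1L, N, by = batch_size)
  batches <- lapply(starts, function(s) ord[s:min(s + batch_size - 1L, N)])
  nb <- length(batches)
  if (nb > 1L && length(batches[[nb]]) == 1L) {
    batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
    batches[[nb]] <- NULL
  }
  batches
}

# Seeded train/validation index split within one training set.
val_split_indices <- function(n, val_fraction, seed) {
  set.seed(seed)
  n_val <- max(2L, round(n * val_fraction))
  val_idx <- sort(sample.int(n, n_val))
  list(train = setdiff(seq_len(n), val_idx), val = val_idx)
}

# ---- user-facing fit -----------------------------------------------------

#' Fit a position-aware cleavage-rate model
#'
#' The main fitting entry point: splits off a seeded inner validation
#' fraction, trains the hybrid convolution/attention predictor with the
#' composite MAE-Pearson objective on z-scored rates, and returns the
#' best-validation-epoch model as a classed object with the usual
#' \code{predict}/\code{summary}/\code{residuals}/\code{plot} methods.
#'
#' @param data a \code{\link{cleavage_dataset}}.
#' @param model a \code{\link{model_config}} (its L must match the guides).
#' @param training a \code{\link{train_config}}.
#' @param seed integer seed; the whole fit is bit-reproducible given the
#'   data and this seed.
#' @return object of class \code{cleavenet}.
#' @examples
#' \donttest{
#' bench <- generate_benchmark(n_guides = 2, seed = 1, L = 12,
#'                             design = library_design(2:8, FALSE))
#' fit <- cleavenet(bench$data, model = model_config(L = 12, d = 8, n_layers = 1),
#'                  training = train_config(lr = 3e-3, max_epochs = 3),
#'                  seed = 1)
#' print(fit)
#' }
#' @export
cleavenet <- function(data, model = model_config(L = data$guides[[1]]$L),
                      training = train_config(), seed = 1L) {
  stopifnot(inherits(data, "cleavage_dataset"))
  sp <- val_split_indices(n_records(data), training$val_fraction, seed)
  fit <- train_model(data[sp$train], data[sp$val], model, training, seed)
  structure(list(model = fit$model, history = fit$history,
                 best_epoch = fit$best_epoch, config = model,
                 training = training, seed = as.integer(seed),
                 data = data, val_idx = sp$val, call = match.call()),
            class = "cleavenet")
}

#' @export
print.cleavenet <- function(x, ...) {
  cat("Position-aware guide-target cleavage rate model\n")
  cat(sprintf("  %d records, %d guide(s); ablation: %s\n",
              n_records(x$data), length(x$data$guides), x$config$ablation))
  cat(sprintf("  best epoch %d of %d; %d parameters\n", x$best_epoch,
              nrow(x$history), count_parameters(x$model)))
  invisible(x)
}

#' Predict cleavage rates from a fitted model
#'
#' @param object a fitted \code{cleavenet} model.
#' @param newdata a \code{cleavage_dataset} (defaults to the training data).
#' @param type \code{"rate"} for de-normalized cleavage rates,
#'   \code{"normalized"} for z-score-space predictions.
#' @param ... unused.
#' @return numeric vector of predictions, one per record.
#' @export
predict.cleavenet <- function(object, newdata = NULL,
                              type = c("rate", "normalized"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  stopifnot(inherits(data, "cleavage_dataset"))
  pred <- model_forward(object$model, dataset_encodings(data))
  if (type == "rate") normalize_invert(object$model$norm, pred) else pred
}

#' @export
fitted.cleavenet <- function(object, ...) predict(object)

#' @export
residuals.cleavenet <- function(object, ...) object$data$k - fitted(object)

#' @export
coef.cleavenet <- function(object, ...) object$model$par

#' @export
summary.cleavenet <- function(object, ...) {
  ev <- evaluate(fitted(object), object$data$k)
  structure(list(fit = object, train_eval = ev), class = "summary.cleavenet")
}

#' @export
print.summary.cleavenet <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  in-sample: PCC %.3f, MAE %.4g (n = %d)\n",
              x$train_eval$pcc, x$train_eval$mae, x$train_eval$n))
  h <- x$fit$history
  cat(sprintf("  final train loss %.4g; best val MAE %.4g (epoch %d)\n",
              h$train_loss[nrow(h)], min(h$val_mae, na.rm = TRUE),
              x$fit$best_epoch))
  invisible(x)
}

#' Plot training history of a fitted model
#'
#' Training and validation composite loss per epoch, with the selected best
#' epoch marked.
#'
#' @param x a \code{cleavenet} fit; @param ... passed to
#'   \code{\link[graphics]{matplot}}.
#' @export
plot.cleavenet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "composite loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
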