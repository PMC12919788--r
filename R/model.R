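ABLATIONS <- c("NONE", "NO_POSITION", "PURE_CNN", "SIMPLE_PAIRING", "NO_INSERT")

#' Model configuration
#'
#' Architecture hyperparameters of the cleavage-rate predictor. Defaults are
#' the reference settings: embedding width d = 16 shared by the positional
#' table and the convolution (16 filters, kernel 3), a 3-layer post-LN
#' transformer encoder with 4 attention heads and a feed-forward width of
#' 4d, an 8-dimensional insertion embedding, and a 64-unit regression head.
#'
#' @param L guide length (positions attended over).
#' @param d per-position embedding width; must be divisible by
#'   \code{n_heads}.
#' @param d_ins insertion-branch embedding width.
#' @param conv_filters convolution output channels (kept equal to d so the
#'   transformer consumes the convolution output directly).
#' @param kernel convolution kernel size (odd; zero padding keeps length L).
#' @param n_layers transformer depth.
#' @param n_heads attention heads.
#' @param head_hidden hidden width of the regression head.
#' @param dropout dropout rate inside transformer blocks (training only).
#' @param ablation one of \code{"NONE"}, \code{"NO_POSITION"} (no positional
#'   table), \code{"PURE_CNN"} (no transformer; the convolution output is
#'   flattened directly), \code{"SIMPLE_PAIRING"} (pairing detail collapsed
#'   to one binary match channel; per-position input width 6 instead of 11),
#'   \code{"NO_INSERT"} (insertion branch removed).
#' @return object of class \code{model_config}.
#' @export
model_config <- function(L = 26L, d = 16L, d_ins = 8L, conv_filters = d,
                         kernel = 3L, n_layers = 3L, n_heads = 4L,
                         head_hidden = 64L, dropout = 0.1,
                         ablation = "NONE") {
  ablation <- match.arg(ablation, ABLATIONS)
  cfg <- list(L = as.integer(L), d = as.integer(d), d_ins = as.integer(d_ins),
              conv_filters = as.integer(conv_filters),
              kernel = as.integer(kernel), n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads),
              head_hidden = as.integer(head_hidden),
              dropout = as.numeric(dropout), ablation = ablation)
  if (cfg$L < 3L) stop("L must be >= 3")
  if (cfg$d %% cfg$n_heads != 0L) {
    stop("embedding width d (", cfg$d, ") must be divisible by n_heads (",
         cfg$n_heads, ")")
  }
  if (cfg$kernel %% 2L == 0L) stop("kernel size must be odd")
  if (cfg$head_hidden < 1L) stop("head_hidden must be >= 1")
  if (cfg$conv_filters != cfg$d) {
    stop("conv_filters must equal d (the transformer consumes the ",
         "convolution output directly)")
  }
  structure(cfg, class = "model_config")
}

# Per-position input channel count: [G(4), M(2), E(4), D(1)] = 11, or
# [G(4), match(1), D(1)] = 6 under the SIMPLE_PAIRING ablation.
input_channels <- function(config) {
  if (config$ablation == "SIMPLE_PAIRING") 6L else 11L
}

head_input_width <- function(config) {
  w <- config$L * config$d
  if (config$ablation != "NO_INSERT") w <- w + config$d_ins
  w
}

uses_position <- function(config) config$ablation != "NO_POSITION"
uses_transformer <- function(config) config$ablation != "PURE_CNN"
uses_insertions <- function(config) config$ablation != "NO_INSERT"

# Uniform fan-in initialization for weight matrices, zero biases,
# small-normal positional table; all draws come from the seeded RNG in a
# fixed order so builds are bit-reproducible.
init_mat <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build a cleavage-rate predictor with freshly initialized parameters
#'
#' Parameters are drawn deterministically from \code{seed}: weight matrices
#' use uniform fan-in scaling, biases start at zero, layer norms at
#' identity, and the positional table at Normal(0, 0.02). Ablation variants
#' change the parameter set as described in \code{\link{model_config}}.
#'
#' @param config a \code{\link{model_config}}.
#' @param seed integer seed.
#' @return object of class \code{predictor} holding \code{config} and the
#'   parameter list; optionally carries z-score normalization parameters
#'   once trained.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  d <- config$d
  cin <- input_channels(config)
  par <- list(W_G = init_mat(cin, d), b_G = numeric(d))
  if (uses_position(config)) {
    par$P <- matrix(stats::rnorm(config$L * d, 0, 0.02), config$L, d)
  }
  par$conv_W <- lapply(seq_len(config$kernel), function(j) init_mat(d, d))
  par$conv_b <- numeric(d)
  if (uses_transformer(config)) {
    par$layers <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = init_mat(d, d), bq = numeric(d),
           Wk = init_mat(d, d), bk = numeric(d),
           Wv = init_mat(d, d), bv = numeric(d),
           Wo = init_mat(d, d), bo = numeric(d),
           g1 = rep(1, d), be1 = numeric(d),
           Wf1 = init_mat(d, 4L * d), bf1 = numeric(4L * d),
           Wf2 = init_mat(4L * d, d), bf2 = numeric(d),
           g2 = rep(1, d), be2 = numeric(d))
    })
  }
  if (uses_insertions(config)) {
    par$W_I <- init_mat(config$L + 1L, config$d_ins)
    par$b_I <- numeric(config$d_ins)
  }
  hin <- head_input_width(config)
  par$W1 <- init_mat(hin, config$head_hidden)
  par$b1 <- numeric(config$head_hidden)
  par$W2 <- init_mat(config$head_hidden, 1L)
  par$b2 <- 0
  structure(list(config = config, par = par, norm = NULL,
                 seed = as.integer(seed)),
            class = "predictor")
}

#' @export
print.predictor <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<predictor> L=%d d=%d d_ins=%d kernel=%d layers=%d ",
                     "heads=%d head=%d ablation=%s\n"),
              cfg$L, cfg$d, cfg$d_ins, cfg$kernel, cfg$n_layers, cfg$n_heads,
              cfg$head_hidden, cfg$ablation))
  cat(sprintf("  %d parameters; %s\n", count_parameters(x),
              if (is.null(x$norm)) "untrained" else "trained (z-score rates)"))
  invisible(x)
}

#' Total number of learnable scalars in a predictor
#' @param model a \code{predictor}.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "predictor"))
  sum(rapply(model$par, length, how = "unlist"))
}

# Flatten per-record position blocks: H is (B*L) x d record-major; returns
# B x (L*d) with record b's row = [h_{b,1}, h_{b,2}, ...].
flatten_positions <- function(H, L, B) {
  t(matrix(t(H), L * ncol(H), B))
}

unflatten_positions <- function(Flat, L, B, d) {
  matrix(t(Flat), ncol = d, byrow = TRUE)
}

# Full forward pass. batch: output of stack_encodings(); training toggles
# dropout. Returns predictions (normalized-rate space) plus the cache the
# backward pass consumes.
nn_forward <- function(model, batch, training = FALSE) {
  cfg <- model$config
  par <- model$par
  L <- cfg$L; B <- batch$B
  if (batch$L != L) stop("batch encodes L = ", batch$L,
                         " but the model expects L = ", cfg$L)
  if (ncol(batch$X) != input_channels(cfg)) {
    stop("batch has ", ncol(batch$X), " input channels but the model expects ",
         input_channels(cfg), " (ablation ", cfg$ablation, ")")
  }
  cache <- list(batch = batch)
  H0 <- linear_fwd(batch$X, par$W_G, par$b_G)
  H1 <- if (uses_position(cfg)) H0 + par$P[rep(seq_len(L), B), , drop = FALSE] else H0
  cache$H1 <- H1
  Hc_pre <- conv1d_fwd(H1, par$conv_W, par$conv_b, L, B)
  Hloc <- relu_fwd(Hc_pre)
  cache$Hc_pre <- Hc_pre
  H <- Hloc
  if (uses_transformer(cfg)) {
    cache$blocks <- vector("list", cfg$n_layers)
    for (l in seq_len(cfg$n_layers)) {
      tb <- transformer_block_fwd(H, par$layers[[l]], L, B, cfg$n_heads,
                                  cfg$dropout, training)
      cache$blocks[[l]] <- tb$cache
      H <- tb$Y
    }
  }
  cache$Hfinal <- H
  Flat <- flatten_positions(H, L, B)
  if (uses_insertions(cfg)) {
    z <- linear_fwd(batch$Imat, par$W_I, par$b_I)
    U <- cbind(Flat, z)
  } else {
    U <- Flat
  }
  cache$U <- U
  Hh_pre <- linear_fwd(U, par$W1, par$b1)
  Hh <- relu_fwd(Hh_pre)
  cache$Hh_pre <- Hh_pre
  cache$Hh <- Hh
  pred <- as.numeric(Hh %*% par$W2) + par$b2
  list(pred = pred, cache = cache)
}

# Full backward pass: dpred is dLoss/dprediction (length B). Returns
# parameter gradients (same structure as model$par) plus input gradients
# dX ((B*L) x channels) and dI (B x (L+1), zero matrix under NO_INSERT).
nn_backward <- function(model, cache, dpred) {
  cfg <- model$config
  par <- model$par
  L <- cfg$L; B <- cache$batch$B
  grads <- list()
  dHh <- matrix(dpred, B, 1L) %*% t(par$W2)
  grads$W2 <- crossprod(cache$Hh, matrix(dpred, B, 1L))
  grads$b2 <- sum(dpred)
  dHh_pre <- relu_bwd(dHh, cache$Hh_pre)
  l1 <- linear_bwd(dHh_pre, cache$U, par$W1)
  grads$W1 <- l1$dW; grads$b1 <- l1$db
  dU <- l1$dX
  flat_w <- cfg$L * cfg$d
  dFlat <- dU[, seq_len(flat_w), drop = FALSE]
  if (uses_insertions(cfg)) {
    dz <- dU[, flat_w + seq_len(cfg$d_ins), drop = FALSE]
    li <- linear_bwd(dz, cache$batch$Imat, par$W_I)
    grads$W_I <- li$dW; grads$b_I <- li$db
    dI <- li$dX
  } else {
    dI <- matrix(0, B, L + 1L)
  }
  dH <- unflatten_positions(dFlat, L, B, cfg$d)
  if (uses_transformer(cfg)) {
    grads$layers <- vector("list", cfg$n_layers)
    for (l in rev(seq_len(cfg$n_layers))) {
      tb <- transformer_block_bwd(dH, cache$blocks[[l]], par$layers[[l]],
                                  L, cfg$n_heads)
      grads$layers[[l]] <- tb$grads
      dH <- tb$dH
    }
  }
  dHc_pre <- relu_bwd(dH, cache$Hc_pre)
  cb <- conv1d_bwd(dHc_pre, cache$H1, par$conv_W, L, B)
  grads$conv_W <- cb$dW; grads$conv_b <- cb$db
  dH1 <- cb$dH
  if (uses_position(cfg)) {
    grads$P <- rowsum(dH1, rep(seq_len(L), B), reorder = TRUE)
  }
  lg <- linear_bwd(dH1, cache$batch$X, par$W_G)
  grads$W_G <- lg$dW; grads$b_G <- lg$db
  list(grads = grads, dX = lg$dX, dI = dI)
}

#' Predict normalized cleavage rates for a batch of encodings
#'
#' Low-level forward pass over interaction encodings (dropout off).
#' Predictions live in z-score-normalized rate space; de-normalization is
#' applied by \code{\link{predict.cleavenet}} when normalization parameters
#' are attached.
#'
#' @param model a \code{predictor}.
#' @param encodings list of \code{interaction_encoding} objects (all with
#'   the model's L).
#' @return numeric vector, one prediction per encoding.
#' @export
model_forward <- function(model, encodings) {
  stopifnot(inherits(model, "predictor"), length(encodings) >= 1L)
  batch <- stack_encodings(encodings,
                           model$config$ablation == "SIMPLE_PAIRING")
  nn_forward(model, batch, training = FALSE)$pred
}

#' Save / load a model checkpoint
#'
#' Serializes config, parameters and normalization parameters; the
#' round-trip is bit-exact.
#'
#' @param model a \code{predictor}; @param path checkpoint path.
#' @return \code{path} (write) or the restored object (read).
#' @export
write_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
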