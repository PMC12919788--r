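# Shared fixtures: tiny guides, specs and model configurations built in
# code so every test is self-contained.

tiny_guide <- function(seq = "ACGUA", id = "tg") guide_sequence(seq, id = id)

# A small but complete model configuration for fast forward/backward tests.
tiny_config <- function(L = 5L, ...) {
  model_config(L = L, d = 4L, d_ins = 3L, kernel = 3L, n_layers = 2L,
               n_heads = 2L, head_hidden = 6L, dropout = 0, ...)
}

# Small multi-guide dataset with mismatch/deletion/insertion variants.
tiny_dataset <- function(n_guides = 2L, L = 8L, seed = 7L,
                         noise_sd = 0.1) {
  generate_benchmark(
    n_guides = n_guides, L = L, seed = seed, noise_sd = noise_sd,
    design = library_design(mismatch_scan = 2:(L - 1L),
                            include_double_consecutive = FALSE,
                            n_deletion_variants = 3L,
                            n_insertion_variants = 4L))
}

# Random valid pairing spec for round-trip/property tests.
random_spec <- function(L, p_ins = 0.15) {
  states <- sample(0:2, L, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  target <- rep(NA_character_, L)
  target[states == 1L] <- sample(c("A", "C", "G", "U"),
                                 sum(states == 1L), replace = TRUE)
  ins <- as.integer(stats::runif(L + 1L) < p_ins)
  pairing_spec(states, target, ins)
}

# A guide compatible with a spec: at mismatch positions the guide must not
# be the Watson-Crick partner of the recorded target nucleotide.
compatible_guide <- function(spec, id = "rg") {
  comp_of <- c(A = "U", C = "G", G = "C", U = "A")
  nts <- vapply(seq_len(spec$L), function(i) {
    if (spec$states[i] == 1L) {
      sample(setdiff(c("A", "C", "G", "U"), comp_of[spec$target[i]]), 1L)
    } else {
      sample(c("A", "C", "G", "U"), 1L)
    }
  }, character(1))
  guide_sequence(paste(nts, collapse = ""), id = id)
}

# Independent naive forward pass written directly from the layer formulas
# with plain per-position loops; deliberately shares no code with the
# package's vectorized implementation so it can serve as an oracle.
naive_forward <- function(model, encs) {
  cfg <- model$config
  par <- model$par
  L <- cfg$L
  simple <- cfg$ablation == "SIMPLE_PAIRING"
  vapply(encs, function(e) {
    X <- if (simple) cbind(e$G, rowSums(e$M), e$D) else cbind(e$G, e$M, e$E, e$D)
    H <- matrix(0, L, cfg$d)
    for (i in seq_len(L)) {
      h <- as.numeric(X[i, ] %*% par$W_G) + par$b_G
      if (!is.null(par$P)) h <- h + par$P[i, ]
      H[i, ] <- h
    }
    half <- (cfg$kernel - 1L) %/% 2L
    Hc <- matrix(0, L, cfg$d)
    for (i in seq_len(L)) {
      acc <- par$conv_b
      for (o in -half:half) {
        j <- i + o
        if (j >= 1L && j <= L) {
          acc <- acc + as.numeric(H[j, ] %*% par$conv_W[[o + half + 1L]])
        }
      }
      Hc[i, ] <- pmax(acc, 0)
    }
    H <- Hc
    if (!is.null(par$layers)) {
      dh <- cfg$d %/% cfg$n_heads
      ln <- function(x, g, b) {
        m <- mean(x); v <- mean((x - m)^2)
        g * (x - m) / sqrt(v + 1e-5) + b
      }
      for (lay in par$layers) {
        Q <- sweep(H %*% lay$Wq, 2, lay$bq, "+")
        K <- sweep(H %*% lay$Wk, 2, lay$bk, "+")
        V <- sweep(H %*% lay$Wv, 2, lay$bv, "+")
        O <- matrix(0, L, cfg$d)
        for (h in seq_len(cfg$n_heads)) {
          cols <- (h - 1L) * dh + seq_len(dh)
          S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
          for (i in seq_len(L)) {
            a <- exp(S[i, ] - max(S[i, ]))
            a <- a / sum(a)
            O[i, cols] <- as.numeric(a %*% V[, cols, drop = FALSE])
          }
        }
        A1 <- H + sweep(O %*% lay$Wo, 2, lay$bo, "+")
        Z1 <- t(apply(A1, 1, ln, g = lay$g1, b = lay$be1))
        FF <- pmax(sweep(Z1 %*% lay$Wf1, 2, lay$bf1, "+"), 0)
        A2 <- Z1 + sweep(FF %*% lay$Wf2, 2, lay$bf2, "+")
        H <- t(apply(A2, 1, ln, g = lay$g2, b = lay$be2))
      }
    }
    u <- as.numeric(t(H))
    if (!is.null(par$W_I)) {
      z <- as.numeric(e$I %*% par$W_I) + par$b_I
      u <- c(u, z)
    }
    hh <- pmax(as.numeric(u %*% par$W1) + par$b1, 0)
    as.numeric(hh %*% par$W2) + par$b2
  }, numeric(1))
}

# Hand-built surrogate predictors with transparent analytic behavior.
# Both use a PURE_CNN configuration with identity-like weights so the
# prediction is a simple linear functional of the encoding.

# Prediction = c * (G[pos, "A"] + 1): gradient w.r.t. G[pos, A] is exactly
# c (both ReLUs kept strictly active by the biases).
surrogate_gA <- function(L = 12L, pos = 10L, c = 2.5) {
  cfg <- model_config(L = L, d = 1L, d_ins = 1L, kernel = 1L,
                      n_heads = 1L, n_layers = 1L, head_hidden = 1L,
                      dropout = 0, ablation = "PURE_CNN")
  m <- build_model(cfg, seed = 1)
  m$par <- cleavenet:::unflatten_params(m$par,
                                        numeric(count_parameters(m)))
  m$par$W_G[1, 1] <- 1              # channel A of the guide one-hot
  m$par$conv_W[[1]][1, 1] <- 1
  m$par$conv_b[1] <- 0.5            # keep both ReLUs strictly active
  m$par$W1[pos, 1] <- 1
  m$par$b1 <- 0.5
  m$par$W2[1, 1] <- c
  m
}

# Prediction = sum_i w_i * match_i + 0.5 (match channels only), so turning
# a mismatch at i into a match raises the prediction by exactly w_i.
surrogate_additive <- function(w, L = length(w)) {
  cfg <- model_config(L = L, d = 1L, d_ins = 1L, kernel = 1L,
                      n_heads = 1L, n_layers = 1L, head_hidden = 1L,
                      dropout = 0, ablation = "PURE_CNN")
  m <- build_model(cfg, seed = 1)
  m$par <- cleavenet:::unflatten_params(m$par,
                                        numeric(count_parameters(m)))
  m$par$W_G[5, 1] <- 1              # match channel A-U
  m$par$W_G[6, 1] <- 1              # match channel C-G
  m$par$conv_W[[1]][1, 1] <- 1
  m$par$W1[seq_len(L), 1] <- w
  m$par$b1 <- 0.5
  m$par$W2[1, 1] <- 1
  m
}

random_encodings <- function(n, L, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sp <- random_spec(L)
    encode_interaction(compatible_guide(sp), sp)
  })
}

# Mismatch-compatible random dataset sharing one guide (used by the
# counterfactual tests).
shared_guide_dataset <- function(n, L, seed, p_ins = 0) {
  set.seed(seed)
  specs <- replicate(n, random_spec(L, p_ins = p_ins), simplify = FALSE)
  g <- compatible_guide(specs[[1]])
  specs <- lapply(specs, function(sp) {
    tg <- sp$target
    mm <- sp$states == 1L
    tg[mm] <- vapply(which(mm), function(i) {
      sample(setdiff(c("A", "C", "G", "U"),
                     cleavenet:::WC_COMPLEMENT[g$seq[i]]), 1)
    }, character(1))
    pairing_spec(sp$states, tg, sp$insertions)
  })
  cleavage_dataset(stats::setNames(list(g), g$id), rep(g$id, n), specs,
                   rep(1, n))
}
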