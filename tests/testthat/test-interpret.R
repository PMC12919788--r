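test_that("saliency of a zero model is zero; of the G-channel surrogate, |c|", {
  L <- 12L
  encs <- random_encodings(5, L, seed = 4)
  zero <- surrogate_gA(L, c = 2.5)
  zero$par$W2[1, 1] <- 0
  s0 <- saliency_scores(zero, encs)
  expect_equal(s0$scores, rep(0, L))

  m <- surrogate_gA(L, pos = 10L, c = -2.5)
  s <- saliency_scores(m, encs)
  expect_equal(s$scores[10], 2.5)
  expect_equal(s$scores[-10], rep(0, L - 1))
  expect_s3_class(s, "position_profile")
  expect_equal(s$kind, "saliency")
})

test_that("saliency matches central finite differences on random models", {
  set.seed(77)
  for (rep in 1:4) {
    L <- 6L
    cfg <- model_config(L = L, d = 4L, d_ins = 2L, n_layers = 1L,
                        n_heads = 2L, head_hidden = 5L, dropout = 0)
    m <- build_model(cfg, seed = 100 + rep)
    encs <- random_encodings(3, L, seed = 200 + rep)
    s <- saliency_scores(m, encs)
    batch <- cleavenet:::stack_encodings(encs)
    eps <- 1e-5
    fd <- matrix(0, nrow(batch$X), 4)
    for (r in seq_len(nrow(batch$X))) for (d in 1:4) {
      bp <- batch; bp$X[r, d] <- bp$X[r, d] + eps
      bm <- batch; bm$X[r, d] <- bm$X[r, d] - eps
      fd[r, d] <- (sum(cleavenet:::nn_forward(m, bp)$pred) -
                     sum(cleavenet:::nn_forward(m, bm)$pred)) / (2 * eps)
    }
    s_fd <- as.numeric(
      rowsum(rowSums(abs(fd)), rep(seq_len(L), batch$B))) / batch$B
    expect_equal(s$scores, s_fd, tolerance = 1e-4)
  }
})

test_that("counterfactual impact recovers planted additive weights", {
  L <- 10L
  w <- seq(0.1, 1, length.out = L)
  m <- surrogate_additive(w)
  set.seed(5)
  specs <- replicate(40, random_spec(L, p_ins = 0), simplify = FALSE)
  g <- compatible_guide(specs[[1]])
  # one shared guide so specs stay valid: regenerate specs compatible with g
  specs <- lapply(specs, function(sp) {
    tg <- sp$target
    mm <- sp$states == 1L
    tg[mm] <- vapply(which(mm), function(i) {
      sample(setdiff(c("A", "C", "G", "U"),
                     cleavenet:::WC_COMPLEMENT[g$seq[i]]), 1)
    }, character(1))
    pairing_spec(sp$states, tg, sp$insertions)
  })
  data <- cleavage_dataset(stats::setNames(list(g), g$id),
                           rep(g$id, length(specs)), specs,
                           rep(1, length(specs)))
  prof <- counterfactual_profile(m, data)
  has_mm <- vapply(seq_len(L), function(i)
    any(vapply(specs, function(s) s$states[i] == 1L, logical(1))),
    logical(1))
  expect_equal(prof$scores[has_mm], w[has_mm], tolerance = 1e-10)
  expect_true(all(is.na(prof$scores[!has_mm])))
  expect_equal(prof$support[has_mm] > 0, rep(TRUE, sum(has_mm)))
})

test_that("counterfactuals on an all-match dataset are all missing", {
  L <- 8L
  g <- guide_sequence(substr(strrep("ACGU", 2), 1, L), id = "g")
  specs <- replicate(3, parse_pairing_string(paste0("M*", L), L),
                     simplify = FALSE)
  data <- cleavage_dataset(stats::setNames(list(g), "g"),
                           rep("g", 3), specs, c(1, 2, 3))
  m <- build_model(model_config(L = L, d = 4L, n_layers = 1L, n_heads = 2L,
                                d_ins = 2L, head_hidden = 4L, dropout = 0),
                   seed = 1)
  prof <- counterfactual_profile(m, data)
  expect_true(all(is.na(prof$scores)))
  expect_true(all(prof$support == 0))
})

test_that("a model blind to pairing channels has zero counterfactual impact", {
  L <- 10L
  m <- surrogate_gA(L)  # reads only the guide A channel, ignores M/E
  set.seed(6)
  sp <- random_spec(L, p_ins = 0)
  g <- compatible_guide(sp)
  data <- cleavage_dataset(stats::setNames(list(g), g$id),
                           g$id, list(sp), 1)
  prof <- counterfactual_profile(m, data)
  defined <- !is.na(prof$scores)
  expect_true(all(prof$scores[defined] == 0))
})

test_that("interpretability scores scale with the final linear layer", {
  L <- 8L
  cfg <- model_config(L = L, d = 4L, d_ins = 2L, n_layers = 1L,
                      n_heads = 2L, head_hidden = 5L, dropout = 0)
  m <- build_model(cfg, seed = 9)
  encs <- random_encodings(4, L, seed = 10)
  s1 <- saliency_scores(m, encs)
  m2 <- m
  m2$par$W2 <- m$par$W2 * -3
  m2$par$b2 <- m$par$b2 * -3
  s2 <- saliency_scores(m2, encs)
  expect_equal(s2$scores, 3 * s1$scores, tolerance = 1e-10)

  specs <- replicate(6, random_spec(L, p_ins = 0), simplify = FALSE)
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
  data <- cleavage_dataset(stats::setNames(list(g), g$id),
                           rep(g$id, 6), specs, rep(1, 6))
  d1 <- counterfactual_profile(m, data)
  d2 <- counterfactual_profile(m2, data)
  defined <- !is.na(d1$scores)
  expect_equal(d2$scores[defined], -3 * d1$scores[defined],
               tolerance = 1e-10)
})

test_that("counterfactuals refuse the SimplePairing ablation", {
  m <- build_model(tiny_config(ablation = "SIMPLE_PAIRING"), seed = 1)
  bench <- tiny_dataset()
  expect_error(counterfactual_profile(m, bench$data), "SIMPLE_PAIRING")
})

test_that("profile reports carry g-notation, regions and NA serialization", {
  scores <- c(rep(0.2, 25), NA)
  prof <- position_profile(scores, rep(NA_real_, 26),
                           c(rep(3L, 25), 0L), "counterfactual")
  df <- profile_report(prof)
  expect_equal(nrow(df), 26)
  expect_equal(df$position, paste0("g", 1:26))
  expect_equal(df$region[1], "5prime_anchor")
  expect_equal(unique(df$region[2:8]), "seed")
  expect_equal(unique(df$region[9:11]), "catalytic_core")
  expect_equal(unique(df$region[12:15]), "central")
  expect_equal(unique(df$region[16:26]), "3prime")
  path <- tempfile(fileext = ".tsv")
  profile_report(prof, path)
  txt <- readLines(path)
  expect_match(txt[27], "^g26\\tNA\\t")
  # zero-support positions must never silently carry 0
  expect_error(position_profile(c(0, 0, 0), rep(NA_real_, 3),
                                c(1L, 0L, 1L), "saliency"),
               "zero support")
})

test_that("multi-model aggregation returns mean and dispersion", {
  L <- 6L
  cfg <- model_config(L = L, d = 4L, d_ins = 2L, n_layers = 1L,
                      n_heads = 2L, head_hidden = 4L, dropout = 0)
  ms <- lapply(1:3, function(s) build_model(cfg, seed = s))
  encs <- random_encodings(3, L, seed = 12)
  prof <- saliency_scores(ms, encs)
  expect_false(any(is.na(prof$dispersion)))
  singles <- sapply(ms, function(m) saliency_scores(m, encs)$scores)
  expect_equal(prof$scores, rowMeans(singles))
  expect_equal(prof$dispersion, apply(singles, 1, sd))
})
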