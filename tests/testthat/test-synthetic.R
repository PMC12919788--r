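test_that("rule profiles have the advertised shapes and are seeded", {
  r <- make_rule(seed = 3, profile = "default")
  expect_true(which.max(r$w) %in% 9:11)
  expect_true(all(r$w >= 0))
  expect_identical(r, make_rule(seed = 3, profile = "default"))

  rf <- make_rule(seed = 5, profile = "flat")
  expect_equal(max(rf$w) - min(rf$w), 0)

  rw <- make_rule(seed = 5, profile = "wobble_sensitive")
  offdiag <- rw$mtype[rw$mtype > 0]
  # wobble pairs carry the mildest multiplier
  expect_equal(rw$mtype["G", "U"], min(offdiag))
  expect_equal(rw$mtype["U", "G"], min(offdiag))
  expect_error(make_rule(1, profile = "nope"), "arg")
})

test_that("variant library enumeration matches the combinatorial counts", {
  g <- compatible_guide(parse_pairing_string("M*26", 26))
  singles <- library_design(mismatch_scan = 2:20,
                            include_double_consecutive = FALSE,
                            n_deletion_variants = 0L)
  specs <- build_variant_library(26, singles, guide = g)
  expect_length(specs, 1 + 19 * 3)

  doubles <- library_design(mismatch_scan = 2:20,
                            include_double_consecutive = TRUE,
                            n_deletion_variants = 0L)
  specs2 <- build_variant_library(26, doubles, guide = g)
  expect_length(specs2, 1 + 19 * 3 + 18 * 9)

  # every scan position has exactly 3 single-mismatch variants, none of
  # which encodes the guide complement (all specs are encodable)
  n_single_at <- vapply(2:20, function(i) {
    sum(vapply(specs, function(s) {
      sum(s$states == 1L) == 1L && s$states[i] == 1L
    }, logical(1)))
  }, numeric(1))
  expect_true(all(n_single_at == 3))
  for (s in specs2) expect_s3_class(encode_interaction(g, s),
                                    "interaction_encoding")

  # no duplicates
  keys <- vapply(specs2, format_pairing_string, character(1))
  expect_equal(anyDuplicated(keys), 0L)

  # indel variants
  full <- library_design(mismatch_scan = 2:20,
                         include_double_consecutive = FALSE,
                         n_deletion_variants = 5L,
                         n_insertion_variants = 27L,
                         n_perfect_replicates = 2L)
  specs3 <- build_variant_library(26, full, guide = g)
  expect_length(specs3, 2 + 57 + 5 + 27)
})

test_that("the generator law is exact at zero noise and monotone", {
  rule <- make_rule(seed = 9, noise_sd = 0)
  g <- compatible_guide(parse_pairing_string("M*26", 26))
  perfect <- parse_pairing_string("M*26", 26)
  ds <- simulate_rates(rule, g, list(perfect), seed = 1)
  expect_equal(ds$k, exp(rule$beta0))

  # single mismatch at i: log k drops by exactly w_i * mtype[guide, target]
  i <- 10L
  nt <- setdiff(c("A", "C", "G", "U"),
                cleavenet:::WC_COMPLEMENT[g$seq[i]])[1]
  st <- integer(26); st[i] <- 1L
  tg <- rep(NA_character_, 26); tg[i] <- nt
  sp1 <- pairing_spec(st, tg)
  k1 <- simulate_rates(rule, g, list(sp1), seed = 1)$k
  expect_equal(log(k1), rule$beta0 - rule$w[i] * rule$mtype[g$seq[i], nt])

  # deletion and insertion penalties
  std <- integer(26); std[5] <- 2L
  kd <- simulate_rates(rule, g, list(pairing_spec(std)), seed = 1)$k
  expect_equal(log(kd), rule$beta0 - rule$w[5] * rule$del_penalty)
  ins <- integer(27); ins[c(3, 9)] <- 1L
  ki <- simulate_rates(rule, g, list(pairing_spec(integer(26),
                                                  insertions = ins)),
                       seed = 1)$k
  expect_equal(log(ki), rule$beta0 - 2 * rule$ins_penalty)

  # adding a mismatch never increases k
  st2 <- st; st2[15] <- 1L
  tg2 <- tg
  tg2[15] <- setdiff(c("A", "C", "G", "U"),
                     cleavenet:::WC_COMPLEMENT[g$seq[15]])[1]
  k2 <- simulate_rates(rule, g, list(pairing_spec(st2, tg2)), seed = 1)$k
  expect_lte(k2, k1)
})

test_that("benchmark generation is deterministic, positive and grouped", {
  b1 <- tiny_dataset(seed = 13)
  b2 <- tiny_dataset(seed = 13)
  expect_identical(b1$data$k, b2$data$k)
  expect_identical(b1$rule, b2$rule)
  expect_true(all(is.finite(b1$data$k) & b1$data$k > 0))
  groups <- guide_groups(b1$data)
  expect_length(groups, 2)
  expect_equal(sort(unlist(groups, use.names = FALSE)),
               seq_len(length(b1$data)))
  # identical library shape per guide
  expect_equal(length(groups[[1]]), length(groups[[2]]))
  b3 <- tiny_dataset(seed = 14)
  expect_false(identical(b1$data$k, b3$data$k))
})

test_that("least squares on flattened features recovers the noiseless law", {
  # the generator law is linear in the flattened interaction basis, so OLS
  # is an exact brute-force oracle for the generator/encoder pair
  bench <- generate_benchmark(n_guides = 3, L = 12, seed = 4, noise_sd = 0,
                              design = library_design(
                                mismatch_scan = 2:11,
                                include_double_consecutive = TRUE,
                                n_deletion_variants = 5L,
                                n_insertion_variants = 13L))
  data <- bench$data
  rule <- bench$rule
  L <- 12L
  # the law couples guide and target identity, so the exact-linearity
  # statement holds guide-wise: fit each guide's library separately; the
  # identifiable quantities are fitted-function differences (the flattened
  # basis is collinear), which equal the penalty products
  feat <- function(g, sp) flatten_interaction(encode_interaction(g, sp))
  set.seed(99)
  for (gid in names(data$guides)) {
    idx <- guide_groups(data)[[gid]]
    sub <- data[idx]
    g <- data$guides[[gid]]
    X <- t(vapply(seq_len(length(sub)),
                  function(i) feat(g, sub$specs[[i]]),
                  numeric(L * 11 + L + 1)))
    fit <- stats::lm.fit(cbind(1, X), log(sub$k))
    expect_lt(max(abs(fit$residuals)), 1e-6)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    pred <- function(sp) sum(co * c(1, feat(g, sp)))
    perfect <- pairing_spec(integer(L))
    # recovered single-mismatch penalty products equal w_i * mtype exactly
    for (i in c(2L, 6L, 11L)) {
      for (nt in setdiff(c("A", "C", "G", "U"),
                         cleavenet:::WC_COMPLEMENT[g$seq[i]])) {
        st <- integer(L); st[i] <- 1L
        tg <- rep(NA_character_, L); tg[i] <- nt
        recovered <- pred(perfect) - pred(pairing_spec(st, tg))
        expect_equal(recovered, rule$w[i] * rule$mtype[g$seq[i], nt],
                     tolerance = 1e-6)
      }
    }
    # and the fit extrapolates exactly to held-out multi-mismatch variants
    for (rep in 1:10) {
      pos <- sort(sample(2:11, 3))
      st <- integer(L); tg <- rep(NA_character_, L)
      for (i in pos) {
        st[i] <- 1L
        tg[i] <- sample(setdiff(c("A", "C", "G", "U"),
                                cleavenet:::WC_COMPLEMENT[g$seq[i]]), 1)
      }
      sp <- pairing_spec(st, tg)
      expect_equal(pred(sp), cleavenet:::rule_log_rate(rule, g, sp),
                   tolerance = 1e-6)
    }
  }
})

test_that("rule JSON round-trips", {
  r <- make_rule(seed = 2, profile = "wobble_sensitive", L = 10)
  path <- tempfile(fileext = ".json")
  write_rule_json(r, path)
  r2 <- read_rule_json(path)
  expect_equal(r2$w, r$w)
  expect_equal(r2$mtype, r$mtype)
  expect_equal(r2$del_penalty, r$del_penalty)
  expect_equal(r2$profile, r$profile)
})
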