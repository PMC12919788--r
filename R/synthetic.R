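#' Parametric ground-truth cleavage-rate rule
#'
#' The synthetic generator draws cleavage rates from a known parametric law,
#' multiplicative on rates (additive on log-rates):
#' \deqn{\log k = \beta_0 - \sum_{i \in mismatch} w_i\, mtype[g_i, t_i]
#'   - \sum_{i \in deletion} w_i\, del - n_{ins}\, ins + \epsilon,\quad
#'   \epsilon \sim N(0, \sigma^2)}
#' so rates are always positive and every mismatch/indel can only reduce the
#' rate. Position weights w peak at the catalytic core (g9-g11), are
#' intermediate over the seed (g2-g8) and decay toward the guide 3' end,
#' mirroring the positional importance profile of PIWI slicing; mismatch-type
#' multipliers give G-U/U-G wobbles the mildest penalty. This is a test
#' harness for parameter recovery, not a claim about the true biochemical
#' rate law.
#'
#' @param seed integer seed (the rule is deterministic given the seed).
#' @param profile one of \code{"default"} (unimodal w as above),
#'   \code{"flat"} (constant w; negative control for recovery tests),
#'   \code{"wobble_sensitive"} (maximally spread mismatch-type multipliers,
#'   used to separate the full pairing encoding from its binary
#'   match/mismatch ablation).
#' @param L guide length.
#' @param noise_sd SD of the Gaussian noise on log-rate.
#' @return object of class \code{cleavage_rule} with fields \code{beta0},
#'   \code{w} (length L), \code{mtype} (4x4, guide nt x target nt),
#'   \code{del_penalty}, \code{ins_penalty}, \code{noise_sd}.
#' @export
make_rule <- function(seed = 1L, profile = c("default", "flat",
                                             "wobble_sensitive"),
                      L = 26L, noise_sd = 0.2) {
  profile <- match.arg(profile)
  L <- as.integer(L)
  stopifnot(L >= 3L, noise_sd >= 0)
  set.seed(seed)
  pos <- seq_len(L)
  if (profile == "flat") {
    w <- rep(0.6, L)
  } else {
    # unimodal positional weight: 5' anchor low, seed intermediate,
    # catalytic core g9-g11 maximal, decay 3' of g15
    w <- numeric(L)
    w[1] <- 0.10
    w[pos >= 2 & pos <= 8] <- 0.50
    w[pos >= 9 & pos <= 11] <- c(1.15, 1.30, 1.15)[seq_len(sum(pos >= 9 & pos <= 11))]
    w[pos >= 12 & pos <= 15] <- seq(0.85, 0.45, length.out = sum(pos >= 12 & pos <= 15))
    w[pos >= 16 & pos <= 19] <- seq(0.30, 0.12, length.out = sum(pos >= 16 & pos <= 19))
    w[pos >= 20] <- 0.05
    w <- w * stats::runif(L, 0.95, 1.05)  # seeded jitter, small enough to
                                          # keep the argmax inside g9-g11
  }
  mtype <- matrix(stats::runif(16, 0.7, 1.3), 4, 4,
                  dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  if (profile == "wobble_sensitive") {
    mtype[] <- stats::runif(16, 0.1, 2.5)
  }
  # wobble pairs retain partial duplex stability -> mildest multiplier
  wob <- if (profile == "wobble_sensitive") 0.05 else 0.30
  mtype["G", "U"] <- wob
  mtype["U", "G"] <- wob
  # Watson-Crick entries are never consulted by the law; zero for clarity
  for (nt in RNA_ALPHABET) mtype[nt, WC_COMPLEMENT[nt]] <- 0
  structure(list(beta0 = 0, w = w, mtype = mtype, del_penalty = 1.5,
                 ins_penalty = 0.5, noise_sd = noise_sd, L = L,
                 profile = profile, seed = as.integer(seed)),
            class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat(sprintf("<cleavage_rule profile=%s L=%d noise_sd=%.3g>\n",
              x$profile, x$L, x$noise_sd))
  cat("  w argmax at g", which.max(x$w), "\n", sep = "")
  invisible(x)
}

#' Variant library design
#'
#' Describes the shape of a CNS-seq-style target variant library: a perfect
#' complement, systematic single (and optionally consecutive double)
#' mismatch scans over a guide-position window, plus single-deletion and
#' single-insertion variants.
#'
#' @param mismatch_scan integer vector of scanned guide positions
#'   (default g2-g20, the window scanned by the assay being emulated).
#' @param include_double_consecutive add all consecutive double-mismatch
#'   variants within the scan window.
#' @param n_deletion_variants number of single-deletion variants (taken from
#'   the start of the scan window).
#' @param n_insertion_variants number of single-insertion variants (boundary
#'   slots 0, 1, ... up to the requested count).
#' @param n_perfect_replicates copies of the perfect-complement spec.
#' @return object of class \code{library_design}.
#' @export
library_design <- function(mismatch_scan = 2:20,
                           include_double_consecutive = TRUE,
                           n_deletion_variants = length(mismatch_scan),
                           n_insertion_variants = 0L,
                           n_perfect_replicates = 1L) {
  structure(list(mismatch_scan = as.integer(mismatch_scan),
                 include_double_consecutive = isTRUE(include_double_consecutive),
                 n_deletion_variants = as.integer(n_deletion_variants),
                 n_insertion_variants = as.integer(n_insertion_variants),
                 n_perfect_replicates = as.integer(n_perfect_replicates)),
            class = "library_design")
}

# Default benchmark design: perfect + single scan + double scan + deletions
# + all single insertions -> 266 specs per 26-nt guide.
default_library_design <- function(L = 26L) {
  library_design(mismatch_scan = 2:min(20L, L - 1L),
                 include_double_consecutive = TRUE,
                 n_insertion_variants = L + 1L)
}

#' Enumerate a variant library for one guide
#'
#' Builds the list of pairing specifications of a
#' \code{\link{library_design}}: the all-match spec, all three
#' non-complementary target identities at each scanned position (single
#' mismatches), optionally all 3 x 3 identity combinations at consecutive
#' scanned position pairs (double mismatches), single deletions and single
#' insertions. No duplicate specs are emitted.
#'
#' @param L guide length.
#' @param design a \code{library_design}.
#' @param guide the \code{\link{guide_sequence}} the library is built
#'   against; required when mismatch variants are requested, because the
#'   three valid (non-complementary) target identities depend on the guide
#'   nucleotide at each position.
#' @return list of \code{\link{pairing_spec}} objects.
#' @export
build_variant_library <- function(L, design = default_library_design(L),
                                  guide = NULL) {
  L <- as.integer(L)
  stopifnot(inherits(design, "library_design"))
  scan <- design$mismatch_scan
  if (any(scan < 1L | scan > L)) stop("mismatch scan positions outside 1..L")
  if (length(scan) > 0L && is.null(guide)) {
    stop("a guide sequence is required to enumerate mismatch identities")
  }
  if (!is.null(guide)) stopifnot(inherits(guide, "guide_sequence"), guide$L == L)
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  for (r in seq_len(max(design$n_perfect_replicates, 1L))) add(all_match_spec(L))
  mm_identities <- function(i) setdiff(RNA_ALPHABET, WC_COMPLEMENT[guide$seq[i]])
  for (i in scan) {
    for (nt in mm_identities(i)) {
      st <- integer(L); st[i] <- STATE_MISMATCH
      tg <- rep(NA_character_, L); tg[i] <- nt
      add(pairing_spec(st, tg))
    }
  }
  if (design$include_double_consecutive) {
    for (i in scan[(scan + 1L) %in% scan]) {
      for (nt1 in mm_identities(i)) {
        for (nt2 in mm_identities(i + 1L)) {
          st <- integer(L); st[c(i, i + 1L)] <- STATE_MISMATCH
          tg <- rep(NA_character_, L); tg[i] <- nt1; tg[i + 1L] <- nt2
          add(pairing_spec(st, tg))
        }
      }
    }
  }
  if (design$n_deletion_variants > 0L) {
    del_pos <- scan[seq_len(min(design$n_deletion_variants, length(scan)))]
    for (i in del_pos) {
      st <- integer(L); st[i] <- STATE_DELETION
      add(pairing_spec(st))
    }
  }
  if (design$n_insertion_variants > 0L) {
    slots <- seq_len(min(design$n_insertion_variants, L + 1L)) - 1L
    for (j in slots) {
      ins <- integer(L + 1L); ins[j + 1L] <- 1L
      add(pairing_spec(integer(L), insertions = ins))
    }
  }
  specs
}

#' Simulate cleavage rates for a set of variants
#'
#' Evaluates the ground-truth law of a \code{\link{make_rule}} for one guide
#' over a list of pairing specs and adds seeded log-normal noise. With
#' \code{rule$noise_sd = 0} the law is exact and k for the all-match spec is
#' exactly \code{exp(beta0)}.
#'
#' @param rule a \code{cleavage_rule}.
#' @param guide a \code{guide_sequence}.
#' @param specs list of \code{pairing_spec} objects.
#' @param seed integer seed for the noise draw.
#' @return a \code{\link{cleavage_dataset}} with one record per spec.
#' @export
simulate_rates <- function(rule, guide, specs, seed = 1L) {
  stopifnot(inherits(rule, "cleavage_rule"), inherits(guide, "guide_sequence"),
            guide$L == rule$L)
  logk <- vapply(specs, function(sp) rule_log_rate(rule, guide, sp), numeric(1))
  set.seed(seed)
  if (rule$noise_sd > 0) logk <- logk + stats::rnorm(length(logk), 0, rule$noise_sd)
  guides <- stats::setNames(list(guide), guide$id)
  cleavage_dataset(guides, rep(guide$id, length(specs)), specs, exp(logk))
}

# Noiseless log-rate of the generator law for one spec.
rule_log_rate <- function(rule, guide, spec) {
  if (spec$L != rule$L) stop("spec length does not match rule L")
  lk <- rule$beta0
  for (i in seq_len(spec$L)) {
    st <- spec$states[i]
    if (st == STATE_MISMATCH) {
      lk <- lk - rule$w[i] * rule$mtype[guide$seq[i], spec$target[i]]
    } else if (st == STATE_DELETION) {
      lk <- lk - rule$w[i] * rule$del_penalty
    }
  }
  lk - sum(spec$insertions) * rule$ins_penalty
}

#' Generate a multi-guide synthetic benchmark
#'
#' Emulates the structure of the real assay data: several guides, each with
#' an identical systematic variant library, all rates drawn from one shared
#' ground-truth rule. Suitable for leave-one-guide-out cross-validation and
#' for parameter-recovery tests (the rule is returned alongside the data).
#'
#' @param n_guides number of guides (>= 2).
#' @param design a \code{\link{library_design}} applied to every guide.
#' @param profile rule profile passed to \code{\link{make_rule}}.
#' @param seed master seed; guides, rule jitter and noise all derive from it.
#' @param L guide length.
#' @param noise_sd log-rate noise SD (default 0.2: large enough to make the
#'   task nontrivial, small enough that the signal is recoverable at the
#'   default library size).
#' @param guide_w_jitter_sd optional SD of a per-guide multiplicative
#'   perturbation of the position weights w (default 0 = one shared rule);
#'   nonzero values emulate guide-specific deviations and stress
#'   leave-one-guide-out generalization.
#' @return list with elements \code{data} (a \code{cleavage_dataset}) and
#'   \code{rule} (the generating \code{cleavage_rule}).
#' @export
generate_benchmark <- function(n_guides = 4L, design = default_library_design(L),
                               profile = "default", seed = 1L, L = 26L,
                               noise_sd = 0.2, guide_w_jitter_sd = 0) {
  n_guides <- as.integer(n_guides)
  stopifnot(n_guides >= 2L)
  seed <- as.integer(seed)
  rule <- make_rule(seed, profile, L = L, noise_sd = noise_sd)
  guides <- random_guides(n_guides, L = L, seed = seed + 1L)
  parts <- vector("list", n_guides)
  for (gi in seq_len(n_guides)) {
    g <- guides[[gi]]
    specs <- build_variant_library(L, design, guide = g)
    rule_g <- rule
    if (guide_w_jitter_sd > 0) {
      set.seed(seed + 1000L + gi)
      rule_g$w <- rule$w * exp(stats::rnorm(L, 0, guide_w_jitter_sd))
    }
    parts[[gi]] <- simulate_rates(rule_g, g, specs, seed = seed + 2L + gi)
  }
  data <- cleavage_dataset(
    guides,
    unlist(lapply(parts, function(p) p$guide_id)),
    do.call(c, lapply(parts, function(p) p$specs)),
    unlist(lapply(parts, function(p) p$k)))
  list(data = data, rule = rule)
}

#' Write / read a ground-truth rule as JSON
#'
#' Plain-text serialization of a \code{cleavage_rule} so simulated datasets
#' can be stored next to the law that generated them for recovery checks.
#'
#' @param rule a \code{cleavage_rule}; @param path output path.
#' @return \code{path} (write) or a \code{cleavage_rule} (read).
#' @export
write_rule_json <- function(rule, path) {
  stopifnot(inherits(rule, "cleavage_rule"))
  obj <- list(beta0 = rule$beta0, w = rule$w,
              mtype = as.list(as.data.frame(rule$mtype)),
              del_penalty = rule$del_penalty, ins_penalty = rule$ins_penalty,
              noise_sd = rule$noise_sd, L = rule$L, profile = rule$profile,
              seed = rule$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule_json
#' @export
read_rule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mtype <- as.matrix(as.data.frame(obj$mtype))
  dimnames(mtype) <- list(RNA_ALPHABET, RNA_ALPHABET)
  structure(list(beta0 = obj$beta0, w = obj$w, mtype = mtype,
                 del_penalty = obj$del_penalty, ins_penalty = obj$ins_penalty,
                 noise_sd = obj$noise_sd, L = obj$L, profile = obj$profile,
                 seed = obj$seed),
            class = "cleavage_rule")
}
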