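#' Interaction-centric encoding of a guide-target variant
#'
#' Converts a guide sequence plus pairing specification into the numeric
#' feature matrices consumed by the model. At each guide position exactly one
#' of three states is active: a Watson-Crick match (recorded by mode in M:
#' channel 1 = A-U/U-A, channel 2 = C-G/G-C, reflecting their different
#' thermodynamic stabilities), a mismatch (recorded by target-nucleotide
#' identity in E, channels A,C,G,U, so e.g. a G-U wobble is distinguishable
#' from an A-A clash), or a deletion (D = 1, no paired target nucleotide).
#' Insertion boundary flags are carried through unchanged in I.
#'
#' @param guide a \code{\link{guide_sequence}}.
#' @param spec a \code{\link{pairing_spec}} of the same length.
#' @return object of class \code{interaction_encoding}: list with binary
#'   matrices \code{G} (L x 4, guide one-hot, channels A,C,G,U), \code{M}
#'   (L x 2), \code{E} (L x 4), vector \code{D} (length L) and \code{I}
#'   (length L+1).
#' @examples
#' g <- guide_sequence("ACG")
#' enc <- encode_interaction(g, parse_pairing_string("M*2,X:A", 3))
#' enc$E[3, ]  # mismatch at g3 with target A
#' @export
encode_interaction <- function(guide, spec) {
  stopifnot(inherits(guide, "guide_sequence"), inherits(spec, "pairing_spec"))
  L <- guide$L
  if (spec$L != L) stop("pairing spec length ", spec$L,
                        " does not match guide length ", L)
  nt_idx <- match(guide$seq, RNA_ALPHABET)
  G <- matrix(0L, L, 4L, dimnames = list(NULL, RNA_ALPHABET))
  G[cbind(seq_len(L), nt_idx)] <- 1L
  M <- matrix(0L, L, 2L, dimnames = list(NULL, c("AU", "CG")))
  E <- matrix(0L, L, 4L, dimnames = list(NULL, RNA_ALPHABET))
  D <- integer(L)
  comp <- WC_COMPLEMENT[guide$seq]
  for (i in seq_len(L)) {
    st <- spec$states[i]
    if (st == STATE_MATCH) {
      # A-U/U-A pairs -> channel 1; C-G/G-C pairs -> channel 2
      M[i, if (guide$seq[i] %in% c("A", "U")) 1L else 2L] <- 1L
    } else if (st == STATE_MISMATCH) {
      if (spec$target[i] == comp[i]) {
        stop("position g", i, ": declared mismatch target '", spec$target[i],
             "' is the Watson-Crick complement of guide '", guide$seq[i],
             "' and would be a match")
      }
      E[i, match(spec$target[i], RNA_ALPHABET)] <- 1L
    } else {
      D[i] <- 1L
    }
  }
  structure(list(G = G, M = M, E = E, D = D, I = spec$insertions, L = L),
            class = "interaction_encoding")
}

#' Flatten an interaction encoding to a feature vector
#'
#' Row-major concatenation of the per-position feature rows
#' \code{[G_i, M_i, E_i, D_i]} (11 values per position) followed by the
#' insertion vector, total length \code{L*11 + (L+1)}. With
#' \code{simple_pairing = TRUE} the match-mode and mismatch-identity channels
#' collapse to a single binary match flag per position (6 values per
#' position, total \code{L*6 + (L+1)}) — the reduced representation used by
#' the SimplePairing ablation. This flattened basis is also what the classic
#' regressor baselines consume.
#'
#' @param enc an \code{interaction_encoding}.
#' @param simple_pairing collapse pairing detail to binary match/mismatch.
#' @return numeric feature vector.
#' @export
flatten_interaction <- function(enc, simple_pairing = FALSE) {
  stopifnot(inherits(enc, "interaction_encoding"))
  X <- interaction_input_matrix(enc, simple_pairing)
  c(as.numeric(t(X)), as.numeric(enc$I))
}

# Per-position input matrix (L x 11, or L x 6 under simple pairing).
interaction_input_matrix <- function(enc, simple_pairing = FALSE) {
  if (simple_pairing) {
    cbind(enc$G, rowSums(enc$M), enc$D)
  } else {
    cbind(enc$G, enc$M, enc$E, enc$D)
  }
}

#' Concatenated one-hot baseline encoding
#'
#' Sequence-based baseline: the guide one-hot (L x 4) and the target one-hot
#' stacked row-major into one flat vector, treating the two sequences as
#' independent strings with no interaction information. Gap characters
#' (deletions) one-hot to an all-zero row.
#'
#' @param guide a \code{guide_sequence}.
#' @param target character scalar (target in guide coordinates; see
#'   \code{\link{target_from_spec}}).
#' @return numeric vector of length \code{(L + nchar(target)) * 4}.
#' @export
encode_concat_onehot <- function(guide, target = "") {
  stopifnot(inherits(guide, "guide_sequence"))
  c(onehot_vec(guide$seq), onehot_vec(strsplit(toupper(target), "")[[1]]))
}

onehot_vec <- function(chars) {
  if (length(chars) == 0L) return(numeric(0))
  chars <- chartr("T", "U", chars)
  bad <- setdiff(unique(chars), c(RNA_ALPHABET, "-"))
  if (length(bad) > 0L) stop("invalid character(s): ", paste(bad, collapse = ", "))
  m <- matrix(0, length(chars), 4L)
  idx <- match(chars, RNA_ALPHABET)
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  as.numeric(t(m))
}

#' K-mer count baseline encoding
#'
#' Sequence-based baseline: raw overlapping-window counts of all 4^k k-mers
#' in the guide, concatenated with the same for the target (gap characters
#' removed first), length \code{2 * 4^k}. Positional information is lost by
#' construction, which is exactly the weakness this baseline probes.
#'
#' @param guide a \code{guide_sequence}.
#' @param target character scalar.
#' @param k k-mer size (the benchmark uses k = 3).
#' @return numeric count vector of length \code{2 * 4^k}.
#' @export
encode_kmer <- function(guide, target, k = 3L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  tg <- gsub("-", "", chartr("T", "U", toupper(target)), fixed = TRUE)
  c(kmer_counts(paste(guide$seq, collapse = ""), k), kmer_counts(tg, k))
}

kmer_counts <- function(s, k) {
  n <- nchar(s)
  if (n < k) stop("sequence of length ", n, " is shorter than k = ", k)
  kmers <- all_kmers(k)
  counts <- stats::setNames(numeric(length(kmers)), kmers)
  for (i in seq_len(n - k + 1L)) {
    w <- substr(s, i, i + k - 1L)
    counts[w] <- counts[w] + 1
  }
  counts
}

all_kmers <- function(k) {
  grids <- rep(list(RNA_ALPHABET), k)
  do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}

# Stack per-record interaction encodings into the dense batch inputs the
# network consumes: X is (B*L) x C record-major (rows b1g1, b1g2, ...), Imat
# is B x (L+1).
stack_encodings <- function(encodings, simple_pairing = FALSE) {
  B <- length(encodings)
  stopifnot(B >= 1L)
  L <- encodings[[1]]$L
  Xs <- lapply(encodings, function(e) {
    if (e$L != L) stop("all encodings in a batch must share L")
    interaction_input_matrix(e, simple_pairing)
  })
  X <- do.call(rbind, Xs)
  Imat <- do.call(rbind, lapply(encodings, function(e) as.numeric(e$I)))
  list(X = X * 1.0, Imat = Imat, B = B, L = L)
}
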