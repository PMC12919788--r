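# Pairing state codes used throughout: 0 = Watson-Crick match,
# 1 = mismatch (target nucleotide recorded), 2 = deletion (no paired target nt)
STATE_MATCH <- 0L
STATE_MISMATCH <- 1L
STATE_DELETION <- 2L

#' Construct a pairing specification
#'
#' A pairing specification is the geometric description of one guide-target
#' variant in duplex coordinates: for each guide position the pairing state
#' (match / mismatch with a recorded target nucleotide / deletion), plus
#' binary flags for inserted target nucleotides at the L+1 boundary slots
#' (slot 0 = 5' of g1, slot j = immediately 3' of guide position j). Inserted
#' nucleotide identity is not represented, only the boundary flag.
#'
#' @param states integer vector of length L; 0 match, 1 mismatch, 2 deletion.
#' @param target character vector of length L; target nucleotide identity at
#'   mismatch positions, NA elsewhere.
#' @param insertions 0/1 vector of length L+1 (boundary slots, 0-based slots
#'   0..L mapped to indices 1..L+1).
#' @return object of class \code{pairing_spec}.
#' @export
pairing_spec <- function(states, target = NULL, insertions = NULL) {
  states <- as.integer(states)
  L <- length(states)
  if (L < 3L) stop("pairing spec must cover at least 3 positions")
  if (!all(states %in% c(STATE_MATCH, STATE_MISMATCH, STATE_DELETION))) {
    stop("states must be 0 (match), 1 (mismatch) or 2 (deletion)")
  }
  if (is.null(target)) target <- rep(NA_character_, L)
  target <- as.character(target)
  if (length(target) != L) stop("target identity vector must have length L")
  mm <- states == STATE_MISMATCH
  if (any(mm & (is.na(target) | !target %in% RNA_ALPHABET))) {
    stop("every mismatch position needs a target nucleotide in {A,C,G,U}")
  }
  target[!mm] <- NA_character_
  if (is.null(insertions)) insertions <- integer(L + 1L)
  insertions <- as.integer(insertions)
  if (length(insertions) != L + 1L) {
    stop("insertions must have length L+1 (one flag per boundary slot)")
  }
  if (!all(insertions %in% c(0L, 1L))) stop("insertion flags must be 0/1")
  structure(list(states = states, target = target, insertions = insertions,
                 L = L),
            class = "pairing_spec")
}

#' @export
print.pairing_spec <- function(x, ...) {
  cat(sprintf("<pairing_spec L=%d> %s\n", x$L, format_pairing_string(x)))
  invisible(x)
}

#' Parse a pairing string
#'
#' Text dialect for the "pairing" column of cleavage tables: comma-separated
#' run-length tokens \code{M*n} (n consecutive matches, \code{M} alone for
#' one), \code{X:N} (mismatch with target nucleotide N), \code{D} or
#' \code{D*n} (deletions); an optional suffix \code{|ins:j1;j2} lists 0-based
#' insertion boundary slots (0..L). Example: \code{"M*9,X:U,M*16"} is a fully
#' matched 26-mer except a U-opposite mismatch at g10.
#'
#' The parser is guide-agnostic: whether a recorded mismatch nucleotide
#' actually equals the Watson-Crick complement of the guide (which would make
#' it a match) is validated at encode time.
#'
#' @param text pairing string.
#' @param L expected number of guide positions.
#' @return a \code{\link{pairing_spec}}.
#' @export
parse_pairing_string <- function(text, L) {
  stopifnot(is.character(text), length(text) == 1L)
  L <- as.integer(L)
  if (L < 3L) stop("L must be >= 3")
  text <- gsub("\\s", "", text)
  parts <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(parts) > 2L || nchar(parts[1]) == 0L) {
    stop("malformed pairing string: '", text, "'")
  }
  states <- integer(0)
  target <- character(0)
  for (tok in strsplit(parts[1], ",", fixed = TRUE)[[1]]) {
    if (grepl("^M(\\*[0-9]+)?$", tok)) {
      n <- if (grepl("*", tok, fixed = TRUE)) {
        as.integer(sub("^M\\*", "", tok))
      } else 1L
      states <- c(states, rep(STATE_MATCH, n))
      target <- c(target, rep(NA_character_, n))
    } else if (grepl("^D(\\*[0-9]+)?$", tok)) {
      n <- if (grepl("*", tok, fixed = TRUE)) {
        as.integer(sub("^D\\*", "", tok))
      } else 1L
      states <- c(states, rep(STATE_DELETION, n))
      target <- c(target, rep(NA_character_, n))
    } else if (grepl("^X:[ACGUT]$", tok)) {
      nt <- chartr("T", "U", sub("^X:", "", tok))
      states <- c(states, STATE_MISMATCH)
      target <- c(target, nt)
    } else {
      stop("malformed pairing token: '", tok, "'")
    }
  }
  if (length(states) != L) {
    stop("pairing string covers ", length(states), " positions, expected ", L)
  }
  ins <- integer(L + 1L)
  if (length(parts) == 2L) {
    if (!grepl("^ins:[0-9]+(;[0-9]+)*$", parts[2])) {
      stop("malformed insertion suffix: '", parts[2], "'")
    }
    slots <- as.integer(strsplit(sub("^ins:", "", parts[2]), ";")[[1]])
    if (any(slots < 0L | slots > L)) {
      stop("insertion slot out of range 0..", L)
    }
    ins[slots + 1L] <- 1L
  }
  pairing_spec(states, target, ins)
}

#' Format a pairing specification as a pairing string
#'
#' Inverse of \code{\link{parse_pairing_string}}: emits the canonical
#' run-length form, so \code{parse_pairing_string(format_pairing_string(s), L)}
#' reproduces \code{s} exactly.
#'
#' @param spec a \code{pairing_spec}.
#' @return character scalar in the pairing dialect.
#' @export
format_pairing_string <- function(spec) {
  stopifnot(inherits(spec, "pairing_spec"))
  toks <- character(0)
  i <- 1L
  while (i <= spec$L) {
    st <- spec$states[i]
    if (st == STATE_MISMATCH) {
      toks <- c(toks, paste0("X:", spec$target[i]))
      i <- i + 1L
    } else {
      j <- i
      while (j < spec$L && spec$states[j + 1L] == st) j <- j + 1L
      n <- j - i + 1L
      lab <- if (st == STATE_MATCH) "M" else "D"
      toks <- c(toks, if (n == 1L) lab else paste0(lab, "*", n))
      i <- j + 1L
    }
  }
  out <- paste(toks, collapse = ",")
  slots <- which(spec$insertions == 1L) - 1L
  if (length(slots) > 0L) {
    out <- paste0(out, "|ins:", paste(slots, collapse = ";"))
  }
  out
}

#' Derive a pairing specification from guide and target sequences
#'
#' Convenience constructor for ungapped duplexes: the target is given in
#' guide coordinates (the nucleotide paired opposite each guide position,
#' 5'->3' of the guide), one nucleotide per guide position. Position i is a
#' match iff the target nucleotide is the Watson-Crick complement of
#' guide[i]; any other identity, including the G-U wobble, is recorded as a
#' mismatch with that identity. Indel-containing variants cannot be
#' expressed this way and need an explicit \code{\link{pairing_spec}}.
#'
#' @param guide a \code{\link{guide_sequence}}.
#' @param target character scalar over A/C/G/U of length \code{guide$L},
#'   giving the paired target nucleotide opposite each guide position.
#' @return a \code{pairing_spec} with no deletions or insertions.
#' @export
spec_from_sequences <- function(guide, target) {
  stopifnot(inherits(guide, "guide_sequence"))
  t <- strsplit(chartr("T", "U", toupper(gsub("\\s", "", target))), "")[[1]]
  if (length(t) != guide$L) {
    stop("target covers ", length(t), " guide positions but guide has L = ",
         guide$L, "; provide an explicit pairing_spec for indel variants")
  }
  bad <- setdiff(unique(t), RNA_ALPHABET)
  if (length(bad) > 0L) stop("invalid target nucleotide(s): ",
                             paste(bad, collapse = ", "))
  comp <- WC_COMPLEMENT[guide$seq]
  states <- ifelse(t == comp, STATE_MATCH, STATE_MISMATCH)
  tgt <- ifelse(t == comp, NA_character_, t)
  pairing_spec(as.integer(states), tgt)
}

#' Reconstruct the paired target nucleotides implied by a pairing spec
#'
#' Matches contribute the Watson-Crick complement of the guide nucleotide,
#' mismatches contribute their recorded identity, deletions contribute a gap
#' character. Inserted nucleotides have no recorded identity and are not
#' representable. Used by the sequence-based baseline encodings.
#'
#' @param guide a \code{guide_sequence}; @param spec a \code{pairing_spec}.
#' @param gap character used at deletion positions.
#' @return character scalar of length L over A/C/G/U plus \code{gap}.
#' @export
target_from_spec <- function(guide, spec, gap = "-") {
  stopifnot(inherits(guide, "guide_sequence"), inherits(spec, "pairing_spec"))
  if (spec$L != guide$L) stop("spec length does not match guide length")
  out <- WC_COMPLEMENT[guide$seq]
  mm <- spec$states == STATE_MISMATCH
  out[mm] <- spec$target[mm]
  out[spec$states == STATE_DELETION] <- gap
  paste(out, collapse = "")
}

all_match_spec <- function(L) pairing_spec(integer(L))
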