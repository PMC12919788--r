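#' @useDynLib cleavenet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

# Watson-Crick partner, named by guide nucleotide
WC_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Construct a guide RNA sequence
#'
#' A guide is the small RNA loaded into the PIWI protein; positions are
#' numbered g1 (5' end) to gL. Thymine is normalized to uracil so DNA-style
#' input is accepted.
#'
#' @param nucleotides character scalar over A/C/G/U (T accepted, mapped to U).
#' @param id short identifier used for grouping records by guide.
#' @return An object of class \code{guide_sequence} with fields \code{id},
#'   \code{seq} (character vector of single nucleotides) and \code{L}.
#' @examples
#' g <- guide_sequence("ACGUACGUACGUACGUACGUACGUAC", id = "g1")
#' g$L
#' @export
guide_sequence <- function(nucleotides, id = "guide") {
  stopifnot(is.character(nucleotides), length(nucleotides) == 1L)
  s <- toupper(gsub("\\s", "", nucleotides))
  s <- chartr("T", "U", s)
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), RNA_ALPHABET)
  if (length(chars) == 0L) stop("guide sequence is empty")
  if (length(bad) > 0L) {
    stop("invalid nucleotide(s) in guide '", id, "': ",
         paste(bad, collapse = ", "))
  }
  if (length(chars) < 3L) stop("guide must be at least 3 nt long")
  structure(list(id = as.character(id), seq = chars, L = length(chars)),
            class = "guide_sequence")
}

#' @export
print.guide_sequence <- function(x, ...) {
  cat(sprintf("<guide %s> %s (L=%d)\n", x$id, paste(x$seq, collapse = ""), x$L))
  invisible(x)
}

guide_string <- function(guide) paste(guide$seq, collapse = "")

#' Read guide sequences from a FASTA file
#'
#' Standard FASTA; T is normalized to U. Record names become guide ids.
#'
#' @param path path to a FASTA file.
#' @return named list of \code{guide_sequence} objects.
#' @export
read_guides_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("package 'Biostrings' is required to read FASTA files")
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) {
    guide_sequence(as.character(ss[[i]]), id = ids[i])
  })
  names(out) <- ids
  out
}

#' Random guide sequences
#'
#' Uniform i.i.d. nucleotides, used by the synthetic benchmark generator.
#'
#' @param n number of guides.
#' @param L guide length in nucleotides.
#' @param seed integer seed.
#' @return named list of \code{guide_sequence} objects with ids guide1..guideN.
#' @export
random_guides <- function(n, L = 26L, seed = 1L) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    guide_sequence(paste(sample(RNA_ALPHABET, L, replace = TRUE), collapse = ""),
                   id = paste0("guide", i))
  })
  names(out) <- vapply(out, function(g) g$id, character(1))
  out
}
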