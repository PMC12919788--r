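#' Construct a cleavage dataset
#'
#' The regression container: one record per guide-target variant, holding
#' the guide, the pairing specification and the measured (or simulated)
#' pre-steady-state cleavage rate k > 0. Records are grouped by guide id,
#' the grouping unit of leave-one-guide-out cross-validation.
#'
#' @param guides named list of \code{\link{guide_sequence}} objects.
#' @param guide_id character vector, one guide id per record.
#' @param specs list of \code{\link{pairing_spec}} objects, one per record.
#' @param k positive numeric vector of cleavage rates.
#' @param split optional character vector of split labels per record.
#' @return object of class \code{cleavage_dataset}.
#' @export
cleavage_dataset <- function(guides, guide_id, specs, k, split = NULL) {
  stopifnot(is.list(guides), length(guides) >= 1L)
  n <- length(guide_id)
  if (length(specs) != n || length(k) != n) {
    stop("guide_id, specs and k must have one entry per record")
  }
  if (is.null(names(guides))) {
    names(guides) <- vapply(guides, function(g) g$id, character(1))
  }
  missing_ids <- setdiff(unique(guide_id), names(guides))
  if (length(missing_ids) > 0L) {
    stop("records reference unknown guide id(s): ",
         paste(missing_ids, collapse = ", "))
  }
  k <- as.numeric(k)
  if (any(!is.finite(k) | k <= 0)) {
    stop("cleavage rates must be finite and > 0 (rows ",
         paste(which(!is.finite(k) | k <= 0), collapse = ", "), ")")
  }
  for (i in seq_len(n)) {
    g <- guides[[guide_id[i]]]
    if (specs[[i]]$L != g$L) {
      stop("record ", i, ": pairing spec length ", specs[[i]]$L,
           " does not match guide ", g$id, " length ", g$L)
    }
  }
  if (is.null(split)) split <- rep(NA_character_, n)
  structure(list(guides = guides, guide_id = as.character(guide_id),
                 specs = specs, k = k, split = as.character(split)),
            class = "cleavage_dataset")
}

#' @export
print.cleavage_dataset <- function(x, ...) {
  cat(sprintf("<cleavage_dataset> %d records, %d guide(s): %s\n",
              n_records(x), length(x$guides),
              paste(names(x$guides), collapse = ", ")))
  cat(sprintf("  k range: [%.4g, %.4g]\n", min(x$k), max(x$k)))
  invisible(x)
}

#' @export
length.cleavage_dataset <- function(x) length(x$k)

n_records <- function(data) length(data$k)

#' Guide-id grouping of records
#'
#' @param data a \code{cleavage_dataset}.
#' @return named list mapping guide id to record indices; the groups
#'   partition the records.
#' @export
guide_groups <- function(data) {
  stopifnot(inherits(data, "cleavage_dataset"))
  split(seq_len(n_records(data)), data$guide_id)
}

#' Subset a cleavage dataset by record index
#' @param x a \code{cleavage_dataset}; @param i integer or logical index.
#' @param ... unused.
#' @export
`[.cleavage_dataset` <- function(x, i, ...) {
  i <- seq_len(n_records(x))[i]
  cleavage_dataset(x$guides, x$guide_id[i], x$specs[i], x$k[i], x$split[i])
}

# Interaction encodings for every record (list of interaction_encoding).
dataset_encodings <- function(data) {
  lapply(seq_len(n_records(data)), function(i) {
    encode_interaction(data$guides[[data$guide_id[i]]], data$specs[[i]])
  })
}

#' Read a cleavage table
#'
#' Reads the tab-separated cleavage table with header columns
#' \code{guide_id}, \code{guide_seq}, \code{pairing}, \code{k}. The pairing
#' column uses the run-length dialect of
#' \code{\link{parse_pairing_string}}. Every row is validated (nucleotides,
#' pairing string, positive rate) and errors name the offending row.
#'
#' @param path path to a TSV file.
#' @return a \code{\link{cleavage_dataset}}.
#' @export
read_cleavage_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("guide_id", "guide_seq", "pairing", "k")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("cleavage table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  guides <- list()
  specs <- vector("list", nrow(df))
  kvec <- numeric(nrow(df))
  for (r in seq_len(nrow(df))) {
    row_fail <- function(msg) stop("row ", r, ": ", msg, call. = FALSE)
    gid <- df$guide_id[r]
    if (is.null(guides[[gid]])) {
      guides[[gid]] <- tryCatch(guide_sequence(df$guide_seq[r], id = gid),
                                error = function(e) row_fail(conditionMessage(e)))
    } else if (guide_string(guides[[gid]]) !=
               chartr("T", "U", toupper(df$guide_seq[r]))) {
      row_fail(paste0("guide id '", gid, "' maps to two different sequences"))
    }
    specs[[r]] <- tryCatch(
      parse_pairing_string(df$pairing[r], guides[[gid]]$L),
      error = function(e) row_fail(conditionMessage(e)))
    kr <- suppressWarnings(as.numeric(df$k[r]))
    if (is.na(kr) || kr <= 0) row_fail(paste0("invalid cleavage rate '", df$k[r], "'"))
    kvec[r] <- kr
  }
  cleavage_dataset(guides, df$guide_id, specs, kvec)
}

#' Write a cleavage table
#'
#' Inverse of \code{\link{read_cleavage_table}}; the written file
#' round-trips losslessly.
#'
#' @param data a \code{cleavage_dataset}; @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_cleavage_table <- function(data, path) {
  stopifnot(inherits(data, "cleavage_dataset"))
  df <- data.frame(
    guide_id = data$guide_id,
    guide_seq = vapply(data$guide_id,
                       function(id) guide_string(data$guides[[id]]),
                       character(1)),
    pairing = vapply(data$specs, format_pairing_string, character(1)),
    k = format(data$k, digits = 17, scientific = FALSE, trim = TRUE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
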