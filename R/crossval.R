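#' Leave-one-guide-out cross-validation
#'
#' One fold per guide: all records of the held-out guide form the test set
#' and appear in no training or validation batch of that fold, probing
#' generalization to unseen guide sequences. Within each fold a seeded
#' validation fraction of the remaining records drives epoch selection.
#' Fold membership depends only on guide ids (folds are ordered by sorted
#' guide id), so it is invariant to record order in the input.
#'
#' @param data a \code{\link{cleavage_dataset}} with >= 2 distinct guides.
#' @param mcfg a \code{\link{model_config}}.
#' @param tcfg a \code{\link{train_config}}.
#' @param seed base seed; fold f trains with seed \code{seed + f}.
#' @param keep_models keep each fold's trained model in the result.
#' @return object of class \code{logo_cv}: list with \code{folds} (data
#'   frame: fold, guide_id, n_test, pcc, mae; pcc is NA when undefined,
#'   never fabricated), \code{models}, \code{predictions} (per-fold list of
#'   de-normalized test predictions), and \code{test_indices}.
#' @export
leave_one_guide_out <- function(data, mcfg, tcfg, seed = 1L,
                                keep_models = TRUE) {
  stopifnot(inherits(data, "cleavage_dataset"))
  groups <- guide_groups(data)
  if (length(groups) < 2L) stop("leave-one-guide-out needs >= 2 distinct guides")
  ids <- sort(names(groups))
  folds <- vector("list", length(ids))
  models <- vector("list", length(ids))
  preds <- vector("list", length(ids))
  test_idx <- vector("list", length(ids))
  for (f in seq_along(ids)) {
    gid <- ids[f]
    te <- groups[[gid]]
    tr_all <- sort(unlist(groups[setdiff(names(groups), gid)], use.names = FALSE))
    sp <- val_split_indices(length(tr_all), tcfg$val_fraction, seed + f)
    fit <- train_model(data[tr_all[sp$train]], data[tr_all[sp$val]],
                       mcfg, tcfg, seed + f)
    pr <- normalize_invert(
      fit$model$norm,
      model_forward(fit$model, dataset_encodings(data[te])))
    ev <- if (length(te) >= 2L) evaluate(pr, data$k[te]) else
      list(pcc = NA_real_, mae = if (length(te) == 1L)
        abs(pr - data$k[te]) else NA_real_, n = length(te))
    folds[[f]] <- data.frame(fold = f, guide_id = gid, n_test = length(te),
                             pcc = ev$pcc, mae = ev$mae,
                             stringsAsFactors = FALSE)
    if (keep_models) models[[f]] <- fit$model
    preds[[f]] <- pr
    test_idx[[f]] <- te
  }
  structure(list(folds = do.call(rbind, folds),
                 models = if (keep_models) models else NULL,
                 predictions = preds, test_indices = test_idx,
                 seed = as.integer(seed)),
            class = "logo_cv")
}

#' @export
print.logo_cv <- function(x, ...) {
  cat("Leave-one-guide-out cross-validation\n")
  print(x$folds, row.names = FALSE)
  ok <- !is.na(x$folds$pcc)
  if (any(ok)) {
    cat(sprintf("  mean held-out PCC %.3f, mean MAE %.4g\n",
                mean(x$folds$pcc[ok]), mean(x$folds$mae[ok])))
  }
  invisible(x)
}

#' Pooled random-split evaluation ("mixed" protocol)
#'
#' Pools all records across guides, splits them at random into
#' \code{train_fraction} training and the rest testing (seeded), trains one
#' model and evaluates on the held-out records. Complements
#' leave-one-guide-out: here every guide is seen in training, so this
#' measures within-guide interpolation rather than guide transfer.
#'
#' @param data a \code{cleavage_dataset}.
#' @param mcfg,tcfg model and training configurations.
#' @param train_fraction fraction of records used for training (reference
#'   protocol: 0.75).
#' @param seed integer seed for the split and training.
#' @return list with \code{eval} (an \code{eval_result} on the test
#'   records), \code{model}, \code{test_indices}, \code{predictions}.
#' @export
mixed_split_eval <- function(data, mcfg, tcfg, train_fraction = 0.75,
                             seed = 1L) {
  stopifnot(inherits(data, "cleavage_dataset"),
            train_fraction > 0, train_fraction < 1)
  N <- n_records(data)
  set.seed(seed)
  tr <- sort(sample.int(N, round(N * train_fraction)))
  te <- setdiff(seq_len(N), tr)
  if (length(te) < 2L) stop("test split too small")
  sp <- val_split_indices(length(tr), tcfg$val_fraction, seed + 1L)
  fit <- train_model(data[tr[sp$train]], data[tr[sp$val]], mcfg, tcfg,
                     seed + 1L)
  pr <- normalize_invert(fit$model$norm,
                         model_forward(fit$model, dataset_encodings(data[te])))
  list(eval = evaluate(pr, data$k[te]), model = fit$model,
       test_indices = te, predictions = pr, history = fit$history)
}

#' Per-fold metrics table
#'
#' @param cv a \code{logo_cv} result.
#' @param seed optional seed column value recorded in the table.
#' @return data frame with columns fold, guide_id, seed, pcc, mae (the
#'   metrics TSV layout written by the command-line interface).
#' @export
cv_metrics_table <- function(cv, seed = cv$seed) {
  stopifnot(inherits(cv, "logo_cv"))
  data.frame(fold = cv$folds$fold, guide_id = cv$folds$guide_id,
             seed = seed, pcc = cv$folds$pcc, mae = cv$folds$mae,
             stringsAsFactors = FALSE)
}
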