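PEARSON_EPS <- 1e-8

#' Composite MAE + Pearson training loss
#'
#' \deqn{L = \alpha \cdot MAE(k, \hat k) + (1-\alpha)(1 - PCC(k, \hat k))}
#' The MAE term drives quantitative accuracy of the predicted rates; the
#' Pearson term (1 - PCC) preserves rank consistency across variants. The
#' correlation inside the loss uses population standard deviations
#' (divide-by-N) with an epsilon guard of \code{1e-8} added to each SD, so a
#' constant prediction batch is maximally penalized (Pearson term near 1)
#' instead of producing NaN. Reported evaluation metrics use the sample
#' correlation (\code{\link{evaluate}}), not this guarded form.
#'
#' @param k observed rates (normalized during training).
#' @param khat predicted rates.
#' @param alpha MAE weight in [0, 1]; the reference setting is 0.8.
#' @return nonnegative scalar loss.
#' @examples
#' composite_loss(c(0, 1), c(1, 0), alpha = 0.8)  # MAE 1, PCC -1 -> 1.2
#' @export
composite_loss <- function(k, khat, alpha = 0.8) {
  stopifnot(length(k) == length(khat), length(k) >= 2L,
            alpha >= 0, alpha <= 1)
  mae <- mean(abs(k - khat))
  alpha * mae + (1 - alpha) * (1 - guarded_pcc(k, khat))
}

# Population-SD Pearson correlation with epsilon-guarded denominators.
guarded_pcc <- function(k, khat) {
  n <- length(k)
  xc <- k - mean(k)
  yc <- khat - mean(khat)
  sx <- sqrt(mean(xc^2))
  sy <- sqrt(mean(yc^2))
  mean(xc * yc) / ((sx + PEARSON_EPS) * (sy + PEARSON_EPS))
}

# Gradient of composite_loss with respect to khat (analytic; verified
# against finite differences in the test suite).
composite_loss_grad <- function(k, khat, alpha = 0.8) {
  n <- length(k)
  g_mae <- alpha * sign(khat - k) / n
  xc <- k - mean(k)
  yc <- khat - mean(khat)
  sx <- sqrt(mean(xc^2))
  sy <- sqrt(mean(yc^2))
  denom <- (sx + PEARSON_EPS) * (sy + PEARSON_EPS)
  cv <- mean(xc * yc)
  # d r / d khat_i for r = cv / denom with sy depending on khat
  if (sy > 0) {
    dr <- xc / (n * denom) - cv * yc / (n * sy * (sx + PEARSON_EPS) *
                                          (sy + PEARSON_EPS)^2)
  } else {
    dr <- xc / (n * denom)
  }
  g_mae - (1 - alpha) * dr
}

#' Z-score normalization of cleavage rates
#'
#' Fits mean and (sample) standard deviation on the training rates only;
#' \code{normalize_apply} maps rates to z-scores, \code{normalize_invert}
#' is its exact inverse. Evaluation is done on de-normalized predictions
#' (the Pearson correlation is affine-invariant, so normalization only
#' affects the MAE scale).
#'
#' @param train_k training-set rates (length >= 2, nonconstant).
#' @return object of class \code{rate_norm} with fields \code{mean},
#'   \code{sd}.
#' @export
normalize_rates <- function(train_k) {
  stopifnot(length(train_k) >= 2L)
  m <- mean(train_k)
  s <- stats::sd(train_k)
  if (!is.finite(s) || s <= 0) {
    stop("training rates are constant; z-score normalization is undefined")
  }
  structure(list(mean = m, sd = s), class = "rate_norm")
}

#' @rdname normalize_rates
#' @param norm a \code{rate_norm}; @param k rates (or z-scores for invert).
#' @export
normalize_apply <- function(norm, k) (k - norm$mean) / norm$sd

#' @rdname normalize_rates
#' @export
normalize_invert <- function(norm, z) z * norm$sd + norm$mean

#' Evaluate predictions against observed rates
#'
#' @param pred predicted rates; @param truth observed rates (same length,
#'   >= 2, de-normalized).
#' @return object of class \code{eval_result}: list with \code{pcc} (sample
#'   Pearson correlation, NA when either vector has zero variance),
#'   \code{mae} and \code{n}.
#' @export
evaluate <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2L)
  pcc <- if (stats::sd(pred) == 0 || stats::sd(truth) == 0) NA_real_ else
    stats::cor(pred, truth)
  structure(list(pcc = pcc, mae = mean(abs(pred - truth)),
                 n = length(pred)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval> n=%d  PCC=%s  MAE=%.4g\n", x$n,
              ifelse(is.na(x$pcc), "NA", sprintf("%.3f", x$pcc)), x$mae))
  invisible(x)
}

#' Paired t-test between per-seed score vectors
#'
#' Two-sided paired t-test on matched per-seed scores of two methods, the
#' significance protocol used for model comparisons. When every paired
#' difference is exactly zero the comparison is degenerate and (t = 0,
#' p = 1) is reported; a nonzero constant difference (zero variance) is
#' reported as t = +/-Inf with p = 0 by convention.
#'
#' @param scores_a,scores_b equal-length numeric vectors (>= 2 pairs).
#' @return list with \code{t}, \code{p}, \code{df}, \code{mean_diff}.
#' @export
repeat_and_compare <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  if (all(d == 0)) {
    return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0))
  }
  if (stats::sd(d) == 0) {
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d))
}
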