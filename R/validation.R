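## Model validation: mean absolute error, Q-squared, and pair-resampling
## bootstrap dispersion of both.

#' Mean absolute error
#'
#' \eqn{\mathrm{MAE} = \frac{1}{n}\sum_i |y_i - y'_i|} between observed and
#' predicted activities.
#'
#' @param y_obs,y_pred Numeric vectors of equal, nonzero length.
#' @return The mean absolute error.
#' @export
#' @examples
#' mae(c(1, 2), c(2, 4))  # 1.5
mae <- function(y_obs, y_pred) {
  if (length(y_obs) == 0L) stop("empty prediction pairs", call. = FALSE)
  if (length(y_obs) != length(y_pred))
    stop("observed and predicted vectors differ in length", call. = FALSE)
  check_finite(y_obs, "y_obs"); check_finite(y_pred, "y_pred")
  mean(abs(y_obs - y_pred))
}

#' Predictive squared correlation (Q-squared)
#'
#' \eqn{Q^2 = 1 - \sum_i (y_i - y'_i)^2 / \sum_i (y_i - \bar y)^2}, with
#' \eqn{\bar y} the mean of the observed values.  Equals 1 for perfect
#' prediction, 0 for predicting the mean, and can be negative.
#'
#' @inheritParams mae
#' @return The Q-squared value.
#' @export
q_square <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred))
    stop("observed and predicted vectors differ in length", call. = FALSE)
  if (length(y_obs) < 2L)
    stop("need at least 2 prediction pairs", call. = FALSE)
  check_finite(y_obs, "y_obs"); check_finite(y_pred, "y_pred")
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst == 0)
    stop("Q-squared undefined: observed values are constant", call. = FALSE)
  1 - sum((y_obs - y_pred)^2) / sst
}

#' Bootstrap validation of prediction pairs
#'
#' Resamples the (observed, predicted) pairs of an already-fitted model
#' with replacement \code{n_boot} times (resample size equal to the data
#' size), computing the MAE and Q-squared on each resample, and reports
#' their bootstrap means and standard deviations alongside the plain point
#' estimates.  A resample whose observed values are constant has no
#' Q-squared; such replicates are skipped for the Q-squared summaries and
#' counted in \code{q2_skipped}.
#'
#' @inheritParams mae
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the same seed and \code{n_boot} always yield
#'   the identical report.
#' @param labels Optional compound names, carried into the report.
#' @return An object of class \code{"qsar_validation"}: a list with
#'   \code{mae}, \code{q2}, \code{mae_boot_mean}, \code{mae_boot_sd},
#'   \code{q2_boot_mean}, \code{q2_boot_sd}, \code{n}, \code{n_boot},
#'   \code{q2_skipped}, \code{seed}, and the per-replicate table in
#'   \code{replicates}.
#' @export
#' @examples
#' act <- qsar_fixtures()$activities
#' bootstrap_validate(act$experimental, act$pm6, n_boot = 200, seed = 1)
bootstrap_validate <- function(y_obs, y_pred, n_boot = 1000, seed = 1,
                               labels = NULL) {
  if (!is.numeric(n_boot) || n_boot < 1)
    stop("n_boot must be a positive integer", call. = FALSE)
  n_boot <- as.integer(n_boot)
  point_mae <- mae(y_obs, y_pred)
  point_q2 <- q_square(y_obs, y_pred)
  n <- length(y_obs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boot_mae <- numeric(n_boot)
  boot_q2 <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_mae[b] <- mean(abs(y_obs[idx] - y_pred[idx]))
    if (sd(y_obs[idx]) > 0)
      boot_q2[b] <- q_square(y_obs[idx], y_pred[idx])
  }
  ok <- !is.na(boot_q2)
  structure(list(
    mae = point_mae, q2 = point_q2,
    mae_boot_mean = mean(boot_mae), mae_boot_sd = sd(boot_mae),
    q2_boot_mean = mean(boot_q2[ok]), q2_boot_sd = sd(boot_q2[ok]),
    n = n, n_boot = n_boot, q2_skipped = sum(!ok), seed = seed,
    labels = labels,
    replicates = data.frame(replicate = seq_len(n_boot), mae = boot_mae,
                            q2 = boot_q2)
  ), class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, digits = 3, ...) {
  cat("Bootstrap validation of prediction pairs\n")
  cat(sprintf("  n = %d pairs, %d resamples (seed %d)\n", x$n, x$n_boot,
              x$seed))
  cat(sprintf("  MAE : %s (bootstrap %s +/- %s)\n",
              format(x$mae, digits = digits),
              format(x$mae_boot_mean, digits = digits),
              format(x$mae_boot_sd, digits = digits)))
  cat(sprintf("  Q^2 : %s (bootstrap %s +/- %s)\n",
              format(x$q2, digits = digits),
              format(x$q2_boot_mean, digits = digits),
              format(x$q2_boot_sd, digits = digits)))
  if (x$q2_skipped > 0)
    cat(sprintf("  (%d resample(s) had constant observed values; skipped for Q^2)\n",
                x$q2_skipped))
  invisible(x)
}
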