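#' @export
print.anfis <- function(x, ...) {
  cat("Takagi-Sugeno neuro-fuzzy model (ANFIS)\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  k <- vapply(x$mfs, nrow, integer(1))
  cat(sprintf("Inputs: %s\n", paste(x$inputs, collapse = ", ")))
  cat(sprintf("Architecture: %s triangular MFs -> %d rules, first-order consequents\n",
              paste(k, collapse = " x "), nrow(x$rules)))
  if (length(x$trace))
    cat(sprintf("Trained %d epochs; final training MSE %.4g\n",
                length(x$trace), x$trace[length(x$trace)]))
  invisible(x)
}

#' @export
coef.anfis <- function(object, ...) object$consequents

#' @export
summary.anfis <- function(object, ...) {
  out <- list(
    inputs = object$inputs,
    n_rules = nrow(object$rules),
    mfs_per_input = vapply(object$mfs, nrow, integer(1)),
    epochs = length(object$trace),
    final_mse = if (length(object$trace))
      object$trace[length(object$trace)] else NA_real_,
    config = object$config
  )
  if (!is.null(object$y)) {
    out$n <- length(object$y)
    out$train_rmse <- sqrt(mean(object$residuals^2))
    out$train_mae <- mean(abs(object$residuals))
    out$train_q2 <- q_square(object$y, object$fitted.values)
  }
  structure(out, class = "summary.anfis")
}

#' @export
print.summary.anfis <- function(x, ...) {
  cat("Takagi-Sugeno neuro-fuzzy model (ANFIS)\n")
  cat(sprintf("  inputs      : %s\n", paste(x$inputs, collapse = ", ")))
  cat(sprintf("  rules       : %d (%s MFs per input)\n", x$n_rules,
              paste(x$mfs_per_input, collapse = " x ")))
  cat(sprintf("  epochs      : %d (final training MSE %.4g)\n",
              x$epochs, x$final_mse))
  if (!is.null(x$n)) {
    cat(sprintf("  n           : %d\n", x$n))
    cat(sprintf("  training fit: MAE %.3f, RMSE %.3f, Q-squared %.3f\n",
                x$train_mae, x$train_rmse, x$train_q2))
  }
  invisible(x)
}

#' @export
plot.anfis <- function(x, which = c("trace", "fit"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("trace" %in% which && length(x$trace))
    plot(seq_along(x$trace), x$trace, type = "l", xlab = "epoch",
         ylab = "training MSE", main = "Learning curve", ...)
  if ("fit" %in% which && !is.null(x$y)) {
    plot(x$y, x$fitted.values, xlab = "observed", ylab = "predicted",
         main = "Training fit", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' @export
simulate.anfis <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                           ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) fitted(object) else predict(object, newdata)
  sigma <- sqrt(mean(object$residuals^2))
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), sd = sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Save an ANFIS model as structured text
#'
#' Serializes the membership functions, rule base, consequent coefficients,
#' input scaling and training trace to versioned JSON with enough digits
#' for a lossless round trip through [read_anfis()].
#'
#' @param model An \code{"anfis"} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_anfis <- function(model, path) {
  payload <- list(
    format = "anfisqsar-model",
    format_version = model$format_version,
    inputs = model$inputs,
    mfs = lapply(model$mfs, function(m) unclass(as.data.frame(m))),
    rules = unname(apply(model$rules, 1, as.integer, simplify = FALSE)),
    consequents = unname(apply(model$consequents, 1, as.numeric,
                               simplify = FALSE)),
    scaling = lapply(model$scaling, as.list),  # keep names in JSON
    input_ranges = unclass(as.data.frame(model$input_ranges)),
    trace = model$trace,
    config = model$config
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' Load an ANFIS model saved by [write_anfis()]
#'
#' @param path Path to the serialized model.
#' @return An \code{"anfis"} object.
#' @export
read_anfis <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(p$format, "anfisqsar-model"))
    stop("not an anfisqsar model file: ", path, call. = FALSE)
  if (p$format_version > 1L)
    stop("unsupported model format version ", p$format_version,
         call. = FALSE)
  inputs <- p$inputs
  mfs <- lapply(p$mfs, function(m)
    cbind(left = m$left, peak = m$peak, right = m$right))
  names(mfs) <- inputs
  as_row_matrix <- function(x, ncol) {
    m <- if (is.matrix(x)) x else matrix(unlist(x), ncol = ncol,
                                         byrow = TRUE)
    unname(m)
  }
  rules <- as_row_matrix(p$rules, length(inputs))
  dimnames(rules) <- list(NULL, inputs)
  storage.mode(rules) <- "integer"
  consequents <- as_row_matrix(p$consequents, length(inputs) + 1L)
  dimnames(consequents) <- list(NULL, c("c0", inputs))
  structure(list(
    inputs = inputs, mfs = mfs, rules = rules, consequents = consequents,
    scaling = list(center = unlist(p$scaling$center),
                   scale = unlist(p$scaling$scale)),
    input_ranges = do.call(cbind, p$input_ranges),
    trace = as.numeric(p$trace),
    config = p$config,
    format_version = as.integer(p$format_version)
  ), class = "anfis")
}
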