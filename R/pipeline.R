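## End-to-end driver: energies -> descriptors -> screening -> ANFIS ->
## bootstrap validation, with optional artifact output.  The exported
## functions are the interface; wrap run_qsar() in Rscript for shell use.

#' Run the QSAR pipeline end to end
#'
#' Orchestrates the full analysis for one semi-empirical method: build the
#' per-compound feature table from energy records (or accept one
#' ready-made), screen all supplied descriptor columns against activity,
#' drop collinear descriptors, fit the neuro-fuzzy model, and
#' bootstrap-validate its predictions.  Supplying \code{predictions}
#' switches to injection mode: the given predicted activities are validated
#' directly and no model is trained, which reproduces published headline
#' statistics independently of any training-hyperparameter choices.
#'
#' @param activity Numeric vector of experimental activities (percent DPPH
#'   scavenged), one per registry compound, in registry order.
#' @param registry Compound registry data frame (default: the packaged
#'   one).
#' @param energies Energy records (see [read_energy_table()]); required
#'   unless \code{feature_table} or \code{predictions} is given.
#' @param feature_table Optional precomputed feature table (rows in
#'   registry order), bypassing [build_feature_table()].
#' @param predictions Optional numeric vector of predicted activities
#'   (injection mode).
#' @param method \code{"PM6"} or \code{"PM7"}.
#' @param features Feature ids for the model (default
#'   \code{c("A_FC", "chi_FC", "I_QB7", "nOH")}).
#' @param r2_threshold Collinearity threshold passed to
#'   [eliminate_collinear()].
#' @param epochs,learning_rate,solver,lambda Training configuration, see
#'   [anfis_train()].
#' @param n_boot,seed Bootstrap configuration, see [bootstrap_validate()].
#' @param bootstrap_mode \code{"pairs"} (default) resamples the
#'   (observed, predicted) pairs of the fitted model;  \code{"refit"}
#'   retrains the model on each resample of the compounds and scores it on
#'   the full panel, which folds refitting variance into the reported
#'   dispersions (slower, training path only).
#' @param output_dir Optional directory; when given, writes the
#'   correlation report, serialized model, predictions table, error trace
#'   and validation summary, each stamped with a configuration hash.
#' @return An object of class \code{"qsar_run"}: a list with elements
#'   \code{config}, \code{screen}, \code{selected}, \code{model} (or
#'   \code{NULL} in injection mode), \code{predictions} (data frame with
#'   compound, experimental and predicted columns) and \code{validation}.
#' @export
#' @examples
#' fx <- qsar_fixtures()
#' run <- run_qsar(fx$activities$experimental, predictions = fx$activities$pm7,
#'                 method = "PM7", n_boot = 200, seed = 1)
#' run
run_qsar <- function(activity, registry = load_registry(), energies = NULL,
                     feature_table = NULL, predictions = NULL,
                     method = c("PM6", "PM7"),
                     features = c("A_FC", "chi_FC", "I_QB7", "nOH"),
                     r2_threshold = 1,
                     epochs = 100, learning_rate = 0.05,
                     solver = "least_squares", lambda = 1e-6,
                     n_boot = 1000, seed = 1,
                     bootstrap_mode = c("pairs", "refit"),
                     output_dir = NULL) {
  method <- match.arg(method)
  bootstrap_mode <- match.arg(bootstrap_mode)
  check_finite(activity, "activity")
  if (length(activity) != nrow(registry))
    stop("activity length does not match the registry", call. = FALSE)
  config <- list(method = method, features = features,
                 r2_threshold = r2_threshold, epochs = epochs,
                 learning_rate = learning_rate, solver = solver,
                 lambda = lambda, n_boot = n_boot, seed = seed,
                 bootstrap_mode = bootstrap_mode,
                 injection = !is.null(predictions))

  model <- NULL
  screen <- NULL
  selected <- NULL
  if (is.null(predictions)) {
    if (is.null(feature_table)) {
      if (is.null(energies))
        stop("supply 'energies', 'feature_table' or 'predictions'",
             call. = FALSE)
      feature_table <- build_feature_table(registry, energies, method,
                                           features)
    }
    screen <- screen_descriptors(feature_table, activity)
    ranked <- screen$feature[!is.na(screen$r)]
    selected <- eliminate_collinear(intersect(c(ranked, "nOH"),
                                              names(feature_table)),
                                    feature_table, r2_threshold)
    fml <- stats::as.formula(paste(
      "activity ~", paste(sprintf("`%s`", selected), collapse = " + ")))
    dat <- cbind(feature_table[selected], activity = activity)
    model <- anfis(fml, dat, epochs = epochs,
                   learning_rate = learning_rate, solver = solver,
                   lambda = lambda)
    predictions <- predict(model, as.matrix(feature_table[selected]))
  } else {
    check_finite(predictions, "predictions")
    if (length(predictions) != length(activity))
      stop("predictions length does not match activity", call. = FALSE)
  }

  if (bootstrap_mode == "refit") {
    if (is.null(model))
      stop("bootstrap_mode = \"refit\" requires the training path",
           call. = FALSE)
    validation <- bootstrap_refit(feature_table[selected], activity,
                                  n_boot = n_boot, seed = seed,
                                  epochs = epochs,
                                  learning_rate = learning_rate,
                                  solver = solver, lambda = lambda,
                                  point_pred = predictions)
  } else {
    validation <- bootstrap_validate(activity, predictions, n_boot = n_boot,
                                     seed = seed, labels = registry$name)
  }
  pred_table <- data.frame(compound = registry$name,
                           experimental = activity,
                           predicted = predictions)
  out <- structure(list(config = config, screen = screen,
                        selected = selected, model = model,
                        predictions = pred_table,
                        validation = validation),
                   class = "qsar_run")
  if (!is.null(output_dir)) write_run_artifacts(out, output_dir)
  out
}

# Retraining bootstrap: refit on each compound resample, score on the full
# panel.  Replicates whose resample degenerates (a constant feature column
# or constant observed activity) are skipped and counted.
bootstrap_refit <- function(features, activity, n_boot, seed, epochs,
                            learning_rate, solver, lambda, point_pred) {
  features <- as.data.frame(features)
  n <- length(activity)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boot_mae <- rep(NA_real_, n_boot)
  boot_q2 <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch({
      m <- anfis_init(features[idx, , drop = FALSE])
      anfis_train(m, features[idx, , drop = FALSE], activity[idx],
                  epochs = epochs, learning_rate = learning_rate,
                  solver = solver, lambda = lambda)
    }, error = function(e) NULL)
    if (is.null(rep_fit)) next
    pred <- tryCatch(predict(rep_fit, as.matrix(features)),
                     error = function(e) NULL)
    if (is.null(pred)) next
    boot_mae[b] <- mean(abs(activity - pred))
    if (sd(activity) > 0) boot_q2[b] <- q_square(activity, pred)
  }
  ok <- !is.na(boot_mae)
  okq <- !is.na(boot_q2)
  structure(list(
    mae = mae(activity, point_pred), q2 = q_square(activity, point_pred),
    mae_boot_mean = mean(boot_mae[ok]), mae_boot_sd = sd(boot_mae[ok]),
    q2_boot_mean = mean(boot_q2[okq]), q2_boot_sd = sd(boot_q2[okq]),
    n = n, n_boot = n_boot, q2_skipped = sum(!okq), seed = seed,
    labels = NULL, mode = "refit",
    replicates = data.frame(replicate = seq_len(n_boot), mae = boot_mae,
                            q2 = boot_q2)
  ), class = "qsar_validation")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = I(17)),
             tmp)
  unname(tools::md5sum(tmp))
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(sprintf("config_hash: %s", config_hash(run$config)),
             sprintf("seed: %d", run$config$seed))
  if (!is.null(run$screen))
    write_correlation_report(run$screen,
                             file.path(dir, "correlation_report.tsv"))
  if (!is.null(run$model)) {
    write_anfis(run$model, file.path(dir, "model.json"))
    write.table(data.frame(epoch = seq_along(run$model$trace),
                           mse = run$model$trace),
                file.path(dir, "error_trace.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(run$predictions, file.path(dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  v <- run$validation
  writeLines(c(stamp,
               sprintf("n: %d", v$n),
               sprintf("mae: %.6f", v$mae),
               sprintf("q2: %.6f", v$q2),
               sprintf("mae_boot: %.6f +/- %.6f", v$mae_boot_mean,
                       v$mae_boot_sd),
               sprintf("q2_boot: %.6f +/- %.6f", v$q2_boot_mean,
                       v$q2_boot_sd),
               sprintf("n_boot: %d", v$n_boot)),
             file.path(dir, "validation.txt"))
  invisible(dir)
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("QSAR pipeline run\n")
  cat(sprintf("  method    : %s%s\n", x$config$method,
              if (x$config$injection) " (injected predictions)" else ""))
  cat(sprintf("  compounds : %d\n", nrow(x$predictions)))
  if (!is.null(x$selected))
    cat(sprintf("  features  : %s\n", paste(x$selected, collapse = ", ")))
  if (!is.null(x$screen)) {
    top <- utils::head(x$screen[x$screen$error == "", ], 4)
    cat("  screening (top |r|):\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-8s r = %6.3f  p = %.4f %s\n", top$feature[i],
                  top$r[i], top$p[i], top$stars[i]))
  }
  if (!is.null(x$model))
    cat(sprintf("  training  : %d epochs, final MSE %.4g\n",
                length(x$model$trace),
                x$model$trace[length(x$model$trace)]))
  v <- x$validation
  cat(sprintf("  MAE = %.3f (bootstrap %.3f +/- %.3f)\n", v$mae,
              v$mae_boot_mean, v$mae_boot_sd))
  cat(sprintf("  Q^2 = %.3f (bootstrap %.3f +/- %.3f)\n", v$q2,
              v$q2_boot_mean, v$q2_boot_sd))
  cat(sprintf("  seed %d, %d bootstrap resamples\n", v$seed, v$n_boot))
  invisible(x)
}
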