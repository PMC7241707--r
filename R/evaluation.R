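#' Root-mean-squared error
#'
#' @param y,yhat Equal-length numeric vectors.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) == 0) stop("empty input")
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation in percent
#'
#' Returns `100 * cor(y, yhat)`; if either input has zero variance the
#' correlation is undefined and reported as 0 by convention (the value a
#' constant predictor scores).
#'
#' @param y,yhat Equal-length numeric vectors, length >= 2.
#' @return Correlation coefficient in `[-100, 100]`.
#' @export
pearson_pct <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(0)
  100 * stats::cor(y, yhat)
}

#' Fit any predictor specification
#'
#' Dispatches on the spec class: an `ncf_config` is trained with
#' [train_ncf()] (or [pretrain_then_train()] when `pretrain = TRUE`); a
#' `baseline_spec` goes through [fit_baseline()].
#'
#' @param spec An `ncf_config` or `baseline_spec`.
#' @param dataset An `indexed_dataset`.
#' @param enc The matching `cross_encoding`.
#' @return A fitted model.
#' @export
fit_predictor <- function(spec, dataset, enc) {
  if (inherits(spec, "ncf_config")) {
    if (isTRUE(spec$pretrain)) pretrain_then_train(dataset, enc, spec) else
      train_ncf(dataset, enc, spec)
  } else if (inherits(spec, "baseline_spec")) {
    fit_baseline(spec, dataset, enc)
  } else {
    stop("spec must be an ncf_config or a baseline_spec")
  }
}

spec_name <- function(spec) {
  if (inherits(spec, "ncf_config")) {
    paste0("ncf_", spec$branch,
           if (!spec$use_parent_ids) "_coarse" else "",
           if (isTRUE(spec$pretrain)) "_pretrained" else "")
  } else {
    spec$kind
  }
}

new_eval_report <- function(model_name, protocol, train_rmse, train_corr_pct,
                            test_rmse, test_corr_pct, per_fold = NULL,
                            config = NULL, predictions = NULL) {
  structure(list(model_name = model_name, protocol = protocol,
                 train_rmse = train_rmse, train_corr_pct = train_corr_pct,
                 test_rmse = test_rmse, test_corr_pct = test_corr_pct,
                 per_fold = per_fold, config = config,
                 predictions = predictions),
            class = "eval_report")
}

#' k-fold cross validation
#'
#' Observation-level folds from [kfold_split()]. Each fold's model is
#' trained on the remaining folds and predicts the held fold with full
#' (inbred, tester, group, location) inputs. Test metrics are pooled over
#' all out-of-fold predictions (each observation predicted exactly once);
#' training metrics are averaged over folds, with per-fold values retained.
#'
#' @param dataset An `indexed_dataset`.
#' @param enc The `cross_encoding`.
#' @param spec An `ncf_config` or `baseline_spec`.
#' @param k Number of folds.
#' @param seed Seed for the fold shuffle.
#' @return An `eval_report`; `predictions` holds the pooled out-of-fold
#'   predictions aligned with the dataset rows.
#' @export
run_cv <- function(dataset, enc, spec, k = 10, seed = 1) {
  folds <- kfold_split(dataset, k, seed)
  pooled <- rep(NA_real_, dataset$N)
  per_fold <- data.frame(fold = seq_len(k), train_rmse = NA_real_,
                         train_corr_pct = NA_real_, test_rmse = NA_real_,
                         test_corr_pct = NA_real_)
  for (f in seq_len(k)) {
    tr <- subset_dataset(dataset, folds[[f]]$train)
    model <- fit_predictor(spec, tr, enc)
    te_idx <- folds[[f]]$test
    ph <- predict_observations(model, dataset$b[te_idx], dataset$t[te_idx],
                               dataset$g[te_idx], dataset$l[te_idx])
    pooled[te_idx] <- ph
    ptr <- predict_observations(model, tr$b, tr$t, tr$g, tr$l)
    per_fold$train_rmse[f] <- rmse(tr$y, ptr)
    per_fold$train_corr_pct[f] <- pearson_pct(tr$y, ptr)
    per_fold$test_rmse[f] <- rmse(dataset$y[te_idx], ph)
    per_fold$test_corr_pct[f] <- if (length(te_idx) >= 2) {
      pearson_pct(dataset$y[te_idx], ph)
    } else {
      NA_real_  # undefined for a single held observation (leave-one-out)
    }
  }
  stopifnot(!anyNA(pooled))
  new_eval_report(spec_name(spec), "cv",
                  mean(per_fold$train_rmse), mean(per_fold$train_corr_pct),
                  rmse(dataset$y, pooled), pearson_pct(dataset$y, pooled),
                  per_fold = per_fold, config = spec, predictions = pooled)
}

#' Hold-out-by-combination evaluation
#'
#' Splits by combination ([holdout_split_by_combination()]), trains on the
#' remaining observations, predicts each held pair at every location
#' through [predict_pair_means()] and scores the location-averaged
#' predictions against the pair-mean observed yields.
#'
#' @inheritParams run_cv
#' @param n_combos Number of combinations to hold out.
#' @return An `eval_report`; `predictions` is a data frame with the held
#'   pairs, their responses and predictions.
#' @export
run_holdout <- function(dataset, enc, spec, n_combos, seed = 1) {
  sp <- holdout_split_by_combination(dataset, n_combos, seed)
  model <- fit_predictor(spec, sp$train, enc)
  pred <- predict_pair_means(model, sp$heldout$b, sp$heldout$t)
  ptr <- predict_observations(model, sp$train$b, sp$train$t, sp$train$g,
                              sp$train$l)
  out <- sp$heldout
  out$prediction <- pred
  new_eval_report(spec_name(spec), "holdout",
                  rmse(sp$train$y, ptr), pearson_pct(sp$train$y, ptr),
                  rmse(out$response, pred), pearson_pct(out$response, pred),
                  config = spec, predictions = out)
}

#' Coarse-model experiment: prediction without parent IDs
#'
#' Runs the requested protocols with the NN-only model stripped of inbred
#' and tester inputs (`use_parent_ids = FALSE`), i.e. prediction from
#' genetic group and location alone.
#'
#' @inheritParams run_cv
#' @param config An `ncf_config`; its branch/parent-ID fields are
#'   overridden to the coarse setting.
#' @param protocols Subset of `c("cv", "holdout")`.
#' @param n_combos Held-out combinations for the holdout protocol.
#' @return Named list of `eval_report`s.
#' @export
run_coarse_experiment <- function(dataset, enc, config,
                                  protocols = c("cv", "holdout"), k = 10,
                                  n_combos = NULL, seed = 1) {
  stopifnot(inherits(config, "ncf_config"))
  coarse <- config
  coarse$branch <- "nn_only"
  coarse$use_parent_ids <- FALSE
  coarse$pretrain <- FALSE
  out <- list()
  if ("cv" %in% protocols) {
    out$cv <- run_cv(dataset, enc, coarse, k = k, seed = seed)
  }
  if ("holdout" %in% protocols) {
    if (is.null(n_combos)) stop("n_combos required for the holdout protocol")
    out$holdout <- run_holdout(dataset, enc, coarse, n_combos, seed = seed)
  }
  out
}

#' Write an evaluation report
#'
#' Writes the report as JSON and appends one flat CSV row per (model,
#' protocol) mirroring a results-table layout.
#'
#' @param report An `eval_report`.
#' @param json_path Optional JSON output path.
#' @param csv_path Optional CSV output path (appended, header written once).
#' @return The report, invisibly.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(json_path)) {
    out <- report[c("model_name", "protocol", "train_rmse",
                    "train_corr_pct", "test_rmse", "test_corr_pct")]
    out$per_fold <- report$per_fold
    out$config <- unclass(report$config)
    jsonlite::write_json(out, json_path, digits = NA, auto_unbox = TRUE,
                         null = "null")
  }
  if (!is.null(csv_path)) {
    row <- data.frame(model = report$model_name, protocol = report$protocol,
                      train_rmse = report$train_rmse,
                      train_corr_pct = report$train_corr_pct,
                      test_rmse = report$test_rmse,
                      test_corr_pct = report$test_corr_pct)
    utils::write.table(row, csv_path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(csv_path), append =
                         file.exists(csv_path), quote = FALSE)
  }
  invisible(report)
}

#' @method print eval_report
#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s, %s]\n  train RMSE %.4f  corr %.2f%%\n",
              x$model_name, x$protocol, x$train_rmse, x$train_corr_pct),
      sprintf(" test  RMSE %.4f  corr %.2f%%\n", x$test_rmse,
              x$test_corr_pct))
  invisible(x)
}
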