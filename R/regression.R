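# epsilon-SVR IC50 predictor: grid-tuned training, prediction, evaluation,
# and the cross-dataset train/validate pipeline.

#' Default SVR hyperparameter grid
#'
#' Cost in \{10, 100\} and RBF gamma in \{1e-6, 1e-5, 1e-4, 1e-3\}, tuned by
#' 10-fold cross-validation on mean squared error.
#' @return list with components `cost` and `gamma`.
#' @export
default_svr_grid <- function() list(cost = c(10, 100),
                                    gamma = c(1e-6, 1e-5, 1e-4, 1e-3))

#' Train the epsilon-SVR drug-sensitivity predictor
#'
#' Fits an RBF-kernel epsilon-regression SVM to predict IC50 (ln uM) from
#' feature columns (typically circuit activities). Every (cost, gamma) pair
#' of the grid is evaluated by k-fold cross-validated mean squared error with
#' a seeded fold assignment; the model is then refit on all samples at the
#' best pair. Ties are broken toward the smaller cost, then smaller gamma.
#'
#' Circuit activities live in [0, 1] and are used as-is; set
#' `scale = TRUE` for raw gene-expression features to standardize columns
#' with training-set statistics (frozen into the model for prediction).
#'
#' @param x numeric matrix, samples x features, with column names.
#' @param y numeric response (IC50, ln uM), length `nrow(x)`.
#' @param grid list with `cost` and `gamma` vectors
#'   (default [default_svr_grid()]).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param epsilon epsilon-insensitive tube width (default 0.1).
#' @param scale standardize feature columns (default FALSE).
#' @param stratify optional factor (e.g. drug) to stratify folds by.
#' @importFrom e1071 svm
#' @return An object of class `ic50_svr` with the fitted e1071 model,
#'   `feature_ids`, chosen `cost`/`gamma`/`epsilon`, the full `cv_table`
#'   (mean and per-fold MSE per grid point), `fold_assignment`, and `seed`.
#' @export
train_predictor <- function(x, y, grid = default_svr_grid(), folds = 10L,
                            seed = 1L, epsilon = 0.1, scale = FALSE,
                            stratify = NULL) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (nrow(x) != length(y))
    stop("feature matrix and response length differ", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite feature values", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  n <- nrow(x)
  if (n < folds)
    stop(sprintf("need at least %d samples for %d folds", folds, folds),
         call. = FALSE)

  center <- NULL; scl <- NULL
  if (scale) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_of <- if (is.null(stratify)) {
    sample(rep(seq_len(folds), length.out = n))
  } else {
    f <- integer(n)
    for (lev in levels(factor(stratify))) {
      i <- which(stratify == lev)
      f[i] <- sample(rep(seq_len(folds), length.out = length(i)))
    }
    f
  }

  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$cost, combos$gamma), , drop = FALSE]
  fold_mse <- matrix(NA_real_, nrow(combos), folds)
  for (i in seq_len(nrow(combos))) {
    for (k in seq_len(folds)) {
      tr <- fold_of != k
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                        type = "eps-regression", kernel = "radial",
                        cost = combos$cost[i], gamma = combos$gamma[i],
                        epsilon = epsilon, scale = FALSE)
      pr <- stats::predict(fit, x[!tr, , drop = FALSE])
      fold_mse[i, k] <- mean((pr - y[!tr])^2)
    }
  }
  cv_mse <- rowMeans(fold_mse)
  # order() above guarantees the smaller-cost-then-gamma tie-break
  best <- which.min(cv_mse)
  model <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                      cost = combos$cost[best], gamma = combos$gamma[best],
                      epsilon = epsilon, scale = FALSE)
  cv_table <- cbind(combos, mse = cv_mse, fold_mse)
  colnames(cv_table) <- c("cost", "gamma", "cv_mse",
                          paste0("fold", seq_len(folds)))
  structure(list(model = model,
                 feature_ids = colnames(x),
                 cost = combos$cost[best], gamma = combos$gamma[best],
                 epsilon = epsilon,
                 cv_table = cv_table,
                 cv_mse = cv_mse[best],
                 fold_assignment = fold_of,
                 folds = folds, seed = seed,
                 center = center, scale = scl,
                 n_train = n,
                 fitted = stats::predict(model, x),
                 y = y),
            class = "ic50_svr")
}

#' @export
print.ic50_svr <- function(x, ...) {
  cat(sprintf("ic50_svr: epsilon-SVR (RBF), %d feature(s), n = %d\n",
              length(x$feature_ids), x$n_train))
  cat(sprintf("  chosen cost = %g, gamma = %g, epsilon = %g (CV MSE %.4f, %d folds)\n",
              x$cost, x$gamma, x$epsilon, x$cv_mse, x$folds))
  invisible(x)
}

#' @export
summary.ic50_svr <- function(object, ...) {
  print(object)
  cat("grid search (mean CV MSE):\n")
  print(object$cv_table[, c("cost", "gamma", "cv_mse")], row.names = FALSE)
  invisible(object)
}

#' Predict IC50 for new samples
#'
#' @param object an `ic50_svr` model.
#' @param newdata numeric matrix whose columns include every model feature;
#'   columns are reordered to match the training matrix.
#' @param ... unused.
#' @return Numeric vector of predicted IC50 (ln uM), one per row.
#' @export
predict.ic50_svr <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, object$feature_ids))
  missing <- setdiff(object$feature_ids, colnames(newdata))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- newdata[, object$feature_ids, drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  unname(stats::predict(object$model, x))
}

#' @export
fitted.ic50_svr <- function(object, ...) unname(object$fitted)

#' @export
residuals.ic50_svr <- function(object, ...) unname(object$y - object$fitted)

#' Evaluate IC50 predictions
#'
#' Computes the global mean square error, root mean square error, Pearson
#' correlation and squared correlation between predicted and observed IC50,
#' plus a per-(cancer, drug) RMSE table. Cells with fewer than `min_cell`
#' samples are reported as `NA` rather than an unstable estimate.
#'
#' @param pred,truth numeric vectors of equal length (>= 2).
#' @param groups optional data.frame with columns `cancer` and `drug`
#'   (length-matched) for the per-group table.
#' @param min_cell minimum samples per (cancer, drug) cell (default 2).
#' @return An object of class `ic50_eval`: `global` (list with `n`, `mse`,
#'   `rmse`, `r`, `r2`) and `per_group` (data.frame or NULL).
#' @export
evaluate_predictions <- function(pred, truth, groups = NULL, min_cell = 2L) {
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ", call. = FALSE)
  if (length(pred) < 2L) stop("need >= 2 samples", call. = FALSE)
  mse <- mean((pred - truth)^2)
  r <- if (stats::sd(pred) == 0 || stats::sd(truth) == 0) NA_real_
       else stats::cor(pred, truth)
  per_group <- NULL
  if (!is.null(groups)) {
    stopifnot(all(c("cancer", "drug") %in% names(groups)),
              nrow(groups) == length(pred))
    cells <- unique(groups[c("cancer", "drug")])
    cells <- cells[order(cells$cancer, cells$drug), , drop = FALSE]
    per_group <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- groups$cancer == cells$cancer[i] & groups$drug == cells$drug[i]
      nn <- sum(sel)
      data.frame(cancer = cells$cancer[i], drug = cells$drug[i], n = nn,
                 rmse = if (nn >= min_cell)
                   sqrt(mean((pred[sel] - truth[sel])^2)) else NA_real_)
    }))
    rownames(per_group) <- NULL
  }
  structure(list(global = list(n = length(pred), mse = mse,
                               rmse = sqrt(mse), r = r, r2 = r^2),
                 per_group = per_group),
            class = "ic50_eval")
}

#' @export
print.ic50_eval <- function(x, ...) {
  g <- x$global
  cat(sprintf("ic50_eval: n = %d, RMSE = %.4f, r = %.4f, r^2 = %.4f\n",
              g$n, g$rmse, g$r, g$r2))
  if (!is.null(x$per_group)) {
    cat("per cancer x drug RMSE:\n")
    print(x$per_group, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.ic50_eval <- function(x, pred = NULL, truth = NULL, ...) {
  if (is.null(pred) || is.null(truth))
    stop("supply pred and truth vectors to plot", call. = FALSE)
  plot(truth, pred, xlab = "observed IC50 (ln uM)",
       ylab = "predicted IC50 (ln uM)",
       main = sprintf("r = %.3f, RMSE = %.3f", x$global$r, x$global$rmse), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(stats::lm(pred ~ truth), col = 2)
  invisible(x)
}

#' Full cross-dataset train/validate pipeline
#'
#' Runs the entire framework on two dataset bundles sharing a platform and
#' pathway set: calibrate ON/OFF mixtures on the training bundle's reference
#' compendium; transform both expression matrices into circuit activity
#' matrices with the frozen calibration; discard invariant circuits (on the
#' training data; the same columns are kept on validation); per shared drug,
#' optionally select features by CFS, train the SVR on the training bundle
#' and predict the validation bundle; pool predictions and evaluate.
#'
#' A bundle is a list with elements `expr` (features x samples matrix),
#' `response` (data.frame `sample_id`, `drug`, `cancer`, `ic50_ln_uM`),
#' `platform_map` (`probeset_id`, `gene_id`), `pathways` (list of
#' [pathway_graph()]), and for the training bundle `reference`
#' (features x arrays matrix), e.g. as produced by [make_bundle()] or
#' [read_bundle()].
#'
#' @param train,validate dataset bundles.
#' @param grid,folds,epsilon,seed passed to [train_predictor()].
#' @param use_cfs run CFS feature selection (default TRUE); FALSE uses all
#'   variable circuits (the "CFS skipped" configuration).
#' @param rule,mode probability combination and inhibitor semantics.
#' @param invariant_tol range tolerance for [filter_invariant()].
#' @param out_dir optional directory: every intermediate (calibrations,
#'   activity matrices, selections, predictions, evaluation, manifest) is
#'   written there as TSV/JSON.
#' @return list with `evaluation` (pooled [evaluate_predictions()] report),
#'   `models` (per-drug `ic50_svr`), `selections` (per-drug), `predictions`
#'   (data.frame), `activity_train`, `activity_validate`, `calibrations`,
#'   `discarded_invariant`.
#' @export
cross_dataset_run <- function(train, validate, grid = default_svr_grid(),
                              folds = 10L, epsilon = 0.1, seed = 1L,
                              use_cfs = TRUE, rule = "union",
                              mode = "context", invariant_tol = 1e-6,
                              out_dir = NULL) {
  drugs <- intersect(unique(train$response$drug),
                     unique(validate$response$drug))
  if (length(drugs) == 0L)
    stop("train and validate share no drugs", call. = FALSE)
  drugs <- sort(drugs)

  cals <- fit_calibrations(train$reference)
  act_tr <- activity_matrix(
    gene_probabilities(probeset_probabilities(train$expr, cals),
                       train$platform_map, rule = rule),
    train$pathways, rule = rule, mode = mode)
  act_va <- activity_matrix(
    gene_probabilities(probeset_probabilities(validate$expr, cals),
                       validate$platform_map, rule = rule),
    validate$pathways, rule = rule, mode = mode)

  flt <- filter_invariant(act_tr, tol = invariant_tol)
  act_tr <- flt$activity
  act_va <- act_va[, colnames(act_tr), drop = FALSE]

  models <- list(); selections <- list(); preds <- list()
  for (d in drugs) {
    rtr <- train$response[train$response$drug == d, ]
    rva <- validate$response[validate$response$drug == d, ]
    xtr <- act_tr[rtr$sample_id, , drop = FALSE]
    xva <- act_va[rva$sample_id, , drop = FALSE]
    feats <- colnames(xtr)
    if (use_cfs) {
      sel <- cfs_select(xtr, rtr$ic50_ln_uM,
                        n_discarded_invariant = length(flt$discarded))
      if (length(sel$selected)) feats <- sel$selected
      selections[[d]] <- sel
    }
    fit <- train_predictor(xtr[, feats, drop = FALSE], rtr$ic50_ln_uM,
                           grid = grid, folds = folds, seed = seed,
                           epsilon = epsilon)
    models[[d]] <- fit
    preds[[d]] <- data.frame(sample_id = rva$sample_id, drug = d,
                             cancer = rva$cancer,
                             truth = rva$ic50_ln_uM,
                             pred = predict(fit, xva))
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  evaluation <- evaluate_predictions(predictions$pred, predictions$truth,
                                     groups = predictions[c("cancer", "drug")])

  result <- list(evaluation = evaluation, models = models,
                 selections = selections, predictions = predictions,
                 activity_train = act_tr, activity_validate = act_va,
                 calibrations = cals,
                 discarded_invariant = flt$discarded)
  if (!is.null(out_dir)) .write_run_artifacts(result, out_dir)
  result
}

.write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_calibrations(result$calibrations,
                     file.path(out_dir, "calibrations.tsv"))
  write_activity_matrix(result$activity_train,
                        file.path(out_dir, "activity_train.tsv"))
  write_activity_matrix(result$activity_validate,
                        file.path(out_dir, "activity_validate.tsv"))
  utils::write.table(result$predictions,
                     file.path(out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (d in names(result$selections))
    write_selection_report(result$selections[[d]],
                           file.path(out_dir, paste0("selection_", d, ".tsv")))
  ev <- result$evaluation
  jsonlite::write_json(list(global = ev$global, per_group = ev$per_group),
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    files = sort(list.files(out_dir)),
    drugs = names(result$models),
    n_circuits = ncol(result$activity_train),
    discarded_invariant = result$discarded_invariant,
    chosen = lapply(result$models, function(m)
      list(cost = m$cost, gamma = m$gamma, cv_mse = m$cv_mse)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
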