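#' @title Target-specific machine-learning scoring functions
#' @description One fitting interface over five supervised learning
#'   algorithms — random forest (RF), extreme gradient boosting (XGB),
#'   support vector machine (SVM), single-hidden-layer neural network
#'   (ANN) and multi-hidden-layer network (DNN) — each in a binary
#'   classification and a regression variant. Classification models score
#'   a complex by the probability of activity; regression models by the
#'   predicted pIC50. In both modes higher scores rank better.
#' @name sf-models
NULL

SF_ALGORITHMS <- c("RF", "XGB", "SVM", "ANN", "DNN")

.check_xy <- function(x, y, mode) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  bad <- which(!stats::complete.cases(x) | apply(x, 1, function(r) any(!is.finite(r))))
  if (length(bad) > 0)
    stop("non-finite feature values in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (mode == "classification") {
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop("classification labels must be 0/1")
    if (length(unique(y)) < 2) stop("degenerate labels: single class")
  } else {
    if (any(!is.finite(y))) stop("non-finite regression targets")
  }
  list(x = x, y = y)
}

#' Default hyperparameter search space for an algorithm/mode pair
#'
#' The axes mirror the usual tuning dimensions of each learner (tree
#' counts and depths for RF/XGB; cost, kernel width and kernel for SVM;
#' layer sizes, weight decay or dropout and learning rate for ANN/DNN);
#' the exact ranges are this package's documented defaults. Most axes are
#' shared between modes; mode-specific entries (the SVM regression
#' epsilon) appear only for that mode.
#'
#' @param algorithm one of `"RF"`, `"XGB"`, `"SVM"`, `"ANN"`, `"DNN"`.
#' @param mode `"classification"` or `"regression"`.
#' @return named list of [hp()] axes.
#' @export
search_space <- function(algorithm,
                         mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  if (!algorithm %in% SF_ALGORITHMS)
    stop("unknown algorithm: ", algorithm)
  switch(algorithm,
    RF = list(
      ntree = hp("quniform", 100, 1000, q = 100),
      mtry_frac = hp("uniform", 0.05, 1),
      nodesize = hp("quniform", 1, 10, q = 1)),
    XGB = list(
      nrounds = hp("quniform", 50, 500, q = 50),
      eta = hp("loguniform", 0.01, 0.3),
      max_depth = hp("quniform", 3, 10, q = 1),
      subsample = hp("uniform", 0.5, 1),
      colsample_bytree = hp("uniform", 0.3, 1)),
    SVM = c(list(
      cost = hp("loguniform", 1e-2, 1e3),
      gamma = hp("loguniform", 1e-5, 1),
      kernel = hp("choice", values = list("radial", "linear"))),
      if (mode == "regression") list(epsilon = hp("uniform", 0.01, 0.5))),
    ANN = list(
      size = hp("quniform", 4, 64, q = 4),
      decay = hp("loguniform", 1e-5, 1e-1),
      maxit = hp("quniform", 100, 300, q = 100)),
    DNN = list(
      units = hp("quniform", 16, 128, q = 16),
      n_layers = hp("choice", values = list(2L, 3L)),
      lr = hp("loguniform", 1e-4, 1e-2),
      dropout = hp("uniform", 0, 0.5),
      epochs = hp("quniform", 30, 90, q = 30)))
}

.default_hp <- function(algorithm, mode) {
  switch(algorithm,
    RF = list(ntree = 500, mtry_frac = if (mode == "classification") NA else NA,
              nodesize = if (mode == "classification") 1 else 5),
    XGB = list(nrounds = 200, eta = 0.1, max_depth = 6, subsample = 1,
               colsample_bytree = 1),
    SVM = c(list(cost = 1, gamma = NA, kernel = "radial"),
            if (mode == "regression") list(epsilon = 0.1)),
    ANN = list(size = 16, decay = 1e-3, maxit = 200),
    DNN = list(units = 64, n_layers = 2L, lr = 1e-3, dropout = 0.1,
               epochs = 60))
}

#' Fit a target-specific scoring function
#'
#' @param x numeric feature matrix (rows = complexes/molecules; any of
#'   the package's featurization schemes, see [feature_matrix()]).
#' @param y response: 0/1 activity labels (classification) or pIC50
#'   values with inactives at 2.0 (regression).
#' @param algorithm one of `"RF"`, `"XGB"`, `"SVM"`, `"ANN"`, `"DNN"`.
#' @param mode `"classification"` or `"regression"`.
#' @param hyperparams named list of hyperparameters (see
#'   [search_space()]); unspecified entries take package defaults.
#' @param seed integer seed; given the seed, fitting is reproducible.
#' @return object of class `sf_model` with [predict.sf_model()],
#'   [print.sf_model()] and [summary.sf_model()] methods.
#' @export
sf_model <- function(x, y, algorithm,
                     mode = c("classification", "regression"),
                     hyperparams = list(), seed = 1) {
  mode <- match.arg(mode)
  if (!algorithm %in% SF_ALGORITHMS) stop("unknown algorithm: ", algorithm)
  chk <- .check_xy(x, y, mode)
  x <- chk$x; y <- chk$y
  hp_full <- utils::modifyList(.default_hp(algorithm, mode), hyperparams)
  set.seed(seed)
  fit <- switch(algorithm,
    RF = {
      mtry <- if (is.na(hp_full$mtry_frac %||% NA)) {
        if (mode == "classification") max(1, floor(sqrt(ncol(x))))
        else max(1, floor(ncol(x) / 3))
      } else max(1, floor(hp_full$mtry_frac * ncol(x)))
      yy <- if (mode == "classification") factor(y, levels = c(0, 1)) else y
      randomForest::randomForest(
        x = x, y = yy, ntree = hp_full$ntree, mtry = mtry,
        nodesize = hp_full$nodesize)
    },
    XGB = {
      obj <- if (mode == "classification") "binary:logistic"
             else "reg:squarederror"
      yy <- if (mode == "classification") factor(y, levels = c(0, 1)) else y
      xgboost::xgboost(
        x = x, y = yy, objective = obj, nrounds = hp_full$nrounds,
        learning_rate = hp_full$eta, max_depth = hp_full$max_depth,
        subsample = hp_full$subsample,
        colsample_bytree = hp_full$colsample_bytree,
        nthreads = 1, seed = seed)
    },
    SVM = {
      gam <- if (is.na(hp_full$gamma %||% NA)) 1 / ncol(x) else hp_full$gamma
      # fingerprint features are binary/counts; per-column standardization
      # is meaningless for near-constant bits, so scaling is disabled
      if (mode == "classification") {
        e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                   type = "C-classification", kernel = hp_full$kernel,
                   cost = hp_full$cost, gamma = gam, probability = TRUE,
                   scale = FALSE)
      } else {
        e1071::svm(x = x, y = y, type = "eps-regression",
                   kernel = hp_full$kernel, cost = hp_full$cost,
                   gamma = gam, epsilon = hp_full$epsilon, scale = FALSE)
      }
    },
    ANN = {
      nnet::nnet(x = x, y = if (mode == "classification") y else y,
                 size = hp_full$size, decay = hp_full$decay,
                 maxit = hp_full$maxit, trace = FALSE,
                 linout = mode == "regression",
                 entropy = mode == "classification",
                 MaxNWts = (ncol(x) + 2) * hp_full$size + hp_full$size + 10)
    },
    DNN = {
      mlp_fit(x, y, hidden = rep(hp_full$units, hp_full$n_layers),
              mode = mode, lr = hp_full$lr, epochs = hp_full$epochs,
              dropout = hp_full$dropout, seed = seed)
    })
  structure(list(algorithm = algorithm, mode = mode, fit = fit,
                 hyperparams = hp_full, seed = seed, p = ncol(x),
                 n_train = nrow(x),
                 class_balance = if (mode == "classification")
                   mean(y) else NA_real_),
            class = "sf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score new complexes with a fitted scoring function
#'
#' @param object an `sf_model`.
#' @param newdata feature matrix with the training column count.
#' @param ... unused.
#' @return numeric scores: probability of activity in `[0, 1]`
#'   (classification) or predicted pIC50 (regression); higher = better.
#' @export
predict.sf_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$p)
    stop(sprintf("feature count mismatch: model has %d, data has %d",
                 object$p, ncol(x)))
  scores <- switch(object$algorithm,
    RF = {
      if (object$mode == "classification")
        stats::predict(object$fit, x, type = "prob")[, "1"]
      else as.numeric(stats::predict(object$fit, x))
    },
    XGB = as.numeric(stats::predict(object$fit, x)),
    SVM = {
      if (object$mode == "classification") {
        pr <- tryCatch(
          attr(stats::predict(object$fit, x, probability = TRUE),
               "probabilities")[, "1"],
          error = function(e) NULL)
        if (is.null(pr)) {
          # probability calibration unavailable (tiny training folds):
          # squash the decision values instead; the column label "a/b"
          # says positive values favor class a
          dv <- attr(stats::predict(object$fit, x, decision.values = TRUE),
                     "decision.values")
          sgn <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
          pr <- stats::plogis(sgn * dv[, 1])
        }
        pr
      } else as.numeric(stats::predict(object$fit, x))
    },
    ANN = as.numeric(stats::predict(object$fit, x)),
    DNN = stats::predict(object$fit, x))
  unname(scores)
}

#' @export
print.sf_model <- function(x, ...) {
  cat(sprintf("<sf_model %s/%s: %d features, %d training rows, seed %d>\n",
              x$algorithm, x$mode, x$p, x$n_train, x$seed))
  invisible(x)
}

#' @export
summary.sf_model <- function(object, ...) {
  cat(sprintf("Target-specific scoring function (%s, %s mode)\n",
              object$algorithm, object$mode))
  cat(sprintf("  features: %d   training rows: %d   seed: %d\n",
              object$p, object$n_train, object$seed))
  if (!is.na(object$class_balance))
    cat(sprintf("  training active fraction: %.3f\n", object$class_balance))
  cat("  hyperparameters:\n")
  for (nm in names(object$hyperparams)) {
    cat(sprintf("    %-18s %s\n", nm,
                paste(format(object$hyperparams[[nm]]), collapse = ", ")))
  }
  invisible(object)
}

# Deterministic k-fold assignment
.cv_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Cross-validated tuning objective
#'
#' The statistical assessment error minimized during tuning: one minus
#' the precision-recall AUC for classification, RMSE for regression,
#' averaged over folds.
#'
#' @param x,y training data.
#' @param algorithm,mode learner selection.
#' @param hyperparams hyperparameter list to assess.
#' @param folds number of CV folds (default 5).
#' @param seed seed controlling fold assignment and fits.
#' @return scalar loss.
#' @export
cv_objective <- function(x, y, algorithm, mode, hyperparams,
                         folds = 5, seed = 1) {
  stopifnot(folds >= 2)
  x <- as.matrix(x)
  fold <- .cv_folds(nrow(x), folds, seed)
  losses <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    if (mode == "classification" && length(unique(y[tr])) < 2) return(NA_real_)
    m <- sf_model(x[tr, , drop = FALSE], y[tr], algorithm, mode,
                  hyperparams, seed = seed)
    s <- predict(m, x[!tr, , drop = FALSE])
    if (mode == "classification") {
      if (sum(y[!tr]) == 0) return(NA_real_)
      sc <- rank_screen(s, y[!tr])
      1 - pr_curve(sc)$auc
    } else {
      sqrt(mean((s - y[!tr])^2))
    }
  }, numeric(1))
  mean(losses, na.rm = TRUE)
}

#' Tune a scoring function with TPE over its search space
#'
#' Five-fold cross-validated TPE minimization of [cv_objective()].
#'
#' @inheritParams cv_objective
#' @param space search space; defaults to [search_space()] for the pair.
#' @param max_evals objective evaluations (default 50).
#' @return list with `best` hyperparameters, `best_loss` and the full
#'   `trace`.
#' @export
tune_sf <- function(x, y, algorithm,
                    mode = c("classification", "regression"),
                    space = NULL, folds = 5, max_evals = 50, seed = 1) {
  mode <- match.arg(mode)
  chk <- .check_xy(x, y, mode)
  if (is.null(space)) space <- search_space(algorithm, mode)
  tpe_optimize(function(cfg) {
    cv_objective(chk$x, chk$y, algorithm, mode, cfg,
                 folds = folds, seed = seed)
  }, space, max_evals = max_evals, seed = seed)
}

#' Repeated training-test runs of one scoring function
#'
#' Fits the same algorithm/mode/hyperparameter combination `n_runs` times
#' with seeds `base_seed .. base_seed + n_runs - 1` on a fixed split,
#' scores the test set each time, and records the per-run NEF. The
#' reported summary is the median NEF across runs, and
#' [select_median_run()] picks the representative run.
#'
#' @param train_x,train_y training data.
#' @param test_x test feature matrix.
#' @param test_labels logical/0-1 test activity labels (true actives vs
#'   everything else; decoys and confirmed inactives are pooled).
#' @param algorithm,mode,hyperparams learner specification.
#' @param n_runs number of runs (default 10).
#' @param base_seed first seed (default 1).
#' @param f enrichment fraction (default 0.01).
#' @return object of class `sf_runs`: list of per-run results plus
#'   `nef_values`, `median_nef`, and `median_run` (index).
#' @export
repeat_runs <- function(train_x, train_y, test_x, test_labels,
                        algorithm, mode, hyperparams = list(),
                        n_runs = 10, base_seed = 1, f = 0.01) {
  stopifnot(n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(r) {
    seed <- base_seed + r - 1
    m <- sf_model(train_x, train_y, algorithm, mode, hyperparams,
                  seed = seed)
    s <- predict(m, test_x)
    screen <- rank_screen(s, test_labels)
    list(run_index = r, seed = seed, model = m, scores = s,
         nef = nef_fraction(screen, f), ef = ef_fraction(screen, f))
  })
  nefs <- vapply(runs, `[[`, numeric(1), "nef")
  structure(list(runs = runs, nef_values = nefs,
                 median_nef = stats::median(nefs),
                 median_run = select_median_run(nefs, tie_seed = base_seed),
                 algorithm = algorithm, mode = mode, f = f),
            class = "sf_runs")
}

#' @export
print.sf_runs <- function(x, ...) {
  cat(sprintf("<sf_runs %s/%s: %d runs, median NEF%g%% = %.3f>\n",
              x$algorithm, x$mode, length(x$runs), 100 * x$f,
              x$median_nef))
  invisible(x)
}

#' Build a feature matrix for a set of complexes or molecules
#'
#' Applies one featurization scheme to each input and stacks the vectors.
#'
#' @param objects list of `pl_complex` (schemes `"PLEC"`, `"GRID"`,
#'   `"COMBINED"`) or `mol_graph` (scheme `"MORGAN"`). For complex-based
#'   schemes the ligand is taken from the complex.
#' @param scheme `"MORGAN"`, `"PLEC"`, `"GRID"`, or `"COMBINED"`
#'   (Morgan 512 then PLEC 4092, total 4604).
#' @param ... passed to the underlying featurizer.
#' @return numeric matrix, one row per input.
#' @export
feature_matrix <- function(objects,
                           scheme = c("PLEC", "GRID", "MORGAN", "COMBINED"),
                           ...) {
  scheme <- match.arg(scheme)
  rows <- lapply(objects, function(obj) {
    switch(scheme,
      MORGAN = morgan_fp(if (inherits(obj, "pl_complex")) obj$ligand else obj,
                         ...)$values,
      PLEC = plec_fp(obj, ...)$values,
      GRID = grid_features(obj, ...)$values,
      COMBINED = concat_features(morgan_fp(obj$ligand), plec_fp(obj, ...))$values)
  })
  do.call(rbind, rows)
}
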