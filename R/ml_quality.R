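#' Classifier specification
#'
#' The five classifier families compared by the package. Each family carries
#' a small deterministic hyperparameter grid searched by inner
#' cross-validation:
#' \itemize{
#'   \item `binary_tree`: CART; max depth \{2, 4, 8, none\} x min leaf
#'     \{1, 5, 20\}.
#'   \item `svm`: primal squared-hinge SVM; kernel \{linear, radial\} x cost
#'     \{0.1, 1, 10\} (features standardised inside each training split).
#'   \item `ensemble_bag`: bagged CART trees (all features at every split);
#'     trees \{100, 300\} x min leaf \{1, 5, 20\}.
#'   \item `random_forest`: bagged CART trees with per-split feature
#'     subsampling (mtry = floor(sqrt(d))); same grid as `ensemble_bag`.
#'   \item `logistic_regression`: ridge-penalised logistic regression; L2
#'     strength \{0.01, 0.1, 1, 10\}.
#' }
#'
#' @param family one of `"binary_tree"`, `"svm"`, `"ensemble_bag"`,
#'   `"random_forest"`, `"logistic_regression"`.
#' @param grid optional `data.frame` overriding the default grid.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("binary_tree", "svm", "ensemble_bag",
                                       "random_forest", "logistic_regression"),
                            grid = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    qc_abort("hyperparameter grid must be a non-empty data.frame", "dscqc_invalid_grid")
  structure(list(family = family, grid = grid), class = "classifier_spec")
}

default_grid <- function(family) {
  switch(family,
    binary_tree = expand.grid(max_depth = c(2L, 4L, 8L, 30L),
                              min_leaf = c(1L, 5L, 20L)),
    svm = expand.grid(kernel = c("linear", "radial"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    ensemble_bag = expand.grid(n_tree = c(100L, 300L), min_leaf = c(1L, 5L, 20L)),
    random_forest = expand.grid(n_tree = c(100L, 300L), min_leaf = c(1L, 5L, 20L)),
    logistic_regression = data.frame(lambda = c(0.01, 0.1, 1, 10)),
    qc_abort(sprintf("unknown family '%s'", family), "dscqc_unknown_family")
  )
}

predictor_columns <- c("sdnr", "rmse_norm", "fwhm_s", "psr_pct")

feature_matrix <- function(table, predictors) {
  missing <- setdiff(predictors, names(table))
  if (length(missing))
    qc_abort(paste("model/feature schema mismatch: missing", paste(missing, collapse = ", ")),
             "dscqc_schema_mismatch")
  as.matrix(table[, predictors, drop = FALSE])
}

## ---- family back-ends -------------------------------------------------

standardise_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
standardise_apply <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")

# Primal squared-hinge SVM. Linear: parameters (w, b); radial: kernel
# expansion coefficients alpha over the training rows plus intercept, with
# gamma = 1 / n_features on standardised inputs. Solved with L-BFGS on the
# smooth squared-hinge objective; deterministic (zero start).
svm_fit <- function(X, y, kernel, cost) {
  yy <- ifelse(y == 1L, 1, -1)
  n <- nrow(X); d <- ncol(X)
  if (kernel == "linear") {
    obj <- function(par) {
      w <- par[1:d]; b <- par[d + 1L]
      f <- drop(X %*% w) + b
      s <- pmax(0, 1 - yy * f)
      0.5 * sum(w * w) + cost * sum(s * s)
    }
    grad <- function(par) {
      w <- par[1:d]; b <- par[d + 1L]
      f <- drop(X %*% w) + b
      s <- pmax(0, 1 - yy * f)
      gy <- -2 * cost * yy * s
      c(w + drop(crossprod(X, gy)), sum(gy))
    }
    fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 1000L))
    list(kernel = "linear", w = fit$par[1:d], b = fit$par[d + 1L])
  } else {
    gamma <- 1 / d
    K <- rbf_kernel(X, X, gamma)
    obj <- function(par) {
      a <- par[1:n]; b <- par[n + 1L]
      Ka <- drop(K %*% a)
      s <- pmax(0, 1 - yy * (Ka + b))
      0.5 * sum(a * Ka) + cost * sum(s * s)
    }
    grad <- function(par) {
      a <- par[1:n]; b <- par[n + 1L]
      Ka <- drop(K %*% a)
      s <- pmax(0, 1 - yy * (Ka + b))
      gy <- -2 * cost * yy * s
      c(Ka + drop(K %*% gy), sum(gy))
    }
    fit <- stats::optim(rep(0, n + 1L), obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 1000L))
    list(kernel = "radial", alpha = fit$par[1:n], b = fit$par[n + 1L],
         gamma = gamma, X_train = X)
  }
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

svm_decision <- function(model, X) {
  if (model$kernel == "linear") drop(X %*% model$w) + model$b
  else drop(rbf_kernel(X, model$X_train, model$gamma) %*% model$alpha) + model$b
}

fit_family <- function(family, X, y, params, seed) {
  switch(family,
    binary_tree = list(tree = .cart_fit(X, as.integer(y),
                                        as.integer(params$max_depth),
                                        as.integer(params$min_leaf))),
    ensemble_bag = list(forest = .forest_fit(X, as.integer(y),
                                             as.integer(params$n_tree), 30L,
                                             as.integer(params$min_leaf),
                                             ncol(X), as.integer(seed)),
                        n_tree = as.integer(params$n_tree)),
    random_forest = list(forest = .forest_fit(X, as.integer(y),
                                              as.integer(params$n_tree), 30L,
                                              as.integer(params$min_leaf),
                                              max(1L, floor(sqrt(ncol(X)))),
                                              as.integer(seed)),
                         n_tree = as.integer(params$n_tree)),
    svm = {
      sc <- standardise_fit(X)
      m <- svm_fit(standardise_apply(X, sc), y, params$kernel, params$cost)
      m$scaling <- sc
      m
    },
    logistic_regression = list(
      fit = glmnet::glmnet(X, factor(y, levels = 0:1), family = "binomial",
                           alpha = 0, lambda = as.numeric(params$lambda),
                           standardize = TRUE),
      lambda = as.numeric(params$lambda)
    ),
    qc_abort(sprintf("unknown family '%s'", family), "dscqc_unknown_family")
  )
}

predict_scores_family <- function(family, model, X) {
  switch(family,
    binary_tree = .cart_predict(model$tree, X),
    ensemble_bag = .forest_predict(model$forest, X, model$n_tree),
    random_forest = .forest_predict(model$forest, X, model$n_tree),
    svm = stats::plogis(svm_decision(model, standardise_apply(X, model$scaling))),
    logistic_regression = if (isTRUE(model$raw_coef)) {
      as.numeric(stats::plogis(cbind(1, X) %*% model$beta))
    } else {
      as.numeric(stats::predict(model$fit, newx = X, s = model$lambda,
                                type = "response"))
    }
  )
}

# When the forest grid varies the tree count with everything else fixed, a
# single fit at the maximum count serves every smaller count via prefix
# prediction. Returns per-grid-row mean inner-CV AUC.
inner_cv_auc <- function(family, grid, X, y, k_inner, seed) {
  fold <- make_stratified_folds(y, k_inner, seed)
  fold_seeds <- derive_seeds(seed, k_inner)
  auc <- matrix(NA_real_, nrow(grid), k_inner)
  forest_family <- family %in% c("ensemble_bag", "random_forest")
  for (f in seq_len(k_inner)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    if (forest_family) {
      for (ml in unique(grid$min_leaf)) {
        rows <- which(grid$min_leaf == ml)
        nmax <- max(grid$n_tree[rows])
        model <- fit_family(family, Xtr, ytr,
                            list(n_tree = nmax, min_leaf = ml), fold_seeds[f])
        for (r in rows) {
          sc <- .forest_predict(model$forest, Xte, as.integer(grid$n_tree[r]))
          auc[r, f] <- safe_auc(sc, yte)
        }
      }
    } else {
      for (r in seq_len(nrow(grid))) {
        model <- fit_family(family, Xtr, ytr, as.list(grid[r, , drop = FALSE]),
                            fold_seeds[f])
        auc[r, f] <- safe_auc(predict_scores_family(family, model, Xte), yte)
      }
    }
  }
  rowMeans(auc, na.rm = TRUE)
}

safe_auc <- function(scores, labels) {
  tryCatch(roc_auc(scores, labels), dscqc_error = function(e) NA_real_)
}

#' Train a quality classifier with nested cross-validation
#'
#' Outer stratified k-fold cross-validation reports honest performance; inside
#' each outer training split, hyperparameters are chosen from the family's
#' grid by inner 5-fold cross-validation maximising AUC (ties broken by grid
#' order), the model refitted on the full training split, and metrics computed
#' on the held-out fold. The deliverable model is refitted on all rows with
#' the modal hyperparameters across outer folds.
#'
#' @param table feature table with predictor columns `sdnr`, `rmse_norm`,
#'   `fwhm_s`, `psr_pct` and binary `qr_label`. Rows with missing predictor
#'   values are dropped with a warning.
#' @param spec a [classifier_spec()].
#' @param k outer fold count (default 10).
#' @param seed integer seed; threads deterministically into fold shuffles,
#'   bootstrap resampling and the inner search.
#' @param k_inner inner fold count for the grid search (default 5).
#' @param predictors predictor column names.
#' @return an object of class `dsc_classifier`: `model`, `family`,
#'   `params` (modal hyperparameters), `predictors`, `report` (a `cv_report`
#'   with `per_fold` metrics, `mean` metrics, per-fold chosen
#'   hyperparameters and `k`), `fingerprint` of the training data, `seed`.
#' @export
train_classifier <- function(table, spec, k = 10L, seed = 1L, k_inner = 5L,
                             predictors = predictor_columns) {
  stopifnot(inherits(spec, "classifier_spec"), "qr_label" %in% names(table))
  X <- feature_matrix(table, predictors)
  y <- as.integer(as.logical(table$qr_label))
  ok <- stats::complete.cases(X) & !is.na(y)
  if (!all(ok)) {
    warning(sprintf("dropping %d rows with missing predictors", sum(!ok)))
    X <- X[ok, , drop = FALSE]; y <- y[ok]
  }
  if (min(table(factor(y, levels = 0:1))) < k)
    qc_abort("insufficient data: each class needs >= k members", "dscqc_insufficient_class")

  fold <- make_stratified_folds(y, k, seed)
  seeds <- derive_seeds(seed, 2L * k + 1L)
  grid <- spec$grid

  per_fold <- vector("list", k)
  chosen <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    mean_auc <- inner_cv_auc(spec$family, grid, Xtr, ytr, k_inner, seeds[f])
    best <- which.max(mean_auc)           # ties: first grid row
    params <- as.list(grid[best, , drop = FALSE])
    model <- fit_family(spec$family, Xtr, ytr, params, seeds[k + f])
    scores <- predict_scores_family(spec$family, model, Xte)
    pred <- as.integer(scores >= 0.5)
    ms <- binary_metrics(confusion_table(pred, yte))
    ms$auc <- safe_auc(scores, yte)
    per_fold[[f]] <- data.frame(
      fold = f, sensitivity = ms$sensitivity, specificity = ms$specificity,
      precision = ms$precision, classification_error = ms$classification_error,
      auc = ms$auc)
    chosen[[f]] <- params
  }
  per_fold <- do.call(rbind, per_fold)
  mean_row <- colMeans(per_fold[, -1L], na.rm = TRUE)

  # modal hyperparameters: most frequent chosen grid row, ties by grid order
  keys <- vapply(chosen, function(p) paste(unlist(p), collapse = "|"), character(1L))
  grid_keys <- vapply(seq_len(nrow(grid)),
                      function(r) paste(unlist(as.list(grid[r, , drop = FALSE])), collapse = "|"),
                      character(1L))
  counts <- vapply(grid_keys, function(gk) sum(keys == gk), integer(1L))
  modal <- as.list(grid[which.max(counts), , drop = FALSE])

  model <- fit_family(spec$family, X, y, modal, seeds[2L * k + 1L])
  structure(
    list(model = model, family = spec$family, params = modal,
         predictors = predictors,
         report = structure(list(per_fold = per_fold, mean = as.list(mean_row),
                                 chosen = chosen, k = k), class = "cv_report"),
         fingerprint = data_fingerprint(X, y), seed = seed),
    class = "dsc_classifier"
  )
}

data_fingerprint <- function(X, y) {
  sprintf("n=%d;d=%d;pos=%d;sum=%.6g", nrow(X), ncol(X), sum(y), sum(X))
}

#' @export
print.dsc_classifier <- function(x, ...) {
  cat(sprintf("<dsc_classifier: %s (%s), outer-CV error %.1f%%, AUC %.3f>\n",
              x$family, paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
              x$report$mean$classification_error, x$report$mean$auc))
  invisible(x)
}

#' Predict quality for feature rows
#'
#' Invalid feature rows (flagged invalid or missing a predictor) fail with
#' their reason; they are never silently dropped.
#'
#' @param object a fitted `dsc_classifier`.
#' @param features a feature table ([feature_table()]).
#' @param ... unused.
#' @return a `data.frame` with `pass` (logical), `score` in `[0, 1]`
#'   (`NA` for invalid rows) and `reason`.
#' @export
predict_quality <- function(object, features, ...) {
  stopifnot(inherits(object, "dsc_classifier"))
  X <- feature_matrix(features, object$predictors)
  ok <- stats::complete.cases(X)
  if ("valid" %in% names(features)) ok <- ok & features$valid
  score <- rep(NA_real_, nrow(X))
  if (any(ok))
    score[ok] <- predict_scores_family(object$family, object$model,
                                       X[ok, , drop = FALSE])
  reason <- rep("", nrow(X))
  reason[!ok] <- if ("reason" %in% names(features))
    ifelse(nzchar(features$reason[!ok]), features$reason[!ok], "missing predictor")
  else "missing predictor"
  data.frame(pass = !is.na(score) & score >= 0.5, score = score,
             reason = reason, stringsAsFactors = FALSE)
}

#' @export
predict.dsc_classifier <- function(object, newdata, ...) predict_quality(object, newdata)

#' Compare classifier families under identical cross-validation
#'
#' Runs [train_classifier()] for each spec on the same table, folds seeded
#' identically, and reports one row of mean outer-CV metrics per family. The
#' winner is the family with the lowest classification error; ties are broken
#' by higher AUC, then alphabetically.
#'
#' @param table labelled feature table (see [train_classifier()]).
#' @param specs list of [classifier_spec()] objects (at least 2).
#' @param k outer fold count.
#' @param seed integer seed.
#' @param ... passed to [train_classifier()].
#' @return a list (class `classifier_comparison`): `table` (one row per
#'   family: sensitivity, specificity, precision, classification error %,
#'   AUC), `winner`, `models` (named list of fitted classifiers).
#' @export
compare_classifiers <- function(table, specs, k = 10L, seed = 1L, ...) {
  if (!is.list(specs) || length(specs) < 2L)
    qc_abort("need at least 2 classifier specs to compare", "dscqc_too_few_specs")
  models <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    fit <- train_classifier(table, sp, k = k, seed = seed, ...)
    models[[i]] <- fit
    names(models)[i] <- sp$family
    m <- fit$report$mean
    rows[[i]] <- data.frame(
      family = sp$family, sensitivity = m$sensitivity,
      specificity = m$specificity, precision = m$precision,
      classification_error = m$classification_error, auc = m$auc,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(tab$classification_error, -tab$auc, tab$family)
  winner <- tab$family[ord[1L]]
  structure(list(table = tab, winner = winner, models = models),
            class = "classifier_comparison")
}

#' @export
print.classifier_comparison <- function(x, ...) {
  print(x$table, digits = 3)
  cat(sprintf("lowest classification error: %s\n", x$winner))
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' Serialised as JSON with a schema version, feature names, family,
#' hyperparameters and a fingerprint of the training data. Tree and forest
#' models store their flattened node tables; SVM and logistic models their
#' coefficients.
#'
#' @param object a `dsc_classifier`.
#' @param path file path.
#' @return `path` invisibly / the restored classifier.
#' @export
write_classifier <- function(object, path) {
  stopifnot(inherits(object, "dsc_classifier"))
  model <- object$model
  ser <- switch(object$family,
    binary_tree = list(tree = unclass(model$tree)),
    ensemble_bag = ,
    random_forest = list(forest = lapply(model$forest, unclass),
                         n_tree = model$n_tree),
    svm = model[setdiff(names(model), "")],
    logistic_regression = list(
      beta = as.numeric(stats::coef(model$fit, s = model$lambda)),
      lambda = model$lambda)
  )
  out <- list(schema = 1L, family = object$family, params = object$params,
              predictors = object$predictors, fingerprint = object$fingerprint,
              seed = object$seed, model = ser)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema) || x$schema != 1L)
    qc_abort("unsupported classifier schema", "dscqc_schema_mismatch")
  model <- switch(x$family,
    binary_tree = list(tree = fix_tree_matrix(x$model$tree)),
    ensemble_bag = ,
    random_forest = list(forest = lapply(x$model$forest, fix_tree_matrix),
                         n_tree = as.integer(x$model$n_tree)),
    svm = restore_svm(x$model),
    logistic_regression = list(beta = as.numeric(x$model$beta),
                               lambda = as.numeric(x$model$lambda),
                               raw_coef = TRUE)
  )
  structure(
    list(model = model, family = x$family, params = as.list(x$params),
         predictors = as.character(x$predictors), report = NULL,
         fingerprint = x$fingerprint, seed = x$seed),
    class = "dsc_classifier"
  )
}

fix_tree_matrix <- function(m) {
  m <- as.matrix(m)
  colnames(m) <- c("feature", "threshold", "left", "right", "prob", "n")
  m
}

restore_svm <- function(m) {
  out <- list(kernel = m$kernel, b = as.numeric(m$b),
              scaling = list(mu = as.numeric(m$scaling$mu),
                             sd = as.numeric(m$scaling$sd)))
  if (m$kernel == "linear") {
    out$w <- as.numeric(m$w)
  } else {
    out$alpha <- as.numeric(m$alpha)
    out$gamma <- as.numeric(m$gamma)
    out$X_train <- as.matrix(m$X_train)
  }
  out
}
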