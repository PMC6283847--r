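#' Fit a support-vector regression model for RRV prediction
#'
#' Fits an epsilon-SVR on ln(RRV) against the encoded feature matrix of an
#' [rrv_dataset()]. The target is ln-transformed because the RRV
#' distribution is close to log-normal; predictions are back-transformed
#' to the RRV scale by [predict.rrv_fit()]. The feature encoder (one-hot
#' levels, shift min-max/bins, descriptor rescaling, imputation means) is
#' fitted on the training rows only and stored with the model, so applying
#' the model to new rows never leaks their statistics.
#'
#' @param dataset An [rrv_dataset()].
#' @param features Optional character vector of encoded feature names to
#'   restrict the design matrix to (e.g. from
#'   [select_features_backward()]).
#' @param kernel,cost,epsilon SVR hyperparameters (linear kernel, C = 1,
#'   epsilon = 0.001 by default; exposed because no single published
#'   setting is canonical).
#' @param subset Integer row indices used for training (default all).
#' @return Object of class `rrv_fit` with `print`, `summary`, `coef`,
#'   `predict`, `residuals` and `plot` methods.
#' @export
rrv_fit <- function(dataset, features = NULL, kernel = "linear",
                    cost = 1, epsilon = 0.001,
                    subset = seq_len(nrow(dataset$raw))) {
  if (!inherits(dataset, "rrv_dataset")) stop("dataset must be an rrv_dataset")
  y <- dataset$raw$ln_rrv[subset]
  if (length(y) < 2L) stop("training error: need at least 2 rows")
  if (stats::sd(y) == 0) stop("training error: constant target")
  enc <- fit_encoder(dataset, subset)
  X <- encode_rows(enc, dataset, subset)
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(X))
    if (length(miss)) stop("unknown feature(s): ", paste(miss, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = kernel,
                    cost = cost, epsilon = epsilon, scale = FALSE)
  yhat <- as.numeric(stats::predict(fit, X))
  structure(list(svm = fit, encoder = enc, features = colnames(X),
                 kernel = kernel, cost = cost, epsilon = epsilon,
                 n = length(y), y_ln = y, fitted_ln = yhat,
                 train_index = dataset$raw$index[subset],
                 call = match.call()),
            class = "rrv_fit")
}

#' Predict RRVs for new building blocks
#'
#' @param object An [rrv_fit()].
#' @param newdata An [rrv_dataset()] or a raw data.frame with the same
#'   columns (an `rrv` column is not required).
#' @param scale `"rrv"` (back-transformed, default) or `"ln"`.
#' @param ... Unused.
#' @return Numeric vector of predictions; positive and finite on the RRV
#'   scale.
#' @export
predict.rrv_fit <- function(object, newdata, scale = c("rrv", "ln"), ...) {
  scale <- match.arg(scale)
  ds <- .as_pred_dataset(newdata, object$encoder$config)
  X <- encode_rows(object$encoder, ds)
  miss <- setdiff(object$features, colnames(X))
  if (length(miss)) stop("newdata lacks feature(s): ",
                         paste(miss, collapse = ", "))
  p <- as.numeric(stats::predict(object$svm,
                                 X[, object$features, drop = FALSE]))
  if (scale == "rrv") exp(p) else p
}

.as_pred_dataset <- function(newdata, config) {
  if (inherits(newdata, "rrv_dataset")) return(newdata)
  raw <- as.data.frame(newdata)
  if (!"rrv" %in% names(raw)) raw$rrv <- 1  # placeholder, never used
  rrv_dataset(config = config, data = raw)
}

#' @export
print.rrv_fit <- function(x, ...) {
  cat("<rrv_fit> eps-SVR (", x$kernel, " kernel, C = ", x$cost,
      ", eps = ", x$epsilon, ") on ln(RRV)\n", sep = "")
  cat("  n = ", x$n, " training BBLs, ", length(x$features),
      " features\n", sep = "")
  cat("  training PCC (ln scale): ",
      sprintf("%.4f", stats::cor(x$y_ln, x$fitted_ln)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.rrv_fit <- function(object, ...) {
  obs <- exp(object$y_ln); pred <- exp(object$fitted_ln)
  out <- list(n = object$n, n_features = length(object$features),
              kernel = object$kernel,
              pcc = stats::cor(obs, pred),
              pcc_ln = stats::cor(object$y_ln, object$fitted_ln),
              mae = mean(abs(pred - obs)),
              rae = sum(abs(pred - obs)) / sum(abs(mean(obs) - obs)))
  class(out) <- "summary.rrv_fit"
  out
}

#' @export
print.summary.rrv_fit <- function(x, ...) {
  cat("RRV SVR fit: n = ", x$n, ", features = ", x$n_features,
      " (", x$kernel, ")\n", sep = "")
  cat(sprintf("  training  PCC %.4f (ln %.4f)  MAE %.2f  RAE %.4f\n",
              x$pcc, x$pcc_ln, x$mae, x$rae))
  invisible(x)
}

#' @export
coef.rrv_fit <- function(object, ...) {
  if (object$kernel != "linear") {
    stop("coefficients are only defined for the linear kernel")
  }
  w <- drop(crossprod(object$svm$coefs, object$svm$SV))
  c("(Intercept)" = -object$svm$rho, stats::setNames(w, object$features))
}

#' @export
residuals.rrv_fit <- function(object, scale = c("ln", "rrv"), ...) {
  scale <- match.arg(scale)
  if (scale == "ln") object$y_ln - object$fitted_ln
  else exp(object$y_ln) - exp(object$fitted_ln)
}

#' @export
plot.rrv_fit <- function(x, ...) {
  graphics::plot(exp(x$y_ln), exp(x$fitted_ln), log = "xy",
                 xlab = "observed RRV", ylab = "predicted RRV",
                 main = "RRV SVR fit (training)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' RRV reactivity category
#'
#' One-pot planning groups reactivities into three bins: `high`
#' (RRV > 15,000), `medium` (1,000 < RRV <= 15,000) and `low`
#' (0 <= RRV <= 1,000).
#'
#' @param rrv Numeric vector of non-negative RRVs.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
#' @examples
#' classify_rrv_category(c(72000, 1462, 850))
classify_rrv_category <- function(rrv) {
  if (any(!is.finite(rrv)) || any(rrv < 0)) {
    stop("RRV must be non-negative and finite")
  }
  factor(ifelse(rrv > 15000, "high", ifelse(rrv > 1000, "medium", "low")),
         levels = c("low", "medium", "high"))
}

#' Cross-validated evaluation of the RRV predictor
#'
#' Runs leave-one-out or k-fold cross-validation, refitting the encoder
#' and the SVR inside every training fold (no statistics leak into the
#' held-out rows), and reports Pearson correlation (PCC), mean absolute
#' error (MAE) and relative absolute error
#' (RAE = sum|pred - obs| / sum|mean(obs) - obs|) on the back-transformed
#' RRV scale, the same metrics on the ln scale, per-category PCC and the
#' three-bin classification accuracy.
#'
#' @inheritParams rrv_fit
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Number of folds for `"kfold"`.
#' @param seed Seed controlling the fold assignment.
#' @return Object of class `rrv_eval`.
#' @export
cv_evaluate <- function(dataset, scheme = c("loocv", "kfold"), k = 10,
                        seed = 1, features = NULL, kernel = "linear",
                        cost = 1, epsilon = 0.001) {
  scheme <- match.arg(scheme)
  n <- nrow(dataset$raw)
  if (scheme == "loocv" || (scheme == "kfold" && k == n)) {
    folds <- seq_len(n)  # n-fold CV is exactly leave-one-out
  } else {
    if (k > n) stop("k (", k, ") may not exceed the number of rows (", n, ")")
    folds <- .stratified_folds(dataset$raw$rrv, k, seed)
  }
  pred_ln <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    fit <- rrv_fit(dataset, features = features, kernel = kernel,
                   cost = cost, epsilon = epsilon,
                   subset = setdiff(seq_len(n), test))
    test_raw <- dataset$raw[test, , drop = FALSE]
    pred_ln[test] <- predict(fit, test_raw, scale = "ln")
  }
  .eval_report(dataset$raw$rrv, exp(pred_ln),
               scheme = if (scheme == "loocv") "LOOCV"
                        else sprintf("%d-fold CV (seed %d)", k, seed),
               n_features = length(if (is.null(features))
                 colnames(encode_rows(fit_encoder(dataset), dataset))
                 else features))
}

.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

.eval_report <- function(obs, pred, scheme, n_features = NA_integer_) {
  cat_obs <- classify_rrv_category(obs)
  cat_pred <- classify_rrv_category(pred)
  per_cat <- vapply(levels(cat_obs), function(lv) {
    i <- cat_obs == lv
    if (sum(i) < 3L) return(NA_real_)
    .safe_cor(obs[i], pred[i])
  }, numeric(1))
  structure(list(
    n = length(obs), n_features = n_features, scheme = scheme,
    pcc = .safe_cor(obs, pred),
    mae = mean(abs(pred - obs)),
    rae = sum(abs(pred - obs)) / sum(abs(mean(obs) - obs)),
    pcc_ln = .safe_cor(log(obs), log(pred)),
    mae_ln = mean(abs(log(pred) - log(obs))),
    rae_ln = sum(abs(log(pred) - log(obs))) /
      sum(abs(mean(log(obs)) - log(obs))),
    per_category_pcc = per_cat,
    category_accuracy = mean(cat_obs == cat_pred),
    observed = obs, predicted = pred),
    class = "rrv_eval")
}

#' @export
print.rrv_eval <- function(x, ...) {
  cat("<rrv_eval> ", x$scheme, ": n = ", x$n,
      if (!is.na(x$n_features)) paste0(", features = ", x$n_features),
      "\n", sep = "")
  cat(sprintf("  RRV scale:  PCC %.4f  MAE %.2f  RAE %.4f\n",
              x$pcc, x$mae, x$rae))
  cat(sprintf("  ln scale:   PCC %.4f  MAE %.4f  RAE %.4f\n",
              x$pcc_ln, x$mae_ln, x$rae_ln))
  cat(sprintf("  category accuracy %.3f (per-category PCC: %s)\n",
              x$category_accuracy,
              paste(names(x$per_category_pcc),
                    sprintf("%.2f", x$per_category_pcc), collapse = ", ")))
  invisible(x)
}

# fold ids stratified by RRV category so every fold sees the spread
.stratified_folds <- function(rrv, k, seed) {
  cat <- classify_rrv_category(rrv)
  folds <- integer(length(rrv))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (lv in levels(cat)) {
    i <- which(cat == lv)
    folds[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Backward greedy wrapper feature selection
#'
#' Starting from the full encoded feature set, repeatedly drops the single
#' feature whose removal increases the cross-validated PCC the most (or
#' decreases it the least), using stratified k-fold CV with per-fold
#' encoder refits. The path is walked down to `min_features` and the
#' subset with the maximal CV PCC is returned (ties resolved toward the
#' smaller set; ties among candidate drops resolved by removing the
#' lexicographically last feature name). Features in `keep` are pinned and
#' never dropped.
#'
#' @inheritParams cv_evaluate
#' @param nfolds CV folds used inside the wrapper (default 5).
#' @param keep Character vector of always-keep feature names.
#' @param min_features Smallest set size explored.
#' @param tol PCC tolerance for the final choice: among all sets on the
#'   greedy path, the smallest one within `tol` of the maximal CV PCC is
#'   returned (near-perfect fits make raw PCC differences pure numerical
#'   jitter, so an exact argmax would keep redundant features).
#' @return List with `selected` (character vector), `best_pcc`, and
#'   `trace` (data.frame: iteration, n_features, pcc, dropped).
#' @export
select_features_backward <- function(dataset, nfolds = 5, seed = 1,
                                     keep = character(0), min_features = 1,
                                     kernel = "linear", cost = 1,
                                     epsilon = 0.001, tol = 1e-4) {
  n <- nrow(dataset$raw)
  all_feats <- colnames(encode_rows(fit_encoder(dataset), dataset))
  if (length(all_feats) < 2L) stop("need at least 2 features to select from")
  bad <- setdiff(keep, all_feats)
  if (length(bad)) stop("unknown keep feature(s): ", paste(bad, collapse = ", "))
  folds <- .stratified_folds(dataset$raw$rrv, min(nfolds, n), seed)
  obs_ln <- dataset$raw$ln_rrv

  # CV PCC on the regression target itself (ln RRV): the raw-RRV scale is
  # dominated by the few largest values and makes the wrapper erratic
  cv_pcc <- function(feats) {
    pred <- rep(NA_real_, n)
    for (f in sort(unique(folds))) {
      test <- which(folds == f)
      fit <- rrv_fit(dataset, features = feats, kernel = kernel, cost = cost,
                     epsilon = epsilon, subset = setdiff(seq_len(n), test))
      pred[test] <- predict(fit, dataset$raw[test, , drop = FALSE],
                            scale = "ln")
    }
    stats::cor(obs_ln, pred)
  }

  current <- all_feats
  path <- list(current)
  trace <- data.frame(iteration = 0L, n_features = length(current),
                      pcc = cv_pcc(current), dropped = NA_character_,
                      stringsAsFactors = FALSE)
  it <- 0L
  while (length(current) > max(min_features, length(keep) + 1L, 1L)) {
    it <- it + 1L
    droppable <- setdiff(current, keep)
    if (!length(droppable)) break
    pccs <- vapply(droppable, function(f)
      cv_pcc(setdiff(current, f)), numeric(1))
    top <- which(pccs >= max(pccs) - 1e-12)
    # lexicographically last among the tied candidates
    drop <- sort(droppable[top])[length(top)]
    current <- setdiff(current, drop)
    path[[it + 1L]] <- current
    trace <- rbind(trace, data.frame(iteration = it,
                                     n_features = length(current),
                                     pcc = pccs[[match(drop, droppable)]],
                                     dropped = drop,
                                     stringsAsFactors = FALSE))
  }
  # the PCC-maximal set; within tol of the maximum, the smallest set wins
  ok <- which(trace$pcc >= max(trace$pcc) - tol)
  pick <- ok[which.max(ok)]  # latest qualifying iteration = smallest set
  list(selected = path[[pick]], best_pcc = trace$pcc[pick], trace = trace)
}
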