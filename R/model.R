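#' Label hot-spot residues from experimental ddG
#'
#' A residue is a hot spot when its alanine-substitution binding free energy
#' change is at least `threshold` kcal/mol (boundary inclusive; default 2.0).
#'
#' @param ddg numeric vector of experimental ddG values (kcal/mol).
#' @param threshold hot-spot cutoff in kcal/mol.
#' @return logical vector, TRUE = hot spot.
#' @export
label_hotspots <- function(ddg, threshold = 2.0) {
  if (anyNA(ddg)) stop("missing ddG value", call. = FALSE)
  ddg >= threshold
}

#' Default SVM hyper-parameter grid
#'
#' The canonical libsvm grid: cost 2^(-5), 2^(-3), ..., 2^15 and gamma
#' 2^(-15), 2^(-13), ..., 2^3.
#'
#' @param cost,gamma candidate values.
#' @return data.frame over the full cross product, columns `cost`, `gamma`.
#' @export
dbac_grid <- function(cost = 2^seq(-5, 15, by = 2),
                      gamma = 2^seq(-15, 3, by = 2)) {
  expand.grid(cost = cost, gamma = gamma, KEEP.OUT.ATTRS = FALSE)
}

# Linear [0,1] scaling fit on training rows only; constant columns map to 0.
fit_scaler <- function(x) {
  lo <- apply(x, 2, min)
  rg <- apply(x, 2, max) - lo
  rg[rg == 0] <- 1
  list(lo = lo, rg = rg)
}
apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$lo, "-"), 2, scaler$rg, "/")
}

# Stratified fold assignment: each class is spread across folds.
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

f1_from_counts <- function(tp, fp, fn) {
  if (tp == 0) return(0)  # zero predicted/true positives convention
  prec <- tp / (tp + fp)
  sens <- tp / (tp + fn)
  2 * prec * sens / (prec + sens)
}

#' Grid search for SVM cost and gamma
#'
#' Evaluates every grid point by stratified k-fold cross-validation on the
#' training data, scoring mean per-fold F1 of the hot-spot class, and
#' returns the best point.  Ties are broken by smaller cost, then smaller
#' gamma.  Deterministic given `seed` (which fixes the fold assignment).
#'
#' @param x numeric feature matrix (training data only).
#' @param y logical labels, TRUE = hot spot.
#' @param grid data.frame of candidate `cost`/`gamma` pairs.
#' @param folds number of inner folds (default 5).
#' @param seed integer seed for the fold split.
#' @return list with `cost`, `gamma`, `f1` (best mean inner F1).
#' @export
grid_search <- function(x, y, grid = dbac_grid(), folds = 5, seed = 0) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2)
    stop("grid search needs both classes in the training labels",
         call. = FALSE)
  folds <- min(folds, min(table(y)))
  fold <- with_private_seed(seed, stratified_folds(y, folds))
  yf <- factor(y, levels = c(FALSE, TRUE))
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    f1s <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2) { f1s[k] <- 0; next }
      sc <- fit_scaler(x[tr, , drop = FALSE])
      fit <- e1071::svm(apply_scaler(sc, x[tr, , drop = FALSE]), yf[tr],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pr <- predict(fit, apply_scaler(sc, x[!tr, , drop = FALSE])) == "TRUE"
      f1s[k] <- f1_from_counts(sum(pr & y[!tr]), sum(pr & !y[!tr]),
                               sum(!pr & y[!tr]))
    }
    score[g] <- mean(f1s)
  }
  best <- order(-score, grid$cost, grid$gamma)[1]
  list(cost = grid$cost[best], gamma = grid$gamma[best], f1 = score[best])
}

#' Fit the hot-spot SVM classifier
#'
#' Trains a radial-basis SVM on residue feature vectors.  Unless `cost` and
#' `gamma` are both supplied, they are chosen by [grid_search()] on the
#' training data.  Features are linearly scaled to the unit interval using
#' training
#' minima/maxima only; the same transform is applied at prediction time.
#'
#' @param x numeric feature matrix or data.frame (rows = residues).
#' @param y logical labels (TRUE = hot spot), or a numeric ddG vector that
#'   is thresholded by [label_hotspots()].
#' @param ddg_threshold hot-spot cutoff used when `y` is numeric.
#' @param cost,gamma fixed SVM hyper-parameters (optional).
#' @param grid,folds,seed grid-search configuration (see [grid_search()]).
#' @return object of class `dbac`: the fitted model with its scaler and the
#'   selected hyper-parameters.
#' @seealso [predict.dbac()], [dbac_cv()], [evaluate()]
#' @export
dbac_fit <- function(x, y, ddg_threshold = 2.0, cost = NULL, gamma = NULL,
                     grid = dbac_grid(), folds = 5, seed = 0) {
  x <- as.matrix(x)
  if (is.numeric(y) && !is.logical(y)) y <- label_hotspots(y, ddg_threshold)
  stopifnot(length(y) == nrow(x))
  if (length(unique(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  inner <- NULL
  if (is.null(cost) || is.null(gamma)) {
    inner <- grid_search(x, y, grid, folds, seed)
    cost <- inner$cost
    gamma <- inner$gamma
  }
  scaler <- fit_scaler(x)
  fit <- e1071::svm(apply_scaler(scaler, x),
                    factor(y, levels = c(FALSE, TRUE)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(model = fit, scaler = scaler, cost = cost, gamma = gamma,
                 inner_f1 = if (is.null(inner)) NA_real_ else inner$f1,
                 n = nrow(x), n_pos = sum(y), features = colnames(x),
                 call = match.call()),
            class = "dbac")
}

#' Predict hot spots with a fitted dbac model
#'
#' @param object a `dbac` model from [dbac_fit()].
#' @param newdata feature matrix/data.frame with the training columns.
#' @param type `"class"` for logical hot-spot calls, `"decision"` for SVM
#'   decision values.
#' @param ... unused.
#' @return logical vector (or numeric decision values).
#' @export
predict.dbac <- function(object, newdata, type = c("class", "decision"),
                         ...) {
  type <- match.arg(type)
  xs <- apply_scaler(object$scaler, as.matrix(newdata))
  if (type == "class")
    return(predict(object$model, xs) == "TRUE")
  dv <- attr(predict(object$model, xs, decision.values = TRUE),
             "decision.values")
  as.vector(dv)
}

#' @export
print.dbac <- function(x, ...) {
  cat("dbac hot-spot SVM (radial kernel)\n")
  cat("  trained on", x$n, "residues (", x$n_pos, "hot spots )\n")
  cat("  cost =", format(x$cost), " gamma =", format(x$gamma),
      if (!is.na(x$inner_f1)) paste(" (inner 5-fold F1 =",
                                    round(x$inner_f1, 4), ")"), "\n")
  invisible(x)
}

#' @export
summary.dbac <- function(object, ...) {
  print(object)
  cat("  features:", paste(object$features, collapse = ", "), "\n")
  cat("  support vectors:", object$model$tot.nSV, "\n")
  invisible(object)
}

#' Nested cross-validation of the hot-spot classifier
#'
#' Outer leave-one-out (or leave-n-out) loop; for each outer fold a full
#' [grid_search()] is run on the training part only, the selected model is
#' refit on that training part, and the held-out records are predicted.
#' Held-out labels are never read before prediction.  When an outer training
#' fold collapses to a single class, the held-out records receive the
#' majority prediction with a warning.
#'
#' @param x feature matrix or data.frame.
#' @param y logical labels (TRUE = hot spot).
#' @param protocol `"loocv"` or `"leave_n_out"`.
#' @param n_out held-out group size for `"leave_n_out"` (seeded random
#'   partition).
#' @param grid,folds grid-search configuration.
#' @param seed top-level seed; inner splits are re-seeded per outer fold.
#' @return object of class `dbac_cv`: list with `predicted` (logical, one
#'   per record), `y`, `params` (per-fold chosen cost/gamma/inner F1),
#'   `protocol`.
#' @export
dbac_cv <- function(x, y, protocol = c("loocv", "leave_n_out"), n_out = 5,
                    grid = dbac_grid(), folds = 5, seed = 0) {
  protocol <- match.arg(protocol)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("dataset must contain both classes", call. = FALSE)
  groups <- if (protocol == "loocv") as.list(seq_len(n)) else
    with_private_seed(seed, split(sample(n), ceiling(seq_len(n) / n_out)))
  pred <- logical(n)
  params <- data.frame(fold = seq_along(groups), cost = NA_real_,
                       gamma = NA_real_, inner_f1 = NA_real_)
  for (k in seq_along(groups)) {
    test <- groups[[k]]
    ytr <- y[-test]
    if (length(unique(ytr)) < 2) {
      warning("outer fold ", k, ": single-class training set; ",
              "falling back to majority prediction", call. = FALSE)
      pred[test] <- sum(ytr) > length(ytr) / 2
      next
    }
    fit <- dbac_fit(x[-test, , drop = FALSE], ytr, grid = grid,
                    folds = folds, seed = seed + k)
    params$cost[k] <- fit$cost
    params$gamma[k] <- fit$gamma
    params$inner_f1[k] <- fit$inner_f1
    pred[test] <- predict(fit, x[test, , drop = FALSE])
  }
  structure(list(predicted = pred, y = y, params = params,
                 protocol = protocol, n_out = n_out, seed = seed),
            class = "dbac_cv")
}

#' @export
print.dbac_cv <- function(x, ...) {
  cat("nested", if (x$protocol == "loocv") "leave-one-out" else
    paste0("leave-", x$n_out, "-out"), "cross-validation:",
    length(x$predicted), "records\n")
  print(evaluate(x$predicted, x$y))
  invisible(x)
}

#' @export
summary.dbac_cv <- function(object, ...) {
  print(object)
  cat("chosen hyper-parameters per outer fold:\n")
  print(table(cost = object$params$cost, gamma = object$params$gamma))
  invisible(object)
}

#' Classification metrics from confusion counts
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return object of class `dbac_eval` with the counts and sensitivity,
#'   precision, specificity, accuracy and F1.  Precision is defined as 0
#'   when there are no positive predictions; F1 is 0 when TP = 0.
#' @export
evaluate_counts <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / n
  f1 <- if (tp == 0) 0 else 2 * prec * sens / (prec + sens)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, precision = prec, specificity = spec,
                 accuracy = acc, f1 = f1),
            class = "dbac_eval")
}

#' Evaluate predictions against labels
#'
#' @param predicted,labels equal-length logical vectors (TRUE = hot spot).
#' @return a `dbac_eval` object (see [evaluate_counts()]).
#' @export
evaluate <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  if (!length(predicted)) stop("empty input", call. = FALSE)
  evaluate_counts(sum(predicted & labels), sum(predicted & !labels),
                  sum(!predicted & !labels), sum(!predicted & labels))
}

#' @export
print.dbac_eval <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "sensitivity %.4f  precision %.4f  specificity %.4f  accuracy %.4f  F1 %.4f\n",
    x$sensitivity, x$precision, x$specificity, x$accuracy, x$f1))
  invisible(x)
}

#' Mann-Whitney test between two groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) p-value: exact for small
#' tie-free samples, normal approximation with tie/continuity correction
#' otherwise (the \code{stats::wilcox.test} conventions).
#'
#' @param a,b numeric vectors (e.g. ddG of predicted hot spots vs predicted
#'   non hot spots).
#' @return two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  suppressWarnings(stats::wilcox.test(a, b,
                                      alternative = "two.sided")$p.value)
}

#' Per-feature Mann-Whitney significance
#'
#' Tests each feature column for a distribution difference between hot-spot
#' and non-hot-spot residues.
#'
#' @param x feature matrix or data.frame.
#' @param labels logical class labels.
#' @return named numeric vector of two-sided p-values, one per column, in
#'   column order.  Constant columns get p = 1 with a warning.
#' @export
feature_significance <- function(x, labels) {
  x <- as.matrix(x)
  if (!ncol(x)) stop("need at least one feature column", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  vapply(stats::setNames(seq_len(ncol(x)), colnames(x)), function(j) {
    v <- x[, j]
    if (length(unique(v)) == 1L) {
      warning("feature ", colnames(x)[j] %||% j,
              " is constant; p set to 1", call. = FALSE)
      return(1)
    }
    mann_whitney(v[labels], v[!labels])
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
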