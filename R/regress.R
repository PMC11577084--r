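# Calibration models (SVR, PCR, PLSR, MLR), their shared fit/predict
# surface, the calibration/prediction split, and the Rc2/RMSEC/Rp2/RMSEP
# scoring.

#' Split samples into calibration and prediction sets
#'
#' Default is the Kennard-Stone algorithm: the pair of samples furthest
#' apart in predictor space seeds the calibration set, then samples are
#' added one at a time by the maximin rule (largest distance to the
#' nearest already-selected sample), giving a deterministic,
#' representative split. `"random"` draws the calibration set uniformly
#' under the seed.
#'
#' @param X spectra: [spectra_matrix()] or numeric matrix.
#' @param y numeric response.
#' @param ratio calibration share of the samples (default 3:1, i.e.
#'   0.75).
#' @param method `"kennard_stone"` or `"random"`.
#' @param seed seed for the random method (ignored by Kennard-Stone).
#' @return list with `cal` and `pred`, each holding `X`, `y` and the row
#'   `idx` into the input; the two index sets partition the rows.
#' @export
split_calibration_prediction <- function(X, y, ratio = 0.75,
                                         method = c("kennard_stone",
                                                    "random"),
                                         seed = 1L) {
  method <- match.arg(method)
  M <- if (inherits(X, "spectra_matrix")) X$values else as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(M)
  if (n != length(y)) stop_config("X rows must match length(y)")
  n_cal <- max(2L, round(ratio * n))
  if (n_cal >= n) n_cal <- n - 1L
  idx <- if (method == "kennard_stone") kennard_stone(M, n_cal)
         else with_seed(seed, sort(sample.int(n, n_cal)))
  pred_idx <- setdiff(seq_len(n), idx)
  list(cal = list(X = M[idx, , drop = FALSE], y = y[idx], idx = idx),
       pred = list(X = M[pred_idx, , drop = FALSE], y = y[pred_idx],
                   idx = pred_idx))
}

# Maximin sample selection on Euclidean distances.
kennard_stone <- function(M, n_cal) {
  n <- nrow(M)
  ss <- rowSums(M^2)
  d2 <- outer(ss, ss, `+`) - 2 * tcrossprod(M)
  first <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  sel <- as.integer(first)
  mind <- pmin(d2[, sel[1]], d2[, sel[2]])
  while (length(sel) < n_cal) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, d2[, nxt])
  }
  sort(sel)
}

#' Fit a calibration model
#'
#' One surface over the four model families:
#' \describe{
#'   \item{MLR}{ordinary least squares; requires more samples than
#'     features (otherwise a not-applicable error, which is why MLR is
#'     never run on the full spectrum).}
#'   \item{PLSR}{NIPALS PLS1 ([pls1()]); the latent-variable count is
#'     chosen by k-fold RMSECV when not supplied.}
#'   \item{PCR}{principal component regression; component count by
#'     k-fold RMSECV (the PCA is refitted inside each fold).}
#'   \item{SVR}{radial-basis support vector regression
#'     ([e1071::svm()]); a small grid over cost, gamma and epsilon is
#'     scored by cross-validation when no hyperparameters are given.}
#' }
#'
#' @param X calibration spectra, matrix or [spectra_matrix()].
#' @param y calibration response.
#' @param method `"MLR"`, `"PLSR"`, `"PCR"` or `"SVR"`.
#' @param hyperparams optional named list: `ncomp` (PLSR/PCR); `cost`,
#'   `gamma`, `epsilon` (SVR).
#' @param cv_folds folds used for hyperparameter cross-validation.
#' @param ncomp_max component cap for PLSR/PCR (further capped at
#'   `n - 1`).
#' @param seed seed for the cross-validation fold draw.
#' @return an object of class `rotospec_fit`.
#' @export
fit_model <- function(X, y, method = c("MLR", "PLSR", "PCR", "SVR"),
                      hyperparams = list(), cv_folds = 10,
                      ncomp_max = 15, seed = 1L) {
  method <- match.arg(method)
  M <- if (inherits(X, "spectra_matrix")) X$values else as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(M)
  p <- ncol(M)
  if (n != length(y)) stop_config("X rows must match length(y)")
  cap <- min(ncomp_max, n - 1L, p)

  fit <- switch(method,
    MLR = {
      if (n <= p)
        stop_config("MLR not applicable: needs more samples (", n,
                    ") than features (", p, ")")
      ols <- stats::lm.fit(cbind(`(Intercept)` = 1, M), y)
      cf <- ols$coefficients
      aliased <- which(is.na(cf))
      cf[aliased] <- 0        # exactly collinear bands carry no weight
      list(coefficients = cf[-1], intercept = cf[1],
           aliased = aliased - 1L)
    },
    PLSR = {
      ncomp <- hyperparams$ncomp
      if (is.null(ncomp)) {
        cv <- pls_rmsecv(M, y, ncomp_max = cap, folds = cv_folds,
                         seed = seed)
        ncomp <- which.min(cv)
      }
      pf <- pls1(M, y, ncomp)
      list(pls = pf, ncomp = min(ncomp, pf$ncomp))
    },
    PCR = {
      ncomp <- hyperparams$ncomp
      if (is.null(ncomp)) {
        cv <- pcr_rmsecv(M, y, cap, cv_folds, seed)
        ncomp <- which.min(cv)
      }
      pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
      ncomp <- min(ncomp, ncol(pc$rotation))
      sc <- pc$x[, seq_len(ncomp), drop = FALSE]
      beta <- stats::lm.fit(cbind(1, sc), y)$coefficients
      # back-transform to the band space
      coefs <- pc$rotation[, seq_len(ncomp), drop = FALSE] %*% beta[-1]
      list(coefficients = drop(coefs),
           intercept = beta[1] - sum(pc$center * coefs),
           ncomp = ncomp)
    },
    SVR = {
      hp <- hyperparams
      if (is.null(hp$cost)) {
        grid <- expand.grid(cost = c(1, 10, 100),
                            gamma = c(0.5, 1, 2) / p,
                            epsilon = c(0.01, 0.1))
        errs <- vapply(seq_len(nrow(grid)), function(i) {
          m <- with_seed(seed, e1071::svm(M, y, type = "eps-regression",
                                          kernel = "radial",
                                          cost = grid$cost[i],
                                          gamma = grid$gamma[i],
                                          epsilon = grid$epsilon[i],
                                          cross = cv_folds))
          m$tot.MSE
        }, numeric(1))
        hp <- as.list(grid[which.min(errs), ])
      }
      m <- e1071::svm(M, y, type = "eps-regression", kernel = "radial",
                      cost = hp$cost, gamma = hp$gamma,
                      epsilon = hp$epsilon)
      list(svm = m, hyperparams = hp)
    })

  structure(list(method = method, fit = fit, n_features = p,
                 n_train = n, hyperparams = hyperparams, seed = seed),
            class = "rotospec_fit")
}

# k-fold RMSECV over PCR component counts; PCA refitted per fold.
pcr_rmsecv <- function(M, y, ncomp_max, folds, seed) {
  n <- nrow(M)
  fold_id <- with_seed(seed, make_folds(n, folds))
  amax <- min(ncomp_max, n - max(table(fold_id)) - 1L, ncol(M))
  amax <- max(amax, 1L)
  sse <- numeric(amax)
  for (f in seq_len(max(fold_id))) {
    tr <- fold_id != f
    pc <- stats::prcomp(M[tr, , drop = FALSE], center = TRUE,
                        scale. = FALSE)
    k <- min(amax, ncol(pc$rotation))
    str <- pc$x[, seq_len(k), drop = FALSE]
    ste <- scale(M[!tr, , drop = FALSE], pc$center, FALSE) %*%
      pc$rotation[, seq_len(k), drop = FALSE]
    for (a in seq_len(amax)) {
      aa <- min(a, k)
      beta <- stats::lm.fit(cbind(1, str[, seq_len(aa), drop = FALSE]),
                            y[tr])$coefficients
      pred <- drop(cbind(1, ste[, seq_len(aa), drop = FALSE]) %*% beta)
      sse[a] <- sse[a] + sum((y[!tr] - pred)^2)
    }
  }
  sqrt(sse / n)
}

#' Predict from a fitted calibration model
#'
#' @param object a `rotospec_fit`.
#' @param newdata matrix (or [spectra_matrix()]) with exactly the
#'   feature count the model was fitted on.
#' @param ... unused.
#' @return numeric vector of predictions, one per row.
#' @export
predict.rotospec_fit <- function(object, newdata, ...) {
  M <- if (inherits(newdata, "spectra_matrix")) newdata$values
       else as.matrix(newdata)
  if (ncol(M) != object$n_features)
    stop_config("newdata has ", ncol(M), " columns; model expects ",
                object$n_features)
  f <- object$fit
  switch(object$method,
         MLR = drop(M %*% f$coefficients + f$intercept),
         PCR = drop(M %*% f$coefficients + f$intercept),
         PLSR = predict(f$pls, M, ncomp = f$ncomp),
         SVR = as.numeric(predict(f$svm, M)))
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Can be negative
#' for predictors worse than the mean; the value is returned unclipped
#' (report formatting may floor at zero with a warning).
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predicted values.
#' @return scalar R-squared.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) < 2) stop_config("need at least 2 observations")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_config("constant y: R-squared undefined")
  1 - sum((y - yhat)^2) / sst
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`.
#'
#' @inheritParams r_squared
#' @return scalar RMSE.
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Evaluate a fitted model on calibration and prediction sets
#'
#' Computes Rc2/RMSEC on the calibration set and Rp2/RMSEP on the
#' prediction set — the four numbers that make up one cell of a model
#' comparison table.
#'
#' @param fit a `rotospec_fit`.
#' @param cal,pred lists with `X` and `y` (as returned by
#'   [split_calibration_prediction()]).
#' @param label optional combination label (preprocess, selector,
#'   model).
#' @return an object of class `evaluation_report`.
#' @export
evaluate <- function(fit, cal, pred, label = NULL) {
  yc <- predict(fit, cal$X)
  yp <- predict(fit, pred$X)
  structure(list(rc2 = r_squared(cal$y, yc),
                 rmsec = rmse(cal$y, yc),
                 rp2 = r_squared(pred$y, yp),
                 rmsep = rmse(pred$y, yp),
                 n_cal = length(cal$y), n_pred = length(pred$y),
                 label = label),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (!is.null(x$label)) cat(paste(unlist(x$label), collapse = "-"), "\n")
  cat(sprintf("  Rc2 %.4f  RMSEC %.4f  (n=%d)\n", x$rc2, x$rmsec, x$n_cal))
  cat(sprintf("  Rp2 %.4f  RMSEP %.4f  (n=%d)\n", x$rp2, x$rmsep,
              x$n_pred))
  invisible(x)
}
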