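#' Fit a univariate partial least squares regression (NIPALS)
#'
#' Iterative bilinear (NIPALS) PLS1: components are extracted by
#' successively deflating the predictor matrix along score directions that
#' maximise covariance with the response. The fit stores regression
#' coefficients and intercepts for every component count up to `ncomp`, so
#' cross-validation can scan component counts from a single decomposition.
#' This one implementation backs the PLSR calibration model, the genetic
#' algorithm's fitness function, and the coefficient weights inside
#' competitive adaptive reweighted sampling.
#'
#' @param X numeric matrix, samples in rows.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param ncomp maximum number of latent variables to extract; silently
#'   capped at `min(nrow(X) - 1, ncol(X))`.
#' @return an object of class `pls1_fit` with elements `coefficients`
#'   (p x ncomp matrix; column a holds the coefficients of the a-component
#'   model on the original data scale), `intercepts`, and `ncomp` (the
#'   number actually extracted, which can fall short of the request when
#'   the residual covariance collapses).
#' @seealso [pls_rmsecv()] for choosing the component count.
#' @export
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.01)
#' fit <- pls1(X, y, ncomp = 3)
#' head(predict(fit, X))
pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_config("nrow(X) must equal length(y)")
  if (length(y) == 0L) stop_config("empty response")
  fit <- .pls1_nipals(X, y, as.integer(ncomp))
  structure(list(coefficients = fit$coefficients,
                 intercepts = as.numeric(fit$intercepts),
                 ncomp = fit$ncomp),
            class = "pls1_fit")
}

#' @param object a `pls1_fit`.
#' @param newdata matrix with the same columns the model was fitted on.
#' @param ncomp component count to predict with; defaults to the largest
#'   extracted.
#' @param ... unused.
#' @rdname pls1
#' @export
predict.pls1_fit <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  a <- if (is.null(ncomp)) max(object$ncomp, 1L) else ncomp
  a <- min(a, max(object$ncomp, 1L))
  drop(newdata %*% object$coefficients[, a] + object$intercepts[a])
}

#' Cross-validated RMSE of PLS1 over component counts
#'
#' Computes the k-fold root mean square error of cross-validation
#' (RMSECV) for every component count `1..ncomp_max`; the minimiser is the
#' usual rule for choosing the number of latent variables.
#'
#' @inheritParams pls1
#' @param ncomp_max largest component count scanned.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment, or `NULL` to use the
#'   current random stream.
#' @return numeric vector of RMSECV values, one per component count.
#' @export
pls_rmsecv <- function(X, y, ncomp_max = 10, folds = 10, seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  fold_id <- with_seed(seed, make_folds(length(y), folds))
  as.numeric(.pls1_cv_rmse(X, y, as.integer(ncomp_max),
                           as.integer(fold_id)))
}
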