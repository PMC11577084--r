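#' Successive-projections-algorithm wavelength selection
#'
#' Deterministic forward selection that fights collinearity: starting
#' from each candidate band, a chain is grown by repeatedly adding the
#' band whose column has the largest projection onto the orthogonal
#' complement of the span of the bands already in the chain
#' (Gram-Schmidt). Every (start band, chain length N) pair with
#' `n_min <= N <= n_max` is then scored by the validation RMSE of an
#' ordinary least-squares fit on the chain prefix, using a deterministic
#' hold-out (the last quarter of the calibration rows), and the best pair
#' wins. No randomness anywhere: repeated calls give identical results.
#'
#' @inheritParams ga_select
#' @param n_min,n_max smallest / largest chain length scored.
#' @param validation_fraction fraction of trailing rows held out for
#'   scoring.
#' @return a [selection_result()]; diagnostics carry the RMSE-vs-N curve
#'   (`rmse_vs_n`, minimised over start bands) and the winning start
#'   band.
#' @export
spa_select <- function(X, y, n_min = 1, n_max = 20,
                       validation_fraction = 0.25) {
  inp <- selector_inputs(X, y)
  M <- inp$X
  yv <- inp$y
  n <- nrow(M)
  p <- ncol(M)
  n_val <- max(1L, floor(n * validation_fraction))
  n_train <- n - n_val
  if (n_max > p) stop_config("n_max must not exceed the band count")
  if (n_max > n_train - 1)
    stop_config("n_max must be below the training row count for the ",
                "validation regressor")
  train <- seq_len(n_train)
  val <- (n_train + 1):n

  chains <- spa_chains(M[train, , drop = FALSE], n_max)

  best <- list(rmse = Inf, start = NA_integer_, n = NA_integer_)
  rmse_vs_n <- rep(Inf, n_max)
  for (s in seq_len(p)) {
    chain <- chains[[s]]
    for (N in n_min:min(n_max, length(chain))) {
      bands <- chain[seq_len(N)]
      fit <- stats::lm.fit(cbind(1, M[train, bands, drop = FALSE]), yv[train])
      if (any(is.na(fit$coefficients))) next
      pred <- drop(cbind(1, M[val, bands, drop = FALSE]) %*%
                     fit$coefficients)
      r <- sqrt(mean((yv[val] - pred)^2))
      if (r < rmse_vs_n[N]) rmse_vs_n[N] <- r
      if (r < best$rmse) best <- list(rmse = r, start = s, n = N)
    }
  }
  if (!is.finite(best$rmse)) stop_config("no admissible SPA chain found")

  selection_result("SPA", chains[[best$start]][seq_len(best$n)], p,
                   wavelengths = inp$wavelengths,
                   diagnostics = list(rmse_vs_n = rmse_vs_n,
                                      start_band = best$start,
                                      best_rmse = best$rmse,
                                      n_selected_path =
                                        chains[[best$start]]),
                   seed = NULL)
}

# One projection chain per start band. Each step projects all columns
# onto the orthocomplement of the chosen set and picks the largest
# residual norm; chains terminate early on rank collapse (all residual
# norms ~ 0), which is recorded by their shorter length.
spa_chains <- function(M, n_max) {
  p <- ncol(M)
  lapply(seq_len(p), function(s) {
    Z <- M
    chain <- s
    taken <- rep(FALSE, p)
    taken[s] <- TRUE
    for (step in seq_len(n_max - 1)) {
      v <- Z[, chain[length(chain)]]
      nv <- sum(v^2)
      if (nv < 1e-12) break
      Z <- Z - v %*% (crossprod(v, Z) / nv)
      norms <- colSums(Z^2)
      norms[taken] <- -1
      nxt <- which.max(norms)
      if (norms[nxt] < 1e-10) break    # rank collapse: early termination
      chain <- c(chain, nxt)
      taken[nxt] <- TRUE
    }
    chain
  })
}
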