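#' Competitive adaptive reweighted sampling wavelength selection
#'
#' Monte Carlo elimination driven by PLS regression-coefficient weights.
#' At sampling run i (of `mc_runs`), a PLS1 model is fitted on a random
#' `subsample_ratio` fraction of the calibration rows using the currently
#' retained bands; per-band weights are the normalised absolute
#' regression coefficients. An exponentially decreasing function (EDF)
#' fixes the fraction of bands surviving run i,
#' `r_i = a * exp(-k * i)`, with `a`, `k` set by the endpoint conditions
#' `r_1 = 1` and `r_N = 2/p` (so the first run keeps every band and the
#' last is forced down to 2 of the `p` bands): the top `r_i * p` bands by
#' weight survive the forced elimination (fast phase then fine phase),
#' and adaptive reweighted sampling (weighted draws with replacement)
#' thins them further. Each run's retained set is scored by k-fold
#' RMSECV, and the set minimising RMSECV over all runs is returned.
#'
#' @inheritParams ga_select
#' @param mc_runs number of Monte Carlo sampling runs (>= 2).
#' @param cv_folds folds of the RMSECV scoring.
#' @param subsample_ratio fraction of rows drawn (without replacement)
#'   for each run's coefficient fit.
#' @param ncomp_max latent-variable cap of the PLS models.
#' @param max_bands optional cap on the size of the returned subset: the
#'   winning run is the RMSECV minimiser among runs retaining at most
#'   `max_bands` bands. Downstream multiple linear regression needs more
#'   samples than bands, which is the usual reason to set this.
#' @return a [selection_result()]; diagnostics carry the retained-count
#'   trajectory (`n_retained`, non-increasing), `rmsecv` per run, the
#'   coefficient path matrix (`coef_path`, runs x bands), the EDF
#'   schedule, and the winning run index.
#' @export
cars_select <- function(X, y, mc_runs = 50, cv_folds = 10,
                        subsample_ratio = 0.8, ncomp_max = 10,
                        max_bands = NULL, seed = 1L) {
  inp <- selector_inputs(X, y)
  M <- inp$X
  yv <- inp$y
  n <- nrow(M)
  p <- ncol(M)
  if (mc_runs < 2) stop_config("mc_runs must be at least 2")
  if (p < 2) stop_config("need at least 2 bands")

  # EDF endpoints: r_1 = 1, r_N = 2/p
  k <- log(p / 2) / (mc_runs - 1)
  a <- exp(k)
  edf <- pmax(2L, round(a * exp(-k * seq_len(mc_runs)) * p))

  with_seed(seed, {
    fold_id <- make_folds(n, cv_folds)
    retained <- seq_len(p)
    n_retained <- integer(0)
    rmsecv <- numeric(0)
    sets <- vector("list", mc_runs)
    coef_path <- matrix(0, mc_runs, p)
    runs_done <- 0L

    for (i in seq_len(mc_runs)) {
      rows <- sample.int(n, max(4L, round(subsample_ratio * n)))
      fit <- pls1(M[rows, retained, drop = FALSE], yv[rows],
                  min(ncomp_max, length(retained)))
      b <- abs(fit$coefficients[, max(fit$ncomp, 1L)])
      w <- if (sum(b) > 0) b / sum(b) else rep(1 / length(b), length(b))
      coef_path[i, retained] <- fit$coefficients[, max(fit$ncomp, 1L)]

      keep <- min(edf[i], length(retained))
      ord <- order(w, decreasing = TRUE)
      forced <- retained[ord[seq_len(keep)]]
      wf <- w[ord[seq_len(keep)]]
      # adaptive reweighted sampling on the survivors; the draw count
      # follows the EDF schedule on the full band count, so the retained
      # trajectory tracks the schedule's fast/fine two-phase shape
      draw <- sample(forced, edf[i], replace = TRUE,
                     prob = if (sum(wf) > 0) wf else NULL)
      retained <- sort(unique(draw))
      if (length(retained) < 2L) {
        runs_done <- i - 1L          # run truncated, recorded below
        break
      }
      cv <- .pls1_cv_rmse(M[, retained, drop = FALSE], yv,
                          as.integer(min(ncomp_max, length(retained))),
                          as.integer(fold_id))
      n_retained <- c(n_retained, length(retained))
      rmsecv <- c(rmsecv, min(cv))
      sets[[i]] <- retained
      runs_done <- i
    }
    if (runs_done == 0L) stop_config("CARS collapsed before any run")

    eligible <- if (is.null(max_bands)) seq_along(rmsecv)
                else which(n_retained <= max_bands)
    if (!length(eligible))
      stop_config("no CARS run retained at most ", max_bands, " bands")
    best_run <- eligible[which.min(rmsecv[eligible])]
    selection_result("CARS", sets[[best_run]], p,
                     wavelengths = inp$wavelengths,
                     diagnostics = list(n_retained = n_retained,
                                        rmsecv = rmsecv,
                                        coef_path =
                                          coef_path[seq_len(runs_done), ,
                                                    drop = FALSE],
                                        edf_schedule = edf,
                                        best_run = best_run,
                                        runs_done = runs_done,
                                        truncated = runs_done < mc_runs),
                     seed = seed)
  })
}
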