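#' Genetic-algorithm wavelength selection
#'
#' Binary-chromosome genetic algorithm with one gene per band. Fitness of
#' a chromosome is the negated k-fold RMSECV of a PLS1 model on its
#' selected bands, with the latent-variable count chosen by the same
#' cross-validation (capped at `ncomp_max`). Selection is roulette-wheel
#' on shifted fitness, variation is single-point crossover and per-gene
#' bit-flip mutation, and the single best chromosome is carried over each
#' generation (elitism). The run terminates at `max_gen` generations or
#' after `stall_gen` generations without improvement of the best fitness.
#' Runs are reproducible under a fixed seed; different seeds can select
#' different bands — an instability inherent to the method.
#'
#' @param X spectra: [spectra_matrix()] or numeric matrix.
#' @param y numeric response, one value per row of `X`.
#' @param pop_size population size.
#' @param max_gen maximum generations.
#' @param stall_gen early-stop patience (generations without
#'   improvement).
#' @param cx_prob crossover probability per mating pair.
#' @param mut_prob per-gene mutation probability.
#' @param cv_folds folds of the fitness cross-validation.
#' @param ncomp_max latent-variable cap for the fitness regressor.
#' @param seed integer seed.
#' @return a [selection_result()] whose diagnostics carry the best-RMSECV
#'   trend per generation (`rmsecv_trend`), final-population per-band
#'   selection counts (`band_counts`), the generations run, and the best
#'   RMSECV.
#' @export
ga_select <- function(X, y, pop_size = 50, max_gen = 100, stall_gen = 20,
                      cx_prob = 0.8, mut_prob = 0.01, cv_folds = 5,
                      ncomp_max = 10, seed = 1L) {
  inp <- selector_inputs(X, y)
  M <- inp$X
  yv <- inp$y
  p <- ncol(M)
  if (p < 2) stop_config("need at least 2 bands")

  with_seed(seed, {
    fold_id <- make_folds(length(yv), cv_folds)
    cache <- new.env(parent = emptyenv())
    eval_rmsecv <- function(genes) {
      key <- paste(which(genes), collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      cv <- .pls1_cv_rmse(M[, genes, drop = FALSE], yv,
                          as.integer(ncomp_max), as.integer(fold_id))
      val <- min(cv)
      cache[[key]] <- val
      val
    }
    repair <- function(genes) {
      if (!any(genes)) genes[sample.int(p, 1)] <- TRUE
      genes
    }

    pop <- matrix(runif(pop_size * p) < 0.5, pop_size, p)
    pop <- t(apply(pop, 1, repair))
    rmse <- apply(pop, 1, eval_rmsecv)
    best_rmse <- min(rmse)
    best_genes <- pop[which.min(rmse), ]
    trend <- best_rmse
    stall <- 0L
    gens <- 0L

    for (g in seq_len(max_gen)) {
      gens <- g
      # roulette selection on shifted fitness (lower RMSECV -> larger slice)
      w <- max(rmse) - rmse + 1e-3 * (max(rmse) - min(rmse) + 1e-12)
      parents <- sample.int(pop_size, pop_size, replace = TRUE,
                            prob = w / sum(w))
      newpop <- pop[parents, , drop = FALSE]
      for (i in seq(1, pop_size - 1, by = 2)) {
        if (runif(1) < cx_prob && p > 1) {
          cut <- sample.int(p - 1, 1)
          tmp <- newpop[i, (cut + 1):p]
          newpop[i, (cut + 1):p] <- newpop[i + 1, (cut + 1):p]
          newpop[i + 1, (cut + 1):p] <- tmp
        }
      }
      flips <- matrix(runif(pop_size * p) < mut_prob, pop_size, p)
      newpop <- xor(newpop, flips)
      newpop <- t(apply(newpop, 1, repair))
      newpop[1, ] <- best_genes           # elitism
      pop <- newpop
      rmse <- apply(pop, 1, eval_rmsecv)
      if (min(rmse) < best_rmse - 1e-10) {
        best_rmse <- min(rmse)
        best_genes <- pop[which.min(rmse), ]
        stall <- 0L
      } else stall <- stall + 1L
      trend <- c(trend, best_rmse)
      if (stall >= stall_gen) break
    }

    selection_result("GA", which(best_genes), p,
                     wavelengths = inp$wavelengths,
                     diagnostics = list(rmsecv_trend = trend,
                                        band_counts = colSums(pop),
                                        generations = gens,
                                        best_rmsecv = best_rmse),
                     seed = seed)
  })
}
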