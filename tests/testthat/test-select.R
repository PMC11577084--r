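test_that("selection fraction arithmetic is exact", {
  expect_equal(selection_result("GA", 1:20, 320)$fraction_of_total, 6.25)
  expect_equal(selection_result("SPA", 1:8, 320)$fraction_of_total, 2.50)
  expect_equal(selection_result("CARS", 1:45, 320)$fraction_of_total,
               14.06)
  # exact for arbitrary pairs
  for (k in c(1, 7, 100, 320))
    expect_equal(selection_result("GA", seq_len(k), 320)$fraction_of_total,
                 round(100 * k / 320, 2))
  expect_error(selection_result("GA", c(0, 5), 320), "range")
})

test_that("SPA never selects duplicated columns and is deterministic", {
  set.seed(10)
  X <- matrix(rnorm(40 * 10), 40, 10)
  X[, 7] <- X[, 3]                 # exact duplicate
  y <- drop(X[, c(1, 3)] %*% c(2, -1)) + rnorm(40, sd = 0.1)
  r1 <- spa_select(X, y, n_max = 8)
  expect_false(all(c(3, 7) %in% r1$indices))
  r2 <- spa_select(X, y, n_max = 8)
  expect_identical(r1$indices, r2$indices)   # no randomness anywhere
  expect_null(r1$seed)
})

test_that("SPA chains agree with a brute-force projection oracle", {
  set.seed(11)
  M <- matrix(rnorm(36), 6, 6)
  # oracle: at each step pick the column with the largest squared norm
  # after projecting out the span of the chain so far, via explicit QR
  oracle_chain <- function(M, start, len) {
    chain <- start
    for (k in seq_len(len - 1)) {
      Q <- qr.Q(qr(M[, chain, drop = FALSE]))
      resid <- M - Q %*% crossprod(Q, M)
      norms <- colSums(resid^2)
      norms[chain] <- -1
      chain <- c(chain, which.max(norms))
    }
    chain
  }
  chains <- rotospec:::spa_chains(M, 6)
  for (s in 1:6)
    expect_equal(chains[[s]], oracle_chain(M, s, 6), label =
                   paste("start", s))
})

test_that("SPA selection order on an orthogonal design ranks by norm", {
  D <- diag(c(5, 1, 4, 2, 3, 6))     # orthogonal columns, known norms
  chains <- rotospec:::spa_chains(D, 6)
  expect_equal(chains[[6]], c(6, 1, 3, 5, 4, 2))
})

test_that("GA without variation operators cannot improve", {
  fx <- planted_bands_fixture(n = 40, p = 12, informative = c(2, 7),
                              coefs = c(3, -2), seed = 1)
  r <- ga_select(fx$X, fx$y, pop_size = 10, max_gen = 15, stall_gen = 5,
                 cx_prob = 0, mut_prob = 0, seed = 4)
  trend <- r$diagnostics$rmsecv_trend
  expect_equal(length(unique(round(trend, 12))), 1L)
})

test_that("GA is seed-reproducible and repairs empty chromosomes", {
  fx <- planted_bands_fixture(n = 40, p = 12, informative = c(2, 7),
                              coefs = c(3, -2), seed = 1)
  r1 <- ga_select(fx$X, fx$y, pop_size = 12, max_gen = 10, seed = 9)
  r2 <- ga_select(fx$X, fx$y, pop_size = 12, max_gen = 10, seed = 9)
  expect_identical(r1$indices, r2$indices)
  expect_identical(r1$diagnostics$rmsecv_trend,
                   r2$diagnostics$rmsecv_trend)
  expect_gte(r1$n_selected, 1L)      # repair guarantees non-empty
  expect_error(ga_select(fx$X, numeric(0)), "empty")
})

test_that("CARS schedule endpoints and trajectory shape are as designed", {
  fx <- planted_bands_fixture(seed = 2)
  r <- cars_select(fx$X, fx$y, mc_runs = 30, seed = 3)
  edf <- r$diagnostics$edf_schedule
  expect_equal(edf[1], ncol(fx$X))      # first run keeps every band
  expect_equal(edf[30], 2)              # floor of the schedule
  expect_true(all(diff(r$diagnostics$n_retained) <= 0))  # non-increasing
  expect_identical(r$indices,
                   cars_select(fx$X, fx$y, mc_runs = 30, seed = 3)$indices)
  expect_error(cars_select(fx$X, fx$y, mc_runs = 1), "mc_runs")
})

test_that("CARS max_bands restricts the winning run", {
  fx <- planted_bands_fixture(seed = 6)
  r <- cars_select(fx$X, fx$y, mc_runs = 30, max_bands = 10, seed = 3)
  expect_lte(r$n_selected, 10)
})

test_that("selected bands beat random subsets of equal size", {
  fx <- planted_bands_fixture(n = 90, seed = 13)
  idx_cal <- 1:60
  idx_val <- 61:90
  val_rmse <- function(bands) {
    fit <- lm.fit(cbind(1, fx$X[idx_cal, bands, drop = FALSE]),
                  fx$y[idx_cal])
    pred <- drop(cbind(1, fx$X[idx_val, bands, drop = FALSE]) %*%
                   fit$coefficients)
    sqrt(mean((fx$y[idx_val] - pred)^2))
  }
  sel <- list(
    GA = ga_select(fx$X[idx_cal, ], fx$y[idx_cal], pop_size = 20,
                   max_gen = 25, stall_gen = 8, seed = 1),
    SPA = spa_select(fx$X[idx_cal, ], fx$y[idx_cal], n_max = 10),
    CARS = cars_select(fx$X[idx_cal, ], fx$y[idx_cal], mc_runs = 30,
                       seed = 1))
  for (nm in names(sel)) {
    bands <- sel[[nm]]$indices
    wins <- 0
    for (s in 1:10) {
      rnd <- rotospec:::with_seed(100 + s,
               sample.int(ncol(fx$X), length(bands)))
      if (val_rmse(bands) < val_rmse(rnd)) wins <- wins + 1
    }
    expect_gte(wins, 9)
  }
})

test_that("selection results serialize to JSON and back", {
  r <- selection_result("SPA", c(3, 8, 1), 20,
                        wavelengths = seq(380, 1018, length.out = 20),
                        diagnostics = list(rmse_vs_n = c(1, 0.5)))
  path <- tempfile(fileext = ".json")
  write_selection_json(r, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$indices, c(1, 3, 8))
  expect_equal(back$n_selected, 3)
  expect_equal(back$fraction_of_total, 15)
})
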