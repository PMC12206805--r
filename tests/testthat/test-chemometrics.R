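test_that("SNV centres and scales each spectrum", {
  expect_equal(as.numeric(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))

  withr::with_seed(4, X <- matrix(runif(200), 10, 20))
  S <- snv(X)
  expect_equal(unname(rowMeans(S)), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(S, 1, sd)), rep(1, 10), tolerance = 1e-10)
  # affine invariance and idempotence
  expect_equal(snv(2.5 * X + 3), S, tolerance = 1e-10)
  expect_equal(snv(S), S, tolerance = 1e-10)
  Xc <- X; Xc[3, ] <- 7
  expect_error(snv(Xc), "row\\(s\\) 3")
})

test_that("NIPALS PLS2 recovers exact and least-squares solutions", {
  # rank-1 noiseless problem: one component fits the response exactly
  withr::with_seed(8, {
    f <- rnorm(30)
    load <- rnorm(12)
    X <- f %*% t(load)
    Y <- cbind(2 * f + 1, -f)
  })
  fit1 <- pls2_fit(X, Y, ncomp = 1)
  expect_lt(max(abs(predict(fit1, X) - Y)), 1e-8)

  # full-rank small problem at maximal ncomp reproduces least squares
  withr::with_seed(9, {
    X2 <- matrix(rnorm(100), 20, 5)
    Y2 <- matrix(rnorm(40), 20, 2)
  })
  fit2 <- pls2_fit(X2, Y2, ncomp = 5)
  Xc <- cbind(1, X2)
  B_ls <- solve(crossprod(Xc), crossprod(Xc, Y2))  # normal-equations oracle
  pred_ls <- Xc %*% B_ls
  expect_lt(max(abs(predict(fit2, X2) - pred_ls)), 1e-6)

  # permutation of sample order leaves the coefficients unchanged
  perm <- sample(20)
  fit3 <- pls2_fit(X2[perm, ], Y2[perm, ], ncomp = 3)
  fit4 <- pls2_fit(X2, Y2, ncomp = 3)
  expect_equal(fit3$B, fit4$B, tolerance = 1e-8)
  expect_error(pls2_fit(X2, Y2, ncomp = 25), "out of range")
})

test_that("RMSECV separates predictable from null responses", {
  # perfectly predictable: duplicated rows per class, no noise
  proto <- matrix(rnorm(6 * 10), 6, 10)
  X <- proto[rep(1:6, each = 10), ]
  y <- rep(1:6, each = 10)
  Y <- hyperleaf:::one_hot(y)
  expect_lt(rmsecv_kfold(X, Y, ncomp = 5, seed = 1), 0.05)

  # label-shuffled null: RMSECV near the response standard deviation
  withr::with_seed(14, {
    Xn <- matrix(rnorm(120 * 10), 120, 10)
    yn <- sample(rep(1:6, each = 20))
  })
  Yn <- hyperleaf:::one_hot(yn)
  null_rmse <- rmsecv_kfold(Xn, Yn, ncomp = 2, seed = 2)
  expect_lt(abs(null_rmse - sd(Yn)) / sd(Yn), 0.10)

  expect_identical(rmsecv_kfold(Xn, Yn, 3, seed = 5),
                   rmsecv_kfold(Xn, Yn, 3, seed = 5))
})

test_that("CARS follows the exponentially decreasing schedule", {
  sched <- cars_edf_schedule(761, 50)
  expect_identical(sched[1], 761L)   # run 1 keeps every variable
  expect_identical(sched[50], 2L)    # run N keeps two
  expect_true(all(diff(sched) <= 0)) # monotone non-increasing

  # a, k as defined: a = (p/2)^(1/(N-1)), k = log(p/2)/(N-1)
  a <- 380.5^(1 / 49); k <- log(380.5) / 49
  expect_equal(hyperleaf:::cars_keep_ratio(1, 761, 50), a * exp(-k),
               tolerance = 1e-12)
  expect_equal(a * exp(-k), 1, tolerance = 1e-12)
  expect_equal(ceiling(hyperleaf:::cars_keep_ratio(50, 761, 50) * 761), 2)
})

test_that("CARS trace is internally consistent and seeded", {
  tab <- snv(simulate_spectra(8, sim_config(
    wavelength = seq(400, 1000, length.out = 80)), seed = 2))
  cfg <- cars_config(n_runs = 12, seed = 5)
  res <- cars_select(tab, cfg)
  tr <- res$trace
  # enforced sizes respect the schedule; ARS can only shrink further
  expect_true(all(tr$size_enforced <= tr$size_schedule))
  expect_true(all(tr$size_retained <= tr$size_enforced))
  expect_identical(res$criterion_curve[res$best_run],
                   min(res$criterion_curve))
  expect_true(all(res$selected_indices >= 1 &
                  res$selected_indices <= 80))
  expect_false(anyDuplicated(res$selected_indices) > 0)
  # determinism
  res2 <- cars_select(tab, cfg)
  expect_identical(res$selected_indices, res2$selected_indices)
})

test_that("SPA projection chains pick dominant orthogonal columns", {
  # three mutually orthogonal columns with norms 3 > 2 > 1: whatever the
  # start, the norm-3 column is in the chain by step 2
  X <- cbind(c(3, 0, 0), c(0, 2, 0), c(0, 0, 1))
  G <- crossprod(X)
  for (j in 1:3) {
    chain <- hyperleaf:::spa_chain_gram(G, j, 3)
    expect_true(1 %in% chain[1:2])
  }
  # chain from start 2: next pick must be column 1 (largest residual norm)
  expect_identical(hyperleaf:::spa_chain_gram(G, 2, 2), c(2L, 1L))

  # selected columns are linearly independent on a random problem
  withr::with_seed(31, Xr <- matrix(rnorm(40 * 25), 40, 25))
  chain <- hyperleaf:::spa_chain_gram(crossprod(Xr), 5, 10)
  expect_identical(qr(Xr[, chain])$rank, length(chain))

  # collinear columns truncate rather than error
  Xc <- cbind(Xr[, 1], Xr[, 1], Xr[, 1])
  chain_c <- hyperleaf:::spa_chain_gram(crossprod(Xc), 1, 3)
  expect_lt(length(chain_c), 3)
})

test_that("SPA selection is deterministic and rank-consistent", {
  tab <- snv(simulate_spectra(10, sim_config(
    wavelength = seq(400, 1000, length.out = 60)), seed = 6))
  idx <- seq_len(nrow(tab$X))
  val <- idx[idx %% 5 == 0]; tr <- setdiff(idx, val)
  run <- function() spa_select(tab$X[tr, ], tab$y[tr], tab$X[val, ],
                               tab$y[val], max_vars = 10,
                               wavelength = tab$wavelength)
  r1 <- run(); r2 <- run()
  expect_identical(r1$selected_indices, r2$selected_indices)
  expect_identical(qr(tab$X[tr, r1$selected_indices, drop = FALSE])$rank,
                   length(r1$selected_indices))
  expect_identical(r1$criterion_curve[r1$best_m],
                   min(r1$criterion_curve))
})

test_that("PLS-DA grid search breaks ties toward fewer components", {
  tabs <- separable_tables(n_per_class = 20, seed = 12)
  fit <- train_plsda(tabs$train, tabs$val, ncomp_grid = 1:8)
  # on a cleanly separable problem several ncomp reach equal accuracy;
  # the retained one must be the smallest among the maximisers
  g <- fit$grid
  expect_identical(fit$ncomp, g$ncomp[which.max(g$accuracy)])
  expect_true(all(g$accuracy[g$ncomp < fit$ncomp] < fit$val_accuracy))
  preds <- predict(fit, tabs$test)
  expect_gte(mean(preds == tabs$test$y), 0.9)
})

test_that("RBF SVM solves the XOR pattern a linear kernel cannot", {
  withr::with_seed(17, {
    n <- 200
    x <- matrix(runif(n * 2, -1, 1), n, 2)
    y <- ifelse(x[, 1] * x[, 2] > 0, 1L, 2L)
    x <- x + rnorm(n * 2, 0, 0.02)
  })
  tr <- seq_len(150); va <- 151:200
  axis <- c(500, 600)
  fit <- train_svm_rbf(spectra_table(x[tr, ], axis, y[tr]),
                       spectra_table(x[va, ], axis, y[va]),
                       C_grid = 2^seq(-1, 7, 2), gamma_grid = 2^seq(-3, 3, 2))
  expect_gt(fit$val_accuracy, 0.9)
  # determinism given the same grids
  fit2 <- train_svm_rbf(spectra_table(x[tr, ], axis, y[tr]),
                        spectra_table(x[va, ], axis, y[va]),
                        C_grid = 2^seq(-1, 7, 2), gamma_grid = 2^seq(-3, 3, 2))
  expect_identical(c(fit$C, fit$gamma), c(fit2$C, fit2$gamma))
})
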