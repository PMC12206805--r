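#' Spectra table
#'
#' The tabular currency of the chemometric stage: an `n x p` matrix of mean
#' spectra with a wavelength axis and per-row class labels.
#'
#' @param X numeric `n x p` matrix (rows = leaves, columns = bands), no NaN.
#' @param wavelength wavelength axis of length `p`.
#' @param y integer class labels in `1..6`, length `n`.
#' @param fold optional character fold tags (`"train"` etc.), length `n`.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(X, wavelength, y, fold = NULL) {
  X <- as.matrix(X)
  assert_that(!anyNA(X) && all(is.finite(X)), "X must be finite with no NA")
  wavelength <- validate_axis(wavelength)
  assert_that(ncol(X) == length(wavelength),
              "ncol(X) (%d) must equal axis length (%d)", ncol(X),
              length(wavelength))
  y <- as.integer(y)
  assert_that(length(y) == nrow(X), "length(y) must equal nrow(X)")
  assert_that(all(y >= 1), "labels must be positive integers")
  assert_that(nrow(X) >= length(unique(y)),
              "need at least as many rows as classes")
  if (!is.null(fold)) assert_that(length(fold) == nrow(X),
                                  "fold tags must match nrow(X)")
  structure(list(X = X, wavelength = wavelength, y = y, fold = fold),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d spectra x %d bands (%.1f-%.1f nm), %d classes\n",
              nrow(x$X), ncol(x$X), min(x$wavelength), max(x$wavelength),
              length(unique(x$y))))
  invisible(x)
}

#' Convert a spectra table to a tibble
#'
#' One row per spectrum: `label`, optional `fold`, and one column per band
#' named by its wavelength.
#'
#' @param x a [spectra_table()].
#' @param ... unused.
#' @return A tibble.
#' @export
as_tibble.spectra_table <- function(x, ...) {
  out <- tibble::as_tibble(x$X, .name_repair = "minimal")
  names(out) <- sprintf("%.2f", x$wavelength)
  out <- tibble::add_column(out, label = x$y, .before = 1)
  if (!is.null(x$fold)) out <- tibble::add_column(out, fold = x$fold,
                                                  .after = "label")
  out
}

#' Standard normal variate (SNV) transform
#'
#' Centres and scales each spectrum (row) to mean 0 and unit sample
#' standard deviation (`n - 1` denominator), removing multiplicative
#' scatter and additive baseline effects caused by uneven particle
#' distribution and path-length differences in diffuse reflectance.
#' SNV is idempotent and invariant to positive affine transforms of a row.
#'
#' @param X numeric matrix (rows = spectra) or a [spectra_table()].
#' @return Same kind of object, row-standardised.
#' @export
snv <- function(X) {
  if (inherits(X, "spectra_table")) {
    X$X <- snv(X$X)
    return(X)
  }
  X <- as.matrix(X)
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  bad <- which(sdv <= 1e-12)
  if (length(bad) > 0)
    stopf("constant spectrum in row(s) %s: SNV undefined",
          paste(head(bad, 5), collapse = ", "))
  (X - mu) / sdv
}

one_hot <- function(y, K = max(y)) {
  Y <- matrix(0, length(y), K)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

#' Fit a PLS2 regression model (NIPALS)
#'
#' Multi-response partial least squares by the NIPALS algorithm. `X` and
#' `Y` are column-centred internally; the fitted model exposes the
#' coefficient matrix `B` (`p x K`) and intercept so that
#' `predict(X*) = X* B + intercept`. Deterministic given its inputs.
#'
#' @param X numeric `n x p` predictor matrix.
#' @param Y numeric `n x K` response matrix (typically one-hot labels).
#' @param ncomp number of latent components, `<= min(n - 1, p)`.
#' @param tol NIPALS convergence tolerance on the score vector.
#' @return Object of class `pls2_model` with elements `B`, `intercept`,
#'   `scores`, `loadings`, `weights`, `yloadings`, `ncomp`.
#' @export
pls2_fit <- function(X, Y, ncomp, tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); K <- ncol(Y)
  assert_that(nrow(Y) == n, "X and Y must have the same number of rows")
  assert_that(ncomp >= 1 && ncomp <= min(n - 1, p),
              "ncomp (%d) out of range 1..min(n-1, p) = %d", ncomp,
              min(n - 1, p))
  xmean <- colMeans(X); ymean <- colMeans(Y)
  Xc <- sweep(X, 2, xmean); Yc <- sweep(Y, 2, ymean)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, K, ncomp); Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    # start u from the Y column with the largest variance
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(Inf, n)
    for (it in 1:500) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      t <- Xc %*% w
      q <- crossprod(Yc, t) / sum(t^2)
      u <- Yc %*% q / sum(q^2)
      if (sqrt(sum((t - t_old)^2)) < tol * sqrt(sum(t^2))) break
      t_old <- t
    }
    tt <- sum(t^2)
    if (tt < 1e-14) { W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Q <- Q[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      ncomp <- a - 1L; break }
    pvec <- crossprod(Xc, t) / tt
    qvec <- crossprod(Yc, t) / tt
    Xc <- Xc - t %*% t(pvec)
    Yc <- Yc - t %*% t(qvec)
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- qvec; Tm[, a] <- t
  }
  assert_that(ncomp >= 1, "NIPALS failed: no usable component")
  # B = W (P'W)^{-1} Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(B = B, intercept = ymean - as.vector(xmean %*% B),
                 xmean = xmean, ymean = ymean,
                 scores = Tm, loadings = P, weights = W, yloadings = Q,
                 ncomp = ncomp),
            class = "pls2_model")
}

#' @export
predict.pls2_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata %*% object$B, 2, object$intercept, `+`)
}

# Stratified k-fold assignment: per class, shuffle then deal round-robin.
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated RMSE of a PLS2 model
#'
#' `RMSECV = sqrt(mean((Y - Yhat)^2))` pooled over all held-out entries and
#' all response columns, with folds stratified by class.
#'
#' @param X predictor matrix.
#' @param Y response matrix (one-hot labels).
#' @param ncomp PLS components.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param y optional class labels for stratification (defaults to the
#'   argmax of `Y`).
#' @return RMSECV, a scalar.
#' @export
rmsecv_kfold <- function(X, Y, ncomp, folds = 5L, seed = 1L, y = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  assert_that(folds >= 2, "need folds >= 2")
  if (is.null(y)) y <- max.col(Y, ties.method = "first")
  fold_of <- stratified_folds(y, folds, seed)
  if (any(vapply(split(y, fold_of), function(v) length(unique(v)), 1L) == 1L))
    warning("a fold contains a single class; stratification impossible")
  sse <- 0; m <- 0
  for (f in seq_len(folds)) {
    te <- fold_of == f
    nc <- min(ncomp, sum(!te) - 1L, ncol(X))
    fit <- pls2_fit(X[!te, , drop = FALSE], Y[!te, , drop = FALSE], nc)
    err <- Y[te, , drop = FALSE] - predict(fit, X[te, , drop = FALSE])
    sse <- sse + sum(err^2); m <- m + length(err)
  }
  sqrt(sse / m)
}

#' CARS configuration
#'
#' @param n_runs number of Monte-Carlo sampling runs `N` (default 50).
#' @param mc_fraction fraction of rows drawn per run (default 0.8).
#' @param max_pls_components cap on PLS components (default 10).
#' @param cv_folds folds for RMSECV (default 5).
#' @param seed integer seed.
#' @return A list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50L, mc_fraction = 0.8,
                        max_pls_components = 10L, cv_folds = 5L, seed = 1L) {
  assert_that(n_runs >= 2, "n_runs must be >= 2")
  assert_that(mc_fraction > 0 && mc_fraction < 1,
              "mc_fraction must be in (0, 1)")
  structure(list(n_runs = as.integer(n_runs), mc_fraction = mc_fraction,
                 max_pls_components = as.integer(max_pls_components),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "cars_config")
}

# Exponentially decreasing function (EDF) keep-ratios for CARS:
# r_i = a exp(-k i) with r_1 = 1 and ceil(r_N p) = 2.
cars_keep_ratio <- function(i, p, N) {
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  a * exp(-k * i)
}

#' CARS enforced-reduction schedule
#'
#' The exponentially decreasing function (EDF) that drives CARS: run `i`
#' of `N` keeps `ceiling(r_i * p)` variables with
#' `r_i = a * exp(-k * i)`, `a = (p/2)^(1/(N-1))`,
#' `k = log(p/2) / (N-1)`, so run 1 keeps all `p` variables and run `N`
#' keeps 2.
#'
#' @param p number of variables.
#' @param n_runs number of sampling runs `N`.
#' @return Integer vector of length `n_runs` of enforced subset sizes.
#' @export
cars_edf_schedule <- function(p, n_runs) {
  pmin(as.integer(ceiling(cars_keep_ratio(seq_len(n_runs), p, n_runs) * p)),
       as.integer(p))
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Runs `N` Monte-Carlo sampling runs. In run `i`: (a) draw
#' `ceil(mc_fraction * n)` calibration rows; (b) fit PLS2 on the current
#' variable set and score each variable by the L2 norm of its row of the
#' coefficient matrix, normalised to sum 1; (c) enforce the exponentially
#' decreasing schedule by keeping the top `ceil(r_i * p)` variables, where
#' `r_i = a exp(-k i)` with `a = (p/2)^(1/(N-1))`, `k = log(p/2)/(N-1)`
#' (all `p` variables at run 1, two at run `N`); (d) adaptive reweighted
#' sampling: `ceil(r_i * p)` weighted draws with replacement, retaining the
#' variables drawn at least once; (e) record the retained subset's RMSECV.
#' The subset with the minimum RMSECV wins.
#'
#' The number of PLS components is chosen once on the full matrix by
#' cross-validated RMSECV over `1..max_pls_components` and then held fixed.
#'
#' @param table a [spectra_table()] (typically SNV-corrected).
#' @param config a [cars_config()].
#' @return A `selection_result`: list with `selected_indices`,
#'   `selected_nm`, `criterion_curve` (per-run RMSECV), `trace` (tibble of
#'   per-run subset sizes), `method`, `seed`, `ncomp`.
#' @export
cars_select <- function(table, config = cars_config()) {
  assert_that(inherits(table, "spectra_table"), "`table` must be a spectra_table")
  X <- table$X; y <- table$y
  n <- nrow(X); p <- ncol(X)
  assert_that(p >= 10, "need p >= 10 variables")
  K <- max(y)
  Y <- one_hot(y, K)
  N <- config$n_runs
  # Fix the component count once on the full matrix.
  ncomp_grid <- seq_len(min(config$max_pls_components, n - 1L, p))
  cv <- vapply(ncomp_grid, function(nc)
    rmsecv_kfold(X, Y, nc, config$cv_folds, seed = config$seed, y = y),
    numeric(1))
  ncomp <- ncomp_grid[which.min(cv)]

  run_seeds <- with_seed(config$seed,
                         sample.int(.Machine$integer.max %/% 2, N))
  schedule <- cars_edf_schedule(p, N)
  current <- seq_len(p)
  sizes_enforced <- integer(N); sizes_retained <- integer(N)
  rmsecv <- rep(Inf, N)
  subsets <- vector("list", N)
  n_cal <- ceiling(config$mc_fraction * n)
  for (i in seq_len(N)) {
    with_seed(run_seeds[i], {
      cal <- sample.int(n, n_cal)
      nc_i <- min(ncomp, length(current), n_cal - 1L)
      fit <- pls2_fit(X[cal, current, drop = FALSE], Y[cal, , drop = FALSE],
                      nc_i)
      w <- sqrt(rowSums(fit$B^2))
      w <- w / sum(w)
      n_keep <- min(schedule[i], length(current))
      keep <- current[order(w, decreasing = TRUE)[seq_len(n_keep)]]
      w_keep <- w[match(keep, current)]
      sizes_enforced[i] <- n_keep
      # adaptive reweighted sampling on the enforced set
      drawn <- keep[sample.int(length(keep), n_keep, replace = TRUE,
                               prob = w_keep)]
      retained <- sort(unique(drawn))
      sizes_retained[i] <- length(retained)
      subsets[[i]] <- retained
      if (length(retained) >= max(2L, 1L)) {
        nc_r <- min(ncomp, length(retained), n - ceiling(n / config$cv_folds) - 1L)
        if (nc_r >= 1) {
          rmsecv[i] <- rmsecv_kfold(X[, retained, drop = FALSE], Y, nc_r,
                                    config$cv_folds, seed = run_seeds[i],
                                    y = y)
        }
      }
      current <- retained
    })
  }
  best <- which.min(rmsecv)
  selected <- subsets[[best]]
  structure(list(selected_indices = selected,
                 selected_nm = table$wavelength[selected],
                 criterion_curve = rmsecv,
                 trace = tibble::tibble(run = seq_len(N),
                                        size_schedule = schedule,
                                        size_enforced = sizes_enforced,
                                        size_retained = sizes_retained,
                                        rmsecv = rmsecv),
                 best_run = best, method = "CARS", seed = config$seed,
                 ncomp = ncomp),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d bands selected (criterion %.4f)\n",
              x$method, length(x$selected_indices),
              min(x$criterion_curve, na.rm = TRUE)))
  cat(" ", paste(round(x$selected_nm, 1), collapse = ", "), "nm\n")
  invisible(x)
}

# One SPA chain: forward selection of max_vars columns starting from j,
# each step appending the column of largest norm after projection onto the
# orthogonal complement of the span of the chosen columns. Works on the
# Gram matrix G = X'X: the squared residual norm of column c after
# projecting out the chosen set is tracked incrementally via Gram-Schmidt
# rows (O(p * m) per step instead of O(n * p) on X itself).
spa_chain_gram <- function(G, j, max_vars) {
  p <- ncol(G)
  FF <- matrix(0, max_vars, p)
  r <- diag(G)
  tol <- max(r) * 1e-12
  chain <- integer(0)
  cur <- as.integer(j)
  for (step in seq_len(max_vars)) {
    if (r[cur] <= tol) break  # collinear residual: truncate the chain
    chain <- c(chain, cur)
    if (step == 1) {
      FF[1, ] <- G[cur, ] / sqrt(r[cur])
    } else {
      prev <- seq_len(step - 1L)
      FF[step, ] <- (G[cur, ] -
                       colSums(FF[prev, , drop = FALSE] * FF[prev, cur])) /
        sqrt(r[cur])
    }
    r <- r - FF[step, ]^2
    r[chain] <- -Inf
    if (length(chain) == max_vars) break
    cur <- which.max(r)
    if (r[cur] <= tol) break
  }
  chain
}

#' Successive projections algorithm (SPA) wavelength selection
#'
#' For every starting column, builds a chain of up to `max_vars` minimally
#' collinear columns by successive orthogonal projections; every (chain
#' prefix, size m) is scored by multiple linear regression on one-hot
#' training labels and RMSEP on the validation split. The (chain, m) with
#' the minimum RMSEP wins; the final size is then reduced to the smallest
#' `m` whose RMSEP is not significantly above the minimum (F-test on the
#' squared-error ratio, `alpha = 0.25`).
#'
#' @param X_train,y_train training spectra and labels.
#' @param X_val,y_val validation spectra and labels.
#' @param max_vars maximum chain length (default 30).
#' @param wavelength optional axis for reporting selected wavelengths.
#' @param alpha F-test level for the parsimony rule.
#' @return A `selection_result` with the per-size best-RMSEP curve in
#'   `criterion_curve`.
#' @export
spa_select <- function(X_train, y_train, X_val, y_val, max_vars = 30L,
                       wavelength = NULL, alpha = 0.25) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  n <- nrow(X_train); p <- ncol(X_train)
  assert_that(max_vars <= min(n - 1, p),
              "max_vars (%d) exceeds min(n_train - 1, p) = %d", max_vars,
              min(n - 1, p))
  K <- max(c(y_train, y_val))
  Yt <- one_hot(y_train, K); Yv <- one_hot(y_val, K)
  # centre once; MLR carries an intercept via the centring
  xm <- colMeans(X_train); ym <- colMeans(Yt)
  Xt <- sweep(X_train, 2, xm); Xv <- sweep(X_val, 2, xm)
  Yt_c <- sweep(Yt, 2, ym)
  best <- list(rmsep = Inf, chain = NULL, m = 0L, start = 0L)
  curve <- rep(Inf, max_vars)
  Gfull <- crossprod(Xt)
  Hfull <- crossprod(Xt, Yt_c)
  ridge <- max(diag(Gfull)) * 1e-10
  for (j in seq_len(p)) {
    chain <- spa_chain_gram(Gfull, j, max_vars)
    if (length(chain) == 0) next
    # prefix regressions via the chain's Gram matrix (chain columns are
    # near-orthogonal by construction, so normal equations are stable)
    G <- Gfull[chain, chain, drop = FALSE]
    H <- Hfull[chain, , drop = FALSE]
    Vv <- Xv[, chain, drop = FALSE]
    for (m in seq_along(chain)) {
      cf <- tryCatch(solve(G[seq_len(m), seq_len(m), drop = FALSE] +
                             diag(ridge, m),
                           H[seq_len(m), , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(cf)) next
      pred <- sweep(Vv[, seq_len(m), drop = FALSE] %*% cf, 2, ym, `+`)
      rmsep <- sqrt(mean((Yv - pred)^2))
      if (rmsep < curve[m]) curve[m] <- rmsep
      if (rmsep < best$rmsep - 1e-12) {
        best <- list(rmsep = rmsep, chain = chain, m = m, start = j)
      }
    }
  }
  assert_that(is.finite(best$rmsep), "SPA found no usable subset")
  # Parsimony: smallest m along the winning chain whose RMSEP is not
  # significantly above the minimum (F-test on squared-error ratios).
  df <- length(Yv)
  fcrit <- stats::qf(1 - alpha, df, df)
  final_m <- best$m
  chain <- best$chain
  G <- Gfull[chain, chain, drop = FALSE]
  H <- Hfull[chain, , drop = FALSE]
  for (m in seq_len(best$m)) {
    cf <- solve(G[seq_len(m), seq_len(m), drop = FALSE] + diag(ridge, m),
                H[seq_len(m), , drop = FALSE])
    pred <- sweep(Xv[, chain[seq_len(m)], drop = FALSE] %*% cf, 2, ym, `+`)
    rmsep <- sqrt(mean((Yv - pred)^2))
    if (rmsep^2 / best$rmsep^2 < fcrit) { final_m <- m; break }
  }
  selected <- sort(chain[seq_len(final_m)])
  if (is.null(wavelength)) wavelength <- seq_len(p)
  structure(list(selected_indices = selected,
                 selected_nm = wavelength[selected],
                 criterion_curve = curve,
                 trace = tibble::tibble(size = seq_len(max_vars),
                                        best_rmsep = curve),
                 best_start = best$start, best_m = best$m,
                 final_m = final_m,
                 method = "SPA", seed = NA_integer_),
            class = "selection_result")
}

#' Train a PLS-DA classifier with a component grid search
#'
#' Fits one-hot PLS2 models over `ncomp_grid`, predicts classes by the
#' argmax of the predicted responses, and retains the component count with
#' the best validation accuracy (ties toward fewer components).
#'
#' @param table_train,table_val training and validation [spectra_table()]s.
#' @param ncomp_grid candidate component counts (default `1:20`).
#' @return Object of class `plsda_model` with the winning `pls2_model`,
#'   `ncomp`, `val_accuracy` and the grid accuracies.
#' @export
train_plsda <- function(table_train, table_val, ncomp_grid = 1:20) {
  Xt <- table_train$X; yt <- table_train$y
  Xv <- table_val$X; yv <- table_val$y
  K <- max(c(yt, yv))
  ncomp_grid <- ncomp_grid[ncomp_grid <= min(nrow(Xt) - 1L, ncol(Xt))]
  assert_that(length(ncomp_grid) > 0, "ncomp_grid empty after rank capping")
  Yt <- one_hot(yt, K)
  acc <- vapply(ncomp_grid, function(nc) {
    fit <- pls2_fit(Xt, Yt, nc)
    mean(max.col(predict(fit, Xv), ties.method = "first") == yv)
  }, numeric(1))
  ncomp <- ncomp_grid[which.max(acc)]  # first max -> smallest ncomp on ties
  fit <- pls2_fit(Xt, Yt, ncomp)
  structure(list(fit = fit, ncomp = ncomp, K = K,
                 val_accuracy = max(acc),
                 grid = tibble::tibble(ncomp = ncomp_grid, accuracy = acc)),
            class = "plsda_model")
}

#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "response"),
                                ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spectra_table")) newdata <- newdata$X
  scores <- predict(object$fit, newdata)
  if (type == "response") return(scores)
  max.col(scores, ties.method = "first")
}

#' Train an RBF-kernel SVM with grid search
#'
#' One-vs-one multiclass support vector machine with a Gaussian kernel
#' (libsvm). The `(C, gamma)` pair with the best validation accuracy is
#' retained; ties resolve toward smaller `C`, then smaller `gamma`. Spectra
#' are expected to be SNV-preprocessed.
#'
#' @param table_train,table_val training and validation [spectra_table()]s.
#' @param C_grid cost grid (default `2^seq(-5, 15, 2)`).
#' @param gamma_grid kernel width grid (default `2^seq(-15, 3, 2)`).
#' @return Object of class `svm_model` with the winning `e1071::svm` fit,
#'   `C`, `gamma`, `val_accuracy` and the grid accuracies.
#' @export
train_svm_rbf <- function(table_train, table_val,
                          C_grid = 2^seq(-5, 15, 2),
                          gamma_grid = 2^seq(-15, 3, 2)) {
  Xt <- table_train$X; yt <- factor(table_train$y)
  Xv <- table_val$X; yv <- table_val$y
  grid <- expand.grid(gamma = sort(gamma_grid), C = sort(C_grid))
  grid <- grid[order(grid$C, grid$gamma), ]
  acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- e1071::svm(Xt, yt, kernel = "radial", cost = grid$C[i],
                      gamma = grid$gamma[i], scale = FALSE)
    acc[i] <- mean(as.integer(as.character(predict(fit, Xv))) == yv)
  }
  best <- which.max(acc)  # grid ordered by (C, gamma): first max = smallest
  fit <- e1071::svm(Xt, yt, kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], scale = FALSE)
  structure(list(fit = fit, C = grid$C[best], gamma = grid$gamma[best],
                 val_accuracy = acc[best],
                 grid = tibble::tibble(C = grid$C, gamma = grid$gamma,
                                       accuracy = acc)),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_table")) newdata <- newdata$X
  as.integer(as.character(predict(object$fit, newdata)))
}
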