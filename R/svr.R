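#' Standardize feature matrices
#'
#' Centers and scales the columns of a training matrix to mean 0, SD 1 and
#' applies either the training statistics (`"train-stats"`, the default,
#' used when testing units are of the same kind as the training units) or
#' the other matrix's own statistics (`"self-stats"`, used for sire-average
#' testing sets whose scale differs from the training records) to a second
#' matrix.
#'
#' @param train_x numeric training matrix.
#' @param other_x optional second matrix with the same columns.
#' @param mode `"train-stats"` or `"self-stats"`.
#' @return list with `train`, `other` (NULL if absent), `center`, `scale`.
#' @export
standardize <- function(train_x, other_x = NULL,
                        mode = c("train-stats", "self-stats")) {
  mode <- match.arg(mode)
  ctr <- colMeans(train_x)
  scl <- apply(train_x, 2, sd)
  if (any(scl == 0))
    stopf("zero-variance training column(s): %s",
          paste(utils::head(colnames(train_x)[scl == 0] %||%
                              which(scl == 0), 5), collapse = ", "))
  tr <- sweep(sweep(train_x, 2, ctr), 2, scl, "/")
  ot <- NULL
  if (!is.null(other_x)) {
    if (mode == "self-stats") {
      if (nrow(other_x) < 2)
        stopf("self-stats standardization needs at least 2 rows")
      octr <- colMeans(other_x)
      oscl <- apply(other_x, 2, sd)
      if (any(oscl == 0))
        stopf("zero-variance column(s) in other_x under self-stats: %s",
              paste(utils::head(colnames(other_x)[oscl == 0] %||%
                                  which(oscl == 0), 5), collapse = ", "))
      ot <- sweep(sweep(other_x, 2, octr), 2, oscl, "/")
    } else {
      ot <- sweep(sweep(other_x, 2, ctr), 2, scl, "/")
    }
  }
  list(train = tr, other = ot, center = ctr, scale = scl)
}

#' Epsilon-insensitive support vector regression with Gaussian kernel
#'
#' Fits the SVR dual by sequential minimal optimization: deviations inside
#' a tube of half-width `epsilon` around the regression function are not
#' penalized, larger deviations cost `C` per unit, and the function lives in
#' the reproducing-kernel space of the Gaussian radial basis kernel
#' k(u, v) = exp(-gamma ||u - v||^2). By default features and target are
#' standardized internally on the training data (so `epsilon` is expressed
#' in target standard deviations) and predictions are mapped back.
#'
#' @param x numeric feature matrix (animals x SNPs).
#' @param y numeric response vector.
#' @param C cost parameter (> 0).
#' @param gamma Gaussian kernel width (> 0); default 1/ncol(x).
#' @param epsilon tube half-width on the (scaled) target; default 0.1.
#' @param scale standardize x columns and y internally (default TRUE).
#' @param tol SMO convergence tolerance on the maximal KKT violation.
#' @param max_iter cap on SMO pair updates.
#' @return an object of class `svr` with the dual coefficients
#'   (alpha - alpha*), bias, kernel settings, scaling parameters, fitted
#'   values and the dual objective value.
#' @seealso [tune_svr()] for grid search, [predict.svr()].
#' @export
svr <- function(x, y, C = 1, gamma = NULL, epsilon = 0.1, scale = TRUE,
                tol = 1e-6, max_iter = 1e7) {
  x <- as.matrix(x)
  if (!is.numeric(x) || !is.numeric(y)) stopf("x and y must be numeric")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("non-finite values in x or y")
  n <- nrow(x)
  if (n < 2 || length(y) != n) stopf("need n >= 2 rows of x matching y")
  if (C <= 0 || epsilon < 0) stopf("C must be > 0 and epsilon >= 0")
  gamma <- gamma %||% (1 / ncol(x))
  if (gamma <= 0) stopf("gamma must be > 0")

  if (scale) {
    x_center <- colMeans(x)
    x_scale <- apply(x, 2, sd)
    x_scale[x_scale < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
    y_center <- mean(y)
    y_scale <- sd(y)
    if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
    ys <- (y - y_center) / y_scale
  } else {
    x_center <- rep(0, ncol(x)); x_scale <- rep(1, ncol(x))
    y_center <- 0; y_scale <- 1
    xs <- x; ys <- y
  }
  D2 <- sq_dist_cpp(xs, xs)
  K <- rbf_kernel_cpp(D2, gamma)
  sol <- svr_smo_cpp(K, ys, C, epsilon, tol, as.integer(max_iter))
  beta <- as.numeric(sol$beta)
  fitted_s <- as.numeric(K %*% beta + sol$b)
  obj <- structure(list(dual = beta, b = sol$b, C = C, gamma = gamma,
                        epsilon = epsilon,
                        x_train = xs, x_center = x_center, x_scale = x_scale,
                        y_center = y_center, y_scale = y_scale,
                        fitted_scaled = fitted_s, y_scaled = ys,
                        fitted = fitted_s * y_scale + y_center, y = y,
                        n_sv = sum(abs(beta) > 1e-10),
                        iter = sol$iter, converged = sol$converged,
                        objective = sol$objective,
                        call = match.call()),
                   class = "svr")
  obj
}

#' @export
print.svr <- function(x, ...) {
  cat("Epsilon-insensitive SVR (Gaussian kernel)\n")
  cat(sprintf("  n = %d, support vectors = %d\n", length(x$dual), x$n_sv))
  cat(sprintf("  C = %g, gamma = %g, epsilon = %g\n", x$C, x$gamma, x$epsilon))
  cat(sprintf("  dual objective = %.6g (%s, %d SMO steps)\n", x$objective,
              if (x$converged) "converged" else "iteration cap hit", x$iter))
  invisible(x)
}

#' @export
summary.svr <- function(object, ...) {
  res <- object$y - object$fitted
  cat("Epsilon-insensitive SVR (Gaussian kernel)\n")
  cat(sprintf("  n = %d, support vectors = %d (%.0f%%)\n",
              length(object$dual), object$n_sv,
              100 * object$n_sv / length(object$dual)))
  cat(sprintf("  C = %g, gamma = %g, epsilon = %g\n",
              object$C, object$gamma, object$epsilon))
  cat(sprintf("  training RMSE = %.4g, in-tube fraction = %.2f\n",
              sqrt(mean(res^2)),
              mean(abs(object$y_scaled - object$fitted_scaled) <= object$epsilon)))
  invisible(object)
}

#' @export
coef.svr <- function(object, ...) {
  setNames(c(object$dual, object$b),
           c(paste0("beta", seq_along(object$dual)), "b"))
}

#' @export
fitted.svr <- function(object, ...) object$fitted

#' @export
residuals.svr <- function(object, ...) object$y - object$fitted

#' Predict from a fitted SVR model
#'
#' @param object an [svr()] fit.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric predictions on the original response scale.
#' @export
predict.svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  Kc <- rbf_kernel_cpp(sq_dist_cpp(xs, object$x_train), object$gamma)
  as.numeric(Kc %*% object$dual + object$b) * object$y_scale + object$y_center
}

#' Grid search for SVR hyper-parameters by inner cross-validation
#'
#' Exhaustive search over the cost and kernel-width grids, scored by the
#' mean validation mean-squared error over an inner k-fold split of the
#' training data; ties break toward smaller C, then smaller gamma. Squared
#' distance matrices are computed once per inner split and shared across
#' the grid.
#'
#' @param x,y training data.
#' @param C_grid,gamma_grid candidate values to search.
#' @param epsilon tube half-width passed to every fit.
#' @param inner_k number of inner folds (default 6).
#' @param seed seed for the inner split.
#' @param tol,max_iter SMO settings forwarded to the fits.
#' @return list with `C`, `gamma`, and `cv_mse` (matrix C x gamma of mean
#'   inner MSE).
#' @export
tune_svr <- function(x, y, C_grid = c(0.001, 0.1, 1, 5, 10),
                     gamma_grid = c(0.005, 0.05, 0.5, 5),
                     epsilon = 0.1, inner_k = 6, seed = 1,
                     tol = 1e-3, max_iter = 1e6) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < inner_k) stopf("need at least inner_k = %d observations", inner_k)
  C_grid <- sort(C_grid)
  gamma_grid <- sort(gamma_grid)
  folds <- make_folds(n, inner_k, seed)
  se_sum <- matrix(0, length(C_grid), length(gamma_grid),
                   dimnames = list(paste0("C=", C_grid),
                                   paste0("g=", gamma_grid)))
  for (f in folds) {
    tr <- setdiff(seq_len(n), f)
    xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
    xc <- colMeans(xtr); xsd <- apply(xtr, 2, sd); xsd[xsd < 1e-12] <- 1
    xs <- sweep(sweep(xtr, 2, xc), 2, xsd, "/")
    vs <- sweep(sweep(x[f, , drop = FALSE], 2, xc), 2, xsd, "/")
    yc <- mean(ytr); ysd <- sd(ytr); if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
    ys <- (ytr - yc) / ysd
    D2t <- sq_dist_cpp(xs, xs)
    D2v <- sq_dist_cpp(vs, xs)
    for (gi in seq_along(gamma_grid)) {
      K <- rbf_kernel_cpp(D2t, gamma_grid[gi])
      Kv <- rbf_kernel_cpp(D2v, gamma_grid[gi])
      for (ci in seq_along(C_grid)) {
        sol <- svr_smo_cpp(K, ys, C_grid[ci], epsilon, tol,
                           as.integer(max_iter))
        pred <- as.numeric(Kv %*% sol$beta + sol$b) * ysd + yc
        se_sum[ci, gi] <- se_sum[ci, gi] + mean((y[f] - pred)^2) / length(folds)
      }
    }
  }
  # ties break toward smaller C, then smaller gamma
  pairs <- expand.grid(ci = seq_along(C_grid), gi = seq_along(gamma_grid))
  pairs <- pairs[order(C_grid[pairs$ci], gamma_grid[pairs$gi]), ]
  vals <- se_sum[cbind(pairs$ci, pairs$gi)]
  best <- pairs[which.min(vals), ]
  list(C = C_grid[best$ci], gamma = gamma_grid[best$gi], cv_mse = se_sum)
}
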