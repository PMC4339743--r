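#' Elastic-net fit at a fixed penalty
#'
#' Minimizes `RSS + lambda * (alpha * ||beta||_1 + (1 - alpha)/2 *
#' ||beta||_2^2)` by cyclic coordinate descent with an unpenalized
#' intercept. Predictors are standardized internally by default (mean 0,
#' variance 1 with denominator n) and coefficients are returned on the
#' original scale; the penalty applies to the standardized coefficients, and
#' `lambda` is interpreted on that standardized scale (the scale of
#' [lambda_grid()]). Every fit carries a subgradient stationarity (KKT)
#' certificate evaluated on the standardized problem.
#'
#' @param x Numeric matrix (n x p) or a `design_matrix`.
#' @param y Numeric response of length n.
#' @param lambda Nonnegative penalty.
#' @param alpha Mixing parameter in `[0, 1]`; 1 is the lasso, 0 pure ridge.
#' @param standardize Standardize predictors internally (default `TRUE`).
#' @param tol Coordinate-descent convergence tolerance.
#' @param max_iter Maximum coordinate passes.
#' @return Object of class `enet_fit`: `beta` (original scale), `intercept`,
#'   `selected` (indices of nonzero coefficients), `mse`, `kkt` (maximum
#'   stationarity violation on the standardized problem), plus the penalty
#'   configuration.
#' @export
fit_enet <- function(x, y, lambda, alpha = 0.5, standardize = TRUE,
                     tol = 1e-10, max_iter = 100000L) {
  x <- design_x(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  std <- standardize_x(x, standardize)
  yc <- y - mean(y)
  bmat <- cd_enet_cov(crossprod(std$xs), drop(crossprod(std$xs, yc)),
                      lambda, alpha, tol, as.integer(max_iter))
  bs <- bmat[, ncol(bmat)]
  kkt <- enet_kkt_violation(std$xs, yc, bs, lambda[length(lambda)], alpha)
  beta <- bs / std$scale
  intercept <- mean(y) - sum(std$center * beta)
  fitted <- intercept + drop(x %*% beta)
  structure(list(beta = setNames(beta, colnames(x)), intercept = intercept,
                 selected = which(beta != 0), mse = mean((y - fitted)^2),
                 kkt = kkt, lambda = lambda[length(lambda)], alpha = alpha,
                 standardize = standardize),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat("Elastic-net fit: lambda =", signif(x$lambda, 4), "alpha =", x$alpha,
      "\n  ", length(x$selected), "nonzero coefficients | mse =",
      signif(x$mse, 4), "| KKT violation =", format(x$kkt, digits = 3),
      "\n")
  invisible(x)
}

standardize_x <- function(x, standardize = TRUE) {
  n <- nrow(x)
  center <- colMeans(x)
  xs <- sweep(x, 2L, center)
  if (standardize) {
    scale <- sqrt(colSums(xs^2) / n)
    scale[scale == 0] <- 1
    xs <- sweep(xs, 2L, scale, "/")
  } else {
    scale <- rep(1, ncol(x))
  }
  list(xs = xs, center = center, scale = scale)
}

#' Geometric regularization-parameter grid
#'
#' A strictly decreasing geometric sequence of `K` penalties from
#' `lambda_max` (the smallest penalty with an all-zero solution on the
#' standardized, centered problem) down to `lambda_max * ratio`. The default
#' ratio is 1e-3 when n > p and 1e-2 otherwise, the path convention of the
#' standard elastic-net software.
#'
#' @inheritParams fit_enet
#' @param K Grid length (default 100).
#' @param ratio Optional ratio of the smallest to the largest penalty.
#' @return Numeric vector of length `K`, strictly decreasing, with
#'   attributes `alpha` and `ratio`.
#' @export
lambda_grid <- function(x, y, alpha = 0.5, K = 100L, ratio = NULL,
                        standardize = TRUE) {
  x <- design_x(x)
  if (alpha <= 0) stop("alpha must be positive (lambda_max is undefined ",
                       "for pure ridge)")
  std <- standardize_x(x, standardize)
  yc <- y - mean(y)
  lambda_max <- max(abs(2 * crossprod(std$xs, yc))) / alpha
  if (is.null(ratio)) ratio <- if (nrow(x) > ncol(x)) 1e-3 else 1e-2
  out <- lambda_max * ratio^(seq(0, 1, length.out = K))
  attr(out, "alpha") <- alpha
  attr(out, "ratio") <- ratio
  out
}

# warm-started path over a descending lambda grid; returns original-scale
# coefficients (p x K), intercepts and the support indicator matrix
enet_path <- function(x, y, lambda, alpha = 0.5, standardize = TRUE,
                      tol = 1e-5, max_iter = 100000L) {
  x <- design_x(x)
  std <- standardize_x(x, standardize)
  yc <- y - mean(y)
  bmat <- cd_enet_cov(crossprod(std$xs), drop(crossprod(std$xs, yc)),
                      lambda, alpha, tol, as.integer(max_iter))
  beta <- bmat / std$scale
  intercept <- mean(y) - drop(crossprod(beta, std$center))
  list(beta = beta, intercept = intercept, support = bmat != 0,
       lambda = lambda, alpha = alpha)
}

#' Elastic net with leave-one-out cross-validation
#'
#' For every mixing parameter on `alpha_grid` a penalty grid is built on the
#' full data ([lambda_grid()]); for every `(alpha, lambda)` pair the
#' leave-one-out mean squared prediction error is computed by refitting on
#' each training set of size n - 1. The minimizing pair is refit on the full
#' data. Ties in the cross-validated MSE are broken toward the larger
#' penalty (the sparser model), then toward the earlier `alpha` on the grid.
#'
#' @inheritParams fit_enet
#' @param alpha_grid Mixing parameters to search (default 0.1, 0.2, ..., 1).
#' @param n_lambda Penalty grid length per `alpha`.
#' @param ratio Optional path ratio passed to [lambda_grid()].
#' @return List of class `enc_cv`: `alpha`, `lambda` (the optimum,
#'   `lambda_ENC`), `fit` (full-data [fit_enet()] at the optimum), `cv_mse`
#'   (matrix `length(alpha_grid)` x `n_lambda`), and `lambda_grids`.
#' @export
enc_cv <- function(x, y, alpha_grid = seq(0.1, 1, by = 0.1),
                   n_lambda = 100L, ratio = NULL, standardize = TRUE,
                   tol = 1e-5, max_iter = 100000L) {
  x <- design_x(x)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out cross-validation needs n >= 3")
  if (var(y) == 0) stop("response is constant; cross-validation undefined")
  grids <- matrix(NA_real_, length(alpha_grid), n_lambda)
  for (a in seq_along(alpha_grid))
    grids[a, ] <- lambda_grid(x, y, alpha_grid[a], K = n_lambda,
                              ratio = ratio, standardize = standardize)
  # leave-one-out folds are the outer loop so each training set's
  # cross-products are formed once and shared across the alpha grid
  se <- array(NA_real_, c(n, length(alpha_grid), n_lambda))
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]
    yt <- y[-i]
    std <- standardize_x(xt, standardize)
    yc <- yt - mean(yt)
    xtx <- crossprod(std$xs)
    xty <- drop(crossprod(std$xs, yc))
    for (a in seq_along(alpha_grid)) {
      bmat <- cd_enet_cov(xtx, xty, grids[a, ], alpha_grid[a], tol,
                          as.integer(max_iter))
      beta <- bmat / std$scale
      icpt <- mean(yt) - drop(crossprod(beta, std$center))
      pred <- drop(x[i, ] %*% beta) + icpt
      se[i, a, ] <- (y[i] - pred)^2
    }
  }
  cv_mse <- apply(se, c(2L, 3L), mean)
  best <- min(cv_mse)
  cand <- which(cv_mse <= best, arr.ind = TRUE)
  # larger lambda first (earlier grid column), then earlier alpha
  cand <- cand[order(cand[, "col"], cand[, "row"]), , drop = FALSE]
  a_star <- cand[1, "row"]
  l_star <- cand[1, "col"]
  lam_opt <- grids[a_star, l_star]
  # refit along the path down to the optimum for a warm-started solution
  fit <- fit_enet(x, y, lambda = grids[a_star, seq_len(l_star)],
                  alpha = alpha_grid[a_star], standardize = standardize,
                  tol = tol, max_iter = max_iter)
  structure(list(alpha = alpha_grid[a_star], lambda = lam_opt, fit = fit,
                 cv_mse = cv_mse, lambda_grids = grids,
                 alpha_grid = alpha_grid),
            class = "enc_cv")
}

#' @export
print.enc_cv <- function(x, ...) {
  cat("Cross-validated elastic net (leave-one-out):\n  alpha* =", x$alpha,
      "| lambda_ENC =", signif(x$lambda, 4), "| CV-MSE =",
      signif(min(x$cv_mse), 4), "\n  ", length(x$fit$selected),
      "variables selected in the full-data refit\n")
  invisible(x)
}
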