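#' Spike-and-slab prior for Bayesian model averaging
#'
#' Constructs the prior of the spike-and-slab linear model: independent
#' Bernoulli spikes with inclusion probability `pi_i = k/p` (k is the
#' expected model size), a Zellner-type slab `beta_gamma | sigma^2 ~
#' N(0, sigma^2 * Omega_gamma^{-1})` whose precision is the smoothed Fisher
#' information `Omega = (g/n) * (w * X'X + (1-w) * diag(X'X))` (the
#' `sigma^2`-free part), and `1/sigma^2 ~ Gamma(shape = nu/2, rate = ss/2)`.
#' By default `ss = 0.5 * sd(y)^2`.
#'
#' @param x Design matrix (n x p) or `design_matrix`.
#' @param y Response (used only for the default `ss`).
#' @param k Expected model size; must satisfy `0 < k < p`. Default 1.
#' @param g Prior information weight (default 1).
#' @param w Smoothing weight in `[0, 1]` between `X'X` and its diagonal
#'   (default 0.5); smoothing guarantees a positive-definite slab precision
#'   under multicollinearity.
#' @param nu Prior degrees of freedom of the noise precision (default 0.01).
#' @param ss Prior sum of squares; default `0.5 * sd(y)^2`.
#' @return Object of class `spike_slab_prior` with `pi`, `Omega`, `nu`,
#'   `ss`, `k`, `g`, `w`.
#' @export
spike_slab_prior <- function(x, y = NULL, k = 1, g = 1, w = 0.5, nu = 0.01,
                             ss = NULL) {
  x <- design_x(x)
  p <- ncol(x)
  if (k <= 0 || k >= p) stop("k must satisfy 0 < k < p")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (is.null(ss)) {
    if (is.null(y)) stop("supply y or an explicit ss")
    ss <- 0.5 * sd(y)^2
  }
  if (!is.finite(ss) || ss <= 0) stop("ss must be positive")
  structure(list(pi = rep(k / p, p),
                 Omega = smoothed_prior_precision(x, g = g, w = w),
                 nu = nu, ss = ss, k = k, g = g, w = w),
            class = "spike_slab_prior")
}

#' Smoothed prior precision (sigma^2-free Fisher information)
#'
#' `Omega = (g/n) * (w * X'X + (1-w) * diag(X'X))`; interpolating `X'X`
#' with its diagonal makes every principal submatrix positive definite as
#' long as all columns have positive norm, even under exact collinearity.
#'
#' @inheritParams spike_slab_prior
#' @return A p x p symmetric positive-definite matrix.
#' @export
smoothed_prior_precision <- function(x, g = 1, w = 0.5) {
  x <- design_x(x)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  xtx <- crossprod(x)
  if (any(diag(xtx) <= 0)) stop("every column must have positive norm")
  (g / nrow(x)) * (w * xtx + (1 - w) * diag(diag(xtx), ncol(x)))
}

#' Closed-form log marginal of a model indicator
#'
#' `log p(y | gamma) + log p(gamma)` under the spike-and-slab prior,
#' obtained from normal--inverse-gamma conjugacy: with `Omega_g` the active
#' submatrix of the slab precision, posterior precision `Vinv = X_g'X_g +
#' Omega_g`, `S = y'y - y'X_g Vinv^{-1} X_g'y`, the marginal is proportional
#' to `|Omega_g|^{1/2} |Vinv|^{-1/2} (ss/2 + S/2)^{-(nu+n)/2}` with all
#' gamma-free constants included.
#'
#' @inheritParams spike_slab_prior
#' @param gamma Binary indicator vector of length p (the null model is
#'   allowed).
#' @param prior A [spike_slab_prior()].
#' @return The log marginal (a finite real).
#' @export
log_marginal <- function(gamma, x, y, prior) {
  x <- design_x(x)
  stopifnot(inherits(prior, "spike_slab_prior"))
  if (length(gamma) != ncol(x)) stop("gamma must have length p")
  ss_log_marginal(crossprod(x), drop(crossprod(x, y)), sum(y^2),
                  prior$Omega, prior$pi, prior$nu, prior$ss, nrow(x),
                  as.integer(gamma != 0))
}

#' Gibbs sampler for spike-and-slab model averaging
#'
#' Stochastic-search variable selection: each sweep updates every spike
#' indicator from its conditional with the coefficients and noise variance
#' integrated out analytically, then redraws `(sigma^2, beta_gamma)` from
#' their exact conditional posteriors. By default the predictors and the
#' response are centered internally (a flat-prior intercept); the prior is
#' then built on the centered design.
#'
#' @inheritParams spike_slab_prior
#' @param prior Optional [spike_slab_prior()]; built with defaults (on the
#'   centered data when `center = TRUE`) if omitted.
#' @param n_iterations Total MCMC sweeps (default 10000).
#' @param burn_in Initial sweeps to discard (default 1000).
#' @param seed Integer seed.
#' @param center Center `x` and `y` internally (default `TRUE`).
#' @param init Initial active set: `"enet"` starts from the cross-validated
#'   elastic-net support truncated to the `ceiling(k)` largest
#'   coefficients; `"null"` starts empty; or an integer vector of indices.
#' @param record_beta Keep the coefficient draws (default `TRUE`).
#' @return Object of class `posterior_draws` with `gamma_draws` (D x p),
#'   `beta_draws` (D x p, zero wherever `gamma_draws` is zero),
#'   `sigma2_draws`, `n_iterations`, `burn_in`, and the centering offsets.
#' @export
gibbs_sample <- function(x, y, prior = NULL, n_iterations = 10000L,
                         burn_in = 1000L, seed = 1L, center = TRUE,
                         init = "enet", record_beta = TRUE) {
  x <- design_x(x)
  if (n_iterations <= burn_in) stop("n_iterations must exceed burn_in")
  x_center <- if (center) colMeans(x) else rep(0, ncol(x))
  y_center <- if (center) mean(y) else 0
  xc <- sweep(x, 2L, x_center)
  yc <- y - y_center
  if (is.null(prior)) prior <- spike_slab_prior(xc, yc)
  p <- ncol(x)
  gamma0 <- integer(p)
  if (is.numeric(init)) {
    gamma0[as.integer(init)] <- 1L
  } else if (identical(init, "enet")) {
    gamma0[head(enet_support_rank(xc, yc), ceiling(prior$k))] <- 1L
  } else if (!identical(init, "null")) {
    stop("init must be 'enet', 'null' or an index vector")
  }
  set.seed(seed)
  draws <- gibbs_spikeslab_cpp(xc, yc, prior$Omega, prior$pi, prior$nu,
                               prior$ss, as.integer(n_iterations),
                               as.integer(burn_in), gamma0,
                               isTRUE(record_beta))
  structure(c(draws,
              list(n_iterations = as.integer(n_iterations),
                   burn_in = as.integer(burn_in), prior = prior,
                   x_center = x_center, y_center = y_center,
                   taxon_ids = colnames(x))),
            class = "posterior_draws")
}

# indices of the cross-validated elastic-net support, strongest first
enet_support_rank <- function(x, y) {
  b <- enc_cv(x, y)$fit$beta
  ord <- order(abs(b), decreasing = TRUE)
  ord[b[ord] != 0]
}

#' @export
print.posterior_draws <- function(x, ...) {
  D <- nrow(x$gamma_draws)
  cat("Spike-and-slab posterior:", D, "draws (",
      x$n_iterations, "sweeps,", x$burn_in, "burn-in )\n  mean model size",
      signif(mean(rowSums(x$gamma_draws)), 3), "\n")
  invisible(x)
}

#' Inclusion probabilities from posterior draws
#'
#' The proportion of retained draws in which each coefficient is nonzero.
#'
#' @param draws A [gibbs_sample()] result.
#' @return Numeric vector of length p in `[0, 1]`.
#' @export
inclusion_from_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  probs <- if (!is.null(draws$beta_draws)) colMeans(draws$beta_draws != 0)
           else colMeans(draws$gamma_draws != 0)
  setNames(probs, draws$taxon_ids)
}

#' Running-mean convergence diagnostic
#'
#' Relative drift of the running mean of the per-sweep model size over the
#' last half of the chain; values near zero indicate a flat running mean.
#'
#' @param draws A [gibbs_sample()] result.
#' @return The relative drift (a nonnegative number).
#' @export
running_mean_drift <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  sizes <- rowSums(draws$gamma_draws)
  rm_all <- cumsum(sizes) / seq_along(sizes)
  half <- seq(floor(length(sizes) / 2), length(sizes))
  seg <- rm_all[half]
  ref <- mean(seg)
  if (ref == 0) return(0)
  (max(seg) - min(seg)) / ref
}

#' Cross-validated expected model size
#'
#' Chooses the expected model size `k` by K-fold cross-validation: for each
#' candidate `k` a shortened chain is run on each training fold, held-out
#' responses are predicted by the posterior-mean linear predictor, and the
#' `k` minimizing the mean squared prediction error is refit on the full
#' data with full-length chains. Ties are broken toward the smaller `k`.
#'
#' @inheritParams gibbs_sample
#' @param k_grid Candidate expected model sizes; values `>= p` are dropped.
#'   Default `c(1, 2, 4, 8, 16, 32)` capped below p.
#' @param folds Number of cross-validation folds (default 5).
#' @param cv_iterations,cv_burn_in Chain length for the fold fits
#'   (defaults 2000 / 200).
#' @param init `"enet"` (rank candidates once on the full data by the
#'   cross-validated elastic net, then truncate to `ceiling(k)` per chain),
#'   `"null"`, or an integer vector of ranked candidate indices.
#' @return List of class `bmac_fit`: `k` (the selected size), `cv_mse`
#'   (named by `k_grid`), and `draws` (full-data [gibbs_sample()] at the
#'   optimum).
#' @export
bmac_select_k <- function(x, y, k_grid = c(1, 2, 4, 8, 16, 32),
                          folds = 5L, n_iterations = 10000L,
                          burn_in = 1000L, cv_iterations = 2000L,
                          cv_burn_in = 200L, seed = 1L, init = "enet") {
  x <- design_x(x)
  n <- nrow(x)
  p <- ncol(x)
  if (folds < 2) stop("folds must be at least 2")
  k_grid <- k_grid[k_grid < p]
  if (length(k_grid) == 0) stop("no candidate k below p")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), n))
  tries <- 0L
  while (any(vapply(seq_len(folds),
                    function(f) var(y[fold_of != f]) == 0, logical(1)))) {
    tries <- tries + 1L
    if (tries > 100L) stop("could not draw folds with non-degenerate ",
                           "training responses")
    set.seed(seed + tries)
    fold_of <- sample(rep_len(seq_len(folds), n))
  }
  # chain starts only shape the burn-in, so one full-data elastic-net
  # ranking is computed and truncated per candidate k for every chain
  rank <- if (identical(init, "enet")) enet_support_rank(x, y)
          else if (is.numeric(init)) as.integer(init)
          else integer(0)
  cv_mse <- setNames(numeric(length(k_grid)), k_grid)
  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    se <- numeric(0)
    for (f in seq_len(folds)) {
      tr <- which(fold_of != f)
      te <- which(fold_of == f)
      xt <- x[tr, , drop = FALSE]
      yt <- y[tr]
      prior <- spike_slab_prior(sweep(xt, 2L, colMeans(xt)),
                                yt - mean(yt), k = k)
      dr <- gibbs_sample(xt, yt, prior = prior,
                         n_iterations = cv_iterations,
                         burn_in = cv_burn_in,
                         seed = seed + 131L * ki + f,
                         init = head(rank, ceiling(k)))
      bhat <- colMeans(dr$beta_draws)
      pred <- dr$y_center +
        drop(sweep(x[te, , drop = FALSE], 2L, dr$x_center) %*% bhat)
      se <- c(se, (y[te] - pred)^2)
    }
    cv_mse[ki] <- mean(se)
  }
  k_star <- k_grid[which.min(cv_mse)]
  prior <- spike_slab_prior(sweep(x, 2L, colMeans(x)), y - mean(y),
                            k = k_star)
  draws <- gibbs_sample(x, y, prior = prior, n_iterations = n_iterations,
                        burn_in = burn_in, seed = seed,
                        init = head(rank, ceiling(k_star)))
  structure(list(k = k_star, cv_mse = cv_mse, draws = draws),
            class = "bmac_fit")
}

#' @export
print.bmac_fit <- function(x, ...) {
  cat("Cross-validated expected model size: k* =", x$k, "\n  CV-MSE:",
      paste(names(x$cv_mse), signif(x$cv_mse, 4), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
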