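#' Fit an ensemble regression approach
#'
#' The common front-end to all eleven modeling approaches compared by the
#' package. Frequentist ensembles build a model space of `B` subsamples
#' (size `floor(n/2)`, methods ending in `S`) or bootstrap resamples
#' (methods ending in `R`), fit elastic-net regularization paths on every
#' member over a shared 100-point penalty grid, and aggregate the selection
#' indicators into per-variable inclusion probabilities; Bayesian ensembles
#' average over models drawn from a spike-and-slab posterior by MCMC.
#'
#' Methods:
#' * `ENC` — the non-ensemble baseline: elastic net with leave-one-out
#'   cross-validated mixing and penalty; outputs a selected set and
#'   coefficients, no inclusion probabilities.
#' * `PS` / `PR` — stability selection with per-family error control:
#'   a stable set at the error-bounded penalty region.
#' * `LS` / `LR` — inclusion probabilities at the single cross-validated
#'   penalty `lambda_ENC`.
#' * `SS` / `SR` — inclusion probabilities averaged over the whole penalty
#'   grid.
#' * `SSW` / `SRW` — grid-averaged with weights proportional to the
#'   selection events at each penalty.
#' * `BMA` — spike-and-slab Bayesian model averaging with expected model
#'   size 1.
#' * `BMAC` — expected model size chosen by K-fold cross-validation.
#'
#' The elastic-net mixing parameter used inside the frequentist ensembles is
#' fixed at the full-data cross-validated optimum unless `alpha` is given.
#'
#' @param x Design matrix (n x p) or a `design_matrix` from
#'   [build_design()].
#' @param y Continuous response of length n.
#' @param method One of `"ENC"`, `"PS"`, `"LS"`, `"SS"`, `"SSW"`, `"PR"`,
#'   `"LR"`, `"SR"`, `"SRW"`, `"BMA"`, `"BMAC"`.
#' @param B Ensemble size for the frequentist methods (default 100).
#' @param alpha Elastic-net mixing parameter; `NULL` (default) uses the
#'   cross-validated optimum.
#' @param n_lambda Penalty grid length (default 100).
#' @param pi_threshold,pfer_bound Stable-set parameters for `PS`/`PR`
#'   (defaults 0.75 and 1).
#' @param n_iterations,burn_in MCMC length for `BMA`/`BMAC` (defaults
#'   10000 / 1000).
#' @param k_grid Candidate expected model sizes for `BMAC`.
#' @param seed Integer seed; fits are deterministic given it.
#' @param lambda_enc Optional precomputed cross-validated penalty for
#'   `LS`/`LR` (must be given together with `alpha`); skips the internal
#'   cross-validation, e.g. when several methods share one dataset.
#' @param enc Optional precomputed [enc_cv()] object for the same data;
#'   supplies `alpha`, `lambda_enc`, the ENC fit, and the MCMC chain
#'   initialization, so the cross-validation runs once per dataset when
#'   several methods are compared.
#' @param ... Passed on to the underlying workers ([enc_cv()],
#'   [gibbs_sample()], [bmac_select_k()]).
#' @return Object of class `ensemble_fit` with components `method`,
#'   `inclusion` (named probabilities, or `NULL` for ENC/PS/PR),
#'   `selected` (integer indices), `beta` and `intercept` (for ENC, BMA and
#'   BMAC), `n`, `p`, and method-specific details in `details`.
#' @examples
#' tab <- generate_counts(preset_profile("fungal-like"))
#' d <- build_design(filter_zero(tab))
#' ds <- simulate_dataset(d, scenario(sparsity = 0.04, snr = 16), 1)
#' fit <- ensemble_fit(ds$x, ds$y, method = "SS", B = 25, seed = 1)
#' head(sort(fit$inclusion, decreasing = TRUE))
#' @export
ensemble_fit <- function(x, y,
                         method = c("ENC", "PS", "LS", "SS", "SSW", "PR",
                                    "LR", "SR", "SRW", "BMA", "BMAC"),
                         B = 100L, alpha = NULL, n_lambda = 100L,
                         pi_threshold = 0.75, pfer_bound = 1,
                         n_iterations = 10000L, burn_in = 1000L,
                         k_grid = c(1, 2, 4, 8, 16, 32), seed = 1L,
                         lambda_enc = NULL, enc = NULL, ...) {
  method <- match.arg(method)
  cl <- match.call()
  x <- design_x(x)
  n <- nrow(x)
  p <- ncol(x)
  inclusion <- NULL
  selected <- integer(0)
  beta <- NULL
  intercept <- NULL
  details <- list()
  if (!is.null(enc)) {
    stopifnot(inherits(enc, "enc_cv"))
    if (is.null(alpha)) alpha <- enc$alpha
    if (is.null(lambda_enc)) lambda_enc <- enc$lambda
  }

  if (method %in% c("ENC", "PS", "LS", "SS", "SSW", "PR", "LR", "SR",
                    "SRW")) {
    cv <- enc
    need_cv <- is.null(cv) &&
      (is.null(alpha) ||
         (method %in% c("ENC", "LS", "LR") && is.null(lambda_enc)))
    if (need_cv) {
      cv <- enc_cv(x, y, ...)
      if (is.null(alpha)) alpha <- cv$alpha
      lambda_enc <- cv$lambda
    }
    details$lambda_enc <- lambda_enc
    details$alpha <- alpha
    if (method == "ENC") {
      if (is.null(cv)) cv <- enc_cv(x, y, ...)
      beta <- cv$fit$beta
      intercept <- cv$fit$intercept
      selected <- cv$fit$selected
      details$cv <- cv
    } else {
      scheme <- if (substr(method, nchar(method), nchar(method)) == "R" ||
                    method %in% c("SRW")) "resample" else "subsample"
      grid <- lambda_grid(x, y, alpha, K = n_lambda)
      space <- build_model_space(n, scheme, B = B, seed = seed)
      profile <- selection_profile(x, y, space, grid, alpha)
      details$profile <- profile
      if (method %in% c("LS", "LR")) {
        li <- which.min(abs(grid - lambda_enc))
        inclusion <- inclusion_at_lambda(profile, li)
        details$lambda_index <- li
      } else if (method %in% c("SS", "SR")) {
        inclusion <- averaged_inclusion(profile)
      } else if (method %in% c("SSW", "SRW")) {
        inclusion <- weighted_inclusion(profile)
      } else {  # PS / PR
        st <- mb_stable_set(profile, pi_threshold, pfer_bound)
        selected <- st$selected
        details$stable_set <- st
      }
    }
  } else {  # BMA / BMAC
    rank_init <- if (is.null(enc)) "enet"
                 else {
                   b <- enc$fit$beta
                   ord <- order(abs(b), decreasing = TRUE)
                   ord[b[ord] != 0]
                 }
    if (method == "BMA") {
      draws <- gibbs_sample(x, y, n_iterations = n_iterations,
                            burn_in = burn_in, seed = seed,
                            init = if (is.numeric(rank_init))
                              head(rank_init, 1) else rank_init, ...)
    } else {
      bm <- bmac_select_k(x, y, k_grid = k_grid,
                          n_iterations = n_iterations, burn_in = burn_in,
                          seed = seed, init = rank_init, ...)
      draws <- bm$draws
      details$k <- bm$k
      details$cv_mse <- bm$cv_mse
    }
    details$draws <- draws
    inclusion <- inclusion_from_draws(draws)
    beta <- setNames(colMeans(draws$beta_draws), colnames(x))
    intercept <- draws$y_center - sum(draws$x_center * beta)
  }

  if (!is.null(inclusion) && length(selected) == 0)
    selected <- suppressWarnings(ld_select(inclusion))
  structure(list(method = method, inclusion = inclusion,
                 selected = selected, beta = beta, intercept = intercept,
                 n = n, p = p, seed = seed, call = cl,
                 x = x, y = y, details = details),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("Ensemble regression fit —", x$method, "\n")
  cat("  n =", x$n, " p =", x$p, "\n")
  if (!is.null(x$inclusion)) {
    top <- head(sort(x$inclusion, decreasing = TRUE), 5)
    cat("  top inclusion probabilities:\n")
    print(round(top, 3))
  }
  cat(" ", length(x$selected), "variables selected\n")
  invisible(x)
}

#' @export
summary.ensemble_fit <- function(object, ...) {
  out <- list(method = object$method, n = object$n, p = object$p,
              n_selected = length(object$selected),
              selected = object$selected,
              inclusion = object$inclusion,
              k = object$details$k,
              lambda_enc = object$details$lambda_enc)
  class(out) <- "summary.ensemble_fit"
  out
}

#' @export
print.summary.ensemble_fit <- function(x, ...) {
  cat("Method:", x$method, "  (n =", x$n, ", p =", x$p, ")\n")
  if (!is.null(x$lambda_enc))
    cat("lambda_ENC =", signif(x$lambda_enc, 4), "\n")
  if (!is.null(x$k)) cat("cross-validated expected model size k* =",
                         x$k, "\n")
  cat("Selected", x$n_selected, "variables:",
      paste(head(x$selected, 20), collapse = ", "),
      if (x$n_selected > 20) "..." else "", "\n")
  if (!is.null(x$inclusion)) {
    cat("Inclusion probability summary:\n")
    print(summary(x$inclusion))
  }
  invisible(x)
}

#' @export
coef.ensemble_fit <- function(object, ...) {
  if (is.null(object$beta))
    return(NULL)
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
predict.ensemble_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$beta))
    stop("method ", object$method, " does not estimate coefficients; ",
         "no predictions available")
  nd <- if (is.null(newdata)) object$x else design_x(newdata)
  drop(object$intercept + nd %*% object$beta)
}

#' @export
fitted.ensemble_fit <- function(object, ...) predict(object)

#' @export
residuals.ensemble_fit <- function(object, ...) {
  object$y - predict(object)
}

#' Plot the sorted inclusion-probability profile
#'
#' @param x An [ensemble_fit()] with inclusion probabilities.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.ensemble_fit <- function(x, ...) {
  if (is.null(x$inclusion))
    stop("method ", x$method, " does not produce inclusion probabilities")
  ip <- sort(x$inclusion, decreasing = TRUE)
  plot(seq_along(ip), ip, type = "b", pch = 16, cex = 0.6,
       xlab = "variable rank", ylab = "inclusion probability",
       main = paste0(x$method, ": inclusion probability profile"), ...)
  if (length(x$selected) > 0)
    abline(v = length(x$selected) + 0.5, lty = 2)
  invisible(x)
}
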