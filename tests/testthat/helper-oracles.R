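# Independent oracles used across the suite.  Each one recomputes a
# quantity by brute force (enumeration, literal loops, quadrature) and is
# kept free of the code paths it checks.

# small Gaussian regression problem with a sparse truth
toy_problem <- function(n, p, nonzero = c(1.5, -1), noise = 0.7,
                        seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(nonzero, rep(0, p - length(nonzero)))
  y <- drop(x %*% beta) + rnorm(n, 0, noise)
  list(x = x, y = y, beta = beta)
}

# exact posterior inclusion probabilities by enumerating all 2^p models
enumerate_inclusion <- function(x, y, prior) {
  p <- ncol(x)
  gam <- as.matrix(expand.grid(rep(list(0:1), p)))
  lm_all <- apply(gam, 1, function(g) log_marginal(g, x, y, prior))
  w <- exp(lm_all - max(lm_all))
  w <- w / sum(w)
  drop(crossprod(gam, w))
}

# brute-force numerical integration of likelihood x prior over (beta,
# sigma^2): tensor Gauss-Legendre over beta on a box centered at the
# least-squares solution, adaptive quadrature over the noise precision
quad_log_marginal <- function(gamma, x, y, prior, nodes = 90) {
  act <- which(gamma != 0)
  q <- length(act)
  n <- length(y)
  lp_gamma <- sum(ifelse(gamma != 0, log(prior$pi), log(1 - prior$pi)))
  if (q > 0) {
    xa <- x[, act, drop = FALSE]
    om <- prior$Omega[act, act, drop = FALSE]
    ld_om <- as.numeric(determinant(om)$modulus)
    ols <- qr.coef(qr(xa), y)
    ols[is.na(ols)] <- 0
    cn <- sqrt(colSums(xa^2))
    pw <- sqrt(diag(solve(om)))
    nn <- if (q <= 2) nodes else min(nodes, 40)
  }
  inner <- function(s_vec) {
    vapply(s_vec, function(si) {
      sig2 <- 1 / si
      sig <- sqrt(sig2)
      if (q == 0)
        return(exp(sum(dnorm(y, 0, sig, log = TRUE))))
      w_j <- sig * pmin(1 / cn, pw)
      gls <- lapply(seq_len(q), function(j) {
        pracma::gaussLegendre(nn, min(0, ols[j]) - 10 * w_j[j],
                              max(0, ols[j]) + 10 * w_j[j])
      })
      grids <- as.matrix(do.call(expand.grid, lapply(gls, `[[`, "x")))
      wts <- Reduce(`*`, do.call(expand.grid, lapply(gls, `[[`, "w")))
      resid <- matrix(y, n, nrow(grids)) - xa %*% t(grids)
      ll <- -colSums(resid^2) / (2 * sig2) - n / 2 * log(2 * pi * sig2)
      qf <- rowSums((grids %*% om) * grids)
      lpb <- -qf / (2 * sig2) - q / 2 * log(2 * pi * sig2) + 0.5 * ld_om
      sum(wts * exp(ll + lpb))
    }, numeric(1))
  }
  f <- function(s) inner(s) * dgamma(s, shape = prior$nu / 2,
                                     rate = prior$ss / 2)
  val <- integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 0)$value
  log(val) + lp_gamma
}

# elastic-net objective of the standardized problem (matches the penalty
# parameterization of fit_enet)
enet_objective <- function(xs, yc, beta, lambda, alpha) {
  sum((yc - xs %*% beta)^2) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# tie-corrected rank-statistic AUC of the thresholded inclusion scores:
# each variable is mapped to the number of thresholds it clears, then the
# Mann-Whitney statistic with average ranks is computed
mw_auc <- function(probs, truth, thresholds) {
  lev <- vapply(probs, function(pr) sum(pr > thresholds), numeric(1))
  is_true <- seq_along(probs) %in% truth
  r <- rank(lev)
  n1 <- sum(is_true)
  n0 <- sum(!is_true)
  (sum(r[is_true]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
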