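#' Build an ensemble model space by subsampling or resampling
#'
#' Generates `B` member index sets: subsampling draws `floor(n/2)` distinct
#' sample indices per member; resampling draws `n` indices with replacement
#' (the bootstrap).
#'
#' @param n Number of samples; must be at least 4.
#' @param scheme `"subsample"` or `"resample"`.
#' @param B Number of ensemble members (default 100).
#' @param seed Integer seed; the space is deterministic given the seed.
#' @return Object of class `model_space` with `members` (list of integer
#'   vectors), `scheme`, `B`, `n`, `seed`.
#' @export
build_model_space <- function(n, scheme = c("subsample", "resample"),
                              B = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (n < 4) stop("n must be at least 4")
  set.seed(seed)
  members <- if (scheme == "subsample") {
    lapply(seq_len(B), function(b) sort(sample.int(n, floor(n / 2))))
  } else {
    lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  }
  structure(list(members = members, scheme = scheme, B = as.integer(B),
                 n = as.integer(n), seed = as.integer(seed)),
            class = "model_space")
}

#' Per-member selection indicators along the regularization path
#'
#' Fits the elastic net on each ensemble member's rows at every penalty of a
#' shared grid (computed once on the full data) and records the support
#' indicator `1{j in S_lambda(b)}`. Members whose response has zero variance
#' after subsampling are refused and redrawn with a seeded retry.
#'
#' @inheritParams fit_enet
#' @param space A [build_model_space()] object.
#' @param grid Decreasing penalty grid from [lambda_grid()].
#' @return Object of class `selection_profile`: `indicator`
#'   (B x length(grid) x p binary array), `lambda` and `space`.
#' @export
selection_profile <- function(x, y, space, grid, alpha = 0.5,
                              standardize = TRUE) {
  x <- design_x(x)
  stopifnot(inherits(space, "model_space"))
  p <- ncol(x)
  K <- length(grid)
  ind <- array(0L, dim = c(space$B, K, p))
  for (b in seq_len(space$B)) {
    idx <- space$members[[b]]
    tries <- 0L
    while (var(y[idx]) == 0) {
      tries <- tries + 1L
      if (tries > 100L)
        stop("member ", b, ": could not draw a non-degenerate response")
      set.seed(space$seed + 1000L * b + tries)
      idx <- if (space$scheme == "subsample")
        sort(sample.int(space$n, floor(space$n / 2)))
      else sample.int(space$n, space$n, replace = TRUE)
    }
    path <- tryCatch(
      enet_path(x[idx, , drop = FALSE], y[idx], grid, alpha,
                standardize = standardize),
      error = function(e) stop("member ", b, ": ", conditionMessage(e)))
    ind[b, , ] <- t(path$support) * 1L
  }
  structure(list(indicator = ind, lambda = grid, space = space,
                 alpha = alpha, taxon_ids = colnames(x)),
            class = "selection_profile")
}

#' Inclusion probabilities at one penalty
#'
#' `P(j in S(lambda)) = (1/B) * sum_b 1{j in S_lambda(b)}` at a single grid
#' point; used at `lambda_ENC` for the single-penalty ensembles (LS/LR).
#'
#' @param profile A [selection_profile()].
#' @param lambda_index Grid position (1-based).
#' @return Numeric vector of length p in `[0, 1]`.
#' @export
inclusion_at_lambda <- function(profile, lambda_index) {
  stopifnot(inherits(profile, "selection_profile"))
  K <- dim(profile$indicator)[2]
  if (lambda_index < 1 || lambda_index > K) stop("invalid lambda_index")
  probs <- apply(profile$indicator[, lambda_index, , drop = FALSE], 3L, mean)
  setNames(probs, profile$taxon_ids)
}

#' Path-averaged inclusion probabilities
#'
#' `I_j = mean over the grid of P(j in S(lambda_i))` — the stability
#' ensemble over the full regularization path (SS with a subsample space,
#' SR with a resample space).
#'
#' @param profile A [selection_profile()].
#' @return Numeric vector of length p in `[0, 1]`.
#' @export
averaged_inclusion <- function(profile) {
  stopifnot(inherits(profile, "selection_profile"))
  probs <- apply(profile$indicator, 3L, mean)
  setNames(probs, profile$taxon_ids)
}

#' Selection-weighted inclusion probabilities
#'
#' `I^w_j = sum_i w_i * P(j in S(lambda_i))` with the weight of each grid
#' point proportional to the total number of selection events at that
#' penalty (summed over members and variables), normalized to sum to 1
#' (SSW/SRW).
#'
#' @param profile A [selection_profile()].
#' @return Numeric vector of length p in `[0, 1]`, with the grid weights as
#'   attribute `"weights"`.
#' @export
weighted_inclusion <- function(profile) {
  stopifnot(inherits(profile, "selection_profile"))
  per_lambda <- apply(profile$indicator, 2L, sum)
  tot <- sum(per_lambda)
  if (tot == 0) stop("no selection events anywhere on the grid; ",
                     "weights are undefined")
  w <- per_lambda / tot
  pj <- apply(profile$indicator, c(2L, 3L), mean)  # K x p
  probs <- drop(crossprod(pj, w))
  out <- setNames(probs, profile$taxon_ids)
  attr(out, "weights") <- w
  out
}

#' Stable-set selection with per-family error control
#'
#' Restricts the penalty grid to the largest region, starting from the
#' null-model end, over which the average selected-set size `q` keeps the
#' stability-selection bound `q^2 / ((2*pi_threshold - 1) * p)` at or below
#' `pfer_bound` (the expected number of false positives). The stable set
#' contains every variable whose inclusion probability reaches
#' `pi_threshold` anywhere in the admissible region (PS with a subsample
#' space, PR with a resample space).
#'
#' @param profile A [selection_profile()].
#' @param pi_threshold Stability threshold in (0.5, 1]; default 0.75.
#' @param pfer_bound Per-family error bound; default 1.
#' @return List of class `stable_set`: `lambda_index` (the boundary grid
#'   point, `lambda_MB`), `selected` (integer indices), `max_probs`,
#'   `status` (`"ok"` or `"empty"`).
#' @export
mb_stable_set <- function(profile, pi_threshold = 0.75, pfer_bound = 1) {
  stopifnot(inherits(profile, "selection_profile"))
  if (pi_threshold <= 0.5 || pi_threshold > 1)
    stop("pi_threshold must lie in (0.5, 1]")
  p <- dim(profile$indicator)[3]
  # average selected-set size at each grid point
  q <- apply(profile$indicator, 2L, sum) / dim(profile$indicator)[1]
  admissible <- q^2 / ((2 * pi_threshold - 1) * p) <= pfer_bound
  if (!admissible[1]) {
    warning("no admissible penalty: the bound is violated at lambda_max")
    return(structure(list(lambda_index = NA_integer_, selected = integer(0),
                          max_probs = rep(NA_real_, p), status = "empty"),
                     class = "stable_set"))
  }
  t_star <- if (all(admissible)) length(q) else which(!admissible)[1] - 1L
  pj <- apply(profile$indicator[, seq_len(t_star), , drop = FALSE],
              c(2L, 3L), mean)
  max_probs <- apply(pj, 2L, max)
  sel <- which(max_probs >= pi_threshold)
  structure(list(lambda_index = t_star,
                 selected = sel,
                 max_probs = setNames(max_probs, profile$taxon_ids),
                 status = "ok"),
            class = "stable_set")
}

#' @export
print.stable_set <- function(x, ...) {
  if (x$status == "empty") {
    cat("Stable set: empty (no admissible penalty region)\n")
  } else {
    cat("Stable set:", length(x$selected), "variables; penalty region ends",
        "at grid point", x$lambda_index, "\n")
  }
  invisible(x)
}
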