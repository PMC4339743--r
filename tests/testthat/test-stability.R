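# construct a selection_profile object directly from a binary array
fake_profile <- function(ind, lambda = NULL) {
  structure(list(indicator = ind,
                 lambda = if (is.null(lambda))
                   rev(seq_len(dim(ind)[2])) else lambda,
                 space = NULL, alpha = 1,
                 taxon_ids = paste0("V", seq_len(dim(ind)[3]))),
            class = "selection_profile")
}

test_that("model spaces obey their sampling schemes deterministically", {
  sub <- build_model_space(30, "subsample", B = 50, seed = 4)
  expect_true(all(vapply(sub$members, function(m)
    length(m) == 15 && !anyDuplicated(m), logical(1))))
  res <- build_model_space(30, "resample", B = 50, seed = 4)
  expect_true(all(lengths(res$members) == 30))
  expect_true(any(vapply(res$members, anyDuplicated, integer(1)) > 0))
  expect_identical(build_model_space(30, "subsample", B = 50, seed = 4),
                   sub)
  expect_error(build_model_space(3), "at least 4")
})

test_that("selection profiles equal member-by-member refits", {
  set.seed(11)
  n <- 20; p <- 6
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% c(2, -2, rep(0, 4))) + rnorm(n, 0, 0.3)
  grid <- lambda_grid(x, y, 1, K = 15)
  space <- build_model_space(n, "subsample", B = 3, seed = 2)
  prof <- selection_profile(x, y, space, grid, alpha = 1)
  for (b in 1:3) {
    idx <- space$members[[b]]
    path <- mbensemble:::enet_path(x[idx, ], y[idx], grid, 1)
    expect_equal(prof$indicator[b, , ], t(path$support) * 1L)
  }
  # at lambda_max nothing is ever selected
  expect_true(all(prof$indicator[, 1, ] == 0))
})

test_that("single-penalty inclusion probabilities are member averages", {
  set.seed(12)
  ind <- array(rbinom(10 * 7 * 5, 1, 0.3), c(10, 7, 5))
  ind[, 1, ] <- 0L
  prof <- fake_profile(ind)
  for (li in c(2, 5, 7)) {
    tally <- vapply(1:5, function(j) sum(ind[, li, j]) / 10, numeric(1))
    expect_equal(unname(inclusion_at_lambda(prof, li)), tally)
  }
  expect_equal(unname(inclusion_at_lambda(prof, 1)), rep(0, 5))
  expect_error(inclusion_at_lambda(prof, 9), "invalid")
})

test_that("grid-averaged inclusion matches the double loop", {
  set.seed(13)
  ind <- array(rbinom(8 * 6 * 4, 1, 0.4), c(8, 6, 4))
  prof <- fake_profile(ind)
  oracle <- vapply(1:4, function(j) {
    mean(vapply(1:6, function(l) mean(ind[, l, j]), numeric(1)))
  }, numeric(1))
  expect_equal(unname(averaged_inclusion(prof)), oracle)

  ones <- fake_profile(array(1L, c(3, 4, 2)))
  expect_equal(unname(averaged_inclusion(ones)), c(1, 1))

  # a profile constant in lambda averages to any single slice
  const <- array(rep(rbinom(3 * 2, 1, 0.5), times = 4), c(3, 2, 4))
  const <- aperm(const, c(1, 3, 2))
  prof_c <- fake_profile(const)
  expect_equal(averaged_inclusion(prof_c), inclusion_at_lambda(prof_c, 2))
})

test_that("selection-weighted inclusion matches the literal weighted sum", {
  set.seed(14)
  ind <- array(rbinom(9 * 5 * 6, 1, 0.35), c(9, 5, 6))
  prof <- fake_profile(ind)
  iw <- weighted_inclusion(prof)
  w <- attr(iw, "weights")
  expect_equal(sum(w), 1, tolerance = 1e-12)
  counts <- vapply(1:5, function(l) sum(ind[, l, ]), numeric(1))
  expect_equal(unname(w), counts / sum(counts))
  oracle <- vapply(1:6, function(j) {
    sum(vapply(1:5, function(l) w[l] * mean(ind[, l, j]), numeric(1)))
  }, numeric(1))
  expect_equal(as.vector(iw), oracle, tolerance = 1e-14)

  # selections concentrated at one penalty reduce to that slice
  one <- array(0L, c(4, 3, 2))
  one[, 2, 1] <- 1L
  prof1 <- fake_profile(one)
  iw1 <- weighted_inclusion(prof1)
  expect_equal(as.vector(iw1),
               unname(inclusion_at_lambda(prof1, 2)))

  # equal per-penalty selection totals reduce to the plain average
  eq <- array(0L, c(2, 3, 2))
  eq[1, , 1] <- 1L
  eq[2, , 2] <- 1L
  prof_eq <- fake_profile(eq)
  expect_equal(as.vector(weighted_inclusion(prof_eq)),
               unname(averaged_inclusion(prof_eq)))

  expect_error(weighted_inclusion(fake_profile(array(0L, c(2, 2, 2)))),
               "undefined")
})

test_that("all inclusion aggregations stay inside [0, 1]", {
  set.seed(15)
  for (rep in 1:5) {
    ind <- array(rbinom(6 * 8 * 5, 1, runif(1, 0.1, 0.9)), c(6, 8, 5))
    prof <- fake_profile(ind)
    vals <- c(averaged_inclusion(prof),
              inclusion_at_lambda(prof, 3),
              if (sum(ind) > 0) weighted_inclusion(prof))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("the stable set controls the admissible penalty region", {
  # one variable always selected, all others never: singleton stable set
  ind <- array(0L, c(10, 6, 8))
  ind[, 2:6, 1] <- 1L
  prof <- fake_profile(ind)
  st <- mb_stable_set(prof, pi_threshold = 0.75, pfer_bound = 1)
  expect_equal(st$selected, 1L)
  expect_equal(st$status, "ok")

  # the admissible region ends where q^2/((2*pi-1)p) crosses the bound:
  # with p = 192, pi = 0.75, bound 1, the largest admissible q is
  # sqrt(0.5 * 192) ~ 9.8 average selections
  p <- 192
  q_per_lambda <- c(0, 2, 5, 9, 11, 20)
  ind2 <- array(0L, c(1, 6, p))
  for (l in seq_along(q_per_lambda))
    if (q_per_lambda[l] > 0) ind2[1, l, seq_len(q_per_lambda[l])] <- 1L
  prof2 <- fake_profile(ind2)
  st2 <- mb_stable_set(prof2, 0.75, 1)
  expect_equal(st2$lambda_index, 4L)  # q = 9 admissible, q = 11 is not

  # stable sets shrink as the threshold rises
  set.seed(16)
  ind3 <- array(rbinom(20 * 5 * 10, 1, 0.5), c(20, 5, 10))
  prof3 <- fake_profile(ind3)
  sizes <- vapply(c(0.6, 0.7, 0.8, 0.9),
                  function(th) length(mb_stable_set(prof3, th,
                                                    pfer_bound = 1e6)$selected),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("stable sets ignore member order", {
  set.seed(17)
  ind <- array(rbinom(12 * 5 * 6, 1, 0.4), c(12, 5, 6))
  st1 <- mb_stable_set(fake_profile(ind), 0.6, 1e6)
  st2 <- mb_stable_set(fake_profile(ind[sample(12), , ]), 0.6, 1e6)
  expect_equal(st1$selected, st2$selected)
  expect_equal(st1$lambda_index, st2$lambda_index)
})

test_that("subsample and resample single-penalty ensembles agree in rank", {
  set.seed(18)
  n <- 40; p <- 10
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% c(3, -3, 3, rep(0, 7))) + rnorm(n, 0, 0.2)
  grid <- lambda_grid(x, y, 1, K = 30)
  li <- 15
  ps <- selection_profile(x, y, build_model_space(n, "subsample", 60, 1),
                          grid, 1)
  pr <- selection_profile(x, y, build_model_space(n, "resample", 60, 1),
                          grid, 1)
  ls <- inclusion_at_lambda(ps, li)
  lr <- inclusion_at_lambda(pr, li)
  expect_gt(cor(ls, lr, method = "spearman"), 0)
})
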