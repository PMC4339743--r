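# a small, fast grid configuration over a toy design
tiny_config <- function(checkpoint_dir = NULL, methods = c("LS", "SS"),
                        n_replicates = 2L) {
  evaluation_config(design = "fungal-like", sparsity = 0.04,
                    beta_schemes = "pm1", snr = 16,
                    n_replicates = n_replicates, methods = methods,
                    seed = 5L, B = 15L, n_iterations = 400L,
                    burn_in = 100L, k_grid = c(1, 2),
                    checkpoint_dir = checkpoint_dir)
}

test_that("the grid produces one record per scenario, replicate, method", {
  res <- run_grid(tiny_config())
  expect_equal(nrow(res), 1 * 2 * 2)
  expect_setequal(unique(res$method), c("LS", "SS"))
  expect_true(all(!is.na(res$auc)))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_true(all(is.na(res$error)))
})

test_that("reruns with the same config are identical", {
  cfg <- tiny_config()
  expect_identical(run_grid(cfg), run_grid(cfg))
})

test_that("a checkpointed grid resumes to the identical table", {
  dir1 <- tempfile("ckpt")
  cfg1 <- tiny_config(checkpoint_dir = dir1)
  full <- run_grid(cfg1)
  # partial run: keep only the first cell's checkpoint and resume
  files <- list.files(dir1, full.names = TRUE)
  unlink(files[-1])
  resumed <- run_grid(cfg1)
  expect_equal(resumed, full)
  # uninterrupted, checkpoint-free run matches too
  expect_equal(run_grid(tiny_config()), full)
  unlink(dir1, recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(evaluation_config(methods = "XYZ"), "unknown method")
  expect_error(evaluation_config(beta_schemes = "spike"), "beta_schemes")
})

test_that("aggregation reproduces boxplot statistics", {
  res <- data.frame(sparsity = 0.04, beta_scheme = "pm1", snr = 16,
                    replicate = 1:5, method = "SS",
                    auc = c(1, 2, 3, 4, 5), f_score = 0.5,
                    spearman_rho = NA_real_, tp = 1L, fp = 0L,
                    error = NA_character_)
  agg <- aggregate_metrics(res)
  auc_row <- agg[agg$metric == "auc", ]
  expect_equal(auc_row$median, 3)
  expect_equal(auc_row$q1, 2)
  expect_equal(auc_row$q3, 4)
  expect_equal(auc_row$n, 5L)
  single <- aggregate_metrics(res[1, ])
  expect_equal(single[single$metric == "auc", "median"], 1)

  set.seed(50)
  res2 <- res
  res2$auc <- rnorm(5)
  agg2 <- aggregate_metrics(res2)
  expect_equal(agg2[agg2$metric == "auc", "median"],
               sort(res2$auc)[3])
})

test_that("method similarity is the inverse-distance transform", {
  v <- list(a = c(1, 0, 0), b = c(0, 1, 0), c = c(1, 0, 0),
            d = c(0.4, 0.4, 0.4))
  ms <- method_similarity(v)
  expect_equal(ms$similarity["a", "c"], 1)
  expect_equal(ms$similarity["a", "b"], 1 / (1 + sqrt(2)))
  expect_equal(ms$similarity, t(ms$similarity))
  expect_equal(unname(diag(ms$similarity)), rep(1, 4))
  expect_true(all(ms$similarity > 0 & ms$similarity <= 1))
  # brute-force distances
  m <- do.call(cbind, v)
  for (i in 1:4) for (j in 1:4) {
    dij <- sqrt(sum((m[, i] - m[, j])^2))
    expect_equal(ms$similarity[i, j], 1 / (1 + dij))
  }
  expect_setequal(ms$order, names(v))
  expect_error(method_similarity(list(a = 1:3, b = 1:4)), "length")
  expect_error(method_similarity(list(a = 1:3)), "two methods")
})

test_that("dual-reference fits identify and exclude the two top genera", {
  set.seed(51)
  tab <- generate_counts(count_profile(24, 10, zero_fraction = 0.2,
                                       dominance = 20, depth_median = 500,
                                       seed = 6))
  # make taxon totals unambiguous: T1 dominant, T2 second
  tab[, 1] <- tab[, 1] + 1000L
  tab[, 2] <- tab[, 2] + 500L
  y <- rnorm(24)
  fit <- dual_reference_fit(tab, y = y, method = "SS", B = 10, seed = 2,
                            alpha = 1)
  expect_equal(fit$references, colnames(tab)[1:2])
  expect_false(fit$references[1] %in% colnames(fit$fits[[1]]$x))
  expect_false(fit$references[2] %in% colnames(fit$fits[[2]]$x))
  # every genus has a probability; references appear in exactly one fit
  expect_setequal(names(fit$inclusion), colnames(tab))
  ref1 <- fit$references[1]
  expect_equal(fit$inclusion[[ref1]],
               fit$fits[[2]]$inclusion[[ref1]])
  # non-reference genera average the two fits
  g <- setdiff(colnames(tab), fit$references)[1]
  expect_equal(fit$inclusion[[g]],
               mean(c(fit$fits[[1]]$inclusion[[g]],
                      fit$fits[[2]]$inclusion[[g]])))
})

test_that("selection-only methods report dual-fit frequencies", {
  set.seed(52)
  tab <- generate_counts(count_profile(20, 8, zero_fraction = 0.2,
                                       dominance = 15, depth_median = 400,
                                       seed = 7))
  d_full <- build_design(tab)
  beta <- rep(0, ncol(d_full$x)); beta[2] <- 3
  y <- drop(d_full$x %*% beta) + rnorm(20, 0, 0.1)
  fit <- dual_reference_fit(tab, y = y, method = "ENC", seed = 3,
                            alpha_grid = 1)
  expect_true(all(fit$inclusion %in% c(0, 0.5, 1)))
})

test_that("covariable blocks ride along both reference fits", {
  set.seed(53)
  tab <- generate_counts(count_profile(20, 6, zero_fraction = 0.1,
                                       dominance = 10, depth_median = 300,
                                       seed = 8))
  cov <- cbind(cyt1 = rnorm(20), trt = rbinom(20, 1, 0.5))
  y <- 2 * cov[, "cyt1"] + rnorm(20, 0, 0.3)
  fit <- dual_reference_fit(tab, covariables = cov, y = y, method = "SS",
                            B = 10, seed = 4, alpha = 1)
  expect_true(all(c("cyt1", "trt") %in% names(fit$inclusion)))
  expect_equal(fit$inclusion[["cyt1"]],
               mean(c(fit$fits[[1]]$inclusion[["cyt1"]],
                      fit$fits[[2]]$inclusion[["cyt1"]])))
  # the informative covariable outranks the uninformative taxa
  expect_gt(fit$inclusion[["cyt1"]], max(fit$inclusion[colnames(tab)[3:6]]))
})
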