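#' Configure an evaluation grid
#'
#' Declares the full factorial evaluation: design source, sparsity grid,
#' coefficient schemes, SNR grid, replicate count, methods and master seed.
#'
#' @param design A design matrix, a `design_matrix`, or the name of a
#'   preset count profile (`"bacterial-like"`, `"fungal-like"`); presets
#'   are generated, zero-filtered and log-transformed with a seed derived
#'   from `seed`.
#' @param sparsity Numeric vector of sparsity settings (default
#'   `c(0.02, 0.03, 0.04)`).
#' @param beta_schemes Character vector from `c("pm1", "uniform")`.
#' @param snr Numeric vector of target SNRs (default
#'   `c(0.25, 4.6, 16)`; 0.25 is the high-noise setting).
#' @param n_replicates Replicates per scenario (default 130).
#' @param methods Methods to run (see [ensemble_fit()]).
#' @param seed Master seed.
#' @param B Ensemble size for frequentist methods.
#' @param n_iterations,burn_in MCMC length for Bayesian methods.
#' @param k_grid `BMAC` candidate expected model sizes.
#' @param checkpoint_dir Optional directory; per-cell results are written
#'   there as tab-delimited files and a rerun resumes from them.
#' @param workers Number of parallel workers (cells are independent and
#'   per-cell seeded, so results do not depend on this).
#' @return Object of class `evaluation_config`.
#' @export
evaluation_config <- function(design = "fungal-like",
                              sparsity = c(0.02, 0.03, 0.04),
                              beta_schemes = "pm1",
                              snr = c(0.25, 4.6, 16),
                              n_replicates = 130L,
                              methods = c("ENC", "PS", "LS", "SS", "SSW",
                                          "PR", "LR", "SR", "SRW", "BMA",
                                          "BMAC"),
                              seed = 1L, B = 100L,
                              n_iterations = 10000L, burn_in = 1000L,
                              k_grid = c(1, 2, 4, 8, 16, 32),
                              checkpoint_dir = NULL, workers = 1L) {
  all_methods <- c("ENC", "PS", "LS", "SS", "SSW", "PR", "LR", "SR",
                   "SRW", "BMA", "BMAC")
  if (!all(methods %in% all_methods))
    stop("unknown method(s): ",
         paste(setdiff(methods, all_methods), collapse = ", "))
  if (!all(beta_schemes %in% c("pm1", "uniform")))
    stop("beta_schemes must be drawn from 'pm1', 'uniform'")
  structure(list(design = design, sparsity = sparsity,
                 beta_schemes = beta_schemes, snr = snr,
                 n_replicates = as.integer(n_replicates),
                 methods = methods, seed = as.integer(seed),
                 B = as.integer(B),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), k_grid = k_grid,
                 checkpoint_dir = checkpoint_dir,
                 workers = as.integer(workers)),
            class = "evaluation_config")
}

resolve_design <- function(config) {
  d <- config$design
  if (is.character(d) && length(d) == 1) {
    prof <- preset_profile(d, seed = config$seed + 7777L)
    build_design(filter_zero(generate_counts(prof)))
  } else d
}

#' Run the evaluation grid
#'
#' For every scenario cell (sparsity x coefficient scheme x SNR) and
#' replicate: simulates a dataset from the design, runs every configured
#' method, applies the largest-gap selection where the method does not
#' select natively, and records the evaluation metrics. Fully reproducible
#' from the config; per-cell seeding makes the result independent of the
#' execution order or worker count. With a `checkpoint_dir`, finished cells
#' are written to disk and a rerun resumes from them.
#'
#' Method failures are caught per cell: the metrics are recorded as `NA`
#' with the condition message in the `error` column and the grid continues.
#'
#' @param config An [evaluation_config()].
#' @return A `data.frame` with one row per (scenario, replicate, method):
#'   columns `sparsity`, `beta_scheme`, `snr`, `replicate`, `method`,
#'   `auc`, `f_score`, `spearman_rho`, `tp`, `fp`, `error`.
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "evaluation_config"))
  design <- resolve_design(config)
  x <- design_x(design)
  cells <- expand.grid(sparsity = config$sparsity,
                       beta_scheme = config$beta_schemes,
                       snr = config$snr,
                       replicate = seq_len(config$n_replicates),
                       stringsAsFactors = FALSE)
  ckpt <- config$checkpoint_dir
  if (!is.null(ckpt) && !dir.exists(ckpt))
    dir.create(ckpt, recursive = TRUE)

  run_cell <- function(ci) {
    cell <- cells[ci, ]
    tag <- sprintf("cell_s%s_%s_snr%s_r%03d.tsv", cell$sparsity,
                   cell$beta_scheme, cell$snr, cell$replicate)
    if (!is.null(ckpt)) {
      path <- file.path(ckpt, tag)
      if (file.exists(path))
        return(read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
    }
    scen_seed <- replicate_seed(config$seed,
                                match(cell$sparsity, config$sparsity) +
                                  10L * match(cell$beta_scheme,
                                              config$beta_schemes) +
                                  100L * match(cell$snr, config$snr))
    scen <- scenario(sparsity = cell$sparsity,
                     beta_scheme = cell$beta_scheme, snr = cell$snr,
                     n_replicates = config$n_replicates, seed = scen_seed)
    ds <- simulate_dataset(x, scen, cell$replicate)
    truth <- sort(c(ds$v1, ds$v2))
    # one cross-validated elastic net per dataset, shared by all methods
    cvd <- tryCatch(enc_cv(ds$x, ds$y), error = function(e) NULL)
    rows <- lapply(config$methods, function(m) {
      res <- tryCatch({
        fit <- ensemble_fit(ds$x, ds$y, method = m, B = config$B,
                            n_iterations = config$n_iterations,
                            burn_in = config$burn_in,
                            k_grid = config$k_grid,
                            seed = ds$replicate_seed, enc = cvd)
        rec <- if (is.null(fit$inclusion))
          metrics_record(selected = fit$selected, truth = truth,
                         true_beta = ds$beta)
        else metrics_record(probs = fit$inclusion, truth = truth,
                            true_beta = ds$beta)
        cbind(rec, error = NA_character_)
      }, error = function(e) {
        data.frame(auc = NA_real_, f_score = NA_real_,
                   spearman_rho = NA_real_, tp = NA_integer_,
                   fp = NA_integer_, error = conditionMessage(e))
      })
      cbind(data.frame(sparsity = cell$sparsity,
                       beta_scheme = cell$beta_scheme, snr = cell$snr,
                       replicate = cell$replicate, method = m,
                       stringsAsFactors = FALSE),
            res)
    })
    out <- do.call(rbind, rows)
    if (!is.null(ckpt))
      write.table(out, file.path(ckpt, tag), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    out
  }

  res <- if (config$workers > 1L) {
    parallel::mclapply(seq_len(nrow(cells)), run_cell,
                       mc.cores = config$workers)
  } else {
    lapply(seq_len(nrow(cells)), run_cell)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize grid results with boxplot statistics
#'
#' Per (scenario, method) and metric: median, type-7 quartiles, whisker
#' bounds at 1.5 IQR (clamped to the observed range) and the outlier count.
#'
#' @param results A [run_grid()] results table.
#' @param metrics Which metric columns to summarize.
#' @return A long-format `data.frame` with one row per (scenario, method,
#'   metric).
#' @export
aggregate_metrics <- function(results,
                              metrics = c("auc", "f_score",
                                          "spearman_rho")) {
  if (nrow(results) == 0) stop("empty results table")
  key <- interaction(results$sparsity, results$beta_scheme, results$snr,
                     results$method, drop = TRUE)
  parts <- split(results, key)
  out <- lapply(parts, function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]]
      v <- v[!is.na(v)]
      if (length(v) == 0)
        return(data.frame(sparsity = d$sparsity[1],
                          beta_scheme = d$beta_scheme[1], snr = d$snr[1],
                          method = d$method[1], metric = m,
                          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                          whisker_lo = NA_real_, whisker_hi = NA_real_,
                          n = 0L, n_outliers = NA_integer_))
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lo <- max(min(v), q[1] - 1.5 * iqr)
      hi <- min(max(v), q[3] + 1.5 * iqr)
      data.frame(sparsity = d$sparsity[1], beta_scheme = d$beta_scheme[1],
                 snr = d$snr[1], method = d$method[1], metric = m,
                 median = q[2], q1 = q[1], q3 = q[3], whisker_lo = lo,
                 whisker_hi = hi, n = length(v),
                 n_outliers = sum(v < lo | v > hi))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Dual-reference application fit
#'
#' The application procedure for real compositional data: the two most
#' abundant genera are taken as references, the chosen method is fit twice
#' — each time excluding one reference from the genus block — and the final
#' inclusion probability of every variable is the average over the models
#' in which it appears (each reference genus appears in exactly one model
#' and keeps that model's value; covariables appear in both and are
#' averaged). For methods producing only a selected set (ENC, PS, PR) the
#' per-variable selection frequency across the two fits is returned
#' (values 0, 0.5 or 1).
#'
#' @param counts Filtered count table with at least 3 taxa.
#' @param covariables Optional numeric matrix of extra columns (e.g. log
#'   normalized cytokine expression and binary treatment indicators) with
#'   the same row count as `counts`.
#' @param y Continuous response (e.g. log CFU per gram).
#' @param method Method name (see [ensemble_fit()]).
#' @param ... Passed to [ensemble_fit()].
#' @return List of class `dual_reference_fit`: `inclusion` (named vector
#'   over all genera and covariables), `references` (the two reference
#'   genera), and `fits` (the two underlying [ensemble_fit()] objects).
#' @export
dual_reference_fit <- function(counts, covariables = NULL, y,
                               method = "BMA", ...) {
  check_count_table(counts)
  if (ncol(counts) < 3) stop("need at least 3 taxa")
  totals <- colSums(counts)
  refs <- colnames(counts)[order(totals, decreasing = TRUE)[1:2]]
  fits <- lapply(refs, function(ref) {
    d <- build_design(counts, log_transform = TRUE, reference = ref)
    xx <- if (is.null(covariables)) d$x else cbind(d$x, covariables)
    ensemble_fit(xx, y, method = method, ...)
  })
  all_vars <- c(colnames(counts),
                if (!is.null(covariables)) colnames(covariables))
  acc <- setNames(numeric(length(all_vars)), all_vars)
  cnt <- setNames(integer(length(all_vars)), all_vars)
  for (f in fits) {
    v <- if (!is.null(f$inclusion)) f$inclusion
         else setNames(as.numeric(seq_len(f$p) %in% f$selected),
                       colnames(f$x))
    if (is.null(names(v))) names(v) <- colnames(f$x)
    acc[names(v)] <- acc[names(v)] + v
    cnt[names(v)] <- cnt[names(v)] + 1L
  }
  seen <- cnt > 0
  inclusion <- acc
  inclusion[seen] <- acc[seen] / cnt[seen]
  structure(list(inclusion = inclusion, references = refs, fits = fits,
                 method = method),
            class = "dual_reference_fit")
}

#' @export
print.dual_reference_fit <- function(x, ...) {
  cat("Dual-reference", x$method, "fit; references:",
      paste(x$references, collapse = ", "), "\n")
  top <- head(sort(x$inclusion, decreasing = TRUE), 5)
  print(round(top, 3))
  invisible(x)
}

#' Similarity of inclusion-probability profiles across methods
#'
#' `S_ij = 1 / (1 + D_ij)` with `D_ij` the Euclidean distance between the
#' inclusion probability vectors of methods i and j, together with the leaf
#' order of agglomerative (centroid linkage) clustering of `D`.
#'
#' @param inclusions A named list (or column matrix) of equal-length
#'   inclusion probability vectors, one per method.
#' @return List of class `method_similarity`: `similarity` (symmetric
#'   matrix with unit diagonal), `distance`, `hclust`, `order` (leaf
#'   labels).
#' @export
method_similarity <- function(inclusions) {
  if (is.list(inclusions)) {
    lens <- lengths(inclusions)
    if (length(unique(lens)) != 1) stop("inclusion vectors differ in length")
    m <- do.call(cbind, inclusions)
  } else m <- as.matrix(inclusions)
  if (ncol(m) < 2) stop("need at least two methods")
  D <- as.matrix(dist(t(m)))
  S <- 1 / (1 + D)
  hc <- hclust(as.dist(D), method = "centroid")
  structure(list(similarity = S, distance = D, hclust = hc,
                 order = colnames(m)[hc$order]),
            class = "method_similarity")
}

#' @export
print.method_similarity <- function(x, ...) {
  cat("Method similarity (1/(1+Euclidean distance)); leaf order:",
      paste(x$order, collapse = " < "), "\n")
  print(round(x$similarity, 3))
  invisible(x)
}
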