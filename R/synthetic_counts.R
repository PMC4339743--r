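#' Specify a synthetic microbiome count profile
#'
#' A `count_profile` describes the structural properties of a samples x taxa
#' sequence count table to be generated by [generate_counts()]: dimensions,
#' sequencing depth, zero inflation, overdispersion of taxon abundances and
#' the dominance of the most abundant taxon (the future reference genus).
#'
#' @param n_samples Number of samples (rows).
#' @param n_taxa Number of taxa (columns), including the future reference
#'   taxon. Must be at least 3.
#' @param zero_fraction Target fraction of zero cells, in `[0, 1)`.
#' @param dominance Ratio of the most abundant taxon's expected abundance to
#'   the median taxon abundance; must exceed 1.
#' @param depth_median Median reads per sample; must be at least `n_taxa`.
#' @param dispersion Standard deviation (log scale) of the across-taxa base
#'   abundance distribution; larger values give a more uneven community.
#' @param seed Integer seed; generation is deterministic given the profile.
#' @return An object of class `count_profile`.
#' @seealso [preset_profile()] for ready-made bacterial-like and fungal-like
#'   profiles, [generate_counts()].
#' @export
count_profile <- function(n_samples, n_taxa, zero_fraction = 0.5,
                          dominance = 50, depth_median = 2000,
                          dispersion = 1.5, seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_taxa <- as.integer(n_taxa)
  depth_median <- as.integer(depth_median)
  if (n_samples < 1L) stop("n_samples must be a positive integer")
  if (n_taxa < 3L) stop("n_taxa must be at least 3")
  if (!is.finite(zero_fraction) || zero_fraction < 0 || zero_fraction >= 1)
    stop("zero_fraction must lie in [0, 1)")
  if (!is.finite(dominance) || dominance <= 1)
    stop("dominance must exceed 1")
  if (depth_median < n_taxa)
    stop("depth_median must be at least n_taxa (profile infeasible: ",
         "a zero_fraction of ", zero_fraction, " cannot be realized when ",
         "rows cannot hold one read per taxon)")
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("dispersion must be a positive real")
  structure(list(n_samples = n_samples, n_taxa = n_taxa,
                 zero_fraction = zero_fraction, dominance = dominance,
                 depth_median = depth_median, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "count_profile")
}

#' Preset count profiles
#'
#' Two named profiles matching the post-filter dimensions of typical mouse
#' gut 16S (bacterial) and ITS (fungal) genus-level count tables:
#' `"bacterial-like"` gives 30 samples x 193 taxa at a median depth of 3500
#' reads, so the design matrix built from it has 192 non-reference taxa;
#' `"fungal-like"` gives 36 samples x 48 taxa at a median depth of 2000
#' reads (47 non-reference taxa).
#'
#' @param name `"bacterial-like"` or `"fungal-like"`.
#' @param seed Integer seed stored in the profile.
#' @return A [count_profile()].
#' @export
preset_profile <- function(name = c("bacterial-like", "fungal-like"),
                           seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "bacterial-like" = count_profile(n_samples = 30L, n_taxa = 193L,
                                     zero_fraction = 0.65, dominance = 300,
                                     depth_median = 3500L, dispersion = 2,
                                     seed = seed),
    "fungal-like" = count_profile(n_samples = 36L, n_taxa = 48L,
                                  zero_fraction = 0.50, dominance = 60,
                                  depth_median = 2000L, dispersion = 1.5,
                                  seed = seed))
}

#' @export
print.count_profile <- function(x, ...) {
  cat("Synthetic count profile:", x$n_samples, "samples x", x$n_taxa,
      "taxa\n  median depth", x$depth_median,
      "| target zero fraction", x$zero_fraction,
      "| dominance", x$dominance,
      "| dispersion", x$dispersion, "| seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic microbiome count table
#'
#' Draws a nonnegative integer samples x taxa table emulating compositional
#' sequence count data: per-taxon log-normal base abundances with one
#' dominant taxon, sample-specific multiplicative noise, multinomial
#' sampling at a depth drawn around the median, and an adjustment of the
#' zero cells toward the target zero fraction. Rows or columns left entirely
#' zero are repaired by placing a single count at a seeded random position,
#' so the output dimensions are deterministic and the table passes
#' [filter_zero()] unchanged.
#'
#' @param profile A [count_profile()].
#' @return An integer matrix with sample IDs as row names and taxon IDs as
#'   column names. Deterministic given the profile (including its seed).
#' @examples
#' tab <- generate_counts(preset_profile("fungal-like", seed = 7))
#' dim(tab)
#' @export
generate_counts <- function(profile) {
  stopifnot(inherits(profile, "count_profile"))
  n <- profile$n_samples
  p <- profile$n_taxa
  set.seed(profile$seed)

  # base community: log-normal abundances, one taxon boosted to dominate
  a <- rlnorm(p, meanlog = 0, sdlog = profile$dispersion)
  ref <- sample.int(p, 1L)
  a[ref] <- profile$dominance * median(a[-ref])
  # winsorize the heavy log-normal tail below the dominant taxon so the
  # reference genus is unambiguous for every seed
  a[-ref] <- pmin(a[-ref], 0.9 * a[ref])

  # sample-specific composition and sequencing depth
  depth <- pmax(p, round(profile$depth_median * exp(rnorm(n, 0, 0.25))))
  counts <- matrix(0L, n, p)
  for (i in seq_len(n)) {
    w <- a * exp(rnorm(p, 0, 0.5))
    counts[i, ] <- as.integer(rmultinom(1L, depth[i], prob = w / sum(w)))
  }

  # push the realized zero fraction toward the target (both directions)
  z0 <- mean(counts == 0L)
  target <- profile$zero_fraction
  if (target > z0) {
    nz <- which(counts > 0L)
    drop <- nz[rbinom(length(nz), 1L, (target - z0) / (1 - z0)) == 1L]
    counts[drop] <- 0L
  } else if (target < z0) {
    zc <- which(counts == 0L)
    fill <- zc[rbinom(length(zc), 1L, (z0 - target) / z0) == 1L]
    counts[fill] <- 1L
  }

  # repair: every row and column keeps at least one positive cell
  for (i in which(rowSums(counts) == 0L))
    counts[i, sample.int(p, 1L)] <- 1L
  for (j in which(colSums(counts) == 0L))
    counts[sample.int(n, 1L), j] <- 1L

  dimnames(counts) <- list(sprintf("S%02d", seq_len(n)),
                           sprintf("T%03d", seq_len(p)))
  counts
}

#' Read and write tab-delimited count tables
#'
#' The on-disk dialect is a tab-delimited matrix with a header row of taxon
#' labels and the sample IDs in the first column, samples as rows.
#'
#' @param counts Integer matrix with sample row names and taxon column names.
#' @param file Path to read from or write to.
#' @return `read_counts()` returns the integer matrix; `write_counts()`
#'   returns `file` invisibly.
#' @export
write_counts <- function(counts, file) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_counts
#' @export
read_counts <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
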