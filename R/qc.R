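#' Pearson correlation between two technical runs
#'
#' Correlates the normalized spot intensities of two runs over the spots
#' present (non-`NA`) in both — matched spots only, without imputing zeros
#' for non-detections.
#'
#' @param a,b numeric vectors of per-spot normalized intensities, `NA`
#'   where the spot was not detected in that run.
#' @return Pearson product-moment coefficient in `[-1, 1]`, or `NA` (with
#'   a warning) if either run has zero variance over the common spots.
#' @export
#' @examples
#' pearson_between_runs(c(1, 2, 3, 4), c(2, 1, 4, 3))
pearson_between_runs <- function(a, b) {
  if (length(a) != length(b)) stop("runs differ in length")
  common <- !is.na(a) & !is.na(b)
  if (sum(common) < 3L)
    stop("need at least 3 spots present in both runs")
  x <- a[common]; y <- b[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a run; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Quantile-quantile points for two runs
#'
#' Pairs the order statistics of two samples after interpolating both to a
#' common length `min(length(a), length(b))` on the uniform plotting grid
#' (`ppoints`), the standard construction behind a Q-Q plot. Identical
#' distributions give points on `y = x`.
#'
#' @param a,b nonempty numeric vectors (`NA` dropped).
#' @return data.frame with columns `qa`, `qb`.
#' @export
qq_points <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("both runs must be nonempty")
  k <- min(length(a), length(b))
  p <- stats::ppoints(k)
  data.frame(qa = as.numeric(stats::quantile(a, p, names = FALSE)),
             qb = as.numeric(stats::quantile(b, p, names = FALSE)))
}

#' Coefficient of variation of one spot across replicates
#'
#' Sample (n-1) standard deviation divided by the mean of the replicate
#' intensities; `NA` if the spot is present in fewer than two replicates.
#'
#' @param values per-replicate normalized intensities of one spot (`NA`
#'   where undetected).
#' @return nonnegative numeric, or `NA`.
#' @export
#' @examples
#' spot_cv(c(1, 2, 3))
spot_cv <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m <= 0) stop("mean intensity must be positive")
  stats::sd(v) / m
}

#' Replicate consensus counts
#'
#' For each `k = 1..n_replicates`, the number of spots present in at least
#' `k` replicates (column-sum thresholding of the replicate presence
#' matrix). Non-increasing in `k` by construction.
#'
#' @param binary presence matrix, replicates in rows (0/1, or intensities
#'   where `NA`/0 marks absence).
#' @return named integer vector, `k>=1 ... k>=n`.
#' @export
consensus_counts <- function(binary) {
  if (nrow(binary) < 2L) stop("need at least 2 replicate rows")
  pres <- !is.na(binary) & binary != 0
  cs <- colSums(pres)
  ks <- seq_len(nrow(binary))
  stats::setNames(vapply(ks, function(k) sum(cs >= k), integer(1)),
                  paste0("k>=", ks))
}

#' Mean and sample SD of per-gel spot counts
#'
#' @param counts numeric vector of per-gel detected-spot totals (>= 2).
#' @return list with `mean`, `sd` (full precision) and `mean_rounded`,
#'   `sd_rounded` (nearest integer, the reporting convention).
#' @export
#' @examples
#' summarize_spot_counts(c(449, 420, 444, 406))
summarize_spot_counts <- function(counts) {
  if (length(counts) < 2L) stop("need at least 2 counts")
  m <- mean(counts); s <- stats::sd(counts)
  list(mean = m, sd = s,
       mean_rounded = round(m), sd_rounded = round(s))
}

#' Histogram of normalized intensities over the four abundance classes
#'
#' Fractions of spots in the classes `<0.02`, `0.02-0.04`, `0.04-0.1` and
#' `>0.1` relative units. Boundaries are left-closed: a value of exactly
#' 0.02 falls in the `0.02-0.04` class.
#'
#' @param values normalized intensities in `[0, 1]` (`NA` dropped).
#' @return named numeric vector of four fractions summing to 1.
#' @export
intensity_class_histogram <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no intensities supplied")
  if (any(v < 0 | v > 1)) stop("normalized intensities must lie in [0, 1]")
  cls <- cut(v, breaks = c(-Inf, 0.02, 0.04, 0.1, Inf), right = FALSE,
             labels = c("<0.02", "0.02-0.04", "0.04-0.1", ">0.1"))
  fr <- as.vector(table(cls)) / length(v)
  stats::setNames(fr, levels(cls))
}

#' Replicate reproducibility report
#'
#' Summarizes a replicate intensity matrix (replicates x spots, normalized
#' per run, `NA` where undetected): all pairwise Pearson correlations with
#' their mean and a 1.96 SD / sqrt(#pairs) half-width (the mean +/- 95% CI
#' convention), per-spot CVs over spots present in all replicates, the
#' intensity-class fractions, consensus counts, and per-replicate
#' spot-count summaries.
#'
#' @param replicates numeric matrix, replicates in rows.
#' @param cv_threshold CV threshold reported on (fraction of spots below).
#' @return list of class `qc_report`.
#' @export
qc_report <- function(replicates, cv_threshold = 0.6) {
  if (nrow(replicates) < 2L) stop("need at least 2 replicates")
  pairs <- utils::combn(nrow(replicates), 2)
  pairwise_r <- apply(pairs, 2, function(ij)
    pearson_between_runs(replicates[ij[1L], ], replicates[ij[2L], ]))
  names(pairwise_r) <- apply(pairs, 2, paste, collapse = "-")
  r_ok <- pairwise_r[!is.na(pairwise_r)]
  mean_r <- mean(r_ok)
  half_width <- 1.96 * stats::sd(r_ok) / sqrt(length(r_ok))
  full <- colSums(!is.na(replicates)) == nrow(replicates)
  cvs <- apply(replicates[, full, drop = FALSE], 2, spot_cv)
  counts <- rowSums(!is.na(replicates))
  structure(list(
    pairwise_r = pairwise_r,
    mean_r = mean_r,
    mean_r_half_width = half_width,
    cv_per_spot = cvs,
    frac_cv_below = mean(cvs < cv_threshold),
    cv_threshold = cv_threshold,
    class_fractions = intensity_class_histogram(as.vector(replicates)),
    consensus_counts = consensus_counts(replicates),
    spot_counts = counts,
    spot_count_summary = summarize_spot_counts(counts)),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Replicate QC report\n")
  cat(sprintf("  spots/run: %s (mean %d +/- %d)\n",
              paste(x$spot_counts, collapse = ", "),
              x$spot_count_summary$mean_rounded, x$spot_count_summary$sd_rounded))
  cat(sprintf("  Pearson r: mean %.2f +/- %.2f over %d pairs\n",
              x$mean_r, x$mean_r_half_width, length(x$pairwise_r)))
  cat(sprintf("  %.0f%% of fully-present spots with CV < %.1f\n",
              100 * x$frac_cv_below, x$cv_threshold))
  cat("  intensity classes:",
      paste(sprintf("%s: %.3f", names(x$class_fractions), x$class_fractions),
            collapse = ", "), "\n")
  cat("  consensus:",
      paste(sprintf("%s: %d", names(x$consensus_counts), x$consensus_counts),
            collapse = ", "), "\n")
  invisible(x)
}
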