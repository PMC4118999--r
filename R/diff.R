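#' Cluster-exclusive spots by presence/absence rule
#'
#' Spot `j` is exclusive to cluster `c` when its presence frequency is at
#' least `tau_present` within `c` and at most `tau_absent` in every other
#' cluster. The strict defaults (`tau_present = 1`, `tau_absent = 0`)
#' implement "present on every gel of one cluster, absent from all gels of
#' the others"; relaxing them can only grow the lists.
#'
#' @param binary 0/1 matrix, gels in rows, spot columns.
#' @param partition named integer vector mapping the row names of `binary`
#'   to cluster labels.
#' @param tau_present,tau_absent frequency thresholds,
#'   `0 <= tau_absent < tau_present <= 1`.
#' @return named list, one element per cluster, of exclusive spot column
#'   names (possibly empty).
#' @export
cluster_specific_spots <- function(binary, partition, tau_present = 1,
                                   tau_absent = 0) {
  if (!(tau_absent >= 0 && tau_absent < tau_present && tau_present <= 1))
    stop("need 0 <= tau_absent < tau_present <= 1")
  if (is.null(rownames(binary)) || !setequal(rownames(binary), names(partition)))
    stop("partition samples do not match the matrix rows")
  partition <- partition[rownames(binary)]
  clusters <- sort(unique(partition))
  freq <- t(vapply(clusters, function(c)
    colMeans(binary[partition == c, , drop = FALSE]),
    numeric(ncol(binary))))
  cols <- colnames(binary) %||% as.character(seq_len(ncol(binary)))
  out <- lapply(seq_along(clusters), function(ci) {
    others <- freq[-ci, , drop = FALSE]
    cols[freq[ci, ] >= tau_present & apply(others <= tau_absent, 2, all)]
  })
  stats::setNames(out, paste0("cluster_", clusters))
}

#' Fold change between two cluster means
#'
#' @param mean_a,mean_b positive mean normalized intensities.
#' @return list with `ratio` (full precision) and `rounded` (1 decimal,
#'   the reporting convention).
#' @export
#' @examples
#' fold_change(0.0174, 0.0114)$rounded
fold_change <- function(mean_a, mean_b) {
  if (!is.finite(mean_b) || mean_b <= 0)
    stop("denominator mean must be positive")
  r <- mean_a / mean_b
  list(ratio = r, rounded = round(r, 1))
}

#' Test intensity differences of shared spots between two clusters
#'
#' For every spot detected in at least `min_presence` gels of each cluster,
#' compares the normalized intensities of the two clusters with Welch's
#' unequal-variance t-test on present values (absent spots are treated as
#' missing, not zero), reports the fold change of cluster means, and
#' adjusts p-values by Bonferroni over the number of tested spots.
#'
#' @param intensities numeric matrix, gels in rows, `NA` at absent cells
#'   (e.g. from [build_matrices()] or [simulate_intensities()]).
#' @param partition named integer vector over the matrix rows with exactly
#'   two clusters.
#' @param min_presence minimum present gels per cluster for a spot to be
#'   tested (default 3).
#' @param alpha family-wise significance level used for the `significant`
#'   flag.
#' @return data.frame with one row per tested spot: `spot`, `n1`, `n2`,
#'   `mean1`, `sd1`, `mean2`, `sd2`, `fold_change`, `p_value`,
#'   `p_bonferroni`, `significant`. Empty (with a warning) if no spot
#'   meets `min_presence`.
#' @export
intensity_difference_test <- function(intensities, partition,
                                      min_presence = 3L, alpha = 0.05) {
  if (is.null(rownames(intensities)) ||
      !setequal(rownames(intensities), names(partition)))
    stop("partition samples do not match the matrix rows")
  partition <- partition[rownames(intensities)]
  clusters <- sort(unique(partition))
  if (length(clusters) != 2L)
    stop("intensity testing requires exactly 2 clusters")
  g1 <- partition == clusters[1L]
  g2 <- partition == clusters[2L]
  cols <- colnames(intensities) %||% as.character(seq_len(ncol(intensities)))
  rows <- lapply(seq_len(ncol(intensities)), function(j) {
    a <- intensities[g1, j]; a <- a[!is.na(a)]
    b <- intensities[g2, j]; b <- b[!is.na(b)]
    if (length(a) < min_presence || length(b) < min_presence) return(NULL)
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    data.frame(spot = cols[j], n1 = length(a), n2 = length(b),
               mean1 = mean(a), sd1 = stats::sd(a),
               mean2 = mean(b), sd2 = stats::sd(b),
               fold_change = mean(a) / mean(b),
               p_value = p)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    warning("no spot meets the per-cluster presence requirement")
    return(data.frame(spot = character(0), n1 = integer(0), n2 = integer(0),
                      mean1 = numeric(0), sd1 = numeric(0),
                      mean2 = numeric(0), sd2 = numeric(0),
                      fold_change = numeric(0), p_value = numeric(0),
                      p_bonferroni = numeric(0), significant = logical(0)))
  }
  rows$p_bonferroni <- stats::p.adjust(rows$p_value, method = "bonferroni")
  rows$significant <- !is.na(rows$p_bonferroni) & rows$p_bonferroni < alpha
  rownames(rows) <- NULL
  rows
}

#' Full differential-spot report
#'
#' Combines the qualitative presence/absence rule
#' ([cluster_specific_spots()]) with the quantitative intensity test
#' ([intensity_difference_test()]).
#'
#' @inheritParams cluster_specific_spots
#' @inheritParams intensity_difference_test
#' @return list of class `differential_report` with `cluster_exclusive`,
#'   `tested_spots`, and the thresholds used.
#' @export
differential_report <- function(binary, intensities, partition,
                                tau_present = 1, tau_absent = 0,
                                min_presence = 3L, alpha = 0.05) {
  structure(list(
    cluster_exclusive = cluster_specific_spots(binary, partition,
                                               tau_present, tau_absent),
    tested_spots = intensity_difference_test(intensities, partition,
                                             min_presence, alpha),
    parameters = list(tau_present = tau_present, tau_absent = tau_absent,
                      min_presence = min_presence, alpha = alpha)),
    class = "differential_report")
}

#' @export
print.differential_report <- function(x, ...) {
  cat("Differential spot report\n")
  for (nm in names(x$cluster_exclusive)) {
    sp <- x$cluster_exclusive[[nm]]
    cat(sprintf("  %s-exclusive: %d spot(s)%s\n", nm, length(sp),
                if (length(sp)) paste0(" (", paste(sp, collapse = ", "), ")") else ""))
  }
  ts <- x$tested_spots
  cat(sprintf("  tested %d shared spot(s); %d significant at Bonferroni alpha=%g\n",
              nrow(ts), sum(ts$significant, na.rm = TRUE), x$parameters$alpha))
  invisible(x)
}
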