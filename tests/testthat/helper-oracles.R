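# Shared fixtures and independent oracles used across test files.

# Published two-group partitions of the 18 liver samples (sample 4 excluded):
# the gel-image clustering and the earlier enzyme-activity clustering.
liver_partitions <- function() {
  samples <- as.character(c(1:3, 5:19))
  proteomic <- stats::setNames(
    ifelse(samples %in% as.character(c(1:3, 5, 7:13)), 1L, 2L), samples)
  biochemical <- stats::setNames(
    ifelse(samples %in% as.character(c(1:3, 5:12)), 1L, 2L), samples)
  list(proteomic = proteomic, biochemical = biochemical)
}

# O(n^4) brute-force Ward agglomeration oracle. Independent of the
# Lance-Williams implementation: at every step it recomputes, from the raw
# data rows, the Ward distance of every cluster pair via the centroid form
#   D(A, B) = 2 |A||B| / (|A| + |B|) * ||mean(A) - mean(B)||^2
# (for 0/1 rows the initial distances are the Hamming distances), then
# merges the minimum with the same near-tie rule the package documents.
ward_oracle <- function(X) {
  n <- nrow(X)
  cl <- lapply(seq_len(n), identity)
  code <- -seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  hts <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(cl); best <- NULL
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- cl[[i]]; b <- cl[[j]]
      mu <- colMeans(X[a, , drop = FALSE]) - colMeans(X[b, , drop = FALSE])
      D <- 2 * length(a) * length(b) / (length(a) + length(b)) * sum(mu^2)
      key <- c(min(min(a), min(b)), max(min(a), min(b)))
      if (is.null(best) || D < best$D * (1 - 1e-9) - 1e-12 ||
          (D <= best$D * (1 + 1e-9) + 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(i = i, j = j, D = D, key = key)
    }
    i <- best$i; j <- best$j
    if (min(cl[[i]]) > min(cl[[j]])) { t <- i; i <- j; j <- t }
    ci <- code[i]; cj <- code[j]
    merges[step, ] <- if (ci < 0 && cj < 0) c(max(ci, cj), min(ci, cj)) else
      c(min(ci, cj), max(ci, cj))
    hts[step] <- best$D
    cl[[i]] <- c(cl[[i]], cl[[j]]); cl[[j]] <- NULL
    code[i] <- step; code <- code[-j]
  }
  list(merge = merges, height = hts)
}

# Greedy one-to-one benchmark of detections against ground truth at a
# fixed match radius; returns recall and precision.
detection_scores <- function(detected, truth, radius = 3) {
  if (nrow(detected) == 0L)
    return(list(recall = 0, precision = NA_real_))
  d <- sqrt(outer(detected$x, truth$x, "-")^2 +
            outer(detected$y, truth$y, "-")^2)
  used <- logical(nrow(truth)); tp <- 0L
  for (i in order(apply(d, 1, min))) {
    j <- which.min(d[i, ] + ifelse(used, 1e9, 0))
    if (d[i, j] <= radius && !used[j]) { used[j] <- TRUE; tp <- tp + 1L }
  }
  list(recall = tp / nrow(truth), precision = tp / nrow(detected))
}

# Build a spot_list directly from a coordinate table (synthetic spot lists
# that bypass image rendering / detection).
toy_spot_list <- function(ids, x, y, raw = rep(1, length(ids)),
                          gel_id = "toy", sigma = 2) {
  n <- length(ids)
  df <- data.frame(spot_id = as.integer(ids), x = x, y = y,
                   sigma = rep(sigma, length.out = n),
                   response = rep(NA_real_, n), raw_intensity = raw,
                   normalized_intensity = rep(NA_real_, n))
  structure(df, gel_id = gel_id, detection_params = NULL,
            class = c("spot_list", "data.frame"))
}
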