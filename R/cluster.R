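#' Hamming distance between two binary vectors
#'
#' Number of positions at which two equal-length 0/1 vectors differ — the
#' distance the gel clustering runs on. For 0/1 vectors this also equals
#' their squared Euclidean distance.
#'
#' @param u,v equal-length 0/1 vectors.
#' @return integer in `[0, length(u)]`.
#' @export
#' @examples
#' hamming_distance(c(1, 0, 1, 0), c(1, 0, 0, 1))
hamming_distance <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors differ in length (", length(u), " vs ", length(v), ")")
  as.integer(sum(u != v))
}

#' Pairwise Hamming distance matrix of a binary matrix
#'
#' @param binary 0/1 matrix, samples in rows.
#' @return a [stats::dist] object with the row names as labels.
#' @export
hamming_dist <- function(binary) {
  x <- as.matrix(binary)
  if (!all(x %in% c(0, 1))) stop("matrix entries must be 0/1")
  h <- tcrossprod(x, 1 - x)
  stats::as.dist(h + t(h))
}

#' Ward hierarchical clustering via the Lance-Williams recurrence
#'
#' Agglomerative clustering with Ward's minimum-variance criterion. The
#' default `"ward.D"` variant applies the Lance-Williams update
#' `alpha_i = (n_i + n_k) / (n_i + n_j + n_k)`, `beta = -n_k / (n_i + n_j + n_k)`,
#' `gamma = 0` directly to the input dissimilarities — the convention of
#' classic R hierarchical clustering. For Hamming distances on binary rows
#' this is genuine Ward clustering, since Hamming equals squared Euclidean
#' distance there. `"ward.D2"` applies the update to squared
#' dissimilarities and reports square-rooted heights.
#'
#' Merges are deterministic: among pairs whose distance is within a
#' relative `1e-9` of the minimum, the pair with the smallest
#' (min original leaf index, then second leaf index) wins.
#'
#' @param d a [stats::dist] or symmetric nonnegative matrix with zero
#'   diagonal, e.g. from [hamming_dist()].
#' @param variant `"ward.D"` (default) or `"ward.D2"`.
#' @return An object of class `hclust` (merge, height, order, labels), so
#'   `plot()`, [stats::cutree()] and [stats::cophenetic()] work on it.
#' @export
ward_linkage <- function(d, variant = c("ward.D", "ward.D2")) {
  variant <- match.arg(variant)
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 samples")
  if (!isSymmetric(unname(m), tol = 1e-9) || any(m < 0) ||
      any(abs(diag(m)) > 1e-12))
    stop("`d` must be symmetric and nonnegative with zero diagonal")
  labels <- rownames(m) %||% as.character(seq_len(n))
  work <- if (variant == "ward.D2") m^2 else m
  diag(work) <- Inf
  active <- seq_len(n)          # positions into work
  code <- -seq_len(n)           # hclust codes of active clusters
  size <- rep(1L, n)
  minleaf <- seq_len(n)         # smallest original leaf per active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    sub <- work[active, active, drop = FALSE]
    dmin <- min(sub)
    tied <- which(sub <= dmin * (1 + 1e-9) + 1e-12, arr.ind = TRUE)
    tied <- tied[tied[, 1L] < tied[, 2L], , drop = FALSE]
    key_a <- pmin(minleaf[tied[, 1L]], minleaf[tied[, 2L]])
    key_b <- pmax(minleaf[tied[, 1L]], minleaf[tied[, 2L]])
    pick <- tied[order(key_a, key_b)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    if (minleaf[i] > minleaf[j]) { tmp <- i; i <- j; j <- tmp }
    ai <- active[i]; aj <- active[j]
    h <- work[ai, aj]
    height[step] <- if (variant == "ward.D2") sqrt(h) else h
    ci <- code[i]; cj <- code[j]
    # hclust row convention: two leaves -> smaller leaf index first;
    # mixed -> leaf first; two merges -> ascending step
    merge[step, ] <- if (ci < 0 && cj < 0) c(max(ci, cj), min(ci, cj)) else
      c(min(ci, cj), max(ci, cj))
    ni <- size[i]; nj <- size[j]
    for (l in seq_len(k)) {
      if (l == i || l == j) next
      al <- active[l]; nk <- size[l]
      work[ai, al] <- work[al, ai] <-
        ((ni + nk) * work[ai, al] + (nj + nk) * work[aj, al] -
           nk * work[ai, aj]) / (ni + nj + nk)
    }
    # merged cluster lives at position ai; drop aj
    code[i] <- step
    size[i] <- ni + nj
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active <- active[-j]; code <- code[-j]
    size <- size[-j]; minleaf <- minleaf[-j]
  }
  order <- hclust_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels,
                 method = variant, call = match.call(),
                 dist.method = "hamming"),
            class = "hclust")
}

hclust_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges and labels clusters `1..k` in order of
#' first-appearing sample, so the same tree always yields the same labels.
#'
#' @param dend an `hclust` object, e.g. from [ward_linkage()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector (a partition): sample label -> cluster.
#' @export
cut_tree <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  raw <- stats::cutree(dend, k = k)
  stats::setNames(match(raw, unique(raw)), names(raw))
}

#' Silhouette widths of a partition
#'
#' Per-sample silhouette widths `(b - a) / max(a, b)` (singleton clusters
#' scored 0) and their mean, computed through \pkg{cluster}.
#'
#' @param d a [stats::dist] or symmetric distance matrix.
#' @param partition named integer vector (sample -> cluster) with `k >= 2`.
#' @return list with `widths` (named numeric) and `mean`.
#' @export
silhouette_widths <- function(d, partition) {
  dd <- stats::as.dist(as.matrix(d))
  labs <- attr(dd, "Labels") %||% as.character(seq_along(partition))
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), labs))
      stop("partition samples do not match distance labels")
    partition <- partition[labs]
  }
  if (length(unique(partition)) < 2L)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(as.integer(partition), dd)
  w <- stats::setNames(sil[, "sil_width"], labs)
  list(widths = w, mean = mean(w))
}

#' Compare two partitions: contingency table and adjusted Rand index
#'
#' The Hubert-Arabie adjusted Rand index is computed from the pair-count
#' contingency table: `(sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `max = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. It equals 1 for
#' identical partitions and is near 0 for chance agreement.
#'
#' @param p1,p2 named vectors mapping the same sample set to cluster labels.
#' @return `compare_partitions()`: list with `contingency` and
#'   `adjusted_rand`; `adjusted_rand_index()`: the numeric index alone.
#' @export
#' @examples
#' p <- c(a = 1, b = 1, c = 2, d = 2)
#' q <- c(a = 1, b = 2, c = 1, d = 2)
#' adjusted_rand_index(p, q)
compare_partitions <- function(p1, p2) {
  if (is.null(names(p1)) || is.null(names(p2)))
    stop("partitions must be named by sample")
  if (!setequal(names(p1), names(p2))) {
    miss <- c(setdiff(names(p1), names(p2)), setdiff(names(p2), names(p1)))
    stop("partitions cover different samples; differing: ",
         paste(miss, collapse = ", "))
  }
  p2 <- p2[names(p1)]
  tab <- table(p1, p2)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maximum <- (sum_a + sum_b) / 2
  ari <- if (maximum == expected) 1 else (sum_ij - expected) / (maximum - expected)
  list(contingency = tab, adjusted_rand = ari)
}

#' @rdname compare_partitions
#' @export
adjusted_rand_index <- function(p1, p2) compare_partitions(p1, p2)$adjusted_rand

#' Permutation test for cluster validity via mean silhouette
#'
#' Empirical p-value for the observed mean silhouette width of a partition
#' against the null of exchangeable labels: cluster labels are permuted
#' `n_perm` times over the samples and
#' `p = (1 + #\{permuted mean >= observed\}) / (n_perm + 1)`.
#'
#' This is a generic label-permutation stand-in for an (unspecified)
#' silhouette-based confidence procedure; it is seeded and reproducible.
#'
#' @param d distance matrix or `dist`.
#' @param partition named integer vector, `k >= 2`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `p_value`, `observed` mean silhouette, and `null`
#'   (the permuted means).
#' @export
permutation_validity_test <- function(d, partition, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be at least 99")
  obs <- silhouette_widths(d, partition)$mean
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- stats::setNames(sample(partition), names(partition))
    silhouette_widths(d, perm)$mean
  }, numeric(1)))
  list(p_value = (1 + sum(null >= obs)) / (n_perm + 1),
       observed = obs, null = null)
}

#' Cluster gels from a binary presence/absence matrix
#'
#' Convenience pipeline: Hamming distances between gel rows, Ward linkage,
#' and a cut at `k` clusters.
#'
#' @param binary 0/1 matrix, gels in rows.
#' @param k number of clusters to cut (default 2).
#' @param variant Ward variant, see [ward_linkage()].
#' @return list with `dist`, `dendrogram` (`hclust`), and `partition`.
#' @export
#' @examples
#' sim <- simulate_binary_dataset(simulation_config(seed = 11))
#' cl <- cluster_gels(sim$binary, k = 2)
#' table(cl$partition, sim$truth$partition)
cluster_gels <- function(binary, k = 2L, variant = "ward.D") {
  d <- hamming_dist(binary)
  dend <- ward_linkage(d, variant = variant)
  list(dist = d, dendrogram = dend, partition = cut_tree(dend, k))
}
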