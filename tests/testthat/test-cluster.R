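test_that("Hamming distance counts differing bits and is a metric", {
  v <- c(1, 0, 1, 1, 0)
  expect_identical(hamming_distance(v, v), 0L)
  expect_identical(hamming_distance(c(0, 0, 0, 0), c(1, 1, 1, 1)), 4L)
  expect_identical(hamming_distance(c(1, 0, 1, 0), c(1, 0, 0, 1)), 2L)
  expect_error(hamming_distance(c(1, 0), c(1, 0, 1)), "length")
  # matrix form agrees with manhattan distance on 0/1 rows, and the
  # triangle inequality holds on random triples
  set.seed(2)
  for (i in 1:20) {
    m <- matrix(rbinom(30, 1, 0.5), 3)
    h <- as.matrix(hamming_dist(m))
    expect_equal(h, as.matrix(dist(m, method = "manhattan")),
                 ignore_attr = TRUE)
    expect_lte(h[1, 3], h[1, 2] + h[2, 3])
  }
})

test_that("Ward linkage handles the smallest cases with the tie rule", {
  two <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  w <- ward_linkage(two)
  expect_equal(w$height, 5)
  expect_identical(w$merge, matrix(c(-1L, -2L), 1))
  # three equidistant points: first merge is the lowest-index pair
  eq3 <- matrix(1, 3, 3) - diag(3)
  w3 <- ward_linkage(eq3)
  expect_identical(w3$merge[1, ], c(-1L, -2L))
  expect_error(ward_linkage(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(ward_linkage(matrix(-1, 2, 2)), "symmetric")
})

test_that("Ward merge heights never decrease", {
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rbinom(8 * 20, 1, 0.5), 8)
    w <- ward_linkage(hamming_dist(m))
    expect_true(all(diff(w$height) >= -1e-12))
  }
})

test_that("linkage equals the brute-force Ward oracle on random binary data", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    m <- matrix(rbinom(n * 12, 1, 0.5), n)
    o <- ward_oracle(m)
    w <- ward_linkage(hamming_dist(m))
    expect_identical(w$merge, o$merge)
    expect_equal(w$height, o$height, tolerance = 1e-8)
  }
})

test_that("both Ward variants agree with classic hclust on tie-free data", {
  set.seed(31)
  x <- matrix(rnorm(9 * 4), 9)
  d <- dist(x)
  refD <- hclust(d, method = "ward.D")
  mineD <- ward_linkage(as.matrix(d), "ward.D")
  expect_identical(mineD$merge, refD$merge)
  expect_equal(mineD$height, refD$height)
  refD2 <- hclust(d, method = "ward.D2")
  mineD2 <- ward_linkage(as.matrix(d), "ward.D2")
  expect_identical(mineD2$merge, refD2$merge)
  expect_equal(mineD2$height, refD2$height)
})

test_that("cutting the tree yields deterministic first-appearance labels", {
  sim <- simulate_binary_dataset(simulation_config(flip_rate = 0.02, seed = 3))
  dend <- ward_linkage(hamming_dist(sim$binary))
  expect_identical(unname(cut_tree(dend, 1)), rep(1L, 18))
  expect_identical(unname(cut_tree(dend, 18)), 1:18)
  p2 <- cut_tree(dend, 2)
  expect_identical(p2[[1]], 1L)  # first sample always labels cluster 1
  expect_identical(sort(as.integer(table(p2))), c(7L, 11L))
  expect_error(cut_tree(dend, 0), "k must")
  expect_error(cut_tree(dend, 19), "k must")
})

test_that("silhouette widths match the textbook formula by hand", {
  # 4 points, two pairs; hand-computed (b - a)/max(a, b)
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 2,
                6, 6, 2, 0), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  p <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  sw <- silhouette_widths(d, p)
  expect_equal(unname(sw$widths), c(1 - 1 / 6, 1 - 1 / 6, 1 - 2 / 6, 1 - 2 / 6))
  expect_equal(sw$mean, mean(c(5 / 6, 5 / 6, 4 / 6, 4 / 6)))
  # two tight far-apart clusters approach width 1
  sim <- simulate_binary_dataset(simulation_config(flip_rate = 0, seed = 2))
  noiseless <- silhouette_widths(hamming_dist(sim$binary), sim$truth$partition)
  expect_gt(noiseless$mean, 0.9)
  expect_error(silhouette_widths(d, c(a = 1L, b = 1L, c = 1L, d = 1L)),
               "2 clusters")
})

test_that("random labels give silhouettes centred near zero", {
  set.seed(77)
  m <- matrix(rbinom(12 * 50, 1, 0.5), 12,
              dimnames = list(sprintf("s%02d", 1:12), NULL))
  d <- hamming_dist(m)
  means <- vapply(1:100, function(i) {
    p <- setNames(sample(rep(1:2, 6)), rownames(m))
    silhouette_widths(d, p)$mean
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("adjusted Rand index reproduces hand and published values", {
  p <- liver_partitions()
  ari <- adjusted_rand_index(p$proteomic, p$biochemical)
  expect_equal(round(ari, 2), 0.58)
  # identical partitions
  expect_equal(adjusted_rand_index(p$proteomic, p$proteomic), 1)
  # brute-force pair counting over all 6 pairs of 4 items gives -0.5
  a <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  b <- c(a = 1L, b = 2L, c = 1L, d = 2L)
  expect_equal(adjusted_rand_index(a, b), -0.5)
  # symmetry and label-renaming invariance
  expect_equal(adjusted_rand_index(p$biochemical, p$proteomic), ari)
  renamed <- setNames(3L - p$biochemical, names(p$biochemical))
  expect_equal(adjusted_rand_index(p$proteomic, renamed), ari)
  expect_error(adjusted_rand_index(a, b[1:3]), "differing")
  # contingency table sums to n
  cmp <- compare_partitions(p$proteomic, p$biochemical)
  expect_identical(sum(cmp$contingency), 18L)
})

test_that("adjusted Rand agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(19)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    ids <- paste0("s", seq_len(n))
    a <- setNames(sample(1:3, n, replace = TRUE), ids)
    b <- setNames(sample(1:3, n, replace = TRUE), ids)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a[ids], b[ids]))
  }
})

test_that("permutation validity test is seeded, calibrated and powerful", {
  sim <- simulate_binary_dataset(simulation_config(flip_rate = 0.02, seed = 5))
  d <- hamming_dist(sim$binary)
  pv <- permutation_validity_test(d, sim$truth$partition, n_perm = 999,
                                  seed = 2)
  expect_lte(pv$p_value, 0.01)
  # determinism
  pv2 <- permutation_validity_test(d, sim$truth$partition, n_perm = 99,
                                   seed = 7)
  pv3 <- permutation_validity_test(d, sim$truth$partition, n_perm = 99,
                                   seed = 7)
  expect_identical(pv2$p_value, pv3$p_value)
  expect_error(permutation_validity_test(d, sim$truth$partition, n_perm = 10),
               "at least 99")
  # null calibration: random labels on structureless data
  set.seed(55)
  m <- matrix(rbinom(12 * 60, 1, 0.5), 12,
              dimnames = list(sprintf("s%02d", 1:12), NULL))
  dn <- hamming_dist(m)
  ps <- vapply(1:50, function(s) {
    p <- withr::with_seed(1000 + s,
                          setNames(sample(rep(1:2, 6)), rownames(m)))
    permutation_validity_test(dn, p, n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("the gel clustering pipeline recovers planted cluster sizes", {
  sim <- simulate_binary_dataset(simulation_config(flip_rate = 0.02, seed = 17))
  cl <- cluster_gels(sim$binary, k = 2)
  expect_identical(sort(as.integer(table(cl$partition))), c(7L, 11L))
  expect_equal(adjusted_rand_index(cl$partition, sim$truth$partition), 1)
})
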