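test_that("a spot list matched to itself gives the identity mapping", {
  sl <- toy_spot_list(1:6, x = c(1, 5, 9, 2, 7, 4) * 10,
                      y = c(3, 8, 1, 6, 2, 9) * 10)
  co <- match_to_master(sl, sl, tolerance = 3)
  expect_identical(co$pairs$gel_spot_id, co$pairs$master_spot_id)
  expect_true(all(co$pairs$distance == 0))
  expect_identical(nrow(co$unmatched_gel_spots), 0L)
})

test_that("jitter below half the tolerance still matches every spot", {
  set.seed(42)
  master <- toy_spot_list(1:30, x = runif(30, 10, 200), y = runif(30, 10, 200))
  for (rep in 1:5) {
    jit <- master
    jit$x <- jit$x + runif(30, -1, 1) * 1.4 / sqrt(2)
    jit$y <- jit$y + runif(30, -1, 1) * 1.4 / sqrt(2)
    co <- match_to_master(jit, master, tolerance = 3)
    expect_identical(nrow(co$pairs), 30L)
    expect_identical(co$pairs$gel_spot_id, co$pairs$master_spot_id)
  }
})

test_that("edge cases: empty gel list is fine, empty master errors", {
  master <- toy_spot_list(1:3, x = c(1, 2, 3), y = c(1, 2, 3))
  empty <- toy_spot_list(integer(0), numeric(0), numeric(0), raw = numeric(0))
  co <- match_to_master(empty, master, tolerance = 2)
  expect_identical(nrow(co$pairs), 0L)
  expect_error(match_to_master(master, empty, tolerance = 2), "master")
  expect_error(match_to_master(master, master, tolerance = 0), "positive")
})

test_that("matching is one-to-one, order-stable, and monotone in tolerance", {
  set.seed(7)
  master <- toy_spot_list(1:20, x = runif(20, 0, 100), y = runif(20, 0, 100))
  gel <- toy_spot_list(1:25, x = runif(25, 0, 100), y = runif(25, 0, 100))
  n_pairs <- vapply(c(10, 5, 2, 1, 0.5), function(tol)
    nrow(match_to_master(gel, master, tolerance = tol)$pairs), integer(1))
  expect_true(all(diff(n_pairs) <= 0))
  co <- match_to_master(gel, master, tolerance = 5)
  expect_false(anyDuplicated(co$pairs$master_spot_id) > 0)
  expect_false(anyDuplicated(co$pairs$gel_spot_id) > 0)
  # permuting input spot order changes nothing (ids are the identity)
  perm <- gel[sample(nrow(gel)), ]
  attr(perm, "gel_id") <- "toy"
  co2 <- match_to_master(perm, master, tolerance = 5)
  o1 <- co$pairs[order(co$pairs$gel_spot_id), ]
  o2 <- co2$pairs[order(co2$pairs$gel_spot_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("similarity pre-registration recovers a shifted, rotated gel", {
  set.seed(11)
  master <- toy_spot_list(1:40, x = runif(40, 20, 230), y = runif(40, 20, 230))
  th <- 2 * pi / 180  # 2 degrees
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(master$x, master$y) %*% t(R) * 1.02
  moved <- master
  moved$x <- xy[, 1] + 6; moved$y <- xy[, 2] - 4
  plain <- match_to_master(moved, master, tolerance = 2)
  reg <- match_to_master(moved, master, tolerance = 2, pre_register = TRUE)
  expect_gt(nrow(reg$pairs), nrow(plain$pairs))
  expect_identical(nrow(reg$pairs), 40L)
  expect_identical(reg$pairs$gel_spot_id, reg$pairs$master_spot_id)
})

test_that("hand-built correspondences assemble the expected matrices", {
  # master: 3 spots far apart; gels: subsets with known positions
  master <- toy_spot_list(1:3, x = c(10, 50, 90), y = c(10, 50, 90),
                          raw = c(5, 5, 5), gel_id = "master")
  g1 <- toy_spot_list(1:3, x = c(10, 50, 90), y = c(10, 50, 90),
                      raw = c(2, 3, 5), gel_id = "g1")
  g2 <- toy_spot_list(1:2, x = c(10.5, 90.2), y = c(10.2, 89.7),
                      raw = c(1, 3), gel_id = "g2")
  g3 <- toy_spot_list(1:2, x = c(49.8, 30), y = c(50.1, 30),
                      raw = c(4, 4), gel_id = "g3")
  cos <- lapply(list(g1, g2, g3), match_to_master, master = master,
                tolerance = 2)
  out <- build_matrices(cos, master, list(g1, g2, g3), union_columns = FALSE)
  expect_identical(out$binary,
                   matrix(c(1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L, 0L), 3,
                          byrow = TRUE,
                          dimnames = list(c("g1", "g2", "g3"),
                                          c("M1", "M2", "M3"))))
  expect_equal(out$intensity["g1", ], c(M1 = 0.2, M2 = 0.3, M3 = 0.5))
  expect_equal(out$intensity["g2", ], c(M1 = 0.25, M2 = NA, M3 = 0.75))
  expect_equal(out$intensity["g3", ], c(M1 = NA, M2 = 1, M3 = NA))
  # master matched to itself -> all-ones row over master columns
  com <- match_to_master(master, master, tolerance = 2)
  outm <- build_matrices(list(com), master, list(master))
  expect_true(all(outm$binary == 1L))
  expect_error(build_matrices(list(com, com), master, list(master, master)),
               "duplicate gel_id")
})

test_that("recurrent unmatched spots open union columns; singletons do not", {
  master <- toy_spot_list(1, x = 10, y = 10, gel_id = "master")
  # g1 and g2 share an off-master spot at ~ (60, 60); g3 has a lone one
  g1 <- toy_spot_list(1:2, x = c(10, 60), y = c(10, 60), raw = c(1, 1),
                      gel_id = "g1")
  g2 <- toy_spot_list(1:2, x = c(10, 60.5), y = c(10, 59.8), raw = c(1, 3),
                      gel_id = "g2")
  g3 <- toy_spot_list(1:2, x = c(10, 200), y = c(10, 200), raw = c(1, 1),
                      gel_id = "g3")
  cos <- lapply(list(g1, g2, g3), match_to_master, master = master,
                tolerance = 2)
  out <- build_matrices(cos, master, list(g1, g2, g3),
                        union_columns = TRUE, tolerance = 2)
  expect_identical(colnames(out$binary), c("M1", "U1"))
  expect_identical(out$binary[, "U1"], c(g1 = 1L, g2 = 1L, g3 = 0L))
  # union cell intensities are normalized over each gel's matched spots
  expect_equal(out$intensity["g2", "U1"], 0.75)
  # master-only mode drops the union column
  outm <- build_matrices(cos, master, list(g1, g2, g3), union_columns = FALSE)
  expect_identical(colnames(outm$binary), "M1")
})

test_that("noiseless simulated spot lists round-trip to the planted matrix", {
  cfg <- simulation_config(n_spots_universe = 40, cluster_sizes = c(3L, 2L),
                           shared_spot_fraction = 0.5,
                           specific_spot_counts = c(2L, 4L),
                           flip_rate = 0, seed = 13)
  sim <- simulate_binary_dataset(cfg)
  # universe spot positions on a grid; every gel's list = its present spots
  pos <- expand.grid(x = seq(10, 10 + 7 * 30, by = 30),
                     y = seq(10, 10 + 4 * 30, by = 30))[1:40, ]
  master <- toy_spot_list(1:40, pos$x, pos$y, gel_id = "master")
  lists <- lapply(rownames(sim$binary), function(g) {
    idx <- which(sim$binary[g, ] == 1L)
    toy_spot_list(idx, pos$x[idx], pos$y[idx], gel_id = g)
  })
  cos <- lapply(lists, match_to_master, master = master, tolerance = 3)
  out <- build_matrices(cos, master, lists, union_columns = FALSE)
  expect_identical(unname(out$binary), unname(sim$binary))
  # row sums equal matched spots per gel
  expect_identical(unname(rowSums(out$binary)),
                   as.numeric(vapply(cos, function(co) nrow(co$pairs),
                                     integer(1))))
})

test_that("manual spot patches add and delete spots", {
  sl <- toy_spot_list(1:3, x = c(10, 20, 30), y = c(10, 20, 30))
  patch <- data.frame(action = c("delete", "add"),
                      spot_id = c(2L, NA),
                      x = c(NA, 55), y = c(NA, 55), sigma = c(NA, 2))
  out <- apply_spot_patch(sl, patch)
  expect_identical(out$spot_id, c(1L, 3L, 4L))
  expect_identical(out$x[3], 55)
})
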