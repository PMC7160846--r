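test_that("group t-map matches hand computation and flags degeneracy", {
  dims <- c(4, 4, 4)
  vals <- c(0.1, 0.2, 0.3)
  maps <- lapply(vals, function(v) fake_map(array(v, dims)))
  g <- group_ttest(maps)
  expect_equal(g$dof, 2L)
  expect_equal(g$t_values[2, 2, 2], 2 * sqrt(3), tolerance = 1e-12)  # hand t
  # identical constant maps: zero variance -> +Inf sentinel, flagged
  same <- lapply(1:3, function(i) fake_map(array(0.2, dims)))
  gs <- group_ttest(same)
  expect_true(all(gs$t_values == Inf))
  expect_true(all(gs$degenerate))
  expect_error(group_ttest(same[1:2]), "length")
})

test_that("sign flip of all subjects negates the t-map exactly", {
  set.seed(9)
  dims <- c(5, 5, 5)
  maps <- lapply(1:6, function(i) fake_map(array(rnorm(125), dims)))
  flipped <- lapply(maps, function(m) { m$values <- -m$values; m })
  t1 <- group_ttest(maps)$t_values
  t2 <- group_ttest(flipped)$t_values
  expect_equal(t2, -t1, tolerance = 1e-12)
})

test_that("cluster extraction honors connectivity and size filters", {
  dims <- c(6, 6, 6)
  tv <- array(0, dims)
  # two components touching only through an edge (diagonal in the i-j plane)
  tv[2, 2, 2] <- 10
  tv[3, 3, 2] <- 11
  stat <- fake_stat(tv, dof = 17)
  expect_equal(nrow(extract_clusters(stat, connectivity = 6)), 2)
  expect_equal(nrow(extract_clusters(stat, connectivity = 18)), 1)
  expect_equal(nrow(extract_clusters(stat, connectivity = 26)), 1)
  expect_error(extract_clusters(stat, connectivity = 10), "connectivity")
  # empty suprathreshold set -> empty table
  expect_equal(nrow(extract_clusters(fake_stat(array(0, dims)))), 0)
  # min_size filter uses a strict inequality (size > min_size)
  expect_equal(nrow(extract_clusters(stat, connectivity = 18, min_size = 2)), 0)
})

test_that("a planted suprathreshold block comes back as one exact cluster", {
  dims <- c(9, 9, 9)
  tv <- array(0, dims)
  lin <- block_lin(c(2, 2, 2), c(7, 7, 7), dims)
  tv[lin] <- 5
  tv[4, 5, 6] <- 9                       # unique peak inside the block
  cl <- extract_clusters(fake_stat(tv, dof = 17))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size_voxels, 343)
  expect_equal(c(cl$peak_i, cl$peak_j, cl$peak_k), c(4, 5, 6))
  expect_equal(cl$peak_t, 9)
  expect_equal(cl$peak_mm_x, 3 * 3)      # (index-1) * 3 mm
  expect_equal(sort(attr(cl, "members")[[1]]), sort(lin))
  # peak z is the quantile-matched normal equivalent
  expect_equal(cl$peak_z, qnorm(pt(9, 17)), tolerance = 1e-10)
})

test_that("voxelwise thresholding is calibrated on null maps", {
  set.seed(12)
  dims <- c(16, 16, 16)
  n_sub <- 8
  frac <- mean(replicate(6, {
    maps <- lapply(seq_len(n_sub), function(i)
      fake_map(array(rnorm(prod(dims), sd = 0.05), dims)))
    g <- group_ttest(maps)
    mean(g$t_values > qt(0.99, g$dof))
  }))
  expect_gt(frac, 0.004)   # nominal 0.01 with binomial slack
  expect_lt(frac, 0.017)
})

test_that("sign-flip null is seeded, monotone in alpha, and settings-checked", {
  set.seed(3)
  dims <- c(8, 8, 8)
  maps <- lapply(1:6, function(i)
    fake_map(array(rnorm(512, mean = 0.05, sd = 0.1), dims)))
  n1 <- signflip_null(maps, p_voxel = 0.05, n_perm = 100, seed = 7)
  n2 <- signflip_null(maps, p_voxel = 0.05, n_perm = 100, seed = 7)
  expect_identical(n1$max_cluster_sizes, n2$max_cluster_sizes)
  n_loose <- signflip_null(maps, p_voxel = 0.05, n_perm = 100, seed = 7,
                           alpha = 0.2)
  expect_lte(n_loose$threshold_size, n1$threshold_size)
  obs <- extract_clusters(group_ttest(maps), p_voxel = 0.05)
  wrong <- extract_clusters(group_ttest(maps), p_voxel = 0.01)
  expect_error(significant_clusters(wrong, n1), "different settings")
  decl <- significant_clusters(obs, n1)
  expect_true(all(c("significant", "p_empirical") %in% names(decl)))
})

test_that("significance against the null follows the >= threshold tie rule", {
  sizes <- c(rep(0L, 90), rep(3L, 6), rep(8L, 4))
  null <- structure(list(max_cluster_sizes = sizes,
                         threshold_size = stickmvpa:::upper_tail_threshold(sizes, 0.05),
                         alpha = 0.05, n_perm = 100L, seed = 1L,
                         settings = list(p_voxel = 0.001, connectivity = 18L,
                                         dof = 7L)),
                    class = "permutation_null")
  # upper tail: P(>=8)=0.04<=0.05 but P(>=3)=0.10 -> threshold 8
  expect_equal(null$threshold_size, 8L)
  tv <- array(0, c(6, 6, 6))
  tv[block_lin(c(2, 2, 2), c(2, 2, 2), c(6, 6, 6))] <- 10   # size 8 cluster
  cl <- significant_clusters(extract_clusters(fake_stat(tv, dof = 7)), null)
  expect_true(cl$significant)            # boundary size == threshold counts
  expect_equal(cl$p_empirical, (1 + 4) / 101)
  tv2 <- array(0, c(6, 6, 6)); tv2[2, 2, 2] <- 10
  cl2 <- significant_clusters(extract_clusters(fake_stat(tv2, dof = 7)), null)
  expect_false(cl2$significant)
  expect_equal(cl2$p_empirical, (1 + 10) / 101)
})

test_that("a strong common signal is always detected", {
  set.seed(21)
  dims <- c(10, 10, 10)
  lin <- block_lin(c(4, 4, 4), c(3, 3, 3), dims)
  maps <- lapply(1:8, function(i) {
    v <- array(rnorm(1000, sd = 0.05), dims)
    v[lin] <- v[lin] + 0.3
    fake_map(v)
  })
  obs <- extract_clusters(group_ttest(maps))
  null <- signflip_null(maps, n_perm = 100, seed = 2)
  decl <- significant_clusters(obs, null)
  expect_true(any(decl$significant))
  expect_gte(max(decl$size_voxels), 27)
})
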