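test_that("bounded-loss pair distance: bounds, symmetry, hand values", {
  expect_equal(pair_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pair_distance(1, 0), 1)          # bounded-loss extreme
  expect_equal(pair_distance(c(1, 2), c(3, 2)), sqrt((4 / 10 + 0) / 2))
  expect_equal(pair_distance(c(1, 2), c(3, 2)), 0.4472, tolerance = 1e-4)
  expect_equal(pair_distance(c(0, 5), c(0, 5)), 0)  # 0/0 terms count as 0
  expect_equal(pair_distance(c(2, 7), c(5, 1)), pair_distance(c(5, 1), c(2, 7)))
  expect_error(pair_distance(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("distance matrix: invariants hold and entries match elementwise
           hand computation", {
  tab <- data.frame(species_id = c("a", "b", "c"),
                    t1 = c(1, 3, 2), t2 = c(2, 2, 5), t3 = c(10, 1, 4))
  D <- trait_distance_matrix(tab, traits = c("t1", "t2", "t3"))
  expect_equal(diag(unclass(D)), c(a = 0, b = 0, c = 0))
  expect_equal(unclass(D), t(unclass(D)))
  expect_true(all(D >= 0 & D <= 1))
  for (i in 1:3) for (j in 1:3) {
    xi <- unlist(tab[i, c("t1", "t2", "t3")])
    xj <- unlist(tab[j, c("t1", "t2", "t3")])
    expect_equal(D[i, j], pair_distance(xi, xj))
  }
  # per-trait rescaling leaves the matrix unchanged
  tab2 <- tab; tab2$t2 <- tab2$t2 * 1000
  expect_equal(unclass(trait_distance_matrix(tab2,
                                             traits = c("t1", "t2", "t3"))),
               unclass(D), tolerance = 1e-14)
})

test_that("species with missing traits are dropped with a count, or raise
           an error on request", {
  tab <- data.frame(species_id = c("a", "b", "c"), t1 = c(1, NA, 2),
                    t2 = c(2, 2, 5))
  D <- trait_distance_matrix(tab, traits = c("t1", "t2"))
  expect_equal(dim(D), c(2L, 2L))
  expect_equal(attr(D, "n_dropped"), 1L)
  expect_error(trait_distance_matrix(tab, traits = c("t1", "t2"),
                                     na_action = "error"), "b")
})

test_that("classical MDS embeds two points at distance 2 at +/-1 and
           recovers planar Euclidean configurations exactly", {
  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("u", "w"), c("u", "w")))
  m2 <- classical_mds(D2, n_axes = 1)
  expect_equal(unname(sort(m2$points[, 1])), c(-1, 1))
  set.seed(7)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(stats::dist(X))
  m <- suppressWarnings(classical_mds(D, n_axes = 5))
  expect_lte(m$n_axes, 2L)  # planar configuration has rank 2
  Dhat <- as.matrix(stats::dist(m$points))
  expect_lt(max(abs(Dhat - D)), 1e-8)
  expect_true(all(abs(m$eig[3:10]) < 1e-8 * m$eig[1]))
  expect_true(all(diff(m$eig) <= 1e-12))  # nonincreasing
})

test_that("authored double-centering agrees with the reference classical
           scaling implementation", {
  set.seed(12)
  X <- matrix(rnorm(24), 8, 3)
  D <- as.matrix(stats::dist(X))
  mine <- classical_mds(D, n_axes = 3)
  ref <- stats::cmdscale(D, k = 3, eig = TRUE)
  expect_equal(mine$eig, ref$eig, tolerance = 1e-9)
  expect_equal(abs(mine$points), abs(ref$points), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("axis signs are deterministic across repeated runs", {
  D <- trait_distance_matrix(fixture_traits())
  m1 <- classical_mds(D)
  m2 <- classical_mds(D)
  expect_identical(m1$points, m2$points)
  for (k in seq_len(ncol(m1$points)))
    expect_gt(m1$points[which.max(abs(m1$points[, k])), k], 0)
})

test_that("trait-axis correlations match the brute-force formula; constant
           traits are flagged missing", {
  tab <- fixture_traits()
  D <- trait_distance_matrix(tab)
  m <- classical_mds(D, n_axes = 2)
  corr <- trait_axis_correlations(tab, m)
  idx <- match(rownames(m$points), tab$species_id)
  brute <- function(v, ax) {
    v <- log10(v)
    sum((v - mean(v)) * (ax - mean(ax))) /
      sqrt(sum((v - mean(v))^2) * sum((ax - mean(ax))^2))
  }
  for (tr in deb_mds_traits())
    expect_equal(corr[tr, 1], brute(tab[[tr]][idx], m$points[, 1]),
                 info = tr)
  # a trait identical to the axis-1 coordinate correlates perfectly
  tab$fake <- NA_real_
  tab$fake[idx] <- m$points[, 1]
  corr2 <- trait_axis_correlations(tab, m, traits = "fake",
                                   log10_transform = FALSE)
  expect_equal(corr2["fake", "axis1"], 1)
  tab$const <- 2
  corr3 <- trait_axis_correlations(tab, m, traits = "const")
  expect_true(all(is.na(corr3["const", ])))
})

test_that("the whole trait-space pipeline is invariant to per-trait unit
           changes", {
  tab <- fixture_traits()
  tab2 <- tab
  tab2$Ww_i <- tab2$Ww_i / 1000   # kg instead of g
  tab2$a_m <- tab2$a_m / 365.25   # years instead of days
  D1 <- trait_distance_matrix(tab)
  D2 <- trait_distance_matrix(tab2)
  expect_equal(unclass(D1), unclass(D2), tolerance = 1e-12)
  m1 <- classical_mds(D1); m2 <- classical_mds(D2)
  expect_equal(m1$points, m2$points, tolerance = 1e-9)
})
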