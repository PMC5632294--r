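test_that("quasi-random directions are unit, deterministic and balanced", {
  d <- generate_directions(3, 1000)
  expect_equal(dim(d), c(1000L, 3L))
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-9))
  expect_identical(unclass(d), unclass(generate_directions(3, 1000)))

  d2 <- generate_directions(2, 4096)
  expect_lt(sqrt(sum(colMeans(d2)^2)), 0.05)

  expect_error(generate_directions(0, 10))
  expect_error(generate_directions(3, 0))
  off <- generate_directions(3, 10, offset = 5L)
  expect_equal(unclass(off)[1, ], unclass(generate_directions(3, 15))[6, ])
})

test_that("the KS statistic matches hand-checked values and the oracle", {
  x <- c(0.3, 1.2, -0.5)
  expect_equal(ks_two_sample(x, x), 0)
  expect_equal(ks_two_sample(c(0, 0), c(1, 1)), 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(2, 3, 4, 5)), 0.25)
  expect_error(ks_two_sample(numeric(0), x), "nonempty")

  set.seed(42)
  for (i in 1:100) {
    n <- sample(1:50, 1); m <- sample(1:50, 1)
    a <- round(rnorm(n), 1)  # rounding forces ties across samples
    b <- round(rnorm(m, sd = runif(1, 0.5, 2)), 1)
    expect_equal(ks_two_sample(a, b), ks_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("pooled median/IQR standardisation behaves at the edges", {
  tr <- assign_orders(simulate_tree(small_params(), 2), force = TRUE)
  st <- segment_table(tr, 0:1)
  std <- standardize_pair(st, st)
  expect_identical(std$model, std$data)

  a <- data.frame(u = c(-1, -1), v = c(5, 5))
  b <- data.frame(u = c(1, 1), v = c(5, 5))
  std <- standardize_pair(a, b)
  # pooled u: median 0, IQR 2 -> {-0.5, 0.5}; constant v passes centred
  expect_equal(std$model[, "u"], c(-0.5, -0.5))
  expect_equal(std$data[, "u"], c(0.5, 0.5))
  expect_equal(std$model[, "v"], c(0, 0))

  expect_error(standardize_pair(a, data.frame(u = 1, w = 2)),
               "column mismatch")
})

test_that("the structural distance is a bounded, symmetric discrepancy", {
  dirs <- generate_directions(4, 300)
  for (s in 1:5) {
    t1 <- assign_orders(simulate_tree(small_params(), s), force = TRUE)
    t2 <- assign_orders(simulate_tree(small_params(), s + 100), force = TRUE)
    u1 <- segment_table(t1, 0:1); u2 <- segment_table(t2, 0:1)
    expect_identical(structural_distance(u1, u1, dirs), 0)
    d12 <- structural_distance(u1, u2, dirs)
    expect_equal(d12, structural_distance(u2, u1, dirs), tolerance = 1e-12)
    expect_gte(d12, 0); expect_lte(d12, 1)
  }
  # empty table: maximal penalty
  empty <- feature_table(data.frame(R = numeric(0), L = numeric(0),
                                    gamma = numeric(0), zeta = numeric(0)),
                         "segment", 4L)
  u <- segment_table(assign_orders(simulate_tree(small_params(), 1)), 0:1)
  expect_equal(structural_distance(empty, u, dirs), 1)
})

test_that("the distance increases with the separation of two Gaussians", {
  dirs <- generate_directions(2, 500)
  meds <- vapply(c(0, 1, 2), function(delta) {
    median(vapply(1:10, function(r) {
      structural_distance(gaussian_table(300, 0, seed = r),
                          gaussian_table(300, delta, seed = 1000 + r), dirs)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(meds[1], meds[2])
  expect_lt(meds[2], meds[3])
})

test_that("aggregate distance averages per-pair values", {
  dirs <- generate_directions(4, 100)
  t1 <- assign_orders(simulate_tree(small_params(), 1), force = TRUE)
  t2 <- assign_orders(simulate_tree(small_params(), 2), force = TRUE)
  u1 <- segment_table(t1, 0:1); u2 <- segment_table(t2, 0:1)
  res <- aggregate_distance(list(same = list(model = u1, data = u1),
                                 diff = list(model = u1, data = u2)), dirs)
  expect_equal(res$mean, mean(res$per_pair))
  expect_equal(res$per_pair[["same"]], 0)
  single <- aggregate_distance(list(list(model = u1, data = u2)), dirs)
  expect_equal(single$mean, single$per_pair[[1]])
  expect_error(aggregate_distance(list(), dirs), "at least one")

  # one identical and one disjoint pair: mean strictly inside (0, 1)
  empty <- feature_table(data.frame(R = numeric(0), L = numeric(0),
                                    gamma = numeric(0), zeta = numeric(0)),
                         "segment", 4L)
  mix <- aggregate_distance(list(list(model = u1, data = u1),
                                 list(model = empty, data = u1)), dirs)
  expect_gt(mix$mean, 0); expect_lt(mix$mean, 1)
})

test_that("height, girth and crown spread have exact closed forms", {
  tr <- chain_tree(1, len = 2)
  expect_equal(tree_height(tr), 2)
  tilted <- tree(cyl_row(0.1, sqrt(2), c(0, 0, 0), c(1, 0, 1), NA_integer_))
  expect_equal(tree_height(tilted), 1, tolerance = 1e-12)

  tr <- simulate_tree(small_params(), 17)
  ends <- cylinder_ends(tr)
  expect_equal(tree_height(tr), max(c(tr$cylinders$start_z, ends[, 3])))

  jt <- junction_tree()
  expect_equal(girth(jt), 0.2)
  expect_equal(girth(chain_tree(1)), girth(chain_tree(5)))  # branches don't move girth

  ct <- circle_tree(r = 3)
  expect_equal(crown_spread(ct, 10), 6, tolerance = 1e-12)
  expect_equal(crown_spread(chain_tree(4)), 0)  # all mass on the axis
  expect_error(crown_spread(ct, 7), "divide 360")
})

test_that("crown spread is invariant to rotation by sector multiples", {
  tr <- assign_orders(simulate_tree(small_params(), 23), force = TRUE)
  c0 <- crown_spread(tr, 10)
  rot <- function(t, deg) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    cyl <- t$cylinders
    s <- as.matrix(cyl[, c("start_x", "start_y", "start_z")]) %*% t(R)
    a <- as.matrix(cyl[, c("axis_x", "axis_y", "axis_z")]) %*% t(R)
    cyl[, c("start_x", "start_y", "start_z")] <- s
    cyl[, c("axis_x", "axis_y", "axis_z")] <- a
    t$cylinders <- cyl
    t
  }
  expect_equal(crown_spread(rot(tr, 20), 10), c0, tolerance = 1e-9)
  expect_equal(crown_spread(rot(tr, 120), 10), c0, tolerance = 1e-9)
})

test_that("classical distances are relative errors against the reference", {
  m <- structure(list(h = 10, g = 0.1, c = 4), class = "classical_metrics")
  expect_equal(classical_distances(m, m), c(d_h = 0, d_g = 0, d_c = 0))
  m2 <- structure(list(h = 8, g = 0.25, c = 4), class = "classical_metrics")
  d <- classical_distances(m2, m)
  expect_equal(d[["d_h"]], 0.2)
  expect_equal(d[["d_g"]], 1.5)  # girth errors can exceed 100%
  bad <- structure(list(h = 0, g = 0.1, c = 1), class = "classical_metrics")
  expect_error(classical_distances(m, bad), "positive")
})

test_that("distance work scales linearly in lines and n log n in samples", {
  ops <- function(n, L) {
    attr(structural_distance(gaussian_table(n, seed = 1),
                             gaussian_table(n, seed = 2),
                             generate_directions(2, L), count_ops = TRUE),
         "ops")
  }
  o1 <- ops(100, 100); o2 <- ops(100, 400)
  expect_equal(o2$sort / o1$sort, 4)   # 4x lines -> 4x work
  expect_equal(o2$proj / o1$proj, 4)
  o3 <- ops(400, 100)
  N1 <- 200; N3 <- 800
  expect_equal(o3$sort / o1$sort,
               (N3 * ceiling(log2(N3))) / (N1 * ceiling(log2(N1))))
  expect_equal(o3$merge / o1$merge, 4)  # merge pass is linear in samples
})
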