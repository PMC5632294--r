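test_that("the parameter set counts 23 grouped plus 4 fixed parameters", {
  g <- sot_param_groups()
  expect_equal(sum(g %in% c("I", "II", "III", "IV", "V")), 23L)
  expect_equal(sum(g == "fixed"), 4L)
  p <- sot_params()
  expect_setequal(names(g), names(p))
  expect_equal(p$segment_length, 0.2)
  expect_equal(p$voxel_size, 0.2)
  expect_equal(p$arena_size, 12)
  expect_error(sot_params(lambda = 1.2), "lambda")
  expect_error(sot_params(n_iterations = 0), "n_iterations")
})

test_that("shadow casting deposits a decaying inverted pyramid", {
  p <- sot_params()
  g <- shadow_grid(p$arena_size, p$voxel_size)
  pt <- c(0.1, 0.1, 6.1)
  g1 <- cast_shadow(g, pt, a = 0.1, b = 2, depth = 4)
  idx <- treeclone:::.voxel_index(g1, matrix(pt, 1))
  expect_equal(g1[idx[1], idx[2], idx[3]], 0.1)               # layer 0: + a
  expect_equal(g1[idx[1], idx[2], idx[3] - 2], 0.1 * 2^-2)    # two layers down
  expect_equal(g1[idx[1] + 2, idx[2] - 2, idx[3] - 2], 0.1 * 2^-2)
  expect_equal(g1[idx[1] + 2, idx[2], idx[3] - 1], 0)          # outside layer 1
  # two buds in one voxel: contributions add, total mass doubles
  g2 <- cast_shadow(g1, pt, a = 0.1, b = 2, depth = 4)
  expect_equal(sum(g2), 2 * sum(g1), tolerance = 1e-12)
  expect_equal(g2[idx[1], idx[2], idx[3]], 0.2)
  expect_warning(cast_shadow(g, c(0, 0, 100), 0.1, 2, 4), "outside arena")
})

test_that("light exposure clamps at full shade and scales with the gradient", {
  p <- sot_params(light_gradient = 0.5)
  g <- shadow_grid(p$arena_size, p$voxel_size)
  pt <- c(0, 0, 6)
  expect_equal(light_exposure(g, pt, p),
               p$base_exposure * (1 + 0.5 * 6 / 12))
  # heavy shading (s >= C + a) drives exposure to zero
  gs <- g
  for (i in 1:15) gs <- cast_shadow(gs, pt, 0.1, 2, 4)
  expect_equal(light_exposure(gs, pt, p, own_shadow = 0.1), 0)
  # a single neighbour above strictly reduces exposure
  g1 <- cast_shadow(g, pt + c(0, 0, 0.4), 0.1, 2, 4)
  expect_lt(light_exposure(g1, pt, p), light_exposure(g, pt, p))
})

test_that("resource allocation conserves and respects apical dominance", {
  al <- allocate_resource(1, c(0.5, 0.5), lambda = 1, v_in = 3)
  expect_equal(al$terminal, 3); expect_equal(al$laterals, c(0, 0))
  al <- allocate_resource(1, c(0.5, 0.5), lambda = 0, v_in = 3)
  expect_equal(al$terminal, 0); expect_equal(sum(al$laterals), 3)
  al <- allocate_resource(1, 1, lambda = 0.5, v_in = 2)
  expect_equal(al$terminal, 1, tolerance = 1e-12)
  expect_equal(al$terminal + sum(al$laterals), 2, tolerance = 1e-12)
  al <- allocate_resource(0, numeric(0), 0.5, 1)  # lightless node
  expect_equal(al$terminal, 0)
})

test_that("a lone seed bud starts a vertical metamer chain", {
  p <- small_params(heading_noise = 0, tropism_strength = 0)
  st <- sot_init_state(p)
  st1 <- grow_step(st, p, 1L)
  n_new <- length(st1$seg$sx)
  expect_gte(n_new, 1L)
  expect_true(all(abs(st1$seg$ax[1:n_new]) < 1e-9))
  expect_true(all(st1$seg$az[1:n_new] == 1))
  # determinism of a single step
  st1b <- grow_step(st, p, 1L)
  expect_identical(st1, st1b)
  # zero resource coefficient: nothing grows
  p0 <- small_params(resource_coef = 0)
  expect_equal(length(grow_step(sot_init_state(p0), p0, 1L)$seg$sx), 0L)
})

test_that("pipe-model radii conserve r^e across every junction", {
  # closed-form 3-4-5 junction at e = 2: with tip radius 0.01, a child
  # carrying 9 leaves gets r = 0.03, one carrying 16 leaves gets 0.04,
  # and their parent must get exactly 0.05
  rows <- list(cyl_row(1, 1, c(0, 0, 0), c(0, 0, 1), NA_integer_),
               cyl_row(1, 1, c(0, 0, 1), c(1, 0, 1), 1L),
               cyl_row(1, 1, c(0, 0, 1), c(-1, 0, 1), 1L))
  endA <- c(0, 0, 1) + c(1, 0, 1) / sqrt(2)
  endB <- c(0, 0, 1) + c(-1, 0, 1) / sqrt(2)
  for (k in 1:9) rows[[length(rows) + 1]] <-
    cyl_row(1, 0.5, endA, c(cos(k), sin(k), 1), 2L)
  for (k in 1:16) rows[[length(rows) + 1]] <-
    cyl_row(1, 0.5, endB, c(cos(k), sin(k), 1), 3L)
  tr <- update_radii(tree(do.call(rbind, rows)),
                     pipe_exponent = 2, tip_radius = 0.01)
  expect_equal(tr$cylinders$radius[2], 0.03, tolerance = 1e-12)
  expect_equal(tr$cylinders$radius[3], 0.04, tolerance = 1e-12)
  expect_equal(tr$cylinders$radius[1], 0.05, tolerance = 1e-12)
  # chain below a single child keeps the child's radius
  chain <- update_radii(chain_tree(4), 2, 0.02)
  expect_true(all(chain$cylinders$radius == 0.02))

  # every junction of a simulated tree, at the simulator's exponent
  for (s in c(1, 8)) {
    p <- small_params(pipe_exponent = 2.5)
    tr <- simulate_tree(p, s)
    cyl <- tr$cylinders
    kids <- treeclone:::.children_of(tr)
    for (i in seq_len(nrow(cyl))) {
      ch <- kids[[i]]
      expected <- if (length(ch) == 0L) p$tip_radius else
        sum(cyl$radius[ch]^2.5)^(1 / 2.5)
      expect_equal(cyl$radius[i], expected, tolerance = 1e-9)
    }
    # chain: uniform tip radius
    expect_true(all(cyl$radius >= p$tip_radius - 1e-12))
  }
})

test_that("simulated trees respect the arena, segment length and seed", {
  p <- small_params()
  tr <- simulate_tree(p, 5)
  cyl <- tr$cylinders
  A <- p$arena_size
  ends <- cylinder_ends(tr)
  pts <- rbind(as.matrix(cyl[, c("start_x", "start_y", "start_z")]), ends)
  expect_true(all(pts[, 1] >= -A / 2 & pts[, 1] <= A / 2))
  expect_true(all(pts[, 2] >= -A / 2 & pts[, 2] <= A / 2))
  expect_true(all(pts[, 3] >= 0 & pts[, 3] <= A))
  expect_true(all(cyl$length == p$segment_length))

  expect_identical(simulate_tree(p, 5)$cylinders, cyl)
  expect_false(identical(simulate_tree(p, 6)$cylinders, cyl))
})

test_that("more growth iterations produce strictly larger trees", {
  p18 <- sot_params(arena_size = 8, n_iterations = 12)
  p30 <- sot_params(arena_size = 8, n_iterations = 18)
  for (s in c(3, 14)) {
    expect_gt(n_cylinders(simulate_tree(p30, s)),
              n_cylinders(simulate_tree(p18, s)))
  }
})

test_that("with zero angle noise the crown is regular up to tropism", {
  p <- small_params(heading_noise = 0, branching_angle_spread = 0,
                    divergence_spread = 0, bud_break_prob = 1,
                    n_iterations = 4)
  a <- simulate_tree(p, 1)
  b <- simulate_tree(p, 2)
  # no stochastic angle terms and deterministic gating: seeds cannot differ
  expect_identical(a$cylinders, b$cylinders)
})

test_that("the distance landscape along lambda is rugged across replicates", {
  target <- make_sot_target(small_params(), seed = 40)
  prof <- distance_profile(small_params(), "lambda",
                           values = c(0.2, 0.4, 0.6), target = target$tree,
                           n_reps = 3, seed_base = 50, n_lines = 100)
  v <- tapply(prof$distance, prof$value, stats::var)
  expect_true(all(v > 0))  # replicate-to-replicate variability at each value
  expect_equal(nrow(prof), 9L)
})
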