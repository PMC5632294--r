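# Shared fixtures and independent oracles, built in code.

# One cylinder row in canonical column layout.
cyl_row <- function(radius, length, start, axis, parent, extension = 0L,
                    branch_id = NA_integer_, branch_order = NA_integer_,
                    pos_in_branch = NA_integer_) {
  axis <- axis / sqrt(sum(axis^2))
  data.frame(radius = radius, length = length,
             start_x = start[1], start_y = start[2], start_z = start[3],
             axis_x = axis[1], axis_y = axis[2], axis_z = axis[3],
             parent = parent, extension = extension,
             branch_id = branch_id, branch_order = branch_order,
             pos_in_branch = pos_in_branch)
}

# Vertical chain of n equal cylinders.
chain_tree <- function(n = 5, radius = 0.1, len = 0.5) {
  rows <- lapply(seq_len(n), function(i) {
    cyl_row(radius, len, c(0, 0, (i - 1) * len), c(0, 0, 1),
            if (i == 1) NA_integer_ else i - 1L,
            extension = as.integer(i > 1))
  })
  tree(do.call(rbind, rows))
}

# Vertical trunk with two lateral children of given radii at its tip.
junction_tree <- function(r1 = 0.05, r2 = 0.03, trunk_radius = 0.1) {
  rows <- rbind(
    cyl_row(trunk_radius, 1, c(0, 0, 0), c(0, 0, 1), NA_integer_),
    cyl_row(r1, 0.5, c(0, 0, 1), c(1, 0, 1), 1L),
    cyl_row(r2, 0.5, c(0, 0, 1), c(-1, 0, 1), 1L))
  tree(rows)
}

# Tree whose cylinder endpoints are 36 points on a circle of radius `r`
# (one per 10-degree sector) around the root, plus the centre column.
circle_tree <- function(r = 3, sep_deg = 10) {
  n <- 360 / sep_deg
  rows <- list(cyl_row(0.05, 1, c(0, 0, 0), c(0, 0, 1), NA_integer_))
  for (k in seq_len(n)) {
    az <- ((k - 1) * sep_deg + sep_deg / 2) * pi / 180
    rows[[k + 1]] <- cyl_row(0.02, r, c(0, 0, 1),
                             c(cos(az), sin(az), 0), 1L)
  }
  tree(do.call(rbind, rows))
}

# Brute-force two-sample KS oracle: evaluate both ECDFs at every pooled
# point and take the largest gap.
ks_oracle <- function(x, y) {
  pts <- c(x, y)
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Independent prefix-length oracle: walk parent links backwards within the
# same branch, summing lengths of the earlier segments.
prefix_length_oracle <- function(tr, i) {
  cyl <- tr$cylinders
  total <- 0
  j <- cyl$parent[i]
  while (!is.na(j) && cyl$branch_id[j] == cyl$branch_id[i]) {
    total <- total + cyl$length[j]
    j <- cyl$parent[j]
  }
  total
}

# Small simulator configuration used across tests (6 m arena keeps trees at
# around a hundred cylinders).
small_params <- function(...) {
  args <- list(arena_size = 6, n_iterations = 8)
  over <- list(...)
  args[names(over)] <- over
  do.call(sot_params, args)
}

# Two-column standard-normal surrogate tables (plain data frames are
# accepted by the distance: only the column layout must match) with an
# optional mean shift in the first coordinate.
gaussian_table <- function(n, shift = 0, seed = 1) {
  set.seed(seed)
  data.frame(u = rnorm(n) + shift, v = rnorm(n))
}
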