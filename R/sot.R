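# Stochastic structure model: a self-organizing tree (SOT) simulator with
# voxel shadow propagation, extended Borchert-Honda resource allocation
# under apical dominance, pipe-model radii, and stochastic angle noise.

#' Simulator parameter set
#'
#' The growth model has 27 parameters: 23 grouped into five process groups
#' plus 4 fixed discretisation constants. Group I: initial growth and pipe
#' model (resource-to-metamer coefficient, pipe exponent, tip radius,
#' maximum Gravelius order, number of growth iterations). Group II:
#' environment (shading sensitivity, vertical light gradient, tropism
#' strength and direction). Group III: apical dominance (`lambda` in
#' \[0, 1\] biasing resources toward terminal buds, bud-break probability,
#' lateral dormancy delay). Group IV: shadow propagation (increment `a`,
#' decay base `b`, full-light exposure `C`, pyramid depth). Group V:
#' angular/branching properties (branching angle mean and spread,
#' phyllotactic divergence angle and spread, heading noise, noise kind).
#' Fixed: segment length 0.2 m, voxel size 0.2 m, a cubic arena of side
#' 12 m grown from the centre of its bottom face (z up).
#'
#' @param resource_coef resource units converted to metamers per unit of
#'   collected light (group I).
#' @param pipe_exponent exponent `e` of the pipe model `r_p^e = sum r_c^e`.
#' @param tip_radius radius (m) of terminal (leaf) segments.
#' @param max_order deepest Gravelius order allowed to bear lateral buds.
#' @param n_iterations number of growth iterations (integer >= 1).
#' @param shading_sensitivity multiplier on accumulated shadow when
#'   computing light exposure (group II).
#' @param light_gradient linear vertical gradient of available light; 0
#'   means uniform light.
#' @param tropism_strength magnitude of the directional growth bias.
#' @param tropism_azimuth,tropism_elevation direction of the tropism vector
#'   (degrees; elevation 90 = straight up).
#' @param lambda apical dominance weight in \[0, 1\] (group III).
#' @param bud_break_prob probability that a dormant lateral flushes in an
#'   iteration once eligible.
#' @param lateral_delay iterations a new lateral bud stays dormant.
#' @param shadow_a,shadow_b shadow increment and decay base: the voxel
#'   pyramid layer q below a shading point gains `a * b^-q` (group IV).
#' @param base_exposure full-light exposure `C`.
#' @param shadow_depth number of pyramid layers below each shading point.
#' @param branching_angle_mean,branching_angle_spread lateral branching
#'   angle from the parent axis, mean and stochastic spread (degrees,
#'   group V).
#' @param divergence_angle,divergence_spread azimuthal advance between
#'   successive laterals along an axis (degrees).
#' @param heading_noise stochastic deflection of the growth direction per
#'   metamer (degrees).
#' @param angle_noise_kind `"normal"` (spreads are standard deviations) or
#'   `"uniform"` (spreads are half-widths).
#' @param segment_length,voxel_size,arena_size fixed discretisation
#'   constants (m).
#' @param arena_origin base of the tree, at the centre of the arena floor.
#' @return object of class `"sot_params"`.
#' @export
sot_params <- function(resource_coef = 2,
                       pipe_exponent = 2,
                       tip_radius = 0.005,
                       max_order = 4L,
                       n_iterations = 20L,
                       shading_sensitivity = 1,
                       light_gradient = 0,
                       tropism_strength = 0.08,
                       tropism_azimuth = 0,
                       tropism_elevation = 90,
                       lambda = 0.5,
                       bud_break_prob = 0.8,
                       lateral_delay = 0L,
                       shadow_a = 0.1,
                       shadow_b = 2,
                       base_exposure = 1,
                       shadow_depth = 4L,
                       branching_angle_mean = 45,
                       branching_angle_spread = 8,
                       divergence_angle = 137.5,
                       divergence_spread = 10,
                       heading_noise = 6,
                       angle_noise_kind = c("normal", "uniform"),
                       segment_length = 0.2,
                       voxel_size = 0.2,
                       arena_size = 12,
                       arena_origin = c(0, 0, 0)) {
  angle_noise_kind <- match.arg(angle_noise_kind)
  p <- list(resource_coef = resource_coef, pipe_exponent = pipe_exponent,
            tip_radius = tip_radius, max_order = as.integer(round(max_order)),
            n_iterations = as.integer(round(n_iterations)),
            shading_sensitivity = shading_sensitivity,
            light_gradient = light_gradient,
            tropism_strength = tropism_strength,
            tropism_azimuth = tropism_azimuth,
            tropism_elevation = tropism_elevation,
            lambda = lambda, bud_break_prob = bud_break_prob,
            lateral_delay = as.integer(round(lateral_delay)),
            shadow_a = shadow_a, shadow_b = shadow_b,
            base_exposure = base_exposure,
            shadow_depth = as.integer(round(shadow_depth)),
            branching_angle_mean = branching_angle_mean,
            branching_angle_spread = branching_angle_spread,
            divergence_angle = divergence_angle,
            divergence_spread = divergence_spread,
            heading_noise = heading_noise,
            angle_noise_kind = angle_noise_kind,
            segment_length = segment_length, voxel_size = voxel_size,
            arena_size = arena_size, arena_origin = arena_origin)
  class(p) <- "sot_params"
  validate_sot_params(p)
  p
}

#' @rdname sot_params
#' @param params an `sot_params` object.
#' @export
validate_sot_params <- function(params) {
  with(params, {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
    if (segment_length <= 0 || voxel_size <= 0 || arena_size <= 0) {
      stop("segment_length, voxel_size and arena_size must be positive")
    }
    if (n_iterations < 1L) stop("n_iterations must be >= 1")
    if (bud_break_prob < 0 || bud_break_prob > 1) {
      stop("bud_break_prob must lie in [0, 1]")
    }
    if (shadow_depth < 0L) stop("shadow_depth must be >= 0")
  })
  invisible(params)
}

#' Parameter grouping of the growth model
#'
#' @return named character vector mapping each parameter to its group
#'   (`"I"` to `"V"`, or `"fixed"`).
#' @export
sot_param_groups <- function() {
  c(resource_coef = "I", pipe_exponent = "I", tip_radius = "I",
    max_order = "I", n_iterations = "I",
    shading_sensitivity = "II", light_gradient = "II",
    tropism_strength = "II", tropism_azimuth = "II",
    tropism_elevation = "II",
    lambda = "III", bud_break_prob = "III", lateral_delay = "III",
    shadow_a = "IV", shadow_b = "IV", base_exposure = "IV",
    shadow_depth = "IV",
    branching_angle_mean = "V", branching_angle_spread = "V",
    divergence_angle = "V", divergence_spread = "V", heading_noise = "V",
    angle_noise_kind = "V",
    segment_length = "fixed", voxel_size = "fixed", arena_size = "fixed",
    arena_origin = "fixed")
}

## ---- shadow grid ----------------------------------------------------------

#' Voxel shadow grid
#'
#' A scalar shadow field on the voxel lattice of the growth arena. Each
#' shading point deposits an inverted pyramid of shadow below itself:
#' layer q (0 = the point's own voxel) is the (2q+1) x (2q+1) square of
#' voxels q layers down, and gains `a * b^-q`.
#'
#' @param arena_size,voxel_size arena side length and voxel edge (m).
#' @return a 3-D array with attributes, all zeros.
#' @export
shadow_grid <- function(arena_size, voxel_size) {
  nxy <- max(1L, ceiling(arena_size / voxel_size))
  structure(array(0, dim = c(nxy, nxy, nxy)),
            arena_size = arena_size, voxel_size = voxel_size)
}

.voxel_index <- function(grid, pts) {
  # pts: n x 3 matrix; arena x,y in [-A/2, A/2], z in [0, A]
  A <- attr(grid, "arena_size"); v <- attr(grid, "voxel_size")
  nd <- dim(grid)
  ix <- pmin(pmax(floor((pts[, 1] + A / 2) / v) + 1, 1), nd[1])
  iy <- pmin(pmax(floor((pts[, 2] + A / 2) / v) + 1, 1), nd[2])
  iz <- pmin(pmax(floor(pts[, 3] / v) + 1, 1), nd[3])
  cbind(ix, iy, iz)
}

#' Deposit shadow from a point
#'
#' @param grid a [shadow_grid()].
#' @param point 3-vector inside the arena (points outside are clipped to the
#'   boundary voxel with a warning).
#' @param a,b shadow increment and decay base.
#' @param depth number of pyramid layers.
#' @return the updated grid.
#' @export
cast_shadow <- function(grid, point, a, b, depth) {
  A <- attr(grid, "arena_size")
  if (point[1] < -A / 2 || point[1] > A / 2 ||
      point[2] < -A / 2 || point[2] > A / 2 ||
      point[3] < 0 || point[3] > A) {
    warning("shading point outside arena; clipped to boundary voxel")
  }
  idx <- .voxel_index(grid, matrix(point, nrow = 1))
  .cast_shadow_idx(grid, idx[1], idx[2], idx[3], a, b, depth)
}

.cast_shadow_idx <- function(grid, ix, iy, iz, a, b, depth) {
  nd <- dim(grid)
  for (q in 0:depth) {
    z <- iz - q
    if (z < 1L) break
    xr <- max(1L, ix - q):min(nd[1], ix + q)
    yr <- max(1L, iy - q):min(nd[2], iy + q)
    grid[xr, yr, z] <- grid[xr, yr, z] + a * b^(-q)
  }
  grid
}

# Batched shadow deposition, equal to summing .cast_shadow_idx over all
# rows of `sidx`: per z-slice point counts are turned into summed-area
# tables, and each pyramid layer becomes a clipped box sum.
.box_from_sat <- function(S, q, nx, ny) {
  i <- seq_len(nx); j <- seq_len(ny)
  hi_i <- pmin(i + q, nx) + 1L; lo_i <- pmax(i - q - 1L, 0L) + 1L
  hi_j <- pmin(j + q, ny) + 1L; lo_j <- pmax(j - q - 1L, 0L) + 1L
  S[hi_i, hi_j] - S[lo_i, hi_j] - S[hi_i, lo_j] + S[lo_i, lo_j]
}

.add_shadow_batch <- function(grid, sidx, a, b, depth) {
  nd <- dim(grid)
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  lin <- (sidx[, 3] - 1L) * nx * ny + (sidx[, 2] - 1L) * nx + sidx[, 1]
  cnt <- array(tabulate(lin, nbins = nx * ny * nz), nd)
  sats <- vector("list", nz)
  occupied <- unique(sidx[, 3])
  for (z in occupied) {
    S <- matrix(0, nx + 1L, ny + 1L)
    S[-1, -1] <- t(apply(apply(cnt[, , z], 2, cumsum), 1, cumsum))
    sats[[z]] <- S
  }
  for (z in seq_len(nz)) {
    for (q in 0:depth) {
      src <- z + q
      if (src > nz || is.null(sats[[src]])) next
      grid[, , z] <- grid[, , z] +
        (a * b^(-q)) * .box_from_sat(sats[[src]], q, nx, ny)
    }
  }
  grid
}

#' Light exposure of a bud
#'
#' `Q = max(C - sensitivity * (s - own_shadow), 0) * g(z)` where `s` is the
#' accumulated shadow in the bud's voxel, `own_shadow` removes the bud's own
#' layer-0 deposit, and `g(z) = max(1 + light_gradient * z / arena, 0)` is
#' the vertical light gradient. An unshaded bud in uniform light receives
#' exactly `C`.
#'
#' @inheritParams cast_shadow
#' @param point bud position.
#' @param params an [sot_params()].
#' @param own_shadow the bud's own contribution to its voxel (usually
#'   `params$shadow_a` after a shadow pass that included the bud).
#' @return nonnegative scalar exposure.
#' @export
light_exposure <- function(grid, point, params, own_shadow = 0) {
  idx <- .voxel_index(grid, matrix(point, nrow = 1))
  s <- grid[idx[1], idx[2], idx[3]] - own_shadow
  g <- max(1 + params$light_gradient * point[3] / params$arena_size, 0)
  max(params$base_exposure - params$shading_sensitivity * s, 0) * g
}

## ---- resource allocation --------------------------------------------------

#' Extended Borchert-Honda resource split
#'
#' At a branching node carrying incoming resource `v_in`, the continuing
#' (terminal) direction with light `Q_terminal` receives
#' `v_in * lambda * Q_m / (lambda * Q_m + (1 - lambda) * sum(Q_l))`, and the
#' laterals share the remainder in proportion to their own light. Total
#' resource is conserved whenever any light reaches the node; `lambda = 1`
#' sends everything to the terminal, `lambda = 0` everything to laterals.
#'
#' @param Q_terminal light exposure of the main (terminal) continuation.
#' @param Q_laterals numeric vector of lateral exposures (may be empty).
#' @param lambda apical dominance weight in \[0, 1\].
#' @param v_in incoming resource.
#' @return list with `terminal` and `laterals` resource shares.
#' @export
allocate_resource <- function(Q_terminal, Q_laterals, lambda, v_in) {
  den <- lambda * Q_terminal + (1 - lambda) * sum(Q_laterals)
  if (den <= 0) {
    return(list(terminal = 0, laterals = rep(0, length(Q_laterals))))
  }
  vt <- v_in * lambda * Q_terminal / den
  rest <- v_in - vt
  ql <- sum(Q_laterals)
  vl <- if (ql > 0) rest * Q_laterals / ql else rep(0, length(Q_laterals))
  list(terminal = vt, laterals = vl)
}

## ---- geometry helpers -----------------------------------------------------

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

.basis_perp <- function(d) {
  ref <- if (abs(d[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- .unit(c(ref[2] * d[3] - ref[3] * d[2],
               ref[3] * d[1] - ref[1] * d[3],
               ref[1] * d[2] - ref[2] * d[1]))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

# Unit direction at polar angle (deg, from `axis`) and azimuth (deg) in the
# plane normal to `axis`.
.dir_at <- function(axis, polar_deg, azim_deg) {
  b <- .basis_perp(axis)
  p <- polar_deg * pi / 180; azv <- azim_deg * pi / 180
  .unit(cos(p) * axis + sin(p) * (cos(azv) * b$u + sin(azv) * b$v))
}

.angle_noise_draw <- function(n, spread, kind) {
  if (spread <= 0) return(rep(0, n))
  if (kind == "normal") stats::rnorm(n, 0, spread)
  else stats::runif(n, -spread, spread)
}

.tropism_vector <- function(params) {
  az <- params$tropism_azimuth * pi / 180
  el <- params$tropism_elevation * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

.in_arena <- function(pt, A) {
  pt[1] >= -A / 2 && pt[1] <= A / 2 &&
    pt[2] >= -A / 2 && pt[2] <= A / 2 &&
    pt[3] >= 0 && pt[3] <= A
}

## ---- growth state ---------------------------------------------------------

#' Initial simulator state
#'
#' A single upward-pointing seed bud at the arena origin and no segments.
#'
#' @param params an [sot_params()].
#' @return object of class `"sot_state"`.
#' @export
sot_init_state <- function(params) {
  structure(list(
    seg = list(sx = numeric(0), sy = numeric(0), sz = numeric(0),
               ax = numeric(0), ay = numeric(0), az = numeric(0),
               parent = integer(0), extension = logical(0),
               ord = integer(0)),
    bud = list(x = params$arena_origin[1], y = params$arena_origin[2],
               z = params$arena_origin[3],
               hx = 0, hy = 0, hz = 1,
               seg = 0L, ord = 0L, terminal = TRUE,
               dormant = 0L, phase = 0),
    iteration = 0L), class = "sot_state")
}

#' One growth iteration
#'
#' Performs the full iteration cycle: a shadow pass over all buds and
#' segment tips, per-bud light exposure, basipetal light aggregation,
#' acropetal resource allocation under apical dominance, and shoot
#' extension (each bud converts its resource `v` into `floor(v)` new
#' metamers of fixed segment length, oriented by the branching, divergence
#' and tropism rules plus stochastic angle noise). Growth is clipped to the
#' arena. The step is a deterministic function of `(state, params,
#' step_seed)`.
#'
#' @param state an `sot_state`.
#' @param params an [sot_params()].
#' @param step_seed integer seed for this iteration's random substream.
#' @return the successor state.
#' @export
grow_step <- function(state, params, step_seed) {
  set.seed(as.integer(step_seed))
  sg <- state$seg
  bd <- state$bud
  n_seg <- length(sg$sx)
  n_bud <- length(bd$x)
  A <- params$arena_size

  ## 1. shadow pass: buds and segment distal ends
  grid <- shadow_grid(A, params$voxel_size)
  shade_pts <- rbind(
    cbind(bd$x, bd$y, bd$z),
    if (n_seg > 0) cbind(sg$sx + params$segment_length * sg$ax,
                         sg$sy + params$segment_length * sg$ay,
                         sg$sz + params$segment_length * sg$az))
  sidx <- .voxel_index(grid, shade_pts)
  grid <- .add_shadow_batch(grid, sidx, params$shadow_a, params$shadow_b,
                            params$shadow_depth)

  ## 2. per-bud light (dormant or unflushed laterals can be gated off)
  Q <- numeric(n_bud)
  gate <- stats::runif(n_bud)
  for (i in seq_len(n_bud)) {
    if (bd$dormant[i] > 0L) next
    if (!bd$terminal[i] && gate[i] > params$bud_break_prob) next
    Q[i] <- light_exposure(grid, c(bd$x[i], bd$y[i], bd$z[i]), params,
                           own_shadow = params$shadow_a)
  }

  ## 3. basipetal aggregation of light over the segment skeleton
  bud_at <- split(seq_len(n_bud), bd$seg)    # bud indices by supporting seg
  Qsub <- numeric(n_seg)
  budQ_at <- function(s) {
    ids <- bud_at[[as.character(s)]]
    if (is.null(ids)) 0 else sum(Q[ids])
  }
  kids <- vector("list", n_seg)
  for (j in seq_len(n_seg)) {
    p <- sg$parent[j]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], j)
  }
  for (j in rev(seq_len(n_seg))) {
    Qsub[j] <- budQ_at(j) + sum(Qsub[kids[[j]]])
  }
  roots <- which(is.na(sg$parent))
  Qtotal <- sum(Qsub[roots]) + budQ_at(0L)

  ## 4. acropetal resource allocation
  v_total <- params$resource_coef * Qtotal
  vseg <- numeric(n_seg)
  vbud <- numeric(n_bud)
  if (n_seg == 0L) {
    seed_ids <- bud_at[["0"]]
    if (!is.null(seed_ids)) vbud[seed_ids] <- v_total
  } else {
    vseg[roots] <- v_total  # single root in practice
    for (j in seq_len(n_seg)) {
      v_in <- vseg[j]
      ch <- kids[[j]]
      bids <- bud_at[[as.character(j)]]
      if (is.null(bids)) bids <- integer(0)
      if (v_in <= 0 || (length(ch) == 0L && length(bids) == 0L)) next
      # main continuation: extension child segment, else the terminal bud
      main_seg <- ch[sg$extension[ch]]
      main_bud <- bids[bd$terminal[bids]]
      lat_seg <- ch[!sg$extension[ch]]
      lat_bud <- bids[!bd$terminal[bids]]
      Qm <- sum(Qsub[main_seg]) + sum(Q[main_bud])
      Ql <- c(Qsub[lat_seg], Q[lat_bud])
      al <- allocate_resource(Qm, Ql, params$lambda, v_in)
      # split the terminal share between extension segs/buds by their Q
      mains_q <- c(Qsub[main_seg], Q[main_bud])
      if (sum(mains_q) > 0) {
        mshare <- al$terminal * mains_q / sum(mains_q)
        if (length(main_seg)) vseg[main_seg] <- mshare[seq_along(main_seg)]
        if (length(main_bud)) {
          vbud[main_bud] <- mshare[length(main_seg) + seq_along(main_bud)]
        }
      }
      nl <- length(lat_seg)
      if (nl) vseg[lat_seg] <- al$laterals[seq_len(nl)]
      if (length(lat_bud)) vbud[lat_bud] <- al$laterals[nl + seq_along(lat_bud)]
    }
  }

  ## 5. shoot extension
  trop <- .tropism_vector(params)
  for (i in seq_len(n_bud)) {
    n_new <- floor(vbud[i])
    if (n_new < 1) next
    pos <- c(bd$x[i], bd$y[i], bd$z[i])
    dir <- .unit(c(bd$hx[i], bd$hy[i], bd$hz[i]))
    parent <- bd$seg[i]
    first <- TRUE
    for (k in seq_len(n_new)) {
      dev <- .angle_noise_draw(1, params$heading_noise,
                               params$angle_noise_kind)
      dir <- .dir_at(dir, dev, stats::runif(1, 0, 360))
      dir <- .unit(dir + params$tropism_strength * trop)
      cand <- pos + params$segment_length * dir
      if (!.in_arena(cand, A)) break
      # append metamer
      j <- length(sg$sx) + 1L
      sg$sx[j] <- pos[1]; sg$sy[j] <- pos[2]; sg$sz[j] <- pos[3]
      sg$ax[j] <- dir[1]; sg$ay[j] <- dir[2]; sg$az[j] <- dir[3]
      sg$parent[j] <- if (parent == 0L) NA_integer_ else parent
      sg$extension[j] <- !first || bd$terminal[i]
      sg$ord[j] <- bd$ord[i]
      first <- FALSE
      # one lateral bud per metamer (respecting the order cap)
      bd$phase[i] <- bd$phase[i] + params$divergence_angle +
        .angle_noise_draw(1, params$divergence_spread,
                          params$angle_noise_kind)
      if (bd$ord[i] + 1L <= params$max_order) {
        bang <- params$branching_angle_mean +
          .angle_noise_draw(1, params$branching_angle_spread,
                            params$angle_noise_kind)
        ldir <- .dir_at(dir, bang, bd$phase[i])
        nb <- length(bd$x) + 1L
        bd$x[nb] <- cand[1]; bd$y[nb] <- cand[2]; bd$z[nb] <- cand[3]
        bd$hx[nb] <- ldir[1]; bd$hy[nb] <- ldir[2]; bd$hz[nb] <- ldir[3]
        bd$seg[nb] <- j; bd$ord[nb] <- bd$ord[i] + 1L
        bd$terminal[nb] <- FALSE
        bd$dormant[nb] <- params$lateral_delay
        bd$phase[nb] <- bd$phase[i]
      }
      pos <- cand
      parent <- j
    }
    bd$x[i] <- pos[1]; bd$y[i] <- pos[2]; bd$z[i] <- pos[3]
    bd$hx[i] <- dir[1]; bd$hy[i] <- dir[2]; bd$hz[i] <- dir[3]
    bd$seg[i] <- parent
    bd$terminal[i] <- TRUE  # a flushed lateral heads its own branch now
  }

  ## 6. dormancy clock
  bd$dormant <- pmax(bd$dormant - 1L, 0L)

  state$seg <- sg
  state$bud <- bd
  state$iteration <- state$iteration + 1L
  state
}

#' Pipe-model radii
#'
#' Assigns `tip_radius` to leaf segments and propagates
#' `r_parent = (sum r_child^e)^(1/e)` basipetally, so cross-sections are
#' conserved (for `e = 2`) at every junction.
#'
#' @param tree a [tree()].
#' @param pipe_exponent exponent `e`.
#' @param tip_radius radius of terminal segments (m).
#' @return the tree with updated radii.
#' @export
update_radii <- function(tree, pipe_exponent, tip_radius) {
  cyl <- tree$cylinders
  n <- nrow(cyl)
  if (n == 0L) return(tree)
  kids <- .children_of(tree)
  # process in reverse BFS order so children precede parents
  root <- which(is.na(cyl$parent))
  order_bfs <- integer(n); order_bfs[1] <- root; head_i <- 1L; tail_i <- 1L
  while (head_i <= tail_i) {
    ch <- kids[[order_bfs[head_i]]]
    if (length(ch)) {
      order_bfs[tail_i + seq_along(ch)] <- ch
      tail_i <- tail_i + length(ch)
    }
    head_i <- head_i + 1L
  }
  r <- numeric(n)
  e <- pipe_exponent
  for (i in rev(order_bfs)) {
    ch <- kids[[i]]
    r[i] <- if (length(ch) == 0L) tip_radius else sum(r[ch]^e)^(1 / e)
  }
  cyl$radius <- r
  tree$cylinders <- cyl
  tree
}

# Per-iteration substream seed; deterministic in (seed, iteration) and
# below 2^31.
.derive_seed <- function(seed, iteration) {
  as.integer((abs(as.numeric(seed)) %% 20011) * 100000 + iteration)
}

#' Simulate a stochastic tree
#'
#' Runs `n_iterations` growth steps from a seed bud, then assigns
#' pipe-model radii and extracts Gravelius orders with the thickest-branch
#' rule (the rule applied to QSM snapshots; for strongly apically dominant
#' forms it coincides with the analytic lateral/extension bookkeeping).
#' The result is a deterministic function of `(params, seed)`.
#'
#' @param params an [sot_params()].
#' @param seed integer random seed.
#' @return a [tree()]; if the parameters produce no growth (e.g. a zero
#'   resource coefficient) an empty, unvalidated tree is returned whose
#'   feature tables are empty.
#' @export
simulate_tree <- function(params, seed) {
  validate_sot_params(params)
  state <- sot_init_state(params)
  for (it in seq_len(params$n_iterations)) {
    state <- grow_step(state, params, .derive_seed(seed, it))
  }
  sg <- state$seg
  n <- length(sg$sx)
  cyl <- data.frame(radius = rep(params$tip_radius, n),
                    length = rep(params$segment_length, n),
                    start_x = sg$sx, start_y = sg$sy, start_z = sg$sz,
                    axis_x = sg$ax, axis_y = sg$ay, axis_z = sg$az,
                    parent = if (n) sg$parent else integer(0),
                    extension = as.integer(sg$extension),
                    branch_id = rep(NA_integer_, n),
                    branch_order = rep(NA_integer_, n),
                    pos_in_branch = rep(NA_integer_, n))
  meta <- list(source = "sot", seed = seed)
  if (n == 0L) {
    return(tree(cyl[0, ], meta = c(meta, list(empty = TRUE)),
                validate = FALSE))
  }
  out <- tree(cyl, meta = meta, validate = FALSE)
  out <- update_radii(out, params$pipe_exponent, params$tip_radius)
  out <- assign_orders(out, force = TRUE, w_max = params$max_order + 6L)
  validate_tree(out, attachment_tol = 1e-6)
  out
}
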