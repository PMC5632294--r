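# Synthetic QSM-like targets: a deterministic fractal tree with closed-form
# allometry, a simulated self-target with known generating parameters, and
# a measurement-noise corrupter. These stand in for laser-scan derived
# cylinder models so the whole pipeline is testable offline.

#' Deterministic fractal target tree
#'
#' Builds a recursive bifurcating tree: a vertical trunk of
#' `segments_per_branch` equal cylinders, and at the tip of every branch of
#' level `l < depth - 1` two children deflected by `branching_angle` from
#' the parent direction at opposite azimuths (the azimuth frame twists by
#' `twist` degrees per level). Child branch length decays by
#' `length_ratio`. Radii follow the pipe model exactly: leaves get
#' `tip_radius` and a level-l branch has radius
#' `tip_radius * 2^((depth - 1 - l) / pipe_exponent)`. Branch orders are
#' annotated analytically (level = order), so level-w branch counts are
#' `2^w`. Optional Gaussian jitter on the two branching angles makes a
#' noisy variant; zero noise is fully deterministic.
#'
#' @param depth number of branching levels (>= 1; `depth = 1` is a bare
#'   trunk).
#' @param trunk_length trunk length (m); children scale by `length_ratio`.
#' @param branching_angle deflection of children from the parent direction
#'   (degrees).
#' @param length_ratio child/parent branch length ratio, in (0, 1].
#' @param segments_per_branch cylinders per branch.
#' @param tip_radius leaf radius (m).
#' @param pipe_exponent pipe-model exponent.
#' @param twist azimuthal rotation of the branching plane per level
#'   (degrees).
#' @param noise standard deviation (degrees) of angle jitter; 0 = none.
#' @param seed RNG seed, used only when `noise > 0`.
#' @return a [tree()] with orders annotated.
#' @export
make_fractal_target <- function(depth, trunk_length = 2,
                                branching_angle = 40, length_ratio = 0.7,
                                segments_per_branch = 3L, tip_radius = 0.05,
                                pipe_exponent = 2, twist = 90,
                                noise = 0, seed = 1L) {
  if (depth < 1L) stop("depth must be >= 1")
  if (length_ratio <= 0 || length_ratio > 1) {
    stop("length_ratio must lie in (0, 1]")
  }
  if (noise < 0) stop("noise must be >= 0")
  set.seed(as.integer(seed))

  rows <- list()
  add_branch <- function(start, dir, level, parent_idx, phase, bid) {
    blen <- trunk_length * length_ratio^level
    seg_len <- blen / segments_per_branch
    radius <- tip_radius * 2^((depth - 1 - level) / pipe_exponent)
    idx <- integer(segments_per_branch)
    pos <- start
    par <- parent_idx
    for (k in seq_len(segments_per_branch)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        radius = radius, length = seg_len,
        start_x = pos[1], start_y = pos[2], start_z = pos[3],
        axis_x = dir[1], axis_y = dir[2], axis_z = dir[3],
        parent = par, extension = as.integer(k > 1L),
        branch_id = bid, branch_order = level, pos_in_branch = k - 1L)
      idx[k] <- length(rows)
      pos <- pos + seg_len * dir
      par <- idx[k]
    }
    list(tip = pos, tip_idx = idx[segments_per_branch], dir = dir)
  }

  next_bid <- 0L
  new_bid <- function() {
    next_bid <<- next_bid + 1L
    next_bid
  }
  queue <- list()
  br <- add_branch(c(0, 0, 0), c(0, 0, 1), 0L, NA_integer_, 0, new_bid())
  if (depth > 1L) queue[[1]] <- c(br, list(level = 0L, phase = 0))
  while (length(queue) > 0L) {
    nd <- queue[[1]]
    queue[[1]] <- NULL
    lvl <- nd$level + 1L
    for (side in c(0, 180)) {
      ang <- branching_angle + if (noise > 0) stats::rnorm(1, 0, noise) else 0
      azv <- nd$phase + side + if (noise > 0) stats::rnorm(1, 0, noise) else 0
      cdir <- .dir_at(nd$dir, ang, azv)
      cb <- add_branch(nd$tip, cdir, lvl, nd$tip_idx,
                       nd$phase + twist, new_bid())
      if (lvl < depth - 1L) {
        queue[[length(queue) + 1L]] <-
          c(cb, list(level = lvl, phase = nd$phase + twist))
      }
    }
  }
  cyl <- do.call(rbind, rows)
  tree(cyl, meta = list(source = "synthetic_fractal", seed = seed,
                        depth = depth),
       validate = TRUE, attachment_tol = 1e-9)
}

#' Simulated self-target with known generating parameters
#'
#' Simulates a stochastic tree and returns it together with the parameters
#' and seed that generated it, for parameter-recovery experiments: the
#' optimisation objective evaluated at the generating parameters with the
#' matched seed is exactly zero.
#'
#' @param params an [sot_params()].
#' @param seed simulation seed.
#' @return list with `tree`, `params`, `seed`.
#' @export
make_sot_target <- function(params = sot_params(), seed = 1L) {
  list(tree = simulate_tree(params, seed), params = params, seed = seed)
}

#' Jitter a tree's radii and axes, preserving topology
#'
#' Emulates measurement and reconstruction noise: radii are perturbed
#' multiplicatively (log-normal, sd `noise`) and each cylinder axis is
#' rotated by a Gaussian angle (sd `noise * 30` degrees) about a random
#' azimuth; start positions are then re-chained so every child still begins
#' at its parent's distal end. Parent links, branch ids and orders are
#' untouched. `noise = 0` returns the tree unchanged.
#'
#' @param tree a [tree()].
#' @param noise nonnegative noise level.
#' @param seed RNG seed.
#' @return the corrupted [tree()].
#' @export
corrupt_tree <- function(tree, noise, seed = 1L) {
  if (noise < 0) stop("noise must be >= 0")
  if (noise == 0) return(tree)
  set.seed(as.integer(seed))
  cyl <- tree$cylinders
  n <- nrow(cyl)
  cyl$radius <- cyl$radius * exp(stats::rnorm(n, 0, noise))
  ang <- stats::rnorm(n, 0, noise * 30)
  azv <- stats::runif(n, 0, 360)
  ax <- cbind(cyl$axis_x, cyl$axis_y, cyl$axis_z)
  for (i in seq_len(n)) {
    d <- .dir_at(ax[i, ], ang[i], azv[i])
    cyl$axis_x[i] <- d[1]; cyl$axis_y[i] <- d[2]; cyl$axis_z[i] <- d[3]
  }
  # re-chain starts so children sit on parent ends (BFS from the root)
  out <- tree
  out$cylinders <- cyl
  kids <- .children_of(out)
  root <- which(is.na(cyl$parent))
  queue <- root
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    ch <- kids[[i]]
    if (length(ch)) {
      endp <- c(cyl$start_x[i] + cyl$length[i] * cyl$axis_x[i],
                cyl$start_y[i] + cyl$length[i] * cyl$axis_y[i],
                cyl$start_z[i] + cyl$length[i] * cyl$axis_z[i])
      cyl$start_x[ch] <- endp[1]
      cyl$start_y[ch] <- endp[2]
      cyl$start_z[ch] <- endp[3]
      queue <- c(queue, ch)
    }
  }
  out$cylinders <- cyl
  out$meta$corrupted <- noise
  validate_tree(out)
  out
}
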