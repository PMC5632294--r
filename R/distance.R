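# Projection-tomography structural distance:
# D_S(U_m, U_d) = (1/n) * sum_i K[P_1D(U_m, L_i), P_1D(U_d, L_i)]
# with K the two-sample Kolmogorov-Smirnov statistic and L_i quasi-random
# unit line directions.

# Van der Corput radical inverse in an integer base, vectorised over index.
.radical_inverse <- function(idx, base) {
  r <- numeric(length(idx))
  f <- 1 / base
  i <- idx
  while (any(i > 0L)) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

.halton_primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L)

# Halton sequence points in (0,1)^dim, indices offset+1 .. offset+n.
.halton <- function(n, dim, offset = 0L) {
  if (dim > length(.halton_primes)) stop("dimension too large for generator")
  idx <- seq_len(n) + as.integer(offset)
  vapply(seq_len(dim),
         function(j) .radical_inverse(idx, .halton_primes[j]),
         numeric(n))
}

#' Deterministic quasi-random unit directions
#'
#' Generates `n` unit vectors in `R^dim` by mapping a low-discrepancy Halton
#' sequence through the standard-normal inverse CDF coordinate-wise and
#' normalising; by the spherical symmetry of the Gaussian this covers the
#' unit sphere asymptotically uniformly and, being quasi-random, more evenly
#' than pseudo-random draws. Regeneration with the same arguments is
#' bit-identical.
#'
#' @param dim dimension (>= 1).
#' @param n number of directions (>= 1; the distance default is 1000 lines).
#' @param sequence_id label of the generator; only `"halton"` is provided.
#' @param offset start offset into the sequence.
#' @return object of class `"direction_set"`: an `n x dim` matrix of unit
#'   rows with attributes `sequence_id` and `offset`.
#' @export
generate_directions <- function(dim, n, sequence_id = "halton", offset = 0L) {
  if (dim < 1L || n < 1L) stop("dim and n must be >= 1")
  if (!identical(sequence_id, "halton")) {
    stop("unknown sequence_id: ", sequence_id)
  }
  u <- .halton(n, dim, offset)
  z <- matrix(stats::qnorm(u), nrow = n, ncol = dim)
  nrm <- sqrt(rowSums(z^2))
  nrm[nrm < 1e-12] <- 1
  v <- z / nrm
  structure(v, sequence_id = sequence_id, offset = as.integer(offset),
            class = c("direction_set", "matrix", "array"))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum over the pooled sample points of the absolute difference of
#' the two empirical cumulative distribution functions; in \[0, 1\].
#'
#' @param x,y nonempty numeric samples.
#' @return the KS statistic.
#' @export
ks_two_sample <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stop("both samples must be nonempty")
  w <- c(x, y)
  o <- order(w)
  step <- c(rep(1 / n, n), rep(-1 / m, m))[o]
  e <- cumsum(step)
  ws <- w[o]
  keep <- c(diff(ws) != 0, TRUE)  # evaluate ties once, at the joint jump
  max(abs(e[keep]))
}

#' Standardise a pair of feature tables for projection
#'
#' Feature tables mix units (degrees, metres); before projecting onto lines
#' each column is centred by the pooled median and scaled by the pooled IQR
#' of the two tables. Columns with zero pooled IQR are centred but left
#' unscaled.
#'
#' @param Um,Ud [feature_table()]s of the same kind and columns.
#' @return list of two numeric matrices (`model`, `data`).
#' @export
standardize_pair <- function(Um, Ud) {
  if (!identical(names(Um), names(Ud))) {
    stop("column mismatch between feature tables")
  }
  if (!identical(attr(Um, "kind"), attr(Ud, "kind"))) {
    stop("kind mismatch between feature tables")
  }
  Xm <- as.matrix(as.data.frame(Um))
  Xd <- as.matrix(as.data.frame(Ud))
  pooled <- rbind(Xm, Xd)
  ctr <- apply(pooled, 2, stats::median)
  scl <- apply(pooled, 2, stats::IQR)
  scl[scl == 0] <- 1
  list(model = sweep(sweep(Xm, 2, ctr), 2, scl, "/"),
       data = sweep(sweep(Xd, 2, ctr), 2, scl, "/"))
}

#' Structural distance between two feature tables
#'
#' Projects both (standardised) tables onto each line direction, compares
#' the projected empirical distributions with the two-sample KS statistic,
#' and averages over lines. The result lies in \[0, 1\]; identical tables
#' give exactly 0. A pair in which either table is empty (e.g. a simulated
#' tree lacking the requested orders) scores the maximal distance 1.
#'
#' @param Um,Ud [feature_table()]s of the same kind.
#' @param dirs a [generate_directions()] set with `dim` equal to the number
#'   of feature columns.
#' @param count_ops if `TRUE`, attach an `"ops"` attribute recording the
#'   elementary work performed (projection multiplies, sort and merge
#'   operations) for complexity audits.
#' @return scalar distance in \[0, 1\].
#' @export
structural_distance <- function(Um, Ud, dirs, count_ops = FALSE) {
  if (nrow(Um) == 0L || nrow(Ud) == 0L) {
    out <- 1
    if (count_ops) attr(out, "ops") <-
        list(n_lines = nrow(dirs), proj = 0, merge = 0, sort = 0)
    return(out)
  }
  std <- standardize_pair(Um, Ud)
  d <- ncol(std$model)
  if (ncol(dirs) != d) {
    stop("direction dimension ", ncol(dirs),
         " does not match feature dimension ", d)
  }
  L <- nrow(dirs)
  Pm <- std$model %*% t(dirs)   # n_m x L projections
  Pd <- std$data %*% t(dirs)
  ks <- numeric(L)
  for (i in seq_len(L)) ks[i] <- ks_two_sample(Pm[, i], Pd[, i])
  out <- mean(ks)
  if (count_ops) {
    nm <- nrow(Pm); nd <- nrow(Pd); N <- nm + nd
    attr(out, "ops") <- list(n_lines = L,
                             proj = L * d * N,
                             merge = L * N,
                             sort = L * N * ceiling(log2(N)))
  }
  out
}

#' Average structural distance over several table pairs
#'
#' When several feature tables are compared at once (e.g. S^{0,1} and
#' B^{2,3,4}), each pair contributes one distance and the objective is their
#' unweighted mean.
#'
#' @param pairs named list; each element a list with components `model` and
#'   `data` ([feature_table()]s of a common kind).
#' @param dirs either a single direction set (applied where dimensions agree)
#'   or a list of direction sets, one per pair.
#' @return object of class `"distance_result"` with `per_pair`, `mean` and
#'   `n_lines`.
#' @export
aggregate_distance <- function(pairs, dirs) {
  if (length(pairs) < 1L) stop("need at least one table pair")
  if (!is.list(dirs) || inherits(dirs, "direction_set")) {
    dirs <- rep(list(dirs), length(pairs))
  }
  per <- vapply(seq_along(pairs), function(i) {
    structural_distance(pairs[[i]]$model, pairs[[i]]$data, dirs[[i]])
  }, numeric(1))
  names(per) <- if (is.null(names(pairs))) {
    paste0("pair", seq_along(pairs))
  } else names(pairs)
  structure(list(per_pair = per, mean = mean(per),
                 n_lines = nrow(dirs[[1]])),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat("<distance_result> mean D_S =", format(x$mean, digits = 4),
      "over", length(x$per_pair), "pair(s),", x$n_lines, "lines\n")
  print(round(x$per_pair, 4))
  invisible(x)
}

#' Classical allometric metrics: height, girth, crown spread
#'
#' Height is the highest point of the tree; girth is the diameter of the
#' ground (root) segment, which suits shrubby trees where breast-height
#' diameter is undefined; crown spread is computed by the spoke method: from
#' the ground segment's XY position, spokes at fixed azimuthal separation
#' (default 10 degrees) extend to the most distant cylinder endpoint in each
#' sector, and the spread is twice the mean spoke length (empty sectors
#' contribute 0).
#'
#' @param tree a [tree()].
#' @return for `classical_metrics()`, a list with `h`, `g`, `c` (metres).
#' @export
classical_metrics <- function(tree) {
  structure(list(h = tree_height(tree), g = girth(tree),
                 c = crown_spread(tree)),
            class = "classical_metrics")
}

#' @rdname classical_metrics
#' @export
tree_height <- function(tree) {
  cyl <- tree$cylinders
  max(cyl$start_z, cylinder_ends(tree)[, 3])
}

#' @rdname classical_metrics
#' @export
girth <- function(tree) {
  2 * tree$cylinders$radius[is.na(tree$cylinders$parent)]
}

#' @rdname classical_metrics
#' @param sep_deg azimuthal spoke separation in degrees; must divide 360.
#' @export
crown_spread <- function(tree, sep_deg = 10) {
  if (360 %% sep_deg != 0) stop("sep_deg must divide 360")
  cyl <- tree$cylinders
  root <- which(is.na(cyl$parent))
  center <- c(cyl$start_x[root], cyl$start_y[root])
  ends <- cylinder_ends(tree)
  px <- c(cyl$start_x, ends[, 1]) - center[1]
  py <- c(cyl$start_y, ends[, 2]) - center[2]
  .spoke_spread(px, py, sep_deg)
}

# Spoke computation on centred XY offsets; half-open sectors
# [k*sep, (k+1)*sep).
.spoke_spread <- function(px, py, sep_deg) {
  n_spokes <- 360 %/% sep_deg
  r <- sqrt(px^2 + py^2)
  az <- (atan2(py, px) * 180 / pi + 360) %% 360
  sector <- pmin(floor(az / sep_deg), n_spokes - 1) + 1
  spokes <- numeric(n_spokes)
  agg <- tapply(r, sector, max)
  spokes[as.integer(names(agg))] <- agg
  2 * mean(spokes)
}

#' Relative classical distances between two trees
#'
#' Relative errors of model height, girth and crown spread against the
#' reference (data/QSM) tree: `d_h = |h_d - h_m| / h_d`, and likewise for
#' girth and crown spread. Errors are unbounded above; girth errors
#' exceeding 100% are representable.
#'
#' @param model,data `classical_metrics()` of the model and reference trees.
#' @return named numeric vector `c(d_h, d_g, d_c)`.
#' @export
classical_distances <- function(model, data) {
  if (data$h <= 0 || data$g <= 0 || data$c <= 0) {
    stop("reference metrics must be positive")
  }
  c(d_h = abs(data$h - model$h) / data$h,
    d_g = abs(data$g - model$g) / data$g,
    d_c = abs(data$c - model$c) / data$c)
}
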