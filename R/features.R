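# Structural feature tables: branch-level (B^w) and segment-level (S^w)
# empirical data sets used by the structural distance.

.branch_columns <- c("beta", "alpha", "L_t", "R_f", "L_a")
.segment_columns <- c("R", "L", "gamma", "zeta")

.rad2deg <- function(x) x * 180 / pi

# Unsigned angle (degrees, [0, 180]) between two 3-vectors.
.angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) return(0)
  cosv <- sum(a * b) / (na * nb)
  .rad2deg(acos(max(-1, min(1, cosv))))
}

# Azimuth (degrees, [0, 360)) of `a` around unit axis `p`, measured from the
# projection of the global +x axis onto the plane normal to `p` (+y if the
# parent axis is essentially parallel to +x). Degenerate projections give 0.
.azimuth_around <- function(a, p) {
  ref <- c(1, 0, 0) - sum(c(1, 0, 0) * p) * p
  if (sqrt(sum(ref^2)) < 1e-6) {
    ref <- c(0, 1, 0) - sum(c(0, 1, 0) * p) * p
  }
  ref <- ref / sqrt(sum(ref^2))
  perp <- c(p[2] * ref[3] - p[3] * ref[2],
            p[3] * ref[1] - p[1] * ref[3],
            p[1] * ref[2] - p[2] * ref[1])
  aproj <- a - sum(a * p) * p
  if (sqrt(sum(aproj^2)) < 1e-9) return(0)
  ang <- .rad2deg(atan2(sum(aproj * perp), sum(aproj * ref)))
  (ang + 360) %% 360
}

#' Construct a feature table
#'
#' @param data data frame of feature rows (columns fixed by `kind`: branch
#'   tables carry `beta`, `alpha`, `L_t`, `R_f`, `L_a`; segment tables carry
#'   `R`, `L`, `gamma`, `zeta`).
#' @param kind `"branch"` or `"segment"`.
#' @param orders integer vector of the Gravelius orders pooled in this table.
#' @return object of class `"feature_table"` (a data frame with attributes).
#' @export
feature_table <- function(data, kind = c("branch", "segment"), orders) {
  kind <- match.arg(kind)
  want <- if (kind == "branch") .branch_columns else .segment_columns
  missing_cols <- setdiff(want, names(data))
  if (length(missing_cols)) {
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data <- data[, want, drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            kind = kind,
            orders = sort(unique(as.integer(orders))),
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table kind=", attr(x, "kind"),
      " orders={", paste(attr(x, "orders"), collapse = ","), "} rows=",
      nrow(x), ">\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

.require_orders <- function(tree) {
  if (anyNA(tree$cylinders$branch_order) || anyNA(tree$cylinders$branch_id)) {
    stop("tree has no order annotations; run assign_orders() first")
  }
}

#' Branch-level feature table B^w
#'
#' One row per branch of the selected Gravelius orders, with the branch
#' inclination angle `beta` (degrees, against the supporting parent segment;
#' the trunk is measured against global vertical), azimuthal angle `alpha`
#' (degrees around the parent segment axis from a fixed reference), total
#' branch length `L_t` (m), first-segment radius `R_f` (m), and `L_a` (m),
#' the length along the parent branch from its first segment to the point
#' where this branch emanates.
#'
#' @param tree a [tree()] with orders assigned.
#' @param orders integer vector of orders to include.
#' @return a [feature_table()] of kind `"branch"`.
#' @export
branch_table <- function(tree, orders) {
  .require_orders(tree)
  cyl <- tree$cylinders
  orders <- as.integer(orders)

  # Branch-level bookkeeping: rows of each branch in pos order.
  first_rows <- which(cyl$pos_in_branch == 0L)
  b_of_first <- cyl$branch_id[first_rows]
  keep <- which(cyl$branch_order[first_rows] %in% orders)

  # Prefix length within each branch (to the segment base).
  prefix <- .branch_prefix_lengths(cyl)

  rows <- lapply(keep, function(k) {
    fr <- first_rows[k]
    bid <- b_of_first[k]
    in_branch <- which(cyl$branch_id == bid)
    L_t <- sum(cyl$length[in_branch])
    R_f <- cyl$radius[fr]
    a <- c(cyl$axis_x[fr], cyl$axis_y[fr], cyl$axis_z[fr])
    par <- cyl$parent[fr]
    if (is.na(par)) {
      p <- c(0, 0, 1)
      L_a <- 0
    } else {
      p <- c(cyl$axis_x[par], cyl$axis_y[par], cyl$axis_z[par])
      # Along the parent branch up to and including the supporting segment.
      L_a <- prefix[par] + cyl$length[par]
    }
    c(beta = .angle_between(a, p),
      alpha = .azimuth_around(a, p),
      L_t = L_t, R_f = R_f, L_a = L_a)
  })
  data <- as.data.frame(do.call(rbind, c(rows, list(matrix(
    numeric(0), ncol = 5, dimnames = list(NULL, .branch_columns))))))
  feature_table(data, "branch", orders)
}

# Length from branch start to each cylinder's base, same order as rows.
.branch_prefix_lengths <- function(cyl) {
  prefix <- numeric(nrow(cyl))
  for (b in unique(cyl$branch_id)) {
    rows <- which(cyl$branch_id == b)
    rows <- rows[order(cyl$pos_in_branch[rows])]
    prefix[rows] <- cumsum(c(0, cyl$length[rows]))[seq_along(rows)]
  }
  prefix
}

#' Segment-level feature table S^w
#'
#' One row per cylinder of the selected orders: segment radius `R` (m),
#' distance `L` (m) from the beginning of its branch to the segment base,
#' `gamma` (degrees), the unsigned angle between the horizontal (XY)
#' projections of the segment axis and its parent segment axis, and `zeta`
#' (degrees), the unsigned difference of their elevation angles. A segment
#' whose axis projects to (numerically) zero horizontal length contributes
#' `gamma = 0`; the root's parent direction is taken as global vertical.
#'
#' @inheritParams branch_table
#' @return a [feature_table()] of kind `"segment"`.
#' @export
segment_table <- function(tree, orders) {
  .require_orders(tree)
  cyl <- tree$cylinders
  orders <- as.integer(orders)
  idx <- which(cyl$branch_order %in% orders)
  prefix <- .branch_prefix_lengths(cyl)

  ax <- cbind(cyl$axis_x, cyl$axis_y, cyl$axis_z)
  par <- cyl$parent
  pax <- matrix(rep(c(0, 0, 1), each = nrow(cyl)), ncol = 3)
  has_par <- !is.na(par)
  pax[has_par, ] <- ax[par[has_par], , drop = FALSE]

  gam <- vapply(idx, function(i) {
    h <- c(ax[i, 1], ax[i, 2]); ph <- c(pax[i, 1], pax[i, 2])
    if (sqrt(sum(h^2)) < 1e-9 || sqrt(sum(ph^2)) < 1e-9) return(0)
    .angle_between(c(h, 0), c(ph, 0))
  }, numeric(1))
  elev <- function(v) .rad2deg(asin(pmax(-1, pmin(1, v))))
  zet <- abs(elev(ax[idx, 3]) - elev(pax[idx, 3]))

  data <- data.frame(R = cyl$radius[idx],
                     L = prefix[idx],
                     gamma = gam,
                     zeta = zet)
  feature_table(data, "segment", orders)
}

#' Merge feature tables of one kind across orders
#'
#' Row-concatenates tables of the same kind, pooling their orders, e.g. the
#' merged segment set S^{0,1} or branch set B^{2,3,4}. Branch and segment
#' tables differ in dimension and are never merged together.
#'
#' @param tables list of [feature_table()] objects of a common kind.
#' @return a single [feature_table()].
#' @export
merge_tables <- function(tables) {
  if (length(tables) < 1L) stop("need at least one table")
  kinds <- vapply(tables, attr, character(1), which = "kind")
  if (length(unique(kinds)) != 1L) {
    stop("cannot merge branch- and segment-related tables: ",
         "they differ in dimension")
  }
  data <- do.call(rbind, lapply(tables, as.data.frame))
  orders <- sort(unique(unlist(lapply(tables, attr, which = "orders"))))
  feature_table(data, kinds[1], orders)
}

#' Write / read a feature table as CSV with a two-line header
#'
#' The header records the kind and pooled orders as comment lines, so a file
#' is self-describing: `# kind: segment` and `# orders: 0,1`.
#'
#' @param x a [feature_table()].
#' @param path file path.
#' @export
write_feature_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# kind: ", attr(x, "kind")),
               paste0("# orders: ", paste(attr(x, "orders"), collapse = ","))),
             con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  kind <- sub("^# kind: *", "", hdr[1])
  orders <- as.integer(strsplit(sub("^# orders: *", "", hdr[2]), ",")[[1]])
  data <- utils::read.csv(path, skip = 2L)
  feature_table(data, kind, orders)
}
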