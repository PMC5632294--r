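# Canonical cylinder-table columns, in file order.
.tree_columns <- c("radius", "length",
                   "start_x", "start_y", "start_z",
                   "axis_x", "axis_y", "axis_z",
                   "parent", "extension",
                   "branch_id", "branch_order", "pos_in_branch")

#' Construct a cylinder-model tree
#'
#' A tree is an ordered table of circular cylinders, each with a start point,
#' a unit axis, a length and a radius, linked by parent indices into a single
#' rooted structure. This is the common container for laser-scan derived
#' quantitative structure models (QSMs) and for simulated trees.
#'
#' @param cylinders data frame with columns `radius`, `length`, `start_x`,
#'   `start_y`, `start_z`, `axis_x`, `axis_y`, `axis_z`, `parent` (1-based
#'   index of the supporting cylinder, `NA` for the root), `extension`
#'   (1 if the cylinder continues its parent's branch, else 0), and the
#'   topology annotations `branch_id`, `branch_order`, `pos_in_branch`
#'   (may be `NA` until [assign_orders()] is run).
#' @param meta named list of free-form metadata (source, seed, units, ...).
#' @param validate check structural invariants (see [validate_tree()]).
#' @param attachment_tol if non-`NULL`, additionally require every child's
#'   start point to lie within this distance (metres) of its parent's distal
#'   end. Used for simulated trees; imported QSMs are not held to it.
#' @return an object of class `"tree"`.
#' @export
tree <- function(cylinders, meta = list(), validate = TRUE,
                 attachment_tol = NULL) {
  stopifnot(is.data.frame(cylinders))
  missing_cols <- setdiff(.tree_columns, names(cylinders))
  if (length(missing_cols) > 0L) {
    stop("cylinder table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cylinders <- cylinders[, .tree_columns]
  rownames(cylinders) <- NULL
  for (col in c("parent", "extension", "branch_id", "branch_order",
                "pos_in_branch")) {
    cylinders[[col]] <- as.integer(cylinders[[col]])
  }
  obj <- structure(list(cylinders = cylinders, meta = meta), class = "tree")
  if (validate) validate_tree(obj, attachment_tol = attachment_tol)
  obj
}

#' Number of cylinders in a tree
#' @param tree a [tree()] object.
#' @return integer count.
#' @export
n_cylinders <- function(tree) nrow(tree$cylinders)

#' Validate the structural invariants of a tree
#'
#' Checks that axes are unit vectors, lengths and radii are positive, exactly
#' one cylinder is the root, parent links are acyclic, and (where annotated)
#' positions within a branch are contiguous from 0.
#'
#' @inheritParams n_cylinders
#' @param attachment_tol optional tolerance (m) for child-start-on-parent-end.
#' @return the tree, invisibly; errors describe the first violated invariant.
#' @export
validate_tree <- function(tree, attachment_tol = NULL) {
  cyl <- tree$cylinders
  n <- nrow(cyl)
  if (n < 1L) stop("a tree must contain at least one cylinder")

  bad <- which(!(cyl$radius > 0))
  if (length(bad)) stop("nonpositive radius at row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(!(cyl$length > 0))
  if (length(bad)) stop("nonpositive length at row(s): ",
                        paste(bad, collapse = ", "))

  nrm <- sqrt(cyl$axis_x^2 + cyl$axis_y^2 + cyl$axis_z^2)
  bad <- which(abs(nrm - 1) > 1e-9)
  if (length(bad)) stop("non-unit axis at row(s): ",
                        paste(utils::head(bad, 10L), collapse = ", "))

  roots <- which(is.na(cyl$parent))
  if (length(roots) != 1L) {
    stop("expected exactly one root cylinder (parent = NA), found ",
         length(roots))
  }
  p <- cyl$parent
  if (any(!is.na(p) & (p < 1L | p > n))) stop("parent index out of range")
  if (any(!is.na(p) & p == seq_len(n))) {
    stop("topology error: cylinder is its own parent")
  }
  # Cycle check: follow parents with a visitation stamp.
  state <- integer(n)  # 0 unseen, 1 on stack, 2 done
  for (i in seq_len(n)) {
    j <- i
    path <- integer(0)
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      j <- p[j]
    }
    if (!is.na(j) && state[j] == 1L) {
      stop("topology error: cyclic parent links involving row ", j)
    }
    state[path] <- 2L
  }

  if (!anyNA(cyl$pos_in_branch) && !anyNA(cyl$branch_id)) {
    for (b in unique(cyl$branch_id)) {
      pos <- sort(cyl$pos_in_branch[cyl$branch_id == b])
      if (!identical(pos, seq_along(pos) - 1L)) {
        stop("pos_in_branch not contiguous from 0 in branch ", b)
      }
    }
  }

  if (!is.null(attachment_tol)) {
    ends <- cylinder_ends(tree)
    idx <- which(!is.na(p))
    d <- sqrt((cyl$start_x[idx] - ends[p[idx], 1])^2 +
              (cyl$start_y[idx] - ends[p[idx], 2])^2 +
              (cyl$start_z[idx] - ends[p[idx], 3])^2)
    if (any(d > attachment_tol)) {
      stop("child start detached from parent end beyond tolerance at row(s): ",
           paste(utils::head(idx[d > attachment_tol], 10L), collapse = ", "))
    }
  }
  invisible(tree)
}

#' Distal end points of every cylinder
#' @inheritParams n_cylinders
#' @return n x 3 matrix of end coordinates (m).
#' @export
cylinder_ends <- function(tree) {
  cyl <- tree$cylinders
  cbind(cyl$start_x + cyl$length * cyl$axis_x,
        cyl$start_y + cyl$length * cyl$axis_y,
        cyl$start_z + cyl$length * cyl$axis_z)
}

#' @export
print.tree <- function(x, ...) {
  cyl <- x$cylinders
  cat("<tree> ", nrow(cyl), " cylinders", sep = "")
  if (nrow(cyl) > 0L && !anyNA(cyl$branch_order)) {
    cat(", ", length(unique(cyl$branch_id)), " branches, orders 0-",
        max(cyl$branch_order), sep = "")
  }
  if (!is.null(x$meta$source)) cat(" [", x$meta$source, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a cylinder table from CSV
#'
#' The file dialect mirrors common QSM cylinder exports: one row per
#' cylinder, columns `radius,length,start_x,start_y,start_z,axis_x,axis_y,
#' axis_z,parent,extension,branch_id,branch_order,pos_in_branch`, with a
#' 0-based `parent` index and -1 marking the root. Units are metres, z-up.
#'
#' @param path CSV file path.
#' @param attachment_tol passed to [validate_tree()]; `NULL` (default) skips
#'   the child-on-parent-end check, appropriate for imported QSMs.
#' @return a [tree()].
#' @export
read_tree <- function(path, attachment_tol = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.tree_columns, names(tab))
  if (length(missing_cols) > 0L) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  par <- as.integer(tab$parent)
  par[par < 0L] <- NA_integer_
  tab$parent <- par + 1L  # 0-based file -> 1-based in memory
  tab$parent[is.na(par)] <- NA_integer_
  tree(tab, meta = list(source = path), validate = TRUE,
       attachment_tol = attachment_tol)
}

#' Write a cylinder table to CSV
#'
#' Columns are written in the canonical order with floats at 9 significant
#' digits; `parent` is written 0-based with -1 for the root, so a written
#' file reads back field-for-field identical.
#'
#' @inheritParams n_cylinders
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  cyl <- tree$cylinders
  out <- cyl
  par <- out$parent - 1L
  par[is.na(par)] <- -1L
  out$parent <- par
  for (col in c("radius", "length", "start_x", "start_y", "start_z",
                "axis_x", "axis_y", "axis_z")) {
    out[[col]] <- signif(out[[col]], 9)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Children lists for every cylinder
#' @inheritParams n_cylinders
#' @return list of integer vectors; element i holds the row indices of the
#'   cylinders whose parent is i.
#' @keywords internal
.children_of <- function(tree) {
  p <- tree$cylinders$parent
  n <- length(p)
  kids <- vector("list", n)
  idx <- which(!is.na(p))
  if (length(idx)) {
    sp <- split(idx, p[idx])
    kids[as.integer(names(sp))] <- sp
  }
  kids
}

#' Assign Gravelius orders and branch identities
#'
#' Orders follow the thickest-branch rule used when extracting topology from
#' a QSM snapshot: the trunk is order 0; at every junction the child with
#' the largest radius continues its parent's order and branch, while thinner
#' children become laterals of order w + 1 with fresh branch ids. Ties in
#' radius are broken toward the lowest row index.
#'
#' @inheritParams n_cylinders
#' @param force recompute even if every cylinder already carries an order.
#' @param w_max orders deeper than this are capped at `w_max`.
#' @return the tree with `branch_id`, `branch_order` and `pos_in_branch`
#'   filled for every cylinder.
#' @export
assign_orders <- function(tree, force = FALSE, w_max = 10L) {
  cyl <- tree$cylinders
  if (!force && !anyNA(cyl$branch_order) && !anyNA(cyl$branch_id) &&
      !anyNA(cyl$pos_in_branch)) {
    return(tree)
  }
  n <- nrow(cyl)
  kids <- .children_of(tree)
  ord <- integer(n); bid <- integer(n); pos <- integer(n)
  root <- which(is.na(cyl$parent))
  next_bid <- 1L

  # Iterative DFS over (cylinder, order, branch_id, pos) to avoid recursion.
  stack <- list(list(i = root, w = 0L, b = next_bid, p = 0L))
  next_bid <- next_bid + 1L
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i
    ord[i] <- fr$w; bid[i] <- fr$b; pos[i] <- fr$p
    ch <- kids[[i]]
    if (length(ch) == 0L) next
    r <- cyl$radius[ch]
    cont <- ch[which.max(r)]  # which.max takes the first maximum: tie-break
    for (j in ch) {
      if (j == cont) {
        stack[[length(stack) + 1L]] <-
          list(i = j, w = fr$w, b = fr$b, p = fr$p + 1L)
      } else {
        stack[[length(stack) + 1L]] <-
          list(i = j, w = min(fr$w + 1L, as.integer(w_max)), b = next_bid,
               p = 0L)
        next_bid <- next_bid + 1L
      }
    }
  }
  cyl$branch_order <- ord
  cyl$branch_id <- bid
  cyl$pos_in_branch <- pos
  tree$cylinders <- cyl
  tree
}
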