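# Morphological clones: stochastic realisations of a fitted growth model
# sharing coarse structure and varying in fine-scale branching.

#' Generate morphological clones
#'
#' Simulates `n` trees from one parameter set with consecutive distinct
#' seeds `seed_base, ..., seed_base + n - 1`. Different random sequences
#' under the same best-fit parameters are what makes the realisations
#' "clones": statistically alike in coarse form, different in detail.
#'
#' @param params an [sot_params()] (typically a best-fit set).
#' @param n number of clones (>= 1; studies of clone variability typically
#'   use n = 100).
#' @param seed_base first seed.
#' @return object of class `"clone_set"`: `params`, `seeds`, `trees`.
#' @export
generate_clones <- function(params, n, seed_base = 1L) {
  if (n < 1L) stop("n must be >= 1")
  seeds <- seed_base + seq_len(n) - 1L
  trees <- lapply(seeds, function(s) simulate_tree(params, s))
  structure(list(params = params, seeds = seeds, trees = trees),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  cat("<clone_set>", length(x$trees), "clones, seeds",
      x$seeds[1], "..", x$seeds[length(x$seeds)], "\n")
  invisible(x)
}

#' Summarise clones against a target tree
#'
#' Computes the classical allometric metrics (height, girth, crown spread)
#' of every clone and their relative distances to the target, plus
#' distribution quantiles of each column.
#'
#' @param set a [generate_clones()] result.
#' @param target reference [tree()].
#' @return data frame with one row per clone (`seed`, `n_cylinders`, `h`,
#'   `g`, `c`, `d_h`, `d_g`, `d_c`) and attribute `"quantiles"` holding the
#'   0/25/50/75/100% quantiles of each metric column.
#' @export
clone_summary <- function(set, target) {
  tm <- classical_metrics(target)
  rows <- lapply(seq_along(set$trees), function(i) {
    tr <- set$trees[[i]]
    cm <- classical_metrics(tr)
    d <- classical_distances(cm, tm)
    data.frame(seed = set$seeds[i], n_cylinders = n_cylinders(tr),
               h = cm$h, g = cm$g, c = cm$c,
               d_h = d[["d_h"]], d_g = d[["d_g"]], d_c = d[["d_c"]])
  })
  out <- do.call(rbind, rows)
  metric_cols <- c("h", "g", "c", "d_h", "d_g", "d_c")
  attr(out, "quantiles") <- vapply(metric_cols, function(col) {
    stats::quantile(out[[col]], c(0, 0.25, 0.5, 0.75, 1))
  }, numeric(5))
  out
}

#' Box plots of clone metric distributions
#'
#' @param x a [clone_summary()] data frame.
#' @param target_metrics optional `classical_metrics()` of the target, drawn
#'   as horizontal reference lines on the metric panels.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot_clone_summary <- function(x, target_metrics = NULL, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::boxplot(x[, c("h", "g", "c")],
                    main = "clone metrics (m)", ...)
  if (!is.null(target_metrics)) {
    graphics::points(1:3, c(target_metrics$h, target_metrics$g,
                            target_metrics$c), pch = 4, col = 2)
  }
  graphics::boxplot(x[, c("d_h", "d_g", "d_c")],
                    main = "relative distances", ...)
  invisible(x)
}
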