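# Inverse fitting: minimise the aggregate structural distance between a
# simulated tree and a target tree over simulator parameters, with a
# mixed-integer genetic algorithm and a fixed simulation seed so the
# objective is a pure function of the parameter vector.

#' Parameter search specification
#'
#' Each free parameter carries global lower/upper bounds (the search never
#' leaves them) and an initial range (a subset from which the initial
#' population is drawn; a narrow initial range recentres the search around
#' a previous fit without shrinking the global space).
#'
#' @param name parameter name in [sot_params()].
#' @param lower,upper global bounds.
#' @param init_lower,init_upper initial-population range (defaults to the
#'   global bounds).
#' @param integer whether the parameter is integer-valued.
#' @return one-row data frame; combine rows with [param_specs()].
#' @export
param_spec <- function(name, lower, upper, init_lower = lower,
                       init_upper = upper, integer = FALSE) {
  if (!(lower < upper)) stop("lower must be < upper for ", name)
  if (init_lower < lower || init_upper > upper || init_lower > init_upper) {
    stop("initial range must be a subset of the global bounds for ", name)
  }
  data.frame(name = name, lower = lower, upper = upper,
             init_lower = init_lower, init_upper = init_upper,
             integer = integer, stringsAsFactors = FALSE)
}

#' @rdname param_spec
#' @param ... [param_spec()] rows.
#' @export
param_specs <- function(...) do.call(rbind, list(...))

#' Extract the feature tables named by a pair configuration
#'
#' @param tree a [tree()] with orders assigned.
#' @param pairs named list mapping kind (`"segment"` or `"branch"`) to the
#'   integer orders to merge, e.g. `list(segment = 0:1, branch = 2:4)`.
#' @return named list of [feature_table()]s.
#' @export
extract_tables <- function(tree, pairs) {
  out <- lapply(seq_along(pairs), function(i) {
    kind <- names(pairs)[i]
    orders <- pairs[[i]]
    if (n_cylinders(tree) == 0L) {
      empty <- as.data.frame(matrix(
        numeric(0), ncol = if (kind == "branch") 5 else 4,
        dimnames = list(NULL, if (kind == "branch") .branch_columns
                        else .segment_columns)))
      return(feature_table(empty, kind, orders))
    }
    if (kind == "segment") segment_table(tree, orders)
    else branch_table(tree, orders)
  })
  names(out) <- vapply(seq_along(pairs), function(i) {
    paste0(if (names(pairs)[i] == "segment") "S" else "B",
           paste(pairs[[i]], collapse = ""))
  }, character(1))
  out
}

#' Build the fixed-seed optimisation objective
#'
#' The returned function maps a parameter vector `v` (in the order of
#' `specs`) to the mean structural distance between the tree simulated at
#' `v` (always with `sim_seed`) and the target's feature tables. Because
#' the simulation seed and the projection directions are fixed, the
#' objective is deterministic in `v`. Simulation failures and missing
#' orders score the maximal distance 1.
#'
#' @param specs a [param_specs()] table of free parameters.
#' @param target target [tree()] (orders will be assigned if absent).
#' @param pairs table-pair configuration as in [extract_tables()].
#' @param sim_seed fixed simulation seed.
#' @param base_params [sot_params()] supplying all non-free parameters.
#' @param n_lines projection lines per table pair.
#' @return function(v) -> distance in \[0, 1\].
#' @export
make_objective <- function(specs, target, pairs = list(segment = 0:1),
                           sim_seed = 1L, base_params = sot_params(),
                           n_lines = 1000L) {
  target <- assign_orders(target)
  target_tables <- extract_tables(target, pairs)
  dirs <- lapply(target_tables, function(tab) {
    generate_directions(ncol(tab), n_lines)
  })
  force(specs); force(base_params); force(sim_seed)
  function(v) {
    p <- base_params
    for (i in seq_len(nrow(specs))) {
      val <- v[i]
      if (specs$integer[i]) val <- as.integer(round(val))
      p[[specs$name[i]]] <- val
    }
    tr <- tryCatch(simulate_tree(p, sim_seed), error = function(e) {
      warning("simulation failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(tr)) return(1)
    model_tables <- extract_tables(tr, pairs)
    per <- vapply(seq_along(pairs), function(i) {
      structural_distance(model_tables[[i]], target_tables[[i]], dirs[[i]])
    }, numeric(1))
    mean(per)
  }
}

.sample_param <- function(n, lo, hi, integer) {
  if (integer) {
    lo <- ceiling(lo); hi <- floor(hi)
    sample(seq(lo, hi), n, replace = TRUE)
  } else {
    stats::runif(n, lo, hi)
  }
}

.clip_round <- function(v, specs) {
  v <- pmin(pmax(v, specs$lower), specs$upper)
  v[specs$integer] <- round(v[specs$integer])
  v
}

#' Genetic-algorithm minimisation
#'
#' Minimises `objective` over the box defined by `specs`. The initial
#' population is drawn from the initial ranges; search is clipped to the
#' global bounds. Selection is a tournament of 3, real parameters recombine
#' by intermediate crossover (rate 0.8 by default), mutation (rate 0.15 by
#' default) resets a gene uniformly within its global bounds, integer
#' parameters are sampled and mutated on the integer lattice, and the best
#' individual survives each generation (elitism). The run stops after
#' `stall_generations` generations without improvement, or at
#' `max_generations`.
#'
#' @param objective function of a parameter vector, as from
#'   [make_objective()] or any scalar function.
#' @param specs a [param_specs()] table.
#' @param pop_size population size.
#' @param max_generations hard generation cap.
#' @param stall_generations stop after this many generations without
#'   improving the best distance.
#' @param crossover_rate,mutation_rate GA variation rates.
#' @param seed RNG seed for the GA's own randomness.
#' @param verbose print per-generation progress.
#' @return object of class `"fit_result"`: `best_params` (named vector),
#'   `best_distance`, `trace` (per-generation best-so-far and median),
#'   `initial_median`, `n_evaluations`, `seed`, `specs`.
#' @export
fit_ga <- function(objective, specs, pop_size = 40L, max_generations = 100L,
                   stall_generations = 10L, crossover_rate = 0.8,
                   mutation_rate = 0.15, seed = 1L, verbose = FALSE) {
  d <- if (is.null(specs)) 0L else nrow(specs)
  if (d < 1L) stop("need at least one free parameter")
  if (all(specs$upper - specs$lower <= 0)) {
    stop("degenerate specification: no parameter has lower < upper")
  }
  set.seed(as.integer(seed))

  pop <- vapply(seq_len(d), function(j) {
    .sample_param(pop_size, specs$init_lower[j], specs$init_upper[j],
                  specs$integer[j])
  }, numeric(pop_size))
  pop <- matrix(pop, nrow = pop_size, ncol = d)

  fitness <- apply(pop, 1, objective)
  n_eval <- pop_size
  initial_median <- stats::median(fitness)

  best_i <- which.min(fitness)
  best_v <- pop[best_i, ]
  best_f <- fitness[best_i]
  trace <- data.frame(generation = 0L, best = best_f,
                      median = stats::median(fitness))
  stall <- 0L

  tournament <- function() {
    cand <- sample.int(pop_size, 3L)
    cand[which.min(fitness[cand])]
  }

  for (gen in seq_len(max_generations)) {
    newpop <- matrix(NA_real_, pop_size, d)
    newpop[1, ] <- best_v  # elitism
    for (k in 2:pop_size) {
      p1 <- pop[tournament(), ]
      if (stats::runif(1) < crossover_rate) {
        p2 <- pop[tournament(), ]
        u <- stats::runif(d, -0.25, 1.25)
        child <- p1 + u * (p2 - p1)
      } else {
        child <- p1
      }
      mut <- stats::runif(d) < mutation_rate
      if (any(mut)) {
        for (j in which(mut)) {
          child[j] <- .sample_param(1L, specs$lower[j], specs$upper[j],
                                    specs$integer[j])
        }
      }
      newpop[k, ] <- .clip_round(child, specs)
    }
    pop <- newpop
    fitness <- c(best_f, apply(pop[-1, , drop = FALSE], 1, objective))
    n_eval <- n_eval + pop_size - 1L
    gen_best <- which.min(fitness)
    if (fitness[gen_best] < best_f - 1e-12) {
      best_f <- fitness[gen_best]
      best_v <- pop[gen_best, ]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- rbind(trace, data.frame(generation = gen, best = best_f,
                                     median = stats::median(fitness)))
    if (verbose) {
      cat(sprintf("gen %3d  best %.5f  median %.5f\n", gen, best_f,
                  stats::median(fitness)))
    }
    if (stall >= stall_generations) break
  }

  structure(list(best_params = stats::setNames(best_v, specs$name),
                 best_distance = best_f,
                 trace = trace,
                 initial_median = initial_median,
                 n_evaluations = n_eval,
                 seed = seed,
                 specs = specs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> best D_S =", format(x$best_distance, digits = 5),
      "after", max(x$trace$generation), "generations,",
      x$n_evaluations, "evaluations\n")
  print(round(x$best_params, 5))
  invisible(x)
}

#' Recentre initial ranges around a previous fit
#'
#' Supports sequential refinement: each optimisation run can draw its
#' initial population around the best point of the previous run while
#' keeping the global bounds intact.
#'
#' @param specs a [param_specs()] table.
#' @param best named best parameter vector from a [fit_ga()] result.
#' @param frac half-width of the new initial range, as a fraction of the
#'   global range.
#' @return the updated specs.
#' @export
recenter_specs <- function(specs, best, frac = 0.25) {
  for (i in seq_len(nrow(specs))) {
    w <- frac * (specs$upper[i] - specs$lower[i])
    b <- best[[specs$name[i]]]
    specs$init_lower[i] <- max(specs$lower[i], b - w)
    specs$init_upper[i] <- min(specs$upper[i], b + w)
  }
  specs
}

#' Structural-distance profile along one parameter
#'
#' Scans a single simulator parameter over `values`, simulating `n_reps`
#' stochastic trees (distinct seeds) per value and recording the structural
#' distance of each to the target; the per-value medians trace the rugged,
#' replicate-dependent distance landscape.
#'
#' @param params base [sot_params()].
#' @param param_name name of the scanned parameter.
#' @param values numeric vector of parameter values.
#' @param target target [tree()].
#' @param pairs table-pair configuration as in [extract_tables()].
#' @param n_reps replicates per value.
#' @param seed_base replicate r uses seed `seed_base + r - 1`.
#' @param n_lines projection lines.
#' @param integer round scanned values to integers before simulating.
#' @return data frame with columns `value`, `rep`, `seed`, `distance`, and
#'   attribute `"medians"` (per-value median distance).
#' @export
distance_profile <- function(params, param_name, values, target,
                             pairs = list(segment = 0:1), n_reps = 10L,
                             seed_base = 1L, n_lines = 500L,
                             integer = FALSE) {
  if (!param_name %in% names(params)) {
    stop("unknown parameter name: ", param_name)
  }
  target <- assign_orders(target)
  target_tables <- extract_tables(target, pairs)
  dirs <- lapply(target_tables, function(tab) {
    generate_directions(ncol(tab), n_lines)
  })
  rows <- list()
  for (val in values) {
    p <- params
    p[[param_name]] <- if (integer) as.integer(round(val)) else val
    for (r in seq_len(n_reps)) {
      sd_r <- seed_base + r - 1L
      tr <- simulate_tree(p, sd_r)
      tabs <- extract_tables(tr, pairs)
      per <- vapply(seq_along(pairs), function(i) {
        structural_distance(tabs[[i]], target_tables[[i]], dirs[[i]])
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(value = val, rep = r, seed = sd_r, distance = mean(per))
    }
  }
  out <- do.call(rbind, rows)
  med <- stats::aggregate(distance ~ value, data = out, FUN = stats::median)
  names(med)[2] <- "median_distance"
  attr(out, "medians") <- med
  out
}
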