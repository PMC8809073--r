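# Minimisation of expected absorption time over the laziness parameters.
# The scalar optimiser combines a dense grid with local (Brent) refinement;
# when the objective is available as a rational function of p the stationary
# points of its derivative are found with polyroot() and compared. Because
# all agents freeze as p -> 1, t(p) diverges at the right boundary, so the
# domain is [0, 1 - 1e-9] and p = 1 is reported infeasible rather than
# evaluated. Ties break toward the smallest p.

P_UPPER <- 1 - 1e-9

#' Minimise an absorption-time objective over a scalar laziness
#'
#' @param objective function `p -> expected time` (may return `Inf`).
#' @param lower,upper domain, default `[0, 1 - 1e-9]`.
#' @param grid_step dense-grid spacing (default 1e-3).
#' @param tol refinement tolerance on `p` (default 1e-8).
#' @param symbolic optional `lrw_rat`: the objective as a rational function
#'   of a single variable. Its stationary points (roots of the derivative
#'   numerator) are solved and entered as candidates.
#' @return an object of class `lrw_optimum`: `p_bar` (argmin), `t_bar`
#'   (minimal expected time), `profile` (data.frame of the sampled `t(p)`
#'   curve), `grid_minimum`, and `stationary_points` when symbolic.
#' @examples
#' g <- build_graph("cycle", 3)
#' ch <- function(p) build_chain(g, 3, goal_distancing(1), laziness_uniform(p))
#' obj <- function(p) expected_time_from(absorption_times(ch(p)), "(0,0)")
#' minimize_scalar_laziness(obj)$p_bar   # 1/3: the loop-random walk
#' @export
minimize_scalar_laziness <- function(objective, lower = 0, upper = P_UPPER,
                                     grid_step = 1e-3, tol = 1e-8,
                                     symbolic = NULL) {
  grid <- unique(c(seq(lower, min(upper, 1 - grid_step), by = grid_step), upper))
  tv <- vapply(grid, objective, numeric(1))
  if (!any(is.finite(tv)))
    stop("the expected absorption time is infinite on the whole domain: ",
         "the goal is unreachable under this strategy class")
  ib <- which.min(replace(tv, !is.finite(tv), Inf))
  candidates <- data.frame(p = grid[ib], t = tv[ib], source = "grid")

  lo <- max(lower, grid[ib] - grid_step); hi <- min(upper, grid[ib] + grid_step)
  refined <- stats::optimize(objective, interval = c(lo, hi), tol = tol)
  candidates <- rbind(candidates,
                      data.frame(p = refined$minimum, t = refined$objective,
                                 source = "refined"))
  # boundary candidate: the left endpoint can be the optimum (e.g. r = 0)
  candidates <- rbind(candidates,
                      data.frame(p = lower, t = objective(lower), source = "boundary"))

  stationary <- NULL
  if (!is.null(symbolic)) {
    symbolic <- as_rat(symbolic)
    var <- unique(c(symbolic$num$vars, symbolic$den$vars))
    if (length(var) == 1L) {
      dnum <- rat_deriv(symbolic, var)$num
      coefs <- trim_poly_coefs(poly_coefs_univariate(dnum, var))
      if (length(coefs) > 1L) {
        roots <- polyroot(coefs)
        re <- Re(roots)[abs(Im(roots)) < 1e-7]
        re <- re[re >= lower & re <= upper]
        if (length(re)) {
          stationary <- data.frame(p = re,
                                   t = vapply(re, objective, numeric(1)),
                                   source = "stationary")
          candidates <- rbind(candidates, stationary)
        }
      }
    }
  }

  candidates <- candidates[is.finite(candidates$t), , drop = FALSE]
  candidates <- candidates[order(candidates$t, candidates$p), , drop = FALSE]
  best <- candidates[1L, ]
  structure(list(p_bar = best$p, t_bar = best$t,
                 profile = data.frame(p = grid, t = tv),
                 grid_minimum = c(p = grid[ib], t = tv[ib]),
                 stationary_points = stationary,
                 candidates = candidates),
            class = "lrw_optimum")
}

#' @export
print.lrw_optimum <- function(x, ...) {
  lab <- if (is.null(x$argmin)) paste0("p_bar = ", format(round(x$p_bar, 6)))
         else paste0("argmin = (", paste(round(x$argmin, 6), collapse = ", "), ")")
  cat("<lrw_optimum> ", lab, ", t_bar = ", format(round(x$t_bar, 6)), "\n", sep = "")
  invisible(x)
}

# small Latin-hypercube sample on [0, upper]^k (plain stratified permutation)
latin_hypercube <- function(n, k, upper = P_UPPER) {
  sapply(seq_len(k), function(j) (sample(n) - stats::runif(n)) / n * upper)
}

#' Minimise over population-dependent laziness parameters
#'
#' Multi-start local optimisation of an objective over `(p_1, ..., p_k)` in
#' `[0, 1 - 1e-9]^k`: Latin-hypercube interior starts plus every boundary
#' corner (printed optima sit on boundaries, e.g. the move-when-crowded rule
#' p_2 = 0), refined with `optim(method = "L-BFGS-B")`.
#'
#' @param objective function taking a numeric vector of length `k`.
#' @param k number of parameters.
#' @param n_starts number of Latin-hypercube starts (default 25).
#' @param tol convergence tolerance (default 1e-8).
#' @return an `lrw_optimum` with `argmin` (vector) and `t_bar`.
#' @export
minimize_popdep_laziness <- function(objective, k, n_starts = 25L, tol = 1e-8) {
  safe <- function(x) {
    v <- objective(pmin(pmax(x, 0), P_UPPER))
    if (!is.finite(v)) 1e12 else v
  }
  corners <- as.matrix(expand.grid(rep(list(c(0, 0.5, P_UPPER)), k)))
  starts <- rbind(latin_hypercube(n_starts, k), corners)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], safe, method = "L-BFGS-B",
                   lower = rep(0, k), upper = rep(P_UPPER, k),
                   control = list(factr = tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value ||
        (abs(fit$value - best$value) < 1e-10 && sum(fit$par) < sum(best$par))) {
      best <- fit
    }
  }
  if (is.null(best) || best$value >= 1e11)
    stop("the expected absorption time is infinite everywhere: goal unreachable")
  # polish near the incumbent with Nelder-Mead (cheap, helps boundary optima)
  pol <- stats::optim(best$par, safe, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (pol$value < best$value) best <- pol
  par <- pmin(pmax(best$par, 0), P_UPPER)
  par[par < 1e-7] <- 0  # snap to the boundary the optimiser is pressing on
  v_snap <- objective(par)
  if (v_snap <= best$value + 1e-10) best <- list(par = par, value = v_snap)
  structure(list(argmin = unname(best$par), t_bar = best$value,
                 p_bar = best$par[1L]),
            class = "lrw_optimum")
}

#' Optimal laziness for a goal on a graph
#'
#' High-level wrapper: builds the (symbolic where possible) absorbing chain,
#' forms the expected-absorption-time objective from the requested start,
#' and minimises over the strategy class.
#'
#' @param g an `lrw_graph`.
#' @param m number of agents.
#' @param goal an `lrw_goal` (distancing or gathering; search games have
#'   their own solvers).
#' @param start a transient-state label (see [build_chain()] for the
#'   labels), `"random"` for independent uniform placement, or a named
#'   weight vector.
#' @param mode `"uniform"` (one p for everyone) or `"population"`
#'   (population-dependent p_1..p_m).
#' @param ... passed to the underlying minimiser.
#' @return an `lrw_optimum`; for `mode = "population"` the `argmin` vector
#'   is ordered `p_1, ..., p_m`.
#' @examples
#' g <- build_graph("cycle", 5)
#' optimize_laziness(g, 2, goal_distancing(2), start = "(1)")  # p = 1/5
#' @export
optimize_laziness <- function(g, m, goal, start, mode = c("uniform", "population"),
                              ...) {
  mode <- match.arg(mode)
  strategy <- symbolic_strategy(if (mode == "uniform") "uniform" else "population_dependent",
                                m = m, var = "p")
  sym_chain <- build_chain(g, m, goal, strategy)
  weights <- start_weights(sym_chain, start)
  wt <- weights[sym_chain$labels]
  active <- which(wt > 0)
  # numeric objective: instantiate the chain and solve (backward stable);
  # the symbolic solution only supplies stationary-point candidates
  numeric_time <- function(vals) {
    res <- absorption_times(chain_eval(sym_chain, vals))
    v <- res$t[active]
    if (any(!is.finite(v))) return(Inf)
    sum(wt[active] * v)
  }
  if (mode == "uniform") {
    sym_obj <- tryCatch({
      sym_res <- absorption_times(sym_chain)
      symbolic_weighted_time(sym_res, wt, active)
    }, error = function(e) NULL)
    objective <- function(p) numeric_time(c(p = p))
    out <- minimize_scalar_laziness(objective, symbolic = sym_obj, ...)
    out$strategy <- laziness_uniform(out$p_bar)
  } else {
    vars <- paste0("p", seq_len(m))
    objective <- function(x) numeric_time(stats::setNames(x, vars))
    out <- minimize_popdep_laziness(objective, k = m, ...)
    out$strategy <- laziness_popdep(out$argmin)
  }
  out$start <- weights
  out
}

# weighted symbolic objective; NULL when any active start is non-absorbing
# with infinite time or when weights make the sum awkward
symbolic_weighted_time <- function(sym_res, wt, active) {
  if (!sym_res$symbolic) return(NULL)
  terms <- sym_res$t[active]
  if (any(vapply(terms, is.numeric, logical(1)))) return(NULL)
  acc <- as_rat(poly_const(0))
  for (i in seq_along(terms))
    acc <- rat_add(acc, rat_mul(as_rat(poly_const(wt[active][i])), terms[[i]]))
  acc
}

start_weights <- function(chain, start) {
  labels <- c(chain$labels, chain$classes)
  if (is.character(start) && length(start) == 1L && start == "random")
    return(random_start_distribution(chain))
  if (is.character(start) && length(start) == 1L) {
    if (!start %in% labels)
      stop("unknown start label '", start, "'; available: ",
           paste(labels, collapse = ", "))
    return(stats::setNames(as.numeric(labels == start), labels))
  }
  w <- stats::setNames(numeric(length(labels)), labels)
  unknown <- setdiff(names(start), labels)
  if (length(unknown)) stop("unknown start label(s): ", paste(unknown, collapse = ", "))
  w[names(start)] <- start
  w
}
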