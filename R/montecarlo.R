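# Seeded Monte Carlo engine for graphs whose exact chains are too large.
# Agents move synchronously per the lazy-walk kernel; the trial stops at the
# first period (period 0 included) whose state satisfies the goal. Default
# 5,000 trials; truncated trials (horizon guard) are reported and excluded
# from the mean, never silently included.

#' Simulate absorption times
#'
#' @param g an `lrw_graph`.
#' @param m number of agents (for capture goals: searchers + 1 hider, with
#'   the hider last in `start`).
#' @param goal an `lrw_goal`.
#' @param strategy an `lrw_strategy`, or `list(searcher =, hider =)` for
#'   capture goals.
#' @param start starting placement: an integer vector of `m` nodes, or one
#'   of `"random"` (independent uniform), `"corner"` / `"center"` (grids;
#'   all agents together), `"end"` (lines; all at node 1), `"together"`
#'   (all at node 1).
#' @param trials number of independent trials (default 5000).
#' @param seed RNG seed for reproducibility.
#' @param max_steps horizon guard per trial (default 1e6).
#' @param keep_times retain the per-trial absorption times?
#' @return an object of class `lrw_sim`: `mean`, `se`, `trials`,
#'   `truncated` (count), `unreliable` (flag: more than half the trials hit
#'   the horizon), and optionally `times`.
#' @examples
#' g <- build_graph("grid", 3)
#' simulate_absorption(g, 3, goal_distancing(2), laziness_uniform(0),
#'                     start = "corner", trials = 200, seed = 1)
#' @export
simulate_absorption <- function(g, m, goal, strategy, start = "random",
                                trials = 5000L, seed = NULL,
                                max_steps = 1e6, keep_times = FALSE) {
  stopifnot(trials >= 1, is.finite(max_steps))
  if (goal$type == "capture") {
    strategy <- normalize_capture_strategy(strategy)
    m <- goal$searchers + 1L
  }
  if (!is.null(seed)) set.seed(seed)
  start_nodes <- resolve_start(g, m, start)
  times <- numeric(trials)
  truncated <- 0L
  adj <- g$adjacency
  for (tr in seq_len(trials)) {
    pos <- if (is.null(start_nodes)) sample.int(g$n, m, replace = TRUE) else start_nodes
    if (goal$type == "gathering") pos <- unique(pos)
    t_abs <- NA_real_
    step <- 0L
    repeat {
      if (sim_is_absorbing(pos, goal, g)) { t_abs <- step; break }
      if (step >= max_steps) break
      pops <- tabulate(pos, nbins = g$n)
      new_pos <- pos
      for (a in seq_along(pos)) {
        sp <- sim_stay_prob(strategy, goal, a, length(pos), pops[pos[a]])
        if (stats::runif(1) >= sp) {
          nb <- adj[[pos[a]]]
          if (length(nb)) new_pos[a] <- nb[sample.int(length(nb), 1L)]
        }
      }
      pos <- new_pos
      if (goal$type == "gathering") pos <- unique(pos)
      step <- step + 1L
    }
    if (is.na(t_abs)) truncated <- truncated + 1L else times[tr] <- t_abs
    if (is.na(t_abs)) times[tr] <- NA_real_
  }
  ok <- !is.na(times)
  if (truncated > 0L)
    warning(truncated, " of ", trials, " trials hit the horizon (max_steps = ",
            max_steps, ") and are excluded from the mean")
  mean_t <- mean(times[ok])
  se_t <- stats::sd(times[ok]) / sqrt(sum(ok))
  structure(list(mean = mean_t, se = se_t, trials = trials,
                 truncated = truncated,
                 unreliable = truncated > trials / 2,
                 times = if (keep_times) times else NULL,
                 spec = list(g = g, m = m, goal = goal, strategy = strategy,
                             start = start, seed = seed, max_steps = max_steps)),
            class = "lrw_sim")
}

sim_is_absorbing <- function(pos, goal, g) {
  switch(goal$type,
         distancing = {
           if (anyDuplicated(pos)) return(goal$D <= 0)
           d <- min(g$dist[pos, pos][upper.tri(diag(length(pos)))])
           d >= goal$D
         },
         gathering = length(unique(pos)) == 1L,
         capture = pos[length(pos)] %in% pos[-length(pos)])
}

sim_stay_prob <- function(strategy, goal, agent, n_agents, population) {
  if (goal$type == "capture") {
    st <- if (agent == n_agents) strategy$hider else strategy$searcher
    return(effective_stay_prob(st, 1L))
  }
  if (goal$type == "gathering") return(effective_stay_prob(strategy, 1L))
  effective_stay_prob(strategy, population)
}

resolve_start <- function(g, m, start) {
  if (is.character(start)) {
    start <- match.arg(start, c("random", "corner", "center", "end", "together"))
    if (start == "random") return(NULL)
    node <- switch(start,
                   corner = {
                     if (g$family != "grid") stop("'corner' start needs a grid graph")
                     grid_node(g, 1L, 1L)
                   },
                   center = {
                     if (g$family != "grid") stop("'center' start needs a grid graph")
                     grid_node(g, max(1L, g$k %/% 2L), max(1L, g$k %/% 2L))
                   },
                   end = {
                     if (g$family != "line") stop("'end' start needs a line graph")
                     1L
                   },
                   together = 1L)
    return(rep(node, m))
  }
  nodes <- check_node(g, start)
  if (length(nodes) != m) stop("start placement must give one node per agent (m = ", m, ")")
  nodes
}

#' @export
print.lrw_sim <- function(x, ...) {
  cat("<lrw_sim> mean absorption time ", round(x$mean, 4), " +/- ",
      round(x$se, 4), " SE over ", x$trials - x$truncated, " trials",
      if (x$truncated) paste0(" (", x$truncated, " truncated)"), "\n", sep = "")
  invisible(x)
}

#' Sweep the laziness over a grid of values
#'
#' Runs [simulate_absorption()] for each `p` in `p_grid` with a shared base
#' seed advanced deterministically per grid point.
#'
#' @param g,m,goal,start,trials,max_steps as in [simulate_absorption()].
#' @param p_grid numeric vector of laziness values in `[0, 1)`.
#' @param seed base seed; grid point `i` uses `seed + i - 1`.
#' @return data.frame with columns `p`, `mean`, `se`, `trials`, `truncated`.
#' @export
sweep_laziness <- function(g, m, goal, p_grid, start = "random",
                           trials = 5000L, seed = 1L, max_steps = 1e6) {
  if (length(p_grid) == 0L)
    return(data.frame(p = numeric(0), mean = numeric(0), se = numeric(0),
                      trials = integer(0), truncated = integer(0)))
  if (any(p_grid < 0 | p_grid >= 1)) stop("p_grid must lie within [0, 1)")
  rows <- lapply(seq_along(p_grid), function(i) {
    sim <- simulate_absorption(g, m, goal, laziness_uniform(p_grid[i]),
                               start = start, trials = trials,
                               seed = seed + i - 1L, max_steps = max_steps)
    data.frame(p = p_grid[i], mean = sim$mean, se = sim$se,
               trials = sim$trials, truncated = sim$truncated)
  })
  do.call(rbind, rows)
}
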