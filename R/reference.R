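# Hand-derived analytic solutions for the desk-scale cases. These are small
# enough to work out on paper (two or three agents on a short cycle) and
# serve as independent regression oracles for the chain builder and the
# absorption solver. Each constructor accepts numeric values or polynomial
# parameters (see poly_var) and returns a list-matrix so that symbolic and
# numeric uses share one code path.

ref_matrix <- function(entries, nrow, labels = NULL) {
  M <- matrix(entries, nrow = nrow, byrow = TRUE)
  if (!is.null(labels)) dimnames(M) <- list(labels, labels)
  M
}

#' Analytic transient blocks for the small cycle problems
#'
#' Reduced (symmetry-lumped) transient transition matrices, derived by hand:
#'
#' * `ref_B_two_agents_distancing(p, r, n)`: two agents on `C_n`, goal
#'   distance 2, population-dependent laziness (`p` alone, `r` together);
#'   states ordered (together, adjacent). The `n = 4` variant differs in the
#'   adjacent-to-adjacent entry because moving apart on the 4-cycle lands
#'   the agents at distance 2 = diameter's complement, i.e. still adjacent
#'   in the reduced state numbering.
#' * `ref_B_c3_distancing(p)`: three agents on `C_3`, goal distinct nodes;
#'   states (all together, two together).
#' * `ref_B_c3_gathering(p)`: sticky gathering on `C_3`; states (two
#'   occupied nodes, three occupied nodes).
#' * `ref_B_c3_search(h, s)`: capture chain on `C_3`; states (searchers
#'   together, searchers apart).
#' * `ref_B_c5_gathering(p)`: sticky gathering of three agents on `C_5`;
#'   gap-labelled states ((1,1), (1,2), (0,1), (0,2)).
#' * `ref_B_c5_distancing(p)`: three agents on `C_5`, goal distinct nodes;
#'   states ((0,0), (0,1), (0,2)).
#'
#' @param p,r,h,s laziness parameters (numeric or `lrw_poly`).
#' @param n cycle size for the two-agent problem (`4` or `>= 5`).
#' @return a list-matrix of transition weights (row = from).
#' @export
ref_B_two_agents_distancing <- function(p, r = p, n = 5) {
  q <- 1 - p; s <- 1 - r
  b22 <- if (n == 4) p^2 + q^2 else p^2 + 0.75 * q^2
  ref_matrix(list(r^2 + 0.5 * s^2, 2 * r * s,
                  p * q,           b22),
             2L, c("(0)", "(1)"))
}

#' @rdname ref_B_two_agents_distancing
#' @export
ref_B_c3_distancing <- function(p) {
  q <- 1 - p
  ref_matrix(list(p^3 + 0.25 * q^3,                 3 * p^2 * q + 1.5 * p * q^2 + 0.75 * q^3,
                  0.5 * p^2 * q + 0.25 * p * q^2 + 0.125 * q^3,
                  p^3 + 1.5 * p^2 * q + 2.25 * p * q^2 + 0.625 * q^3),
             2L, c("(0,0)", "(0,1)"))
}

#' @rdname ref_B_two_agents_distancing
#' @export
ref_B_c3_gathering <- function(p) {
  q <- 1 - p
  ref_matrix(list(p^2 + p * q + 0.75 * q^2,                         0 * p,
                  3 * p^2 * q + 1.5 * p * q^2 + 0.75 * q^3,
                  p^3 + 0.75 * p * q^2 + 0.25 * q^3),
             2L, c("(0,1)", "(1,1)"))
}

#' @rdname ref_B_two_agents_distancing
#' @export
ref_B_c3_search_kernel <- function(h, s) {
  hp <- 1 - h; sp <- 1 - s
  ref_matrix(list(0.25 * hp * sp^2 + 0.25 * h * sp^2 + 0.5 * hp * s * sp + h * s^2,
                  0.25 * hp * sp^2 + 0.5 * hp * s * sp + h * s * sp,
                  0.25 * hp * sp^2 + 0.5 * hp * s * sp + h * s * sp,
                  0.375 * hp * sp^2 + 0.25 * h * sp^2 + 0.5 * hp * s^2 + h * s^2),
             2L, c("apart", "together"))
}

#' @rdname ref_B_two_agents_distancing
#' @export
ref_B_c3_search_benchmark <- function(h, s) {
  # fixed reference block behind the game's classical solution; differs from
  # the kernel block in three coefficients (see the methods vignette)
  ref_matrix(list(0.25 * (1 - s^2 - 2 * h * s + 6 * h * s^2),
                  0.25 * (1 - h - s + 5 * h * s - 4 * h * s^2),
                  0.25 * (1 + 2 * h * s - s^2 - 2 * h * s^2),
                  0.25 * (2 - h - 4 * s + 2 * h * s + 4 * s^2 + h * s^2)),
             2L, c("apart", "together"))
}

#' @rdname ref_B_two_agents_distancing
#' @export
ref_B_c5_gathering <- function(p) {
  q <- 1 - p
  ref_matrix(list(
    p^3 + 0.5 * p * q^2 + 0.5 * q^3,      p^2 * q + 0.75 * p * q^2 + 0.25 * q^3,
    p^2 * q + 0.5 * p * q^2 + 0.25 * q^3, p^2 * q + p * q^2,
    p^2 * q + 0.75 * p * q^2 + 0.25 * q^3, p^3 + p^2 * q + 0.75 * p * q^2 + 0.25 * q^3,
    0.5 * p * q^2 + 0.25 * q^3,           p^2 * q + p * q^2 + 0.25 * q^3,
    0 * p, 0 * p, p^2 + 0.75 * q^2,       p * q + 0.25 * q^2,
    0 * p, 0 * p, p * q + 0.25 * q^2,     p^2 + p * q + 0.5 * q^2),
    4L, c("(1,1)", "(1,2)", "(0,1)", "(0,2)"))
}

#' @rdname ref_B_two_agents_distancing
#' @export
ref_B_c5_distancing <- function(p) {
  q <- 1 - p
  ref_matrix(list(
    p^3 + 0.25 * q^3,                      3 * p^2 * q + 1.5 * p * q^2,        0.75 * q^3,
    0.25 * p * q^2 + 0.5 * p^2 * q,        p^3 + p * q^2 + p^2 * q + 0.375 * q^3,
    0.5 * p^2 * q + 0.75 * p * q^2 + 0.125 * q^3,
    0.125 * q^3,                           0.5 * p^2 * q + 0.75 * p * q^2 + 0.125 * q^3,
    p^3 + 0.5 * p^2 * q + 0.25 * p * q^2 + 0.5 * q^3),
    3L, c("(0,0)", "(0,1)", "(0,2)"))
}

#' Analytic absorption-time curves
#'
#' Expected absorption times as explicit functions of the common laziness
#' `p`, solved by hand from the reduced chains above:
#'
#' * `ref_t_c3_distancing(p)`: from (all together, two together) on `C_3`.
#' * `ref_t_c3_gathering(p)`: from (two occupied, three occupied) on `C_3`.
#' * `ref_t2_two_agents_common(p)`: adjacent start on `C_n` (n >= 5), goal
#'   distance 2, common laziness.
#' * `ref_t_c5_gathering(p)` / `ref_t_c5_distancing(p)`: gap-state starts on
#'   `C_5` in the orders of the matrices above.
#'
#' @param p common laziness (numeric vector).
#' @return numeric vector/matrix of expected times.
#' @export
ref_t_c3_distancing <- function(p) {
  cbind(`(0,0)` = 6 / (1 + 2 * p - 3 * p^2),
        `(0,1)` = 2 * (7 + 12 * p + 9 * p^2) / (3 + 6 * p + 18 * p^3 - 27 * p^4))
}

#' @rdname ref_t_c3_distancing
#' @export
ref_t_c3_gathering <- function(p) {
  cbind(`(0,1)` = 4 / (1 + 2 * p - 3 * p^2),
        `(1,1)` = 4 * (4 + 3 * p + 9 * p^2) / (3 * (1 + 3 * p + p^2 + p^3 - 6 * p^4)))
}

#' @rdname ref_t_c3_distancing
#' @export
ref_t2_two_agents_common <- function(p) {
  (20 * p + 4) / ((1 - p) * (10 * p + 5 * p^2 + 1))
}

#' @rdname ref_t_c3_distancing
#' @export
ref_t_c5_gathering <- function(p) {
  den1 <- (p - 1) * (5 + 72 * p + 274 * p^2 + 420 * p^3 + 349 * p^4 + 140 * p^5 + 20 * p^6)
  den2 <- 1 + 9 * p - 5 * p^2 - 5 * p^3
  cbind(`(1,1)` = -(8 * (9 + 58 * p + 152 * p^2 + 170 * p^3 + 103 * p^4 + 20 * p^5)) / den1,
        `(1,2)` = -(4 * (16 + 121 * p + 331 * p^2 + 385 * p^3 + 249 * p^4 + 50 * p^5)) / den1,
        `(0,1)` = (12 + 20 * p) / den2,
        `(0,2)` = (8 + 40 * p) / den2)
}

#' @rdname ref_t_c3_distancing
#' @export
ref_t_c5_distancing <- function(p) {
  den <- 3 * (p - 1) * (7 + 67 * p + 126 * p^2 + 158 * p^3 + 75 * p^4 + 15 * p^5)
  cbind(`(0,0)` = -(2 * (55 + 134 * p + 316 * p^2 + 330 * p^3 + 45 * p^4)) / den,
        `(0,1)` = -(2 * (25 + 214 * p + 232 * p^2 + 170 * p^3 + 15 * p^4)) / den,
        `(0,2)` = -(2 * (41 + 142 * p + 152 * p^2 + 50 * p^3 + 15 * p^4)) / den)
}

#' Analytic team-game time and balance quintic
#'
#' `ref_team_time(h, s)`: the expected capture time from a random start as
#' the ratio of two hand-derived polynomials. `ref_balance_quintic()`:
#' ascending coefficients of the quintic whose (0,1) root is the searcher
#' laziness equalising the hider's two extreme replies,
#' `14 - 15 s - 117 s^2 - 33 s^3 - 5 s^4 + 60 s^5`.
#'
#' @param h,s lazinesses.
#' @return numeric value / coefficient vector.
#' @export
ref_team_time <- function(h, s) {
  a <- 8 * (-7 - 3 * s - 7 * h * s + 4 * s^2 + 13 * h * s^2)
  b <- -45 - 36 * h - 117 * s + 81 * h * s - 36 * h^2 * s + 81 * s^2 -
    9 * h * s^2 + 198 * h^2 * s^2 - 27 * s^3 + 279 * h * s^3 -
    252 * h^2 * s^3 + 36 * s^4 - 171 * h * s^4 + 18 * h^2 * s^4
  a / b
}

#' @rdname ref_team_time
#' @export
ref_balance_quintic <- function() c(14, -15, -117, -33, -5, 60)

#' Write the reference fixture bundle
#'
#' Emits the analytic reference material as plain-text CSV fixtures for
#' regression testing and external use: the reduced transition matrices at
#' a grid of laziness values, the absorption-time curves, and the optimal-p
#' tables for the 5-cycle (recomputed through the optimiser, not copied).
#' Every file starts with a descriptive header comment.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
generate_reference_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(name, header, df) {
    path <- file.path(dir, name)
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines(paste0("# ", header), con)
    utils::write.csv(format(df, digits = 17), con, row.names = FALSE)
    paths <<- c(paths, path)
    path
  }
  pgrid <- seq(0, 0.95, by = 0.05)
  put("t_curves_c3.csv",
      "expected absorption times on C_3: distancing (from together / two-together) and gathering (from two / three occupied nodes), common laziness p",
      data.frame(p = pgrid,
                 distancing = ref_t_c3_distancing(pgrid),
                 gathering = ref_t_c3_gathering(pgrid), check.names = FALSE))
  put("t_curves_c5.csv",
      "expected absorption times on C_5, three agents: gathering and distancing gap states, common laziness p",
      data.frame(p = pgrid, gathering = ref_t_c5_gathering(pgrid),
                 distancing = ref_t_c5_distancing(pgrid), check.names = FALSE))
  g5 <- build_graph("cycle", 5)
  opt_rows <- function(goal, starts) {
    do.call(rbind, lapply(starts, function(s0) {
      opt <- optimize_laziness(g5, 3, goal, start = s0)
      data.frame(start = s0, p_bar = opt$p_bar, t_bar = opt$t_bar)
    }))
  }
  put("optimal_p_c5_gathering.csv",
      "optimal common laziness for sticky gathering of 3 agents on C_5, per start class and from a random start",
      opt_rows(goal_gathering(), c("(1,1)", "(1,2)", "(0,1)", "(0,2)", "random")))
  put("optimal_p_c5_distancing.csv",
      "optimal common laziness for distancing (distinct nodes) of 3 agents on C_5, per start class",
      opt_rows(goal_distancing(1), c("(0,0)", "(0,1)", "(0,2)")))
  ch <- chain_eval(build_chain(g5, 2, goal_distancing(2),
                               symbolic_strategy("uniform")), c(p = 0.2))
  path <- file.path(dir, "chain_c5_two_agents_p02.csv")
  write_chain_csv(ch, path,
                  header = "# two-agent distance-2 chain on C_5, common laziness p = 0.2")
  paths <- c(paths, path)
  invisible(paths)
}
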