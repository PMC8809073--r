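# First-to-disperse game on the line L_n: n players start together at end
# node 1, each picks a laziness, and the first players to be alone at their
# node split a unit prize. "Alone" is evaluated at the end of each
# synchronous period (period 0 included; with everyone starting at node 1 it
# can never terminate at time 0, which is asserted, not assumed). The
# labelled-agent absorbing chain below is the exact oracle behind the two
# closed-form payoffs and behind the no-symmetric-equilibrium scan.

#' Closed-form payoffs in the first-to-disperse game on L_3
#'
#' `stay_forever_payoff(p)`: payoff to a player who never moves (laziness 1)
#' at end node 1 while both opponents use laziness `p`:
#' `(1-p)^2 / (1-p^2) = (1-p)/(1+p)`. Strictly decreasing, equal to 1/3 at
#' `p = 1/2`.
#'
#' `random_walk_modified_payoff(p)`: *modified* payoff (ties pay the deviator
#' 0) to a player who always moves (laziness 0) against two opponents using
#' `p`, starting all together at an end:
#' `(1 - 4p + 14p^2 - 12p^3 + 5p^4) / (3 + 4p - 6p^2 + 4p^3 - p^4)`.
#' Exceeds 1/3 exactly when `p > 1/2`.
#'
#' @param p the common laziness of the two opponents.
#' @return payoff in `[0, 1]`.
#' @export
stay_forever_payoff <- function(p) {
  stopifnot(all(p >= 0))
  if (any(p >= 1)) stop("undefined at p = 1: the opponents never move")
  (1 - p)^2 / (1 - p^2)
}

#' @rdname stay_forever_payoff
#' @export
random_walk_modified_payoff <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  (-4 * p + 14 * p^2 - 12 * p^3 + 5 * p^4 + 1) /
    (4 * p - 6 * p^2 + 4 * p^3 - p^4 + 3)
}

#' Exact payoffs of the first-to-disperse game
#'
#' Labelled-agent absorbing-chain computation of each player's expected
#' payoff on the line `L_n`, all players starting at node 1. Terminal
#' classes are keyed by the winner set (the players alone at their node at
#' the end of the period).
#'
#' @param profile numeric vector of per-player lazinesses `(p_1, ..., p_n)`,
#'   at least one below 1.
#' @param tie_rule `"split"`: a tie of `k` winners pays `1/k` each (the
#'   actual game); `"zero"`: any tie pays every player 0 (the modified
#'   payoff used to simplify the closed forms).
#' @param n_nodes number of line nodes (defaults to `length(profile)`).
#' @return numeric payoff vector, one entry per player.
#' @examples
#' exact_game_payoffs(c(0.4, 0.4))            # 0.5, 0.5
#' exact_game_payoffs(c(1, 0.3, 0.3))[1]      # = stay_forever_payoff(0.3)
#' @export
exact_game_payoffs <- function(profile, tie_rule = c("split", "zero"),
                               n_nodes = length(profile)) {
  tie_rule <- match.arg(tie_rule)
  n <- length(profile)
  if (n < 2L) stop("the game needs at least two players")
  if (n > 4L) stop("exact payoffs enumerate n^n states per period; limited to n <= 4")
  stopifnot(all(profile >= 0 & profile <= 1))
  if (all(profile >= 1)) stop("all players frozen: the game never ends")
  g <- build_graph("line", n_nodes)

  # transient states: every occupied node holds at least two players
  all_states <- as.matrix(expand.grid(rep(list(seq_len(g$n)), n)))
  winners_of <- function(cfg) {
    tab <- tabulate(cfg, nbins = g$n)
    which(tab[cfg] == 1L)
  }
  is_terminal <- apply(all_states, 1L, function(cfg) length(winners_of(cfg)) > 0L)
  trans <- all_states[!is_terminal, , drop = FALSE]
  t_keys <- apply(trans, 1L, paste, collapse = ",")
  start_cfg <- rep(1L, n)
  start_key <- paste(start_cfg, collapse = ",")
  stopifnot(start_key %in% t_keys)  # all-together start never terminates at 0

  winner_key <- function(w) paste(w, collapse = "+")
  classes <- character(0)
  Nt <- nrow(trans)
  B <- matrix(0, Nt, Nt, dimnames = list(t_keys, t_keys))
  Rcols <- list()
  for (i in seq_len(Nt)) {
    jd <- joint_move_distribution(trans[i, ], g, as.list(profile))
    for (kk in seq_along(jd$probs)) {
      cfg <- jd$configs[kk, ]
      w <- winners_of(cfg)
      pr <- jd$probs[[kk]]
      if (length(w)) {
        key <- winner_key(w)
        if (is.null(Rcols[[key]])) Rcols[[key]] <- numeric(Nt)
        Rcols[[key]][i] <- Rcols[[key]][i] + pr
      } else {
        j <- match(paste(cfg, collapse = ","), t_keys)
        B[i, j] <- B[i, j] + pr
      }
    }
  }
  R <- do.call(cbind, Rcols)
  colnames(R) <- names(Rcols)

  # absorption probabilities from the all-at-node-1 start
  supp <- B > 1e-14
  reachable <- backward_closure(rowSums(R) > 0, supp)
  if (!reachable[match(start_key, t_keys)])
    stop("the game cannot end from the all-together start under this profile")
  idx <- which(reachable)
  Asub <- solve(diag(length(idx)) - B[idx, idx, drop = FALSE],
                R[idx, , drop = FALSE])
  arow <- stats::setNames(Asub[match(start_key, t_keys[idx]), ], colnames(R))
  if (abs(sum(arow) - 1) > 1e-9)
    stop("the game ends with probability ", format(sum(arow)),
         " < 1 under this profile; payoffs undefined")

  pay <- numeric(n)
  for (key in names(arow)) {
    w <- as.integer(strsplit(key, "+", fixed = TRUE)[[1L]])
    share <- if (tie_rule == "split") 1 / length(w) else as.numeric(length(w) == 1L)
    pay[w] <- pay[w] + arow[[key]] * share
  }
  pay
}

#' Scan for symmetric equilibria in the three-player game
#'
#' For each common laziness `p` on a grid, exhibits a profitable deviation
#' for a single player: staying put (`q = 1`) when `p < 1/2`, always moving
#' (`q = 0`) otherwise; both candidates are evaluated through
#' [exact_game_payoffs()] with the actual (`split`) tie rule and the better
#' one is reported. A symmetric profile is an equilibrium only if no
#' deviation beats the symmetric payoff 1/3.
#'
#' @param grid_step grid spacing over `p` in `(0, 1)` (must be `<= 0.01`).
#' @param tol strictness margin over 1/3 (default 1e-9).
#' @return data.frame with columns `p`, `deviation` (best `q`), `payoff`,
#'   and `profitable`; attribute `equilibrium_free` is `TRUE` when every
#'   grid point admits a profitable deviation.
#' @export
symmetric_equilibrium_scan <- function(grid_step = 0.01, tol = 1e-9) {
  if (grid_step > 0.01) stop("grid_step must be at most 0.01")
  ps <- seq(grid_step, 1 - grid_step, by = grid_step)
  rows <- lapply(ps, function(p) {
    cand <- c(0, 1)
    pays <- vapply(cand, function(q)
      exact_game_payoffs(c(q, p, p), tie_rule = "split")[1L], numeric(1))
    best <- which.max(pays)
    data.frame(p = p, deviation = cand[best], payoff = pays[best],
               profitable = pays[best] > 1 / 3 + tol)
  })
  out <- do.call(rbind, rows)
  attr(out, "equilibrium_free") <- all(out$profitable)
  out
}
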