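# Fundamental-matrix absorption analysis. For the transient block B the
# fundamental matrix is F = (I - B)^{-1}; its row sums are the expected
# absorption times t and F R the absorption probabilities. States that are
# not absorbed almost surely are detected *structurally* (reachability on
# the support of B) before any inversion: on C_4 with p = 0 the adjacent
# class is an exact trap and I - B is exactly singular there, so blind
# inversion would be wrong, not merely ill-conditioned.

#' Absorption times, probabilities and fundamental matrix
#'
#' @param chain an `lrw_chain` (numeric or symbolic).
#' @return an object of class `lrw_absorption`:
#'   * `t`: expected absorption times per transient state (`Inf` where
#'     absorption is not almost sure; rational functions for symbolic
#'     chains),
#'   * `reachable`: per state, can the absorbing set be reached at all,
#'   * `almost_sure`: per state, is absorption almost sure (`t` finite),
#'   * `F`: fundamental matrix on the almost-surely-absorbed states (numeric
#'     chains; `NA` rows/columns elsewhere),
#'   * `A`: absorption probability matrix (numeric chains; rows sum to 1
#'     where absorption is almost sure).
#' @examples
#' g <- build_graph("cycle", 5)
#' ch <- build_chain(g, 2, goal_distancing(2), laziness_uniform(0))
#' absorption_times(ch)$t   # adjacent start: 4 periods
#' @export
absorption_times <- function(chain) {
  stopifnot(inherits(chain, "lrw_chain"))
  N <- length(chain$labels)
  supp_B <- chain_support(chain$B)
  supp_R <- chain_support(chain$R)

  # states that can reach the absorbing set
  reachable <- backward_closure(rowSums(supp_R) > 0, supp_B)
  # states that can reach a state from which absorption is unreachable
  doomed <- backward_closure(!reachable, supp_B)
  almost_sure <- !doomed

  if (chain$symbolic) {
    t <- vector("list", N)
    if (any(almost_sure)) {
      idx <- which(almost_sure)
      A_sub <- matrix(list(), length(idx), length(idx))
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        e <- as_poly(chain$B[[idx[a], idx[b]]])
        A_sub[[a, b]] <- poly_add(poly_const(as.numeric(a == b)), poly_neg(e))
      }
      sol <- rat_solve(A_sub, rep(list(poly_const(1)), length(idx)))
      for (a in seq_along(idx)) t[[idx[a]]] <- sol[[a]]
    }
    for (i in which(!almost_sure)) t[[i]] <- Inf
    names(t) <- chain$labels
    return(structure(list(t = t, F = NULL, A = NULL,
                          reachable = stats::setNames(reachable, chain$labels),
                          almost_sure = stats::setNames(almost_sure, chain$labels),
                          chain = chain, symbolic = TRUE),
                     class = "lrw_absorption"))
  }

  t <- rep(Inf, N)
  Fm <- matrix(NA_real_, N, N, dimnames = list(chain$labels, chain$labels))
  A <- matrix(NA_real_, N, ncol(chain$R),
              dimnames = list(chain$labels, chain$classes))
  if (any(almost_sure)) {
    idx <- which(almost_sure)
    M <- diag(length(idx)) - chain$B[idx, idx, drop = FALSE]
    kap <- kappa(M, exact = FALSE)
    Fsub <- solve(M)
    if (kap > 1e12) {
      warning("ill-conditioned I - B (condition number ~ ",
              format(kap, digits = 3), "); applying iterative refinement")
      Fsub <- Fsub + solve(M, diag(length(idx)) - M %*% Fsub)
    }
    Fm[idx, idx] <- Fsub
    t[idx] <- as.numeric(Fsub %*% rep(1, length(idx)))
    A[idx, ] <- Fsub %*% chain$R[idx, , drop = FALSE]
  }
  # absorption probabilities are still defined wherever the absorbing set is
  # reachable (rows then sum to < 1 when a trap is also reachable)
  extra <- reachable & !almost_sure
  if (any(extra)) {
    idx <- which(reachable)
    M <- diag(length(idx)) - chain$B[idx, idx, drop = FALSE]
    A[idx, ] <- solve(M, chain$R[idx, , drop = FALSE])
  }
  A[!reachable, ] <- 0
  names(t) <- chain$labels
  structure(list(t = t, F = Fm, A = A,
                 reachable = stats::setNames(reachable, chain$labels),
                 almost_sure = stats::setNames(almost_sure, chain$labels),
                 chain = chain, symbolic = FALSE),
            class = "lrw_absorption")
}

chain_support <- function(M, tol = 1e-14) {
  if (is.list(M)) {
    matrix(vapply(M, function(e) !poly_is_zero(as_poly(e)), logical(1)),
           nrow(M), ncol(M))
  } else {
    M > tol
  }
}

# states from which the seed set is reachable along the support of B
backward_closure <- function(seed, supp_B) {
  reach <- seed
  repeat {
    new <- reach | (supp_B %*% reach > 0)
    if (all(new == reach)) return(as.vector(reach))
    reach <- new
  }
}

#' @rdname absorption_times
#' @export
absorption_probabilities <- function(chain) {
  if (inherits(chain, "lrw_absorption")) return(chain$A)
  absorption_times(chain)$A
}

#' @export
print.lrw_absorption <- function(x, ...) {
  cat("<lrw_absorption> ", length(x$t), " transient states\n", sep = "")
  if (x$symbolic) {
    for (i in seq_along(x$t)) {
      v <- x$t[[i]]
      cat("  t[", names(x$t)[i], "] = ",
          if (is.numeric(v)) format(v) else format(v), "\n", sep = "")
    }
  } else {
    print(round(x$t, 6))
  }
  invisible(x)
}

#' Expected absorption time from a start distribution
#'
#' Averages the per-state expected times over a distribution on the full
#' state space; starts in an absorbing class contribute time 0.
#'
#' @param result an `lrw_absorption` (or an `lrw_chain`, solved on the fly).
#' @param start either a single transient-state or class label (point mass),
#'   or a named numeric vector of weights over
#'   `c(transient labels, class labels)` summing to 1 (tolerance 1e-9).
#'   Missing names are taken as weight 0.
#' @param vals for symbolic chains: parameter values at which to evaluate.
#' @return expected time (numeric; `Inf` if a non-absorbed start has weight).
#' @export
expected_time_from <- function(result, start, vals = NULL) {
  if (inherits(result, "lrw_chain")) result <- absorption_times(result)
  chain <- result$chain
  all_labels <- c(chain$labels, chain$classes)
  if (is.character(start) && length(start) == 1L) {
    if (!start %in% all_labels)
      stop("unknown state/class label '", start, "'; available: ",
           paste(all_labels, collapse = ", "))
    w <- stats::setNames(numeric(length(all_labels)), all_labels)
    w[start] <- 1
  } else {
    if (is.null(names(start)))
      stop("start weights must be named by state/class labels")
    unknown <- setdiff(names(start), all_labels)
    if (length(unknown))
      stop("unknown state/class label(s): ", paste(unknown, collapse = ", "))
    w <- stats::setNames(numeric(length(all_labels)), all_labels)
    w[names(start)] <- start
    if (any(w < -1e-12)) stop("start weights must be nonnegative")
    if (abs(sum(w) - 1) > 1e-9)
      stop("start weights sum to ", format(sum(w), digits = 12), ", not 1")
  }
  wt <- w[chain$labels]
  tt <- result$t
  if (result$symbolic) {
    tt <- vapply(tt, function(v) {
      if (is.numeric(v)) return(v)
      if (is.null(vals)) stop("symbolic result: supply parameter values via `vals`")
      rat_eval(v, vals)
    }, numeric(1))
  }
  active <- wt > 0
  if (!any(active)) return(0)
  if (any(!is.finite(tt[active]))) return(Inf)
  sum(wt[active] * tt[active])
}

#' Random-start distribution by independent uniform placement
#'
#' Places every agent independently and uniformly on the nodes, pushes each
#' labelled placement through the chain's canonicalisation (merging
#' co-located agents for gathering, capture check at time 0), and returns
#' the induced weights over the chain's transient states and absorbing
#' classes. Nothing is entered by hand: the classic lumped weights (e.g.
#' (6,6,6,6,1)/25 for three agents on the 5-cycle, or (2/9, 2/9, 4/9, 1/9)
#' for two searchers and a hider on the triangle) fall out of this
#' enumeration.
#'
#' @param chain an `lrw_chain`.
#' @return named numeric vector over `c(transient labels, class labels)`.
#' @export
random_start_distribution <- function(chain) {
  g <- chain$g; goal <- chain$goal; m <- chain$m
  if (g$n^m > 1e6) stop("too many labelled placements to enumerate; m = ", m,
                        " on n = ", g$n)
  labels <- c(chain$labels, chain$classes)
  w <- stats::setNames(numeric(length(labels)), labels)
  perms <- if (chain$lumped) cycle_automorphisms(g$n) else NULL
  placements <- as.matrix(expand.grid(rep(list(seq_len(g$n)), m)))
  p_each <- 1 / nrow(placements)
  for (i in seq_len(nrow(placements))) {
    cfg <- placements[i, ]
    st <- switch(goal$type,
                 distancing = state_occupancy(tabulate(cfg, nbins = g$n)),
                 gathering = state_coalesced(unique(cfg)),
                 capture = state_capture(cfg[seq_len(goal$searchers)],
                                         cfg[goal$searchers + 1L],
                                         labelled = goal$labelled))
    if (chain$lumped) st <- canonical_cycle_state(st, g, perms)
    key <- if (state_is_absorbing(st, goal, g)) {
      absorbing_class_key(st, goal, g, chain$lumped, m)
    } else {
      format_state(st, goal, g, lumped = chain$lumped, m = m)
    }
    w[key] <- w[key] + p_each
  }
  w
}

#' Results table of an absorption analysis
#'
#' @param result an `lrw_absorption` from a numeric chain.
#' @return data.frame with the state label, expected absorption time and
#'   per-class absorption probabilities.
#' @export
absorption_table <- function(result) {
  stopifnot(inherits(result, "lrw_absorption"), !result$symbolic)
  data.frame(state = result$chain$labels,
             t = unname(result$t),
             as.data.frame(result$A, optional = TRUE),
             check.names = FALSE, row.names = NULL)
}
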