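# Lazy-random-walk motion rule. Each period an agent stays at its node with
# probability p (its laziness) and otherwise moves to a uniformly chosen
# neighbour. The laziness may depend on the population of the agent's node
# evaluated *before* anyone moves, which is the only timing consistent with
# the two-agent reduced chains on cycles (both co-located agents use the
# population-2 value in the same period).

#' Laziness strategies
#'
#' `laziness_uniform(p)` uses one stay probability regardless of node
#' population; `laziness_popdep(p_by_population)` maps the population `k` of
#' the agent's node (counted before the synchronous move) to a stay
#' probability `p_k`. For two agents the field convention is `p_1 = p`
#' (alone) and `p_2 = r` (sharing a node).
#'
#' @param p stay probability in `[0, 1]`.
#' @param p_by_population numeric vector of stay probabilities indexed by
#'   population `1..m` (names optional).
#' @return an object of class `lrw_strategy`.
#' @examples
#' laziness_uniform(1/3)
#' laziness_popdep(c(0.37228, 0))   # p_1, p_2
#' @export
laziness_uniform <- function(p) {
  check_prob(p)
  structure(list(mode = "uniform", p = p), class = "lrw_strategy")
}

#' @rdname laziness_uniform
#' @export
laziness_popdep <- function(p_by_population) {
  vapply(p_by_population, check_prob, logical(1))
  structure(list(mode = "population_dependent",
                 p_by_population = unname(p_by_population)),
            class = "lrw_strategy")
}

check_prob <- function(p) {
  if (is_poly(p)) return(TRUE)  # symbolic parameter, validated on evaluation
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("stay probabilities must be single numbers in [0, 1]")
  TRUE
}

is_strategy <- function(x) inherits(x, "lrw_strategy")

#' @export
print.lrw_strategy <- function(x, ...) {
  if (x$mode == "uniform") {
    cat("<lrw_strategy> uniform laziness p =", format_param(x$p), "\n")
  } else {
    cat("<lrw_strategy> population-dependent laziness:",
        paste0("p_", seq_along(x$p_by_population), " = ",
               vapply(x$p_by_population, format_param, character(1)),
               collapse = ", "), "\n")
  }
  invisible(x)
}

format_param <- function(p) if (is_poly(p)) format(p) else format(p)

#' Stay probability for a given node population
#'
#' @param strategy an `lrw_strategy`.
#' @param population number of agents (>= 1) at the agent's node before the
#'   synchronous move.
#' @return the stay probability (numeric, or a polynomial for symbolic
#'   strategies).
#' @export
effective_stay_prob <- function(strategy, population) {
  stopifnot(is_strategy(strategy), population >= 1, population == round(population))
  if (strategy$mode == "uniform") return(strategy$p)
  k <- as.integer(population)
  if (k > length(strategy$p_by_population))
    stop("population-dependent strategy has no entry for population k = ", k)
  strategy$p_by_population[[k]]
}

# symbolic counterpart: uniform -> variable `var`; population-dependent with
# m populations -> variables var1..varm
symbolic_strategy <- function(mode = c("uniform", "population_dependent"),
                              m = 2L, var = "p") {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    laziness_uniform(poly_var(var))
  } else {
    laziness_popdep(lapply(seq_len(m), function(k) poly_var(paste0(var, k))))
  }
}

#' One-period move kernel of a lazy random walk
#'
#' Probability distribution of the next node for an agent at `node` with a
#' given stay probability: mass `stay_prob` on `node` and
#' `(1 - stay_prob) / degree` on each neighbour.
#'
#' @param g an `lrw_graph`.
#' @param node current node.
#' @param stay_prob stay probability in `[0, 1]` (numeric or polynomial).
#' @return numeric vector of length `n` summing to 1 (numeric input), or a
#'   list of polynomials (symbolic input).
#' @examples
#' g <- build_graph("cycle", 3)
#' step_kernel(g, 1, 1/3)  # uniform over closed neighbourhood
#' @export
step_kernel <- function(g, node, stay_prob) {
  node <- check_node(g, node)
  check_prob(stay_prob)
  nbrs <- g$adjacency[[node]]
  if (length(nbrs) == 0L) { # isolated node (L_1): nowhere to move
    if (is_poly(stay_prob)) {
      out <- rep(list(poly_const(0)), g$n); out[[node]] <- poly_const(1)
      return(out)
    }
    out <- numeric(g$n); out[node] <- 1
    return(out)
  }
  if (is_poly(stay_prob)) {
    out <- rep(list(poly_const(0)), g$n)
    out[[node]] <- stay_prob
    move <- (poly_const(1) - stay_prob) * (1 / length(nbrs))
    for (v in nbrs) out[[v]] <- out[[v]] + move
    return(out)
  }
  out <- numeric(g$n)
  out[node] <- stay_prob
  out[nbrs] <- out[nbrs] + (1 - stay_prob) / length(nbrs)
  out
}

# compact per-agent move options used by the joint expansion: targets and
# weights (weights may be polynomials)
kernel_options <- function(g, node, stay_prob) {
  nbrs <- g$adjacency[[node]]
  deg <- length(nbrs)
  if (deg == 0L) return(list(targets = node, weights = list(1)))
  if (is_poly(stay_prob)) {
    move <- (poly_const(1) - stay_prob) * (1 / deg)
    list(targets = c(node, nbrs),
         weights = c(list(stay_prob), rep(list(move), deg)))
  } else {
    # drop zero-probability options so the joint support stays exact
    w <- c(stay_prob, rep((1 - stay_prob) / deg, deg))
    keep <- w > 0
    list(targets = c(node, nbrs)[keep], weights = as.list(w[keep]))
  }
}
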