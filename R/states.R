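# State spaces for the three goals.
#
# Agents are exchangeable, so a configuration is recorded as an occupancy
# vector [j_1, ..., j_n] (distancing), as the set of occupied nodes after
# sticky coalescence (gathering), or as (searcher positions, hider position)
# for capture. On cycles the dihedral symmetry lumps configurations into
# gap-coordinate classes: the sorted arc lengths between consecutive agents,
# of which the first m - 1 label the class (for three agents this is the
# (j, k) pair of the two closest inter-agent distances).

#' Goal specifications
#'
#' @param D minimum pairwise graph distance required for the distancing goal
#'   (`D = 1`: distinct nodes, i.e. dispersion; `D = 2`: non-adjacent).
#' @param searchers number of searchers in the capture goal.
#' @param labelled if `TRUE`, searchers are distinguishable and the absorbing
#'   classes record which searcher(s) captured the hider (the competitive
#'   game); if `FALSE` searchers are an exchangeable team.
#' @return an object of class `lrw_goal`.
#' @export
goal_distancing <- function(D) {
  stopifnot(length(D) == 1L, D >= 1, D == round(D))
  structure(list(type = "distancing", D = as.integer(D)), class = "lrw_goal")
}

#' @rdname goal_distancing
#' @export
goal_gathering <- function() {
  structure(list(type = "gathering"), class = "lrw_goal")
}

#' @rdname goal_distancing
#' @export
goal_capture <- function(searchers = 2L, labelled = FALSE) {
  stopifnot(searchers >= 1, searchers == round(searchers))
  structure(list(type = "capture", searchers = as.integer(searchers),
                 labelled = isTRUE(labelled)), class = "lrw_goal")
}

#' @export
print.lrw_goal <- function(x, ...) {
  desc <- switch(x$type,
                 distancing = paste0("social distancing, D = ", x$D),
                 gathering = "gathering (sticky multi-rendezvous)",
                 capture = paste0("capture, ", x$searchers,
                                  if (x$labelled) " labelled searchers" else " team searchers"))
  cat("<lrw_goal> ", desc, "\n", sep = "")
  invisible(x)
}

#' Minimum pairwise distance of an occupancy state
#'
#' The distance statistic d of a configuration: the minimum over unordered
#' agent pairs of the graph distance between their nodes, counted with
#' multiplicity (`d = 0` as soon as two agents share a node). Undefined for
#' fewer than two agents.
#'
#' @param s occupancy vector of length `n` (counts per node) summing to the
#'   number of agents `m >= 2`.
#' @param g an `lrw_graph`.
#' @return a nonnegative integer.
#' @examples
#' g <- build_graph("line", 6)
#' min_pairwise_distance(c(1, 0, 0, 1, 0, 1), g)  # 2
#' @export
min_pairwise_distance <- function(s, g) {
  s <- check_occupancy(s, g)
  if (sum(s) < 2L) stop("pairwise distance needs at least two agents")
  if (any(s >= 2L)) return(0L)
  occ <- which(s > 0L)
  min(g$dist[occ, occ][upper.tri(diag(length(occ)))])
}

check_occupancy <- function(s, g) {
  if (length(s) != g$n || any(s < 0) || any(s != round(s)))
    stop("an occupancy state is a vector of ", g$n, " nonnegative counts")
  as.integer(s)
}

# ---- internal state records ----------------------------------------------
# occupancy: integer counts; coalesced: sorted occupied nodes; capture:
# list(searchers = <int vec>, hider = <int>)

state_occupancy <- function(counts) structure(list(counts = as.integer(counts)),
                                              class = c("lrw_state_occ", "lrw_state"))
state_coalesced <- function(occupied) structure(list(occupied = sort(as.integer(occupied))),
                                                class = c("lrw_state_coal", "lrw_state"))
state_capture <- function(searchers, hider, labelled = FALSE) {
  s <- as.integer(searchers)
  if (!labelled) s <- sort(s)
  structure(list(searchers = s, hider = as.integer(hider), labelled = labelled),
            class = c("lrw_state_capture", "lrw_state"))
}

state_key <- function(st) {
  if (inherits(st, "lrw_state_occ")) return(paste0("o", paste(st$counts, collapse = ",")))
  if (inherits(st, "lrw_state_coal")) return(paste0("c", paste(st$occupied, collapse = ",")))
  paste0("s", paste(st$searchers, collapse = ","), ";h", st$hider)
}

#' Test whether a state satisfies the goal
#'
#' @param state an occupancy vector (distancing), a vector of occupied nodes
#'   (gathering), or a `list(searchers =, hider =)` (capture).
#' @param goal an `lrw_goal`.
#' @param g an `lrw_graph`.
#' @return logical: is the state absorbing for this goal?
#' @export
is_absorbing <- function(state, goal, g) {
  st <- coerce_state(state, goal, g)
  state_is_absorbing(st, goal, g)
}

state_is_absorbing <- function(st, goal, g) {
  switch(goal$type,
         distancing = min_pairwise_distance(st$counts, g) >= goal$D,
         gathering = length(st$occupied) == 1L,
         capture = st$hider %in% st$searchers)
}

coerce_state <- function(state, goal, g) {
  if (inherits(state, "lrw_state")) return(state)
  switch(goal$type,
         distancing = state_occupancy(check_occupancy(state, g)),
         gathering = state_coalesced(check_node(g, unique(as.integer(state)))),
         capture = {
           if (!is.list(state) || is.null(state$searchers) || is.null(state$hider))
             stop("a capture state is list(searchers = <nodes>, hider = <node>)")
           state_capture(check_node(g, state$searchers),
                         check_node(g, state$hider), labelled = goal$labelled)
         })
}

# gap coordinates: the sorted arc lengths between consecutive agents on the
# cycle, of which the first m - 1 label the symmetry class. For coalesced
# states the label is padded with leading zeros to the original agent count
# (a merged pair contributes a zero gap).
cycle_gap_label <- function(st, g, m = NULL) {
  n <- g$n
  pos <- sort(switch(class(st)[1L],
                     lrw_state_occ = rep(seq_len(n), st$counts),
                     lrw_state_coal = st$occupied,
                     lrw_state_capture = c(st$searchers, st$hider)))
  m_eff <- length(pos)
  n_coords <- max(1L, (if (is.null(m)) m_eff else m) - 1L)
  gaps <- if (m_eff == 1L) integer(0) else sort(diff(c(pos, pos[1L] + n)))[seq_len(m_eff - 1L)]
  gaps <- c(rep(0L, n_coords - length(gaps)), gaps)
  paste0("(", paste(gaps, collapse = ","), ")")
}

# apply a node permutation to a state
permute_state <- function(st, perm) {
  if (inherits(st, "lrw_state_occ")) {
    counts <- integer(length(st$counts))
    counts[perm] <- st$counts
    return(state_occupancy(counts))
  }
  if (inherits(st, "lrw_state_coal")) return(state_coalesced(perm[st$occupied]))
  state_capture(perm[st$searchers], perm[st$hider], labelled = st$labelled)
}

# canonical representative under the cycle's dihedral group: the image with
# the lexicographically smallest key
canonical_cycle_state <- function(st, g, perms = cycle_automorphisms(g$n)) {
  best <- NULL; best_key <- NULL
  for (perm in perms) {
    img <- permute_state(st, perm)
    key <- state_key(img)
    if (is.null(best_key) || key < best_key) { best <- img; best_key <- key }
  }
  best
}

#' Default state label
#'
#' Occupancy states print in bracket notation `[j1,...,jn]`; coalesced
#' states as the occupied-node set; capture states as `S{..}H{..}`. Lumped
#' cycle states use the gap notation `(j,k)`.
#'
#' @param state a state (as accepted by [is_absorbing()]).
#' @param goal an `lrw_goal`.
#' @param g an `lrw_graph`.
#' @param lumped use the cycle gap notation?
#' @param m original agent count (pads gap labels of coalesced states).
#' @return a string.
#' @export
format_state <- function(state, goal, g, lumped = FALSE, m = NULL) {
  st <- coerce_state(state, goal, g)
  # gap labels are ambiguous for capture states (they ignore who is where),
  # so capture classes keep the canonical S{..}H{..} notation
  if (lumped && !inherits(st, "lrw_state_capture")) return(cycle_gap_label(st, g, m))
  if (inherits(st, "lrw_state_occ"))
    return(paste0("[", paste(st$counts, collapse = ","), "]"))
  if (inherits(st, "lrw_state_coal"))
    return(paste0("{", paste(st$occupied, collapse = ","), "}"))
  paste0("S{", paste(st$searchers, collapse = ","), "}H{", st$hider, "}")
}

# all occupancy vectors of m agents on n nodes (lexicographic)
enumerate_occupancies <- function(n, m) {
  rec <- function(prefix, left, slots) {
    if (slots == 1L) return(list(c(prefix, left)))
    res <- list()
    for (j in 0:left) res <- c(res, rec(c(prefix, j), left - j, slots - 1L))
    res
  }
  lapply(rec(integer(0), m, n), as.integer)
}

# multisets of size k from 1..n (combinations with repetition)
enumerate_multisets <- function(n, k) {
  rec <- function(prefix, low, left) {
    if (left == 0L) return(list(prefix))
    res <- list()
    for (v in low:n) res <- c(res, rec(c(prefix, v), v, left - 1L))
    res
  }
  lapply(rec(integer(0), 1L, k), as.integer)
}

#' Enumerate the state space
#'
#' Lists every state for the goal's representation, deterministically
#' ordered, with the absorbing partition. On cycle graphs (`lump = TRUE`,
#' the default there) states are lumped into dihedral symmetry classes
#' labelled by gap coordinates.
#'
#' @param g an `lrw_graph`.
#' @param m number of agents (for capture: searchers + 1 hider; `m` may be
#'   omitted and defaults to `searchers + 1`).
#' @param goal an `lrw_goal`.
#' @param lump `"auto"` (lump on cycles), `"cycle"` (force; errors off
#'   cycles) or `"none"`.
#' @return an object of class `lrw_state_space`: list with `states` (the
#'   canonical states, transient first), `labels`, `absorbing` (logical),
#'   `lumped`, and `class_sizes` (number of raw states in each class).
#' @examples
#' g <- build_graph("cycle", 5)
#' enumerate_states(g, 3, goal_gathering())
#' @export
enumerate_states <- function(g, m, goal, lump = c("auto", "cycle", "none")) {
  lump <- match.arg(lump)
  if (lump == "cycle" && g$family != "cycle")
    stop("symmetry lumping is only implemented for cycle graphs")
  lumped <- switch(lump, auto = g$family == "cycle", cycle = TRUE, none = FALSE)
  if (goal$type == "capture") m <- goal$searchers + 1L
  stopifnot(m >= 1, m == round(m)); m <- as.integer(m)
  if (goal$type == "distancing" && m < 2L)
    stop("the distancing goal needs at least two agents (d is undefined for one)")

  raw <- switch(goal$type,
    distancing = lapply(enumerate_occupancies(g$n, m), state_occupancy),
    gathering = {
      subs <- unlist(lapply(seq_len(min(m, g$n)), function(k)
        utils::combn(g$n, k, simplify = FALSE)), recursive = FALSE)
      lapply(subs, state_coalesced)
    },
    capture = {
      smulti <- enumerate_multisets(g$n, goal$searchers)
      if (goal$labelled) {
        grid <- expand.grid(rep(list(seq_len(g$n)), goal$searchers + 1L))
        lapply(seq_len(nrow(grid)), function(i)
          state_capture(as.integer(grid[i, seq_len(goal$searchers)]),
                        as.integer(grid[i, goal$searchers + 1L]), labelled = TRUE))
      } else {
        out <- list()
        for (sv in smulti) for (h in seq_len(g$n))
          out <- c(out, list(state_capture(sv, h)))
        out
      }
    })

  class_sizes <- NULL
  if (lumped) {
    perms <- cycle_automorphisms(g$n)
    canon <- lapply(raw, canonical_cycle_state, g = g, perms = perms)
    keys <- vapply(canon, state_key, character(1))
    first <- !duplicated(keys)
    class_sizes <- as.integer(table(factor(keys, levels = keys[first])))
    states <- canon[first]
  } else {
    keys <- vapply(raw, state_key, character(1))
    ord <- order(keys)
    states <- raw[ord]
  }

  absorbing <- vapply(states, state_is_absorbing, logical(1), goal = goal, g = g)
  if (goal$type == "distancing" && !any(absorbing))
    stop("infeasible distancing goal: no state of ", m, " agents on this graph ",
         "attains pairwise distance >= ", goal$D,
         " (the D-independence number is below m)")

  ord <- order(absorbing, vapply(states, state_key, character(1)))
  states <- states[ord]
  absorbing <- absorbing[ord]
  if (!is.null(class_sizes)) class_sizes <- class_sizes[ord]
  labels <- vapply(states, function(st)
    format_state(st, goal, g, lumped = lumped, m = m), character(1))

  structure(list(g = g, m = m, goal = goal, lumped = lumped,
                 states = states, labels = labels, absorbing = absorbing,
                 class_sizes = class_sizes),
            class = "lrw_state_space")
}

#' @export
print.lrw_state_space <- function(x, ...) {
  cat("<lrw_state_space> ", length(x$states), if (x$lumped) " symmetry classes" else " states",
      " (", sum(!x$absorbing), " transient, ", sum(x$absorbing), " absorbing)\n", sep = "")
  cat("  transient: ", paste(x$labels[!x$absorbing], collapse = " "), "\n", sep = "")
  cat("  absorbing: ", paste(x$labels[x$absorbing], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Lump states of a cycle graph by rotation/reflection symmetry
#'
#' Maps each state to its canonical dihedral representative and gap label.
#'
#' @param g a cycle `lrw_graph`.
#' @param states a list of states (as accepted by [is_absorbing()]).
#' @param goal an `lrw_goal` fixing the representation.
#' @param m original agent count (pads gap labels of coalesced states).
#' @return a data.frame with columns `state` (input label), `class` (gap
#'   label of the canonical class) and `canonical` (canonical state label in
#'   raw notation).
#' @export
lump_cycle_states <- function(g, states, goal, m = NULL) {
  if (g$family != "cycle") stop("symmetry lumping is only defined on cycle graphs")
  perms <- cycle_automorphisms(g$n)
  rows <- lapply(states, function(s) {
    st <- coerce_state(s, goal, g)
    can <- canonical_cycle_state(st, g, perms)
    data.frame(state = format_state(st, goal, g),
               class = format_state(can, goal, g, lumped = TRUE, m = m),
               canonical = format_state(can, goal, g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
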