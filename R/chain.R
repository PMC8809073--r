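# Absorbing Markov chain induced by all agents moving synchronously and
# independently. One period: every agent draws its move from its lazy-walk
# kernel (population-dependent laziness evaluated on the pre-move state);
# for the gathering goal co-located agents merge at period end and continue
# as a single agent; for capture goals the hider is caught iff it shares a
# node with a searcher at period end (edge-crossing swaps do not capture).
# Transitions are only computed out of non-absorbing states, so absorbing
# classes admit no exit by construction.

#' Exact joint move distribution of several agents
#'
#' Expands the product of the per-agent one-step kernels: the distribution
#' over raw successor position tuples before any canonicalisation or
#' merging. Weights are numeric, or polynomials when the stay probabilities
#' are symbolic.
#'
#' @param positions integer vector of current agent positions.
#' @param g an `lrw_graph`.
#' @param stay_probs list (or vector) of per-agent stay probabilities.
#' @return list with `configs` (matrix, one row per outcome, one column per
#'   agent) and `probs` (list of weights).
#' @export
joint_move_distribution <- function(positions, g, stay_probs) {
  n_agents <- length(positions)
  if (n_agents > 8L)
    stop("joint move expansion is limited to 8 agents; use simulate_absorption()")
  stopifnot(length(stay_probs) == n_agents)
  if (!is.list(stay_probs)) stay_probs <- as.list(stay_probs)
  opts <- lapply(seq_len(n_agents), function(i)
    kernel_options(g, positions[i], stay_probs[[i]]))
  configs <- matrix(opts[[1L]]$targets, ncol = 1L)
  probs <- opts[[1L]]$weights
  for (i in seq_len(n_agents)[-1L]) {
    ti <- opts[[i]]$targets; wi <- opts[[i]]$weights
    k_old <- nrow(configs); k_new <- length(ti)
    configs <- cbind(configs[rep(seq_len(k_old), times = k_new), , drop = FALSE],
                     rep(ti, each = k_old))
    probs <- lapply(seq_len(k_old * k_new), function(idx) {
      io <- ((idx - 1L) %% k_old) + 1L
      ii <- ((idx - 1L) %/% k_old) + 1L
      probs[[io]] * wi[[ii]]
    })
  }
  list(configs = configs, probs = probs)
}

# agents implied by a state: positions plus per-agent stay probabilities
state_agents <- function(st, goal, strategy) {
  if (inherits(st, "lrw_state_occ")) {
    pos <- rep(seq_along(st$counts), st$counts)
    stay <- lapply(pos, function(v) effective_stay_prob(strategy, st$counts[v]))
    return(list(positions = pos, stay = stay))
  }
  if (inherits(st, "lrw_state_coal")) {
    # merged agents are single agents: population 1
    pos <- st$occupied
    stay <- rep(list(effective_stay_prob(strategy, 1L)), length(pos))
    return(list(positions = pos, stay = stay))
  }
  # capture: strategy is list(searcher = , hider = )
  pos <- c(st$searchers, st$hider)
  stay <- c(rep(list(effective_stay_prob(strategy$searcher, 1L)),
               length(st$searchers)),
            list(effective_stay_prob(strategy$hider, 1L)))
  list(positions = pos, stay = stay)
}

# successor state from a raw configuration
config_to_state <- function(config, st, goal, g) {
  if (goal$type == "distancing")
    return(state_occupancy(tabulate(config, nbins = g$n)))
  if (goal$type == "gathering")
    return(state_coalesced(unique(config)))
  ns <- length(st$searchers)
  state_capture(config[seq_len(ns)], config[ns + 1L], labelled = st$labelled)
}

# absorbing-class key for an absorbing state
absorbing_class_key <- function(st, goal, g, lumped, m = NULL) {
  if (goal$type == "capture" && goal$labelled) {
    winners <- sort(unique(which(st$searchers == st$hider)))
    return(paste0("wins:", paste(winners, collapse = "+")))
  }
  if (lumped) {
    can <- canonical_cycle_state(st, g)
    return(format_state(can, goal, g, lumped = TRUE, m = m))
  }
  switch(goal$type,
         distancing = "distanced",
         gathering = "gathered",
         capture = "captured")
}

normalize_capture_strategy <- function(strategy) {
  if (is_strategy(strategy)) stop("the capture goal needs per-type strategies: ",
                                  "list(searcher = , hider = )")
  stopifnot(is.list(strategy), !is.null(strategy$searcher), !is.null(strategy$hider))
  wrap <- function(x) if (is_strategy(x)) x else laziness_uniform(x)
  list(searcher = wrap(strategy$searcher), hider = wrap(strategy$hider))
}

#' Build the absorbing Markov chain for a goal
#'
#' Enumerates the (optionally symmetry-lumped) state space and computes the
#' exact transition probabilities between non-absorbing states (matrix `B`)
#' and into labelled absorbing classes (matrix `R`). If any stay probability
#' is a polynomial (see [poly_var()] / [symbolic_strategy()]) the matrices
#' are symbolic in those parameters.
#'
#' @param g an `lrw_graph`.
#' @param m number of agents (ignored for capture goals, where it is
#'   `searchers + 1`).
#' @param goal an `lrw_goal`.
#' @param strategy an `lrw_strategy`; for capture goals a
#'   `list(searcher = , hider = )` of strategies (or plain stay
#'   probabilities).
#' @param lump `"auto"` (lump on cycles), `"cycle"`, or `"none"`.
#' @return an object of class `lrw_chain`: `states`/`labels` (transient),
#'   `classes` (absorbing class labels), `B`, `R` (numeric matrices, or
#'   list-matrices of polynomials when symbolic), `symbolic`, `vars`, plus
#'   the inputs.
#' @examples
#' g <- build_graph("cycle", 5)
#' ch <- build_chain(g, 2, goal_distancing(2), laziness_uniform(0))
#' ch$B
#' @export
build_chain <- function(g, m, goal, strategy, lump = c("auto", "cycle", "none")) {
  lump <- match.arg(lump)
  if (goal$type == "capture") strategy <- normalize_capture_strategy(strategy)
  ss <- enumerate_states(g, m, goal, lump = lump)
  transient <- ss$states[!ss$absorbing]
  t_labels <- ss$labels[!ss$absorbing]
  if (length(transient) == 0L)
    stop("every state is absorbing; the chain is trivial")

  class_keys <- vapply(ss$states[ss$absorbing], absorbing_class_key,
                       character(1), goal = goal, g = g, lumped = ss$lumped,
                       m = ss$m)
  classes <- sort(unique(class_keys))

  symbolic <- chain_is_symbolic(strategy, goal)
  N <- length(transient)
  zero <- if (symbolic) list(poly_const(0)) else 0
  B <- if (symbolic) matrix(rep(zero, N * N), N, N) else matrix(0, N, N)
  R <- if (symbolic) matrix(rep(zero, N * length(classes)), N, length(classes))
       else matrix(0, N, length(classes))
  rownames(B) <- t_labels; colnames(B) <- t_labels
  rownames(R) <- t_labels; colnames(R) <- classes

  perms <- if (ss$lumped) cycle_automorphisms(g$n) else NULL
  t_index <- stats::setNames(seq_len(N), vapply(transient, state_key, character(1)))

  for (i in seq_len(N)) {
    ag <- state_agents(transient[[i]], goal, strategy)
    jd <- joint_move_distribution(ag$positions, g, ag$stay)
    for (kk in seq_along(jd$probs)) {
      succ <- config_to_state(jd$configs[kk, ], transient[[i]], goal, g)
      if (ss$lumped) succ <- canonical_cycle_state(succ, g, perms)
      w <- jd$probs[[kk]]
      if (state_is_absorbing(succ, goal, g)) {
        jcl <- match(absorbing_class_key(succ, goal, g, ss$lumped, ss$m), classes)
        if (symbolic) R[[i, jcl]] <- R[[i, jcl]] + w
        else R[i, jcl] <- R[i, jcl] + w
      } else {
        j <- t_index[state_key(succ)]
        if (is.na(j)) stop("internal error: successor state not enumerated")
        if (symbolic) B[[i, j]] <- B[[i, j]] + w
        else B[i, j] <- B[i, j] + w
      }
    }
  }

  chain <- structure(list(states = transient, labels = t_labels,
                          classes = classes, B = B, R = R,
                          symbolic = symbolic,
                          vars = if (symbolic) chain_vars(B, R) else character(0),
                          lumped = ss$lumped, state_space = ss,
                          g = g, m = ss$m, goal = goal, strategy = strategy),
                     class = "lrw_chain")
  validate_chain_rows(chain)
  chain
}

chain_is_symbolic <- function(strategy, goal) {
  vals <- if (goal$type == "capture") {
    c(strategy_params(strategy$searcher), strategy_params(strategy$hider))
  } else strategy_params(strategy)
  any(vapply(vals, is_poly, logical(1)))
}

strategy_params <- function(strategy) {
  if (strategy$mode == "uniform") list(strategy$p) else as.list(strategy$p_by_population)
}

chain_vars <- function(B, R) {
  sort(unique(unlist(lapply(c(B, R), function(e) as_poly(e)$vars))))
}

# every row of [B | R] must sum to exactly 1; never renormalise silently
validate_chain_rows <- function(chain, tol = 1e-12) {
  if (chain$symbolic) {
    for (i in seq_len(nrow(chain$B))) {
      s <- Reduce(poly_add, c(chain$B[i, ], chain$R[i, ]), poly_const(0))
      if (!poly_equal(s, poly_const(1), tol = 1e-9))
        stop("internal consistency failure: symbolic row ", i,
             " of [B | R] sums to ", format(s), " rather than 1")
    }
  } else {
    rs <- rowSums(chain$B) + rowSums(chain$R)
    if (any(abs(rs - 1) > tol) || any(chain$B < -tol) || any(chain$R < -tol))
      stop("internal consistency failure: row sums of [B | R] are ",
           paste(format(rs, digits = 15), collapse = ", "))
  }
  invisible(chain)
}

#' Instantiate a symbolic chain numerically
#'
#' @param chain a symbolic `lrw_chain`.
#' @param vals named numeric vector giving every symbolic parameter, e.g.
#'   `c(p = 0.2)` or `c(h = 0.51, s = 0.28)`.
#' @return a numeric `lrw_chain` with the same states and classes.
#' @export
chain_eval <- function(chain, vals) {
  if (!chain$symbolic) return(chain)
  ev <- function(M) {
    out <- matrix(vapply(M, poly_eval, numeric(1), vals = vals),
                  nrow(M), ncol(M), dimnames = dimnames(M))
    out
  }
  chain$B <- ev(chain$B); chain$R <- ev(chain$R)
  chain$symbolic <- FALSE
  chain$vars <- character(0)
  validate_chain_rows(chain)
  chain
}

#' @export
print.lrw_chain <- function(x, ...) {
  cat("<lrw_chain> ", x$goal$type, " on ", x$g$family, " graph (n = ", x$g$n,
      "), m = ", x$m, if (x$lumped) ", symmetry-lumped" else "",
      if (x$symbolic) paste0(", symbolic in {", paste(x$vars, collapse = ", "), "}") else "",
      "\n", sep = "")
  cat("  transient states: ", paste(x$labels, collapse = " "), "\n", sep = "")
  cat("  absorbing classes: ", paste(x$classes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Export / import a numeric chain as labelled CSV
#'
#' Writes the transient block `B` and exit block `R` side by side with a
#' descriptive header comment; `read_chain_csv()` round-trips the matrices
#' at full double precision.
#'
#' @param chain a numeric `lrw_chain` (symbolic chains: evaluate first).
#' @param path file path.
#' @param header descriptive comment placed on the first line.
#' @return `write_chain_csv()`: `path`, invisibly. `read_chain_csv()`: a
#'   list with `B`, `R`.
#' @export
write_chain_csv <- function(chain, path, header = NULL) {
  if (chain$symbolic)
    stop("symbolic chains cannot round-trip through CSV; use chain_eval() first")
  if (is.null(header))
    header <- paste0("# ", chain$goal$type, " chain on ", chain$g$family,
                     " graph, n = ", chain$g$n, ", m = ", chain$m)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  df <- data.frame(state = chain$labels,
                   stats::setNames(as.data.frame(chain$B),
                                   paste0("B.", colnames(chain$B))),
                   stats::setNames(as.data.frame(chain$R),
                                   paste0("R.", colnames(chain$R))),
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
read_chain_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  bcols <- grep("^B\\.", names(df)); rcols <- grep("^R\\.", names(df))
  B <- as.matrix(df[bcols]); R <- as.matrix(df[rcols])
  rownames(B) <- rownames(R) <- df$state
  colnames(B) <- sub("^B\\.", "", colnames(B))
  colnames(R) <- sub("^R\\.", "", colnames(R))
  list(B = B, R = R)
}
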