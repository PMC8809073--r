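# shared helpers: graphs, symbolic shortcuts, independent mini-oracles

g_cycle <- function(n) build_graph("cycle", n)
g_line <- function(n) build_graph("line", n)

pv <- function(x = "p") poly_var(x)

# absolute-tolerance comparison (testthat's expect_equal tolerance is
# relative, which is the wrong yardstick for values printed to k decimals)
expect_near <- function(actual, expected, tol, label = NULL) {
  if (is.null(label))
    label <- sprintf("|%s - %s|", deparse(substitute(actual)),
                     deparse(substitute(expected)))
  expect_lt(max(abs(actual - expected)), tol, label = label)
}

expect_poly_equal <- function(a, b, tol = 1e-9) {
  expect_true(poly_equal(a, b, tol = tol),
              label = sprintf("polynomials differ: %s vs %s",
                              format(a), format(b)))
}

# independent oracle for the balance quintic root: bisection on the
# hand-derived coefficients
quintic_root <- function() {
  f <- function(s) sum(ref_balance_quintic() * s^(0:5))
  stats::uniroot(f, c(0.01, 0.99), tol = 1e-12)$root
}

# brute-force absorption oracle: simulate the chain's state process directly
# from B/R (independent of the fundamental-matrix solver)
neumann_times <- function(chain, k_max = 4000L) {
  stopifnot(!chain$symbolic)
  acc <- diag(nrow(chain$B))
  pow <- diag(nrow(chain$B))
  for (k in seq_len(k_max)) {
    pow <- pow %*% chain$B
    acc <- acc + pow
  }
  as.numeric(acc %*% rep(1, nrow(chain$B)))
}

# exhaustive labelled-agent chain for distancing/gathering on tiny graphs:
# the test oracle for symmetry lumping (agents carry identities; states are
# position tuples)
labelled_absorption_times <- function(g, m, goal, p) {
  states <- as.matrix(expand.grid(rep(list(seq_len(g$n)), m)))
  key <- apply(states, 1L, paste, collapse = ",")
  absorbing <- apply(states, 1L, function(cfg) {
    if (goal$type == "distancing")
      is_absorbing(tabulate(cfg, nbins = g$n), goal, g)
    else length(unique(cfg)) == 1L
  })
  trans <- which(!absorbing)
  B <- matrix(0, length(trans), length(trans))
  exit <- numeric(length(trans))
  for (a in seq_along(trans)) {
    cfg <- states[trans[a], ]
    if (goal$type == "distancing") {
      # every labelled agent moves independently
      jd <- joint_move_distribution(cfg, g, rep(list(p), m))
      targets <- jd$configs
    } else {
      # sticky gathering: co-located labelled agents move as one; move one
      # representative per occupied node and copy its target
      occ <- unique(cfg)
      jd <- joint_move_distribution(occ, g, rep(list(p), length(occ)))
      targets <- jd$configs[, match(cfg, occ), drop = FALSE]
    }
    for (kk in seq_along(jd$probs)) {
      j <- match(paste(targets[kk, ], collapse = ","), key[trans])
      if (is.na(j)) exit[a] <- exit[a] + jd$probs[[kk]]
      else B[a, j] <- B[a, j] + jd$probs[[kk]]
    }
  }
  t <- solve(diag(length(trans)) - B, rep(1, length(trans)))
  stats::setNames(t, key[trans])
}
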