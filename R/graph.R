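# Graph construction and exact graph distances. igraph does the standard
# work (connectivity, BFS distances); this layer fixes the conventions used
# throughout: 1-based node labels, unit arc lengths, no self-loops, and the
# line / cycle / grid families.

#' Build a walk arena graph
#'
#' Constructs one of the standard graph families, or a custom undirected
#' graph from an edge list. All arcs have length 1; nodes are labelled
#' `1..n`. Grid nodes `(i, j)` (row, column), `1 <= i, j <= k`, are flattened
#' to index `(i - 1) * k + j` and are also addressable through
#' [grid_node()].
#'
#' @param family one of `"line"`, `"cycle"`, `"grid"`, `"custom"`.
#' @param size number of nodes for `"line"`/`"cycle"` (cycle needs `>= 3`),
#'   side length `k >= 2` for `"grid"` (giving `k^2` nodes); ignored for
#'   `"custom"`.
#' @param edges for `"custom"`: a two-column matrix/data.frame of 1-based
#'   node pairs. Duplicate edges collapse; self-loops are rejected (the
#'   "loop" of a loop-random walk lives in the motion rule, not the graph).
#' @return an object of class `lrw_graph` with fields `n`, `adjacency`
#'   (list of neighbour vectors), `degrees`, `family`, `k` (grid side, else
#'   `NA`), and the full integer distance matrix `dist`.
#' @examples
#' g <- build_graph("cycle", 5)
#' graph_distance(g, 1, 4)  # 2
#' @export
build_graph <- function(family = c("line", "cycle", "grid", "custom"),
                        size = NULL, edges = NULL) {
  family <- match.arg(family)
  k <- NA_integer_
  if (family == "custom") {
    if (is.null(edges)) stop("custom graphs need an edge list")
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("edge list must have two columns")
    storage.mode(em) <- "integer"
    if (anyNA(em) || any(em < 1L)) stop("edge list entries must be positive integers")
    if (any(em[, 1L] == em[, 2L]))
      stop("self-loops are not allowed (offending node(s): ",
           paste(unique(em[em[, 1L] == em[, 2L], 1L]), collapse = ", "), ")")
    n <- max(em)
    em <- unique(t(apply(em, 1L, sort)))
    ig <- igraph::graph_from_edgelist(em, directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    comps <- igraph::components(ig)
    if (comps$no > 1L) {
      parts <- split(seq_len(n), comps$membership)
      stop("edge list is disconnected; components: ",
           paste(vapply(parts, function(v)
             paste0("{", paste(v, collapse = ","), "}"), character(1)),
             collapse = " "))
    }
  } else {
    if (is.null(size) || length(size) != 1L || size != round(size))
      stop("size must be a single integer")
    size <- as.integer(size)
    if (family == "line") {
      if (size < 1L) stop("line graphs need at least 1 node")
      ig <- igraph::make_lattice(size)
    } else if (family == "cycle") {
      if (size < 3L) stop("cycle graphs need at least 3 nodes")
      ig <- igraph::make_ring(size)
    } else { # grid
      if (size < 2L) stop("grid graphs need side length k >= 2")
      k <- size
      ig <- igraph::make_lattice(c(size, size))
    }
    n <- igraph::vcount(ig)
  }
  dist <- igraph::distances(ig)
  storage.mode(dist) <- "integer"
  adjacency <- lapply(igraph::as_adj_list(ig), function(v) sort(as.integer(v)))
  structure(list(n = n,
                 adjacency = adjacency,
                 degrees = vapply(adjacency, length, integer(1)),
                 family = family,
                 k = k,
                 dist = dist,
                 igraph = ig),
            class = "lrw_graph")
}

#' @export
print.lrw_graph <- function(x, ...) {
  fam <- switch(x$family,
                line = paste0("line L_", x$n),
                cycle = paste0("cycle C_", x$n),
                grid = paste0("grid GR_", x$k, " (", x$n, " nodes)"),
                paste0("custom graph (", x$n, " nodes)"))
  cat("<lrw_graph> ", fam, ", ", sum(x$degrees) / 2, " edges\n", sep = "")
  invisible(x)
}

check_node <- function(g, v) {
  if (!all(v %in% seq_len(g$n)))
    stop("unknown node(s): ", paste(setdiff(v, seq_len(g$n)), collapse = ", "),
         " (graph has nodes 1..", g$n, ")")
  as.integer(v)
}

#' Graph distance between two nodes
#'
#' Shortest-path length (number of arcs) between `u` and `v`.
#'
#' @param g an `lrw_graph`.
#' @param u,v node indices.
#' @return a nonnegative integer.
#' @export
graph_distance <- function(g, u, v) {
  u <- check_node(g, u); v <- check_node(g, v)
  g$dist[u, v]
}

#' Grid node addressing
#'
#' Converts a `(row, column)` pair on a `k x k` grid graph to its flattened
#' 1-based node index. The corner start is `(1, 1)`; the centre start is
#' `(floor(k/2), floor(k/2))`.
#'
#' @param g a grid `lrw_graph`.
#' @param i,j row and column, `1 <= i, j <= k`.
#' @return integer node index.
#' @export
grid_node <- function(g, i, j) {
  if (g$family != "grid") stop("grid_node() is only defined for grid graphs")
  if (any(c(i, j) < 1) || any(c(i, j) > g$k)) stop("grid coordinates out of range")
  as.integer((i - 1L) * g$k + j)
}

#' Read and write plain-text edge lists
#'
#' The format is one `"u v"` pair per line (whitespace separated, 1-based
#' integers, undirected). The writer emits the sorted canonical form
#' (`u < v`, rows ordered).
#'
#' @param path file path.
#' @return `read_edge_list()` returns an `lrw_graph`;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path) {
  em <- utils::read.table(path, header = FALSE,
                          col.names = c("u", "v"),
                          colClasses = "integer")
  build_graph("custom", edges = as.matrix(em))
}

#' @rdname read_edge_list
#' @param g an `lrw_graph`.
#' @export
write_edge_list <- function(g, path) {
  em <- igraph::as_edgelist(g$igraph)
  em <- t(apply(em, 1L, sort))
  em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  utils::write.table(em, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# dihedral symmetry group of the cycle C_n: perm[v] = image of node v under
# rotation v -> v + r or reflection v -> r - v (mod n), r = 0..n-1
cycle_automorphisms <- function(n) {
  idx <- seq_len(n) - 1L
  perms <- vector("list", 2L * n)
  for (r in 0:(n - 1L)) {
    perms[[r + 1L]] <- ((idx + r) %% n) + 1L
    perms[[n + r + 1L]] <- ((r - idx) %% n) + 1L
  }
  unique(perms)
}
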