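# Network construction and import.
#
# All generators return an `epi_network`: a lightweight adjacency-list
# representation of a simple undirected graph with nodes indexed 1..n.
# igraph does the heavy lifting for the random-graph families; the wrapper
# keeps only what the epidemic code needs (edge arrays and neighbour lists),
# so downstream loops never touch igraph objects.

#' Construct an epi_network from an edge matrix
#'
#' @param n_nodes number of nodes; node indices are 1..n_nodes.
#' @param edges two-column integer matrix of undirected edges (may be empty).
#'   Self-loops and duplicate edges are removed.
#' @param labels optional character vector of external node labels, one per
#'   node, preserved from [read_edge_list()].
#'
#' @return An object of class `epi_network` with elements `n`, `edges`
#'   (deduplicated, each row `i < j`), `adj` (list of integer neighbour
#'   vectors), `src`/`dst` (directed edge arrays, both orientations, used by
#'   the simulator and master equations) and `labels`.
#' @export
epi_network <- function(n_nodes, edges, labels = NULL) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 0)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge endpoint out of range 1..n_nodes")
    # canonical orientation, drop self-loops and duplicates
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    edges <- unique(edges)
  }
  src <- c(edges[, 1], edges[, 2])
  dst <- c(edges[, 2], edges[, 1])
  adj <- vector("list", n_nodes)
  if (length(src) > 0) {
    spl <- split(dst, factor(src, levels = seq_len(n_nodes)))
    adj <- unname(lapply(spl, function(v) sort(as.integer(v))))
  } else {
    adj <- replicate(n_nodes, integer(0), simplify = FALSE)
  }
  structure(
    list(n = n_nodes, edges = edges, adj = adj,
         src = as.integer(src), dst = as.integer(dst), labels = labels),
    class = "epi_network")
}

#' @export
print.epi_network <- function(x, ...) {
  cat(sprintf("epi_network: %d nodes, %d edges, mean degree %.2f\n",
              x$n, nrow(x$edges),
              if (x$n > 0) 2 * nrow(x$edges) / x$n else 0))
  invisible(x)
}

#' Node degrees
#' @param network an `epi_network`.
#' @return integer vector of degrees.
#' @export
degrees <- function(network) {
  unname(lengths(network$adj))
}

as_epi_network <- function(ig, labels = NULL) {
  el <- igraph::as_edgelist(ig, names = FALSE)
  epi_network(igraph::vcount(ig), el, labels = labels)
}

# Run expr with a locally seeded RNG stream; global .Random.seed restored.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Complete b-ary tree
#'
#' Builds the complete tree in which every internal node has `branching`
#' children, down to the given depth. The root is node 1.
#'
#' @param branching number of children per internal node (>= 1).
#' @param depth tree depth (>= 0); depth 0 is a single node.
#' @return an `epi_network` with `sum(branching^(0:depth))` nodes.
#' @examples
#' net <- build_complete_tree(5, 4)   # 781 nodes, 780 edges
#' @export
build_complete_tree <- function(branching, depth) {
  if (length(branching) != 1 || is.na(branching) || branching < 1)
    stop("branching must be a positive integer")
  if (length(depth) != 1 || is.na(depth) || depth < 0)
    stop("depth must be a non-negative integer")
  b <- as.integer(branching)
  n <- sum(b ^ (0:depth))
  if (n == 1) return(epi_network(1L, matrix(integer(0), ncol = 2)))
  as_epi_network(igraph::make_tree(n, children = b, mode = "undirected"))
}

#' Erdős–Rényi random graph
#'
#' G(n, p) with p chosen so the expected mean degree equals `mean_degree`.
#' The whole graph is kept: isolated nodes are legal and simply never get
#' infected.
#'
#' @param n number of nodes (>= 2).
#' @param mean_degree target mean degree, in `[0, n-1]`.
#' @param seed optional integer seed; the same seed yields the same graph.
#' @return an `epi_network`.
#' @export
build_er <- function(n, mean_degree, seed = NULL) {
  if (n < 2) stop("n must be at least 2")
  if (mean_degree < 0 || mean_degree > n - 1)
    stop("mean_degree must lie in [0, n-1]")
  p <- mean_degree / (n - 1)
  with_seed(seed, as_epi_network(igraph::sample_gnp(n, p)))
}

#' Configuration-model graph with a power-law degree distribution
#'
#' Degrees are drawn i.i.d. from P(k) proportional to k^(-gamma) on
#' k = k_min, ..., n-1 (sum forced even), wired by the configuration model,
#' then simplified: self-loops and multi-edges are dropped, the usual
#' convention for sparse scale-free graphs.
#'
#' @param n number of nodes.
#' @param gamma power-law exponent (> 2).
#' @param k_min minimum degree before simplification (>= 1).
#' @param seed optional integer seed.
#' @return an `epi_network`.
#' @export
build_powerlaw_config <- function(n, gamma, k_min = 1, seed = NULL) {
  if (gamma <= 2)
    stop("gamma must exceed 2 (heavier tails have non-normalizable moments)")
  if (k_min < 1) stop("k_min must be >= 1")
  with_seed(seed, {
    ks <- k_min:(n - 1)
    pk <- ks ^ (-gamma)
    deg <- sample(ks, n, replace = TRUE, prob = pk)
    if (sum(deg) %% 2 == 1) deg[which.min(deg)] <- deg[which.min(deg)] + 1L
    ig <- igraph::sample_degseq(deg, method = "configuration")
    as_epi_network(igraph::simplify(ig))
  })
}

#' Random regular graph
#'
#' @param n number of nodes.
#' @param k common degree; `n * k` must be even and `k < n`.
#' @param seed optional integer seed.
#' @return an `epi_network` in which every node has degree exactly `k`.
#' @export
build_random_regular <- function(n, k, seed = NULL) {
  if ((n * k) %% 2 != 0) stop("n * k must be even for a k-regular graph")
  if (k >= n) stop("k must be smaller than n")
  with_seed(seed, as_epi_network(igraph::sample_k_regular(n, k)))
}

#' Read an undirected edge list from a text file
#'
#' Accepts the plain two-tokens-per-line format used by SNAP/KONECT dumps.
#' Lines starting with `#` or `%` are comments. Self-loops and duplicate
#' (including reversed) edges are dropped; node labels are mapped to
#' contiguous indices and kept in `$labels`.
#'
#' @param path path to the edge-list file.
#' @return an `epi_network`; `$labels[i]` is the original label of node `i`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|%)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2)
  if (length(bad) > 0)
    stop(sprintf("malformed edge-list line %d: '%s'", idx[bad[1]],
                 lines[idx[bad[1]]]))
  if (length(toks) == 0)
    return(epi_network(0L, matrix(integer(0), ncol = 2)))
  a <- vapply(toks, `[`, character(1), 1)
  b <- vapply(toks, `[`, character(1), 2)
  labels <- sort(unique(c(a, b)))
  ia <- match(a, labels)
  ib <- match(b, labels)
  epi_network(length(labels), cbind(ia, ib), labels = labels)
}
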