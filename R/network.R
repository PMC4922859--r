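#' Define the node set of a screen
#'
#' A node is a reactant of the reaction-diffusion system: diffusible nodes
#' model secreted molecules (ligands, extracellular inhibitors), while
#' non-diffusible nodes model cell-autonomous components (receptors, kinases,
#' transcription factors) whose diffusion coefficient is exactly zero.
#'
#' @param diffusible logical vector; one entry per node, `TRUE` for
#'   diffusible nodes.
#' @param labels optional character vector of short node names; defaults to
#'   `n1, n2, ...`.
#' @return An object of class `rd_nodes`: a data frame with columns `index`,
#'   `diffusible` and `label`.
#' @examples
#' rd_nodes(c(TRUE, TRUE, FALSE), labels = c("v", "w", "u"))
#' @export
rd_nodes <- function(diffusible, labels = NULL) {
  stopifnot(is.logical(diffusible), length(diffusible) >= 1L, !anyNA(diffusible))
  n <- length(diffusible)
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  out <- data.frame(index = seq_len(n), diffusible = diffusible,
                    label = as.character(labels), stringsAsFactors = FALSE)
  class(out) <- c("rd_nodes", "data.frame")
  out
}

# row-major linear index of Jacobian cell (target i, source j); the cell
# ordering used for enumeration, canonical keys and sign bit strings
cell_index <- function(i, j, n) (i - 1L) * n + j

cell_from_index <- function(idx, n) {
  i <- (idx - 1L) %/% n + 1L
  cbind(target = i, source = idx - (i - 1L) * n)
}

#' Construct an unsigned interaction network
#'
#' A network is a set of `k` ordered regulatory edges over typed nodes.
#' Edge `(i, j)` means "node j regulates node i" and corresponds to the
#' Jacobian cell `J[i, j]`; diagonal cells are self-regulations and count
#' toward `k`.
#'
#' @param nodes an [rd_nodes] object.
#' @param edges a two-column matrix (`target`, `source`) of node indices, or
#'   an integer vector of row-major cell indices in `1..N^2`.
#' @return An object of class `rd_network`.
#' @examples
#' nodes <- rd_nodes(c(TRUE, TRUE))
#' rd_network(nodes, rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2)))
#' @export
rd_network <- function(nodes, edges) {
  stopifnot(inherits(nodes, "rd_nodes"))
  n <- nrow(nodes)
  if (is.matrix(edges)) {
    stopifnot(ncol(edges) == 2L)
    cells <- cell_index(as.integer(edges[, 1L]), as.integer(edges[, 2L]), n)
  } else {
    cells <- as.integer(edges)
  }
  if (anyDuplicated(cells)) stop("duplicate edges are not allowed")
  if (length(cells) && (min(cells) < 1L || max(cells) > n * n))
    stop("edge indices out of range for ", n, " nodes")
  cells <- sort(cells)
  structure(list(nodes = nodes, cells = cells, k = length(cells)),
            class = "rd_network")
}

#' @export
print.rd_network <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("<rd_network> %d nodes (%d diffusible), k = %d\n",
              n, sum(x$nodes$diffusible), x$k))
  cat(format_edges(x), sep = "\n")
  invisible(x)
}

#' Edge-list text form of a network
#'
#' One line per edge, `"i<-j"`, meaning node `j` regulates node `i`.
#'
#' @param net an [rd_network].
#' @param use_labels write node labels instead of indices.
#' @return character vector, one entry per edge.
#' @export
format_edges <- function(net, use_labels = TRUE) {
  ts <- cell_from_index(net$cells, nrow(net$nodes))
  nm <- if (use_labels) net$nodes$label else as.character(net$nodes$index)
  sprintf("%s<-%s", nm[ts[, "target"]], nm[ts[, "source"]])
}

#' Number of candidate networks of size k
#'
#' Closed-form count of the unsigned networks with `k` edges on `N` nodes:
#' the number of k-subsets of the `N x N` Jacobian cells, `choose(N^2, k)`.
#'
#' @param n_nodes number of nodes N.
#' @param k number of regulatory interactions; must satisfy `1 <= k <= N^2`.
#' @return integer-valued numeric.
#' @examples
#' count_networks(3, 6) # 84
#' @export
count_networks <- function(n_nodes, k) {
  stopifnot(length(n_nodes) == 1L, length(k) == 1L)
  n2 <- n_nodes * n_nodes
  if (k < 1 || k > n2)
    stop("k must be between 1 and N*N = ", n2, " (got ", k, ")")
  choose(n2, k)
}

#' Enumerate all candidate networks of size k
#'
#' Yields every k-subset of allowed Jacobian cells that contains all forced
#' edges, each exactly once, in row-major lexicographic order of cell
#' indices (deterministic catalogs).
#'
#' @param nodes an [rd_nodes] object.
#' @param k number of edges.
#' @param forced_edges,forbidden_edges optional edge sets (two-column
#'   matrices or cell-index vectors) that must / must not appear.
#' @return list of [rd_network] objects.
#' @examples
#' length(enumerate_networks(rd_nodes(c(TRUE, TRUE, FALSE)), 6)) # 84
#' @export
enumerate_networks <- function(nodes, k, forced_edges = NULL,
                               forbidden_edges = NULL) {
  stopifnot(inherits(nodes, "rd_nodes"))
  n <- nrow(nodes)
  n2 <- n * n
  if (k < 1 || k > n2)
    stop("k must be between 1 and N*N = ", n2, " (got ", k, ")")
  forced <- as_cells(forced_edges, n)
  forbidden <- as_cells(forbidden_edges, n)
  if (length(intersect(forced, forbidden)))
    stop("forced and forbidden edge sets overlap")
  free <- setdiff(seq_len(n2), union(forced, forbidden))
  need <- k - length(forced)
  if (need < 0L || need > length(free)) {
    warning("infeasible constraints: no network has ", k,
            " edges under the given forced/forbidden sets")
    return(list())
  }
  combos <- if (need == 0L) matrix(integer(0), nrow = 0L, ncol = 1L)
            else utils::combn(free, need)
  lapply(seq_len(ncol(combos)), function(c_i)
    rd_network(nodes, c(forced, combos[, c_i])))
}

as_cells <- function(edges, n) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0L)) return(integer(0))
  if (is.matrix(edges))
    return(sort(cell_index(as.integer(edges[, 1L]), as.integer(edges[, 2L]), n)))
  sort(as.integer(edges))
}

# adjacency matrix A[i, j] = 1 iff edge (i<-j) present
adjacency_matrix <- function(net) {
  n <- nrow(net$nodes)
  a <- matrix(0L, n, n)
  ts <- cell_from_index(net$cells, n)
  a[cbind(ts[, "target"], ts[, "source"])] <- 1L
  a
}

#' Connectivity filter for candidate networks
#'
#' A network passes when the directed graph, with self-loops removed, is
#' strongly connected on all N nodes. This excludes isolated nodes and pure
#' read-out nodes (nodes with no outgoing non-self edge), which cannot take
#' part in any feedback.
#'
#' @param net an [rd_network].
#' @return `TRUE` or `FALSE`.
#' @export
passes_connectivity_filter <- function(net) {
  a <- adjacency_matrix(net)
  diag(a) <- 0L
  n <- nrow(a)
  if (n == 1L) return(TRUE)
  # boolean transitive closure; tiny n so repeated squaring is overkill
  reach <- a > 0L
  for (step in seq_len(n - 1L))
    reach <- reach | ((reach %*% a) > 0L)
  all(reach | diag(TRUE, n))
}

#' Permutations of the nodes that preserve the diffusible classes
#'
#' @param diffusible logical vector of node types.
#' @return list of permutation vectors `p` (node `v` is relabeled `p[v]`).
#' @export
class_permutations <- function(diffusible) {
  n <- length(diffusible)
  perms <- all_permutations(n)
  keep <- vapply(perms, function(p) all(diffusible[p] == diffusible),
                 logical(1L))
  perms[keep]
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    idx <- idx + 1L
    out[[idx]] <- as.integer(append(p, n, after = pos - 1L))
  }
  out
}

# numeric key of an adjacency matrix under a relabeling p: bits of A' where
# A'[p[i], p[j]] = A[i, j], read in row-major order (fits a double exactly
# for N <= 5: 25 bits)
perm_key <- function(a, p) {
  n <- nrow(a)
  inv <- integer(n)
  inv[p] <- seq_len(n)
  ap <- a[inv, inv, drop = FALSE]
  sum(t(ap) * 2^((n * n - 1L):0L))
}

#' Canonical key of a network under class-preserving relabelings
#'
#' Two networks related by a node permutation that maps diffusible nodes to
#' diffusible nodes (and non-diffusible to non-diffusible) are isomorphic
#' and receive identical keys, so isomorphic networks are considered only
#' once in the catalogs. The key is the lexicographically minimal row-major
#' adjacency bit string over all allowed permutations, found by brute-force
#' minimization (N <= 5, at most 120 permutations).
#'
#' @param net an [rd_network].
#' @param perms optional list of allowed permutations (defaults to all
#'   class-preserving ones); constrained screens pass the subset that also
#'   preserves their constraint structure.
#' @return An object of class `canonical_key`: the N^2-bit string, with the
#'   packed numeric key as attribute `value`.
#' @export
canonical_key <- function(net, perms = NULL) {
  a <- adjacency_matrix(net)
  if (is.null(perms)) perms <- class_permutations(net$nodes$diffusible)
  v <- min(vapply(perms, function(p) perm_key(a, p), numeric(1L)))
  n2 <- length(a)
  bits <- as.integer(intToBits(as.integer(v)))[25:1] # low bits, reversed
  key <- paste(bits[(25 - n2 + 1):25], collapse = "")
  structure(key, value = v, class = "canonical_key")
}

#' @export
print.canonical_key <- function(x, ...) {
  cat("<canonical_key>", unclass(x), "\n")
  invisible(x)
}

#' De-duplicate networks up to class-preserving isomorphism
#'
#' Keeps the first representative of each canonical-key class, preserving
#' enumeration order. Idempotent.
#'
#' @param nets list of [rd_network] objects.
#' @param perms see [canonical_key()].
#' @return list of networks, one per isomorphism class, with the canonical
#'   keys attached as attribute `keys`.
#' @export
dedup_networks <- function(nets, perms = NULL) {
  if (!length(nets)) return(nets)
  if (is.null(perms)) perms <- class_permutations(nets[[1L]]$nodes$diffusible)
  keys <- vapply(nets, function(nt) as.character(canonical_key(nt, perms)),
                 character(1L))
  keep <- !duplicated(keys)
  structure(nets[keep], keys = keys[keep])
}

#' Export a network to GraphML or DOT
#'
#' Writes the directed graph with a `diffusible` vertex attribute, for
#' visualization in standard graph tools.
#'
#' @param net an [rd_network].
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  n <- nrow(net$nodes)
  ts <- cell_from_index(net$cells, n)
  g <- igraph::graph_from_edgelist(
    cbind(net$nodes$label[ts[, "source"]], net$nodes$label[ts[, "target"]]),
    directed = TRUE)
  miss <- setdiff(net$nodes$label, igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  dif <- net$nodes$diffusible[match(igraph::V(g)$name, net$nodes$label)]
  # DOT has no boolean attribute type; write 0/1 there
  igraph::V(g)$diffusible <- if (format == "dot") as.integer(dif) else dif
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
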