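#' Construct a hypergraph
#'
#' A hypergraph is a set of \code{n} nodes together with a multiset of
#' hyperedges, each an unordered set of nodes carrying a positive weight
#' (multiplicity). Duplicate hyperedges are merged by summing their weights.
#'
#' @param edges list of integer vectors, each the node indices of one
#'   hyperedge. Node indices must lie in \code{1..n}.
#' @param weights numeric vector of edge weights, recycled to
#'   \code{length(edges)}. Data hyperedges carry positive integer weights;
#'   real-valued weights are permitted when \code{real_weights = TRUE}
#'   (used for projected dyadic graphs).
#' @param n number of nodes. Defaults to the largest index appearing in
#'   \code{edges}.
#' @param node_names optional character vector of external node identifiers
#'   (length \code{n}).
#' @param allow_repeats allow a hyperedge to contain the same node more than
#'   once (a node tuple with repeated nodes, as permitted by the generative
#'   model). Off by default: observed data edges are node sets.
#' @param real_weights allow non-integer edge weights.
#' @return An object of class \code{"hypergraph"} with fields \code{n},
#'   \code{edges} (sorted integer vectors), \code{weights}, \code{sizes},
#'   \code{d} (weighted node degrees) and \code{node_names}.
#' @examples
#' H <- hypergraph(list(c(1, 2), c(1, 2, 3), c(2, 3, 4)))
#' degrees(H)
#' size_counts(H)
#' @export
hypergraph <- function(edges, weights = 1, n = NULL, node_names = NULL,
                       allow_repeats = FALSE, real_weights = FALSE) {
  stopifnot(is.list(edges))
  edges <- lapply(edges, function(e) sort(as.integer(e)))
  weights <- rep_len(as.numeric(weights), length(edges))
  if (length(edges)) {
    if (any(vapply(edges, length, 1L) < 1L)) stop("empty hyperedge")
    mx <- max(vapply(edges, max, 1L), 0L)
  } else mx <- 0L
  if (is.null(n)) n <- mx
  n <- as.integer(n)
  if (mx > n || (length(edges) && min(vapply(edges, min, 1L)) < 1L))
    stop("node index outside [1..n]")
  if (any(weights <= 0)) stop("non-positive edge weight")
  if (!real_weights && any(weights != round(weights)))
    stop("edge weights must be positive integers (set real_weights = TRUE to override)")
  if (!allow_repeats && any(vapply(edges, anyDuplicated, 1L) > 0L))
    stop("hyperedge with repeated node (set allow_repeats = TRUE for model-side tuples)")
  ## merge duplicate hyperedges
  if (length(edges)) {
    key <- vapply(edges, paste, "", collapse = ",")
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      wsum <- rowsum(weights, key)
      edges <- edges[first]
      weights <- as.numeric(wsum[match(key[first], rownames(wsum)), 1L])
    }
  }
  sizes <- vapply(edges, length, 1L)
  d <- numeric(n)
  if (length(edges)) {
    idx <- unlist(edges, use.names = FALSE)
    w <- rep.int(weights, sizes)
    agg <- rowsum(w, idx)
    d[as.integer(rownames(agg))] <- agg[, 1L]
  }
  if (is.null(node_names)) node_names <- as.character(seq_len(n))
  stopifnot(length(node_names) == n)
  structure(list(n = n, edges = edges, weights = weights, sizes = sizes,
                 d = d, node_names = node_names),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("Hypergraph: %d nodes, %d distinct hyperedges (total weight %g)\n",
              x$n, length(x$edges), sum(x$weights)))
  mk <- size_counts(x)
  if (length(mk))
    cat("  edge sizes:",
        paste(sprintf("m_%s=%g", names(mk), mk), collapse = ", "), "\n")
  invisible(x)
}

#' Weighted node degrees
#'
#' The degree of node \code{i} is the weighted number of hyperedges in which
#' it appears (each incidence counted with the edge weight, and with
#' multiplicity for repeated-node tuples).
#'
#' @param H a \code{hypergraph}.
#' @return numeric vector of length \code{H$n}.
#' @export
degrees <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  H$d
}

#' Total volume of a hypergraph
#'
#' \code{vol(H)} is the sum of all node degrees, equal to the weighted number
#' of (node, edge) incidences.
#'
#' @param H a \code{hypergraph}.
#' @export
hg_volume <- function(H) sum(degrees(H))

#' Weighted edge counts by size
#'
#' @param H a \code{hypergraph}.
#' @return named numeric vector: for each observed edge size \code{k}, the
#'   total weight \code{m_k} of size-\code{k} hyperedges.
#' @export
size_counts <- function(H) {
  stopifnot(inherits(H, "hypergraph"))
  if (!length(H$edges)) return(stats::setNames(numeric(0), character(0)))
  agg <- rowsum(H$weights, H$sizes)
  stats::setNames(as.numeric(agg[, 1L]), rownames(agg))
}

#' Largest observed edge size
#' @param H a \code{hypergraph}.
#' @export
max_edge_size <- function(H) if (length(H$sizes)) max(H$sizes) else 0L

#' Per-cluster volumes of a clustering
#'
#' The volume of cluster \code{l} is the sum of degrees of its member nodes.
#' Volumes sum to \code{hg_volume(H)} for any full labelling.
#'
#' @param H a \code{hypergraph}.
#' @param z integer vector of cluster labels, one per node, with labels in
#'   \code{1..max(z)}.
#' @return numeric vector of cluster volumes, indexed by label.
#' @export
cluster_volumes <- function(H, z) {
  z <- check_labels(z, H$n)
  vols <- numeric(max(z))
  agg <- rowsum(degrees(H), z)
  vols[as.integer(rownames(agg))] <- agg[, 1L]
  vols
}

## validate a label vector against n nodes
check_labels <- function(z, n) {
  z <- as.integer(z)
  if (length(z) != n) stop("label vector must cover all nodes")
  if (anyNA(z) || any(z < 1L)) stop("cluster labels must be positive integers")
  z
}

#' Relabel clusters to contiguous 1..l
#'
#' Empty labels are dropped and remaining labels renumbered in order of first
#' appearance of the sorted label set, so the result is a canonical
#' clustering with no empty cluster.
#'
#' @param z integer label vector.
#' @export
compress_labels <- function(z) {
  z <- as.integer(z)
  match(z, sort(unique(z)))
}

#' Extract a subhypergraph on a node subset
#'
#' Keeps the given nodes and every hyperedge all of whose nodes are kept;
#' hyperedges touching a removed node are removed whole.
#'
#' @param H a \code{hypergraph}.
#' @param keep integer or logical index of nodes to keep.
#' @return a \code{hypergraph} on the kept nodes (reindexed; external names
#'   preserved in \code{node_names}).
#' @export
subhypergraph <- function(H, keep) {
  stopifnot(inherits(H, "hypergraph"))
  keep <- seq_len(H$n)[keep]
  map <- rep(NA_integer_, H$n)
  map[keep] <- seq_along(keep)
  ok <- vapply(H$edges, function(e) !anyNA(map[e]), TRUE)
  hypergraph(lapply(H$edges[ok], function(e) map[e]), H$weights[ok],
             n = length(keep), node_names = H$node_names[keep],
             allow_repeats = TRUE, real_weights = TRUE)
}

#' c-core of a hypergraph
#'
#' The c-core is the largest subhypergraph in which every node has degree at
#' least \code{c}. Nodes of degree below \code{c} are removed together with
#' all hyperedges incident to them, iterating to a fixed point; the result is
#' independent of removal order.
#'
#' @param H a \code{hypergraph}.
#' @param c non-negative degree threshold.
#' @return the core as a \code{hypergraph} (possibly with zero nodes).
#' @export
c_core <- function(H, c) {
  stopifnot(inherits(H, "hypergraph"), c >= 0)
  repeat {
    low <- degrees(H) < c
    if (!any(low)) return(H)
    H <- subhypergraph(H, !low)
    if (H$n == 0L) return(H)
  }
}

#' Restrict a hypergraph to edges of bounded size
#'
#' Drops every hyperedge with more than \code{kmax} nodes, leaving the node
#' set unchanged. Used to study how inference responds to the inclusion of
#' progressively larger edges.
#'
#' @param H a \code{hypergraph}.
#' @param kmax maximum edge size to retain (at least 2).
#' @export
restrict_edge_size <- function(H, kmax) {
  stopifnot(inherits(H, "hypergraph"), kmax >= 2)
  ok <- H$sizes <= kmax
  hypergraph(H$edges[ok], H$weights[ok], n = H$n, node_names = H$node_names,
             allow_repeats = TRUE, real_weights = TRUE)
}

## per-node incidence lists: for each node, the ids of edges containing it
incidence_lists <- function(H) {
  inc <- vector("list", H$n)
  if (!length(H$edges)) return(inc)
  eid <- rep.int(seq_along(H$edges), H$sizes)
  node <- unlist(H$edges, use.names = FALSE)
  split(eid, factor(node, levels = seq_len(H$n)))
}
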