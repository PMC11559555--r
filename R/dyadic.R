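#' Clique projection of a hypergraph
#'
#' Replaces every hyperedge of size k by a weighted k-clique among its
#' nodes, accumulating weights over hyperedges. In the normalized variant
#' each of the \code{choose(k, 2)} dyadic edges gets weight
#' \code{a_e / (k - 1)}, so the weighted dyadic degree of every node equals
#' its hypergraph degree exactly; unnormalized, each pair gets the full edge
#' weight \code{a_e}.
#'
#' @param H a \code{hypergraph} with all edges of size at least 2 (and no
#'   repeated nodes within an edge).
#' @param normalized use the degree-preserving \code{1/(k-1)} weighting.
#' @return the projected graph, encoded as a 2-uniform \code{hypergraph}
#'   with real-valued edge weights (usable directly by \code{\link{gmll}}).
#' @examples
#' H <- hypergraph(list(c(1, 2, 3)))
#' clique_project(H)$weights # 1/2 on each of the three pairs
#' @export
clique_project <- function(H, normalized = TRUE) {
  stopifnot(inherits(H, "hypergraph"))
  if (any(H$sizes < 2L)) stop("size-1 edges cannot be projected")
  if (any(vapply(H$edges, anyDuplicated, 1L) > 0L))
    stop("repeated-node tuples cannot be projected")
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (idx in seq_along(H$edges)) {
    e <- H$edges[[idx]]
    k <- length(e)
    prs <- utils::combn(e, 2L)
    w <- if (normalized) H$weights[idx] / (k - 1) else H$weights[idx]
    ii <- c(ii, prs[1L, ]); jj <- c(jj, prs[2L, ])
    ww <- c(ww, rep(w, ncol(prs)))
  }
  key <- paste(ii, jj)
  first <- !duplicated(key)
  wsum <- rowsum(ww, key)
  ii <- ii[first]; jj <- jj[first]
  ww <- as.numeric(wsum[match(key[first], rownames(wsum)), 1L])
  hypergraph(mapply(c, ii, jj, SIMPLIFY = FALSE), ww, n = H$n,
             node_names = H$node_names, real_weights = TRUE)
}

#' Write a weighted dyadic edge list
#'
#' Emits \code{i j w} lines (external node names) for a projected graph.
#'
#' @param G a 2-uniform \code{hypergraph} (e.g. from
#'   \code{\link{clique_project}}).
#' @param con file path or connection; \code{NULL} returns the text.
#' @export
write_weighted_edge_list <- function(G, con = NULL) {
  stopifnot(inherits(G, "hypergraph"), all(G$sizes == 2L))
  body <- vapply(seq_along(G$edges), function(i)
    paste(G$node_names[G$edges[[i]][1L]], G$node_names[G$edges[[i]][2L]],
          format(G$weights[i])), "")
  out <- paste(body, collapse = "\n")
  if (is.null(con)) return(invisible(out))
  writeLines(out, con)
  invisible(out)
}

#' Classical dyadic modularity of a weighted graph
#'
#' \code{Q = sum_l [ int_l / m - (vol_l / (2 m))^2 ]} with \code{m} the total
#' edge weight, \code{int_l} the weight of edges inside cluster l, and
#' \code{vol_l} the weighted-degree volume of cluster l.
#'
#' @param G a 2-uniform \code{hypergraph}.
#' @param z integer label vector.
#' @export
graph_modularity <- function(G, z) {
  stopifnot(inherits(G, "hypergraph"), all(G$sizes == 2L))
  z <- check_labels(z, G$n)
  m <- sum(G$weights)
  if (m == 0) stop("empty graph")
  vols <- cluster_volumes(G, z)
  int_l <- numeric(max(z))
  for (i in seq_along(G$edges)) {
    e <- G$edges[[i]]
    if (z[e[1L]] == z[e[2L]]) int_l[z[e[1L]]] <- int_l[z[e[1L]]] + G$weights[i]
  }
  sum(int_l / m - (vols / (2 * m))^2)
}

#' Graph maximum-likelihood Louvain on a weighted graph
#'
#' The dyadic baseline: alternates graph Louvain with conditional
#' maximum-likelihood estimation of the planted-partition parameters
#' (omega_21, omega_20), i.e. a single adaptively estimated resolution.
#' Implemented as the k = 2 specialization of the AON coordinate ascent,
#' with real-valued projected weights flowing through the cut and volume
#' formulas (a Poisson quasi-likelihood). By default it returns the
#' alternation with the highest planted-partition likelihood;
#' \code{criterion = "modularity"} returns the alternation maximizing the
#' classical dyadic modularity instead.
#'
#' @param G a 2-uniform \code{hypergraph} (typically from
#'   \code{\link{clique_project}}).
#' @param alternations number of Louvain/estimation alternations.
#' @param seed optional integer seed.
#' @param criterion partition selection rule across alternations.
#' @param regularize use the cluster-count penalty.
#' @param z0 optional initial labelling.
#' @param ... further arguments to \code{\link{fit_dchsbm}}.
#' @return a \code{"dchsbm_fit"} object.
#' @export
gmll <- function(G, alternations = 20L, seed = NULL,
                 criterion = c("likelihood", "modularity"),
                 regularize = FALSE, z0 = NULL, ...) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(G, "hypergraph"))
  if (!length(G$edges)) stop("empty graph")
  if (any(G$sizes != 2L)) stop("gmll expects a 2-uniform (projected) graph")
  fit <- fit_dchsbm(G, family = "aon", alternations = alternations,
                    z0 = z0, regularize = regularize, seed = seed, kmax = 2L,
                    keep_partitions = (criterion == "modularity"), ...)
  if (criterion == "modularity") {
    qs <- vapply(fit$partitions, function(z) graph_modularity(G, z), 0)
    ibest <- which.max(qs)
    fit$labels <- fit$partitions[[ibest]]
    fit$best_alternation <- ibest
    fit$loglik <- fit$trace$loglik[ibest]
    fit$score <- qs[ibest]
    fit$affinity <- estimate_omega(G, fit$labels, "aon", kmax = 2L)
    fit$aon <- tryCatch(aon_params(fit$affinity), error = function(e) NULL)
  }
  fit$settings$criterion <- criterion
  fit
}
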