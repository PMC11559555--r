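## ---- generalized volumes -------------------------------------------------

## Sum over ordered tuples of t *distinct* clusters of prod vol^(e_j),
## from power sums S[q] = sum_l vol_l^q. Inclusion-exclusion recursion:
## D(e) = S[e1] D(e[-1]) - sum_j D(e[-1] with e_j += e1).
distinct_tuple_sum <- function(S, e) {
  t <- length(e)
  if (t == 0L) return(1)
  if (t == 1L) return(S[e])
  acc <- S[e[1]] * distinct_tuple_sum(S, e[-1])
  for (j in 2:t) {
    e2 <- e[-1]
    e2[j - 1L] <- e2[j - 1L] + e[1]
    acc <- acc - distinct_tuple_sum(S, e2)
  }
  acc
}

power_sums <- function(vols, kmax) {
  vapply(seq_len(kmax), function(q) sum(vols^q), 0)
}

## ordered-tuple volume from power sums: (k! / prod p_j!) orderings per
## label multiset, divided by prod mult! for permutations of equal parts
## among distinct clusters.
vol_p_from_powersums <- function(S, p) {
  p <- as.integer(p)
  k <- sum(p)
  mult <- exp(lgamma(k + 1) - sum(lgamma(p + 1))) / prod(factorial(table(p)))
  mult * distinct_tuple_sum(S, p)
}

#' Generalized volume of a partition vector
#'
#' \code{vol_p} is the sum, over all ordered tuples of \code{sum(p)} cluster
#' labels whose partition vector equals \code{p}, of the product of cluster
#' volumes. It is evaluated from the power sums of the cluster volumes via
#' an inclusion-exclusion identity, never by enumerating the label tuples,
#' so the cost depends on the number of parts of \code{p} but not on the
#' number of clusters.
#'
#' @param vols numeric vector of per-cluster volumes.
#' @param p a partition vector (non-increasing positive integers).
#' @return a non-negative real. Summing over all partitions of \code{k}
#'   gives \code{sum(vols)^k}.
#' @examples
#' vol_p(c(7, 1), c(3))    # 344
#' vol_p(c(7, 1), c(2, 1)) # 168
#' @export
vol_p <- function(vols, p) {
  p <- as.integer(p)
  if (any(diff(p) > 0L) || any(p < 1L)) stop("p must be non-increasing positive")
  ## more parts than clusters with positive volume: structurally zero
  if (length(p) > sum(vols > 0)) return(0)
  vol_p_from_powersums(power_sums(vols, sum(p)), p)
}

#' Update a generalized volume after a single move
#'
#' Recomputes \code{vol_p} after moving a node (or node set) of total degree
#' \code{d} from cluster \code{from} to cluster \code{to}, by updating the
#' volume power sums in O(k) — the cost is independent of the number of
#' nodes and clusters. Equals recomputing \code{\link{vol_p}} from the
#' updated volume vector.
#'
#' @param vols per-cluster volumes before the move.
#' @param p partition vector.
#' @param d degree mass moved.
#' @param from,to source and target cluster indices.
#' @export
vol_p_update <- function(vols, p, d, from, to) {
  k <- sum(p)
  vols2 <- vols
  vols2[from] <- vols2[from] - d
  vols2[to] <- vols2[to] + d
  if (length(p) > sum(vols2 > 0)) return(0)
  q <- seq_len(k)
  S <- power_sums(vols, k)
  S <- S - vols[from]^q - vols[to]^q + (vols[from] - d)^q + (vols[to] + d)^q
  vol_p_from_powersums(S, p)
}

## total expected edge mass sum_p vol_p(z) * Omega(p) over sizes 2..kmax
edge_mass <- function(vols, aff) {
  S <- power_sums(vols, aff$kmax)
  acc <- 0
  for (k in 2:aff$kmax) {
    for (p in integer_partitions(k)) {
      w <- omega_value(aff, p)
      if (w != 0) acc <- acc + w * vol_p_from_powersums(S, p)
    }
  }
  acc
}

## ---- generalized cuts ----------------------------------------------------

#' Generalized cut of a partition vector
#'
#' Weighted count of size-\code{sum(p)} hyperedges whose label composition
#' under \code{z} has partition vector exactly \code{p}.
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector.
#' @param p partition vector.
#' @export
cut_p <- function(H, z, p) {
  z <- check_labels(z, H$n)
  p <- as.integer(p)
  k <- sum(p)
  sel <- which(H$sizes == k)
  if (!length(sel)) return(0)
  acc <- 0
  for (i in sel) {
    if (identical(partition_vector(z[H$edges[[i]]]), p))
      acc <- acc + H$weights[i]
  }
  acc
}

## weighted edge counts per partition-vector key
cut_table <- function(H, z) {
  z <- check_labels(z, H$n)
  if (!length(H$edges)) return(numeric(0))
  keys <- vapply(seq_along(H$edges), function(i)
    p_key(partition_vector(z[H$edges[[i]]])), "")
  agg <- rowsum(H$weights, keys)
  stats::setNames(as.numeric(agg[, 1L]), rownames(agg))
}

#' All-or-nothing cut at a given edge size
#'
#' The weighted number of size-\code{k} hyperedges containing nodes from two
#' or more distinct clusters: \code{m_k} minus the weight of size-k edges
#' fully inside one cluster.
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector.
#' @param k edge size.
#' @export
cut_k <- function(H, z, k) {
  z <- check_labels(z, H$n)
  sel <- which(H$sizes == k)
  if (!length(sel)) return(0)
  internal <- vapply(sel, function(i) {
    zr <- z[H$edges[[i]]]
    all(zr == zr[1L])
  }, TRUE)
  sum(H$weights[sel]) - sum(H$weights[sel][internal])
}

## ---- objectives ----------------------------------------------------------

#' Symmetric hypergraph modularity
#'
#' The label-dependent part of the DCHSBM log-likelihood under a symmetric
#' affinity function, written over partition vectors:
#' \code{Q = sum_p [ cut_p log Omega(p) - vol_p Omega(p) ]},
#' with the convention \code{0 * log 0 = 0}. Returns \code{-Inf} when some
#' observed edge has a zero-affinity pattern.
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector.
#' @param aff an \code{hg_affinity} with \code{kmax >= max_edge_size(H)}.
#' @return scalar modularity Q.
#' @export
symmetric_modularity <- function(H, z, aff) {
  stopifnot(inherits(aff, "hg_affinity"))
  if (max_edge_size(H) > aff$kmax) stop("hypergraph has edges larger than aff$kmax")
  z <- check_labels(z, H$n)
  cuts <- cut_table(H, z)
  qcut <- 0
  for (key in names(cuts)) {
    w <- omega_value(aff, p_unkey(key))
    if (w == 0) return(-Inf)
    qcut <- qcut + cuts[[key]] * log(w)
  }
  qcut - edge_mass(cluster_volumes(H, z), aff)
}

#' All-or-nothing hypergraph modularity
#'
#' The AON specialization of the symmetric modularity, up to the
#' z-independent constant J(omega):
#' \code{Q = - sum_k beta_k [ cut_k + gamma_k * sum_l vol(l)^k ]}.
#' Differences of this objective across partitions equal the corresponding
#' symmetric-modularity differences under the matching AON affinity.
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector.
#' @param params an \code{aon_params} (or anything with \code{sizes},
#'   \code{beta}, \code{gamma}); must cover every observed edge size.
#' @param n_reg if non-NULL, subtract the cluster-count penalty
#'   \code{n_reg * log(lbar)} (Bayesian regularization).
#' @export
aon_modularity <- function(H, z, params, n_reg = NULL) {
  z <- check_labels(z, H$n)
  sizes <- params$sizes
  obs <- as.integer(names(size_counts(H)))
  if (length(setdiff(obs, sizes)))
    stop("params missing beta/gamma for some observed edge size")
  vols <- cluster_volumes(H, z)
  acc <- 0
  for (j in seq_along(sizes)) {
    k <- sizes[j]
    acc <- acc - params$beta[j] * (cut_k(H, z, k) + params$gamma[j] * sum(vols^k))
  }
  if (!is.null(n_reg)) acc <- acc - n_reg * log(length(unique(z)))
  unname(acc)
}

## log of the number of distinct orderings of a tuple (multinomial coeff)
log_orderings <- function(e) {
  lgamma(length(e) + 1) - sum(lgamma(tabulate(match(e, unique(e))) + 1))
}

#' DCHSBM log-likelihood decomposition
#'
#' Splits the Poisson log-likelihood of an integer-weighted hypergraph under
#' the degree-corrected hypergraph stochastic blockmodel into
#' \code{L = Q + K + C}: the modularity term Q (depends on z and Omega), the
#' degree term \code{K = sum_i d_i log theta_i}, and the data constant
#' \code{C = sum_R [a_R log b_R - log a_R!]} with \code{b_R} the number of
#' distinct orderings of the tuple R. The expected-mass part of Q is summed
#' in closed form over all node tuples (including repeated-node tuples) via
#' the generalized volume identities.
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector.
#' @param aff an \code{hg_affinity}.
#' @param theta degree parameters (default: \code{degrees(H)}, the
#'   conditional ML estimate). Must be non-negative.
#' @return object of class \code{"hg_loglik"}: list with \code{L}, \code{Q},
#'   \code{K}, \code{C}. \code{L} is \code{-Inf} when an observed edge has a
#'   zero rate.
#' @export
dchsbm_loglik <- function(H, z, aff, theta = NULL) {
  stopifnot(inherits(aff, "hg_affinity"))
  z <- check_labels(z, H$n)
  if (is.null(theta)) theta <- degrees(H)
  if (length(theta) != H$n || any(theta < 0)) stop("invalid theta")
  ## Q: observed-edge term + expectation over all tuples with theta-volumes
  cuts <- cut_table(H, z)
  qcut <- 0
  for (key in names(cuts)) {
    w <- omega_value(aff, p_unkey(key))
    qcut <- qcut + if (w == 0) -Inf else cuts[[key]] * log(w)
  }
  tvols <- numeric(max(z))
  agg <- rowsum(theta, z)
  tvols[as.integer(rownames(agg))] <- agg[, 1L]
  Q <- qcut - edge_mass(tvols, aff)
  d <- degrees(H)
  K <- sum(ifelse(d == 0, 0, d * log(theta)))
  C <- if (length(H$edges))
    sum(H$weights * vapply(H$edges, log_orderings, 0) - lgamma(H$weights + 1))
  else 0
  structure(list(L = unname(Q + K + C), Q = unname(Q), K = unname(K),
                 C = unname(C)), class = "hg_loglik")
}

#' @export
print.hg_loglik <- function(x, ...) {
  cat(sprintf("DCHSBM log-likelihood: L = %.6g (Q = %.6g, K = %.6g, C = %.6g)\n",
              x$L, x$Q, x$K, x$C))
  invisible(x)
}
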