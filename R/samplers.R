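## evaluate expr with a temporarily seeded RNG, restoring the caller's state
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Sample a hypergraph from the DCHSBM
#'
#' Draws a hypergraph exactly from the degree-corrected hypergraph
#' stochastic blockmodel: the weight of each unordered node tuple R is
#' Poisson with rate \code{b_R * prod(theta[R]) * Omega(z[R])}, where
#' \code{b_R} counts the distinct orderings of R. Sampling is grouped by
#' (edge size, affinity class): a Poisson total is drawn from the closed-form
#' class rate, and each edge is then placed by i.i.d. node draws with
#' probability proportional to theta, rejecting tuples outside the class.
#' No enumeration over node tuples is performed.
#'
#' @param z integer label vector (defines \code{n = length(z)}).
#' @param theta non-negative degree parameters, one per node.
#' @param aff an \code{hg_affinity}; tuples of sizes 2..\code{aff$kmax}
#'   are generated.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param allow_repeats if \code{TRUE} (the model's convention) node tuples
#'   may contain repeated nodes; if \code{FALSE} the sample is restricted to
#'   distinct-node edges (the weight of each distinct tuple keeps its exact
#'   Poisson law).
#' @return a \code{hypergraph} (weights are the sampled tuple counts).
#' @export
sample_dchsbm <- function(z, theta, aff, seed = NULL, allow_repeats = TRUE) {
  stopifnot(inherits(aff, "hg_affinity"), length(theta) == length(z),
            all(theta >= 0))
  z <- check_labels(z, length(z))
  n <- length(z)
  tvols <- numeric(max(z))
  agg <- rowsum(theta, z)
  tvols[as.integer(rownames(agg))] <- agg[, 1L]
  S <- power_sums(tvols, aff$kmax)
  ## closed-form rate per (size, class)
  rates <- new.env(parent = emptyenv())
  for (k in 2:aff$kmax) {
    for (p in integer_partitions(k)) {
      key <- affinity_class(aff$family, p, aff$kmax)
      w <- omega_value(aff, p)
      if (w > 0) {
        rates[[key]] <- (if (is.null(rates[[key]])) 0 else rates[[key]]) +
          w * vol_p_from_powersums(S, p)
      }
    }
  }
  with_rng(seed, {
    edges <- list()
    for (key in ls(rates)) {
      k <- as.integer(sub(":.*", "", key))
      total <- stats::rpois(1L, rates[[key]])
      if (total == 0L) next
      got <- 0L
      guard <- 0L
      while (got < total) {
        guard <- guard + 1L
        if (guard > 10000L) stop("rejection sampling failed to place edges (class ", key, ")")
        batch <- min(50000L, max(256L, 4L * (total - got)))
        draws <- matrix(sample.int(n, batch * k, replace = TRUE, prob = theta),
                        nrow = k)
        for (j in seq_len(batch)) {
          tup <- draws[, j]
          if (!allow_repeats && anyDuplicated(tup)) next
          ck <- affinity_class(aff$family, partition_vector(z[tup]), aff$kmax)
          if (ck == key) {
            got <- got + 1L
            edges[[length(edges) + 1L]] <- tup
            if (got == total) break
          }
        }
      }
    }
    hypergraph(edges, 1, n = n, allow_repeats = TRUE)
  })
}

#' Two-block planted-partition hypergraph generator
#'
#' Generates a hypergraph on two equal-sized communities, the synthetic
#' design used for the detectability experiments: each node is incident on
#' average to \code{c2} 2-edges and \code{c3} 3-edges; a fraction \code{p_k}
#' of size-k edges joins nodes within one community (chosen uniformly), the
#' rest join nodes spanning both communities (uniform over spanning k-sets).
#' Per-size edge counts are Poisson with mean \code{n * c_k / k}.
#'
#' @param n number of nodes (even; default 500, two communities of 250).
#' @param p2,p3 within-community fractions for 2- and 3-edges, in [0, 1].
#' @param c2,c3 mean per-node 2- and 3-degrees (default 5 each).
#' @param seed optional integer seed.
#' @return list with \code{H} (the \code{hypergraph}) and \code{z} (the true
#'   labels, 1 and 2).
#' @export
sample_two_block <- function(n = 500, p2 = 0.5, p3 = 0.5, c2 = 5, c3 = 5,
                             seed = NULL) {
  stopifnot(n %% 2 == 0, p2 >= 0, p2 <= 1, p3 >= 0, p3 <= 1)
  half <- n %/% 2L
  if (half < 3L) stop("community smaller than the largest edge size")
  z <- rep(1:2, each = half)
  comm <- list(seq_len(half), half + seq_len(half))
  with_rng(seed, {
    edges <- list()
    for (k in 2:3) {
      ck <- if (k == 2L) c2 else c3
      pk <- if (k == 2L) p2 else p3
      m <- stats::rpois(1L, n * ck / k)
      if (m == 0L) next
      within <- stats::runif(m) < pk
      for (e in seq_len(m)) {
        if (within[e]) {
          cc <- comm[[sample.int(2L, 1L)]]
          edges[[length(edges) + 1L]] <- cc[sample.int(half, k)]
        } else {
          repeat {
            tup <- sample.int(n, k)
            if (length(unique(z[tup])) > 1L) break
          }
          edges[[length(edges) + 1L]] <- tup
        }
      }
    }
    list(H = hypergraph(edges, 1, n = n), z = z)
  })
}

#' Runtime-testbed hypergraph generator
#'
#' A blockmodel-like benchmark with \code{n/200} equal clusters of 200 nodes
#' and exactly \code{m = 10n} hyperedges. Each edge size k is uniform on
#' \{2, 3, 4\}; with probability \code{p_k} the edge is placed uniformly on
#' k distinct nodes inside one uniformly chosen cluster, otherwise uniformly
#' on k distinct nodes among all n.
#'
#' @param n number of nodes, a multiple of 200.
#' @param p2,p3,p4 within-cluster placement probabilities per edge size.
#'   \code{fig1 = TRUE} overrides them with the benchmark regime
#'   \code{p2 = 3/5, p3 = 1/n^3, p4 = 1/n^4}.
#' @param fig1 use the sparse-large-edge benchmark regime.
#' @param seed optional integer seed.
#' @return list with \code{H} and true labels \code{z}.
#' @export
sample_runtime_testbed <- function(n, p2 = 3 / 5, p3 = NULL, p4 = NULL,
                                   fig1 = FALSE, seed = NULL) {
  if (n < 200 || n %% 200 != 0) stop("n must be a positive multiple of 200")
  if (fig1 || is.null(p3)) p3 <- 1 / n^3
  if (fig1 || is.null(p4)) p4 <- 1 / n^4
  if (fig1) p2 <- 3 / 5
  lbar <- n %/% 200L
  z <- rep(seq_len(lbar), each = 200L)
  clusters <- split(seq_len(n), z)
  pk <- c(`2` = p2, `3` = p3, `4` = p4)
  m <- 10L * n
  with_rng(seed, {
    ks <- sample(2:4, m, replace = TRUE)
    within <- stats::runif(m) < pk[as.character(ks)]
    cl <- sample.int(lbar, m, replace = TRUE)
    edges <- vector("list", m)
    for (e in seq_len(m)) {
      edges[[e]] <- if (within[e]) clusters[[cl[e]]][sample.int(200L, ks[e])]
                    else sample.int(n, ks[e])
    }
    list(H = hypergraph(edges, 1, n = n), z = z)
  })
}

#' Planted-partition detectability signal
#'
#' For a two-block dyadic planted partition with mean within-cluster degree
#' \code{ci} and mean between-cluster degree \code{co}, community detection
#' is information-theoretically possible in the large-graph limit only when
#' \code{(ci - co)^2 / (2 (ci + co)) >= 1}.
#'
#' @param ci,co mean within- and between-cluster dyadic degrees.
#' @return the signal value; compare to 1.
#' @examples
#' detectability_threshold(8, 2) # 1.8: above threshold
#' @export
detectability_threshold <- function(ci, co) {
  if (any(ci < 0) || any(co < 0)) stop("degrees must be non-negative")
  if (any(ci + co == 0)) stop("ci + co must be positive")
  (ci - co)^2 / (2 * (ci + co))
}
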