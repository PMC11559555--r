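## Shared fixtures and independent brute-force oracles.

## toy hypergraph: edges {1,2}, {1,2,3}, {2,3,4}; degrees (2,3,2,1)
toy_t1 <- function() hypergraph(list(c(1, 2), c(1, 2, 3), c(2, 3, 4)))

## random small integer-weighted hypergraph (edges with distinct nodes)
rand_hypergraph <- function(n, m, kmax = 3, seed = 1) {
  set.seed(seed)
  ks <- 2:kmax
  edges <- lapply(seq_len(m), function(i)
    sample.int(n, ks[sample.int(length(ks), 1)]))
  hypergraph(edges, weights = sample(1:3, m, replace = TRUE), n = n)
}

rand_labels <- function(n, lbar, seed = 1) {
  set.seed(seed)
  compress_labels(c(seq_len(lbar), sample.int(lbar, n - lbar, replace = TRUE)))
}

## all multisets of size k over 1..n, as a list of sorted vectors
all_multisets <- function(n, k) {
  combs <- utils::combn(n + k - 1, k)
  lapply(seq_len(ncol(combs)), function(j) combs[, j] - seq_len(k) + 1L)
}

## brute-force generalized volume: enumerate all ordered label tuples
bf_vol_p <- function(vols, p) {
  k <- sum(p)
  l <- length(vols)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(l)), k)))
  tot <- 0
  for (r in seq_len(nrow(tuples))) {
    y <- tuples[r, ]
    if (identical(partition_vector(y), as.integer(sort(p, decreasing = TRUE))))
      tot <- tot + prod(vols[y])
  }
  tot
}

## brute-force DCHSBM log-likelihood: sum Poisson log-probabilities over
## every node multiset of the sizes covered by the affinity
bf_loglik <- function(H, z, aff, theta = NULL) {
  if (is.null(theta)) theta <- degrees(H)
  keyw <- new.env(parent = emptyenv())
  for (i in seq_along(H$edges))
    keyw[[paste(H$edges[[i]], collapse = ",")]] <- H$weights[i]
  tot <- 0
  for (k in 2:aff$kmax) {
    for (R in all_multisets(H$n, k)) {
      key <- paste(R, collapse = ",")
      a <- if (is.null(keyw[[key]])) 0 else keyw[[key]]
      b <- exp(lgamma(k + 1) - sum(lgamma(tabulate(match(R, unique(R))) + 1)))
      rate <- b * prod(theta[R]) * omega_value(aff, partition_vector(z[R]))
      tot <- tot + if (a == 0) -rate else (-rate + a * log(rate) - lgamma(a + 1))
    }
  }
  tot
}

## brute-force modularity term (observed-edge term minus expected mass over
## all multisets), i.e. the Q of the likelihood decomposition
bf_modularity <- function(H, z, aff, theta = NULL) {
  if (is.null(theta)) theta <- degrees(H)
  qcut <- 0
  for (i in seq_along(H$edges)) {
    w <- omega_value(aff, partition_vector(z[H$edges[[i]]]))
    qcut <- qcut + if (w == 0) -Inf else H$weights[i] * log(w)
  }
  emass <- 0
  for (k in 2:aff$kmax) {
    for (R in all_multisets(H$n, k)) {
      b <- exp(lgamma(k + 1) - sum(lgamma(tabulate(match(R, unique(R))) + 1)))
      emass <- emass + b * prod(theta[R]) * omega_value(aff, partition_vector(z[R]))
    }
  }
  qcut - emass
}

## all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(z, mx) {
    i <- length(z) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- z
      return(invisible())
    }
    for (lab in seq_len(mx + 1L)) rec(c(z, lab), max(mx, lab))
  }
  rec(integer(0), 0L)
  out
}

## a small assortative AON affinity for inference tests
test_aon_affinity <- function(kmax = 3, within = 1, cross = 0.01) {
  keys <- c(paste0(2:kmax, ":1"), paste0(2:kmax, ":0"))
  affinity("aon", stats::setNames(c(rep(within, kmax - 1), rep(cross, kmax - 1)),
                                  keys), kmax)
}
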