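test_that("generalized volumes match brute-force enumeration and conserve mass", {
  expect_equal(vol_p(c(7, 1), 3), 344)
  expect_equal(vol_p(c(7, 1), c(2, 1)), 168)
  expect_equal(344 + 168, 8^3)
  set.seed(3)
  for (l in 2:4) {
    vols <- round(runif(l, 1, 9), 2)
    for (k in 2:4) {
      for (p in hyperlouvain:::integer_partitions(k)) {
        expect_equal(vol_p(vols, p), bf_vol_p(vols, p), tolerance = 1e-10)
      }
      tot <- sum(vapply(hyperlouvain:::integer_partitions(k),
                        function(p) vol_p(vols, p), 0))
      expect_equal(tot, sum(vols)^k, tolerance = 1e-10)
    }
  }
})

test_that("volume updates equal recomputation from moved volumes", {
  expect_equal(vol_p_update(c(7, 1), 2, d = 1, from = 1, to = 2), 6^2 + 2^2)
  set.seed(4)
  vols <- c(5, 3, 2)
  for (p in list(2L, c(1L, 1L), 3L, c(2L, 1L), c(1L, 1L, 1L))) {
    upd <- vol_p_update(vols, p, d = 1.5, from = 1, to = 3)
    vols2 <- vols + c(-1.5, 0, 1.5)
    expect_equal(upd, vol_p(vols2, p), tolerance = 1e-10)
    ## degree-0 move changes nothing
    expect_equal(vol_p_update(vols, p, d = 0, from = 2, to = 1), vol_p(vols, p))
  }
})

test_that("generalized cuts count edges by split pattern", {
  H <- toy_t1()
  z <- c(1, 1, 1, 2)
  expect_equal(cut_p(H, z, c(2, 1)), 1)
  expect_equal(cut_p(H, z, 3), 1)
  expect_equal(cut_p(H, z, 2), 1)
  ## every edge contributes to exactly one pattern
  for (k in 2:3) {
    tot <- sum(vapply(hyperlouvain:::integer_partitions(k),
                      function(p) cut_p(H, z, p), 0))
    expect_equal(tot, unname(size_counts(H)[as.character(k)]))
  }
})

test_that("all-or-nothing cuts count multi-cluster edges", {
  H <- toy_t1()
  z <- c(1, 1, 1, 2)
  expect_equal(cut_k(H, z, 2), 0)
  expect_equal(cut_k(H, z, 3), 1)
  expect_equal(cut_k(H, rep(1, 4), 2), 0)
  expect_equal(cut_k(H, rep(1, 4), 3), 0)
  expect_equal(cut_k(H, 1:4, 2), 1)
  expect_equal(cut_k(H, 1:4, 3), 2)
})

test_that("symmetric modularity equals its brute-force definition", {
  H <- toy_t1()
  z <- c(1, 1, 1, 2)
  aff <- estimate_omega(H, z, "aon")
  expect_equal(symmetric_modularity(H, z, aff), dchsbm_loglik(H, z, aff)$Q)
  ## uniform affinity: Q reduces to minus the total expected mass
  unif <- affinity("custom", stats::setNames(
    rep(1, 5), vapply(c(hyperlouvain:::integer_partitions(2),
                        hyperlouvain:::integer_partitions(3)),
                      function(p) paste(p, collapse = "|"), "")), 3)
  expect_equal(symmetric_modularity(H, z, unif), -(8^2 + 8^3))
  expect_equal(symmetric_modularity(H, z, unif), bf_modularity(H, z, unif),
               tolerance = 1e-10)
  ## labels with an unused value do not change Q once compressed
  expect_equal(symmetric_modularity(H, compress_labels(c(1, 1, 1, 5)), aff),
               symmetric_modularity(H, z, aff))
})

test_that("likelihood decomposition matches brute-force tuple summation", {
  for (seed in 1:6) {
    H <- rand_hypergraph(5, 6, kmax = 3, seed = seed)
    z <- rand_labels(5, 2, seed)
    aff <- estimate_omega(H, z, "aon")
    ll <- dchsbm_loglik(H, z, aff)
    expect_equal(ll$L, ll$Q + ll$K + ll$C)
    expect_equal(ll$L, bf_loglik(H, z, aff), tolerance = 1e-9)
  }
  ## a non-ML theta changes K and the expected mass but the identity holds
  H <- rand_hypergraph(5, 6, kmax = 3, seed = 9)
  z <- rand_labels(5, 2, 9)
  aff <- estimate_omega(H, z, "aon")
  theta <- runif(5, 0.5, 2)
  ll <- dchsbm_loglik(H, z, aff, theta)
  expect_equal(ll$L, bf_loglik(H, z, aff, theta), tolerance = 1e-9)
})

test_that("zero-rate observed edges give minus-infinity likelihood", {
  H <- toy_t1()
  z <- c(1, 1, 1, 2)
  aff <- affinity("aon", c("2:1" = 1, "3:1" = 1, "3:0" = 0, "2:0" = 0), 3)
  expect_equal(dchsbm_loglik(H, z, aff)$L, -Inf)
  expect_equal(symmetric_modularity(H, z, aff), -Inf)
  ## with every observed pattern supported, zero values elsewhere are fine
  z1 <- rep(1, 4)
  expect_true(is.finite(symmetric_modularity(H, z1, aff)))
})

test_that("AON modularity matches the plug-in formula and the symmetric objective", {
  H <- toy_t1()
  z <- c(1, 1, 1, 2)
  p <- list(sizes = 2:3, beta = c(1, 1), gamma = c(0, 0))
  expect_equal(aon_modularity(H, z, p), -1)
  ## differences across partitions equal symmetric-modularity differences
  aff <- estimate_omega(H, z, "aon")
  ap <- aon_params(aff)
  parts <- all_partitions(4)
  qa <- vapply(parts, function(zz) aon_modularity(H, zz, ap), 0)
  qs <- vapply(parts, function(zz) symmetric_modularity(H, zz, aff), 0)
  expect_equal(qa - qa[1], qs - qs[1], tolerance = 1e-9)
})

test_that("empty hypergraph likelihood reduces to the expected-mass penalty", {
  H <- hypergraph(list(), n = 3)
  aff <- test_aon_affinity(kmax = 2, within = 0.5, cross = 0.1)
  ll <- dchsbm_loglik(H, c(1, 1, 2), aff, theta = c(1, 1, 1))
  expect_equal(ll$K, 0)
  expect_equal(ll$C, 0)
  ## volumes (2,1): within mass 0.5*(4+1), cross mass 0.1*(9-5)
  expect_equal(ll$Q, -(0.5 * 5 + 0.1 * 4))
})
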