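test_that("a single node stays a singleton", {
  H <- hypergraph(list(), n = 1)
  p <- strict_modularity_params(H, sizes = 2:3)
  out <- aon_hmll(H, p, seed = 1)
  expect_equal(out$labels, 1L)
  aff <- test_aon_affinity(3)
  out2 <- symmetric_hmll(H, aff, seed = 1)
  expect_equal(out2$labels, 1L)
})

test_that("objective traces are non-decreasing and runs terminate", {
  for (seed in 1:4) {
    H <- rand_hypergraph(12, 18, kmax = 3, seed = seed)
    aff <- estimate_omega(H, rand_labels(12, 3, seed), "aon")
    ap <- aon_params(aff)
    oa <- aon_hmll(H, ap, seed = seed)
    expect_true(all(diff(oa$trace) >= -1e-9))
    expect_equal(oa$objective, aon_modularity(H, oa$labels, ap), tolerance = 1e-9)
    os <- symmetric_hmll(H, aff, seed = seed)
    expect_true(all(diff(os$trace) >= -1e-9))
    expect_equal(os$objective, symmetric_modularity(H, os$labels, aff),
                 tolerance = 1e-9)
    ## ascent from singletons never loses to the start
    expect_gte(oa$objective, aon_modularity(H, seq_len(12), ap) - 1e-9)
    expect_gte(os$objective, symmetric_modularity(H, seq_len(12), aff) - 1e-9)
  }
})

test_that("two disjoint assortative components are recovered exactly", {
  H <- hypergraph(list(c(1, 2), c(2, 3), c(1, 2, 3), c(4, 5), c(5, 6),
                       c(4, 5, 6)))
  truth <- c(1, 1, 1, 2, 2, 2)
  ## maximum-likelihood affinity at the planted structure (assortative,
  ## density-scaled)
  aff <- estimate_omega(H, truth, "aon")
  ## exhaustive global optimum over all set partitions of 6 nodes
  parts <- all_partitions(6)
  qs <- vapply(parts, function(z) symmetric_modularity(H, z, aff), 0)
  zstar <- parts[[which.max(qs)]]
  expect_equal(ari(zstar, truth), 1)
  out <- symmetric_hmll(H, aff, seed = 2)
  expect_equal(ari(out$labels, truth), 1)
  expect_equal(out$objective, max(qs), tolerance = 1e-9)
  out2 <- aon_hmll(H, aon_params(aff), seed = 2)
  expect_equal(ari(out2$labels, truth), 1)
})

test_that("AON fast path matches the symmetric path under AON affinities", {
  for (seed in 1:6) {
    H <- rand_hypergraph(8, 14, kmax = 3, seed = seed)
    aff <- test_aon_affinity(3, within = 0.5, cross = 0.05)
    ap <- aon_params(aff)
    za <- aon_hmll(H, ap, seed = 1, visit = "sequential")
    zs <- symmetric_hmll(H, aff, seed = 1, visit = "sequential")
    expect_identical(za$labels, zs$labels)
    ## the two objectives differ by the z-independent constant only
    expect_equal(za$objective - aon_modularity(H, zs$labels, ap), 0,
                 tolerance = 1e-9)
  }
})

test_that("returned partitions are locally optimal under whole-cluster moves", {
  ## assortative parameters: under them a whole-cluster move can only gain
  ## through cut or volume terms that the move enumeration below covers
  H <- rand_hypergraph(40, 80, kmax = 4, seed = 11)
  aff <- test_aon_affinity(4, within = 0.3, cross = 0.02)
  ap <- aon_params(aff)
  out <- aon_hmll(H, ap, seed = 3)
  z <- out$labels
  q0 <- aon_modularity(H, z, ap)
  L <- max(z)
  if (L > 1) {
    for (a in seq_len(L)) for (b in seq_len(L)[-a]) {
      z2 <- z
      z2[z == a] <- b
      expect_lte(aon_modularity(H, compress_labels(z2), ap), q0 + 1e-9)
    }
  }
  outs <- symmetric_hmll(H, aff, seed = 3)
  zs <- outs$labels
  qs0 <- symmetric_modularity(H, zs, aff)
  Ls <- max(zs)
  if (Ls > 1) {
    for (a in seq_len(Ls)) for (b in seq_len(Ls)[-a]) {
      z2 <- zs
      z2[zs == a] <- b
      expect_lte(symmetric_modularity(H, compress_labels(z2), aff), qs0 + 1e-9)
    }
  }
})

test_that("cluster-count regularization behaves as a label prior", {
  expect_equal(regularized_objective(10, 100, 1), 10)
  expect_equal(regularized_objective(0, 50, 4) - regularized_objective(0, 50, 5),
               50 * log(5 / 4))
  ## penalized runs return at most as many clusters (median over seeds)
  ncl <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    tb <- sample_two_block(n = 100, p2 = 0.9, p3 = 0.9, seed = 200 + s)
    p <- aon_params(estimate_omega(tb$H, tb$z, "aon"))
    ncl[s, 1] <- aon_hmll(tb$H, p, seed = s, regularize = TRUE)$n_clusters
    ncl[s, 2] <- aon_hmll(tb$H, p, seed = s)$n_clusters
  }
  expect_lte(stats::median(ncl[, 1]), stats::median(ncl[, 2]))
})

test_that("coordinate ascent reports the best alternation and recovers easy planted structure", {
  tb <- sample_two_block(n = 200, p2 = 0.95, p3 = 0.95, seed = 31)
  fit <- fit_dchsbm(tb$H, "aon", alternations = 8, seed = 5, regularize = TRUE)
  expect_equal(fit$score, max(fit$trace$score))
  expect_equal(fit$loglik, fit$trace$loglik[fit$best_alternation])
  expect_equal(ari(fit$labels, tb$z), 1)
  expect_equal(nrow(fit$trace), 8L)
  ## a single alternation is one Louvain pass plus one estimation
  fit1 <- fit_dchsbm(tb$H, "aon", alternations = 1, seed = 5, regularize = TRUE)
  expect_equal(nrow(fit1$trace), 1L)
  expect_s3_class(fit1$affinity, "hg_affinity")
})

test_that("symmetric-family coordinate ascent runs end to end", {
  tb <- sample_two_block(n = 60, p2 = 0.95, p3 = 0.95, c2 = 4, c3 = 4, seed = 8)
  fit <- fit_dchsbm(tb$H, "gn", alternations = 3, seed = 2)
  expect_true(is.finite(fit$loglik))
  expect_gte(ari(fit$labels, tb$z), 0.8)
})

test_that("hypergraph ascent exploits higher-order signal that clique projections blur", {
  ## disassortative 2-edges (p2 = 0.1) carry signal a pooled projection
  ## largely cancels; the hypergraph fit learns beta_2 < 0 and uses both
  ## edge sizes
  hm <- gm <- numeric(4)
  for (s in 1:4) {
    tb <- sample_two_block(n = 500, p2 = 0.1, p3 = 0.95, seed = 100 + s)
    fit <- fit_dchsbm(tb$H, "aon", alternations = 20, regularize = TRUE,
                      seed = s)
    hm[s] <- ari(fit$labels, tb$z)
    gfit <- gmll(clique_project(tb$H, normalized = FALSE), alternations = 20,
                 regularize = TRUE, seed = 50 + s)
    gm[s] <- ari(gfit$labels, tb$z)
  }
  expect_gt(mean(hm), 0.5)
  expect_gt(mean(hm), mean(gm))
})

test_that("refinement is monotone and fixes locally optimal partitions", {
  tb <- sample_two_block(n = 100, p2 = 0.9, p3 = 0.9, seed = 77)
  fit <- fit_dchsbm(tb$H, "aon", alternations = 6, seed = 9, regularize = TRUE)
  ## refining the returned optimum changes nothing
  ref <- refine_partition(tb$H, fit$labels, "aon", alternations = 3,
                          regularize = TRUE, seed = 10)
  expect_identical(ref$labels, fit$labels)
  ## refining a coarse initial guess cannot end below its own start
  z0 <- rep(1:2, each = 50)
  ref2 <- refine_partition(tb$H, z0, "aon", alternations = 3, seed = 11)
  om0 <- estimate_omega(tb$H, z0, "aon")
  expect_gte(ref2$loglik, dchsbm_loglik(tb$H, z0, om0)$L - 1e-9)
})
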