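test_that("partition vector is the sorted multiplicity profile", {
  expect_equal(partition_vector(c(1, 1, 4, 1, 2, 3, 2)), c(3L, 2L, 1L, 1L))
  expect_equal(partition_vector(c(7, 7, 7)), 3L)
  expect_equal(partition_vector(c(1, 2, 3)), c(1L, 1L, 1L))
  expect_error(partition_vector(integer(0)), "empty")
  ## invariance under relabelling
  set.seed(1)
  for (i in 1:20) {
    z <- sample.int(4, 6, replace = TRUE)
    sig <- sample.int(9)
    expect_equal(partition_vector(sig[z]), partition_vector(z))
  }
})

test_that("affinity classes follow the family definitions", {
  expect_equal(affinity_class("aon", 3), "3:1")
  expect_equal(affinity_class("aon", c(2, 1)), "3:0")
  ## relative plurality: gap below k/4 is the balanced class
  expect_equal(affinity_class("rp", c(2, 2)), "4:1")
  expect_equal(affinity_class("rp", c(3, 1)), "4:0")
  expect_equal(affinity_class("rp", 4), "4:0")
  ## pairwise: ordered discordant pairs below k(k-1)/4
  expect_equal(affinity_class("pairwise", c(1, 1, 1)), "3:0")
  expect_equal(affinity_class("pairwise", 3), "3:1")
  expect_equal(affinity_class("gn", c(2, 1, 1)), "4:3")
  expect_equal(affinity_class("custom", c(2, 1)), "2|1")
  expect_error(affinity_class("aon", c(2, 2), kmax = 3), "exceeds kmax")
})

test_that("theta estimate equals the degree vector and satisfies the volume constraint", {
  H <- toy_t1()
  expect_equal(estimate_theta(H), c(2, 3, 2, 1))
  expect_equal(estimate_theta(hypergraph(list(), n = 2)), c(0, 0))
  for (seed in 1:5) {
    z <- rand_labels(4, 2, seed)
    th <- estimate_theta(H)
    vols <- cluster_volumes(H, z)
    for (l in seq_along(vols))
      expect_equal(sum(th[z == l]), vols[l])
  }
})

test_that("closed-form affinity estimates match the worked values", {
  H <- toy_t1()
  z <- c(1, 1, 1, 2)
  om <- estimate_omega(H, z, "aon", smoothing = 0)
  expect_equal(unname(om$values["3:1"]), 1 / 344)
  expect_equal(unname(om$values["3:0"]), 1 / 168)
  expect_equal(unname(om$values["2:1"]), 1 / 50)
  ## zero observed edges in a class with positive volume
  expect_equal(unname(om$values["2:0"]), 0)
  ## smoothing keeps every positive-volume class positive
  oms <- estimate_omega(H, z, "aon")
  expect_true(all(oms$values > 0))
})

test_that("AON beta/gamma parameters follow from the affinity pair", {
  p <- aon_params(matrix(c(1, exp(1)), 1, 2,
                         dimnames = list("2", c("omega0", "omega1"))))
  expect_equal(unname(p$beta), 1)
  expect_equal(unname(p$gamma), exp(1) - 1)
  ## equal rates: beta 0, gamma continues to the common value
  expect_warning(
    pl <- aon_params(matrix(c(2, 2), 1, 2,
                            dimnames = list("2", c("omega0", "omega1")))),
    "limit")
  expect_equal(unname(pl$beta), 0)
  expect_equal(unname(pl$gamma), 2)
  expect_error(aon_params(matrix(c(0, 1), 1, 2,
                                 dimnames = list("2", c("omega0", "omega1")))),
               "positive")
})

test_that("strict modularity parameters are beta = 1, gamma = m_k / vol^k", {
  H <- toy_t1()
  p <- strict_modularity_params(H)
  expect_equal(unname(p$beta), c(1, 1))
  expect_equal(unname(p$gamma), c(1 / 64, 2 / 512))
})

test_that("aon_affinity inverts the beta/gamma parameterisation", {
  om <- estimate_omega(toy_t1(), c(1, 1, 1, 2), "aon")
  p <- aon_params(om)
  back <- aon_affinity(p)
  expect_equal(sort(names(back$values)), sort(names(om$values)))
  expect_equal(back$values[names(om$values)], om$values, tolerance = 1e-12)
  p2 <- aon_params(back)
  expect_equal(p2$beta, p$beta)
  expect_equal(p2$gamma, p$gamma)
})

test_that("affinity parameter counts match the family conventions", {
  expect_equal(count_parameters("aon", 4), 8L)
  expect_equal(count_parameters("rp", 4), 8L)
  expect_equal(count_parameters("pairwise", 3), 6L)
  expect_equal(count_parameters("gn", 4, lbar = 3), 8)
  expect_equal(count_parameters("gn", 4, lbar = 1), 3)
  expect_equal(count_parameters("gn", 4, restrict_groups = FALSE), 9)
})

test_that("affinity functions serialize to JSON and back", {
  om <- estimate_omega(toy_t1(), c(1, 1, 1, 2), "aon")
  om2 <- affinity_from_json(affinity_to_json(om))
  expect_equal(om2$family, om$family)
  expect_equal(om2$kmax, om$kmax)
  expect_equal(om2$values[names(om$values)], om$values)
})
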