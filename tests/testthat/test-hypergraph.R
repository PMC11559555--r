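test_that("hyperedge-list reader counts nodes, sizes and duplicate weights", {
  H <- read_hyperedge_list(text = "1 2\n1 2 3\n2 3 4")
  expect_equal(H$n, 4L)
  expect_equal(sum(H$weights), 3)
  expect_equal(unname(size_counts(H)[c("2", "3")]), c(1, 2))

  dup <- read_hyperedge_list(text = "1 2\n1 2")
  expect_equal(length(dup$edges), 1L)
  expect_equal(dup$weights, 2)

  expect_error(read_hyperedge_list(text = ""), "empty")
  expect_error(read_hyperedge_list(text = "# only a comment\n"), "empty")
  expect_error(read_hyperedge_list(text = "1 2\n1 1 2"), "repeated node")
  expect_error(read_hyperedge_list(text = "1 2 0\n", weighted = TRUE),
               "positive integer")
})

test_that("reader handles dialects: comma separation, weights, names", {
  H <- read_hyperedge_list(text = "a,b,2\nb,c,1", sep = ",", weighted = TRUE)
  expect_equal(H$n, 3L)
  expect_equal(H$node_names, c("a", "b", "c"))
  expect_equal(sort(H$weights), c(1, 2))
  expect_equal(unname(degrees(H)[2]), 3)
})

test_that("write/read round-trip preserves n, size counts and degrees", {
  H <- read_hyperedge_list(text = "a b\na b c\nb c d\na b")
  txt <- write_hyperedge_list(H)
  H2 <- read_hyperedge_list(text = txt, weighted = TRUE)
  expect_equal(H2$n, H$n)
  expect_equal(size_counts(H2), size_counts(H))
  expect_equal(degrees(H2), degrees(H))
  expect_equal(H2$node_names, H$node_names)
  ## the duplicated edge is written once, with its accumulated weight
  expect_equal(sum(grepl("^a b 2$", strsplit(txt, "\n")[[1]])), 1L)
})

test_that("bipartite incidence reader builds the same hypergraph", {
  H <- read_bipartite_edge_list(text = "a e1\nb e1\nb e2\nc e2\nd e2")
  expect_equal(H$n, 4L)
  expect_equal(unname(size_counts(H)[c("2", "3")]), c(1, 1))
  expect_equal(unname(degrees(H)), c(1, 2, 1, 1))
})

test_that("node label TSV round-trips through external names", {
  H <- read_hyperedge_list(text = "a b\nb c")
  txt <- write_node_labels(H, c(1, 1, 2))
  z <- read_node_labels(text = txt, H = H)
  expect_equal(as.integer(z), c(1, 1, 2))
  expect_error(read_node_labels(text = "a\t1", H = H), "missing label")
})

test_that("degrees count weighted incidences", {
  expect_equal(degrees(toy_t1()), c(2, 3, 2, 1))
  expect_equal(degrees(hypergraph(list(c(1, 2)), 2)), c(2, 2))
  expect_equal(degrees(hypergraph(list(), n = 3)), c(0, 0, 0))
})

test_that("cluster volumes partition the total volume", {
  H <- toy_t1()
  v <- cluster_volumes(H, c(1, 1, 1, 2))
  expect_equal(v, c(7, 1))
  expect_equal(sum(v), hg_volume(H))
  expect_equal(cluster_volumes(H, rep(1, 4)), 8)
  expect_equal(cluster_volumes(H, 1:4), degrees(H))
  expect_error(cluster_volumes(H, c(1, 1, 1)), "cover all nodes")
})

test_that("degree-incidence conservation holds after construction and filters", {
  for (seed in 1:5) {
    H <- rand_hypergraph(8, 12, kmax = 4, seed = seed)
    expect_equal(sum(degrees(H)), sum(H$weights * H$sizes))
    Hf <- restrict_edge_size(H, 2)
    expect_equal(sum(degrees(Hf)), sum(Hf$weights * Hf$sizes))
    Hc <- c_core(H, 3)
    expect_equal(sum(degrees(Hc)), sum(Hc$weights * Hc$sizes))
  }
})

test_that("c-core reaches the fixed point and is idempotent", {
  H <- toy_t1()
  expect_identical(c_core(H, 0)$edges, H$edges)
  ## brute-force fixed point: remove low-degree nodes + incident edges
  bf_core <- function(H, c) {
    repeat {
      low <- which(degrees(H) < c)
      if (!length(low)) return(H)
      H <- subhypergraph(H, setdiff(seq_len(H$n), low))
      if (H$n == 0) return(H)
    }
  }
  H2 <- c_core(H, 2)
  O2 <- bf_core(H, 2)
  expect_equal(H2$n, O2$n)
  expect_equal(degrees(H2), degrees(O2))
  expect_true(all(degrees(H2) >= 2))
  expect_equal(c_core(H, 10)$n, 0L)
  for (seed in 1:5) {
    H <- rand_hypergraph(10, 10, kmax = 4, seed = seed)
    core <- c_core(H, 3)
    expect_true(all(degrees(core) >= 3) || core$n == 0)
    again <- c_core(core, 3)
    expect_equal(again$edges, core$edges)
    expect_equal(again$n, core$n)
  }
})

test_that("edge-size restriction drops only oversized edges", {
  H <- toy_t1()
  H2 <- restrict_edge_size(H, 2)
  expect_equal(length(H2$edges), 1L)
  expect_equal(degrees(H2), c(1, 1, 0, 0))
  H3 <- restrict_edge_size(H, 3)
  expect_equal(size_counts(H3), size_counts(H))
})

test_that("label compression yields contiguous labels", {
  expect_equal(compress_labels(c(5L, 2L, 5L, 9L)), c(2L, 1L, 2L, 3L))
})
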