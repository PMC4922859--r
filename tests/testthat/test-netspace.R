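test_that("closed-form network counts match the combinatorics", {
  expect_equal(count_networks(3, 6), 84)
  expect_equal(count_networks(2, 4), 1)
  expect_equal(count_networks(4, 7), 11440)
  expect_error(count_networks(3, 10), "between 1 and N\\*N")
  expect_error(count_networks(3, 0), "between 1 and N\\*N")
})

test_that("enumeration agrees with the closed form and honors constraints", {
  for (case in list(c(2, 4), c(3, 4), c(3, 6))) {
    nodes <- rd_nodes(rep(c(TRUE, FALSE), length.out = case[1]))
    expect_length(enumerate_networks(nodes, case[2]),
                  count_networks(case[1], case[2]))
  }
  nodes3 <- three_nodes()
  # forbidding all three diagonal cells forces the single all-off-diagonal
  # network at k = 6
  no_diag <- enumerate_networks(nodes3, 6,
                                forbidden_edges = rbind(c(1, 1), c(2, 2),
                                                        c(3, 3)))
  expect_length(no_diag, 1L)
  # forced edges appear in every enumerated network
  forced <- rbind(c(1, 2), c(2, 1))
  nets <- enumerate_networks(nodes3, 4, forced_edges = forced)
  expect_length(nets, choose(7, 2))
  for (nt in nets[seq(1, length(nets), by = 7)])
    expect_true(all(turingnets:::cell_index(forced[, 1], forced[, 2], 3) %in% nt$cells))
  # infeasible constraints yield an empty stream with a warning
  expect_warning(out <- enumerate_networks(nodes3, 2,
                                           forced_edges = rbind(c(1, 1),
                                                                c(1, 2),
                                                                c(1, 3))),
                 "infeasible")
  expect_length(out, 0L)
  # duplicate edges rejected
  expect_error(rd_network(nodes3, c(1L, 1L, 5L)), "duplicate")
})

test_that("connectivity filter implements strong connectivity sans self-loops", {
  expect_true(passes_connectivity_filter(complete_two_node()))
  # node 3 only receives: a pure read-out node
  readout <- rd_network(three_nodes(),
                        rbind(c(1, 2), c(2, 1), c(3, 1), c(3, 2), c(1, 1)))
  expect_false(passes_connectivity_filter(readout))
  # self-loops alone do not connect: 2-cycle plus self-loop on node 3
  selfy <- rd_network(three_nodes(),
                      rbind(c(1, 2), c(2, 1), c(3, 3)))
  expect_false(passes_connectivity_filter(selfy))
  # agreement with igraph strong connectivity on random 4-node graphs
  nodes4 <- rd_nodes(c(TRUE, TRUE, FALSE, FALSE))
  set.seed(11)
  for (rep in 1:50) {
    cells <- sample(16, 6)
    net <- rd_network(nodes4, cells)
    ts <- turingnets:::cell_from_index(net$cells, 4)
    keep <- ts[, "target"] != ts[, "source"]
    g <- igraph::graph_from_edgelist(
      cbind(ts[keep, "source"], ts[keep, "target"]), directed = TRUE)
    if (igraph::vcount(g) < 4)
      g <- igraph::add_vertices(g, 4 - igraph::vcount(g))
    expect_identical(passes_connectivity_filter(net),
                     igraph::is_connected(g, mode = "strong"))
  }
})

test_that("canonical keys are invariant under class-preserving relabeling", {
  nodes3 <- three_nodes()
  set.seed(42)
  perms <- class_permutations(nodes3$diffusible)
  for (rep in 1:200) {
    cells <- sample(9, 6)
    net <- rd_network(nodes3, cells)
    p <- perms[[sample(length(perms), 1)]]
    ts <- turingnets:::cell_from_index(net$cells, 3)
    permuted <- rd_network(nodes3, cbind(p[ts[, "target"]],
                                         p[ts[, "source"]]))
    expect_identical(as.character(canonical_key(net)),
                     as.character(canonical_key(permuted)))
  }
})

test_that("graph filters reproduce the 3-node catalog and are monotone", {
  nets <- enumerate_networks(three_nodes(), 6)
  sc <- Filter(passes_connectivity_filter, nets)
  expect_length(sc, 48L)
  dd <- dedup_networks(sc)
  expect_length(dd, 25L)
  # monotone: step-3 survivors are step-2 survivors are step-1 networks
  key_of <- function(nt) paste(nt$cells, collapse = ",")
  expect_true(all(vapply(dd, key_of, "") %in% vapply(sc, key_of, "")))
  # idempotent
  expect_length(dedup_networks(dd), 25L)
})

test_that("networks serialize to edge lists, GraphML and DOT", {
  net <- rd_network(three_nodes(), rbind(c(1, 2), c(2, 1), c(3, 1), c(1, 3),
                                         c(2, 3), c(3, 2)))
  expect_setequal(format_edges(net),
                  c("v<-w", "w<-v", "u<-v", "v<-u", "w<-u", "u<-w"))
  gml <- tempfile(fileext = ".graphml")
  write_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 6)
  expect_setequal(igraph::V(g)$diffusible[order(igraph::V(g)$name)],
                  c(FALSE, TRUE, TRUE))
  dot <- tempfile(fileext = ".dot")
  write_network(net, dot, "dot")
  expect_true(any(grepl("->", readLines(dot))))
})
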