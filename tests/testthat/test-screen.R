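test_that("topology enumeration respects sign and value constraints", {
  net <- complete_two_node()
  tops <- enumerate_topologies(net)
  expect_length(tops, 16L)
  # deterministic order: sign vectors unique, first all-activating
  keys <- vapply(tops, function(tp) paste(tp$signs, collapse = ","), "")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(tops[[1]]$signs, rep(1, 4))
  cons <- constraint_set(two_nodes(),
                         sign_constraints = data.frame(
                           target = c("v", "w"), source = c("v", "w"),
                           sign = c(-1, -1)))
  expect_length(enumerate_topologies(net, cons), 4L)
  # all signs constrained: a single topology
  cons_all <- constraint_set(two_nodes(),
                             sign_constraints = data.frame(
                               target = c(1, 1, 2, 2), source = c(1, 2, 1, 2),
                               sign = c(1, -1, 1, -1)))
  expect_length(enumerate_topologies(net, cons_all), 1L)
  # value constraints propagate into the topology and imply the sign
  cons_val <- constraint_set(two_nodes(),
                             value_constraints = data.frame(
                               target = 1, source = 1, value = -0.2))
  tops_v <- enumerate_topologies(net, cons_val)
  expect_length(tops_v, 8L)
  expect_true(all(vapply(tops_v, function(tp) tp$values[1] == -0.2,
                         logical(1L))))
})

test_that("inconsistent constraints are rejected", {
  expect_error(constraint_set(two_nodes(),
                              forced_edges = rbind(c(1, 2)),
                              forbidden_edges = rbind(c(1, 2))),
               "overlap")
  expect_error(constraint_set(two_nodes(),
                              sign_constraints = data.frame(
                                target = 1, source = 2, sign = 1),
                              value_constraints = data.frame(
                                target = 1, source = 2, value = -0.3)),
               "conflicting")
  expect_error(constraint_set(two_nodes(),
                              sign_constraints = data.frame(
                                target = "x", source = "v", sign = 1)),
               "unknown node label")
  expect_error(topology(complete_two_node(), c(1, 1, 1, 1),
                        values = c(-0.1, NA, NA, NA)),
               "conflict")
})

test_that("stability search finds witnesses where they exist", {
  # pure mutual activation with positive self-loops: trace > 0 always
  all_pos <- topology(complete_two_node(), c(1, 1, 1, 1))
  expect_false(topology_is_stable(all_pos, budget = 4000, seed = 1)$stable)
  st <- topology_is_stable(ai_topology(), budget = 4000, seed = 1)
  expect_true(st$stable)
  expect_true(routh_hurwitz_stable(char_poly_coeffs(st$witness$J, 0, 0)))
  # witness sign pattern matches the topology
  expect_identical(sign(st$witness$J), matrix(c(1, 1, -1, -1), 2, 2))
})

test_that("capability searches respect the diffusion regime", {
  cap_free <- topology_turing_capable(ai_topology(), regime = "free",
                                      budget = 8000, seed = 2)
  expect_true(cap_free$capable)
  wit <- cap_free$witness
  expect_true(is_turing_unstable(wit$J, D = wit$D)$turing_unstable)
  # equal diffusivities can never pattern in a 2-node system
  cap_eq <- topology_turing_capable(ai_topology(), regime = "equal",
                                    budget = 8000, seed = 2)
  expect_false(cap_eq$capable)
  # capacitor sign pattern is universally capable via the analytic
  # certificate under the permissive criterion
  gen <- rbind(c(-1, 0, 2), c(0, -1, 2), c(-1, -0.5, 0.25))
  net <- rd_network(three_nodes(), which(t(gen) != 0))
  signs_rowmajor <- sign(t(gen))[t(gen) != 0]
  cap_u <- topology_turing_capable(topology(net, signs_rowmajor),
                                   regime = "universal", criterion = "any",
                                   budget = 8000, seed = 2)
  expect_true(cap_u$capable)
  expect_true(cap_u$certificate)
})

test_that("phase predictions match the classical two-node mechanisms", {
  expect_identical(unname(phase_pattern(rd_system(ai_jacobian(),
                                                  c(1, 10)))), c(1L, 1L))
  expect_identical(unname(phase_pattern(rd_system(sd_jacobian(),
                                                  c(1, 10)))), c(1L, -1L))
  # direct eigenvector check at the dispersion maximum
  d <- dispersion(ai_jacobian(), c(1, 10))
  v <- Re(eigen(ai_jacobian() - d$q2_star * diag(c(1, 10)))$vectors[, 1])
  expect_identical(unname(sign(v)[1] * sign(v))[2], 1)
})

test_that("robustness estimates behave like Turing-space volumes", {
  # all-inhibition two-node system never patterns
  neg <- topology(complete_two_node(), c(-1, -1, -1, -1))
  expect_identical(robustness(neg, n = 2000, seed = 1)$estimate, 0)
  # activator-inhibitor at equal diffusivities: volume zero
  expect_identical(robustness(ai_topology(), regime = "equal", n = 2000,
                              seed = 1)$estimate, 0)
  # free regime: agrees with a dense independent evaluation of the
  # closed-form conditions (the thin Turing sliver defeats coarse lattice
  # quadrature, so the oracle samples the closed form densely instead)
  rb <- robustness(ai_topology(), regime = "free", n = 40000, seed = 8)
  orc <- two_node_oracle_volume(5e5, seed = 1234)
  expect_lt(abs(rb$estimate - orc$estimate), 3 * (rb$se + orc$se))
  # convergence: the standard error halves (roughly) when n quadruples
  rb_small <- robustness(ai_topology(), regime = "free", n = 10000, seed = 8)
  expect_equal(rb_small$se / rb$se, 2, tolerance = 0.35)
})

test_that("minimum diffusion ratio recovers the closed-form threshold", {
  vals <- c(1, -1, 3, -2) # row-major: J = [[1, -1], [3, -2]]
  top <- topology(complete_two_node(), sign(vals), values = vals)
  d_min <- min_diffusion_ratio(top, tol = 1e-5)
  expect_equal(d_min, 4 + 2 * sqrt(3), tolerance = 1e-3)
  # an all-negative topology has no feasible ratio at all
  neg <- topology(complete_two_node(), c(-1, -1, -1, -1))
  expect_null(min_diffusion_ratio(neg, n_scan = 9, budget = 1500, seed = 1))
})

test_that("the two-node pipeline finds the classical control catalog", {
  cat2 <- run_pipeline(two_nodes(), 4, budget = 8000, robustness_n = 500,
                       seed = 3)
  expect_length(cat2$entries, 1L)
  e <- cat2$entries[[1]]
  expect_identical(e$type, "I")
  expect_identical(e$n_phase_patterns, 2L)
  expect_equal(cat2$steps$networks, c(1, 1, 1, 1, 1))
  expect_equal(cat2$steps$topologies[1:3], c(16, 16, 16))
  # step counts are non-increasing
  expect_true(all(diff(cat2$steps$networks) <= 0))
  expect_true(all(diff(cat2$steps$topologies) <= 0))
  # every witness replays from its recorded parameters
  for (tp in e$topologies) {
    expect_true(is_turing_unstable(tp$witness$J,
                                   D = tp$witness$D)$turing_unstable)
    expect_identical(unname(tp$phase[1]), 1L)
  }
  # catalog summary carries one row with the robustness estimate
  sm <- summary(cat2)
  expect_identical(nrow(sm), 1L)
  expect_gt(sm$robustness, 0)
  expect_identical(sm$relative_robustness, 1)
})

test_that("raising the budget never loses survivors", {
  nodes <- three_nodes()
  cons <- constraint_set(nodes,
                         forced_edges = rbind(c(1, 3), c(3, 1), c(2, 3),
                                              c(1, 1), c(2, 2)),
                         sign_constraints = data.frame(
                           target = c(1, 3, 2, 1, 2), source = c(3, 1, 3, 1, 2),
                           sign = c(1, 1, 1, -1, -1)))
  lo <- run_pipeline(nodes, 6, constraints = cons, budget = 2000,
                     robustness_n = 0, seed = 5, classify = FALSE)
  hi <- run_pipeline(nodes, 6, constraints = cons, budget = 8000,
                     robustness_n = 0, seed = 5, classify = FALSE)
  lo_keys <- vapply(lo$entries, `[[`, character(1L), "key")
  hi_keys <- vapply(hi$entries, `[[`, character(1L), "key")
  expect_true(all(lo_keys %in% hi_keys))
})

test_that("classification respects the diffusivity hierarchy", {
  # Type III implies equal-diffusivity capability on the capacitor pattern
  gen <- rbind(c(-1, 0, 2), c(0, -1, 2), c(-1, -0.5, 0.25))
  net <- rd_network(three_nodes(), which(t(gen) != 0))
  top <- topology(net, sign(t(gen))[t(gen) != 0])
  cls <- classify_network(list(top), budget = 8000, seed = 4)
  if (cls$type == "III") {
    eq <- topology_turing_capable(top, regime = "equal", budget = 8000,
                                  seed = 4)
    expect_true(eq$capable)
  }
  # the 2-node activator-inhibitor is Type I: not even equal-capable
  expect_identical(classify_network(list(ai_topology()), budget = 4000,
                                    seed = 4)$type, "I")
})
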