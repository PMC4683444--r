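test_that("transmission probability matches hand closed forms", {
  g <- toy_chain()
  expect_equal(transmission_probability(first_circuit(g), g,
                                        c(R = 0.9, A = 0.8, E = 0.7)),
               0.9 * 0.8 * 0.7)
  gi <- toy_inhibited_chain()
  expect_equal(transmission_probability(first_circuit(gi), gi,
                                        c(R = 0.9, E = 0.8, B = 0.5)),
               0.9 * 0.8 * 0.5)
  gd <- toy_diamond()
  p <- c(R = 0.5, A = 0.5, B = 0.5, E = 0.5)
  # shared receptor: 0.1875, not the naive path-union 0.4375
  expect_equal(transmission_probability(first_circuit(gd), gd, p), 0.1875)
})

test_that("exact engine agrees with the brute-force oracle on random DAGs", {
  for (seed in 1:40) {
    fx <- random_circuit_fixture(seed, n_members = sample(3:8, 1))
    got <- transmission_probability(fx$circuit, fx$graph, fx$probs)
    expect_equal(got, oracle_transmission(fx$circuit, fx$graph, fx$probs),
                 tolerance = 1e-10)
  }
})

test_that("degenerate probability bounds hold", {
  gd <- toy_diamond()
  cir <- first_circuit(gd)
  expect_equal(transmission_probability(cir, gd,
                                        c(R = 1, A = 1, B = 1, E = 1)), 1)
  expect_equal(transmission_probability(cir, gd,
                                        c(R = 0, A = 1, B = 1, E = 1)), 0)
  expect_equal(transmission_probability(cir, gd,
                                        c(R = 1, A = 1, B = 1, E = 0)), 0)
  gi <- toy_inhibited_chain()
  expect_equal(transmission_probability(first_circuit(gi), gi,
                                        c(R = 1, E = 1, B = 0)), 1)
  expect_equal(transmission_probability(first_circuit(gi), gi,
                                        c(R = 1, E = 1, B = 1)), 0)
})

test_that("transmission is monotone in member and inhibitor probabilities", {
  fx <- random_circuit_fixture(99, n_members = 6, n_inhibitors = 2)
  base <- transmission_probability(fx$circuit, fx$graph, fx$probs)
  for (n in fx$circuit$member_nodes) {
    up <- fx$probs
    up[n] <- min(1, up[n] + 0.3)
    expect_gte(transmission_probability(fx$circuit, fx$graph, up),
               base - 1e-12)
  }
  pure_inh <- setdiff(fx$circuit$inhibitor_context$source,
                      fx$circuit$member_nodes)
  for (n in pure_inh) {
    up <- fx$probs
    up[n] <- min(1, up[n] + 0.3)
    expect_lte(transmission_probability(fx$circuit, fx$graph, up),
               base + 1e-12)
  }
})

test_that("input validation names offenders and enforces the size cap", {
  g <- toy_chain()
  cir <- first_circuit(g)
  expect_error(transmission_probability(cir, g, c(R = 0.5, A = 0.5)),
               "missing node probability.*E")
  expect_error(transmission_probability(cir, g,
                                        c(R = 0.5, A = 1.5, E = 0.5)),
               "\\[0, 1\\]")
  expect_error(transmission_probability(cir, g,
                                        c(R = 0.5, A = 0.5, E = 0.5),
                                        max_exact_nodes = 2),
               "transmission_probability_mc")
})

test_that("both inhibitor semantics are computable and ordered sensibly", {
  # member inhibitor: A -> E activation chain, E also inhibited by A's
  # downstream member? use external-vs-member contrast on a 4-node graph
  g <- pathway_graph("m",
                     data.frame(source = c("R", "A", "A"),
                                target = c("A", "E", "R"),
                                sign = c("activation", "activation",
                                         "inhibition")),
                     genes = list(R = "g1", A = "g2", E = "g3"),
                     receptors = "R", effectors = "E")
  cir <- first_circuit(g)
  p <- c(R = 0.9, A = 0.6, E = 0.8)
  ctx <- transmission_probability(cir, g, p, mode = "context")
  sig <- transmission_probability(cir, g, p, mode = "signal")
  # in signal mode the member inhibitor must also be reached, so it blocks
  # in no more states than in context mode
  expect_gte(sig, ctx)
  expect_equal(ctx, oracle_transmission(cir, g, p), tolerance = 1e-10)
})

test_that("Monte-Carlo estimates converge to the exact value and are seeded", {
  gd <- toy_diamond()
  cir <- first_circuit(gd)
  p <- c(R = 0.5, A = 0.5, B = 0.5, E = 0.5)
  mc <- transmission_probability_mc(cir, gd, p, n_draws = 1e5, seed = 5)
  expect_lt(abs(mc$estimate - 0.1875), 3 * mc$stderr)
  mc2 <- transmission_probability_mc(cir, gd, p, n_draws = 1e5, seed = 5)
  expect_identical(mc, mc2)
  expect_equal(transmission_probability_mc(cir, gd,
                                           c(R = 1, A = 1, B = 1, E = 1),
                                           n_draws = 1000, seed = 1)$estimate,
               1)
  expect_equal(transmission_probability_mc(cir, gd,
                                           c(R = 0, A = 1, B = 1, E = 1),
                                           n_draws = 1000, seed = 1)$estimate,
               0)
  expect_error(transmission_probability_mc(cir, gd, p, n_draws = 10), "1000")
})

test_that("activity_matrix is deterministic with circuit columns in [0,1]", {
  set.seed(17)
  gp <- matrix(runif(12 * 7), 12,
               dimnames = list(sprintf("s%02d", 1:12),
                               c("gR", "gA", "gB", "gE", "x1", "x2", "x3")))
  pws <- list(toy_chain(), toy_diamond())
  act <- activity_matrix(gp, pws)
  expect_equal(colnames(act), c("chain:R-E", "diamond:R-E"))
  expect_equal(rownames(act), rownames(gp))
  expect_true(all(act >= 0 & act <= 1))
  expect_identical(act, activity_matrix(gp, pws))
  # column values equal per-sample scalar calls
  cir <- first_circuit(toy_chain())
  np <- node_probabilities(gp, toy_chain())
  expect_equal(act[3, "chain:R-E"],
               transmission_probability(cir, toy_chain(), np[3, ]))
})

test_that("differential activation finds planted shifts and is symmetric", {
  set.seed(23)
  n <- 20
  act <- matrix(runif(2 * n * 50, 0.2, 0.6), 2 * n, 50,
                dimnames = list(NULL, sprintf("c%02d", 1:50)))
  groups <- rep(c("g1", "g2"), each = n)
  act[groups == "g2", "c07"] <- act[groups == "g2", "c07"] + 0.4
  res <- differential_activation(act, groups)
  expect_equal(res$circuit_id[1], "c07")
  expect_equal(res$direction[res$circuit_id == "c07"], "Up")
  expect_lt(res$adj_p[1], 0.01)

  flipped <- differential_activation(act, factor(groups,
                                                 levels = c("g2", "g1")))
  m <- match(res$circuit_id, flipped$circuit_id)
  expect_equal(flipped$p_value[m], res$p_value)
  swap <- c(Up = "Down", Down = "Up", none = "none")
  expect_equal(flipped$direction[m], unname(swap[res$direction]))
})

test_that("identical groups give p = 1 and no direction", {
  act <- matrix(0.4, 8, 2, dimnames = list(NULL, c("c1", "c2")))
  act[, 2] <- rep(c(0.1, 0.9), 4)
  res <- differential_activation(act, rep(c("a", "b"), each = 4))
  expect_equal(res$p_value[res$circuit_id == "c1"], 1)
  expect_equal(res$direction[res$circuit_id == "c1"], "none")
  expect_error(differential_activation(act, c("a", rep("b", 7))),
               "at least 2")
  expect_error(differential_activation(act, rep("a", 8)), "two levels")
})
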