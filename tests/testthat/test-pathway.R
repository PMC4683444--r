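write_triple <- function(dir, edges, nodes, annot, prefix = "p") {
  paths <- file.path(dir, paste0(prefix, c(".edges.tsv", ".nodes.tsv",
                                           ".annot.tsv")))
  writeLines(edges, paths[1L])
  writeLines(nodes, paths[2L])
  writeLines(annot, paths[3L])
  paths
}

test_that("a minimal chain pathway loads with validated structure", {
  d <- withr::local_tempdir()
  p <- write_triple(d,
                    c("R\tA\tactivation", "A\tE\tactivation"),
                    c("R\tg1", "A\tg2;g3", "E\tg4"),
                    c("R\treceptor", "E\teffector"))
  g <- load_pathway(p[1], p[2], p[3], pathway_id = "toy")
  expect_s3_class(g, "pathway_graph")
  expect_equal(g$node_ids, c("A", "E", "R"))
  expect_equal(nrow(g$edges), 2L)
  expect_true(all(g$edges$sign == "activation"))
  expect_equal(g$genes$A, c("g2", "g3"))
  expect_equal(g$receptors, "R")
  expect_equal(g$effectors, "E")
})

test_that("load errors name the offending input", {
  d <- withr::local_tempdir()
  # edge references a node absent from the node file
  p <- write_triple(d, c("R\tX\tactivation"), c("R\tg1", "E\tg2"),
                    c("R\treceptor", "E\teffector"))
  expect_error(load_pathway(p[1], p[2], p[3]), "X")
  # empty gene set
  p <- write_triple(d, c("R\tE\tactivation"), c("R\tg1", "E\t"),
                    c("R\treceptor", "E\teffector"), prefix = "q")
  expect_error(load_pathway(p[1], p[2], p[3]), "empty gene set.*E")
  # cycle within the receptor->effector reachable subgraph
  p <- write_triple(d,
                    c("R\tA\tactivation", "A\tB\tactivation",
                      "B\tA\tactivation", "B\tE\tactivation"),
                    c("R\tg1", "A\tg2", "B\tg3", "E\tg4"),
                    c("R\treceptor", "E\teffector"), prefix = "c")
  expect_error(load_pathway(p[1], p[2], p[3]), "cycle.*A.*B")
  # self loops rejected
  expect_error(pathway_graph("s",
                             data.frame(source = "A", target = "A",
                                        sign = "activation"),
                             genes = list(A = "g"), receptors = "A",
                             effectors = "A"),
               "self-loop")
})

test_that("circuit enumeration merges furcations and orders deterministically", {
  expect_length(enumerate_circuits(toy_chain()), 1L)
  expect_equal(first_circuit(toy_chain())$member_nodes, c("A", "E", "R"))

  dia <- enumerate_circuits(toy_diamond())
  expect_length(dia, 1L)
  expect_equal(dia[[1]]$member_nodes, c("A", "B", "E", "R"))
  expect_equal(dia[[1]]$circuit_id, "diamond:R-E")

  # 2 receptors x 2 effectors, all connected -> 4 circuits
  g <- pathway_graph("grid",
                     data.frame(source = c("R1", "R1", "R2", "R2", "M", "M"),
                                target = c("M", "E1", "M", "E1", "E1", "E2"),
                                sign = "activation"),
                     genes = list(R1 = "a", R2 = "b", M = "c", E1 = "d",
                                  E2 = "e"),
                     receptors = c("R1", "R2"), effectors = c("E1", "E2"))
  circ <- enumerate_circuits(g)
  expect_length(circ, 4L)
  expect_equal(names(circ), sort(names(circ)))
  # pairs without a path are omitted, not errored
  g2 <- pathway_graph("part",
                      data.frame(source = "R1", target = "E1",
                                 sign = "activation"),
                      genes = list(R1 = "a", E1 = "b", E2 = "c"),
                      receptors = "R1", effectors = c("E1", "E2"))
  expect_length(enumerate_circuits(g2), 1L)
})

test_that("every member node lies on a receptor->effector path", {
  for (seed in 1:10) {
    fx <- random_circuit_fixture(seed)
    cir <- fx$circuit
    act <- fx$graph$edges[fx$graph$edges$sign == "activation", ]
    # forward BFS from the receptor, backward BFS from the effector
    walk <- function(start, forward) {
      seen <- start
      frontier <- start
      while (length(frontier)) {
        nxt <- if (forward) act$target[act$source %in% frontier]
               else act$source[act$target %in% frontier]
        frontier <- setdiff(nxt, seen)
        seen <- union(seen, frontier)
      }
      seen
    }
    on_path <- intersect(walk(cir$receptor, TRUE),
                         walk(cir$effector, FALSE))
    expect_setequal(cir$member_nodes, on_path)
  }
})

test_that("enumeration is invariant to edge-file row order", {
  d <- withr::local_tempdir()
  rows <- c("R\tA\tactivation", "A\tE\tactivation", "R\tB\tactivation",
            "B\tE\tactivation", "I\tA\tinhibition")
  nodes <- c("R\tg1", "A\tg2", "B\tg3", "E\tg4", "I\tg5")
  annot <- c("R\treceptor", "E\teffector")
  p1 <- write_triple(d, rows, nodes, annot, prefix = "fwd")
  p2 <- write_triple(d, rev(rows), rev(nodes), annot, prefix = "rev")
  g1 <- load_pathway(p1[1], p1[2], p1[3], pathway_id = "pw")
  g2 <- load_pathway(p2[1], p2[2], p2[3], pathway_id = "pw")
  expect_identical(enumerate_circuits(g1), enumerate_circuits(g2))
})

test_that("removing an activation edge never adds a circuit", {
  g <- toy_diamond()
  full <- names(enumerate_circuits(g))
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[-i, , drop = FALSE]
    sub <- tryCatch(
      names(enumerate_circuits(
        pathway_graph("diamond", e, genes = g$genes,
                      receptors = g$receptors, effectors = g$effectors))),
      error = function(e) character(0))
    expect_true(all(sub %in% full))
  }
})

test_that("the TNF-NPY toy pathway round-trips through files", {
  g <- tnf_npy_pathway()
  circ <- enumerate_circuits(g)
  expect_true("hsa04920:TNF-NPY" %in% names(circ))
  expect_true("TRAF2" %in% circ[["hsa04920:TNF-NPY"]]$member_nodes)
  expect_equal(circ[["hsa04920:TNF-NPY"]]$inhibitor_context$source, "PPARA")

  d <- withr::local_tempdir()
  paths <- write_pathway(g, d)
  g2 <- load_pathway(paths["edges"], paths["nodes"], paths["annotation"],
                     pathway_id = "hsa04920")
  expect_identical(enumerate_circuits(g2), circ)

  jf <- file.path(d, "circuits.json")
  write_circuits_json(circ, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$circuit_id, "hsa04920:TNF-NPY")
})
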