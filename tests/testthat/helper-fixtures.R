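# Shared fixtures and independent oracles.

toy_chain <- function() {
  pathway_graph("chain",
                data.frame(source = c("R", "A"), target = c("A", "E"),
                           sign = "activation"),
                genes = list(R = "gR", A = "gA", E = "gE"),
                receptors = "R", effectors = "E")
}

toy_inhibited_chain <- function() {
  pathway_graph("inh",
                data.frame(source = c("R", "B"), target = c("E", "E"),
                           sign = c("activation", "inhibition")),
                genes = list(R = "gR", E = "gE", B = "gB"),
                receptors = "R", effectors = "E")
}

toy_diamond <- function() {
  pathway_graph("diamond",
                data.frame(source = c("R", "R", "A", "B"),
                           target = c("A", "B", "E", "E"),
                           sign = "activation"),
                genes = list(R = "gR", A = "gA", B = "gB", E = "gE"),
                receptors = "R", effectors = "E")
}

first_circuit <- function(graph) enumerate_circuits(graph)[[1L]]

# Independent brute-force oracle for the transmission probability: loops over
# every joint Boolean state and evaluates the event by naive recursion on the
# graph, sharing no code with the package's vectorized engine.
oracle_transmission <- function(circuit, graph, probs) {
  nodes <- sort(unique(c(circuit$member_nodes,
                         circuit$inhibitor_context$source)))
  k <- length(nodes)
  act <- graph$edges[graph$edges$sign == "activation", , drop = FALSE]
  inh <- circuit$inhibitor_context
  total <- 0
  for (s in 0:(2^k - 1)) {
    state <- stats::setNames(bitwAnd(s, 2^(seq_len(k) - 1L)) > 0, nodes)
    w <- prod(ifelse(state, probs[nodes], 1 - probs[nodes]))
    if (w == 0) next
    transmits <- function(n) {
      if (!state[[n]]) return(FALSE)
      blockers <- inh$source[inh$target == n]
      if (length(blockers) && any(state[blockers])) return(FALSE)
      if (n == circuit$receptor) return(TRUE)
      parents <- intersect(act$source[act$target == n],
                           circuit$member_nodes)
      length(parents) > 0 && any(vapply(parents, transmits, logical(1)))
    }
    if (transmits(circuit$effector)) total <- total + w
  }
  total
}

# Random DAG circuit fixture: m member nodes on a guaranteed receptor ->
# effector spine with extra random forward activation edges, plus up to
# `n_inhibitors` inhibition edges from external context nodes.
random_circuit_fixture <- function(seed, n_members = 6L, n_inhibitors = 2L,
                                   edge_prob = 0.35) {
  set.seed(seed)
  members <- sprintf("n%02d", seq_len(n_members))
  edges <- data.frame(source = members[-n_members],
                      target = members[-1L], sign = "activation")
  for (i in seq_len(n_members - 1L)) {
    for (j in seq(i + 1L, n_members)) {
      if (j - i > 1L && stats::runif(1) < edge_prob)
        edges <- rbind(edges, data.frame(source = members[i],
                                         target = members[j],
                                         sign = "activation"))
    }
  }
  k_inh <- sample(0:n_inhibitors, 1L)
  ext <- character(0)
  if (k_inh > 0L) {
    ext <- sprintf("x%02d", seq_len(k_inh))
    edges <- rbind(edges,
                   data.frame(source = ext,
                              target = sample(members[-1L], k_inh,
                                              replace = TRUE),
                              sign = "inhibition"))
  }
  nodes <- c(members, ext)
  g <- pathway_graph(paste0("rnd", seed), edges,
                     genes = stats::setNames(as.list(paste0("g_", nodes)),
                                             nodes),
                     receptors = members[1L], effectors = members[n_members])
  cir <- first_circuit(g)
  probs <- stats::setNames(stats::runif(length(nodes)), nodes)
  list(graph = g, circuit = cir, probs = probs)
}

# Exhaustive CFS oracle: the best merit over every non-empty feature subset,
# computed straight from cfs_merit (independent of the search code).
exhaustive_best_merit <- function(x, y) {
  m <- ncol(x)
  best <- -Inf
  for (k in seq_len(m)) {
    sets <- utils::combn(m, k)
    for (i in seq_len(ncol(sets)))
      best <- max(best, cfs_merit(x[, sets[, i], drop = FALSE], y))
  }
  best
}

# Small synthetic configuration for fast unit tests.
small_cfg <- function(seed = 42L, ...) {
  args <- utils::modifyList(list(seed = seed, n_reference_arrays = 120L,
                                 n_train_samples = 50L,
                                 n_validate_samples = 30L,
                                 n_pathways = 2L,
                                 n_informative_circuits = 2L),
                            list(...))
  do.call(synth_config, args)
}

run_cli <- function(args) {
  script <- system.file("cli", "circuitry.R", package = "circuitry")
  stopifnot(nzchar(script))
  out <- system2(file.path(R.home("bin"), "Rscript"), c(script, args),
                 stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
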