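# Probability that signal is transmitted from receptor to effector in a
# circuit, under independent Bernoulli node activation states.

# Deterministic transmission event, evaluated for many joint states at once.
# `states`: logical matrix, one row per joint activation state, columns named
# with every involved node (members + inhibitor-context sources). Returns the
# logical vector "effector transmits" per row.
#
# Semantics: node n transmits iff
#   active(n) AND (n is the receptor OR some activating parent among the
#   member nodes transmits) AND no inhibitor impinging on n blocks.
# mode = "context": an inhibitor blocks iff its node is active.
# mode = "signal":  a member inhibitor blocks iff it is active and reached
#   from the receptor in an activation-only pass (inhibition ignored there,
#   which keeps the definition acyclic under feedback inhibition); an
#   inhibitor outside the member set blocks iff active.
.propagate_states <- function(circuit, graph, states,
                              mode = c("context", "signal")) {
  mode <- match.arg(mode)
  members <- circuit$member_nodes
  act <- graph$edges[graph$edges$sign == "activation" &
                       graph$edges$source %in% members &
                       graph$edges$target %in% members, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(act[c("source", "target")],
                                      directed = TRUE,
                                      vertices = data.frame(name = members))
  topo <- names(igraph::topo_sort(ig, mode = "out"))
  parents <- lapply(stats::setNames(members, members),
                    function(n) act$source[act$target == n])
  inh <- circuit$inhibitor_context
  inhibitors <- lapply(stats::setNames(members, members),
                       function(n) inh$source[inh$target == n])

  n_states <- nrow(states)
  transmit <- matrix(FALSE, n_states, length(members),
                     dimnames = list(NULL, members))

  pure <- NULL
  if (mode == "signal") {              # activation-only reachability pass
    pure <- matrix(FALSE, n_states, length(members),
                   dimnames = list(NULL, members))
    for (n in topo) {
      up <- if (n == circuit$receptor) TRUE
            else if (length(parents[[n]]) == 0L) FALSE
            else rowSums(pure[, parents[[n]], drop = FALSE]) > 0L
      pure[, n] <- states[, n] & up
    }
  }

  for (n in topo) {
    up <- if (n == circuit$receptor) TRUE
          else if (length(parents[[n]]) == 0L) FALSE
          else rowSums(transmit[, parents[[n]], drop = FALSE]) > 0L
    blocked <- FALSE
    for (i in inhibitors[[n]]) {
      b <- if (mode == "context" || !(i %in% members)) states[, i]
           else pure[, i]
      blocked <- blocked | b
    }
    transmit[, n] <- states[, n] & up & !blocked
  }
  transmit[, circuit$effector]
}

.involved_nodes <- function(circuit) {
  sort(unique(c(circuit$member_nodes, circuit$inhibitor_context$source)))
}

.check_probs <- function(circuit, probs) {
  nodes <- .involved_nodes(circuit)
  missing <- nodes[!(nodes %in% names(probs)) | is.na(probs[nodes])]
  if (length(missing))
    stop("missing node probability for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- probs[nodes]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("node probabilities must be finite and in [0, 1]", call. = FALSE)
  p
}

#' Exact circuit transmission probability
#'
#' Computes, under independent Bernoulli activation states of the involved
#' nodes (circuit members plus inhibitor-context sources), the exact
#' probability that signal traverses from the receptor to the effector:
#' a node transmits iff it is active, it is the receptor or at least one
#' activating parent among the member nodes transmits, and no inhibitor
#' impinging on it blocks. With the default `mode = "context"` an inhibitor
#' blocks while its node is active; with `mode = "signal"` a member inhibitor
#' must additionally be reached from the receptor (activation-only pass).
#'
#' The joint state space (2^k for k involved nodes) is enumerated in chunks,
#' so the result is exact (to floating point). Circuits with more than
#' `max_exact_nodes` involved nodes are refused with a pointer to
#' [transmission_probability_mc()].
#'
#' @param circuit a circuit from [enumerate_circuits()].
#' @param graph the [pathway_graph()] the circuit came from.
#' @param probs named numeric vector: activation probability per node,
#'   covering every member and inhibitor-context node.
#' @param mode inhibitor semantics, `"context"` (default) or `"signal"`.
#' @param max_exact_nodes refuse exact enumeration beyond this many involved
#'   nodes (default 22).
#' @return A single probability.
#' @examples
#' g <- pathway_graph("toy",
#'   data.frame(source = c("R", "A"), target = c("A", "E"),
#'              sign = "activation"),
#'   genes = list(R = "g1", A = "g2", E = "g3"),
#'   receptors = "R", effectors = "E")
#' cir <- enumerate_circuits(g)[[1]]
#' transmission_probability(cir, g, c(R = 0.9, A = 0.8, E = 0.7)) # 0.504
#' @export
transmission_probability <- function(circuit, graph, probs,
                                     mode = c("context", "signal"),
                                     max_exact_nodes = 22L) {
  mode <- match.arg(mode)
  p <- .check_probs(circuit, probs)
  nodes <- names(p)
  k <- length(nodes)
  if (k > max_exact_nodes)
    stop(sprintf("%d involved nodes exceed max_exact_nodes = %d; use transmission_probability_mc()",
                 k, max_exact_nodes), call. = FALSE)
  total <- 0
  chunk <- 2^min(k, 16L)
  n_states <- 2^k
  bits <- 2^(seq_len(k) - 1L)
  for (start in seq(0, n_states - 1, by = chunk)) {
    idx <- start + seq_len(min(chunk, n_states - start)) - 1
    states <- matrix(FALSE, length(idx), k, dimnames = list(NULL, nodes))
    for (j in seq_len(k))
      states[, j] <- (idx %/% bits[j]) %% 2 == 1
    w <- rep(1, length(idx))
    for (j in seq_len(k))
      w <- w * ifelse(states[, j], p[j], 1 - p[j])
    ok <- .propagate_states(circuit, graph, states, mode)
    total <- total + sum(w[ok])
  }
  min(max(total, 0), 1)
}

#' Monte-Carlo circuit transmission probability
#'
#' Seeded Monte-Carlo estimate of the same Boolean transmission event as
#' [transmission_probability()], for circuits too large for exact
#' enumeration.
#'
#' @inheritParams transmission_probability
#' @param n_draws number of joint states to sample (>= 1000).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @return A list with `estimate`, `stderr` (binomial), `n_draws`.
#' @export
transmission_probability_mc <- function(circuit, graph, probs,
                                        n_draws = 1e5L, seed = 1L,
                                        mode = c("context", "signal")) {
  mode <- match.arg(mode)
  if (n_draws < 1000L) stop("n_draws must be >= 1000", call. = FALSE)
  p <- .check_probs(circuit, probs)
  k <- length(p)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  states <- matrix(stats::runif(n_draws * k) < rep(p, each = n_draws),
                   n_draws, k, dimnames = list(NULL, names(p)))
  ok <- .propagate_states(circuit, graph, states, mode)
  est <- mean(ok)
  list(estimate = est,
       stderr = sqrt(est * (1 - est) / n_draws),
       n_draws = n_draws)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Activity matrix: circuit transmission probabilities per sample
#'
#' Converts per-gene activation probabilities into the samples x circuits
#' matrix of transmission probabilities — the mechanism-based biomarkers used
#' as features downstream. Columns are ordered deterministically (pathway,
#' then receptor, then effector); sample order is preserved.
#'
#' @param gene_prob samples x genes probability matrix
#'   (see [gene_probabilities()]).
#' @param pathways list of [pathway_graph()] objects.
#' @param rule node combination rule, see [combine_probabilities()].
#' @param mode inhibitor semantics, see [transmission_probability()].
#' @return samples x circuits numeric matrix, attribute `level = "circuit"`.
#' @export
activity_matrix <- function(gene_prob, pathways, rule = "union",
                            mode = "context") {
  stopifnot(is.matrix(gene_prob))
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  cols <- list()
  for (g in pathways) {
    np <- node_probabilities(gene_prob, g, rule = rule)
    for (cir in enumerate_circuits(g)) {
      cols[[cir$circuit_id]] <- vapply(seq_len(nrow(np)), function(i)
        transmission_probability(cir, g, np[i, ], mode = mode),
        numeric(1))
    }
  }
  if (length(cols) == 0L) stop("no circuits found in pathway set", call. = FALSE)
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(gene_prob)
  attr(out, "level") <- "circuit"
  out
}

#' Differentially activated circuits between two sample groups
#'
#' Per-circuit two-sample test on transmission probabilities with
#' Benjamini-Hochberg adjustment across circuits. Direction is the sign of
#' (mean of group 2 minus mean of group 1): `"Up"`, `"Down"`, or `"none"`
#' when the means are equal. Rows are ordered by adjusted p-value with ties
#' broken lexicographically by circuit id.
#'
#' @param activity samples x circuits matrix from [activity_matrix()].
#' @param groups two-level factor (or vector) of length `nrow(activity)`;
#'   group 1 is the first level (reference).
#' @param method `"wilcoxon"` (rank-sum, default) or `"welch"` (t-test).
#' @return data.frame with columns `circuit_id`, `statistic`, `p_value`,
#'   `adj_p`, `direction`.
#' @export
differential_activation <- function(activity, groups,
                                    method = c("wilcoxon", "welch")) {
  method <- match.arg(method)
  stopifnot(is.matrix(activity))
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples", call. = FALSE)
  g1 <- groups == levels(groups)[1L]
  res <- lapply(colnames(activity), function(cid) {
    x <- activity[g1, cid]; y <- activity[!g1, cid]
    d <- mean(y) - mean(x)
    if (stats::sd(c(x, y)) == 0) {
      return(data.frame(circuit_id = cid, statistic = NA_real_,
                        p_value = 1, direction = "none"))
    }
    ht <- suppressWarnings(
      if (method == "wilcoxon") stats::wilcox.test(y, x, exact = FALSE)
      else stats::t.test(y, x))
    data.frame(circuit_id = cid,
               statistic = unname(ht$statistic),
               p_value = ht$p.value,
               direction = if (d > 0) "Up" else if (d < 0) "Down" else "none")
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$adj_p, out$circuit_id),
             c("circuit_id", "statistic", "p_value", "adj_p", "direction")]
  rownames(out) <- NULL
  out
}
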