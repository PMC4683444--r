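# Signed pathway topologies with multi-protein nodes, and enumeration of
# receptor->effector signaling circuits.

#' Construct a validated pathway graph
#'
#' A pathway is a signed directed graph whose vertices ("nodes") are sets of
#' one or more proteins/genes and whose edges are activations or inhibitions.
#' Receptor and effector nodes are explicit annotations; signaling circuits
#' are the sub-graphs that transmit signal from a receptor to an effector.
#'
#' Validation enforces: unique node ids, non-empty gene sets, no self-loops,
#' edges referencing known nodes, at least one receptor and one effector, and
#' acyclicity of the activation subgraph restricted to every
#' receptor->effector reachable set (transmission probabilities are defined on
#' acyclic structure only).
#'
#' @param pathway_id identifier, e.g. `"hsa04920"`.
#' @param edges data.frame with columns `source`, `target`,
#'   `sign` (`"activation"` or `"inhibition"`).
#' @param genes named list mapping each `node_id` to a non-empty character
#'   vector of gene identifiers.
#' @param receptors,effectors character vectors of node ids.
#' @param labels optional named character vector of display labels per node;
#'   defaults to the node ids. Labels are used in circuit names.
#' @return An object of class `pathway_graph`.
#' @seealso [load_pathway()], [enumerate_circuits()]
#' @export
pathway_graph <- function(pathway_id, edges, genes, receptors, effectors,
                          labels = NULL) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("source", "target", "sign")
  if (!all(required %in% names(edges)))
    stop("edges must have columns source, target, sign", call. = FALSE)
  edges <- edges[required]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.character(edges$sign)
  if (!all(edges$sign %in% c("activation", "inhibition")))
    stop("edge sign must be 'activation' or 'inhibition'", call. = FALSE)
  if (any(edges$source == edges$target))
    stop("self-loops are not accepted: ",
         paste(unique(edges$source[edges$source == edges$target]),
               collapse = ", "), call. = FALSE)

  node_ids <- sort(unique(names(genes)))
  if (length(node_ids) != length(genes))
    stop("duplicate node_id in gene table", call. = FALSE)
  empty <- node_ids[vapply(genes[node_ids],
                           function(g) length(g) == 0L || all(!nzchar(g)),
                           logical(1))]
  if (length(empty))
    stop("node with empty gene set: ", paste(empty, collapse = ", "),
         call. = FALSE)
  genes <- lapply(genes[node_ids], function(g) unique(as.character(g)))

  unknown <- setdiff(unique(c(edges$source, edges$target)), node_ids)
  if (length(unknown))
    stop("edge references unknown node_id: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)

  receptors <- sort(unique(as.character(receptors)))
  effectors <- sort(unique(as.character(effectors)))
  bad <- setdiff(c(receptors, effectors), node_ids)
  if (length(bad))
    stop("receptor/effector annotation for unknown node_id: ",
         paste(sort(bad), collapse = ", "), call. = FALSE)
  if (length(receptors) == 0L || length(effectors) == 0L)
    stop("pathway must annotate at least one receptor and one effector",
         call. = FALSE)

  if (is.null(labels)) labels <- stats::setNames(node_ids, node_ids)
  labels <- stats::setNames(as.character(labels[node_ids]), node_ids)
  labels[is.na(labels) | !nzchar(labels)] <-
    node_ids[is.na(labels) | !nzchar(labels)]

  # deterministic edge ordering regardless of input row order
  edges <- edges[order(edges$source, edges$target, edges$sign), , drop = FALSE]
  edges <- unique(edges)
  rownames(edges) <- NULL

  g <- structure(list(pathway_id = pathway_id,
                      node_ids = node_ids,
                      genes = genes,
                      labels = labels,
                      edges = edges,
                      receptors = receptors,
                      effectors = effectors),
                 class = "pathway_graph")
  .check_circuit_acyclicity(g)
  g
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s': %d nodes, %d edges (%d inhibition), %d receptor(s), %d effector(s)\n",
              x$pathway_id, length(x$node_ids), nrow(x$edges),
              sum(x$edges$sign == "inhibition"),
              length(x$receptors), length(x$effectors)))
  invisible(x)
}

# igraph over activation edges only; vertices = all nodes
.activation_igraph <- function(graph) {
  act <- graph$edges[graph$edges$sign == "activation", , drop = FALSE]
  igraph::graph_from_data_frame(act[c("source", "target")],
                                directed = TRUE,
                                vertices = data.frame(name = graph$node_ids))
}

# nodes on >=1 directed activation path receptor -> effector (empty if none)
.path_node_set <- function(ig, receptor, effector) {
  fwd <- names(igraph::subcomponent(ig, receptor, mode = "out"))
  if (!(effector %in% fwd)) return(character(0))
  bwd <- names(igraph::subcomponent(ig, effector, mode = "in"))
  sort(intersect(fwd, bwd))
}

.check_circuit_acyclicity <- function(graph) {
  ig <- .activation_igraph(graph)
  for (r in graph$receptors) {
    for (e in graph$effectors) {
      members <- .path_node_set(ig, r, e)
      if (length(members) < 2L) next
      sub <- igraph::induced_subgraph(ig, members)
      if (!igraph::is_dag(sub)) {
        comp <- igraph::components(sub, mode = "strong")
        cyc <- names(comp$membership)[comp$membership ==
                                        which.max(comp$csize)]
        stop(sprintf("cycle in receptor->effector subgraph %s->%s among nodes: %s",
                     r, e, paste(sort(cyc), collapse = ", ")), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Load a pathway from its edge/node/annotation file triple
#'
#' File formats (tab-separated, no header):
#' * edge file: `source<TAB>target<TAB>sign`, sign in
#'   \{`activation`, `inhibition`\} (SIF-like);
#' * node file: `node_id<TAB>gene1;gene2;...` and optionally a third column
#'   with a display label;
#' * annotation file: `node_id<TAB>role`, role in \{`receptor`, `effector`\}.
#'
#' @param edge_file,node_file,annotation_file paths.
#' @param pathway_id identifier; defaults to the edge file's base name
#'   without extension.
#' @return A validated [pathway_graph()].
#' @export
load_pathway <- function(edge_file, node_file, annotation_file,
                         pathway_id = NULL) {
  for (f in c(edge_file, node_file, annotation_file))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  if (is.null(pathway_id))
    pathway_id <- sub("\\.[^.]*$", "", basename(edge_file))

  ed <- utils::read.delim(edge_file, header = FALSE,
                          colClasses = "character",
                          col.names = c("source", "target", "sign"))
  nd <- utils::read.delim(node_file, header = FALSE,
                          colClasses = "character")
  if (ncol(nd) < 2L) stop("node file needs >= 2 columns", call. = FALSE)
  genes <- stats::setNames(strsplit(nd[[2L]], ";", fixed = TRUE), nd[[1L]])
  labels <- if (ncol(nd) >= 3L) stats::setNames(nd[[3L]], nd[[1L]]) else NULL
  an <- utils::read.delim(annotation_file, header = FALSE,
                          colClasses = "character",
                          col.names = c("node_id", "role"))
  if (!all(an$role %in% c("receptor", "effector")))
    stop("annotation role must be 'receptor' or 'effector'", call. = FALSE)

  pathway_graph(pathway_id, ed, genes,
                receptors = an$node_id[an$role == "receptor"],
                effectors = an$node_id[an$role == "effector"],
                labels = labels)
}

#' Write a pathway graph as its file triple
#'
#' Inverse of [load_pathway()]; used to materialize synthetic fixtures.
#'
#' @param graph a [pathway_graph()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; defaults to the pathway id.
#' @return Invisibly, the three file paths written.
#' @export
write_pathway <- function(graph, dir, prefix = graph$pathway_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".edges.tsv", ".nodes.tsv",
                                           ".annot.tsv")))
  utils::write.table(graph$edges, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  nd <- data.frame(node_id = graph$node_ids,
                   genes = vapply(graph$genes, paste, "", collapse = ";"),
                   label = graph$labels[graph$node_ids])
  utils::write.table(nd, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  an <- rbind(data.frame(node_id = graph$receptors, role = "receptor"),
              data.frame(node_id = graph$effectors, role = "effector"))
  utils::write.table(an, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(stats::setNames(paths, c("edges", "nodes", "annotation")))
}

#' Enumerate receptor->effector circuits of a pathway
#'
#' One circuit is emitted per (receptor, effector) pair connected by at least
#' one directed path of activation edges. All parallel paths between the pair
#' (bi-/multi-furcations) are merged into a single circuit whose
#' `member_nodes` is the union of nodes on any such path. Inhibition edges
#' never carry forward signal flow; every inhibition edge whose target is a
#' member node enters the circuit's `inhibitor_context`. Circuits are named
#' `<pathway_id>:<receptor label>-<effector label>` and returned ordered by
#' receptor id then effector id.
#'
#' @param graph a [pathway_graph()].
#' @return A list of `circuit` objects.
#' @export
enumerate_circuits <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ig <- .activation_igraph(graph)
  inh <- graph$edges[graph$edges$sign == "inhibition", , drop = FALSE]
  out <- list()
  for (r in graph$receptors) {
    for (e in graph$effectors) {
      if (r == e) next
      members <- .path_node_set(ig, r, e)
      if (length(members) == 0L) next
      ctx <- inh[inh$target %in% members, c("source", "target"), drop = FALSE]
      rownames(ctx) <- NULL
      cid <- sprintf("%s:%s-%s", graph$pathway_id,
                     graph$labels[[r]], graph$labels[[e]])
      out[[cid]] <- structure(list(circuit_id = cid,
                                   pathway_id = graph$pathway_id,
                                   receptor = r,
                                   effector = e,
                                   member_nodes = members,
                                   inhibitor_context = ctx),
                              class = "circuit")
    }
  }
  out[order(names(out))]
}

#' @export
print.circuit <- function(x, ...) {
  cat(sprintf("circuit %s: %s -> %s via %d node(s), %d inhibition edge(s) in context\n",
              x$circuit_id, x$receptor, x$effector,
              length(x$member_nodes), nrow(x$inhibitor_context)))
  invisible(x)
}

#' Export circuits as JSON
#'
#' @param circuits list of circuits from [enumerate_circuits()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_circuits_json <- function(circuits, path) {
  payload <- lapply(unname(circuits), function(cc) {
    list(circuit_id = cc$circuit_id,
         pathway_id = cc$pathway_id,
         receptor = cc$receptor,
         effector = cc$effector,
         member_nodes = cc$member_nodes,
         inhibitor_context = cc$inhibitor_context)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
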