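# Phospho-proteomic concordance: protein-level SILAC ratio summaries,
# hyperP/deP/NC classification, and the join against predicted circuit
# signaling directions.

#' Mean protein-level phosphorylation ratio
#'
#' Summarizes a protein's phosphosite SILAC ratios into one value. The
#' default is the arithmetic mean; `type = "geometric"` is available since
#' ratios are multiplicative.
#'
#' @param site_ratios numeric vector of positive phosphosite ratios.
#' @param type `"arithmetic"` (default) or `"geometric"`.
#' @return The mean ratio, or `NA` for an empty vector.
#' @export
mean_protein_ratio <- function(site_ratios, type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  site_ratios <- site_ratios[!is.na(site_ratios)]
  if (length(site_ratios) == 0L) return(NA_real_)
  if (any(site_ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  if (type == "arithmetic") mean(site_ratios)
  else exp(mean(log(site_ratios)))
}

#' Classify a phosphorylation ratio
#'
#' Ratio cutoffs: above 1.1 is `"increased"`, within the closed interval
#' `[0.9, 1.1]` `"unchanged"`, below 0.9 `"decreased"`.
#'
#' @param r numeric vector of positive ratios (NA allowed).
#' @return Character vector in \{`increased`, `unchanged`, `decreased`, NA\}.
#' @export
classify_ratio <- function(r) {
  out <- rep(NA_character_, length(r))
  out[!is.na(r) & r > 1.1] <- "increased"
  out[!is.na(r) & r >= 0.9 & r <= 1.1] <- "unchanged"
  out[!is.na(r) & r < 0.9] <- "decreased"
  out
}

#' Protein phosphorylation state from the two ratio categories
#'
#' Hyperphosphorylation (`"hyperP"`) is a decreased stimulated/control ratio
#' together with an increased treated/stimulated ratio; dephosphorylation
#' (`"deP"`) is an increased stimulated/control ratio with a decreased
#' treated/stimulated ratio. Every other combination is no-change (`"NC"`);
#' a missing category gives `NA`.
#'
#' @param stim_ctrl,treat_stim categories from [classify_ratio()]
#'   (vectorized, recycled to common length).
#' @return Character vector in \{`hyperP`, `deP`, `NC`, NA\}.
#' @export
phospho_state <- function(stim_ctrl, treat_stim) {
  n <- max(length(stim_ctrl), length(treat_stim))
  sc <- rep_len(stim_ctrl, n); ts <- rep_len(treat_stim, n)
  out <- rep("NC", n)
  out[sc == "decreased" & ts == "increased"] <- "hyperP"
  out[sc == "increased" & ts == "decreased"] <- "deP"
  out[is.na(sc) | is.na(ts)] <- NA_character_
  out
}

#' Summarize a phosphosite table into per-protein records
#'
#' Input: long-format table with columns `protein`, `cell_line`, `site`,
#' `condition_pair` (`"stim_ctrl"` or `"treat_stim"`), `ratio`. Sites are
#' averaged per (protein, cell_line, condition_pair) with
#' [mean_protein_ratio()], classified with [classify_ratio()], and combined
#' into a state with [phospho_state()].
#'
#' @param sites data.frame as described (e.g. from [read_phospho_table()]).
#' @param mean_type passed to [mean_protein_ratio()].
#' @return data.frame with one row per (protein, cell_line):
#'   `protein`, `cell_line`, `stim_ctrl_ratio`, `treat_stim_ratio`, `state`.
#' @export
phospho_records <- function(sites, mean_type = "arithmetic") {
  need <- c("protein", "cell_line", "site", "condition_pair", "ratio")
  stopifnot(all(need %in% names(sites)))
  if (!all(sites$condition_pair %in% c("stim_ctrl", "treat_stim")))
    stop("condition_pair must be 'stim_ctrl' or 'treat_stim'", call. = FALSE)
  keys <- unique(sites[c("protein", "cell_line")])
  keys <- keys[order(keys$protein, keys$cell_line), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- sites$protein == keys$protein[i] &
      sites$cell_line == keys$cell_line[i]
    sc <- mean_protein_ratio(
      sites$ratio[sel & sites$condition_pair == "stim_ctrl"], mean_type)
    ts <- mean_protein_ratio(
      sites$ratio[sel & sites$condition_pair == "treat_stim"], mean_type)
    data.frame(protein = keys$protein[i], cell_line = keys$cell_line[i],
               stim_ctrl_ratio = sc, treat_stim_ratio = ts,
               state = phospho_state(classify_ratio(sc), classify_ratio(ts)))
  }))
  rownames(out) <- NULL
  out
}

#' Concordance table of phospho states against predicted circuit directions
#'
#' Joins each phospho-profiled protein to the circuit nodes containing it and
#' emits one row per (protein, circuit) with the per-cell-line states, the
#' circuit's predicted signaling direction, and the full protein list of the
#' matching node. Proteins found in no circuit are dropped; their count is
#' returned as attribute `n_unmatched`.
#'
#' @param records per-protein records from [phospho_records()].
#' @param circuits list of circuits (see [enumerate_circuits()]) restricted
#'   to the ones of interest (e.g. the predictor's selected circuits).
#' @param pathways list of [pathway_graph()] objects (for node gene sets and
#'   pathway ids).
#' @param directions named character vector circuit_id -> `"Up"`/`"Down"`
#'   (e.g. from [differential_activation()]).
#' @return data.frame with columns `protein`, `cell_line`, `state`,
#'   `pathway_id`, `circuit_id`, `signalling`, `node_proteins`;
#'   attribute `n_unmatched`.
#' @export
concordance_table <- function(records, circuits, pathways, directions) {
  if (inherits(pathways, "pathway_graph")) pathways <- list(pathways)
  names(pathways) <- vapply(pathways, `[[`, "", "pathway_id")
  rows <- list()
  matched <- character(0)
  for (cir in circuits) {
    g <- pathways[[cir$pathway_id]]
    if (is.null(g)) stop("pathway not supplied: ", cir$pathway_id,
                         call. = FALSE)
    for (nid in cir$member_nodes) {
      node_genes <- g$genes[[nid]]
      hits <- records[records$protein %in% node_genes, , drop = FALSE]
      if (nrow(hits) == 0L) next
      matched <- union(matched, unique(hits$protein))
      for (i in seq_len(nrow(hits))) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein = hits$protein[i],
          cell_line = hits$cell_line[i],
          state = hits$state[i],
          pathway_id = cir$pathway_id,
          circuit_id = cir$circuit_id,
          signalling = unname(directions[cir$circuit_id]),
          node_proteins = paste(node_genes, collapse = " "))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(protein = character(), cell_line = character(),
                         state = character(), pathway_id = character(),
                         circuit_id = character(), signalling = character(),
                         node_proteins = character())
  out <- out[order(out$protein, out$circuit_id, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- length(setdiff(unique(records$protein), matched))
  out
}

#' Read a phosphosite ratio table
#'
#' TSV with header columns `protein`, `cell_line`, `site`, `condition_pair`,
#' `ratio`.
#' @param path file path.
#' @return data.frame.
#' @export
read_phospho_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "cell_line", "site", "condition_pair", "ratio")
  if (!all(need %in% names(df)))
    stop("phospho table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
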