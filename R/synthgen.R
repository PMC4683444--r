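# Synthetic-data generator: reference compendium, toy pathway set, paired
# train/validate cohorts with planted circuit effects, IC50 responses and
# phosphosite tables. Every generator is a pure function of (config, seed).

#' Synthetic study configuration
#'
#' Defaults define the study conditions used throughout the package's tests:
#' a reference compendium of 500 arrays; paired cohorts of 200 training and
#' 150 validation samples sharing the platform and pathway set, with the
#' validation cohort shifted by 0.3 intensity units (batch effect); 5 random
#' toy pathways plus a miniature of the adipocytokine TNF-NPY circuit; 4
#' informative circuits whose latent activation states drive IC50 with unit
#' effect size and residual noise of 0.5 ln uM; ON/OFF expression components
#' N(10, 1) and N(4, 1) on the log2-like scale.
#'
#' @param seed integer seed (mandatory; all generators derive their streams
#'   from it).
#' @param n_reference_arrays,n_train_samples,n_validate_samples cohort sizes.
#' @param n_pathways number of random toy pathways.
#' @param nodes_per_circuit integer range (min, max) of member nodes per
#'   circuit.
#' @param genes_per_node,probesets_per_gene integer ranges.
#' @param n_informative_circuits circuits whose state enters the IC50 model.
#' @param n_drugs number of drugs (each with its own effect-sign pattern).
#' @param beta effect size per informative circuit (ln uM per active state).
#' @param beta0 IC50 intercept (ln uM).
#' @param noise_sd residual IC50 noise (ln uM).
#' @param off_mean,on_mean,off_sd,on_sd expression component parameters.
#' @param mean_jitter_sd per-probeset jitter of the component means.
#' @param batch_shift intensity shift added to the validation cohort.
#' @param include_tnf_npy include the TNF-NPY miniature pathway.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_reference_arrays = 500L,
                         n_train_samples = 200L,
                         n_validate_samples = 150L,
                         n_pathways = 5L,
                         nodes_per_circuit = c(3L, 5L),
                         genes_per_node = c(1L, 3L),
                         probesets_per_gene = c(1L, 2L),
                         n_informative_circuits = 4L,
                         n_drugs = 2L,
                         beta = 1,
                         beta0 = 2,
                         noise_sd = 0.5,
                         off_mean = 4, on_mean = 10,
                         off_sd = 1, on_sd = 1,
                         mean_jitter_sd = 0.15,
                         batch_shift = 0.3,
                         include_tnf_npy = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  stopifnot(cfg$n_reference_arrays > 0, cfg$n_train_samples > 0,
            cfg$n_validate_samples > 0, cfg$n_pathways > 0,
            cfg$noise_sd >= 0, cfg$on_mean >= cfg$off_mean)
  structure(cfg, class = "synth_config")
}

# run expr under a deterministic sub-stream derived from the config seed
.with_stream <- function(cfg, offset, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((cfg$seed * 7L + offset) %% 2147483647L)
  expr
}

.rint <- function(range) {
  if (range[1L] >= range[2L]) range[1L]
  else sample(seq(range[1L], range[2L]), 1L)
}

#' Miniature TNF-NPY pathway (adipocytokine signaling, hsa04920 toy)
#'
#' A hand-written miniature reproducing the topology of the TNF-NPY circuit:
#' TNF (receptor) activates TRAF2, which activates an NFKB node (NFKB1,
#' RELA), which activates the NPY effector; a PPARA node inhibits NFKB.
#' Synthetic stand-in for the KEGG-derived pathway; used by fixtures and the
#' concordance example.
#' @return A [pathway_graph()].
#' @export
tnf_npy_pathway <- function() {
  pathway_graph(
    "hsa04920",
    data.frame(source = c("TNF", "TRAF2", "NFKB", "PPARA"),
               target = c("TRAF2", "NFKB", "NPY", "NFKB"),
               sign = c("activation", "activation", "activation",
                        "inhibition")),
    genes = list(TNF = "TNF", TRAF2 = "TRAF2",
                 NFKB = c("NFKB1", "RELA"), NPY = "NPY", PPARA = "PPARA"),
    receptors = "TNF", effectors = "NPY")
}

#' Generate the toy pathway set
#'
#' Deterministic given the config seed: `n_pathways` small DAG pathways
#' mixing chains, diamonds and external inhibitors, plus (by default) the
#' [tnf_npy_pathway()] miniature appended last.
#'
#' @param cfg a [synth_config()].
#' @return Named list of [pathway_graph()] objects.
#' @export
make_pathway_fixtures <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_stream(cfg, 1L, {
    out <- list()
    for (i in seq_len(cfg$n_pathways)) {
      pid <- sprintf("syn%02d", i)
      n_mid <- max(1L, .rint(cfg$nodes_per_circuit) - 2L)
      mids <- paste0("M", seq_len(n_mid))
      nodes <- c("R", mids, "E")
      edges <- if (n_mid == 1L) {
        data.frame(source = c("R", "M1"), target = c("M1", "E"))
      } else if (stats::runif(1) < 0.5) {
        # diamond head: R -> {M1, M2} -> (chain of the rest) -> E
        rest <- mids[-(1:2)]
        chain <- c("M1", rest, "E")
        data.frame(source = c("R", "R", "M2", chain[-length(chain)]),
                   target = c("M1", "M2", chain[2L], chain[-1L]))
      } else {
        chain <- c("R", mids, "E")
        data.frame(source = chain[-length(chain)], target = chain[-1L])
      }
      edges <- unique(edges)
      edges$sign <- "activation"
      if (stats::runif(1) < 0.6) {      # external inhibitor on a mid node
        nodes <- c(nodes, "I")
        edges <- rbind(edges,
                       data.frame(source = "I", target = sample(mids, 1L),
                                  sign = "inhibition"))
      }
      genes <- lapply(stats::setNames(nodes, nodes), function(nd)
        paste0(pid, "_", nd, "_g", seq_len(.rint(cfg$genes_per_node))))
      out[[pid]] <- pathway_graph(pid, edges, genes,
                                  receptors = "R", effectors = "E")
    }
    if (cfg$include_tnf_npy) out[["hsa04920"]] <- tnf_npy_pathway()
    out
  })
}

#' Generate the probeset platform for a pathway set
#'
#' One to `probesets_per_gene` probesets per gene; each probeset carries its
#' own ON/OFF component truth (means jittered around the configured values).
#'
#' @param cfg a [synth_config()].
#' @param pathways from [make_pathway_fixtures()].
#' @return data.frame with columns `probeset_id`, `gene_id`, `off_mean`,
#'   `on_mean`, `off_sd`, `on_sd`, `on_weight` (the ground-truth mixture).
#' @export
make_platform <- function(cfg, pathways) {
  stopifnot(inherits(cfg, "synth_config"))
  genes <- unique(unlist(lapply(pathways, function(g) unlist(g$genes)),
                         use.names = FALSE))
  .with_stream(cfg, 2L, {
    rows <- lapply(genes, function(g) {
      k <- .rint(cfg$probesets_per_gene)
      data.frame(probeset_id = paste0(g, "_ps", seq_len(k)), gene_id = g)
    })
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df$off_mean <- cfg$off_mean + stats::rnorm(n, 0, cfg$mean_jitter_sd)
    df$on_mean <- cfg$on_mean + stats::rnorm(n, 0, cfg$mean_jitter_sd)
    df$off_sd <- cfg$off_sd
    df$on_sd <- cfg$on_sd
    df$on_weight <- stats::runif(n, 0.35, 0.65)
    df
  })
}

#' Generate the reference expression compendium
#'
#' Each probeset is drawn from its own two-component mixture across
#' heterogeneous reference arrays — the small-scale stand-in for a public
#' microarray compendium against which ON/OFF calibrations are fitted.
#'
#' @param cfg a [synth_config()].
#' @param platform from [make_platform()].
#' @return numeric matrix, probesets x arrays.
#' @export
make_reference_compendium <- function(cfg, platform) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_stream(cfg, 3L, {
    n <- cfg$n_reference_arrays
    m <- t(vapply(seq_len(nrow(platform)), function(i) {
      on <- stats::runif(n) < platform$on_weight[i]
      ifelse(on,
             stats::rnorm(n, platform$on_mean[i], platform$on_sd[i]),
             stats::rnorm(n, platform$off_mean[i], platform$off_sd[i]))
    }, numeric(n)))
    dimnames(m) <- list(platform$probeset_id,
                        sprintf("ref%04d", seq_len(n)))
    m
  })
}

# gene-level ON probability so that P(node active) = q under union semantics
.gene_on_prob <- function(q, n_genes) 1 - (1 - q)^(1 / n_genes)

#' Generate one cohort (expression + IC50 response + ground truth)
#'
#' Samples carry latent circuit states: for each informative circuit a
#' per-sample activity driver u ~ U(0, 1) sets the member-node activation
#' probability (0.05 + 0.9 u); non-informative circuit nodes sit at 0.5 and
#' inhibitor-context nodes at 0.1. Gene states are drawn so the node-level
#' union matches the node probability, probeset intensities come from the
#' corresponding ON/OFF component, and the realized Boolean transmission
#' state of every circuit is evaluated on the drawn node states. IC50 per
#' drug is `beta0 + sum_j beta_dj * state_j + N(0, noise_sd)` over the
#' informative circuits (alternating effect signs across drugs). The
#' validation cohort adds `batch_shift` to all intensities.
#'
#' @param cfg a [synth_config()].
#' @param pathways,platform shared fixtures (see [make_pathway_fixtures()],
#'   [make_platform()]).
#' @param role `"train"` or `"validate"`.
#' @return list with `expr` (probesets x samples), `response` (data.frame
#'   `sample_id`, `drug`, `cancer`, `ic50_ln_uM`) and `truth` (list:
#'   `informative_circuits`, `beta` per drug, `beta0`, `states`
#'   samples x circuits 0/1 matrix, `u` samples x informative drivers).
#' @export
make_cohort <- function(cfg, pathways, platform,
                        role = c("train", "validate")) {
  stopifnot(inherits(cfg, "synth_config"))
  role <- match.arg(role)
  n <- if (role == "train") cfg$n_train_samples else cfg$n_validate_samples
  prefix <- if (role == "train") "tr" else "va"
  samples <- sprintf("%s%04d", prefix, seq_len(n))

  circuits <- unlist(lapply(pathways, enumerate_circuits), recursive = FALSE)
  names(circuits) <- vapply(circuits, `[[`, "", "circuit_id")
  # keep the random toy pathways first so informative circuits come from them
  cids <- names(circuits)
  if (cfg$n_informative_circuits > length(cids))
    stop("n_informative_circuits exceeds available circuits", call. = FALSE)
  informative <- cids[seq_len(cfg$n_informative_circuits)]

  pw_of <- vapply(circuits, `[[`, "", "pathway_id")
  genes_all <- lapply(pathways, `[[`, "genes")

  .with_stream(cfg, if (role == "train") 4L else 5L, {
    u <- matrix(stats::runif(n * length(informative)), n,
                dimnames = list(samples, informative))
    states <- matrix(0L, n, length(cids), dimnames = list(samples, cids))
    gene_state <- matrix(FALSE, n, 0)

    for (pid in names(pathways)) {
      g <- pathways[[pid]]
      pw_circ <- circuits[pw_of == pid]
      pw_inf <- intersect(names(pw_circ), informative)
      members <- unique(unlist(lapply(pw_circ, `[[`, "member_nodes")))
      ctx <- setdiff(unique(unlist(lapply(pw_circ, function(cc)
        cc$inhibitor_context$source))), members)
      # per-sample node activation probability
      q <- matrix(0.5, n, length(g$node_ids),
                  dimnames = list(samples, g$node_ids))
      if (length(pw_inf)) {
        drv <- if (length(pw_inf) == 1L) u[, pw_inf] else
          rowMeans(u[, pw_inf, drop = FALSE])
        for (nd in members) q[, nd] <- 0.05 + 0.9 * drv
      }
      for (nd in ctx) q[, nd] <- 0.1
      # gene states: union over genes reproduces the node probability
      node_state <- matrix(FALSE, n, length(g$node_ids),
                           dimnames = list(samples, g$node_ids))
      for (nd in g$node_ids) {
        gs <- g$genes[[nd]]
        pg <- .gene_on_prob(q[, nd], length(gs))
        st <- matrix(stats::runif(n * length(gs)) < pg, n,
                     dimnames = list(samples, gs))
        gene_state <- cbind(gene_state, st)
        node_state[, nd] <- rowSums(st) > 0L
      }
      for (cc in pw_circ) {
        inv <- .involved_nodes(cc)
        states[, cc$circuit_id] <-
          as.integer(.propagate_states(cc, g,
                                       node_state[, inv, drop = FALSE]))
      }
    }

    # probeset intensities from the gene states
    expr <- t(vapply(seq_len(nrow(platform)), function(i) {
      on <- gene_state[, platform$gene_id[i]]
      ifelse(on,
             stats::rnorm(n, platform$on_mean[i], platform$on_sd[i]),
             stats::rnorm(n, platform$off_mean[i], platform$off_sd[i]))
    }, numeric(n)))
    dimnames(expr) <- list(platform$probeset_id, samples)
    if (role == "validate") expr <- expr + cfg$batch_shift

    drugs <- paste0("drug", seq_len(cfg$n_drugs))
    beta <- lapply(stats::setNames(seq_len(cfg$n_drugs), drugs), function(d)
      stats::setNames(cfg$beta * ifelse((seq_along(informative) + d) %% 2 == 0,
                                        1, -1), informative))
    cancer <- sample(c("lung", "breast"), n, replace = TRUE)
    response <- do.call(rbind, lapply(drugs, function(d) {
      ic50 <- cfg$beta0 +
        as.vector(states[, informative, drop = FALSE] %*% beta[[d]]) +
        stats::rnorm(n, 0, cfg$noise_sd)
      data.frame(sample_id = samples, drug = d, cancer = cancer,
                 ic50_ln_uM = ic50)
    }))
    rownames(response) <- NULL

    list(expr = expr, response = response,
         truth = list(informative_circuits = informative, beta = beta,
                      beta0 = cfg$beta0, states = states, u = u))
  })
}

#' Generate a phosphosite ratio fixture
#'
#' Proteins sampled from the pathway nodes, with site ratios designed to
#' exercise every (stimulated/control x treated/stimulated) category
#' combination of the phospho classification.
#'
#' @param cfg a [synth_config()].
#' @param pathways from [make_pathway_fixtures()].
#' @return data.frame with columns `protein`, `cell_line`, `site`,
#'   `condition_pair`, `ratio`.
#' @export
make_phospho_fixture <- function(cfg, pathways) {
  stopifnot(inherits(cfg, "synth_config"))
  proteins <- unique(unlist(lapply(pathways, function(g) unlist(g$genes)),
                            use.names = FALSE))
  # representative mean per category; two sites jittered around it
  level <- c(decreased = 0.8, unchanged = 1.0, increased = 1.2)
  combos <- expand.grid(sc = names(level), ts = names(level),
                        stringsAsFactors = FALSE)
  .with_stream(cfg, 6L, {
    proteins <- c(intersect("TRAF2", proteins),
                  sample(setdiff(proteins, "TRAF2")))
    rows <- list()
    for (i in seq_len(nrow(combos))) {
      p <- proteins[(i - 1L) %% length(proteins) + 1L]
      for (pair in c("stim_ctrl", "treat_stim")) {
        target <- level[[combos[i, if (pair == "stim_ctrl") "sc" else "ts"]]]
        d <- stats::runif(1, 0, 0.04)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = p, cell_line = "cellA",
          site = paste0("S", c(1L, 2L)), condition_pair = pair,
          ratio = round(target + c(-d, d), 4))
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
}

#' Assemble a complete dataset bundle
#'
#' Builds the pathway set, platform, (for the training role) the reference
#' compendium, and the cohort for the requested role — everything
#' [cross_dataset_run()] needs, plus the generator's ground truth.
#'
#' @param cfg a [synth_config()].
#' @param role `"train"` or `"validate"`.
#' @return list: `expr`, `response`, `platform_map`, `pathways`,
#'   `reference` (train only), `truth`, `config`.
#' @export
make_bundle <- function(cfg, role = c("train", "validate")) {
  role <- match.arg(role)
  pathways <- make_pathway_fixtures(cfg)
  platform <- make_platform(cfg, pathways)
  cohort <- make_cohort(cfg, pathways, platform, role)
  out <- list(expr = cohort$expr, response = cohort$response,
              platform_map = platform[c("probeset_id", "gene_id")],
              platform_truth = platform,
              pathways = pathways, truth = cohort$truth,
              config = cfg, role = role)
  if (role == "train")
    out$reference <- make_reference_compendium(cfg, platform)
  out
}

#' Write / read a dataset bundle as plain-text files
#'
#' Writes `expression.tsv`, `response.tsv`, `platform.tsv` (with mixture
#' truth columns), per-pathway file triples under `pathways/`,
#' `reference.tsv` (training role), `truth.json` and `phospho.tsv`;
#' `read_bundle()` reconstructs the bundle from such a directory.
#'
#' @param bundle from [make_bundle()].
#' @param dir output directory.
#' @return `write_bundle`: invisibly `dir`; `read_bundle`: a bundle list.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(bundle$expr, file.path(dir, "expression.tsv"),
                          id_col = "probeset_id")
  utils::write.table(bundle$response, file.path(dir, "response.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(bundle$platform_truth, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     file.path(dir, "platform.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in bundle$pathways)
    write_pathway(g, file.path(dir, "pathways"))
  if (!is.null(bundle$reference))
    write_expression_matrix(bundle$reference, file.path(dir, "reference.tsv"),
                            id_col = "probeset_id")
  tr <- bundle$truth
  jsonlite::write_json(
    list(informative_circuits = tr$informative_circuits,
         beta = tr$beta, beta0 = tr$beta0,
         states = as.data.frame(tr$states),
         sample_ids = rownames(tr$states)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  ph <- make_phospho_fixture(bundle$config, bundle$pathways)
  utils::write.table(ph, file.path(dir, "phospho.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  pdir <- file.path(dir, "pathways")
  prefixes <- unique(sub("\\.edges\\.tsv$", "",
                         list.files(pdir, pattern = "\\.edges\\.tsv$")))
  pathways <- lapply(stats::setNames(prefixes, prefixes), function(p)
    load_pathway(file.path(pdir, paste0(p, ".edges.tsv")),
                 file.path(pdir, paste0(p, ".nodes.tsv")),
                 file.path(pdir, paste0(p, ".annot.tsv")),
                 pathway_id = p))
  platform <- utils::read.delim(file.path(dir, "platform.tsv"),
                                stringsAsFactors = FALSE)
  out <- list(expr = read_expression_matrix(file.path(dir, "expression.tsv")),
              response = read_response_table(file.path(dir, "response.tsv")),
              platform_map = platform[c("probeset_id", "gene_id")],
              platform_truth = platform,
              pathways = pathways)
  ref <- file.path(dir, "reference.tsv")
  if (file.exists(ref)) out$reference <- read_expression_matrix(ref)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj, simplifyVector = TRUE)
    states <- as.matrix(raw$states)
    rownames(states) <- raw$sample_ids
    out$truth <- list(informative_circuits = raw$informative_circuits,
                      beta = lapply(raw$beta, function(b)
                        stats::setNames(unlist(b),
                                        raw$informative_circuits)),
                      beta0 = raw$beta0, states = states)
  }
  out
}
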