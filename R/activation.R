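# ON/OFF mixture calibration and conversion of expression values into
# probeset, gene and node activation probabilities.

#' Fit a two-component ON/OFF Gaussian mixture to reference expression values
#'
#' Expression of a feature across a heterogeneous reference compendium is
#' modeled as a mixture of a low ("OFF") and a high ("ON") Gaussian
#' component, fitted by EM on the (log2) intensity scale. Components are
#' relabeled so that the ON mean is the larger one. The fit is deterministic:
#' means initialize at the 25th/75th percentiles, standard deviations at the
#' overall standard deviation, weights at 0.5/0.5; at most 200 iterations;
#' convergence at 1e-8 relative log-likelihood change.
#'
#' Degenerate inputs are flagged rather than errored: a (near-)constant
#' vector yields `degenerate_flag = "constant"`; a fit whose component means
#' differ by less than two pooled standard deviations — the separation below
#' which a balanced two-Gaussian mixture has a single mode, so the two
#' "components" describe one peak — yields `degenerate_flag = "unimodal"`.
#' Degenerate calibrations score every value as 0.5 (uninformative)
#' downstream.
#'
#' @param values numeric vector of finite expression intensities.
#' @param min_n minimum number of values required (default 50).
#' @param feature_id optional identifier stored in the result.
#' @return An object of class `mixture_calibration` with fields
#'   `off_mean`, `off_sd`, `on_mean`, `on_sd`, `on_weight`, `n_reference`,
#'   `degenerate_flag`, `loglik`, `iterations`.
#' @export
fit_mixture <- function(values, min_n = 50L, feature_id = NA_character_) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (length(values) < min_n)
    stop(sprintf("need at least %d values, got %d", min_n, length(values)),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)

  n <- length(values)
  s <- stats::sd(values)
  make <- function(off_mean, off_sd, on_mean, on_sd, on_weight, flag,
                   loglik = NA_real_, iter = 0L) {
    structure(list(feature_id = feature_id,
                   off_mean = off_mean, off_sd = off_sd,
                   on_mean = on_mean, on_sd = on_sd,
                   on_weight = on_weight, n_reference = n,
                   degenerate_flag = flag, loglik = loglik,
                   iterations = iter),
              class = "mixture_calibration")
  }

  if (!is.finite(s) || s < 1e-8)
    return(make(mean(values), 0, mean(values), 0, 0.5, "constant"))

  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- q
  if (mu[1L] == mu[2L]) mu <- mu + c(-0.5, 0.5) * s
  sig <- c(s, s)
  w <- c(0.5, 0.5)
  sd_floor <- 1e-4 * s
  ll_old <- -Inf
  iter <- 0L
  for (iter in seq_len(200L)) {
    d1 <- w[1L] * stats::dnorm(values, mu[1L], sig[1L])
    d2 <- w[2L] * stats::dnorm(values, mu[2L], sig[2L])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= 1e-8 * (abs(ll_old) + 1e-8)) break
    ll_old <- ll
    r2 <- d2 / tot                      # responsibility of component 2
    n2 <- sum(r2); n1 <- n - n2
    if (n1 < 1e-10 || n2 < 1e-10) break # one component vanished
    mu <- c(sum((1 - r2) * values) / n1, sum(r2 * values) / n2)
    sig <- sqrt(c(sum((1 - r2) * (values - mu[1L])^2) / n1,
                  sum(r2 * (values - mu[2L])^2) / n2))
    sig <- pmax(sig, sd_floor)
    w <- c(n1, n2) / n
  }

  if (mu[2L] < mu[1L]) {                # relabel: ON is the upper component
    mu <- rev(mu); sig <- rev(sig); w <- rev(w)
  }
  pooled_sd <- sqrt((sig[1L]^2 + sig[2L]^2) / 2)
  # below 2 pooled sd a balanced two-Gaussian mixture is unimodal
  flag <- if ((mu[2L] - mu[1L]) < 2 * pooled_sd) "unimodal" else "ok"
  make(mu[1L], sig[1L], mu[2L], sig[2L], w[2L], flag, ll_old, iter)
}

#' @export
print.mixture_calibration <- function(x, ...) {
  cat(sprintf("mixture_calibration%s [%s]: OFF N(%.3f, %.3f), ON N(%.3f, %.3f), w_on = %.3f, n = %d\n",
              if (is.na(x$feature_id)) "" else paste0(" ", x$feature_id),
              x$degenerate_flag, x$off_mean, x$off_sd,
              x$on_mean, x$on_sd, x$on_weight, x$n_reference))
  invisible(x)
}

#' Posterior probability that an expression value comes from the ON component
#'
#' `P(ON | x) = w N(x; mu_on, sd_on) / [w N(x; mu_on, sd_on) +
#' (1 - w) N(x; mu_off, sd_off)]`, clipped to `[1e-12, 1 - 1e-12]`.
#' Degenerate calibrations return 0.5 for every value.
#'
#' @param x numeric vector of expression values (finite).
#' @param cal a [fit_mixture()] calibration.
#' @return Probabilities in `[0, 1]`, same length as `x`.
#' @export
activation_probability <- function(x, cal) {
  stopifnot(inherits(cal, "mixture_calibration"))
  if (any(!is.finite(x))) stop("expression values must be finite", call. = FALSE)
  if (cal$degenerate_flag != "ok") return(rep(0.5, length(x)))
  eps <- 1e-12
  # log-space for tail stability
  lon <- log(cal$on_weight) + stats::dnorm(x, cal$on_mean, cal$on_sd, log = TRUE)
  loff <- log(1 - cal$on_weight) + stats::dnorm(x, cal$off_mean, cal$off_sd, log = TRUE)
  p <- 1 / (1 + exp(loff - lon))
  pmin(pmax(p, eps), 1 - eps)
}

#' Combine probabilities by probability-of-union under independence
#'
#' `1 - prod(1 - p)`: the probability that at least one of several
#' independent events occurs. This is the default rule both for combining
#' probeset activation probabilities into a gene probability
#' ([combine_to_gene()]) and gene probabilities into a node probability
#' ([node_probability()]): pathway nodes are typically redundant protein
#' families, any active member of which can transmit signal. `"mean"` and
#' `"min"` are available as alternative strategies.
#'
#' @param p numeric vector of probabilities in `[0, 1]`, non-empty.
#' @param rule combination rule, `"union"` (default), `"mean"` or `"min"`.
#' @return A single probability.
#' @export
combine_probabilities <- function(p, rule = c("union", "mean", "min")) {
  rule <- match.arg(rule)
  if (length(p) == 0L) stop("empty probability vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must be finite and in [0, 1]", call. = FALSE)
  switch(rule,
         union = 1 - prod(1 - p),
         mean = mean(p),
         min = min(p))
}

#' @rdname combine_probabilities
#' @param probeset_probs probabilities of the gene's probesets.
#' @export
combine_to_gene <- function(probeset_probs, rule = "union") {
  combine_probabilities(probeset_probs, rule)
}

#' @rdname combine_probabilities
#' @param gene_probs probabilities of the node's genes.
#' @export
node_probability <- function(gene_probs, rule = "union") {
  combine_probabilities(gene_probs, rule)
}

#' Calibrate every feature of a reference expression matrix
#'
#' @param expr numeric matrix, features x samples (as read by
#'   [read_expression_matrix()]).
#' @param min_n passed to [fit_mixture()].
#' @return A named list of `mixture_calibration` objects, class
#'   `calibration_set`.
#' @export
fit_calibrations <- function(expr, min_n = 50L) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  out <- lapply(rownames(expr), function(f)
    fit_mixture(expr[f, ], min_n = min_n, feature_id = f))
  structure(stats::setNames(out, rownames(expr)), class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  flags <- table(vapply(x, `[[`, "", "degenerate_flag"))
  cat(sprintf("calibration_set: %d features (%s)\n", length(x),
              paste(sprintf("%s: %d", names(flags), flags), collapse = ", ")))
  invisible(x)
}

#' Serialize / read a calibration set as TSV
#'
#' One row per feature with all calibration fields.
#' @param cals a `calibration_set`.
#' @param path TSV file.
#' @return `write_calibrations`: invisibly `path`;
#'   `read_calibrations`: a `calibration_set`.
#' @export
write_calibrations <- function(cals, path) {
  df <- do.call(rbind, lapply(cals, function(cl)
    data.frame(feature_id = cl$feature_id, off_mean = cl$off_mean,
               off_sd = cl$off_sd, on_mean = cl$on_mean, on_sd = cl$on_sd,
               on_weight = cl$on_weight, n_reference = cl$n_reference,
               degenerate_flag = cl$degenerate_flag)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibrations
#' @export
read_calibrations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    structure(list(feature_id = df$feature_id[i],
                   off_mean = df$off_mean[i], off_sd = df$off_sd[i],
                   on_mean = df$on_mean[i], on_sd = df$on_sd[i],
                   on_weight = df$on_weight[i],
                   n_reference = df$n_reference[i],
                   degenerate_flag = df$degenerate_flag[i],
                   loglik = NA_real_, iterations = NA_integer_),
              class = "mixture_calibration"))
  structure(stats::setNames(out, df$feature_id), class = "calibration_set")
}

#' Score an expression matrix into probeset activation probabilities
#'
#' Each study sample is contrasted with the frozen reference calibration;
#' features without a calibration are dropped with a warning.
#'
#' @param expr numeric matrix, features x samples.
#' @param cals a `calibration_set` from [fit_calibrations()].
#' @return samples x features probability matrix with attribute
#'   `level = "probeset"`.
#' @export
probeset_probabilities <- function(expr, cals) {
  stopifnot(is.matrix(expr), inherits(cals, "calibration_set"))
  feats <- intersect(rownames(expr), names(cals))
  missing <- setdiff(rownames(expr), names(cals))
  if (length(missing))
    warning(length(missing), " feature(s) without calibration dropped")
  if (length(feats) == 0L) stop("no calibrated features in matrix", call. = FALSE)
  out <- vapply(feats, function(f) activation_probability(expr[f, ], cals[[f]]),
                numeric(ncol(expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, feats))
  rownames(out) <- colnames(expr)
  attr(out, "level") <- "probeset"
  out
}

#' Collapse probeset probabilities to gene probabilities
#'
#' @param prob samples x probesets matrix from [probeset_probabilities()].
#' @param platform_map data.frame with columns `probeset_id`, `gene_id`.
#' @param rule combination rule, see [combine_probabilities()].
#' @return samples x genes probability matrix, attribute `level = "gene"`.
#' @export
gene_probabilities <- function(prob, platform_map, rule = "union") {
  stopifnot(is.matrix(prob),
            all(c("probeset_id", "gene_id") %in% names(platform_map)))
  map <- platform_map[platform_map$probeset_id %in% colnames(prob), ]
  if (nrow(map) == 0L) stop("platform map matches no probeset", call. = FALSE)
  genes <- sort(unique(map$gene_id))
  out <- vapply(genes, function(g) {
    ps <- map$probeset_id[map$gene_id == g]
    apply(prob[, ps, drop = FALSE], 1L, combine_probabilities, rule = rule)
  }, numeric(nrow(prob)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(prob), genes))
  rownames(out) <- rownames(prob)
  attr(out, "level") <- "gene"
  out
}

#' Node activation probabilities for one pathway
#'
#' Genes of a node absent from the probability matrix (not measured on the
#' platform) are dropped from the combination; a node with no measured gene
#' gets probability 0.5 with a warning.
#'
#' @param gene_prob samples x genes probability matrix.
#' @param graph a [pathway_graph()].
#' @param rule combination rule, see [combine_probabilities()].
#' @return samples x nodes probability matrix, attribute `level = "node"`.
#' @export
node_probabilities <- function(gene_prob, graph, rule = "union") {
  stopifnot(is.matrix(gene_prob), inherits(graph, "pathway_graph"))
  out <- vapply(graph$node_ids, function(nid) {
    gs <- intersect(graph$genes[[nid]], colnames(gene_prob))
    if (length(gs) == 0L) {
      warning(sprintf("node %s:%s has no measured gene; probability set to 0.5",
                      graph$pathway_id, nid))
      return(rep(0.5, nrow(gene_prob)))
    }
    apply(gene_prob[, gs, drop = FALSE], 1L, combine_probabilities, rule = rule)
  }, numeric(nrow(gene_prob)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(gene_prob),
                                                       graph$node_ids))
  rownames(out) <- rownames(gene_prob)
  attr(out, "level") <- "node"
  out
}
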