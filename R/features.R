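# Invariant-circuit filtering and correlation-based feature selection (CFS)
# for a continuous drug-sensitivity target.

#' Discard invariant circuits
#'
#' Circuits whose activation status does not change across the samples carry
#' no information for prediction and are removed before feature selection.
#' A column is invariant when its range (max - min) is at most `tol`.
#'
#' @param activity samples x circuits numeric matrix.
#' @param tol numeric tolerance on the column range (default 1e-6).
#' @return list with `activity` (surviving columns, order preserved) and
#'   `discarded` (character vector of removed circuit ids).
#' @export
filter_invariant <- function(activity, tol = 1e-6) {
  stopifnot(is.matrix(activity), nrow(activity) >= 2L)
  rng <- apply(activity, 2L, function(x) max(x) - min(x))
  drop <- rng <= tol
  if (all(drop)) stop("all circuits invariant: no features left", call. = FALSE)
  list(activity = activity[, !drop, drop = FALSE],
       discarded = colnames(activity)[drop])
}

# |Pearson| with zero-variance guard: a constant vector contributes 0.
.abs_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  abs(stats::cor(x, y))
}

#' CFS merit of a feature subset for a continuous target
#'
#' `merit = k * rcf / sqrt(k + k (k - 1) * rff)` where `k` is the subset
#' size, `rcf` the mean absolute Pearson correlation between each feature and
#' the target, and `rff` the mean pairwise absolute Pearson correlation among
#' the subset's features. The score rewards relevance to the target and
#' penalizes redundancy within the subset. Zero-variance features contribute
#' correlation 0.
#'
#' @param subset numeric matrix (samples x selected features), non-empty.
#' @param target numeric vector with nonzero variance.
#' @return The merit (dimensionless, finite).
#' @export
cfs_merit <- function(subset, target) {
  if (is.null(dim(subset))) subset <- matrix(subset, ncol = 1L)
  k <- ncol(subset)
  if (k == 0L) stop("subset must be non-empty", call. = FALSE)
  if (stats::sd(target) == 0) stop("target has zero variance", call. = FALSE)
  rcf <- mean(vapply(seq_len(k), function(j) .abs_cor(subset[, j], target),
                     numeric(1)))
  rff <- 0
  if (k > 1L) {
    pr <- utils::combn(k, 2L)
    rff <- mean(vapply(seq_len(ncol(pr)), function(i)
      .abs_cor(subset[, pr[1L, i]], subset[, pr[2L, i]]), numeric(1)))
  }
  k * rcf / sqrt(k + k * (k - 1L) * rff)
}

# merit from precomputed correlations; idx = integer feature indices
.merit_from_cors <- function(idx, rcf, rff) {
  k <- length(idx)
  mrff <- if (k > 1L) mean(rff[idx, idx][upper.tri(matrix(0, k, k))]) else 0
  k * mean(rcf[idx]) / sqrt(k + k * (k - 1L) * mrff)
}

#' Select a discriminative circuit subset by CFS
#'
#' Searches for the feature subset maximizing [cfs_merit()]. With
#' `search = "auto"` the search is exhaustive for up to 15 candidate
#' features and best-first beyond. Best-first keeps a queue of subsets
#' ordered by merit, repeatedly expands the best unexpanded subset by one
#' feature, and stops after `max_stale` consecutive expansions that fail to
#' improve the best merit found (classic CFS default of 5). The search is
#' deterministic; merit ties are broken toward the lexicographically
#' smaller circuit-id subset, so the result is invariant to column
#' permutation of the input.
#'
#' @param activity samples x circuits numeric matrix (invariant circuits
#'   already removed, see [filter_invariant()]).
#' @param target numeric response vector (e.g. IC50 on the ln uM scale).
#' @param search `"auto"`, `"best-first"` or `"exhaustive"`.
#' @param max_stale best-first stop criterion (default 5).
#' @param n_discarded_invariant optional count recorded in the result.
#' @return An object of class `cfs_selection`: `selected` (circuit ids,
#'   lexicographic order), `merit`, `search_trace` (data.frame of subset
#'   size and merit at each improvement), `n_discarded_invariant`, `rcf`
#'   (named per-feature |correlation| with the target).
#' @export
cfs_select <- function(activity, target,
                       search = c("auto", "best-first", "exhaustive"),
                       max_stale = 5L, n_discarded_invariant = NA_integer_) {
  search <- match.arg(search)
  stopifnot(is.matrix(activity), nrow(activity) == length(target))
  if (stats::sd(target) == 0) stop("target has zero variance", call. = FALSE)
  ids <- colnames(activity)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(activity)))
  # canonical lexicographic column order makes tie-breaks permutation-proof
  ord <- order(ids)
  activity <- activity[, ord, drop = FALSE]
  ids <- ids[ord]
  m <- ncol(activity)
  rcf <- vapply(seq_len(m), function(j) .abs_cor(activity[, j], target),
                numeric(1))
  rff <- abs(suppressWarnings(stats::cor(activity)))
  rff[!is.finite(rff)] <- 0
  if (search == "auto") search <- if (m <= 15L) "exhaustive" else "best-first"

  best_idx <- integer(0); best_merit <- -Inf
  trace <- list()
  note <- function(idx, merit) {
    trace[[length(trace) + 1L]] <<- data.frame(size = length(idx),
                                               merit = merit)
  }
  better <- function(merit, idx) {
    merit > best_merit + 1e-12 ||
      (abs(merit - best_merit) <= 1e-12 && length(best_idx) &&
         paste(idx, collapse = ",") < paste(best_idx, collapse = ","))
  }

  if (search == "exhaustive") {
    for (k in seq_len(m)) {
      sets <- utils::combn(m, k)
      for (i in seq_len(ncol(sets))) {
        idx <- sets[, i]
        mer <- .merit_from_cors(idx, rcf, rff)
        if (better(mer, idx)) {
          best_idx <- idx; best_merit <- mer; note(idx, mer)
        }
      }
    }
  } else {
    # best-first forward search over subsets
    key <- function(idx) paste(idx, collapse = ",")
    open <- list()                       # each: list(idx, merit)
    expanded <- new.env(parent = emptyenv())
    for (j in seq_len(m))
      open[[length(open) + 1L]] <- list(idx = j,
                                        merit = .merit_from_cors(j, rcf, rff))
    stale <- 0L
    while (length(open) > 0L && stale < max_stale) {
      merits <- vapply(open, `[[`, numeric(1), "merit")
      pick <- which.max(merits)        # which.max: first (lexicographic) tie
      cur <- open[[pick]]
      open[[pick]] <- NULL
      kk <- key(cur$idx)
      if (!is.null(expanded[[kk]])) next
      expanded[[kk]] <- TRUE
      if (better(cur$merit, cur$idx)) {
        best_idx <- cur$idx; best_merit <- cur$merit; note(cur$idx, cur$merit)
        stale <- 0L
      } else stale <- stale + 1L
      for (j in setdiff(seq_len(m), cur$idx)) {
        idx <- sort(c(cur$idx, j))
        if (!is.null(expanded[[key(idx)]])) next
        open[[length(open) + 1L]] <- list(idx = idx,
                                          merit = .merit_from_cors(idx, rcf, rff))
      }
    }
  }

  structure(list(selected = ids[best_idx],
                 merit = best_merit,
                 search = search,
                 search_trace = if (length(trace)) do.call(rbind, trace)
                                else data.frame(size = integer(), merit = numeric()),
                 n_discarded_invariant = n_discarded_invariant,
                 rcf = stats::setNames(rcf, ids)),
            class = "cfs_selection")
}

#' @export
print.cfs_selection <- function(x, ...) {
  cat(sprintf("cfs_selection (%s): %d feature(s), merit = %.4f\n",
              x$search, length(x$selected), x$merit))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Filter invariant circuits then run CFS
#'
#' Convenience wrapper chaining [filter_invariant()] and [cfs_select()].
#'
#' @inheritParams cfs_select
#' @inheritParams filter_invariant
#' @return A `cfs_selection` with `n_discarded_invariant` filled in.
#' @export
select_features <- function(activity, target, tol = 1e-6,
                            search = "auto", max_stale = 5L) {
  flt <- filter_invariant(activity, tol = tol)
  cfs_select(flt$activity, target, search = search, max_stale = max_stale,
             n_discarded_invariant = length(flt$discarded))
}

#' Write a CFS selection report
#'
#' TSV with one row per candidate circuit (`circuit_id`, `abs_r_cf`,
#' `selected`), plus a JSON search trace alongside when `trace_path` given.
#'
#' @param sel a `cfs_selection`.
#' @param path TSV output path.
#' @param trace_path optional JSON output path for the search trace.
#' @return Invisibly, `path`.
#' @export
write_selection_report <- function(sel, path, trace_path = NULL) {
  df <- data.frame(circuit_id = names(sel$rcf),
                   abs_r_cf = unname(sel$rcf),
                   selected = names(sel$rcf) %in% sel$selected)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trace_path))
    jsonlite::write_json(list(search = sel$search, merit = sel$merit,
                              selected = sel$selected,
                              trace = sel$search_trace),
                         trace_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
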