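# Three-stage descriptor selection: useless-attribute removal,
# correlation-based (CFS) subset evaluation under forward best-first search,
# and backward "F-stepping" elimination against a user-supplied performance
# oracle. All tie-breaks are lexicographic on feature name so runs are
# bit-reproducible.

numeric_feature_cols <- function(data, features = NULL) {
  if (!is.null(features)) return(features)
  fc <- feature_cols(data)
  if (!is.null(fc)) return(fc)
  names(data)[vapply(data, is.numeric, logical(1))]
}

#' Remove useless descriptor columns
#'
#' Drops columns that carry no usable signal before any model sees them:
#' constant columns; columns whose most frequent value accounts for strictly
#' more than `max_variance_pct` percent of rows; and near-identifier columns
#' -- integer-valued columns whose distinct-value count equals the row count
#' (only tested when the table has more than `id_row_threshold` rows;
#' continuous descriptors are all-distinct by nature and are never treated
#' as identifiers).
#'
#' @param data Data frame whose numeric columns are descriptors.
#' @param max_variance_pct Dominance threshold in percent (default 99; a
#'   column exactly at the threshold is kept).
#' @param features Descriptor column names (default: all numeric columns).
#' @param id_row_threshold Minimum row count before the near-identifier rule
#'   applies (default 20).
#' @return A list with `data` (the table restricted to kept descriptors,
#'   non-descriptor columns untouched) and `trace` (a tibble with one row
#'   per descriptor: `feature`, `kept`, `reason`).
#' @export
remove_useless <- function(data, max_variance_pct = 99, features = NULL,
                           id_row_threshold = 20) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    abort("Descriptor table has no rows.", class = "ahtpep_error_empty_matrix")
  }
  features <- numeric_feature_cols(data, features)
  n <- nrow(data)
  verdict <- purrr::map_chr(features, function(f) {
    x <- data[[f]]
    freq <- max(table(x))
    if (freq == n) return("constant")
    if (100 * freq / n > max_variance_pct) return("dominant_value")
    # all-distinct integer-valued columns in a non-trivial table look like
    # row indices, not measurements; continuous descriptors are all-distinct
    # by nature and must survive this rule
    if (n > id_row_threshold && dplyr::n_distinct(x) == n &&
        all(x == round(x))) return("near_identifier")
    "kept"
  })
  trace <- tibble::tibble(feature = features, kept = verdict == "kept",
                          reason = verdict)
  kept <- features[trace$kept]
  out <- data[, c(setdiff(names(data), features), kept), drop = FALSE]
  spec <- feature_spec(data)
  if (!is.null(spec)) {
    spec$names <- kept
    out <- set_spec(out, spec)
  }
  list(data = tibble::as_tibble(out), trace = trace)
}

feature_target_cor <- function(X, y) {
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("Zero-variance feature(s): %s",
                  paste(colnames(X)[sds == 0], collapse = ", ")),
          class = "ahtpep_error_zero_variance")
  }
  if (stats::sd(y) == 0) {
    abort("Target has zero variance.", class = "ahtpep_error_zero_variance")
  }
  abs(as.numeric(stats::cor(X, y)))
}

#' CFS merit of a feature subset
#'
#' Hall's correlation-based feature selection merit:
#' `k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the mean absolute
#' Pearson correlation of the subset's features with the target and `rff`
#' the mean absolute pairwise correlation within the subset (the merit
#' reduces to `rcf` for a single feature). High merit rewards relevance and
#' punishes redundancy. Binary targets are used as numeric 0/1.
#'
#' @param data Data frame holding the feature columns.
#' @param y Numeric target vector (length `nrow(data)`).
#' @param subset Character vector of feature names (non-empty).
#' @return The merit, a non-negative scalar.
#' @export
cfs_merit <- function(data, y, subset) {
  stopifnot(length(subset) >= 1, length(y) == nrow(data))
  X <- as.matrix(data[subset])
  k <- length(subset)
  rcf <- mean(feature_target_cor(X, as.numeric(y)))
  if (k == 1) return(rcf)
  C <- abs(stats::cor(X))
  rff <- mean(C[upper.tri(C)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

subset_key <- function(s) paste0("k:", paste(sort(s), collapse = "\r"))

#' Forward best-first search over CFS merit
#'
#' Starts from the empty set and repeatedly expands the highest-merit open
#' subset by adding one feature at a time, keeping the best subset seen.
#' The search stops after `backtrack` consecutive expansions that fail to
#' improve on the best merit (default 5, with a one-step lookup), the
#' standard stopping rule for this search. Ties in merit are broken by
#' lexicographic subset key, making the result deterministic.
#'
#' @param data Data frame holding the feature columns.
#' @param y Numeric target vector.
#' @param features Candidate feature names (default: all numeric columns).
#' @param lookup Lookahead size (kept at 1, the conventional default).
#' @param backtrack Consecutive non-improving expansions before stopping.
#' @return A list with `subset` (selected feature names, in the order they
#'   entered), `merit`, and `trace` (expansion log tibble).
#' @export
best_first_search <- function(data, y, features = NULL, lookup = 1,
                              backtrack = 5) {
  features <- sort(numeric_feature_cols(data, features))
  stopifnot(length(features) >= 1)
  # precompute correlations once; merit evaluated from them
  X <- as.matrix(data[features])
  rcf_all <- feature_target_cor(X, as.numeric(y))
  names(rcf_all) <- features
  Cff <- abs(stats::cor(X))
  merit_of <- function(s) {
    k <- length(s)
    if (k == 0) return(0)
    rcf <- mean(rcf_all[s])
    if (k == 1) return(unname(rcf))
    rff <- mean(Cff[s, s][upper.tri(diag(k))])
    unname(k * rcf / sqrt(k + k * (k - 1) * rff))
  }
  open <- list(list(subset = character(), merit = 0))
  visited <- new.env(parent = emptyenv())
  assign(subset_key(character()), TRUE, envir = visited)
  best <- list(subset = character(), merit = 0)
  stale <- 0
  log <- list()
  while (length(open) > 0 && stale < backtrack) {
    merits <- vapply(open, function(nd) nd$merit, numeric(1))
    keys <- vapply(open, function(nd) subset_key(nd$subset), character(1))
    pick <- order(-merits, keys)[1]
    node <- open[[pick]]
    open <- open[-pick]
    improved <- FALSE
    for (f in setdiff(features, node$subset)) {
      child <- c(node$subset, f)
      key <- subset_key(child)
      if (exists(key, envir = visited, inherits = FALSE)) next
      assign(key, TRUE, envir = visited)
      m <- merit_of(child)
      open[[length(open) + 1]] <- list(subset = child, merit = m)
      better <- m > best$merit ||
        (m == best$merit && subset_key(child) < subset_key(best$subset))
      if (m > best$merit) improved <- TRUE
      if (better) best <- list(subset = child, merit = m)
    }
    stale <- if (improved) 0 else stale + 1
    log[[length(log) + 1]] <- tibble::tibble(
      expanded = paste(node$subset, collapse = "+"),
      merit = node$merit, best_merit = best$merit, stale = stale
    )
  }
  list(subset = best$subset, merit = best$merit,
       trace = dplyr::bind_rows(log))
}

#' Backward elimination by F-stepping
#'
#' Visits the features in the given order and tentatively removes each one:
#' if the performance metric is unchanged or improves without it, the
#' removal is permanent; if performance drops, the feature is put back.
#' With `passes = "until_stable"` the sweep repeats until a full pass
#' removes nothing. The returned subset never scores strictly worse than
#' the input set, and is never allowed to become empty: if every feature is
#' removable the single best feature is kept and flagged in the trace.
#'
#' @param features Ordered character vector of feature names.
#' @param evaluate Function taking a character vector of feature names and
#'   returning a scalar performance where larger is better (e.g. LOOCV R
#'   or accuracy).
#' @param passes `"single"` (default) or `"until_stable"`.
#' @return A list with `subset`, `metric` (final evaluate value), and
#'   `trace` (one row per tentative removal).
#' @export
f_stepping <- function(features, evaluate, passes = c("single", "until_stable")) {
  passes <- match.arg(passes)
  stopifnot(length(features) >= 1, is.function(evaluate))
  current <- features
  metric <- evaluate(current)
  log <- list()
  repeat {
    removed_any <- FALSE
    for (f in intersect(features, current)) {
      if (length(current) == 1) break
      candidate <- setdiff(current, f)
      m <- evaluate(candidate)
      drop_it <- m >= metric
      if (drop_it) {
        current <- candidate
        metric <- m
        removed_any <- TRUE
      }
      log[[length(log) + 1]] <- tibble::tibble(
        feature = f, metric_without = m, removed = drop_it,
        metric_after = metric
      )
    }
    if (passes == "single" || !removed_any) break
  }
  if (length(current) == 1 && length(features) > 1) {
    # every other feature proved removable; keep the best-scoring single
    # feature rather than the arbitrary last survivor
    singles <- vapply(sort(features), function(f) evaluate(f), numeric(1))
    best_single <- names(singles)[which.max(singles)]
    if (best_single != current) {
      current <- best_single
      metric <- max(singles)
    }
    log[[length(log) + 1]] <- tibble::tibble(
      feature = current, metric_without = NA_real_, removed = FALSE,
      metric_after = metric
    )
  }
  list(subset = current, metric = metric, trace = dplyr::bind_rows(log))
}

#' Full descriptor-selection pipeline
#'
#' Chains the three stages: [remove_useless()], [best_first_search()] over
#' CFS merit, and (when a performance oracle is supplied)
#' [f_stepping()] backward elimination in the order features emerged from
#' the search.
#'
#' @param data Data frame holding the feature columns.
#' @param y Numeric target vector.
#' @param evaluate Optional oracle for the F-stepping stage (see
#'   [f_stepping()]); skipped when `NULL`.
#' @param features Candidate feature names (default: all numeric columns).
#' @param max_variance_pct Passed to [remove_useless()].
#' @param passes Passed to [f_stepping()].
#' @return A list with `subset` and per-stage traces.
#' @export
select_features <- function(data, y, evaluate = NULL, features = NULL,
                            max_variance_pct = 99,
                            passes = c("single", "until_stable")) {
  features <- numeric_feature_cols(data, features)
  ru <- remove_useless(data, max_variance_pct, features = features)
  kept <- ru$trace$feature[ru$trace$kept]
  if (length(kept) == 0) {
    abort("All descriptors removed as useless.", class = "ahtpep_error_empty_result")
  }
  bf <- best_first_search(data, y, features = kept)
  subset <- bf$subset
  fs <- NULL
  if (!is.null(evaluate) && length(subset) > 0) {
    fs <- f_stepping(subset, evaluate, passes = passes)
    subset <- fs$subset
  }
  list(subset = subset,
       trace = list(remove_useless = ru$trace, best_first = bf$trace,
                    f_stepping = if (is.null(fs)) NULL else fs$trace),
       merit = bf$merit,
       metric = if (is.null(fs)) NULL else fs$metric)
}
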