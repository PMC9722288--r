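# Target set algebra: probability-filtered compound-target cluster,
# per-source top-N disease-target cluster, their intersection, and Venn
# partitions over up to five labeled sets.
#
# Gene symbols are uppercased and whitespace-trimmed before any set
# operation; the upstream databases differ in case conventions.

#' Filter compound-target predictions
#'
#' Retains predictions with probability strictly greater than zero and
#' collapses duplicate (cid, target) pairs keeping the maximum probability.
#'
#' @param preds Tibble with columns `cid`, `target`, `probability`.
#' @return Filtered tibble with normalized symbols.
#' @export
filter_predictions <- function(preds) {
  preds <- as_tibble(preds)
  np_assert_finite(preds$probability, "probability")
  if (any(preds$probability < 0 | preds$probability > 1)) {
    np_stop("np_value_error", "probability values must lie in [0, 1]")
  }
  out <- preds |>
    mutate(target = toupper(trimws(target))) |>
    filter(probability > 0)
  if (nrow(out) == 0) return(out)
  out |>
    group_by(cid, target) |>
    summarise(probability = max(probability), .groups = "drop")
}

#' Top-N disease targets by score
#'
#' Sorts a single source's records by score from high to low and returns the
#' symbols of the `n` highest-scored records. Ties at the cut are resolved by
#' lexicographic symbol order, so the result is invariant to input row order.
#' With fewer than `n` records, all symbols are returned.
#'
#' @param records Tibble with columns `target` and `score` (one source).
#' @param n Number of targets to keep.
#' @param source Source label used in error messages.
#' @return Character vector of gene symbols.
#' @export
top_n_by_score <- function(records, n = 1000L, source = "source") {
  records <- as_tibble(records)
  if (anyNA(records$score) || !is.numeric(records$score)) {
    np_stop("np_value_error",
            "records from '%s' carry missing scores; ranking needs them", source)
  }
  records <- records |>
    mutate(target = toupper(trimws(target))) |>
    distinct(target, .keep_all = TRUE) |>
    arrange(desc(score), target)
  head(records$target, n)
}

#' Union of per-source disease-target sets
#'
#' @param per_source_sets Named list of gene-symbol vectors.
#' @return Character vector: the normalized set union.
#' @export
union_disease_targets <- function(per_source_sets) {
  unique(normalize_symbols(unlist(per_source_sets, use.names = FALSE)))
}

#' Intersect compound-target and disease-target clusters
#'
#' @param compound_targets,disease_targets Gene-symbol vectors.
#' @return Character vector of shared symbols.
#' @export
intersect_clusters <- function(compound_targets, disease_targets) {
  intersect(unique(normalize_symbols(compound_targets)),
            unique(normalize_symbols(disease_targets)))
}

#' Venn partition of up to five labeled sets
#'
#' Computes all `2^k - 1` disjoint region counts: each region holds the
#' elements belonging to exactly that combination of input sets. Regions are
#' disjoint and cover the union of the inputs.
#'
#' @param labeled_sets Named list of at most five symbol vectors.
#' @return Tibble with columns `region` (set labels joined by `"&"`),
#'   `sets` (list of member set labels), `count` and `symbols` (list-column).
#' @export
venn_partition <- function(labeled_sets) {
  k <- length(labeled_sets)
  if (k > 5) {
    np_stop("np_capacity_error", "venn_partition supports at most 5 sets, got %d", k)
  }
  if (k == 0) {
    return(tibble(region = character(), sets = list(), count = integer(),
                  symbols = list()))
  }
  labels <- names(labeled_sets) %||% paste0("set", seq_len(k))
  sets <- lapply(labeled_sets, function(s) unique(normalize_symbols(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe), ncol = k)
  masks <- seq_len(2^k - 1)
  rows <- lapply(masks, function(m) {
    inset <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1)))
    in_region <- if (length(universe) == 0) logical(0) else {
      rowSums(member[, inset, drop = FALSE]) == sum(inset) &
        rowSums(member[, !inset, drop = FALSE]) == 0
    }
    tibble(region = paste(labels[inset], collapse = "&"),
           sets = list(labels[inset]),
           count = sum(in_region),
           symbols = list(universe[in_region]))
  })
  bind_rows(rows)
}
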