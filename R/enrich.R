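# Over-representation analysis: hypergeometric upper tail (with the
# conservative one-penalized EASE variant), Benjamini-Hochberg adjustment
# within each annotation category, and top-k term selection with the
# KEGG-style count ordering.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a background of `N` genes of which `K` carry the annotation.
#'
#' @param k Observed overlap.
#' @param K Term (annotation) size.
#' @param n Query size.
#' @param N Background size.
#' @return Upper-tail probability; vectorized over its arguments.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  for (v in list(k, K, n, N)) np_assert_finite(v, "hypergeometric parameter")
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0)) {
    np_stop("np_value_error",
            "invalid hypergeometric parameters: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-style conservative enrichment p-value
#'
#' The hypergeometric upper tail evaluated after removing one gene from the
#' overlap (`k - 1`), the convention used by DAVID's EASE score. Always at
#' least as large as the plain hypergeometric p-value.
#'
#' @inheritParams hypergeom_upper
#' @return Upper-tail probability at the penalized overlap.
#' @export
ease_p <- function(k, K, n, N) {
  if (any(k < 1)) {
    np_stop("np_value_error", "EASE penalization requires overlap k >= 1")
  }
  hypergeom_upper(k - 1, K, n, N)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in input
#' order (order-equivariant).
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, elementwise at least as large as the input.
#' @export
bh_adjust <- function(p_values) {
  np_assert_finite(p_values, "p_values")
  if (any(p_values <= 0 | p_values > 1)) {
    np_stop("np_value_error", "p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Read a GMT annotation catalog
#'
#' One term per line: `term_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Descriptions written by [write_gmt()] encode `term_name||category`; a
#' missing `||` leaves the category `NA`.
#'
#' @param file Path to a GMT file, or literal text containing newlines.
#' @return Tibble with `term_id`, `term_name`, `category` and `genes`
#'   (list-column of symbol vectors).
#' @export
read_gmt <- function(file) {
  lines <- if (length(file) == 1 && !grepl("[\n\t]", file)) {
    if (!file.exists(file)) np_stop("np_io_error", "cannot read '%s'", file)
    readLines(file)
  } else {
    unlist(strsplit(file, "\n"))
  }
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      np_stop("np_format_error", "GMT line with fewer than 3 fields: '%s'",
              substr(l, 1, 40))
    }
    desc <- strsplit(f[2], "||", fixed = TRUE)[[1]]
    tibble(term_id = f[1],
           term_name = desc[1],
           category = if (length(desc) > 1) desc[2] else NA_character_,
           genes = list(unique(normalize_symbols(f[-(1:2)]))))
  })
  bind_rows(rows)
}

#' Write a GMT annotation catalog
#'
#' @param terms Tibble with `term_id`, `term_name`, `category`, `genes`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    desc <- if (is.na(terms$category[i])) terms$term_name[i] else
      paste0(terms$term_name[i], "||", terms$category[i])
    paste(c(terms$term_id[i], desc, terms$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation term with non-empty query overlap against the
#' hypergeometric null (or its EASE variant) and adjusts p-values with
#' Benjamini-Hochberg within each annotation category separately, matching
#' per-category reporting of annotation tools.
#'
#' @param query Character vector of gene symbols.
#' @param terms Annotation tibble (`term_id`, `term_name`, `category`,
#'   `genes` list-column), e.g. from [read_gmt()].
#' @param background Background symbol set; defaults to the union of all
#'   term gene sets (the implicit annotation background).
#' @param method `"hypergeometric"` (default) or `"ease"`.
#' @return Tibble of enrichment results (`term_id`, `term_name`, `category`,
#'   `count`, `gene_ratio`, `p_raw`, `p_adj`, `neg_log10_p_adj`,
#'   `overlap_genes`), terms with zero overlap omitted.
#' @export
enrich <- function(query, terms, background = NULL,
                   method = c("hypergeometric", "ease")) {
  method <- match.arg(method)
  terms <- as_tibble(terms)
  if (nrow(terms) == 0) np_stop("np_value_error", "no annotation terms supplied")
  if (is.null(background)) {
    background <- unique(unlist(terms$genes, use.names = FALSE))
  }
  background <- unique(normalize_symbols(background))
  query <- intersect(unique(normalize_symbols(query)), background)
  if (length(query) == 0) {
    np_stop("np_value_error",
            "effective query is empty (no query gene lies in the background)")
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- intersect(terms$genes[[i]], background)
    overlap <- intersect(query, genes)
    k <- length(overlap)
    if (k == 0) return(NULL)
    p <- if (method == "ease") ease_p(k, length(genes), n, N) else
      hypergeom_upper(k, length(genes), n, N)
    tibble(term_id = terms$term_id[i], term_name = terms$term_name[i],
           category = terms$category[i], count = k, gene_ratio = k / n,
           p_raw = p, overlap_genes = list(sort(overlap)))
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    np_stop("np_value_error", "no term overlaps the query (k >= 1 rule)")
  }
  res <- res |>
    group_by(category) |>
    mutate(p_adj = bh_adjust(p_raw)) |>
    ungroup() |>
    mutate(neg_log10_p_adj = -log10(p_adj))
  res[, c("term_id", "term_name", "category", "count", "gene_ratio",
          "p_raw", "p_adj", "neg_log10_p_adj", "overlap_genes")]
}

#' Top enriched terms of a category
#'
#' Selects at most `k` results of one category, ordered either by adjusted
#' p-value ascending (the default used for GO categories) or by overlap
#' count descending (the ordering used for KEGG pathway charts). Ties are
#' broken by lexicographic `term_id`.
#'
#' @param results Enrichment tibble from [enrich()].
#' @param category Annotation category, e.g. `"KEGG"`, `"BP"`.
#' @param k Maximum number of terms (default 10).
#' @param order `"p_adj_asc"` or `"count_desc"`.
#' @return Ordered tibble of at most `k` rows.
#' @export
top_terms <- function(results, category, k = 10L,
                      order = c("p_adj_asc", "count_desc")) {
  order <- match.arg(order)
  if (k < 1) np_stop("np_value_error", "k must be at least 1")
  if (!category %in% results$category) {
    np_stop("np_value_error", "unknown category '%s' (have: %s)", category,
            paste(unique(results$category), collapse = ", "))
  }
  res <- results[results$category == category, , drop = FALSE]
  res <- if (order == "count_desc") {
    arrange(res, desc(count), term_id)
  } else {
    arrange(res, p_adj, term_id)
  }
  head(res, k)
}
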