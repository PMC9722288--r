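# Relative quantification of qPCR data by 2^-ddCt with reference-gene
# normalization, paired-sample t-tests and significance-tier annotation.
#
# Conventions (the standard Livak formulation):
#   - technical replicates are averaged on the Ct scale before dCt;
#   - dCt   = Ct(target) - Ct(reference) per sample;
#   - ddCt  = dCt - mean(dCt over control-group samples), per gene;
#   - rq    = 2^(-ddCt), so the control group's mean ddCt is 0 by
#     construction and its geometric-mean rq is 1.

#' Relative quantification by 2^-ddCt
#'
#' @param table Long-format Ct tibble with columns `sample_id`, `group`,
#'   `gene`, `replicate`, `ct` (cycles, finite and positive).
#' @param reference_gene Internal reference gene symbol (e.g. `"GAPDH"`).
#' @param control_group Label of the control (calibrator) group.
#' @return Tibble with one row per (sample, target gene): `sample_id`,
#'   `group`, `gene`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
delta_delta_ct <- function(table, reference_gene = "GAPDH",
                           control_group = "control") {
  table <- as_tibble(table)
  need <- c("sample_id", "group", "gene", "ct")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    np_stop("np_format_error", "Ct table is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    np_stop("np_value_error", "Ct values must be finite and positive")
  }
  if (!control_group %in% table$group) {
    np_stop("np_data_error", "control group '%s' not present", control_group)
  }
  # average technical replicates on the Ct scale
  ct1 <- table |>
    group_by(sample_id, group, gene) |>
    summarise(ct = mean(ct), .groups = "drop")
  ref <- ct1[ct1$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ref_ct"
  tgt <- ct1[ct1$gene != reference_gene, , drop = FALSE]
  no_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(no_ref) > 0) {
    np_stop("np_data_error",
            "reference gene '%s' not measured for sample(s): %s",
            reference_gene, paste(no_ref, collapse = ", "))
  }
  out <- left_join(tgt, ref, by = "sample_id") |>
    mutate(delta_ct = ct - ref_ct) |>
    group_by(gene) |>
    mutate(delta_delta_ct =
             delta_ct - mean(delta_ct[group == control_group])) |>
    ungroup() |>
    mutate(rq = 2^(-delta_delta_ct))
  out[, c("sample_id", "group", "gene", "delta_ct", "delta_delta_ct", "rq")]
}

#' Paired-sample t-test
#'
#' Two-sided paired t-test with `length - 1` degrees of freedom; the
#' statistic's sign follows `mean(a - b)`.
#'
#' @param a,b Paired numeric vectors of equal length (at least 2).
#' @return List with `t`, `df` and `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    np_stop("np_value_error",
            "paired_t needs two equal-length vectors with at least 2 pairs")
  }
  d <- a - b
  if (sd(d) == 0) {
    np_stop("np_degenerate_error",
            "paired differences have zero standard deviation")
  }
  fit <- t.test(a, b, paired = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Significance tiers
#'
#' Maps p-values to the conventional star annotation with strict
#' thresholds: `***` if p < 0.001, `**` if p < 0.01, `*` if p < 0.05,
#' `ns` otherwise (so p = 0.05 exactly is `ns`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
stars <- function(p) {
  np_assert_finite(p, "p")
  if (any(p < 0 | p > 1)) np_stop("np_value_error", "p must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Per-gene paired group comparison
#'
#' Runs a paired t-test per gene between two groups of a relative
#' quantification table, pairing samples by their sorted `sample_id` order
#' within each group.
#'
#' @param relquant Tibble from [delta_delta_ct()].
#' @param group_a,group_b Group labels to compare.
#' @param value Column to compare: `"delta_ct"` (default, the scale on which
#'   the data are approximately normal) or `"rq"`.
#' @return Tibble `gene`, `group_a`, `group_b`, `t`, `p`, `stars`.
#' @export
compare_groups <- function(relquant, group_a, group_b, value = "delta_ct") {
  if (!value %in% c("delta_ct", "rq")) {
    np_stop("np_config_error", "value must be 'delta_ct' or 'rq'")
  }
  genes <- sort(unique(relquant$gene))
  rows <- lapply(genes, function(g) {
    sub <- relquant[relquant$gene == g, , drop = FALSE]
    va <- sub[sub$group == group_a, , drop = FALSE]
    vb <- sub[sub$group == group_b, , drop = FALSE]
    va <- va[order(va$sample_id), ][[value]]
    vb <- vb[order(vb$sample_id), ][[value]]
    if (length(va) != length(vb) || length(va) < 2) {
      np_stop("np_data_error",
              "gene %s: groups '%s' and '%s' are not pairable", g,
              group_a, group_b)
    }
    res <- paired_t(va, vb)
    tibble(gene = g, group_a = group_a, group_b = group_b,
           t = res$t, p = res$p, stars = stars(res$p))
  })
  bind_rows(rows)
}
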