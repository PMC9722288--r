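# Study-scale synthetic preset: one seeded bundle of inputs shaped like a
# full herbal network-pharmacology screen (90-row compound table with 4 CID
# duplicates -> 86 distinct compounds, 17 of which pass the superior-property
# screen; a 410-target compound cluster sharing exactly 134 planted symbols
# with a 2081-target disease cluster assembled from five sources sized
# 1000/1000/339/30/30; a planted-hub PPI graph over the 134 shared targets;
# a four-category annotation catalog; Ct plates with planted folds).

#' Study-scale synthetic input bundle
#'
#' Generates, from one seed, every input file the screening pipeline
#' consumes, together with the ground-truth ledger of what was planted.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, all inputs are written there
#'   (CSV/TSV/GMT) and the returned object gains a `paths` element.
#' @return List with `compounds`, `descriptors`, `predictions`,
#'   `disease_tables`, `ppi`, `annotations`, `ct`, `truth` and optionally
#'   `paths`.
#' @export
synth_preset_study <- function(seed, dir = NULL) {
  seeds <- make_subseeds(seed, 6)
  lib <- gen_compound_library(n = 86, pass_fraction = 17 / 86,
                              seed = seeds[1], n_duplicates = 4)
  superior <- lib$truth$pass_cids

  planted <- synth_symbols("XT", 134)
  compound_only <- synth_symbols("CT", 276)
  all_targets <- c(planted, compound_only)
  predictions <- withr::with_seed(seeds[2], {
    rows <- lapply(all_targets, function(tg) {
      cids <- sample(superior, sample(1:3, 1))
      tibble(cid = cids, target = tg,
             probability = round(runif(length(cids), 0.05, 0.95), 4))
    })
    preds <- bind_rows(rows)
    # zero-probability rows (dropped by the probability > 0 filter) and
    # rows for non-superior compounds (dropped by the CID restriction)
    zero <- tibble(cid = sample(superior, 30, TRUE),
                   target = synth_symbols("ZP", 30), probability = 0)
    nonsup <- setdiff(unique(lib$compounds$cid), superior)
    extra <- tibble(cid = sample(nonsup, 25, TRUE),
                    target = synth_symbols("NS", 25),
                    probability = round(runif(25, 0.1, 0.9), 4))
    out <- bind_rows(preds, zero, extra)
    out[sample(nrow(out)), ]
  })

  disease <- gen_disease_tables(
    per_source_sizes = c(CTD = 1000, GeneCards = 1000, OMIM = 339,
                         TTD = 30, DrugBank = 30),
    planted_shared = 134, seed = seeds[3],
    planted_symbols = planted, n_union = 2081)

  ppi <- gen_ppi_planted_hubs(n = 134, n_hubs = 12, p_in = 0.55,
                              p_out = 0.06, seed = seeds[4], nodes = planted)

  annotations <- withr::with_seed(seeds[5], {
    cats <- c(BP = 12, CC = 12, MF = 12, KEGG = 15)
    rows <- lapply(names(cats), function(cat) {
      n_t <- cats[[cat]]
      tibble(
        term_id = sprintf("%s%03d", cat, seq_len(n_t)),
        term_name = sprintf("synthetic %s term %03d", cat, seq_len(n_t)),
        category = cat,
        genes = lapply(seq_len(n_t),
                       function(i) sample(planted, sample(15:40, 1))))
    })
    bind_rows(rows)
  })

  ct <- gen_ct_table(
    genes = c("ACTA2", "COL1A2", "COL3A1"),
    fold_changes = c(3.2, 2.6, 2.2),
    n_per_group = 3, noise_sd = 0.2, seed = seeds[6])

  out <- list(
    compounds = lib$compounds, descriptors = lib$descriptors,
    predictions = predictions, disease_tables = disease$tables,
    ppi = ppi$network, annotations = annotations, ct = ct$ct,
    truth = list(
      n_distinct_compounds = 86L, superior_cids = superior,
      compound_targets = sort(all_targets), planted_intersection = planted,
      disease_union = disease$union, ppi_hubs = ppi$truth$hubs,
      ct_folds = ct$truth$fold_changes
    )
  )
  if (!is.null(dir)) out$paths <- write_preset(out, dir)
  out
}

# Derive stage seeds from one master seed, keeping them valid 32-bit ints.
make_subseeds <- function(seed, n) {
  (as.integer(seed) * 1103L + 7919L * seq_len(n)) %% .Machine$integer.max
}

write_preset <- function(preset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    compounds = file.path(dir, "compounds.csv"),
    descriptors = file.path(dir, "descriptors.csv"),
    predictions = file.path(dir, "predictions.csv"),
    ppi = file.path(dir, "ppi_string.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    ct = file.path(dir, "ct_table.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(preset$compounds, p$compounds, progress = FALSE)
  readr::write_csv(preset$descriptors, p$descriptors, progress = FALSE)
  readr::write_csv(preset$predictions, p$predictions, progress = FALSE)
  write_string_tsv(preset$ppi, p$ppi)
  write_gmt(preset$annotations, p$gmt)
  readr::write_csv(preset$ct, p$ct, progress = FALSE)
  disease_paths <- character()
  for (s in names(preset$disease_tables)) {
    path <- file.path(dir, sprintf("disease_%s.csv", s))
    readr::write_csv(preset$disease_tables[[s]], path, progress = FALSE)
    disease_paths[s] <- path
  }
  p$disease <- disease_paths
  jsonlite::write_json(preset$truth, p$truth, auto_unbox = TRUE, digits = NA)
  p
}
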