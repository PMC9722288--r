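# Seeded synthetic-data generators with machine-readable ground truth for
# every pipeline stage, replacing live database and web-tool queries.
#
# Every generator is deterministic under a fixed seed and returns, next to
# the generated tables, a `truth` ledger that stage tests consume directly.

synth_symbols <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

# Curated pool of valid SMILES; screening logic consumes descriptors, not
# structures, so descriptors are generated separately and these strings only
# keep the records structurally realistic.
smiles_pool <- c(
  "CC(=O)OC1=CC=CC=C1C(=O)O", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
  "C1=CC=C(C=C1)C=O", "CCO", "CC(C)CC1=CC=C(C=C1)C(C)C(=O)O",
  "C1CCCCC1", "C1=CC=C2C(=C1)C=CC=C2", "CC(=O)NC1=CC=C(C=C1)O",
  "OC1=CC=C(C=C1)C2=CC(=O)C3=C(O)C=C(O)C=C3O2", "CCN(CC)CC",
  "OCC1OC(O)C(O)C(O)C1O", "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
  "CN1CCC23C4OC5=C(O)C=CC(CC1C2C=CC4O)=C35", "CC(C)C1=CC=C(C)C=C1O",
  "C1=CC=C(C=C1)CC2=CC=CC=C2", "OC(=O)C1=CC=CC=C1O"
)

# Sample points uniformly inside a scaled copy of the GI ellipse, rejecting
# any that leave the box every rule accepts.
sample_in_ellipse <- function(n, ellipse, shrink = 0.85,
                              tpsa_range = c(5, 125), wlogp_range = c(-0.3, 5.4)) {
  out <- matrix(NA_real_, n, 2)
  filled <- 0
  while (filled < n) {
    m <- 2 * (n - filled) + 8
    r <- sqrt(runif(m)) * shrink
    th <- runif(m, 0, 2 * pi)
    u <- r * cos(th) * ellipse$a
    v <- r * sin(th) * ellipse$b
    co <- cos(ellipse$rotation); si <- sin(ellipse$rotation)
    tp <- ellipse$center[["tpsa"]] + u * co - v * si
    wl <- ellipse$center[["wlogp"]] + u * si + v * co
    ok <- tp >= tpsa_range[1] & tp <= tpsa_range[2] &
      wl >= wlogp_range[1] & wl <= wlogp_range[2]
    take <- min(sum(ok), n - filled)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[filled + seq_len(take), ] <- cbind(tp[idx], wl[idx])
      filled <- filled + take
    }
  }
  colnames(out) <- c("tpsa", "wlogp")
  out
}

# Descriptors guaranteed to satisfy all five rules with zero violations and
# to sit inside the GI ellipse.
synth_pass_descriptors <- function(n, ellipse) {
  pt <- sample_in_ellipse(n, ellipse)
  tibble(
    mw = runif(n, 210, 470), tpsa = pt[, "tpsa"], wlogp = pt[, "wlogp"],
    mlogp = runif(n, 0, 3.5), xlogp = runif(n, 0, 4.5),
    hbd = sample(0:4, n, TRUE), hba = sample(2:9, n, TRUE),
    rotb = sample(0:9, n, TRUE), mr = runif(n, 45, 125),
    heavy_atoms = sample(15:33, n, TRUE), total_atoms = sample(25:65, n, TRUE),
    rings = sample(1:6, n, TRUE), carbons = sample(10:24, n, TRUE),
    heteroatoms = sample(2:8, n, TRUE)
  )
}

# Descriptors guaranteed to violate at least one screening condition, by one
# of three planted failure modes.
synth_fail_descriptors <- function(n, ellipse) {
  base <- synth_pass_descriptors(n, ellipse)
  mode <- sample(c("gi_low", "low_yes", "viol_in_yes"), n, TRUE)
  for (i in seq_len(n)) {
    if (mode[i] == "gi_low") {
      # all five rules stay YES with zero violations; the (tpsa, wlogp)
      # point alone leaves the absorption ellipse
      repeat {
        tp <- runif(1, 127, 131); wl <- runif(1, 5.25, 5.55)
        if (gi_classify(tp, wl, ellipse) == "low") break
      }
      base$tpsa[i] <- tp; base$wlogp[i] <- wl
    } else if (mode[i] == "low_yes") {
      # mw below the Ghose and Muegge windows plus a Veber rotor excess:
      # at most 3 rules answer YES
      base$mw[i] <- runif(1, 80, 150)
      base$rotb[i] <- sample(11:15, 1)
    } else {
      # Lipinski passes with exactly one violation (mw), Ghose fails:
      # 4 YES rules but a violation inside a YES rule
      base$mw[i] <- runif(1, 510, 590)
    }
  }
  list(descriptors = base, mode = mode)
}

#' Generate a synthetic compound library
#'
#' Produces a raw compound table (optionally containing CID duplicates), a
#' CID-keyed descriptor table and a ground-truth list of the compounds that
#' satisfy all three superior-property screening conditions by construction:
#' exactly `round(n * pass_fraction)` compounds have descriptors placed
#' inside every rule box and the GI ellipse; the remainder carry a planted
#' violation.
#'
#' @param n Number of distinct compounds (distinct CIDs).
#' @param pass_fraction Fraction of compounds passing the full screen.
#' @param seed Integer seed.
#' @param n_duplicates Number of extra duplicate rows (same CID, different
#'   source label) appended to the raw table.
#' @param thresholds,ellipse Screening configuration the construction
#'   targets.
#' @return List: `compounds` (raw table with `n + n_duplicates` rows),
#'   `descriptors` (one row per CID) and `truth` (`pass_cids`,
#'   `fail_modes`).
#' @export
gen_compound_library <- function(n, pass_fraction, seed, n_duplicates = 0L,
                                 thresholds = default_rule_thresholds(),
                                 ellipse = default_gi_ellipse()) {
  if (n < 1) np_stop("np_value_error", "n must be at least 1")
  withr::with_seed(seed, {
    n_pass <- round(n * pass_fraction)
    cids <- sample(10000:999999, n)
    pass_idx <- sample(n, n_pass)
    desc <- synth_pass_descriptors(n, ellipse)
    fail_modes <- rep(NA_character_, n)
    if (n_pass < n) {
      f <- synth_fail_descriptors(n - n_pass, ellipse)
      desc[setdiff(seq_len(n), pass_idx), ] <- f$descriptors
      fail_modes[setdiff(seq_len(n), pass_idx)] <- f$mode
    }
    descriptors <- dplyr::bind_cols(tibble(cid = cids), desc)
    compounds <- tibble(
      cid = cids,
      name = sprintf("compound-%06d", cids),
      smiles = rep_len(smiles_pool, n),
      source = sample(c("tcmsp", "tcm-taiwan", "literature"), n, TRUE)
    )
    if (n_duplicates > 0) {
      dup <- compounds[sample(n, n_duplicates, replace = FALSE), ]
      dup$source <- "duplicate-source"
      compounds <- bind_rows(compounds, dup)
      compounds <- compounds[sample(nrow(compounds)), ]
    }
    # construction self-check: the screen must recover exactly the plant
    rep_check <- druglikeness_report(descriptors, thresholds, ellipse)
    stopifnot(setequal(screen_superior(rep_check), cids[pass_idx]))
    list(compounds = compounds, descriptors = descriptors,
         truth = list(pass_cids = sort(cids[pass_idx]),
                      fail_modes = setNames(fail_modes, cids)))
  })
}

#' Generate a synthetic compound-target prediction world
#'
#' Bipartite prediction table over `n_compounds x n_targets` pairs: each
#' pair is present with probability `density`; of the present rows, a fixed
#' fraction carries probability exactly 0 and the rest a positive score.
#'
#' @param n_compounds,n_targets World dimensions.
#' @param density Probability that a (compound, target) pair has a row.
#' @param zero_prob_fraction Fraction of rows with probability exactly 0.
#' @param seed Integer seed.
#' @return List: `predictions` (tibble `cid`, `target`, `probability`) and
#'   `truth` (`positive_rows`, `positive_targets`).
#' @export
gen_target_world <- function(n_compounds, n_targets, density,
                             zero_prob_fraction, seed) {
  withr::with_seed(seed, {
    cids <- 1000L + seq_len(n_compounds)
    targets <- synth_symbols("TGT", n_targets)
    grid <- expand.grid(cid = cids, target = targets,
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < density
    preds <- as_tibble(grid[keep, , drop = FALSE])
    m <- nrow(preds)
    prob <- runif(m, min = 1e-3, max = 1)
    n_zero <- round(m * zero_prob_fraction)
    if (n_zero > 0) prob[sample(m, n_zero)] <- 0
    preds$probability <- prob
    list(predictions = preds,
         truth = list(positive_rows = sum(prob > 0),
                      positive_targets = sort(unique(preds$target[prob > 0]))))
  })
}

#' Generate scored per-database disease-target tables
#'
#' Five source tables with controlled overlap. Planted symbols are placed in
#' every source large enough to hold them (sources smaller than the planted
#' set receive none) and, in ranked sources, receive scores high enough to
#' survive any top-N cut at `n_rank`. Decoy rows with sub-threshold scores
#' are appended to ranked sources so that ranking is exercised.
#'
#' @param per_source_sizes Named integer vector of intended post-ranking
#'   set sizes, e.g. `c(CTD = 1000, GeneCards = 1000, OMIM = 339, TTD = 30,
#'   DrugBank = 30)`.
#' @param planted_shared Number of planted shared symbols (ignored when
#'   `planted_symbols` is given).
#' @param seed Integer seed.
#' @param planted_symbols Optional explicit planted symbol vector.
#' @param n_union Optional exact union size (planted + others); defaults to
#'   no overlap among the non-planted symbols.
#' @param ranked_sources Sources where a top-N score cut applies.
#' @param decoy_frac Fraction of extra low-scored decoy rows per ranked
#'   source.
#' @return List: `tables` (named list of tibbles `target`, `score`,
#'   `score_name`, `source`), `planted`, `union` (expected union) and
#'   `truth`.
#' @export
gen_disease_tables <- function(per_source_sizes, planted_shared, seed,
                               planted_symbols = NULL, n_union = NULL,
                               ranked_sources = c("CTD", "GeneCards"),
                               decoy_frac = 0.2) {
  sizes <- per_source_sizes
  withr::with_seed(seed, {
    planted <- planted_symbols %||% synth_symbols("XT", planted_shared)
    p <- length(planted)
    hosts <- names(sizes)[sizes >= p]
    if (p > 0 && length(hosts) == 0) {
      np_stop("np_value_error",
              "no source is large enough to host %d planted symbols", p)
    }
    capacity <- sizes - ifelse(names(sizes) %in% hosts, p, 0)
    n_union <- n_union %||% (p + sum(capacity))
    n_other <- n_union - p
    total_slots <- sum(capacity)
    n_dup <- total_slots - n_other
    if (n_other < 0 || n_dup < 0) {
      np_stop("np_value_error",
              "n_union incompatible with source sizes and planted count")
    }
    others <- synth_symbols("DT", n_other)
    # one home membership per unique symbol, respecting capacities
    membership <- stats::setNames(vector("list", length(sizes)), names(sizes))
    pool <- sample(others)
    quota <- if (total_slots == 0) capacity * 0L else
      floor(capacity * n_other / total_slots)
    while (sum(quota) < n_other) {
      room <- which(quota < capacity)
      pick <- room[which.max(capacity[room] - quota[room])]
      quota[pick] <- quota[pick] + 1
    }
    offset <- 0
    for (s in names(sizes)) {
      membership[[s]] <- pool[seq_len(quota[s]) + offset]
      offset <- offset + quota[s]
    }
    # extra duplicated memberships across different sources
    dups_left <- n_dup
    guard <- 0
    while (dups_left > 0 && guard < 10000) {
      guard <- guard + 1
      s <- sample(names(sizes), 1)
      if (length(membership[[s]]) >= capacity[s]) next
      cand <- setdiff(others, membership[[s]])
      if (length(cand) == 0) next
      membership[[s]] <- c(membership[[s]], sample(cand, 1))
      dups_left <- dups_left - 1
    }
    if (dups_left > 0) {
      np_stop("np_value_error", "could not place all duplicate memberships")
    }
    for (s in hosts) membership[[s]] <- c(planted, membership[[s]])
    score_names <- c(CTD = "inference_score", GeneCards = "relevance_score")
    tables <- lapply(names(sizes), function(s) {
      syms <- membership[[s]]
      if (s %in% ranked_sources) {
        is_planted <- syms %in% planted
        score <- ifelse(is_planted, runif(length(syms), 800, 1000),
                        runif(length(syms), 100, 790))
        n_dec <- round(decoy_frac * length(syms))
        decoys <- tibble(
          target = sprintf("ZZDECOY%s%04d", toupper(s), seq_len(n_dec)),
          score = runif(n_dec, 0, 90))
        tab <- bind_rows(tibble(target = syms, score = score), decoys)
        tab$score_name <- score_names[s] %||% "score"
      } else {
        tab <- tibble(target = syms, score = NA_real_,
                      score_name = NA_character_)
      }
      tab$source <- s
      tab[sample(nrow(tab)), ]
    })
    names(tables) <- names(sizes)
    expected_union <- sort(unique(c(planted, others)))
    stopifnot(length(expected_union) == n_union)
    list(tables = tables, planted = sort(planted), union = expected_union,
         truth = list(hosts = hosts, n_union = n_union))
  })
}

#' Generate a PPI graph with planted hubs
#'
#' Hub nodes attach to each non-hub with probability `p_in`; non-hub pairs
#' connect with probability `p_out`; hub-hub pairs with `p_hub_hub`
#' (0 by default, so that with `p_in = 1, p_out = 0` every hub has degree
#' exactly `n - n_hubs`).
#'
#' @param n Number of nodes.
#' @param n_hubs Number of planted hubs (`n_hubs < n`).
#' @param p_in Hub to non-hub attachment probability.
#' @param p_out Non-hub pair attachment probability (`p_out < p_in`).
#' @param seed Integer seed.
#' @param p_hub_hub Hub-hub attachment probability.
#' @param nodes Optional node label vector of length `n`.
#' @return List: `network` (a `ppi_network`), `edges` (STRING-style tibble)
#'   and `truth` (`hubs`).
#' @export
gen_ppi_planted_hubs <- function(n, n_hubs, p_in, p_out, seed,
                                 p_hub_hub = 0, nodes = NULL) {
  if (n_hubs >= n) np_stop("np_value_error", "n_hubs must be smaller than n")
  if (!(p_out <= p_in)) np_stop("np_value_error", "need p_out <= p_in")
  withr::with_seed(seed, {
    labels <- nodes %||% synth_symbols("PRO", n)
    stopifnot(length(labels) == n)
    hubs <- sample(labels, n_hubs)
    pairs <- utils::combn(labels, 2)
    is_hub_a <- pairs[1, ] %in% hubs
    is_hub_b <- pairs[2, ] %in% hubs
    prob <- ifelse(is_hub_a & is_hub_b, p_hub_hub,
                   ifelse(is_hub_a | is_hub_b, p_in, p_out))
    keep <- runif(ncol(pairs)) < prob
    edges <- tibble(a = pairs[1, keep], b = pairs[2, keep],
                    combined_score = round(runif(sum(keep), 0.4, 0.999), 3))
    net <- ppi_network(edges, nodes = labels)
    list(network = net, edges = edges, truth = list(hubs = sort(hubs)))
  })
}

#' Write a PPI network as a STRING-dialect TSV
#'
#' @param net A `ppi_network` (or the `edges` tibble of one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_string_tsv <- function(net, path) {
  edges <- if (inherits(net, "ppi_network")) net$edges else as_tibble(net)
  lines <- c("#node1\tnode2\tcombined_score",
             sprintf("%s\t%s\t%s", edges$a, edges$b,
                     format(edges$combined_score, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Generate an annotation catalog with one planted enriched term
#'
#' All terms draw their genes uniformly from the background except the
#' planted term, whose overlap with the query is forced to
#' `factor x` the null expectation `|query| x K / N`. With `factor = 1` the
#' planted term is drawn uniformly like every other term (pure null).
#'
#' @param n_terms Number of annotation terms.
#' @param term_size_range Length-2 range of term sizes.
#' @param planted_term_overlap_factor Enrichment factor (>= 1).
#' @param query_size,background_size Query and background sizes.
#' @param seed Integer seed.
#' @param category Category label for all terms.
#' @return List: `terms` (annotation tibble), `query`, `background`,
#'   `planted_term` (term id, or `NA` when `factor = 1`).
#' @export
gen_annotations <- function(n_terms, term_size_range,
                            planted_term_overlap_factor,
                            query_size, background_size, seed,
                            category = "KEGG") {
  if (planted_term_overlap_factor < 1) {
    np_stop("np_value_error", "overlap factor must be >= 1")
  }
  withr::with_seed(seed, {
    background <- synth_symbols("BG", background_size)
    query <- sample(background, query_size)
    sizes <- sample(term_size_range[1]:term_size_range[2], n_terms,
                    replace = TRUE)
    ids <- sprintf("%s%03d", toupper(substr(category, 1, 2)), seq_len(n_terms))
    planted_i <- if (planted_term_overlap_factor > 1) sample(n_terms, 1) else NA
    genes <- lapply(seq_len(n_terms), function(i) {
      K <- sizes[i]
      if (!is.na(planted_i) && i == planted_i) {
        k_target <- min(K, query_size,
                        round(planted_term_overlap_factor * query_size * K /
                                background_size))
        c(sample(query, k_target),
          sample(setdiff(background, query), K - k_target))
      } else {
        sample(background, K)
      }
    })
    terms <- tibble(term_id = ids,
                    term_name = sprintf("synthetic %s term %03d",
                                        category, seq_len(n_terms)),
                    category = category, genes = genes)
    list(terms = terms, query = sort(query), background = background,
         planted_term = if (is.na(planted_i)) NA_character_ else ids[planted_i])
  })
}

#' Generate a synthetic Ct plate with planted fold changes
#'
#' Control samples carry a per-gene baseline dCt; treated samples carry
#' `dCt - log2(fold) + Gaussian(0, noise_sd)`. All noise is placed on the
#' target-gene Ct, the reference gene is exact, so `noise_sd = 0` recovers
#' the planted folds exactly.
#'
#' @param genes Character vector of target gene symbols.
#' @param fold_changes Positive fold change per gene (recycled).
#' @param n_per_group Samples per group (>= 2).
#' @param noise_sd Gaussian noise on treated/control target Ct, in cycles.
#' @param seed Integer seed.
#' @param reference_gene,control_group,treated_group Labels.
#' @param n_replicates Technical replicates per (sample, gene).
#' @return List: `ct` (long-format Ct tibble) and `truth` (named folds).
#' @export
gen_ct_table <- function(genes, fold_changes, n_per_group = 3L,
                         noise_sd = 0.2, seed = 1L,
                         reference_gene = "GAPDH",
                         control_group = "control",
                         treated_group = "treated",
                         n_replicates = 1L) {
  if (any(fold_changes <= 0)) np_stop("np_value_error", "folds must be > 0")
  if (n_per_group < 2) np_stop("np_value_error", "n_per_group must be >= 2")
  folds <- setNames(rep_len(fold_changes, length(genes)), genes)
  withr::with_seed(seed, {
    base_ref <- 18
    base_dct <- setNames(runif(length(genes), 2, 8), genes)
    rows <- list()
    for (grp in c(control_group, treated_group)) {
      shift <- if (grp == treated_group) -log2(folds) else
        setNames(rep(0, length(genes)), genes)
      for (i in seq_len(n_per_group)) {
        sid <- sprintf("%s_%02d", grp, i)
        for (g in genes) {
          noise <- rnorm(1, 0, noise_sd)
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sid, group = grp, gene = g,
            replicate = seq_len(n_replicates),
            ct = base_ref + base_dct[[g]] + shift[[g]] + noise)
        }
        rows[[length(rows) + 1]] <- tibble(
          sample_id = sid, group = grp, gene = reference_gene,
          replicate = seq_len(n_replicates), ct = base_ref)
      }
    }
    list(ct = bind_rows(rows), truth = list(fold_changes = folds))
  })
}
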