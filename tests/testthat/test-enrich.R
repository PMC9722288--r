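test_that("hypergeometric upper tail matches enumeration on known cases", {
  expect_equal(hypergeom_upper(0, 5, 5, 10), 1)
  expect_equal(hypergeom_upper(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_upper(4, 8, 6, 20), oracle_hyper_enum(4, 8, 6, 20))
  expect_error(hypergeom_upper(6, 5, 5, 10), class = "np_value_error")
  expect_error(hypergeom_upper(1, 11, 5, 10), class = "np_value_error")
})

test_that("the subset-enumeration and count-summation oracles agree", {
  withr::with_seed(1, {
    for (rep in 1:20) {
      N <- sample(4:9, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(oracle_hyper_sum(k, K, n, N), oracle_hyper_enum(k, K, n, N))
    }
  })
})

test_that("the EASE variant penalizes one overlap gene", {
  expect_equal(ease_p(1, 5, 5, 10), 1)
  expect_equal(ease_p(5, 5, 5, 10), hypergeom_upper(4, 5, 5, 10))
  withr::with_seed(13, {
    for (rep in 1:25) {
      N <- sample(10:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      k <- sample(1:max(1, min(K, n)), 1)
      expect_gte(ease_p(k, K, n, N), hypergeom_upper(k, K, n, N))
    }
  })
  expect_error(ease_p(0, 5, 5, 10), class = "np_value_error")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(3, {
    p <- runif(50)
    expect_true(all(bh_adjust(p) >= p))
    # order-equivariance
    perm <- sample(50)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  })
  expect_error(bh_adjust(c(0.5, 0)), class = "np_value_error")
})

test_that("enrichment handles degenerate and zero-overlap terms", {
  genes <- paste0("G", 1:10)
  terms <- tibble::tibble(term_id = c("t1", "t2"), term_name = c("a", "b"),
                          category = "KEGG",
                          genes = list(genes, paste0("H", 1:5)))
  # query == term genes == background: overlap is forced, p = 1
  res <- enrich(genes, terms[1, ], background = genes)
  expect_equal(res$p_raw, 1)
  expect_equal(res$gene_ratio, 1)
  # zero-overlap terms are absent from results
  res2 <- enrich(genes, terms, background = c(genes, paste0("H", 1:5)))
  expect_equal(res2$term_id, "t1")
  expect_error(enrich(paste0("Q", 1:3), terms, background = genes),
               class = "np_value_error")
})

test_that("a planted enriched term attains the smallest adjusted p", {
  world <- gen_annotations(n_terms = 20, term_size_range = c(20, 60),
                           planted_term_overlap_factor = 6,
                           query_size = 50, background_size = 1000,
                           seed = 77)
  res <- enrich(world$query, world$terms, background = world$background)
  expect_equal(res$term_id[which.min(res$p_adj)], world$planted_term)
})

test_that("null enrichment p-values follow the exact hypergeometric null", {
  # The statistic is discrete, so null p-values are super-uniform on a
  # lattice rather than exactly uniform: compare against p-values simulated
  # from the exact null, and check the tail is not anti-conservative.
  withr::with_seed(2024, {
    N <- 2000; n <- 100
    bg <- sprintf("B%04d", seq_len(N))
    sizes <- sample(80:400, 200, replace = TRUE)
    p_obs <- vapply(seq_len(200), function(i) {
      query <- sample(bg, n)
      term <- sample(bg, sizes[i])
      k <- length(intersect(query, term))
      if (k == 0) return(NA_real_)
      hypergeom_upper(k, sizes[i], n, N)
    }, numeric(1))
    p_null <- vapply(seq_len(200), function(i) {
      k <- stats::rhyper(1, sizes[i], N - sizes[i], n)
      if (k == 0) return(NA_real_)
      hypergeom_upper(k, sizes[i], n, N)
    }, numeric(1))
    ks <- suppressWarnings(
      stats::ks.test(p_obs[!is.na(p_obs)], p_null[!is.na(p_null)]))
    expect_gt(ks$p.value, 0.01)
    # not anti-conservative: small p-values occur at most at nominal rate
    expect_lte(mean(p_obs <= 0.05, na.rm = TRUE), 0.05 + 0.04)
    expect_gt(mean(p_obs, na.rm = TRUE), 0.45)
  })
})

test_that("top-term selection orders by the requested key with id tie-break", {
  res <- tibble::tibble(
    term_id = c("hsa04151", "hsa04010", "hsa05200", "hsa04668"),
    term_name = letters[1:4], category = "KEGG",
    count = c(9, 9, 12, 4), gene_ratio = 0.1,
    p_raw = c(0.01, 0.02, 0.001, 0.2), p_adj = c(0.02, 0.04, 0.004, 0.2),
    neg_log10_p_adj = 1, overlap_genes = list("x"))
  expect_equal(top_terms(res, "KEGG", 10, "count_desc")$term_id,
               c("hsa05200", "hsa04010", "hsa04151", "hsa04668"))
  expect_equal(nrow(top_terms(res[1:3, ], "KEGG", 10)), 3)

  withr::with_seed(10, {
    go <- tibble::tibble(
      term_id = sprintf("GO%03d", 1:12), term_name = "t", category = "BP",
      count = sample(3:20, 12, TRUE), gene_ratio = 0.1,
      p_raw = runif(12), p_adj = runif(12), neg_log10_p_adj = 1,
      overlap_genes = list("x"))
    got <- top_terms(go, "BP", 10, "p_adj_asc")$term_id
    expect_equal(got, go$term_id[order(go$p_adj, go$term_id)][1:10])
  })
  expect_error(top_terms(res, "REACTOME"), class = "np_value_error")
})

test_that("GMT files round-trip terms with their categories", {
  terms <- tibble::tibble(
    term_id = c("hsa04151", "GO0001"),
    term_name = c("PI3K-Akt signaling pathway", "response to hypoxia"),
    category = c("KEGG", "BP"),
    genes = list(c("AKT1", "PIK3CA"), c("EGFR", "MAPK1", "SRC")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(terms, path)
  back <- read_gmt(path)
  expect_identical(back, terms)
  expect_error(read_gmt("one\ttwo"), class = "np_format_error")
})
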