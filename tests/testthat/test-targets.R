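test_that("prediction filtering keeps strictly positive probabilities", {
  preds <- tibble::tibble(cid = 1, target = "ABC", probability = 0)
  expect_equal(nrow(filter_predictions(preds)), 0)

  all_half <- tibble::tibble(cid = 1:4, target = letters[1:4],
                             probability = 0.5)
  expect_equal(nrow(filter_predictions(all_half)), 4)

  withr::with_seed(2, {
    mixed <- tibble::tibble(cid = rep(1:4, 5), target = paste0("T", 1:20),
                            probability = runif(20))
    zero_rows <- sample(20, 7)
    mixed$probability[zero_rows] <- 0
    expect_equal(nrow(filter_predictions(mixed)), 13)
  })

  # duplicates collapse keeping the maximum probability
  dup <- tibble::tibble(cid = c(1, 1), target = c("gene1", "GENE1"),
                        probability = c(0.2, 0.7))
  out <- filter_predictions(dup)
  expect_equal(nrow(out), 1)
  expect_equal(out$probability, 0.7)
  expect_equal(out$target, "GENE1")

  expect_error(filter_predictions(
    tibble::tibble(cid = 1, target = "A", probability = 1.2)),
    class = "np_value_error")
})

test_that("top-N by score ranks high-to-low with lexicographic tie-break", {
  small <- tibble::tibble(target = paste0("G", 1:5), score = 5:1)
  expect_setequal(top_n_by_score(small, 1000), small$target)

  tied <- tibble::tibble(target = c("TOP", "B", "A", "LOW"),
                         score = c(9, 8, 8, 7))
  expect_equal(top_n_by_score(tied, 2), c("TOP", "A"))

  withr::with_seed(31, {
    big <- tibble::tibble(target = sprintf("G%04d", 1:2000),
                          score = sample(seq(1, 20000), 2000))
    got <- top_n_by_score(big, 1000)
    oracle <- big$target[order(-big$score)][1:1000]
    expect_setequal(got, oracle)
    # row-order invariance
    shuf <- big[sample(nrow(big)), ]
    expect_equal(sort(top_n_by_score(shuf, 1000)), sort(got))
  })

  expect_error(top_n_by_score(tibble::tibble(target = "A", score = NA), 10,
                              source = "OMIM"),
               class = "np_value_error")
})

test_that("union and intersection behave as set algebra on normalized symbols", {
  expect_equal(union_disease_targets(rep(list(character()), 5)), character())
  expect_equal(length(union_disease_targets(list(A = c("x", "y"),
                                                 B = c("X", "Y")))), 2)
  expect_equal(intersect_clusters(c("a", "b"), c("C", "D")), character())
  expect_setequal(intersect_clusters(c("a", "b"), c("A", "B", "C")),
                  c("A", "B"))
  withr::with_seed(4, {
    sets <- lapply(1:4, function(i) sample(sprintf("S%03d", 1:120), 50))
    expect_equal(sort(union_disease_targets(sets)),
                 sort(unique(unlist(sets))))
  })
})

test_that("a planted intersection is recovered exactly at study scale", {
  planted <- sprintf("XT%04d", 1:134)
  disease <- gen_disease_tables(
    per_source_sizes = c(CTD = 1000, GeneCards = 1000, OMIM = 339,
                         TTD = 30, DrugBank = 30),
    planted_shared = 134, seed = 17, planted_symbols = planted,
    n_union = 2081)
  sets <- lapply(names(disease$tables), function(s) {
    tab <- disease$tables[[s]]
    if (s %in% c("CTD", "GeneCards")) top_n_by_score(tab, 1000, s)
    else unique(tab$target)
  })
  u <- union_disease_targets(sets)
  expect_equal(length(u), 2081)
  compound_cluster <- c(planted, sprintf("CT%04d", 1:276))
  expect_setequal(intersect_clusters(compound_cluster, u), planted)
})

test_that("Venn partitions are disjoint, covering and correct", {
  one <- venn_partition(list(A = c("x", "y", "z")))
  expect_equal(one$count, 3)

  two <- venn_partition(list(A = c("a", "b"), B = c("c", "d", "e")))
  expect_equal(setNames(two$count, two$region),
               c(A = 2, B = 3, "A&B" = 0))

  withr::with_seed(6, {
    sets <- list(A = sample(letters, 10), B = sample(letters, 12),
                 C = sample(letters, 8))
    vp <- venn_partition(sets)
    expect_equal(nrow(vp), 7)
    expect_equal(sum(vp$count), length(unique(toupper(unlist(sets)))))
    # oracle: exhaustive membership enumeration per element
    uni <- unique(toupper(unlist(sets)))
    for (i in seq_len(nrow(vp))) {
      inset <- vp$sets[[i]]
      expected <- Filter(function(el) {
        all(el %in% toupper(sets[[inset[1]]]) |
              length(inset) == 0) &&
          all(vapply(names(sets), function(s)
            (el %in% toupper(sets[[s]])) == (s %in% inset), logical(1)))
      }, uni)
      expect_setequal(vp$symbols[[i]], expected)
    }
  })

  expect_error(venn_partition(setNames(rep(list("x"), 6), letters[1:6])),
               class = "np_capacity_error")
})
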