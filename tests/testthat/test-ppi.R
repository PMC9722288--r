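string_tsv <- function(...) paste(c("#node1\tnode2\tcombined_score", ...),
                                  collapse = "\n")

test_that("STRING TSV parsing builds an undirected simple graph", {
  empty <- parse_string_tsv(string_tsv())
  expect_equal(length(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)

  net <- parse_string_tsv(string_tsv("A\tB\t0.9", "B\tA\t0.7"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$combined_score, 0.9)

  # 10 rows: 2 duplicates and 1 self-loop collapse to 7 edges
  rows <- c("A\tB\t0.5", "B\tA\t0.6", "A\tC\t0.4", "C\tA\t0.3",
            "D\tD\t0.9", "A\tD\t0.2", "B\tC\t0.8", "B\tD\t0.7",
            "C\tD\t0.55", "A\tE\t0.45")
  net10 <- parse_string_tsv(string_tsv(rows))
  expect_equal(nrow(net10$edges), 7)

  expect_error(parse_string_tsv("#node1\tnode2\nA\tB"),
               class = "np_format_error")
  expect_error(parse_string_tsv(string_tsv("A\tB\t1.5")),
               class = "np_value_error")
})

test_that("centralities match closed forms on star, triangle and path", {
  star <- parse_string_tsv(string_tsv(sprintf("C\tL%d\t0.9", 1:4)))
  cent <- centralities(star)
  ctr <- cent[cent$node == "C", ]
  expect_equal(ctr$degree, 4L)
  expect_equal(ctr$betweenness, 1)
  expect_equal(ctr$closeness, 1)
  leaves <- cent[cent$node != "C", ]
  expect_equal(leaves$degree, rep(1L, 4))
  expect_equal(leaves$betweenness, rep(0, 4))
  expect_equal(leaves$closeness, rep(4 / 7, 4))  # distances 1+2+2+2

  tri <- parse_string_tsv(string_tsv("A\tB\t0.9", "B\tC\t0.9", "A\tC\t0.9"))
  ct <- centralities(tri)
  expect_equal(ct$degree, rep(2L, 3))
  expect_equal(ct$betweenness, rep(0, 3))
  expect_equal(ct$closeness, rep(1, 3))

  path <- parse_string_tsv(string_tsv("A\tB\t0.9", "B\tC\t0.9"))
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$node == "B"], 1)
  expect_equal(cp$closeness[cp$node == "B"], 1)
  expect_equal(cp$closeness[cp$node == "A"], 2 / 3)

  expect_error(centralities(ppi_network(tibble::tibble(
    a = character(), b = character(), combined_score = numeric()))),
    class = "np_value_error")
})

test_that("centralities agree with the brute-force oracle, including
           disconnected graphs", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      n <- sample(4:8, 1)
      adj <- random_adjacency(n, runif(1, 0.15, 0.8))
      net <- adj_to_network(adj)
      got <- centralities(net)
      got <- got[match(sprintf("N%02d", 1:n), got$node), ]
      want <- oracle_centralities(adj)
      expect_equal(got$degree, as.integer(want$degree))
      expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
      expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    }
  })
})

test_that("centralities are invariant to node relabeling", {
  withr::with_seed(123, {
    adj <- random_adjacency(7, 0.4)
    perm <- sample(7)
    net1 <- adj_to_network(adj)
    net2 <- adj_to_network(adj[perm, perm])
    c1 <- centralities(net1)
    c2 <- centralities(net2)
    # node i of net1 is node match(i, perm) of net2
    for (i in 1:7) {
      a <- c1[c1$node == sprintf("N%02d", perm[i]), ]
      b <- c2[c2$node == sprintf("N%02d", i), ]
      expect_equal(a$degree, b$degree)
      expect_equal(a$betweenness, b$betweenness)
      expect_equal(a$closeness, b$closeness)
    }
  })
})

test_that("the triple-median filter uses strict inequalities on all metrics", {
  identical_recs <- tibble::tibble(node = letters[1:6], degree = 3L,
                                   betweenness = 0.2, closeness = 0.5)
  expect_equal(median_filter(identical_recs), character())

  # 5 records with one strict ordering on all three metrics: top 2 retained
  ordered <- tibble::tibble(node = paste0("n", 1:5), degree = 1:5,
                            betweenness = (1:5) / 10, closeness = (1:5) / 6)
  expect_setequal(median_filter(ordered), c("n4", "n5"))

  expect_error(median_filter(identical_recs[0, ]), class = "np_value_error")
})

test_that("with all-distinct metrics at most ceiling(n/2) - 1 nodes survive", {
  withr::with_seed(44, {
    for (rep in 1:20) {
      n <- sample(3:25, 1)
      recs <- tibble::tibble(node = paste0("x", 1:n),
                             degree = sample(1000, n),
                             betweenness = runif(n), closeness = runif(n))
      expect_lte(length(median_filter(recs)), ceiling(n / 2) - 1)
    }
  })
})

test_that("planted hubs pass the median filter", {
  sim <- gen_ppi_planted_hubs(n = 60, n_hubs = 6, p_in = 0.8, p_out = 0.05,
                              seed = 7)
  kept <- median_filter(centralities(sim$network))
  expect_gte(length(intersect(kept, sim$truth$hubs)), 5)
})
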