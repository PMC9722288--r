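ct_row <- function(sample_id, group, gene, ct) {
  tibble::tibble(sample_id = sample_id, group = group, gene = gene,
                 replicate = 1L, ct = ct)
}

test_that("2^-ddCt identities hold on constructed plates", {
  # target Ct == reference Ct everywhere: rq = 1 for all samples
  tab <- dplyr::bind_rows(lapply(c("c1", "c2", "t1", "t2"), function(s) {
    grp <- if (startsWith(s, "c")) "control" else "treated"
    dplyr::bind_rows(ct_row(s, grp, "ACTA2", 20), ct_row(s, grp, "GAPDH", 20))
  }))
  rq <- delta_delta_ct(tab, "GAPDH", "control")
  expect_equal(rq$rq, rep(1, 4))

  # a treated sample exactly one cycle below the control mean dCt: rq = 2
  tab2 <- dplyr::bind_rows(
    ct_row("c1", "control", "ACTA2", 25), ct_row("c1", "control", "GAPDH", 20),
    ct_row("c2", "control", "ACTA2", 25), ct_row("c2", "control", "GAPDH", 20),
    ct_row("t1", "treated", "ACTA2", 24), ct_row("t1", "treated", "GAPDH", 20))
  rq2 <- delta_delta_ct(tab2, "GAPDH", "control")
  expect_equal(rq2$rq[rq2$group == "treated"], 2)
})

test_that("a 3v3 plate matches a spreadsheet-style hand computation", {
  # control dCt: 5.0, 5.4, 5.2 (mean 5.2); treated dCt: 3.0, 3.4, 3.2
  cts <- dplyr::bind_rows(
    ct_row("c1", "control", "X", 23.0), ct_row("c1", "control", "GAPDH", 18),
    ct_row("c2", "control", "X", 23.4), ct_row("c2", "control", "GAPDH", 18),
    ct_row("c3", "control", "X", 23.2), ct_row("c3", "control", "GAPDH", 18),
    ct_row("m1", "treated", "X", 21.0), ct_row("m1", "treated", "GAPDH", 18),
    ct_row("m2", "treated", "X", 21.4), ct_row("m2", "treated", "GAPDH", 18),
    ct_row("m3", "treated", "X", 21.2), ct_row("m3", "treated", "GAPDH", 18))
  rq <- delta_delta_ct(cts, "GAPDH", "control")
  expect_equal(rq$delta_delta_ct[rq$group == "control"],
               c(-0.2, 0.2, 0.0))
  expect_equal(rq$rq[rq$group == "treated"],
               2^(-c(-2.2, -1.8, -2.0)))
  # control-group ddCt mean is 0, geometric-mean control rq is 1
  expect_equal(mean(rq$delta_delta_ct[rq$group == "control"]), 0)
  expect_equal(exp(mean(log(rq$rq[rq$group == "control"]))), 1)
})

test_that("replicates average on the Ct scale and missing references error", {
  tab <- dplyr::bind_rows(
    tibble::tibble(sample_id = "c1", group = "control", gene = "X",
                   replicate = 1:3, ct = c(24, 25, 26)),
    ct_row("c1", "control", "GAPDH", 20),
    ct_row("t1", "treated", "X", 23), ct_row("t1", "treated", "GAPDH", 20))
  rq <- delta_delta_ct(tab, "GAPDH", "control")
  expect_equal(rq$delta_ct[rq$sample_id == "c1"], 5)

  no_ref <- dplyr::bind_rows(ct_row("s9", "control", "X", 22))
  expect_error(delta_delta_ct(no_ref, "GAPDH", "control"),
               class = "np_data_error")
  expect_error(delta_delta_ct(dplyr::mutate(tab, ct = -ct), "GAPDH", "control"),
               class = "np_value_error")
})

test_that("rq is invariant to a constant shift of every Ct", {
  sim <- gen_ct_table(genes = c("A", "B"), fold_changes = c(2, 3),
                      n_per_group = 4, noise_sd = 0.3, seed = 5)
  rq1 <- delta_delta_ct(sim$ct, "GAPDH", "control")
  shifted <- dplyr::mutate(sim$ct, ct = ct + 3.7)
  rq2 <- delta_delta_ct(shifted, "GAPDH", "control")
  expect_equal(rq2$rq, rq1$rq)
})

test_that("the paired t-test matches its closed form and flags degeneracy", {
  a <- c(5.0, 6.0, 7.0); b <- c(6.0, 7.5, 7.5)
  d <- a - b  # -1.0, -1.5, -0.5
  res <- paired_t(a, b)
  t_expected <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_expected)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-abs(t_expected), df = 2))
  # antisymmetry
  expect_equal(paired_t(b, a)$t, -res$t)
  # constant differences are degenerate
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)),
               class = "np_degenerate_error")
  expect_error(paired_t(1, 1:2), class = "np_value_error")
})

test_that("significance tiers use strict thresholds", {
  expect_equal(stars(c(0.0009, 0.05, 0.02, 0.009, 0.9)),
               c("***", "ns", "*", "**", "ns"))
  expect_error(stars(1.2), class = "np_value_error")
})

test_that("per-gene group comparisons annotate significance", {
  sim <- gen_ct_table(genes = c("AKT1", "EGFR"), fold_changes = c(4, 1),
                      n_per_group = 6, noise_sd = 0.15, seed = 12)
  rq <- delta_delta_ct(sim$ct, "GAPDH", "control")
  cmp <- compare_groups(rq, "treated", "control")
  expect_equal(cmp$gene, c("AKT1", "EGFR"))
  # a planted fold-4 effect at low noise is detected; its dCt drops
  akt <- cmp[cmp$gene == "AKT1", ]
  expect_lt(akt$t, 0)
  expect_lt(akt$p, 0.05)
  expect_true(akt$stars %in% c("*", "**", "***"))
})

test_that("planted fold changes are recovered from synthetic plates", {
  clean <- gen_ct_table(genes = "X", fold_changes = 4, n_per_group = 3,
                        noise_sd = 0, seed = 2)
  rq <- delta_delta_ct(clean$ct, "GAPDH", "control")
  expect_equal(rq$rq[rq$group == "treated"], rep(4, 3))
  flat <- gen_ct_table(genes = "X", fold_changes = 1, noise_sd = 0, seed = 2)
  rqf <- delta_delta_ct(flat$ct, "GAPDH", "control")
  expect_equal(rqf$rq, rep(1, 6))
})
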