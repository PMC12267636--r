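test_that("two-sided Fisher test reproduces hand-derived tables", {
  expect_equal(fisher_two_sided(1, 9, 1, 9)$p.value, 1)
  expect_equal(fisher_two_sided(5, 0, 0, 5)$p.value, 2 / 252)
  expect_equal(fisher_two_sided(5, 0, 0, 5)$odds_ratio, Inf)
  degen <- fisher_two_sided(0, 0, 3, 7)
  expect_equal(degen$p.value, 1)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$odds_ratio))
})

test_that("Fisher p matches enumeration and stats::fisher.test on random tables", {
  withr::with_seed(61, {
    for (rep in 1:200) {
      tab <- sample(0:15, 4, replace = TRUE)
      got <- fisher_two_sided(tab[1], tab[2], tab[3], tab[4])$p.value
      expect_equal(got, enum_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-10)
      if (sum(tab[1:2]) > 0 && sum(tab[3:4]) > 0 &&
          sum(tab[c(1, 3)]) > 0 && sum(tab[c(2, 4)]) > 0) {
        ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
        expect_equal(got, ref, tolerance = 1e-8)
      }
    }
  })
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  withr::with_seed(62, p <- runif(100)^2)
  expect_equal(bh_fdr(p), stepup_bh(p))
  # monotone: ordering by p and by fdr agree after step-up smoothing
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("state enrichment finds a subset planted inside one state", {
  withr::with_seed(63, {
    universe <- random_regions(300, chroms = "chrI", max_pos = 1e6,
                               max_width = 200)
  })
  # state A covers the first 40 regions exactly; B and C are elsewhere
  states <- dplyr::bind_rows(
    tibble::tibble(chrom = "chrI", start = universe$start[1:40],
                   end = universe$end[1:40], label = "A"),
    tibble::tibble(chrom = "chrI", start = 2e6 + (1:30) * 1000L,
                   end = 2e6 + (1:30) * 1000L + 500L, label = "B"),
    tibble::tibble(chrom = "chrII", start = (1:10) * 1000L,
                   end = (1:10) * 1000L + 500L, label = "C"))
  res <- state_enrichment(universe[1:40, ], universe[-(1:40), ], states)
  a <- res[res$target_label == "A", ]
  expect_equal(a$ov_da, 40)
  expect_equal(a$tot_tgt, 40)
  expect_lt(a$fdr, 1e-10)
  expect_equal(which.min(res$p), which(res$target_label == "A"))
  # a uniformly drawn subset shows no strong state signal
  withr::with_seed(64, idx <- sample(300, 50))
  null_res <- state_enrichment(universe[idx, ], universe[-idx, ], states)
  expect_true(all(null_res$fdr > 0.01))
})

test_that("state aggregation sums counts and matches a direct recount", {
  rec <- new_enrichment_result_for_test(
    target_label = c("s1", "s2", "s3"),
    ov_da = c(5, 3, 2), ov_nda = c(10, 10, 4), tot_tgt = c(100, 150, 30),
    n_da = 50, n_nda = 200)
  merged <- aggregate_states(rec, c(s1 = "PC", s2 = "PC"))
  pc <- merged[merged$target_label == "PC", ]
  expect_equal(c(pc$ov_da, pc$ov_nda, pc$tot_tgt), c(8, 20, 250))
  expect_equal(pc$p,
               fisher_two_sided(8, 50 - 8, 20, 200 - 20)$p.value)
  # totals are conserved
  expect_equal(sum(merged$ov_da), sum(rec$ov_da))
  # merging with an all-zero state changes nothing but the label
  zero <- new_enrichment_result_for_test(
    target_label = c("x", "empty"), ov_da = c(4, 0), ov_nda = c(6, 0),
    tot_tgt = c(50, 0), n_da = 20, n_nda = 100)
  mz <- aggregate_states(zero, c(x = "x+", empty = "x+"))
  expect_equal(c(mz$ov_da, mz$ov_nda, mz$tot_tgt), c(4, 6, 50))
  expect_error(aggregate_states(rec, c(nope = "PC")), "unknown")
})

test_that("aggregation equals re-testing the merged interval set", {
  withr::with_seed(65, {
    universe <- random_regions(200, chroms = "chrI", max_pos = 5e5,
                               max_width = 150)
    sub <- sample(200, 60)
    states <- tibble::tibble(
      chrom = "chrI", start = sample.int(5e5, 80),
      label = sample(c("m1", "m2", "other"), 80, replace = TRUE)) |>
      dplyr::mutate(end = start + 400L)
  })
  res <- state_enrichment(universe[sub, ], universe[-sub, ], states)
  merged <- aggregate_states(res, c(m1 = "m", m2 = "m"))
  relabeled <- dplyr::mutate(states,
                             label = ifelse(label %in% c("m1", "m2"), "m",
                                            label))
  direct <- state_enrichment(universe[sub, ], universe[-sub, ], relabeled)
  m_agg <- merged[merged$target_label == "m", ]
  m_dir <- direct[direct$target_label == "m", ]
  # summed counts can double-count a region overlapping both sub-states,
  # so compare the aggregated table against a recount that sums per state
  expect_equal(m_agg$tot_tgt, m_dir$tot_tgt)
  per_state <- res[res$target_label %in% c("m1", "m2"), ]
  expect_equal(m_agg$ov_da, sum(per_state$ov_da))
  expect_equal(m_agg$ov_nda, sum(per_state$ov_nda))
})

test_that("gene-set overlap ranks a self-match first and handles edge rules", {
  universe <- sprintf("gene%03d", 1:200)
  sets <- list(self = universe[1:20],
               half = universe[c(1:10, 101:110)],
               unrelated = universe[150:180])
  res <- gene_set_overlap(universe[1:20], sets, universe)
  expect_equal(res$target_label[which.min(res$p)], "self")
  expect_lt(res$fdr[res$target_label == "self"], 1e-6)
  # empty query: degenerate tables, all p = 1
  empty <- gene_set_overlap(character(0), sets, universe)
  expect_equal(empty$p, rep(1, 3))
  # query must live in the universe
  expect_error(gene_set_overlap("nope", sets, universe), "subset")
})

test_that("signature and age-DEG set builders apply strict thresholds", {
  expr <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         neuronA = c(100, 101, 250),
                         neuronB = c(5, 100.5, 99.9))
  sig <- celltype_signatures(expr, min_counts = 100)
  expect_equal(sig$neuronA, c("g2", "g3"))  # exactly 100 is excluded
  expect_equal(sig$neuronB, "g2")
  degs <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         p = c(0.01, 0.04, 0.2, 0.01),
                         fc = c(2, 0.5, 3, 1))
  sets <- age_deg_sets(degs)
  expect_equal(sets$age_up, "a")     # fc exactly 1 excluded, p 0.2 excluded
  expect_equal(sets$age_down, "b")
  logsets <- age_deg_sets(dplyr::mutate(degs, fc = log2(fc)),
                          fc_scale = "log")
  expect_equal(logsets$age_up, "a")
  expect_equal(logsets$age_down, "b")
})

test_that("gene-set overlap is calibrated under a random-query null", {
  universe <- sprintf("g%04d", 1:1000)
  withr::with_seed(66, {
    sets <- purrr::map(1:20, ~sample(universe, 50))
    names(sets) <- paste0("set", 1:20)
    hits <- purrr::map_dbl(1:60, function(i) {
      q <- sample(universe, 50)
      mean(gene_set_overlap(q, sets, universe)$fdr <= 0.05)
    })
  })
  expect_lte(mean(hits), 0.05)
})
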