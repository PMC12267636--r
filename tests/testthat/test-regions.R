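test_that("promoter window classification follows the -1500/+500 rule", {
  genes <- toy_gene("g1", "chrI", "+", 10000L)
  peaks <- tibble::tibble(chrom = "chrI",
                          start = c(9000L, 8400L, 10450L, 10500L),
                          end = c(9400L, 8500L, 10490L, 10700L),
                          id = paste0("p", 1:4))
  ann <- classify_regions(peaks, genes)
  # inside [8500, 10500): promoter; just left of it: not; window half-open
  expect_equal(as.character(ann$category[1]), "Promoter")
  expect_false(ann$is_prom[2])
  expect_equal(as.character(ann$category[3]), "Promoter")
  expect_false(ann$is_prom[4])  # starts exactly at the half-open boundary
})

test_that("category precedence and distNC flags behave as defined", {
  genes <- toy_gene("g1", "chrI", "+", 10000L)
  peaks <- tibble::tibble(
    chrom = "chrI",
    start = c(13500L, 12900L, 30000L),
    end = c(13700L, 13100L, 30200L),
    id = c("intronic", "exon_intron", "distal"))
  ann <- classify_regions(peaks, genes)
  expect_equal(as.character(ann$category),
               c("Intron", "Exon", "Distal Intergenic"))
  # spanning exon 2 and intron 2 resolves to Exon by precedence
  expect_equal(ann$is_distnc, c(TRUE, FALSE, TRUE))
  # exactly one category each, and is_distnc is a pure function of category
  expect_equal(ann$is_distnc,
               ann$category %in% c("Intron", "Distal Intergenic"))
})

test_that("classification matches a per-base brute-force annotator", {
  genes <- toy_genome(n_genes = 30)
  withr::with_seed(11, {
    regions <- random_regions(1000, max_pos = 60000, max_width = 800)
  })
  ann <- classify_regions(regions, genes)
  expect_equal(as.character(ann$category), brute_annotate(regions, genes))
  expect_equal(ann$closest_gene, brute_closest(regions, genes))
  # every region got exactly one category
  expect_equal(sum(table(ann$category)), nrow(regions))
})

test_that("signed TSS distance is strand-aware and ties break lexicographically", {
  genes <- dplyr::bind_rows(toy_gene("gB", "chrI", "+", 10000L),
                            toy_gene("gA", "chrI", "-", 20000L - 6000L + 1L))
  # gA tss = 19999 + 1 - 1 = 20000; place a region equidistant from both TSS
  gA_tss <- genes$end[2] - 1L
  mid <- (10000L + gA_tss) %/% 2L
  region <- tibble::tibble(chrom = "chrI", start = mid - 50L, end = mid + 52L,
                           id = "tie")
  ann <- classify_regions(region, genes)
  expect_equal(ann$closest_gene, "gA")
  # upstream of a + strand gene is negative
  up <- classify_regions(
    tibble::tibble(chrom = "chrI", start = 9000L, end = 9100L, id = "u"),
    toy_gene("g1", "chrI", "+", 10000L))
  expect_lt(up$distance_to_tss, 0)
  # upstream of a - strand gene lies at larger coordinates
  gm <- toy_gene("g2", "chrI", "-", 10000L)
  upm <- classify_regions(
    tibble::tibble(chrom = "chrI", start = 17000L, end = 17100L, id = "u"),
    gm)
  expect_lt(upm$distance_to_tss, 0)
})

test_that("regions on unannotated chromosomes are flagged, not dropped", {
  genes <- toy_gene("g1", "chrI", "+", 10000L)
  peaks <- tibble::tibble(chrom = c("chrI", "chrX"),
                          start = c(9000L, 100L), end = c(9200L, 300L),
                          id = c("a", "b"))
  expect_warning(ann <- classify_regions(peaks, genes), "absent")
  expect_equal(nrow(ann), 2L)
  expect_equal(as.character(ann$category[2]), "Distal Intergenic")
  expect_true(is.na(ann$closest_gene[2]))
})

test_that("blacklist filtering removes any 1-bp overlap and nothing else", {
  peaks <- tibble::tibble(chrom = "chrI", start = c(0L, 200L),
                          end = c(100L, 300L), id = c("A", "B"))
  hot <- tibble::tibble(chrom = "chrI", start = 250L, end = 260L)
  expect_message(out <- filter_blacklist(peaks, hot), "removed 1 of 2")
  expect_equal(out$id, "A")
  # empty hotspot set is the identity
  expect_message(same <- filter_blacklist(peaks, hot[0, ]), "0 peaks")
  expect_equal(same$id, peaks$id)
  # random case against the all-pairs oracle
  withr::with_seed(5, {
    p <- random_regions(50, prefix = "p")
    h <- random_regions(10, prefix = "h")
  })
  suppressMessages(filtered <- filter_blacklist(p, h))
  bad <- unique(quadratic_overlap(p, h)$a_id)
  expect_setequal(filtered$id, setdiff(p$id, bad))
})

test_that("overlap_regions is half-open, symmetric, and matches brute force", {
  a <- tibble::tibble(chrom = "chrI", start = 0L, end = 10L, id = "a1")
  touching <- tibble::tibble(chrom = "chrI", start = 10L, end = 20L, id = "b1")
  overlapping <- tibble::tibble(chrom = "chrI", start = 9L, end = 20L,
                                id = "b2")
  expect_equal(nrow(overlap_regions(a, touching)), 0L)
  expect_equal(nrow(overlap_regions(a, overlapping)), 1L)
  withr::with_seed(13, {
    x <- random_regions(100, prefix = "x")
    y <- random_regions(100, prefix = "y")
  })
  got <- overlap_regions(x, y) |> dplyr::arrange(a_id, b_id)
  want <- quadratic_overlap(x, y) |> dplyr::arrange(a_id, b_id)
  expect_equal(got, want)
  # symmetry of the underlying relation
  rev <- overlap_regions(y, x)
  expect_setequal(paste(got$a_id, got$b_id), paste(rev$b_id, rev$a_id))
  # reflexive on self-comparison
  self <- overlap_regions(x, x)
  expect_true(all(paste(x$id, x$id) %in% paste(self$a_id, self$b_id)))
})
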