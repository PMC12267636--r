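# exhaustive scorer over all 4^L sequences; independent of the DP
enum_pwm_tail <- function(pwm, background, grid, score) {
  L <- nrow(pwm$matrix)
  k <- darlinker:::pwm_int_scores(pwm, background, grid)
  seqs <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- rep(0L, nrow(seqs))
  probs <- rep(1, nrow(seqs))
  bg <- background / sum(background)
  for (i in seq_len(L)) {
    scores <- scores + k[i, seqs[, i]]
    probs <- probs * bg[seqs[, i]]
  }
  sum(probs[scores * grid >= score - 1e-12])
}

test_that("Homer motif files round-trip and parse headers", {
  pwm <- planted_motif("TAATGG", name = "lin39_like")
  path <- withr::local_tempfile(fileext = ".motif")
  write_homer_motifs(list(pwm, planted_motif("CCCGGG", name = "m2")), path)
  back <- read_homer_motifs(path)
  expect_named(back, c("lin39_like", "m2"))
  expect_equal(back$lin39_like$matrix, pwm$matrix, tolerance = 1e-9)
  expect_equal(back$lin39_like$consensus, "TAATGG")
  # a second round-trip is bit-stable
  path2 <- withr::local_tempfile(fileext = ".motif")
  write_homer_motifs(back, path2)
  expect_equal(read_homer_motifs(path2)$m2$matrix, back$m2$matrix)
})

test_that("malformed motif input is reported precisely", {
  path <- withr::local_tempfile(fileext = ".motif")
  writeLines(c(">TAAT\tok\t0", "0.9\t0.03\t0.03\t0.04",
               ">broken_header_no_tabs"), path)
  expect_error(read_homer_motifs(path), "line 3")
  writeLines(c(">TAAT\tbadrow\t0", "0.5\t0.5\t0.5\t0.5"), path)
  expect_warning(m <- read_homer_motifs(path), "renormalized")
  expect_equal(sum(m$badrow$matrix[1, ]), 1, tolerance = 1e-9)
  # zero probabilities are floored by the pseudocount
  writeLines(c(">ACGT\tzeros\t0", "1\t0\t0\t0"), path)
  m <- read_homer_motifs(path)
  expect_true(all(m$zeros$matrix > 0))
})

test_that("a uniform PWM has an all-zero score distribution", {
  mat <- matrix(0.25, nrow = 4, ncol = 4)
  pwm <- darlinker:::new_pwm("uniform", mat)
  expect_warning(th <- exact_score_threshold(pwm, alpha = 0.01),
                 "minimum attainable tail")
  expect_equal(as.numeric(th), 0)
})

test_that("the exact DP tail matches full enumeration for short motifs", {
  withr::with_seed(81, {
    for (L in c(2, 4, 6)) {
      mat <- matrix(rgamma(4 * L, 1), nrow = L)
      mat <- mat / rowSums(mat)
      pwm <- darlinker:::new_pwm(sprintf("r%d", L), mat)
      bg <- c(0.3, 0.2, 0.2, 0.3)
      for (alpha in c(0.3, 0.05, 0.01)) {
        saturated <- FALSE
        th <- withCallingHandlers(
          exact_score_threshold(pwm, bg, alpha = alpha),
          warning = function(w) {
            saturated <<- TRUE
            invokeRestart("muffleWarning")
          })
        tail_p <- enum_pwm_tail(pwm, bg, 1e-3, as.numeric(th))
        expect_equal(attr(th, "tail_prob"), tail_p, tolerance = 1e-9)
        if (!saturated) expect_lte(tail_p, alpha)
      }
    }
  })
})

test_that("halving alpha never lowers the threshold", {
  pwm <- planted_motif("TGATTACG")
  alphas <- 0.2 / 2^(0:8)
  ths <- vapply(alphas,
                function(a) as.numeric(exact_score_threshold(pwm, alpha = a)),
                numeric(1))
  expect_true(all(diff(ths) >= 0))
})

test_that("scanning finds planted consensus hits at the right offset", {
  pwm <- planted_motif("TGATTACG")
  th <- exact_score_threshold(pwm, alpha = 1e-4)
  withr::with_seed(82, seq_body <- random_dna(1, 100))
  planted <- paste0(substr(seq_body, 1, 40), "TGATTACG",
                    substr(seq_body, 49, 100))
  hits <- scan_regions(c(r1 = planted), pwm, th)
  expect_true(any(hits$offset == 40 & hits$strand == "+"))
  # no hits in all-N or too-short sequences
  expect_equal(nrow(scan_regions(c(r = strrep("N", 50)), pwm, th)), 0)
  expect_equal(nrow(scan_regions(c(r = "ACG"), pwm, th)), 0)
})

test_that("hit status is strand-symmetric", {
  pwm <- planted_motif("TGATTACG")
  th <- exact_score_threshold(pwm, alpha = 1e-3)
  withr::with_seed(83, seqs <- random_dna(60, 150))
  seqs[1:10] <- paste0(substr(seqs[1:10], 1, 60), "TGATTACG",
                       substr(seqs[1:10], 69, 150))
  names(seqs) <- sprintf("s%02d", seq_along(seqs))
  rc <- vapply(seqs, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  hit_fwd <- unique(scan_regions(seqs, pwm, th)$region_id)
  hit_rc <- unique(scan_regions(rc, pwm, th)$region_id)
  expect_setequal(hit_fwd, hit_rc)
  expect_true(all(sprintf("s%02d", 1:10) %in% hit_fwd))
})

test_that("per-window hit rate agrees with the analytic tail probability", {
  pwm <- planted_motif("TGAT", weight = 0.7)
  bg <- rep(0.25, 4)
  th <- exact_score_threshold(pwm, bg, alpha = 0.01)
  p_window <- attr(th, "tail_prob")
  withr::with_seed(84, seqs <- random_dna(300, 104))
  names(seqs) <- sprintf("q%03d", seq_along(seqs))
  hits <- scan_regions(seqs, pwm, th, bg)
  n_windows <- 300 * (104 - 4 + 1) * 2
  rate <- nrow(hits) / n_windows
  se <- sqrt(p_window * (1 - p_window) / n_windows)
  expect_lt(abs(rate - p_window), 5 * se)
})

test_that("motif enrichment flags the planted motif and stays null otherwise", {
  pwm <- planted_motif("TGATTACG")
  withr::with_seed(85, {
    tg <- random_dna(120, 150)
    bg <- random_dna(400, 150)
    plant <- function(s) {
      off <- sample.int(140, 1)
      paste0(substr(s, 1, off), "TGATTACG", substr(s, off + 9, 150))
    }
    tg[1:60] <- vapply(tg[1:60], plant, character(1))
    bg[1:20] <- vapply(bg[1:20], plant, character(1))
  })
  targets <- tibble::tibble(id = sprintf("t%03d", seq_along(tg)), seq = tg)
  background <- tibble::tibble(id = sprintf("b%03d", seq_along(bg)), seq = bg)
  motifs <- c(setNames(list(pwm), "planted_tf"), decoy_motifs(8, seed = 85))
  res <- motif_enrichment(targets, background, motifs)
  expect_equal(res$target_label[which.min(res$p)], "planted_tf")
  expect_lt(res$fdr[res$target_label == "planted_tf"], 1e-6)
  # a random split of the same pool is null
  withr::with_seed(86, {
    pool <- random_dna(300, 150)
    idx <- sample(300, 100)
  })
  t2 <- tibble::tibble(id = sprintf("x%03d", 1:100), seq = pool[idx])
  b2 <- tibble::tibble(id = sprintf("y%03d", 1:200), seq = pool[-idx])
  null_res <- motif_enrichment(t2, b2, motifs)
  expect_true(all(null_res$fdr > 0.05))
  expect_error(motif_enrichment(t2, t2, motifs), "share ids")
})

test_that("ChIP-mode enrichment is maximal when peaks cover the targets", {
  withr::with_seed(87, {
    universe <- random_regions(150, chroms = "chrI", max_pos = 1e6,
                               max_width = 200)
  })
  targets <- universe[1:30, ]
  background <- universe[-(1:30), ]
  chip <- targets[, c("chrom", "start", "end")]
  res <- chip_enrichment(targets, background, list(tf_a = chip))
  expect_equal(res$ov_da, 30)
  expect_lt(res$p, 1e-10)
})
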