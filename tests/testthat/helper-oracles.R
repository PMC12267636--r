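# Independent oracles and fixture builders used across the suite.
# Each oracle re-derives its quantity from first principles (per-base scans,
# full enumeration, closed forms) so it shares no code path with the
# implementation it checks.

# -- toy genome builders ------------------------------------------------------

toy_gene <- function(gene_id, chrom, strand, start) {
  # 6 kb gene: exons [0,500), [2500,3000), [5500,6000); UTRs at the ends
  offset <- start
  rel <- function(tbl) tibble::tibble(start = tbl$start + offset,
                                      end = tbl$end + offset)
  exons <- rel(tibble::tibble(start = c(0L, 2500L, 5500L),
                              end = c(500L, 3000L, 6000L)))
  if (strand == "+") {
    five <- rel(tibble::tibble(start = 0L, end = 100L))
    three <- rel(tibble::tibble(start = 5850L, end = 6000L))
  } else {
    five <- rel(tibble::tibble(start = 5900L, end = 6000L))
    three <- rel(tibble::tibble(start = 0L, end = 150L))
  }
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = start, end = start + 6000L,
                 exons = list(exons), five_utr = list(five),
                 three_utr = list(three))
}

toy_genome <- function(n_genes = 24, chroms = c("chrI", "chrII"),
                       spacing = 15000L, seed = 7) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_genes), function(i) {
      toy_gene(sprintf("g%02d", i),
               chroms[(i %% length(chroms)) + 1L],
               sample(c("+", "-"), 1),
               3000L + ((i - 1L) %/% length(chroms)) * spacing +
                 sample(-500:500, 1))
    })
  })
}

# -- per-base annotation oracle ----------------------------------------------

# label each base of the genome from the signed-distance promoter rule and
# the raw feature tables, then classify a region by precedence over the
# union of labels of its covered bases
brute_annotate <- function(regions, genes, up = 1500, down = 500) {
  chrom_len <- max(genes$end, regions$end) + up + down + 10L
  cats <- c("Promoter", "5' UTR", "3' UTR", "Exon", "Intron",
            "Distal Intergenic")
  masks <- list()
  for (chr in unique(c(genes$chrom, regions$chrom))) {
    m <- matrix(FALSE, nrow = 5, ncol = chrom_len)
    gs <- genes[genes$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(gs))) {
      g <- gs[i, ]
      tss <- if (g$strand == "+") g$start else g$end - 1L
      for (s in (-up):(down - 1L)) {
        p <- if (g$strand == "+") tss + s else tss - s
        if (p >= 0 && p < chrom_len) m[1, p + 1L] <- TRUE
      }
      mark <- function(row, tbl) {
        for (j in seq_len(nrow(tbl))) {
          m[row, (tbl$start[j] + 1L):tbl$end[j]] <<- TRUE
        }
      }
      mark(2, g$five_utr[[1]])
      mark(3, g$three_utr[[1]])
      mark(4, g$exons[[1]])
      m[5, (g$start + 1L):g$end] <- TRUE
    }
    masks[[chr]] <- m
  }
  vapply(seq_len(nrow(regions)), function(k) {
    m <- masks[[regions$chrom[k]]]
    span <- (regions$start[k] + 1L):regions$end[k]
    hit <- vapply(1:5, function(r) any(m[r, span]), logical(1))
    if (any(hit)) cats[which(hit)[1]] else cats[6]
  }, character(1))
}

# closest gene by TSS distance to the midpoint, lexicographic tie-break
brute_closest <- function(regions, genes) {
  vapply(seq_len(nrow(regions)), function(k) {
    gs <- genes[genes$chrom == regions$chrom[k], , drop = FALSE]
    if (nrow(gs) == 0) return(NA_character_)
    tss <- ifelse(gs$strand == "+", gs$start, gs$end - 1L)
    mid <- (regions$start[k] + regions$end[k]) %/% 2L
    d <- abs(mid - tss)
    cand <- gs$gene_id[d == min(d)]
    sort(cand)[1]
  }, character(1))
}

# -- interval oracles ---------------------------------------------------------

random_regions <- function(n, chroms = c("chrI", "chrII"), max_pos = 5e4,
                           max_width = 500, prefix = "r") {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(max_width, n, replace = TRUE),
                 id = sprintf("%s%04d", prefix, seq_len(n)))
}

quadratic_overlap <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1L]] <- c(a$id[i], b$id[j])
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(a_id = character(), b_id = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(a_id = m[, 1], b_id = m[, 2])
}

# -- statistical oracles ------------------------------------------------------

# two-sided Fisher p by direct enumeration with binomial-coefficient table
# probabilities (no dhyper)
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p_obs <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  min(1, sum(exp(logp[logp <= p_obs + 1e-7])))
}

# BH step-up re-implemented directly from the definition
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# exact two-sided rank-sum p by enumerating all n1-subsets
enum_ranksum_p <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(n1)])
  sums <- apply(utils::combn(length(r), n1), 2, function(i) sum(r[i]))
  lower <- mean(sums <= obs + 1e-9)
  upper <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# -- count-data fixtures ------------------------------------------------------

null_counts <- function(n_features, n_per_group, mu = 100, phi = 0.1) {
  m <- matrix(stats::rnbinom(n_features * 2 * n_per_group, mu = mu,
                             size = 1 / phi),
              nrow = n_features)
  colnames(m) <- paste0("s", seq_len(2 * n_per_group))
  list(counts = dplyr::bind_cols(
         tibble::tibble(feature_id = sprintf("f%04d", seq_len(n_features))),
         tibble::as_tibble(m)),
       groups = stats::setNames(rep(c("a", "b"), each = n_per_group),
                                colnames(m)))
}

random_dna <- function(n, len) {
  big <- paste(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
               collapse = "")
  substring(big, (seq_len(n) - 1L) * len + 1L, seq_len(n) * len)
}

random_censored <- function(n, rate = 0.1, lambda = 0.08) {
  t <- stats::rexp(n, lambda)
  cens <- stats::runif(n) < rate
  tibble::tibble(time = ifelse(cens, stats::runif(n, 0, t), t),
                 event = as.integer(!cens))
}

# minimal enrichment_result for aggregation tests
new_enrichment_result_for_test <- function(target_label, ov_da, ov_nda,
                                           tot_tgt, n_da, n_nda) {
  n <- length(target_label)
  res <- tibble::tibble(
    set_label = "subset", target_label = target_label,
    ov_da = ov_da, ov_nda = ov_nda, tot_tgt = tot_tgt,
    n_da = rep(n_da, n), n_nda = rep(n_nda, n),
    odds_ratio = NA_real_, p = NA_real_, fdr = NA_real_)
  structure(res, class = c("enrichment_result", class(res)))
}
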