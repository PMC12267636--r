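#' @title Position weight matrices
#' @description
#' A `pwm` is a list with `name`, `consensus`, `matrix` (L x 4 base
#' probabilities, columns A, C, G, T) and `pseudocount`. Probabilities are
#' zero-guarded on read: a row containing values below the pseudocount (or
#' not summing to 1) is renormalized as `(p + pc) / (sum(p) + 4 pc)`;
#' well-formed rows pass through untouched so write/read round-trips are
#' exact. Log-odds scores are in bits against a background base
#' distribution.
#' @name pwm
#' @keywords internal
NULL

BASES <- c("A", "C", "G", "T")

new_pwm <- function(name, mat, consensus = NULL, pseudocount = 1e-3) {
  colnames(mat) <- BASES
  if (is.null(consensus)) {
    consensus <- paste(BASES[max.col(mat)], collapse = "")
  }
  structure(list(name = name, consensus = consensus, matrix = mat,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  consensus %s  length %d\n",
              x$name, x$consensus, nrow(x$matrix)))
  invisible(x)
}

guard_pwm_rows <- function(mat, pseudocount, path = NULL) {
  bad_sum <- abs(rowSums(mat) - 1) > 1e-6
  if (any(bad_sum)) {
    warn(sprintf("%d PWM row(s) did not sum to 1; renormalized.",
                 sum(bad_sum)))
  }
  fix <- bad_sum | apply(mat, 1, function(r) any(r < pseudocount))
  if (any(fix)) {
    mat[fix, ] <- (mat[fix, , drop = FALSE] + pseudocount) /
      (rowSums(mat[fix, , drop = FALSE]) + 4 * pseudocount)
  }
  mat
}

#' Read TF motifs in Homer format
#'
#' Homer `.motif` files hold one record per motif: a header line
#' `>consensus<TAB>name<TAB>...` followed by one row of four tab-separated
#' base probabilities (A, C, G, T) per motif position.
#'
#' @param path Path to a `.motif` file.
#' @param pseudocount Zero guard applied to degenerate rows (default 1e-3).
#' @return A named list of `pwm` objects.
#' @export
read_homer_motifs <- function(path, pseudocount = 1e-3) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (length(starts) == 0) abort("no '>' motif headers found.")
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- purrr::map2(starts, ends, function(s, e) {
    fields <- strsplit(sub("^>", "", lines[s]), "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      abort(sprintf("malformed motif header at line %d (need >= 2 tab-separated fields).", s))
    }
    if (e <= s) abort(sprintf("motif '%s' (line %d) has no probability rows.",
                              fields[2], s))
    rows <- strsplit(lines[(s + 1):e], "\t", fixed = TRUE)
    if (any(lengths(rows) != 4)) {
      abort(sprintf("motif '%s': probability rows must have 4 columns.",
                    fields[2]))
    }
    mat <- do.call(rbind, purrr::map(rows, as.numeric))
    mat <- guard_pwm_rows(mat, pseudocount)
    new_pwm(fields[2], mat, consensus = fields[1], pseudocount = pseudocount)
  })
  setNames(pwms, purrr::map_chr(pwms, "name"))
}

#' Write motifs in Homer format
#'
#' @param pwms A list of `pwm` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homer_motifs <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- purrr::map(pwms, function(p) {
    c(sprintf(">%s\t%s\t0", p$consensus, p$name),
      apply(p$matrix, 1, function(r) paste(sprintf("%.10g", r),
                                           collapse = "\t")))
  })
  readr::write_lines(unlist(lines), path)
  invisible(path)
}

#' Reverse complement of a PWM
#'
#' @param pwm A `pwm`.
#' @return The reverse-complement `pwm`.
#' @export
pwm_revcomp <- function(pwm) {
  mat <- pwm$matrix[rev(seq_len(nrow(pwm$matrix))), c("T", "G", "C", "A"),
                    drop = FALSE]
  new_pwm(pwm$name, mat, pseudocount = pwm$pseudocount)
}

# integer log-odds matrix on the discretized grid (bits / grid units)
pwm_int_scores <- function(pwm, background, grid) {
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  lo <- log2(sweep(pwm$matrix, 2, background, "/"))
  round(lo / grid)
}

#' Exact score threshold for PWM scanning
#'
#' Computes the exact null distribution of the log-odds score of a random
#' background sequence by positionwise convolution over a discretized score
#' lattice (default grid 1e-3 bits), and returns the smallest score whose
#' upper-tail probability is at most `alpha`. If `alpha` is below the
#' probability of the maximum score, the maximum score is returned with a
#' warning.
#'
#' @param pwm A `pwm`.
#' @param background Background base frequencies (A, C, G, T); default
#'   uniform.
#' @param alpha Per-window false-positive rate in (0, 0.5); default 1e-4.
#' @param grid Score discretization in bits (default 1e-3).
#' @return The threshold score in bits, with the achieved tail probability
#'   in attribute `"tail_prob"`.
#' @export
exact_score_threshold <- function(pwm, background = rep(0.25, 4),
                                  alpha = 1e-4, grid = 1e-3) {
  stopifnot(alpha > 0, alpha < 0.5)
  background <- background / sum(background)
  k <- pwm_int_scores(pwm, background, grid)
  dist <- score_distribution(k, background)
  tail_p <- rev(cumsum(rev(dist$prob)))
  ok <- which(tail_p <= alpha)
  if (length(ok) == 0) {
    warn(sprintf(
      "alpha = %g below the minimum attainable tail (%g); returning the maximum score.",
      alpha, tail_p[length(tail_p)]))
    idx <- length(tail_p)
  } else {
    idx <- ok[1]
  }
  structure(dist$score[idx] * grid, tail_prob = tail_p[idx])
}

# exact distribution of the integer score sum under the background model
score_distribution <- function(k, background) {
  cur_lo <- 0
  v <- 1
  for (i in seq_len(nrow(k))) {
    rmin <- min(k[i, ]); rmax <- max(k[i, ])
    newv <- rep(0, length(v) + rmax - rmin)
    for (l in 1:4) {
      sh <- k[i, l] - rmin
      idx <- seq_along(v) + sh
      newv[idx] <- newv[idx] + v * background[l]
    }
    v <- newv
    cur_lo <- cur_lo + rmin
  }
  list(score = cur_lo + seq_along(v) - 1L, prob = v)
}

seqs_to_tbl <- function(seqs, arg = "seqs") {
  if (is.data.frame(seqs)) {
    if (!all(c("id", "seq") %in% names(seqs))) {
      abort(sprintf("`%s` needs `id` and `seq` columns.", arg))
    }
    return(as_tibble(seqs)[, c("id", "seq")])
  }
  if (is.null(names(seqs))) abort(sprintf("`%s` must be named.", arg))
  tibble(id = names(seqs), seq = unname(as.character(seqs)))
}

#' Scan region sequences with a PWM
#'
#' Scores every window on both strands with the discretized log-odds matrix
#' and reports windows at or above the threshold. Windows containing `N`
#' are skipped; sequences shorter than the motif yield no hits.
#'
#' @param seqs Sequences as a tibble (`id`, `seq`) or a named character
#'   vector, alphabet `A,C,G,T,N`.
#' @param pwm A `pwm`.
#' @param threshold Score threshold in bits, typically from
#'   [exact_score_threshold()] with the same `background` and `grid`.
#' @param background Background base frequencies used for the log-odds.
#' @param grid Score discretization in bits (must match the threshold's).
#' @return A tibble of hits: `region_id`, `offset` (0-based window start),
#'   `strand`, `score` (bits).
#' @export
scan_regions <- function(seqs, pwm, threshold, background = rep(0.25, 4),
                         grid = 1e-3) {
  seqs <- seqs_to_tbl(seqs)
  L <- nrow(pwm$matrix)
  th_int <- round(threshold / grid)
  kf <- pwm_int_scores(pwm, background, grid)
  kr <- pwm_int_scores(pwm_revcomp(pwm), background, grid)

  sep <- strrep("N", L)
  big <- paste(toupper(seqs$seq), collapse = sep)
  enc <- match(strsplit(big, "", fixed = TRUE)[[1]], BASES)
  m <- length(enc)
  if (m < L) return(empty_hits())
  region_start <- cumsum(c(1L, nchar(seqs$seq) + L))[seq_len(nrow(seqs))]

  window_scores <- function(k) {
    n_win <- m - L + 1L
    ws <- rep(0L, n_win)
    for (i in seq_len(L)) {
      ws <- ws + k[i, enc[i:(n_win + i - 1L)]]
    }
    ws
  }
  hits_for <- function(k, strand) {
    ws <- window_scores(k)
    j <- which(!is.na(ws) & ws >= th_int)
    if (length(j) == 0) return(NULL)
    ri <- findInterval(j, region_start)
    tibble(region_id = seqs$id[ri], offset = j - region_start[ri],
           strand = strand, score = ws[j] * grid)
  }
  out <- bind_rows(hits_for(kf, "+"), hits_for(kr, "-"))
  if (nrow(out) == 0) empty_hits() else arrange(out, .data$region_id,
                                                .data$offset)
}

empty_hits <- function() {
  tibble(region_id = character(), offset = integer(), strand = character(),
         score = double())
}

#' Pooled base frequencies of a sequence set
#'
#' @param seqs Sequences (tibble or named vector); `N` bases are ignored.
#' @param pseudocount Added to each base count to guard zero frequencies.
#' @return Length-4 frequency vector (A, C, G, T).
#' @export
base_frequencies <- function(seqs, pseudocount = 1) {
  seqs <- seqs_to_tbl(seqs)
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(toupper(seqs$seq)))[, BASES, drop = FALSE])
  (counts + pseudocount) / sum(counts + 4 * pseudocount)
}

#' Motif enrichment in target vs background regions
#'
#' For each motif: the per-window threshold is set by
#' [exact_score_threshold()] at `alpha` against the pooled background base
#' frequencies, each region's hit status is binary (any window at or above
#' threshold on either strand), and enrichment of hit regions in targets vs
#' background is tested with the two-sided Fisher test, BH-corrected across
#' motifs.
#'
#' @param targets,background Sequence sets (tibble with `id`, `seq`, or
#'   named character vectors). Ids must be disjoint unless
#'   `allow_overlap = TRUE`.
#' @param motifs A list of `pwm` objects.
#' @param alpha Per-window scan threshold tail probability (default 1e-4).
#' @param grid Score discretization in bits.
#' @param allow_overlap Allow shared ids between targets and background.
#' @return An `enrichment_result` tibble, one row per motif, where `ov_da`
#'   and `ov_nda` count hit regions in targets and background and
#'   `tot_tgt` their sum.
#' @export
motif_enrichment <- function(targets, background, motifs, alpha = 1e-4,
                             grid = 1e-3, allow_overlap = FALSE) {
  targets <- seqs_to_tbl(targets, "targets")
  background <- seqs_to_tbl(background, "background")
  if (nrow(background) == 0) abort("`background` is empty.")
  if (!allow_overlap && length(intersect(targets$id, background$id))) {
    abort("targets and background share ids; set allow_overlap = TRUE to permit.")
  }
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  bg_freq <- base_frequencies(background)
  n_da <- nrow(targets); n_nda <- nrow(background)
  res <- purrr::map_dfr(motifs, function(p) {
    th <- exact_score_threshold(p, bg_freq, alpha = alpha, grid = grid)
    ov_da <- n_distinct(scan_regions(targets, p, th, bg_freq, grid)$region_id)
    ov_nda <- n_distinct(scan_regions(background, p, th, bg_freq,
                                      grid)$region_id)
    ft <- fisher_two_sided(ov_da, n_da - ov_da, ov_nda, n_nda - ov_nda)
    tibble(set_label = "targets", target_label = p$name,
           ov_da = ov_da, ov_nda = ov_nda, tot_tgt = ov_da + ov_nda,
           n_da = n_da, n_nda = n_nda,
           odds_ratio = ft$odds_ratio, p = ft$p.value)
  })
  res$fdr <- bh_fdr(res$p)
  new_enrichment_result(res)
}

#' ChIP-peak enrichment in target vs background regions
#'
#' Same 2x2 design as [motif_enrichment()], but a region's hit status is a
#' one-or-more-base overlap with any peak of each ChIP peak set.
#'
#' @param targets,background Region tibbles.
#' @param chip_peaks A named list of region tibbles (one per TF ChIP
#'   experiment) or a single region tibble.
#' @return An `enrichment_result` tibble, one row per ChIP set.
#' @export
chip_enrichment <- function(targets, background, chip_peaks) {
  targets <- check_regions(targets, "targets")
  background <- check_regions(background, "background")
  if (nrow(background) == 0) abort("`background` is empty.")
  if (is.data.frame(chip_peaks)) chip_peaks <- list(chip = chip_peaks)
  n_da <- nrow(targets); n_nda <- nrow(background)
  res <- purrr::imap_dfr(chip_peaks, function(peaks, nm) {
    peaks <- check_regions(peaks, nm)
    ov_da <- count_hits(targets, peaks)
    ov_nda <- count_hits(background, peaks)
    ft <- fisher_two_sided(ov_da, n_da - ov_da, ov_nda, n_nda - ov_nda)
    tibble(set_label = "targets", target_label = nm,
           ov_da = ov_da, ov_nda = ov_nda, tot_tgt = nrow(peaks),
           n_da = n_da, n_nda = n_nda,
           odds_ratio = ft$odds_ratio, p = ft$p.value)
  })
  res$fdr <- bh_fdr(res$p)
  new_enrichment_result(res)
}
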