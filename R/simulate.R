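#' @title Synthetic multi-omics benchmark generator
#' @description
#' Generates every input the pipeline consumes — gene models, consensus
#' peaks, chromatin states, region sequences, count tables, lifespan
#' tables — with planted effect structure mirroring the biology the
#' analysis assumes: distal non-coding (distNC) regions that close with
#' aging, a configurable fraction of which reopen under reduced
#' insulin/IGF-like signaling (anti-concordance), concordant expression
#' changes at the closest genes, a TF motif planted in the reopening
#' regions, an enhancer chromatin state preferentially covering the planted
#' regions, and Weibull lifespans with group-specific target medians.
#' Promoter regions receive independent (non-anti-concordant) differential
#' effects so that category-restricted contrasts have a built-in negative
#' control. All randomness flows from a single seed.
#' @name synthetic-data
#' @keywords internal
NULL

#' Default planted TF motif
#'
#' An 8-position PWM with 0.94 weight on the consensus base, standing in
#' for an experimentally defined TF binding motif.
#'
#' @param consensus Consensus string (A/C/G/T).
#' @param name Motif name.
#' @param weight Probability of the consensus base at each position.
#' @return A `pwm`.
#' @export
planted_motif <- function(consensus = "TGATTACG", name = "planted_tf",
                          weight = 0.94) {
  letters <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - weight) / 3, nrow = length(letters), ncol = 4,
                dimnames = list(NULL, BASES))
  for (i in seq_along(letters)) mat[i, letters[i]] <- weight
  new_pwm(name, mat, consensus = consensus)
}

# deterministic within-gene layout (relative to gene start, + strand)
gene_layout <- function(strand) {
  exons <- tibble(start = c(0L, 2500L, 5500L), end = c(500L, 3000L, 6000L))
  if (strand == "+") {
    list(exons = exons,
         five_utr = tibble(start = 0L, end = 100L),
         three_utr = tibble(start = 5850L, end = 6000L))
  } else {
    list(exons = exons,
         five_utr = tibble(start = 5900L, end = 6000L),
         three_utr = tibble(start = 0L, end = 150L))
  }
}

#' Simulate a toy genome with planted regulatory structure
#'
#' Lays out non-overlapping genes (three exons, UTRs, introns) on a small
#' multi-chromosome genome, places one consensus peak per gene with the
#' configured genomic-category mix, classifies the peaks with
#' [classify_regions()], and plants the effect structure described in
#' [synthetic-data]: a fraction of distNC peaks close with aging, a
#' fraction of those reopen under reduced IIS, promoter peaks change
#' independently in both contrasts, closest genes change concordantly, the
#' motif is planted in IIS-reopening regions, and an enhancer state covers
#' planted distNC peaks with probability `enhancer_state_prob`.
#'
#' @param seed Integer seed; every downstream file is bit-identical for a
#'   fixed seed.
#' @param n_genes Number of genes (= number of peaks).
#' @param n_chroms Number of chromosomes.
#' @param gene_spacing Distance between successive gene anchors (bases).
#' @param peak_width Peak width in bases (also the sequence length).
#' @param category_mix Named fractions for peak placement over
#'   `Promoter`, `Exon`, `Intron`, `Distal Intergenic`; must sum to 1.
#' @param frac_distnc_closing Fraction of distNC peaks closing with aging.
#' @param anti_concordance Fraction of aging-closing distNC peaks that
#'   reopen under reduced IIS.
#' @param frac_promoter_da Fraction of promoter peaks differential in each
#'   contrast, independently (random direction).
#' @param effect_log2fc Planted |log2 fold change| for peaks and genes.
#' @param motif The planted `pwm` (default [planted_motif()]).
#' @param motif_fraction Fraction of IIS-reopening regions carrying a
#'   planted motif instance.
#' @param enhancer_state_prob Probability that a planted distNC peak is
#'   covered by the enhancer state.
#' @return A list: `genes`, `peaks`, `annot` (classified peaks), `states`,
#'   `sequences` (tibble `id`, `seq`), `motif`, `truth` (per-peak planted
#'   log2 fold changes and motif status), `gene_truth` (per-gene planted
#'   log2 fold changes).
#' @export
simulate_genome <- function(seed = 1, n_genes = 240, n_chroms = 3,
                            gene_spacing = 12000, peak_width = 200,
                            category_mix = c(Promoter = 0.25, Exon = 0.10,
                                             Intron = 0.30,
                                             `Distal Intergenic` = 0.35),
                            frac_distnc_closing = 0.5,
                            anti_concordance = 0.6,
                            frac_promoter_da = 0.3,
                            effect_log2fc = 2,
                            motif = planted_motif(),
                            motif_fraction = 0.5,
                            enhancer_state_prob = 0.9) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-8,
            all(category_mix >= 0),
            frac_distnc_closing >= 0, frac_distnc_closing <= 1,
            anti_concordance >= 0, anti_concordance <= 1,
            gene_spacing >= 10000)
  withr::with_seed(seed, {
    per_chrom <- ceiling(n_genes / n_chroms)
    chrom <- rep(paste0("chr", seq_len(n_chroms)), each = per_chrom)[1:n_genes]
    slot <- unlist(lapply(table(chrom), seq_len), use.names = FALSE)
    anchor <- 3000L + (slot - 1L) * as.integer(gene_spacing)
    gstart <- anchor + sample(-800:800, n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- tibble(
      gene_id = sprintf("g%03d", seq_len(n_genes)),
      chrom = chrom, strand = strand,
      start = gstart, end = gstart + 6000L)
    layouts <- purrr::map(strand, gene_layout)
    shift_tbl <- function(tbl, off) tibble(start = tbl$start + off,
                                           end = tbl$end + off)
    genes$exons <- purrr::map2(layouts, gstart, ~shift_tbl(.x$exons, .y))
    genes$five_utr <- purrr::map2(layouts, gstart,
                                  ~shift_tbl(.x$five_utr, .y))
    genes$three_utr <- purrr::map2(layouts, gstart,
                                   ~shift_tbl(.x$three_utr, .y))

    # one peak per gene, category by mix; offsets keep each category's
    # classification unambiguous under the -1500/+500 promoter window
    cats <- sample(names(category_mix), n_genes, replace = TRUE,
                   prob = category_mix)
    half <- as.integer(peak_width / 2)
    pstart <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      pstart[i] <- gstart[i] + switch(
        cats[i],
        Promoter = if (strand[i] == "+") -1100L - half else 6900L - half,
        Exon = 2750L - half,
        Intron = 4200L - half,
        `Distal Intergenic` = 8100L - half)
    }
    peaks <- tibble(chrom = chrom, start = pstart,
                    end = pstart + as.integer(peak_width),
                    id = sprintf("peak_%03d", seq_len(n_genes)))
    annot <- classify_regions(peaks, genes)

    # planted effects -------------------------------------------------------
    truth <- annot |>
      select("id", "category", "closest_gene", "is_distnc", "is_prom") |>
      mutate(aging_lfc = 0, iis_lfc = 0, motif_planted = FALSE)
    # distNC: close with aging; a fraction reopen under reduced IIS
    distnc <- which(truth$is_distnc & !duplicated(truth$closest_gene))
    closing <- sample(distnc, round(frac_distnc_closing * length(distnc)))
    truth$aging_lfc[closing] <- -effect_log2fc
    reopen <- sample(closing, round(anti_concordance * length(closing)))
    truth$iis_lfc[reopen] <- effect_log2fc
    # promoters: effects in the two contrasts on disjoint peaks (zero
    # anti-concordance), random direction
    prom <- which(truth$is_prom & !duplicated(truth$closest_gene))
    prom_aging <- sample(prom, round(frac_promoter_da * length(prom)))
    truth$aging_lfc[prom_aging] <-
      sample(c(-1, 1), length(prom_aging), replace = TRUE) * effect_log2fc
    prom_iis <- sample(setdiff(prom, prom_aging),
                       min(round(frac_promoter_da * length(prom)),
                           length(prom) - length(prom_aging)))
    truth$iis_lfc[prom_iis] <-
      sample(c(-1, 1), length(prom_iis), replace = TRUE) * effect_log2fc

    # concordant closest-gene expression changes
    gene_truth <- tibble(gene_id = genes$gene_id, aging_lfc = 0, iis_lfc = 0)
    for (k in which(truth$aging_lfc != 0)) {
      gene_truth$aging_lfc[gene_truth$gene_id == truth$closest_gene[k]] <-
        truth$aging_lfc[k]
    }
    for (k in which(truth$iis_lfc != 0)) {
      gene_truth$iis_lfc[gene_truth$gene_id == truth$closest_gene[k]] <-
        truth$iis_lfc[k]
    }

    # sequences, with the motif planted in a fraction of reopening regions
    rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                  collapse = "")
    seqs <- vapply(seq_len(n_genes), function(i) rand_seq(peak_width),
                   character(1))
    lm <- nchar(motif$consensus)
    planted <- sample(reopen, round(motif_fraction * length(reopen)))
    for (k in planted) {
      off <- sample.int(peak_width - lm + 1L, 1)
      substr(seqs[k], off, off + lm - 1L) <- motif$consensus
    }
    truth$motif_planted[planted] <- TRUE
    sequences <- tibble(id = peaks$id, seq = seqs)

    # chromatin states -------------------------------------------------------
    enh_idx <- closing[runif(length(closing)) < enhancer_state_prob]
    states <- bind_rows(
      promoter_windows(check_genes(genes), 1500L, 500L) |>
        mutate(label = "promoter state"),
      tibble(chrom = genes$chrom, start = genes$start, end = genes$end,
             label = "transcribed"),
      tibble(chrom = peaks$chrom[enh_idx],
             start = pmax(0L, peaks$start[enh_idx] - 100L),
             end = peaks$end[enh_idx] + 100L, label = "enhancer"),
      tibble(chrom = chrom, start = anchor + 9500L, end = anchor + 10500L,
             label = sample(c("PC repressed 1", "PC repressed 2"),
                            n_genes, replace = TRUE)))
    states$id <- sprintf("state_%04d", seq_len(nrow(states)))

    list(genes = genes, peaks = peaks, annot = annot, states = states,
         sequences = sequences, motif = motif,
         truth = select(truth, -"is_distnc", -"is_prom"),
         gene_truth = gene_truth)
  })
}

nb_counts <- function(base_mu, lfc, n_a, n_b, dispersion, prefix) {
  mu <- cbind(matrix(base_mu, length(base_mu), n_a),
              matrix(base_mu * 2^lfc, length(base_mu), n_b))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu))
  colnames(counts) <- c(sprintf("%s_a%d", prefix, seq_len(n_a)),
                        sprintf("%s_b%d", prefix, seq_len(n_b)))
  counts
}

#' Simulate count tables for the planted genome
#'
#' Draws negative-binomial counts for every peak and gene, per contrast,
#' with the planted fold changes applied to group B (old animals for the
#' aging contrast, reduced-IIS animals for the IIS contrast). Per-feature
#' baseline means are log-normal around `mu`.
#'
#' @param sim Output of [simulate_genome()].
#' @param seed Integer seed.
#' @param n_per_group Replicates per group (default 3).
#' @param mu Median baseline mean count (default 100).
#' @param dispersion NB dispersion phi (default 0.1).
#' @return A list with, per contrast (`aging`, `iis`): `peak_counts`,
#'   `gene_counts` (count tibbles) and `groups` (sample-to-group vector,
#'   groups `"a"` = reference, `"b"` = aged / reduced-IIS).
#' @export
simulate_counts <- function(sim, seed = 1, n_per_group = 3, mu = 100,
                            dispersion = 0.1) {
  withr::with_seed(seed + 1000L, {
    out <- purrr::map(c(aging = "aging", iis = "iis"), function(ctr) {
      lfc_peak <- sim$truth[[paste0(ctr, "_lfc")]]
      lfc_gene <- sim$gene_truth[[paste0(ctr, "_lfc")]]
      base_peak <- rlnorm(nrow(sim$truth), log(mu), 0.4)
      base_gene <- rlnorm(nrow(sim$gene_truth), log(mu), 0.4)
      pc <- nb_counts(base_peak, lfc_peak, n_per_group, n_per_group, dispersion,
                      ctr)
      gc <- nb_counts(base_gene, lfc_gene, n_per_group, n_per_group,
                      dispersion, ctr)
      groups <- setNames(rep(c("a", "b"), each = n_per_group), colnames(pc))
      list(peak_counts = bind_cols(tibble(feature_id = sim$truth$id),
                                   as_tibble(pc)),
           gene_counts = bind_cols(tibble(feature_id = sim$gene_truth$gene_id),
                                   as_tibble(gc)),
           groups = groups)
    })
    out
  })
}

#' Simulate lifespan tables with target medians
#'
#' Weibull event times with shape `shape` (steep, worm-like mortality),
#' scaled so each group's true median equals its target; a fraction
#' `censor_rate` of individuals is censored at a uniform time before their
#' death.
#'
#' @param seed Integer seed.
#' @param medians Named vector of target median lifespans in days. The
#'   defaults emulate a control, a long-lived reduced-IIS group (doubled
#'   median), and a knockdown that halves the reduced-IIS median.
#' @param n_per_group Animals per group (default 150).
#' @param shape Weibull shape parameter (default 4).
#' @param censor_rate Fraction of censored individuals (default 0.05).
#' @return A tibble with `time`, `event`, `group`.
#' @export
simulate_lifespans <- function(seed = 1,
                               medians = c(control = 17, daf2 = 34,
                                           daf2_lin39i = 17),
                               n_per_group = 150, shape = 4,
                               censor_rate = 0.05) {
  stopifnot(all(medians > 0), censor_rate >= 0, censor_rate < 1)
  withr::with_seed(seed + 2000L, {
    purrr::imap_dfr(medians, function(m, g) {
      scale <- m / log(2)^(1 / shape)
      t <- stats::rweibull(n_per_group, shape = shape, scale = scale)
      cens <- runif(n_per_group) < censor_rate
      time <- ifelse(cens, runif(n_per_group, 0, t), t)
      tibble(time = time, event = as.integer(!cens), group = g)
    })
  })
}

#' Write a simulated dataset to a run directory in standard formats
#'
#' GFF3 gene models, BED peaks and states, FASTA region sequences, a Homer
#' motif file, TSV count tables, a lifespan CSV, and JSON truth tables.
#'
#' @param sim Output of [simulate_genome()].
#' @param counts Output of [simulate_counts()].
#' @param lifespans Output of [simulate_lifespans()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, counts, lifespans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_gff3_genes(sim$genes, fp("genes.gff3"))
  write_bed(sim$peaks, fp("peaks.bed"))
  write_bed(tibble(chrom = sim$states$chrom, start = sim$states$start,
                   end = sim$states$end, id = sim$states$label),
            fp("states.bed"))
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(sim$sequences$seq), sim$sequences$id),
    fp("peak_sequences.fa"))
  write_homer_motifs(sim$motif, fp("motifs.motif"))
  for (ctr in names(counts)) {
    readr::write_tsv(counts[[ctr]]$peak_counts,
                     fp(sprintf("peak_counts_%s.tsv", ctr)))
    readr::write_tsv(counts[[ctr]]$gene_counts,
                     fp(sprintf("gene_counts_%s.tsv", ctr)))
  }
  readr::write_csv(lifespans, fp("lifespans.csv"))
  jsonlite::write_json(list(peaks = sim$truth, genes = sim$gene_truth),
                       fp("truth.json"), dataframe = "rows")
  invisible(dir)
}
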