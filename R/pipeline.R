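#' Random decoy motifs
#'
#' Companion PWMs with random consensus sequences, used as a competitive
#' background in motif-enrichment benchmarks.
#'
#' @param n Number of decoys.
#' @param length Motif length.
#' @param seed Integer seed.
#' @param weight Consensus-base probability.
#' @return A named list of `pwm` objects.
#' @export
decoy_motifs <- function(n = 20, length = 8, seed = 1, weight = 0.94) {
  withr::with_seed(seed + 3000L, {
    pwms <- purrr::map(seq_len(n), function(i) {
      planted_motif(paste(sample(BASES, length, replace = TRUE),
                          collapse = ""),
                    name = sprintf("decoy_%02d", i), weight = weight)
    })
    setNames(pwms, purrr::map_chr(pwms, "name"))
  })
}

#' Run the full synthetic integration pipeline
#'
#' End-to-end driver over the package's stages, on a simulated dataset:
#' simulate genome and counts; call differential peaks and genes per
#' contrast (aging, reduced IIS) with the common-dispersion NB test; join
#' them into trDARs; compute directional cross-condition overlaps genome
#' wide, in distNC and in promoters; chromatin-state enrichment of the
#' reduced-IIS trDARs (with the Polycomb sub-states aggregated); motif
#' enrichment of IIS-opening distNC trDARs against the planted motif plus
#' decoys; and the bootstrap Kaplan-Meier lifespan summary. Each stage can
#' be reproduced individually from the returned inputs.
#'
#' @param seed Integer seed driving every stage.
#' @param out_dir Optional directory; when given, inputs and result tables
#'   are written there (TSV with metadata headers, plus the standard-format
#'   input files).
#' @param n_decoys Decoy motifs scanned alongside the planted one.
#' @param ... Passed to [simulate_genome()].
#' @return A list with `sim`, `counts`, `lifespans` (the inputs) and the
#'   result tables `dars`, `degs`, `trdars`, `overlap` (per scope),
#'   `states`, `motifs`, `survival`, plus `summary` (named scalar list).
#' @export
run_trdar_pipeline <- function(seed = 1, out_dir = NULL, n_decoys = 5, ...) {
  sim <- simulate_genome(seed = seed, ...)
  counts <- simulate_counts(sim, seed = seed)
  lifespans <- simulate_lifespans(seed = seed)

  dars <- purrr::map(counts, function(x) {
    nb_test(x$peak_counts, x$groups, "a", "b",
            direction_labels = c("open", "closed"))
  })
  degs <- purrr::map(counts, function(x) {
    nb_test(x$gene_counts, x$groups, "a", "b")
  })
  trdars <- purrr::imap(dars, function(d, ctr) {
    call_trdars(d, degs[[ctr]], sim$annot, contrast_id = ctr)
  })

  overlap <- purrr::map(
    c(genome = "genome", distNC = "distNC", prom = "prom"),
    function(scope) {
      directional_overlap_all(trdars, sim$peaks,
                              category = if (scope == "genome") NULL
                                         else scope)
    })

  iis_ids <- trdars$iis$id
  background_peaks <- sim$peaks[!sim$peaks$id %in% iis_ids, , drop = FALSE]
  states <- state_enrichment(sim$peaks[sim$peaks$id %in% iis_ids, ,
                                       drop = FALSE],
                             background_peaks, sim$states,
                             set_label = "iis trDARs") |>
    aggregate_states(c("PC repressed 1" = "PC repressed",
                       "PC repressed 2" = "PC repressed"))

  opening <- trdars$iis |>
    filter(.data$acc_direction == "open", .data$is_distnc)
  distnc_bg <- sim$annot$id[sim$annot$is_distnc &
                              !sim$annot$id %in% opening$id]
  seq_by_id <- setNames(sim$sequences$seq, sim$sequences$id)
  motifs <- motif_enrichment(
    tibble(id = opening$id, seq = unname(seq_by_id[opening$id])),
    tibble(id = distnc_bg, seq = unname(seq_by_id[distnc_bg])),
    c(setNames(list(sim$motif), sim$motif$name),
      decoy_motifs(n_decoys, seed = seed)))

  surv <- lifespan_summary(lifespans, control = "daf2", seed = seed)

  summary <- list(
    seed = seed,
    n_trdars_aging = nrow(trdars$aging),
    n_trdars_iis = nrow(trdars$iis),
    distnc_overlap_min_fdr = min(overlap$distNC$fdr),
    prom_overlap_min_fdr = min(overlap$prom$fdr),
    enhancer_state_fdr =
      states$fdr[states$target_label == "enhancer"],
    top_motif = motifs$target_label[which.min(motifs$fdr)],
    knockdown_pct_change =
      surv$pct_change[surv$group == "daf2_lin39i"])

  res <- list(sim = sim, counts = counts, lifespans = lifespans,
              dars = dars, degs = degs, trdars = trdars, overlap = overlap,
              states = states, motifs = motifs, survival = surv,
              summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_simulation(sim, counts, lifespans, file.path(out_dir, "inputs"))
    meta <- list(seed = seed)
    for (ctr in names(dars)) {
      write_result_tsv(as_tibble(dars[[ctr]]),
                       file.path(out_dir, sprintf("dars_%s.tsv", ctr)), meta)
      write_result_tsv(as_tibble(degs[[ctr]]),
                       file.path(out_dir, sprintf("degs_%s.tsv", ctr)), meta)
      write_result_tsv(as_tibble(trdars[[ctr]]),
                       file.path(out_dir, sprintf("trdars_%s.tsv", ctr)),
                       meta)
    }
    for (scope in names(overlap)) {
      write_result_tsv(overlap[[scope]],
                       file.path(out_dir,
                                 sprintf("overlap_%s.tsv", scope)), meta)
    }
    write_result_tsv(as_tibble(states), file.path(out_dir, "states.tsv"),
                     meta)
    write_result_tsv(as_tibble(motifs), file.path(out_dir, "motifs.tsv"),
                     meta)
    write_result_tsv(surv, file.path(out_dir, "survival.tsv"), meta)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
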