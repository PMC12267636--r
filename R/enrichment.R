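#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p computed by summing the hypergeometric probabilities of
#' all tables (with the observed margins) no more probable than the observed
#' one. The odds ratio is the sample odds ratio \eqn{ad/bc} (`Inf` when
#' `b*c == 0` with `a*d > 0`). A zero margin makes the table degenerate:
#' p = 1 and the odds ratio is `NA` with `degenerate = TRUE`.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return A one-row tibble: `odds_ratio`, `p.value`, `degenerate`.
#' @examples
#' fisher_two_sided(5, 0, 0, 5)  # p = 2/252
#' @export
fisher_two_sided <- function(a, b, c, d) {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  p <- fisher_p(a, b, c, d)
  degenerate <- (a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)
  or <- if (degenerate) NA_real_ else (a * d) / (b * c)
  tibble(odds_ratio = or, p.value = p, degenerate = degenerate)
}

# scalar exact two-sided p; degenerate margins give 1
fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (via \code{stats::p.adjust}), aligned to the
#' input order and capped at 1. An empty input returns an empty vector.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

new_enrichment_result <- function(x) {
  structure(x, class = c("enrichment_result", class(x)))
}

#' @exportS3Method generics::tidy
tidy.enrichment_result <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble(n_tests = nrow(x),
         n_significant = sum(x$fdr <= 0.05, na.rm = TRUE),
         min_fdr = suppressWarnings(min(x$fdr, na.rm = TRUE)))
}

#' Dot plot of enrichment results
#'
#' @param object An `enrichment_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(target_label = stats::reorder(.data$target_label, -.data$fdr))
  ggplot(df, aes(x = log2(pmax(.data$odds_ratio, 2^-8)),
                 y = .data$target_label,
                 size = .data$ov_da, colour = -log10(pmax(.data$fdr, 1e-300)))) +
    geom_point() +
    scale_colour_viridis_c(name = "-log10 FDR") +
    labs(x = "log2 odds ratio", y = NULL, size = "overlap") +
    theme_minimal()
}

count_hits <- function(regions, target_tbl) {
  sum(overlaps_any(as_gr(regions), target_tbl))
}

#' Chromatin-state enrichment of a region subset
#'
#' For every state label, counts the subset regions (`ov_da`) and background
#' regions (`ov_nda`) overlapping that state's intervals by at least one
#' base, records the state's interval count (`tot_tgt`), and applies the
#' exact two-sided Fisher test to
#' `[[ov_da, n_da - ov_da], [ov_nda, n_nda - ov_nda]]` with BH correction
#' across states. Regions on chromosomes the state track does not cover
#' simply count as non-overlapping.
#'
#' @param subset Region tibble of the differential subset (e.g. trDARs).
#' @param background Region tibble of the remaining universe (disjoint from
#'   `subset`).
#' @param states Region tibble with a `label` column naming the state of
#'   each interval.
#' @param set_label Label recorded in the output's `set_label` column.
#' @return An `enrichment_result` tibble, one row per state.
#' @export
state_enrichment <- function(subset, background, states,
                             set_label = "subset") {
  subset <- check_regions(subset, "subset")
  background <- check_regions(background, "background")
  states <- check_regions(states, "states")
  if (!"label" %in% names(states)) {
    abort("`states` needs a `label` column with state names.")
  }
  n_da <- nrow(subset); n_nda <- nrow(background)
  if (n_da == 0 || n_nda == 0) abort("subset and background must be non-empty.")
  res <- purrr::map_dfr(unique(states$label), function(st) {
    tgt <- states[states$label == st, , drop = FALSE]
    ov_da <- count_hits(subset, tgt)
    ov_nda <- count_hits(background, tgt)
    ft <- fisher_two_sided(ov_da, n_da - ov_da, ov_nda, n_nda - ov_nda)
    tibble(set_label = set_label, target_label = st,
           ov_da = ov_da, ov_nda = ov_nda, tot_tgt = nrow(tgt),
           n_da = n_da, n_nda = n_nda,
           odds_ratio = ft$odds_ratio, p = ft$p.value)
  })
  res$fdr <- bh_fdr(res$p)
  new_enrichment_result(res)
}

#' Aggregate enrichment records over merged state labels
#'
#' States annotating the same kind of genomic region (e.g. two
#' Polycomb-repressed sub-states) are merged by summing their `ov_da`,
#' `ov_nda` and `tot_tgt` counts; the Fisher test and BH correction are then
#' recomputed on the merged tables. All merged records must share the same
#' subset and background sizes.
#'
#' @param records An `enrichment_result` from [state_enrichment()].
#' @param merge_map Named character vector `state -> merged label`; states
#'   not named keep their own label.
#' @return An `enrichment_result` with one row per merged label.
#' @export
aggregate_states <- function(records, merge_map) {
  unknown <- setdiff(names(merge_map), records$target_label)
  if (length(unknown)) {
    abort(sprintf("merge_map refers to unknown states: %s",
                  paste(unknown, collapse = ", ")))
  }
  df <- as_tibble(records) |>
    mutate(merged = ifelse(.data$target_label %in% names(merge_map),
                           unname(merge_map[.data$target_label]),
                           .data$target_label))
  if (length(unique(df$n_da)) != 1 || length(unique(df$n_nda)) != 1) {
    abort("all records must share the same subset/background sizes.")
  }
  agg <- df |>
    group_by(.data$set_label, target_label = .data$merged,
             .data$n_da, .data$n_nda) |>
    summarise(ov_da = sum(.data$ov_da), ov_nda = sum(.data$ov_nda),
              tot_tgt = sum(.data$tot_tgt), .groups = "drop")
  ft <- purrr::pmap_dfr(
    list(agg$ov_da, agg$n_da - agg$ov_da, agg$ov_nda, agg$n_nda - agg$ov_nda),
    fisher_two_sided)
  agg$odds_ratio <- ft$odds_ratio
  agg$p <- ft$p.value
  agg$fdr <- bh_fdr(agg$p)
  new_enrichment_result(
    agg[, c("set_label", "target_label", "ov_da", "ov_nda", "tot_tgt",
            "n_da", "n_nda", "odds_ratio", "p", "fdr")])
}

#' Gene-set overlap enrichment
#'
#' Tests a query gene list against named target sets (cell-type signatures,
#' age-regulated gene lists, GO-style term collections) with the two-sided
#' Fisher test, background = `universe \ query`, and BH correction across
#' sets. Target sets are intersected with the universe before testing.
#'
#' @param query Character vector of query genes (or a data frame with a
#'   `gene` column), a subset of `universe`.
#' @param target_sets Named list of character gene vectors (e.g. from
#'   [read_gmt()], [celltype_signatures()] or [age_deg_sets()]).
#' @param universe Character vector of all genes evaluated.
#' @param set_label Label recorded in the output's `set_label` column.
#' @return An `enrichment_result` tibble, one row per target set.
#' @export
gene_set_overlap <- function(query, target_sets, universe,
                             set_label = "query") {
  if (is.data.frame(query)) query <- query$gene
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe)) {
    abort("`query` must be a subset of `universe`.")
  }
  if (is.null(names(target_sets)) || any(!nzchar(names(target_sets)))) {
    abort("`target_sets` must be a named list.")
  }
  n_da <- length(query)
  n_nda <- length(universe) - n_da
  res <- purrr::imap_dfr(target_sets, function(genes, nm) {
    tgt <- intersect(unique(genes), universe)
    ov_da <- length(intersect(tgt, query))
    ov_nda <- length(tgt) - ov_da
    ft <- fisher_two_sided(ov_da, n_da - ov_da, ov_nda, n_nda - ov_nda)
    tibble(set_label = set_label, target_label = nm,
           ov_da = ov_da, ov_nda = ov_nda, tot_tgt = length(tgt),
           n_da = n_da, n_nda = n_nda,
           odds_ratio = ft$odds_ratio, p = ft$p.value)
  })
  res$fdr <- bh_fdr(res$p)
  new_enrichment_result(res)
}

#' Cell-type expression signatures
#'
#' Builds one gene set per cell type from an expression table, keeping the
#' genes with strictly more than `min_counts` counts in that cell type
#' (a row at exactly `min_counts` is excluded).
#'
#' @param expr Tibble: `gene` plus one numeric column per cell type.
#' @param min_counts Count threshold (default 100).
#' @return Named list of character gene vectors, one per cell type.
#' @export
celltype_signatures <- function(expr, min_counts = 100) {
  stopifnot(min_counts > 0)
  if (!"gene" %in% names(expr)) abort("`expr` needs a `gene` column.")
  cols <- setdiff(names(expr), "gene")
  setNames(purrr::map(cols, ~expr$gene[expr[[.x]] > min_counts]), cols)
}

#' Age-regulated gene sets from a differential table
#'
#' Splits an age-DE table into up- and downregulated sets: genes with
#' p below `p_threshold` and a fold change above (up) or below (down) the
#' null value — 1 on the linear scale (default), 0 on the log scale. Genes
#' with fold change exactly at the null value are excluded from both sets.
#'
#' @param df Tibble with columns `gene`, `p`, `fc`.
#' @param p_threshold p-value cutoff (default 0.05).
#' @param fc_scale `"linear"` (default) or `"log"`.
#' @param prefix Prefix for the set names (`<prefix>_up`, `<prefix>_down`).
#' @return Named list with the two gene sets.
#' @export
age_deg_sets <- function(df, p_threshold = 0.05,
                         fc_scale = c("linear", "log"), prefix = "age") {
  fc_scale <- match.arg(fc_scale)
  stopifnot(p_threshold > 0)
  null_fc <- if (fc_scale == "linear") 1 else 0
  sig <- df$p < p_threshold
  setNames(
    list(df$gene[sig & df$fc > null_fc], df$gene[sig & df$fc < null_fc]),
    paste0(prefix, c("_up", "_down")))
}
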