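#' Call transcriptionally relevant DARs (trDARs)
#'
#' A trDAR is a differentially accessible region whose closest gene changes
#' expression in the concordant direction: regions that open with an
#' upregulated closest gene, or regions that close with a repressed closest
#' gene. Discordant pairs and DARs whose closest gene is missing from the
#' DEG universe are excluded and tallied in the `"diagnostics"` attribute.
#'
#' Differential tables may come from [nb_test()] or from any external
#' caller, as long as they carry `feature_id`, `log2fc` and `fdr`.
#'
#' @param dars Differential table over region ids.
#' @param degs Differential table over gene ids.
#' @param annot Annotated regions from [classify_regions()] covering every
#'   DAR id.
#' @param contrast_id Label for the comparison (e.g. `"iis"`).
#' @param fdr_threshold Significance cutoff applied to both tables.
#' @return A `trdar_result` tibble: the annotation columns plus
#'   `acc_direction` (`open`/`closed`), `expr_direction` (`up`/`down`) and
#'   `contrast_id`. Attributes: `diagnostics` (exclusion tallies),
#'   `genes_per_direction` (unique proximal genes per direction).
#' @export
call_trdars <- function(dars, degs, annot, contrast_id = "contrast",
                        fdr_threshold = 0.05) {
  for (col in c("feature_id", "log2fc", "fdr")) {
    if (!col %in% names(dars) || !col %in% names(degs)) {
      abort(sprintf("differential tables need a `%s` column.", col))
    }
  }
  missing_annot <- setdiff(dars$feature_id, annot$id)
  if (length(missing_annot)) {
    abort(sprintf("%d DAR id(s) missing from the annotation (e.g. %s).",
                  length(missing_annot), missing_annot[1]))
  }

  sig_dars <- dars |>
    filter(.data$fdr <= fdr_threshold) |>
    mutate(acc_direction = ifelse(.data$log2fc > 0, "open", "closed")) |>
    select("feature_id", "acc_direction")
  deg_dir <- degs |>
    filter(.data$fdr <= fdr_threshold) |>
    mutate(expr_direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    select(gene = "feature_id", "expr_direction")

  joined <- sig_dars |>
    inner_join(annot, by = c(feature_id = "id")) |>
    left_join(deg_dir, by = c(closest_gene = "gene"))

  gene_missing <- !joined$closest_gene %in% degs$feature_id
  concordant <- !is.na(joined$expr_direction) &
    ((joined$acc_direction == "open" & joined$expr_direction == "up") |
     (joined$acc_direction == "closed" & joined$expr_direction == "down"))

  diagnostics <- tibble(
    reason = c("significant DARs", "closest gene not in DEG universe",
               "closest gene not significant", "discordant direction",
               "trDARs"),
    n = c(nrow(joined), sum(gene_missing),
          sum(!gene_missing & is.na(joined$expr_direction)),
          sum(!is.na(joined$expr_direction) & !concordant),
          sum(concordant)))

  out <- joined[concordant, , drop = FALSE] |>
    rename(id = "feature_id") |>
    relocate("chrom", "start", "end", "id") |>
    mutate(contrast_id = contrast_id)
  genes_per_direction <- out |>
    group_by(.data$acc_direction) |>
    summarise(n_genes = n_distinct(.data$closest_gene), .groups = "drop")

  structure(out,
            class = c("trdar_result", class(out)),
            diagnostics = diagnostics,
            genes_per_direction = genes_per_direction)
}

#' @exportS3Method generics::glance
glance.trdar_result <- function(x, ...) {
  tibble(n_trdars = nrow(x),
         n_open_up = sum(x$acc_direction == "open"),
         n_closed_down = sum(x$acc_direction == "closed"),
         n_genes = n_distinct(x$closest_gene),
         n_distnc = sum(x$is_distnc))
}

map_to_universe <- function(regions, universe) {
  if (all(regions$id %in% universe$id)) return(unique(regions$id))
  unique(overlap_regions(regions, universe)$b_id)
}

#' Directional overlap of trDAR sets across two contrasts
#'
#' Tests whether regions changing in one direction in contrast x coincide
#' with regions changing in the opposite direction in contrast y —
#' "x > y" pairs regions open in x with regions closed in y, "x < y" the
#' reverse. Region identity across contrasts uses shared universe ids when
#' available, otherwise a one-or-more-base overlap against the universe.
#' Significance is a two-sided Fisher test on the 2x2 table (in both sets /
#' x only / y only / universe remainder).
#'
#' @param trdars_x,trdars_y `trdar_result` tibbles for the two contrasts.
#' @param relation `"x_gt_y"` (open in x, closed in y) or `"x_lt_y"`.
#' @param universe Region tibble of all consensus regions tested in both
#'   contrasts.
#' @return A one-row tibble: `contrast_x`, `contrast_y`, `relation`,
#'   `n_x`, `n_y`, `n_xy`, `n_universe`, `odds_ratio`, `p`.
#' @export
directional_overlap <- function(trdars_x, trdars_y,
                                relation = c("x_gt_y", "x_lt_y"), universe) {
  relation <- match.arg(relation)
  universe <- check_regions(universe, "universe", require_id = TRUE)
  if (nrow(universe) == 0) abort("`universe` is empty.")
  dir_x <- if (relation == "x_gt_y") "open" else "closed"
  dir_y <- if (relation == "x_gt_y") "closed" else "open"
  x_ids <- map_to_universe(
    trdars_x[trdars_x$acc_direction == dir_x, , drop = FALSE], universe)
  y_ids <- map_to_universe(
    trdars_y[trdars_y$acc_direction == dir_y, , drop = FALSE], universe)
  a <- length(intersect(x_ids, y_ids))
  b <- length(setdiff(x_ids, y_ids))
  cc <- length(setdiff(y_ids, x_ids))
  d <- nrow(universe) - a - b - cc
  ft <- fisher_two_sided(a, b, cc, d)
  tibble(contrast_x = trdars_x$contrast_id[1] %||% "x",
         contrast_y = trdars_y$contrast_id[1] %||% "y",
         relation = relation,
         n_x = length(x_ids), n_y = length(y_ids), n_xy = a,
         n_universe = nrow(universe),
         odds_ratio = ft$odds_ratio, p = ft$p.value)
}

#' All pairwise directional overlaps with FDR correction
#'
#' Runs [directional_overlap()] for every ordered pair of distinct
#' contrasts and both directional relations, optionally within one genomic
#' category (e.g. distNC only), then BH-adjusts across all tests in the
#' run.
#'
#' @param trdars A list of `trdar_result` tibbles (one per contrast) or one
#'   combined tibble with a `contrast_id` column.
#' @param universe Region tibble of the shared consensus universe.
#' @param category Optional filter: keep only trDARs whose `category` is in
#'   this set, or `"distNC"` / `"prom"` / `"3pUTR"` shorthands.
#' @return A tibble with one row per (pair, relation) and an `fdr` column.
#' @export
directional_overlap_all <- function(trdars, universe, category = NULL) {
  if (is.data.frame(trdars)) {
    trdars <- split(as_tibble(trdars), trdars$contrast_id)
  }
  if (!is.null(category)) {
    trdars <- purrr::map(trdars, filter_category, category)
  }
  ids <- names(trdars)
  grid <- tidyr::expand_grid(x = ids, y = ids,
                             relation = c("x_gt_y", "x_lt_y")) |>
    filter(.data$x != .data$y)
  res <- purrr::pmap_dfr(grid, function(x, y, relation) {
    directional_overlap(trdars[[x]], trdars[[y]], relation, universe)
  })
  res$fdr <- bh_fdr(res$p)
  res
}

filter_category <- function(x, category) {
  keep <- switch(category[1],
                 distNC = x$is_distnc,
                 prom = x$is_prom,
                 `3pUTR` = x$is_3putr,
                 x$category %in% category)
  x[keep, , drop = FALSE]
}
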