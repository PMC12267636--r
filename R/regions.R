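#' @title Genomic region tables
#'
#' @description
#' Regions (ATAC peaks, ChIP peaks, chromatin-state segments, blacklist
#' hotspots) are plain tibbles with columns `chrom`, `start`, `end` and,
#' optionally, `id` and `strand`. Coordinates are 0-based half-open
#' (BED-native); GFF3 input is converted on read. Region strand is ignored
#' for classification (ATAC peaks are unstranded) but kept for provenance.
#'
#' @name region-tables
#' @keywords internal
NULL

CATEGORY_LEVELS <- c("Promoter", "5' UTR", "3' UTR", "Exon", "Intron",
                     "Distal Intergenic")

# -- validation ---------------------------------------------------------------

check_regions <- function(x, arg = "regions", require_id = FALSE,
                          allow_dup = FALSE) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of regions.", arg))
  }
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols)) {
    abort(sprintf("`%s` lacks column(s): %s.", arg,
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    abort(sprintf("`%s` has empty chromosome names.", arg))
  }
  if (any(x$start < 0) || any(x$end <= x$start)) {
    abort(sprintf("`%s` must satisfy 0 <= start < end.", arg))
  }
  if (!"id" %in% names(x)) {
    if (require_id) {
      x$id <- sprintf("region_%d", seq_len(nrow(x)))
    }
  } else if (!allow_dup && anyDuplicated(x$id)) {
    abort(sprintf("`%s` has duplicated region ids.", arg))
  }
  x
}

# 0-based half-open tibble -> GRanges (1-based closed)
as_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  if ("id" %in% names(x)) names(gr) <- x$id
  gr
}

# -- gene models --------------------------------------------------------------

#' Validate a gene-model table
#'
#' Gene models are tibbles with one row per gene: `gene_id`, `chrom`,
#' `strand` (`+`/`-`), `start`, `end` (gene span, 0-based half-open) and
#' optional list-columns `exons`, `five_utr`, `three_utr`, each holding a
#' tibble of `start`/`end` intervals inside the span. The transcription
#' start site is the span start on `+` and `end - 1` on `-`.
#'
#' @param genes A gene-model data frame.
#' @return The validated tibble with a `tss` column added.
#' @export
check_genes <- function(genes) {
  if (!is.data.frame(genes) ||
      !all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes))) {
    abort("`genes` needs columns gene_id, chrom, strand, start, end.")
  }
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) abort("`genes` is empty.")
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'.")
  }
  if (anyDuplicated(genes$gene_id)) abort("`genes` has duplicated gene_id.")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

# flatten a list-column of interval tibbles into one region tibble
flatten_feature <- function(genes, col) {
  if (!col %in% names(genes)) return(tibble(chrom = character(),
                                            start = integer(),
                                            end = integer()))
  purrr::map2_dfr(genes[[col]], seq_len(nrow(genes)), function(tbl, i) {
    if (is.null(tbl) || nrow(tbl) == 0) return(NULL)
    tibble(chrom = genes$chrom[i], start = tbl$start, end = tbl$end)
  })
}

promoter_windows <- function(genes, tss_upstream, tss_downstream) {
  # strand-aware window: signed distance s from the TSS lies in
  # [-tss_upstream, tss_downstream); on '-' the window is mirrored.
  start <- ifelse(genes$strand == "+",
                  genes$tss - tss_upstream,
                  genes$tss - tss_downstream + 1L)
  end <- ifelse(genes$strand == "+",
                genes$tss + tss_downstream,
                genes$tss + tss_upstream + 1L)
  tibble(chrom = genes$chrom, start = pmax(0L, as.integer(start)),
         end = as.integer(end))
}

# put two GRanges on the union of their seqlevels so overlap machinery does
# not warn when one set misses a chromosome entirely
share_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

overlaps_any <- function(regions_gr, feature_tbl) {
  if (nrow(feature_tbl) == 0) return(rep(FALSE, length(regions_gr)))
  feature_tbl <- feature_tbl[feature_tbl$end > feature_tbl$start, , drop = FALSE]
  if (nrow(feature_tbl) == 0) return(rep(FALSE, length(regions_gr)))
  grs <- share_seqlevels(regions_gr, as_gr(feature_tbl))
  IRanges::overlapsAny(grs[[1]], grs[[2]], ignore.strand = TRUE)
}

# -- classification -----------------------------------------------------------

#' Classify regions by genomic context and assign the closest gene
#'
#' Assigns each region exactly one genomic category by precedence
#' (Promoter > 5' UTR > 3' UTR > Exon > Intron > Distal Intergenic), where a
#' category applies if the region shares at least one base with any feature
#' of that kind. The promoter window spans `tss_upstream` bases upstream to
#' `tss_downstream` bases downstream of the TSS (default -1500/+500),
#' oriented by gene strand; region strand is ignored. "Intron" means inside
#' a gene span but in none of the higher categories. The closest gene is the
#' gene whose TSS is nearest to the region midpoint; ties go to the
#' lexicographically smallest `gene_id`. `distance_to_tss` is signed and
#' strand-aware (negative upstream of the TSS).
#'
#' Distal non-coding (distNC) status — the enhancer proxy — is category
#' Intron or Distal Intergenic.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`, optional `id`).
#' @param genes Gene-model tibble (see [check_genes()]).
#' @param tss_upstream,tss_downstream Promoter window half-widths in bases.
#' @return A tibble with the region columns plus `category`, `closest_gene`,
#'   `distance_to_tss`, `is_distnc`, `is_prom`, `is_3putr`.
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "I", strand = "+",
#'                         start = 10000L, end = 16000L)
#' peaks <- tibble::tibble(chrom = "I", start = 9000L, end = 9400L, id = "p1")
#' classify_regions(peaks, genes)
#' @export
classify_regions <- function(regions, genes, tss_upstream = 1500,
                             tss_downstream = 500) {
  regions <- check_regions(regions, require_id = TRUE)
  genes <- check_genes(genes)
  stopifnot(tss_upstream >= 0, tss_downstream >= 0)

  gr <- as_gr(regions)
  prom <- promoter_windows(genes, as.integer(tss_upstream),
                           as.integer(tss_downstream))
  span <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end)

  hit <- cbind(
    Promoter = overlaps_any(gr, prom),
    `5' UTR` = overlaps_any(gr, flatten_feature(genes, "five_utr")),
    `3' UTR` = overlaps_any(gr, flatten_feature(genes, "three_utr")),
    Exon = overlaps_any(gr, flatten_feature(genes, "exons")),
    Intron = overlaps_any(gr, span)
  )
  first_hit <- apply(hit, 1L, function(z) {
    i <- which(z)
    if (length(i)) i[1] else 6L
  })
  category <- CATEGORY_LEVELS[first_hit]

  mid <- (regions$start + regions$end) %/% 2L
  closest <- rep(NA_character_, nrow(regions))
  dist_tss <- rep(NA_real_, nrow(regions))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0) next
    gsub <- genes[gi, ]
    d <- abs(outer(mid[ri], gsub$tss, "-"))
    for (k in seq_along(ri)) {
      best <- which(d[k, ] == min(d[k, ]))
      pick <- best[order(gsub$gene_id[best])][1]
      closest[ri[k]] <- gsub$gene_id[pick]
      dist_tss[ri[k]] <- if (gsub$strand[pick] == "+") {
        mid[ri[k]] - gsub$tss[pick]
      } else {
        gsub$tss[pick] - mid[ri[k]]
      }
    }
  }
  orphan <- is.na(closest)
  if (any(orphan)) {
    warn(sprintf(
      "%d region(s) on chromosomes absent from the annotation; labelled 'Distal Intergenic' with no closest gene.",
      sum(orphan)))
    category[orphan] <- "Distal Intergenic"
  }

  regions |>
    mutate(
      category = factor(category, levels = CATEGORY_LEVELS),
      closest_gene = closest,
      distance_to_tss = dist_tss,
      is_distnc = category %in% c("Intron", "Distal Intergenic"),
      is_prom = category == "Promoter",
      is_3putr = category == "3' UTR"
    )
}

# -- interval plumbing --------------------------------------------------------

#' Remove regions overlapping a blacklist
#'
#' Drops every region sharing at least one base with any hotspot interval
#' (zero tolerance), as done against genomic-DNA control hotspots before
#' differential analysis. The number of removed regions is reported via a
#' message.
#'
#' @param peaks Region tibble.
#' @param hotspots Region tibble of blacklist intervals; may be empty.
#' @return The filtered peak tibble.
#' @export
filter_blacklist <- function(peaks, hotspots) {
  peaks <- check_regions(peaks, "peaks")
  if (is.null(hotspots) || nrow(hotspots) == 0) {
    inform("filter_blacklist: empty hotspot set, 0 peaks removed.")
    return(peaks)
  }
  hotspots <- check_regions(hotspots, "hotspots")
  grs <- share_seqlevels(as_gr(peaks), as_gr(hotspots))
  drop <- IRanges::overlapsAny(grs[[1]], grs[[2]], ignore.strand = TRUE)
  inform(sprintf("filter_blacklist: removed %d of %d peaks.",
                 sum(drop), nrow(peaks)))
  peaks[!drop, , drop = FALSE]
}

#' Overlapping pairs between two region sets
#'
#' Reports every pair of regions from `a` and `b` that share at least one
#' base on the same chromosome (half-open coordinates, so `(0,10)` and
#' `(10,20)` do not overlap). The relation is symmetric.
#'
#' @param a,b Region tibbles; ids are generated if absent.
#' @return A tibble with columns `a_id`, `b_id`, one row per overlapping pair.
#' @export
overlap_regions <- function(a, b) {
  a <- check_regions(a, "a", require_id = TRUE)
  b <- check_regions(b, "b", require_id = TRUE)
  grs <- share_seqlevels(as_gr(a), as_gr(b))
  ov <- GenomicRanges::findOverlaps(grs[[1]], grs[[2]], ignore.strand = TRUE)
  tibble(a_id = a$id[S4Vectors::queryHits(ov)],
         b_id = b$id[S4Vectors::subjectHits(ov)])
}
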