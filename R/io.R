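#' Read a BED file into a region tibble
#'
#' BED3/BED4/BED6 are supported; coordinates stay 0-based half-open. The 4th
#' column becomes `id` (for peak files) and is also exposed as `label`,
#' which is how chromatin-state segmentations (4th column = state name)
#' are read.
#'
#' @param path Path to a BED file.
#' @return A region tibble with `chrom`, `start`, `end` and, when present,
#'   `id`, `label`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr_to_regions(gr)
}

#' Read an ENCODE narrowPeak file
#'
#' @param path Path to a narrowPeak file.
#' @return A region tibble with the narrowPeak statistics columns.
#' @export
read_narrowpeak <- function(path) {
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer"))
  gr_to_regions(gr)
}

gr_to_regions <- function(gr) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(mc)) {
    out$id <- as.character(mc$name)
    out$label <- out$id
  }
  if ("score" %in% names(mc)) out$score <- mc$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  for (col in setdiff(names(mc), c("name", "score"))) out[[col]] <- mc[[col]]
  out
}

#' Write a region tibble as BED
#'
#' @param regions Region tibble; `id` (or `label`) becomes the BED name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- check_regions(regions, allow_dup = TRUE)
  gr <- as_gr(regions)
  nm <- regions$id %||% regions$label
  if (!is.null(nm)) S4Vectors::mcols(gr)$name <- nm
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Converts 1-based inclusive GFF3 coordinates to the package's 0-based
#' half-open convention. `gene` features define spans; `exon`,
#' `five_prime_UTR` and `three_prime_UTR` features are attached to the gene
#' named by their `Parent` attribute (the flat gene-parent dialect written
#' by [write_gff3_genes()]).
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble (see [check_genes()]).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) abort("no 'gene' features in GFF3.")
  child_tbl <- function(type, gid) {
    sub <- df[df$type == type & !is.na(df$Parent) & df$Parent == gid, ,
              drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    tibble(start = sub$start - 1L, end = sub$end) |> arrange(.data$start)
  }
  tibble(
    gene_id = as.character(genes$ID),
    chrom = as.character(genes$seqnames),
    strand = as.character(genes$strand),
    start = genes$start - 1L,
    end = genes$end,
    exons = purrr::map(as.character(genes$ID), ~child_tbl("exon", .x)),
    five_utr = purrr::map(as.character(genes$ID),
                          ~child_tbl("five_prime_UTR", .x)),
    three_utr = purrr::map(as.character(genes$ID),
                           ~child_tbl("three_prime_UTR", .x))
  ) |> check_genes()
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  genes <- check_genes(genes)
  rows <- list()
  add <- function(chrom, start0, end, strand, type, id, parent) {
    tibble(chrom = chrom, start = start0 + 1L, end = end, strand = strand,
           type = type, ID = id, Parent = parent)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rows[[length(rows) + 1L]] <-
      add(g$chrom, g$start, g$end, g$strand, "gene", g$gene_id, NA_character_)
    feats <- list(exon = g$exons[[1]], five_prime_UTR = g$five_utr[[1]],
                  three_prime_UTR = g$three_utr[[1]])
    for (type in names(feats)) {
      tbl <- feats[[type]]
      if (is.null(tbl) || nrow(tbl) == 0) next
      rows[[length(rows) + 1L]] <-
        add(g$chrom, tbl$start, tbl$end, g$strand, type,
            sprintf("%s_%s_%d", g$gene_id, type, seq_len(nrow(tbl))),
            g$gene_id)
    }
  }
  df <- bind_rows(rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA, df$Parent)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a feature-by-sample count table
#'
#' Expects a TSV whose first column holds feature ids and remaining columns
#' one sample each; `#`-prefixed lines are metadata and skipped.
#'
#' @param path Path to a TSV count table.
#' @return A tibble with `feature_id` plus one numeric column per sample.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(x)[1] <- "feature_id"
  x
}

#' Read a lifespan event table
#'
#' @param path CSV with columns `time`, `event` (1 = death, 0 = censored),
#'   `group` and optionally `replicate`.
#' @return A tibble.
#' @export
read_survival <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  missing_cols <- setdiff(c("time", "event", "group"), names(x))
  if (length(missing_cols)) {
    abort(sprintf("survival table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x
}

#' Read gene sets in GMT-style TSV
#'
#' Each line: set name, description, then one gene per field, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A named list of character gene vectors; descriptions are kept in
#'   the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- purrr::map(parts, ~unique(.x[-(1:2)]))
  names(sets) <- purrr::map_chr(parts, 1)
  attr(sets, "description") <- setNames(purrr::map_chr(parts, 2), names(sets))
  sets
}

#' Write a result tibble as TSV with a metadata header
#'
#' Metadata (tool version, seed, configuration hash, ...) is written as
#' `# key: value` lines before the table so that every result file is
#' self-describing; [read_result_tsv()] skips them.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param meta Named list of metadata scalars.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, meta = list()) {
  meta <- c(list(tool = paste0("darlinker ",
                               as.character(utils::packageVersion("darlinker"))),
                 written = format(Sys.time(), "%Y-%m-%d")),
            meta)
  header <- sprintf("# %s: %s", names(meta),
                    vapply(meta, function(v) paste(format(v), collapse = ","),
                           character(1)))
  readr::write_lines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
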