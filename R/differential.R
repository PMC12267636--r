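#' @title Differential counts
#' @description
#' Count tables are tibbles whose first column is `feature_id` and whose
#' remaining columns hold non-negative integer counts, one per sample.
#' Group membership is a named character vector (`sample -> group`) or a
#' tibble with `sample` and `group` columns.
#' @name differential-counts
#' @keywords internal
NULL

count_matrix <- function(counts) {
  if (!is.data.frame(counts) || !"feature_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a feature_id column.")
  }
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  if (!is.numeric(m) || any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers.")
  }
  rownames(m) <- counts$feature_id
  storage.mode(m) <- "double"
  m
}

group_vector <- function(groups, samples) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample)
  missing_s <- setdiff(samples, names(groups))
  if (length(missing_s)) {
    abort(sprintf("samples without group assignment: %s",
                  paste(missing_s, collapse = ", ")))
  }
  groups[samples]
}

#' TMM effective size factors
#'
#' Between-sample scaling factors for count libraries: the trimmed mean of
#' M-values (reference = sample whose upper quartile is closest to the mean
#' upper quartile; 30% trim on M, 5% on A; precision-weighted mean of the
#' remaining M-values) multiplied by library size and rescaled to geometric
#' mean 1. Dividing a sample's counts by its `size_factor` puts all samples
#' on a common scale. The TMM step itself is delegated to
#' \code{edgeR::calcNormFactors}.
#'
#' @param counts Count tibble (see [nb_test()]).
#' @return A tibble with `sample`, `lib_size`, `norm_factor` (pure TMM
#'   component) and `size_factor` (effective, geometric mean 1).
#' @examples
#' counts <- tibble::tibble(feature_id = c("f1", "f2"),
#'                          s1 = c(10L, 10L), s2 = c(10L, 10L))
#' tmm_factors(counts)
#' @export
tmm_factors <- function(counts) {
  m <- count_matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("sample(s) with all-zero counts: %s",
                  paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  nf <- edgeR::calcNormFactors(m, method = "TMM")
  eff <- lib * nf
  sf <- eff / exp(mean(log(eff)))
  tibble(sample = colnames(m), lib_size = unname(lib),
         norm_factor = unname(nf), size_factor = unname(sf))
}

#' Negative-binomial Wald test for differential counts
#'
#' Calls differential features (accessible regions or expressed genes)
#' between two groups from an integer count table, with a common dispersion
#' shared by all features — the configuration used for differential
#' accessibility here (no tagwise dispersion). The procedure:
#' TMM (or plain library-size) size factors; counts normalized by them;
#' a single dispersion \eqn{\phi} estimated by method of moments as the
#' median over features of \eqn{\max(0, (s^2 - \bar\mu c_f)/\bar\mu^2)}
#' (pooled within-group variance \eqn{s^2}, overall normalized mean
#' \eqn{\bar\mu}, \eqn{c_f} the mean inverse size factor); a two-sided Wald
#' test on the log2 fold change with a delta-method standard error under
#' \eqn{NB(\mu, \phi)}; Benjamini-Hochberg FDR across tested features.
#'
#' Features with zero counts in every sample are excluded and listed in the
#' `"skipped"` attribute. A half-count is added to each group's total when
#' forming means so fold changes stay finite.
#'
#' @param counts Count tibble: `feature_id` plus one column per sample.
#' @param groups Sample-to-group mapping (named vector or tibble).
#' @param group_a,group_b Labels of the two groups to compare; `log2fc` is
#'   `group_b` over `group_a`.
#' @param fdr_threshold Significance cutoff on the BH-adjusted p (default
#'   0.05).
#' @param normalization `"TMM"` (default) or `"library-size"`.
#' @param direction_labels Length-2 labels for positive / negative calls,
#'   e.g. `c("up", "down")` for genes or `c("open", "closed")` for regions.
#' @return A `da_result` tibble: `feature_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `p`, `fdr`, `direction` (one of the two labels or `"ns"`). Attributes:
#'   `dispersion`, `fdr_threshold`, `skipped`.
#' @export
nb_test <- function(counts, groups, group_a, group_b,
                    fdr_threshold = 0.05,
                    normalization = c("TMM", "library-size"),
                    direction_labels = c("up", "down")) {
  normalization <- match.arg(normalization)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            length(direction_labels) == 2)
  m <- count_matrix(counts)
  grp <- group_vector(groups, colnames(m))
  keep_samples <- grp %in% c(group_a, group_b)
  m <- m[, keep_samples, drop = FALSE]
  grp <- grp[keep_samples]
  n_a <- sum(grp == group_a); n_b <- sum(grp == group_b)
  if (n_a < 2 || n_b < 2) {
    abort("each compared group needs at least 2 samples.")
  }

  skipped <- rownames(m)[rowSums(m) == 0]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) abort("no feature with nonzero counts.")

  sf <- if (normalization == "TMM") {
    f <- tmm_factors(tibble(feature_id = rownames(m), as_tibble(m)))
    setNames(f$size_factor, f$sample)[colnames(m)]
  } else {
    lib <- colSums(m)
    lib / exp(mean(log(lib)))
  }
  y <- sweep(m, 2, sf, "/")

  ia <- grp == group_a; ib <- grp == group_b
  mu_a <- (rowSums(y[, ia, drop = FALSE]) + 0.5) / n_a
  mu_b <- (rowSums(y[, ib, drop = FALSE]) + 0.5) / n_b

  # common dispersion, method of moments on normalized counts
  cf <- mean(1 / sf)
  va <- apply(y[, ia, drop = FALSE], 1, var)
  vb <- apply(y[, ib, drop = FALSE], 1, var)
  df <- n_a + n_b - 2
  # pooled within-group variance, rescaled so its *median* across features
  # is unbiased (a chi-square_df variance has median qchisq(0.5, df)/df of
  # its mean); without this the median-of-moments dispersion is biased low
  s2 <- ((n_a - 1) * va + (n_b - 1) * vb) / df / (qchisq(0.5, df) / df)
  mu <- rowMeans(y)
  phi <- median(pmax(0, (s2 - mu * cf) / mu^2))

  var_mean <- function(mu_g, idx, n_g) {
    (mu_g * sum(1 / sf[idx]) / n_g + phi * mu_g^2) / n_g
  }
  v_log2 <- function(mu_g, idx, n_g) {
    var_mean(mu_g, idx, n_g) / (mu_g * log(2))^2
  }
  log2fc <- log2(mu_b) - log2(mu_a)
  se <- sqrt(v_log2(mu_a, ia, n_a) + v_log2(mu_b, ib, n_b))
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  fdr <- bh_fdr(p)
  direction <- ifelse(fdr <= fdr_threshold,
                      ifelse(log2fc > 0, direction_labels[1],
                             direction_labels[2]),
                      "ns")

  out <- tibble(feature_id = rownames(m),
                mean_a = unname(mu_a), mean_b = unname(mu_b),
                log2fc = unname(log2fc), p = unname(p), fdr = unname(fdr),
                direction = unname(direction))
  structure(out,
            class = c("da_result", class(out)),
            dispersion = phi, fdr_threshold = fdr_threshold,
            direction_labels = direction_labels, skipped = skipped)
}

#' @exportS3Method generics::tidy
tidy.da_result <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.da_result <- function(x, ...) {
  labels <- attr(x, "direction_labels")
  tibble(
    n_features = nrow(x),
    n_skipped = length(attr(x, "skipped")),
    n_significant = sum(x$direction != "ns"),
    n_positive = sum(x$direction == labels[1]),
    n_negative = sum(x$direction == labels[2]),
    dispersion = attr(x, "dispersion"),
    fdr_threshold = attr(x, "fdr_threshold")
  )
}

#' Volcano plot of a differential test
#'
#' @param object A `da_result` from [nb_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.da_result <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$log2fc, y = -log10(pmax(.data$p, 1e-300)),
             colour = .data$direction)) +
    geom_point(alpha = 0.6, size = 0.8) +
    scale_colour_manual(values = setNames(
      c("#d73027", "#4575b4", "grey60"),
      c(attr(object, "direction_labels"), "ns"))) +
    labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    theme_minimal()
}

# -- Wilcoxon rank-sum --------------------------------------------------------

#' Wilcoxon rank-sum test (exact with ties for small samples)
#'
#' Two-sided rank-sum test used for per-cell-type differential expression.
#' Ties receive midranks. For combined sample sizes of at most 25 the exact
#' null distribution of the rank sum is computed by dynamic programming over
#' the (doubled) midrank multiset — equivalent to enumerating all
#' assignments — and the two-sided p is twice the smaller tail (capped at
#' 1). Larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric vectors of per-cell expression values.
#' @return A tibble with `statistic` (rank sum of `a`), `p.value`, `method`.
#' @examples
#' wilcoxon_de(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
wilcoxon_de <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty.")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  if (n <= 25) {
    p <- exact_ranksum_p(r, n1)
    method <- "exact"
  } else {
    e <- n1 * (n + 1) / 2
    ties <- table(r)
    v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (w - e - sign(w - e) * 0.5) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble(statistic = w, p.value = p, method = method)
}

# exact two-sided rank-sum p via DP over the doubled-midrank multiset
exact_ranksum_p <- function(r, n1) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  # counts[k+1, s+1] = number of k-subsets with doubled-rank sum s
  counts <- matrix(0, nrow = n1 + 1, ncol = smax + 1)
  counts[1, 1] <- 1
  for (item in r2) {
    kmax <- n1
    for (k in kmax:1) {
      shifted <- c(rep(0, item), counts[k, seq_len(smax + 1 - item)])
      counts[k + 1, ] <- counts[k + 1, ] + shifted
    }
  }
  dist <- counts[n1 + 1, ]
  total <- sum(dist)
  obs <- sum(r2[seq_len(n1)])
  lower <- sum(dist[seq_len(obs + 1)]) / total
  upper <- sum(dist[(obs + 1):(smax + 1)]) / total
  min(1, 2 * min(lower, upper))
}

#' Gene-wise rank-sum differential expression
#'
#' Applies [wilcoxon_de()] to every row of a per-cell expression table and
#' adjusts p-values with Benjamini-Hochberg; genes at adjusted p < `fdr`
#' are flagged as retained.
#'
#' @param expr Tibble: `feature_id` plus one numeric column per cell.
#' @param groups Cell-to-group mapping (named vector or tibble).
#' @param group_a,group_b The two group labels to compare.
#' @param fdr Retention threshold on the adjusted p (default 0.05).
#' @return A tibble with `feature_id`, `statistic`, `p`, `fdr`, `retained`.
#' @export
wilcoxon_de_all <- function(expr, groups, group_a, group_b, fdr = 0.05) {
  m <- as.matrix(expr[setdiff(names(expr), "feature_id")])
  grp <- group_vector(groups, colnames(m))
  ia <- grp == group_a; ib <- grp == group_b
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    wilcoxon_de(m[i, ia], m[i, ib])[, c("statistic", "p.value")]
  })
  adj <- bh_fdr(res$p.value)
  keep <- adj < fdr
  tibble(feature_id = expr$feature_id, statistic = res$statistic,
         p = res$p.value, fdr = adj, retained = keep)
}
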