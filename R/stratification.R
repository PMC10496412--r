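# Nc-ranked bias stratification, optimal codon identification by pooled
# RSCU difference, stop codon usage, and per-category GC comparisons.

#' Assign high/mid/low bias categories by Nc rank
#'
#' Ranks genes by Nc and takes the `floor(p * N)` genes with the lowest Nc
#' as the high-bias (putatively highly expressed) category and the
#' `floor(p * N)` with the highest Nc as the low-bias category; the rest are
#' mid-bias. Ties at a boundary are broken by ascending gene id, so the
#' partition is a deterministic function of (Nc, p, ids). Genes with
#' undefined Nc are excluded beforehand and reported in the `excluded`
#' attribute.
#'
#' @param metrics A [codon_metrics()] tibble (needs `gene_id`, `nc`).
#' @param p Fraction per extreme category, in (0, 0.5] (the source study
#'   used 5-10% depending on species).
#' @return A tibble `gene_id`, `nc`, `category` (factor high/mid/low), with
#'   attributes `p`, `counts` and `excluded`.
#' @examples
#' m <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), nc = seq(25, 61, length.out = 100))
#' table(assign_bias_categories(m, p = 0.05)$category)
#' @export
assign_bias_categories <- function(metrics, p = 0.05) {
  stopifnot(p > 0, p <= 0.5)
  excluded <- metrics$gene_id[is.na(metrics$nc)]
  d <- metrics[!is.na(metrics$nc), c("gene_id", "nc")]
  n <- nrow(d)
  k <- floor(p * n)
  if (k == 0) stop("category empty: floor(p * N) = 0 with N = ", n)
  d <- d[order(d$nc, d$gene_id), , drop = FALSE]
  category <- rep("mid", n)
  category[seq_len(k)] <- "high"
  category[seq(n - k + 1, n)] <- "low"
  out <- tibble::tibble(
    gene_id = d$gene_id, nc = d$nc,
    category = factor(category, levels = c("high", "mid", "low"))
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  attr(out, "p") <- p
  attr(out, "counts") <- table(out$category)
  attr(out, "excluded") <- excluded
  if (length(unique(d$nc)) == 1) attr(out, "degenerate") <- TRUE
  out
}

#' Identify optimal codons from pooled category counts
#'
#' A codon is optimal when its RSCU in the pooled high-bias category exceeds
#' its RSCU in the pooled low-bias category by more than `delta` (default
#' 0.08, strict inequality). With `strict = TRUE` the codon must additionally
#' have RSCU > 1 in the high category. Codons of families absent from either
#' pool are skipped (RSCU undefined). The modal stop codon of the high pool
#' is reported as the optimal termination codon.
#'
#' @param high_counts,low_counts Pooled codon counts (named vectors from
#'   [pool_counts()] or [count_codons()] tibbles) for the two categories.
#' @param delta RSCU difference threshold (default 0.08).
#' @param strict Additionally require RSCU_high > 1 (default `FALSE`).
#' @return A tibble of class `cub_optimal` with one row per synonymous codon:
#'   `amino_acid`, `codon`, `rscu_high`, `rscu_low`, `delta_rscu`, `optimal`;
#'   attributes `optimal_stop` (modal stop codon(s) of the high pool) and
#'   `skipped` (codons with undefined RSCU in either pool).
#' @export
identify_optimal_codons <- function(high_counts, low_counts, delta = 0.08,
                                    strict = FALSE) {
  rh <- rscu(high_counts)
  rl <- rscu(low_counts)
  out <- tibble::tibble(
    amino_acid = rh$amino_acid,
    codon = rh$codon,
    rscu_high = rh$rscu,
    rscu_low = rl$rscu,
    delta_rscu = rh$rscu - rl$rscu
  )
  out$optimal <- !is.na(out$delta_rscu) & out$delta_rscu > delta
  if (strict) out$optimal <- out$optimal & out$rscu_high > 1
  hv <- as_count_vector(high_counts)[STOP_CODONS]
  modal <- if (sum(hv) > 0) names(hv)[hv == max(hv)] else character()
  attr(out, "optimal_stop") <- modal
  attr(out, "skipped") <- out$codon[is.na(out$delta_rscu)]
  class(out) <- c("cub_optimal", class(out))
  out
}

#' Stop codon usage per bias category
#'
#' Counts TAA/TAG/TGA usage (the recorded terminal stop of each gene) per
#' bias category and reports the modal stop codon; ties report all tied
#' codons as co-modal.
#'
#' @param genes A data frame with `gene_id` and `cds` (pass records; the
#'   terminal codon of each CDS is its stop).
#' @param partition Optional [assign_bias_categories()] tibble; when absent
#'   all genes form one `"all"` category.
#' @return A tibble `category`, `codon`, `n`, `freq`, `modal`.
#' @export
stop_codon_usage <- function(genes, partition = NULL) {
  len <- nchar(genes$cds)
  stop_cod <- toupper(substr(genes$cds, len - 2, len))
  d <- tibble::tibble(gene_id = genes$gene_id, stop = stop_cod)
  d <- d[d$stop %in% STOP_CODONS, , drop = FALSE]
  if (is.null(partition)) {
    d$category <- "all"
  } else {
    d$category <- as.character(partition$category[match(d$gene_id, partition$gene_id)])
    d <- d[!is.na(d$category), , drop = FALSE]
  }
  out <- tidyr::complete(
    dplyr::count(d, .data$category, codon = .data$stop),
    .data$category, codon = STOP_CODONS, fill = list(n = 0L)
  )
  out <- dplyr::group_by(out, .data$category)
  out <- dplyr::mutate(out,
    freq = .data$n / sum(.data$n),
    modal = .data$n == max(.data$n) & .data$n > 0
  )
  dplyr::ungroup(out)
}

#' Compare GC composition across bias categories
#'
#' For each supplied per-gene value (GC3s of the CDS, GC of flanking DNA, GC
#' of concatenated introns, ...), reports per-category mean, SD and n, and
#' Welch two-sample t-tests for the high-vs-mid and mid-vs-low comparisons.
#' A category contributing fewer than two non-missing values to a comparison
#' skips that test (reported with `NA` statistics and `skipped = TRUE`) —
#' intronless genomes are the archetypal case.
#'
#' @param partition An [assign_bias_categories()] tibble.
#' @param values A data frame with `gene_id` and one or more numeric value
#'   columns (e.g. `gc3s`, `flank_gc`, `intron_gc`); `NA`s are dropped per
#'   metric.
#' @return A list with `summary` (metric, category, mean, sd, n) and `tests`
#'   (metric, comparison, t, df, p, skipped).
#' @export
category_gc_comparison <- function(partition, values) {
  vars <- setdiff(names(values), "gene_id")
  d <- dplyr::inner_join(partition[, c("gene_id", "category")], values, by = "gene_id")
  long <- tidyr::pivot_longer(d, dplyr::all_of(vars),
                              names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$category),
    mean = mean(.data$value), sd = stats::sd(.data$value), n = dplyr::n(),
    .groups = "drop"
  )
  pairs <- list(c("high", "mid"), c("mid", "low"))
  tests <- purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(pairs, function(pr) {
      x <- long$value[long$metric == v & long$category == pr[1]]
      y <- long$value[long$metric == v & long$category == pr[2]]
      if (length(x) < 2 || length(y) < 2) {
        return(tibble::tibble(metric = v, comparison = paste(pr, collapse = "_vs_"),
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              skipped = TRUE))
      }
      tt <- stats::t.test(x, y)
      tibble::tibble(metric = v, comparison = paste(pr, collapse = "_vs_"),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, skipped = FALSE)
    })
  })
  list(summary = summary, tests = tests)
}
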