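# Protein-domain versus non-domain codon usage: split each gene's codons by
# domain interval membership, apply the exclusion rules, and compare Fop
# between segments within each bias category.

# merge overlapping/adjacent 0-based half-open intervals
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Convert amino-acid domain coordinates to codon intervals
#'
#' CDD hit tables report domain hits in 1-based closed protein coordinates;
#' codon intervals here are 0-based half-open (amino acid position i maps to
#' codon index i - 1).
#'
#' @param aa_from,aa_to 1-based closed amino-acid positions.
#' @return A tibble `start_codon`, `end_codon` (0-based half-open).
#' @export
cdd_to_codon_intervals <- function(aa_from, aa_to) {
  tibble::tibble(start_codon = aa_from - 1L, end_codon = aa_to)
}

#' Per-gene domain and non-domain Fop
#'
#' Partitions each gene's codons into domain and non-domain segments by
#' membership in the (merged) domain intervals, then computes Fop for each
#' segment. Following the exclusion rules of the source protocol, a gene is
#' excluded when it has no domain annotation, when the domain spans every
#' codon, or when the domain spans every codon except the start and/or stop
#' codon. Intervals extending beyond the gene length are an error naming the
#' gene.
#'
#' @param genes A data frame of pass records with `gene_id` and `cds`.
#' @param domains A data frame with `gene_id`, `start_codon`, `end_codon`
#'   (0-based half-open codon units over the CDS including start and stop
#'   codons).
#' @param optimal An optimal codon set (see [fop()]).
#' @return A tibble `gene_id`, `fop_domain`, `fop_nondomain`, `n_domain`,
#'   `n_nondomain` (synonymous codon counts), `excluded`, `reason`.
#' @export
domain_fop <- function(genes, domains, optimal) {
  opt <- optimal_codon_vector(optimal)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    cds <- toupper(genes$cds[i])
    n_cod <- nchar(cds) / 3
    dom <- domains[domains$gene_id == gid, , drop = FALSE]
    base <- tibble::tibble(gene_id = gid, fop_domain = NA_real_,
                           fop_nondomain = NA_real_, n_domain = NA_real_,
                           n_nondomain = NA_real_, excluded = TRUE,
                           reason = NA_character_)
    if (nrow(dom) == 0) {
      base$reason <- "no_domain_annotation"
      return(base)
    }
    if (any(dom$start_codon < 0) || any(dom$end_codon > n_cod)) {
      stop("domain interval out of bounds for gene ", gid)
    }
    iv <- merge_intervals(dom$start_codon, dom$end_codon)
    in_dom <- rep(FALSE, n_cod)
    for (j in seq_len(nrow(iv))) {
      in_dom[seq(iv[j, "start"] + 1, iv[j, "end"])] <- TRUE
    }
    nondom_idx <- which(!in_dom)
    # excluded: domain covers everything, or everything but start/stop codons
    if (length(nondom_idx) == 0 || all(nondom_idx %in% c(1L, n_cod))) {
      base$reason <- "domain_spans_gene"
      return(base)
    }
    codons <- substring(cds, 3 * (seq_len(n_cod) - 1) + 1, 3 * seq_len(n_cod))
    seg_fop <- function(cod) {
      syn <- cod[cod %in% SYN_CODONS]
      if (length(syn) == 0) return(c(NA_real_, 0))
      c(mean(syn %in% opt), length(syn))
    }
    d <- seg_fop(codons[in_dom])
    nd <- seg_fop(codons[!in_dom])
    tibble::tibble(gene_id = gid, fop_domain = d[1], fop_nondomain = nd[1],
                   n_domain = d[2], n_nondomain = nd[2],
                   excluded = is.na(d[1]) || is.na(nd[1]),
                   reason = ifelse(is.na(d[1]) || is.na(nd[1]),
                                   "no_synonymous_codons", NA_character_))
  })
}

#' Compare domain and non-domain Fop across bias categories
#'
#' Per bias category, reports mean, SD and n of the domain and non-domain
#' Fop over included genes, and a two-tailed paired t-test across genes
#' (each gene contributes its own domain and non-domain value; set
#' `paired = FALSE` for an independent-samples Welch test). Categories with
#' fewer than two included genes skip the test.
#'
#' @param fops A [domain_fop()] tibble.
#' @param partition An [assign_bias_categories()] tibble.
#' @param paired Use a paired t-test (default `TRUE`).
#' @return A list with `summary` (category, segment, mean, sd, n) and
#'   `tests` (category, t, df, p, stars, skipped).
#' @export
domain_fop_comparison <- function(fops, partition, paired = TRUE) {
  d <- dplyr::inner_join(fops[!fops$excluded, , drop = FALSE],
                         partition[, c("gene_id", "category")], by = "gene_id")
  long <- tidyr::pivot_longer(d, c("fop_domain", "fop_nondomain"),
                              names_to = "segment", values_to = "fop")
  long$segment <- sub("fop_", "", long$segment)
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$category, .data$segment),
    mean = mean(.data$fop), sd = stats::sd(.data$fop), n = dplyr::n(),
    .groups = "drop"
  )
  tests <- purrr::map_dfr(levels(partition$category), function(cat) {
    sub <- d[d$category == cat, , drop = FALSE]
    if (nrow(sub) < 2) {
      return(tibble::tibble(category = cat, t = NA_real_, df = NA_real_,
                            p = NA_real_, stars = "", skipped = TRUE))
    }
    diffs <- sub$fop_domain - sub$fop_nondomain
    if (paired && stats::sd(diffs) == 0) {
      # constant differences: t.test is undefined; a zero difference is the
      # no-effect case (p = 1), a constant nonzero one a certain effect
      tt <- list(statistic = c(t = if (all(diffs == 0)) 0 else Inf),
                 parameter = c(df = nrow(sub) - 1),
                 p.value = if (all(diffs == 0)) 1 else 0)
    } else {
      tt <- stats::t.test(sub$fop_domain, sub$fop_nondomain, paired = paired)
    }
    p <- tt$p.value
    tibble::tibble(
      category = cat, t = unname(tt$statistic), df = unname(tt$parameter),
      p = p,
      stars = dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                               p < 0.05 ~ "*", TRUE ~ ""),
      skipped = FALSE
    )
  })
  list(summary = summary, tests = tests)
}
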