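# End-to-end analysis: genome -> filtered records -> metrics -> bias
# partition -> optimal codons -> adaptation indices -> selection strength,
# plus the per-species Table-1-style summary.

#' Run the full codon usage bias pipeline
#'
#' From a genome FASTA and GFF3 annotation: load and splice gene models,
#' apply the CDS filters, compute per-gene metrics, stratify by Nc into
#' high/mid/low bias categories, identify optimal codons from the pooled
#' category RSCU difference, recompute CAI/CBI/Fop against the
#' high-category reference, and estimate translational selection strength.
#' tRNA predictions and domain intervals, when given, add the
#' optimal-vs-major tRNA comparison and the domain/non-domain Fop contrast.
#'
#' @param fasta_path,gff3_path Genome assembly and annotation.
#' @param trna_path Optional tRNAscan-SE tabular output.
#' @param domains_path Optional domain interval TSV (`gene_id`,
#'   `start_codon`, `end_codon` in 0-based half-open codon units).
#' @param p Fraction per extreme bias category (default 0.05).
#' @param delta RSCU difference threshold for optimal codons (default 0.08).
#' @param flank Maximum flank length in bp (default 200).
#' @param min_len Minimum CDS length in bp, exclusive (default 300).
#' @return A list of class `cub_pipeline`: `genome`, `records` (filtered),
#'   `pass` (pass records), `metrics` (with CAI/CBI/Fop), `partition`,
#'   `optimal`, `selection` (a `cub_selstrength`), `neutrality`, `pr2`,
#'   `nc_dev`, `stops`, `gc_comparison`, and when inputs allow `trna`
#'   (majors + optimal_vs_major) and `domain` (fops + comparison).
#' @export
cub_pipeline <- function(fasta_path, gff3_path, trna_path = NULL,
                         domains_path = NULL, p = 0.05, delta = 0.08,
                         flank = 200, min_len = 300) {
  genome <- load_genome(fasta_path, gff3_path, flank = flank)
  records <- filter_cds(genome$genes, min_len = min_len)
  pass <- records[records$filter == "pass", , drop = FALSE]

  metrics <- codon_metrics(pass)
  partition <- assign_bias_categories(metrics, p = p)
  high_ids <- partition$gene_id[partition$category == "high"]
  low_ids <- partition$gene_id[partition$category == "low"]
  high_counts <- pool_counts(pass, high_ids)
  low_counts <- pool_counts(pass, low_ids)
  optimal <- identify_optimal_codons(high_counts, low_counts, delta = delta)
  metrics <- codon_metrics(pass, ref_weights = cai_weights(high_counts),
                           optimal = optimal)

  out <- list(
    genome = genome, records = records, pass = pass, metrics = metrics,
    partition = partition, optimal = optimal,
    selection = selection_strength(high_counts, low_counts, optimal),
    neutrality = neutrality_fit(metrics),
    pr2 = pr2_analysis(metrics),
    nc_dev = nc_deviation(metrics),
    stops = stop_codon_usage(pass, partition),
    gc_comparison = category_gc_comparison(
      partition,
      dplyr::inner_join(metrics[, c("gene_id", "gc3s")],
                        pass[, c("gene_id", "flank_gc", "intron_gc")],
                        by = "gene_id")
    )
  )
  if (!is.null(trna_path)) {
    trnas <- read_trnascan(trna_path)
    majors <- major_trna(trna_copy_numbers(trnas))
    out$trna <- list(genes = trnas, majors = majors,
                     matches = optimal_vs_major(optimal, majors))
  }
  if (!is.null(domains_path)) {
    domains <- utils::read.delim(domains_path, stringsAsFactors = FALSE)
    fops <- domain_fop(pass, domains, optimal)
    out$domain <- list(fops = fops,
                       comparison = domain_fop_comparison(fops, partition))
  }
  class(out) <- "cub_pipeline"
  out
}

#' @export
print.cub_pipeline <- function(x, ...) {
  cat("<cub_pipeline> ", nrow(x$pass), " of ", nrow(x$records),
      " CDSs pass filters; ", sum(x$optimal$optimal), " optimal codons; ",
      "S-hat = ", signif(x$selection$s_hat, 3), "\n", sep = "")
  invisible(x)
}

#' Genome-level codon usage summary
#'
#' The one-row-per-species summary of a pipeline run: filtered CDS count,
#' mean GC, mean/SD of GC3s, GC3 and Nc, mean/SD Fop, S-hat, and the
#' neutrality slope as a percentage.
#'
#' @param pipeline A [cub_pipeline()] result.
#' @param species Optional species label.
#' @return A one-row tibble.
#' @export
species_summary <- function(pipeline, species = NA_character_) {
  m <- pipeline$metrics
  tibble::tibble(
    species = species,
    n_cds = nrow(pipeline$records),
    n_cds_filtered = nrow(pipeline$pass),
    gc = mean(m$gc, na.rm = TRUE),
    gc3s_mean = mean(m$gc3s, na.rm = TRUE),
    gc3s_sd = stats::sd(m$gc3s, na.rm = TRUE),
    gc3_mean = mean(m$gc3, na.rm = TRUE),
    gc3_sd = stats::sd(m$gc3, na.rm = TRUE),
    nc_mean = mean(m$nc, na.rm = TRUE),
    nc_sd = stats::sd(m$nc, na.rm = TRUE),
    fop_mean = mean(m$fop, na.rm = TRUE),
    fop_sd = stats::sd(m$fop, na.rm = TRUE),
    s_hat = pipeline$selection$s_hat,
    neutrality_slope_pct = pipeline$neutrality$slope_pct
  )
}
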