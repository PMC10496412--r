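# Genome input: FASTA + GFF3 -> spliced gene records with introns and
# flanking DNA, plus the seven-rule CDS quality filter.
#
# Coordinates are 0-based half-open internally; GFF3's 1-based closed
# convention is converted at the boundary.

#' Load a genome assembly and gene annotation
#'
#' Reads a FASTA assembly and a GFF3 annotation (gene/mRNA/CDS hierarchy with
#' `ID`/`Parent` attributes), assembles one spliced coding sequence per mRNA
#' (reverse-complemented for minus-strand genes), extracts intron sequences
#' (coding-strand orientation) and 5'/3' flanking DNA, and records gene-level
#' bounds used as neighbor limits for the flanks.
#'
#' Gene models whose CDS intervals fall outside contig bounds, or whose first
#' CDS segment has a phase other than 0, are rejected with a logged reason
#' (attribute `rejected` on the result).
#'
#' @param fasta_path Path to a (multi-)FASTA file.
#' @param gff3_path Path to a GFF3 file.
#' @param flank Maximum flank length in bp on each side (default 200); each
#'   flank is truncated at the contig end and at the nearest neighboring
#'   gene.
#' @return An object of class `cub_genome`: a list with `contigs` (a
#'   `DNAStringSet`), `genes` (a tibble of gene records: `gene_id`,
#'   `transcript_id`, `contig`, `strand`, `cds`, `exons` (list of 0-based
#'   half-open interval matrices), `introns` (list of character vectors),
#'   `intron_gc`, `flank_5`, `flank_3`, `flank_gc`, `pseudo`) and `bounds`
#'   (gene-level intervals).
#' @export
load_genome <- function(fasta_path, gff3_path, flank = 200) {
  stopifnot(file.exists(fasta_path), file.exists(gff3_path))
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(gff3_path, format = "gff3")

  type <- as.character(gff$type)
  is_gene <- type %in% c("gene", "pseudogene")
  is_mrna <- type %in% c("mRNA", "transcript")
  is_cds <- type == "CDS"

  gene_ids <- gff$ID[is_gene]
  gene_pseudo <- type[is_gene] == "pseudogene"
  if (!is.null(gff$pseudo)) {
    gene_pseudo <- gene_pseudo | tolower(as.character(gff$pseudo[is_gene])) %in% "true"
  }
  names(gene_pseudo) <- gene_ids

  bounds <- tibble::tibble(
    gene_id = gene_ids,
    contig = as.character(GenomicRanges::seqnames(gff))[is_gene],
    start = GenomicRanges::start(gff)[is_gene] - 1L,  # 0-based half-open
    end = GenomicRanges::end(gff)[is_gene],
    strand = as.character(GenomicRanges::strand(gff))[is_gene]
  )

  mrna_id <- gff$ID[is_mrna]
  mrna_parent <- vapply(gff$Parent[is_mrna], function(p) p[1] %||% NA_character_, "")
  names(mrna_parent) <- mrna_id

  cds_parent <- vapply(gff$Parent[is_cds], function(p) p[1] %||% NA_character_, "")
  cds_tbl <- tibble::tibble(
    transcript_id = cds_parent,
    contig = as.character(GenomicRanges::seqnames(gff))[is_cds],
    start = GenomicRanges::start(gff)[is_cds] - 1L,
    end = GenomicRanges::end(gff)[is_cds],
    strand = as.character(GenomicRanges::strand(gff))[is_cds],
    phase = as.integer(as.character(gff$phase[is_cds]))
  )

  rejected <- character()
  recs <- lapply(split(cds_tbl, cds_tbl$transcript_id), function(tx) {
    tid <- tx$transcript_id[1]
    ctg <- tx$contig[1]
    strand <- tx$strand[1]
    if (!ctg %in% names(contigs)) {
      rejected[[length(rejected) + 1]] <<- paste0(tid, ": unknown contig ", ctg)
      return(NULL)
    }
    clen <- length(contigs[[ctg]])
    if (any(tx$start < 0) || any(tx$end > clen)) {
      rejected[[length(rejected) + 1]] <<- paste0(tid, ": CDS interval outside contig bounds")
      return(NULL)
    }
    tx <- tx[order(tx$start), , drop = FALSE]
    # first segment in coding orientation: leftmost on +, rightmost on -
    first_phase <- if (strand == "-") tx$phase[nrow(tx)] else tx$phase[1]
    if (!is.na(first_phase) && first_phase != 0L) {
      rejected[[length(rejected) + 1]] <<- paste0(tid, ": nonzero phase on first CDS segment")
      return(NULL)
    }
    seq <- as.character(contigs[[ctg]])
    exon_seqs <- substring(seq, tx$start + 1L, tx$end)
    intron_seqs <- if (nrow(tx) > 1) {
      substring(seq, tx$end[-nrow(tx)] + 1L, tx$start[-1])
    } else {
      character()
    }
    if (strand == "-") {
      exon_seqs <- rev(revcomp(exon_seqs))
      intron_seqs <- if (length(intron_seqs)) rev(revcomp(intron_seqs)) else character()
    }
    list(
      transcript_id = tid, contig = ctg, strand = strand,
      cds = paste(exon_seqs, collapse = ""),
      exons = cbind(start = tx$start, end = tx$end),
      introns = intron_seqs
    )
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]

  tids <- unname(vapply(recs, `[[`, "", "transcript_id"))
  genes <- tibble::tibble(
    transcript_id = tids,
    gene_id = unname(mrna_parent[tids]),
    contig = unname(vapply(recs, `[[`, "", "contig")),
    strand = unname(vapply(recs, `[[`, "", "strand")),
    cds = unname(vapply(recs, `[[`, "", "cds")),
    exons = unname(lapply(recs, `[[`, "exons")),
    introns = unname(lapply(recs, `[[`, "introns"))
  )
  # mRNAs without a parent gene feature stand for themselves
  genes$gene_id[is.na(genes$gene_id)] <- genes$transcript_id[is.na(genes$gene_id)]
  genes$pseudo <- unname(gene_pseudo[genes$gene_id])
  genes$pseudo[is.na(genes$pseudo)] <- FALSE
  genes$intron_gc <- unname(vapply(genes$introns, function(x) gc_fraction(concat_introns(x)), 1))

  obj <- structure(
    list(contigs = contigs, genes = genes, bounds = bounds, rejected = rejected),
    class = "cub_genome"
  )
  obj$genes <- extract_flanks(obj, flank = flank)
  obj
}

#' @export
print.cub_genome <- function(x, ...) {
  cat("<cub_genome> ", length(x$contigs), " contigs, ",
      nrow(x$genes), " gene records",
      if (length(x$rejected)) paste0(" (", length(x$rejected), " rejected)"),
      "\n", sep = "")
  invisible(x)
}

gc_fraction <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_real_)
  b <- strsplit(toupper(x), "")[[1]]
  mean(b %in% c("G", "C"))
}

#' Concatenate the introns of a gene
#'
#' @param introns Character vector of intron sequences (coding-strand order).
#' @return A single concatenated string, or `NA` for an intronless gene
#'   (such genes are excluded from intron GC statistics).
#' @export
concat_introns <- function(introns) {
  if (length(introns) == 0) return(NA_character_)
  paste(introns, collapse = "")
}

#' Extract flanking DNA for every gene record
#'
#' Each flank is `min(flank, distance to contig end, distance to the nearest
#' neighboring gene)` bp of genomic sequence adjacent to the gene span,
#' reported in coding-strand orientation (the 5' flank precedes the start
#' codon). A gene abutting its neighbor gets an empty flank. `flank_gc` is
#' the GC fraction of both flanks concatenated.
#'
#' @param genome A `cub_genome` object from [load_genome()].
#' @param flank Maximum flank length in bp (default 200).
#' @return The `genes` tibble with `flank_5`, `flank_3`, `flank_gc` columns.
#' @export
extract_flanks <- function(genome, flank = 200) {
  genes <- genome$genes
  bounds <- genome$bounds
  # span of each record: min/max of its CDS exons; prefer gene-level bounds
  span_start <- vapply(genes$exons, function(e) min(e[, "start"]), 1)
  span_end <- vapply(genes$exons, function(e) max(e[, "end"]), 1)
  bidx <- match(genes$gene_id, bounds$gene_id)
  span_start <- ifelse(!is.na(bidx), bounds$start[bidx], span_start)
  span_end <- ifelse(!is.na(bidx), bounds$end[bidx], span_end)

  # neighbor-aware gap on each genomic side, per contig
  left_flank <- character(nrow(genes))
  right_flank <- character(nrow(genes))
  all_sp <- tibble::tibble(contig = genes$contig, start = span_start, end = span_end)
  # include bounds of annotated genes with no surviving record as neighbors
  nb <- dplyr::bind_rows(all_sp, bounds[, c("contig", "start", "end")])
  for (i in seq_len(nrow(genes))) {
    ctg <- genes$contig[i]
    clen <- length(genome$contigs[[ctg]])
    others <- nb[nb$contig == ctg &
                   !(nb$start == span_start[i] & nb$end == span_end[i]), , drop = FALSE]
    left_bound <- max(c(0, others$end[others$end <= span_start[i]]))
    right_bound <- min(c(clen, others$start[others$start >= span_end[i]]))
    l_len <- min(flank, span_start[i] - left_bound)
    r_len <- min(flank, right_bound - span_end[i])
    seq <- as.character(genome$contigs[[ctg]])
    left_flank[i] <- if (l_len > 0) substr(seq, span_start[i] - l_len + 1, span_start[i]) else ""
    right_flank[i] <- if (r_len > 0) substr(seq, span_end[i] + 1, span_end[i] + r_len) else ""
  }
  flank_5 <- ifelse(genes$strand == "-",
                    ifelse(nzchar(right_flank), revcomp(right_flank), ""),
                    left_flank)
  flank_3 <- ifelse(genes$strand == "-",
                    ifelse(nzchar(left_flank), revcomp(left_flank), ""),
                    right_flank)
  genes$flank_5 <- unname(flank_5)
  genes$flank_3 <- unname(flank_3)
  both <- paste0(flank_5, flank_3)
  genes$flank_gc <- vapply(both, function(x) if (nzchar(x)) gc_fraction(x) else NA_real_, 1,
                           USE.NAMES = FALSE)
  genes
}

FILTER_RULES <- c("not_multiple_of_3", "bad_start", "bad_stop", "internal_stop",
                  "too_short", "not_longest", "pseudogene", "ambiguous_base")

#' Apply the seven CDS quality filters
#'
#' A record passes when: (1) its length is a multiple of three; (2) it starts
#' with ATG and ends with TAA/TAG/TGA; (3) it has no internal stop codon;
#' (4) its length exceeds `min_len` (300 bp); (5) it is the longest
#' transcript of its gene (ties broken by lexicographically smallest
#' transcript id); (6) its gene is not flagged pseudogene; and (7) it
#' contains no ambiguity (non-ACGT) characters, the sequence-intrinsic proxy
#' for poor sequencing quality. The first failed rule, in that order, is
#' recorded.
#'
#' @param records A gene-record tibble (needs `gene_id`, `transcript_id`,
#'   `cds`; `pseudo` optional), e.g. `load_genome(...)$genes`.
#' @param min_len Minimum CDS length in bp, exclusive (default 300).
#' @return The input tibble with a `filter` column (`"pass"` or the first
#'   failed rule) and attribute `tally`, a tibble of per-rule rejection
#'   counts.
#' @examples
#' recs <- tibble::tibble(gene_id = "g1", transcript_id = "t1",
#'                        cds = paste0("ATG", strrep("GCTGAA", 51), "TAA"))
#' filter_cds(recs)$filter
#' @export
filter_cds <- function(records, min_len = 300) {
  n <- nrow(records)
  if (n == 0) {
    records$filter <- character()
    attr(records, "tally") <- tibble::tibble(rule = FILTER_RULES, n = 0L)
    return(records)
  }
  cds <- toupper(records$cds)
  len <- nchar(cds)
  pseudo <- records$pseudo %||% rep(FALSE, n)
  pseudo[is.na(pseudo)] <- FALSE

  mult3 <- len %% 3 == 0
  starts <- substr(cds, 1, 3) == "ATG"
  last <- ifelse(mult3 & len >= 3, substr(cds, len - 2, len), "")
  stops <- last %in% STOP_CODONS
  internal <- vapply(seq_len(n), function(i) {
    if (!mult3[i] || len[i] < 6) return(FALSE)
    cod <- substring(cds[i], seq(1, len[i] - 3, 3), seq(3, len[i] - 3, 3) + 0)
    any(cod %in% STOP_CODONS)
  }, TRUE)
  long_enough <- len > min_len
  # longest transcript per gene, ties to the smallest transcript id
  ord <- order(records$gene_id, -len, records$transcript_id)
  keep_tx <- rep(FALSE, n)
  keep_tx[ord[!duplicated(records$gene_id[ord])]] <- TRUE
  clean <- !grepl("[^ACGT]", cds)

  filter <- rep("pass", n)
  filter[!clean] <- "ambiguous_base"
  filter[pseudo] <- "pseudogene"
  filter[!keep_tx] <- "not_longest"
  filter[!long_enough] <- "too_short"
  filter[internal] <- "internal_stop"
  filter[!stops] <- "bad_stop"
  filter[!starts] <- "bad_start"
  filter[!mult3] <- "not_multiple_of_3"

  records$filter <- filter
  tally <- tibble::tibble(
    rule = FILTER_RULES,
    n = vapply(FILTER_RULES, function(r) sum(filter == r), 1L)
  )
  attr(records, "tally") <- tally
  records
}

#' Rejection tally of a filtered record set
#'
#' @param records A tibble returned by [filter_cds()].
#' @return A tibble with columns `rule` and `n`.
#' @export
filter_tally <- function(records) {
  attr(records, "tally") %||%
    dplyr::count(records[records$filter != "pass", ], .data$filter, name = "n")
}
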