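# Independent oracles and fixture builders, written from first principles
# and kept free of the package's internal code paths.

GCT <- genetic_code_table()
SYN59 <- GCT$codon[!GCT$is_stop & GCT$degeneracy > 1]
ONE_PER_AA <- GCT$codon[!GCT$is_stop][!duplicated(GCT$amino_acid[!GCT$is_stop])]

make_cds <- function(codons, start = TRUE, stop = "TAA") {
  paste(c(if (start) "ATG", codons, stop), collapse = "")
}

zero_counts <- function() stats::setNames(numeric(64), GCT$codon)

# Wright's Nc by direct summation, independent of the package implementation
oracle_nc <- function(counts) {
  aa_of <- stats::setNames(GCT$amino_acid, GCT$codon)
  fams <- split(SYN59, aa_of[SYN59])
  f_vals <- list()
  for (aa in names(fams)) {
    n <- 0
    for (cod in fams[[aa]]) n <- n + counts[[cod]]
    if (n < 2) {
      f_vals[[aa]] <- NA_real_
      next
    }
    s <- 0
    for (cod in fams[[aa]]) s <- s + (counts[[cod]] / n)^2
    f_vals[[aa]] <- (n * s - 1) / (n - 1)
  }
  deg <- vapply(fams, length, 1L)
  cls_mean <- function(k) {
    v <- unlist(f_vals[names(deg)[deg == k]])
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  f2 <- cls_mean(2); f3 <- cls_mean(3); f4 <- cls_mean(4); f6 <- cls_mean(6)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (any(is.na(c(f2, f3, f4, f6))) || any(c(f2, f3, f4, f6) <= 0)) {
    return(NA_real_)
  }
  min(2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6, 61)
}

random_count_table <- function() {
  counts <- zero_counts()
  counts[SYN59] <- stats::rpois(length(SYN59), lambda = stats::runif(1, 1, 12))
  counts
}

# independent wobble classifier: literal restatement of the pairing rules
oracle_match_class <- function(codon, anticodon) {
  rc1 <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  if (codon == rc1(anticodon)) return("watson_crick")
  stem <- substr(codon, 1, 2) == substr(rc1(anticodon), 1, 2)
  a34 <- substr(anticodon, 1, 1)
  c3 <- substr(codon, 3, 3)
  if (stem && a34 == "G" && c3 == "T") return("gu_wobble")
  if (stem && a34 == "A" && c3 %in% c("C", "A")) return("inosine")
  "none"
}

# minimal FASTA / GFF3 writers for hand-built toy genomes
write_toy_fasta <- function(contigs, path) {
  writeLines(unlist(lapply(names(contigs), function(n) {
    c(paste0(">", n), contigs[[n]])
  })), path)
  path
}

# feature rows: list(contig, type, start, end, strand, id, parent, phase)
write_toy_gff <- function(rows, path) {
  lines <- vapply(rows, function(r) {
    attrs <- paste0("ID=", r$id,
                    if (!is.null(r$parent)) paste0(";Parent=", r$parent) else "")
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            r$contig, r$type, r$start, r$end, r$strand,
            if (is.null(r$phase)) "." else as.character(r$phase), attrs)
  }, "")
  writeLines(c("##gff-version 3", lines), path)
  path
}

# gene/mRNA/CDS triple for a single-exon or multi-exon gene (1-based closed)
toy_gene_rows <- function(contig, exons, strand, gid) {
  tid <- paste0(gid, ".t")
  rows <- list(
    list(contig = contig, type = "gene", start = min(exons[, 1]),
         end = max(exons[, 2]), strand = strand, id = gid, parent = NULL),
    list(contig = contig, type = "mRNA", start = min(exons[, 1]),
         end = max(exons[, 2]), strand = strand, id = tid, parent = gid)
  )
  for (i in seq_len(nrow(exons))) {
    rows[[length(rows) + 1]] <- list(
      contig = contig, type = "CDS", start = exons[i, 1], end = exons[i, 2],
      strand = strand, id = paste0("cds-", tid), parent = tid, phase = 0
    )
  }
  rows
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(b)
    paste(rev(b), collapse = ""), ""))
}
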