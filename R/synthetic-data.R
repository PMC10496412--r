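# Synthetic genome generator with known ground truth: coding sequences with
# a per-gene mutational GC parameter and an expression-linked selection
# gradient toward a designated optimal codon set, assembled into FASTA +
# GFF3 contigs with introns, intergenic spacers, tRNA gene predictions and
# protein-domain tables, so every pipeline stage runs offline.
#
# Codon model, per gene:
#   stage 1 (mutation): codons drawn i.i.d. over the 61 sense codons with
#     weight prod(base weights), base weight gc/2 for G/C and (1-gc)/2 for
#     A/T under the gene's mutational GC parameter — amino-acid composition
#     and backbone GC respond to mutation pressure together;
#   selection: each codon of a degenerate family is replaced by the family's
#     designated optimal codon with probability equal to the gene's
#     selection intensity;
#   stage 2 (silent sites): third positions of unselected codons are redrawn
#     within the codon's synonymous box (same first two bases, same amino
#     acid) with a GC target chosen so the gene's expected GC3 equals its
#     realized GC12 — under zero intensity the neutrality (GC12 ~ GC3)
#     relationship has unit slope by construction.

DEFAULT_OPTIMAL <- c(
  F = "TTC", Y = "TAC", H = "CAC", Q = "CAG", N = "AAC", K = "AAG",
  D = "GAC", E = "GAG", C = "TGC", I = "ATC", V = "GTG", P = "CCG",
  T = "ACG", A = "GCG", G = "GGC", L = "CTG", S = "TCG", R = "CGC"
)

default_trna_complement <- function(optimal = DEFAULT_OPTIMAL) {
  # two-fold families: Watson-Crick anticodon of the optimal codon (3
  # copies) plus one minor copy of the alternative; 3-6-fold families: an
  # A34 anticodon reading the C-ending optimal codon via inosine, except
  # Gly/Val kept Watson-Crick (the mixed profile seen in multicellular
  # genomes)
  rows <- purrr::map_dfr(names(optimal), function(aa) {
    fam <- SYN_CODONS[CODON_AA[SYN_CODONS] == aa]
    opt <- optimal[[aa]]
    wc <- revcomp(opt)
    if (length(fam) == 2) {
      minor <- revcomp(setdiff(fam, opt))
      tibble::tibble(aa = aa, anticodon = c(wc, minor), copies = c(3L, 1L))
    } else if (aa %in% c("G", "V")) {
      tibble::tibble(aa = aa, anticodon = wc, copies = 3L)
    } else {
      # A34: reads the C-ending codon of the box through inosine
      a34 <- paste0("A", substr(wc, 2, 3))
      tibble::tibble(aa = aa, anticodon = c(a34, wc), copies = c(3L, 1L))
    }
  })
  rows$amino_acid <- unname(AA_ONE_TO_THREE[rows$aa])
  rows
}

#' Specification for a synthetic genome
#'
#' Collects every parameter of the generator; the seed fixes all randomness,
#' so identical specs give byte-identical outputs. Defaults emulate the
#' statistical structure of red-algal nuclear genomes: per-gene mutational
#' GC3 spanning 0.30-0.85, small high/low expression classes (7% each, the
#' middle of the 5-10% percentile range used for Nc stratification), a
#' moderate selection gradient toward a G/C-ending optimal codon set,
#' introns and flanks whose GC tracks the gene's coding GC, and a tRNA
#' complement mixing Watson-Crick and A34 (inosine) anticodons.
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_genes Number of genes.
#' @param length_mean,length_shape Gamma parameters for gene length in sense
#'   codons (minimum 110, so every gene exceeds the 300 bp filter).
#' @param mut_gc_range Range of the per-gene mutational GC parameter.
#' @param class_fractions Named fractions (high/mid/low) of expression
#'   classes; must sum to 1.
#' @param intensities Named selection intensities in \[0, 1\] per class
#'   (probability that a codon is replaced by its family's optimal codon).
#' @param optimal_codons Designated optimal set: named character vector,
#'   amino acid (one-letter) to codon.
#' @param stop_probs Named sampling probabilities for TAA/TAG/TGA.
#' @param intron_lambda Poisson mean number of introns per gene.
#' @param intron_len_range,intergenic_len_range Length ranges (bp).
#' @param intron_gc_track Weight of the gene's coding GC (versus the
#'   intergenic base GC) in intron and flank GC targets.
#' @param intergenic_gc Base GC of intergenic DNA.
#' @param genes_per_contig Genes per contig.
#' @param minus_strand_prob Probability a gene is on the minus strand.
#' @param trna Data frame `amino_acid` (three-letter), `anticodon`, `copies`
#'   describing the tRNA complement.
#' @param include_sec Emit a selenocysteine tRNA row (anticodon TCA).
#' @param domain_fraction Fraction of genes given a domain interval.
#' @return A list of class `cub_synth_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 500L,
                           length_mean = 400,
                           length_shape = 6,
                           mut_gc_range = c(0.30, 0.85),
                           class_fractions = c(high = 0.07, mid = 0.86, low = 0.07),
                           intensities = c(high = 0.45, mid = 0.15, low = 0),
                           optimal_codons = DEFAULT_OPTIMAL,
                           stop_probs = c(TAA = 0.6, TAG = 0.2, TGA = 0.2),
                           intron_lambda = 1.5,
                           intron_len_range = c(60, 300),
                           intergenic_len_range = c(250, 1200),
                           intron_gc_track = 0.8,
                           intergenic_gc = 0.45,
                           genes_per_contig = 25L,
                           minus_strand_prob = 0.5,
                           trna = NULL,
                           include_sec = TRUE,
                           domain_fraction = 0.7) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8, all(intensities >= 0),
            all(intensities <= 1), all(names(optimal_codons) %in% DEGENERATE_AA),
            all(optimal_codons %in% SYN_CODONS),
            all(CODON_AA[optimal_codons] == names(optimal_codons)))
  if (is.null(trna)) trna <- default_trna_complement(optimal_codons)
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         length_mean = length_mean, length_shape = length_shape,
         mut_gc_range = mut_gc_range, class_fractions = class_fractions,
         intensities = intensities, optimal_codons = optimal_codons,
         stop_probs = stop_probs, intron_lambda = intron_lambda,
         intron_len_range = intron_len_range,
         intergenic_len_range = intergenic_len_range,
         intron_gc_track = intron_gc_track, intergenic_gc = intergenic_gc,
         genes_per_contig = as.integer(genes_per_contig),
         minus_strand_prob = minus_strand_prob, trna = trna,
         include_sec = include_sec, domain_fraction = domain_fraction),
    class = "cub_synth_spec"
  )
}

random_seq <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# stage 1 weights over the 61 sense codons for a mutational GC parameter
mutational_codon_weights <- function(gc) {
  w <- (gc / 2)^CODON_GC_COUNT[SENSE_CODONS] *
    ((1 - gc) / 2)^(3 - CODON_GC_COUNT[SENSE_CODONS])
  w / sum(w)
}

# third bases available in each synonymous box, keyed by box id
BOX_THIRDS <- split(substr(SYN_CODONS, 3, 3), CODON_BOX[SYN_CODONS])

# redraw third positions within boxes with P(G or C third) = t
redraw_thirds <- function(codons, t) {
  boxes <- CODON_BOX[codons]
  redraw <- boxes %in% names(BOX_THIRDS)
  if (!any(redraw)) return(codons)
  idx <- which(redraw)
  thirds <- character(length(idx))
  for (b in unique(boxes[idx])) {
    avail <- BOX_THIRDS[[b]]
    gcv <- avail %in% c("G", "C")
    pr <- ifelse(gcv, t / sum(gcv), (1 - t) / sum(!gcv))
    sel <- idx[boxes[idx] == b]
    thirds[match(sel, idx)] <- sample(avail, length(sel), replace = TRUE, prob = pr)
  }
  codons[idx] <- paste0(substr(codons[idx], 1, 2), thirds)
  codons
}

sim_cds_impl <- function(spec) {
  n <- spec$n_genes
  classes <- sample(names(spec$class_fractions), n, replace = TRUE,
                    prob = spec$class_fractions)
  intensity <- unname(spec$intensities[classes])
  mut_gc <- stats::runif(n, spec$mut_gc_range[1], spec$mut_gc_range[2])
  len <- pmax(110L, as.integer(round(stats::rgamma(
    n, shape = spec$length_shape, scale = spec$length_mean / spec$length_shape))))
  opt <- spec$optimal_codons
  stops <- sample(names(spec$stop_probs), n, replace = TRUE, prob = spec$stop_probs)

  cds <- character(n)
  for (i in seq_len(n)) {
    w <- mutational_codon_weights(mut_gc[i])
    codons <- sample(SENSE_CODONS, len[i] - 1L, replace = TRUE, prob = w)
    # selection: replace degenerate-family codons by their optimal codon
    aa <- CODON_AA[codons]
    sel <- stats::runif(len[i] - 1L) < intensity[i] & aa %in% names(opt)
    codons[sel] <- unname(opt[aa[sel]])
    codons <- c("ATG", codons)
    # mutational silent-site target: expected GC3 of the unselected codons
    # (free thirds plus the boxless Met/Trp/start thirds) equals the
    # realized GC12; selected codons keep their optimal third on top, so
    # selection raises GC3 above the mutational expectation
    gc12 <- mean(c(CODON_GC_POS[[1]], CODON_GC_POS[[2]])[
      rep(match(codons, CODONS), 2) + rep(c(0, 64), each = len[i])])
    unsel <- !c(TRUE, sel)
    unsel[1] <- TRUE  # the start codon is unselected but boxless
    free <- unsel & CODON_BOX[codons] %in% names(BOX_THIRDS)
    boxless <- unsel & !free
    gc3_boxless <- sum(substr(codons[boxless], 3, 3) %in% c("G", "C"))
    t <- (gc12 * (sum(free) + sum(boxless)) - gc3_boxless) / max(sum(free), 1)
    t <- min(max(t, 0.02), 0.98)
    codons[free] <- redraw_thirds(codons[free], t)
    cds[i] <- paste(c(codons, stops[i]), collapse = "")
  }
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    class = classes, intensity = intensity, mut_gc = mut_gc,
    length_codons = len, cds = cds
  )
}

#' Simulate coding sequences with known ground truth
#'
#' Runs the codon-level simulator of [synthetic_spec()] without genome
#' assembly: every gene gets a mutational GC parameter, an expression class
#' with its selection intensity, and a CDS (ATG start, sampled stop) that
#' passes all CDS filters by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble `gene_id`, `class`, `intensity`, `mut_gc`,
#'   `length_codons` (sense codons), `cds`.
#' @export
simulate_cds <- function(spec) {
  withr::with_seed(spec$seed, sim_cds_impl(spec))
}

# ---- genome assembly -------------------------------------------------------

# genomic exon layout for a gene block of coding-orientation pieces
exon_coords <- function(exon_lens, intron_lens, offset, strand) {
  k <- length(exon_lens)
  piece_lens <- numeric(2 * k - 1)
  piece_lens[seq(1, 2 * k - 1, 2)] <- exon_lens
  if (k > 1) piece_lens[seq(2, 2 * k - 2, 2)] <- intron_lens
  prefix <- c(0, cumsum(piece_lens))[seq(1, 2 * k - 1, 2)]
  g <- sum(piece_lens)
  if (strand == "+") {
    start <- offset + prefix
  } else {
    start <- offset + g - prefix - exon_lens
  }
  phase <- (3 - (cumsum(c(0, exon_lens))[seq_len(k)] %% 3)) %% 3
  cbind(start = start, end = start + exon_lens, phase = phase)
}

#' Generate a synthetic genome on disk
#'
#' Simulates coding sequences ([simulate_cds()]), splits each CDS with
#' introns whose GC tracks the gene's coding GC, assembles multi-gene
#' contigs with intergenic spacers (minus-strand genes are
#' reverse-complemented in place), and writes the genome FASTA, a
#' gene/mRNA/CDS GFF3, a tRNAscan-SE-format tRNA prediction file placed in
#' intergenic space, a protein-domain interval table, and the ground-truth
#' table. All outputs are deterministic functions of the spec.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the output `paths` (fasta, gff3, trna,
#'   domains, truth), the `truth` tibble and the `spec`.
#' @export
generate_genome <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    trna = file.path(dir, "trnascan.out"),
    domains = file.path(dir, "domains.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  res <- withr::with_seed(spec$seed, {
    sim <- sim_cds_impl(spec)
    n <- nrow(sim)
    strands <- ifelse(stats::runif(n) < spec$minus_strand_prob, "-", "+")
    n_introns <- stats::rpois(n, spec$intron_lambda)

    contig_of <- ceiling(seq_len(n) / spec$genes_per_contig)
    contigs <- character(max(contig_of))
    gff <- character()
    spacer_iv <- list()  # free intergenic intervals per contig for tRNAs

    for (ci in seq_len(max(contig_of))) {
      gidx <- which(contig_of == ci)
      cname <- sprintf("ctg%03d", ci)
      pos <- 0L
      seqs <- character()
      for (i in gidx) {
        sp_len <- as.integer(round(stats::runif(1, spec$intergenic_len_range[1],
                                                spec$intergenic_len_range[2])))
        spacer <- random_seq(sp_len, spec$intergenic_gc)
        spacer_iv[[length(spacer_iv) + 1]] <- c(ci, pos, pos + sp_len)
        seqs <- c(seqs, spacer)
        pos <- pos + sp_len

        cds <- sim$cds[i]
        cds_len <- nchar(cds)
        k <- n_introns[i] + 1L
        cut_sites <- if (k > 1) {
          sort(sample(seq(3, cds_len - 3, 3), k - 1L))
        } else integer()
        exon_lens <- diff(c(0L, cut_sites, cds_len))
        coding_gc <- gc_fraction(cds)
        intron_gc <- spec$intron_gc_track * coding_gc +
          (1 - spec$intron_gc_track) * spec$intergenic_gc
        intron_lens <- if (k > 1) as.integer(round(stats::runif(
          k - 1L, spec$intron_len_range[1], spec$intron_len_range[2]))) else integer()
        introns <- vapply(intron_lens, random_seq, "", gc = intron_gc)

        pieces <- character(2 * k - 1)
        pieces[seq(1, 2 * k - 1, 2)] <-
          substring(cds, c(0L, cut_sites) + 1L, c(cut_sites, cds_len))
        if (k > 1) pieces[seq(2, 2 * k - 2, 2)] <- introns
        block <- paste(pieces, collapse = "")
        if (strands[i] == "-") block <- revcomp(block)
        ec <- exon_coords(exon_lens, intron_lens, pos, strands[i])

        gid <- sim$gene_id[i]
        tid <- paste0(gid, ".t1")
        g_start <- pos + 1L
        g_end <- pos + nchar(block)
        gff <- c(gff,
          sprintf("%s\tcubkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s", cname,
                  g_start, g_end, strands[i], gid),
          sprintf("%s\tcubkit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                  cname, g_start, g_end, strands[i], tid, gid),
          sprintf("%s\tcubkit\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
                  cname, ec[, "start"] + 1, ec[, "end"], strands[i],
                  ec[, "phase"], tid, tid)
        )
        seqs <- c(seqs, block)
        pos <- pos + nchar(block)
      }
      tail_len <- as.integer(round(stats::runif(1, spec$intergenic_len_range[1],
                                                spec$intergenic_len_range[2])))
      spacer_iv[[length(spacer_iv) + 1]] <- c(ci, pos, pos + tail_len)
      seqs <- c(seqs, random_seq(tail_len, spec$intergenic_gc))
      contigs[ci] <- paste(seqs, collapse = "")
    }

    trna_rows <- place_trnas(spec, spacer_iv)

    # domain intervals (codon units over the CDS incl. start and stop)
    has_dom <- stats::runif(n) < spec$domain_fraction
    n_cod <- nchar(sim$cds) / 3
    dom_span <- pmax(5L, as.integer(round(n_cod * stats::runif(n, 0.2, 0.6))))
    dom_start <- 1L + as.integer(floor(stats::runif(n) *
                                         pmax(1, n_cod - dom_span - 1L)))
    domains <- tibble::tibble(
      gene_id = sim$gene_id[has_dom],
      start_codon = dom_start[has_dom],
      end_codon = pmin(dom_start[has_dom] + dom_span[has_dom],
                       as.integer(n_cod[has_dom]) - 1L),
      domain_accession = sprintf("SYNTH%04d", seq_len(sum(has_dom)))
    )

    truth <- dplyr::mutate(sim[, c("gene_id", "class", "intensity", "mut_gc",
                                   "length_codons")],
                           contig = sprintf("ctg%03d", contig_of),
                           strand = strands, n_introns = n_introns)
    list(contigs = contigs, gff = gff, trna_rows = trna_rows,
         domains = domains, truth = truth)
  })

  ctg <- Biostrings::DNAStringSet(res$contigs)
  names(ctg) <- sprintf("ctg%03d", seq_along(res$contigs))
  Biostrings::writeXStringSet(ctg, paths$fasta, width = 70)
  writeLines(c("##gff-version 3", res$gff), paths$gff3)
  write_trnascan(res$trna_rows, paths$trna)
  utils::write.table(res$domains, paths$domains, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, truth = res$truth, spec = spec))
}

# expand the tRNA complement into placed rows within intergenic intervals
place_trnas <- function(spec, spacer_iv) {
  comp <- spec$trna
  rows <- comp[rep(seq_len(nrow(comp)), comp$copies), , drop = FALSE]
  if (spec$include_sec) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      aa = NA_character_, anticodon = "TCA", copies = 1L, amino_acid = "SeC"))
  }
  n <- nrow(rows)
  if (n == 0) return(tibble::tibble())
  # 100-bp non-overlapping slots carved out of the intergenic intervals
  slots <- purrr::map_dfr(spacer_iv, function(x) {
    k <- floor((x[3] - x[2] - 20) / 100)
    if (k < 1) return(NULL)
    tibble::tibble(contig = x[1], start = x[2] + 10 + 100 * (seq_len(k) - 1))
  })
  if (nrow(slots) < n) {
    stop("more tRNAs (", n, ") than available intergenic space (",
         nrow(slots), " slots)")
  }
  slots <- slots[seq_len(n), , drop = FALSE]
  tibble::tibble(
    contig = sprintf("ctg%03d", slots$contig),
    trna_no = seq_len(n),
    begin = as.integer(slots$start + 1),
    end = as.integer(slots$start + 72),
    amino_acid = rows$amino_acid,
    anticodon = rows$anticodon,
    score = round(stats::runif(n, 40, 90), 1)
  )
}

write_trnascan <- function(rows, path) {
  header <- c(
    "Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tInf\t",
    "Name\ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\tNote",
    "--------\t------\t-----\t----\t----\t-----\t-----\t----\t------\t----"
  )
  body <- if (nrow(rows) == 0) character() else sprintf(
    "%s\t%d\t%d\t%d\t%s\t%s\t0\t0\t%.1f\t",
    rows$contig, rows$trna_no, rows$begin, rows$end, rows$amino_acid,
    rows$anticodon, rows$score
  )
  writeLines(c(header, body), path)
}

#' Write a tRNAscan-SE-format file for a spec's tRNA complement
#'
#' Emits syntactically valid tRNAscan-SE 2.x tabular output with the
#' requested per-anticodon copy numbers at non-overlapping synthetic
#' coordinates (no genome required; [generate_genome()] places the same
#' complement in real intergenic space).
#'
#' @param spec A [synthetic_spec()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
generate_trna_file <- function(spec, path) {
  rows <- withr::with_seed(spec$seed, {
    virtual <- lapply(seq_len(sum(spec$trna$copies) + 2), function(i) {
      c(1, (i - 1) * 200, i * 200)
    })
    place_trnas(spec, virtual)
  })
  write_trnascan(rows, path)
  invisible(path)
}
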