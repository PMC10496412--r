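cds303 <- make_cds(rep(c("GCT", "GAA", "TGC", "AAG"), 25), stop = "TAA")
stopifnot(nchar(cds303) == 306)

test_that("single-exon genes are extracted identically on both strands", {
  dir <- withr::local_tempdir()
  spacer <- strrep("T", 50)
  contig <- paste0(spacer, cds303, spacer)
  fa <- write_toy_fasta(list(c1 = contig), file.path(dir, "g.fa"))
  gff <- write_toy_gff(
    toy_gene_rows("c1", cbind(51, 50 + nchar(cds303)), "+", "gf"),
    file.path(dir, "g.gff3")
  )
  gen <- load_genome(fa, gff)
  expect_equal(unname(gen$genes$cds), cds303)

  # same interval on the minus strand: CDS is the reverse complement
  contig2 <- paste0(spacer, oracle_revcomp(cds303), spacer)
  fa2 <- write_toy_fasta(list(c1 = contig2), file.path(dir, "g2.fa"))
  gff2 <- write_toy_gff(
    toy_gene_rows("c1", cbind(51, 50 + nchar(cds303)), "-", "gr"),
    file.path(dir, "g2.gff3")
  )
  gen2 <- load_genome(fa2, gff2)
  expect_equal(unname(gen2$genes$cds), cds303)
})

test_that("two-exon genes are spliced and the intron is recorded", {
  dir <- withr::local_tempdir()
  exon1 <- substr(cds303, 1, 150)
  exon2 <- substr(cds303, 151, nchar(cds303))
  intron <- strrep("GT", 25)  # 50 bp
  contig <- paste0(strrep("A", 30), exon1, intron, exon2, strrep("A", 30))
  fa <- write_toy_fasta(list(c1 = contig), file.path(dir, "g.fa"))
  e1 <- c(31, 30 + 150)
  e2 <- c(30 + 150 + 50 + 1, 30 + 150 + 50 + nchar(exon2))
  gff <- write_toy_gff(toy_gene_rows("c1", rbind(e1, e2), "+", "g1"),
                       file.path(dir, "g.gff3"))
  gen <- load_genome(fa, gff)
  expect_equal(unname(gen$genes$cds), cds303)
  expect_equal(gen$genes$introns[[1]], intron)
  expect_equal(nchar(gen$genes$introns[[1]]), 50)
})

test_that("the seven filters reject one rule each and tally correctly", {
  good <- cds303
  recs <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g5", "g6", "g7"),
    transcript_id = c("t1", "t2", "t3", "t4", "t5a", "t5b", "t6", "t7"),
    cds = c(
      paste0(good, "AC"),                                   # not multiple of 3
      paste0("CTG", substr(good, 4, nchar(good))),          # bad start
      paste0(substr(good, 1, nchar(good) - 3), "GGG"),      # bad stop
      paste0("ATGTAA", substr(good, 4, nchar(good))),       # internal stop
      good,                                                 # longest isoform
      paste0(substr(good, 1, 300), "TAA"),                  # shorter isoform (303 bp, clean)
      make_cds(rep("GCT", 33)),                             # 102 bp: too short
      good                                                  # clean survivor is g5/t5a and g7
    ),
    pseudo = FALSE
  )
  recs$cds[recs$transcript_id == "t7"] <-
    paste0("ATG", "GNT", substr(good, 7, nchar(good)))      # ambiguous base
  out <- filter_cds(recs)
  # one clean survivor; every other record fails exactly one rule
  expect_equal(sum(out$filter == "pass"), 1)
  expect_equal(out$transcript_id[out$filter == "pass"], "t5a")
  tal <- filter_tally(out)
  expect_equal(sum(tal$n), 7)
  expect_equal(sum(tal$n) + sum(out$filter == "pass"), nrow(recs))
  expect_setequal(tal$rule[tal$n > 0],
                  c("not_multiple_of_3", "bad_start", "bad_stop",
                    "internal_stop", "too_short", "not_longest",
                    "ambiguous_base"))
})

test_that("length and internal-stop rules match the protocol", {
  # 299 bp sequence is rejected (fails before any start/stop logic)
  recs <- tibble::tibble(gene_id = "g", transcript_id = "t",
                         cds = substr(strrep("A", 299), 1, 299), pseudo = FALSE)
  expect_false(filter_cds(recs)$filter == "pass")

  # in-frame internal TAA is rejected
  recs <- tibble::tibble(
    gene_id = "g", transcript_id = "t",
    cds = paste0("ATG", "TAA", strrep("AAA", 100), "TAA"), pseudo = FALSE
  )
  expect_equal(filter_cds(recs)$filter, "internal_stop")

  # 306 bp clean CDS passes (length strictly greater than 300)
  recs <- tibble::tibble(gene_id = "g", transcript_id = "t", cds = cds303,
                         pseudo = FALSE)
  expect_equal(filter_cds(recs)$filter, "pass")
  # 300 bp exactly does not
  cds300 <- make_cds(rep(c("GCT", "GAA"), 49), stop = "TAA")
  stopifnot(nchar(cds300) == 300)
  recs$cds <- cds300
  expect_equal(filter_cds(recs)$filter, "too_short")

  # pseudogenes are removed
  recs <- tibble::tibble(gene_id = "g", transcript_id = "t", cds = cds303,
                         pseudo = TRUE)
  expect_equal(filter_cds(recs)$filter, "pseudogene")

  # empty input gives empty output with zero tallies
  out <- filter_cds(tibble::tibble(gene_id = character(),
                                   transcript_id = character(),
                                   cds = character(), pseudo = logical()))
  expect_equal(nrow(out), 0)
  expect_equal(sum(filter_tally(out)$n), 0)
})

test_that("flanks are clipped by contig ends and neighboring genes", {
  dir <- withr::local_tempdir()
  # gene A starts 50 bp into the contig; gene B sits 120 bp downstream of A;
  # both have >=200 bp clearance elsewhere
  gA <- cds303
  gB <- cds303
  part1 <- strrep("C", 50)
  gap <- strrep("A", 120)
  tail_sp <- strrep("G", 400)
  contig <- paste0(part1, gA, gap, gB, tail_sp)
  fa <- write_toy_fasta(list(c1 = contig), file.path(dir, "g.fa"))
  rows <- c(
    toy_gene_rows("c1", cbind(51, 50 + nchar(gA)), "+", "gA"),
    toy_gene_rows("c1", cbind(50 + nchar(gA) + 121,
                              50 + nchar(gA) + 120 + nchar(gB)), "+", "gB")
  )
  gff <- write_toy_gff(rows, file.path(dir, "g.gff3"))
  gen <- load_genome(fa, gff)
  recs <- gen$genes[order(gen$genes$gene_id), ]
  # gene A: 5' flank clipped to 50 by the contig start, 3' to 120 by gene B
  expect_equal(nchar(recs$flank_5[1]), 50)
  expect_equal(nchar(recs$flank_3[1]), 120)
  # gene B: 5' flank is the 120 bp gap, 3' flank the full 200
  expect_equal(nchar(recs$flank_5[2]), 120)
  expect_equal(nchar(recs$flank_3[2]), 200)
  expect_equal(recs$flank_5[1], part1)
  expect_equal(recs$flank_3[1], gap)
})

test_that("abutting genes get empty flanks", {
  dir <- withr::local_tempdir()
  contig <- paste0(strrep("C", 300), cds303, cds303, strrep("C", 300))
  fa <- write_toy_fasta(list(c1 = contig), file.path(dir, "g.fa"))
  s1 <- 301
  rows <- c(
    toy_gene_rows("c1", cbind(s1, s1 + nchar(cds303) - 1), "+", "gA"),
    toy_gene_rows("c1", cbind(s1 + nchar(cds303),
                              s1 + 2 * nchar(cds303) - 1), "+", "gB")
  )
  gff <- write_toy_gff(rows, file.path(dir, "g.gff3"))
  gen <- load_genome(fa, gff)
  recs <- gen$genes[order(gen$genes$gene_id), ]
  expect_equal(nchar(recs$flank_3[1]), 0)
  expect_equal(nchar(recs$flank_5[2]), 0)
})

test_that("intron concatenation and GC follow the protocol", {
  expect_equal(concat_introns(c(strrep("A", 40), strrep("T", 60))),
               paste0(strrep("A", 40), strrep("T", 60)))
  expect_equal(nchar(concat_introns(c(strrep("A", 40), strrep("T", 60)))), 100)
  expect_true(is.na(concat_introns(character())))
  # an all-GC intron gives downstream GC of exactly 1
  dir <- withr::local_tempdir()
  exon1 <- substr(cds303, 1, 150)
  exon2 <- substr(cds303, 151, nchar(cds303))
  intron <- strrep("GC", 15)
  contig <- paste0(strrep("A", 30), exon1, intron, exon2, strrep("A", 30))
  fa <- write_toy_fasta(list(c1 = contig), file.path(dir, "g.fa"))
  gff <- write_toy_gff(
    toy_gene_rows("c1", rbind(c(31, 180), c(211, 210 + nchar(exon2))), "+", "g1"),
    file.path(dir, "g.gff3"))
  gen <- load_genome(fa, gff)
  expect_equal(gen$genes$intron_gc, 1)
})

test_that("CDS intervals outside contig bounds reject the gene model", {
  dir <- withr::local_tempdir()
  fa <- write_toy_fasta(list(c1 = strrep("A", 100)), file.path(dir, "g.fa"))
  gff <- write_toy_gff(toy_gene_rows("c1", cbind(51, 400), "+", "bad"),
                       file.path(dir, "g.gff3"))
  gen <- load_genome(fa, gff)
  expect_equal(nrow(gen$genes), 0)
  expect_match(gen$rejected[[1]], "outside contig bounds")
})

test_that("pass records round-trip through FASTA byte-identically", {
  dir <- withr::local_tempdir()
  g <- generate_genome(synthetic_spec(seed = 3, n_genes = 25,
                                      genes_per_contig = 25), dir)
  gen <- load_genome(g$paths$fasta, g$paths$gff3)
  recs <- filter_cds(gen$genes)
  pass <- recs[recs$filter == "pass", ]
  out_fa <- file.path(dir, "pass.fa")
  seqs <- Biostrings::DNAStringSet(stats::setNames(pass$cds, pass$gene_id))
  Biostrings::writeXStringSet(seqs, out_fa, width = 60)
  back <- Biostrings::readDNAStringSet(out_fa)
  expect_equal(as.character(back), stats::setNames(pass$cds, pass$gene_id))
})

test_that("reverse-complementing the genome with a mirrored annotation is a no-op", {
  dir <- withr::local_tempdir()
  g <- generate_genome(synthetic_spec(seed = 4, n_genes = 20,
                                      genes_per_contig = 10), dir)
  gen <- load_genome(g$paths$fasta, g$paths$gff3)

  # mirror: revcomp every contig, flip coordinates and strands
  contigs <- Biostrings::readDNAStringSet(g$paths$fasta)
  lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  rc <- Biostrings::reverseComplement(contigs)
  fa2 <- file.path(dir, "rc.fa")
  Biostrings::writeXStringSet(rc, fa2, width = 70)
  lines <- readLines(g$paths$gff3)
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t")
  body2 <- vapply(f, function(x) {
    L <- lens[[x[1]]]
    s <- as.integer(x[4]); e <- as.integer(x[5])
    x[4] <- as.character(L - e + 1L)
    x[5] <- as.character(L - s + 1L)
    x[7] <- if (x[7] == "+") "-" else "+"
    paste(x, collapse = "\t")
  }, "")
  gff2 <- file.path(dir, "rc.gff3")
  writeLines(c("##gff-version 3", body2), gff2)

  gen2 <- load_genome(fa2, gff2)
  m <- match(gen$genes$gene_id, gen2$genes$gene_id)
  expect_false(anyNA(m))
  expect_equal(unname(gen2$genes$cds[m]), unname(gen$genes$cds))
  expect_equal(gen2$genes$flank_5[m], gen$genes$flank_5)
  expect_equal(gen2$genes$flank_3[m], gen$genes$flank_3)
  m1 <- codon_metrics(gen$genes[gen$genes$gene_id %in% gen2$genes$gene_id, ])
  m2 <- codon_metrics(gen2$genes[m, ])
  expect_equal(m2$nc, m1$nc)
  expect_equal(m2$gc3s, m1$gc3s)
})
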