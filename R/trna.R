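# tRNA gene predictions: tRNAscan-SE tabular parsing, major tRNA calling,
# and codon/anticodon match classification (Watson-Crick, G:U wobble,
# inosine at position 34).
#
# Anticodons are stored 5'->3' in the DNA alphabet as tRNAscan-SE emits
# them; the wobble base (tRNA position 34) is the FIRST character of the
# anticodon, pairing with the codon's third base.

#' Parse tRNAscan-SE tabular output
#'
#' Reads the whitespace-delimited tabular output of tRNAscan-SE 2.x (three
#' header lines, then columns: sequence name, tRNA number, begin, end,
#' isotype, anticodon, intron begin, intron end, score, optional note).
#' Pseudo-tRNAs (isotype `Pseudo` or a note containing `pseudo`) and
#' undetermined isotypes are flagged; selenocysteine (`SeC`) genes are
#' retained and flagged. Malformed rows are skipped with their line numbers
#' recorded in the `skipped_lines` attribute.
#'
#' @param path Path to a tRNAscan-SE tabular output file.
#' @return A tibble `contig`, `trna_no`, `begin`, `end`, `amino_acid`
#'   (three-letter isotype as printed), `aa` (one-letter, `NA` for
#'   SeC/Und/pseudo), `anticodon`, `score`, `pseudo`, `sec`, `undetermined`.
#' @export
read_trnascan <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  # header: two title lines plus the dashed separator
  body_start <- grep("^-+\\s", lines)[1]
  body <- if (is.na(body_start)) lines[-seq_len(min(3, length(lines)))] else
    lines[-seq_len(body_start)]
  body <- body[nzchar(trimws(body))]
  skipped <- integer()
  rows <- purrr::map_dfr(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.numeric(f[9])))) {
      skipped <<- c(skipped, i)
      return(NULL)
    }
    tibble::tibble(
      contig = f[1], trna_no = as.integer(f[2]),
      begin = as.integer(f[3]), end = as.integer(f[4]),
      amino_acid = f[5], anticodon = toupper(f[6]),
      score = as.numeric(f[9]),
      note = if (length(f) >= 10) paste(f[-(1:9)], collapse = " ") else ""
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(contig = character(), trna_no = integer(),
                           begin = integer(), end = integer(),
                           amino_acid = character(), anticodon = character(),
                           score = numeric(), note = character())
  }
  rows$pseudo <- grepl("pseudo", rows$amino_acid, ignore.case = TRUE) |
    grepl("pseudo", rows$note, ignore.case = TRUE)
  rows$sec <- grepl("^SeC", rows$amino_acid)
  rows$undetermined <- grepl("^Und", rows$amino_acid)
  rows$aa <- unname(AA_THREE_TO_ONE[rows$amino_acid])
  rows$aa[rows$sec | rows$undetermined] <- NA_character_
  attr(rows, "skipped_lines") <- skipped
  rows
}

#' Per-anticodon tRNA gene copy numbers
#'
#' Tallies tRNA gene copies by amino acid and anticodon. Pseudo-tRNAs,
#' undetermined isotypes and selenocysteine genes are excluded from the
#' standard 18/20 amino-acid tallies by default (SeC rows are available via
#' the `sec` attribute).
#'
#' @param trnas A [read_trnascan()] tibble.
#' @param include_pseudo Count pseudo-tRNAs too (default `FALSE`).
#' @return A tibble `aa`, `anticodon`, `copies`; attribute `sec` holds the
#'   selenocysteine rows.
#' @export
trna_copy_numbers <- function(trnas, include_pseudo = FALSE) {
  keep <- !trnas$sec & !trnas$undetermined & !is.na(trnas$aa)
  if (!include_pseudo) keep <- keep & !trnas$pseudo
  out <- dplyr::count(trnas[keep, , drop = FALSE], .data$aa, .data$anticodon,
                      name = "copies")
  attr(out, "sec") <- trnas[trnas$sec, , drop = FALSE]
  out
}

#' Major tRNA genes per amino acid
#'
#' The major tRNA gene of an amino acid is its most abundant anticodon by
#' genomic copy number; ties are all reported as co-major (`tie = TRUE`).
#' Amino acids with no tRNA gene are simply absent.
#'
#' @param copy_numbers A [trna_copy_numbers()] tibble.
#' @return A tibble `aa`, `anticodon`, `copies`, `tie`.
#' @export
major_trna <- function(copy_numbers) {
  out <- dplyr::filter(
    dplyr::group_by(copy_numbers, .data$aa),
    .data$copies == max(.data$copies)
  )
  out <- dplyr::mutate(out, tie = dplyr::n() > 1)
  dplyr::ungroup(out)
}

#' Classify a codon/anticodon pairing
#'
#' Anticodons are 5'->3'; the codon pairs antiparallel, so codon position 1
#' pairs anticodon position 3 and the codon's third (wobble) position pairs
#' the anticodon's first base (tRNA position 34). Classes:
#' `watson_crick` when the codon equals the reverse complement of the
#' anticodon; `gu_wobble` when positions 1-2 are Watson-Crick and a G at the
#' anticodon wobble site reads a U(T)-ending codon; `inosine` when positions
#' 1-2 are Watson-Crick and an A at the wobble site (deaminated to inosine
#' in the mature tRNA) reads a C- or A-ending codon (a U-ending codon is the
#' Watson-Crick A:U pairing and is reported as such); otherwise `none`.
#' Classes are mutually exclusive.
#'
#' @param codon,anticodon Equal-length character vectors of DNA triplets.
#' @return A character vector: `"watson_crick"`, `"gu_wobble"`, `"inosine"`
#'   or `"none"`.
#' @examples
#' classify_match("AGC", "GCT")  # watson_crick
#' classify_match("GCC", "AGC")  # inosine (A34 reads C)
#' @export
classify_match <- function(codon, anticodon) {
  codon <- toupper(codon)
  anticodon <- toupper(anticodon)
  if (any(!grepl("^[ACGT]{3}$", c(codon, anticodon)))) {
    stop("codons and anticodons must be ACGT triplets")
  }
  n <- max(length(codon), length(anticodon))
  codon <- rep_len(codon, n)
  anticodon <- rep_len(anticodon, n)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  c1 <- substr(codon, 1, 1); c2 <- substr(codon, 2, 2); c3 <- substr(codon, 3, 3)
  a1 <- substr(anticodon, 1, 1); a2 <- substr(anticodon, 2, 2)
  a3 <- substr(anticodon, 3, 3)
  stem_wc <- comp[c1] == a3 & comp[c2] == a2
  full_wc <- stem_wc & comp[c3] == a1
  dplyr::case_when(
    full_wc ~ "watson_crick",
    stem_wc & a1 == "G" & c3 == "T" ~ "gu_wobble",
    stem_wc & a1 == "A" & c3 %in% c("C", "A") ~ "inosine",
    TRUE ~ "none"
  )
}

#' Compare optimal codons with major tRNA genes
#'
#' For each optimal codon, classifies its pairing against every co-major
#' anticodon of its amino acid and reports the best class with precedence
#' watson_crick > gu_wobble > inosine > none. Optimal codons whose amino
#' acid has no tRNA gene get class `none` with a missing anticodon.
#'
#' @param optimal An [identify_optimal_codons()] result (or a tibble with
#'   `codon` (+ optionally `amino_acid`, `optimal`) columns).
#' @param majors A [major_trna()] tibble.
#' @return A tibble `amino_acid`, `codon`, `anticodon`, `copies`,
#'   `match_class`, with attribute `class_counts`.
#' @export
optimal_vs_major <- function(optimal, majors) {
  codons <- optimal_codon_vector(optimal)
  precedence <- c("watson_crick", "gu_wobble", "inosine", "none")
  out <- purrr::map_dfr(codons, function(cod) {
    aa <- CODON_AA[[cod]]
    m <- majors[majors$aa == aa, , drop = FALSE]
    if (nrow(m) == 0) {
      return(tibble::tibble(amino_acid = aa, codon = cod,
                            anticodon = NA_character_, copies = NA_integer_,
                            match_class = "none"))
    }
    cls <- classify_match(rep(cod, nrow(m)), m$anticodon)
    best <- which.min(match(cls, precedence))
    tibble::tibble(amino_acid = aa, codon = cod,
                   anticodon = m$anticodon[best], copies = m$copies[best],
                   match_class = cls[best])
  })
  out$match_class <- factor(out$match_class, levels = precedence)
  attr(out, "class_counts") <- table(out$match_class)
  out
}
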