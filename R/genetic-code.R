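# Standard genetic code tables used throughout the package.
# All sequences are DNA alphabet (T, not U), uppercase; codon order is the
# fixed alphabetical ACGT order that Biostrings::trinucleotideFrequency uses.

#' @importFrom Biostrings GENETIC_CODE mkAllStrings
NULL

CODONS <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3)

# one-letter amino acid per codon ("*" = stop)
CODON_AA <- unname(Biostrings::GENETIC_CODE[CODONS])
names(CODON_AA) <- CODONS

STOP_CODONS <- CODONS[CODON_AA == "*"]
SENSE_CODONS <- CODONS[CODON_AA != "*"]

# degeneracy (number of synonymous codons) per amino acid
AA_DEGENERACY <- table(CODON_AA[SENSE_CODONS])
CODON_DEGENERACY <- as.integer(AA_DEGENERACY[CODON_AA])
names(CODON_DEGENERACY) <- CODONS
CODON_DEGENERACY[STOP_CODONS] <- NA_integer_

# the 59 codons of the 18 degenerate amino acids (Met, Trp, stops excluded)
SYN_CODONS <- SENSE_CODONS[CODON_DEGENERACY[SENSE_CODONS] > 1L]

DEGENERATE_AA <- sort(names(AA_DEGENERACY[AA_DEGENERACY > 1L]))
TWOFOLD_AA <- sort(names(AA_DEGENERACY[AA_DEGENERACY == 2L]))   # 9 amino acids
THREEFOLD_AA <- names(AA_DEGENERACY[AA_DEGENERACY == 3L])       # Ile
FOURFOLD_AA <- sort(names(AA_DEGENERACY[AA_DEGENERACY == 4L]))  # 5 amino acids
SIXFOLD_AA <- sort(names(AA_DEGENERACY[AA_DEGENERACY == 6L]))   # Leu, Ser, Arg

# per-codon base at each position, and G/C indicators
CODON_POS <- lapply(1:3, function(i) substr(CODONS, i, i))
CODON_GC_POS <- lapply(CODON_POS, function(b) b %in% c("G", "C"))
CODON_GC_COUNT <- CODON_GC_POS[[1]] + CODON_GC_POS[[2]] + CODON_GC_POS[[3]]
names(CODON_GC_COUNT) <- CODONS

# synonymous "box": codons sharing first two bases and amino acid (used by the
# synthetic generator, where third positions are redrawn within a box)
CODON_BOX <- paste0(substr(CODONS, 1, 2), CODON_AA)
names(CODON_BOX) <- CODONS

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V"
)
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

#' Standard genetic code reference table
#'
#' One row per codon of the standard genetic code, with its amino acid,
#' degeneracy (number of synonymous codons for that amino acid) and stop
#' status. The 59 codons with `degeneracy > 1` and `!is_stop` are the
#' synonymous codons over which RSCU, GC3s, CAI, CBI and Fop are defined.
#'
#' @return A tibble with columns `codon`, `amino_acid` (one-letter, `*` for
#'   stop), `degeneracy` and `is_stop`.
#' @examples
#' genetic_code_table()
#' @export
genetic_code_table <- function() {
  tibble::tibble(
    codon = CODONS,
    amino_acid = unname(CODON_AA),
    degeneracy = unname(CODON_DEGENERACY),
    is_stop = CODONS %in% STOP_CODONS
  )
}

# reverse complement of plain character codons/sequences (vectorized)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
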