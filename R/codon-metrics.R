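# Per-gene codon usage metrics: codon counts, RSCU, positional GC, Wright's
# effective number of codons, CAI, CBI and Fop.
#
# All metrics are computed on the coding sequence including the initiator ATG
# and excluding the terminal stop codon: stop codons never enter the sense
# totals, so counting the full CDS and restricting to sense columns is exact.

# frame-0 codon count matrix (genes x 64), stop codons included as columns
codon_count_matrix <- function(cds) {
  stopifnot(all(nchar(cds) %% 3 == 0))
  m <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(cds), step = 3)
  storage.mode(m) <- "double"
  colnames(m) <- CODONS
  m
}

#' Count codons of a coding sequence
#'
#' Tallies frame-0 triplets of a CDS. The terminal stop codon (and any other
#' stop triplet) is kept in separate stop rows and excluded from the sense
#' total; triplets containing ambiguity characters are skipped and counted in
#' the `n_skipped` attribute.
#'
#' @param cds A single nucleotide string, length divisible by 3 (may be
#'   empty).
#' @return A tibble with columns `codon`, `amino_acid`, `is_stop`, `n`
#'   (64 rows), with attributes `n_sense` (total sense codons) and
#'   `n_skipped` (codons containing non-ACGT characters).
#' @examples
#' count_codons("ATGTTTTAA")
#' @export
count_codons <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length must be divisible by 3, got ", nchar(cds))
  }
  n <- if (nchar(cds) == 0) {
    stats::setNames(numeric(64), CODONS)
  } else {
    codon_count_matrix(toupper(cds))[1, ]
  }
  out <- tibble::tibble(
    codon = CODONS,
    amino_acid = unname(CODON_AA),
    is_stop = CODONS %in% STOP_CODONS,
    n = unname(n)
  )
  attr(out, "n_sense") <- sum(n[SENSE_CODONS])
  attr(out, "n_skipped") <- nchar(cds) / 3 - sum(n)
  out
}

# accept either a count_codons() tibble or a named numeric vector over codons
as_count_vector <- function(counts) {
  if (is.data.frame(counts)) {
    v <- stats::setNames(counts$n, counts$codon)
  } else {
    v <- counts
  }
  stopifnot(all(CODONS %in% names(v)))
  v[CODONS]
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c with family degeneracy d and family total N is
#' `count(c) * d / N`: the observed count relative to the count expected if
#' all synonymous codons of the amino acid were used equally. Met, Trp and
#' stop codons are excluded; families absent from the counts get `NA`
#' (undefined, not zero).
#'
#' @param counts A [count_codons()] tibble or named count vector over the 64
#'   codons (e.g. pooled over a gene category).
#' @return A tibble with columns `amino_acid`, `codon`, `n`, `rscu`
#'   (59 rows, one per synonymous codon).
#' @examples
#' cc <- count_codons("ATGTTTTTTTTCTAA")
#' dplyr::filter(rscu(cc), amino_acid == "F")
#' @export
rscu <- function(counts) {
  v <- as_count_vector(counts)[SYN_CODONS]
  aa <- CODON_AA[SYN_CODONS]
  fam_n <- tapply(v, aa, sum)[aa]
  d <- CODON_DEGENERACY[SYN_CODONS]
  out <- tibble::tibble(
    amino_acid = unname(aa),
    codon = SYN_CODONS,
    n = unname(v),
    rscu = as.numeric(ifelse(fam_n > 0, v * d / fam_n, NA_real_))
  )
  dplyr::arrange(out, .data$amino_acid, .data$codon)
}

# ---- vectorized metric engine over a count matrix --------------------------

# Wright's per-family codon homozygosity F = (n * sum(p^2) - 1) / (n - 1),
# computed for each of the 18 degenerate families; NA when family count < 2.
family_homozygosity <- function(m) {
  out <- vapply(DEGENERATE_AA, function(aa) {
    cols <- SYN_CODONS[CODON_AA[SYN_CODONS] == aa]
    mf <- m[, cols, drop = FALSE]
    n <- rowSums(mf)
    sp2 <- rowSums(mf^2) / n^2
    ifelse(n >= 2, (n * sp2 - 1) / (n - 1), NA_real_)
  }, numeric(nrow(m)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = 1, dimnames = list(NULL, DEGENERATE_AA))
  }
  out
}

# class mean of F over families present; NA if no family in the class usable
class_mean <- function(fmat, aas) {
  sub <- fmat[, aas, drop = FALSE]
  k <- rowSums(!is.na(sub))
  ifelse(k > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
}

nc_from_matrix <- function(m) {
  fmat <- family_homozygosity(m)
  f2 <- class_mean(fmat, TWOFOLD_AA)
  f4 <- class_mean(fmat, FOURFOLD_AA)
  f6 <- class_mean(fmat, SIXFOLD_AA)
  f3 <- fmat[, THREEFOLD_AA]
  # Ile absent: impute the 3-fold class from the neighboring classes
  f3 <- ifelse(is.na(f3), (f2 + f4) / 2, f3)
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  # undefined when any needed class mean is missing or non-positive
  bad <- is.na(f2) | is.na(f3) | is.na(f4) | is.na(f6) |
    f2 <= 0 | f3 <= 0 | f4 <= 0 | f6 <= 0
  nc[bad] <- NA_real_
  unname(pmin(nc, 61))
}

#' Effective number of codons (Wright's Nc)
#'
#' Wright's estimator of how far a gene departs from uniform synonymous codon
#' usage, ranging from 20 (one codon per amino acid) to 61 (all synonymous
#' codons used equally). Per-family homozygosity
#' `F = (n * sum(p_i^2) - 1) / (n - 1)` is averaged within degeneracy classes
#' and `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61. Families with
#' fewer than two codons are omitted from their class mean; a missing 3-fold
#' class (Ile) is imputed as `(F2 + F4)/2`; a gene missing an entire 2-, 4-
#' or 6-fold class gets `NA`.
#'
#' @param counts A [count_codons()] tibble or named count vector.
#' @return A single numeric Nc value (`NA` if undefined).
#' @export
effective_number_of_codons <- function(counts) {
  v <- as_count_vector(counts)
  nc_from_matrix(matrix(v, nrow = 1, dimnames = list(NULL, CODONS)))
}

#' Relative adaptiveness weights for CAI
#'
#' Converts pooled codon counts of a reference set (conventionally the
#' high-bias, putatively highly expressed genes) into CAI weights
#' `w(c) = RSCU(c) / max RSCU in family`. Codons unobserved in the reference
#' but belonging to an observed family get w = 0.01; codons of families
#' entirely absent from the reference get the uninformative weight 1.
#'
#' @param ref_counts Pooled reference counts (tibble or named vector).
#' @return A tibble with columns `codon`, `amino_acid`, `w` (59 rows).
#' @export
cai_weights <- function(ref_counts) {
  r <- rscu(ref_counts)
  r <- dplyr::group_by(r, .data$amino_acid)
  r <- dplyr::mutate(r, w = .data$rscu / max(.data$rscu))
  r <- dplyr::ungroup(r)
  w <- dplyr::case_when(
    is.na(r$rscu) ~ 1,        # family absent from reference: uninformative
    r$n == 0 ~ 0.01,          # unobserved codon in an observed family
    TRUE ~ r$w
  )
  tibble::tibble(codon = r$codon, amino_acid = r$amino_acid, w = w)
}

weights_vector <- function(weights) {
  if (is.data.frame(weights)) {
    v <- stats::setNames(weights$w, weights$codon)
  } else {
    v <- weights
  }
  # codons without a supplied weight are neutral (w = 1)
  full <- stats::setNames(rep(1, length(SYN_CODONS)), SYN_CODONS)
  v <- v[names(v) %in% SYN_CODONS]
  full[names(v)] <- v
  full
}

cai_from_matrix <- function(m, w) {
  ms <- m[, SYN_CODONS, drop = FALSE]
  tot <- rowSums(ms)
  ifelse(tot > 0, exp(as.vector(ms %*% log(w)) / tot), NA_real_)
}

#' Codon adaptation index
#'
#' Geometric mean of relative adaptiveness weights over a gene's synonymous
#' codons (Met, Trp and stops excluded).
#'
#' @param counts A [count_codons()] tibble or named count vector.
#' @param weights Weights from [cai_weights()] (tibble or named vector).
#' @return CAI in (0, 1]; `NA` for a gene with no synonymous codons.
#' @export
cai <- function(counts, weights) {
  v <- as_count_vector(counts)
  cai_from_matrix(matrix(v, 1, dimnames = list(NULL, CODONS)), weights_vector(weights))
}

optimal_codon_vector <- function(optimal) {
  if (is.data.frame(optimal)) {
    codons <- if ("optimal" %in% names(optimal)) {
      optimal$codon[optimal$optimal %in% TRUE]
    } else {
      optimal$codon
    }
  } else {
    codons <- optimal
  }
  codons <- intersect(codons, SYN_CODONS)
  codons
}

fop_from_matrix <- function(m, opt) {
  tot <- rowSums(m[, SYN_CODONS, drop = FALSE])
  n_opt <- rowSums(m[, opt, drop = FALSE])
  ifelse(tot > 0, n_opt / tot, NA_real_)
}

#' Frequency of optimal codons
#'
#' Fop = (optimal codons) / (all synonymous codons); Met, Trp and stops are
#' excluded from the denominator.
#'
#' @param counts A [count_codons()] tibble or named count vector.
#' @param optimal An optimal codon set: an [identify_optimal_codons()] result,
#'   a tibble with a `codon` column, or a character vector of codons.
#' @return Fop in \[0, 1\]; `NA` when the gene has no synonymous codons.
#' @export
fop <- function(counts, optimal) {
  v <- as_count_vector(counts)
  fop_from_matrix(matrix(v, 1, dimnames = list(NULL, CODONS)),
                  optimal_codon_vector(optimal))
}

cbi_from_matrix <- function(m, opt) {
  opt_aa <- unique(CODON_AA[opt])
  fam_cols <- SYN_CODONS[CODON_AA[SYN_CODONS] %in% opt_aa]
  n_opt <- rowSums(m[, opt, drop = FALSE])
  n_tot <- rowSums(m[, fam_cols, drop = FALSE])
  # random expectation: per family, count * (optimal codons in family) / d
  n_ran <- rep(0, nrow(m))
  for (aa in opt_aa) {
    cols <- SYN_CODONS[CODON_AA[SYN_CODONS] == aa]
    k <- sum(CODON_AA[opt] == aa)
    n_ran <- n_ran + rowSums(m[, cols, drop = FALSE]) * k / AA_DEGENERACY[[aa]]
  }
  ifelse(abs(n_tot - n_ran) > 0, (n_opt - n_ran) / (n_tot - n_ran), NA_real_)
}

#' Codon bias index
#'
#' CBI = (Nopt - Nran) / (Ntot - Nran): the excess usage of optimal codons
#' over the uniform-usage expectation, over amino acids that have at least
#' one optimal codon. 1 means exclusive optimal usage, 0 usage at random
#' expectation, negative values anti-optimal usage.
#'
#' @inheritParams fop
#' @return CBI (at most 1); `NA` when Ntot equals Nran.
#' @export
cbi <- function(counts, optimal) {
  v <- as_count_vector(counts)
  cbi_from_matrix(matrix(v, 1, dimnames = list(NULL, CODONS)),
                  optimal_codon_vector(optimal))
}

#' Per-gene codon usage metrics table
#'
#' Computes the full per-gene metric vector for a set of coding sequences:
#' overall and positional GC (GC, GC1, GC2, GC3, GC12 = (GC1+GC2)/2), silent
#' third-position GC (GC3s, over the 59 synonymous codons only), third-base
#' composition A3/T3/G3/C3 (over all sense codons including Met and Trp, the
#' convention of MEGA; set `silent_only = TRUE` for the synonymous-only
#' variant), Wright's Nc, and — when reference weights / an optimal set are
#' supplied — CAI, CBI and Fop.
#'
#' @param genes A data frame with columns `gene_id` and `cds`, or a (named)
#'   character vector of coding sequences. CDS lengths must be multiples of
#'   3; a terminal stop codon, if present, is excluded from all metrics.
#' @param ref_weights Optional [cai_weights()] table for CAI.
#' @param optimal Optional optimal codon set for Fop and CBI.
#' @param silent_only If `TRUE`, compute A3/T3/G3/C3 over synonymous codons
#'   only instead of all sense codons.
#' @return A tibble with one row per gene and columns `gene_id`,
#'   `length_codons`, `gc`, `gc1`, `gc2`, `gc3`, `gc12`, `gc3s`, `a3`, `t3`,
#'   `g3`, `c3`, `nc`, `cai`, `cbi`, `fop`.
#' @examples
#' codon_metrics(c(g1 = "ATGTTTTTCAAAAAGGGTGGCTAA"))
#' @export
codon_metrics <- function(genes, ref_weights = NULL, optimal = NULL,
                          silent_only = FALSE) {
  if (is.data.frame(genes)) {
    ids <- genes$gene_id
    cds <- genes$cds
  } else {
    cds <- unname(genes)
    ids <- names(genes) %||% paste0("gene", seq_along(cds))
  }
  stopifnot(all(nchar(cds) %% 3 == 0))
  m <- codon_count_matrix(toupper(cds))

  sense <- CODONS %in% SENSE_CODONS
  syn <- CODONS %in% SYN_CODONS
  ms <- m[, sense, drop = FALSE]
  len <- rowSums(ms)

  frac <- function(pos, base_set, scope) {
    sel <- scope & (CODON_POS[[pos]] %in% base_set)
    den <- rowSums(m[, scope, drop = FALSE])
    ifelse(den > 0, rowSums(m[, sel, drop = FALSE]) / den, NA_real_)
  }
  gc1 <- frac(1, c("G", "C"), sense)
  gc2 <- frac(2, c("G", "C"), sense)
  gc3 <- frac(3, c("G", "C"), sense)
  gc3s <- frac(3, c("G", "C"), syn)
  gc <- ifelse(len > 0, as.vector(ms %*% CODON_GC_COUNT[sense]) / (3 * len), NA_real_)
  base_scope <- if (silent_only) syn else sense
  a3 <- frac(3, "A", base_scope)
  t3 <- frac(3, "T", base_scope)
  g3 <- frac(3, "G", base_scope)
  c3 <- frac(3, "C", base_scope)

  out <- tibble::tibble(
    gene_id = ids,
    length_codons = len,
    gc = gc, gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2,
    gc3s = gc3s,
    a3 = a3, t3 = t3, g3 = g3, c3 = c3,
    nc = nc_from_matrix(m),
    cai = if (is.null(ref_weights)) NA_real_ else
      cai_from_matrix(m, weights_vector(ref_weights)),
    cbi = if (is.null(optimal)) NA_real_ else
      cbi_from_matrix(m, optimal_codon_vector(optimal)),
    fop = if (is.null(optimal)) NA_real_ else
      fop_from_matrix(m, optimal_codon_vector(optimal))
  )
  out
}

#' Pool codon counts over a set of genes
#'
#' @param genes A data frame with `gene_id` and `cds` columns, or a character
#'   vector of coding sequences.
#' @param ids Optional gene ids to restrict to.
#' @return A named numeric vector of pooled counts over the 64 codons.
#' @export
pool_counts <- function(genes, ids = NULL) {
  if (is.data.frame(genes)) {
    if (!is.null(ids)) genes <- genes[genes$gene_id %in% ids, , drop = FALSE]
    cds <- genes$cds
  } else {
    cds <- genes
  }
  if (length(cds) == 0) return(stats::setNames(numeric(64), CODONS))
  colSums(codon_count_matrix(toupper(cds)))
}
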