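# Translational selection strength from the nine two-fold degenerate amino
# acids: per-amino-acid odds ratios, S = ln(odds ratio), and the
# codon-count-weighted genome statistic S-hat.

#' Optimal/suboptimal tallies for the two-fold degenerate amino acids
#'
#' For each of the nine two-fold degenerate amino acids (Phe, Tyr, His, Gln,
#' Asn, Lys, Asp, Glu, Cys), identifies the optimal and suboptimal codon and
#' tallies their pooled counts and within-family frequencies in the
#' high-bias and low-bias categories. The optimal codon is taken from the
#' supplied optimal set; an amino acid with no called optimal codon falls
#' back to the codon with the higher pooled RSCU in the high category.
#' Amino acids absent from either pool are dropped (attribute `dropped`).
#'
#' @param high_counts,low_counts Pooled codon counts per category.
#' @param optimal An [identify_optimal_codons()] result (or tibble with
#'   `codon` and `optimal` columns, or a character vector of codons).
#' @return A tibble `amino_acid`, `codon_opt`, `codon_sub`, `opt_source`
#'   (`"called"` or `"fallback"`), `n1h`, `n2h`, `n1l`, `n2l`, `f1h`, `f2h`,
#'   `f1l`, `f2l`.
#' @export
two_fold_tallies <- function(high_counts, low_counts, optimal) {
  hv <- as_count_vector(high_counts)
  lv <- as_count_vector(low_counts)
  opt <- optimal_codon_vector(optimal)
  dropped <- character()
  rows <- purrr::map_dfr(TWOFOLD_AA, function(aa) {
    fam <- SYN_CODONS[CODON_AA[SYN_CODONS] == aa]
    if (sum(hv[fam]) == 0 || sum(lv[fam]) == 0) {
      dropped <<- c(dropped, aa)
      return(NULL)
    }
    called <- intersect(opt, fam)
    if (length(called) == 1) {
      c_opt <- called
      src <- "called"
    } else {
      # no (or ambiguous) called optimal codon: higher RSCU in the high
      # category, which for a two-fold family is simply the higher count
      c_opt <- fam[order(-hv[fam], fam)][1]
      src <- "fallback"
    }
    c_sub <- setdiff(fam, c_opt)
    tibble::tibble(
      amino_acid = aa, codon_opt = c_opt, codon_sub = c_sub, opt_source = src,
      n1h = unname(hv[c_opt]), n2h = unname(hv[c_sub]),
      n1l = unname(lv[c_opt]), n2l = unname(lv[c_sub])
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      amino_acid = character(), codon_opt = character(),
      codon_sub = character(), opt_source = character(),
      n1h = numeric(), n2h = numeric(), n1l = numeric(), n2l = numeric()
    )
  }
  rows$f1h <- rows$n1h / (rows$n1h + rows$n2h)
  rows$f2h <- rows$n2h / (rows$n1h + rows$n2h)
  rows$f1l <- rows$n1l / (rows$n1l + rows$n2l)
  rows$f2l <- rows$n2l / (rows$n1l + rows$n2l)
  attr(rows, "dropped") <- dropped
  rows
}

#' Odds ratio and S for a two-fold tally
#'
#' The enrichment of the optimal codon in the high-bias relative to the
#' low-bias category, as the standard 2x2 odds ratio
#' `OR = (f1H/f2H) * (f2L/f1L)`, with `S = ln(OR)`. A zero cell leaves OR
#' undefined unless `continuity = TRUE`, which applies the Haldane-Anscombe
#' 0.5 pseudo-count to all four counts. `literal = TRUE` evaluates the
#' non-standard form `(f1H/f2H) * (f2L/f1H)` for audit only.
#'
#' @param tallies A [two_fold_tallies()] tibble.
#' @param continuity Apply the 0.5 pseudo-count to rows with a zero cell.
#' @param literal Use the literal (typographic) variant of the formula.
#' @return The input tibble with `odds_ratio` and `s` columns.
#' @export
odds_ratio <- function(tallies, continuity = FALSE, literal = FALSE) {
  t <- tallies
  zero <- t$n1h == 0 | t$n2h == 0 | t$n1l == 0 | t$n2l == 0
  if (continuity && any(zero)) {
    for (col in c("n1h", "n2h", "n1l", "n2l")) t[[col]][zero] <- t[[col]][zero] + 0.5
    t$f1h <- t$n1h / (t$n1h + t$n2h); t$f2h <- t$n2h / (t$n1h + t$n2h)
    t$f1l <- t$n1l / (t$n1l + t$n2l); t$f2l <- t$n2l / (t$n1l + t$n2l)
    zero <- rep(FALSE, nrow(t))
  }
  or <- if (literal) {
    (t$f1h / t$f2h) * (t$f2l / t$f1h)
  } else {
    (t$f1h / t$f2h) * (t$f2l / t$f1l)
  }
  or[zero] <- NA_real_
  t$odds_ratio <- or
  t$s <- log(or)
  t
}

#' Codon-count-weighted genome selection strength
#'
#' `S-hat = sum(w_i * S_i) / sum(w_i)` over the two-fold degenerate amino
#' acids with defined S, weighted by each amino acid's total codon count in
#' the high-bias category (`n1h + n2h`).
#'
#' @param s Per-amino-acid S values.
#' @param weights High-category codon totals per amino acid.
#' @return S-hat (a single number).
#' @export
s_hat <- function(s, weights) {
  ok <- !is.na(s) & !is.na(weights)
  if (!any(ok)) stop("all S values undefined: S-hat cannot be computed")
  sum(s[ok] * weights[ok]) / sum(weights[ok])
}

#' Estimate translational selection strength
#'
#' Full workflow over the nine two-fold degenerate amino acids: tally the
#' optimal/suboptimal codons in the pooled high- and low-bias categories,
#' compute each amino acid's odds ratio and S = ln(OR), and combine them
#' into the genome-level S-hat weighted by high-category codon counts.
#'
#' @inheritParams two_fold_tallies
#' @inheritParams odds_ratio
#' @return An object of class `cub_selstrength`: list with `per_aa` (tibble
#'   with OR, S and weights) and `s_hat`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
selection_strength <- function(high_counts, low_counts, optimal,
                               continuity = FALSE, literal = FALSE) {
  t <- odds_ratio(two_fold_tallies(high_counts, low_counts, optimal),
                  continuity = continuity, literal = literal)
  t$weight <- t$n1h + t$n2h
  structure(
    list(per_aa = t, s_hat = s_hat(t$s, t$weight)),
    class = "cub_selstrength"
  )
}

#' @export
print.cub_selstrength <- function(x, ...) {
  cat("Translational selection strength (", nrow(x$per_aa),
      " two-fold amino acids)\n", sep = "")
  print(x$per_aa[, c("amino_acid", "codon_opt", "codon_sub",
                     "odds_ratio", "s", "weight")])
  cat("S-hat =", signif(x$s_hat, 4), "\n")
  invisible(x)
}

#' @export
tidy.cub_selstrength <- function(x, ...) {
  x$per_aa[, c("amino_acid", "codon_opt", "codon_sub", "opt_source",
               "odds_ratio", "s", "weight")]
}

#' @export
glance.cub_selstrength <- function(x, ...) {
  tibble::tibble(s_hat = x$s_hat,
                 n_amino_acids = sum(!is.na(x$per_aa$s)),
                 total_weight = sum(x$per_aa$weight[!is.na(x$per_aa$s)]))
}
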