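# Mutation-versus-selection diagnostics: expected Nc under neutrality,
# deviations from the Nc-GC3s curve, neutrality (GC12 ~ GC3) regression,
# parity rule 2 quadrants, and metric correlation matrices.

#' Expected Nc under a neutral mutation model
#'
#' Wright's expectation for the effective number of codons of a gene whose
#' codon usage is set purely by its silent-site GC content s:
#' `Nc = 2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param gc3s Silent third-position GC content(s), in \[0, 1\].
#' @return Expected Nc (vectorized).
#' @examples
#' expected_nc(0.5)  # 60.5
#' @export
expected_nc <- function(gc3s) {
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' Deviation of observed Nc from the neutral expectation
#'
#' Genes under pure mutation pressure sit on the expected Nc-GC3s curve;
#' translational selection depresses Nc below it. Reports the signed
#' deviation `expected - observed` per gene and, as attribute
#' `fraction_below_curve`, the fraction of genes with positive deviation
#' (below the curve).
#'
#' @param metrics A [codon_metrics()] tibble (needs `gene_id`, `nc`, `gc3s`).
#' @return A tibble `gene_id`, `gc3s`, `nc`, `nc_expected`, `deviation`.
#' @export
nc_deviation <- function(metrics) {
  d <- metrics[!is.na(metrics$nc) & !is.na(metrics$gc3s),
               c("gene_id", "gc3s", "nc")]
  d$nc_expected <- pmin(expected_nc(d$gc3s), 61)
  d$deviation <- d$nc_expected - d$nc
  out <- tibble::as_tibble(d)
  attr(out, "fraction_below_curve") <- mean(out$deviation > 0)
  out
}

#' Neutrality plot regression (GC12 vs GC3)
#'
#' Ordinary least-squares regression with GC12 (mean GC of codon positions 1
#' and 2) on the x-axis and GC3 on the y-axis. Under pure mutation pressure
#' all three positions track the same mutational GC and the slope approaches
#' 1; under selection on silent sites GC3 decouples from GC12 and the slope
#' approaches 0, so the slope is read as the proportional contribution of
#' mutation pressure. `transpose = TRUE` swaps the axes (the orientation
#' much of the literature plots).
#'
#' @param metrics A [codon_metrics()] tibble (needs `gc12`, `gc3`; at least
#'   3 genes).
#' @param transpose Regress GC12 on GC3 instead.
#' @return An object of class `cub_neutrality`: list with `slope`,
#'   `intercept`, `slope_pct`, `r`, `p`, `n`, `x`, `y` (axis names), `model`
#'   (the `lm` fit) and `ci` (95% confidence interval of the slope).
#'   Supports [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @export
neutrality_fit <- function(metrics, transpose = FALSE) {
  d <- metrics[!is.na(metrics$gc12) & !is.na(metrics$gc3), , drop = FALSE]
  if (nrow(d) < 3) stop("neutrality regression needs at least 3 genes")
  if (transpose) {
    xv <- d$gc3; yv <- d$gc12; xn <- "gc3"; yn <- "gc12"
  } else {
    xv <- d$gc12; yv <- d$gc3; xn <- "gc12"; yn <- "gc3"
  }
  if (stats::sd(xv) == 0) {
    warning("zero variance in ", xn, ": slope undefined")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          slope_pct = NA_real_, r = NA_real_, p = NA_real_,
                          n = nrow(d), x = xn, y = yn, model = NULL,
                          ci = c(NA_real_, NA_real_), data = tibble::tibble(x = xv, y = yv)),
                     class = "cub_neutrality"))
  }
  fit <- stats::lm(yv ~ xv)
  ct <- stats::cor.test(xv, yv)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_pct = unname(stats::coef(fit)[2]) * 100,
    r = unname(ct$estimate),
    p = ct$p.value,
    n = nrow(d),
    x = xn, y = yn,
    model = fit,
    ci = unname(stats::confint(fit)[2, ]),
    data = tibble::tibble(x = xv, y = yv)
  ), class = "cub_neutrality")
}

#' @export
print.cub_neutrality <- function(x, ...) {
  cat("Neutrality regression (", x$y, " ~ ", x$x, "), n = ", x$n, "\n",
      "  slope = ", signif(x$slope, 4), " (", signif(x$slope_pct, 3),
      "% mutation), intercept = ", signif(x$intercept, 4), "\n",
      "  Pearson r = ", signif(x$r, 4), ", p = ", format.pval(x$p), "\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cub_neutrality <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(NA_real_, x$ci[1]),
    conf.high = c(NA_real_, x$ci[2])
  )
}

#' @export
glance.cub_neutrality <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 slope_pct = x$slope_pct, r = x$r, p.value = x$p, n = x$n)
}

#' Parity rule 2 analysis
#'
#' Plots each gene at `x = G3/(G3 + C3)`, `y = A3/(A3 + T3)`; the center
#' (0.5, 0.5) means A = T and G = C at third positions (no strand-asymmetric
#' bias). Quadrants: Q1 x>0.5 & y>0.5, Q2 x<0.5 & y>0.5, Q3 x<0.5 & y<0.5,
#' Q4 x>0.5 & y<0.5; points with x or y exactly 0.5 are assigned to no
#' quadrant (`"boundary"`). Genes with a zero denominator are excluded and
#' listed in the `excluded` attribute.
#'
#' @param metrics A [codon_metrics()] tibble (needs `a3`, `t3`, `g3`, `c3`).
#' @return A tibble `gene_id`, `x`, `y`, `quadrant`, with attributes
#'   `quadrant_counts` and `excluded`.
#' @export
pr2_analysis <- function(metrics) {
  gcd <- metrics$g3 + metrics$c3
  atd <- metrics$a3 + metrics$t3
  ok <- !is.na(gcd) & !is.na(atd) & gcd > 0 & atd > 0
  x <- metrics$g3[ok] / gcd[ok]
  y <- metrics$a3[ok] / atd[ok]
  quadrant <- dplyr::case_when(
    x == 0.5 | y == 0.5 ~ "boundary",
    x > 0.5 & y > 0.5 ~ "Q1",
    x < 0.5 & y > 0.5 ~ "Q2",
    x < 0.5 & y < 0.5 ~ "Q3",
    TRUE ~ "Q4"
  )
  out <- tibble::tibble(
    gene_id = metrics$gene_id[ok], x = x, y = y,
    quadrant = factor(quadrant, levels = c("Q1", "Q2", "Q3", "Q4", "boundary"))
  )
  attr(out, "quadrant_counts") <- table(out$quadrant)
  attr(out, "excluded") <- metrics$gene_id[!ok]
  out
}

#' Pairwise Pearson correlation matrix of codon usage parameters
#'
#' Pearson r with two-tailed p for every pair of the requested metric
#' columns (pairwise-complete observations). Pairs involving a zero-variance
#' column are flagged.
#'
#' @param metrics A [codon_metrics()] tibble.
#' @param vars Columns to correlate (default: the positional-composition
#'   parameter set plus Nc and the adaptation indices, where present).
#' @return A tibble `var1`, `var2`, `r`, `p`, `n`, `zero_variance`, one row
#'   per unordered pair plus the unit diagonal.
#' @export
correlation_matrix <- function(metrics,
                               vars = intersect(
                                 c("gc", "gc1", "gc2", "gc3", "gc12", "gc3s",
                                   "a3", "t3", "g3", "c3", "nc", "cai", "cbi",
                                   "fop"),
                                 names(metrics))) {
  stopifnot(length(vars) >= 2)
  purrr::map_dfr(seq_along(vars), function(i) {
    purrr::map_dfr(seq_len(i), function(j) {
      x <- metrics[[vars[i]]]
      y <- metrics[[vars[j]]]
      ok <- !is.na(x) & !is.na(y)
      zv <- stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
      if (i == j) {
        tibble::tibble(var1 = vars[i], var2 = vars[j], r = 1, p = NA_real_,
                       n = sum(ok), zero_variance = zv)
      } else if (zv || sum(ok) < 3) {
        tibble::tibble(var1 = vars[i], var2 = vars[j], r = NA_real_,
                       p = NA_real_, n = sum(ok), zero_variance = zv)
      } else {
        ct <- stats::cor.test(x[ok], y[ok])
        tibble::tibble(var1 = vars[i], var2 = vars[j],
                       r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                       zero_variance = FALSE)
      }
    })
  })
}
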