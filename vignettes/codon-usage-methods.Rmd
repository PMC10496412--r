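---
title: "Methods: whole-genome codon usage bias analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-genome codon usage bias analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

cubkit implements a whole-genome codon usage bias (CUB) workflow of the kind
used to characterize translational selection in nuclear genomes — the
motivating system being red algae (Rhodophyta), whose genomes span a wide
range of GC content and selection intensity. This vignette is the package's
account of the models and procedures, the tunable parameters, the synthetic
data generator and its limits, and the numerical choices made where the
design was genuinely open.

## From assembly to filtered coding sequences

`load_genome()` reads a FASTA assembly (Biostrings) and a GFF3 annotation
(rtracklayer), splices each mRNA's CDS exons (reverse-complementing
minus-strand genes), and keeps the introns in coding orientation.
Coordinates are 0-based half-open internally; GFF3's 1-based closed
convention is converted at the boundary. Gene models with a nonzero phase on
their first CDS segment are rejected rather than trimmed: every downstream
metric assumes an ATG-anchored reading frame.

`filter_cds()` applies seven quality rules, each record reporting the first
rule it fails: length a multiple of three; ATG start; TAA/TAG/TGA stop; no
internal stop; length strictly greater than 300 bp; longest transcript per
gene (ties broken by smallest transcript id, for determinism); no
pseudogenes; and no ambiguity characters. The ambiguity rule is the
operational proxy for "poor sequencing quality": it is the only
sequence-intrinsic criterion available from a FASTA record alone.

Noncoding GC comes from two sources per gene: up to 200 bp of flanking DNA
on each side — truncated at contig ends and at the nearest neighboring gene,
with abutting genes yielding empty flanks — and the concatenation of all
introns. Intronless genes are excluded from intron statistics rather than
scored zero (single-celled genomes can have essentially no introns in
high-bias genes, which is informative in itself). Flank truncation uses
gene-level intervals as neighbor bounds; UTRs are not modeled because many
annotations provide only CDS features.

## Per-gene metrics

All metrics are computed on the CDS including the initiator ATG and
excluding the terminal stop. With counts $n_c$ for codon $c$ in a family of
degeneracy $d$ and total $N$:

* **RSCU** $= n_c d / N$; undefined (not zero) for absent families.
* **Nc**, Wright's effective number of codons, from per-family
  homozygosities $F = (n \sum_i \hat p_i^2 - 1)/(n - 1)$ averaged within
  degeneracy classes: $N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 +
  3/\bar F_6$, capped at 61. Families with fewer than two codons are
  omitted from their class mean. A missing 3-fold class (Ile) is imputed as
  $(\bar F_2 + \bar F_4)/2$; a gene missing an entire 2-, 4- or 6-fold
  class is flagged Nc-undefined. This follows the canonical estimator with
  defaults; no low-GC3s ("Bulmer") correction is applied.
* **GC3s** over third positions of the 59 synonymous codons; **GC1/GC2/GC3**
  over all sense codons; **GC12** $= ($GC1$+$GC2$)/2$ exactly.
* **A3/T3/G3/C3** over all sense codons including Met and Trp, matching the
  MEGA convention used for parity-rule plots; `silent_only = TRUE` gives
  the synonymous-only variant.
* **CAI**: geometric mean of relative adaptiveness weights
  $w_c = \mathrm{RSCU}_c / \max_{\text{family}} \mathrm{RSCU}$ from a
  high-expression reference set; codons unobserved in the reference get
  $w = 0.01$ (the CodonW convention), and families entirely absent from the
  reference get the uninformative $w = 1$.
* **Fop**: fraction of synonymous codons that are optimal. **CBI**
  $= (N_{opt} - N_{ran})/(N_{tot} - N_{ran})$ over families with at least
  one optimal codon, where $N_{ran}$ is the uniform-usage expectation.

## Stratification and optimal codons

Genes are ranked by Nc; the lowest-Nc $\lfloor pN \rfloor$ genes form the
high-bias (putatively highly expressed) category and the highest-Nc
$\lfloor pN \rfloor$ the low-bias category, with $p$ between 5 and 10%
depending on genome size (default 0.05). Ties at a boundary break by gene
id so the partition is a pure function of its inputs. A codon is **optimal**
when its RSCU in the pooled high category exceeds the pooled low category by
more than 0.08 (strict inequality); pooled counts, not means of per-gene
RSCU, because the category is treated as one composite reference gene. The
published rule is the difference threshold alone; `strict = TRUE` adds the
requirement RSCU$_{high} > 1$ found in some of the surrounding literature.
The modal stop codon of the high pool is reported as the optimal
termination codon.

## Mutation-versus-selection diagnostics

* **Nc–GC3s**: the neutral expectation $N_c = 2 + s + 29/(s^2 + (1-s)^2)$;
  genes below the curve (positive deviation) are candidates for selection.
* **Neutrality regression**: GC12 on the x-axis, GC3 on y, ordinary least
  squares. Under pure mutation pressure all positions track the same
  mutational GC and the slope approaches 1; under silent-site selection GC3
  decouples and the slope approaches 0, so the slope reads as the
  proportional mutation contribution. Much of the literature plots the
  transpose; `transpose = TRUE` reproduces that orientation, and the
  default follows the protocol's stated axes.
* **PR2**: $x = G_3/(G_3+C_3)$, $y = A_3/(A_3+T_3)$. Points exactly on 0.5
  are assigned to no quadrant — the center is the null hypothesis, not a
  quadrant.
* **Correlations**: Pearson r with two-tailed p (the SPSS default used for
  the published tables), pairwise-complete.

## Translational selection strength

For each of the nine two-fold degenerate amino acids (Phe, Tyr, His, Gln,
Asn, Lys, Asp, Glu, Cys), with within-family frequencies $f_{1H}, f_{2H}$
(optimal, suboptimal; high category) and $f_{1L}, f_{2L}$ (low category):

$$\mathrm{OR} = \frac{f_{1H}}{f_{2H}} \cdot \frac{f_{2L}}{f_{1L}}, \qquad
  S = \ln \mathrm{OR}, \qquad
  \hat S = \frac{\sum_i w_i S_i}{\sum_i w_i}$$

with weights $w_i$ the amino acid's total codon count in the high category.
The odds-ratio denominator is $f_{1L}$ — the standard 2×2 odds ratio; the
variant with $f_{1H}$ repeated in the denominator, which appears in one
typeset version of the formula, is not an odds ratio and is available only
as `literal = TRUE` for audit. An amino acid without a called optimal codon
falls back to the codon with higher pooled RSCU in the high category; zero
cells drop the amino acid unless `continuity = TRUE` applies the
Haldane–Anscombe 0.5 correction. S is a natural logarithm throughout.

## tRNA adaptation

`read_trnascan()` parses tRNAscan-SE 2.x tabular output verbatim.
Anticodons are kept 5'→3' in the DNA alphabet as the tool emits them; the
wobble base (tRNA position 34) is therefore the *first* anticodon character,
pairing with the codon's third base. Published reports write anticodons in
both orientations; fixing one convention and documenting it was the only
robust choice. Matching classes, mutually exclusive with precedence
watson_crick > gu_wobble > inosine > none:

* **watson_crick** — codon equals the reverse complement of the anticodon;
* **gu_wobble** — stem positions Watson–Crick, G34 reading a U-ending codon;
* **inosine** — stem positions Watson–Crick, A34 (deaminated to inosine in
  the mature tRNA) reading a C- or A-ending codon. A U-ending codon against
  A34 is the plain A:U pair and is classified watson_crick, keeping the
  classes exclusive.

Major tRNA genes are the copy-number argmax per amino acid (ties co-major);
pseudo-tRNAs are excluded from tallies by default and selenocysteine genes
(anticodon TCA) are flagged and kept out of the 18-amino-acid tallies.

## Domain versus non-domain Fop

Domain intervals (codon units, convertible from 1-based amino-acid CDD
coordinates with `cdd_to_codon_intervals()`) partition each gene's codons;
genes with no annotation, a domain spanning everything, or a domain
spanning everything but the start/stop codons are excluded. Fop, not Nc, is
the segment statistic — segments are routinely too short for Nc to be
defined. The category-level comparison is a paired t-test across genes
(each gene contributes one domain and one non-domain value); the published
protocol does not state its test beyond significance stars, and pairing is
the natural choice since the segments share a gene, but `paired = FALSE`
gives the Welch alternative.

## The synthetic genome generator

`synthetic_spec()` + `generate_genome()` produce FASTA, GFF3, tRNAscan-SE
output, domain tables and a ground-truth table, deterministically from a
seed. Per gene, codons arise in two stages:

1. **Mutation**: codons are drawn i.i.d. over the 61 sense codons with
   weight proportional to the product of per-base weights ($gc/2$ for G/C,
   $(1-gc)/2$ for A/T) under the gene's mutational GC parameter. Amino-acid
   composition and backbone GC therefore respond to mutation pressure
   together, which is what gives the neutrality plot its GC12 signal.
2. **Selection, then silent sites**: each codon of a degenerate family is
   replaced by the family's designated optimal codon with probability equal
   to the gene's selection intensity. Third positions of the *unselected*
   codons are then redrawn within each codon's synonymous box (same first
   two bases, same amino acid) with a GC target chosen so that the expected
   GC3 of the unselected portion equals the gene's realized GC12.

The stage-2 construction is deliberate: with a latent mutational parameter
and finite genes, regressing GC3 on GC12 suffers classical errors-in-
variables attenuation, so a "pure mutation" genome would sit detectably
below slope 1 at any realistic gene length. Conditioning the silent-site
target on the *realized* backbone GC makes the neutral relationship have
unit slope by construction, which is precisely the property a neutral
calibration scenario must have. Selection intensity then tilts GC3 above
the mutational expectation (high-bias genes gain GC3s relative to their
flanks and introns) and drives the slope toward zero — the two signatures
the diagnostics are meant to separate.

Default study conditions: 500 genes (simulation experiments in the tests
use 150–2000 as stated per experiment), gamma-distributed lengths with mean
400 codons (minimum 110, so everything passes the 300 bp filter), per-gene
mutational GC uniform on 0.30–0.85 (the span observed across red-algal
genomes), expression classes high/mid/low = 7%/86%/7% (the middle of the
5–10% stratification range) with intensities 0.45/0.15/0, a G/C-ending
designated optimal set (one codon per degenerate amino acid), stop
probabilities 0.6/0.2/0.2 for TAA/TAG/TGA, Poisson(1.5) introns of 60–300 bp
whose GC tracks coding GC with weight 0.8, intergenic spacers of
250–1200 bp at GC 0.45, and a tRNA complement mixing Watson–Crick
anticodons (two-fold families, Gly, Val) with A34 anticodons (other 4- and
6-fold families), plus an optional selenocysteine gene.

Three scenario choices in the tests deserve their rationale:

* **Neutral calibration of $\hat S$** uses a *constant* mutational GC of
  0.5 and the generator's designated optimal set. With a GC-asymmetric
  spectrum, the lowest-Nc genes are the most GC-extreme ones, so Nc-ranked
  categories correlate with composition and the pooled odds ratio inherits
  a bias that has nothing to do with selection — a real caveat of the
  statistic, worth knowing, but not a test of its calibration. Likewise,
  calling optimal codons on a neutral genome and then scoring their
  enrichment is winner's-curse-biased positive by construction, so the
  designated set is used.
* **The $\hat S$ gradient** uses the same symmetric spectrum with common
  seeds across intensity levels (common random numbers), isolating the
  selection signal.
* **The Table-1-like regime** for the $\hat S$ range check uses a per-genome
  mutational GC spread of 0.45–0.70 (GC3s SD ≈ 0.08, matching the
  within-species dispersion of real red-algal genomes, which is far
  narrower than the cross-species span) and high-class intensity 0.35;
  this lands $\hat S$ in the empirically observed 0.6–1.5 band.

What the generator does *not* emulate: codon autocorrelation along genes,
amino-acid composition driven by protein function, splice-site motifs,
UTRs, overlapping genes, assembly gaps, and annotation errors. Passing
tests therefore demonstrate correctness of the estimators under a
well-specified generative model, not robustness to every pathology of real
annotations.

## Numerical choices and degenerate inputs

* Nc is capped at 61; class means that are missing or non-positive give NA.
* CAI uses $\exp(\sum n_c \ln w_c / \sum n_c)$, stable for long genes.
* Boundary PR2 points (x or y exactly 0.5) count separately, in no quadrant.
* Genes with no synonymous codons get NA CAI/Fop/CBI; empty categories and
  single-value categories skip t-tests rather than erroring.
* A paired domain comparison with identically zero differences reports
  p = 1 (no effect), avoiding the undefined 0/0 t statistic.

## Reproducing the headline numbers

`scripts/acceptance.R` (repository root) regenerates the package's two
closed-form anchors from scratch — the Nc of a uniform-usage synthetic CDS
(61) and of a one-codon-per-amino-acid CDS (20) — and writes them as JSON.
The README shows a worked pipeline run on a generated genome with the
numbers it prints.

## Known limitations

Only the standard nuclear genetic code is supported; organellar genomes and
trans-spliced genes are out of scope. The longest-transcript rule keeps one
isoform per gene rather than merging evidence across isoforms. Flank
extraction treats gene-level intervals as hard neighbor bounds even where
UTRs are unannotated. The Nc estimator follows the canonical defaults, so
genomes dominated by very short genes will show more Nc-undefined flags
than CodonW variants that impute more aggressively.
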