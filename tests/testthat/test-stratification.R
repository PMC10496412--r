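test_that("bias categories take floor(p*N) genes from each Nc extreme", {
  m <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                      nc = seq(25, 61, length.out = 100))
  part <- assign_bias_categories(m, p = 0.05)
  expect_equal(unname(table(part$category)[c("high", "mid", "low")]),
               c(5L, 90L, 5L), ignore_attr = TRUE)
  # the high category holds the five lowest-Nc genes
  expect_setequal(part$gene_id[part$category == "high"], sprintf("g%03d", 1:5))
  expect_setequal(part$gene_id[part$category == "low"], sprintf("g%03d", 96:100))

  # 10% of 10021 genes: 1002 per extreme category (floor rule)
  m2 <- tibble::tibble(gene_id = sprintf("g%05d", 1:10021),
                       nc = stats::runif(10021, 20, 61))
  part2 <- assign_bias_categories(m2, p = 0.10)
  expect_equal(sum(part2$category == "high"), 1002L)
  expect_equal(sum(part2$category == "low"), 1002L)
})

test_that("ties and degenerate Nc vectors partition deterministically by id", {
  m <- tibble::tibble(gene_id = sprintf("g%02d", 10:1), nc = rep(50, 10))
  part <- assign_bias_categories(m, p = 0.2)
  expect_equal(sort(part$gene_id[part$category == "high"]), c("g01", "g02"))
  expect_true(isTRUE(attr(part, "degenerate")))
  # reruns are bit-identical
  expect_identical(part, assign_bias_categories(m, p = 0.2))
  # shuffling input order changes nothing
  part2 <- assign_bias_categories(m[sample(10), ], p = 0.2)
  expect_equal(part2[order(part2$gene_id), ]$category,
               part[order(part$gene_id), ]$category)
})

test_that("undefined-Nc genes are excluded and tiny categories error", {
  m <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                      nc = c(30, NA, 50, 60))
  part <- assign_bias_categories(m, p = 0.34)
  expect_equal(attr(part, "excluded"), "b")
  expect_equal(nrow(part), 3)
  expect_error(assign_bias_categories(m, p = 0.05), "category empty")
})

test_that("optimal codons require delta RSCU strictly above the threshold", {
  high <- zero_counts(); low <- zero_counts()
  # Ala: GCC enriched in high (delta 0.5); Gly engineered to exactly 0.08
  high[c("GCC", "GCA", "GCG", "GCT")] <- c(50, 20, 15, 15)  # RSCU GCC = 2.0
  low[c("GCC", "GCA", "GCG", "GCT")] <- c(37.5, 25, 20, 17.5)  # RSCU GCC = 1.5
  high[c("GGA", "GGC")] <- c(52, 48)
  low[c("GGA", "GGC")] <- c(54, 46)  # delta RSCU(GGC) = 4*(0.48 - 0.46) = 0.08
  opt <- identify_optimal_codons(high, low)
  expect_true(opt$optimal[opt$codon == "GCC"])
  expect_equal(opt$delta_rscu[opt$codon == "GCC"], 0.5, tolerance = 1e-12)
  # exactly at the threshold is not optimal (strict >)
  expect_equal(opt$delta_rscu[opt$codon == "GGC"], 0.08, tolerance = 1e-12)
  expect_false(opt$optimal[opt$codon == "GGC"])
  # families absent from either pool are skipped, not called
  expect_true("TTT" %in% attr(opt, "skipped"))
  expect_false(any(opt$optimal[opt$amino_acid == "F"]))
})

test_that("strict mode additionally requires RSCU_high > 1", {
  high <- zero_counts(); low <- zero_counts()
  high[c("GCC", "GCA", "GCG", "GCT")] <- c(20, 30, 30, 20)  # RSCU GCC = 0.8
  low[c("GCC", "GCA", "GCG", "GCT")] <- c(10, 35, 35, 20)   # RSCU GCC = 0.4
  expect_true(identify_optimal_codons(high, low)$optimal[
    identify_optimal_codons(high, low)$codon == "GCC"])
  strict <- identify_optimal_codons(high, low, strict = TRUE)
  expect_false(strict$optimal[strict$codon == "GCC"])
})

test_that("a designated optimal set is recovered from a selected genome", {
  sp <- synthetic_spec(seed = 55, n_genes = 400,
                       intensities = c(high = 0.9, mid = 0.1, low = 0))
  sim <- simulate_cds(sp)
  m <- codon_metrics(sim)
  part <- assign_bias_categories(m, p = 0.07)
  hi <- pool_counts(sim, part$gene_id[part$category == "high"])
  lo <- pool_counts(sim, part$gene_id[part$category == "low"])
  opt <- identify_optimal_codons(hi, lo)
  expect_setequal(opt$codon[opt$optimal], unname(sp$optimal_codons))
})

test_that("stop codon usage reports modal and tied stops", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    cds = vapply(c(rep("TAA", 7), rep("TAG", 2), "TGA"),
                 function(s) make_cds(rep("GCT", 34), stop = s), "",
                 USE.NAMES = FALSE)
  )
  su <- stop_codon_usage(genes)
  expect_equal(su$n[su$codon == "TAA"], 7L)
  expect_equal(su$freq[su$codon == "TAA"], 0.7)
  expect_equal(su$codon[su$modal], "TAA")

  genes2 <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    cds = vapply(c(rep("TAA", 4), rep("TGA", 4), rep("TAG", 2)),
                 function(s) make_cds(rep("GCT", 34), stop = s), "",
                 USE.NAMES = FALSE)
  )
  su2 <- stop_codon_usage(genes2)
  expect_setequal(su2$codon[su2$modal], c("TAA", "TGA"))
})

test_that("simulated stop preference lands within its binomial interval", {
  sp <- synthetic_spec(seed = 77, n_genes = 300,
                       stop_probs = c(TAA = 0.6, TAG = 0.2, TGA = 0.2))
  sim <- simulate_cds(sp)
  su <- stop_codon_usage(sim)
  f <- su$freq[su$codon == "TAA"]
  expect_equal(su$codon[su$modal], "TAA")
  ci <- 0.6 + c(-4, 4) * sqrt(0.6 * 0.4 / 300)
  expect_gt(f, ci[1]); expect_lt(f, ci[2])
})

test_that("category GC comparisons test what they can and skip what they cannot", {
  part <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:60),
    nc = c(stats::runif(20, 25, 35), stats::runif(20, 45, 55),
           stats::runif(20, 57, 61)),
    category = factor(rep(c("high", "mid", "low"), each = 20),
                      levels = c("high", "mid", "low"))
  )
  # identical distributions: difference ~ 0, p not small
  withr::with_seed(9, {
    vals <- tibble::tibble(gene_id = part$gene_id,
                           gc3s = rep(seq(0.4, 0.6, length.out = 20), 3))
    out <- category_gc_comparison(part, vals)
    expect_true(all(out$tests$p > 0.9))
    expect_equal(out$summary$mean[1], out$summary$mean[2])
  })
  # a category with one intron value skips that test
  vals2 <- tibble::tibble(
    gene_id = part$gene_id,
    intron_gc = c(rep(NA, 19), 0.5, stats::runif(20, 0.4, 0.6),
                  stats::runif(20, 0.3, 0.5))
  )
  out2 <- category_gc_comparison(part, vals2)
  expect_true(out2$tests$skipped[out2$tests$comparison == "high_vs_mid"])
  expect_false(out2$tests$skipped[out2$tests$comparison == "mid_vs_low"])
})

test_that("a designed GC3s gradient is significant at alpha 0.001", {
  sp <- synthetic_spec(seed = 88, n_genes = 400)
  sim <- simulate_cds(sp)
  m <- codon_metrics(sim)
  part <- assign_bias_categories(m, p = 0.07)
  out <- category_gc_comparison(part, m[, c("gene_id", "gc3s")])
  expect_true(all(out$tests$p < 0.001))
  s <- out$summary
  expect_gt(s$mean[s$category == "high"], s$mean[s$category == "mid"])
  expect_gt(s$mean[s$category == "mid"], s$mean[s$category == "low"])
})

test_that("raising p weakly grows the extreme categories", {
  m <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                      nc = stats::runif(200, 20, 61))
  sizes <- vapply(c(0.05, 0.1, 0.2), function(p) {
    sum(assign_bias_categories(m, p)$category != "mid")
  }, 1)
  expect_true(all(diff(sizes) >= 0))
})
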