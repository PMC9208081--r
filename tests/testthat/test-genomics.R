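test_that("VCF loading normalizes chromosome prefixes and deduplicates", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(data.frame(
    chrom = c("chr7", "7", "7"), pos = c(140453136, 140453136, 140453136),
    ref = "A", alt = "T",
    info = "GENE=BRAF;CLASS=missense;PCHANGE=V600E;VAF=0.42"), vcf)
  calls <- load_variants(vcf)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom, "7")
  expect_equal(calls$gene, "BRAF")
  expect_equal(calls$vaf, 0.42)
  expect_equal(calls$effect, "nonsilent")

  empty <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(data.frame(chrom = character(0), pos = integer(0),
                            ref = character(0), alt = character(0)), empty)
  expect_equal(nrow(load_variants(empty)), 0)
})

test_that("variant normalization trims alleles and classifies types", {
  raw <- data.frame(chrom = c("chr7", "12"), pos = c(100, 25398284),
                    ref = c("ATG", "C"), alt = c("ATA", "T"))
  norm <- normalize_variants(raw)
  expect_equal(norm$pos, c(102L, 25398284L))
  expect_equal(norm$ref, c("G", "C"))
  expect_equal(norm$type, c("SNV", "SNV"))
  indel <- normalize_variants(data.frame(chrom = "1", pos = 10,
                                         ref = "CTT", alt = "CT"))
  expect_equal(indel$type, "indel")
  expect_equal(indel$ref, "CT")  # shared suffix trimmed first
  expect_error(normalize_variants(data.frame(chrom = "1", pos = 1,
                                             ref = "A", alt = "A")),
               "identical")
})

test_that("concordance follows set arithmetic on the union", {
  mk <- function(keys) data.frame(chrom = "1", pos = keys, ref = "A", alt = "T")
  a <- normalize_variants(mk(1:10))
  expect_equal(concordance(a, a)$overall_pct, 100)
  b <- normalize_variants(mk(11:20))
  expect_equal(concordance(a, b)$overall_pct, 0)
  c5 <- normalize_variants(mk(6:15))  # |A| = |B| = 10, |shared| = 5
  cc <- concordance(a, c5)
  expect_equal(cc$overall_pct, 100 * 5 / 15, tolerance = 1e-10)
  expect_equal(cc$n_shared, 5)
  expect_equal(sum(cc$proportions), 100)
  # symmetry
  expect_equal(concordance(c5, a)$overall_pct, cc$overall_pct)
  # tissue-denominator mode
  expect_equal(concordance(a, c5, denominator = "tissue")$overall_pct, 50)
  expect_error(concordance(a[0, ], b[0, ]), "empty")
})

test_that("mutation burden applies the strict >10 per Mb hypermutation rule", {
  mk_calls <- function(n) data.frame(effect = rep("nonsilent", n))
  r1 <- mutation_rate(mk_calls(100), callable_mb = 40)
  expect_equal(r1$rate_per_mb, 2.5)
  expect_false(r1$hypermutated)
  r2 <- mutation_rate(mk_calls(500), callable_mb = 40)
  expect_equal(r2$rate_per_mb, 12.5)
  expect_true(r2$hypermutated)
  r3 <- mutation_rate(mk_calls(400), callable_mb = 40)
  expect_equal(r3$rate_per_mb, 10.0)
  expect_false(r3$hypermutated)  # strict inequality at the boundary
  expect_error(mutation_rate(mk_calls(10), callable_mb = 0), "positive")
})

test_that("genotype flags implement the hotspot and LoF rules with evidence", {
  kras <- data.frame(chrom = "12", pos = 25398284, ref = "C", alt = "T",
                     gene = "KRAS", class = "missense",
                     protein_change = "G12D", vaf = 0.35)
  f <- genotype_flags(kras)
  expect_true(f$anti_egfr_resistant)
  expect_false(f$rnf43_lof)
  expect_equal(f$evidence$protein_change, "G12D")

  none <- genotype_flags(kras[0, ])
  expect_false(none$anti_egfr_resistant || none$rnf43_lof || none$apc_truncating)

  both <- data.frame(chrom = c("17", "5"), pos = c(56435161, 112175240),
                     ref = c("CG", "T"), alt = c("C", "A"),
                     gene = c("RNF43", "APC"),
                     class = c("frameshift", "nonsense"),
                     protein_change = c("G532fs", "Y1447*"),
                     vaf = c(0.90, 0.05))
  fb <- genotype_flags(both)
  expect_true(fb$rnf43_lof)
  expect_true(fb$apc_truncating)
  expect_equal(nrow(fb$evidence), 2)
  expect_equal(fb$evidence$vaf[fb$evidence$gene == "RNF43"], 0.90)

  # non-hotspot codon or silent class does not flag
  silent <- data.frame(gene = "KRAS", class = "silent", protein_change = "G12G")
  expect_false(genotype_flags(silent)$anti_egfr_resistant)
  braf <- data.frame(gene = c("BRAF", "PIK3CA"), class = "missense",
                     protein_change = c("V600E", "E545K"))
  expect_true(genotype_flags(braf)$anti_egfr_resistant)
})

test_that("cetuximab AUC separates by hotspot genotype in simulation", {
  co <- simulate_cohort(sim_config(seed = 19))
  cv <- fit_cohort(co$viability, fit = FALSE)
  res <- compare_auc_by_genotype(cv, co$genotype, "cetuximab")
  expect_gt(res$median_flagged, res$median_unflagged)
  expect_true(res$p.value >= 0 && res$p.value <= 1)
  # identical groups sit at the null center
  cvs <- cv[cv$drug == "cetuximab", ][1:6, ]
  cvs$auc_norm <- rep(c(0.5, 0.7, 0.9), 2)
  flags <- data.frame(organoid = cvs$organoid,
                      anti_egfr_resistant = rep(c(TRUE, FALSE), each = 3))
  same <- compare_auc_by_genotype(cvs, flags, "cetuximab")
  expect_equal(same$p.value, 1)
})
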