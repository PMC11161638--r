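mini_guide <- function(start0, strand, chrom = "chr1") {
  data.frame(guide_id = paste0("g", start0, strand), gene = "geneX",
             chrom = chrom, start0 = start0, end0 = start0 + 23L,
             strand = strand, protospacer = strrep("A", 20), pam = "AGG",
             stringsAsFactors = FALSE)
}

mini_genotypes <- function(pos0, dosages, chrom = "chr1") {
  variants <- data.frame(id = paste0("v", seq_along(pos0)), chrom = chrom,
                         start0 = as.integer(pos0), ref = "A", alt = "C",
                         stringsAsFactors = FALSE)
  dosage <- matrix(dosages, ncol = length(pos0),
                   dimnames = list(paste0("S", seq_len(length(dosages) /
                                                         length(pos0))),
                                   variants$id))
  structure(list(variants = variants, dosage = dosage,
                 samples = rownames(dosage)),
            class = "variant_genotypes")
}

test_that("targeting intervals span 23 bp and malformed guides fail", {
  g <- mini_guide(999980L, "+")
  iv <- targeting_interval(g)
  expect_equal(iv$start0, 999980L)
  expect_equal(iv$end0, 1000003L)
  g2 <- mini_guide(99L, "-")
  expect_equal(targeting_interval(g2)$end0, 122L)
  bad <- g; bad$protospacer <- strrep("A", 19)
  expect_error(targeting_interval(bad), "20 nt")
  bad2 <- g; bad2$pam <- "AGT"
  expect_error(targeting_interval(bad2), "NGG")
})

test_that("position-from-PAM arithmetic matches the stated conventions", {
  # '+' guide [980, 1003), PAM N at 1000; het SNV at 999 -> position 1
  g <- mini_guide(980L, "+")
  gt <- mini_genotypes(c(999L, 1000L, 1001L, 1002L, 980L), rep(1L, 5))
  mm <- map_variants_to_guides(gt, g)
  expect_equal(mm$position_from_pam[mm$pos0 == 999], 1L)
  expect_equal(mm$position_from_pam[mm$pos0 == 1000], 0L)   # PAM N
  expect_equal(mm$position_from_pam[mm$pos0 == 1001], -1L)  # PAM G
  expect_equal(mm$position_from_pam[mm$pos0 == 1002], -2L)  # PAM G
  expect_equal(mm$position_from_pam[mm$pos0 == 980], 20L)   # PAM-distal
  expect_true(all(mm$zygosity == "het"))

  # '-' guide with PAM at [99, 102): interval [99, 122), protospacer
  # [102, 122). The base at 121 is the protospacer's 5' end, i.e. the
  # PAM-distal position 20 (confirmed by the sequence-reconstruction oracle).
  gm <- mini_guide(99L, "-")
  gtm <- mini_genotypes(c(121L, 101L, 100L, 99L, 102L), rep(2L, 5))
  mmm <- map_variants_to_guides(gtm, gm)
  expect_equal(mmm$position_from_pam[mmm$pos0 == 121], 20L)
  expect_equal(mmm$position_from_pam[mmm$pos0 == 101], 0L)
  expect_equal(mmm$position_from_pam[mmm$pos0 == 100], -1L)
  expect_equal(mmm$position_from_pam[mmm$pos0 == 99], -2L)
  expect_equal(mmm$position_from_pam[mmm$pos0 == 102], 1L)
  expect_true(all(mmm$zygosity == "hom"))
})

test_that("homozygous-reference samples produce no record", {
  g <- mini_guide(100L, "+")
  gt <- mini_genotypes(110L, c(0L, 1L, 2L))  # 3 samples, one variant
  mm <- map_variants_to_guides(gt, g)
  expect_equal(sort(mm$sample), c("S2", "S3"))
  expect_setequal(mm$zygosity, c("het", "hom"))
})

test_that("mapping agrees with the sequence-reconstruction oracle", {
  ref <- random_reference(c(chr1 = 30000L, chr2 = 20000L), seed = 51)
  rg <- reference_guide_library(ref, n_guides = 120, seed = 52)
  gt <- random_snvs(rg$reference, n_variants = 1500, n_samples = 4,
                    seed = 53)
  mm <- map_variants_to_guides(gt, rg$library)
  oracle <- oracle_map_variants(gt, rg$library, rg$reference)
  got <- as.data.frame(mm)[order(mm$guide_id, mm$sample, mm$variant_id),
                           c("guide_id", "sample", "variant_id",
                             "position_from_pam", "zygosity")]
  rownames(got) <- NULL; rownames(oracle) <- NULL
  expect_equal(got, oracle)
})

test_that("mapping errors when chromosome naming is inconsistent", {
  g <- mini_guide(100L, "+")
  gt <- mini_genotypes(110L, 1L, chrom = "1")
  expect_error(map_variants_to_guides(gt, g), "chromosome")
})

test_that("affected fractions, recurrent guides and histograms match brute
           force", {
  co <- dense_cohort(seed = 61)
  mm <- co$screen$mismatches
  lib <- co$library
  expect_gt(nrow(mm), 50)
  fr <- per_sample_affected_fraction(mm, lib,
                                     samples = co$genotypes$samples)
  mm_no_n <- mm[mm$position_from_pam != 0, ]
  for (s in co$genotypes$samples[1:5]) {
    expect_equal(unname(fr[s]),
                 length(unique(mm_no_n$guide_id[mm_no_n$sample == s])) /
                   nrow(lib))
  }
  expect_true(all(fr >= 0 & fr <= 1))
  # monotone under adding variants: PAM-N inclusion can only increase it
  fr_all <- per_sample_affected_fraction(mm, lib,
                                         samples = co$genotypes$samples,
                                         include_pam_n = TRUE)
  expect_true(all(fr_all >= fr))

  # recurrent guides equal a direct tally
  k <- 3
  got <- guides_affected_in_k_samples(mm, k)
  tally <- tapply(mm_no_n$sample, mm_no_n$guide_id,
                  function(x) length(unique(x)))
  expect_setequal(got, names(tally)[tally >= k])
  expect_setequal(guides_affected_in_k_samples(mm, 1),
                  unique(mm_no_n$guide_id))

  # histogram conserves the gene count
  h <- per_gene_affected_guide_histogram(mm, lib)
  expect_equal(sum(h), length(unique(lib$gene)))
  expect_equal(names(h), as.character(0:4))
  h_empty <- per_gene_affected_guide_histogram(mm[0, ], lib)
  expect_equal(unname(h_empty["0"]), length(unique(lib$gene)))
})

test_that("depletion test flags protective shifts and degenerate input", {
  set.seed(62)
  lfc <- setNames(c(rnorm(50, -1, 0.2), rnorm(50, 0, 0.2)),
                  sprintf("S%03d", 1:100))
  present <- names(lfc)[51:100]
  out <- guide_variant_depletion_test(lfc, present)
  expect_lt(out$p, 1e-6)
  expect_true(out$protective)
  expect_equal(out$effect, mean(lfc[51:100]) - mean(lfc[1:50]))
  # identical distributions: no signal
  out0 <- guide_variant_depletion_test(lfc, sample(names(lfc), 50))
  expect_gt(out0$p, 1e-4)
  # constant LFC: zero variance, missing p
  outc <- guide_variant_depletion_test(setNames(rep(1, 10), paste0("S", 1:10)),
                                       paste0("S", 1:5))
  expect_true(is.na(outc$p))
  # class too small
  expect_true(is.na(guide_variant_depletion_test(lfc, present[1])$p))
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  # diagonal table: two-sided p = 2/choose(10,5)
  d <- c(rep(1, 5), rep(-1, 5) * 0)
  out <- snp_guide_enrichment(depletion_diff = c(rep(1, 5), rep(0, 5)),
                              has_snp = c(rep(TRUE, 5), rep(FALSE, 5)),
                              threshold = 0.5)
  expect_equal(out$p, 2 / choose(10, 5))
  expect_equal(out$p, oracle_fisher_p(matrix(c(5, 0, 0, 5), 2)))
  # balanced table: no association
  out1 <- snp_guide_enrichment(
    depletion_diff = rep(c(1, 0), 20),
    has_snp = rep(c(TRUE, TRUE, FALSE, FALSE), 10), threshold = 0.5)
  expect_equal(out1$p, 1)
  expect_equal(unname(out1$table[1, 1]), 10)
  # symmetry: swapping rows and columns together preserves p
  out2 <- snp_guide_enrichment(
    depletion_diff = 1 - rep(c(1, 0), 20),
    has_snp = !rep(c(TRUE, TRUE, FALSE, FALSE), 10), threshold = 0.5)
  expect_equal(out1$p, out2$p)
})

test_that("strand flip leaves the affected-guide set unchanged", {
  co <- dense_cohort(seed = 63)
  lib <- co$library
  flipped <- lib
  flipped$strand <- ifelse(lib$strand == "+", "-", "+")
  mm1 <- map_variants_to_guides(co$genotypes, lib)
  mm2 <- map_variants_to_guides(co$genotypes, flipped)
  key1 <- unique(paste(mm1$guide_id, mm1$sample, mm1$variant_id))
  key2 <- unique(paste(mm2$guide_id, mm2$sample, mm2$variant_id))
  expect_setequal(key1, key2)
})

test_that("positional effects recover an injected gradient", {
  w <- seq(1, 0.05, length.out = 20)
  art <- data.frame(gene = 1:20, guide = 1, position = 1:20, effect = -2)
  cfg <- sim_config(n_samples = 80, n_genes = 30,
                    n_variants_per_chrom = 300, n_chromosomes = 2,
                    cm_per_chrom = 15, artifacts = art,
                    artifact_freqs = c(0.3, 0.3), positional_weights = w,
                    noise_sd = 0.4, seed = 64)
  co <- simulate_cohort(cfg)
  mm <- co$screen$mismatches
  pe <- positional_effects(mm[mm$position_from_pam >= 1, ],
                           co$screen$guide_lfc)
  pe20 <- pe[pe$position %in% 1:20, ]
  expect_gt(nrow(pe20), 15)
  expect_gt(cor(pe20$effect, w[pe20$position], method = "spearman"), 0.7)
  # PAM-proximal effect strictly larger than PAM-distal
  expect_gt(pe20$effect[pe20$position == 1],
            pe20$effect[pe20$position == max(pe20$position)])
  expect_true(all(c("p_t", "p_wilcoxon") %in% names(pe)))
})

test_that("burden ratio reflects group medians", {
  fr <- setNames(c(0.2, 0.4, 0.1, 0.2), paste0("S", 1:4))
  lab <- setNames(c("AFR", "AFR", "EUR", "EUR"), names(fr))
  expect_equal(afr_burden_ratio(fr, lab), 0.3 / 0.15)
  expect_equal(afr_burden_ratio(setNames(rep(0.1, 4), names(fr)), lab), 1)
  expect_true(is.na(afr_burden_ratio(fr, setNames(rep("EUR", 4),
                                                  names(fr)))))
})
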