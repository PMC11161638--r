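test_that("config validation rejects bad inputs", {
  expect_error(sim_config(n_populations = 1), "n_populations")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fst = NaN), "fst")
  expect_error(sim_config(positional_weights = rep(0.5, 19)),
               "positional_weights")
  expect_error(sim_config(n_samples = 0), "counts")
  expect_error(sim_config(admixture_proportions =
                            matrix(c(0.7, 0.7), 1, 2), n_samples = 1),
               "sum to 1")
})

test_that("panel frequencies follow the Balding-Nichols construction", {
  # zero-divergence limit: population frequencies equal the ancestral ones
  cfg0 <- sim_config(fst = 0, n_variants_per_chrom = 200, n_chromosomes = 1)
  p0 <- simulate_panel(cfg0)
  expect_equal(unname(p0$freq[, 1]),
               pmin(pmax(p0$ancestral, 0.001), 0.999))
  expect_equal(unname(p0$freq[, 1]), unname(p0$freq[, 2]))

  # law of large numbers: per-population mean ~ ancestral mean
  cfg <- sim_config(fst = 0.1, n_variants_per_chrom = 10000,
                    n_chromosomes = 1, cm_per_chrom = 50)
  p <- simulate_panel(cfg)
  # Beta(p(1-F)/F,...) has mean p and variance F p(1-p) <= F/4
  se <- sqrt(0.1 / 4 / 10000) + sd(p$ancestral) / sqrt(10000)
  for (k in 1:2) {
    expect_lt(abs(mean(p$freq[, k]) - mean(p$ancestral)), 3 * se + 0.002)
  }
  expect_true(all(p$freq >= 0.001 & p$freq <= 0.999))
})

test_that("admixed genomes respect degenerate and balanced mixtures", {
  n <- 6
  admix <- matrix(rep(c(1, 0), each = n), n, 2)  # everyone pure population 1
  cfg <- sim_config(n_samples = n, n_variants_per_chrom = 400,
                    n_chromosomes = 1, cm_per_chrom = 4,
                    admixture_proportions = admix, seed = 9)
  panel <- simulate_panel(cfg)
  map <- uniform_genetic_map(c(chr1 = 4e6))
  gen <- simulate_admixed_genomes(panel, map, cfg)
  pop1 <- cfg$population_labels[1]
  expect_true(all(gen$truth$hap1 == pop1))
  expect_true(all(gen$truth$hap2 == pop1))
  # empirical allele frequencies track population-1 panel frequencies
  emp <- colMeans(gen$genotypes$dosage) / 2
  f <- panel$freq[, 1]
  se <- sqrt(f * (1 - f) / (2 * n))
  expect_gt(mean(abs(emp - f) <= 3 * se + 1e-9), 0.95)

  # 50/50 admixture: genome-wide painted fraction of population 1 near 0.5.
  # Windows are correlated within ancestry blocks, so the binomial SE uses
  # the effective number of independent blocks, not windows.
  admix50 <- matrix(0.5, 20, 2)
  cfg2 <- sim_config(n_samples = 20, n_variants_per_chrom = 500,
                     n_chromosomes = 2, cm_per_chrom = 50,
                     admixture_proportions = admix50, seed = 10)
  panel2 <- simulate_panel(cfg2)
  map2 <- uniform_genetic_map(c(chr1 = 5e7, chr2 = 5e7))
  gen2 <- simulate_admixed_genomes(panel2, map2, cfg2)
  frac <- mean(cbind(gen2$truth$hap1, gen2$truth$hap2) ==
                 cfg2$population_labels[1])
  n_blocks <- 20 * 2 * 2 * (50 * cfg2$block_rate_per_cm + 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_blocks))
})

test_that("the generator is deterministic in the seed", {
  cfg <- sim_config(n_samples = 8, n_genes = 5, n_variants_per_chrom = 100,
                    n_chromosomes = 1, cm_per_chrom = 5, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$screen$guide_lfc, b$screen$guide_lfc)
  expect_identical(a$truth$hap1, b$truth$hap1)
  c <- simulate_cohort(sim_config(n_samples = 8, n_genes = 5,
                                  n_variants_per_chrom = 100,
                                  n_chromosomes = 1, cm_per_chrom = 5,
                                  seed = 78))
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
})

test_that("guide library has the declared shape and conventions", {
  cfg <- sim_config(n_genes = 50, guides_per_gene = 4, n_chromosomes = 2,
                    cm_per_chrom = 20)
  map <- uniform_genetic_map(c(chr1 = 2e7, chr2 = 2e7))
  lib <- simulate_guide_library(cfg, map)
  expect_equal(nrow(lib$library), 200)
  expect_true(all(table(lib$library$gene) == 4))
  expect_true(all(lib$library$end0 - lib$library$start0 == 23))
  expect_true(all(nchar(lib$library$protospacer) == 20))
  expect_true(all(substr(lib$library$pam, 2, 3) == "GG"))
  expect_setequal(unique(lib$library$strand), c("+", "-"))
  expect_equal(anyDuplicated(lib$tss$tss0[lib$tss$chrom == "chr1"]), 0)
  # too many genes for the genome
  expect_error(simulate_guide_library(
    sim_config(n_genes = 5000, n_chromosomes = 1, cm_per_chrom = 1),
    uniform_genetic_map(c(chr1 = 1e6))), "overlap")
})

test_that("screen attenuation follows the positional-weight model", {
  # one artifact with w = 0.5 at its position, het carriers at factor 1:
  # activity 0.5, so mean LFC over many cells is about half the effect
  w <- rep(0.5, 20)
  art <- data.frame(gene = 1, guide = 1, position = 5, effect = -2)
  cfg <- sim_config(n_samples = 400, n_genes = 4, n_variants_per_chrom = 200,
                    n_chromosomes = 1, cm_per_chrom = 10,
                    positional_weights = w, artifacts = art,
                    artifact_freqs = c(0.999, 0.999),  # everyone carries it
                    noise_sd = 0.3, lineage_effect_sd = 0, seed = 4)
  co <- simulate_cohort(cfg)
  gid <- co$truth$causal_artifact_table$guide_id[1]
  carriers <- unique(co$screen$mismatches$sample[
    co$screen$mismatches$guide_id == gid])
  expect_gt(length(carriers), 350)
  m <- mean(co$screen$guide_lfc[carriers, gid])
  se <- 0.3 / sqrt(length(carriers))
  expect_lt(abs(m - (-2 * 0.5)), 3 * se + 0.02)
  # a clean guide of the same gene keeps the full effect
  clean <- setdiff(co$library$guide_id[co$library$gene == "gene001"], gid)
  clean <- clean[!clean %in% co$screen$mismatches$guide_id]
  expect_gt(length(clean), 0)
  m2 <- mean(co$screen$guide_lfc[, clean[1]])
  expect_lt(abs(m2 - (-2)), 3 * 0.3 / sqrt(400) + 0.02)
})

test_that("screen null: no injected effects gives zero-centred guide means", {
  cfg <- sim_config(n_samples = 300, n_genes = 10,
                    n_variants_per_chrom = 50, n_chromosomes = 1,
                    cm_per_chrom = 10, gene_effect_mean = 0,
                    gene_effect_sd = 0, lineage_effect_sd = 0,
                    noise_sd = 1, seed = 6)
  co <- simulate_cohort(cfg)
  means <- colMeans(co$screen$guide_lfc)
  se <- 1 / sqrt(300)
  expect_gt(mean(abs(means) < 3 * se), 0.95)
})

test_that("painting consistency: regenerating alleles from the recorded
           painting reproduces the dosage distribution", {
  cfg <- sim_config(n_samples = 12, n_variants_per_chrom = 600,
                    n_chromosomes = 1, cm_per_chrom = 6, seed = 21)
  panel <- simulate_panel(cfg)
  map <- uniform_genetic_map(c(chr1 = 6e6))
  gen <- simulate_admixed_genomes(panel, map, cfg)
  w <- gen$windows
  pops <- cfg$population_labels
  # per sample, expected dosage from the recorded painting
  for (i in c(1, 7)) {
    win_of_var <- rep(NA_integer_, nrow(panel$variants))
    for (k in seq_len(nrow(w))) {
      if (!is.na(w$first_variant[k]))
        win_of_var[w$first_variant[k]:w$last_variant[k]] <- k
    }
    f1 <- panel$freq[cbind(seq_len(nrow(panel$variants)),
                           match(gen$truth$hap1[i, win_of_var], pops))]
    f2 <- panel$freq[cbind(seq_len(nrow(panel$variants)),
                           match(gen$truth$hap2[i, win_of_var], pops))]
    expected <- f1 + f2
    obs <- gen$genotypes$dosage[i, ]
    # aggregate check: total dosage within 3 SE of its painting expectation
    se <- sqrt(sum(f1 * (1 - f1) + f2 * (1 - f2)))
    expect_lt(abs(sum(obs) - sum(expected)), 3 * se)
  }
})

test_that("artifact injection places a differential variant in the guide", {
  art <- data.frame(gene = 2, guide = 3, position = 7, effect = -1.5)
  cfg <- sim_config(n_samples = 10, n_genes = 5, n_variants_per_chrom = 300,
                    n_chromosomes = 1, cm_per_chrom = 10, artifacts = art,
                    seed = 13)
  co <- simulate_cohort(cfg)
  tab <- co$truth$causal_artifact_table
  expect_equal(nrow(tab), 1)
  vrow <- co$panel$variants[co$panel$variants$id == tab$variant_id, ]
  grow <- co$library[co$library$guide_id == tab$guide_id, ]
  expect_true(vrow$start0 >= grow$start0 && vrow$start0 < grow$end0)
  expect_equal(unname(co$panel$freq[tab$variant_id, ]),
               cfg$artifact_freqs)
  # the mapper reports it at the injected position for carriers
  mm <- co$screen$mismatches
  rec <- mm[mm$variant_id == tab$variant_id & mm$guide_id == tab$guide_id, ]
  expect_true(all(rec$position_from_pam == 7))
})
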