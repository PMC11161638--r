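fake_genotypes <- function(dosage) {
  n_var <- ncol(dosage)
  variants <- data.frame(id = colnames(dosage), chrom = "chr1",
                         start0 = seq_len(n_var) * 100L, ref = "A",
                         alt = "G", stringsAsFactors = FALSE)
  structure(list(variants = variants, dosage = dosage,
                 samples = rownames(dosage)),
            class = "variant_genotypes")
}

test_that("MAF filtering applies a strict 1% floor", {
  n <- 200
  dosage <- cbind(
    rare = c(rep(1L, 2), rep(0L, n - 2)),        # f = 0.005 -> removed
    common = rep(c(0L, 2L), n / 2),              # f = 0.5  -> kept
    flipped = c(1L, rep(2L, n - 1)))             # f = 0.9975 -> removed
  rownames(dosage) <- sprintf("S%03d", 1:n)
  g <- fake_genotypes(dosage)
  out <- filter_by_maf(g, 0.01)
  expect_equal(out$variants$id, "common")
  # brute-force recount
  f <- colMeans(dosage) / 2
  expect_equal(sum(pmin(f, 1 - f) > 0.01), ncol(out$dosage))
  expect_warning(filter_by_maf(fake_genotypes(dosage[, 1, drop = FALSE])),
                 "no variants")
})

test_that("BH and BY q-values match the direct step-up formulas", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  expect_equal(oracle_bh(p), rep(0.04, 4))
  h4 <- 1 + 1 / 2 + 1 / 3 + 1 / 4
  expect_equal(p.adjust(p, "BY"), rep(0.04 * h4, 4))
  expect_equal(oracle_by(p), rep(0.04 * h4, 4))
  expect_equal(0.04 * h4, 0.0833333333, tolerance = 1e-6)
  set.seed(11)
  for (i in 1:50) {
    pv <- runif(sample(2:50, 1))
    expect_equal(p.adjust(pv, "BH"), oracle_bh(pv))
    expect_equal(p.adjust(pv, "BY"), oracle_by(pv))
    expect_true(all(p.adjust(pv, "BY") >= p.adjust(pv, "BH") - 1e-12))
    expect_true(all(p.adjust(pv, "BH") >= pv - 1e-12))
  }
})

test_that("a perfectly collinear dosage gives the fitted slope and tiny p", {
  n <- 30
  dosage <- matrix(rep(0:2, each = 10), n, 1,
                   dimnames = list(sprintf("S%02d", 1:n), "v1"))
  dep <- setNames(-0.7 * dosage[, 1], rownames(dosage))
  res <- dqtl_scan(dep, fake_genotypes(dosage), rep("only", n))
  expect_equal(res$beta, -0.7, tolerance = 1e-10)
  expect_lt(res$p, 1e-20)
  expect_true(res$significant)
})

test_that("the scan matches per-variant lm fits and controls the null", {
  set.seed(12)
  n <- 80
  dosage <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
                   dimnames = list(sprintf("S%02d", 1:n), paste0("v", 1:20)))
  lineage <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  dep <- setNames(rnorm(n) + 0.5 * dosage[, 3], rownames(dosage))
  res <- dqtl_scan(dep, fake_genotypes(dosage), lineage)
  for (j in c(1, 3, 9)) {
    fit <- summary(lm(dep ~ dosage[, j] + lineage))$coefficients
    expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-9)
    expect_equal(res$p[j], fit[2, 4], tolerance = 1e-9)
  }
  expect_true(all(res$q >= res$q_bh - 1e-12))
  expect_true(all(res$q_bh >= res$p - 1e-12))

  # permuted dosages: significant count is 0 in nearly all null runs
  hits <- vapply(1:60, function(i) {
    dep_null <- setNames(rnorm(n), rownames(dosage))
    sum(dqtl_scan(dep_null, fake_genotypes(dosage), lineage)$significant)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("marker selection takes lowest q, then p, then genomic order", {
  res <- data.frame(variant_id = c("a", "b", "c", "d"),
                    chrom = "chr1", pos0 = c(400L, 100L, 300L, 200L),
                    beta = 1, p = c(0.02, 0.001, 0.001, 0.005),
                    q_bh = 0.01, q = c(0.04, 0.01, 0.01, 0.02),
                    significant = c(TRUE, TRUE, TRUE, TRUE))
  mk <- select_marker(res)
  expect_equal(mk$variant_id, "b")  # q tie with c, p tie, earlier position
  # brute-force argmin check
  ord <- order(res$q, res$p, res$pos0)
  expect_equal(mk$variant_id, res$variant_id[ord[1]])
  res$significant <- FALSE
  expect_null(select_marker(res))
  expect_equal(select_marker(res, require_significant = FALSE)$variant_id,
               "b")
})

test_that("per-group frequencies and the 0.2 differential rule", {
  dosage <- setNames(c(2L, 2L, 1L, 0L, 0L, 0L), sprintf("S%d", 1:6))
  labels <- setNames(c("AFR", "AFR", "AFR", "EUR", "EUR", "EUR"),
                     names(dosage))
  # hand count: AFR 5/6 alleles alt, EUR 0/6
  out <- ancestry_maf(dosage, labels)
  expect_equal(unname(out$freq["AFR"]), 5 / 6)
  expect_equal(unname(out$freq["EUR"]), 0)
  expect_equal(unname(out$freq["all"]), 5 / 12)
  expect_equal(out$differential, 5 / 6)
  expect_true(out$ancestry_associated)
  # all groups equal -> no flag; AMR/SAS never enter the differential
  labels2 <- setNames(c("AFR", "EUR", "AFR", "EUR", "SAS", "SAS"),
                      names(dosage))
  dos2 <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L), names(dosage))
  out2 <- ancestry_maf(dos2, labels2)
  expect_equal(out2$differential, 0)
  expect_false(out2$ancestry_associated)
  expect_false("SAS" %in% names(out2$freq))
})

test_that("the differential flag is invariant under allele complement", {
  set.seed(14)
  dosage <- setNames(sample(0:2, 40, replace = TRUE), sprintf("S%d", 1:40))
  labels <- setNames(sample(c("AFR", "EUR", "EAS"), 40, replace = TRUE),
                     names(dosage))
  a <- ancestry_maf(dosage, labels)
  b <- ancestry_maf(2L - dosage, labels)
  expect_equal(a$differential, b$differential)
  expect_equal(a$ancestry_associated, b$ancestry_associated)
})

test_that("proximity classification uses a strict 1 Mb same-chromosome rule", {
  expect_true(classify_proximal("chr1", 1.5e6, "chr1", 1e6)$proximal)
  expect_equal(classify_proximal("chr1", 1.5e6, "chr1", 1e6)$distance, 5e5)
  expect_false(classify_proximal("chr1", 2e6, "chr1", 1e6)$proximal)
  expect_false(classify_proximal("chr2", 1e6, "chr1", 1e6)$proximal)
  expect_true(is.na(classify_proximal("chr2", 1e6, "chr1", 1e6)$distance))
  expect_true(is.na(classify_proximal("chr1", 1e6, NA, NA)$proximal))
})

test_that("eQTL testing collapses dosage to presence and detects shifts", {
  set.seed(15)
  n <- 100
  dosage <- setNames(sample(0:2, n, replace = TRUE), sprintf("S%03d", 1:n))
  lineage <- factor(sample(c("a", "b"), n, replace = TRUE))
  # null: identical distributions
  expr0 <- setNames(rnorm(n), names(dosage))
  out0 <- eqtl_test(dosage, expr0, lineage)
  expect_gt(out0$p, 0.001)
  # shift of 2 units on presence
  expr1 <- expr0 + 2 * (dosage >= 1)
  out1 <- eqtl_test(dosage, expr1, lineage)
  expect_lt(out1$p, 1e-3)
  # dosage 1 and 2 are the same class: recoding 2 -> 1 changes nothing
  out2 <- eqtl_test(pmin(dosage, 1L), expr1, lineage)
  expect_equal(out1$beta, out2$beta)
  expect_equal(out1$p, out2$p)
  # empty class
  expect_true(is.na(eqtl_test(rep(1L, n), expr1, lineage)$p))
})

test_that("ld_r2 behaves on exact, mirrored, and null inputs", {
  expect_equal(ld_r2(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0)), 1)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  set.seed(16)
  n <- 60
  r2s <- replicate(400, ld_r2(rbinom(n, 2, 0.4), rbinom(n, 2, 0.4)))
  # independent variants: E[r^2] ~ 1/(n-1)
  expect_lt(abs(mean(r2s) - 1 / (n - 1)), 3 * sd(r2s) / sqrt(400))
})

test_that("weak-expression flags use a strict 5 RPM median rule", {
  expr <- cbind(zero = rep(0, 5), low = c(1, 2, 3, 4, 100),
                edge = rep(5, 5), high = rep(50, 5))
  rownames(expr) <- sprintf("S%d", 1:5)
  out <- weak_expression_fraction(expr, 5)
  expect_equal(unname(out$flag), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$fraction, 0.5)
})
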