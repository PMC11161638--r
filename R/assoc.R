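#' Local-ancestry label of every gene's TSS in every sample
#'
#' Maps each gene's transcription start site to its ancestry window and
#' evaluates [ancestry_at_locus()] for all samples, giving the sample x gene
#' matrix of locus ancestry labels used to bin cell lines per gene.
#'
#' @param tss Data.frame with columns `gene`, `chrom`, `tss0`.
#' @param track A `"local_ancestry_track"`.
#' @param global Optional precomputed `"global_ancestry"`.
#' @return Character matrix samples x genes. Genes whose TSS is not covered
#'   by any window are dropped with a warning.
#' @export
bin_samples_by_locus_ancestry <- function(tss, track, global = NULL) {
  if (is.null(global)) global <- global_ancestry_fractions(track)
  cols <- lapply(seq_len(nrow(tss)), function(i) {
    w <- window_at(track$windows, tss$chrom[i], tss$tss0[i])
    if (is.na(w)) return(NULL)
    ancestry_at_locus(track, tss$chrom[i], tss$tss0[i], global = global)
  })
  keep <- !vapply(cols, is.null, logical(1))
  if (any(!keep)) {
    warning("TSS not covered by ancestry windows for gene(s): ",
            paste(tss$gene[!keep], collapse = ", "), call. = FALSE)
  }
  out <- do.call(cbind, cols[keep])
  colnames(out) <- tss$gene[keep]
  out
}

#' Ancestry-dependency association scan
#'
#' For one ancestry group, tests every gene's dependency scores for
#' association with local ancestry at its TSS: ordinary least squares of
#' dependency on the indicator `label == group` with cancer-lineage dummies
#' as covariates, two-sided coefficient p-value, and Benjamini-Hochberg FDR
#' across the genes tested for that group (each group is its own FDR family).
#'
#' @param screen A `"screen_data"` (or list with `gene_dependency` samples x
#'   genes matrix and `lineage` factor).
#' @param labels Samples x genes ancestry-label matrix from
#'   [bin_samples_by_locus_ancestry()].
#' @param group Ancestry group to test (one-vs-rest).
#' @param fdr_q Significance threshold on q (default 0.05).
#' @param min_group Minimum samples carrying the group label at a locus
#'   (default 2); genes below it are skipped.
#' @return Data.frame: `gene`, `group`, `beta`, `p`, `q`, `n_in`, `n_out`,
#'   `significant`, `singular`. Genes with singular designs (group confounded
#'   with lineage) keep a row with `NA` p and are excluded from the FDR
#'   family.
#' @export
test_ancestry_dependency <- function(screen, labels, group, fdr_q = 0.05,
                                     min_group = 2) {
  dep <- screen$gene_dependency
  genes <- intersect(colnames(dep), colnames(labels))
  covs <- lineage_design(screen$lineage)[, -1, drop = FALSE]
  rows <- lapply(genes, function(g) {
    lab <- labels[rownames(dep), g]
    ind <- as.numeric(lab == group)
    n_in <- sum(ind == 1); n_out <- sum(ind == 0)
    if (n_in < min_group || n_out < min_group) return(NULL)
    fit <- .ols_test(dep[, g], ind, covs)
    data.frame(gene = g, group = group, beta = fit$beta, p = fit$p,
               n_in = n_in, n_out = n_out, singular = fit$singular,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    warning("no genes testable for group ", group, call. = FALSE)
    return(data.frame(gene = character(), group = character(),
                      beta = numeric(), p = numeric(), q = numeric(),
                      n_in = integer(), n_out = integer(),
                      significant = logical(), singular = logical()))
  }
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$q) & res$q < fdr_q
  rownames(res) <- NULL
  res[, c("gene", "group", "beta", "p", "q", "n_in", "n_out",
          "significant", "singular")]
}

#' Power to detect ancestry-associated dependencies
#'
#' Monte-Carlo power of the lineage-adjusted one-vs-rest regression: for each
#' effect size `delta`, group-member scores are drawn `N(delta, noise_sd^2)`
#' and the complement `N(0, noise_sd^2)`, the same regression as
#' [test_ancestry_dependency()] is fitted, and power is the fraction of
#' replicates with `p < alpha`. Noise is drawn once per replicate and shared
#' across the effect grid (common random numbers), so estimated power is
#' monotone in `delta` by construction up to Monte-Carlo noise in the
#' comparison across sample sizes.
#'
#' @param n_by_group Named integer vector of per-group sample sizes, e.g.
#'   `c(AFR = 26, AMR = 6, EAS = 203, EUR = 373, SAS = 4)`.
#' @param effects Effect grid (default `seq(0, 1, 0.01)`).
#' @param reps Replicates per effect (default 1000).
#' @param alpha Test level (default 0.05).
#' @param lineage_probs Optional named probabilities used to draw lineage
#'   labels (default: four equally likely lineages).
#' @param noise_sd Score standard deviation (default 1).
#' @param seed Seed for the simulation streams.
#' @return Data.frame of class `"power_curve"`: `group`, `n`, `effect`,
#'   `power`. Groups with `n < 2` report `NA` power.
#' @export
power_simulation <- function(n_by_group, effects = seq(0, 1, 0.01),
                             reps = 1000, alpha = 0.05,
                             lineage_probs = NULL, noise_sd = 1,
                             seed = 1L) {
  stopifnot(reps >= 100, !is.null(names(n_by_group)))
  if (is.null(lineage_probs)) {
    lineage_probs <- setNames(rep(0.25, 4), paste0("lineage", 1:4))
  }
  n_total <- sum(n_by_group)
  out <- list()
  for (g in names(n_by_group)) {
    n_g <- n_by_group[[g]]
    if (n_g < 2) {
      out[[g]] <- data.frame(group = g, n = n_g, effect = effects,
                             power = NA_real_)
      next
    }
    set.seed(stage_seed(seed + match(g, names(n_by_group)), "power"))
    lineage <- factor(sample(names(lineage_probs), n_total, replace = TRUE,
                             prob = lineage_probs))
    ind <- c(rep(1, n_g), rep(0, n_total - n_g))
    X <- cbind(1, ind, lineage_design(lineage)[, -1, drop = FALSE])
    noise <- matrix(rnorm(n_total * reps, 0, noise_sd), n_total, reps)
    power <- vapply(effects, function(delta) {
      Y <- noise + delta * ind
      mean(.ols_test_batch(X, Y, 2L)$p < alpha)
    }, numeric(1))
    out[[g]] <- data.frame(group = g, n = n_g, effect = effects,
                           power = power)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("power_curve", "data.frame")
  res
}
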