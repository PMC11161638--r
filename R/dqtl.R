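#' Filter variants by minor allele frequency
#'
#' Keeps variants whose cohort minor allele frequency strictly exceeds
#' `min_maf`, with `f` the mean dosage over non-missing samples divided by 2
#' and MAF `min(f, 1 - f)`.
#'
#' @param genotypes A `"variant_genotypes"`.
#' @param min_maf MAF floor (default 0.01).
#' @return The filtered `"variant_genotypes"`, with an added attribute
#'   `"maf"` giving the kept variants' MAFs. Warns when nothing survives.
#' @export
filter_by_maf <- function(genotypes, min_maf = 0.01) {
  f <- colMeans(genotypes$dosage, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep)) warning("no variants pass the MAF filter", call. = FALSE)
  out <- genotypes
  out$variants <- genotypes$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$dosage <- genotypes$dosage[, keep, drop = FALSE]
  attr(out, "maf") <- maf[keep]
  out
}

#' Genome-wide dependency-QTL scan for one gene
#'
#' Ordinary least squares of the gene's dependency scores on each variant's
#' additive dosage with cancer-lineage dummies as covariates; two-sided
#' coefficient p-values are corrected across all variants tested for the gene
#' with the Benjamini-Yekutieli procedure, and significance is called at
#' `q < fdr_q`. Variants with missing dosages are fitted casewise; variants
#' constant after missing-removal are skipped.
#'
#' @param dep Named numeric vector: the gene's dependency score per sample.
#' @param genotypes A (MAF-filtered) `"variant_genotypes"`.
#' @param lineage Per-sample lineage factor.
#' @param fdr_q Significance threshold (default 0.05).
#' @param min_n Minimum samples with non-missing dosage and dependency
#'   (default 10).
#' @return Data.frame: `variant_id`, `chrom`, `pos0`, `beta`, `p`, `q_bh`,
#'   `q` (Benjamini-Yekutieli), `significant`.
#' @export
dqtl_scan <- function(dep, genotypes, lineage, fdr_q = 0.05, min_n = 10) {
  G <- genotypes$dosage
  stopifnot(!is.null(names(dep)))
  dep <- dep[rownames(G)]
  keep_s <- !is.na(dep)
  if (sum(keep_s) < min_n) {
    stop("fewer than ", min_n, " samples with dependency scores",
         call. = FALSE)
  }
  G <- G[keep_s, , drop = FALSE]
  y <- dep[keep_s]
  C <- lineage_design(droplevels(factor(lineage[keep_s])))
  v <- genotypes$variants
  sds <- apply(G, 2, sd, na.rm = TRUE)
  complete <- !anyNA(G)
  beta <- rep(NA_real_, ncol(G)); p <- rep(NA_real_, ncol(G))
  testable <- !is.na(sds) & sds > 0
  if (complete) {
    if (any(testable)) {
      fit <- .scan_fwl(y, G[, testable, drop = FALSE], C)
      beta[testable] <- fit$beta; p[testable] <- fit$p
    }
  } else {
    for (j in which(testable)) {
      ok <- !is.na(G[, j])
      if (sum(ok) < min_n || sd(G[ok, j]) == 0) next
      fit <- .ols_test(y[ok], G[ok, j], C[ok, -1, drop = FALSE])
      beta[j] <- fit$beta; p[j] <- fit$p
    }
  }
  q_bh <- rep(NA_real_, length(p)); q_by <- q_bh
  ok <- !is.na(p)
  q_bh[ok] <- p.adjust(p[ok], method = "BH")
  q_by[ok] <- p.adjust(p[ok], method = "BY")
  res <- data.frame(variant_id = v$id, chrom = v$chrom, pos0 = v$start0,
                    beta = beta, p = p, q_bh = q_bh, q = q_by,
                    significant = !is.na(q_by) & q_by < fdr_q,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Marker d-QTL for one gene
#'
#' The significant variant with the lowest Benjamini-Yekutieli q; ties are
#' broken by lower raw p, then genomic order `(chrom, pos)`.
#'
#' @param results A [dqtl_scan()] result frame.
#' @param require_significant If `TRUE` (default) return `NULL` when no
#'   variant is significant; if `FALSE` pick the strongest association
#'   regardless of significance.
#' @return The marker's one-row data.frame, or `NULL`.
#' @export
select_marker <- function(results, require_significant = TRUE) {
  cand <- if (require_significant) {
    results[results$significant %in% TRUE, , drop = FALSE]
  } else {
    results[!is.na(results$q), , drop = FALSE]
  }
  if (nrow(cand) == 0) return(NULL)
  ord <- order(cand$q, cand$p,
               match(cand$chrom, unique(results$chrom)), cand$pos0)
  cand[ord[1], , drop = FALSE]
}

#' Per-ancestry-group allele frequencies of a marker
#'
#' Alternate-allele frequency of one variant within each predominant-ancestry
#' group (by default AFR, EAS, EUR and Admixed; groups with too few samples
#' are simply absent from `labels`) and across all samples. The differential
#' is the max-minus-min over the included groups with at least one sample; a
#' marker is flagged ancestry-associated when the differential exceeds
#' `differential_maf`.
#'
#' @param dosage Named dosage vector for the marker (names = samples).
#' @param labels Named per-sample predominant-ancestry labels.
#' @param groups Groups entering the differential (default
#'   `c("AFR", "EAS", "EUR", "Admixed")`, intersected with observed labels).
#' @param differential_maf Flag threshold (default 0.2, strict).
#' @return List with `freq` (named per-group frequency, plus `all`),
#'   `differential`, `ancestry_associated`.
#' @export
ancestry_maf <- function(dosage, labels,
                         groups = c("AFR", "EAS", "EUR", "Admixed"),
                         differential_maf = 0.2) {
  labels <- labels[names(dosage)]
  groups <- intersect(groups, unique(labels))
  freq <- vapply(groups, function(g) {
    d <- dosage[labels == g]
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE) / 2
  }, numeric(1))
  freq <- c(freq, all = mean(dosage, na.rm = TRUE) / 2)
  present <- freq[names(freq) != "all"]
  present <- present[!is.na(present)]
  differential <- if (length(present) >= 2) {
    max(present) - min(present)
  } else {
    NA_real_
  }
  list(freq = freq, differential = differential,
       ancestry_associated = !is.na(differential) &&
         differential > differential_maf)
}

#' Classify a marker as TSS-proximal or distal
#'
#' Proximal iff on the same chromosome as the gene's TSS and strictly closer
#' than `proximal_bp` (default 1 Mb); markers at exactly the threshold or on
#' a different chromosome are distal.
#'
#' @param marker_chrom,marker_pos0 Marker locus.
#' @param tss_chrom,tss_pos0 Gene TSS locus (NA allowed).
#' @param proximal_bp Distance threshold in bp.
#' @return List with `proximal` (logical, NA when the TSS is unknown) and
#'   `distance` (bp, or NA on a different chromosome).
#' @export
classify_proximal <- function(marker_chrom, marker_pos0, tss_chrom, tss_pos0,
                              proximal_bp = 1e6) {
  if (is.na(tss_chrom) || is.na(tss_pos0)) {
    return(list(proximal = NA, distance = NA_real_))
  }
  if (marker_chrom != tss_chrom) {
    return(list(proximal = FALSE, distance = NA_real_))
  }
  d <- abs(marker_pos0 - tss_pos0)
  list(proximal = d < proximal_bp, distance = d)
}

#' Expression association of a marker (eQTL test)
#'
#' Samples are stratified by presence (dosage 1 or 2) versus absence
#' (homozygous reference) of the variant, and log expression is regressed on
#' the presence indicator with lineage dummies.
#'
#' @param dosage Named marker dosage vector.
#' @param expression Named expression vector on a log scale.
#' @param lineage Per-sample lineage factor.
#' @param min_per_class Minimum samples per presence class (default 2).
#' @return List with `beta`, `p`, `n_present`, `n_absent` (all `NA`-filled
#'   when a class is too small).
#' @export
eqtl_test <- function(dosage, expression, lineage, min_per_class = 2) {
  keep <- !is.na(dosage) & !is.na(expression)
  dosage <- dosage[keep]; expression <- expression[keep]
  lineage <- droplevels(factor(lineage[keep]))
  presence <- as.numeric(dosage >= 1)
  if (sum(presence == 1) < min_per_class ||
      sum(presence == 0) < min_per_class) {
    return(list(beta = NA_real_, p = NA_real_,
                n_present = sum(presence == 1),
                n_absent = sum(presence == 0)))
  }
  fit <- .ols_test(expression, presence,
                   lineage_design(lineage)[, -1, drop = FALSE])
  list(beta = fit$beta, p = fit$p, n_present = sum(presence == 1),
       n_absent = sum(presence == 0))
}

#' Weakly expressed genes
#'
#' Flags genes whose median expression across samples is strictly below
#' `threshold` reads per million, and reports the flagged fraction.
#'
#' @param expression Samples x genes matrix on the RPM scale.
#' @param threshold RPM cutoff (default 5).
#' @return List with `flag` (named logical per gene) and `fraction`.
#' @export
weak_expression_fraction <- function(expression, threshold = 5) {
  med <- apply(expression, 2, median, na.rm = TRUE)
  flag <- med < threshold
  list(flag = flag, fraction = mean(flag))
}
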