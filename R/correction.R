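#' Correct gene scores by per-cell-line guide exclusion
#'
#' Recomputes the gene-level dependency matrix from guide-level
#' log-fold-changes, excluding each guide only for the cell lines in which
#' its targeting sequence carries a mismatch. Cells without mismatches
#' reproduce the uncorrected aggregate exactly; cells whose guides are all
#' excluded become missing.
#'
#' @param guide_lfc Samples x guides LFC matrix.
#' @param library The `"guide_library"` (maps guides to genes).
#' @param mismatch_table A `"mismatch_table"` for the same samples/guides.
#' @param aggregator `"mean"` (default) or `"median"`.
#' @param include_pam_n Count PAM-N records as mismatches (default `FALSE`).
#' @return Samples x genes corrected matrix (NA where all guides excluded).
#' @export
correct_gene_scores <- function(guide_lfc, library, mismatch_table,
                                aggregator = c("mean", "median"),
                                include_pam_n = FALSE) {
  aggregator <- match.arg(aggregator)
  mismatch_table <- filter_pam_n(mismatch_table, include_pam_n)
  genes <- unique(library$gene)
  samples <- rownames(guide_lfc)
  masked <- guide_lfc
  if (nrow(mismatch_table)) {
    rec <- unique(mismatch_table[, c("sample", "guide_id")])
    rec <- rec[rec$sample %in% samples &
                 rec$guide_id %in% colnames(guide_lfc), , drop = FALSE]
    masked[cbind(rec$sample, rec$guide_id)] <- NA
  }
  out <- vapply(genes, function(g) {
    cols <- library$guide_id[library$gene == g]
    if (length(cols) == 0) return(rep(NA_real_, nrow(guide_lfc)))
    block <- masked[, cols, drop = FALSE]
    if (aggregator == "mean") {
      v <- rowMeans(block, na.rm = TRUE)
    } else {
      v <- apply(block, 1, median, na.rm = TRUE)
    }
    v[!is.finite(v)] <- NA_real_
    v
  }, numeric(nrow(guide_lfc)))
  dimnames(out) <- list(samples, genes)
  out
}

#' Pre- versus post-correction differential dependency
#'
#' Per gene, a paired two-sided t-test of the per-sample differences between
#' the corrected and uncorrected matrices over samples where both are
#' defined, with Benjamini-Hochberg FDR across genes.
#'
#' @param dep_pre,dep_post Matched samples x genes matrices.
#' @param fdr_q Significance threshold (default 0.05).
#' @return Data.frame: `gene`, `delta` (mean post minus pre), `p`, `q`,
#'   `n_pairs`, `significant`. Genes with fewer than 3 pairs, or identical
#'   columns, report `NA` p.
#' @export
pre_post_differential <- function(dep_pre, dep_post, fdr_q = 0.05) {
  stopifnot(identical(dim(dep_pre), dim(dep_post)),
            identical(colnames(dep_pre), colnames(dep_post)))
  rows <- lapply(colnames(dep_pre), function(g) {
    d <- dep_post[, g] - dep_pre[, g]
    d <- d[!is.na(d)]
    if (length(d) < 3) {
      return(data.frame(gene = g, delta = NA_real_, p = NA_real_,
                        n_pairs = length(d)))
    }
    p <- if (sd(d) == 0) NA_real_ else t.test(d)$p.value
    data.frame(gene = g, delta = mean(d), p = p, n_pairs = length(d))
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$q) & res$q < fdr_q
  rownames(res) <- NULL
  res[, c("gene", "delta", "p", "q", "n_pairs", "significant")]
}

#' Re-run the ancestry association on corrected scores
#'
#' Delegates to [test_ancestry_dependency()] on the corrected matrix and
#' returns a paired pre/post significance table for one ancestry group.
#'
#' @param corrected Samples x genes corrected matrix from
#'   [correct_gene_scores()].
#' @param screen The original `"screen_data"` (supplies the uncorrected
#'   matrix and lineage).
#' @param labels Samples x genes ancestry-label matrix.
#' @param group Ancestry group to test.
#' @param fdr_q Significance threshold.
#' @return Data.frame: `gene`, `group`, `beta_pre`, `q_pre`,
#'   `significant_pre`, `beta_post`, `q_post`, `significant_post`.
#' @export
rerun_association_post_correction <- function(corrected, screen, labels,
                                              group, fdr_q = 0.05) {
  pre <- test_ancestry_dependency(screen, labels, group, fdr_q)
  post_screen <- list(gene_dependency = corrected, lineage = screen$lineage)
  post <- test_ancestry_dependency(post_screen, labels, group, fdr_q)
  merged <- merge(pre[, c("gene", "beta", "q", "significant")],
                  post[, c("gene", "beta", "q", "significant")],
                  by = "gene", suffixes = c("_pre", "_post"), all = TRUE)
  names(merged) <- c("gene", "beta_pre", "q_pre", "significant_pre",
                     "beta_post", "q_post", "significant_post")
  merged$group <- group
  merged[, c("gene", "group", "beta_pre", "q_pre", "significant_pre",
             "beta_post", "q_post", "significant_post")]
}
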