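#' Genomic targeting interval of a guide
#'
#' The targeting sequence of an SpCas9 guide is the NGG PAM plus the 20
#' protospacer nucleotides 5' of it, a 23-bp genomic interval. On the '+'
#' strand the protospacer occupies `[start0, start0 + 20)` and the PAM
#' `[start0 + 20, start0 + 23)`; on the '-' strand the PAM occupies
#' `[start0, start0 + 3)` (reading CCN on the reference strand, with the
#' degenerate N at `start0 + 2`) and the protospacer `[start0 + 3,
#' start0 + 23)`.
#'
#' @param guide A one-or-more-row data.frame with columns `chrom`, `start0`,
#'   `strand`, `protospacer`, `pam`.
#' @return A data.frame with columns `chrom`, `start0`, `end0` (0-based
#'   half-open, width 23), `strand`.
#' @export
targeting_interval <- function(guide) {
  validate_guides(guide)
  data.frame(chrom = guide$chrom, start0 = guide$start0,
             end0 = guide$start0 + 23L, strand = guide$strand,
             stringsAsFactors = FALSE)
}

validate_guides <- function(guide) {
  stopifnot(is.data.frame(guide),
            all(c("chrom", "start0", "strand", "protospacer", "pam") %in%
                  names(guide)))
  if (!all(guide$strand %in% c("+", "-"))) {
    stop("guide strand must be '+' or '-'", call. = FALSE)
  }
  if (any(nchar(guide$protospacer) != 20)) {
    stop("protospacer must be 20 nt", call. = FALSE)
  }
  if (any(nchar(guide$pam) != 3) || any(substr(guide$pam, 2, 3) != "GG")) {
    stop("PAM must be a 3-nt NGG on the guide strand", call. = FALSE)
  }
  if (any(guide$start0 < 0)) stop("negative guide coordinates", call. = FALSE)
  invisible(guide)
}

#' Map variants onto guide targeting sequences
#'
#' Emits one record for every (sample, guide, variant) combination where the
#' sample carries at least one alternate allele (dosage 1 or 2) of an SNV
#' whose position lies inside the guide's 23-bp targeting interval.
#' `position_from_pam` counts protospacer bases from the PAM-proximal end
#' (1 = adjacent to the PAM, 20 = PAM-distal); PAM bases get 0 (the degenerate
#' N) and -1/-2 (the two Gs, N-to-3' order). Position arithmetic is
#' strand-aware.
#'
#' @param genotypes A `"variant_genotypes"` (or any list with `variants`
#'   data.frame and samples x variants `dosage` matrix).
#' @param library A `"guide_library"` data.frame.
#' @return A data.frame of class `"mismatch_table"`: `guide_id`, `gene`,
#'   `sample`, `variant_id`, `chrom`, `pos0`, `ref`, `alt`,
#'   `position_from_pam`, `zygosity` (`"het"`/`"hom"`).
#' @export
map_variants_to_guides <- function(genotypes, library) {
  validate_guides(library)
  v <- genotypes$variants
  shared <- intersect(unique(v$chrom), unique(library$chrom))
  if (length(shared) == 0 && nrow(v) > 0 && nrow(library) > 0) {
    stop("no shared chromosome names between variants (",
         paste(head(unique(v$chrom)), collapse = ","), ") and guides (",
         paste(head(unique(library$chrom)), collapse = ","), ")",
         call. = FALSE)
  }
  hits <- list()
  for (chr in shared) {
    gi <- which(library$chrom == chr)
    vi <- which(v$chrom == chr)
    if (!length(gi) || !length(vi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = v$start0[vi] + 1L, width = 1L),
      IRanges::IRanges(start = library$start0[gi] + 1L, width = 23L))
    if (length(ov)) {
      hits[[chr]] <- data.frame(var = vi[S4Vectors::queryHits(ov)],
                                gd = gi[S4Vectors::subjectHits(ov)])
    }
  }
  empty <- data.frame(guide_id = character(), gene = character(),
                      sample = character(), variant_id = character(),
                      chrom = character(), pos0 = integer(),
                      ref = character(), alt = character(),
                      position_from_pam = integer(), zygosity = character(),
                      stringsAsFactors = FALSE)
  if (length(hits) == 0) return(structure(empty,
                                          class = c("mismatch_table",
                                                    "data.frame")))
  hits <- do.call(rbind, hits)
  s0 <- library$start0[hits$gd]
  strand <- library$strand[hits$gd]
  p0 <- v$start0[hits$var]
  pos_from_pam <- ifelse(strand == "+", (s0 + 20L) - p0, p0 - (s0 + 2L))
  # expand over carrier samples
  dos <- genotypes$dosage[, hits$var, drop = FALSE]
  carrier <- which(dos >= 1L, arr.ind = TRUE)
  if (nrow(carrier) == 0) return(structure(empty,
                                           class = c("mismatch_table",
                                                     "data.frame")))
  hc <- carrier[, "col"]
  out <- data.frame(
    guide_id = library$guide_id[hits$gd][hc],
    gene = library$gene[hits$gd][hc],
    sample = rownames(genotypes$dosage)[carrier[, "row"]],
    variant_id = v$id[hits$var][hc],
    chrom = v$chrom[hits$var][hc],
    pos0 = p0[hc],
    ref = v$ref[hits$var][hc],
    alt = v$alt[hits$var][hc],
    position_from_pam = as.integer(pos_from_pam[hc]),
    zygosity = ifelse(dos[carrier] == 2L, "hom", "het"),
    stringsAsFactors = FALSE)
  out <- out[order(out$guide_id, out$sample, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mismatch_table", "data.frame"))
}

# drop PAM-N records unless they are wanted
filter_pam_n <- function(table, include_pam_n = FALSE) {
  if (include_pam_n) table else
    table[table$position_from_pam != 0L, , drop = FALSE]
}

#' Fraction of the library affected per sample
#'
#' For each sample, the fraction of library guides carrying at least one
#' mismatch record (variants at the degenerate PAM N position are excluded by
#' default).
#'
#' @param table A `"mismatch_table"`.
#' @param library The `"guide_library"` the table was computed against.
#' @param samples Optional character vector fixing the sample universe (so
#'   samples with zero mismatches report 0).
#' @param include_pam_n Count PAM-N records as mismatches.
#' @return Named numeric vector of per-sample fractions.
#' @export
per_sample_affected_fraction <- function(table, library, samples = NULL,
                                         include_pam_n = FALSE) {
  table <- filter_pam_n(table, include_pam_n)
  if (is.null(samples)) samples <- sort(unique(table$sample))
  n_guides <- nrow(library)
  counts <- vapply(samples, function(s) {
    length(unique(table$guide_id[table$sample == s]))
  }, integer(1))
  counts / n_guides
}

#' Guides affected in at least k samples
#'
#' @param table A `"mismatch_table"`.
#' @param k Minimum number of distinct affected samples (default 10).
#' @param include_pam_n Count PAM-N records as mismatches.
#' @return Character vector of guide ids.
#' @export
guides_affected_in_k_samples <- function(table, k = 10,
                                         include_pam_n = FALSE) {
  table <- filter_pam_n(table, include_pam_n)
  if (nrow(table) == 0) return(character(0))
  n_by_guide <- tapply(table$sample, table$guide_id,
                       function(s) length(unique(s)))
  sort(names(n_by_guide)[n_by_guide >= k])
}

#' Histogram of genes by number of affected guides
#'
#' Counts, per gene, how many of its guides carry a mismatch in at least one
#' sample, and tabulates genes over 0..guides_per_gene affected guides.
#'
#' @param table A `"mismatch_table"`.
#' @param library The `"guide_library"`.
#' @param include_pam_n Count PAM-N records as mismatches.
#' @return Named integer vector; names are the affected-guide counts
#'   `0:max(guides per gene)`, values are numbers of genes.
#' @export
per_gene_affected_guide_histogram <- function(table, library,
                                              include_pam_n = FALSE) {
  table <- filter_pam_n(table, include_pam_n)
  genes <- unique(library$gene)
  kmax <- max(table(library$gene))
  affected <- unique(table$guide_id)
  n_aff <- vapply(genes, function(g) {
    sum(library$guide_id[library$gene == g] %in% affected)
  }, integer(1))
  tabulate(factor(n_aff, levels = 0:kmax), nbins = kmax + 1) |>
    setNames(as.character(0:kmax))
}

#' Depletion difference between carriers and non-carriers of one variant
#'
#' Welch two-sided t-test of a guide's log-fold-changes between samples with
#' and without the variant in its targeting sequence. A positive effect
#' (carriers less depleted) on a depleting guide is flagged protective.
#'
#' @param lfc Named numeric vector of the guide's LFCs (names = samples).
#' @param present Logical or character: carrier samples.
#' @param min_per_class Minimum samples per class (default 3).
#' @return A list with `effect` (mean(present) - mean(absent)), `p`,
#'   `protective`, `n_present`, `n_absent` (`effect`/`p` are `NA` when a class
#'   is too small or degenerate).
#' @export
guide_variant_depletion_test <- function(lfc, present, min_per_class = 3) {
  if (is.character(present)) present <- names(lfc) %in% present
  stopifnot(length(present) == length(lfc))
  a <- lfc[present]; b <- lfc[!present]
  if (length(a) < min_per_class || length(b) < min_per_class) {
    return(list(effect = NA_real_, p = NA_real_, protective = NA,
                n_present = length(a), n_absent = length(b)))
  }
  eff <- mean(a) - mean(b)
  p <- if (sd(a) == 0 && sd(b) == 0) NA_real_ else
    tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
  list(effect = eff, p = p, protective = if (is.na(p)) NA else eff > 0,
       n_present = length(a), n_absent = length(b))
}

#' Enrichment of differential depletion among SNP-containing guides
#'
#' Builds the 2x2 table of guides classified by (a) whether their
#' between-group depletion difference exceeds `threshold` in absolute value
#' and (b) whether they carry an in-guide SNP, and tests association with a
#' two-sided Fisher exact test.
#'
#' @param depletion_diff Numeric per-guide depletion difference between two
#'   ancestry groups (e.g. EAS minus EUR group means).
#' @param has_snp Logical per-guide SNP-in-targeting-sequence flag.
#' @param threshold Absolute LFC difference defining "differential"
#'   (default 0.25).
#' @return A list with `table` (2x2), `odds_ratio`, `p`.
#' @export
snp_guide_enrichment <- function(depletion_diff, has_snp, threshold = 0.25) {
  stopifnot(length(depletion_diff) == length(has_snp))
  differential <- abs(depletion_diff) > threshold
  tab <- table(differential = factor(differential, c(TRUE, FALSE)),
               snp = factor(has_snp, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(table = tab, odds_ratio = NA_real_, p = NA_real_))
  }
  ft <- fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Positional impact of guide mismatches
#'
#' For each position from the PAM, pools (guide, sample) pairs with a mismatch
#' at that position against pairs on the same guides without any mismatch, and
#' reports the mean LFC difference with both Welch-t and Wilcoxon rank-sum
#' p-values. Protospacer positions 1-20 are analysed; PAM positions present in
#' the table (0, -1, -2) are reported separately in the same frame.
#'
#' @param table A `"mismatch_table"`.
#' @param guide_lfc Samples x guides LFC matrix.
#' @return Data.frame with columns `position`, `n_mismatch`, `n_control`,
#'   `effect` (mean mismatch LFC minus mean control LFC), `p_t`, `p_wilcoxon`.
#'   Positions absent from the table are omitted.
#' @export
positional_effects <- function(table, guide_lfc) {
  if (nrow(table) == 0) {
    return(data.frame(position = integer(), n_mismatch = integer(),
                      n_control = integer(), effect = numeric(),
                      p_t = numeric(), p_wilcoxon = numeric()))
  }
  samples <- rownames(guide_lfc)
  # mismatch-anywhere flag per (sample, guide) for building clean controls
  mm_key <- paste(table$sample, table$guide_id)
  out <- lapply(sort(unique(table$position_from_pam)), function(pos) {
    sub <- table[table$position_from_pam == pos, , drop = FALSE]
    guides <- unique(sub$guide_id)
    case_key <- unique(paste(sub$sample, sub$guide_id))
    grid <- expand.grid(sample = samples, guide_id = guides,
                        stringsAsFactors = FALSE)
    grid_key <- paste(grid$sample, grid$guide_id)
    is_case <- grid_key %in% case_key
    is_clean <- !(grid_key %in% mm_key)
    vals <- guide_lfc[cbind(grid$sample, grid$guide_id)]
    a <- vals[is_case]; b <- vals[is_clean]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    data.frame(position = pos, n_mismatch = length(a), n_control = length(b),
               effect = mean(a) - mean(b),
               p_t = tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_),
               p_wilcoxon = suppressWarnings(wilcox.test(a, b)$p.value))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' AFR / non-AFR burden ratio
#'
#' Ratio of the median per-sample affected-guide fraction in one ancestry
#' group (default AFR) to the median in all other samples.
#'
#' @param fractions Named per-sample fractions from
#'   [per_sample_affected_fraction()].
#' @param labels Named per-sample ancestry labels (same samples).
#' @param group Focal group (default `"AFR"`).
#' @return Single numeric ratio (`NA` if either group is empty, `Inf`-safe:
#'   `NA` when the denominator median is 0).
#' @export
afr_burden_ratio <- function(fractions, labels, group = "AFR") {
  labels <- labels[names(fractions)]
  a <- fractions[labels == group]
  b <- fractions[labels != group]
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  mb <- median(b)
  if (mb == 0) return(NA_real_)
  median(a) / mb
}
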