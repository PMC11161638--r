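#' Enumerate NGG PAM sites
#'
#' Scans sequences (both strands) for canonical SpCas9 PAM sites: on the '+'
#' strand a 3-mer reading NGG, on the '-' strand a 3-mer reading CCN on the
#' reference (NGG on the minus strand). With `require_fit = TRUE` a site is
#' kept only when its full 23-bp targeting interval (20-nt protospacer plus
#' PAM) fits inside the region.
#'
#' @param sequences Named character vector of DNA sequences (A/C/G/T).
#' @param regions Optional data.frame `seqname`, `start0`, `end0` (0-based
#'   half-open) restricting the scan; default is each whole sequence.
#' @param require_fit Keep only sites whose 23-bp interval fits in the region
#'   (default `TRUE`).
#' @param n_sample Optional random subsample size.
#' @param seed Seed for the subsample.
#' @return Data.frame: `seqname`, `strand`, `pam_start0` (start of the PAM
#'   3-mer in reference coordinates), `interval_start0`, `interval_end0`
#'   (NA when the interval does not fit and `require_fit` is `FALSE`).
#' @export
enumerate_pam_sites <- function(sequences, regions = NULL,
                                require_fit = TRUE, n_sample = NULL,
                                seed = NULL) {
  stopifnot(!is.null(names(sequences)))
  if (is.null(regions)) {
    regions <- data.frame(seqname = names(sequences), start0 = 0L,
                          end0 = nchar(sequences), stringsAsFactors = FALSE)
  }
  out <- list()
  for (r in seq_len(nrow(regions))) {
    sq <- sequences[[regions$seqname[r]]]
    s0 <- regions$start0[r]; e0 <- regions$end0[r]
    if (s0 < 0 || e0 > nchar(sq) || s0 >= e0) {
      stop("region ", r, " outside sequence bounds", call. = FALSE)
    }
    chars <- strsplit(substr(sq, s0 + 1L, e0), "")[[1]]
    n <- length(chars)
    if (n < 3) next
    isG <- chars == "G"; isC <- chars == "C"
    i <- seq_len(n - 2)  # 1-based 3-mer starts within region
    plus <- i[isG[i + 1] & isG[i + 2]]
    minus <- i[isC[i] & isC[i + 1]]
    rows <- list()
    if (length(plus)) {
      pam0 <- s0 + plus - 1L
      int0 <- pam0 - 20L
      fits <- int0 >= s0 & pam0 + 3L <= e0
      rows$plus <- data.frame(seqname = regions$seqname[r], strand = "+",
                              pam_start0 = pam0, interval_start0 = int0,
                              interval_end0 = pam0 + 3L, fits = fits,
                              stringsAsFactors = FALSE)
    }
    if (length(minus)) {
      pam0 <- s0 + minus - 1L
      fits <- pam0 >= s0 & pam0 + 23L <= e0
      rows$minus <- data.frame(seqname = regions$seqname[r], strand = "-",
                               pam_start0 = pam0, interval_start0 = pam0,
                               interval_end0 = pam0 + 23L, fits = fits,
                               stringsAsFactors = FALSE)
    }
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seqname = character(), strand = character(),
                      pam_start0 = integer(), interval_start0 = integer(),
                      interval_end0 = integer(), fits = logical())
  }
  if (require_fit) {
    res <- res[res$fits, , drop = FALSE]
  } else {
    res$interval_start0[!res$fits] <- NA_integer_
    res$interval_end0[!res$fits] <- NA_integer_
  }
  res$fits <- NULL
  res <- res[order(res$seqname, res$pam_start0, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(n_sample) && n_sample < nrow(res)) {
    if (!is.null(seed)) set.seed(stage_seed(seed, "pam"))
    res <- res[sort(sample.int(nrow(res), n_sample)), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

# Hardy-Weinberg carrier rate: probability an individual carries >= 1
# alternate allele across a guide's variants, assuming independence.
carrier_rate <- function(freqs) {
  if (length(freqs) == 0) return(0)
  1 - prod((1 - freqs)^2)
}

#' Ancestry-aware guide selection
#'
#' Per gene, candidates are ranked by on-target score and filtered by two
#' population-genetic constraints before taking the top `guides_per_gene`:
#' (1) no targeting-interval variant may have overall population frequency
#' above `maf_threshold`; (2) the Hardy-Weinberg per-individual mismatch
#' carrier rate in AFR may not exceed `afr_ratio_max` times the non-AFR rate
#' (applied only when the AFR rate exceeds `afr_floor`). When fewer than
#' `guides_per_gene` candidates survive, the best excluded candidates fill
#' the deficit and the gene is flagged `fallback_used`.
#'
#' @param candidates Data.frame with columns `gene`, `guide_id`,
#'   `on_target_score` (one row per candidate guide).
#' @param candidate_variants Data.frame with columns `guide_id`, `freq_all`,
#'   `freq_afr`, `freq_nonafr` (one row per variant overlapping a candidate's
#'   targeting interval; guides absent from it carry no variants).
#' @param maf_threshold Overall-frequency cap per variant (default 0.01).
#' @param afr_ratio_max AFR/non-AFR carrier-rate cap (default 2.5).
#' @param afr_floor AFR carrier rate below which the ratio rule is waived
#'   (default 1e-4).
#' @param guides_per_gene Guides selected per gene (default 4).
#' @param constraints Apply the two constraints (set `FALSE` to reproduce the
#'   unconstrained top-`guides_per_gene` selection).
#' @return A list of class `"library_design"`: `selected` (data.frame
#'   `gene`, `guide_id`, `on_target_score`, `rank`, `fallback`),
#'   `gene_summary` (`gene`, `mean_score_selected`, `mean_score_top`,
#'   `unconstrained_identical`, `fallback_used`, `any_variant_candidate`),
#'   and the thresholds used.
#' @export
design_library <- function(candidates, candidate_variants = NULL,
                           maf_threshold = 0.01, afr_ratio_max = 2.5,
                           afr_floor = 1e-4, guides_per_gene = 4,
                           constraints = TRUE) {
  stopifnot(all(c("gene", "guide_id", "on_target_score") %in%
                  names(candidates)),
            all(is.finite(candidates$on_target_score)))
  if (is.null(candidate_variants)) {
    candidate_variants <- data.frame(guide_id = character(),
                                     freq_all = numeric(),
                                     freq_afr = numeric(),
                                     freq_nonafr = numeric())
  }
  viol <- vapply(candidates$guide_id, function(gid) {
    v <- candidate_variants[candidate_variants$guide_id == gid, , drop = FALSE]
    if (nrow(v) == 0) return(c(maf = FALSE, ratio = FALSE))
    maf_bad <- any(v$freq_all > maf_threshold)
    afr <- carrier_rate(v$freq_afr)
    nonafr <- carrier_rate(v$freq_nonafr)
    ratio_bad <- afr > afr_floor && afr > afr_ratio_max * nonafr
    c(maf = maf_bad, ratio = ratio_bad)
  }, logical(2))
  excluded <- if (constraints) colSums(viol) > 0 else
    rep(FALSE, nrow(candidates))

  sel_rows <- list(); summaries <- list()
  for (g in unique(candidates$gene)) {
    idx <- which(candidates$gene == g)
    if (length(idx) == 0) next
    ord <- idx[order(-candidates$on_target_score[idx],
                     candidates$guide_id[idx])]
    top <- head(ord, guides_per_gene)
    ok <- ord[!excluded[ord]]
    chosen <- head(ok, guides_per_gene)
    fallback <- logical(length(chosen))
    if (length(chosen) < guides_per_gene) {
      fill <- head(setdiff(ord, chosen), guides_per_gene - length(chosen))
      fallback <- c(fallback, rep(TRUE, length(fill)))
      chosen <- c(chosen, fill)
    }
    sel_rows[[g]] <- data.frame(
      gene = g, guide_id = candidates$guide_id[chosen],
      on_target_score = candidates$on_target_score[chosen],
      rank = seq_along(chosen), fallback = fallback,
      stringsAsFactors = FALSE)
    summaries[[g]] <- data.frame(
      gene = g,
      mean_score_selected = mean(candidates$on_target_score[chosen]),
      mean_score_top = mean(candidates$on_target_score[top]),
      unconstrained_identical = setequal(chosen, top),
      fallback_used = any(fallback),
      any_variant_candidate = any(candidates$guide_id[idx] %in%
                                    candidate_variants$guide_id),
      stringsAsFactors = FALSE)
  }
  if (length(sel_rows) == 0) stop("no candidate guides supplied",
                                  call. = FALSE)
  missing_genes <- setdiff(unique(candidates$gene), names(sel_rows))
  if (length(missing_genes)) {
    stop("genes without candidates: ", paste(missing_genes, collapse = ", "),
         call. = FALSE)
  }
  structure(list(selected = do.call(rbind, c(sel_rows,
                                             make.row.names = FALSE)),
                 gene_summary = do.call(rbind, c(summaries,
                                                 make.row.names = FALSE)),
                 maf_threshold = maf_threshold,
                 afr_ratio_max = afr_ratio_max, afr_floor = afr_floor,
                 guides_per_gene = guides_per_gene,
                 constraints = constraints),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  gs <- x$gene_summary
  cat(sprintf("Library design: %d genes, %d guides/gene%s\n",
              nrow(gs), x$guides_per_gene,
              if (x$constraints) "" else " (constraints off)"))
  cat(sprintf("  unconstrained top-%d retained for %d/%d genes; fallback in %d\n",
              x$guides_per_gene, sum(gs$unconstrained_identical), nrow(gs),
              sum(gs$fallback_used)))
  invisible(x)
}

#' On-target score cost of the design constraints
#'
#' Mean on-target score of the selected guides versus the unconstrained
#' top-`guides_per_gene`, per gene and overall, and restricted to genes with
#' at least one variant-carrying candidate.
#'
#' @param design A `"library_design"`.
#' @return List with `per_gene` (`gene`, `delta`), `overall_delta`,
#'   `variant_gene_delta` (genes with a variant-hit candidate; `NA` when
#'   there are none).
#' @export
design_quality_benchmark <- function(design) {
  gs <- design$gene_summary
  delta <- gs$mean_score_selected - gs$mean_score_top
  vg <- gs$any_variant_candidate
  list(per_gene = data.frame(gene = gs$gene, delta = delta,
                             stringsAsFactors = FALSE),
       overall_delta = mean(delta),
       variant_gene_delta = if (any(vg)) mean(delta[vg]) else NA_real_)
}
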