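#' Infer local ancestry per window
#'
#' Window-based diploid ancestry assignment from unphased dosages: for each
#' sample and window the unordered population pair `(a, b)` maximising the
#' naive-Bayes window log-likelihood
#' `sum_i log P(g_i | f_a,i, f_b,i)` is chosen, where one allele is drawn
#' Bernoulli from each population's panel frequency, so
#' `P(0) = (1-f_a)(1-f_b)`, `P(1) = f_a(1-f_b) + f_b(1-f_a)`,
#' `P(2) = f_a f_b`. Ties are broken towards homozygous pairs, then
#' lexicographic label order. Windows with zero informative variants inherit
#' the nearest assigned window on the same chromosome (left neighbour
#' preferred) and are flagged.
#'
#' This is a deliberately simple classifier: it conditions on each window
#' independently (no linkage between windows, no phasing) and treats sites
#' within a window as independent given ancestry.
#'
#' @param genotypes A `"variant_genotypes"`.
#' @param panel An `"ancestry_panel"` covering the window variants.
#' @param windows An `"ancestry_windows"` frame from [build_windows()].
#' @return A list of class `"local_ancestry_track"` with samples x windows
#'   character matrices `pair1`, `pair2` (unordered pair, `pair1 <=` label
#'   order of `pair2`), numeric matrix `margin` (best minus second-best
#'   log-likelihood), `windows`, and logical `copied` (windows filled by
#'   neighbour copy).
#' @export
infer_local_ancestry <- function(genotypes, panel, windows) {
  pops <- sort(colnames(panel$freq))
  K <- length(pops)
  # homozygous pairs first, then heterozygous, both in label order
  hom <- cbind(pops, pops)
  het <- if (K > 1) t(utils::combn(pops, 2)) else NULL
  pairs <- rbind(hom, het)
  n_pairs <- nrow(pairs)
  n_s <- nrow(genotypes$dosage)
  n_win <- nrow(windows)
  vid <- match(genotypes$variants$id, panel$variants$id)
  if (anyNA(vid)) stop("panel does not cover all genotype variants",
                       call. = FALSE)
  freq <- panel$freq[vid, pops, drop = FALSE]

  pair1 <- matrix(NA_character_, n_s, n_win,
                  dimnames = list(rownames(genotypes$dosage), NULL))
  pair2 <- pair1
  margin <- matrix(NA_real_, n_s, n_win)
  copied <- rep(FALSE, n_win)

  for (w in seq_len(n_win)) {
    if (is.na(windows$first_variant[w])) { copied[w] <- TRUE; next }
    idx <- windows$first_variant[w]:windows$last_variant[w]
    D <- genotypes$dosage[, idx, drop = FALSE]
    miss <- is.na(D)
    I0 <- (!miss & D == 0L) + 0; I1 <- (!miss & D == 1L) + 0
    I2 <- (!miss & D == 2L) + 0
    ll <- matrix(NA_real_, n_s, n_pairs)
    for (p in seq_len(n_pairs)) {
      fa <- freq[idx, pairs[p, 1]]; fb <- freq[idx, pairs[p, 2]]
      lp0 <- log((1 - fa) * (1 - fb))
      lp1 <- log(fa * (1 - fb) + fb * (1 - fa))
      lp2 <- log(fa * fb)
      ll[, p] <- I0 %*% lp0 + I1 %*% lp1 + I2 %*% lp2
    }
    best <- apply(ll, 1, which.max)  # first max: hom-then-lexicographic ties
    pair1[, w] <- pairs[best, 1]
    pair2[, w] <- pairs[best, 2]
    margin[, w] <- vapply(seq_len(n_s), function(s) {
      srt <- sort(ll[s, ], decreasing = TRUE)
      srt[1] - srt[2]
    }, numeric(1))
  }
  # fill uninformative windows from the nearest assigned neighbour
  for (chr in unique(windows$chrom)) {
    sel <- which(windows$chrom == chr)
    assigned <- sel[!copied[sel]]
    if (length(assigned) == 0) next
    for (w in sel[copied[sel]]) {
      left <- assigned[assigned < w]
      src <- if (length(left)) max(left) else min(assigned[assigned > w])
      pair1[, w] <- pair1[, src]; pair2[, w] <- pair2[, src]
    }
  }
  structure(list(pair1 = pair1, pair2 = pair2, margin = margin,
                 windows = windows, copied = copied,
                 populations = pops),
            class = "local_ancestry_track")
}

#' @export
print.local_ancestry_track <- function(x, ...) {
  cat(sprintf("Local ancestry track: %d samples x %d windows, populations %s\n",
              nrow(x$pair1), ncol(x$pair1),
              paste(x$populations, collapse = "/")))
  invisible(x)
}

#' Global ancestry fractions
#'
#' Within each chromosome, the fraction of haplotype-window assignments per
#' population (each diploid pair contributes one half per member); the global
#' fraction is the unweighted mean over chromosomes, so every chromosome
#' carries equal weight regardless of its window count.
#'
#' @param track A `"local_ancestry_track"`.
#' @param threshold Predominance threshold passed to [assign_predominant()].
#' @return A list of class `"global_ancestry"` with `fractions` (samples x
#'   populations, rows summing to 1) and `predominant` (per-sample label or
#'   `"Admixed"`).
#' @export
global_ancestry_fractions <- function(track, threshold = 0.8) {
  pops <- track$populations
  chroms <- unique(track$windows$chrom)
  n_s <- nrow(track$pair1)
  per_chrom <- array(0, c(n_s, length(pops), length(chroms)),
                     dimnames = list(rownames(track$pair1), pops, chroms))
  for (ci in seq_along(chroms)) {
    sel <- track$windows$chrom == chroms[ci]
    n_w <- sum(sel)
    for (k in seq_along(pops)) {
      cnt <- rowSums(track$pair1[, sel, drop = FALSE] == pops[k]) +
        rowSums(track$pair2[, sel, drop = FALSE] == pops[k])
      per_chrom[, k, ci] <- cnt / (2 * n_w)
    }
  }
  fractions <- apply(per_chrom, c(1, 2), mean)
  structure(list(fractions = fractions,
                 predominant = assign_predominant(fractions, threshold)),
            class = "global_ancestry")
}

#' Predominant-ancestry label
#'
#' A sample is labelled with its maximal-fraction population only when that
#' fraction strictly exceeds `threshold` (default 0.8); otherwise
#' `"Admixed"`.
#'
#' @param fractions Numeric vector (one sample) or samples x populations
#'   matrix of ancestry fractions; names/colnames are population labels.
#' @param threshold Strict predominance threshold.
#' @return Character label(s).
#' @export
assign_predominant <- function(fractions, threshold = 0.8) {
  if (is.matrix(fractions)) {
    return(apply(fractions, 1, assign_predominant, threshold = threshold))
  }
  stopifnot(!is.null(names(fractions)),
            abs(sum(fractions) - 1) < 1e-6, all(fractions >= 0))
  k <- which.max(fractions)
  if (fractions[k] > threshold) names(fractions)[k] else "Admixed"
}

#' Single-population ancestry label at a genomic locus
#'
#' The population holding the majority of the diploid pair at the window
#' containing the position: a homozygous pair gives its population directly;
#' a heterozygous pair is resolved towards the member with the higher global
#' ancestry fraction in that sample, with lexicographic order as the final
#' tie-break.
#'
#' @param track A `"local_ancestry_track"`.
#' @param chrom,pos0 Locus (0-based position).
#' @param global Optional `"global_ancestry"`; computed from `track` if
#'   missing.
#' @return Named character vector: one label per sample.
#' @export
ancestry_at_locus <- function(track, chrom, pos0, global = NULL) {
  w <- window_at(track$windows, chrom, pos0)
  if (is.na(w)) {
    stop("position ", chrom, ":", pos0, " not covered by any ancestry window",
         call. = FALSE)
  }
  a <- track$pair1[, w]; b <- track$pair2[, w]
  het <- a != b
  out <- a
  if (any(het)) {
    if (is.null(global)) global <- global_ancestry_fractions(track)
    fa <- global$fractions[cbind(which(het), match(a[het], colnames(global$fractions)))]
    fb <- global$fractions[cbind(which(het), match(b[het], colnames(global$fractions)))]
    # pair1 is lexicographically first, so ties resolve to it
    out[het] <- ifelse(fb > fa, b[het], a[het])
  }
  out
}
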