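# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# Random reference genome as named character vector of A/C/G/T strings.
random_reference <- function(chrom_lengths, seed) {
  set.seed(seed)
  vapply(chrom_lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
}

# Build a guide library consistent with a reference: guides are placed
# non-overlapping; the reference is edited so every guide has a valid NGG
# PAM on its strand; protospacer/PAM fields are read back from the edited
# reference. Returns list(reference, library).
reference_guide_library <- function(reference, n_guides, seed) {
  set.seed(seed)
  chroms <- names(reference)
  per <- ceiling(n_guides / length(chroms))
  recs <- list()
  for (ch in chroms) {
    L <- nchar(reference[[ch]])
    slots <- seq(1L, L - 30L, by = 30L)
    starts0 <- sort(sample(slots, min(per, length(slots)))) - 1L
    strand <- sample(c("+", "-"), length(starts0), replace = TRUE)
    chars <- strsplit(reference[[ch]], "")[[1]]
    for (j in seq_along(starts0)) {
      s <- starts0[j]
      if (strand[j] == "+") {
        chars[s + 22] <- "G"; chars[s + 23] <- "G"  # PAM GG (1-based)
      } else {
        chars[s + 1] <- "C"; chars[s + 2] <- "C"    # CCN on reference
      }
    }
    reference[[ch]] <- paste(chars, collapse = "")
    for (j in seq_along(starts0)) {
      s <- starts0[j]
      seq23 <- substr(reference[[ch]], s + 1, s + 23)
      gseq <- if (strand[j] == "+") seq23 else revcomp_chr(seq23)
      recs[[length(recs) + 1L]] <- data.frame(
        guide_id = sprintf("%s_%d_%s", ch, s, strand[j]),
        gene = sprintf("gene_%s_%d", ch, j %/% 4L),
        chrom = ch, start0 = s, end0 = s + 23L, strand = strand[j],
        protospacer = substr(gseq, 1, 20), pam = substr(gseq, 21, 23),
        stringsAsFactors = FALSE)
    }
  }
  library <- do.call(rbind, recs)
  rownames(library) <- NULL
  class(library) <- c("guide_library", "data.frame")
  list(reference = reference, library = library)
}

# Random SNVs on a reference with dosages for a few samples.
random_snvs <- function(reference, n_variants, n_samples, seed) {
  set.seed(seed)
  chroms <- names(reference)
  per <- ceiling(n_variants / length(chroms))
  recs <- list()
  for (ch in chroms) {
    L <- nchar(reference[[ch]])
    pos0 <- sort(sample.int(L, min(per, L)) - 1L)
    ref <- substring(reference[[ch]], pos0 + 1, pos0 + 1)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1), "")
    recs[[ch]] <- data.frame(
      id = paste0(ch, ":", pos0 + 1L, ":", ref, ":", alt),
      chrom = ch, start0 = pos0, ref = ref, alt = unname(alt),
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, recs)
  rownames(variants) <- NULL
  samples <- sprintf("S%02d", seq_len(n_samples))
  dosage <- matrix(sample(0:2, nrow(variants) * n_samples, replace = TRUE,
                          prob = c(0.6, 0.25, 0.15)),
                   n_samples, nrow(variants),
                   dimnames = list(samples, variants$id))
  structure(list(variants = variants, dosage = dosage, samples = samples),
            class = "variant_genotypes")
}

# Brute-force mismatch-mapping oracle: reconstructs every guide's 23-bp
# targeting sequence from the reference, substitutes each carried alternate
# allele, and reports any base change with its guide-strand offset converted
# to a position from the PAM.
oracle_map_variants <- function(genotypes, library, reference) {
  v <- genotypes$variants
  out <- list()
  for (gi in seq_len(nrow(library))) {
    g <- library[gi, ]
    ref23 <- substr(reference[[g$chrom]], g$start0 + 1, g$start0 + 23)
    hit <- which(v$chrom == g$chrom & v$start0 >= g$start0 &
                   v$start0 < g$start0 + 23L)
    for (vi in hit) {
      offset_ref <- v$start0[vi] - g$start0  # 0-based within interval
      mut23 <- ref23
      substr(mut23, offset_ref + 1, offset_ref + 1) <- v$alt[vi]
      gseq_ref <- if (g$strand == "+") ref23 else revcomp_chr(ref23)
      gseq_mut <- if (g$strand == "+") mut23 else revcomp_chr(mut23)
      diff <- which(strsplit(gseq_ref, "")[[1]] != strsplit(gseq_mut, "")[[1]])
      stopifnot(length(diff) == 1)  # an SNV changes exactly one base
      # guide-strand index 1..20 = protospacer (5'->3'), 21..23 = PAM N,G,G;
      # protospacer index 20 sits next to the PAM (position 1) and PAM
      # indices 21,22,23 map to 0,-1,-2 -- uniformly 21 - index
      pos_from_pam <- 21L - diff
      carriers <- which(genotypes$dosage[, v$id[vi]] >= 1)
      for (s in carriers) {
        out[[length(out) + 1L]] <- data.frame(
          guide_id = g$guide_id, sample = rownames(genotypes$dosage)[s],
          variant_id = v$id[vi], position_from_pam = as.integer(pos_from_pam),
          zygosity = if (genotypes$dosage[s, v$id[vi]] == 2) "hom" else "het",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(guide_id = character(), sample = character(),
                      variant_id = character(),
                      position_from_pam = integer(), zygosity = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$guide_id, res$sample, res$variant_id), , drop = FALSE]
}

# Direct step-up FDR formulas (independent of p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

oracle_by <- function(p) {
  pmin(oracle_bh(p) * sum(1 / seq_along(p)), 1)
}

# Two-sided Fisher exact p by enumerating all tables with the observed
# margins and summing hypergeometric probabilities <= the observed one.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exhaustive PAM-site scan through Biostrings pattern matching
oracle_pam_sites <- function(seqname, seq, require_fit = TRUE) {
  dna <- Biostrings::DNAString(seq)
  plus <- Biostrings::start(Biostrings::matchPattern("NGG", dna,
                                                     fixed = FALSE)) - 1L
  minus <- Biostrings::start(Biostrings::matchPattern("CCN", dna,
                                                      fixed = FALSE)) - 1L
  L <- nchar(seq)
  rows <- rbind(
    if (length(plus)) data.frame(seqname = seqname, strand = "+",
                                 pam_start0 = plus,
                                 fits = plus - 20L >= 0L & plus + 3L <= L),
    if (length(minus)) data.frame(seqname = seqname, strand = "-",
                                  pam_start0 = minus,
                                  fits = minus + 23L <= L))
  if (is.null(rows)) return(data.frame(seqname = character(),
                                       strand = character(),
                                       pam_start0 = integer()))
  if (require_fit) rows <- rows[rows$fits, , drop = FALSE]
  rows$fits <- NULL
  rows <- rows[order(rows$seqname, rows$pam_start0, rows$strand), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# seeded candidate pool for library-design tests: 8 scored candidates per
# gene, about a third carrying one variant with random frequencies
design_fixture <- function(n_genes = 20, seed = 83) {
  set.seed(seed)
  cand <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    data.frame(gene = sprintf("gene%03d", g),
               guide_id = sprintf("gene%03d_c%02d", g, 1:8),
               on_target_score = round(runif(8), 4),
               stringsAsFactors = FALSE)
  }))
  hit <- cand$guide_id[runif(nrow(cand)) < 0.33]
  vars <- data.frame(guide_id = hit,
                     freq_all = round(runif(length(hit), 0, 0.05), 4),
                     freq_afr = round(runif(length(hit), 0, 0.05), 4),
                     freq_nonafr = round(runif(length(hit), 0, 0.05), 4),
                     stringsAsFactors = FALSE)
  list(candidates = cand, variants = vars)
}

# small standard cohort used by several test files
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(sim_config(n_samples = 30, n_genes = 10,
                             n_variants_per_chrom = 300,
                             n_chromosomes = 2, cm_per_chrom = 10,
                             seed = seed, ...))
}

# variant-dense cohort: enough natural guide/variant overlaps for burden
# statistics
dense_cohort <- function(seed = 1, ...) {
  simulate_cohort(sim_config(n_samples = 30, n_genes = 40,
                             n_variants_per_chrom = 5000,
                             n_chromosomes = 2, cm_per_chrom = 1,
                             seed = seed, ...))
}
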