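#' Simulate a reference allele-frequency panel
#'
#' Draws per-population alternate-allele frequencies under the
#' Balding-Nichols model: for each variant an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)` is drawn, and each population's frequency is
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F` that population's divergence
#' parameter. Frequencies are clipped to `[0.001, 0.999]`. Variant positions
#' are placed uniformly (distinct, sorted) along each chromosome with random
#' ref/alt single-nucleotide alleles.
#'
#' @param config A [sim_config()].
#' @return A list of class `"ancestry_panel"` with elements
#'   `variants` (data.frame: `id`, `chrom`, `start0`, `ref`, `alt`),
#'   `freq` (variants x populations matrix of alternate-allele frequencies),
#'   and `ancestral` (the ancestral frequencies).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "panel"))
  chrom_len <- as.integer(config$cm_per_chrom * 1e6)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  v_per <- config$n_variants_per_chrom
  pos0 <- unlist(lapply(chroms, function(ch) {
    sort(sample.int(chrom_len - 46L, v_per) + 22L)  # keep clear of ends
  }))
  chrom <- rep(chroms, each = v_per)
  n_var <- length(pos0)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  ancestral <- runif(n_var, 0.05, 0.95)
  freq <- matrix(NA_real_, n_var, config$n_populations,
                 dimnames = list(NULL, config$population_labels))
  for (k in seq_len(config$n_populations)) {
    f <- config$fst[k]
    freq[, k] <- if (f == 0) ancestral else {
      rbeta(n_var, ancestral * (1 - f) / f, (1 - ancestral) * (1 - f) / f)
    }
  }
  freq <- pmin(pmax(freq, 0.001), 0.999)
  variants <- data.frame(
    id = paste0(chrom, ":", pos0 + 1L, ":", ref, ":", alt),
    chrom = chrom, start0 = as.integer(pos0), ref = ref, alt = alt,
    stringsAsFactors = FALSE)
  rownames(freq) <- variants$id
  structure(list(variants = variants, freq = freq, ancestral = ancestral),
            class = "ancestry_panel")
}

# default admixture: samples split evenly across populations, each 90% its
# own population and 10% spread over the others
default_admixture <- function(n_samples, n_populations) {
  own <- rep(seq_len(n_populations), length.out = n_samples)
  m <- matrix(0.1 / (n_populations - 1), n_samples, n_populations)
  m[cbind(seq_len(n_samples), own)] <- 0.9
  m
}

#' Simulate admixed diploid genomes over a genetic map
#'
#' Each haplotype of each sample is a mosaic of ancestry blocks: breakpoints
#' follow a Poisson process on the centimorgan scale with rate
#' `config$block_rate_per_cm`, and each block's population is drawn from the
#' sample's admixture proportions. The painting is discretised to the
#' genetic-map windows of [build_windows()] (a window takes the population of
#' the block covering its cM midpoint), and alleles within a window are drawn
#' `Bernoulli(f_pop)` from the panel. Diploid dosages are the sum of the two
#' haplotypes.
#'
#' @param panel An `"ancestry_panel"`.
#' @param map A [genetic_map()] covering all panel variants.
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (class `"variant_genotypes"`:
#'   `variants` data.frame plus a samples x variants `dosage` matrix in
#'   `{0,1,2}`), `truth` (class `"truth_set"`: `windows`, per-haplotype
#'   painting matrices `hap1`/`hap2` of samples x windows population labels,
#'   `admixture`), and `windows`.
#' @export
simulate_admixed_genomes <- function(panel, map, config) {
  stopifnot(inherits(panel, "ancestry_panel"), inherits(config, "sim_config"))
  if (nrow(map) == 0) stop("empty genetic map", call. = FALSE)
  set.seed(stage_seed(config$seed, "genomes"))
  windows <- build_windows(map, panel$variants, min_cm = config$window_cm)
  n_win <- nrow(windows)
  n_var <- nrow(panel$variants)
  n_s <- config$n_samples
  pops <- config$population_labels
  admix <- config$admixture_proportions
  if (is.null(admix)) admix <- default_admixture(n_s, config$n_populations)

  # cM midpoint of each window, relative to its chromosome start
  chr_of_win <- windows$chrom
  cm_mid <- (windows$cm_start + windows$cm_end) / 2
  cm_lo_chr <- tapply(windows$cm_start, chr_of_win, min)[chr_of_win]
  cm_len_chr <- tapply(windows$cm_end, chr_of_win, max)[chr_of_win]
  rel_mid <- cm_mid - cm_lo_chr

  # population index of each variant's window, per haplotype painting
  win_of_var <- rep(NA_integer_, n_var)
  ok <- !is.na(windows$first_variant)
  for (w in which(ok)) {
    win_of_var[windows$first_variant[w]:windows$last_variant[w]] <- w
  }

  paint_hap <- function(props) {
    # one haplotype: per-window population labels across all chromosomes
    lab <- character(n_win)
    for (chr in unique(chr_of_win)) {
      sel <- chr_of_win == chr
      len <- max(windows$cm_end[sel]) - min(windows$cm_start[sel])
      brk <- 0
      repeat {
        nxt <- brk[length(brk)] + rexp(1, rate = config$block_rate_per_cm)
        if (nxt >= len) break
        brk <- c(brk, nxt)
      }
      seg_pop <- sample(pops, length(brk), replace = TRUE, prob = props)
      lab[sel] <- seg_pop[findInterval(rel_mid[sel], brk)]
    }
    lab
  }

  sample_ids <- sprintf("S%03d", seq_len(n_s))
  hap1 <- matrix(NA_character_, n_s, n_win,
                 dimnames = list(sample_ids, NULL))
  hap2 <- hap1
  dosage <- matrix(0L, n_s, n_var,
                   dimnames = list(sample_ids, panel$variants$id))
  for (i in seq_len(n_s)) {
    h1 <- paint_hap(admix[i, ]); h2 <- paint_hap(admix[i, ])
    hap1[i, ] <- h1; hap2[i, ] <- h2
    f1 <- panel$freq[cbind(seq_len(n_var), match(h1[win_of_var], pops))]
    f2 <- panel$freq[cbind(seq_len(n_var), match(h2[win_of_var], pops))]
    dosage[i, ] <- (runif(n_var) < f1) + (runif(n_var) < f2)
  }

  genotypes <- structure(list(variants = panel$variants, dosage = dosage,
                              samples = sample_ids),
                         class = "variant_genotypes")
  truth <- structure(list(windows = windows, hap1 = hap1, hap2 = hap2,
                          admixture = admix, population_labels = pops,
                          causal_artifact_table = NULL,
                          true_effects = config$true_effects,
                          positional_weights_used = config$positional_weights),
                     class = "truth_set")
  list(genotypes = genotypes, truth = truth, windows = windows)
}

#' Simulate a tiled guide library and TSS table
#'
#' Places `n_genes` at distinct, evenly spaced transcription start sites along
#' the chromosomes and tiles each gene with `guides_per_gene` guides on mixed
#' strands within a 2 kb locus downstream of the TSS. Every guide has a 20-nt
#' protospacer, an NGG PAM on the guide strand, and a 23-bp genomic targeting
#' interval that stays clear of chromosome ends.
#'
#' @param config A [sim_config()].
#' @param map A [genetic_map()] defining chromosome extents.
#' @return A list with `library` (data.frame of class `"guide_library"`:
#'   `guide_id`, `gene`, `chrom`, `start0`, `end0`, `strand`, `protospacer`,
#'   `pam`) and `tss` (data.frame: `gene`, `chrom`, `tss0`).
#' @export
simulate_guide_library <- function(config, map) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "library"))
  chroms <- unique(map$chrom)
  chr_len <- vapply(chroms, function(ch) max(map$pos[map$chrom == ch]), 0)
  locus_span <- 2000L
  genes_per_chrom <- ceiling(config$n_genes / length(chroms))
  spacing <- floor((min(chr_len) - 2 * locus_span) / genes_per_chrom)
  if (spacing < locus_span + 100L) {
    stop("gene loci would overlap: too many genes for the simulated genome",
         call. = FALSE)
  }
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  gene_chr <- chroms[rep(seq_along(chroms), each = genes_per_chrom)][
    seq_len(config$n_genes)]
  within_idx <- unlist(lapply(table(factor(gene_chr, levels = chroms)),
                              seq_len), use.names = FALSE)
  tss0 <- as.integer(locus_span + (within_idx - 1L) * spacing)
  bases <- c("A", "C", "G", "T")
  recs <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    k <- config$guides_per_gene
    strand <- sample(c("+", "-"), k, replace = TRUE)
    # non-overlapping guide starts inside the gene locus
    offs <- sort(sample.int(locus_span - 23L, k))
    while (any(diff(offs) < 23L)) offs <- sort(sample.int(locus_span - 23L, k))
    start0 <- tss0[g] + offs
    protospacer <- vapply(seq_len(k), function(j) {
      paste(sample(bases, 20, replace = TRUE), collapse = "")
    }, "")
    pam <- vapply(seq_len(k), function(j) {
      paste(c(sample(bases, 1), "G", "G"), collapse = "")
    }, "")
    recs[[g]] <- data.frame(
      guide_id = sprintf("%s_g%d", gene_ids[g], seq_len(k)),
      gene = gene_ids[g], chrom = gene_chr[g],
      start0 = start0, end0 = start0 + 23L, strand = strand,
      protospacer = protospacer, pam = pam, stringsAsFactors = FALSE)
  }
  library <- do.call(rbind, recs)
  rownames(library) <- NULL
  class(library) <- c("guide_library", "data.frame")
  tss <- data.frame(gene = gene_ids, chrom = gene_chr, tss0 = tss0,
                    stringsAsFactors = FALSE)
  list(library = library, tss = tss)
}

# Genomic 0-based position of a protospacer position-from-PAM (1..20) or a
# PAM position (0, -1, -2) for one guide record.
position_to_genomic <- function(start0, strand, position) {
  ifelse(strand == "+", start0 + 20L - position, start0 + 2L + position)
}

#' Inject artifact variants into a panel
#'
#' For every row of `config$artifacts`, relocates the panel variant nearest to
#' the targeted guide position into the guide's targeting sequence at the
#' requested position-from-PAM and sets its population allele frequencies to
#' `config$artifact_freqs`, making it an ancestry-differential in-guide SNV.
#' Run before [simulate_admixed_genomes()] so genotypes reflect the injected
#' frequencies.
#'
#' @param panel An `"ancestry_panel"`.
#' @param library A `"guide_library"`.
#' @param config A [sim_config()] with a non-NULL `artifacts` table.
#' @return A list with the modified `panel` and `artifact_table` (data.frame:
#'   `gene`, `guide_id`, `variant_id`, `position`, `effect`).
#' @export
inject_artifacts <- function(panel, library, config) {
  art <- config$artifacts
  if (is.null(art) || nrow(art) == 0) {
    return(list(panel = panel, artifact_table = NULL))
  }
  genes <- unique(library$gene)
  rows <- integer(nrow(art)); pos0 <- integer(nrow(art))
  for (r in seq_len(nrow(art))) {
    gl <- library[library$gene == genes[art$gene[r]], , drop = FALSE]
    gd <- gl[art$guide[r], ]
    pos0[r] <- position_to_genomic(gd$start0, gd$strand, art$position[r])
    cand <- which(panel$variants$chrom == gd$chrom)
    cand <- cand[!(cand %in% rows)]
    rows[r] <- cand[which.min(abs(panel$variants$start0[cand] - pos0[r]))]
  }
  if (anyDuplicated(pos0)) {
    stop("injected artifact positions collide; choose distinct guides",
         call. = FALSE)
  }
  v <- panel$variants
  v$start0[rows] <- pos0
  panel$freq[rows, ] <- matrix(config$artifact_freqs, length(rows),
                               config$n_populations, byrow = TRUE)
  v$id[rows] <- paste0(v$chrom[rows], ":", pos0 + 1L, ":", v$ref[rows],
                       ":", v$alt[rows])
  # restore sort order after relocation
  ord <- order(match(v$chrom, unique(v$chrom)), v$start0)
  panel$variants <- v[ord, , drop = FALSE]
  rownames(panel$variants) <- NULL
  panel$freq <- panel$freq[ord, , drop = FALSE]
  rownames(panel$freq) <- panel$variants$id
  panel$ancestral <- panel$ancestral[ord]
  gl_rows <- do.call(rbind, lapply(seq_len(nrow(art)), function(r) {
    gl <- library[library$gene == genes[art$gene[r]], , drop = FALSE]
    data.frame(gene = genes[art$gene[r]], guide_id = gl$guide_id[art$guide[r]],
               variant_id = v$id[rows[r]], position = art$position[r],
               effect = if ("effect" %in% names(art)) art$effect[r] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(panel = panel, artifact_table = gl_rows)
}

#' Simulate a pooled CRISPR screen with mismatch attenuation
#'
#' Guide-level log-fold-changes follow
#' `LFC(g, c) = effect(gene(g), c) * activity(g, c) + N(0, noise_sd^2)`.
#' The per-cell effect is the gene's baseline dependency plus a per-lineage
#' offset plus any injected true ancestry effect (added in proportion to the
#' number of matching haplotypes at the gene's TSS). Activity multiplies, over
#' every variant mismatching the guide's targeting sequence in that cell,
#' `(1 - w_position * d)` where `d` is 1 for homozygous-alternate carriers and
#' `het_attenuation_factor` for heterozygous carriers. The gene-level matrix
#' is the per-gene mean of guide scores (uncorrected).
#'
#' @param library A `"guide_library"`.
#' @param genotypes A `"variant_genotypes"`.
#' @param truth The `"truth_set"` from [simulate_admixed_genomes()] (supplies
#'   the painting used for true ancestry effects).
#' @param config A [sim_config()].
#' @param tss TSS table (needed when `config$true_effects` is set).
#' @param artifact_table Artifact table from [inject_artifacts()] (optional;
#'   used to override baseline effects of artifact genes).
#' @return A list of class `"screen_data"`: `guide_lfc` (samples x guides),
#'   `gene_dependency` (samples x genes), `expression` (samples x genes, RPM),
#'   `lineage` (factor), `gene_effects`, `activity` (samples x guides), and
#'   `mismatches` (the mismatch table used).
#' @export
simulate_screen <- function(library, genotypes, truth, config,
                            tss = NULL, artifact_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "screen"))
  n_s <- nrow(genotypes$dosage)
  samples <- rownames(genotypes$dosage)
  genes <- unique(library$gene)
  n_genes <- length(genes)
  n_guides <- nrow(library)

  lineage <- factor(paste0("lineage", sample.int(config$n_lineages, n_s,
                                                 replace = TRUE)))
  gene_eff <- rnorm(n_genes, config$gene_effect_mean, config$gene_effect_sd)
  names(gene_eff) <- genes
  if (!is.null(artifact_table) && "effect" %in% names(artifact_table)) {
    ov <- !is.na(artifact_table$effect)
    gene_eff[artifact_table$gene[ov]] <- artifact_table$effect[ov]
  }
  lin_off <- matrix(rnorm(nlevels(lineage) * n_genes, 0,
                          config$lineage_effect_sd),
                    nlevels(lineage), n_genes,
                    dimnames = list(levels(lineage), genes))

  # effect matrix: samples x genes
  eff <- matrix(gene_eff, n_s, n_genes, byrow = TRUE,
                dimnames = list(samples, genes))
  eff <- eff + lin_off[as.integer(lineage), , drop = FALSE]
  if (!is.null(config$true_effects)) {
    stopifnot(!is.null(tss))
    te <- config$true_effects
    for (r in seq_len(nrow(te))) {
      gname <- if (is.numeric(te$gene)) genes[te$gene[r]] else te$gene[r]
      trow <- tss[tss$gene == gname, ]
      w <- window_at(truth$windows, trow$chrom, trow$tss0)
      match1 <- truth$hap1[, w] == te$ancestry[r]
      match2 <- truth$hap2[, w] == te$ancestry[r]
      eff[, gname] <- eff[, gname] + te$effect[r] * (match1 + match2) / 2
    }
  }

  mm <- map_variants_to_guides(genotypes, library)
  w_all <- c(config$pam_weights[3], config$pam_weights[2],
             config$pam_weights[1], config$positional_weights)
  # index by position + 3 (position -2 -> 1, ..., position 20 -> 23)
  activity <- matrix(1, n_s, n_guides, dimnames = list(samples,
                                                       library$guide_id))
  if (nrow(mm)) {
    d <- ifelse(mm$zygosity == "hom", 1, config$het_attenuation_factor)
    fac <- 1 - w_all[mm$position_from_pam + 3L] * d
    cell <- (match(mm$guide_id, library$guide_id) - 1L) * n_s +
      match(mm$sample, samples)
    prod_by_cell <- exp(rowsum(log(fac), cell))  # log(0) -> -Inf -> 0, exact
    activity[as.integer(rownames(prod_by_cell))] <- prod_by_cell[, 1]
  }
  gene_of_guide <- match(library$gene, genes)
  guide_lfc <- eff[, gene_of_guide, drop = FALSE] * activity +
    matrix(rnorm(n_s * n_guides, 0, config$noise_sd), n_s, n_guides)
  dimnames(guide_lfc) <- list(samples, library$guide_id)
  gene_dep <- vapply(seq_len(n_genes), function(g) {
    rowMeans(guide_lfc[, gene_of_guide == g, drop = FALSE])
  }, numeric(n_s))
  dimnames(gene_dep) <- list(samples, genes)

  set.seed(stage_seed(config$seed, "expression"))
  expression <- matrix(
    rlnorm(n_s * n_genes, config$expression_meanlog, config$expression_sdlog),
    n_s, n_genes, dimnames = list(samples, genes))

  structure(list(guide_lfc = guide_lfc, gene_dependency = gene_dep,
                 expression = expression, lineage = lineage,
                 gene_effects = gene_eff, activity = activity,
                 mismatches = mm),
            class = "screen_data")
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: genetic map, Balding-Nichols panel, guide library
#' and TSS table, artifact injection, admixed genomes with ancestry painting,
#' and the pooled screen. Everything is a pure function of `config` (same
#' config, same seed, identical output).
#'
#' @param config A [sim_config()].
#' @return A list of class `"cohort"` with elements `config`, `map`, `panel`,
#'   `library`, `tss`, `genotypes`, `truth`, `windows`, `screen`, `metadata`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20, n_genes = 10,
#'                                      n_variants_per_chrom = 200))
#' dim(cohort$screen$gene_dependency)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  chrom_len <- setNames(rep(as.integer(config$cm_per_chrom * 1e6),
                            config$n_chromosomes),
                        paste0("chr", seq_len(config$n_chromosomes)))
  map <- uniform_genetic_map(chrom_len)
  panel <- simulate_panel(config)
  lib <- simulate_guide_library(config, map)
  inj <- inject_artifacts(panel, lib$library, config)
  gen <- simulate_admixed_genomes(inj$panel, map, config)
  gen$truth$causal_artifact_table <- inj$artifact_table
  screen <- simulate_screen(lib$library, gen$genotypes, gen$truth, config,
                            tss = lib$tss, artifact_table = inj$artifact_table)
  admix <- gen$truth$admixture
  metadata <- data.frame(
    sample_id = gen$genotypes$samples,
    lineage = as.character(screen$lineage),
    true_global_ancestry = config$population_labels[apply(admix, 1, which.max)],
    stringsAsFactors = FALSE)
  structure(list(config = config, map = map, panel = inj$panel,
                 library = lib$library, tss = lib$tss,
                 genotypes = gen$genotypes, truth = gen$truth,
                 windows = gen$windows, screen = screen, metadata = metadata),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d variants, %d genes x %d guides, %d windows\n",
              nrow(x$genotypes$dosage), nrow(x$genotypes$variants),
              length(unique(x$library$gene)),
              nrow(x$library) / length(unique(x$library$gene)),
              nrow(x$windows)))
  invisible(x)
}
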