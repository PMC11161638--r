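#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator into a validated list.
#' Defaults describe a small admixed cohort screened with a 4-guides-per-gene
#' library; all randomness downstream is a pure function of `seed`.
#'
#' @param n_populations Number of ancestral populations (>= 2).
#' @param fst Balding-Nichols divergence parameter per population, each in
#'   `[0, 1)`; recycled to `n_populations`.
#' @param population_labels Labels for the populations. Defaults to the first
#'   `n_populations` of `c("AFR", "EUR", "EAS", "AMR", "SAS")` so that the
#'   groups used by downstream ancestry-restricted analyses come first.
#' @param n_samples Number of diploid samples (cell lines).
#' @param n_chromosomes,n_variants_per_chrom,cm_per_chrom Genome shape: number
#'   of chromosomes, SNVs per chromosome, and genetic length per chromosome in
#'   centimorgans. Physical length is `cm_per_chrom` megabases (uniform
#'   1 cM/Mb map).
#' @param admixture_proportions Either `NULL` (each sample drawn mostly from
#'   one population: 90% its own ancestry, 10% spread over the rest, with
#'   samples assigned to populations in equal shares) or an
#'   `n_samples x n_populations` matrix of mixture weights with rows summing
#'   to 1.
#' @param block_rate_per_cm Rate of the Poisson ancestry-breakpoint process on
#'   the centimorgan scale; the default 0.1 gives a mean ancestry-block length
#'   of 10 cM.
#' @param n_genes,guides_per_gene Library shape (default 4 guides per gene).
#' @param positional_weights Numeric vector of length 20 in `[0, 1]`: the
#'   attenuation weight of a mismatch at each protospacer position, position 1
#'   being PAM-proximal. Default 1 for positions 1-12 decaying linearly to 0.2
#'   at position 20 (PAM-proximal mismatches abolish cutting, PAM-distal ones
#'   are partially tolerated).
#' @param pam_weights Attenuation for PAM-site mismatches, a length-3 vector
#'   for positions 0 (the degenerate N, default 0), -1 and -2 (the two Gs,
#'   default 1).
#' @param het_attenuation_factor Mismatch "dose" of a heterozygous carrier in
#'   `[0, 1]`; the default 1 treats presence as binary (het and hom carriers
#'   are equally attenuated).
#' @param noise_sd Standard deviation of guide-level log-fold-change noise.
#' @param gene_effect_mean,gene_effect_sd Per-gene baseline dependency effect
#'   drawn `N(gene_effect_mean, gene_effect_sd^2)`; more negative = more
#'   depleted.
#' @param n_lineages,lineage_effect_sd Number of cancer lineages and the SD of
#'   per-gene lineage offsets.
#' @param artifacts `NULL` or a data.frame with columns `gene` (gene index),
#'   `guide` (guide index within gene, 1-based), `position` (position from PAM,
#'   1-20) and optionally `effect` (overrides the gene's baseline effect).
#'   Each row injects one SNV into that guide's targeting sequence at that
#'   position, with population allele frequencies given by `artifact_freqs`.
#' @param artifact_freqs Population alternate-allele frequencies for injected
#'   artifact variants; recycled to `n_populations`. The default
#'   `c(0.85, 0.02, ...)` makes artifact variants strongly
#'   ancestry-differential (common in population 1, rare elsewhere).
#' @param true_effects `NULL` or a data.frame with columns `gene` (gene
#'   index), `ancestry` (population label) and `effect`: a genuine
#'   ancestry-specific dependency added to samples whose local ancestry at the
#'   gene's TSS is the given population.
#' @param window_cm Minimum genetic-map window size in centimorgans used for
#'   the ancestry painting (and downstream inference); default 0.2.
#' @param expression_meanlog,expression_sdlog Log-normal parameters of
#'   simulated per-gene expression (reads per million).
#' @param seed Integer seed; every simulation stage derives its own stream
#'   from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_populations = 2,
                       fst = 0.1,
                       population_labels = NULL,
                       n_samples = 100,
                       n_chromosomes = 2,
                       n_variants_per_chrom = 1000,
                       cm_per_chrom = 20,
                       admixture_proportions = NULL,
                       block_rate_per_cm = 0.1,
                       n_genes = 50,
                       guides_per_gene = 4,
                       positional_weights = default_positional_weights(),
                       pam_weights = c(0, 1, 1),
                       het_attenuation_factor = 1,
                       noise_sd = 1,
                       gene_effect_mean = -1,
                       gene_effect_sd = 0.5,
                       n_lineages = 4,
                       lineage_effect_sd = 0.2,
                       artifacts = NULL,
                       artifact_freqs = c(0.85, 0.02),
                       true_effects = NULL,
                       window_cm = 0.2,
                       expression_meanlog = log(20),
                       expression_sdlog = 1.5,
                       seed = 1L) {
  if (!is.numeric(n_populations) || n_populations < 2) {
    stop("n_populations must be >= 2", call. = FALSE)
  }
  n_populations <- as.integer(n_populations)
  fst <- rep_len(as.numeric(fst), n_populations)
  if (any(!is.finite(fst)) || any(fst < 0) || any(fst >= 1)) {
    stop("fst values must be finite and in [0, 1)", call. = FALSE)
  }
  if (is.null(population_labels)) {
    defaults <- c("AFR", "EUR", "EAS", "AMR", "SAS")
    population_labels <- if (n_populations <= length(defaults)) {
      defaults[seq_len(n_populations)]
    } else {
      c(defaults, paste0("POP", seq_len(n_populations - length(defaults))))
    }
  }
  stopifnot(length(population_labels) == n_populations,
            !anyDuplicated(population_labels))
  counts <- c(n_samples = n_samples, n_chromosomes = n_chromosomes,
              n_variants_per_chrom = n_variants_per_chrom,
              n_genes = n_genes, guides_per_gene = guides_per_gene,
              n_lineages = n_lineages)
  if (any(counts < 1)) {
    stop("all counts must be positive: ",
         paste(names(counts)[counts < 1], collapse = ", "), call. = FALSE)
  }
  if (!is.null(admixture_proportions)) {
    admixture_proportions <- as.matrix(admixture_proportions)
    if (nrow(admixture_proportions) != n_samples ||
        ncol(admixture_proportions) != n_populations) {
      stop("admixture_proportions must be n_samples x n_populations",
           call. = FALSE)
    }
    if (any(abs(rowSums(admixture_proportions) - 1) > 1e-8) ||
        any(admixture_proportions < 0)) {
      stop("admixture proportions must be non-negative and sum to 1 per sample",
           call. = FALSE)
    }
  }
  if (length(positional_weights) != 20 ||
      any(positional_weights < 0 | positional_weights > 1)) {
    stop("positional_weights must be 20 values in [0, 1]", call. = FALSE)
  }
  stopifnot(length(pam_weights) == 3,
            het_attenuation_factor >= 0, het_attenuation_factor <= 1,
            noise_sd > 0, lineage_effect_sd >= 0, cm_per_chrom > 0,
            block_rate_per_cm > 0, window_cm > 0)
  if (!is.null(artifacts)) {
    artifacts <- as.data.frame(artifacts)
    stopifnot(all(c("gene", "guide", "position") %in% names(artifacts)))
    if (any(artifacts$gene < 1 | artifacts$gene > n_genes) ||
        any(artifacts$guide < 1 | artifacts$guide > guides_per_gene)) {
      stop("artifact gene/guide indices out of range", call. = FALSE)
    }
    if (any(artifacts$position < 1 | artifacts$position > 20)) {
      stop("artifact positions must be protospacer positions 1-20",
           call. = FALSE)
    }
  }
  if (!is.null(true_effects)) {
    true_effects <- as.data.frame(true_effects)
    stopifnot(all(c("gene", "ancestry", "effect") %in% names(true_effects)))
    if (!all(true_effects$ancestry %in% population_labels)) {
      stop("true_effects ancestry labels must be population labels",
           call. = FALSE)
    }
  }
  structure(list(
    n_populations = n_populations, fst = fst,
    population_labels = population_labels,
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    n_variants_per_chrom = as.integer(n_variants_per_chrom),
    cm_per_chrom = cm_per_chrom,
    admixture_proportions = admixture_proportions,
    block_rate_per_cm = block_rate_per_cm,
    n_genes = as.integer(n_genes),
    guides_per_gene = as.integer(guides_per_gene),
    positional_weights = as.numeric(positional_weights),
    pam_weights = as.numeric(pam_weights),
    het_attenuation_factor = het_attenuation_factor,
    noise_sd = noise_sd,
    gene_effect_mean = gene_effect_mean, gene_effect_sd = gene_effect_sd,
    n_lineages = as.integer(n_lineages),
    lineage_effect_sd = lineage_effect_sd,
    artifacts = artifacts,
    artifact_freqs = rep_len(as.numeric(artifact_freqs), n_populations),
    true_effects = true_effects,
    window_cm = window_cm,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default positional mismatch-attenuation weights
#'
#' Weight 1 (complete loss of cutting) for PAM-proximal seed positions 1-12,
#' decaying linearly to 0.2 at the PAM-distal position 20.
#'
#' @return Numeric vector of length 20.
#' @export
default_positional_weights <- function() {
  c(rep(1, 12), seq(1, 0.2, length.out = 9)[-1])
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d populations (%s), Fst %s\n", x$n_populations,
              paste(x$population_labels, collapse = ", "),
              paste(unique(x$fst), collapse = "/")))
  cat(sprintf("  %d samples, %d chromosome(s) x %d variants (%g cM each)\n",
              x$n_samples, x$n_chromosomes, x$n_variants_per_chrom,
              x$cm_per_chrom))
  cat(sprintf("  %d genes x %d guides; noise sd %g; %d lineages\n",
              x$n_genes, x$guides_per_gene, x$noise_sd, x$n_lineages))
  cat(sprintf("  artifacts: %d; true ancestry effects: %d; seed %d\n",
              if (is.null(x$artifacts)) 0L else nrow(x$artifacts),
              if (is.null(x$true_effects)) 0L else nrow(x$true_effects),
              x$seed))
  invisible(x)
}

#' Pipeline thresholds
#'
#' All analysis thresholds in one place. Defaults are the standard operating
#' point of the pipeline: 0.2 cM ancestry windows, a strict 80% predominance
#' rule, FDR 0.05 for both BH and BY families, a 1% minor-allele-frequency
#' floor for the d-QTL scan, a 0.2 differential-frequency rule for calling a
#' marker ancestry-associated, a 1 Mb TSS proximity rule, a 10-cell-line floor
#' for flagging recurrently affected guides, a 2.5x AFR/non-AFR carrier-rate
#' cap and 1% variant-frequency cap for library design, 4 guides per gene,
#' 1000 power-simulation replicates, a 5 reads-per-million weak-expression
#' cutoff, and r^2 >= 0.8 for linkage between a marker and an in-guide
#' variant.
#'
#' @param window_cm,predominance_threshold,fdr_q,maf_min,differential_maf
#'   Ancestry window size (cM), global-ancestry predominance fraction, FDR
#'   cutoff, minimum MAF, differential-MAF threshold.
#' @param proximal_bp,min_affected_lines,afr_ratio_max,guides_per_gene
#'   TSS-proximity distance (bp), minimum affected cell lines per flagged
#'   guide, maximum AFR/non-AFR carrier ratio, guides per gene.
#' @param power_reps,expression_rpm_threshold,ld_r2_threshold,
#'   differential_lfc Replicates for power simulation, weak-expression
#'   threshold (RPM), LD r^2 threshold, and the |LFC difference| above which a
#'   guide counts as differentially depleted between two ancestry groups.
#' @param include_pam_n Count variants at the degenerate PAM N position as
#'   mismatches (default `FALSE`: an N-site SNV cannot disrupt NGG
#'   recognition).
#' @param positional_test Headline test for positional effects, `"t"` or
#'   `"wilcoxon"` (both are always computed).
#' @param seed Integer seed used by [run_pipeline()].
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(window_cm = 0.2,
                            predominance_threshold = 0.8,
                            fdr_q = 0.05,
                            maf_min = 0.01,
                            differential_maf = 0.2,
                            proximal_bp = 1e6,
                            min_affected_lines = 10,
                            afr_ratio_max = 2.5,
                            guides_per_gene = 4,
                            power_reps = 1000,
                            expression_rpm_threshold = 5,
                            ld_r2_threshold = 0.8,
                            differential_lfc = 0.25,
                            include_pam_n = FALSE,
                            positional_test = c("t", "wilcoxon"),
                            seed = 1L) {
  positional_test <- match.arg(positional_test)
  probs <- c(predominance_threshold = predominance_threshold,
             fdr_q = fdr_q, maf_min = maf_min,
             differential_maf = differential_maf,
             ld_r2_threshold = ld_r2_threshold)
  if (any(probs <= 0 | probs >= 1)) {
    stop("thresholds on the probability scale must lie in (0, 1): ",
         paste(names(probs)[probs <= 0 | probs >= 1], collapse = ", "),
         call. = FALSE)
  }
  pos <- c(window_cm = window_cm, proximal_bp = proximal_bp,
           min_affected_lines = min_affected_lines,
           afr_ratio_max = afr_ratio_max, guides_per_gene = guides_per_gene,
           power_reps = power_reps,
           expression_rpm_threshold = expression_rpm_threshold,
           differential_lfc = differential_lfc)
  if (any(pos <= 0)) {
    stop("thresholds must be positive: ",
         paste(names(pos)[pos <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(
    window_cm = window_cm,
    predominance_threshold = predominance_threshold,
    fdr_q = fdr_q, maf_min = maf_min, differential_maf = differential_maf,
    proximal_bp = proximal_bp,
    min_affected_lines = as.integer(min_affected_lines),
    afr_ratio_max = afr_ratio_max,
    guides_per_gene = as.integer(guides_per_gene),
    power_reps = as.integer(power_reps),
    expression_rpm_threshold = expression_rpm_threshold,
    ld_r2_threshold = ld_r2_threshold,
    differential_lfc = differential_lfc,
    include_pam_n = include_pam_n,
    positional_test = positional_test,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

# Derive an independent per-stage RNG seed from the global seed.
# Kept below 2^31 so it is always a valid R integer.
stage_seed <- function(seed, stage) {
  stages <- c(panel = 11L, genomes = 23L, library = 37L, screen = 51L,
              expression = 67L, power = 83L, pam = 97L, design = 113L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 127L + off) %% 2147483647)
}
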