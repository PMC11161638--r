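#' Candidate guides for library design from a simulated cohort
#'
#' Builds a per-gene candidate pool for [design_library()]: `n_per_gene`
#' candidate guides tiled over each gene locus with seeded on-target scores
#' in `[0, 1]`, annotated with the panel variants overlapping each targeting
#' interval (`freq_all` = mean across populations, `freq_afr` = the AFR
#' column when present, `freq_nonafr` = mean of the remaining populations).
#'
#' @param cohort A `"cohort"`.
#' @param n_per_gene Candidates per gene (default 8).
#' @param seed Seed for placement and scores.
#' @return List with `candidates` and `candidate_variants` frames in the
#'   shapes [design_library()] expects.
#' @export
candidates_from_cohort <- function(cohort, n_per_gene = 8, seed = 1L) {
  set.seed(stage_seed(seed, "design"))
  tss <- cohort$tss
  bases <- c("A", "C", "G", "T")
  cand <- list()
  for (i in seq_len(nrow(tss))) {
    offs <- sort(sample.int(1977L, n_per_gene))
    start0 <- tss$tss0[i] + offs
    cand[[i]] <- data.frame(
      gene = tss$gene[i],
      guide_id = sprintf("%s_cand%02d", tss$gene[i], seq_len(n_per_gene)),
      chrom = tss$chrom[i], start0 = start0, end0 = start0 + 23L,
      strand = sample(c("+", "-"), n_per_gene, replace = TRUE),
      protospacer = vapply(seq_len(n_per_gene), function(j)
        paste(sample(bases, 20, replace = TRUE), collapse = ""), ""),
      pam = vapply(seq_len(n_per_gene), function(j)
        paste(c(sample(bases, 1), "G", "G"), collapse = ""), ""),
      on_target_score = round(runif(n_per_gene), 4),
      stringsAsFactors = FALSE)
  }
  candidates <- do.call(rbind, cand)
  pv <- cohort$panel$variants
  freq <- cohort$panel$freq
  pops <- colnames(freq)
  afr_col <- if ("AFR" %in% pops) "AFR" else pops[1]
  hits <- list()
  for (chr in unique(candidates$chrom)) {
    ci <- which(candidates$chrom == chr)
    vi <- which(pv$chrom == chr)
    if (!length(ci) || !length(vi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(pv$start0[vi] + 1L, width = 1L),
      IRanges::IRanges(candidates$start0[ci] + 1L, width = 23L))
    if (length(ov)) {
      v <- vi[S4Vectors::queryHits(ov)]
      hits[[chr]] <- data.frame(
        guide_id = candidates$guide_id[ci[S4Vectors::subjectHits(ov)]],
        variant_id = pv$id[v],
        freq_all = rowMeans(freq[v, , drop = FALSE]),
        freq_afr = freq[v, afr_col],
        freq_nonafr = rowMeans(freq[v, setdiff(pops, afr_col),
                                    drop = FALSE]),
        stringsAsFactors = FALSE)
    }
  }
  candidate_variants <- if (length(hits)) do.call(rbind, hits) else
    data.frame(guide_id = character(), variant_id = character(),
               freq_all = numeric(), freq_afr = numeric(),
               freq_nonafr = numeric())
  rownames(candidate_variants) <- NULL
  list(candidates = candidates, candidate_variants = candidate_variants)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in order: cohort simulation, local-ancestry
#' inference, per-group ancestry-dependency association, mismatch mapping and
#' burden summaries, d-QTL scanning for the flagged dependencies, positional
#' effect estimation, guide-exclusion correction with pre/post differential
#' testing and re-association, and ancestry-aware library design. All
#' randomness derives from the two configs, so identical configs give
#' identical outputs.
#'
#' @param sim_cfg A [sim_config()] describing the cohort.
#' @param config A [pipeline_config()] of analysis thresholds.
#' @param outdir Optional output directory; when given, per-stage TSVs, a
#'   `summary.json` and a `log.txt` are written.
#' @return A list of class `"pipeline_result"` with the stage outputs
#'   (`cohort`, `track`, `global`, `labels`, `associations`, `mismatches`,
#'   `burden`, `dqtl`, `positional`, `corrected`, `pre_post`,
#'   `reassociation`, `design`, `summary`).
#' @export
run_pipeline <- function(sim_cfg, config = pipeline_config(),
                         outdir = NULL) {
  stopifnot(inherits(sim_cfg, "sim_config"),
            inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("guidebias pipeline, seed %d / %d",
                         sim_cfg$seed, config$seed),
                 sprintf("config hash: %s", config_hash(sim_cfg, config)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", simulate_cohort(sim_cfg))
  track <- stage("ancestry", infer_local_ancestry(cohort$genotypes,
                                                  cohort$panel,
                                                  cohort$windows))
  global <- global_ancestry_fractions(track, config$predominance_threshold)
  labels <- stage("bin", bin_samples_by_locus_ancestry(cohort$tss, track,
                                                       global))
  groups <- sort(unique(as.vector(labels)))
  assoc <- stage("associate", do.call(rbind, lapply(groups, function(g) {
    test_ancestry_dependency(cohort$screen, labels, g, config$fdr_q)
  })))

  mm <- stage("guides", map_variants_to_guides(cohort$genotypes,
                                               cohort$library))
  fractions <- per_sample_affected_fraction(
    mm, cohort$library, samples = cohort$genotypes$samples,
    include_pam_n = config$include_pam_n)
  recurrent <- guides_affected_in_k_samples(mm, config$min_affected_lines,
                                            config$include_pam_n)
  histo <- per_gene_affected_guide_histogram(mm, cohort$library,
                                             config$include_pam_n)
  burden_ratio <- afr_burden_ratio(fractions,
                                   setNames(global$predominant,
                                            names(fractions)))

  # d-QTL scan over the dependencies flagged by the association stage
  flagged <- unique(assoc$gene[assoc$significant])
  filt <- filter_by_maf(cohort$genotypes, config$maf_min)
  dqtl_rows <- list()
  for (g in flagged) {
    scan <- stage("dqtl", dqtl_scan(cohort$screen$gene_dependency[, g],
                                    filt, cohort$screen$lineage,
                                    config$fdr_q))
    marker <- select_marker(scan)
    if (is.null(marker)) next
    amaf <- ancestry_maf(filt$dosage[, marker$variant_id],
                         setNames(global$predominant,
                                  rownames(filt$dosage)),
                         differential_maf = config$differential_maf)
    trow <- cohort$tss[cohort$tss$gene == g, ]
    prox <- classify_proximal(marker$chrom, marker$pos0, trow$chrom,
                              trow$tss0, config$proximal_bp)
    eq <- eqtl_test(filt$dosage[, marker$variant_id],
                    log2(cohort$screen$expression[, g] + 1),
                    cohort$screen$lineage)
    # linkage of the marker to any in-guide variant of this gene's guides
    gv <- unique(mm$variant_id[mm$gene == g])
    r2 <- if (length(gv)) {
      gv <- intersect(gv, colnames(cohort$genotypes$dosage))
      suppressWarnings(max(vapply(gv, function(v) {
        r <- ld_r2(filt$dosage[, marker$variant_id],
                   cohort$genotypes$dosage[rownames(filt$dosage), v])
        if (is.na(r)) -Inf else r
      }, numeric(1))))
    } else {
      NA_real_
    }
    dqtl_rows[[g]] <- data.frame(
      gene = g, variant_id = marker$variant_id, beta = marker$beta,
      p = marker$p, q = marker$q,
      differential_maf = amaf$differential,
      ancestry_associated = amaf$ancestry_associated,
      proximal = prox$proximal,
      distance_to_tss = ifelse(is.na(prox$distance), NA, prox$distance),
      eqtl_p = eq$p,
      max_r2_in_guide = if (is.finite(r2)) r2 else NA_real_,
      stringsAsFactors = FALSE)
  }
  dqtl_table <- if (length(dqtl_rows)) {
    do.call(rbind, c(dqtl_rows, make.row.names = FALSE))
  } else {
    NULL
  }

  positional <- stage("positions",
                      positional_effects(filter_pam_n(mm,
                                                      config$include_pam_n),
                                         cohort$screen$guide_lfc))

  corrected <- stage("correct",
                     correct_gene_scores(cohort$screen$guide_lfc,
                                         cohort$library, mm,
                                         include_pam_n = config$include_pam_n))
  pre_post <- pre_post_differential(cohort$screen$gene_dependency, corrected,
                                    config$fdr_q)
  reassoc <- stage("reassociate", do.call(rbind, lapply(groups, function(g) {
    rerun_association_post_correction(corrected, cohort$screen, labels, g,
                                      config$fdr_q)
  })))

  cand <- candidates_from_cohort(cohort, seed = sim_cfg$seed)
  design <- stage("design",
                  design_library(cand$candidates, cand$candidate_variants,
                                 maf_threshold = config$maf_min,
                                 afr_ratio_max = config$afr_ratio_max,
                                 guides_per_gene = config$guides_per_gene))
  bench <- design_quality_benchmark(design)

  weak <- weak_expression_fraction(cohort$screen$expression,
                                   config$expression_rpm_threshold)

  summary <- list(
    n_samples = nrow(cohort$genotypes$dosage),
    n_variants = nrow(cohort$genotypes$variants),
    n_genes = length(unique(cohort$library$gene)),
    n_windows = nrow(cohort$windows),
    predominant_counts = as.list(table(global$predominant)),
    n_significant_pre = sum(assoc$significant),
    n_significant_post = sum(reassoc$significant_post, na.rm = TRUE),
    n_flagged_dependencies = length(flagged),
    n_marker_dqtls = if (is.null(dqtl_table)) 0L else nrow(dqtl_table),
    n_ancestry_associated_dqtls = if (is.null(dqtl_table)) 0L else
      sum(dqtl_table$ancestry_associated),
    n_proximal_dqtls = if (is.null(dqtl_table)) 0L else
      sum(dqtl_table$proximal, na.rm = TRUE),
    median_affected_fraction = median(fractions),
    afr_burden_ratio = burden_ratio,
    n_recurrent_guides = length(recurrent),
    affected_guide_histogram = as.list(histo),
    n_genes_changed_by_correction = sum(pre_post$significant),
    weak_expression_fraction = weak$fraction,
    design_unconstrained_identical_fraction =
      mean(design$gene_summary$unconstrained_identical),
    design_mean_score_delta = bench$overall_delta)

  result <- structure(list(cohort = cohort, track = track, global = global,
                           labels = labels, associations = assoc,
                           mismatches = mm, fractions = fractions,
                           recurrent_guides = recurrent, histogram = histo,
                           dqtl = dqtl_table, positional = positional,
                           corrected = corrected, pre_post = pre_post,
                           reassociation = reassoc, design = design,
                           benchmark = bench, summary = summary,
                           config = config, sim_config = sim_cfg),
                      class = "pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fixtures(cohort, file.path(outdir, "inputs"))
    write_tsv_commented(assoc, file.path(outdir, "associations.tsv"))
    if (!is.null(dqtl_table)) {
      write_tsv_commented(dqtl_table, file.path(outdir, "dqtl.tsv"))
    }
    write_tsv_commented(as.data.frame(mm), file.path(outdir,
                                                     "mismatches.tsv"))
    write_tsv_commented(positional, file.path(outdir, "positional.tsv"))
    write_tsv_commented(pre_post, file.path(outdir, "pre_post.tsv"))
    write_tsv_commented(reassoc, file.path(outdir, "reassociation.tsv"))
    write_tsv_commented(design$selected, file.path(outdir, "design.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(log_lines, paste("stages completed:",
                                  "simulate ancestry associate guides dqtl",
                                  "positions correct reassociate design")),
               file.path(outdir, "log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Pipeline result\n")
  cat(sprintf("  %d samples, %d genes, %d windows\n", s$n_samples,
              s$n_genes, s$n_windows))
  cat(sprintf("  ancestry-associated dependencies: %d pre-, %d post-correction\n",
              s$n_significant_pre, s$n_significant_post))
  cat(sprintf("  marker d-QTLs: %d (%d ancestry-associated, %d proximal)\n",
              s$n_marker_dqtls, s$n_ancestry_associated_dqtls,
              s$n_proximal_dqtls))
  cat(sprintf("  median affected guide fraction: %.4f (AFR ratio %s)\n",
              s$median_affected_fraction,
              if (is.na(s$afr_burden_ratio)) "NA" else
                sprintf("%.2f", s$afr_burden_ratio)))
  invisible(x)
}

# hash the two configs through serialisation (used only for the log)
config_hash <- function(sim_cfg, config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(sim_cfg, config), f, version = 2)
  unname(tools::md5sum(f))
}
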