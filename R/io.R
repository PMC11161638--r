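# File formats. Internal coordinates are 0-based half-open everywhere; the
# conversion to the 1-based conventions of VCF happens only here.

#' Write genotypes as VCF
#'
#' VCF v4.2 with a single GT FORMAT field; diploid, unphased. Dosage 0/1/2
#' maps to 0/0, 0/1, 1/1 and missing to ./.. POS is 1-based (internal
#' `start0 + 1`).
#'
#' @param genotypes A `"variant_genotypes"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  samples <- rownames(genotypes$dosage)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(v), length(samples))
  d <- t(genotypes$dosage)
  ok <- !is.na(d)
  gt[ok] <- gt_code[d[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=guidebias",
              paste0("##contig=<ID=", unique(v$chrom), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(v$chrom, v$start0 + 1L, v$id, v$ref, v$alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses a VCF (via \pkg{vcfR}) into a `"variant_genotypes"`: biallelic SNV
#' records only (multi-allelic records are split; non-SNV alleles are dropped
#' and counted), GT converted to dosage with missing preserved, POS converted
#' to internal 0-based `start0`.
#'
#' @param path VCF path.
#' @return A `"variant_genotypes"` with attribute `"n_dropped_non_snv"`.
#' @export
read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rec <- list(); dos <- list(); dropped <- 0L
  count_allele <- function(s, ai) {
    if (is.na(s)) return(NA_integer_)
    parts <- strsplit(s, "[/|]")[[1]]
    if (any(parts == ".")) return(NA_integer_)
    sum(parts == as.character(ai))
  }
  simple <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
              "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      if (nchar(fix$REF[i]) != 1 || nchar(alts[ai]) != 1 ||
          !alts[ai] %in% c("A", "C", "G", "T")) {
        dropped <- dropped + 1L
        next
      }
      g <- gt[i, ]
      if (length(alts) == 1 && all(is.na(g) | g %in% names(simple))) {
        dos[[length(dos) + 1L]] <- unname(simple[g])
      } else {
        dos[[length(dos) + 1L]] <- vapply(g, count_allele, integer(1), ai = ai)
      }
      pos1 <- as.integer(fix$POS[i])
      id <- fix$ID[i]
      if (is.na(id) || id == ".") {
        id <- paste0(fix$CHROM[i], ":", pos1, ":", fix$REF[i], ":", alts[ai])
      }
      rec[[length(rec) + 1L]] <- data.frame(
        id = id, chrom = fix$CHROM[i], start0 = pos1 - 1L,
        ref = fix$REF[i], alt = alts[ai], stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, rec)
  rownames(variants) <- NULL
  dosage <- do.call(cbind, dos)
  dimnames(dosage) <- list(colnames(gt), variants$id)
  out <- structure(list(variants = variants, dosage = dosage,
                        samples = colnames(gt)),
                   class = "variant_genotypes")
  attr(out, "n_dropped_non_snv") <- dropped
  out
}

coord_header <- "# coordinates: 0-based half-open (start0/end0); VCF POS is start0 + 1"

write_tsv_commented <- function(df, path, comment = coord_header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a guide map
#'
#' TSV with columns `guide_id`, `gene`, `chrom`, `start0`, `end0`, `strand`,
#' `protospacer`, `pam` (0-based half-open interval of the 23-bp targeting
#' sequence).
#'
#' @param library A `"guide_library"`.
#' @param path File path.
#' @return The path ([write_guide_map()]) or a validated `"guide_library"`
#'   ([read_guide_map()]).
#' @export
write_guide_map <- function(library, path) {
  write_tsv_commented(as.data.frame(library), path)
}

#' @rdname write_guide_map
#' @export
read_guide_map <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("guide_id", "gene", "chrom", "start0", "end0", "strand",
            "protospacer", "pam")
  if (!all(need %in% names(df))) {
    stop("guide map ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (any(df$end0 - df$start0 != 23L)) {
    bad <- which(df$end0 - df$start0 != 23L)[1]
    stop("guide map ", path, " row ", bad,
         ": targeting interval is not 23 bp", call. = FALSE)
  }
  validate_guides(df)
  class(df) <- c("guide_library", "data.frame")
  df
}

#' Write / read a samples-by-features matrix as CSV
#'
#' Row names are sample ids; columns are guides or genes.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return The path, or the matrix on read.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a TSS table as BED
#'
#' BED (0-based half-open) with columns chrom, start, end, name.
#'
#' @param tss Data.frame `gene`, `chrom`, `tss0`.
#' @param path File path.
#' @return Path / TSS data.frame.
#' @export
write_tss_bed <- function(tss, path) {
  bed <- data.frame(chrom = tss$chrom, start = tss$tss0,
                    end = tss$tss0 + 1L, name = tss$gene)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(coord_header, con)
  write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_bed
#' @export
read_tss_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  data.frame(gene = bed$V4, chrom = bed$V1, tss0 = as.integer(bed$V2),
             stringsAsFactors = FALSE)
}

#' Write / read the reference-panel allele frequencies
#'
#' TSV `variant_id`, `chrom`, `start0`, `ref`, `alt`, then one `freq_<pop>`
#' column per population.
#'
#' @param panel An `"ancestry_panel"`.
#' @param path File path.
#' @return Path / `"ancestry_panel"`.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- cbind(data.frame(variant_id = panel$variants$id,
                         chrom = panel$variants$chrom,
                         start0 = panel$variants$start0,
                         ref = panel$variants$ref, alt = panel$variants$alt,
                         stringsAsFactors = FALSE),
              setNames(as.data.frame(panel$freq),
                       paste0("freq_", colnames(panel$freq))))
  write_tsv_commented(df, path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- read_tsv_commented(path)
  fcols <- grep("^freq_", names(df), value = TRUE)
  freq <- as.matrix(df[, fcols, drop = FALSE])
  colnames(freq) <- sub("^freq_", "", fcols)
  rownames(freq) <- df$variant_id
  structure(list(variants = data.frame(id = df$variant_id, chrom = df$chrom,
                                       start0 = df$start0, ref = df$ref,
                                       alt = df$alt,
                                       stringsAsFactors = FALSE),
                 freq = freq, ancestral = NULL),
            class = "ancestry_panel")
}

#' Write / read a genetic map
#'
#' TSV `chrom`, `pos` (1-based bp), `cm`.
#'
#' @param map A `"genetic_map"`.
#' @param path File path.
#' @return Path / `"genetic_map"`.
#' @export
write_genetic_map_tsv <- function(map, path) {
  write_tsv_commented(as.data.frame(map), path,
                      comment = "# pos: 1-based bp; cm: centimorgans")
}

#' @rdname write_genetic_map_tsv
#' @export
read_genetic_map_tsv <- function(path) {
  df <- read_tsv_commented(path)
  genetic_map(df$chrom, df$pos, df$cm)
}

#' Write all cohort fixtures
#'
#' Writes the standard file set a real analysis would start from: VCF
#' genotypes, guide-map TSV, guide-level and gene-level matrices (CSV),
#' expression matrix, TSS BED, sample metadata TSV, panel TSV and genetic-map
#' TSV. Identifiers are cross-checked before writing.
#'
#' @param cohort A `"cohort"` from [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixtures <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  samples <- rownames(cohort$genotypes$dosage)
  if (!identical(samples, rownames(cohort$screen$guide_lfc)) ||
      !identical(samples, cohort$metadata$sample_id)) {
    stop("sample identifiers differ between genotypes, screen and metadata",
         call. = FALSE)
  }
  if (!identical(colnames(cohort$screen$guide_lfc),
                 cohort$library$guide_id)) {
    stop("guide identifiers differ between screen and library",
         call. = FALSE)
  }
  paths <- c(
    vcf = file.path(outdir, "genotypes.vcf"),
    guide_map = file.path(outdir, "guide_map.tsv"),
    guide_lfc = file.path(outdir, "guide_lfc.csv"),
    gene_dependency = file.path(outdir, "gene_dependency.csv"),
    expression = file.path(outdir, "expression.csv"),
    tss = file.path(outdir, "tss.bed"),
    metadata = file.path(outdir, "metadata.tsv"),
    panel = file.path(outdir, "panel.tsv"),
    map = file.path(outdir, "genetic_map.tsv"))
  write_vcf(cohort$genotypes, paths["vcf"])
  write_guide_map(cohort$library, paths["guide_map"])
  write_matrix_csv(cohort$screen$guide_lfc, paths["guide_lfc"])
  write_matrix_csv(cohort$screen$gene_dependency, paths["gene_dependency"])
  write_matrix_csv(cohort$screen$expression, paths["expression"])
  write_tss_bed(cohort$tss, paths["tss"])
  write_tsv_commented(cohort$metadata, paths["metadata"],
                      comment = "# sample metadata")
  write_panel_tsv(cohort$panel, paths["panel"])
  write_genetic_map_tsv(cohort$map, paths["map"])
  paths
}

#' Read and validate a fixture set
#'
#' Reads the file set written by [write_fixtures()] back into memory and
#' validates cross-file identifier consistency.
#'
#' @param paths Named character vector as returned by [write_fixtures()].
#' @return A list with `genotypes`, `library`, `guide_lfc`,
#'   `gene_dependency`, `expression`, `tss`, `metadata`, `panel`, `map`.
#' @export
read_inputs <- function(paths) {
  out <- list(
    genotypes = read_vcf_genotypes(paths[["vcf"]]),
    library = read_guide_map(paths[["guide_map"]]),
    guide_lfc = read_matrix_csv(paths[["guide_lfc"]]),
    gene_dependency = read_matrix_csv(paths[["gene_dependency"]]),
    expression = read_matrix_csv(paths[["expression"]]),
    tss = read_tss_bed(paths[["tss"]]),
    metadata = read_tsv_commented(paths[["metadata"]]),
    panel = read_panel_tsv(paths[["panel"]]),
    map = read_genetic_map_tsv(paths[["map"]]))
  samples <- rownames(out$genotypes$dosage)
  if (!identical(sort(samples), sort(rownames(out$guide_lfc)))) {
    stop("sample ids in ", paths[["vcf"]], " and ", paths[["guide_lfc"]],
         " disagree", call. = FALSE)
  }
  if (!identical(sort(out$metadata$sample_id), sort(samples))) {
    stop("sample ids in ", paths[["metadata"]], " do not match the VCF",
         call. = FALSE)
  }
  if (!all(colnames(out$guide_lfc) %in% out$library$guide_id)) {
    stop("guide ids in ", paths[["guide_lfc"]],
         " missing from the guide map", call. = FALSE)
  }
  out
}
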