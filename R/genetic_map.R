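#' Construct a genetic map
#'
#' A genetic map is a per-chromosome monotone lookup between physical position
#' (1-based bp) and genetic position (centimorgans). Positions between knots
#' are linearly interpolated.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based physical positions.
#' @param cm Numeric vector of genetic positions in centimorgans,
#'   non-decreasing within each chromosome.
#' @return A data.frame of class `"genetic_map"` with columns
#'   `chrom`, `pos`, `cm`, sorted by `(chrom, pos)`.
#' @export
genetic_map <- function(chrom, pos, cm) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(cm))
  if (length(pos) == 0) stop("empty genetic map", call. = FALSE)
  map <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    cm = as.numeric(cm), stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  bad <- unlist(lapply(split(map$cm, map$chrom), function(x) any(diff(x) < 0)))
  if (any(bad)) {
    stop("cM must be non-decreasing in position on chromosome(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Uniform-rate genetic map
#'
#' Convenience constructor for a constant-recombination-rate map
#' (default 1 cM per megabase), with knots at both chromosome ends.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param cm_per_mb Recombination rate in cM/Mb.
#' @return A `"genetic_map"`.
#' @export
uniform_genetic_map <- function(chrom_lengths, cm_per_mb = 1) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  genetic_map(chrom = rep(names(chrom_lengths), each = 2),
              pos = as.vector(rbind(1L, as.integer(chrom_lengths))),
              cm = as.vector(rbind(0, chrom_lengths / 1e6 * cm_per_mb)))
}

# Interpolate cM at 1-based physical positions on one chromosome.
# Positions outside the knot range are an error: the map must cover the data.
interpolate_cm <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("chromosome ", chrom, " absent from genetic map", call. = FALSE)
  }
  if (any(pos < min(sub$pos) | pos > max(sub$pos))) {
    stop("position outside genetic-map range on chromosome ", chrom,
         call. = FALSE)
  }
  if (nrow(sub) == 1) return(rep(sub$cm, length(pos)))
  approx(sub$pos, sub$cm, xout = pos, ties = "ordered")$y
}

#' Tile chromosomes into genetic-map windows
#'
#' Greedy left-to-right tiling of each chromosome into windows of at least
#' `min_cm` centimorgans. The final window of a chromosome absorbs any
#' terminal remainder (so it may span less than `min_cm`). Every variant
#' falls in exactly one window.
#'
#' @param map A [genetic_map()].
#' @param variants A data.frame with columns `chrom` and `start0` (0-based
#'   variant positions), sorted by `(chrom, start0)`.
#' @param min_cm Minimum window span in centimorgans (default 0.2).
#' @return A data.frame of class `"ancestry_windows"` with columns `chrom`,
#'   `start0`, `end0` (0-based half-open bp), `cm_start`, `cm_end`,
#'   `first_variant`, `last_variant` (row indices into `variants`, NA when the
#'   window holds none), `window_id`.
#' @export
build_windows <- function(map, variants, min_cm = 0.2) {
  stopifnot(is.data.frame(variants), all(c("chrom", "start0") %in%
                                           names(variants)))
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$start0)
  if (!identical(ord, seq_len(nrow(variants)))) {
    stop("variants must be sorted by (chrom, start0)", call. = FALSE)
  }
  out <- list()
  for (chr in unique(map$chrom)) {
    knots <- map[map$chrom == chr, , drop = FALSE]
    lo_bp <- min(knots$pos); hi_bp <- max(knots$pos)
    cm_lo <- min(knots$cm); cm_hi <- max(knots$cm)
    n_win <- max(1L, floor((cm_hi - cm_lo) / min_cm + 1e-9))
    cm_breaks <- cm_lo + min_cm * seq(0, n_win)
    cm_breaks[n_win + 1] <- cm_hi  # last window takes the remainder
    # invert the map at interior breaks (cm -> bp)
    bp_breaks <- if (nrow(knots) > 1) {
      approx(knots$cm, knots$pos, xout = cm_breaks, ties = "ordered")$y
    } else {
      rep(lo_bp, length(cm_breaks))
    }
    start0 <- as.integer(floor(bp_breaks[-length(bp_breaks)])) - 1L
    end0 <- c(start0[-1], as.integer(hi_bp))
    start0[1] <- lo_bp - 1L
    df <- data.frame(chrom = chr, start0 = start0, end0 = end0,
                     cm_start = cm_breaks[-length(cm_breaks)],
                     cm_end = cm_breaks[-1], stringsAsFactors = FALSE)
    idx <- which(variants$chrom == chr)
    if (length(idx)) {
      p <- variants$start0[idx]
      if (any(p + 1L < lo_bp | p + 1L > hi_bp)) {
        stop("variant outside genetic-map range on chromosome ", chr,
             call. = FALSE)
      }
      # membership is defined on the cM scale; the last window is closed
      cm_v <- interpolate_cm(map, chr, p + 1L)
      w <- pmin(findInterval(cm_v, cm_breaks), n_win)
      df$first_variant <- NA_integer_; df$last_variant <- NA_integer_
      for (k in unique(w)) {
        df$first_variant[k] <- idx[which.max(w == k)]
        df$last_variant[k] <- idx[length(w) - which.max(rev(w == k)) + 1]
      }
    } else {
      df$first_variant <- NA_integer_; df$last_variant <- NA_integer_
    }
    out[[chr]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$window_id <- seq_len(nrow(res))
  class(res) <- c("ancestry_windows", "data.frame")
  res
}

# window index containing a 0-based position, or NA
window_at <- function(windows, chrom, pos0) {
  sel <- which(windows$chrom == chrom & windows$start0 <= pos0 &
                 windows$end0 > pos0)
  if (length(sel) == 0) NA_integer_ else sel[1]
}
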