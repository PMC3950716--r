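#' Eight splice-site-flanking segments for an event
#'
#' From each of the four splice sites a segment extends `exon_ext` bases
#' into the adjoining exon and `intron_ext` bases into the adjoining
#' intron (in transcription orientation; mirrored for `"-"` events).
#' Segments never cross the opposite boundary of their exon or intron:
#' when two segments share a short feature (the two middle-exon exonic
#' segments, or the two segments inside one intron) the feature is split
#' at its midpoint so segments never overlap. Zero-length extents are
#' omitted with a warning.
#'
#' @param ev One event row.
#' @param exon_ext,intron_ext Extents in bases (both >= 1); defaults 50
#'   and 100.
#' @return data.frame: `event_id`, `site`, `side` (`"exonic"`/
#'   `"intronic"`), `chrom`, `start`, `end`, `length` (0-based half-open).
#' @export
event_segments <- function(ev, exon_ext = 50L, intron_ext = 100L) {
  stopifnot(exon_ext >= 1, intron_ext >= 1)
  minus <- ev$strand == "-"
  # genomic feature boundaries, left to right
  ex <- matrix(c(ev$up_exon_start, ev$up_exon_end,
                 ev$mid_exon_start, ev$mid_exon_end,
                 ev$dn_exon_start, ev$dn_exon_end),
               ncol = 2, byrow = TRUE)
  ex <- ex[order(ex[, 1]), , drop = FALSE]   # rows: left, mid, right exon
  upI <- c(ex[1, 2], ex[2, 1]); dnI <- c(ex[2, 2], ex[3, 1])
  # site labels by transcription role at each genomic boundary
  # boundaries: b1 = left exon end, b2 = mid start, b3 = mid end, b4 = right start
  lab <- if (minus) c("dnI_ss3", "dnI_ss5", "upI_ss3", "upI_ss5")
         else c("upI_ss5", "upI_ss3", "dnI_ss5", "dnI_ss3")
  half <- function(len) c(floor(len / 2), ceiling(len / 2))
  rows <- list()
  add <- function(site, side, start, end) {
    if (end <= start) {
      warning("zero-length ", side, " segment at ", site, " omitted")
      return(invisible())
    }
    start <- as.integer(start); end <- as.integer(end)
    rows[[length(rows) + 1L]] <<- data.frame(
      event_id = ev$event_id %||% NA_character_, site = site, side = side,
      chrom = ev$chrom, start = start, end = end, length = end - start,
      stringsAsFactors = FALSE)
  }
  exlen <- ex[, 2] - ex[, 1]
  upIlen <- upI[2] - upI[1]; dnIlen <- dnI[2] - dnI[1]
  # exonic segment in left exon (from boundary b1 leftward)
  add(lab[1], "exonic", max(ex[1, 1], ex[1, 2] - exon_ext), ex[1, 2])
  # the two segments inside the upstream(-genomic) intron
  iext <- if (2 * intron_ext > upIlen) half(upIlen)
          else c(intron_ext, intron_ext)
  add(lab[1], "intronic", upI[1], upI[1] + iext[1])
  add(lab[2], "intronic", upI[2] - iext[2], upI[2])
  # the two exonic segments inside the middle exon
  eext <- if (2 * exon_ext > exlen[2]) half(exlen[2])
          else c(exon_ext, exon_ext)
  add(lab[2], "exonic", ex[2, 1], ex[2, 1] + eext[1])
  add(lab[3], "exonic", ex[2, 2] - eext[2], ex[2, 2])
  # the two segments inside the downstream(-genomic) intron
  iext <- if (2 * intron_ext > dnIlen) half(dnIlen)
          else c(intron_ext, intron_ext)
  add(lab[3], "intronic", dnI[1], dnI[1] + iext[1])
  add(lab[4], "intronic", dnI[2] - iext[2], dnI[2])
  # exonic segment in right exon (from boundary b4 rightward)
  add(lab[4], "exonic", ex[3, 1], min(ex[3, 2], ex[3, 1] + exon_ext))
  do.call(rbind, rows)
}

#' Segments for a whole event table
#'
#' @param events Event data.frame.
#' @inheritParams event_segments
#' @return Row-bound segment data.frame for all events.
#' @export
events_segments <- function(events, exon_ext = 50L, intron_ext = 100L) {
  do.call(rbind, lapply(seq_len(nrow(events)), function(i)
    event_segments(events[i, ], exon_ext, intron_ext)))
}

#' Write segments as 6-column BED
#'
#' @param segments Segment data.frame from [events_segments()].
#' @param path Output file.
#' @export
write_segment_bed <- function(segments, path) {
  bed <- data.frame(segments$chrom, segments$start, segments$end,
                    paste(segments$event_id, segments$site, segments$side,
                          sep = ":"),
                    0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# coerce interval input (data.frame chrom/start/end 0-based half-open,
# GRanges, or BED path) to GRanges
.as_intervals <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(rtracklayer::import(x, format = "bed"))
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1L, x$end))
}

#' Normalized signal density over event segments
#'
#' Counts reads/fragments overlapping each segment by at least one base,
#' then normalizes: `count / length * (1e7 / library_size)` (reads per ten
#' million per base). When a control is supplied its identically
#' normalized density is subtracted, so values may be negative.
#'
#' @param segments Segment data.frame from [events_segments()].
#' @param intervals Signal reads: data.frame (`chrom`,`start`,`end`,
#'   0-based half-open), `GRanges`, or BED path.
#' @param library_size Total mapped reads of the signal library.
#' @param control Optional `list(intervals=, library_size=)` input control.
#' @return The segment data.frame with a `density` column; attribute
#'   `control_subtracted` records whether a control was applied.
#' @export
tag_density <- function(segments, intervals, library_size, control = NULL) {
  if (is.null(library_size) || library_size <= 0)
    stop("library_size must be positive")
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start + 1L,
                                                    segments$end))
  cnt <- GenomicRanges::countOverlaps(seg_gr, .as_intervals(intervals),
                                      minoverlap = 1L)
  dens <- cnt / segments$length * (1e7 / library_size)
  if (!is.null(control)) {
    ccnt <- GenomicRanges::countOverlaps(seg_gr,
                                         .as_intervals(control$intervals),
                                         minoverlap = 1L)
    dens <- dens - ccnt / segments$length * (1e7 / control$library_size)
  }
  out <- segments
  out$density <- dens
  attr(out, "control_subtracted") <- !is.null(control)
  out
}

# canonical ordering of the 8 segment labels along the tri-exon layout
segment_levels <- function() {
  c("upI_ss5:exonic", "upI_ss5:intronic", "upI_ss3:intronic",
    "upI_ss3:exonic", "dnI_ss5:exonic", "dnI_ss5:intronic",
    "dnI_ss3:intronic", "dnI_ss3:exonic")
}

#' Z-score heat table and between-group profile similarity
#'
#' For each factor, the eight per-group mean densities (one value per
#' segment, averaged over the group's events) are standardized to mean 0
#' and SD 1 within each group; the Pearson correlation r of the two
#' standardized 8-vectors measures how similar the factor's positional
#' pattern is between the groups. Factors are returned in ascending order
#' of |r|. A factor with zero variance in either group is flagged and gets
#' `r = NA`.
#'
#' @param densities Long data.frame with columns `factor`, `event_id`,
#'   `site`, `side`, `density` (e.g. several [tag_density()] results
#'   row-bound with a `factor` column).
#' @param groups Named character vector mapping `event_id` to `"SIDG"` /
#'   `"IIDG"`.
#' @return List with `z` (long data.frame: factor, group, segment,
#'   mean_density, z) and `r` (data.frame: factor, r, flagged).
#' @export
zscore_heat <- function(densities, groups) {
  densities$segment <- factor(paste(densities$site, densities$side,
                                    sep = ":"), levels = segment_levels())
  densities$group <- groups[densities$event_id]
  densities <- densities[densities$group %in% c("SIDG", "IIDG"), ,
                         drop = FALSE]
  zrows <- list(); rrows <- list()
  for (fac in unique(densities$factor)) {
    d <- densities[densities$factor == fac, , drop = FALSE]
    prof <- list()
    for (g in c("SIDG", "IIDG")) {
      mu <- tapply(d$density[d$group == g], d$segment[d$group == g], mean)
      mu <- as.numeric(mu[segment_levels()])
      z <- if (stats::sd(mu, na.rm = TRUE) > 0)
        (mu - mean(mu, na.rm = TRUE)) / stats::sd(mu, na.rm = TRUE)
      else rep(NA_real_, length(mu))
      prof[[g]] <- z
      zrows[[length(zrows) + 1L]] <- data.frame(
        factor = fac, group = g, segment = segment_levels(),
        mean_density = mu, z = z, stringsAsFactors = FALSE)
    }
    ok <- !anyNA(prof$SIDG) && !anyNA(prof$IIDG)
    rrows[[length(rrows) + 1L]] <- data.frame(
      factor = fac,
      r = if (ok) stats::cor(prof$SIDG, prof$IIDG) else NA_real_,
      flagged = !ok, stringsAsFactors = FALSE)
  }
  r <- do.call(rbind, rrows)
  r <- r[order(abs(r$r)), , drop = FALSE]
  rownames(r) <- NULL
  list(z = do.call(rbind, zrows), r = r)
}

#' Motif-hit enrichment between SIDG and IIDG, per segment
#'
#' Motif hits are produced externally and supplied as counts per event,
#' segment and factor. Counts are normalized to hits per base using the
#' segment length, then each factor x segment cell is tested SIDG versus
#' IIDG with a two-sided Mann-Whitney test. The heat value is
#' `-log10(p)`, signed positive when the factor is enriched in SIDG
#' (skipping group) and negative when enriched in IIDG.
#'
#' @param hits Long data.frame: `event_id`, `site`, `side`, `factor`,
#'   `count`, `length` (segment length in bases; if absent, counts are
#'   used unnormalized).
#' @param groups Named character vector: `event_id` -> `"SIDG"`/`"IIDG"`.
#' @param bh Also report Benjamini-Hochberg adjusted q-values across the
#'   factor x segment grid. Default `FALSE` (raw p, as the heat values).
#' @return data.frame: `factor`, `segment`, `p_value`, `direction`
#'   (+1 SIDG / -1 IIDG / 0), `heat`, `flagged` (all-zero cell), and `q`
#'   when `bh`.
#' @export
motif_enrichment <- function(hits, groups, bh = FALSE) {
  hits$segment <- paste(hits$site, hits$side, sep = ":")
  hits$group <- groups[hits$event_id]
  hits <- hits[hits$group %in% c("SIDG", "IIDG"), , drop = FALSE]
  hits$dens <- if ("length" %in% names(hits)) hits$count / hits$length
               else hits$count
  out <- list()
  for (fac in unique(hits$factor)) {
    for (seg in intersect(segment_levels(),
                          unique(hits$segment[hits$factor == fac]))) {
      d <- hits[hits$factor == fac & hits$segment == seg, , drop = FALSE]
      a <- d$dens[d$group == "SIDG"]; b <- d$dens[d$group == "IIDG"]
      if (!length(a) || !length(b)) next
      if (all(c(a, b) == 0)) {
        out[[length(out) + 1L]] <- data.frame(
          factor = fac, segment = seg, p_value = 1, direction = 0L,
          heat = 0, flagged = TRUE, stringsAsFactors = FALSE)
        next
      }
      mw <- mann_whitney(a, b)
      dir <- sign(mean(a) - mean(b))
      out[[length(out) + 1L]] <- data.frame(
        factor = fac, segment = seg, p_value = mw$p_value,
        direction = as.integer(dir),
        heat = dir * -log10(max(mw$p_value, .Machine$double.xmin)),
        flagged = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (bh && !is.null(res)) res$q <- stats::p.adjust(res$p_value, "BH")
  res
}
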