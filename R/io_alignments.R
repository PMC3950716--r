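#' Load splicing-aware alignments as junction and coverage evidence
#'
#' Reads a SAM or BAM file and splits the records that pass the read filters
#' into two evidence sets: spliced reads (at least one `N` CIGAR operator)
#' contribute one junction-support increment per intron gap, provided the
#' read anchors at least `min_junction_overhang` aligned bases on each side
#' of the gap; constitutive reads (no `N`) contribute their aligned span to
#' a per-base coverage track. Multi-mapped records (secondary-alignment flag
#' or `NH` tag > 1), unmapped records, low-MAPQ records and records with too
#' many ambiguous bases are discarded. Records whose CIGAR contains
#' operators outside `MIDNSHP=X` are skipped and counted.
#'
#' All returned coordinates are 0-based, half-open: `intron_start` is the
#' first intronic base, `intron_end` the first base of the next exon. SAM's
#' 1-based convention is converted at this boundary and nowhere else.
#'
#' @param path SAM or BAM file (header required; sorting not required).
#' @param cfg A [read_filter_config()].
#'
#' @return A list of class `gess_alignments` with elements
#'   \describe{
#'     \item{junctions}{data.frame with `chrom`, `intron_start`,
#'       `intron_end`, `support`, `strand` (always `"unknown"` here;
#'       orientation is assigned later from the genome).}
#'     \item{coverage}{named list of integer [S4Vectors::Rle] per
#'       chromosome, per-base depth from constitutive reads.}
#'     \item{stats}{named integer vector accounting for every input record:
#'       `n_records`, `n_spliced`, `n_constitutive`, `n_discarded`,
#'       `n_skipped_cigar`, plus `n_junction_increments` and
#'       `n_overhang_failed` for the junction side.}
#'   }
#' @export
load_alignments <- function(path, cfg = read_filter_config()) {
  stopifnot(inherits(cfg, "gess_read_filter"))
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    # htslib converts headerless SAM to an empty BAM silently; reject it
    # explicitly so malformed input is named rather than swallowed
    con <- file(path, "r"); on.exit(close(con), add = TRUE)
    has_sq <- FALSE
    repeat {
      ln <- readLines(con, 1L)
      if (!length(ln) || !startsWith(ln, "@")) break
      if (startsWith(ln, "@SQ")) { has_sq <- TRUE; break }
    }
    if (!has_sq)
      stop("format error: '", path, "' has no @SQ header lines")
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("format error: cannot parse '", path,
                               "' as SAM (missing/invalid header?): ",
                               conditionMessage(e)))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "NH")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$pos)

  stats <- c(n_records = n, n_spliced = 0L, n_constitutive = 0L,
             n_discarded = 0L, n_skipped_cigar = 0L,
             n_junction_increments = 0L, n_overhang_failed = 0L)
  if (n == 0) {
    return(structure(list(junctions = empty_junctions(),
                          coverage = list(), stats = stats),
                     class = "gess_alignments"))
  }

  flag <- b$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L
  nh <- b$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  multi <- secondary | (!is.na(nh) & nh > 1L)
  mapq_bad <- !is.na(b$mapq) & b$mapq < cfg$min_mapping_quality
  n_amb <- Biostrings::vcountPattern("N", b$seq)
  amb_bad <- n_amb > cfg$max_ambiguous_bases

  drop <- unmapped | mapq_bad | amb_bad
  if (cfg$discard_multimapped) drop <- drop | multi
  bad_ops <- grepl("[^0-9MIDNSHP=X]", b$cigar) | is.na(b$cigar)
  keep <- !drop & !bad_ops
  stats["n_discarded"] <- sum(drop)
  stats["n_skipped_cigar"] <- sum(bad_ops & !drop)

  cigar <- b$cigar[keep]
  pos <- b$pos[keep]
  chrom <- as.character(b$rname[keep])
  spliced <- grepl("N", cigar, fixed = TRUE)
  stats["n_spliced"] <- sum(spliced)
  stats["n_constitutive"] <- sum(!spliced)

  # --- junctions from spliced reads ------------------------------------
  junctions <- empty_junctions()
  if (any(spliced)) {
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
      cigar[spliced], pos = pos[spliced], drop.D.ranges = FALSE)
    bl_start <- IRanges::start(blocks)   # IntegerList, 1-based
    bl_end <- IRanges::end(blocks)
    bl_w <- IRanges::width(blocks)
    nb <- S4Vectors::elementNROWS(blocks)
    # gap k of a read lies between aligned block k and block k+1
    rid <- rep.int(seq_along(nb), nb - 1L)
    all_start <- unlist(bl_start, use.names = FALSE)
    all_end <- unlist(bl_end, use.names = FALSE)
    all_w <- unlist(bl_w, use.names = FALSE)
    grp <- rep.int(seq_along(nb), nb)
    within <- sequence(nb)
    not_last <- within < nb[grp]
    not_first <- within > 1L
    left_end <- all_end[not_last]
    right_start <- all_start[not_first]
    left_anchor <- all_w[not_last]
    right_anchor <- all_w[not_first]
    ok <- left_anchor >= cfg$min_junction_overhang &
      right_anchor >= cfg$min_junction_overhang
    stats["n_overhang_failed"] <- sum(!ok)
    stats["n_junction_increments"] <- sum(ok)
    if (any(ok)) {
      jdf <- data.frame(chrom = chrom[spliced][rid[ok]],
                        intron_start = left_end[ok],        # 1-based end == 0-based start
                        intron_end = right_start[ok] - 1L,   # 0-based half-open end
                        stringsAsFactors = FALSE)
      agg <- stats::aggregate(list(support = rep(1L, nrow(jdf))),
                              by = jdf, FUN = sum)
      agg <- agg[order(agg$chrom, agg$intron_start, agg$intron_end), ,
                 drop = FALSE]
      rownames(agg) <- NULL
      agg$strand <- "unknown"
      junctions <- agg
    }
  }

  # --- coverage from constitutive reads --------------------------------
  coverage <- list()
  if (any(!spliced)) {
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[!spliced])
    gr <- GenomicRanges::GRanges(chrom[!spliced],
                                 IRanges::IRanges(pos[!spliced], width = w))
    cov <- GenomicRanges::coverage(gr)
    coverage <- as.list(cov)
  }

  structure(list(junctions = junctions, coverage = coverage, stats = stats),
            class = "gess_alignments")
}

#' @export
print.gess_alignments <- function(x, ...) {
  cat("gess alignments:", x$stats["n_records"], "records;",
      x$stats["n_spliced"], "spliced,", x$stats["n_constitutive"],
      "constitutive,", x$stats["n_discarded"], "discarded\n")
  cat("  junctions:", nrow(x$junctions), "distinct\n")
  invisible(x)
}

#' Write junctions as 6-column BED
#'
#' BED is 0-based half-open, matching the internal convention; `score` is
#' the junction support.
#'
#' @param junctions Junction data.frame from [load_alignments()].
#' @param path Output file.
#' @export
write_junction_bed <- function(junctions, path) {
  strand <- ifelse(junctions$strand %in% c("+", "-"), junctions$strand, ".")
  bed <- data.frame(junctions$chrom, junctions$intron_start,
                    junctions$intron_end,
                    sprintf("J%05d", seq_len(nrow(junctions))),
                    junctions$support, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
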