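#' Specification of one simulated cassette-exon locus
#'
#' A locus is a five-exon gene: two constitutive flanking exons (needed so
#' the outer boundaries of the tri-exon core are splice-site nodes), then
#' the upstream exon, the middle (cassette) exon and the downstream exon.
#' Two isoforms are mixed at the true inclusion fraction `true_psi`; reads
#' start uniformly over isoform positions, so the isoform of each read is
#' drawn with probability proportional to `psi * positions(inclusion)`
#' versus `(1 - psi) * positions(skipping)`.
#'
#' Defaults model a compact vertebrate-like locus: 150/120/150 bp core
#' exons, 300 bp introns, 150 bp flanking exons with 300 bp constitutive
#' introns, 50x read depth, 100 bp reads, strong consensus splice sites.
#'
#' @param exon_lengths Lengths of the (upstream, middle, downstream) exons.
#' @param intron_lengths Lengths of the two introns flanking the middle
#'   exon (>= 30).
#' @param flank_exon_length,flank_intron_length Constitutive flank sizes.
#' @param true_psi True inclusion fraction in `[0, 1]`.
#' @param depth Mean read depth over the inclusion isoform.
#' @param read_length Read length (uniform).
#' @param strand `"+"` or `"-"`.
#' @param site_quality Named character vector over
#'   `upI_ss5, upI_ss3, dnI_ss5, dnI_ss3` with values `"strong"` or
#'   `"weak"`. Weak sites keep the canonical GT/AG dinucleotide but lose
#'   the rest of the consensus.
#' @return List of class `locus_spec`.
#' @export
locus_spec <- function(exon_lengths = c(150L, 120L, 150L),
                       intron_lengths = c(300L, 300L),
                       flank_exon_length = 150L,
                       flank_intron_length = 300L,
                       true_psi = 0.5,
                       depth = 50,
                       read_length = 100L,
                       strand = "+",
                       site_quality = c(upI_ss5 = "strong",
                                        upI_ss3 = "strong",
                                        dnI_ss5 = "strong",
                                        dnI_ss3 = "strong")) {
  stopifnot(length(exon_lengths) == 3, all(exon_lengths >= 1),
            length(intron_lengths) == 2, all(intron_lengths >= 30),
            flank_exon_length >= 30, flank_intron_length >= 30,
            true_psi >= 0, true_psi <= 1, depth > 0, read_length >= 20,
            strand %in% c("+", "-"),
            all(names(site_quality) == c("upI_ss5", "upI_ss3",
                                         "dnI_ss5", "dnI_ss3")),
            all(site_quality %in% c("strong", "weak")))
  structure(list(exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 flank_exon_length = as.integer(flank_exon_length),
                 flank_intron_length = as.integer(flank_intron_length),
                 true_psi = true_psi, depth = depth,
                 read_length = as.integer(read_length), strand = strand,
                 site_quality = site_quality),
            class = "locus_spec")
}

.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

# sample one site sequence from a consensus profile; `fixed` positions are
# kept verbatim (canonical GT / AG), others take the consensus base with
# probability `cons_p` ("strong") or uniformly ("weak").
.sample_site <- function(consensus, fixed, quality, cons_p = 0.85) {
  cons <- strsplit(consensus, "")[[1]]
  out <- vapply(seq_along(cons), function(i) {
    if (i %in% fixed) return(cons[i])
    if (quality == "strong") {
      probs <- rep((1 - cons_p) / 3, 4)
      probs[match(cons[i], .BASES)] <- cons_p
      sample(.BASES, 1, prob = probs)
    } else sample(.BASES, 1)
  }, character(1))
  paste(out, collapse = "")
}

# consensus profiles: donor = 3 exonic + GT + 4 intronic; acceptor =
# 20 intronic (pyrimidine tract ending ..AG) + 3 exonic
.DONOR_CONS <- "CAGGTAAGT"     # GT at positions 4-5
.ACC_CONS <- paste0(strrep("T", 16), "TCAG", "GTG")  # AG at positions 19-20

#' Simulate a single cassette-exon locus
#'
#' Builds the locus genome with canonical GT..AG introns (site strength per
#' `spec$site_quality`), samples reads from the two isoforms at the true
#' psi, and returns genome, reads (with genomic positions and N-CIGARs),
#' the planted junction table with overhang-filtered supports, and a truth
#' row. All randomness comes from the caller's RNG stream; seed it with
#' `set.seed()` for reproducibility.
#'
#' @param spec A [locus_spec()].
#' @param overhang Anchor length used when tallying planted junction
#'   supports, matching the read filter that will process the reads.
#' @return List of class `sim_locus`: `genome` (character), `glen`,
#'   `reads` (data.frame: `flag`, `pos` 0-based, `cigar`, `seq`,
#'   `isoform`), `junctions` (planted introns with `support`), `truth`
#'   (one-row data.frame of event coordinates, true psi, expected group),
#'   `site_seqs`.
#' @export
simulate_locus <- function(spec, overhang = 6L) {
  stopifnot(inherits(spec, "locus_spec"))
  L <- spec$read_length
  el <- c(spec$flank_exon_length, spec$exon_lengths, spec$flank_exon_length)
  il <- c(spec$flank_intron_length, spec$intron_lengths,
          spec$flank_intron_length)
  # segment order: e0 i0 e1 i1 e2 i2 e3 i3 e4 (plus orientation)
  seg_len <- c(el[1], il[1], el[2], il[2], el[3], il[3], el[4], il[4], el[5])
  seg_start <- cumsum(c(0L, seg_len[-length(seg_len)]))
  glen <- sum(seg_len)
  exon_idx <- c(1L, 3L, 5L, 7L, 9L)
  intron_idx <- c(2L, 4L, 6L, 8L)

  exons <- vapply(el, .rand_seq, character(1))
  introns <- vapply(il, .rand_seq, character(1))

  # plant splice sites: intron k has donor (left) and acceptor (right)
  qual <- c(i0_d = "strong", i0_a = "strong",
            i1_d = unname(spec$site_quality["upI_ss5"]),
            i1_a = unname(spec$site_quality["upI_ss3"]),
            i2_d = unname(spec$site_quality["dnI_ss5"]),
            i2_a = unname(spec$site_quality["dnI_ss3"]),
            i3_d = "strong", i3_a = "strong")
  site_seqs <- character(0)
  for (k in seq_len(4)) {
    d9 <- .sample_site(.DONOR_CONS, c(4, 5), qual[[2 * k - 1]])
    a23 <- .sample_site(.ACC_CONS, c(19, 20), qual[[2 * k]])
    substr(exons[k], el[k] - 2L, el[k]) <- substr(d9, 1, 3)
    substr(introns[k], 1L, 6L) <- substr(d9, 4, 9)
    substr(introns[k], il[k] - 19L, il[k]) <- substr(a23, 1, 20)
    substr(exons[k + 1L], 1L, 3L) <- substr(a23, 21, 23)
    site_seqs <- c(site_seqs,
                   stats::setNames(c(d9, a23),
                                   paste0("i", k - 1, c("_donor", "_acceptor"))))
  }
  genome <- paste(c(rbind(exons, c(introns, ""))), collapse = "")

  exon_gstart <- seg_start[exon_idx]
  exon_len <- seg_len[exon_idx]
  iso_exons <- list(inclusion = 1:5, skipping = c(1, 2, 4, 5))
  lookups <- lapply(iso_exons, function(ix)
    .tx_lookup(exon_gstart[ix], exon_len[ix], L))
  n_pos <- vapply(lookups, nrow, integer(1))

  n_reads <- round(spec$depth * sum(exon_len) / L)
  p_inc <- spec$true_psi * n_pos["inclusion"] /
    (spec$true_psi * n_pos["inclusion"] +
       (1 - spec$true_psi) * n_pos["skipping"])
  if (!is.finite(p_inc)) p_inc <- 0   # psi = 0 with degenerate weights
  iso <- ifelse(stats::rbinom(n_reads, 1, p_inc) == 1, "inclusion",
                "skipping")
  start_i <- integer(n_reads)
  for (nm in c("inclusion", "skipping")) {
    sel <- iso == nm
    start_i[sel] <- sample.int(n_pos[[nm]], sum(sel), replace = TRUE)
  }
  rows <- lapply(c("inclusion", "skipping"), function(nm) {
    sel <- which(iso == nm)
    lk <- lookups[[nm]][start_i[sel], , drop = FALSE]
    if (!length(sel)) return(NULL)
    data.frame(flag = 0L, pos = lk$pos, cigar = lk$cigar,
               seq = substring(.iso_seq(exons, introns, iso_exons[[nm]]),
                               lk$tstart + 1L, lk$tstart + L),
               isoform = nm, stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, rows)

  # planted junctions: the four constitutive/inclusion introns + skip
  intron_gstart <- seg_start[intron_idx]
  intron_gend <- intron_gstart + seg_len[intron_idx]
  jn <- data.frame(
    name = c("i0", "i1", "i2", "i3", "skip"),
    gstart = c(intron_gstart, intron_gstart[2]),
    gend = c(intron_gend, intron_gend[3]),
    stringsAsFactors = FALSE)
  jn$support <- .junction_supports(jn, lookups, iso, start_i, overhang, L)
  jn <- jn[jn$support > 0, , drop = FALSE]

  # tri-exon truth (plus orientation; mirrored below if '-')
  b <- c(up_exon_start = seg_start[3], up_exon_end = seg_start[4],
         mid_exon_start = seg_start[5], mid_exon_end = seg_start[6],
         dn_exon_start = seg_start[7], dn_exon_end = seg_start[8])

  out <- list(genome = genome, glen = glen, reads = reads,
              junctions = jn[, c("gstart", "gend", "support")],
              boundaries = b, site_seqs = site_seqs, spec = spec)
  if (spec$strand == "-") out <- .mirror_locus(out)
  out$truth <- data.frame(
    strand = spec$strand, true_psi = spec$true_psi,
    expected_group = classify_event(spec$true_psi),
    t(out$boundaries), stringsAsFactors = FALSE)
  class(out) <- "sim_locus"
  out
}

.iso_seq <- function(exons, introns, ix) paste(exons[ix], collapse = "")

# start-position lookup for one isoform: genomic pos (0-based), CIGAR and
# transcript start for every read start; also block structure for junction
# support tallies
.tx_lookup <- function(exon_gstart, exon_len, L) {
  tx_start <- cumsum(c(0L, exon_len[-length(exon_len)]))
  total <- sum(exon_len)
  n <- total - L + 1L
  pos <- integer(n); cig <- character(n)
  blocks <- vector("list", n)
  for (s in 0:(n - 1L)) {
    rem <- L; tpos <- s; bl <- NULL
    while (rem > 0L) {
      ei <- findInterval(tpos, tx_start)
      off <- tpos - tx_start[ei]
      take <- min(rem, exon_len[ei] - off)
      bl <- rbind(bl, c(g = exon_gstart[ei] + off, w = take))
      rem <- rem - take; tpos <- tpos + take
    }
    pos[s + 1L] <- bl[1, "g"]
    parts <- sprintf("%dM", bl[, "w"])
    if (nrow(bl) > 1) {
      gaps <- bl[-1, "g"] - (bl[-nrow(bl), "g"] + bl[-nrow(bl), "w"])
      parts <- c(rbind(parts[-length(parts)], sprintf("%dN", gaps)),
                 parts[length(parts)])
    }
    cig[s + 1L] <- paste(parts, collapse = "")
    blocks[[s + 1L]] <- bl
  }
  out <- data.frame(tstart = 0:(n - 1L), pos = pos, cigar = cig,
                    stringsAsFactors = FALSE)
  attr(out, "blocks") <- blocks
  out
}

# count reads supporting each planted junction with both anchors >= overhang
.junction_supports <- function(jn, lookups, iso, start_i, overhang, L) {
  sup <- stats::setNames(numeric(nrow(jn)), paste(jn$gstart, jn$gend))
  for (nm in names(lookups)) {
    lk <- lookups[[nm]]
    blocks <- attr(lk, "blocks")
    cnt <- table(start_i[iso == nm])
    for (s in names(cnt)) {
      bl <- blocks[[as.integer(s)]]
      if (nrow(bl) < 2) next
      for (g in seq_len(nrow(bl) - 1L)) {
        if (bl[g, "w"] < overhang || bl[g + 1L, "w"] < overhang) next
        key <- paste(bl[g, "g"] + bl[g, "w"], bl[g + 1L, "g"])
        if (key %in% names(sup)) sup[key] <- sup[key] + cnt[[s]]
      }
    }
  }
  as.integer(sup)
}

# reverse-complement a plus-built locus: mirror coordinates, reverse block
# order inside CIGARs, flag reads as reverse-strand
.mirror_locus <- function(x) {
  glen <- x$glen
  x$genome <- revcomp(x$genome)
  mir <- function(s, e) c(glen - e, glen - s)
  # reads
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$reads$cigar)
  new_pos <- glen - (x$reads$pos + ref_w)
  x$reads$cigar <- vapply(x$reads$cigar, .reverse_cigar, character(1),
                          USE.NAMES = FALSE)
  x$reads$pos <- new_pos
  x$reads$flag <- 16L
  x$reads$seq <- revcomp(x$reads$seq)
  # junctions
  j <- x$junctions
  newj <- data.frame(gstart = glen - j$gend, gend = glen - j$gstart,
                     support = j$support)
  x$junctions <- newj[order(newj$gstart), , drop = FALSE]
  # boundaries keep their transcription-role names; coordinates mirror and
  # each (start,end) pair swaps
  b <- x$boundaries
  x$boundaries <- c(up_exon_start = glen - b[["up_exon_end"]],
                    up_exon_end = glen - b[["up_exon_start"]],
                    mid_exon_start = glen - b[["mid_exon_end"]],
                    mid_exon_end = glen - b[["mid_exon_start"]],
                    dn_exon_start = glen - b[["dn_exon_end"]],
                    dn_exon_end = glen - b[["dn_exon_start"]])
  x
}

.reverse_cigar <- function(cig) {
  ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
  paste(rev(ops), collapse = "")
}

# spacer free of GT and AG dinucleotides (so no accidental canonical
# boundaries arise between loci)
.spacer_seq <- function(n) {
  s <- sample(.BASES, n, replace = TRUE)
  repeat {
    pair <- paste0(s[-length(s)], s[-1])
    bad <- which(pair %in% c("GT", "AG"))
    if (!length(bad)) break
    s[bad + 1L] <- sample(c("C", "A"), length(bad), replace = TRUE)
    # 'A' after 'A' is safe; 'C' after anything is safe
    s[bad + 1L][s[bad] == "A"] <- "C"
  }
  paste(s, collapse = "")
}

#' Simulate a multi-locus dataset
#'
#' Concatenates independently simulated loci on one chromosome, separated
#' by spacer sequence free of GT/AG dinucleotides, and (optionally) writes
#' genome FASTA, coordinate-sorted SAM, a truth table and a planted
#' junction table. All randomness derives from `seed`; the same seed gives
#' byte-identical files.
#'
#' @param n_loci Number of loci (>= 1).
#' @param true_psi Scalar or vector (recycled) of true inclusion fractions.
#' @param spec_template A [locus_spec()] whose fields other than
#'   `true_psi`/`site_quality` apply to every locus.
#' @param weak_low_psi_sites When `TRUE`, loci with `true_psi <= 0.3` get
#'   weak middle-exon-flanking sites (`dnI_ss5`, `upI_ss3`) - the planted
#'   group effect used to validate the competition analysis.
#' @param spacer Spacer length between loci (>= 1000).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, write `genome.fa`, `reads.sam`,
#'   `truth.tsv`, `junctions.tsv` and a `manifest.yaml` there.
#' @param overhang Anchor length for planted junction supports.
#' @return List of class `sim_dataset`: `genome` (named character),
#'   `reads` (data.frame with `qname`, `flag`, `chrom`, `pos`, `cigar`,
#'   `seq`), `truth` (per-locus event coordinates in chromosome space),
#'   `junctions`, `site_seqs` (data.frame: locus, site, quality, seq),
#'   `files` (paths, when written).
#' @export
simulate_dataset <- function(n_loci, true_psi = 0.5,
                             spec_template = locus_spec(),
                             weak_low_psi_sites = FALSE,
                             spacer = 1000L, chrom = "synth1",
                             seed = 1L, out_dir = NULL, overhang = 6L) {
  stopifnot(n_loci >= 1, spacer >= 1000)
  set.seed(seed)
  psi <- rep_len(true_psi, n_loci)
  parts <- character(0); offset <- 0L
  truth <- list(); reads <- list(); junctions <- list(); sseqs <- list()
  for (i in seq_len(n_loci)) {
    sp <- .spacer_seq(spacer)
    parts <- c(parts, sp); offset <- offset + spacer
    spec <- spec_template
    spec$true_psi <- psi[i]
    if (weak_low_psi_sites && psi[i] <= 0.3) {
      spec$site_quality[c("upI_ss3", "dnI_ss5")] <- "weak"
    }
    loc <- simulate_locus(spec, overhang = overhang)
    parts <- c(parts, loc$genome)
    lid <- sprintf("L%04d", i)
    tr <- loc$truth
    coord_cols <- grep("_exon_", names(tr))
    tr[coord_cols] <- tr[coord_cols] + offset
    tr <- cbind(locus = lid, chrom = chrom, tr, stringsAsFactors = FALSE)
    truth[[i]] <- tr
    if (nrow(loc$reads)) {
      rd <- loc$reads
      rd$pos <- rd$pos + offset
      rd$chrom <- chrom
      rd$qname <- sprintf("%s.r%05d", lid, seq_len(nrow(rd)))
      reads[[i]] <- rd
    }
    jn <- loc$junctions
    if (nrow(jn)) {
      jn$gstart <- jn$gstart + offset; jn$gend <- jn$gend + offset
      jn$chrom <- chrom; jn$locus <- lid
      junctions[[i]] <- jn
    }
    sseqs[[i]] <- data.frame(locus = lid, site = names(loc$site_seqs),
                             seq = unname(loc$site_seqs),
                             stringsAsFactors = FALSE)
    offset <- offset + loc$glen
  }
  parts <- c(parts, .spacer_seq(spacer))
  genome <- stats::setNames(paste(parts, collapse = ""), chrom)
  reads <- do.call(rbind, reads)
  reads <- reads[order(reads$pos), , drop = FALSE]
  rownames(reads) <- NULL
  out <- list(genome = genome,
              reads = reads,
              truth = do.call(rbind, truth),
              junctions = do.call(rbind, junctions),
              site_seqs = do.call(rbind, sseqs),
              chrom = chrom, seed = seed, files = NULL)
  class(out) <- "sim_dataset"
  if (!is.null(out_dir)) out <- write_sim_dataset(out, out_dir)
  out
}

#' Write a simulated dataset to disk
#'
#' @param ds A `sim_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return The dataset with `files` filled in.
#' @export
write_sim_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$genome), fa)
  sam <- file.path(out_dir, "reads.sam")
  write_sam(ds$reads, stats::setNames(nchar(ds$genome), names(ds$genome)),
            sam)
  truth <- file.path(out_dir, "truth.tsv")
  utils::write.table(ds$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jn <- file.path(out_dir, "junctions.tsv")
  utils::write.table(ds$junctions, jn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(generator = "gess::simulate_dataset",
                        package_version = as.character(
                          utils::packageVersion("gess")),
                        seed = ds$seed, chrom = ds$chrom,
                        n_loci = nrow(ds$truth),
                        files = list(genome = "genome.fa",
                                     reads = "reads.sam",
                                     truth = "truth.tsv",
                                     junctions = "junctions.tsv")),
                   manifest)
  ds$files <- c(genome = fa, reads = sam, truth = truth, junctions = jn,
                manifest = manifest)
  ds
}

#' Write reads as SAM
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header then one record per read
#' (MAPQ 50, `NH:i:1`), 1-based positions converted from the internal
#' 0-based convention.
#'
#' @param reads data.frame with `qname`, `flag`, `chrom`, `pos` (0-based),
#'   `cigar`, `seq`.
#' @param seqlens Named vector of chromosome lengths.
#' @param path Output file.
#' @export
write_sam <- function(reads, seqlens, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                   as.integer(seqlens)))
  body <- if (nrow(reads)) sprintf(
    "%s\t%d\t%s\t%d\t50\t%s\t*\t0\t0\t%s\t%s\tNH:i:1",
    reads$qname, reads$flag, reads$chrom, reads$pos + 1L, reads$cigar,
    reads$seq, strrep("I", nchar(reads$seq))) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a signal track (BED intervals) over event segments
#'
#' Generates background fragments uniformly over the event neighbourhoods
#' plus, optionally, extra fragments concentrated in one segment class of
#' one psi group - the planted positional enrichment used to validate the
#' density and motif-direction analyses.
#'
#' @param events Detected or truth-derived event table (needs the exon
#'   coordinate columns, `chrom` and `event_id`).
#' @param groups Named vector `event_id -> "SIDG"/"IIDG"`.
#' @param target Segment label, e.g. `"dnI_ss5:intronic"`.
#' @param target_group Group receiving the enrichment.
#' @param n_background Background fragments per event.
#' @param n_target Extra fragments in the target segment per event of the
#'   target group.
#' @param frag_len Fragment length.
#' @param exon_ext,intron_ext Segment extents (as in [event_segments()]).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
simulate_signal_bed <- function(events, groups, target = "dnI_ss5:intronic",
                                target_group = "SIDG", n_background = 20L,
                                n_target = 30L, frag_len = 50L,
                                exon_ext = 50L, intron_ext = 100L) {
  segs <- events_segments(events, exon_ext, intron_ext)
  segs$label <- paste(segs$site, segs$side, sep = ":")
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    s <- segs[segs$event_id == ev$event_id, , drop = FALSE]
    lo <- min(s$start) - intron_ext; hi <- max(s$end) + intron_ext
    bg_start <- sample(lo:(hi - frag_len), n_background, replace = TRUE)
    out[[length(out) + 1L]] <- data.frame(chrom = ev$chrom, start = bg_start,
                                          end = bg_start + frag_len)
    grp <- groups[[ev$event_id]] %||% NA_character_
    tseg <- s[s$label == target, , drop = FALSE]
    if (!is.na(grp) && grp == target_group && nrow(tseg) == 1 && n_target > 0) {
      ts <- sample(tseg$start:max(tseg$start, tseg$end - frag_len),
                   n_target, replace = TRUE)
      out[[length(out) + 1L]] <- data.frame(chrom = ev$chrom, start = ts,
                                            end = ts + frag_len)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Simulate a motif-hit count table over event segments
#'
#' Poisson background hit counts proportional to segment length, plus an
#' additive enrichment in one segment class for one group.
#'
#' @inheritParams simulate_signal_bed
#' @param factors Character vector of motif/factor names.
#' @param target_factor Factor receiving the planted enrichment.
#' @param bg_rate Background hits per base.
#' @param effect Extra expected hits in the target segment.
#' @return Long data.frame: `event_id`, `site`, `side`, `factor`, `count`,
#'   `length`.
#' @export
simulate_motif_hits <- function(events, groups, factors = c("SF1", "SF2"),
                                target_factor = factors[1],
                                target = "dnI_ss5:intronic",
                                target_group = "SIDG",
                                bg_rate = 0.02, effect = 3,
                                exon_ext = 50L, intron_ext = 100L) {
  segs <- events_segments(events, exon_ext, intron_ext)
  segs$label <- paste(segs$site, segs$side, sep = ":")
  out <- list()
  for (fac in factors) {
    d <- segs
    lam <- bg_rate * d$length
    boost <- fac == target_factor & d$label == target &
      groups[d$event_id] == target_group
    lam <- lam + ifelse(!is.na(boost) & boost, effect, 0)
    out[[length(out) + 1L]] <- data.frame(
      event_id = d$event_id, site = d$site, side = d$side, factor = fac,
      count = stats::rpois(nrow(d), lam), length = d$length,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
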