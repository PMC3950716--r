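#' Scan the splice graph for exon-skipping events
#'
#' Searches for the six-node signature of a cassette exon, in genomic order
#' `n1 < n2 < n3 < n4 < n5 < n6` on one chromosome: solid (exon) edges
#' `(n1,n2)`, `(n3,n4)`, `(n5,n6)`; dotted (intron) edges `(n2,n3)` and
#' `(n4,n5)` for the two flanking introns, plus the skip edge `(n2,n5)`
#' joining the outer exons directly. Node kinds must be consistent with the
#' pattern (`n2`,`n4` at intron starts; `n3`,`n5` at intron ends) and all
#' participating edges must agree on strand (`"unknown"` is compatible with
#' either). Sub-graphs missing any required edge are ignored; intron
#' retention and other alternative-splicing patterns never match.
#'
#' Enumeration is seeded from skip-candidate intron edges rather than from
#' all \eqn{\binom{n}{6}} sextets; equivalence with exhaustive enumeration
#' is a tested property, not an assumption.
#'
#' @param g A `gess_graph` from [build_splice_graph()].
#' @param extents `"shortest"` (default) reports one event per tri-exon
#'   core, taking the shortest solid edge reaching each outer boundary;
#'   `"all"` emits one event per matching sextet.
#' @return data.frame of class `gess_events`, one row per event, with
#'   genomic exon coordinates labelled by transcription role (`up_` =
#'   upstream exon, `mid_` = cassette exon, `dn_` = downstream exon), the
#'   four splice-site positions `upI_ss5`, `upI_ss3`, `dnI_ss5`, `dnI_ss3`,
#'   and junction supports `inc_up_support`, `inc_dn_support`,
#'   `skip_support`. On `"-"` events the upstream exon is the genomic
#'   rightmost; on `"unknown"` strand roles are assigned as if `"+"`.
#' @export
scan_skipping_events <- function(g, extents = c("shortest", "all")) {
  extents <- match.arg(extents)
  ie <- g$intron_edges
  ee <- g$exon_edges
  out <- list()
  if (nrow(ie) && nrow(ee)) {
    for (k in seq_len(nrow(ie))) {
      skip <- ie[k, ]
      n2 <- skip$intron_start; n5 <- skip$intron_end; chr <- skip$chrom
      # inclusion intron edges inside the skip span
      up <- ie[ie$chrom == chr & ie$intron_start == n2 &
                 ie$intron_end < n5, , drop = FALSE]
      dn <- ie[ie$chrom == chr & ie$intron_end == n5 &
                 ie$intron_start > n2, , drop = FALSE]
      if (!nrow(up) || !nrow(dn)) next
      for (iu in seq_len(nrow(up))) for (idn in seq_len(nrow(dn))) {
        n3 <- up$intron_end[iu]; n4 <- dn$intron_start[idn]
        if (n3 >= n4) next
        strands <- c(skip$strand, up$strand[iu], dn$strand[idn])
        known <- setdiff(strands, "unknown")
        if (length(unique(known)) > 1) next
        ev_strand <- if (length(known)) known[1] else "unknown"
        # middle exon must be a solid edge exactly (n3, n4)
        mid_ok <- any(ee$chrom == chr & ee$start == n3 & ee$end == n4 &
                        (ee$strand == "unknown" | ee$strand == ev_strand |
                           ev_strand == "unknown"))
        if (!mid_ok) next
        upex <- ee[ee$chrom == chr & ee$end == n2 & ee$start < n2 &
                     (ee$strand == "unknown" | ee$strand == ev_strand |
                        ev_strand == "unknown"), , drop = FALSE]
        dnex <- ee[ee$chrom == chr & ee$start == n5 & ee$end > n5 &
                     (ee$strand == "unknown" | ee$strand == ev_strand |
                        ev_strand == "unknown"), , drop = FALSE]
        if (!nrow(upex) || !nrow(dnex)) next
        if (extents == "shortest") {
          upex <- upex[which.max(upex$start), , drop = FALSE]
          dnex <- dnex[which.min(dnex$end), , drop = FALSE]
        }
        for (a in seq_len(nrow(upex))) for (b in seq_len(nrow(dnex))) {
          out[[length(out) + 1L]] <- .make_event(
            chr, ev_strand, upex$start[a], n2, n3, n4, n5, dnex$end[b],
            up$support[iu], dn$support[idn], skip$support)
        }
      }
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else .empty_events()
  ev <- deduplicate_events(ev)
  class(ev) <- c("gess_events", "data.frame")
  ev
}

# assemble one event row from genomic boundaries; transcription roles are
# mirrored on '-' strand (upstream exon = genomic rightmost)
.make_event <- function(chr, strand, g1, g2, g3, g4, g5, g6,
                        sup_left, sup_right, sup_skip) {
  if (strand == "-") {
    data.frame(chrom = chr, strand = strand,
               up_exon_start = g5, up_exon_end = g6,
               mid_exon_start = g3, mid_exon_end = g4,
               dn_exon_start = g1, dn_exon_end = g2,
               upI_ss5 = g5, upI_ss3 = g4, dnI_ss5 = g3, dnI_ss3 = g2,
               inc_up_support = sup_right, inc_dn_support = sup_left,
               skip_support = sup_skip, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = chr, strand = strand,
               up_exon_start = g1, up_exon_end = g2,
               mid_exon_start = g3, mid_exon_end = g4,
               dn_exon_start = g5, dn_exon_end = g6,
               upI_ss5 = g2, upI_ss3 = g3, dnI_ss5 = g4, dnI_ss3 = g5,
               inc_up_support = sup_left, inc_dn_support = sup_right,
               skip_support = sup_skip, stringsAsFactors = FALSE)
  }
}

.empty_events <- function() {
  data.frame(chrom = character(), strand = character(),
             up_exon_start = integer(), up_exon_end = integer(),
             mid_exon_start = integer(), mid_exon_end = integer(),
             dn_exon_start = integer(), dn_exon_end = integer(),
             upI_ss5 = integer(), upI_ss3 = integer(),
             dnI_ss5 = integer(), dnI_ss3 = integer(),
             inc_up_support = integer(), inc_dn_support = integer(),
             skip_support = integer(), stringsAsFactors = FALSE)
}

#' Collapse duplicate events and sort
#'
#' Events identical in all six exon boundary coordinates (and chromosome)
#' collapse to one; output is sorted by chromosome and genomic start.
#'
#' @param events Event data.frame from [scan_skipping_events()].
#' @return De-duplicated, sorted event data.frame with an `event_id` column.
#' @export
deduplicate_events <- function(events) {
  if (nrow(events)) {
    key <- c("chrom", "up_exon_start", "up_exon_end", "mid_exon_start",
             "mid_exon_end", "dn_exon_start", "dn_exon_end")
    events <- events[!duplicated(events[, key]), , drop = FALSE]
    gstart <- pmin(events$up_exon_start, events$dn_exon_start)
    events <- events[order(events$chrom, gstart, events$mid_exon_start), ,
                     drop = FALSE]
    rownames(events) <- NULL
  }
  events$event_id <- if (nrow(events))
    sprintf("EV%05d", seq_len(nrow(events))) else character(0)
  events
}

#' Write events as tab-separated table, BED12 or GFF3
#'
#' `write_event_table` emits one row per event with all coordinates and
#' supports. `write_event_bed12` writes two BED12 lines per event (the
#' three-exon inclusion isoform and the two-exon skipping isoform).
#' `write_event_gff3` writes a gene/mRNA/exon hierarchy per isoform.
#'
#' @param events Event data.frame.
#' @param path Output file.
#' @name event-export
#' @export
write_event_table <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# genomic (left-to-right) exon blocks of both isoforms of one event
.event_blocks <- function(ev) {
  ex <- matrix(c(ev$up_exon_start, ev$up_exon_end,
                 ev$mid_exon_start, ev$mid_exon_end,
                 ev$dn_exon_start, ev$dn_exon_end),
               ncol = 2, byrow = TRUE)
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  list(inclusion = ex, skipping = ex[-2, , drop = FALSE])
}

#' @rdname event-export
#' @export
write_event_bed12 <- function(events, path) {
  lines <- character(0)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    bl <- .event_blocks(ev)
    strand <- if (ev$strand %in% c("+", "-")) ev$strand else "."
    for (iso in names(bl)) {
      ex <- bl[[iso]]
      start <- ex[1, 1]; end <- ex[nrow(ex), 2]
      lines <- c(lines, paste(
        ev$chrom, start, end, paste0(ev$event_id, ".", iso), 0, strand,
        start, end, "0,0,0", nrow(ex),
        paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
        paste0(paste(ex[, 1] - start, collapse = ","), ","),
        sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname event-export
#' @export
write_event_gff3 <- function(events, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    bl <- .event_blocks(ev)
    strand <- if (ev$strand %in% c("+", "-")) ev$strand else "."
    gid <- ev$event_id
    span <- range(unlist(bl$inclusion))
    lines <- c(lines, paste(ev$chrom, "gess", "gene", span[1] + 1, span[2],
                            ".", strand, ".", paste0("ID=", gid), sep = "\t"))
    for (iso in names(bl)) {
      mid <- paste0(gid, ".", iso)
      ex <- bl[[iso]]
      lines <- c(lines, paste(ev$chrom, "gess", "mRNA", ex[1, 1] + 1,
                              ex[nrow(ex), 2], ".", strand, ".",
                              paste0("ID=", mid, ";Parent=", gid), sep = "\t"))
      for (e in seq_len(nrow(ex))) {
        lines <- c(lines, paste(ev$chrom, "gess", "exon", ex[e, 1] + 1,
                                ex[e, 2], ".", strand, ".",
                                paste0("ID=", mid, ".e", e, ";Parent=", mid),
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
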