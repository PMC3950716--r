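#' Orient junctions by the GT-AG consensus
#'
#' A junction is `"+"` when the intron reads `GT..AG` on the forward strand,
#' `"-"` when it reads `CT..AC` (the reverse complement pattern), and
#' `"unknown"` otherwise or when no genome is supplied.
#'
#' @param junctions Junction data.frame (see [load_alignments()]).
#' @param genome FASTA path, `DNAStringSet`, or named character vector;
#'   `NULL` leaves all strands `"unknown"`.
#' @return The data.frame with its `strand` column filled in.
#' @export
orient_junctions <- function(junctions, genome = NULL) {
  genome <- as_genome(genome)
  if (is.null(genome) || nrow(junctions) == 0) {
    if (nrow(junctions)) junctions$strand <- "unknown"
    return(junctions)
  }
  junctions$strand <- vapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    first2 <- genome_slice(genome, j$chrom, j$intron_start, j$intron_start + 2L)
    last2 <- genome_slice(genome, j$chrom, j$intron_end - 2L, j$intron_end)
    plus <- first2 == "GT" && last2 == "AG"
    minus <- first2 == "CT" && last2 == "AC"
    if (plus && !minus) "+" else if (minus && !plus) "-" else "unknown"
  }, character(1))
  junctions
}

#' Build splice-site nodes from junctions
#'
#' One node per distinct (chrom, pos, kind). On a `"+"` (or unknown)
#' junction the intron start is the donor and the intron end the acceptor;
#' on `"-"` the roles are swapped (the donor sits at the genomic right
#' boundary). Nodes are sorted by (chrom, pos).
#'
#' @param junctions Oriented junction data.frame.
#' @return data.frame with `chrom`, `pos` (0-based boundary coordinate),
#'   `kind` (`"donor"`/`"acceptor"`), `strand`.
#' @export
build_nodes <- function(junctions) {
  if (nrow(junctions) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      kind = character(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  minus <- junctions$strand == "-"
  left <- data.frame(chrom = junctions$chrom, pos = junctions$intron_start,
                     kind = ifelse(minus, "acceptor", "donor"),
                     strand = junctions$strand, stringsAsFactors = FALSE)
  right <- data.frame(chrom = junctions$chrom, pos = junctions$intron_end,
                      kind = ifelse(minus, "donor", "acceptor"),
                      strand = junctions$strand, stringsAsFactors = FALSE)
  nodes <- unique(rbind(left, right))
  nodes <- nodes[order(nodes$chrom, nodes$pos, nodes$kind), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' Add intron ("dotted") edges
#'
#' A dotted edge links the two boundary nodes of a junction when its spliced
#' read support reaches `min_junction_support` (the threshold is met at
#' exactly the default, 8). Edge direction is donor to acceptor.
#'
#' @param junctions Oriented junction data.frame.
#' @param cfg A [graph_config()].
#' @param genome Optional genome used to mark `canonical` (GT..AG in either
#'   orientation).
#' @return data.frame of intron edges: `chrom`, `intron_start`,
#'   `intron_end`, `support`, `strand`, `canonical`.
#' @export
add_intron_edges <- function(junctions, cfg = graph_config(), genome = NULL) {
  keep <- junctions$support >= cfg$min_junction_support
  e <- junctions[keep, , drop = FALSE]
  e$canonical <- e$strand %in% c("+", "-")
  rownames(e) <- NULL
  e
}

#' Add exon ("solid") edges from coverage contrast
#'
#' Splice-site coordinates partition each chromosome into segments; a
#' segment between two adjacent sites becomes a solid edge when its mean
#' constitutive-read depth is at least `min_exon_signal_ratio` times the
#' larger of its two flanking segments' means (boundary inclusive) and it
#' is no longer than `max_exon_length`. The flank of a first/last segment
#' is a window of the segment's own length outside the node range; at a
#' chromosome end only the single available flank is used. A zero
#' background with positive signal counts as an infinite ratio (edge
#' accepted). Nodes with conflicting known strands never share an edge.
#'
#' @param nodes Node data.frame from [build_nodes()].
#' @param coverage Named list of per-chromosome depth Rle
#'   (from [load_alignments()]).
#' @param cfg A [graph_config()].
#' @return data.frame of exon edges: `chrom`, `start`, `end`, `mean_depth`,
#'   `flank_ratio`, `strand`.
#' @export
add_exon_edges <- function(nodes, coverage, cfg = graph_config()) {
  out <- list()
  for (chr in unique(nodes$chrom)) {
    nd <- nodes[nodes$chrom == chr, , drop = FALSE]
    pos <- sort(unique(nd$pos))
    if (length(pos) < 2) next
    segs <- data.frame(start = pos[-length(pos)], end = pos[-1])
    segs$len <- segs$end - segs$start
    segs$depth <- vapply(seq_len(nrow(segs)), function(i)
      coverage_mean(coverage, chr, segs$start[i], segs$end[i]), numeric(1))
    nseg <- nrow(segs)
    for (i in seq_len(nseg)) {
      if (segs$len[i] < 1 || segs$len[i] > cfg$max_exon_length) next
      lf <- if (i > 1) segs$depth[i - 1] else
        coverage_mean(coverage, chr, max(0L, segs$start[i] - segs$len[i]),
                      segs$start[i])
      rf <- if (i < nseg) segs$depth[i + 1] else
        coverage_mean(coverage, chr, segs$end[i], segs$end[i] + segs$len[i])
      bg <- max(c(lf, rf), na.rm = TRUE)
      if (!is.finite(bg)) bg <- 0
      ratio <- if (bg > 0) segs$depth[i] / bg else
        if (segs$depth[i] > 0) Inf else 0
      if (ratio < cfg$min_exon_signal_ratio) next
      # strand compatibility of the two endpoint nodes
      s_left <- unique(nd$strand[nd$pos == segs$start[i]])
      s_right <- unique(nd$strand[nd$pos == segs$end[i]])
      known <- setdiff(union(s_left, s_right), "unknown")
      if (length(known) > 1) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = segs$start[i], end = segs$end[i],
        mean_depth = segs$depth[i], flank_ratio = ratio,
        strand = if (length(known) == 1) known else "unknown",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mean_depth = numeric(),
                      flank_ratio = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the splice-site link graph
#'
#' Runs orientation, node construction and both edge classes; the result is
#' the substrate scanned by [scan_skipping_events()].
#'
#' @param junctions Junction data.frame from [load_alignments()].
#' @param coverage Coverage list from [load_alignments()].
#' @param cfg A [graph_config()].
#' @param genome Optional genome for GT-AG orientation.
#' @return List of class `gess_graph`: `nodes`, `intron_edges`,
#'   `exon_edges`, `config`.
#' @export
build_splice_graph <- function(junctions, coverage, cfg = graph_config(),
                               genome = NULL) {
  junctions <- orient_junctions(junctions, genome)
  nodes <- build_nodes(junctions)
  intron_edges <- add_intron_edges(junctions, cfg, genome)
  exon_edges <- add_exon_edges(nodes, coverage, cfg)
  structure(list(nodes = nodes, intron_edges = intron_edges,
                 exon_edges = exon_edges, config = cfg),
            class = "gess_graph")
}

#' @export
print.gess_graph <- function(x, ...) {
  cat("gess splice graph:", nrow(x$nodes), "nodes,",
      nrow(x$intron_edges), "intron edges,",
      nrow(x$exon_edges), "exon edges\n")
  invisible(x)
}
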