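#' Run the detection stage: alignments to event table
#'
#' Composes [load_alignments()], [build_splice_graph()] and
#' [scan_skipping_events()], writes the event table plus BED12 and GFF3
#' exports and a run manifest, and logs filter counts to stderr.
#'
#' @param alignments SAM/BAM path.
#' @param genome Optional genome FASTA for GT-AG orientation; without it
#'   events carry strand `"unknown"`.
#' @param out_dir Output directory.
#' @param cfg A [run_config()].
#' @return The event data.frame, invisibly; files `events.tsv`,
#'   `events.bed12`, `events.gff3`, `junctions.bed`, `manifest.yaml` in
#'   `out_dir`.
#' @export
run_detect <- function(alignments, genome = NULL, out_dir = ".",
                       cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genome))
    message("no genome supplied; junction strands will be 'unknown'")
  al <- load_alignments(alignments, cfg$read_filter)
  message(sprintf(
    "records: %d (spliced %d, constitutive %d, discarded %d, bad CIGAR %d)",
    al$stats["n_records"], al$stats["n_spliced"],
    al$stats["n_constitutive"], al$stats["n_discarded"],
    al$stats["n_skipped_cigar"]))
  g <- build_splice_graph(al$junctions, al$coverage, cfg$graph, genome)
  message(sprintf(
    "graph: %d nodes, %d intron edges (of %d junctions), %d exon edges",
    nrow(g$nodes), nrow(g$intron_edges), nrow(al$junctions),
    nrow(g$exon_edges)))
  events <- scan_skipping_events(g)
  message("events: ", nrow(events))
  write_event_table(events, file.path(out_dir, "events.tsv"))
  write_event_bed12(events, file.path(out_dir, "events.bed12"))
  write_event_gff3(events, file.path(out_dir, "events.gff3"))
  write_junction_bed(al$junctions, file.path(out_dir, "junctions.bed"))
  .write_manifest(out_dir, "detect", cfg,
                  inputs = c(alignments = alignments,
                             genome = if (is.character(genome)) genome))
  invisible(events)
}

#' Run the psi stage: events + alignments to psi table
#'
#' @param events Event table (data.frame or `events.tsv` path).
#' @param alignments SAM/BAM path (the same set used for detection).
#' @param out_dir Output directory.
#' @param cfg A [run_config()].
#' @return psi data.frame, invisibly; writes `psi.tsv`.
#' @export
run_psi <- function(events, alignments, out_dir = ".", cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- .read_events(events)
  al <- load_alignments(alignments, cfg$read_filter)
  psi <- psi_events(events, al$junctions, cfg)
  utils::write.table(psi, file.path(out_dir, "psi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("psi estimated for ", nrow(psi), " events (",
          sum(psi$group == "SIDG"), " SIDG, ",
          sum(psi$group == "IIDG"), " IIDG)")
  .write_manifest(out_dir, "psi", cfg, inputs = c(alignments = alignments))
  invisible(psi)
}

#' Run the splice-strength stage
#'
#' Trains donor and acceptor maxent models (from user-supplied training
#' sites, or from all detected canonical sites when none are given),
#' scores the four sites of every event, computes the competition score S,
#' and - when a psi table is supplied - a SIDG-versus-IIDG summary in the
#' four-sites-plus-S layout.
#'
#' @param events Event table (data.frame or path).
#' @param genome Genome FASTA/`DNAStringSet`.
#' @param psi Optional psi table (data.frame or path) for the group
#'   comparison.
#' @param donor_training,acceptor_training Optional character vectors of
#'   9-mer / 23-mer training sites.
#' @param out_dir Output directory.
#' @param cfg A [run_config()].
#' @return List with `scores` (per-event) and `summary` (per-site-class,
#'   or `NULL`), invisibly; writes `site_scores.tsv` and
#'   `strength_summary.tsv`.
#' @export
run_strength <- function(events, genome, psi = NULL,
                         donor_training = NULL, acceptor_training = NULL,
                         out_dir = ".", cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- .read_events(events)
  genome <- as_genome(genome)
  seqs <- t(vapply(seq_len(nrow(events)), function(i)
    extract_site_sequences(events[i, ], genome), character(4)))
  colnames(seqs) <- c("upI_ss5", "upI_ss3", "dnI_ss5", "dnI_ss3")
  if (is.null(donor_training))
    donor_training <- as.vector(seqs[, c("upI_ss5", "dnI_ss5")])
  if (is.null(acceptor_training))
    acceptor_training <- as.vector(seqs[, c("upI_ss3", "dnI_ss3")])
  dm <- train_maxent(donor_training, kind = "donor5")
  am <- train_maxent(acceptor_training, kind = "acceptor3")
  sc <- data.frame(event_id = events$event_id,
                   upI_ss5 = score_site(dm, seqs[, "upI_ss5"]),
                   upI_ss3 = score_site(am, seqs[, "upI_ss3"]),
                   dnI_ss5 = score_site(dm, seqs[, "dnI_ss5"]),
                   dnI_ss3 = score_site(am, seqs[, "dnI_ss3"]),
                   stringsAsFactors = FALSE)
  sc <- cbind(sc[1], competition_score(sc[-1]))
  utils::write.table(sc, file.path(out_dir, "site_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- NULL
  if (!is.null(psi)) {
    psi <- .read_table_arg(psi)
    grp <- stats::setNames(psi$group, psi$event_id)[sc$event_id]
    if (any(grp == "SIDG", na.rm = TRUE) &&
        any(grp == "IIDG", na.rm = TRUE)) {
      summary <- compare_site_strengths(
        sc[!is.na(grp) & grp == "SIDG", , drop = FALSE],
        sc[!is.na(grp) & grp == "IIDG", , drop = FALSE])
      utils::write.table(summary,
                         file.path(out_dir, "strength_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      message("one psi group is empty; skipping group comparison")
    }
  }
  write_maxent_model(dm, file.path(out_dir, "donor_model.txt"))
  write_maxent_model(am, file.path(out_dir, "acceptor_model.txt"))
  .write_manifest(out_dir, "strength", cfg)
  invisible(list(scores = sc, summary = summary))
}

#' Run the region-profile stage
#'
#' Computes the eight splice-site-flanking segments per event, signal
#' densities (optionally control-subtracted), per-factor Z-score profiles
#' with between-group Pearson similarity, and motif-hit enrichment when a
#' hit table is supplied.
#'
#' @param events Event table (data.frame or path).
#' @param psi psi table (data.frame or path) supplying group labels.
#' @param signal Signal intervals (BED path, data.frame or GRanges).
#' @param library_size Signal library size.
#' @param control Optional `list(intervals=, library_size=)`.
#' @param motif_hits Optional motif-hit table (path or data.frame, long
#'   format as in [motif_enrichment()]).
#' @param factor_name Name for the signal track in outputs.
#' @param out_dir Output directory.
#' @param cfg A [run_config()].
#' @return List with `segments`, `density`, `zscore` and `motif`,
#'   invisibly; writes TSV matrices.
#' @export
run_profile <- function(events, psi, signal = NULL, library_size = NULL,
                        control = NULL, motif_hits = NULL,
                        factor_name = "signal", out_dir = ".",
                        cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- .read_events(events)
  psi <- .read_table_arg(psi)
  groups <- stats::setNames(psi$group, psi$event_id)
  segs <- events_segments(events, cfg$exon_ext, cfg$intron_ext)
  write_segment_bed(segs, file.path(out_dir, "segments.bed"))
  dens <- z <- NULL
  if (!is.null(signal)) {
    dens <- tag_density(segs, signal, library_size, control)
    dens$factor <- factor_name
    utils::write.table(dens, file.path(out_dir, "density.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    z <- zscore_heat(dens, groups)
    utils::write.table(z$z, file.path(out_dir, "zscores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(z$r, file.path(out_dir, "pearson_r.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  motif <- NULL
  if (!is.null(motif_hits)) {
    motif <- motif_enrichment(.read_table_arg(motif_hits), groups)
    utils::write.table(motif, file.path(out_dir, "motif_heat.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_manifest(out_dir, "profile", cfg)
  invisible(list(segments = segs, density = dens, zscore = z,
                 motif = motif))
}

#' Run the simulation stage
#'
#' @param out_dir Output directory for the dataset files.
#' @param n_loci,true_psi,weak_low_psi_sites,seed Passed to
#'   [simulate_dataset()].
#' @param spec_template A [locus_spec()].
#' @return The `sim_dataset`, invisibly.
#' @export
run_simulate <- function(out_dir, n_loci = 20L, true_psi = 0.5,
                         weak_low_psi_sites = FALSE, seed = 1L,
                         spec_template = locus_spec()) {
  ds <- simulate_dataset(n_loci = n_loci, true_psi = true_psi,
                         spec_template = spec_template,
                         weak_low_psi_sites = weak_low_psi_sites,
                         seed = seed, out_dir = out_dir)
  message("simulated ", n_loci, " loci -> ", out_dir)
  invisible(ds)
}

.read_events <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  need <- c("chrom", "strand", "up_exon_start", "up_exon_end",
            "mid_exon_start", "mid_exon_end", "dn_exon_start",
            "dn_exon_end", "event_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  x
}

.read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1)
    utils::read.table(x, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else x
}

.write_manifest <- function(out_dir, stage, cfg, inputs = NULL) {
  hashes <- NULL
  if (!is.null(inputs)) {
    inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
    if (length(inputs))
      hashes <- as.list(tools::md5sum(unname(inputs)))
  }
  yaml::write_yaml(
    list(stage = stage,
         package_version = as.character(utils::packageVersion("gess")),
         config = lapply(unclass(cfg),
                         function(x) if (is.list(x)) unclass(x) else x),
         input_md5 = hashes),
    file.path(out_dir, paste0("manifest_", stage, ".yaml")))
}
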