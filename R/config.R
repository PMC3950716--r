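#' Read-filter configuration
#'
#' Filters applied to alignment records before they contribute junction or
#' coverage evidence.
#'
#' @param min_mapping_quality Minimum MAPQ; records below are discarded.
#'   Default 0 (permissive; splicing-aware mappers already encode multi-hit
#'   status in flags/tags).
#' @param max_ambiguous_bases Maximum number of `N` bases allowed in a read
#'   sequence. Default 2.
#' @param discard_multimapped Drop records whose mapper hit count (`NH` tag)
#'   exceeds 1 or whose secondary-alignment flag is set. Default `TRUE`.
#' @param min_junction_overhang Minimum aligned bases a spliced read must
#'   anchor on each side of an intron gap for that gap to count as junction
#'   support. Default 6.
#'
#' @return A list of class `gess_read_filter`.
#' @export
read_filter_config <- function(min_mapping_quality = 0L,
                               max_ambiguous_bases = 2L,
                               discard_multimapped = TRUE,
                               min_junction_overhang = 6L) {
  stopifnot(min_junction_overhang >= 1, min_mapping_quality >= 0,
            max_ambiguous_bases >= 0)
  structure(list(min_mapping_quality = as.integer(min_mapping_quality),
                 max_ambiguous_bases = as.integer(max_ambiguous_bases),
                 discard_multimapped = isTRUE(discard_multimapped),
                 min_junction_overhang = as.integer(min_junction_overhang)),
            class = "gess_read_filter")
}

#' Splice-graph construction parameters
#'
#' @param min_junction_support Minimum spliced-read support for an intron
#'   ("dotted") edge; the threshold is met at exactly this count. Default 8.
#' @param min_exon_signal_ratio Minimum ratio of a segment's mean coverage to
#'   the larger of its two flanking segments' means for an exon ("solid")
#'   edge. Default 3.0, inclusive.
#' @param max_exon_length Segments longer than this are never called exons.
#'   Default 5000 bases.
#'
#' @return A list of class `gess_graph_config`.
#' @export
graph_config <- function(min_junction_support = 8L,
                         min_exon_signal_ratio = 3.0,
                         max_exon_length = 5000L) {
  stopifnot(min_junction_support >= 1, min_exon_signal_ratio > 1,
            max_exon_length >= 1)
  structure(list(min_junction_support = as.integer(min_junction_support),
                 min_exon_signal_ratio = as.numeric(min_exon_signal_ratio),
                 max_exon_length = as.integer(max_exon_length)),
            class = "gess_graph_config")
}

#' Full pipeline configuration
#'
#' Collects every stage's parameters with the method's published defaults
#' (junction support 8, exon signal ratio 3.0, psi group thresholds 0.7/0.3,
#' 50 bp exonic / 100 bp intronic flanking segments). Serializes losslessly
#' to YAML via [write_run_config()].
#'
#' @param read_filter A [read_filter_config()].
#' @param graph A [graph_config()].
#' @param read_length Read length used for effective-position rescaling.
#' @param psi_prior Beta prior `c(alpha, beta)` on psi. Default `c(1, 1)`.
#' @param iidg_threshold psi at or above which an event is
#'   inclusion-isoform-dominated (IIDG). Default 0.7.
#' @param sidg_threshold psi at or below which an event is
#'   skipping-isoform-dominated (SIDG). Default 0.3.
#' @param exon_ext,intron_ext Flanking-segment extents in bases. Defaults
#'   50 and 100.
#' @param seed Integer seed for any stochastic stage.
#'
#' @return A list of class `gess_run_config`.
#' @export
run_config <- function(read_filter = read_filter_config(),
                       graph = graph_config(),
                       read_length = 100L,
                       psi_prior = c(1, 1),
                       iidg_threshold = 0.7,
                       sidg_threshold = 0.3,
                       exon_ext = 50L,
                       intron_ext = 100L,
                       seed = 1L) {
  stopifnot(length(psi_prior) == 2, all(psi_prior > 0),
            sidg_threshold < iidg_threshold, exon_ext >= 1, intron_ext >= 1)
  structure(list(read_filter = read_filter, graph = graph,
                 read_length = as.integer(read_length),
                 psi_prior = as.numeric(psi_prior),
                 iidg_threshold = as.numeric(iidg_threshold),
                 sidg_threshold = as.numeric(sidg_threshold),
                 exon_ext = as.integer(exon_ext),
                 intron_ext = as.integer(intron_ext),
                 seed = as.integer(seed)),
            class = "gess_run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns the reconstructed `gess_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "gess_run_config"))
  yaml::write_yaml(lapply(cfg, function(x) if (is.list(x)) unclass(x) else x),
                   path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    read_filter = do.call(read_filter_config, y$read_filter),
    graph = do.call(graph_config, y$graph),
    read_length = y$read_length,
    psi_prior = as.numeric(y$psi_prior),
    iidg_threshold = y$iidg_threshold,
    sidg_threshold = y$sidg_threshold,
    exon_ext = y$exon_ext,
    intron_ext = y$intron_ext,
    seed = y$seed)
}
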