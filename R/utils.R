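# internal helpers shared across modules

# Coerce a genome argument to a named DNAStringSet. Accepts a FASTA path,
# a DNAStringSet, or a named character vector of chromosome sequences.
as_genome <- function(genome) {
  if (is.null(genome)) return(NULL)
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("genome must be a FASTA path, DNAStringSet, or named character vector")
}

# 0-based half-open slice of one chromosome; errors outside bounds.
genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not in genome")
  len <- Biostrings::width(genome[chrom])
  if (start < 0 || end > len || start > end)
    stop("coordinates [", start, ",", end, ") outside '", chrom,
         "' (length ", len, ")")
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# empty junction table (internal coordinates: 0-based half-open)
empty_junctions <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), support = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

# mean depth of a coverage RleList over [start, end); zero-width -> NA
coverage_mean <- function(coverage, chrom, start, end) {
  if (end <= start) return(NA_real_)
  if (is.null(coverage) || !chrom %in% names(coverage)) return(0)
  rle <- coverage[[chrom]]
  n <- length(rle)
  if (start >= n) return(0)
  s <- start + 1L
  e <- min(end, n)
  tot <- sum(as.numeric(S4Vectors::window(rle, s, e)))
  tot / (end - start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
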