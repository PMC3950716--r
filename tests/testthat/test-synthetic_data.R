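test_that("psi extremes silence the corresponding junctions", {
  set.seed(41)
  inc_only <- simulate_locus(locus_spec(true_psi = 1))
  # skip junction (from up-exon end to dn-exon start) absent
  b <- inc_only$boundaries
  expect_false(any(inc_only$junctions$gstart == b[["up_exon_end"]] &
                     inc_only$junctions$gend == b[["dn_exon_start"]]))
  skip_only <- simulate_locus(locus_spec(true_psi = 0))
  b <- skip_only$boundaries
  expect_false(any(skip_only$junctions$gstart == b[["up_exon_end"]] &
                     skip_only$junctions$gend == b[["mid_exon_start"]]))
  expect_false(any(skip_only$junctions$gstart == b[["mid_exon_end"]] &
                     skip_only$junctions$gend == b[["dn_exon_start"]]))
  expect_true(all(skip_only$reads$isoform == "skipping"))
})

test_that("inclusion read fraction follows the position-weighted mixture", {
  set.seed(42)
  spec <- locus_spec(true_psi = 0.5, depth = 300)
  loc <- simulate_locus(spec)
  L <- spec$read_length
  len_inc <- sum(c(150, 150, 120, 150, 150))
  len_skip <- len_inc - 120
  p_inc <- 0.5 * (len_inc - L + 1) /
    (0.5 * (len_inc - L + 1) + 0.5 * (len_skip - L + 1))
  n <- nrow(loc$reads)
  got <- mean(loc$reads$isoform == "inclusion")
  expect_lt(abs(got - p_inc), 3 * sqrt(p_inc * (1 - p_inc) / n))
})

test_that("isoform sampling is binomial at the mixture rate (chi-square, 50 replicates)", {
  set.seed(43)
  spec <- locus_spec(true_psi = 0.3, depth = 60)
  len_inc <- 720; len_skip <- 600; L <- 100
  p_inc <- 0.3 * (len_inc - L + 1) /
    (0.3 * (len_inc - L + 1) + 0.7 * (len_skip - L + 1))
  pass <- 0L
  for (i in 1:50) {
    loc <- simulate_locus(spec)
    k <- sum(loc$reads$isoform == "inclusion")
    n <- nrow(loc$reads)
    p <- suppressWarnings(chisq.test(c(k, n - k),
                                     p = c(p_inc, 1 - p_inc))$p.value)
    if (p >= 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 49L)
})

test_that("every simulated spliced read implies a planted intron exactly", {
  ds <- simulate_dataset(4, true_psi = c(0.2, 0.5, 0.8, 0.5), seed = 44,
                         out_dir = file.path(tempdir(), "imply"))
  al <- load_alignments(ds$files[["reads"]],
                        read_filter_config(min_junction_overhang = 1))
  key <- paste(ds$junctions$gstart, ds$junctions$gend)
  got <- paste(al$junctions$intron_start, al$junctions$intron_end)
  expect_true(all(got %in% key))
})

test_that("same seed gives byte-identical dataset files", {
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  simulate_dataset(3, true_psi = c(0.2, 0.5, 0.8), seed = 45, out_dir = d1)
  simulate_dataset(3, true_psi = c(0.2, 0.5, 0.8), seed = 45, out_dir = d2)
  for (f in c("genome.fa", "reads.sam", "truth.tsv", "junctions.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # and a different seed does not
  d3 <- file.path(tempdir(), "rep3")
  simulate_dataset(3, true_psi = c(0.2, 0.5, 0.8), seed = 46, out_dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "reads.sam"))),
                         unname(tools::md5sum(file.path(d3, "reads.sam")))))
})

test_that("read sequences match the genome over their aligned blocks", {
  ds <- simulate_dataset(2, true_psi = 0.5, seed = 47,
                         out_dir = file.path(tempdir(), "seqmatch"))
  gen <- Biostrings::readDNAStringSet(ds$files[["genome"]])[[1]]
  set.seed(1)
  for (i in sample(nrow(ds$reads), 25)) {
    r <- ds$reads[i, ]
    blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
      r$cigar, pos = r$pos + 1L)[[1]]
    want <- paste(vapply(seq_along(blocks), function(b)
      as.character(Biostrings::subseq(gen, IRanges::start(blocks)[b],
                                      IRanges::end(blocks)[b])),
      character(1)), collapse = "")
    expect_identical(r$seq, want)
  }
})

test_that("spacers contain no GT or AG dinucleotide", {
  set.seed(48)
  sp <- gess:::.spacer_seq(3000)
  expect_false(grepl("GT|AG", sp))
})

test_that("weak site planting degrades only the middle-flanking sites of low-psi loci", {
  ds <- simulate_dataset(6, true_psi = c(0.1, 0.9, 0.1, 0.9, 0.1, 0.9),
                         weak_low_psi_sites = TRUE, seed = 49)
  tr <- ds$truth
  lows <- tr$locus[tr$true_psi <= 0.3]
  sq <- ds$site_seqs
  # weak donors keep GT; weak acceptors keep AG
  i1a <- sq[sq$site == "i1_acceptor", ]   # upI_ss3
  i2d <- sq[sq$site == "i2_donor", ]      # dnI_ss5
  expect_true(all(substr(i2d$seq, 4, 5) == "GT"))
  expect_true(all(substr(i1a$seq, 19, 20) == "AG"))
  # outer event sites remain strong consensus-like: exact consensus match
  # rate must be clearly higher than for weak planted sites
  match_rate <- function(x, cons, drop) {
    mean(vapply(x, function(s) {
      b <- strsplit(s, "")[[1]]; cb <- strsplit(cons, "")[[1]]
      mean(b[-drop] == cb[-drop])
    }, numeric(1)))
  }
  weak_d <- i2d$seq[i2d$locus %in% lows]
  strong_d <- sq$seq[sq$site == "i1_donor" & sq$locus %in% lows]
  expect_gt(match_rate(strong_d, "CAGGTAAGT", 4:5),
            match_rate(weak_d, "CAGGTAAGT", 4:5))
})

test_that("a one-locus dataset embeds the single-locus structure at its offset", {
  set.seed(50)
  ds <- simulate_dataset(1, true_psi = 0.5, seed = 51, spacer = 1000L)
  tr <- ds$truth
  expect_identical(nrow(tr), 1L)
  # offset is one spacer: boundaries sit at locus coords + 1000
  expect_identical(tr$up_exon_start, 1000L + 450L)
  expect_identical(tr$mid_exon_start, 1000L + 900L)
  # 2 spacers + 4x150+120 exon bases + 4x300 intron bases
  expect_identical(nchar(ds$genome[[1]]), 2000L + 720L + 1200L)
})

test_that("impossible locus specifications fail before any output", {
  expect_error(locus_spec(intron_lengths = c(10, 300)))
  expect_error(locus_spec(true_psi = 1.5))
  expect_error(locus_spec(site_quality = c(a = "strong")))
})
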