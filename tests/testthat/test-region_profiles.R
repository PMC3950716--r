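mk_event <- function(mid_len = 120L, intron_len = 300L, strand = "+",
                     id = "E1") {
  b1 <- 500L; b2 <- b1 + intron_len; b3 <- b2 + mid_len
  b4 <- b3 + intron_len
  data.frame(event_id = id, chrom = "c1", strand = strand,
             up_exon_start = b1 - 150L, up_exon_end = b1,
             mid_exon_start = b2, mid_exon_end = b3,
             dn_exon_start = b4, dn_exon_end = b4 + 150L,
             upI_ss5 = if (strand == "+") b1 else b4,
             upI_ss3 = if (strand == "+") b2 else b3,
             dnI_ss5 = if (strand == "+") b3 else b2,
             dnI_ss3 = if (strand == "+") b4 else b1,
             stringsAsFactors = FALSE)
}

seg_key <- function(s) paste(s$site, s$side, sep = ":")

test_that("long features give all eight segments at full 50/100 extents", {
  s <- event_segments(mk_event())
  expect_identical(nrow(s), 8L)
  expect_setequal(seg_key(s), gess:::segment_levels())
  expect_identical(s$length[s$side == "exonic"], rep(50L, 4))
  expect_identical(s$length[s$side == "intronic"], rep(100L, 4))
  # exonic segments sit against their boundary
  expect_identical(s$end[seg_key(s) == "upI_ss5:exonic"], 500L)
  expect_identical(s$start[seg_key(s) == "upI_ss5:intronic"], 500L)
})

test_that("a short middle exon splits at the midpoint without overlap", {
  s <- event_segments(mk_event(mid_len = 60L))
  a <- s[seg_key(s) == "upI_ss3:exonic", ]
  b <- s[seg_key(s) == "dnI_ss5:exonic", ]
  expect_identical(a$length, 30L)
  expect_identical(b$length, 30L)
  expect_identical(a$end, b$start)
  expect_error(event_segments(mk_event(), exon_ext = 0), "exon_ext")
})

test_that("segments are pairwise disjoint and stay inside the padded span", {
  for (cse in list(mk_event(), mk_event(mid_len = 40L),
                   mk_event(intron_len = 120L),
                   mk_event(strand = "-"),
                   mk_event(mid_len = 30L, intron_len = 80L,
                            strand = "-"))) {
    s <- event_segments(cse)
    ir <- IRanges::IRanges(s$start + 1L, s$end)
    expect_true(all(IRanges::countOverlaps(ir, ir) == 1))
    lo <- min(cse$up_exon_start, cse$dn_exon_start) - 100L
    hi <- max(cse$up_exon_end, cse$dn_exon_end) + 100L
    expect_true(all(s$start >= lo & s$end <= hi))
  }
})

test_that("minus-strand segments mirror transcription orientation", {
  s <- event_segments(mk_event(strand = "-"))
  # upI_ss5 is the genomic right exon's start boundary; its exonic segment
  # extends genomically rightward (into the transcriptionally upstream exon)
  up5e <- s[seg_key(s) == "upI_ss5:exonic", ]
  expect_identical(up5e$start, 1220L)
  expect_identical(up5e$end, 1270L)
  up5i <- s[seg_key(s) == "upI_ss5:intronic", ]
  expect_identical(up5i$end, 1220L)
})

test_that("tag density equals brute-force interval overlap counting", {
  segs <- events_segments(mk_event())
  # formula: 10 reads fully inside a 100 bp segment, library 1e7 -> 0.1/bp
  tgt <- segs[seg_key(segs) == "upI_ss5:intronic", ]
  reads <- data.frame(chrom = "c1",
                      start = seq(tgt$start, tgt$start + 45, by = 5),
                      end = seq(tgt$start, tgt$start + 45, by = 5) + 30L)
  d <- tag_density(segs, reads, library_size = 1e7)
  expect_equal(d$density[seg_key(d) == "upI_ss5:intronic"], 0.1)
  # brute force: a read overlaps if >= 1 base intersects
  set.seed(13)
  rnd <- data.frame(chrom = "c1",
                    start = sample(200:1500, 300, replace = TRUE))
  rnd$end <- rnd$start + 36L
  d2 <- tag_density(segs, rnd, library_size = 5e6)
  brute <- vapply(seq_len(nrow(segs)), function(i) {
    sum(rnd$start < segs$end[i] & rnd$end > segs$start[i])
  }, numeric(1))
  expect_equal(d2$density, brute / segs$length * (1e7 / 5e6),
               tolerance = 1e-12)
  # a BED file on disk is equivalent interval input
  bed <- tempfile(fileext = ".bed")
  write.table(cbind(rnd, name = ".", score = 0L, strand = "."), bed,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  d2b <- tag_density(segs, bed, library_size = 5e6)
  expect_equal(d2b$density, d2$density, tolerance = 1e-12)
  # empty signal and signal == control
  expect_equal(tag_density(segs, rnd[0, ], 1e7)$density, rep(0, 8))
  dc <- tag_density(segs, rnd, 5e6,
                    control = list(intervals = rnd, library_size = 5e6))
  expect_equal(dc$density, rep(0, 8))
  expect_error(tag_density(segs, rnd, 0), "library_size")
})

test_that("z-score profiles standardize per group and Pearson r ranks similarity", {
  evs <- do.call(rbind, lapply(1:6, function(i) {
    e <- mk_event(id = sprintf("E%d", i))
    shift <- i * 2000L
    cc <- grep("exon_|ss", names(e))
    e[cc] <- e[cc] + shift
    e
  }))
  groups <- stats::setNames(rep(c("SIDG", "IIDG"), each = 3), evs$event_id)
  segs <- events_segments(evs)
  base <- c(5, 9, 2, 7, 4, 8, 1, 6)
  mkdens <- function(fac, flip) {
    d <- segs
    ord <- match(paste(d$site, d$side, sep = ":"), gess:::segment_levels())
    v <- base[ord]
    if (flip) v[d$event_id %in% names(groups)[groups == "IIDG"]] <-
        rev(base)[ord[d$event_id %in% names(groups)[groups == "IIDG"]]]
    d$density <- v
    d$factor <- fac
    d
  }
  dens <- rbind(mkdens("same", FALSE), mkdens("diff", TRUE))
  out <- zscore_heat(dens, groups)
  zz <- out$z
  for (fac in c("same", "diff")) for (g in c("SIDG", "IIDG")) {
    v <- zz$z[zz$factor == fac & zz$group == g]
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
  r_same <- out$r$r[out$r$factor == "same"]
  expect_equal(r_same, 1.0, tolerance = 1e-12)
  r_diff <- out$r$r[out$r$factor == "diff"]
  expect_lt(r_diff, r_same)
  # hand-check r with the closed-form correlation
  a <- zz$z[zz$factor == "diff" & zz$group == "SIDG"]
  b <- zz$z[zz$factor == "diff" & zz$group == "IIDG"]
  expect_equal(r_diff, sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
               tolerance = 1e-12)
  # ascending |r| ordering
  expect_identical(out$r$factor, c("diff", "same")[order(abs(c(r_diff, r_same)))])
  # zero variance flags the factor
  flat <- mkdens("flat", FALSE); flat$density <- 1
  out2 <- zscore_heat(flat, groups)
  expect_true(out2$r$flagged)
  expect_true(is.na(out2$r$r))
})

test_that("a perfectly anti-correlated profile gives r of minus one", {
  evs <- rbind(mk_event(id = "A"), {
    e <- mk_event(id = "B"); cc <- grep("exon_|ss", names(e))
    e[cc] <- e[cc] + 5000L; e
  })
  groups <- c(A = "SIDG", B = "IIDG")
  segs <- events_segments(evs)
  ord <- match(paste(segs$site, segs$side, sep = ":"),
               gess:::segment_levels())
  base <- c(5, 9, 2, 7, 4, 8, 1, 6)
  zbase <- (base - mean(base)) / sd(base)
  segs$density <- ifelse(segs$event_id == "A", base[ord], -zbase[ord])
  segs$factor <- "anti"
  out <- zscore_heat(segs, groups)
  expect_equal(out$r$r, -1, tolerance = 1e-12)
})

test_that("motif enrichment signs toward the enriched group and flags empty cells", {
  evs <- do.call(rbind, lapply(1:10, function(i) {
    e <- mk_event(id = sprintf("E%02d", i))
    cc <- grep("exon_|ss", names(e)); e[cc] <- e[cc] + i * 3000L; e
  }))
  groups <- stats::setNames(rep(c("SIDG", "IIDG"), each = 5), evs$event_id)
  segs <- events_segments(evs)
  hits <- segs[, c("event_id", "site", "side", "length")]
  hits$factor <- "SF1"
  # identical groups -> p = 1 -> heat 0
  hits$count <- 3L
  same <- motif_enrichment(hits, groups)
  expect_true(all(same$heat == 0))
  # SIDG uniformly higher in one segment, no ties -> positive heat there
  hits2 <- hits
  tgt <- hits2$site == "dnI_ss5" & hits2$side == "intronic"
  hits2$count[tgt] <- ifelse(groups[hits2$event_id[tgt]] == "SIDG",
                             10L + seq_len(sum(tgt)), seq_len(sum(tgt)))
  enr <- motif_enrichment(hits2, groups, bh = TRUE)
  cell <- enr[enr$segment == "dnI_ss5:intronic", ]
  expect_identical(cell$direction, 1L)
  expect_equal(cell$p_value, oracle_mw_p(c(1, 2, 3, 4, 5),
                                         c(11, 12, 13, 14, 15)),
               tolerance = 1e-12)
  expect_gt(cell$heat, 0)
  expect_true("q" %in% names(enr))
  # all-zero counts are flagged with zero heat
  hits3 <- hits; hits3$count <- 0L
  zero <- motif_enrichment(hits3, groups)
  expect_true(all(zero$flagged))
  expect_true(all(zero$heat == 0))
})
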