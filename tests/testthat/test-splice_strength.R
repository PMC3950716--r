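test_that("site sequences are definitional slices with canonical dinucleotides", {
  # build a genome where every base is unique enough to check slices
  set.seed(5)
  g <- c(c1 = paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                    collapse = ""))
  ev <- data.frame(event_id = "E1", chrom = "c1", strand = "+",
                   up_exon_start = 100L, up_exon_end = 200L,
                   mid_exon_start = 300L, mid_exon_end = 400L,
                   dn_exon_start = 500L, dn_exon_end = 600L,
                   upI_ss5 = 200L, upI_ss3 = 300L, dnI_ss5 = 400L,
                   dnI_ss3 = 500L, stringsAsFactors = FALSE)
  ss <- extract_site_sequences(ev, g)
  gs <- g[["c1"]]
  expect_identical(ss[["upI_ss5"]], substr(gs, 198, 206))  # [197,206) 0-based
  expect_identical(ss[["upI_ss3"]], substr(gs, 281, 303))
  expect_identical(ss[["dnI_ss5"]], substr(gs, 398, 406))
  expect_identical(ss[["dnI_ss3"]], substr(gs, 481, 503))
  expect_identical(nchar(ss), c(upI_ss5 = 9L, upI_ss3 = 23L,
                                dnI_ss5 = 9L, dnI_ss3 = 23L))
  # out of bounds is a coordinate error
  ev2 <- ev; ev2$upI_ss5 <- 2L
  expect_error(extract_site_sequences(ev2, g), "outside")
})

test_that("minus-strand extraction reverse-complements to reading orientation", {
  set.seed(6)
  ds <- simulate_dataset(2, true_psi = 0.5, seed = 61,
                         spec_template = locus_spec(strand = "-"),
                         out_dir = file.path(tempdir(), "minus_ss"))
  gn <- stats::setNames(as.character(
    Biostrings::readDNAStringSet(ds$files[["genome"]])), "synth1")
  al <- load_alignments(ds$files[["reads"]])
  g <- build_splice_graph(al$junctions, al$coverage, graph_config(), gn)
  ev <- scan_skipping_events(g)
  for (i in seq_len(nrow(ev))) {
    ss <- extract_site_sequences(ev[i, ], gn)
    expect_identical(substr(ss[c("upI_ss5", "dnI_ss5")], 4, 5),
                     c(upI_ss5 = "GT", dnI_ss5 = "GT"))
    expect_identical(substr(ss[c("upI_ss3", "dnI_ss3")], 19, 20),
                     c(upI_ss3 = "AG", dnI_ss3 = "AG"))
  }
  # double reverse complement is the identity
  s <- "CAGGTAAGT"
  expect_identical(gess:::revcomp(gess:::revcomp(s)), s)
})

test_that("order-1 maxent equals the positional-marginal product (PWM)", {
  set.seed(7)
  seqs <- replicate(200, paste(sample(c("A", "C", "G", "T"), 3,
                                      replace = TRUE, prob = c(4, 3, 2, 1)),
                               collapse = ""))
  m <- train_maxent(seqs, kind = "custom", constraint_order = 1)
  p <- model_distribution(m)
  sm <- do.call(rbind, strsplit(seqs, ""))
  marg <- lapply(1:3, function(i)
    table(factor(sm[, i], levels = c("A", "C", "G", "T"))) / length(seqs))
  pwm <- vapply(names(p), function(s) {
    b <- strsplit(s, "")[[1]]
    prod(vapply(1:3, function(i) marg[[i]][[b[i]]], numeric(1)))
  }, numeric(1))
  expect_equal(unname(p), unname(pwm), tolerance = 1e-12)
})

test_that("chain-fitted maxent matches brute-force convex solutions on toy spaces", {
  cases <- list(
    list(alpha = c("A", "C"), len = 3, n = 300, seed = 71),
    list(alpha = c("A", "C"), len = 4, n = 500, seed = 72),
    list(alpha = c("A", "C", "G", "T"), len = 3, n = 800, seed = 73))
  for (cs in cases) {
    set.seed(cs$seed)
    probs <- runif(length(cs$alpha))^2 + 0.2
    seqs <- replicate(cs$n, paste(sample(cs$alpha, cs$len, replace = TRUE,
                                         prob = probs), collapse = ""))
    # correlate adjacent positions so pairs carry information
    seqs <- vapply(seqs, function(s) {
      if (runif(1) < 0.5) substr(s, 2, 2) <- substr(s, 1, 1)
      s
    }, character(1), USE.NAMES = FALSE)
    m <- train_maxent(seqs, kind = "custom", alphabet = cs$alpha,
                      constraint_order = c(1, 2), tol = 1e-7)
    got <- model_distribution(m)
    want <- oracle_maxent(seqs, cs$alpha)
    expect_identical(names(got), names(want))
    tv <- 0.5 * sum(abs(got - want))
    expect_lt(tv, 1e-5)
  }
})

test_that("a uniform training set gives the uniform distribution", {
  space <- apply(expand.grid(c("A", "C"), c("A", "C"), c("A", "C")), 1,
                 paste, collapse = "")
  m <- train_maxent(rep(space, 10), kind = "custom", alphabet = c("A", "C"))
  p <- model_distribution(m)
  expect_equal(unname(p), rep(1 / 8, 8), tolerance = 1e-10)
})

test_that("scores are log2 odds against the decoy composition", {
  # signal: A and C equally likely; decoys: A three times as likely
  m <- suppressWarnings(
    train_maxent(c("A", "A", "C", "C"), decoy_seqs = c("A", "A", "A", "C"),
                 kind = "custom", alphabet = c("A", "C")))
  expect_equal(score_site(m, "C"), 1.0, tolerance = 1e-9)  # 0.5 / 0.25
  expect_equal(score_site(m, "A"), log2(0.5 / 0.75), tolerance = 1e-9)
  # signal == background: every score 0
  m0 <- suppressWarnings(
    train_maxent(c("A", "C", "A", "C"), decoy_seqs = c("A", "C"),
                 kind = "custom", alphabet = c("A", "C")))
  expect_equal(score_site(m0, c("A", "C")), c(0, 0), tolerance = 1e-9)
  expect_error(score_site(m0, "AC"), "length")
})

test_that("toy model scores equal hand-computed log2 ratios", {
  set.seed(8)
  seqs <- replicate(400, paste(sample(c("A", "C"), 3, replace = TRUE,
                                      prob = c(0.7, 0.3)), collapse = ""))
  decoys <- replicate(300, paste(sample(c("A", "C"), 3, replace = TRUE),
                                 collapse = ""))
  m <- train_maxent(seqs, decoys, kind = "custom", alphabet = c("A", "C"),
                    tol = 1e-8)
  p <- model_distribution(m)
  dm <- do.call(rbind, strsplit(decoys, ""))
  qa <- mean(dm == "A")
  for (s in names(p)) {
    nA <- lengths(regmatches(s, gregexpr("A", s)))
    want <- log2(p[[s]] / (qa^nA * (1 - qa)^(3 - nA)))
    expect_equal(score_site(m, s), want, tolerance = 1e-6)
  }
})

test_that("model serialization round-trips scores exactly", {
  set.seed(9)
  ds <- simulate_dataset(10, true_psi = 0.5, seed = 91)
  don <- ds$site_seqs$seq[grepl("donor", ds$site_seqs$site)]
  m <- suppressWarnings(train_maxent(don, kind = "donor5"))
  path <- tempfile()
  write_maxent_model(m, path)
  m2 <- read_maxent_model(path)
  probe <- c("CAGGTAAGT", "TTTGTTTTT", don[1:5])
  expect_equal(score_site(m2, probe), score_site(m, probe),
               tolerance = 1e-12)
})

test_that("competition score follows the pairing-priority sign convention", {
  s <- competition_score(c(upI_ss5 = 9, upI_ss3 = 5, dnI_ss5 = 5,
                           dnI_ss3 = 9))
  expect_identical(s$delta_ss5, 4)
  expect_identical(s$delta_ss3, 4)
  expect_identical(s$S, 8)
  eq <- competition_score(c(upI_ss5 = 3, upI_ss3 = 3, dnI_ss5 = 3,
                            dnI_ss3 = 3))
  expect_identical(eq$S, 0)
  # weakening a middle-flanking donor raises S one for one
  s2 <- competition_score(c(upI_ss5 = 9, upI_ss3 = 5, dnI_ss5 = 4,
                            dnI_ss3 = 9))
  expect_identical(s2$S, s$S + 1)
  # S is invariant to a constant shift of all four scores
  s3 <- competition_score(c(upI_ss5 = 14, upI_ss3 = 10, dnI_ss5 = 10,
                            dnI_ss3 = 14))
  expect_identical(s3$S, s$S)
})

test_that("Mann-Whitney is exact for small samples, including ties", {
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$p_value, 1)
  shifted <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(shifted$U, 0)
  expect_identical(shifted$p_value, 0.1)
  set.seed(10)
  for (i in 1:25) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    got <- mann_whitney(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, oracle_mw_p(x, y), tolerance = 1e-12)
  }
  # tie-free small samples: base wilcox.test is an independent cross-check
  for (i in 1:10) {
    x <- sample(seq(0, 1, by = 0.001), 6); y <- sample(seq(2, 3, by = 0.001), 7)
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, w$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal form", {
  set.seed(11)
  x <- rnorm(20); y <- rnorm(25, 0.7)
  got <- mann_whitney(x, y)
  expect_identical(got$method, "normal")
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, w$p.value, tolerance = 1e-10)
})

test_that("group strength comparison mirrors the four-sites-plus-S layout", {
  set.seed(12)
  mk <- function(shift) data.frame(upI_ss5 = rnorm(10, 8),
                                   upI_ss3 = rnorm(10, 8 - shift),
                                   dnI_ss5 = rnorm(10, 8 - shift),
                                   dnI_ss3 = rnorm(10, 8))
  out <- compare_site_strengths(mk(3), mk(0))
  expect_identical(out$site, c("upI_ss5", "upI_ss3", "dnI_ss5",
                               "dnI_ss3", "S"))
  expect_true(all(c("mean_sidg", "sd_sidg", "mean_iidg", "sd_iidg",
                    "p_value") %in% names(out)))
  expect_lt(out$mean_sidg[out$site == "dnI_ss5"],
            out$mean_iidg[out$site == "dnI_ss5"])
  expect_gt(out$mean_sidg[out$site == "S"], out$mean_iidg[out$site == "S"])
  expect_error(compare_site_strengths(mk(0)[0, ], mk(0)), "empty")
})
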