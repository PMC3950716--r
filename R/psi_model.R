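#' Count inclusion and exclusion junction reads for an event
#'
#' Inclusion reads are spliced reads supporting either flanking-intron
#' junction (upstream-exon to middle-exon, or middle-exon to
#' downstream-exon); exclusion reads support the skip junction joining the
#' outer exons. Only junction-spanning reads count; reads lying in the
#' middle-exon body do not enter the likelihood.
#'
#' @param ev One event row from [scan_skipping_events()].
#' @param junctions Junction data.frame from the same alignment set.
#' @return List with `inclusion_reads` and `exclusion_reads`.
#' @export
count_isoform_reads <- function(ev, junctions) {
  sup <- function(s, e) {
    hit <- junctions$chrom == ev$chrom & junctions$intron_start == s &
      junctions$intron_end == e
    if (!any(hit)) return(NA_integer_)
    sum(junctions$support[hit])
  }
  if (ev$strand == "-") {
    up <- sup(ev$mid_exon_end, ev$up_exon_start)
    dn <- sup(ev$dn_exon_end, ev$mid_exon_start)
    skp <- sup(ev$dn_exon_end, ev$up_exon_start)
  } else {
    up <- sup(ev$up_exon_end, ev$mid_exon_start)
    dn <- sup(ev$mid_exon_end, ev$dn_exon_start)
    skp <- sup(ev$up_exon_end, ev$dn_exon_start)
  }
  if (any(is.na(c(up, dn, skp)))) {
    warning("event ", ev$event_id %||% "?",
            ": junction(s) absent from junction set; counted as 0")
  }
  list(inclusion_reads = as.integer(sum(c(up, dn), na.rm = TRUE)),
       exclusion_reads = as.integer(sum(skp, na.rm = TRUE)))
}

#' Effective junction-spanning start positions per isoform
#'
#' Counts, by direct enumeration, the read start positions on each isoform
#' that yield a junction-spanning read with at least `overhang` aligned
#' bases on each side of a junction. On the inclusion isoform a read may
#' span the upstream-exon/middle junction, the middle/downstream junction,
#' or (for short middle exons) both at once; positions spanning both count
#' once. These counts rescale the two-isoform mixture: a longer inclusion
#' window generates junction reads at a higher rate per transcript.
#'
#' @param mid_len Middle (cassette) exon length in bases.
#' @param read_length Read length.
#' @param overhang Minimum anchor on each side of a junction; must satisfy
#'   `read_length > 2 * overhang`.
#' @param up_len,dn_len Flanking exon lengths (cap the enumeration; default
#'   effectively unbounded).
#' @return Named numeric vector `c(c_inclusion, c_skipping)`.
#' @export
effective_positions <- function(mid_len, read_length, overhang = 6L,
                                up_len = Inf, dn_len = Inf) {
  L <- as.integer(read_length); v <- as.integer(overhang)
  m <- as.integer(mid_len)
  if (L <= 2L * v)
    stop("configuration error: read_length must exceed 2*overhang")
  up_cap <- if (is.finite(up_len)) as.integer(up_len) else L
  dn_cap <- if (is.finite(dn_len)) as.integer(dn_len) else L
  vv <- max(v, 1L)   # spanning needs at least one base on each side
  # inclusion isoform coordinates: junction 1 at u, junction 2 at u + m
  u <- up_cap
  starts <- seq.int(0L, up_cap + m + dn_cap - L)
  starts <- starts[starts >= 0]
  span1 <- starts <= u - vv & starts + L >= u + vv
  span2 <- starts <= u + m - vv & starts + L >= u + m + vv
  c_inc <- sum(span1 | span2)
  # skipping isoform: single junction at u
  sk_starts <- seq.int(0L, up_cap + dn_cap - L)
  c_skip <- sum(sk_starts <= u - vv & sk_starts + L >= u + vv)
  if (c_skip <= 0 || c_inc <= 0)
    stop("configuration error: non-positive effective position count")
  c(c_inclusion = c_inc, c_skipping = c_skip)
}

#' Estimate the inclusion fraction psi for one event
#'
#' Two-isoform Bayesian model: if a fraction psi of transcripts carry the
#' middle exon, a junction-spanning read is inclusion-type with probability
#' \deqn{p(\psi) = \psi c_i / (\psi c_i + (1-\psi) c_s)}
#' where \eqn{c_i, c_s} are the effective junction-position counts of the
#' two isoforms (the length rescaling). The likelihood is binomial in the
#' inclusion-read count; the posterior over psi under a Beta prior is
#' integrated on a fine deterministic grid (trapezoid rule, default 16384
#' intervals). With equal rescaling constants the posterior is exactly
#' conjugate, `Beta(alpha + inc, beta + exc)`, which bounds the quadrature
#' error in tests.
#'
#' @param counts List or vector with `inclusion_reads`, `exclusion_reads`.
#' @param c_positions Vector `c(c_inclusion, c_skipping)`, both positive.
#' @param prior Beta prior parameters `c(alpha, beta)`; default uniform.
#' @param n_grid Number of grid intervals (>= 4096).
#' @param low_conf_min_reads Events with fewer total junction reads are
#'   flagged `low_confidence`. Default 10.
#' @return List of class `gess_psi`: `psi_mean`, `ci_low`, `ci_high`
#'   (central 95% credible bounds), the counts and constants, and
#'   `low_confidence`.
#' @export
estimate_psi <- function(counts, c_positions, prior = c(1, 1),
                         n_grid = 16384L, low_conf_min_reads = 10L) {
  inc <- as.numeric(counts[["inclusion_reads"]])
  exc <- as.numeric(counts[["exclusion_reads"]])
  ci <- as.numeric(c_positions[[1]]); cs <- as.numeric(c_positions[[2]])
  stopifnot(ci > 0, cs > 0, inc >= 0, exc >= 0, all(prior > 0),
            n_grid >= 4096)
  psi <- seq(0, 1, length.out = n_grid + 1L)
  p <- psi * ci / (psi * ci + (1 - psi) * cs)
  lp <- rep(0, length(psi))
  if (prior[1] != 1) lp <- lp + (prior[1] - 1) * log(psi)
  if (prior[2] != 1) lp <- lp + (prior[2] - 1) * log1p(-psi)
  if (inc > 0) lp <- lp + inc * log(p)
  if (exc > 0) lp <- lp + exc * log1p(-p)
  lp[!is.finite(lp)] <- -Inf
  w <- exp(lp - max(lp))
  h <- 1 / n_grid
  # trapezoid weights
  tw <- c(0.5, rep(1, n_grid - 1L), 0.5) * h
  z <- sum(w * tw)
  post_mean <- sum(w * tw * psi) / z
  # CDF at grid nodes by cumulative trapezoid, then interpolate quantiles
  inc_area <- (w[-1] + w[-length(w)]) / 2 * h
  cdf <- c(0, cumsum(inc_area)) / z
  qfun <- function(q) stats::approx(cdf, psi, xout = q, ties = "ordered")$y
  structure(list(psi_mean = post_mean,
                 ci_low = qfun(0.025), ci_high = qfun(0.975),
                 inclusion_reads = inc, exclusion_reads = exc,
                 c_inclusion = ci, c_skipping = cs,
                 low_confidence = (inc + exc) < low_conf_min_reads),
            class = "gess_psi")
}

#' Classify an event by its psi estimate
#'
#' Inclusive thresholds: psi >= `iidg` is inclusion-isoform-dominated
#' (IIDG), psi <= `sidg` is skipping-isoform-dominated (SIDG), anything
#' between is `"intermediate"`.
#'
#' @param psi_mean Posterior mean psi (or a vector of them).
#' @param iidg,sidg Group thresholds; defaults 0.7 and 0.3.
#' @return Character vector of group labels.
#' @export
classify_event <- function(psi_mean, iidg = 0.7, sidg = 0.3) {
  ifelse(psi_mean >= iidg, "IIDG",
         ifelse(psi_mean <= sidg, "SIDG", "intermediate"))
}

#' Estimate psi for every event in a table
#'
#' @param events Event data.frame from [scan_skipping_events()].
#' @param junctions Junction data.frame from [load_alignments()].
#' @param cfg A [run_config()] supplying read length, overhang, prior and
#'   group thresholds.
#' @return data.frame: one row per event with counts, rescaling constants,
#'   `psi_mean`, credible bounds, `group` and `low_confidence`.
#' @export
psi_events <- function(events, junctions, cfg = run_config()) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    cnt <- count_isoform_reads(ev, junctions)
    cp <- effective_positions(
      mid_len = ev$mid_exon_end - ev$mid_exon_start,
      read_length = cfg$read_length,
      overhang = cfg$read_filter$min_junction_overhang,
      up_len = abs(ev$up_exon_end - ev$up_exon_start),
      dn_len = abs(ev$dn_exon_end - ev$dn_exon_start))
    est <- estimate_psi(cnt, cp, prior = cfg$psi_prior)
    data.frame(event_id = ev$event_id, chrom = ev$chrom,
               strand = ev$strand,
               inclusion_reads = est$inclusion_reads,
               exclusion_reads = est$exclusion_reads,
               c_inclusion = est$c_inclusion, c_skipping = est$c_skipping,
               psi_mean = est$psi_mean, ci_low = est$ci_low,
               ci_high = est$ci_high,
               group = classify_event(est$psi_mean, cfg$iidg_threshold,
                                      cfg$sidg_threshold),
               low_confidence = est$low_confidence,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(event_id = character(), chrom = character(),
                      strand = character(), inclusion_reads = numeric(),
                      exclusion_reads = numeric(), c_inclusion = numeric(),
                      c_skipping = numeric(), psi_mean = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      group = character(), low_confidence = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
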