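# Independent oracles and tiny fixture builders. Everything here is
# deliberately written by the dumbest correct method available (per-base
# walks, exhaustive enumeration, generic convex optimization) and never
# calls the code paths it checks.

# ---- SAM fixture writer ----------------------------------------------

# records: data.frame qname, flag, chrom, pos1 (1-based), mapq, cigar, seq;
# optional column `tags` (e.g. "NH:i:2")
write_sam_fixture <- function(records, seqlens, path,
                              header = TRUE) {
  lines <- character(0)
  if (header) {
    lines <- c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens),
                       as.integer(seqlens)))
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ln <- paste(r$qname, r$flag, r$chrom, r$pos1, r$mapq, r$cigar,
                "*", 0, 0, r$seq, strrep("I", nchar(r$seq)), sep = "\t")
    if (!is.null(r$tags) && !is.na(r$tags) && nzchar(r$tags))
      ln <- paste(ln, r$tags, sep = "\t")
    lines <- c(lines, ln)
  }
  writeLines(lines, path)
  path
}

sam_record <- function(pos1, cigar, qname = "r1", flag = 0L,
                       chrom = "chr1", mapq = 50L, seq = NULL,
                       tags = "NH:i:1") {
  if (is.null(seq)) {
    # sequence length = query-consuming ops
    ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
    qlen <- sum(vapply(ops, function(o) {
      n <- as.integer(sub("[A-Z=]", "", o))
      if (grepl("[MIS=X]", o)) n else 0L
    }, integer(1)))
    seq <- strrep("A", qlen)
  }
  data.frame(qname = qname, flag = flag, chrom = chrom, pos1 = pos1,
             mapq = mapq, cigar = cigar, seq = seq, tags = tags,
             stringsAsFactors = FALSE)
}

# ---- brute-force per-base pileup -------------------------------------

# per-base depth over [1, len] (1-based) of the aligned spans of
# constitutive (N-free) records, walking each CIGAR one operator at a time
oracle_pileup_span <- function(records, len) {
  depth <- integer(len)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (grepl("N", r$cigar)) next
    ops <- regmatches(r$cigar, gregexpr("\\d+[MIDNSHP=X]", r$cigar))[[1]]
    p <- r$pos1
    for (o in ops) {
      n <- as.integer(sub("[A-Z=]", "", o))
      type <- sub("\\d+", "", o)
      if (type %in% c("M", "=", "X", "D")) {
        depth[p:(p + n - 1L)] <- depth[p:(p + n - 1L)] + 1L
        p <- p + n
      } else if (type == "N") p <- p + n
    }
  }
  depth
}

# ---- splice-graph fixtures -------------------------------------------

make_graph <- function(intron_edges, exon_edges, cfg = graph_config()) {
  ie <- if (nrow(intron_edges)) {
    data.frame(chrom = intron_edges$chrom,
               intron_start = intron_edges$intron_start,
               intron_end = intron_edges$intron_end,
               support = intron_edges$support %||% 10L,
               strand = intron_edges$strand %||% "+",
               canonical = TRUE, stringsAsFactors = FALSE)
  } else intron_edges
  ee <- if (nrow(exon_edges)) {
    data.frame(chrom = exon_edges$chrom, start = exon_edges$start,
               end = exon_edges$end, mean_depth = 30,
               flank_ratio = 10, strand = exon_edges$strand %||% "+",
               stringsAsFactors = FALSE)
  } else exon_edges
  structure(list(nodes = NULL, intron_edges = ie, exon_edges = ee,
                 config = cfg), class = "gess_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive C(n,6) sextet enumeration over the union of edge endpoint
# coordinates; checks the same pattern the scanner is defined by
oracle_scan <- function(g) {
  ie <- g$intron_edges; ee <- g$exon_edges
  out <- list()
  for (chr in unique(c(ie$chrom, ee$chrom))) {
    iec <- ie[ie$chrom == chr, , drop = FALSE]
    eec <- ee[ee$chrom == chr, , drop = FALSE]
    pos <- sort(unique(c(iec$intron_start, iec$intron_end,
                         eec$start, eec$end)))
    if (length(pos) < 6) next
    for (sx in utils::combn(pos, 6, simplify = FALSE)) {
      p <- sort(sx)
      has_ie <- function(a, b)
        which(iec$intron_start == a & iec$intron_end == b)
      has_ee <- function(a, b, strand_ok)
        any(eec$start == a & eec$end == b & strand_ok(eec$strand))
      i_up <- has_ie(p[2], p[3]); i_dn <- has_ie(p[4], p[5])
      i_sk <- has_ie(p[2], p[5])
      if (!length(i_up) || !length(i_dn) || !length(i_sk)) next
      strands <- c(iec$strand[i_sk], iec$strand[i_up], iec$strand[i_dn])
      known <- setdiff(strands, "unknown")
      if (length(unique(known)) > 1) next
      ev_strand <- if (length(known)) known[1] else "unknown"
      ok_strand <- function(s) s == "unknown" | s == ev_strand |
        ev_strand == "unknown"
      if (!has_ee(p[1], p[2], ok_strand)) next
      if (!has_ee(p[3], p[4], ok_strand)) next
      if (!has_ee(p[5], p[6], ok_strand)) next
      p <- as.integer(p)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, strand = ev_strand, g1 = p[1], g2 = p[2], g3 = p[3],
        g4 = p[4], g5 = p[5], g6 = p[6], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  res <- unique(do.call(rbind, out))
  res[order(res$chrom, res$g1, res$g3), , drop = FALSE]
}

# project scanner output onto genomic sextets for comparison
events_as_sextets <- function(ev) {
  if (!nrow(ev)) return(NULL)
  g <- t(apply(ev, 1, function(r) {
    sort(as.integer(r[c("up_exon_start", "up_exon_end", "mid_exon_start",
                        "mid_exon_end", "dn_exon_start", "dn_exon_end")]))
  }))
  res <- data.frame(chrom = ev$chrom, strand = ev$strand,
                    g1 = g[, 1], g2 = g[, 2], g3 = g[, 3], g4 = g[, 4],
                    g5 = g[, 5], g6 = g[, 6], stringsAsFactors = FALSE)
  res <- unique(res)
  res[order(res$chrom, res$g1, res$g3), , drop = FALSE]
}

random_graph <- function(seed, n_nodes = 12) {
  set.seed(seed)
  pos <- sort(sample(as.integer(seq(100L, 5000L, by = 50L)), n_nodes))
  ie <- NULL; ee <- NULL
  # candidate ordered pairs
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < 0.18)
        ie <- rbind(ie, data.frame(chrom = "c1", intron_start = pos[i],
                                   intron_end = pos[j],
                                   support = sample(8:40, 1),
                                   strand = sample(c("+", "-", "unknown"),
                                                   1, prob = c(.5, .2, .3)),
                                   canonical = TRUE))
      if ((j == i + 1 && runif(1) < 0.6) ||
          (j == i + 2 && runif(1) < 0.1))
        ee <- rbind(ee, data.frame(chrom = "c1", start = pos[i],
                                   end = pos[j], mean_depth = 30,
                                   flank_ratio = 10,
                                   strand = sample(c("+", "unknown"), 1)))
    }
  }
  if (is.null(ie)) ie <- data.frame(chrom = character(),
                                    intron_start = integer(),
                                    intron_end = integer(),
                                    support = integer(),
                                    strand = character(),
                                    canonical = logical())
  if (is.null(ee)) ee <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), mean_depth = numeric(),
                                    flank_ratio = numeric(),
                                    strand = character())
  structure(list(nodes = NULL, intron_edges = ie, exon_edges = ee,
                 config = graph_config()), class = "gess_graph")
}

# ---- Mann-Whitney full enumeration -----------------------------------

oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  us <- vapply(utils::combn(n1 + n2, n1, simplify = FALSE), function(ix)
    ustat(pooled[ix], pooled[-ix]), numeric(1))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# ---- maximum-entropy dual oracle -------------------------------------

# brute-force maxent over the fully enumerated sequence space: minimize
# the convex dual log Z(lambda) - lambda.b by BFGS; features are
# positional indicators (order 1) and adjacent-pair indicators (order 2)
oracle_maxent <- function(seqs, alphabet, constraint_order = c(1, 2)) {
  len <- nchar(seqs[1]); K <- length(alphabet)
  space <- do.call(expand.grid,
                   rep(list(alphabet), len))[, len:1, drop = FALSE]
  space <- apply(space, 1, paste, collapse = "")
  sm <- do.call(rbind, strsplit(seqs, ""))
  feats <- list()
  if (1 %in% constraint_order) {
    for (i in seq_len(len)) for (a in alphabet)
      feats[[length(feats) + 1L]] <- list(
        f = function(s, i, a) substr(s, i, i) == a, i = i, a = a, j = NA)
  }
  if (2 %in% constraint_order && len >= 2) {
    for (i in seq_len(len - 1)) for (a in alphabet) for (b in alphabet)
      feats[[length(feats) + 1L]] <- list(
        f = function(s, i, a, b) substr(s, i, i + 1) == paste0(a, b),
        i = i, a = a, j = b)
  }
  F <- vapply(feats, function(ft) {
    if (is.na(ft$j)) as.numeric(substr(space, ft$i, ft$i) == ft$a)
    else as.numeric(substr(space, ft$i, ft$i + 1) == paste0(ft$a, ft$j))
  }, numeric(length(space)))
  Femp <- vapply(feats, function(ft) {
    if (is.na(ft$j)) mean(sm[, ft$i] == ft$a)
    else mean(sm[, ft$i] == ft$a & sm[, ft$i + 1] == ft$j)
  }, numeric(1))
  obj <- function(l) {
    e <- F %*% l
    m <- max(e)
    log(sum(exp(e - m))) + m - sum(l * Femp)
  }
  grad <- function(l) {
    e <- as.numeric(F %*% l)
    p <- exp(e - max(e)); p <- p / sum(p)
    as.numeric(t(F) %*% p) - Femp
  }
  fit <- stats::optim(rep(0, length(feats)), obj, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  e <- as.numeric(F %*% fit$par)
  p <- exp(e - max(e)); p <- p / sum(p)
  stats::setNames(p, space)
}

# implementation's full signal distribution on a (small) toy space
model_distribution <- function(model) {
  K <- length(model$alphabet); len <- model$length
  space <- do.call(expand.grid,
                   rep(list(model$alphabet), len))[, len:1, drop = FALSE]
  space <- apply(space, 1, paste, collapse = "")
  lp <- gess:::.signal_logprob(model, space)
  stats::setNames(exp(lp), space)
}
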